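label	measure	point	ci_low	ci_high
Shi et al. (case-control)	OR	1.96	1.37	2.80
Shi et al. (cross-sectional)	OR	1.41	1.11	1.79
Han et al. (time-to-event)	HR	1.33	1.10	1.60
Lin et al. (matched cohort)	OR	1.67	1.30	2.17
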