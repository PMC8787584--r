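#' Accessor generics
#'
#' Accessors for the S4 containers used throughout the package:
#' [InstrumentSet-class], [MRResult-class], [InstrumentStrength-class],
#' [ScaledOR-class], [ObsEstimate-class] and [MRComparison-class].
#' Slot access by users is discouraged; use these instead.
#'
#' @param x An object of one of the classes above.
#' @return The corresponding component; see each class page for details.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("exposureData", function(x) standardGeneric("exposureData"))

#' @rdname accessors
#' @export
setGeneric("outcomeData", function(x) standardGeneric("outcomeData"))

#' @rdname accessors
#' @export
setGeneric("dropLog", function(x) standardGeneric("dropLog"))

#' @rdname accessors
#' @export
setGeneric("ivMetadata", function(x) standardGeneric("ivMetadata"))

#' @rdname accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))

#' @rdname accessors
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))

#' @rdname accessors
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))

#' @rdname accessors
#' @export
setGeneric("mrPval", function(x) standardGeneric("mrPval"))

#' @rdname accessors
#' @export
setGeneric("kUsed", function(x) standardGeneric("kUsed"))

#' @rdname accessors
#' @export
setGeneric("eggerIntercept", function(x) standardGeneric("eggerIntercept"))

#' @rdname accessors
#' @export
setGeneric("excludedSnps", function(x) standardGeneric("excludedSnps"))

#' @rdname accessors
#' @export
setGeneric("heterogeneity", function(x) standardGeneric("heterogeneity"))

#' @rdname accessors
#' @export
setGeneric("perSnpR2", function(x) standardGeneric("perSnpR2"))

#' @rdname accessors
#' @export
setGeneric("totalR2", function(x) standardGeneric("totalR2"))

#' @rdname accessors
#' @export
setGeneric("fStatistic", function(x) standardGeneric("fStatistic"))

#' @rdname accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))
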