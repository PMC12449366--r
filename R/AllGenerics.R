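#' Accessors for pleiodecomp classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `scenarioConfig()` returns the generating [ScenarioConfig] of a cohort,
#' `phenotypes()` the per-individual phenotype table, `dosages()` a genotype
#' dosage matrix (individuals x SNPs) for a chosen SNP set,
#' `vcEstimates()`/`samplingCov()` the variance-component estimates and
#' their sampling covariance, `omegaBlock()` a named sub-block of the
#' sampling covariance, `tauValue()`/`tauSE()`/`tauScale()` the causal
#' effect fields, and `correctedEstimates()`/`correctedSE()` the corrected
#' parameter table.
#'
#' @param x an object of the documented class.
#' @param ... passed to methods.
#' @return See the individual method descriptions.
#' @name pleiodecomp-accessors
#' @aliases scenarioConfig phenotypes dosages vcEstimates samplingCov
#'   omegaBlock tauValue tauSE tauScale correctedEstimates correctedSE
#'   isConverged
NULL

#' @rdname pleiodecomp-accessors
#' @export
setGeneric("scenarioConfig", function(x) standardGeneric("scenarioConfig"))

#' @rdname pleiodecomp-accessors
#' @export
setGeneric("phenotypes", function(x, ...) standardGeneric("phenotypes"))

#' @rdname pleiodecomp-accessors
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname pleiodecomp-accessors
#' @export
setGeneric("vcEstimates", function(x) standardGeneric("vcEstimates"))

#' @rdname pleiodecomp-accessors
#' @export
setGeneric("samplingCov", function(x) standardGeneric("samplingCov"))

#' @rdname pleiodecomp-accessors
#' @export
setGeneric("omegaBlock", function(x, which) standardGeneric("omegaBlock"))

#' @rdname pleiodecomp-accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname pleiodecomp-accessors
#' @export
setGeneric("tauValue", function(x) standardGeneric("tauValue"))

#' @rdname pleiodecomp-accessors
#' @export
setGeneric("tauSE", function(x) standardGeneric("tauSE"))

#' @rdname pleiodecomp-accessors
#' @export
setGeneric("tauScale", function(x) standardGeneric("tauScale"))

#' @rdname pleiodecomp-accessors
#' @export
setGeneric("correctedEstimates", function(x) standardGeneric("correctedEstimates"))

#' @rdname pleiodecomp-accessors
#' @export
setGeneric("correctedSE", function(x) standardGeneric("correctedSE"))
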