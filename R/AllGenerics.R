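#' @include AllClasses.R
NULL

#' Per-sample depth factors stored in an MpraExperiment
#'
#' @param x an [MpraExperiment-class].
#' @return Named numeric vector of depth factors (computed on demand with
#'   [computeDepthFactors()] if not stored).
#' @export
setGeneric("depthFactors", function(x) standardGeneric("depthFactors"))

#' @rdname depthFactors
#' @param value named numeric vector of positive depth factors.
#' @export
setGeneric("depthFactors<-",
           function(x, value) standardGeneric("depthFactors<-"))

#' @rdname MpraExperiment-class
#' @param x an [MpraExperiment-class].
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname MpraExperiment-class
#' @export
setGeneric("sampleType", function(x) standardGeneric("sampleType"))

#' Per-variant results table
#'
#' @param x an [MpraResults-class] object.
#' @return data.frame with columns `variant_id`, `ts_mean`, `hdi_lower`,
#'   `hdi_upper`, `score`, `functional_call`, `stage`, `rhat_max`, `ess_min`.
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))

#' @rdname VariantFit-class
#' @param x a [VariantFit-class] or [MpraResults-class].
#' @export
setGeneric("variantFits", function(x) standardGeneric("variantFits"))

setMethod("depthFactors", "MpraExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("depth_factor" %in% colnames(cd))
    setNames(cd$depth_factor, cd$sample_id)
  else computeDepthFactors(x)
})

setReplaceMethod("depthFactors", "MpraExperiment", function(x, value) {
  stopifnot(length(value) == ncol(x), all(value > 0))
  SummarizedExperiment::colData(x)$depth_factor <- as.numeric(value)
  x
})

setMethod("variantIds", "MpraExperiment", function(x)
  unique(SummarizedExperiment::rowData(x)$variant_id))

setMethod("sampleType", "MpraExperiment", function(x)
  setNames(SummarizedExperiment::colData(x)$sample_type,
           SummarizedExperiment::colData(x)$sample_id))

setMethod("show", "MpraExperiment", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  st <- SummarizedExperiment::colData(object)$sample_type
  cat(sprintf(
    "MpraExperiment: %d barcodes, %d variants, %d DNA + %d RNA samples\n",
    nrow(object), length(unique(rd$variant_id)),
    sum(st == "DNA"), sum(st == "RNA")))
})

setMethod("show", "GammaPrior", function(object) {
  cat(sprintf("GammaPrior(shape = %.4g, rate = %.4g) [mean %.4g]\n",
              object@shape, object@rate, object@shape / object@rate))
})

setMethod("show", "PriorSet", function(object) {
  cat(sprintf("PriorSet [%s]\n", object@provenance))
  for (nm in .PRIOR_FAMILIES) {
    p <- object@priors[[nm]]
    cat(sprintf("  %-10s Gamma(%.4g, %.4g)  mean %.4g\n",
                nm, p@shape, p@rate, p@shape / p@rate))
  }
})

setMethod("show", "VariantFit", function(object) {
  cat(sprintf(
    "VariantFit %s [%s]: TS mean %.3f, %s HDI (%.3f, %.3f), %s, score %.3f\n",
    object@variantId, object@stage, object@tsMean,
    "decision", object@hdi[1L], object@hdi[2L],
    if (object@functionalCall) "functional" else "non-functional",
    object@score))
})

setMethod("show", "MpraResults", function(object) {
  cat(sprintf(
    "MpraResults: %d variants (%d functional calls, %d failures)\n",
    nrow(object@table), sum(object@table$functional_call, na.rm = TRUE),
    length(object@failures)))
})

setMethod("resultsTable", "MpraResults", function(x) x@table)
setMethod("variantFits", "MpraResults", function(x) x@fits)
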