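#' @include mprabayes-package.R
NULL

#' MpraExperiment: barcode-level MPRA counts
#'
#' An extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' integer count matrix (`assay(x, "counts")`) with barcodes as rows and
#' sequencing samples as columns. Row metadata carries `variant_id`, `allele`
#' (`"ref"`/`"alt"`) and the `barcode` sequence; column metadata carries
#' `sample_id` and `sample_type` (`"DNA"`/`"RNA"`).
#'
#' Validity requires: all counts are non-negative integers; barcodes are
#' unique; at least one DNA and at least two RNA samples; and every variant
#' has at least one barcode for each allele.
#'
#' @seealso [MpraExperiment()] for the constructor, [readCountTable()].
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @import methods
#' @export
setClass("MpraExperiment", contains = "SummarizedExperiment")

.validMpraExperiment <- function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is missing")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (anyNA(cts) || any(cts < 0) || any(cts != floor(cts)))
    msg <- c(msg, "counts must be non-negative integers")
  rd <- SummarizedExperiment::rowData(object)
  for (f in c("variant_id", "allele", "barcode"))
    if (!f %in% colnames(rd)) msg <- c(msg, sprintf("rowData lacks '%s'", f))
  cd <- SummarizedExperiment::colData(object)
  for (f in c("sample_id", "sample_type"))
    if (!f %in% colnames(cd)) msg <- c(msg, sprintf("colData lacks '%s'", f))
  if (length(msg)) return(msg)
  if (!all(rd$allele %in% c("ref", "alt")))
    msg <- c(msg, "allele must be 'ref' or 'alt'")
  if (anyDuplicated(rd$barcode))
    msg <- c(msg, "barcode sequences must be unique")
  if (!all(cd$sample_type %in% c("DNA", "RNA")))
    msg <- c(msg, "sample_type must be 'DNA' or 'RNA'")
  if (sum(cd$sample_type == "DNA") < 1L)
    msg <- c(msg, "at least 1 DNA sample required")
  if (sum(cd$sample_type == "RNA") < 2L)
    msg <- c(msg, "at least 2 RNA samples required")
  tab <- table(rd$variant_id, rd$allele)
  if (nrow(tab) && any(tab == 0))
    msg <- c(msg, "every variant needs >= 1 barcode per allele")
  if (length(msg)) msg else TRUE
}
setValidity("MpraExperiment", .validMpraExperiment)

#' Construct an MpraExperiment
#'
#' @param counts integer matrix, barcodes x samples.
#' @param variant_id,allele,barcode per-row metadata vectors.
#' @param sample_id,sample_type per-column metadata vectors
#'   (`sample_type` in `"DNA"`/`"RNA"`).
#' @param drop_incomplete drop (with a warning) barcodes of variants missing
#'   one of the two alleles instead of failing validity.
#' @return A validated [MpraExperiment-class] object. The number of rows
#'   dropped by the allele-completeness rule is recorded in
#'   `metadata(x)$n_excluded_rows`.
#' @export
MpraExperiment <- function(counts, variant_id, allele, barcode,
                           sample_id = colnames(counts), sample_type,
                           drop_incomplete = TRUE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  allele <- as.character(allele)
  variant_id <- as.character(variant_id)
  n_excluded <- 0L
  if (drop_incomplete && nrow(counts)) {
    tab <- table(factor(variant_id), factor(allele, levels = c("ref", "alt")))
    bad <- rownames(tab)[apply(tab == 0, 1L, any)]
    if (length(bad)) {
      keep <- !(variant_id %in% bad)
      n_excluded <- sum(!keep)
      warning(sprintf(
        "dropping %d barcode row(s) of %d variant(s) lacking a ref or alt allele: %s",
        n_excluded, length(bad), paste(utils::head(bad, 5L), collapse = ", ")))
      counts <- counts[keep, , drop = FALSE]
      variant_id <- variant_id[keep]
      allele <- allele[keep]
      barcode <- barcode[keep]
    }
  }
  rownames(counts) <- barcode
  colnames(counts) <- sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(variant_id = variant_id, allele = allele,
                                   barcode = as.character(barcode)),
    colData = S4Vectors::DataFrame(sample_id = as.character(sample_id),
                                   sample_type = as.character(sample_type),
                                   row.names = sample_id))
  obj <- methods::new("MpraExperiment", se)
  S4Vectors::metadata(obj)$n_excluded_rows <- n_excluded
  obj
}

#' Gamma prior (shape/rate)
#'
#' @slot shape,rate strictly positive finite reals.
#' @export
setClass("GammaPrior", representation(shape = "numeric", rate = "numeric"))

setValidity("GammaPrior", function(object) {
  ok <- length(object@shape) == 1L && length(object@rate) == 1L &&
    is.finite(object@shape) && is.finite(object@rate) &&
    object@shape > 0 && object@rate > 0
  if (ok) TRUE else "shape and rate must be single positive finite numbers"
})

#' @rdname GammaPrior-class
#' @param shape,rate gamma parameters (rate, not scale).
#' @export
gammaPrior <- function(shape, rate) {
  methods::new("GammaPrior", shape = as.numeric(shape), rate = as.numeric(rate))
}

.PRIOR_FAMILIES <- c("mu_dna", "mu_rna_ref", "mu_rna_alt", "phi_dna", "phi_rna")

#' A full set of empirical gamma priors for one variant model
#'
#' Holds one [GammaPrior-class] per parameter family: `mu_dna` (per-barcode
#' plasmid input), `mu_rna_ref` / `mu_rna_alt` (allelic transcription-rate
#' multipliers), `phi_dna` and `phi_rna` (dispersions; the RNA dispersion
#' prior is shared between alleles). `provenance` records how it was
#' estimated (`"marginal"`, `"grouped:<label>"`, `"conditional:<variant>"`).
#'
#' @export
setClass("PriorSet",
         representation(priors = "list", provenance = "character"))

setValidity("PriorSet", function(object) {
  if (!identical(sort(names(object@priors)), sort(.PRIOR_FAMILIES)))
    return(sprintf("priors must be named exactly: %s",
                   paste(.PRIOR_FAMILIES, collapse = ", ")))
  if (!all(vapply(object@priors, methods::is, logical(1L), "GammaPrior")))
    return("all priors must be GammaPrior objects")
  TRUE
})

#' @rdname PriorSet-class
#' @param mu_dna,mu_rna_ref,mu_rna_alt,phi_dna,phi_rna [GammaPrior-class]
#'   objects.
#' @param provenance character tag.
#' @export
priorSet <- function(mu_dna, mu_rna_ref, mu_rna_alt, phi_dna, phi_rna,
                     provenance = "manual") {
  methods::new("PriorSet",
               priors = list(mu_dna = mu_dna, mu_rna_ref = mu_rna_ref,
                             mu_rna_alt = mu_rna_alt, phi_dna = phi_dna,
                             phi_rna = phi_rna),
               provenance = provenance)
}

#' Adaptive kernel configuration for the conditional prior
#'
#' @slot nTop rank used by the widening rule (default 100): the kernel scale
#'   is widened until the `nTop`-th largest weight reaches
#'   `weightFloorRatio` times the largest.
#' @slot weightFloorRatio ratio floor in (0,1), default 0.01.
#' @slot df degrees of freedom of the t kernel (default 3).
#' @export
setClass("KernelConfig",
         representation(nTop = "integer", weightFloorRatio = "numeric",
                        df = "numeric"),
         prototype(nTop = 100L, weightFloorRatio = 0.01, df = 3))

setValidity("KernelConfig", function(object) {
  msg <- character(0)
  if (object@nTop < 2L) msg <- c(msg, "nTop must be >= 2")
  if (object@weightFloorRatio <= 0 || object@weightFloorRatio >= 1)
    msg <- c(msg, "weightFloorRatio must be in (0,1)")
  if (object@df <= 0) msg <- c(msg, "df must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname KernelConfig-class
#' @param nTop,weightFloorRatio,df see slots.
#' @export
kernelConfig <- function(nTop = 100L, weightFloorRatio = 0.01, df = 3) {
  methods::new("KernelConfig", nTop = as.integer(nTop),
               weightFloorRatio = weightFloorRatio, df = df)
}

#' Posterior fitting configuration
#'
#' @slot hdiMass posterior mass of the decision HDI (default 0.95).
#' @slot screenMass mass of the fast-screen interval (default 0.80).
#' @slot chains,warmup,sampling MCMC geometry (defaults 4 / 200 / 500,
#'   i.e. 2000 retained draws).
#' @slot refineMargin refine when an HDI edge is within this fraction of the
#'   HDI width from zero (default 0.10).
#' @slot maxRefineFactor cap on the total chain-lengthening factor
#'   (default 25; refinement multiplies by 4 each round).
#' @slot rope optional length-2 region of practical equivalence around zero
#'   transcription shift; `numeric(0)` (the default) disables it.
#' @slot screen run the fast Laplace screen before MCMC (default TRUE).
#' @slot seed global seed; per-variant seeds are derived from it.
#' @slot sliceWidth,maxSteps slice-sampler stepping-out width (log scale) and
#'   maximum stepping-out count.
#' @export
setClass("FitConfig",
         representation(hdiMass = "numeric", screenMass = "numeric",
                        chains = "integer", warmup = "integer",
                        sampling = "integer", refineMargin = "numeric",
                        maxRefineFactor = "numeric", rope = "numeric",
                        screen = "logical", seed = "integer",
                        sliceWidth = "numeric", maxSteps = "integer"),
         prototype(hdiMass = 0.95, screenMass = 0.80, chains = 4L,
                   warmup = 200L, sampling = 500L, refineMargin = 0.10,
                   maxRefineFactor = 25, rope = numeric(0), screen = TRUE,
                   seed = 1L, sliceWidth = 1, maxSteps = 30L))

setValidity("FitConfig", function(object) {
  msg <- character(0)
  if (!(object@screenMass > 0 && object@screenMass < object@hdiMass &&
        object@hdiMass < 1))
    msg <- c(msg, "need 0 < screenMass < hdiMass < 1")
  if (object@chains < 2L) msg <- c(msg, "chains must be >= 2")
  if (!length(object@rope) %in% c(0L, 2L))
    msg <- c(msg, "rope must be empty (disabled) or length 2")
  if (length(msg)) msg else TRUE
})

#' @rdname FitConfig-class
#' @param hdiMass,screenMass,chains,warmup,sampling,refineMargin
#'   see slots.
#' @param maxRefineFactor,rope,screen,seed,sliceWidth,maxSteps see slots.
#' @export
fitConfig <- function(hdiMass = 0.95, screenMass = 0.80, chains = 4L,
                      warmup = 200L, sampling = 500L, refineMargin = 0.10,
                      maxRefineFactor = 25, rope = NULL, screen = TRUE,
                      seed = 1L, sliceWidth = 1, maxSteps = 30L) {
  methods::new("FitConfig", hdiMass = hdiMass, screenMass = screenMass,
               chains = as.integer(chains), warmup = as.integer(warmup),
               sampling = as.integer(sampling), refineMargin = refineMargin,
               maxRefineFactor = maxRefineFactor,
               rope = if (is.null(rope)) numeric(0) else as.numeric(rope),
               screen = screen, seed = as.integer(seed),
               sliceWidth = sliceWidth, maxSteps = as.integer(maxSteps))
}

#' Simulation configuration for synthetic MPRA assays
#'
#' Defaults reproduce the reference study conditions for a full-size assay:
#' 3000 variants, 5% truly functional, 10 barcodes per allele, 2 DNA and 5
#' RNA sequencing samples, log-normal depth variation (sd 0.3) and 5%
#' barcode dropout. Truth hyperparameters give mean DNA input ~ 50 counts
#' and dispersions ~ 10, so per-variant maximum likelihood estimates are
#' well identified. Functional effect sizes are +/-|N(0, 0.5^2)| truncated
#' away from zero at 0.1.
#'
#' @export
setClass("SimConfig",
         representation(nVariants = "integer", fracFunctional = "numeric",
                        barcodesPerAllele = "integer", nDnaSamples = "integer",
                        nRnaSamples = "integer", depthLogSd = "numeric",
                        meanDepthTotal = "numeric", dropout = "numeric",
                        muDnaShape = "numeric", muDnaRate = "numeric",
                        muAlleleShape = "numeric", muAlleleRate = "numeric",
                        phiDnaShape = "numeric", phiDnaRate = "numeric",
                        phiRnaShape = "numeric", phiRnaRate = "numeric",
                        tsSd = "numeric", tsMin = "numeric", seed = "integer"),
         prototype(nVariants = 3000L, fracFunctional = 0.05,
                   barcodesPerAllele = 10L, nDnaSamples = 2L,
                   nRnaSamples = 5L, depthLogSd = 0.3,
                   meanDepthTotal = NA_real_, dropout = 0.05,
                   muDnaShape = 4, muDnaRate = 0.08,
                   muAlleleShape = 4, muAlleleRate = 4,
                   phiDnaShape = 15, phiDnaRate = 1.5,
                   phiRnaShape = 15, phiRnaRate = 1.5,
                   tsSd = 0.5, tsMin = 0.1, seed = 1L))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nVariants < 1L) msg <- c(msg, "nVariants must be >= 1")
  if (object@fracFunctional < 0 || object@fracFunctional > 1)
    msg <- c(msg, "fracFunctional must be in [0,1]")
  if (object@dropout < 0 || object@dropout > 1)
    msg <- c(msg, "dropout must be in [0,1]")
  pos <- c(object@depthLogSd, object@muDnaShape, object@muDnaRate,
           object@muAlleleShape, object@muAlleleRate, object@phiDnaShape,
           object@phiDnaRate, object@phiRnaShape, object@phiRnaRate,
           object@tsSd)
  if (any(pos <= 0)) msg <- c(msg, "scale/shape parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param nVariants,fracFunctional,barcodesPerAllele assay geometry.
#' @param nDnaSamples,nRnaSamples sequencing samples per type.
#' @param depthLogSd log-normal sd of per-sample depth factors.
#' @param meanDepthTotal optional target mean column total; `NA` leaves
#'   totals implied by the DNA-input hyperparameters.
#' @param dropout per-barcode library-prep failure probability.
#' @param muDnaShape,muDnaRate,muAlleleShape,muAlleleRate gamma truth
#'   hyperparameters for DNA input and baseline allelic rate.
#' @param phiDnaShape,phiDnaRate,phiRnaShape,phiRnaRate dispersion truth
#'   hyperparameters.
#' @param tsSd,tsMin functional effect scale and truncation.
#' @param seed RNG seed used by [simulateAssay()].
#' @export
simConfig <- function(nVariants = 3000L, fracFunctional = 0.05,
                      barcodesPerAllele = 10L, nDnaSamples = 2L,
                      nRnaSamples = 5L, depthLogSd = 0.3,
                      meanDepthTotal = NA_real_, dropout = 0.05,
                      muDnaShape = 4, muDnaRate = 0.08,
                      muAlleleShape = 4, muAlleleRate = 4,
                      phiDnaShape = 15, phiDnaRate = 1.5,
                      phiRnaShape = 15, phiRnaRate = 1.5,
                      tsSd = 0.5, tsMin = 0.1, seed = 1L) {
  methods::new("SimConfig", nVariants = as.integer(nVariants),
               fracFunctional = fracFunctional,
               barcodesPerAllele = as.integer(barcodesPerAllele),
               nDnaSamples = as.integer(nDnaSamples),
               nRnaSamples = as.integer(nRnaSamples),
               depthLogSd = depthLogSd, meanDepthTotal = meanDepthTotal,
               dropout = dropout, muDnaShape = muDnaShape,
               muDnaRate = muDnaRate, muAlleleShape = muAlleleShape,
               muAlleleRate = muAlleleRate, phiDnaShape = phiDnaShape,
               phiDnaRate = phiDnaRate, phiRnaShape = phiRnaShape,
               phiRnaRate = phiRnaRate, tsSd = tsSd, tsMin = tsMin,
               seed = as.integer(seed))
}

#' Ground truth of a simulated assay
#'
#' @slot variants data.frame: `variant_id`, `true_ts`, `functional`,
#'   dispersion truths.
#' @slot barcodes data.frame: per-barcode `mu_dna` truth and dropout flag.
#' @slot samples data.frame: `sample_id`, `sample_type`, realized
#'   `depth_factor`.
#' @slot seed the seed the assay was generated with.
#' @export
setClass("SimTruth",
         representation(variants = "data.frame", barcodes = "data.frame",
                        samples = "data.frame", seed = "integer"))

setValidity("SimTruth", function(object) {
  v <- object@variants
  if (!all(c("variant_id", "true_ts", "functional") %in% colnames(v)))
    return("variants needs variant_id, true_ts, functional")
  if (!isTRUE(all.equal(v$functional, v$true_ts != 0)))
    return("functional flag must match true_ts != 0")
  TRUE
})

#' Posterior fit of a single variant
#'
#' @slot variantId variant identifier.
#' @slot draws matrix of posterior draws (rows = samples) over the
#'   log-scale model parameters; empty for screen-only fits.
#' @slot tsDraws transcription-shift draws, `log(mu_alt) - log(mu_ref)`.
#' @slot tsMean posterior mean TS.
#' @slot hdi length-2 highest-density interval at the configured mass.
#' @slot functionalCall HDI (or ROPE) decision.
#' @slot score pseudo-significance in \[0,1\]; lower = stronger evidence.
#' @slot diagnostics list with `rhat` (per parameter), `rhat_max`,
#'   `ess_min` (TS and allelic components), `n_draws`.
#' @slot stage one of `"screen_only"`, `"mcmc"`, `"mcmc_refined"`.
#' @export
setClass("VariantFit",
         representation(variantId = "character", draws = "matrix",
                        tsDraws = "numeric", tsMean = "numeric",
                        hdi = "numeric", functionalCall = "logical",
                        score = "numeric", diagnostics = "list",
                        stage = "character"))

setValidity("VariantFit", function(object) {
  msg <- character(0)
  if (length(object@hdi) != 2L || object@hdi[1L] >= object@hdi[2L])
    msg <- c(msg, "hdi must be (lower, upper) with lower < upper")
  if (object@score < 0 || object@score > 1)
    msg <- c(msg, "score must be in [0,1]")
  if (!object@stage %in% c("screen_only", "mcmc", "mcmc_refined"))
    msg <- c(msg, "invalid stage")
  if (length(msg)) msg else TRUE
})

#' Assay-level results container
#'
#' @slot table per-variant results data.frame (see [resultsTable()]).
#' @slot fits named list of [VariantFit-class] objects.
#' @slot priors the prior specification used (a [PriorSet-class], a list of
#'   them, or a label).
#' @slot config the [FitConfig-class] used.
#' @slot failures named character vector of per-variant error messages.
#' @export
setClass("MpraResults",
         representation(table = "data.frame", fits = "list", priors = "ANY",
                        config = "FitConfig", failures = "character"))
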