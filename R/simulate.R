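#' Simulate an MPRA assay with known ground truth
#'
#' Draws per-barcode DNA inputs, baseline allelic rates and dispersions from
#' the gamma truth hyperparameters of `cfg`; functional variants (a
#' `fracFunctional` share) get `mu_alt = mu_ref * exp(TS)` with TS drawn as
#' a Rademacher sign times `|N(0, tsSd^2)|` truncated below at `tsMin`;
#' non-functional variants have TS = 0. Per-sample depth factors are
#' log-normal; dropped-out barcodes (per-barcode Bernoulli, library-prep
#' failure) are removed from the table entirely. All counts are drawn from
#' the negative-binomial observation model.
#'
#' @param cfg a [SimConfig-class].
#' @return list with `mpra` (an [MpraExperiment-class]) and `truth`
#'   (a [SimTruth-class]).
#' @export
simulateAssay <- function(cfg = simConfig()) {
  set.seed(cfg@seed)
  nV <- cfg@nVariants
  bpa <- cfg@barcodesPerAllele
  vids <- sprintf("var_%04d", seq_len(nV))

  nFun <- round(cfg@fracFunctional * nV)
  functional <- rep(FALSE, nV)
  if (nFun > 0) functional[sample.int(nV, nFun)] <- TRUE
  ts <- numeric(nV)
  if (nFun > 0) {
    mag <- pmax(abs(rnorm(nFun, 0, cfg@tsSd)), cfg@tsMin)
    ts[functional] <- mag * sample(c(-1, 1), nFun, replace = TRUE)
  }
  muRef <- rgamma(nV, cfg@muAlleleShape, cfg@muAlleleRate)
  muAlt <- muRef * exp(ts)
  phiDna <- rgamma(nV, cfg@phiDnaShape, cfg@phiDnaRate)
  phiRnaRef <- rgamma(nV, cfg@phiRnaShape, cfg@phiRnaRate)
  phiRnaAlt <- rgamma(nV, cfg@phiRnaShape, cfg@phiRnaRate)

  nBc <- nV * 2L * bpa
  bcVariant <- rep(vids, each = 2L * bpa)
  bcAllele <- rep(rep(c("ref", "alt"), each = bpa), nV)
  bcSeq <- randomBarcodes(nBc, width = 14L)
  muDna <- rgamma(nBc, cfg@muDnaShape, cfg@muDnaRate)
  dropped <- runif(nBc) < cfg@dropout
  if (all(dropped)) stop("dropout removed every barcode; empty assay")

  sid <- c(sprintf("DNA_%d", seq_len(cfg@nDnaSamples)),
           sprintf("RNA_%d", seq_len(cfg@nRnaSamples)))
  sty <- rep(c("DNA", "RNA"), c(cfg@nDnaSamples, cfg@nRnaSamples))
  d <- exp(rnorm(length(sid), 0, cfg@depthLogSd))
  # depth factors are identifiable only up to a per-type scale; state the
  # truth in the model's convention (geometric mean 1 within each type)
  for (ty in c("DNA", "RNA")) {
    i <- sty == ty
    d[i] <- d[i] / geometricMean(d[i])
  }
  if (!is.na(cfg@meanDepthTotal)) {
    implied <- mean(muDna[!dropped]) * sum(!dropped)
    d <- d * cfg@meanDepthTotal / implied
  }

  keep <- which(!dropped)
  vIdx <- match(bcVariant, vids)
  muAlleleBc <- ifelse(bcAllele == "ref", muRef[vIdx], muAlt[vIdx])
  phiRnaBc <- ifelse(bcAllele == "ref", phiRnaRef[vIdx], phiRnaAlt[vIdx])
  counts <- matrix(0, length(keep), length(sid),
                   dimnames = list(NULL, sid))
  for (s in seq_along(sid)) {
    mu <- if (sty[s] == "DNA") d[s] * muDna[keep]
          else d[s] * muDna[keep] * muAlleleBc[keep]
    phi <- if (sty[s] == "DNA") phiDna[vIdx[keep]] else phiRnaBc[keep]
    counts[, s] <- rnbinom(length(keep), size = phi, mu = mu)
  }
  if (mean(counts) < 0.1)
    warning("expected counts below 0.1; the assay is mostly zeros")

  mpra <- suppressWarnings(MpraExperiment(
    counts, variant_id = bcVariant[keep], allele = bcAllele[keep],
    barcode = bcSeq[keep], sample_id = sid, sample_type = sty))

  truth <- methods::new(
    "SimTruth",
    variants = data.frame(variant_id = vids, true_ts = ts,
                          functional = functional, mu_ref = muRef,
                          mu_alt = muAlt, phi_dna = phiDna,
                          phi_rna_ref = phiRnaRef, phi_rna_alt = phiRnaAlt),
    barcodes = data.frame(variant_id = bcVariant, allele = bcAllele,
                          barcode = bcSeq, mu_dna = muDna,
                          dropped = dropped),
    samples = data.frame(sample_id = sid, sample_type = sty,
                         depth_factor = d),
    seed = cfg@seed)
  list(mpra = mpra, truth = truth)
}

randomBarcodes <- function(n, width = 14L) {
  repeat {
    bc <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = ""), character(1L))
    if (!anyDuplicated(bc)) return(bc)
  }
}

#' Deterministic grid of simulation configurations
#'
#' Cartesian product over the supplied parameter vectors, each cell paired
#' with a seed derived deterministically from `baseSeed` and the cell's
#' parameter values.
#'
#' @param nVariants,fracFunctional,barcodesPerAllele parameter vectors.
#' @param baseSeed integer base seed.
#' @param ... fixed arguments forwarded to [simConfig()].
#' @return list of [SimConfig-class] objects (one per grid cell).
#' @export
simulationGrid <- function(nVariants = 3000L, fracFunctional = 0.05,
                           barcodesPerAllele = 10L, baseSeed = 1L, ...) {
  grid <- expand.grid(nVariants = nVariants,
                      fracFunctional = fracFunctional,
                      barcodesPerAllele = barcodesPerAllele)
  if (!nrow(grid)) stop("empty simulation grid")
  lapply(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    simConfig(nVariants = cell$nVariants,
              fracFunctional = cell$fracFunctional,
              barcodesPerAllele = cell$barcodesPerAllele,
              seed = stableSeed(baseSeed,
                                paste(cell, collapse = "_")), ...)
  })
}

#' Write the ground truth of a simulated assay
#'
#' @param truth a [SimTruth-class].
#' @param path output TSV path (columns `variant_id`, `true_ts`,
#'   `functional`).
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
  write.table(truth@variants[, c("variant_id", "true_ts", "functional")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
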