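# Method-of-moments initialization on the log scale. Dispersion starts come
# from the excess of squared residuals over the Poisson variance, pooled
# across cells (fallback 10 when the excess is non-positive).
mleInit <- function(data) {
  dnaAdj <- sweep(data$dna, 2L, data$dDna, "/")
  muDna <- pmax(rowMeans(dnaAdj), 0.5)
  momPhi <- function(x, mu) {
    excess <- sum((x - mu)^2) - sum(mu)
    if (!is.finite(excess) || excess <= 0) return(10)
    min(max(sum(mu^2) / excess, 0.1), 1e4)
  }
  muA <- c(1, 1)
  phiR <- c(10, 10)
  if (ncol(data$rna)) {
    rnaAdj <- sweep(data$rna, 2L, data$dRna, "/")
    for (a in 0:1) {
      i <- data$allele == a
      if (!any(i)) next
      muA[a + 1L] <- max(mean(rnaAdj[i, , drop = FALSE]) / mean(muDna[i]),
                         1e-3)
    }
    phiR <- vapply(0:1, function(a) {
      i <- data$allele == a
      if (!any(i)) return(10)
      momPhi(data$rna[i, , drop = FALSE],
             outer(muDna[i] * muA[a + 1L], data$dRna))
    }, numeric(1L))
  }
  phiD <- momPhi(data$dna, outer(muDna, data$dDna))
  log(c(muDna, muA, phiD, phiR))
}

.THETA_BOUND <- 12  # |log parameter| beyond this is treated as a boundary fit

#' Maximum-likelihood fit of one variant's NB model
#'
#' Maximizes [variantLogLikelihood()] over all parameters on the
#' unconstrained log scale with analytic gradients (BFGS), using a
#' method-of-moments start plus `nStarts - 1` jittered restarts. Fits that
#' land on the parameter bounds are flagged (`boundary = TRUE`); such
#' variants are excluded from prior estimation but still receive posterior
#' fits.
#'
#' @param data one variant's data (see [variantLogLikelihood()]).
#' @param nStarts number of optimizer starts (default 3).
#' @return list with `params` (natural scale), `theta` (log scale),
#'   `logLik`, `converged`, `boundary`.
#' @export
fitVariantMle <- function(data, nStarts = 3L) {
  obj <- cachedObjective(data, pv = NULL)
  th0 <- mleInit(data)
  best <- NULL
  for (s in seq_len(nStarts)) {
    start <- if (s == 1L) th0 else th0 + rnorm(length(th0), sd = 0.3)
    fit <- tryCatch(
      optim(start, obj$fn, obj$gr, method = "BFGS",
            control = list(maxit = 500L, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(list(params = NULL, theta = th0, logLik = -Inf,
                converged = FALSE, boundary = TRUE))
  th <- pmin(pmax(best$par, -.THETA_BOUND), .THETA_BOUND)
  B <- nrow(data$dna)
  # lower bound: no natural-scale parameter near zero is interpretable;
  # upper: dispersions drifting towards +Inf (underdispersed cells) are
  # boundary fits even when the optimizer halts short of the hard clamp
  boundary <- any(best$par >= .THETA_BOUND) || any(best$par <= -9) ||
    any(best$par[(B + 3L):(B + 5L)] >= 9)
  # an allele whose RNA counts are all zero has its exact MLE on the
  # mu_allele = 0 boundary; pin it there explicitly
  if (ncol(data$rna)) {
    for (a in 0:1) {
      i <- data$allele == a
      if (any(i) && all(data$rna[i, ] == 0)) {
        th[B + 1L + a] <- -.THETA_BOUND
        boundary <- TRUE
      }
    }
  }
  list(params = thetaToParams(th, B),
       theta = th,
       logLik = -best$value,
       converged = best$convergence == 0L,
       boundary = boundary)
}

#' Fit per-variant MLEs across a whole assay
#'
#' @param x an [MpraExperiment-class].
#' @param depths optional depth factors (default [computeDepthFactors()]).
#' @param nStarts optimizer starts per variant.
#' @return list with `variants` (one row per variant: allelic rates,
#'   dispersions, `ts` = log(mu_alt/mu_ref), convergence flags) and
#'   `mu_dna` (one row per barcode).
#' @export
fitAllMle <- function(x, depths = NULL, nStarts = 3L) {
  if (is.null(depths)) depths <- computeDepthFactors(x)
  vdl <- allVariantData(x, depths)
  vids <- vapply(vdl, `[[`, character(1L), "variant_id")
  rows <- vector("list", length(vids))
  bcrows <- vector("list", length(vids))
  for (k in seq_along(vids)) {
    vd <- vdl[[k]]
    fit <- fitVariantMle(vd, nStarts = nStarts)
    p <- fit$params
    if (is.null(p)) {
      rows[[k]] <- data.frame(variant_id = vids[k], mu_ref = NA, mu_alt = NA,
                              phi_dna = NA, phi_rna_ref = NA,
                              phi_rna_alt = NA, ts = NA, logLik = -Inf,
                              converged = FALSE, boundary = TRUE)
      next
    }
    rows[[k]] <- data.frame(
      variant_id = vids[k],
      mu_ref = p$mu_allele[["ref"]], mu_alt = p$mu_allele[["alt"]],
      phi_dna = p$phi_dna,
      phi_rna_ref = p$phi_allele[["ref"]], phi_rna_alt = p$phi_allele[["alt"]],
      ts = log(p$mu_allele[["alt"]]) - log(p$mu_allele[["ref"]]),
      logLik = fit$logLik, converged = fit$converged,
      boundary = fit$boundary)
    bcrows[[k]] <- data.frame(variant_id = vids[k], barcode = vd$barcode,
                              mu_dna = p$mu_dna,
                              converged = fit$converged,
                              boundary = fit$boundary)
  }
  list(variants = do.call(rbind, rows),
       mu_dna = do.call(rbind, bcrows))
}
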