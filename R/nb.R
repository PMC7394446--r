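#' Negative binomial log-pmf in mean-dispersion form
#'
#' Parameterized so that `E[X] = mean` and
#' `Var[X] = mean + mean^2 / dispersion`: larger dispersion means closer to
#' Poisson. (This is `dnbinom(size = dispersion, mu = mean)`; conventions
#' for "dispersion" differ between packages, so the variance identity is
#' the contract.)
#'
#' @param x non-negative integer count(s).
#' @param mean positive NB mean.
#' @param dispersion positive NB dispersion.
#' @return log probability mass.
#' @export
nbLogPmf <- function(x, mean, dispersion) {
  if (any(mean <= 0) || any(dispersion <= 0))
    stop("mean and dispersion must be positive")
  if (any(x < 0) || any(x != floor(x)))
    stop("x must be non-negative integers")
  dnbinom(x, size = dispersion, mu = mean, log = TRUE)
}

# Named-list parameter bundle <-> flat log-scale vector
paramsToTheta <- function(params) {
  log(c(params$mu_dna, params$mu_allele[1L], params$mu_allele[2L],
        params$phi_dna, params$phi_allele[1L], params$phi_allele[2L]))
}

thetaToParams <- function(theta, B) {
  list(mu_dna = exp(theta[seq_len(B)]),
       mu_allele = c(ref = exp(theta[B + 1L]), alt = exp(theta[B + 2L])),
       phi_dna = exp(theta[B + 3L]),
       phi_allele = c(ref = exp(theta[B + 4L]), alt = exp(theta[B + 5L])))
}

#' Joint log-likelihood of one variant's counts
#'
#' Sums NB log-pmfs over all cells: DNA count of barcode bc in sample s has
#' mean `d_s * mu_dna[bc]` and dispersion `phi_dna`; an RNA count has mean
#' `d_s * mu_dna[bc] * mu_allele[allele(bc)]` and dispersion
#' `phi_allele[allele(bc)]`.
#'
#' @param params list with `mu_dna` (length = barcodes), `mu_allele`
#'   (ref, alt), `phi_dna`, `phi_allele` (ref, alt); all strictly positive.
#' @param data one variant's data as produced internally from an
#'   [MpraExperiment-class] (elements `dna`, `rna`, `dDna`, `dRna`,
#'   `allele`).
#' @return Scalar log-likelihood.
#' @export
variantLogLikelihood <- function(params, data) {
  B <- nrow(data$dna)
  if (length(params$mu_dna) != B)
    stop("mu_dna length must equal the variant's barcode count")
  stopifnot(length(params$mu_allele) == 2L, length(params$phi_allele) == 2L)
  if (any(unlist(params) <= 0)) stop("all parameters must be positive")
  ll_variant_cpp(paramsToTheta(params), data$dna, data$rna,
                 data$dDna, data$dRna, as.integer(data$allele))
}
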