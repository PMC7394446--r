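geometricMean <- function(x) exp(mean(log(x)))

#' Derive a reproducible per-variant seed
#'
#' Combines a global seed with a variant identifier by a polynomial string
#' hash modulo 2^31 - 1, so per-variant RNG streams do not depend on the
#' order in which variants are fitted or on the number of workers.
#'
#' @param seed integer global seed.
#' @param id character identifier.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
stableSeed <- function(seed, id) {
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(as.character(id))) h <- (h * 131 + k) %% m
  as.integer(h %% (m - 1L) + 1)
}

# split-Rhat (Gelman et al.); draws: iterations x chains
splitRhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  x <- cbind(draws[seq_len(half), , drop = FALSE],
             draws[seq.int(n - half + 1L, n), , drop = FALSE])
  m <- ncol(x); nn <- nrow(x)
  mu <- colMeans(x)
  s2 <- apply(x, 2L, var)
  W <- mean(s2)
  B <- nn * var(mu)
  if (W <= .Machine$double.eps) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# effective sample size from chain-averaged autocorrelations
essBasic <- function(draws) {
  n <- nrow(draws); m <- ncol(draws)
  if (var(as.vector(draws)) <= .Machine$double.eps) return(n * m)
  maxLag <- min(n - 1L, 100L)
  rho <- rowMeans(vapply(seq_len(m), function(j) {
    v <- var(draws[, j])
    if (v <= .Machine$double.eps) return(rep(0, maxLag))
    drop(acf(draws[, j], lag.max = maxLag, plot = FALSE,
             demean = TRUE)$acf)[-1L]
  }, numeric(maxLag)))
  # truncate at first negative paired sum (Geyer initial positive sequence)
  tau <- 1
  for (k in seq(1L, maxLag - 1L, by = 2L)) {
    pair <- rho[k] + rho[k + 1L]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
  }
  max(1, n * m / tau)
}
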