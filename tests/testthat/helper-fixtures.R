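# Small in-code fixtures shared across test files.

# A minimal hand-built MpraExperiment: 2 variants x (ref, alt) x nBc
# barcodes, 1 DNA + 2 RNA samples, deterministic counts.
tinyMpra <- function(nBc = 2L, seed = 42L) {
  set.seed(seed)
  nVar <- 2L
  vid <- rep(sprintf("rs%d", seq_len(nVar)), each = 2L * nBc)
  allele <- rep(rep(c("ref", "alt"), each = nBc), nVar)
  n <- length(vid)
  bc <- sprintf("%s%04d", strrep("ACGT", 3L), seq_len(n))
  counts <- cbind(DNA_1 = rpois(n, 100),
                  RNA_1 = rpois(n, 80),
                  RNA_2 = rpois(n, 120))
  MpraExperiment(counts, variant_id = vid, allele = allele, barcode = bc,
                 sample_type = c("DNA", "RNA", "RNA"))
}

# One variant's data list in the sampler layout, generated from known
# parameters.
simVariantData <- function(nBc = 10L, nDna = 1L, nRna = 5L,
                           muDna = 50, muRef = 1, muAlt = 2,
                           phiDna = 10, phiRna = 10,
                           dDna = rep(1, nDna), dRna = rep(1, nRna)) {
  B <- 2L * nBc
  allele <- rep(0:1, each = nBc)
  md <- rgamma(B, shape = 8, rate = 8 / muDna)
  muA <- c(muRef, muAlt)[allele + 1L]
  dna <- sapply(seq_len(nDna), function(s)
    rnbinom(B, size = phiDna, mu = dDna[s] * md))
  rna <- sapply(seq_len(nRna), function(s)
    rnbinom(B, size = phiRna, mu = dRna[s] * md * muA))
  list(variant_id = "sim_variant",
       dna = matrix(dna, B, nDna), rna = matrix(rna, B, nRna),
       dDna = dDna, dRna = dRna, allele = allele,
       barcode = sprintf("BC%03d", seq_len(B)))
}

# Broad priors for posterior tests where the data should dominate.
broadPriors <- function() {
  priorSet(mu_dna = gammaPrior(1, 0.02),
           mu_rna_ref = gammaPrior(1, 0.5),
           mu_rna_alt = gammaPrior(1, 0.5),
           phi_dna = gammaPrior(1, 0.1),
           phi_rna = gammaPrior(1, 0.1),
           provenance = "test-broad")
}

# Write a count-table TSV from vectors (for readCountTable tests).
writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Naive R reimplementation of the variant log-likelihood (independent
# oracle: explicit double loop over cells).
naiveVariantLogLik <- function(params, data) {
  ll <- 0
  B <- nrow(data$dna)
  for (b in seq_len(B)) {
    for (s in seq_along(data$dDna))
      ll <- ll + dnbinom(data$dna[b, s], size = params$phi_dna,
                         mu = data$dDna[s] * params$mu_dna[b], log = TRUE)
    a <- data$allele[b] + 1L
    for (s in seq_along(data$dRna))
      ll <- ll + dnbinom(data$rna[b, s], size = params$phi_allele[a],
                         mu = data$dRna[s] * params$mu_dna[b] *
                           params$mu_allele[a], log = TRUE)
  }
  ll
}

# Brute-force significance score oracle: literal grid scan over HDI masses.
bruteSignificanceScore <- function(tsDraws, gridStep = 0.001) {
  n <- length(tsDraws)
  x <- sort(tsDraws)
  masses <- seq_len(floor((1 - gridStep) / gridStep + 1e-9)) * gridStep
  qstar <- masses[length(masses)]
  for (q in masses) {
    m <- ceiling(q * n - 1e-9)
    widths <- x[m:n] - x[seq_len(n - m + 1L)]
    j <- which.min(widths)
    if (x[j] <= 0 && x[j + m - 1L] >= 0) { qstar <- q; break }
  }
  1 - qstar
}

# Brute-force pairwise AUC oracle (Mann-Whitney over all pos/neg pairs;
# stat is lower-is-stronger).
pairwiseAuc <- function(stat, pos) {
  ip <- which(pos); in_ <- which(!pos)
  tot <- 0
  for (i in ip) for (j in in_)
    tot <- tot + (stat[i] < stat[j]) + 0.5 * (stat[i] == stat[j])
  tot / (length(ip) * length(in_))
}
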