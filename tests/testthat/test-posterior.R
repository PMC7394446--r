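test_that("log posterior equals likelihood plus naive prior sum", {
  set.seed(21)
  vd <- simVariantData(nBc = 3L)
  ps <- broadPriors()
  params <- list(mu_dna = rgamma(6L, 5, 0.1), mu_allele = c(0.9, 1.4),
                 phi_dna = 6, phi_allele = c(11, 9))
  naive <- naiveVariantLogLik(params, vd) +
    sum(dgamma(params$mu_dna, 1, 0.02, log = TRUE)) +
    dgamma(params$mu_allele[1L], 1, 0.5, log = TRUE) +
    dgamma(params$mu_allele[2L], 1, 0.5, log = TRUE) +
    dgamma(params$phi_dna, 1, 0.1, log = TRUE) +
    sum(dgamma(params$phi_allele, 1, 0.1, log = TRUE))
  expect_equal(logPosterior(params, vd, ps), naive, tolerance = 1e-10)

  # near-flat prior: posterior differences reduce to likelihood differences
  flat <- priorSet(gammaPrior(1, 1e-6), gammaPrior(1, 1e-6),
                   gammaPrior(1, 1e-6), gammaPrior(1, 1e-6),
                   gammaPrior(1, 1e-6), provenance = "flat")
  params2 <- params
  params2$mu_allele <- c(1.6, 0.7)
  dPost <- logPosterior(params2, vd, flat) - logPosterior(params, vd, flat)
  dLik <- variantLogLikelihood(params2, vd) -
    variantLogLikelihood(params, vd)
  expect_equal(dPost, dLik, tolerance = 1e-3)
})

test_that("transcription shift is the log allelic ratio, antisymmetric", {
  draws <- cbind(log_mu_ref = c(rep(0, 60L), rnorm(60L)),
                 log_mu_alt = c(rep(0, 60L), rnorm(60L)))
  ts <- transcriptionShift(draws)
  expect_identical(ts[1:60], rep(0, 60L))
  swapped <- draws[, c(2L, 1L)]
  colnames(swapped) <- c("log_mu_ref", "log_mu_alt")
  expect_identical(transcriptionShift(swapped), -ts)
  draws2 <- cbind(log_mu_ref = rep(log(2), 120L),
                  log_mu_alt = rep(log(4), 120L))
  expect_equal(unique(transcriptionShift(draws2)), log(2))
})

test_that("hdi finds the shortest interval with tie-break at lowest start", {
  h <- hdi(1:100, 0.95)
  expect_identical(unname(h[2L] - h[1L]), 94L)
  expect_identical(unname(h[1L]), 1L)

  set.seed(2)
  z <- rnorm(1e5)
  hz <- hdi(z, 0.95)
  expect_lt(abs(hz[1L] + 1.96), 0.03)
  expect_lt(abs(hz[2L] - 1.96), 0.03)

  e <- rexp(1e5)
  he <- hdi(e, 0.9)
  expect_lt(he[1L], 0.02)           # HDI of a monotone density starts at 0
  expect_lt(abs(he[2L] - qexp(0.9)), 0.1)

  expect_error(hdi(rnorm(50L)), "100 samples")
})

test_that("functional calls implement the HDI and ROPE rules exactly", {
  expect_true(classifyFunctional(c(0.1, 0.5)))
  expect_false(classifyFunctional(c(-0.2, 0.5)))
  expect_false(classifyFunctional(c(0.05, 0.5), rope = c(-0.1, 0.1)))
  expect_true(classifyFunctional(c(0.05, 0.5)))
  expect_true(classifyFunctional(c(0.15, 0.5), rope = c(-0.1, 0.1)))
  expect_false(classifyFunctional(c(-0.5, -0.05), rope = c(-0.1, 0.1)))
})

test_that("significance score matches the brute-force grid oracle", {
  set.seed(14)
  cases <- list(rnorm(2000L),                 # symmetric about 0
                rnorm(2000L, 1, 1),          # mixed
                rnorm(2000L, 0.1, 0.05),     # borderline
                runif(2000L, 0.5, 2))        # all positive
  for (x in cases)
    expect_identical(significanceScore(x), bruteSignificanceScore(x))
  # symmetric null draws: only near-total mass is needed to reach zero
  expect_gt(significanceScore(cases[[1L]]), 0.95)
  expect_equal(significanceScore(cases[[4L]]), 0.001)
})

test_that("ranking refinement only resolves ties at the score floor", {
  scores <- c(1 - 0.999, 1 - 0.999, 0.002, 0.5, NA)
  tails <- c(1e-20, 1e-5, 1e-6, 0.4, 0.1)
  rs <- rankingStat(scores, tails)
  expect_lt(rs[1L], rs[2L])            # within-floor ordering by tail
  expect_lt(rs[2L], 0.001 + 1e-9)      # refined values stay below the floor
  expect_identical(rs[3L], 0.002)      # non-saturated scores untouched
  expect_identical(rs[4L], 0.5)
  expect_true(is.na(rs[5L]))
  expect_identical(rankingStat(1 - 0.999, NA_real_), 1 - 0.999)
})

test_that("posterior sampling is seed-stable and label-antisymmetric", {
  set.seed(61)
  vd <- simVariantData(nBc = 10L, muAlt = 2)
  ps <- broadPriors()
  set.seed(1); s1 <- samplePosterior(vd, ps)
  set.seed(2); s2 <- samplePosterior(vd, ps)
  mcse <- sd(s1$tsDraws) / sqrt(s1$essMin)
  expect_lt(abs(mean(s1$tsDraws) - mean(s2$tsDraws)), 3 * mcse)

  # relabeling ref<->alt negates the TS posterior (within MC error)
  vdSwap <- vd
  vdSwap$allele <- 1L - vd$allele
  set.seed(1); sSwap <- samplePosterior(vdSwap, ps)
  expect_lt(abs(mean(sSwap$tsDraws) + mean(s1$tsDraws)), 4 * mcse)
})

test_that("a near-degenerate allelic prior dominates the data", {
  set.seed(9)
  tight <- priorSet(gammaPrior(1, 0.02),
                    gammaPrior(1e6, 1e6), gammaPrior(1e6, 1e6),
                    gammaPrior(1, 0.1), gammaPrior(1, 0.1),
                    provenance = "tight-allele")
  for (i in 1:4) {
    vd <- simVariantData(nBc = 5L, muAlt = runif(1, 0.5, 3))
    s <- samplePosterior(vd, tight)
    expect_lt(abs(mean(s$tsDraws)), 0.05)
  }
})

test_that("with broad priors and many barcodes the data dominate", {
  set.seed(10)
  vd <- simVariantData(nBc = 100L, muAlt = 2)
  s <- samplePosterior(vd, broadPriors())
  mleTs <- {
    fit <- fitVariantMle(vd)
    log(fit$params$mu_allele[["alt"]] / fit$params$mu_allele[["ref"]])
  }
  expect_lt(abs(mean(s$tsDraws) - mleTs), 0.05)
})

test_that("the Laplace screen keeps strong signals and drops tight nulls", {
  set.seed(71)
  ps <- broadPriors()
  keepStrong <- replicate(10L, {
    vd <- simVariantData(nBc = 30L, muAlt = exp(1.5))
    screenVariant(vd, ps)$keep
  })
  expect_gte(mean(keepStrong), 0.95)
  keepNull <- replicate(10L, {
    vd <- simVariantData(nBc = 30L, muAlt = 1)
    screenVariant(vd, ps)$keep
  })
  expect_lte(mean(keepNull), 0.4)
})

test_that("disabling the screen sends every variant to MCMC", {
  sim <- simulateAssay(simConfig(nVariants = 6L, fracFunctional = 0,
                                 barcodesPerAllele = 5L, seed = 5L))
  res <- fitAssay(sim$mpra, priors = broadPriors(),
                  cfg = fitConfig(seed = 2L, screen = FALSE,
                                  maxRefineFactor = 1))
  expect_true(all(resultsTable(res)$stage == "mcmc"))
})

test_that("borderline intervals trigger refinement; clear ones do not", {
  set.seed(19)
  vd <- simVariantData(nBc = 5L)
  ps <- broadPriors()
  cfg <- fitConfig(seed = 2L)
  mk <- function(lo, hi) methods::new(
    "VariantFit", variantId = "sim_variant",
    draws = matrix(numeric(0), 0L, 0L), tsDraws = numeric(0),
    tsMean = (lo + hi) / 2, hdi = c(lo, hi), functionalCall = TRUE,
    score = 0.5, diagnostics = list(), stage = "mcmc")
  clear <- refineIfBorderline(mk(0.2, 0.6), vd, ps, cfg)
  expect_identical(clear@stage, "mcmc")
  expect_identical(clear@hdi, c(0.2, 0.6))
  refined <- refineIfBorderline(mk(0.001, 0.4), vd, ps, cfg)
  expect_identical(refined@stage, "mcmc_refined")
  expect_gte(refined@diagnostics$n_draws, 4L * 500L * 4L)
})

test_that("assay fits are deterministic across worker counts and reruns", {
  sim <- simulateAssay(simConfig(nVariants = 20L, fracFunctional = 0.3,
                                 barcodesPerAllele = 5L, seed = 33L))
  cfg <- fitConfig(seed = 4L, maxRefineFactor = 1)
  r1 <- fitAssay(sim$mpra, cfg = cfg)
  r2 <- fitAssay(sim$mpra, cfg = cfg, workers = 2L)
  r3 <- fitAssay(sim$mpra, cfg = cfg)
  expect_identical(resultsTable(r1), resultsTable(r2))
  expect_identical(resultsTable(r1), resultsTable(r3))
})

test_that("per-variant failures are isolated, not fatal", {
  sim <- simulateAssay(simConfig(nVariants = 6L, fracFunctional = 0,
                                 barcodesPerAllele = 5L, seed = 9L))
  real <- mprabayes:::fitVariantBayes
  testthat::local_mocked_bindings(
    fitVariantBayes = function(data, priors, cfg) {
      if (data$variant_id == "var_0003") stop("corrupt variant data")
      real(data, priors, cfg)
    },
    .package = "mprabayes")
  res <- fitAssay(sim$mpra, priors = broadPriors(),
                  cfg = fitConfig(seed = 2L, maxRefineFactor = 1))
  expect_identical(names(res@failures), "var_0003")
  expect_match(unname(res@failures), "corrupt")
  expect_identical(nrow(resultsTable(res)), 5L)
})
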