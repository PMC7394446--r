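# Shared simulated assays + MLE tables (computed once for this file).
# simA: null assay generated with mu_allele ~ Gamma(4, 4) (prior mean 1).
# simB: null assay with mu_allele ~ Gamma(4, 2) (prior mean 2).
simA <- simulateAssay(simConfig(nVariants = 2000L, fracFunctional = 0,
                                barcodesPerAllele = 10L, dropout = 0,
                                seed = 101L))
mleA <- fitAllMle(simA$mpra)
simB <- simulateAssay(simConfig(nVariants = 500L, fracFunctional = 0,
                                barcodesPerAllele = 10L, dropout = 0,
                                muAlleleShape = 4, muAlleleRate = 2,
                                seed = 102L))
mleB <- fitAllMle(simB$mpra)

priorMean <- function(ps, family = "mu_rna_alt") {
  p <- ps@priors[[family]]
  p@shape / p@rate
}

test_that("gamma MLE maximizes the (weighted) likelihood on a lattice", {
  set.seed(55)
  wLogLik <- function(x, w, a, b) sum(w * dgamma(x, a, b, log = TRUE))
  for (rep in 1:5) {
    x <- rgamma(60L, shape = runif(1, 0.5, 5), rate = runif(1, 0.2, 3))
    w <- if (rep %% 2) rep(1, 60L) else runif(60L)
    fit <- fitGammaMle(x, w)
    lattice <- expand.grid(a = fit@shape * seq(0.7, 1.4, by = 0.02),
                           b = fit@rate * seq(0.7, 1.4, by = 0.02))
    best <- max(mapply(function(a, b) wLogLik(x, w, a, b),
                       lattice$a, lattice$b))
    expect_gte(wLogLik(x, w, fit@shape, fit@rate), best - 1e-9)
  }
})

test_that("gamma MLE recovers known parameters from large samples", {
  for (seed in 1:3) {
    set.seed(seed)
    fit <- fitGammaMle(rgamma(5000L, shape = 2, rate = 0.5))
    expect_gte(fit@shape, 1.85); expect_lte(fit@shape, 2.15)
    expect_gte(fit@rate, 0.46);  expect_lte(fit@rate, 0.54)
  }
})

test_that("unweighted gamma MLE agrees with an established fitter", {
  set.seed(71)
  x <- rgamma(400L, shape = 2.7, rate = 1.3)
  ours <- fitGammaMle(x)
  ref <- fitdistrplus::fitdist(x, "gamma", method = "mle")
  expect_equal(ours@shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(ours@rate, unname(ref$estimate["rate"]), tolerance = 1e-3)
})

test_that("gamma MLE rejects degenerate or under-sized inputs", {
  expect_error(fitGammaMle(rep(3, 100L)), "degenerate")
  expect_error(fitGammaMle(rgamma(5L, 2, 1)), "fewer than 10")
  x <- rgamma(50L, 2, 1)
  w <- c(rep(0, 45L), rep(1, 5L))
  expect_error(fitGammaMle(x, w), "fewer than 10")
})

test_that("weights concentrated on a subset reduce to the subset fit", {
  set.seed(8)
  x <- rgamma(40L, shape = 3, rate = 1)
  w <- rep(c(0, 1), each = 20L)
  weighted <- fitGammaMle(x, w)
  subset <- fitGammaMle(x[21:40])
  expect_equal(weighted@shape, subset@shape, tolerance = 1e-10)
  expect_equal(weighted@rate, subset@rate, tolerance = 1e-10)
})

test_that("marginal priors close the loop on the generating hyperprior", {
  ps <- estimateMarginalPriors(mleA)
  # generated with mu_allele ~ Gamma(4, 4): refit prior mean within 15% of 1
  expect_lt(abs(priorMean(ps, "mu_rna_ref") - 1), 0.15)
  expect_lt(abs(priorMean(ps, "mu_rna_alt") - 1), 0.15)
  # DNA input generated with mean 50
  expect_lt(abs(priorMean(ps, "mu_dna") / 50 - 1), 0.15)
})

test_that("the marginal prior is insensitive to any single variant", {
  ps <- estimateMarginalPriors(mleA)
  drop1 <- list(
    variants = mleA$variants[-1L, ],
    mu_dna = mleA$mu_dna[mleA$mu_dna$variant_id !=
                           mleA$variants$variant_id[1L], ])
  ps1 <- estimateMarginalPriors(drop1)
  for (fam in c("mu_dna", "mu_rna_ref", "mu_rna_alt", "phi_dna", "phi_rna"))
    expect_lt(abs(priorMean(ps1, fam) / priorMean(ps, fam) - 1), 0.01)
})

test_that("grouped priors recover group-specific hyperpriors", {
  # disambiguate the two assays' variant ids before pooling
  vB <- mleB$variants; vB$variant_id <- paste0("B_", vB$variant_id)
  bB <- mleB$mu_dna; bB$variant_id <- paste0("B_", bB$variant_id)
  mle <- list(variants = rbind(mleA$variants, vB),
              mu_dna = rbind(mleA$mu_dna, bB))
  groups <- setNames(rep(c("low", "high"),
                         c(nrow(mleA$variants), nrow(vB))),
                     mle$variants$variant_id)
  psl <- estimateGroupedPriors(mle, groups)
  mLow <- priorMean(psl$low); mHigh <- priorMean(psl$high)
  expect_lt(mLow, mHigh)
  expect_lt(abs(mLow - 1), 0.2)
  expect_lt(abs(mHigh - 2) / 2, 0.2)
})

test_that("a single group reproduces the marginal prior bitwise", {
  groups <- setNames(rep("all", nrow(mleA$variants)),
                     mleA$variants$variant_id)
  psl <- estimateGroupedPriors(mleA, groups)
  psm <- estimateMarginalPriors(mleA)
  for (fam in names(psm@priors)) {
    expect_identical(psl$all@priors[[fam]]@shape, psm@priors[[fam]]@shape)
    expect_identical(psl$all@priors[[fam]]@rate, psm@priors[[fam]]@rate)
  }
})

test_that("undersized groups fall back to the marginal prior with warning", {
  groups <- setNames(c(rep("big", nrow(mleA$variants) - 3L), rep("tiny", 3L)),
                     mleA$variants$variant_id)
  expect_warning(psl <- estimateGroupedPriors(mleA, groups),
                 "marginal prior")
  expect_match(psl$tiny@provenance, "fallback")
})

test_that("kernel widening stops exactly at the weight-floor rule", {
  set.seed(12)
  ann <- matrix(rnorm(1000L), ncol = 1L)
  cfg <- kernelConfig(nTop = 100L)
  cw <- conditionalWeights(ann[which.min(abs(ann)), ], ann, cfg)
  sorted <- sort(cw$weights, decreasing = TRUE)
  expect_gte(sorted[100L], 0.01 * sorted[1L])
  # the next-smaller grid scale violates the rule
  smaller <- cw$scale / 1.1
  wS <- dt(sqrt(rowSums((ann - ann[which.min(abs(ann)), ])^2)) / smaller,
           df = 3) / dt(0, df = 3)
  sortedS <- sort(wS, decreasing = TRUE)
  expect_lt(sortedS[100L], 0.01 * sortedS[1L])
  # widening 10x beyond the stopping point strictly raises the ratio
  wW <- dt(sqrt(rowSums((ann - ann[which.min(abs(ann)), ])^2)) /
             (cw$scale * 10), df = 3) / dt(0, df = 3)
  sortedW <- sort(wW, decreasing = TRUE)
  expect_gt(sortedW[100L] / sortedW[1L], sorted[100L] / sorted[1L])
})

test_that("kernel weights depend only on annotation distance", {
  ann <- matrix(c(-2, -1, 0, 1, 2, seq(-3, 3, length.out = 195)), ncol = 1L)
  cw <- conditionalWeights(0, ann, kernelConfig(nTop = 50L))
  expect_equal(cw$weights[2L], cw$weights[4L], tolerance = 1e-12)
  expect_equal(cw$weights[1L], cw$weights[5L], tolerance = 1e-12)
})

test_that("degenerate annotations give uniform weights with a warning", {
  ann <- matrix(rep(1, 200L), ncol = 1L)
  expect_warning(cw <- conditionalWeights(1, ann, kernelConfig(nTop = 50L)),
                 "uniform")
  expect_true(all(cw$weights == 1))
})

test_that("missing annotations are excluded from weighting with a warning", {
  set.seed(3)
  ann <- matrix(rnorm(300L), ncol = 1L)
  ann[7L] <- NaN
  expect_warning(cw <- conditionalWeights(0, ann, kernelConfig(nTop = 50L)),
                 "weight 0")
  expect_identical(cw$weights[7L], 0)
})

test_that("null annotations leave the conditional prior near the marginal", {
  set.seed(44)
  annotations <- data.frame(variant_id = mleA$variants$variant_id,
                            score = rnorm(nrow(mleA$variants)))
  psm <- estimateMarginalPriors(mleA)
  devs <- unlist(lapply(sample(mleA$variants$variant_id, 8L), function(vid) {
    psc <- estimateConditionalPrior(vid, mleA, annotations)
    c(abs(priorMean(psc, "mu_rna_alt") / priorMean(psm, "mu_rna_alt") - 1),
      abs(priorMean(psc, "mu_rna_ref") / priorMean(psm, "mu_rna_ref") - 1))
  }))
  # each conditional prior averages ~100-200 effective neighbours, so a
  # single target can deviate by a couple of SE; the typical deviation
  # must stay within sampling noise of the marginal mean
  expect_lt(median(devs), 0.10)
  expect_lt(max(devs), 0.25)
})

test_that("an informative annotation shifts the conditional prior", {
  simC <- simulateAssay(simConfig(nVariants = 300L, fracFunctional = 0.5,
                                  barcodesPerAllele = 10L, dropout = 0,
                                  seed = 103L))
  mleC <- fitAllMle(simC$mpra)
  tv <- simC$truth@variants
  annotations <- data.frame(variant_id = tv$variant_id, score = tv$true_ts)
  psm <- estimateMarginalPriors(mleC)
  vHi <- tv$variant_id[which.max(tv$true_ts)]
  vLo <- tv$variant_id[which.min(tv$true_ts)]
  pmHi <- priorMean(estimateConditionalPrior(vHi, mleC, annotations),
                    "mu_rna_alt")
  pmLo <- priorMean(estimateConditionalPrior(vLo, mleC, annotations),
                    "mu_rna_alt")
  pmMarg <- priorMean(psm, "mu_rna_alt")
  expect_gt(pmHi, pmMarg)
  expect_lt(pmLo, pmMarg)
})

test_that("prior sets survive a JSON round trip", {
  ps <- broadPriors()
  path <- tempfile(fileext = ".json")
  writePriorSet(ps, path)
  ps2 <- readPriorSet(path)
  for (fam in names(ps@priors)) {
    expect_equal(ps2@priors[[fam]]@shape, ps@priors[[fam]]@shape)
    expect_equal(ps2@priors[[fam]]@rate, ps@priors[[fam]]@rate)
  }
  expect_identical(ps2@provenance, "test-broad")
})
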