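# mprabayes

Bayesian analysis of massively parallel reporter assays (MPRA) from
barcode-level counts.

MPRA measure the transcriptional impact of thousands of genetic variants at
once: barcoded oligonucleotides carrying the reference or alternate allele
of each variant are cloned into plasmids, transfected into cells, and both
the plasmid DNA and the transcribed RNA are sequenced. The analysis problem
is to decide, per variant, whether the alternate allele shifts
transcription — despite overdispersed counts, unequal sequencing depths,
and unknown per-barcode plasmid input.

## The model

Counts are modelled directly with negative binomials in mean–dispersion
form (`Var = μ + μ²/φ`):

    Counts_DNA[s, bc] ~ NB(mean = d_s · μ_DNA[bc],            dispersion = φ_DNA)
    Counts_RNA[s, bc] ~ NB(mean = d_s · μ_DNA[bc] · μ_allele, dispersion = φ_allele)

with gamma priors on every parameter, estimated empirically from the
population of per-variant maximum-likelihood fits — marginally, within
annotation groups, or conditionally via adaptive t-kernel weights over
continuous annotations. The **transcription shift**
`TS = log μ_alt − log μ_ref` is computed per posterior draw; a variant is
called **functional** when the 95% highest density interval (HDI) of its TS
posterior excludes zero (optionally a region of practical equivalence).
Per variant, a fast Laplace screen on the 80% TS interval decides whether a
full MCMC fit (componentwise slice sampling, 4 chains × 200 warmup + 500
sampling) is warranted, and chains are adaptively lengthened when an HDI
edge is near the decision boundary.

The package also ships an assay simulator with known ground truth, the
classical activity t-test baseline, ROC/PR evaluation utilities, exact
barcode counting from FASTQ, and a command-line front end
(`inst/scripts/mpra-tool.R` — subcommands `simulate`, `fit`, `evaluate`,
`count-barcodes`, `compare`).

## A worked example

```r
library(mprabayes)

sim <- simulateAssay(simConfig(nVariants = 300, seed = 1))   # 5% functional
res <- fitAssay(sim$mpra, priors = "marginal", cfg = fitConfig(seed = 1))
res
#> MpraResults: 300 variants (24 functional calls, 0 failures)

head(resultsTable(res), 3)
#>   variant_id     ts_mean   hdi_lower hdi_upper     score  tail_prob functional_call       stage rhat_max  ess_min
#> 1   var_0001 0.293918588  0.07457505 0.5364947 0.0210000 0.01418137            TRUE        mcmc 1.009447 310.2720
#> 2   var_0002 0.002518327 -0.25113017 0.2561668 0.9844747 0.98447468           FALSE screen_only       NA       NA
#> 3   var_0003 0.159387343 -0.10368859 0.3855825 0.2150000 0.20159624           FALSE        mcmc 1.004198 391.8468
```

Each row gives the posterior mean TS, the 95% HDI, the pseudo-significance
score (one minus the smallest HDI mass containing zero; lower = stronger
evidence, used as the ROC/PR ranking statistic), the HDI-based functional
call, and the fitting stage (`screen_only` variants were settled by the
Laplace screen; `mcmc`/`mcmc_refined` by full sampling, with convergence
diagnostics). Here `var_0001` is called functional: its alternate allele
raises transcription by about `exp(0.29) ≈ 1.3`-fold and the 95% HDI
excludes zero.

Comparing with the classical activity t-test on the same assay:

```r
ev <- evaluateCalls(with(resultsTable(res),
        data.frame(variant_id = variant_id, effect = ts_mean,
                   stat = rankingStat(score, tail_prob))),
      sim$truth)
tt <- evaluateCalls(activityTtest(sim$mpra), sim$truth)
round(c(bayes_auc = ev$auc, ttest_auc = tt$auc,
        bayes_spread = ev$spread_at_zero, ttest_spread = tt$spread_at_zero), 3)
#>    bayes_auc    ttest_auc bayes_spread ttest_spread
#>        0.841        0.765        0.126        0.148
```

The Bayesian fit ranks functional variants better and — because the
empirical prior shrinks extreme null estimates — spreads the truly
non-functional variants more tightly around zero.

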