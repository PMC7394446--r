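---
title: "Modelling MPRA barcode counts with empirical-Bayes negative binomials"
author: "mprabayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MPRA barcode counts with empirical-Bayes negative binomials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mprabayes)
```

## The assay and the model

A massively parallel reporter assay (MPRA) clones thousands of short
genomic fragments — each carrying the reference or alternate allele of a
variant, tagged with multiple inert barcodes — into a plasmid library,
transfects it into cells, and sequences both the plasmid DNA and the
transcribed RNA. A barcode's DNA count measures its input concentration; its
RNA count additionally reflects the transcription rate of the fragment it
tags. Comparing the two alleles' transcription rates yields the
*transcription shift* (TS); a variant whose TS credibly differs from zero is
called *functional*.

`mprabayes` models each variant's barcode-level counts directly with
negative binomials in mean–dispersion form, `Var = mu + mu^2 / phi` (larger
`phi` means closer to Poisson — conventions differ between packages, so the
variance identity is the contract used throughout):

* DNA count of barcode *bc* in sample *s*:
  `NB(mean = d_s * mu_dna[bc], dispersion = phi_dna)`
* RNA count of barcode *bc* in sample *s*:
  `NB(mean = d_s * mu_dna[bc] * mu_allele[a(bc)], dispersion = phi_rna[a(bc)])`

Here `d_s` is the per-sample depth factor, `mu_dna[bc]` the unknown plasmid
input of the barcode, and `mu_allele` the transcription-rate multiplier of
the barcode's allele. TS is `log(mu_allele[alt]) - log(mu_allele[ref])`,
computed per posterior draw as a generated quantity. Every parameter gets a
gamma prior (correct support, maximum entropy for a positive variable with
finite mean and mean-log, and flexible enough with two parameters); the RNA
dispersions of the two alleles share one prior family.

Depth factors are identifiable only up to a per-type scale, so the package
fixes the convention: `d_s` is the column total divided by the geometric
mean of the column totals of the same sample type, hence geometric mean 1
within DNA and within RNA separately. The DNA-to-RNA scale is absorbed by
`mu_allele`. The simulator states its ground-truth depths in the same
convention — any other scaling would make truth and estimate incomparable.

## Empirical priors

The priors are estimated from the assay itself. Each variant is first fit by
maximum likelihood (BFGS on log parameters with analytic gradients, a
method-of-moments start and two jittered restarts; fits that hit the
parameter bounds — e.g. an allele with all-zero RNA counts, or a dispersion
drifting to infinity on underdispersed cells — are excluded from the prior
population but still receive posterior fits). Gamma distributions are then
fit by maximum likelihood to the populations of estimates:

* **marginal** — all variants weighted equally: pooled barcode-level
  `mu_dna`, the two allelic rates (separately), `phi_dna`, and `phi_rna`
  pooled over alleles;
* **grouped** — an independent prior per level of a categorical annotation
  (groups below 10 variants fall back to the marginal prior with a
  warning);
* **conditional** — per-variant priors with weights from a t-kernel
  (3 degrees of freedom, heavy-tailed so distant variants keep non-zero
  weight) centered at the target's standardized continuous annotations. The
  kernel scale grows on a geometric grid (factor 1.1) until the 100th
  largest weight reaches 1% of the largest, so no prior is dominated by a
  handful of nearest neighbours. Both `nTop = 100` and the 1% floor are
  configurable (`kernelConfig()`). The target's own estimate is included in
  the weighting; it is one observation among hundreds.

The weighted gamma MLE profiles out the rate and solves the shape equation
`log(a) - digamma(a) = log(weighted mean) - weighted mean log` by bisection;
it requires at least 10 positively weighted values and refuses near-constant
inputs, where the MLE diverges.

Because the prior is shared across thousands of variants, it shrinks
extreme estimates toward the assay average — regularization that acts in
place of post hoc multiple-testing correction (the interval width is left
intact; the estimate moves).

## Posterior inference and decisions

Per variant, the joint posterior over all log-scale parameters is explored
with a componentwise slice sampler (stepping-out and shrinkage; widths tuned
from accepted move sizes during the first half of warmup). The sampler
exploits the model's conditional structure — a barcode's `mu_dna` touches
only its own row of counts — so a sweep is cheap, and it has no accept/
reject tuning failure modes. Chains are initialized at the posterior mode
(found by BFGS) with small jitter. Defaults are 4 chains, 200 warmup and 500
retained sweeps each (2000 draws). Convergence is gated on split-R-hat
<= 1.05 and effective sample size >= 100 for the TS-relevant parameters,
with one automatic retry at 4x lengths.

Two speed/precision devices wrap the sampler:

* **Fast screen.** A Laplace (normal) approximation at the posterior mode
  gives an approximate 80% interval on TS via the delta method. Only
  variants whose interval excludes zero proceed to MCMC; the rest are
  finalized as non-functional (`screen_only`) with the analytic version of
  the significance score. The contract is behavioural — the screen must
  pass truly functional variants at least as often as the exact fit would —
  and approximation failures fail open into MCMC.
* **Adaptive refinement.** If either 95% HDI edge lies within 10% of the
  HDI width from zero (the margin is configurable; "close to zero" needs an
  operational definition), sampling is rerun at 4x length, repeating while
  borderline up to a total factor of 25. This buys Monte-Carlo precision
  exactly where the binary decision is sensitive to it.

Decisions use the highest density interval — the shortest contiguous
interval containing `ceiling(mass * n)` sorted draws, ties broken at the
lowest start. A variant is functional iff 0 is outside its 95% HDI, or, with
a region of practical equivalence (ROPE), iff the HDI and ROPE are disjoint.
For ranking (ROC/PR), the package reports `1 - q*`, where `q*` is the
smallest mass on a 0.001 grid whose HDI contains zero; smaller is stronger.
The grid scan evaluates window sizes with a 1e-9 guard so that the C++
implementation and a literal R scan agree bit-for-bit.

The score saturates at its grid floor: every variant whose 99.9% HDI
excludes zero scores 0.001, so a variant at twelve posterior standard
deviations from zero ties with one at four, and the tie block sits exactly
where precision-recall analysis is most sensitive. When the score is used
as a ranking statistic, ties at the floor are therefore resolved by the
posterior's standardized tail probability `2 * pnorm(-|mean|/sd)`
(`rankingStat()`), mapped strictly below the floor so that all
non-saturated scores keep their exact grid values. The reported `score`
column itself is never altered.

## The simulator

`simulateAssay()` draws every quantity from the generative model above:
gamma truth hyperparameters giving mean DNA input ~50 counts and dispersions
~10 (well-identified MLEs at realistic depth), log-normal depth variation
(sd 0.3, normalized to the geometric-mean-1 convention), and per-barcode
dropout (Bernoulli 0.05) that removes a barcode from all samples —
library-preparation failure, the reason barcode counts are missing rather
than zero. Functional variants (default 5%) receive
`TS = sign * |N(0, 0.5^2)|` truncated below at 0.1 — a stand-in effect
distribution chosen so that effects are neither trivially large nor
undetectable; it is configurable. The default geometry mirrors the
reference study conditions (3000 variants, 10 barcodes per allele, 2 DNA +
5 RNA samples); the test suite and acceptance script run a 300-variant
desk-scale version of the same point so the full studies finish in minutes
on one core.

What the simulator does *not* emulate: sequencing-read-level errors (counts
are drawn directly, so barcode mis-assignment is absent), composition
effects between variants sharing a library, batch structure across
replicates, and any dependence of dropout on GC content or input
concentration. Passing simulation studies therefore demonstrate that the
inference machinery is correct and well-calibrated *under the model*, not
that real assays satisfy the model.

## Numerical choices

* All optimization and sampling happen on log parameters; hard support
  bounds at `|log theta| = 30`, with MLE boundary flags at 12 (and 9 for
  downward drift, where optimizers stall short of the bound).
* The gamma-MLE shape equation is solved to 1e-12 on the log scale.
* Per-variant RNG seeds are a polynomial hash of the global seed and the
  variant id (`stableSeed()`), so results are byte-identical across reruns
  and worker counts, and independent of fitting order.
* Evaluation: AUC by the rank (Mann-Whitney) formula with tied ranks
  averaged — identical to the trapezoidal ROC area; AUPR as average
  precision. Variants missing from a result table get the worst rank and
  are excluded from the accuracy metrics.
* The activity t-test baseline replaces zero RNA counts by 0.5 before the
  log, drops zero-DNA-factor barcodes, and uses Welch's unequal-variance
  test on pooled (barcode x RNA sample) activities with
  Benjamini-Hochberg correction at FDR 0.05. Pooling pseudo-replicates
  barcodes, so the baseline runs anti-conservative — one of the classical
  approach's documented weaknesses, visible in its null behaviour.

## Design choices made where the design was open

* The per-variant `phi_dna` is shared across that variant's barcodes (one
  dispersion symbol per variant model), not global.
* `mu_ref` and `mu_alt` populations are fit separately for the marginal
  prior (a pooled option would also be defensible; separate fits let an
  asymmetric assay express itself).
* The screen is a Laplace approximation rather than a variational fit: the
  contract on the screen is behavioural (conservative pass-through), and on
  log parameters with unimodal conditionals the mode-centered Gaussian is
  accurate enough at a fraction of the cost.
* Refinement multiplies only the post-warmup length (the chain is already
  adapted); the nonconvergence retry multiplies both.
* The evaluation studies in the test-suite and acceptance script run with
  refinement disabled: spread-at-zero, correlation and AUC depend on
  posterior means and score rankings, not on the boundary precision of HDI
  edges, and a fixed configuration keeps replicate studies comparable.
* Multi-annotation conditional distances are Euclidean after per-dimension
  standardization (a product kernel was rejected for simplicity).

## Known limitations

* Two alleles per variant, one cell type, no experimental perturbations —
  the model mirrors the standard MPRA design only.
* Prior hyperparameters are treated as known after estimation; their
  uncertainty is not propagated (the fully joint hierarchical model over
  all variants is out of scope).
* Exact barcode matching only; no error-correcting decoder.
* The classical baseline implements the activity t-test only, not the
  other published MPRA methods.

## A worked example

```{r example, eval = FALSE}
sim <- simulateAssay(simConfig(nVariants = 300, seed = 1))
res <- fitAssay(sim$mpra, priors = "marginal", cfg = fitConfig(seed = 1))
head(resultsTable(res))
ev <- evaluateCalls(
  with(resultsTable(res),
       data.frame(variant_id = variant_id, effect = ts_mean,
                  stat = rankingStat(score, tail_prob))),
  sim$truth)
unlist(ev[c("auc", "aupr", "spread_at_zero")])
```
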