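#' Classical activity t-test analysis
#'
#' The traditional MPRA analysis: each barcode's DNA factor is the mean of
#' its depth-adjusted DNA counts; the activity of a barcode in an RNA
#' sample is `log((count / d_s) / dna_factor)`, with zero RNA counts
#' replaced by a 0.5 pseudocount and zero-DNA-factor barcodes dropped.
#' Per variant, the activities of the two alleles are compared by Welch's
#' t-test; the effect is `mean(alt) - mean(ref)` (TS scale). P-values get a
#' Benjamini-Hochberg correction across the assay and calls are made at
#' `fdr`.
#'
#' @param x an [MpraExperiment-class].
#' @param depths optional depth factors.
#' @param fdr assay-wide false discovery rate for calls (default 0.05).
#' @param pseudocount replacement for zero RNA counts (default 0.5).
#' @return data.frame: `variant_id`, `effect`, `stat` (the p-value; lower =
#'   stronger), `p`, `q`, `call`, `method`. Variants with fewer than two
#'   usable activity values per allele are flagged with `NA`.
#' @export
activityTtest <- function(x, depths = NULL, fdr = 0.05, pseudocount = 0.5) {
  if (is.null(depths)) depths <- computeDepthFactors(x)
  vids <- variantIds(x)
  rows <- lapply(vids, function(vid) {
    vd <- variantData(x, vid, depths)
    dnaf <- rowMeans(sweep(vd$dna, 2L, vd$dDna, "/"))
    use <- dnaf > 0
    act <- function(a) {
      i <- which(vd$allele == a & use)
      if (!length(i)) return(numeric(0))
      cts <- vd$rna[i, , drop = FALSE]
      cts[cts == 0] <- pseudocount
      as.vector(log(sweep(sweep(cts, 2L, vd$dRna, "/"), 1L, dnaf[i], "/")))
    }
    aRef <- act(0L); aAlt <- act(1L)
    if (length(aRef) < 2L || length(aAlt) < 2L)
      return(data.frame(variant_id = vid, effect = NA_real_, p = NA_real_))
    tt <- tryCatch(t.test(aAlt, aRef), error = function(e) NULL)
    data.frame(variant_id = vid,
               effect = mean(aAlt) - mean(aRef),
               p = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$stat <- out$p
  out$call <- !is.na(out$q) & out$q <= fdr
  out$method <- "ttest"
  out[, c("variant_id", "effect", "stat", "p", "q", "call", "method")]
}

#' Evaluate a method's output against simulation truth
#'
#' Computes ranking metrics from the method's ranking statistic (lower =
#' stronger evidence) against the true functional flags: AUC by the
#' rank/Mann-Whitney formula (equivalent to the trapezoidal ROC area with
#' tied ranks averaged) and AUPR as average precision. Accuracy metrics:
#' `spread_at_zero` (SD of effect estimates over truly null variants) and
#' `cor_functional` (Pearson correlation of estimates with true TS over
#' truly functional variants). Truth variants missing from `result` are
#' assigned the worst possible rank and excluded from the accuracy metrics.
#'
#' @param result data.frame with `variant_id`, `effect`, `stat`.
#' @param truth a [SimTruth-class] or its `variants` data.frame.
#' @return list with `auc`, `aupr`, `spread_at_zero`, `cor_functional`,
#'   `n_missing`.
#' @export
evaluateCalls <- function(result, truth) {
  tv <- if (methods::is(truth, "SimTruth")) truth@variants else truth
  i <- match(tv$variant_id, result$variant_id)
  stat <- result$stat[i]
  effect <- result$effect[i]
  nMissing <- sum(is.na(i))
  worst <- if (all(is.na(stat))) 1 else max(stat, na.rm = TRUE) + 1
  stat[is.na(stat)] <- worst
  pos <- tv$functional
  auc <- aupr <- NA_real_
  if (any(pos) && any(!pos)) {
    auc <- rankAuc(stat, pos)
    aupr <- averagePrecision(stat, pos)
  }
  spread <- if (any(!pos)) sd(effect[!pos], na.rm = TRUE) else NA_real_
  corf <- if (sum(pos & !is.na(effect)) >= 3L)
    suppressWarnings(cor(effect[pos], tv$true_ts[pos],
                         use = "complete.obs"))
  else NA_real_
  list(auc = auc, aupr = aupr, spread_at_zero = spread,
       cor_functional = corf, n_missing = nMissing)
}

# AUC via mean ranks; stat is lower-is-stronger.
rankAuc <- function(stat, pos) {
  r <- rank(-stat, ties.method = "average")
  nP <- sum(pos); nN <- sum(!pos)
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

# Average precision (step-wise PR integral over distinct thresholds, so
# tied statistics enter as one block); stat is lower-is-stronger.
averagePrecision <- function(stat, pos) {
  o <- order(stat)
  stat <- stat[o]; pos <- pos[o]
  last <- cumsum(rle(stat)$lengths)  # last index of each tied block
  cumPos <- cumsum(pos)[last]
  prec <- cumPos / last
  recall <- cumPos / sum(pos)
  sum(diff(c(0, recall)) * prec)
}

#' Run and compare several in-package methods on one assay
#'
#' @param x an [MpraExperiment-class].
#' @param truth optional [SimTruth-class] for metric computation.
#' @param methods character subset of `"bayes-marginal"`,
#'   `"bayes-conditional"`, `"bayes-grouped"`, `"ttest"`.
#' @param annotations annotations for the non-marginal Bayesian modes.
#' @param cfg a [FitConfig-class].
#' @param corMethod correlation type for the estimate matrix
#'   (`"pearson"` or `"spearman"`).
#' @param ... forwarded to [fitAssay()].
#' @return list with `estimates` (variant x method effect matrix),
#'   `correlation` (method x method), and `metrics` (long data.frame, when
#'   truth is given). Failed methods are recorded in `failed` and excluded.
#' @export
compareMethods <- function(x, truth = NULL,
                           methods = c("bayes-marginal", "ttest"),
                           annotations = NULL, cfg = fitConfig(),
                           corMethod = "pearson", ...) {
  sharedMle <- NULL
  runOne <- function(m) {
    if (m == "ttest") {
      tt <- activityTtest(x)
      return(tt[, c("variant_id", "effect", "stat")])
    }
    mode <- sub("^bayes-", "", m)
    if (is.null(sharedMle)) {
      set.seed(stableSeed(cfg@seed, "mle"))
      sharedMle <<- fitAllMle(x)
    }
    res <- resultsTable(fitAssay(x, priors = mode,
                                 annotations = annotations, cfg = cfg,
                                 mle = sharedMle, ...))
    data.frame(variant_id = res$variant_id, effect = res$ts_mean,
               stat = rankingStat(res$score, res$tail_prob))
  }
  outs <- list(); failed <- character(0)
  for (m in methods) {
    r <- tryCatch(runOne(m), error = function(e) e)
    if (inherits(r, "condition")) failed[m] <- conditionMessage(r)
    else outs[[m]] <- r
  }
  if (!length(outs)) stop("all methods failed")
  vids <- sort(unique(unlist(lapply(outs, `[[`, "variant_id"))))
  est <- vapply(outs, function(r) r$effect[match(vids, r$variant_id)],
                numeric(length(vids)))
  est <- matrix(est, nrow = length(vids),
                dimnames = list(vids, names(outs)))
  corr <- cor(est, use = "pairwise.complete.obs", method = corMethod)
  metrics <- NULL
  if (!is.null(truth)) {
    metrics <- do.call(rbind, lapply(names(outs), function(m) {
      ev <- evaluateCalls(outs[[m]], truth)
      data.frame(method = m,
                 metric = c("auc", "aupr", "spread_at_zero",
                            "cor_functional"),
                 value = c(ev$auc, ev$aupr, ev$spread_at_zero,
                           ev$cor_functional))
    }))
  }
  list(estimates = est, correlation = corr, metrics = metrics,
       results = outs, failed = failed)
}
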