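#' (Weighted) maximum-likelihood gamma fit
#'
#' Maximizes the weighted gamma log-likelihood by profiling out the rate:
#' given the shape a, the optimal rate is `a / weighted mean`, and the shape
#' solves `log(a) - digamma(a) = log(wmean(x)) - wmean(log x)` (a strictly
#' decreasing function, solved by bisection). With equal weights this is the
#' exact gamma MLE.
#'
#' @param values strictly positive reals (at least 10 with positive weight).
#' @param weights optional non-negative weights (default equal).
#' @return A [GammaPrior-class].
#' @export
fitGammaMle <- function(values, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(weights) == length(values), all(weights >= 0))
  keep <- weights > 0 & is.finite(values)
  if (sum(keep) < 10L)
    stop("fewer than 10 usable values for gamma fitting; ",
         "fall back to the marginal prior")
  x <- values[keep]; w <- weights[keep]
  if (any(x <= 0)) stop("gamma fitting requires strictly positive values")
  W <- sum(w)
  m <- sum(w * x) / W
  s <- log(m) - sum(w * log(x)) / W   # >= 0 by Jensen; 0 iff degenerate
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate (near-constant) values: gamma MLE diverges")
  g <- function(la) {
    a <- exp(la)
    log(a) - digamma(a) - s
  }
  la <- uniroot(g, lower = log(1e-8), upper = log(1e8), tol = 1e-12)$root
  shape <- exp(la)
  gammaPrior(shape = shape, rate = shape / m)
}

.cleanMle <- function(mle) {
  v <- mle$variants
  keep <- v$converged & !v$boundary & is.finite(v$ts)
  if (!any(keep)) stop("no converged, non-boundary MLE fits available")
  list(variants = v[keep, , drop = FALSE],
       mu_dna = mle$mu_dna[mle$mu_dna$variant_id %in% v$variant_id[keep], ,
                           drop = FALSE])
}

.fitPriorSet <- function(v, bc, weightsVariant = NULL, provenance) {
  wv <- if (is.null(weightsVariant)) rep(1, nrow(v)) else weightsVariant
  wb <- if (is.null(weightsVariant)) rep(1, nrow(bc))
        else weightsVariant[match(bc$variant_id, v$variant_id)]
  priorSet(
    mu_dna     = fitGammaMle(bc$mu_dna, wb),
    mu_rna_ref = fitGammaMle(v$mu_ref, wv),
    mu_rna_alt = fitGammaMle(v$mu_alt, wv),
    phi_dna    = fitGammaMle(v$phi_dna, wv),
    phi_rna    = fitGammaMle(c(v$phi_rna_ref, v$phi_rna_alt), c(wv, wv)),
    provenance = provenance)
}

#' Marginal empirical priors
#'
#' Fits one gamma prior per parameter family to the population of converged
#' per-variant MLEs, weighting all variants equally: pooled barcode-level
#' DNA inputs, reference and alternate allelic rates (separately), DNA
#' dispersions, and RNA dispersions pooled over both alleles.
#'
#' @param mle output of [fitAllMle()].
#' @return A [PriorSet-class] with provenance `"marginal"`.
#' @export
estimateMarginalPriors <- function(mle) {
  cl <- .cleanMle(mle)
  .fitPriorSet(cl$variants, cl$mu_dna, NULL, "marginal")
}

#' Grouped empirical priors from a categorical annotation
#'
#' Fits an independent [PriorSet-class] within each annotation group.
#' Groups smaller than `minGroup` fall back to the marginal prior with a
#' warning.
#'
#' @param mle output of [fitAllMle()].
#' @param groups named character vector (names = variant ids) or a
#'   categorical annotation data.frame from [readAnnotations()].
#' @param minGroup minimum variants per group (default 10).
#' @return Named list of [PriorSet-class] objects, one per group level.
#' @export
estimateGroupedPriors <- function(mle, groups, minGroup = 10L) {
  if (is.data.frame(groups)) {
    lab <- setdiff(colnames(groups), "variant_id")[1L]
    groups <- setNames(as.character(groups[[lab]]), groups$variant_id)
  }
  cl <- .cleanMle(mle)
  v <- cl$variants
  g <- unname(groups[v$variant_id])
  if (anyNA(g)) stop("groups must cover every variant in the MLE table")
  marginal <- NULL
  out <- list()
  for (lev in unique(g)) {
    i <- g == lev
    if (sum(i) < minGroup) {
      warning(sprintf(
        "group '%s' has %d variants (< %d); using the marginal prior",
        lev, sum(i), minGroup))
      if (is.null(marginal)) marginal <- estimateMarginalPriors(mle)
      ps <- marginal
      ps@provenance <- sprintf("grouped:%s (marginal fallback)", lev)
      out[[lev]] <- ps
    } else {
      vb <- v[i, , drop = FALSE]
      bb <- cl$mu_dna[cl$mu_dna$variant_id %in% vb$variant_id, , drop = FALSE]
      out[[lev]] <- .fitPriorSet(vb, bb, NULL, sprintf("grouped:%s", lev))
    }
  }
  out
}

#' Adaptive t-kernel weights over variants
#'
#' Centers a t-distribution kernel at the target variant's (standardized)
#' annotation and widens its scale on a geometric grid (factor 1.1) until
#' the `nTop`-th largest weight is at least `weightFloorRatio` times the
#' largest, so the conditional prior is never dominated by a few nearest
#' neighbours in annotation space. Weights are returned normalized to
#' maximum 1. Variants with missing annotations get weight 0 (with a
#' warning); if all annotations are identical the weights are uniform.
#'
#' @param target numeric annotation vector of the target variant
#'   (standardized scale must match `ann`).
#' @param ann numeric matrix of standardized annotations
#'   (variants x dimensions).
#' @param cfg a [KernelConfig-class].
#' @return list with `weights` (length `nrow(ann)`), the selected `scale`,
#'   and the searched `grid` of scales.
#' @export
conditionalWeights <- function(target, ann, cfg = kernelConfig()) {
  ann <- as.matrix(ann)
  if (nrow(ann) < cfg@nTop + 1L)
    stop(sprintf("need at least nTop + 1 = %d variants", cfg@nTop + 1L))
  dist <- sqrt(rowSums((ann - matrix(target, nrow(ann), ncol(ann),
                                     byrow = TRUE))^2))
  miss <- !is.finite(dist)
  if (any(miss))
    warning(sprintf("%d variant(s) with missing annotations get weight 0",
                    sum(miss)))
  usable <- dist[!miss]
  if (max(usable) < 1e-12) {
    warning("all annotations identical; using uniform weights")
    w <- as.numeric(!miss)
    return(list(weights = w, scale = Inf, grid = numeric(0)))
  }
  sigma0 <- 1e-3
  kernelW <- function(sigma) {
    w <- rep(0, length(dist))
    w[!miss] <- dt(usable / sigma, df = cfg@df) / dt(0, df = cfg@df)
    w
  }
  grid <- sigma0
  repeat {
    sigma <- grid[length(grid)]
    w <- kernelW(sigma)
    ws <- sort(w[!miss], decreasing = TRUE)
    if (ws[cfg@nTop] >= cfg@weightFloorRatio * ws[1L])
      return(list(weights = w, scale = sigma, grid = grid))
    if (length(grid) > 2000L)
      stop("kernel widening failed to satisfy the stopping rule")
    grid <- c(grid, sigma * 1.1)
  }
}

#' Conditional (annotation-weighted) empirical prior for one variant
#'
#' Standardizes each continuous annotation dimension, computes adaptive
#' t-kernel weights centered at the target variant ([conditionalWeights()]),
#' and fits every prior family by weighted gamma MLE. The target's own MLE
#' is included in the weighting (its contribution is one among thousands).
#'
#' @param variant_id target variant.
#' @param mle output of [fitAllMle()].
#' @param annotations continuous annotation data.frame
#'   (`variant_id` + numeric columns).
#' @param cfg a [KernelConfig-class].
#' @return A [PriorSet-class] with provenance `"conditional:<variant_id>"`.
#' @export
estimateConditionalPrior <- function(variant_id, mle, annotations,
                                     cfg = kernelConfig()) {
  cl <- .cleanMle(mle)
  v <- cl$variants
  annCols <- setdiff(colnames(annotations), "variant_id")
  ann <- as.matrix(annotations[match(v$variant_id, annotations$variant_id),
                               annCols, drop = FALSE])
  ann <- scale(ann)
  ann[, attr(ann, "scaled:scale") == 0] <- 0
  ti <- match(variant_id, v$variant_id)
  if (is.na(ti)) {
    ta <- annotations[match(variant_id, annotations$variant_id), annCols]
    if (anyNA(ta)) stop(sprintf("no annotation for variant '%s'", variant_id))
    target <- (as.numeric(ta) - attr(ann, "scaled:center")) /
      pmax(attr(ann, "scaled:scale"), 1e-12)
  } else {
    target <- ann[ti, ]
  }
  w <- conditionalWeights(target, ann, cfg)$weights
  .fitPriorSet(v, cl$mu_dna, w, sprintf("conditional:%s", variant_id))
}

#' Serialize / restore a PriorSet as JSON
#'
#' @param ps a [PriorSet-class].
#' @param path JSON file path.
#' @return `writePriorSet` returns `path` invisibly; `readPriorSet` returns
#'   a [PriorSet-class].
#' @export
writePriorSet <- function(ps, path) {
  obj <- c(lapply(ps@priors, function(p) list(shape = p@shape,
                                              rate = p@rate)),
           list(provenance = ps@provenance))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePriorSet
#' @export
readPriorSet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(priorSet, c(
    lapply(setNames(.PRIOR_FAMILIES, .PRIOR_FAMILIES), function(nm)
      gammaPrior(obj[[nm]]$shape, obj[[nm]]$rate)),
    list(provenance = obj$provenance)))
}

# shape/rate vectors in the order the C++ code expects
priorVectors <- function(ps) {
  list(shape = vapply(.PRIOR_FAMILIES, function(nm) ps@priors[[nm]]@shape,
                      numeric(1L)),
       rate = vapply(.PRIOR_FAMILIES, function(nm) ps@priors[[nm]]@rate,
                     numeric(1L)))
}
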