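# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Clamp to [-1, 1] before acos(); guards against floating-point overshoot.
clamp_cos <- function(x) pmin(1, pmax(-1, x))

rad2deg <- function(x) x * 180 / pi

# Per-column variance with denominator n (population variance). Both matrices
# entering the joint statistic share a sample count, so the denominator choice
# cancels in the ratio; it matters only in the floored regime.
col_pop_vars <- function(x) {
  mu <- colMeans(x)
  colMeans(x * x) - mu * mu
}

# Orthonormal basis of a uniformly random r-dimensional subspace of R^n.
random_orthonormal <- function(n, r) {
  if (r == 0L) {
    return(matrix(0, n, 0L))
  }
  qr.Q(qr(matrix(stats::rnorm(n * r), n, r)))[, seq_len(r), drop = FALSE]
}

# Deterministic sign convention for singular vectors: the largest-magnitude
# entry of each column of v is made positive and u is flipped to match.
fix_svd_signs <- function(u, v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) {
      v[, j] <- -v[, j]
      if (!is.null(u)) u[, j] <- -u[, j]
    }
  }
  list(u = u, v = v)
}

frobenius_sq <- function(x) sum(x * x)

# ROC curve by threshold sweep over descending scores; tied scores collapse to
# a single operating point so the trapezoid AUC equals the rank statistic with
# ties counted 1/2.
roc_points <- function(scores, y01) {
  stopifnot(length(scores) == length(y01))
  n_pos <- sum(y01 == 1L)
  n_neg <- sum(y01 == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC is undefined when only one class is present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y01[ord]
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[keep] / n_pos)
  fpr <- c(0, fp[keep] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(
    thresholds = c(Inf, s[keep]),
    tpr = tpr,
    fpr = fpr,
    auc = auc
  )
}

roc_auc <- function(scores, y01) roc_points(scores, y01)$auc

# Coerce labels to 0/1 against a positive class. If positive_class is NULL a
# sensible default is taken (TRUE, 1, or the last factor level).
binarize_labels <- function(labels, positive_class = NULL) {
  if (is.logical(labels)) {
    pos <- positive_class %||% TRUE
  } else if (is.factor(labels)) {
    pos <- positive_class %||% levels(labels)[nlevels(labels)]
  } else if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    pos <- positive_class %||% 1
  } else {
    if (is.null(positive_class)) {
      stop("positive_class must be given for labels of type ", class(labels)[1])
    }
    pos <- positive_class
  }
  y <- as.integer(labels == pos)
  if (anyNA(y)) stop("labels contain missing values")
  list(y01 = y, positive_class = pos)
}
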