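# Elastic-net response modeling on decomposed expression matrices.
#
# Penalty parametrization note: the mixing weight between the lasso and ridge
# penalties is called l1_ratio here (glmnet's `alpha`), and the overall
# penalty strength is called alpha (glmnet's `lambda`), matching the common
# drug-response modeling convention.

mc_splits <- function(n, n_splits, train_frac, stratify_by, seed) {
  set.seed(seed)
  if (is.null(stratify_by)) {
    strata <- factor(rep("all", n))
  } else {
    stopifnot(length(stratify_by) == n)
    strata <- factor(stratify_by)
    small <- names(which(table(strata) < 2))
    if (length(small) > 0) {
      warning("stratification class(es) with < 2 members merged: ",
              paste(small, collapse = ", "))
      levels(strata)[levels(strata) %in% small] <- "(merged)"
    }
  }
  lapply(seq_len(n_splits), function(i) {
    tr <- unlist(lapply(split(seq_len(n), strata), function(ix) {
      k <- max(1L, min(length(ix) - 1L, round(train_frac * length(ix))))
      sample(ix, k)
    }), use.names = FALSE)
    sort(tr)
  })
}

fit_enet_grid <- function(X, y, family, l1_grid, n_alphas, n_splits,
                          train_frac, stratify_by, seed, matrix_tag,
                          score_fun, kind) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) stop("at least 10 samples are required")
  if (is.null(colnames(X))) colnames(X) <- sprintf("g%d", seq_len(ncol(X)))

  # per-l1_ratio penalty path from the full data
  paths <- lapply(l1_grid, function(a) {
    glmnet::glmnet(X, y, family = family, alpha = a, nlambda = n_alphas,
                   standardize = FALSE)$lambda
  })
  splits <- mc_splits(n, n_splits, train_frac, stratify_by, seed)
  scores <- lapply(seq_along(l1_grid), function(j) {
    matrix(NA_real_, n_splits, length(paths[[j]]))
  })
  for (i in seq_len(n_splits)) {
    tr <- splits[[i]]
    te <- setdiff(seq_len(n), tr)
    for (j in seq_along(l1_grid)) {
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = family,
                            alpha = l1_grid[j], lambda = paths[[j]],
                            standardize = FALSE)
      pred <- stats::predict(fit, X[te, , drop = FALSE], s = paths[[j]],
                             type = "link")
      scores[[j]][i, ] <- score_fun(y[te], pred)
    }
  }
  grid <- do.call(rbind, lapply(seq_along(l1_grid), function(j) {
    data.frame(l1_ratio = l1_grid[j], alpha = paths[[j]],
               mean_score = colMeans(scores[[j]], na.rm = TRUE))
  }))
  best <- max(grid$mean_score)
  winners <- grid[grid$mean_score == best, , drop = FALSE]
  winners <- winners[order(-winners$alpha), , drop = FALSE] # sparser first
  sel <- winners[1, ]
  j_sel <- match(sel$l1_ratio, l1_grid)
  final <- glmnet::glmnet(X, y, family = family, alpha = sel$l1_ratio,
                          lambda = paths[[j_sel]], standardize = FALSE)
  co <- stats::coef(final, s = sel$alpha)
  coefs <- stats::setNames(as.numeric(co)[-1], rownames(co)[-1])
  structure(
    list(kind = kind, coefficients = coefs,
         intercept = as.numeric(co)[1],
         alpha = sel$alpha, l1_ratio = sel$l1_ratio,
         cv_mean_score = sel$mean_score, cv_grid = grid,
         matrix_tag = matrix_tag,
         n_splits = n_splits, train_frac = train_frac, seed = seed),
    class = "prediction_model")
}

#' Fit a linear elastic-net response model with Monte-Carlo cross-validation
#'
#' Penalty-strength values are taken from the elastic-net regularization path
#' computed at each mixing ratio; the full grid is searched exhaustively over
#' repeated random train/test splits, scoring held-out R-squared. The winner
#' (best mean test R-squared, ties broken toward the larger, sparser penalty)
#' is refit on all samples.
#'
#' @param X Samples x genes predictor matrix (an original, joint or
#'   individual matrix).
#' @param y Continuous response (e.g. drug-response AUC), one value per row.
#' @param l1_grid Mixing ratios between lasso (1) and ridge (0); default
#'   `c(0.1, 0.5, 0.7, 0.9, 0.95, 1)`.
#' @param n_alphas Number of penalty-strength values per mixing ratio
#'   (default 100).
#' @param n_splits Number of random train/test iterations (default 20).
#' @param train_frac Fraction of samples used for training (default 0.67).
#' @param stratify_by Optional per-sample labels (e.g. tissue of origin) used
#'   to stratify the splits; classes with fewer than two members are merged
#'   with a warning.
#' @param seed Integer seed controlling the splits.
#' @param matrix_tag Free-text tag recording which matrix the model was
#'   trained on (`"original"`, `"joint"`, `"individual"`).
#' @return A `prediction_model` with named `coefficients` over genes,
#'   `intercept`, selected `alpha` (penalty strength) and `l1_ratio`,
#'   `cv_mean_score`, and the full cross-validation grid.
#' @export
fit_elastic_net_response <- function(X, y,
                                     l1_grid = c(0.1, 0.5, 0.7, 0.9, 0.95, 1),
                                     n_alphas = 100, n_splits = 20,
                                     train_frac = 0.67, stratify_by = NULL,
                                     seed = 1, matrix_tag = "original") {
  y <- as.numeric(y)
  if (stats::var(y) == 0) stop("degenerate response: y is constant")
  r2 <- function(y_te, pred) {
    sst <- sum((y_te - mean(y_te))^2)
    1 - colSums((y_te - pred)^2) / sst
  }
  fit_enet_grid(X, y, "gaussian", l1_grid, n_alphas, n_splits, train_frac,
                stratify_by, seed, matrix_tag, r2, "linear_elastic_net")
}

#' Fit a logistic elastic-net classifier with Monte-Carlo cross-validation
#'
#' Identical grid-search procedure to [fit_elastic_net_response()] with a
#' binomial likelihood; held-out performance is scored by area under the ROC
#' curve (R-squared is undefined for classification). Splits are stratified
#' by class so both labels appear in every test set whenever possible.
#'
#' @inheritParams fit_elastic_net_response
#' @param y Binary labels (0/1, logical, or two-level factor).
#' @param positive_class Label treated as positive; defaults as in
#'   [predict_and_roc()].
#' @return A `prediction_model` of kind `logistic_elastic_net`.
#' @export
fit_elastic_net_classifier <- function(X, y,
                                       l1_grid = c(0.1, 0.5, 0.7, 0.9, 0.95, 1),
                                       n_alphas = 100, n_splits = 20,
                                       train_frac = 0.67, stratify_by = NULL,
                                       seed = 1, matrix_tag = "original",
                                       positive_class = NULL) {
  bl <- binarize_labels(y, positive_class)
  y01 <- bl$y01
  if (min(table(y01)) < 3) stop("each class needs at least 3 samples")
  strat <- if (is.null(stratify_by)) factor(y01) else
    interaction(factor(y01), factor(stratify_by), drop = TRUE)
  auc_score <- function(y_te, pred) {
    if (length(unique(y_te)) < 2L) return(rep(NA_real_, ncol(pred)))
    apply(pred, 2L, function(s) roc_auc(s, y_te))
  }
  mod <- fit_enet_grid(X, y01, "binomial", l1_grid, n_alphas, n_splits,
                       train_frac, strat, seed, matrix_tag, auc_score,
                       "logistic_elastic_net")
  mod$positive_class <- bl$positive_class
  mod
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf(
    "prediction_model (%s, %s matrix): l1_ratio %.2f, alpha %.4g, cv score %.3f, %d nonzero coefficients\n",
    x$kind, x$matrix_tag, x$l1_ratio, x$alpha, x$cv_mean_score,
    sum(x$coefficients != 0)))
  invisible(x)
}

model_scores <- function(model, X_test) {
  X_test <- as.matrix(X_test)
  genes <- names(model$coefficients)
  missing <- setdiff(genes, colnames(X_test))
  if (length(missing) > 0) {
    warning(length(missing),
            " model gene(s) absent from test matrix; imputed as 0")
  }
  common <- intersect(genes, colnames(X_test))
  drop(X_test[, common, drop = FALSE] %*% model$coefficients[common]) +
    model$intercept
}

#' Score a model on external data and compute its ROC curve
#'
#' Continuous scores come from the model's linear predictor (genes missing
#' from the test matrix contribute zero, with a warning). The ROC curve is
#' built by a threshold sweep; tied scores collapse to one operating point so
#' the trapezoid AUC equals the Mann-Whitney rank statistic with ties
#' counted one half.
#'
#' @param model A `prediction_model`.
#' @param X_test Samples x genes test matrix on the model's gene labels.
#' @param labels Binary outcome per test sample (e.g. pathological complete
#'   response).
#' @param positive_class Label treated as the positive class; defaults to
#'   `TRUE`/`1`/last factor level, or the class stored in a classifier model.
#' @return A `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `positive_class`, and the per-sample `scores`.
#' @export
predict_and_roc <- function(model, X_test, labels, positive_class = NULL) {
  scores <- model_scores(model, X_test)
  bl <- binarize_labels(labels, positive_class %||% model$positive_class)
  if (length(unique(bl$y01)) < 2L) stop("labels contain a single class")
  rc <- roc_points(scores, bl$y01)
  structure(c(rc, list(positive_class = bl$positive_class, scores = scores)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f (%d thresholds, positive class '%s')\n",
              x$auc, length(x$thresholds), format(x$positive_class)))
  invisible(x)
}

#' Bootstrap comparison of two models' ROC-AUCs
#'
#' Resamples the evaluation cohort with replacement, recomputes both AUCs per
#' resample, and reports the one-sided empirical p-value for the claim that
#' score set A outperforms B: the fraction of resamples with
#' `AUC_A - AUC_B < 0`, with exact zero differences counted one half so that
#' identical score sets give p = 0.5. Resamples containing a single outcome
#' class are redrawn.
#'
#' @param scores_a,scores_b Per-sample continuous scores from the two models,
#'   on the same samples.
#' @param labels Binary outcome per sample.
#' @param positive_class Positive class label (see [predict_and_roc()]).
#' @param n_boot Number of bootstrap resamples, default 1000.
#' @param seed Integer seed.
#' @return List with `p_value`, `auc_a`, `auc_b` (observed), `boot_auc_a`,
#'   `boot_auc_b`, `boot_diff` (per-resample distributions).
#' @export
bootstrap_auc_comparison <- function(scores_a, scores_b, labels,
                                     positive_class = NULL, n_boot = 1000,
                                     seed = 1) {
  stopifnot(length(scores_a) == length(scores_b))
  bl <- binarize_labels(labels, positive_class)
  y <- bl$y01
  stopifnot(length(y) == length(scores_a))
  set.seed(seed)
  n <- length(y)
  aa <- ab <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
    }
    aa[b] <- roc_auc(scores_a[idx], y[idx])
    ab[b] <- roc_auc(scores_b[idx], y[idx])
  }
  list(p_value = mean(aa - ab < 0) + 0.5 * mean(aa == ab),
       auc_a = roc_auc(scores_a, y), auc_b = roc_auc(scores_b, y),
       boot_auc_a = aa, boot_auc_b = ab, boot_diff = aa - ab)
}

#' Median-expression signature score
#'
#' Per-sample median of a gene set's expression values; gene labels are
#' matched after upper-casing, and missing genes are reported.
#'
#' @param block An [expression_block] (or samples x genes matrix).
#' @param gene_set Character vector of gene labels.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(block, gene_set) {
  vals <- if (inherits(block, "expression_block")) block$values else
    as.matrix(block)
  labs <- toupper(colnames(vals))
  idx <- match(unique(toupper(gene_set)), labs)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " signature gene(s) absent from block")
    idx <- idx[!is.na(idx)]
  }
  if (length(idx) == 0L) stop("empty intersection of signature with block")
  apply(vals[, idx, drop = FALSE], 1L, stats::median)
}

#' Compare signature scores between two outcome groups
#'
#' Two-sample t-test (pooled variance by default, Welch optional) of
#' per-sample signature scores split by a binary outcome such as
#' pathological complete response.
#'
#' @param scores Per-sample signature scores.
#' @param groups Two-level grouping labels.
#' @param welch Use the Welch (unequal-variance) test instead of the pooled
#'   test.
#' @return List with `t_statistic`, `p_value`, `group_means`, `method`.
#' @export
compare_signature_groups <- function(scores, groups, welch = FALSE) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("groups must have exactly two levels")
  if (min(table(g)) < 2L) stop("both groups need at least 2 samples")
  tt <- stats::t.test(scores ~ g, var.equal = !welch)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       group_means = stats::setNames(tapply(scores, g, mean), levels(g)),
       method = tt$method)
}

#' Per-gene Spearman correlation with drug response
#'
#' Correlates every gene, in each supplied matrix version (original, joint,
#' individual), with a per-sample drug-response value using tie-corrected
#' Spearman rank correlation. Multiple response values for one sample are
#' collapsed by their median (or mean). P-values use the t approximation on
#' the rank correlation.
#'
#' @param matrices Named list of samples x genes matrices sharing row names
#'   (e.g. `list(original = O, joint = J, individual = I)`).
#' @param response Either a named numeric vector keyed by sample id or a
#'   two-column data.frame (`sample_id`, value), possibly with repeated
#'   samples.
#' @param collapse How to collapse repeated response values per sample.
#' @return Data.frame with columns `matrix`, `gene`, `rho`, `p_value`.
#' @export
drug_response_correlation <- function(matrices, response,
                                      collapse = c("median", "mean")) {
  collapse <- match.arg(collapse)
  stopifnot(is.list(matrices), length(matrices) >= 1,
            !is.null(names(matrices)))
  if (is.data.frame(response)) {
    stopifnot(ncol(response) >= 2)
    agg <- tapply(response[[2]], as.character(response[[1]]),
                  if (collapse == "median") stats::median else mean)
    response <- stats::setNames(as.numeric(agg), names(agg))
  }
  if (is.null(names(response))) stop("response must be keyed by sample id")
  response <- response[!is.na(response)]
  do.call(rbind, lapply(names(matrices), function(nm) {
    m <- as.matrix(matrices[[nm]])
    common <- intersect(rownames(m), names(response))
    if (length(common) < 3L) {
      stop("fewer than 3 samples with response data in matrix '", nm, "'")
    }
    x <- m[common, , drop = FALSE]
    yv <- rank(response[common])
    rx <- apply(x, 2L, rank)
    rho <- suppressWarnings(as.vector(stats::cor(rx, yv)))
    rho[is.na(rho)] <- 0 # constant gene: no association
    n <- length(common)
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    data.frame(matrix = nm, gene = colnames(m), rho = rho, p_value = p,
               row.names = NULL)
  }))
}
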