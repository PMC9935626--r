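#' Per-gene joint statistic
#'
#' The joint behaviour of a gene is summarized by the natural-log ratio of
#' its variance in the joint matrix to its variance in the individual matrix,
#' each floored at `s`:
#' `statistic = log(max(var_J, s) / max(var_I, s))`.
#' Positive values indicate joint (shared) behaviour, negative values
#' cohort-specific behaviour, and the floor suppresses artifacts from
#' low-variance genes: the statistic is exactly zero when both variances are
#' at or below `s`. Variances use denominator n; both matrices share the
#' sample count, so the choice cancels except in the floored regime. A
#' strict mode additionally zeroes the statistic when either variance is at
#' or below the floor.
#'
#' @param J,I Samples x genes joint and individual matrices of one block.
#' @param s Variance floor, default 0.5.
#' @param strict_floor If `TRUE`, the statistic is set to zero whenever
#'   either variance is `<= s` (not only when both are). Default `FALSE`.
#' @return A data.frame with columns `gene`, `var_joint`, `var_individual`,
#'   `statistic`.
#' @export
gene_joint_statistic <- function(J, I, s = 0.5, strict_floor = FALSE) {
  J <- as.matrix(J)
  I <- as.matrix(I)
  if (!identical(dim(J), dim(I))) {
    stop("dimension mismatch: J is ", paste(dim(J), collapse = "x"),
         ", I is ", paste(dim(I), collapse = "x"))
  }
  stopifnot(s > 0)
  vj <- col_pop_vars(J)
  vi <- col_pop_vars(I)
  stat <- log(pmax(vj, s)) - log(pmax(vi, s))
  if (strict_floor) stat[vj <= s | vi <= s] <- 0
  data.frame(gene = colnames(J) %||% sprintf("g%d", seq_along(vj)),
             var_joint = unname(vj), var_individual = unname(vi),
             statistic = unname(stat))
}

#' Permutation null for the joint statistic
#'
#' For each permutation the joint and individual rows of every gene are
#' pooled, shuffled and re-split into two pseudo-matrices of the original
#' sample counts, and the joint statistic is recomputed. One random
#' permutation of the stacked rows is shared across genes per iteration,
#' which preserves gene-gene correlation in the null. Two-tailed p-values
#' use +1 smoothing: `p = (1 + #{|null| >= |observed|}) / (1 + n_perm)`.
#'
#' An alternative scheme, `"label_swap"`, swaps the joint/individual labels
#' of whole gene rows (negating the statistic) instead of pooling values.
#'
#' @param J,I Samples x genes matrices of one block.
#' @param s Variance floor, as in [gene_joint_statistic()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param scheme `"pool_resplit"` (default) or `"label_swap"`.
#' @param strict_floor Passed through to the statistic.
#' @return List with `null` (n_perm x genes matrix of null statistics),
#'   `p_value` (per gene), `observed` (per-gene observed statistics).
#' @export
permutation_null <- function(J, I, s = 0.5, n_perm = 1000, seed = 1,
                             scheme = c("pool_resplit", "label_swap"),
                             strict_floor = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 100)
  J <- as.matrix(J)
  I <- as.matrix(I)
  if (!identical(dim(J), dim(I))) stop("dimension mismatch between J and I")
  n <- nrow(J)
  g <- ncol(J)
  obs <- gene_joint_statistic(J, I, s, strict_floor)$statistic
  set.seed(seed)
  null <- matrix(NA_real_, n_perm, g)
  if (scheme == "pool_resplit") {
    z <- rbind(J, I)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(2L * n)
      vj <- col_pop_vars(z[idx[seq_len(n)], , drop = FALSE])
      vi <- col_pop_vars(z[idx[n + seq_len(n)], , drop = FALSE])
      stat <- log(pmax(vj, s)) - log(pmax(vi, s))
      if (strict_floor) stat[vj <= s | vi <= s] <- 0
      null[b, ] <- stat
    }
  } else {
    for (b in seq_len(n_perm)) {
      flip <- sample(c(-1, 1), g, replace = TRUE)
      null[b, ] <- flip * obs
    }
  }
  exceed <- colSums(abs(null) >=
                      matrix(abs(obs), n_perm, g, byrow = TRUE))
  p <- (1 + exceed) / (1 + n_perm)
  list(null = null, p_value = p, observed = obs)
}

#' SAM-style FDR cutoffs on the joint statistic
#'
#' For a candidate positive cutoff c, the estimated false discovery rate is
#' the median over permutations of the number of null statistics >= c,
#' divided by the number of observed statistics >= c. The positive cutoff
#' returned is the smallest observed value attaining `FDR <= target_fdr`;
#' the negative tail is treated independently by mirroring. When no cutoff
#' attains the target the corresponding cutoff is `+Inf` (or `-Inf`) and no
#' gene is called on that side.
#'
#' @param observed Per-gene observed statistics.
#' @param null Permutation null matrix (n_perm x genes) from
#'   [permutation_null()].
#' @param target_fdr Target false discovery rate in (0, 1).
#' @return List with `positive`, `negative` (cutoffs) and `fdr_table`, a
#'   data.frame of candidate cutoffs with their estimated FDR per tail.
#' @export
fdr_cutoffs <- function(observed, null, target_fdr = 0.05) {
  stopifnot(target_fdr > 0, target_fdr <= 1)
  tail_cutoff <- function(obs, nl) {
    cand <- sort(unique(obs[obs > 0]))
    if (length(cand) == 0L) {
      return(list(cutoff = Inf, table = data.frame(cutoff = numeric(0),
                                                   fdr = numeric(0))))
    }
    n_obs_ge <- length(obs) - findInterval(cand, sort(obs), left.open = TRUE)
    counts <- apply(nl, 1L, function(row) {
      length(row) - findInterval(cand, sort(row), left.open = TRUE)
    })
    counts <- matrix(counts, nrow = length(cand)) # candidates x permutations
    med_null <- apply(counts, 1L, stats::median)
    fdr <- med_null / n_obs_ge
    ok <- which(fdr <= target_fdr)
    cutoff <- if (length(ok) == 0L) Inf else cand[min(ok)]
    list(cutoff = cutoff, table = data.frame(cutoff = cand, fdr = fdr))
  }
  pos <- tail_cutoff(observed, null)
  neg <- tail_cutoff(-observed, -null)
  tab <- rbind(
    if (nrow(pos$table)) cbind(pos$table, tail = "positive"),
    if (nrow(neg$table)) cbind(transform(neg$table, cutoff = -cutoff),
                               tail = "negative"))
  list(positive = pos$cutoff, negative = -neg$cutoff, fdr_table = tab)
}

#' Full per-gene joint-statistic table for one block
#'
#' Convenience wrapper chaining [gene_joint_statistic()],
#' [permutation_null()] and [fdr_cutoffs()]: per-gene statistics, two-tailed
#' permutation p-values, tail-specific FDR cutoffs and significance flags.
#'
#' @param J,I Samples x genes joint and individual matrices of one block.
#' @param s Variance floor, default 0.5.
#' @param n_perm Permutations, default 1000.
#' @param target_fdr Target FDR, default 0.05.
#' @param seed Integer seed.
#' @param scheme,strict_floor Passed to [permutation_null()].
#' @return A `joint_stat_table`: data.frame with columns `gene`, `var_joint`,
#'   `var_individual`, `statistic`, `p_value`, `significant_joint`,
#'   `significant_individual`; attributes `fdr_cutoff_pos`,
#'   `fdr_cutoff_neg`, `s`, `n_permutations`, `target_fdr`, `seed`.
#' @export
joint_stat_table <- function(J, I, s = 0.5, n_perm = 1000, target_fdr = 0.05,
                             seed = 1,
                             scheme = c("pool_resplit", "label_swap"),
                             strict_floor = FALSE) {
  scheme <- match.arg(scheme)
  tab <- gene_joint_statistic(J, I, s, strict_floor)
  pn <- permutation_null(J, I, s, n_perm, seed, scheme, strict_floor)
  cut <- fdr_cutoffs(tab$statistic, pn$null, target_fdr)
  tab$p_value <- pn$p_value
  tab$significant_joint <- tab$statistic >= cut$positive
  tab$significant_individual <- tab$statistic <= cut$negative
  attr(tab, "fdr_cutoff_pos") <- cut$positive
  attr(tab, "fdr_cutoff_neg") <- cut$negative
  attr(tab, "s") <- s
  attr(tab, "n_permutations") <- n_perm
  attr(tab, "target_fdr") <- target_fdr
  attr(tab, "seed") <- seed
  class(tab) <- c("joint_stat_table", "data.frame")
  tab
}

#' Classify genes by cross-block joint behaviour
#'
#' A gene significantly joint in both blocks is fully joint-behaving
#' (translatable between cohorts); significant in only one block indicates
#' partial, unidirectional joint behaviour; significant in neither means the
#' gene's variation does not translate.
#'
#' @param table_a,table_b `joint_stat_table`s for the two blocks, on shared
#'   gene labels (post homolog mapping).
#' @return Data.frame with columns `gene`, `class` (factor: `fully_joint`,
#'   `unidirectional_A`, `unidirectional_B`, `not_joint`), `statistic_a`,
#'   `statistic_b`.
#' @export
classify_translatability <- function(table_a, table_b) {
  if (!setequal(table_a$gene, table_b$gene)) {
    stop("gene label mismatch between the two tables")
  }
  b <- table_b[match(table_a$gene, table_b$gene), ]
  cls <- ifelse(table_a$significant_joint & b$significant_joint, "fully_joint",
         ifelse(table_a$significant_joint, "unidirectional_A",
         ifelse(b$significant_joint, "unidirectional_B", "not_joint")))
  data.frame(gene = table_a$gene,
             class = factor(cls, levels = c("fully_joint", "unidirectional_A",
                                            "unidirectional_B", "not_joint")),
             statistic_a = table_a$statistic,
             statistic_b = b$statistic)
}

#' @export
print.joint_stat_table <- function(x, ...) {
  cat(sprintf(
    "joint_stat_table: %d genes; cutoffs [%.3f, %.3f] at FDR %.2g; %d joint, %d individual\n",
    nrow(x), attr(x, "fdr_cutoff_neg"), attr(x, "fdr_cutoff_pos"),
    attr(x, "target_fdr"), sum(x$significant_joint),
    sum(x$significant_individual)))
  invisible(x)
}
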