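#' Half-split bootstrap curve for choosing the initial signal rank
#'
#' Samples of one block are randomly divided into two equal halves (an odd
#' sample is dropped at random) and the joint decomposition is run between the
#' two halves at every candidate rank, both halves receiving the same rank.
#' Genuine signal directions reappear in both halves and register as joint;
#' once the rank grows past the signal, the extra directions are
#' half-specific noise and register as individual. Percentages of total sum
#' of squares explained by joint and individual structure are pooled over
#' both halves; residual variation is everything not explained by either.
#' The procedure is repeated `n_reps` times.
#'
#' @param block An [expression_block] (centered or not; halves are centered
#'   internally).
#' @param rank_grid Ascending candidate ranks; the maximum must not exceed
#'   `floor(n_samples / 2)`.
#' @param n_reps Number of random splits, default 10.
#' @param seed Integer seed.
#' @param config An [ajive_config()]; the random-angle cutoff is computed
#'   once per candidate rank and reused across repetitions.
#' @return A `rank_curve`: `rank_grid`, matrices `pct_joint`,
#'   `pct_individual`, `pct_residual` (ranks x reps), `n_reps`, `seed` and
#'   `selected_rank` from [select_rank()].
#' @export
half_split_curve <- function(block, rank_grid, n_reps = 10, seed = 1,
                             config = ajive_config()) {
  stopifnot(inherits(block, "expression_block"), n_reps >= 1)
  rank_grid <- sort(as.integer(rank_grid))
  x <- block$values
  n <- nrow(x)
  half <- floor(n / 2)
  if (max(rank_grid) > half) {
    stop("rank grid infeasible: max rank ", max(rank_grid),
         " exceeds half the sample count (", half, ")")
  }
  n_genes <- ncol(x)
  if (max(rank_grid) > min(half, n_genes)) stop("rank grid exceeds gene count")

  cutoffs <- vapply(rank_grid, function(r) {
    random_angle_cutoff(n_genes, r, r, config$n_random,
                        config$angle_percentile, config$seed + r)
  }, numeric(1))

  nr <- length(rank_grid)
  pj <- pi_ <- matrix(NA_real_, nr, n_reps,
                      dimnames = list(rank_grid, NULL))
  set.seed(seed)
  r_max <- max(rank_grid)
  for (rep in seq_len(n_reps)) {
    idx <- sample.int(n, 2 * half)
    h1 <- scale(x[idx[seq_len(half)], , drop = FALSE], scale = FALSE)
    h2 <- scale(x[idx[half + seq_len(half)], , drop = FALSE], scale = FALSE)
    sv1 <- svd(h1, nu = r_max, nv = r_max)
    sv2 <- svd(h2, nu = r_max, nv = r_max)
    tot <- frobenius_sq(h1) + frobenius_sq(h2)
    for (k in seq_along(rank_grid)) {
      r <- rank_grid[k]
      trunc_decomp <- function(sv, nm) {
        s <- fix_svd_signs(sv$u[, seq_len(r), drop = FALSE],
                           sv$v[, seq_len(r), drop = FALSE])
        structure(list(u = s$u, d = sv$d[seq_len(r)], v = s$v, r = r,
                       block_name = nm),
                  class = "initial_decomposition")
      }
      d1 <- trunc_decomp(sv1, "half1")
      d2 <- trunc_decomp(sv2, "half2")
      pa <- principal_angles(list(d1, d2))
      jr <- select_joint_rank(pa$phi, cutoffs[k])
      basis <- if (jr > 0L) {
        qr.Q(qr(pa$v_m[, seq_len(jr), drop = FALSE]))
      } else {
        matrix(0, n_genes, 0L)
      }
      p1 <- reproject(h1, d1, basis)
      p2 <- reproject(h2, d2, basis)
      pj[k, rep] <- 100 * (frobenius_sq(p1$J) + frobenius_sq(p2$J)) / tot
      pi_[k, rep] <- 100 * (frobenius_sq(p1$I) + frobenius_sq(p2$I)) / tot
    }
  }
  curve <- structure(
    list(rank_grid = rank_grid, pct_joint = pj, pct_individual = pi_,
         pct_residual = 100 - pj - pi_, n_reps = n_reps, seed = seed,
         selected_rank = NA_integer_),
    class = "rank_curve")
  curve$selected_rank <- select_rank(curve)
  curve
}

#' Select the initial signal rank from a half-split curve
#'
#' Operationalizes "joint variation maximized while individual variation
#' minimized" as the rank maximizing `mean(pct_joint) - mean(pct_individual)`
#' over repetitions, with ties broken toward the smaller rank. The raw curve
#' is retained so an elbow criterion can be applied by eye instead.
#'
#' @param curve A `rank_curve` from [half_split_curve()].
#' @return The selected rank (integer).
#' @export
select_rank <- function(curve) {
  stopifnot(inherits(curve, "rank_curve"))
  score <- rowMeans(curve$pct_joint) - rowMeans(curve$pct_individual)
  curve$rank_grid[which.max(score)]
}

#' @export
print.rank_curve <- function(x, ...) {
  cat(sprintf("rank_curve: %d candidate ranks x %d repetitions; selected %d\n",
              length(x$rank_grid), x$n_reps, x$selected_rank))
  df <- data.frame(rank = x$rank_grid,
                   mean_pct_joint = rowMeans(x$pct_joint),
                   mean_pct_individual = rowMeans(x$pct_individual),
                   mean_pct_residual = rowMeans(x$pct_residual))
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}
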