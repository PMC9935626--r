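#' Configuration for the joint decomposition
#'
#' @param angle_percentile Percentile (in percent) of the random smallest
#'   principal-angle distribution used as the joint cutoff; default 5.
#' @param n_random Number of random subspace pairs drawn for the cutoff.
#' @param seed Seed for the random-angle draw.
#' @param angle_cutoff Optional fixed cutoff in degrees; when supplied the
#'   random draw is skipped (useful for cutoffs computed externally, e.g.
#'   a Wedin-bound refinement).
#' @return A list of class `ajive_config`.
#' @export
ajive_config <- function(angle_percentile = 5, n_random = 1000, seed = 1,
                         angle_cutoff = NULL) {
  stopifnot(angle_percentile > 0, angle_percentile < 100, n_random >= 1)
  structure(list(angle_percentile = angle_percentile, n_random = n_random,
                 seed = as.integer(seed), angle_cutoff = angle_cutoff),
            class = "ajive_config")
}

#' Initial truncated SVD of one centered block
#'
#' First stage of the decomposition: a rank-`r` truncated SVD `X = U D V'`
#' removing residual variation below the initial signal rank. Right singular
#' vectors (columns of `V`) are metagenes over the shared gene axis. A
#' deterministic sign convention (largest-magnitude entry of each metagene
#' positive) makes results reproducible across platforms.
#'
#' @param block A centered [expression_block].
#' @param r Initial signal rank, at most `min(n_samples, n_genes)`.
#' @return An `initial_decomposition` with fields `u` (samples x r), `d`
#'   (positive, non-increasing), `v` (genes x r), `r` and `block_name`. If the
#'   numerical rank of the matrix is below `r` a warning is issued and the
#'   decomposition is truncated.
#' @export
initial_svd <- function(block, r) {
  x <- if (inherits(block, "expression_block")) block$values else as.matrix(block)
  name <- if (inherits(block, "expression_block")) block$block_name else "block"
  r <- as.integer(r)
  if (r < 1L || r > min(dim(x))) {
    stop("r must be between 1 and min(n_samples, n_genes) = ", min(dim(x)))
  }
  sv <- svd(x, nu = r, nv = r)
  d <- sv$d[seq_len(r)]
  tol <- max(dim(x)) * .Machine$double.eps * sv$d[1]
  r_eff <- sum(d > tol)
  if (r_eff < r) {
    warning("requested rank ", r, " exceeds numerical rank ", r_eff,
            "; truncating")
    r <- r_eff
  }
  signs <- fix_svd_signs(sv$u[, seq_len(r), drop = FALSE],
                         sv$v[, seq_len(r), drop = FALSE])
  structure(list(u = signs$u, d = d[seq_len(r)], v = signs$v, r = r,
                 block_name = name),
            class = "initial_decomposition")
}

#' @export
print.initial_decomposition <- function(x, ...) {
  cat(sprintf("initial_decomposition '%s': rank %d, top singular value %.4g\n",
              x$block_name, x$r, x$d[1]))
  invisible(x)
}

#' Principal angles between two blocks' metagene subspaces
#'
#' Stacks the transposed right singular vectors of the two initial
#' decompositions into `M = rbind(t(V1), t(V2))` and takes its SVD. The
#' singular values `sigma_M` give the principal angles between the two
#' metagene subspaces, `phi_i = acos(sigma_M_i^2 - 1)`, for
#' `i = 1 .. min(r1, r2)`; arguments to `acos` are clamped to `[-1, 1]`.
#' Angles are returned ascending, in degrees: 0 means a shared (joint)
#' direction, 90 an orthogonal one.
#'
#' @param decomps List of exactly two `initial_decomposition`s sharing the
#'   gene dimension.
#' @return An object of class `principal_angle_analysis` with `sigma_m`,
#'   `phi` (degrees), and `v_m` (gene-space right singular vectors of `M`,
#'   used to build the joint basis). The angle cutoff and joint rank are
#'   filled in by [run_ajive()].
#' @export
principal_angles <- function(decomps) {
  if (length(decomps) != 2L) {
    stop("exactly two blocks are supported; got ", length(decomps))
  }
  v1 <- decomps[[1]]$v
  v2 <- decomps[[2]]$v
  if (nrow(v1) != nrow(v2)) {
    stop("gene-dimension mismatch: ", nrow(v1), " vs ", nrow(v2))
  }
  m <- rbind(t(v1), t(v2))
  k <- min(decomps[[1]]$r, decomps[[2]]$r)
  sv <- svd(m)
  sigma <- sv$d
  phi <- rad2deg(acos(clamp_cos(sigma[seq_len(k)]^2 - 1)))
  v_m <- fix_svd_signs(NULL, sv$v[, seq_len(k), drop = FALSE])$v
  structure(list(sigma_m = sigma, phi = phi, v_m = v_m,
                 ranks = c(decomps[[1]]$r, decomps[[2]]$r),
                 angle_cutoff = NULL, joint_rank = NULL, joint_basis = NULL),
            class = "principal_angle_analysis")
}

#' @export
print.principal_angle_analysis <- function(x, ...) {
  cat(sprintf("principal_angle_analysis: ranks (%d, %d)\n",
              x$ranks[1], x$ranks[2]))
  cat("  angles (deg):", paste(sprintf("%.2f", utils::head(x$phi, 8)),
                               collapse = ", "),
      if (length(x$phi) > 8) "..." else "", "\n")
  if (!is.null(x$angle_cutoff)) {
    cat(sprintf("  cutoff %.2f deg -> joint rank %d\n",
                x$angle_cutoff, x$joint_rank))
  }
  invisible(x)
}

#' Null distribution cutoff for joint angles
#'
#' Draws `n_draws` pairs of uniformly random `r_1`- and `r_2`-dimensional
#' subspaces of gene space, records the smallest principal angle of each
#' pair, and returns the requested percentile of that distribution. Observed
#' angles below this cutoff are smaller than random subspaces typically
#' achieve and are labelled joint.
#'
#' @param n_genes Ambient gene-space dimension.
#' @param r_1,r_2 Subspace dimensions (the initial signal ranks).
#' @param n_draws Monte-Carlo draws, default 1000.
#' @param percentile Percentile in percent, default 5.
#' @param seed Integer seed.
#' @return Cutoff in degrees.
#' @export
random_angle_cutoff <- function(n_genes, r_1, r_2, n_draws = 1000,
                                percentile = 5, seed = 1) {
  stopifnot(r_1 >= 1, r_2 >= 1, r_1 <= n_genes, r_2 <= n_genes)
  # the distribution is symmetric in (r_1, r_2); order them so the draw is too
  r <- sort(c(r_1, r_2))
  r_1 <- r[1]
  r_2 <- r[2]
  set.seed(seed)
  mins <- vapply(seq_len(n_draws), function(i) {
    q1 <- random_orthonormal(n_genes, r_1)
    q2 <- random_orthonormal(n_genes, r_2)
    smax <- svd(crossprod(q1, q2), nu = 0, nv = 0)$d[1]
    rad2deg(acos(clamp_cos(smax)))
  }, numeric(1))
  stats::quantile(mins, percentile / 100, names = FALSE, type = 7)
}

#' Count joint ranks below the angle cutoff
#'
#' @param phi Ascending principal angles in degrees.
#' @param cutoff Cutoff in degrees.
#' @return Number of angles strictly below the cutoff.
#' @export
select_joint_rank <- function(phi, cutoff) {
  sum(phi < cutoff)
}

#' Reproject one block through the joint gene-space basis
#'
#' Splits a centered block into `J = X P_J` (projection of the original data
#' onto the joint gene subspace), `I = X_hat (Id - P_J)` (the rank-r signal
#' approximation minus its joint part) and `E = X - J - I`. With `P_J` an
#' orthogonal projector this yields exact Frobenius orthogonality between the
#' three components and the additive sum-of-squares decomposition
#' `|X|^2 = |J|^2 + |I|^2 + |E|^2`.
#'
#' @param block Centered [expression_block] (or bare matrix).
#' @param decomp The block's `initial_decomposition`.
#' @param joint_basis Orthonormal genes x joint_rank matrix (possibly 0
#'   columns).
#' @return List with matrices `J`, `I`, `E` (samples x genes, named like the
#'   input).
#' @export
reproject <- function(block, decomp, joint_basis) {
  x <- if (inherits(block, "expression_block")) block$values else as.matrix(block)
  if (nrow(joint_basis) != ncol(x)) {
    stop("joint basis rows (", nrow(joint_basis),
         ") do not match gene count (", ncol(x), ")")
  }
  xhat <- decomp$u %*% (decomp$d * t(decomp$v))
  if (ncol(joint_basis) == 0L) {
    j <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
    i <- xhat
  } else {
    j <- (x %*% joint_basis) %*% t(joint_basis)
    i <- xhat - (xhat %*% joint_basis) %*% t(joint_basis)
  }
  e <- x - j - i
  dimnames(j) <- dimnames(i) <- dimnames(e) <- dimnames(x)
  list(J = j, I = i, E = e)
}

#' Run the full two-block joint decomposition
#'
#' Pipeline: initial truncated SVD per block, principal-angle analysis of the
#' stacked metagene matrices, random-subspace angle cutoff, joint-rank
#' selection, joint gene-space basis (top right singular vectors of the
#' stacked matrix, re-orthonormalized), and reprojection of each block into
#' joint, individual and residual matrices.
#'
#' @param block_a,block_b Gene-aligned, centered [expression_block]s.
#' @param r_a,r_b Initial signal ranks (see [half_split_curve()] for a
#'   data-driven choice).
#' @param config An [ajive_config()].
#' @return An `ajive_result` with per-block `J`, `I`, `E` matrices, the
#'   `principal_angle_analysis` (including cutoff, joint rank, joint basis),
#'   the per-block initial decompositions, a block-level variation summary
#'   (percent joint / individual / residual sum of squares) and the config.
#' @export
run_ajive <- function(block_a, block_b, r_a, r_b, config = ajive_config()) {
  stopifnot(inherits(block_a, "expression_block"),
            inherits(block_b, "expression_block"))
  if (!identical(gene_labels(block_a), gene_labels(block_b))) {
    stop("blocks are not gene-aligned; run intersect_and_align() first")
  }
  for (b in list(block_a, block_b)) {
    if (!b$centered) {
      stop("block '", b$block_name,
           "' is not centered; run mean_center_genes() first")
    }
  }
  d1 <- initial_svd(block_a, r_a)
  d2 <- initial_svd(block_b, r_b)
  pa <- principal_angles(list(d1, d2))
  n_genes <- ncol(block_a$values)
  cutoff <- config$angle_cutoff %||%
    random_angle_cutoff(n_genes, d1$r, d2$r, config$n_random,
                        config$angle_percentile, config$seed)
  jr <- select_joint_rank(pa$phi, cutoff)
  basis <- if (jr > 0L) {
    q <- qr.Q(qr(pa$v_m[, seq_len(jr), drop = FALSE]))
    fix_svd_signs(NULL, q)$v
  } else {
    matrix(0, n_genes, 0L)
  }
  rownames(basis) <- gene_labels(block_a)
  pa$angle_cutoff <- cutoff
  pa$joint_rank <- jr
  pa$joint_basis <- basis

  rp <- list(reproject(block_a, d1, basis), reproject(block_b, d2, basis))
  names(rp) <- c(block_a$block_name, block_b$block_name)
  summary <- do.call(rbind, lapply(names(rp), function(nm) {
    p <- rp[[nm]]
    tot <- frobenius_sq(p$J) + frobenius_sq(p$I) + frobenius_sq(p$E)
    data.frame(block = nm,
               pct_joint = 100 * frobenius_sq(p$J) / tot,
               pct_individual = 100 * frobenius_sq(p$I) / tot,
               pct_residual = 100 * frobenius_sq(p$E) / tot)
  }))
  structure(
    list(blocks = names(rp),
         J = lapply(rp, `[[`, "J"),
         I = lapply(rp, `[[`, "I"),
         E = lapply(rp, `[[`, "E"),
         angles = pa,
         initial = stats::setNames(list(d1, d2), names(rp)),
         variation_summary = summary,
         config = config),
    class = "ajive_result")
}

#' @export
print.ajive_result <- function(x, ...) {
  cat(sprintf("ajive_result: blocks %s; joint rank %d (cutoff %.2f deg)\n",
              paste(x$blocks, collapse = " + "),
              x$angles$joint_rank, x$angles$angle_cutoff))
  print(x$variation_summary, row.names = FALSE, digits = 4)
  invisible(x)
}
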