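#' Simulate a pair of expression blocks with planted joint structure
#'
#' Generates two sample x gene blocks sharing a gene axis, each built as
#' `scores_joint %*% t(joint_basis) + scores_indiv %*% t(individual_basis) +
#' noise`. Genes are partitioned into classes: joint genes carry the shared
#' low-rank signal, individual genes carry block-specific signal, null genes
#' carry only isotropic Gaussian noise. The block-specific bases have disjoint
#' gene support from the joint basis and from each other, so they are exactly
#' orthogonal. The generator targets the post-normalization log scale the
#' decomposition consumes; it does not emulate count-level sequencing noise.
#'
#' @param n_samples_a,n_samples_b Samples per block.
#' @param n_genes Number of genes (shared axis).
#' @param joint_rank Planted joint rank (0 allowed).
#' @param individual_ranks Integer pair: block-specific ranks.
#' @param signal_sd Standard deviation of the i.i.d. normal scores on every
#'   signal component.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed; fixed seed gives bitwise-identical output.
#' @param gene_fractions Named fractions of genes assigned to the `joint`,
#'   `individual_a` and `individual_b` classes (remainder is `null`). A class
#'   whose planted rank is 0 receives no genes.
#' @return A list with elements `block_a`, `block_b` (uncentered
#'   [expression_block]s) and `truth`, a `synthetic_truth` object recording
#'   the planted ranks, orthonormal bases, per-gene classes, score matrices
#'   and response coefficients used by [simulate_response()].
#' @export
simulate_joint_blocks <- function(n_samples_a, n_samples_b, n_genes,
                                  joint_rank,
                                  individual_ranks = c(0L, 0L),
                                  signal_sd = 1, noise_sd = 1, seed = 1,
                                  gene_fractions = c(joint = 0.1,
                                                     individual_a = 0.1,
                                                     individual_b = 0.1)) {
  stopifnot(length(individual_ranks) == 2L, joint_rank >= 0,
            all(individual_ranks >= 0), signal_sd > 0, noise_sd >= 0)
  if (joint_rank + max(individual_ranks) >=
        min(n_samples_a, n_samples_b, n_genes)) {
    stop("infeasible ranks: joint_rank + max individual rank must be below ",
         "min(n_samples_a, n_samples_b, n_genes)")
  }
  set.seed(seed)
  fr <- gene_fractions[c("joint", "individual_a", "individual_b")]
  n_class <- function(rank, frac) {
    if (rank == 0L) 0L else max(as.integer(ceiling(frac * n_genes)), rank)
  }
  nj <- n_class(joint_rank, fr[["joint"]])
  na <- n_class(individual_ranks[1], fr[["individual_a"]])
  nb <- n_class(individual_ranks[2], fr[["individual_b"]])
  if (nj + na + nb > n_genes) stop("gene class fractions exceed the gene count")
  idx <- sample.int(n_genes)
  ij <- idx[seq_len(nj)]
  ia <- idx[nj + seq_len(na)]
  ib <- idx[nj + na + seq_len(nb)]
  classes <- rep("null", n_genes)
  classes[ij] <- "joint"
  classes[ia] <- "individual_A"
  classes[ib] <- "individual_B"

  support_basis <- function(rows, rank) {
    basis <- matrix(0, n_genes, rank)
    if (rank > 0L) basis[rows, ] <- random_orthonormal(length(rows), rank)
    basis
  }
  w <- support_basis(ij, joint_rank)
  basis_a <- support_basis(ia, individual_ranks[1])
  basis_b <- support_basis(ib, individual_ranks[2])

  draw_scores <- function(n, r) matrix(stats::rnorm(n * r, sd = signal_sd), n, r)
  sj_a <- draw_scores(n_samples_a, joint_rank)
  sj_b <- draw_scores(n_samples_b, joint_rank)
  si_a <- draw_scores(n_samples_a, individual_ranks[1])
  si_b <- draw_scores(n_samples_b, individual_ranks[2])
  beta <- if (joint_rank > 0L) stats::rnorm(joint_rank) else numeric(0)

  assemble <- function(sj, si, basis_i, n) {
    sj %*% t(w) + si %*% t(basis_i) +
      matrix(stats::rnorm(n * n_genes, sd = noise_sd), n, n_genes)
  }
  xa <- assemble(sj_a, si_a, basis_a, n_samples_a)
  xb <- assemble(sj_b, si_b, basis_b, n_samples_b)
  genes <- sprintf("G%04d", seq_len(n_genes))
  dimnames(xa) <- list(sprintf("A%03d", seq_len(n_samples_a)), genes)
  dimnames(xb) <- list(sprintf("B%03d", seq_len(n_samples_b)), genes)

  truth <- structure(
    list(joint_rank = as.integer(joint_rank),
         individual_ranks = as.integer(individual_ranks),
         joint_basis_true = `rownames<-`(w, genes),
         individual_bases_true = list(A = `rownames<-`(basis_a, genes),
                                      B = `rownames<-`(basis_b, genes)),
         gene_classes = stats::setNames(
           factor(classes,
                  levels = c("joint", "individual_A", "individual_B", "null")),
           genes),
         scores_joint = list(A = sj_a, B = sj_b),
         scores_individual = list(A = si_a, B = si_b),
         response_coefficients = beta,
         signal_sd = signal_sd, noise_sd = noise_sd, seed = seed),
    class = "synthetic_truth")

  list(block_a = expression_block(xa, block_name = "A"),
       block_b = expression_block(xb, block_name = "B"),
       truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: joint rank %d, individual ranks (%d, %d), %d genes (%s)\n",
    x$joint_rank, x$individual_ranks[1], x$individual_ranks[2],
    length(x$gene_classes),
    paste(sprintf("%s: %d", levels(x$gene_classes),
                  tabulate(x$gene_classes, nbins = 4)), collapse = ", ")))
  invisible(x)
}

#' Simulate a response variable linear in joint metagene scores
#'
#' Continuous responses are `scores_joint %*% response_coefficients` plus
#' Gaussian noise; binary responses are Bernoulli draws from the logistic
#' transform of the same (noisy) linear predictor, emulating outcomes such as
#' drug-response AUC or pathological complete response.
#'
#' @param truth A `synthetic_truth` from [simulate_joint_blocks()].
#' @param scores_joint Joint score matrix of one simulated block, e.g.
#'   `truth$scores_joint$A`.
#' @param noise_sd Standard deviation of noise added to the linear predictor.
#' @param seed Integer seed.
#' @param kind `"continuous"` or `"binary"`.
#' @return Numeric (or 0/1 integer) response vector, one value per row of
#'   `scores_joint`.
#' @export
simulate_response <- function(truth, scores_joint, noise_sd = 0.5, seed = 1,
                              kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  stopifnot(inherits(truth, "synthetic_truth"))
  scores_joint <- as.matrix(scores_joint)
  if (ncol(scores_joint) != truth$joint_rank) {
    stop("dimension mismatch: scores_joint has ", ncol(scores_joint),
         " columns but the planted joint rank is ", truth$joint_rank)
  }
  set.seed(seed)
  eta <- if (truth$joint_rank > 0L) {
    drop(scores_joint %*% truth$response_coefficients)
  } else {
    rep(0, nrow(scores_joint))
  }
  eta <- eta + stats::rnorm(nrow(scores_joint), sd = noise_sd)
  if (kind == "continuous") eta else stats::rbinom(length(eta), 1L, stats::plogis(eta))
}

#' Simulate a translation scenario with adversarial individual variation
#'
#' Builds a training block whose block-specific (individual) scores are
#' positively correlated with the response during training, plus an external
#' evaluation cohort in which the same individual direction is
#' anti-correlated with outcome. The response itself depends only on the
#' joint metagene scores, so a model trained on the joint matrix should
#' transfer while a model trained on the original matrix, which can exploit
#' the confounded individual genes, degrades out of sample. This emulates
#' cell-line nuisance variation that misleads drug-response models applied to
#' clinical cohorts.
#'
#' @param n_train,n_partner,n_test Samples in the training block, the partner
#'   block used only for integration, and the external test cohort.
#' @param n_genes,joint_rank,individual_ranks,signal_sd,noise_sd,seed As in
#'   [simulate_joint_blocks()].
#' @param confound_strength Correlation strength between the first individual
#'   score and the response's linear predictor (positive in training,
#'   negative in the test cohort).
#' @param response_noise_sd Noise on the continuous training response.
#' @return List with `block_train`, `block_partner` (uncentered blocks),
#'   `y_train` (continuous), `x_test` (centered matrix), `y_test` (0/1),
#'   and `truth`.
#' @export
simulate_translation_scenario <- function(n_train = 100, n_partner = 100,
                                          n_test = 150, n_genes = 200,
                                          joint_rank = 2,
                                          individual_ranks = c(2L, 2L),
                                          signal_sd = 1, noise_sd = 0.3,
                                          confound_strength = 1,
                                          response_noise_sd = 0.25,
                                          seed = 1) {
  sim <- simulate_joint_blocks(n_train, n_partner, n_genes, joint_rank,
                               individual_ranks, signal_sd, noise_sd,
                               seed = seed)
  truth <- sim$truth
  set.seed(seed + 1L)
  w <- truth$joint_basis_true
  basis_i <- truth$individual_bases_true$A
  beta <- truth$response_coefficients
  eta_tr <- drop(truth$scores_joint$A %*% beta)
  eta_sc <- scale(eta_tr)[, 1]
  # confound the first individual score with the response in training
  si <- truth$scores_individual$A
  si[, 1] <- signal_sd * (confound_strength * eta_sc +
                            sqrt(max(1 - confound_strength^2, 0.01)) *
                              stats::rnorm(n_train))
  x_train <- truth$scores_joint$A %*% t(w) + si %*% t(basis_i) +
    matrix(stats::rnorm(n_train * n_genes, sd = noise_sd), n_train, n_genes)
  dimnames(x_train) <- dimnames(sim$block_a$values)
  y_train <- eta_tr + stats::rnorm(n_train, sd = response_noise_sd)

  # external cohort: same joint structure, individual direction flipped
  sj_t <- matrix(stats::rnorm(n_test * joint_rank, sd = signal_sd),
                 n_test, joint_rank)
  eta_t <- drop(sj_t %*% beta)
  eta_t_sc <- scale(eta_t)[, 1]
  si_t <- matrix(stats::rnorm(n_test * ncol(basis_i), sd = signal_sd),
                 n_test, ncol(basis_i))
  si_t[, 1] <- signal_sd * (-confound_strength * eta_t_sc +
                              sqrt(max(1 - confound_strength^2, 0.01)) *
                                stats::rnorm(n_test))
  x_test <- sj_t %*% t(w) + si_t %*% t(basis_i) +
    matrix(stats::rnorm(n_test * n_genes, sd = noise_sd), n_test, n_genes)
  dimnames(x_test) <- list(sprintf("T%03d", seq_len(n_test)),
                           colnames(x_train))
  x_test <- scale(x_test, scale = FALSE)
  y_test <- stats::rbinom(n_test, 1L, stats::plogis(2 * eta_t_sc))

  list(block_train = expression_block(x_train, block_name = "train"),
       block_partner = sim$block_b,
       y_train = y_train, x_test = x_test, y_test = y_test, truth = truth)
}
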