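#' Per-sample split of variation into joint, individual and residual
#'
#' For each sample, the percent of its sum of squares captured by the joint
#' and individual matrices: `pct_joint = 100 |J[i,]|^2 / |X[i,]|^2` and
#' likewise for the individual rows. Residual variation is defined as any
#' variation not explained by joint or individual structure,
#' `100 - pct_joint - pct_individual`. The joint/individual ratio summarizes
#' how well a sample is represented by the partner cohort: high joint and low
#' individual percent means the sample's expression structure is shared.
#'
#' @param result An `ajive_result` from [run_ajive()].
#' @param block_name Which block to profile.
#' @param groups Optional per-sample grouping labels (e.g. tissue), either a
#'   vector of length n_samples or the name of a column in the block's
#'   `sample_meta` used when the result was built from blocks carrying
#'   metadata.
#' @return A `variation_profile` data.frame with columns `sample_id`,
#'   `pct_joint`, `pct_individual`, `pct_residual`,
#'   `joint_individual_ratio` and optionally `group`. Zero-variance samples
#'   get `NA` percents and a warning.
#' @export
sample_variation_profile <- function(result, block_name, groups = NULL) {
  stopifnot(inherits(result, "ajive_result"))
  if (!block_name %in% result$blocks) {
    stop("block '", block_name, "' not in result (",
         paste(result$blocks, collapse = ", "), ")")
  }
  j <- result$J[[block_name]]
  i <- result$I[[block_name]]
  e <- result$E[[block_name]]
  x <- j + i + e
  tot <- rowSums(x * x)
  zero <- tot <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance sample(s); percents set to NA")
    tot[zero] <- NA_real_
  }
  pj <- 100 * rowSums(j * j) / tot
  pi_ <- 100 * rowSums(i * i) / tot
  out <- data.frame(sample_id = rownames(x),
                    pct_joint = pj,
                    pct_individual = pi_,
                    pct_residual = 100 - pj - pi_,
                    joint_individual_ratio = pj / pi_,
                    row.names = NULL)
  if (!is.null(groups)) {
    if (length(groups) != nrow(out)) {
      stop("groups must have one entry per sample")
    }
    out$group <- groups
  }
  class(out) <- c("variation_profile", "data.frame")
  out
}

#' Partition a gene set's variance across decomposition components
#'
#' Sums per-gene variances (across samples) within the original matrix
#' `O = J + I + E`, the joint matrix and the individual matrix, restricted to
#' a gene set, and reports the fraction of the original variance persisting
#' into each component. Used to check whether, say, a molecular-subtype
#' signature is shared across cohorts while an immune signature is
#' cohort-specific.
#'
#' @param result An `ajive_result`.
#' @param block_name Which block to evaluate.
#' @param gene_set Character vector of gene labels; genes absent from the
#'   block are dropped with a warning.
#' @param set_name Optional label stored with the output.
#' @return A `gene_set_partition` list: `gene_set`, `n_genes_used`,
#'   `var_original`, `var_joint`, `var_individual`, `frac_joint`,
#'   `frac_individual`.
#' @export
gene_set_partition <- function(result, block_name, gene_set,
                               set_name = "gene_set") {
  stopifnot(inherits(result, "ajive_result"))
  j <- result$J[[block_name]]
  if (is.null(j)) stop("block '", block_name, "' not in result")
  i <- result$I[[block_name]]
  o <- j + i + result$E[[block_name]]
  present <- intersect(toupper(gene_set), toupper(colnames(o)))
  missing <- setdiff(toupper(gene_set), toupper(colnames(o)))
  if (length(missing) > 0) {
    warning(length(missing), " gene(s) of '", set_name,
            "' absent from block: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  if (length(present) == 0L) stop("empty intersection of gene set with block")
  idx <- match(present, toupper(colnames(o)))
  vo <- sum(col_pop_vars(o[, idx, drop = FALSE]))
  vj <- sum(col_pop_vars(j[, idx, drop = FALSE]))
  vi <- sum(col_pop_vars(i[, idx, drop = FALSE]))
  structure(list(gene_set = set_name, n_genes_used = length(present),
                 var_original = vo, var_joint = vj, var_individual = vi,
                 frac_joint = vj / vo, frac_individual = vi / vo),
            class = "gene_set_partition")
}

#' @export
print.gene_set_partition <- function(x, ...) {
  cat(sprintf(
    "gene_set_partition '%s' (%d genes): %.1f%% joint, %.1f%% individual\n",
    x$gene_set, x$n_genes_used, 100 * x$frac_joint, 100 * x$frac_individual))
  invisible(x)
}
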