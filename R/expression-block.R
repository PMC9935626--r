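#' Construct an expression block
#'
#' An expression block holds one cohort's expression matrix in the package's
#' internal orientation, samples in rows and genes in columns, together with
#' optional per-sample metadata. Genes form the shared axis along which two
#' cohorts are later integrated, so gene labels must be unique after
#' upper-casing.
#'
#' @param values Numeric matrix, samples x genes, with row names (sample ids)
#'   and column names (gene labels). Log-scale expression is expected by the
#'   decomposition but not enforced here.
#' @param sample_meta Optional data.frame of per-sample annotations (tissue,
#'   subtype, response ...). Row order must match `rownames(values)`; a
#'   `sample_id` column is used for alignment when present.
#' @param centered Logical; `TRUE` declares every gene column has mean zero.
#'   Verified at construction when set.
#' @param block_name Short label used in printed output and results.
#'
#' @return An object of class `expression_block`.
#' @export
expression_block <- function(values, sample_meta = NULL, centered = FALSE,
                             block_name = "block") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix (samples x genes)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry sample ids as rownames and gene labels as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  up <- toupper(colnames(values))
  if (anyDuplicated(up)) {
    dup <- unique(up[duplicated(up)])
    stop("duplicate gene labels after upper-casing: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if ("sample_id" %in% names(sample_meta)) {
      idx <- match(rownames(values), sample_meta$sample_id)
      if (anyNA(idx)) stop("sample_meta is missing entries for some samples")
      sample_meta <- sample_meta[idx, , drop = FALSE]
    } else if (nrow(sample_meta) != nrow(values)) {
      stop("sample_meta must have one row per sample")
    }
    rownames(sample_meta) <- rownames(values)
  }
  if (isTRUE(centered)) {
    mx <- max(abs(colMeans(values)))
    if (mx > 1e-8) {
      stop("centered = TRUE but gene column means deviate from 0 (max ",
           format(mx), ")")
    }
  }
  structure(
    list(values = values, sample_meta = sample_meta,
         centered = isTRUE(centered), block_name = block_name),
    class = "expression_block"
  )
}

#' @export
print.expression_block <- function(x, ...) {
  cat(sprintf(
    "expression_block '%s': %d samples x %d genes%s%s\n",
    x$block_name, nrow(x$values), ncol(x$values),
    if (x$centered) ", gene-centered" else "",
    if (!is.null(x$sample_meta))
      sprintf(", metadata: %s", paste(names(x$sample_meta), collapse = ", "))
    else ""
  ))
  invisible(x)
}

#' @rdname expression_block
#' @param block An `expression_block`.
#' @export
gene_labels <- function(block) colnames(block$values)

#' @rdname expression_block
#' @export
sample_ids <- function(block) rownames(block$values)
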