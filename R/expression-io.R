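#' Read an expression matrix from a tab-separated file
#'
#' Expects one header row of ids and one leading label column. On-disk
#' matrices may be stored either way round; the internal orientation is
#' always samples x genes so that right singular vectors of the decomposition
#' are metagenes.
#'
#' @param path Path to a TSV file.
#' @param orientation `"genes_as_rows"` (the common convention for expression
#'   matrices, the default) or `"samples_as_rows"`.
#' @param block_name Label for the resulting block; defaults to the file name.
#' @return An [expression_block].
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_as_rows",
                                                   "samples_as_rows"),
                                   block_name = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, fill = FALSE)
  if (nrow(dt) == 0L || ncol(dt) < 2L) {
    stop("no samples: file has an empty data section")
  }
  labels <- as.character(dt[[1]])
  mat <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric cell in expression matrix")
  rownames(mat) <- labels
  if (orientation == "genes_as_rows") mat <- t(mat)
  up <- toupper(colnames(mat))
  if (anyDuplicated(up)) {
    stop("duplicate gene labels after upper-casing: ",
         paste(unique(up[duplicated(up)]), collapse = ", "))
  }
  expression_block(mat, block_name = block_name %||% basename(path))
}

#' Write an expression block to a tab-separated file
#'
#' @param block An [expression_block].
#' @param path Output path.
#' @param orientation Orientation for the file on disk.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(block, path,
                                    orientation = c("genes_as_rows",
                                                    "samples_as_rows")) {
  orientation <- match.arg(orientation)
  mat <- block$values
  if (orientation == "genes_as_rows") mat <- t(mat)
  out <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  names(out)[1] <- ""
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Upper-quartile normalize and log-transform raw expression
#'
#' Scales each sample by `target / UQ`, where `UQ` is the 75th percentile of
#' that sample's nonzero values (linear interpolation), then applies
#' `log2(x + pseudo)`. This removes per-sample sequencing-depth scale:
#' proportional samples map to identical vectors.
#'
#' @param block An [expression_block] of non-negative raw quantifications.
#' @param target Scale the upper quartiles are brought to. Default: the
#'   geometric mean of the per-sample upper quartiles, which keeps the output
#'   on the scale of the data.
#' @param pseudo Pseudo-count added before the log, default 1.
#' @return An [expression_block] of log2 normalized values.
#' @export
upper_quartile_log_normalize <- function(block, target = NULL, pseudo = 1) {
  vals <- block$values
  if (any(vals < 0)) stop("negative input value; raw quantifications expected")
  stopifnot(pseudo > 0)
  uq <- apply(vals, 1L, function(v) {
    nz <- v[v > 0]
    if (length(nz) == 0L) return(NA_real_)
    stats::quantile(nz, 0.75, names = FALSE, type = 7)
  })
  if (anyNA(uq)) {
    stop("all-zero sample(s): ",
         paste(rownames(vals)[is.na(uq)], collapse = ", "))
  }
  if (is.null(target)) target <- exp(mean(log(uq)))
  stopifnot(target > 0)
  scaled <- vals * (target / uq)
  out <- log2(scaled + pseudo)
  expression_block(out, sample_meta = block$sample_meta,
                   block_name = block$block_name)
}

#' Intersect gene sets across blocks and align gene order
#'
#' Restricts every block to the genes present in all blocks, in the gene order
#' of the first block, and optionally removes unexpressed genes. Sample sets
#' are untouched.
#'
#' @param blocks List of at least two [expression_block]s.
#' @param zero_filter Removal rule for unexpressed genes: `"any_block"`
#'   (default) drops a gene that is zero in every sample of at least one
#'   block, the strictest reading; `"all_blocks"` drops it only when zero
#'   everywhere in every block; `"none"` disables the filter.
#' @return List of aligned [expression_block]s, same length and order as the
#'   input.
#' @export
intersect_and_align <- function(blocks,
                                zero_filter = c("any_block", "all_blocks",
                                                "none")) {
  zero_filter <- match.arg(zero_filter)
  stopifnot(length(blocks) >= 2L)
  sets <- lapply(blocks, gene_labels)
  common <- Reduce(intersect, sets)
  common <- sets[[1]][sets[[1]] %in% common] # first block's order
  if (length(common) == 0L) stop("empty gene intersection across blocks")
  aligned <- lapply(blocks, function(b) b$values[, common, drop = FALSE])
  if (zero_filter != "none") {
    zero_by_block <- vapply(aligned, function(m) colSums(m != 0) == 0,
                            logical(length(common)))
    zero_by_block <- matrix(zero_by_block, nrow = length(common))
    drop <- if (zero_filter == "any_block") {
      rowSums(zero_by_block) > 0
    } else {
      rowSums(zero_by_block) == length(blocks)
    }
    if (all(drop)) stop("empty gene intersection after zero filtering")
    common <- common[!drop]
    aligned <- lapply(aligned, function(m) m[, common, drop = FALSE])
  }
  mapply(function(b, m) {
    expression_block(m, sample_meta = b$sample_meta, centered = FALSE,
                     block_name = b$block_name)
  }, blocks, aligned, SIMPLIFY = FALSE)
}

#' Mean-center every gene column
#'
#' The decomposition operates on gene-centered data; run this after
#' normalization and gene alignment. Idempotent.
#'
#' @param block An [expression_block].
#' @return The centered [expression_block] with its `centered` flag set.
#' @export
mean_center_genes <- function(block) {
  vals <- sweep(block$values, 2L, colMeans(block$values))
  expression_block(vals, sample_meta = block$sample_meta, centered = TRUE,
                   block_name = block$block_name)
}

#' Parse a Jackson Laboratory mouse-human homology report
#'
#' Reads the tabular `HOM_MouseHumanSequence.rpt` layout: rows carry a
#' homology-class key (`DB Class Key`), an organism name and a gene symbol.
#' Within each class, every symbol of `organism` is paired with the first
#' human symbol listed; classes without a human entry are dropped. Symbols
#' are upper-cased.
#'
#' @param path Path to the report.
#' @param organism Source organism name as written in the file, default
#'   `"mouse, laboratory"`.
#' @return An object of class `homolog_map` with fields `pairs` (named
#'   character vector, source symbol -> human symbol) and `source_organism`.
#' @export
parse_homolog_map <- function(path, organism = "mouse, laboratory") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, fill = FALSE)
  needed <- c("DB Class Key", "Common Organism Name", "Symbol")
  if (!all(needed %in% names(dt))) {
    stop("malformed header: expected columns ",
         paste(needed, collapse = ", "))
  }
  orgs <- unique(dt[["Common Organism Name"]])
  if (!organism %in% orgs) {
    stop("unknown organism '", organism, "'; file contains: ",
         paste(orgs, collapse = "; "))
  }
  key <- dt[["DB Class Key"]]
  org <- dt[["Common Organism Name"]]
  sym <- toupper(dt[["Symbol"]])
  human_rows <- grepl("^human$", org, ignore.case = TRUE)
  src_rows <- org == organism
  # first human symbol per class, in file order
  hk <- key[human_rows]
  hs <- sym[human_rows]
  first_human <- hs[!duplicated(hk)]
  names(first_human) <- hk[!duplicated(hk)]
  src_key <- as.character(key[src_rows])
  src_sym <- sym[src_rows]
  target <- first_human[src_key]
  keep <- !is.na(target)
  pairs <- stats::setNames(unname(target[keep]), src_sym[keep])
  if (anyDuplicated(names(pairs))) {
    dup <- unique(names(pairs)[duplicated(names(pairs))])
    message("homolog map: ", length(dup),
            " source symbol(s) in multiple classes; keeping first occurrence")
    pairs <- pairs[!duplicated(names(pairs))]
  }
  structure(list(pairs = pairs, source_organism = organism),
            class = "homolog_map")
}

#' @export
print.homolog_map <- function(x, ...) {
  cat(sprintf("homolog_map: %d %s -> human symbol pairs\n",
              length(x$pairs), x$source_organism))
  invisible(x)
}

#' Rename a block's genes to human symbols via a homolog map
#'
#' Gene labels are upper-cased; labels found in the map are renamed to their
#' human symbol, all others are retained under the upper-cased label. When two
#' source genes collide on one human symbol, the gene with the higher variance
#' across samples is kept and the drop is reported.
#'
#' @param block An [expression_block] (typically mouse).
#' @param map A `homolog_map` from [parse_homolog_map()].
#' @return An [expression_block] on human symbols.
#' @export
apply_homolog_map <- function(block, map) {
  stopifnot(inherits(map, "homolog_map"))
  vals <- block$values
  labs <- toupper(colnames(vals))
  hit <- labs %in% names(map$pairs)
  labs[hit] <- unname(map$pairs[labs[hit]])
  if (anyDuplicated(labs)) {
    v <- col_pop_vars(vals)
    ord <- order(-v) # highest variance first within each collision group
    keep_first <- !duplicated(labs[ord])
    keep <- sort(ord[keep_first])
    dropped <- colnames(vals)[setdiff(seq_along(labs), keep)]
    message("homolog mapping collisions: dropping lower-variance gene(s) ",
            paste(dropped, collapse = ", "))
    vals <- vals[, keep, drop = FALSE]
    labs <- labs[keep]
  }
  colnames(vals) <- labs
  expression_block(vals, sample_meta = block$sample_meta,
                   centered = block$centered, block_name = block$block_name)
}
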