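test_that("reading transposes to samples x genes and validates input", {
  mat <- matrix(1:6, nrow = 3, dimnames = list(c("GA", "GB", "GC"),
                                               c("s1", "s2")))
  path <- write_tsv_matrix(mat, withr::local_tempfile(fileext = ".tsv"))
  b <- read_expression_matrix(path, "genes_as_rows")
  expect_equal(dim(b$values), c(2L, 3L))
  expect_equal(gene_labels(b), c("GA", "GB", "GC"))
  expect_equal(unname(b$values["s1", ]), c(1, 2, 3))

  b2 <- read_expression_matrix(path, "samples_as_rows")
  expect_equal(dim(b2$values), c(3L, 2L))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("\ts1\ts2", empty)
  expect_error(read_expression_matrix(empty), "no samples")

  dup <- write_tsv_matrix(
    matrix(1:4, 2, dimnames = list(c("Tp53", "TP53"), c("s1", "s2"))),
    withr::local_tempfile(fileext = ".tsv"))
  expect_error(read_expression_matrix(dup), "duplicate gene")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\ts1\ts2", "GA\t1\tx"), bad)
  expect_error(read_expression_matrix(bad), "non-numeric")

  expect_error(read_expression_matrix("/nonexistent/file.tsv"), "not found")
})

test_that("expression matrices round-trip through disk", {
  b <- toy_block(5, 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(b, path)
  b2 <- read_expression_matrix(path, "genes_as_rows")
  expect_equal(b2$values, b$values, tolerance = 1e-12)
})

test_that("upper-quartile normalization follows the interpolated percentile", {
  # sample [0, 2, 4, 8]: nonzero values (2, 4, 8); the interpolated 75th
  # percentile sits at position 1 + 0.75 * 2 = 2.5, i.e. 4 + 0.5 * (8 - 4) = 6
  x <- matrix(c(0, 2, 4, 8), nrow = 1,
              dimnames = list("s1", paste0("G", 1:4)))
  b <- expression_block(x)
  out <- upper_quartile_log_normalize(b, target = 4, pseudo = 1)
  expect_equal(unname(out$values[1, ]), log2(c(0, 2, 4, 8) * 4 / 6 + 1),
               tolerance = 1e-12)

  # constant sample with target equal to the constant: all values log2(c + 1)
  cb <- expression_block(matrix(5, 2, 3, dimnames = list(c("a", "b"),
                                                         paste0("G", 1:3))))
  outc <- upper_quartile_log_normalize(cb, target = 5, pseudo = 1)
  expect_true(all(abs(outc$values - log2(6)) < 1e-12))
})

test_that("proportional samples become identical after UQ normalization", {
  set.seed(11)
  base <- rexp(40)
  x <- rbind(s1 = base, s2 = 3.7 * base)
  colnames(x) <- paste0("G", 1:40)
  out <- upper_quartile_log_normalize(expression_block(x))
  expect_equal(out$values["s1", ], out$values["s2", ], tolerance = 1e-10)
})

test_that("UQ normalization rejects degenerate input", {
  x <- matrix(c(1, 2, 0, 0), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("G1", "G2")))
  expect_error(upper_quartile_log_normalize(expression_block(x)), "all-zero")
  neg <- matrix(c(-1, 2), 1, dimnames = list("s1", c("G1", "G2")))
  expect_error(upper_quartile_log_normalize(expression_block(neg)),
               "negative")
})

test_that("gene intersection aligns blocks and honours the zero filter", {
  m1 <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  m2 <- matrix(1:6, 2, 3, dimnames = list(c("t1", "t2"), c("B", "C", "D")))
  out <- intersect_and_align(list(expression_block(m1),
                                  expression_block(m2)))
  expect_equal(gene_labels(out[[1]]), c("B", "C"))
  expect_equal(gene_labels(out[[2]]), c("B", "C"))
  expect_equal(sample_ids(out[[1]]), c("s1", "s2"))

  # identical blocks pass through unchanged
  same <- intersect_and_align(list(expression_block(m1),
                                   expression_block(m1)))
  expect_equal(same[[1]]$values, m1)

  # zero filter: gene B all-zero in block 2 only
  m2z <- m2
  m2z[, "B"] <- 0
  strict <- intersect_and_align(list(expression_block(m1),
                                     expression_block(m2z)))
  expect_equal(gene_labels(strict[[1]]), "C")
  lax <- intersect_and_align(list(expression_block(m1),
                                  expression_block(m2z)),
                             zero_filter = "all_blocks")
  expect_equal(gene_labels(lax[[1]]), c("B", "C"))

  disjoint <- expression_block(
    matrix(1:2, 1, 2, dimnames = list("u1", c("X", "Y"))))
  expect_error(intersect_and_align(list(expression_block(m1), disjoint)),
               "empty")
})

test_that("intersection is idempotent and order-independent in its gene set", {
  set.seed(2)
  m1 <- matrix(rpois(30, 5), 3, 10,
               dimnames = list(paste0("s", 1:3), paste0("G", 1:10)))
  m2 <- matrix(rpois(24, 5), 3, 8,
               dimnames = list(paste0("t", 1:3), paste0("G", 3:10)))
  b1 <- expression_block(m1)
  b2 <- expression_block(m2)
  once <- intersect_and_align(list(b1, b2))
  twice <- intersect_and_align(once)
  expect_equal(lapply(twice, `[[`, "values"), lapply(once, `[[`, "values"))
  swapped <- intersect_and_align(list(b2, b1))
  expect_setequal(gene_labels(swapped[[1]]), gene_labels(once[[1]]))
})

test_that("gene centering is exact and idempotent", {
  b <- expression_block(matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
                               dimnames = list(paste0("s", 1:3),
                                               c("G1", "G2"))))
  c1 <- mean_center_genes(b)
  expect_equal(unname(c1$values[, "G1"]), c(-1, 0, 1))
  expect_true(c1$centered)
  c2 <- mean_center_genes(c1)
  expect_equal(c2$values, c1$values, tolerance = 1e-10)

  single <- mean_center_genes(expression_block(
    matrix(c(4, 9), 1, 2, dimnames = list("s1", c("G1", "G2")))))
  expect_true(all(single$values == 0))
})

make_hom_report <- function(lines) {
  path <- withr::local_tempfile(fileext = ".rpt", .local_envir = parent.frame())
  header <- paste("DB Class Key", "Common Organism Name", "NCBI Taxon ID",
                  "Symbol", "EntrezGene ID", sep = "\t")
  writeLines(c(header, lines), path)
  path
}

test_that("the homolog report parser pairs source and human symbols", {
  path <- make_hom_report(c(
    "1\tmouse, laboratory\t10090\tTrp53\t22059",
    "1\thuman\t9606\tTP53\t7157",
    "2\tmouse, laboratory\t10090\tOrphan\t1",
    "3\tmouse, laboratory\t10090\tGeneX\t2",
    "3\thuman\t9606\tHUMX1\t3",
    "3\thuman\t9606\tHUMX2\t4"))
  map <- parse_homolog_map(path)
  expect_equal(unname(map$pairs["TRP53"]), "TP53")
  expect_false("ORPHAN" %in% names(map$pairs)) # no human partner
  expect_equal(unname(map$pairs["GENEX"]), "HUMX1") # first human symbol wins

  expect_error(parse_homolog_map(path, organism = "zebrafish"),
               "unknown organism")
  bad <- withr::local_tempfile(fileext = ".rpt")
  writeLines(c("a\tb", "1\t2"), bad)
  expect_error(parse_homolog_map(bad), "malformed header")
})

test_that("homolog mapping renames, upper-cases and resolves collisions", {
  path <- make_hom_report(c(
    "1\tmouse, laboratory\t10090\tTrp53\t1",
    "1\thuman\t9606\tTP53\t2",
    "2\tmouse, laboratory\t10090\tGm1\t3",
    "2\thuman\t9606\tSHARED\t4",
    "3\tmouse, laboratory\t10090\tGm2\t5",
    "3\thuman\t9606\tSHARED\t6"))
  map <- parse_homolog_map(path)
  vals <- matrix(c(1, 2, 3,
                   2, 4, 30,
                   3, 6, 3), nrow = 3, byrow = TRUE,
                 dimnames = list(paste0("s", 1:3),
                                 c("Erbb2", "TRP53", "GM1")))
  b <- expression_block(vals)
  out <- apply_homolog_map(b, map)
  expect_setequal(gene_labels(out), c("ERBB2", "TP53", "SHARED"))

  # two mouse genes -> one human symbol: higher-variance gene wins
  coll <- matrix(c(1, 0.1, 5, 0.2, 9, 0.3), nrow = 3, byrow = TRUE,
                 dimnames = list(paste0("s", 1:3), c("Gm1", "Gm2")))
  expect_message(out2 <- apply_homolog_map(expression_block(coll), map),
                 "collision")
  expect_equal(gene_labels(out2), "SHARED")
  expect_equal(unname(out2$values[, 1]), c(1, 5, 9)) # the variable gene
})
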