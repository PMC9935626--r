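# Independent oracles and small fixture builders used across the suite.

# AUC by exhaustive pair counting (Mann-Whitney with ties counted 1/2).
auc_by_pairs <- function(scores, y01) {
  pos <- scores[y01 == 1]
  neg <- scores[y01 == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Principal angles (degrees) between the column spans of two orthonormal
# bases, computed directly from the SVD of V1' V2.
direct_principal_angles <- function(v1, v2) {
  s <- svd(crossprod(v1, v2), nu = 0, nv = 0)$d
  sort(acos(pmin(1, pmax(-1, s))) * 180 / pi)
}

# Wrap a bare orthonormal basis as an initial_decomposition for angle tests.
fake_decomp <- function(v, name = "blk") {
  structure(list(u = NULL, d = rep(1, ncol(v)), v = v, r = ncol(v),
                 block_name = name),
            class = "initial_decomposition")
}

rand_orth <- function(n, r) qr.Q(qr(matrix(rnorm(n * r), n, r)))

# signal_sd giving a target spiked-model SNR: leading signal singular value
# over the noise operator norm, signal_sd * sqrt(n) = snr * noise_sd *
# (sqrt(n) + sqrt(g)).
snr_signal_sd <- function(snr, n, g, noise_sd = 1) {
  snr * noise_sd * (sqrt(n) + sqrt(g)) / sqrt(n)
}

# A tiny centered expression block with deterministic values.
toy_block <- function(n = 6, g = 10, seed = 1, name = "toy") {
  set.seed(seed)
  m <- matrix(rnorm(n * g), n, g,
              dimnames = list(sprintf("s%d", 1:n), sprintf("G%d", 1:g)))
  mean_center_genes(expression_block(m, block_name = name))
}

write_tsv_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
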