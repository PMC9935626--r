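test_that("a noiseless linear response is recovered with near-perfect CV R2", {
  set.seed(111)
  X <- matrix(rnorm(60 * 20), 60, 20,
              dimnames = list(NULL, sprintf("G%d", 1:20)))
  y <- 2 * X[, 1] - X[, 5] + 0.5 * X[, 9]
  mod <- fit_elastic_net_response(X, y, l1_grid = c(0.5, 1), n_alphas = 50,
                                  n_splits = 5, seed = 2)
  expect_gte(mod$cv_mean_score, 0.99)
  expect_true(all(c("G1", "G5", "G9") %in%
                    names(which(mod$coefficients != 0))))
  # fixed seed: identical winner and coefficients
  mod2 <- fit_elastic_net_response(X, y, l1_grid = c(0.5, 1), n_alphas = 50,
                                   n_splits = 5, seed = 2)
  expect_identical(mod$coefficients, mod2$coefficients)
  expect_identical(mod$alpha, mod2$alpha)
})

test_that("an unrelated response yields a weak, near-empty model", {
  set.seed(112)
  X <- matrix(rnorm(80 * 30), 80, 30,
              dimnames = list(NULL, sprintf("G%d", 1:30)))
  y <- rnorm(80)
  mod <- fit_elastic_net_response(X, y, l1_grid = c(0.5, 1), n_alphas = 50,
                                  n_splits = 8, seed = 3)
  expect_lte(mod$cv_mean_score, 0.1)
  expect_lte(sum(mod$coefficients != 0), 3)
})

test_that("response fitting validates inputs and stratifies splits", {
  X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("G", 1:5)))
  expect_error(fit_elastic_net_response(X, rep(1, 40)), "constant")
  expect_error(fit_elastic_net_response(X[1:5, ], rnorm(5)), "10 samples")
  tissue <- c("singleton", rep(c("breast", "lung"), length.out = 39))
  expect_warning(
    fit_elastic_net_response(X, rnorm(40), l1_grid = 1, n_alphas = 20,
                             n_splits = 3, stratify_by = tissue, seed = 4),
    "merged")
})

test_that("separable classes give near-perfect CV AUC, permuted labels do not", {
  set.seed(113)
  n <- 60
  X <- matrix(rnorm(n * 15), n, 15,
              dimnames = list(NULL, sprintf("G%d", 1:15)))
  y <- as.integer(X[, 3] > 0)
  mod <- fit_elastic_net_classifier(X, y, l1_grid = c(0.5, 1), n_alphas = 40,
                                    n_splits = 5, seed = 5)
  expect_gte(mod$cv_mean_score, 0.95)
  expect_identical(
    mod$coefficients,
    fit_elastic_net_classifier(X, y, l1_grid = c(0.5, 1), n_alphas = 40,
                               n_splits = 5, seed = 5)$coefficients)

  y_perm <- sample(y)
  mod_null <- fit_elastic_net_classifier(X, y_perm, l1_grid = 1,
                                         n_alphas = 40, n_splits = 5,
                                         seed = 6)
  expect_lt(abs(mod_null$cv_mean_score - 0.5), 0.2)
})

test_that("trapezoid ROC-AUC equals brute-force pair counting", {
  # frozen example: scores (0.9, 0.8, 0.3, 0.1), labels (1, 0, 1, 0) -> 0.75
  mod <- structure(list(coefficients = c(G1 = 1), intercept = 0,
                        kind = "linear_elastic_net",
                        positive_class = NULL),
                   class = "prediction_model")
  X <- matrix(c(0.9, 0.8, 0.3, 0.1), 4, 1, dimnames = list(NULL, "G1"))
  rc <- predict_and_roc(mod, X, labels = c(1, 0, 1, 0), positive_class = 1)
  expect_equal(rc$auc, 0.75)
  expect_equal(rc$auc, auc_by_pairs(X[, 1], c(1, 0, 1, 0)))

  # perfect ranking and constant scores
  Xp <- matrix(c(3, 2, 1, 0), 4, 1, dimnames = list(NULL, "G1"))
  expect_equal(predict_and_roc(mod, Xp, c(1, 1, 0, 0),
                               positive_class = 1)$auc, 1)
  Xc <- matrix(rep(1, 6), 6, 1, dimnames = list(NULL, "G1"))
  expect_equal(predict_and_roc(mod, Xc, c(1, 0, 1, 0, 1, 0),
                               positive_class = 1)$auc, 0.5)

  expect_error(predict_and_roc(mod, Xp, c(1, 1, 1, 1), positive_class = 1),
               "single class")
  # missing model genes are imputed as zero with a warning
  mod2 <- structure(list(coefficients = c(G1 = 1, G2 = 5), intercept = 0,
                         positive_class = NULL),
                    class = "prediction_model")
  expect_warning(rc2 <- predict_and_roc(mod2, Xp, c(1, 1, 0, 0),
                                        positive_class = 1),
                 "imputed")
  expect_equal(rc2$auc, 1)
})

test_that("ROC-AUC matches brute-force pairs on many random score sets", {
  set.seed(114)
  for (k in 1:60) {
    n <- sample(4:25, 1)
    scores <- round(rnorm(n), 1) # coarse rounding forces ties
    y <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    rc <- jdr:::roc_points(scores, y)
    expect_equal(rc$auc, auc_by_pairs(scores, y), tolerance = 1e-12)
    expect_true(all(diff(rc$tpr) >= 0) && all(diff(rc$fpr) >= 0))
  }
  # independent cross-check against pROC on one instance
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(115)
    scores <- round(rnorm(40), 1)
    y <- sample(c(0L, 1L), 40, replace = TRUE)
    proc_auc <- as.numeric(pROC::auc(suppressMessages(
      pROC::roc(y, scores, direction = "<", levels = c(0, 1)))))
    expect_equal(jdr:::roc_auc(scores, y), proc_auc, tolerance = 1e-10)
  }
})

test_that("bootstrap AUC comparison behaves at the identity and under separation", {
  set.seed(116)
  y <- rep(c(0L, 1L), each = 100)
  s_perfect <- y + rnorm(200, sd = 0.05)
  s_random <- rnorm(200)
  same <- bootstrap_auc_comparison(s_random, s_random, y, n_boot = 200,
                                   seed = 7)
  expect_equal(same$p_value, 0.5, tolerance = 1e-8) # diff identically zero
  better <- bootstrap_auc_comparison(s_perfect, s_random, y, n_boot = 1000,
                                     seed = 8)
  expect_lt(better$p_value, 0.01)
  expect_identical(better$boot_diff,
                   bootstrap_auc_comparison(s_perfect, s_random, y,
                                            n_boot = 1000,
                                            seed = 8)$boot_diff)
})

test_that("signature scores are per-sample medians with the usual conventions", {
  vals <- matrix(c(1, 2, 3,
                   4, 6, 8), 2, 3, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("GA", "GB", "GC")))
  b <- expression_block(vals)
  expect_equal(signature_score(b, c("GA", "GB", "GC")),
               c(s1 = 2, s2 = 6))
  expect_equal(signature_score(b, c("ga", "gc")), c(s1 = 2, s2 = 6))
  expect_equal(signature_score(b, "GB"), c(s1 = 2, s2 = 6))
  expect_warning(sc <- signature_score(b, c("GA", "MISSING")), "absent")
  expect_equal(sc, c(s1 = 1, s2 = 4))
  expect_error(suppressWarnings(signature_score(b, "MISSING")), "empty")
})

test_that("group comparison reproduces the closed-form pooled t-test", {
  x <- c(0.01, -0.02, 0.00, 0.01, 1.01, 0.99, 1.00, 1.02)
  g <- rep(c("no", "yes"), each = 4)
  got <- compare_signature_groups(x, g)
  oracle <- t.test(x[g == "no"], x[g == "yes"], var.equal = TRUE)
  expect_equal(got$t_statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, oracle$p.value, tolerance = 1e-12)
  expect_lt(got$p_value, 0.01)

  # swapping labels negates t, preserves p
  swapped <- compare_signature_groups(x, rev(g))
  expect_equal(swapped$t_statistic, -got$t_statistic, tolerance = 1e-10)
  expect_equal(swapped$p_value, got$p_value, tolerance = 1e-12)

  # equal group means: t = 0, p = 1
  eq <- compare_signature_groups(c(1, 2, 3, 1, 2, 3),
                                 rep(c("a", "b"), each = 3))
  expect_equal(eq$t_statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p_value, 1, tolerance = 1e-12)

  expect_error(compare_signature_groups(x, rep("one", 8)), "two levels")
})

test_that("Spearman correlations are exact for monotone genes and null for noise", {
  set.seed(117)
  n <- 60
  auc <- rnorm(n)
  names(auc) <- sprintf("c%d", 1:n)
  X <- cbind(mono = sort(rnorm(n))[rank(auc)],
             anti = -sort(rnorm(n))[rank(auc)],
             noise = rnorm(n))
  rownames(X) <- names(auc)
  out <- drug_response_correlation(list(original = X), auc)
  expect_equal(out$rho[out$gene == "mono"], 1, tolerance = 1e-12)
  expect_equal(out$rho[out$gene == "anti"], -1, tolerance = 1e-12)
  expect_lt(abs(out$rho[out$gene == "noise"]), 0.3)

  # invariance under monotone transforms of either variable
  out2 <- drug_response_correlation(list(original = exp(X)),
                                    rank(auc)^3)
  expect_equal(out2$rho, out$rho, tolerance = 1e-12)

  # tie-corrected rho matches cor(..., method = "spearman")
  Xt <- matrix(round(rnorm(n * 3), 1), n, 3,
               dimnames = list(names(auc), c("a", "b", "c")))
  got <- drug_response_correlation(list(m = Xt), round(auc, 1))
  expect_equal(got$rho,
               unname(apply(Xt, 2, cor, y = round(auc, 1),
                            method = "spearman")),
               tolerance = 1e-12)
})

test_that("duplicate response measurements collapse by median or mean", {
  X <- matrix(rnorm(12), 4, 3,
              dimnames = list(c("c1", "c2", "c3", "c4"), c("a", "b", "c")))
  resp <- data.frame(sample_id = c("c1", "c1", "c2", "c3", "c4", "c4", "c4"),
                     auc = c(4, 6, 5, 2, 1, 1, 100))
  med <- drug_response_correlation(list(m = X), resp)
  mn <- drug_response_correlation(list(m = X), resp, collapse = "mean")
  # per-sample medians (5, 5, 2, 1) and means (5, 5, 2, 34) order c4
  # differently, so the rank correlations must differ
  expect_equal(nrow(med), 3)
  oracle_med <- apply(X, 2, cor, y = c(5, 5, 2, 1), method = "spearman")
  expect_equal(med$rho, unname(oracle_med), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(med$rho, mn$rho)))
  expect_error(drug_response_correlation(list(m = X[1:2, ]),
                                         resp), "fewer than 3")
})
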