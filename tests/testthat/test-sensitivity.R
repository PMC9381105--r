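test_that("quartile assignment: even split, remainder rule, ties,
          direction and monotone invariance", {
  q <- assign_quartiles(stats::setNames(1:8, paste0("s", 1:8)))
  expect_equal(as.character(q), rep(paste0("Q", 1:4), each = 2))

  q5 <- assign_quartiles(stats::setNames(c(5, 3, 1, 2, 4),
                                         paste0("s", 1:5)))
  expect_equal(as.integer(table(q5)), c(2L, 1L, 1L, 1L))  # remainders first

  tied <- assign_quartiles(stats::setNames(rep(1, 8), paste0("s", 1:8)))
  expect_equal(as.integer(table(tied)), rep(2L, 4))
  expect_equal(as.character(tied[c("s1", "s8")]), c("Q1", "Q4"))

  expect_error(assign_quartiles(c(a = 1, b = 2, c = 3)), "at least 4")

  rev <- assign_quartiles(stats::setNames(1:8, paste0("s", 1:8)),
                          direction = "resistant_first")
  expect_equal(as.character(rev), rep(paste0("Q", 4:1), each = 2))

  # invariance under strictly monotone transforms
  set.seed(1)
  v <- stats::setNames(stats::runif(13), paste0("s", 1:13))
  expect_identical(assign_quartiles(v), assign_quartiles(exp(5 * v)))
  expect_identical(assign_quartiles(v), assign_quartiles(rank(v)))
})

test_that("RFE: identity at keep = p, planted-signal recovery, constant
          flagging", {
  set.seed(11)
  n <- 40
  X <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, sprintf("F%02d", 1:20)))
  y <- factor(ifelse(X[, 1] + X[, 2] + X[, 3] > 0, "hi", "lo"))
  expect_equal(sort(rf_recursive_feature_selection(X, y, keep = 20)),
               sort(colnames(X)))
  sel <- rf_recursive_feature_selection(X, y, keep = 6, seed = 2)
  expect_gte(length(intersect(sel, c("F01", "F02", "F03"))), 2L)
  # deterministic under seed
  expect_identical(sel, rf_recursive_feature_selection(X, y, keep = 6,
                                                       seed = 2))
  Xc <- cbind(X, CONST = 1)
  selc <- rf_recursive_feature_selection(Xc, y, keep = 21)
  expect_equal(attr(selc, "flagged_constant"), "CONST")
  expect_error(rf_recursive_feature_selection(X, y, keep = 25), "keep")
})

test_that("fold fitting uses only training rows (no leakage)", {
  set.seed(3)
  X <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(NULL, sprintf("F%02d", 1:10)))
  y <- factor(rep(paste0("Q", 1:4), length.out = 30),
              levels = paste0("Q", 1:4))
  train <- 1:24; holdout <- 25:30
  a <- phosphoresponse:::.fit_predict_fold(X, y, train, holdout,
                                           "rf_classifier", select = 4,
                                           ntree = 100, alpha = 0.5,
                                           seed = 5)
  # garble everything outside the training rows, including labels
  X2 <- X; X2[holdout, ] <- 99 * matrix(rnorm(60), 6, 10)
  y2 <- y; y2[holdout] <- sample(y2[holdout])
  b <- phosphoresponse:::.fit_predict_fold(X2, y2, train, holdout,
                                           "rf_classifier", select = 4,
                                           ntree = 100, alpha = 0.5,
                                           seed = 5)
  expect_identical(a$features, b$features)
})

test_that("cross-validation: separable labels give AUC 1, identical seeds
          identical results, permuted labels hover at 0.5", {
  set.seed(8)
  n <- 100
  # four well-separated clusters in two features: separable classes
  y <- factor(rep(paste0("Q", 1:4), length.out = n),
              levels = paste0("Q", 1:4))
  centers <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10))
  X <- cbind(centers[as.integer(y), ] + rnorm(2 * n, 0, 0.1),
             matrix(rnorm(n * 6), n, 6))
  colnames(X) <- sprintf("F%02d", 1:8)
  cv <- cross_validate_predictor(X, y, "rf_classifier", n_folds = 20,
                                 ntree = 150, seed = 1)
  expect_gte(min(cv$pooled_auc), 0.99)
  cv2 <- cross_validate_predictor(X, y, "rf_classifier", n_folds = 20,
                                  ntree = 150, seed = 1)
  expect_identical(cv$pooled_auc, cv2$pooled_auc)
  expect_identical(cv$fold_auc, cv2$fold_auc)

  set.seed(9)
  yperm <- sample(y)
  cvp <- cross_validate_predictor(X, yperm, "rf_classifier",
                                  n_folds = 50, ntree = 150, seed = 2)
  expect_true(all(cvp$pooled_auc > 0.3 & cvp$pooled_auc < 0.7))
  expect_true(mean(cvp$pooled_auc) > 0.4 && mean(cvp$pooled_auc) < 0.6)
})

test_that("AUC is antisymmetric under score negation", {
  set.seed(5)
  sc <- rnorm(60); lab <- rbinom(60, 1, 0.4) == 1
  a1 <- phosphoresponse:::.auc(sc, lab)
  a2 <- phosphoresponse:::.auc(-sc, lab)
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("elastic-net weights obey the +/-0.1 significance rule exactly", {
  set.seed(21)
  n <- 120
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, sprintf("F%02d", 1:10)))
  lin <- 2 * X[, 1] - 2 * X[, 2]
  y <- assign_quartiles(stats::setNames(lin, paste0("s", 1:n)))
  w <- elastic_net_weights(X, y, quartile = "Q1", seed = 3)
  expect_identical(w$significant, w$weight > 0.1 | w$weight < -0.1)
  expect_true(w$significant[w$analyte == "F01"] ||
                w$significant[w$analyte == "F02"])
  expect_error(
    elastic_net_weights(matrix(1, 20, 3,
                               dimnames = list(NULL, c("a", "b", "c"))),
                        factor(rep(c("Q1", "Q2"), 10))), "degenerate")
})

test_that("genomic baseline validates input and detects deterministic
          genotype-quartile links", {
  set.seed(2)
  n <- 24
  y <- factor(rep(paste0("Q", 1:4), each = 6), levels = paste0("Q", 1:4))
  names(y) <- paste0("s", 1:n)
  geno <- data.frame(sample = names(y),
                     EGFR = as.integer(y == "Q1"),
                     KRAS = rbinom(n, 1, 0.3),
                     PIK3CA = rbinom(n, 1, 0.3))
  expect_error(genomic_baseline(geno[, 1:3], y), "PIK3CA")
  cv <- genomic_baseline(geno, y, n_folds = 25, ntree = 150, seed = 4)
  expect_gte(cv$pooled_auc[["Q1"]], 0.95)
})

test_that("Yates-corrected chi-square enrichment matches hand computation", {
  # [[10,0],[0,10]]: E = 5 everywhere, 4 * (4.5)^2 / 5 = 16.2
  mut <- rep(c(TRUE, FALSE), each = 10)
  qt <- factor(rep(c("Q1", "Q4"), each = 10))
  res <- mutation_quartile_enrichment(mut, qt)
  expect_equal(res$statistic, 16.2)

  balanced <- mutation_quartile_enrichment(
    rep(c(TRUE, TRUE, FALSE, FALSE), 5),
    factor(rep(c("Q1", "Q4", "Q1", "Q4"), 5)))
  expect_equal(balanced$statistic, 0)
  expect_equal(balanced$p_value, 1)

  expect_warning(
    degenerate <- mutation_quartile_enrichment(
      rep(FALSE, 10), factor(rep(c("Q1", "Q4"), 5))), "margin")
  expect_equal(degenerate$p_value, 1)
})
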