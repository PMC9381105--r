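# quartile group sizes with remainders allocated to earlier quartiles
.quartile_sizes <- function(n) {
  base <- n %/% 4L
  rem <- n %% 4L
  base + as.integer(seq_len(4L) <= rem)
}

#' Assign drug-sensitivity quartile labels
#'
#' Samples are sorted ascending by GI50 and split into four contiguous
#' near-equal groups; remainders go to the earlier quartiles (5 samples
#' give sizes 2,1,1,1). By this package's convention Q1 is the most
#' sensitive group (lowest GI50); set `direction = "resistant_first"` to
#' reverse. Ties are broken by stable sample-id order, so labelling is
#' deterministic.
#'
#' @param gi50 Named numeric vector of GI50 values (molar) for one drug;
#'   names are sample ids.
#' @param direction `"sensitive_first"` (Q1 = most sensitive, default) or
#'   `"resistant_first"`.
#' @return Named factor with levels `Q1..Q4`, aligned with `gi50`.
#' @examples
#' assign_quartiles(setNames(1:8, paste0("s", 1:8)))
#' @export
assign_quartiles <- function(gi50,
                             direction = c("sensitive_first",
                                           "resistant_first")) {
  direction <- match.arg(direction)
  v <- gi50[is.finite(gi50)]
  if (length(v) < 4L) stop("need at least 4 samples with finite GI50")
  if (is.null(names(v))) names(v) <- as.character(seq_along(v))
  ord <- order(v, names(v))
  sizes <- .quartile_sizes(length(v))
  labs <- rep(paste0("Q", 1:4), times = sizes)
  if (direction == "resistant_first") labs <- rep(paste0("Q", 4:1),
                                                  times = sizes)
  out <- factor(rep(NA_character_, length(gi50)),
                levels = paste0("Q", 1:4))
  names(out) <- names(gi50)
  out[names(v)[ord]] <- labs
  out
}

#' Build a sensitivity table from GI50 values
#'
#' @param gi50 Data frame `sample, drug, gi50` (molar).
#' @param direction Passed to [assign_quartiles()]; quartiles are assigned
#'   per drug across samples.
#' @return Data frame of class `sensitivity_table` with added `quartile`.
#' @export
sensitivity_table <- function(gi50,
                              direction = "sensitive_first") {
  stopifnot(all(c("sample", "drug", "gi50") %in% names(gi50)))
  gi50$quartile <- factor(NA_character_, levels = paste0("Q", 1:4))
  for (d in unique(gi50$drug)) {
    i <- gi50$drug == d
    gi50$quartile[i] <- assign_quartiles(
      stats::setNames(gi50$gi50[i], gi50$sample[i]), direction = direction)
  }
  class(gi50) <- c("sensitivity_table", "data.frame")
  gi50
}

#' Random-forest recursive feature selection
#'
#' Iteratively fits a random forest on the current feature set, drops the
#' lowest-importance fraction (`drop_frac` of the current set per round,
#' at least one feature), and repeats until `keep` features remain.
#' Importance is mean decrease in node impurity. Constant feature columns
#' are retained in the candidate set but flagged in the
#' `"flagged_constant"` attribute of the result.
#'
#' @param X Numeric feature matrix (rows = conditions, columns = analytes).
#' @param y Response: factor (classification) or numeric (regression).
#' @param keep Target number of features to retain.
#' @param drop_frac Fraction of current features dropped per round.
#' @param ntree Trees per forest.
#' @param seed Integer seed; selection is deterministic given the seed.
#' @return Character vector of `keep` selected feature names, with
#'   attribute `flagged_constant`.
#' @export
rf_recursive_feature_selection <- function(X, y, keep,
                                           drop_frac = 0.2, ntree = 500,
                                           seed = 1L) {
  X <- as.matrix(X)
  if (keep > ncol(X)) stop("keep exceeds the number of features")
  if (nrow(X) != length(y)) stop("X rows must align with y")
  const <- colnames(X)[apply(X, 2L, function(v) length(unique(v)) == 1L)]
  feats <- colnames(X)
  set.seed(seed)
  while (length(feats) > keep) {
    fit <- randomForest::randomForest(X[, feats, drop = FALSE], y,
                                      ntree = ntree, importance = FALSE)
    imp <- randomForest::importance(fit)[, 1L]
    ndrop <- min(max(1L, floor(length(feats) * drop_frac)),
                 length(feats) - keep)
    feats <- feats[!feats %in% names(sort(imp))[seq_len(ndrop)]]
  }
  structure(feats, flagged_constant = intersect(const, feats))
}

# class-balanced fold assignment so every internal CV fold sees every class
.stratified_foldid <- function(y, nfolds) {
  id <- integer(length(y))
  for (cl in levels(y)) {
    i <- which(y == cl)
    id[i] <- rep_len(seq_len(nfolds), length(i))
  }
  id
}

# cv.glmnet with class-stratified folds; falls back to a fixed mid-path
# penalty when a class is too small to cross-validate
.glmnet_cv_fit <- function(X, y, family, alpha) {
  minc <- min(table(y))
  if (minc >= 2L) {
    nf <- max(3L, min(5L, minc))
    fit <- glmnet::cv.glmnet(X, y, family = family, alpha = alpha,
                             foldid = .stratified_foldid(y, nf),
                             standardize = FALSE)
    list(fit = fit, s = "lambda.min")
  } else {
    fit <- glmnet::glmnet(X, y, family = family, alpha = alpha,
                          standardize = FALSE)
    list(fit = fit, s = fit$lambda[ceiling(length(fit$lambda) / 2)])
  }
}

# One-vs-rest ROC AUC; higher score should indicate the positive class.
.auc <- function(scores, positive) {
  if (length(unique(positive)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(
    response = factor(positive, levels = c(FALSE, TRUE)),
    predictor = as.numeric(scores),
    levels = c("FALSE", "TRUE"), direction = "<", quiet = TRUE)))
}

# Feature selection + model fit on the training rows only, prediction on
# the holdout rows. Isolated so leakage (dependence on non-training rows)
# can be asserted directly in tests. Returns per-quartile scores for the
# holdout and the selected feature set.
.fit_predict_fold <- function(X, y, train, holdout, model, select,
                              ntree, alpha, seed) {
  Xtr <- X[train, , drop = FALSE]; ytr <- y[train]
  feats <- colnames(X)
  if (!is.null(select) && select < ncol(X) && model != "elastic_net") {
    yfs <- if (model == "rf_regressor") as.numeric(ytr) else ytr
    feats <- rf_recursive_feature_selection(Xtr, yfs, keep = select,
                                            ntree = ntree, seed = seed)
  }
  Xtr <- Xtr[, feats, drop = FALSE]
  Xho <- X[holdout, feats, drop = FALSE]
  qs <- levels(y)
  scores <- switch(model,
    rf_classifier = {
      fit <- randomForest::randomForest(Xtr, droplevels(ytr), ntree = ntree)
      pr <- stats::predict(fit, Xho, type = "prob")
      out <- matrix(0, nrow(Xho), length(qs), dimnames = list(NULL, qs))
      out[, colnames(pr)] <- pr
      out
    },
    rf_regressor = {
      # train on the numeric quartile index; per-quartile score is the
      # negative distance of the predicted index to that quartile
      fit <- randomForest::randomForest(Xtr, as.numeric(ytr), ntree = ntree)
      pred <- stats::predict(fit, Xho)
      -abs(outer(pred, seq_along(qs), "-"))
    },
    elastic_net = {
      ytr2 <- droplevels(ytr)
      cf <- .glmnet_cv_fit(Xtr, ytr2, "multinomial", alpha)
      pr <- stats::predict(cf$fit, Xho, s = cf$s, type = "response")
      pr <- pr[, , 1L, drop = FALSE]; dim(pr) <- dim(pr)[1:2]
      colnames(pr) <- levels(ytr2)
      out <- matrix(0, nrow(Xho), length(qs), dimnames = list(NULL, qs))
      out[, colnames(pr)] <- pr
      out
    },
    stop("unknown model kind: ", model))
  dimnames(scores) <- list(NULL, qs)
  list(scores = scores, features = feats)
}

# stratified random holdout indices: ~holdout fraction from each class
.stratified_holdout <- function(y, holdout) {
  idx <- unlist(lapply(levels(y), function(q) {
    i <- which(y == q)
    if (length(i) < 2L) return(integer(0))
    sample(i, max(1L, round(length(i) * holdout)))
  }))
  sort(idx)
}

#' Monte-Carlo cross-validated quartile prediction
#'
#' Runs `n_folds` independent random stratified train/validation splits
#' (default 100 splits holding out 15%). In each fold, feature selection
#' (when `select` is given) and model fitting use only the training rows;
#' the held-out rows are scored per quartile. One-vs-rest ROC AUCs are
#' reported both pooled over all out-of-fold predictions (headline) and as
#' per-fold mean and SD. A fold whose holdout lacks both classes for a
#' quartile contributes no per-fold AUC for it; such skips are counted.
#'
#' @param X Numeric feature matrix.
#' @param y Factor of quartile labels (levels `Q1..Q4`), aligned with rows
#'   of `X`.
#' @param model `"rf_classifier"`, `"rf_regressor"` or `"elastic_net"`.
#' @param n_folds Number of random splits.
#' @param holdout Held-out fraction per split.
#' @param select Number of features retained by in-fold random-forest
#'   recursive selection; `NULL` disables selection.
#' @param ntree Trees per random forest.
#' @param alpha Elastic-net mixing parameter.
#' @param seed Integer seed controlling splits and model fits.
#' @return Object of class `cv_result`: `pooled_auc` (named per quartile),
#'   `fold_auc_mean`, `fold_auc_sd`, `n_skipped`, `selected_features`
#'   (list per fold), `pooled` (scores and labels, reusable for pooling
#'   across drugs), plus the settings.
#' @export
cross_validate_predictor <- function(X, y,
                                     model = c("rf_classifier",
                                               "rf_regressor",
                                               "elastic_net"),
                                     n_folds = 100L, holdout = 0.15,
                                     select = NULL, ntree = 500L,
                                     alpha = 0.5, seed = 1L) {
  model <- match.arg(model)
  X <- as.matrix(X)
  y <- factor(y, levels = if (is.factor(y)) levels(y) else sort(unique(y)))
  if (nrow(X) < 10L) stop("need at least 10 labelled rows")
  if (nrow(X) != length(y)) stop("X rows must align with y")
  qs <- levels(y)
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max, n_folds)
  pooled_scores <- NULL; pooled_labels <- factor(character(0), levels = qs)
  fold_auc <- matrix(NA_real_, n_folds, length(qs),
                     dimnames = list(NULL, qs))
  selected <- vector("list", n_folds)
  n_skipped <- stats::setNames(integer(length(qs)), qs)
  for (f in seq_len(n_folds)) {
    set.seed(fold_seeds[f])
    ho <- .stratified_holdout(y, holdout)
    tr <- setdiff(seq_along(y), ho)
    fp <- .fit_predict_fold(X, y, tr, ho, model, select, ntree, alpha,
                            seed = fold_seeds[f])
    selected[[f]] <- fp$features
    pooled_scores <- rbind(pooled_scores, fp$scores)
    pooled_labels <- c(pooled_labels, y[ho])
    for (q in qs) {
      pos <- y[ho] == q
      if (length(unique(pos)) < 2L) {
        n_skipped[q] <- n_skipped[q] + 1L
      } else {
        fold_auc[f, q] <- .auc(fp$scores[, q], pos)
      }
    }
  }
  pooled_auc <- vapply(qs, function(q)
    .auc(pooled_scores[, q], pooled_labels == q), 0)
  structure(
    list(pooled_auc = pooled_auc,
         fold_auc_mean = colMeans(fold_auc, na.rm = TRUE),
         fold_auc_sd = apply(fold_auc, 2L, stats::sd, na.rm = TRUE),
         fold_auc = fold_auc, n_skipped = n_skipped,
         selected_features = selected,
         pooled = list(scores = pooled_scores, labels = pooled_labels),
         model = model, n_folds = n_folds, holdout = holdout,
         select = select, seed = seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Monte-Carlo CV (", x$model, "): ", x$n_folds, " splits, ",
      round(100 * x$holdout), "% holdout\n", sep = "")
  cat("Pooled one-vs-rest AUC:\n")
  print(round(x$pooled_auc, 3))
  cat("Per-fold mean (SD):\n")
  print(paste0(round(x$fold_auc_mean, 3), " (",
               round(x$fold_auc_sd, 3), ")"))
  invisible(x)
}

#' Cohort-level cross-validation pooled across drugs
#'
#' Runs [cross_validate_predictor()] per drug on a perturbation matrix and
#' its matched sensitivity table, then pools out-of-fold predictions over
#' all drugs for cohort-level per-quartile AUCs.
#'
#' @param x A [perturbation_matrix] (cell-line conditions are used).
#' @param sens A [sensitivity_table()] covering the matrix's (sample,
#'   drug) pairs.
#' @param ... Passed to [cross_validate_predictor()].
#' @return List of class `cohort_cv`: `pooled_auc` (across drugs),
#'   `per_drug` (list of `cv_result`).
#' @export
cohort_cv <- function(x, sens, ...) {
  qs <- paste0("Q", 1:4)
  per_drug <- list(); sc <- NULL
  lb <- factor(character(0), levels = qs)
  for (d in unique(sens$drug)) {
    i <- which(x$drug == d & x$sample %in% sens$sample[sens$drug == d])
    y <- sens$quartile[match(paste(x$sample[i], d),
                             paste(sens$sample, sens$drug))]
    cv <- cross_validate_predictor(x$changes[i, , drop = FALSE],
                                   factor(y, levels = qs), ...)
    per_drug[[d]] <- cv
    sc <- rbind(sc, cv$pooled$scores)
    lb <- c(lb, cv$pooled$labels)
  }
  pooled_auc <- vapply(qs, function(q) .auc(sc[, q], lb == q), 0)
  structure(list(pooled_auc = pooled_auc, per_drug = per_drug),
            class = "cohort_cv")
}

#' Elastic-net feature weights with the ±0.1 significance rule
#'
#' Fits a one-vs-rest elastic-net logistic model for one quartile on
#' standardized features (zero mean, unit variance per analyte; required
#' so that the weight threshold is scale-meaningful) with the penalty
#' chosen by internal cross-validation, and flags features whose
#' standardized coefficient exceeds `+threshold` or falls below
#' `-threshold`.
#'
#' @param X Numeric feature matrix.
#' @param y Quartile factor aligned with rows of `X`.
#' @param quartile Which quartile is encoded as the positive class.
#' @param alpha Elastic-net mixing parameter (0 = ridge, 1 = lasso).
#' @param threshold Significance threshold on the absolute weight.
#' @param seed Integer seed (penalty CV folds).
#' @return Data frame of class `feature_weights`: `analyte, weight,
#'   significant`.
#' @export
elastic_net_weights <- function(X, y, quartile = "Q1", alpha = 0.5,
                                threshold = 0.1, seed = 1L) {
  X <- as.matrix(X)
  sds <- apply(X, 2L, stats::sd)
  if (all(sds == 0)) stop("degenerate feature matrix (all constant)")
  Xs <- scale(X[, sds > 0, drop = FALSE])
  yy <- factor(ifelse(y == quartile, quartile, "rest"),
               levels = c("rest", quartile))
  set.seed(seed)
  cf <- .glmnet_cv_fit(Xs, yy, "binomial", alpha)
  co <- as.matrix(stats::coef(cf$fit, s = cf$s))[-1L, 1L]
  w <- stats::setNames(rep(0, ncol(X)), colnames(X))
  w[names(co)] <- co
  out <- data.frame(analyte = names(w), weight = unname(w),
                    significant = unname(w > threshold | w < -threshold),
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_weights", "data.frame")
  out
}

#' Genomic-mutation baseline predictor
#'
#' Runs the identical cross-validation protocol with the binary mutation
#' flags (EGFR, KRAS, PIK3CA) as the only features, enabling the
#' head-to-head comparison of phosphoproteomic against genomic prediction
#' of sensitivity quartiles.
#'
#' @param genotypes Data frame with column `sample` and one 0/1 column per
#'   gene in `genes`.
#' @param y Named quartile factor (names are sample ids).
#' @param genes Required mutation columns.
#' @param ... Passed to [cross_validate_predictor()] (feature selection is
#'   disabled).
#' @return A `cv_result`.
#' @export
genomic_baseline <- function(genotypes, y,
                             genes = c("EGFR", "KRAS", "PIK3CA"), ...) {
  missing <- setdiff(genes, names(genotypes))
  if (length(missing))
    stop("missing gene column(s): ", paste(missing, collapse = ", "))
  G <- as.matrix(genotypes[match(names(y), genotypes$sample), genes])
  if (!all(G %in% c(0, 1))) stop("genotype flags must be 0/1")
  # jitter-free RF on 3 binary features; no feature selection
  cross_validate_predictor(G, y, select = NULL, ...)
}

#' Cohort-level genomic baseline pooled across drugs
#'
#' Runs [genomic_baseline()] per drug and pools the out-of-fold
#' predictions over all drugs, mirroring [cohort_cv()] for the mutation
#' features.
#'
#' @param genotypes Data frame with `sample` and gene flag columns.
#' @param sens A [sensitivity_table()].
#' @param genes Mutation columns used as features.
#' @param ... Passed to [cross_validate_predictor()].
#' @return List of class `cohort_cv`: `pooled_auc`, `per_drug`.
#' @export
cohort_genomic_baseline <- function(genotypes, sens,
                                    genes = c("EGFR", "KRAS", "PIK3CA"),
                                    ...) {
  qs <- paste0("Q", 1:4)
  per_drug <- list(); sc <- NULL
  lb <- factor(character(0), levels = qs)
  for (d in unique(sens$drug)) {
    i <- sens$drug == d
    y <- stats::setNames(factor(sens$quartile[i], levels = qs),
                         sens$sample[i])
    cv <- genomic_baseline(genotypes, y, genes = genes, ...)
    per_drug[[d]] <- cv
    sc <- rbind(sc, cv$pooled$scores)
    lb <- c(lb, cv$pooled$labels)
  }
  pooled_auc <- vapply(qs, function(q) .auc(sc[, q], lb == q), 0)
  structure(list(pooled_auc = pooled_auc, per_drug = per_drug),
            class = "cohort_cv")
}

#' Mutation-by-quartile enrichment test
#'
#' Tests association between a gene's mutation status and expected drug
#' sensitivity by collapsing quartiles into sensitive (Q1 or Q2) versus
#' resistant (Q3 or Q4) halves and applying the chi-square test with Yates
#' continuity correction (1 df, correction term clipped at 0 when
#' |O - E| < 0.5).
#'
#' @param mutated Logical/0-1 vector of mutation flags per sample.
#' @param quartile Quartile factor for the matched drug, aligned with
#'   `mutated`.
#' @return List with `table` (2x2), `statistic`, `p_value`.
#' @export
mutation_quartile_enrichment <- function(mutated, quartile) {
  mutated <- as.logical(mutated)
  sens <- quartile %in% c("Q1", "Q2")
  tab <- table(factor(mutated, levels = c(TRUE, FALSE)),
               factor(sens, levels = c(TRUE, FALSE)),
               dnn = c("mutated", "sensitive"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("a table margin is zero; no association testable")
    return(list(table = tab, statistic = 0, p_value = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(table = tab, statistic = unname(ct$statistic),
       p_value = unname(ct$p.value))
}
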