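# Early classification of learners (L) vs non-learners (notL) from
# handcrafted block-performance features, with a class-weighted
# gradient-boosted tree ensemble and stratified cross-validation.

.sens_features <- paste0("sens_", c("1_to_40", "41_to_80", "81_to_120",
                                    "121_to_160", "161_to_200", "201_to_240"))
.spec_features <- sub("sens", "spec", .sens_features)
.cat_features <- c("TargetConf", "Button")

#' Build the handcrafted feature table
#'
#' One row per participant: block sensitivity and specificity at block size
#' 40 (six blocks each, columns `sens_1_to_40` ... `spec_201_to_240`), the
#' target configuration and response button as categorical predictors, and
#' the binary learner label (`L` = 1, `notL` = 0).
#'
#' @param cohort a `cohort` object, or a list with elements `participants`
#'   and `trials` in the cohort layout.
#' @return data frame of 15 columns (12 numeric + 2 categorical predictors +
#'   `Learner`).
#' @export
build_feature_table <- function(cohort) {
  meta <- cohort$participants
  trials <- cohort$trials
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$participant_id[i]
    tr <- trials[trials$participant_id == id, , drop = FALSE]
    if (nrow(tr) != 240L) {
      stop("participant ", id, " has ", nrow(tr), " trials (240 expected)")
    }
    sens <- block_series(tr, "sensitivity", 40L)
    spec <- block_series(tr, "specificity", 40L)
    stats::setNames(c(sens, spec), c(.sens_features, .spec_features))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$TargetConf <- factor(meta$config, levels = 1:4)
  out$Button <- factor(meta$button, levels = c("left", "right"))
  out$Learner <- as.integer(meta$label == "L")
  rownames(out) <- meta$participant_id
  out
}

#' Nested feature subspaces
#'
#' The prefix subspace `upto_40k` contains the sensitivity and specificity
#' features of blocks 1..k plus the configuration and button; `complete` is
#' the full predictor set. The label is never included.
#'
#' @param name one of `upto_40`, `upto_80`, `upto_120`, `upto_160`,
#'   `upto_200`, `complete`.
#' @return character vector of predictor column names.
#' @export
subspace_features <- function(name = c("upto_40", "upto_80", "upto_120",
                                       "upto_160", "upto_200", "complete")) {
  name <- match.arg(name)
  k <- if (name == "complete") 6L else match(name, paste0("upto_", 40 * 1:5))
  c(.sens_features[seq_len(k)], .spec_features[seq_len(k)], .cat_features)
}

#' Restrict a feature table to a subspace
#'
#' @param table output of [build_feature_table()].
#' @inheritParams subspace_features
#' @return the table restricted to the subspace predictors (label dropped).
#' @export
subspace_select <- function(table, name) {
  feats <- subspace_features(name)
  missing <- setdiff(feats, names(table))
  if (length(missing)) stop("table lacks columns: ", paste(missing, collapse = ", "))
  table[, feats, drop = FALSE]
}

#' Class weights for the skewed label distribution
#'
#' Positive instances (label 1, the learners — here the majority class) get
#' weight `n_negative / n_positive`; negative instances get weight 1. With
#' 62 L and 14 notL this gives the learners weight 14/62 = 0.225.
#'
#' @param labels 0/1 vector.
#' @return numeric weight per instance.
#' @export
compute_weights <- function(labels) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  ifelse(labels == 1L, n0 / n1, 1)
}

#' Balanced accuracy
#'
#' Mean of the classifier's sensitivity (recall on class 1) and specificity
#' (recall on class 0); robust to class imbalance.
#'
#' @param y_true,y_pred 0/1 vectors.
#' @return value in \[0, 1\].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(unique(y_true)) < 2L) {
    stop("balanced accuracy requires both classes in `y_true`")
  }
  tp <- sum(y_true == 1L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  0.5 * tp / (tp + fn) + 0.5 * tn / (tn + fp)
}

# One-hot design matrix for the boosted trees; categorical predictors are
# expanded to full dummy sets so importances can be re-aggregated per factor.
.design_matrix <- function(X) {
  num <- X[, setdiff(names(X), .cat_features), drop = FALSE]
  mats <- list(as.matrix(num))
  for (cf in intersect(.cat_features, names(X))) {
    f <- X[[cf]]
    d <- outer(as.character(f), levels(f), `==`) * 1
    colnames(d) <- paste0(cf, "=", levels(f))
    mats <- c(mats, list(d))
  }
  do.call(cbind, mats)
}

#' Train the gradient-boosted learner classifier
#'
#' Fits a gradient-boosted decision-tree ensemble (xgboost, logistic
#' objective) on the feature table with per-instance class weights.
#' Categorical predictors are one-hot encoded; the split-gain importances of
#' the dummy columns are summed back into their parent feature and
#' normalised to 100.
#'
#' @param X predictor data frame (numeric columns plus the `TargetConf` /
#'   `Button` factors).
#' @param y 0/1 labels.
#' @param weights per-instance weights; defaults to [compute_weights()].
#' @param seed integer seed (results are deterministic given the seed since
#'   no row or column subsampling is used and a single thread is requested).
#' @param nrounds,max_depth,eta boosting hyperparameters.
#' @return object of class `learner_model`: the booster plus feature
#'   metadata and the normalised `importance` data frame.
#' @export
train_classifier <- function(X, y, weights = compute_weights(y), seed = 1L,
                             nrounds = 500L, max_depth = 6L, eta = 0.1) {
  stopifnot(nrow(X) == length(y))
  # only relative weights carry information; normalising to mean 1 makes the
  # fit invariant to rescaling all weights by a constant
  weights <- weights / mean(weights)
  dm <- .design_matrix(X)
  with_seed(seed, {
    booster <- xgboost::xgboost(
      x = dm, y = factor(y, levels = c(0, 1)),
      weights = weights,
      nrounds = nrounds, max_depth = max_depth, learning_rate = eta,
      nthreads = 1L, verbosity = 0L
    )
  })
  imp <- tryCatch(xgboost::xgb.importance(model = booster),
                  error = function(e) NULL)
  gain <- stats::setNames(rep(0, ncol(dm)), colnames(dm))
  if (!is.null(imp) && nrow(imp)) gain[imp$Feature] <- imp$Gain
  parent <- sub("=.*$", "", names(gain))
  agg <- tapply(gain, parent, sum)
  feats <- unique(sub("=.*$", "", colnames(dm)))
  scores <- stats::setNames(rep(0, length(feats)), feats)
  scores[names(agg)] <- agg
  if (sum(scores) > 0) scores <- 100 * scores / sum(scores)
  importance <- data.frame(feature = names(scores),
                           score = as.numeric(scores),
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$score), ]
  rownames(importance) <- NULL
  structure(list(booster = booster, features = names(X),
                 design_columns = colnames(dm), importance = importance),
            class = "learner_model")
}

#' @export
predict.learner_model <- function(object, newdata,
                                  type = c("class", "prob"), ...) {
  type <- match.arg(type)
  dm <- .design_matrix(newdata[, object$features, drop = FALSE])
  dm <- dm[, object$design_columns, drop = FALSE]
  pr <- predict(object$booster, dm, type = "response")
  if (is.matrix(pr)) pr <- pr[, ncol(pr)]
  pr <- as.numeric(pr)
  if (type == "prob") pr else as.integer(pr >= 0.5)
}

#' @export
print.learner_model <- function(x, ...) {
  cat("Gradient-boosted learner classifier (", length(x$features),
      " predictors)\n", sep = "")
  cat("top features:\n")
  print(utils::head(x$importance, 5), digits = 3)
  invisible(x)
}

# Stratified fold assignment: shuffle within class, deal round-robin.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified cross-validated evaluation of a feature subspace
#'
#' Stratified k-fold cross-validation of the class-weighted boosted
#' classifier on one feature subspace: folds preserve the class ratio within
#' one instance, balanced accuracy is computed on each held-out fold, and
#' the summary reports the fold mean with a 95% t-interval half-width
#' (`t_{0.975, k-1} * sd / sqrt(k)`). Feature importances come from a refit
#' on the full table.
#'
#' @param table output of [build_feature_table()] (must contain `Learner`).
#' @param subspace subspace name, see [subspace_features()].
#' @param k number of folds; the minority class must have at least `k`
#'   members.
#' @param seed governs fold assignment and model fits.
#' @param ... passed to [train_classifier()] (e.g. `nrounds`).
#' @return object of class `cv_report`: list with `subspace`, `fold_scores`,
#'   `mean`, `ci_half`, `importance`.
#' @export
stratified_cv <- function(table, subspace = "complete", k = 5L, seed = 1L, ...) {
  y <- table$Learner
  if (min(table(y)) < k) {
    stop("minority class has fewer than k = ", k,
         " instances; use a smaller k")
  }
  X <- subspace_select(table, subspace)
  fold <- stratified_folds(y, k, derive_seed(seed, 0L))
  scores <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    model <- train_classifier(X[tr, , drop = FALSE], y[tr],
                              weights = compute_weights(y[tr]),
                              seed = derive_seed(seed, f), ...)
    pred <- predict(model, X[!tr, , drop = FALSE])
    balanced_accuracy(y[!tr], pred)
  }, numeric(1))
  full <- train_classifier(X, y, weights = compute_weights(y),
                           seed = derive_seed(seed, k + 1L), ...)
  structure(
    list(subspace = subspace, fold_scores = scores, mean = mean(scores),
         ci_half = stats::qt(0.975, df = k - 1) * stats::sd(scores) / sqrt(k),
         importance = full$importance),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Subspace %s: balanced accuracy %.1f%% (+/- %.1f%%)\n",
              x$subspace, 100 * x$mean, 100 * x$ci_half))
  cat("fold scores:", paste(sprintf("%.3f", x$fold_scores), collapse = " "),
      "\n")
  cat("top features:\n")
  print(utils::head(x$importance, 3), digits = 3)
  invisible(x)
}
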