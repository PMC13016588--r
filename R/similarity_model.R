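# The pairwise similarity classifier: a constrained random forest (100 trees,
# depth <= 5, inverse-frequency class weights) over the five absolute-
# difference features, with evaluation metrics, k-fold cross-validation and
# linear baselines.

MODEL_FORMAT <- "snpsim_model"
MODEL_FORMAT_VERSION <- 1L

#' Model configuration
#'
#' @param n_trees Number of trees (default 100).
#' @param max_depth Maximum tree depth (default 5); a deliberately shallow
#'   forest that captures interactions among five features while resisting
#'   overfitting on small pair sets.
#' @param class_balancing Apply inverse-frequency class weights (default TRUE).
#' @param threshold Score threshold for the confusion matrix (default 0.5).
#' @param seed Integer seed for the forest's bootstrap and feature sampling.
#' @return A `model_config` list.
#' @export
model_config <- function(n_trees = 100, max_depth = 5, class_balancing = TRUE,
                         threshold = 0.5, seed = 42) {
  if (n_trees < 1 || max_depth < 1) {
    stop_config("n_trees and max_depth must both be >= 1")
  }
  if (threshold <= 0 || threshold >= 1) stop_config("threshold must be in (0, 1)")
  structure(list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 class_balancing = isTRUE(class_balancing),
                 threshold = threshold, seed = as.integer(seed)),
            class = "model_config")
}

pair_matrix <- function(pairset) {
  as.data.frame(pairset$pairs[, PAIR_FEATURE_NAMES, drop = FALSE])
}

pair_labels <- function(pairset) {
  factor(pairset$pairs$pair_label, levels = c(0L, 1L))
}

#' Train the pairwise similarity random forest
#'
#' @param train_pairs A `pair_set` containing both classes.
#' @param config A [model_config()].
#' @return A `similarity_model`: the fitted ensemble, the config, the fixed
#'   feature order and the training class counts.
#' @export
train_similarity_model <- function(train_pairs, config = model_config()) {
  x <- pair_matrix(train_pairs)
  y <- pair_labels(train_pairs)
  counts <- table(y)
  if (any(counts == 0)) {
    stop_data("training set must contain both similar and dissimilar pairs")
  }
  weights <- if (config$class_balancing) {
    as.numeric(length(y) / (2 * counts))
  } else {
    c(1, 1)
  }
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = config$n_trees,
    max.depth = config$max_depth,
    min.node.size = 1,  # depth is the only growth limit
    class.weights = weights,
    probability = TRUE,
    importance = "impurity",
    seed = config$seed,
    num.threads = 1
  )
  structure(
    list(forest = fit, config = config, feature_order = PAIR_FEATURE_NAMES,
         training_class_counts = as.integer(counts)),
    class = "similarity_model"
  )
}

#' @export
print.similarity_model <- function(x, ...) {
  cat(sprintf("<similarity_model> %d trees, max depth %d, trained on %d pairs\n",
              x$config$n_trees, x$config$max_depth,
              sum(x$training_class_counts)))
  invisible(x)
}

check_fitted <- function(model) {
  if (!inherits(model, "similarity_model") || is.null(model$forest)) {
    stop_data("model is not a fitted similarity_model")
  }
}

#' Score pairs with a trained model
#'
#' @param model A trained `similarity_model`.
#' @param pairs A data frame with the five pairwise feature columns (a
#'   `pair_set$pairs` tibble also works).
#' @return Numeric vector of similarity scores in \eqn{[0, 1]}: the fraction
#'   of trees voting "similar". Downstream reports express these as
#'   percentages.
#' @export
predict_similarity <- function(model, pairs) {
  check_fitted(model)
  if (inherits(pairs, "pair_set")) pairs <- pairs$pairs
  missing <- setdiff(model$feature_order, names(pairs))
  if (length(missing) > 0) {
    stop_data("pair features missing column(s): %s", paste(missing, collapse = ", "))
  }
  x <- as.data.frame(pairs[, model$feature_order, drop = FALSE])
  pred <- stats::predict(model$forest, data = x, num.threads = 1)
  unname(pred$predictions[, "1"])
}

#' ROC-AUC of scores against binary labels
#' @param labels Integer 0/1 labels.
#' @param scores Numeric scores.
#' @return The area under the ROC curve.
#' @export
auc_score <- function(labels, scores) {
  if (length(unique(labels)) < 2) stop_data("AUC undefined: only one class present")
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c("0", "1"), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(roc))
}

#' Average precision of scores against binary labels
#'
#' Step-interpolated summary of the precision-recall curve:
#' \eqn{\sum_n (R_n - R_{n-1}) P_n} over descending score thresholds, with
#' tied scores handled as one threshold.
#'
#' @inheritParams auc_score
#' @return Average precision in \eqn{[0, 1]}.
#' @export
average_precision <- function(labels, scores) {
  if (sum(labels == 1) == 0) stop_data("average precision undefined: no positives")
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]
  scores <- scores[ord]
  tp <- cumsum(labels == 1)
  fp <- cumsum(labels == 0)
  # last index of each distinct threshold
  keep <- c(scores[-1] != scores[-length(scores)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / sum(labels == 1)
  sum(diff(c(0, recall)) * precision)
}

#' Threshold metrics from confusion-matrix counts
#'
#' Computes accuracy, per-class precision/recall/F1 and macro/weighted
#' averages from the four counts alone. Zero-denominator metrics are
#' reported as 0 with `zero_division = TRUE` flagged.
#'
#' @param tn,fp,fn,tp Non-negative integer counts.
#' @return An `evaluation_report` list: `confusion` (named counts),
#'   `per_class` tibble (class, precision, recall, f1, support), `accuracy`,
#'   `macro_avg`, `weighted_avg`, `support`, `zero_division`.
#' @export
confusion_metrics <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0)) stop_config("confusion counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop_config("confusion matrix is empty")
  zero_division <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { zero_division <<- TRUE; return(0) }
    num / den
  }
  prec <- c(`0` = safe_div(tn, tn + fn), `1` = safe_div(tp, tp + fp))
  rec <- c(`0` = safe_div(tn, tn + fp), `1` = safe_div(tp, tp + fn))
  f1 <- mapply(function(p, r) if (p + r == 0) { zero_division <<- TRUE; 0 }
               else 2 * p * r / (p + r), prec, rec)
  support <- c(`0` = tn + fp, `1` = tp + fn)
  weighted <- function(v) sum(v * support) / total
  structure(
    list(
      confusion = counts,
      per_class = tibble::tibble(class = c(0L, 1L), precision = unname(prec),
                                 recall = unname(rec), f1 = unname(f1),
                                 support = unname(support)),
      accuracy = (tp + tn) / total,
      macro_avg = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)),
      weighted_avg = c(precision = weighted(prec), recall = weighted(rec),
                       f1 = weighted(f1)),
      support = total,
      zero_division = zero_division
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(format_classification_report(x))
  invisible(x)
}

#' Render an evaluation report as a classification-report text block
#'
#' @param report An `evaluation_report`.
#' @param digits Decimals to print (default 2).
#' @return A single string.
#' @export
format_classification_report <- function(report, digits = 2) {
  f <- function(v) formatC(v, digits = digits, format = "f")
  lines <- c(
    sprintf("%12s %9s %9s %9s %9s", "", "precision", "recall", "f1-score", "support"),
    sprintf("%12d %9s %9s %9s %9d", report$per_class$class,
            f(report$per_class$precision), f(report$per_class$recall),
            f(report$per_class$f1), report$per_class$support),
    "",
    sprintf("%12s %9s %9s %9s %9d", "accuracy", "", "", f(report$accuracy),
            report$support),
    sprintf("%12s %9s %9s %9s %9d", "macro avg", f(report$macro_avg[["precision"]]),
            f(report$macro_avg[["recall"]]), f(report$macro_avg[["f1"]]),
            report$support),
    sprintf("%12s %9s %9s %9s %9d", "weighted avg",
            f(report$weighted_avg[["precision"]]),
            f(report$weighted_avg[["recall"]]), f(report$weighted_avg[["f1"]]),
            report$support)
  )
  if (!is.null(report$roc_auc)) {
    lines <- c(lines, "",
               sprintf("ROC-AUC: %s   Average precision: %s",
                       formatC(report$roc_auc, digits = 3, format = "f"),
                       formatC(report$average_precision, digits = 3, format = "f")))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' ROC and precision-recall curve point tables
#'
#' @inheritParams auc_score
#' @return A list of two tibbles: `roc` (threshold, fpr, tpr) and `pr`
#'   (threshold, recall, precision), suitable for TSV export and plotting.
#' @export
curve_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]; scores <- scores[ord]
  tp <- cumsum(labels == 1); fp <- cumsum(labels == 0)
  keep <- c(scores[-1] != scores[-length(scores)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]; thr <- scores[keep]
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  list(
    roc = tibble::tibble(threshold = c(Inf, thr),
                         fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos)),
    pr = tibble::tibble(threshold = thr, recall = tp / n_pos,
                        precision = tp / (tp + fp))
  )
}

#' Evaluate a model on labeled test pairs
#'
#' The confusion matrix is taken at the configured score threshold
#' (default 0.5); ROC-AUC and average precision use the raw scores.
#'
#' @param model A trained `similarity_model`.
#' @param test_pairs A labeled `pair_set` containing both classes.
#' @return An `evaluation_report` (see [confusion_metrics()]) extended with
#'   `roc_auc`, `average_precision`, `threshold`, `scores`, `labels` and
#'   `curves`.
#' @export
evaluate_model <- function(model, test_pairs) {
  check_fitted(model)
  labels <- test_pairs$pairs$pair_label
  if (length(unique(labels)) < 2) {
    stop_data("test set must contain both classes (AUC undefined otherwise)")
  }
  scores <- predict_similarity(model, test_pairs)
  thr <- model$config$threshold
  pred <- as.integer(scores >= thr)
  report <- confusion_metrics(
    tn = sum(pred == 0 & labels == 0), fp = sum(pred == 1 & labels == 0),
    fn = sum(pred == 0 & labels == 1), tp = sum(pred == 1 & labels == 1)
  )
  report$roc_auc <- auc_score(labels, scores)
  report$average_precision <- average_precision(labels, scores)
  report$threshold <- thr
  report$scores <- scores
  report$labels <- labels
  report$curves <- curve_points(labels, scores)
  report
}

#' Stratified k-fold cross-validation of the similarity model
#'
#' @param pairs A labeled `pair_set`.
#' @param k Number of folds (default 5).
#' @param config A [model_config()].
#' @param seed Integer seed for the fold assignment.
#' @return A list with `mean_auc`, `sd_auc`, `fold_auc` (length `k`) and `k`.
#' @export
cross_validate <- function(pairs, k = 5, config = model_config(), seed = 42) {
  labels <- pairs$pairs$pair_label
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (k < 2) stop_config("k must be >= 2")
  if (any(counts < k)) {
    stop_data("k = %d exceeds the smallest class count (%d)", k, min(counts))
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold_auc <- vapply(seq_len(k), function(f) {
    fit <- train_similarity_model(subset_pair_set(pairs, which(fold != f)), config)
    held <- subset_pair_set(pairs, which(fold == f))
    auc_score(held$pairs$pair_label, predict_similarity(fit, held))
  }, numeric(1))
  list(mean_auc = mean(fold_auc), sd_auc = stats::sd(fold_auc),
       fold_auc = fold_auc, k = k)
}

# Ridge "classifier": penalized least squares on targets in {-1, +1},
# class = sign of the linear score; scores are min-max mapped to [0, 1] for
# AUC/AP (rank-preserving, so the ranking metrics are unaffected).
fit_ridge_classifier <- function(x_train, y_train, x_test) {
  y_pm <- ifelse(y_train == 1L, 1, -1)
  fit <- glmnet::glmnet(as.matrix(x_train), y_pm, family = "gaussian",
                        alpha = 0, lambda = 1 / length(y_pm))
  raw <- as.numeric(stats::predict(fit, newx = as.matrix(x_test)))
  rng <- range(raw)
  score <- if (diff(rng) == 0) rep(0.5, length(raw)) else (raw - rng[1]) / diff(rng)
  list(class = as.integer(raw >= 0), score = score)
}

fit_logistic_classifier <- function(x_train, y_train, x_test) {
  fit <- glmnet::glmnet(as.matrix(x_train), factor(y_train, levels = c(0L, 1L)),
                        family = "binomial", alpha = 0,
                        lambda = 1 / length(y_train))
  prob <- as.numeric(stats::predict(fit, newx = as.matrix(x_test),
                                    type = "response"))
  list(class = as.integer(prob >= 0.5), score = prob)
}

six_metrics <- function(labels, class_pred, scores) {
  rep_ <- confusion_metrics(
    tn = sum(class_pred == 0 & labels == 0), fp = sum(class_pred == 1 & labels == 0),
    fn = sum(class_pred == 0 & labels == 1), tp = sum(class_pred == 1 & labels == 1)
  )
  c(accuracy = rep_$accuracy,
    precision = rep_$per_class$precision[2],
    recall = rep_$per_class$recall[2],
    f1 = rep_$per_class$f1[2],
    roc_auc = auc_score(labels, scores),
    average_precision = average_precision(labels, scores))
}

#' Compare the random forest against linear baselines
#'
#' Fits the random forest, an L2-regularized logistic classifier and a ridge
#' (penalized least-squares) classifier on an identical stratified train/test
#' split and reports six metrics for each: accuracy, precision, recall, F1,
#' ROC-AUC and average precision. Both linear models use the same ridge
#' penalty strength (lambda = 1/n).
#'
#' @param pairs A labeled `pair_set`.
#' @param config A [model_config()] (used for the forest).
#' @param seed Seed for the shared split.
#' @param test_fraction Hold-out fraction (default 0.2).
#' @return A tibble with one row per model (`random_forest`,
#'   `logistic_regression`, `ridge_regression`) and six metric columns.
#' @export
compare_baselines <- function(pairs, config = model_config(), seed = 42,
                              test_fraction = 0.2) {
  split <- split_train_test(pairs, test_fraction = test_fraction, seed = seed)
  x_train <- pair_matrix(split$train)
  x_test <- pair_matrix(split$test)
  y_train <- split$train$pairs$pair_label
  y_test <- split$test$pairs$pair_label

  rf <- train_similarity_model(split$train, config)
  rf_scores <- predict_similarity(rf, split$test)
  logi <- fit_logistic_classifier(x_train, y_train, x_test)
  ridge <- fit_ridge_classifier(x_train, y_train, x_test)

  rows <- rbind(
    six_metrics(y_test, as.integer(rf_scores >= config$threshold), rf_scores),
    six_metrics(y_test, logi$class, logi$score),
    six_metrics(y_test, ridge$class, ridge$score)
  )
  out <- tibble::as_tibble(as.data.frame(rows))
  out <- tibble::add_column(out, model = c("random_forest",
                                           "logistic_regression",
                                           "ridge_regression"),
                            .before = 1)
  out
}

#' Impurity-based feature importances
#'
#' @param model A trained `similarity_model`.
#' @return A tibble (`feature`, `importance`) sorted descending; importances
#'   are normalized to sum to 1.
#' @export
feature_importances <- function(model) {
  check_fitted(model)
  imp <- model$forest$variable.importance
  imp <- imp / sum(imp)
  imp <- sort(imp, decreasing = TRUE)
  tibble::tibble(feature = names(imp), importance = unname(imp))
}

#' Persist a trained model
#'
#' The file embeds a format tag, a format version, the config and the
#' feature order, so [load_model()] can refuse incompatible or corrupted
#' files instead of silently mispredicting.
#'
#' @param model A trained `similarity_model`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  check_fitted(model)
  saveRDS(list(format = MODEL_FORMAT, version = MODEL_FORMAT_VERSION,
               config = model$config, feature_order = model$feature_order,
               training_class_counts = model$training_class_counts,
               forest = model$forest),
          path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to a saved model file.
#' @return A `similarity_model`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop_data("cannot read model file %s: %s", path, conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT)) {
    stop_data("file %s is not a snpsim model file", path)
  }
  if (!identical(obj$version, MODEL_FORMAT_VERSION)) {
    stop_data("model format version %s is not supported (expected %d)",
              obj$version, MODEL_FORMAT_VERSION)
  }
  structure(list(forest = obj$forest, config = obj$config,
                 feature_order = obj$feature_order,
                 training_class_counts = obj$training_class_counts),
            class = "similarity_model")
}
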