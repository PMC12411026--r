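#' Cross-validation configuration
#'
#' @param n_folds number of folds (default 10).
#' @param regularization_C SVM cost (default 1).
#' @param feature_subset feature names to use; `NULL` means all 8.
#' @param seed integer seed controlling the fold shuffle.
#' @param stratified build folds stratified by class (default `TRUE`).
#' @param standardize standardize features with training-fold statistics
#'   (default `TRUE`).
#' @param kernel only `"linear"` is supported.
#' @return an object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10L, regularization_C = 1,
                      feature_subset = NULL, seed = 7L, stratified = TRUE,
                      standardize = TRUE, kernel = "linear") {
  if (n_folds < 2L) stop_config("n_folds must be >= 2")
  if (regularization_C <= 0) stop_config("C must be > 0")
  if (!identical(kernel, "linear"))
    stop("unsupported kernel: ", kernel, call. = FALSE)
  structure(list(n_folds = as.integer(n_folds),
                 regularization_C = regularization_C,
                 feature_subset = feature_subset, seed = as.integer(seed),
                 stratified = stratified, standardize = standardize,
                 kernel = kernel),
            class = "cv_config")
}

# Empirical ROC of decision scores (TRUE = positive class). Ties are grouped,
# so the curve — and its trapezoidal area — matches the midrank Mann-Whitney
# statistic exactly.
roc_points <- function(scores, is_pos) {
  stopifnot(length(scores) == length(is_pos), any(is_pos), any(!is_pos))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- is_pos[o]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(l)[last_of_tie] / sum(l))
  fpr <- c(0, cumsum(!l)[last_of_tie] / sum(!l))
  list(fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Fold TPR interpolated onto a common FPR grid, anchored at (0,0) and (1,1).
interp_tpr <- function(roc, grid) {
  y <- approx(x = roc$fpr, y = roc$tpr, xout = grid, ties = max,
              yleft = 0, yright = 1)$y
  y[1] <- 0; y[length(y)] <- 1
  y
}

# Stratified fold assignment: classes are shuffled independently, laid out
# contiguously, and folds dealt round-robin, so per-class and total fold
# sizes each differ by at most one.
make_folds <- function(labels, n_folds, seed, stratified = TRUE) {
  n <- length(labels)
  set.seed(seed)
  ord <- if (stratified) {
    unlist(lapply(split(seq_len(n), labels), sample), use.names = FALSE)
  } else sample(n)
  fold <- integer(n)
  fold[ord] <- rep(seq_len(n_folds), length.out = n)
  fold
}

#' Cross-validated linear-SVM classification of binned OCT features
#'
#' Runs stratified k-fold cross-validation of a linear SVM on the 8-feature
#' (or subsetted) table, pooling out-of-fold predictions so every instance is
#' scored exactly once. Per fold, an ROC curve is computed from the decision
#' scores and its exact trapezoidal AUC recorded; fold ROCs are interpolated
#' onto a common 101-point false-positive-rate grid to give the mean ROC with
#' its across-fold SD, and the mean AUC +/- SD. A final model refit on all
#' data supplies the feature weight vector, and out-of-fold predictions feed
#' the per-sample majority report.
#'
#' @param features a `binned_features` table ([assemble_dataset()]).
#' @param cfg a [cv_config()].
#' @return an object of class `cv_report`: list with `fold_accuracies`,
#'   `overall_accuracy`, `confusion_matrix` (truth in rows), `fold_aucs`,
#'   `mean_auc`, `auc_sd`, `mean_roc` (`fpr_grid`, `mean_tpr`, `sd_tpr`),
#'   `weights`, `bias`, `per_sample`, `predictions`
#'   (row-aligned out-of-fold data frame), `feature_names`, `config`.
#' @export
cross_validate <- function(features, cfg = cv_config()) {
  stopifnot(is.data.frame(features))
  labels <- as.character(features$label)
  if (length(unique(labels)) < 2L)
    stop("classification needs both classes present", call. = FALSE)
  feat_names <- cfg$feature_subset
  if (is.null(feat_names)) feat_names <- .feature_cols
  missing_f <- setdiff(feat_names, names(features))
  if (length(missing_f))
    stop("unknown feature(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(features[, feat_names, drop = FALSE])
  n <- nrow(x)
  if (min(table(labels)) < cfg$n_folds)
    stop_config("need at least n_folds instances per class")

  fold <- make_folds(labels, cfg$n_folds, cfg$seed, cfg$stratified)
  scores <- numeric(n)
  pred <- character(n)
  fold_acc <- fold_auc <- numeric(cfg$n_folds)
  grid <- seq(0, 1, length.out = 101L)
  tpr_mat <- matrix(NA_real_, cfg$n_folds, length(grid))

  for (k in seq_len(cfg$n_folds)) {
    te <- which(fold == k); tr <- which(fold != k)
    model <- svm_linear(x[tr, , drop = FALSE], labels[tr],
                        C = cfg$regularization_C,
                        standardize = cfg$standardize)
    s <- svm_decision(model, x[te, , drop = FALSE])
    scores[te] <- s
    pred[te] <- ifelse(s > 0, "MM", "BN")
    fold_acc[k] <- mean(pred[te] == labels[te])
    roc <- roc_points(s, labels[te] == "MM")
    fold_auc[k] <- trapezoid_auc(roc$fpr, roc$tpr)
    tpr_mat[k, ] <- interp_tpr(roc, grid)
  }

  mean_tpr <- colMeans(tpr_mat)
  mean_tpr[1] <- 0; mean_tpr[length(grid)] <- 1
  final <- svm_linear(x, labels, C = cfg$regularization_C,
                      standardize = cfg$standardize)
  cm <- table(factor(labels, c("BN", "MM")), factor(pred, c("BN", "MM")),
              dnn = c("truth", "predicted"))
  structure(list(
    fold_accuracies = fold_acc,
    overall_accuracy = mean(pred == labels),
    n_correct = sum(pred == labels), n_total = n,
    confusion_matrix = cm,
    fold_aucs = fold_auc, mean_auc = mean(fold_auc), auc_sd = sd(fold_auc),
    mean_roc = list(fpr_grid = grid, mean_tpr = mean_tpr,
                    sd_tpr = apply(tpr_mat, 2, sd)),
    weights = final$weights, bias = final$bias,
    per_sample = per_sample_report(pred, features$sample_id, labels),
    predictions = data.frame(sample_id = features$sample_id, label = labels,
                             fold = fold, score = scores, predicted = pred,
                             stringsAsFactors = FALSE),
    feature_names = feat_names, config = cfg, final_model = final
  ), class = "cv_report")
}

#' Per-sample majority report from out-of-fold predictions
#'
#' For each measured sample, counts how many of its instances were predicted
#' consistent with the sample's true type; a lesion is called correctly when
#' more than half of its instances are (`proportion > 0.5`).
#'
#' @param predictions character vector of predicted labels.
#' @param sample_ids sample identifier per instance.
#' @param labels true label per instance.
#' @return data frame with `sample_id`, `total`, `correct`, `proportion`,
#'   `majority_correct`.
#' @export
per_sample_report <- function(predictions, sample_ids, labels) {
  stopifnot(length(predictions) == length(sample_ids),
            length(labels) == length(sample_ids))
  ids <- unique(sample_ids)
  out <- do.call(rbind, lapply(ids, function(id) {
    sel <- sample_ids == id
    total <- sum(sel)
    correct <- sum(predictions[sel] == labels[sel])
    data.frame(sample_id = id, total = total, correct = correct,
               proportion = correct / total,
               majority_correct = correct / total > 0.5,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Feature weight vector of a fitted linear SVM
#'
#' One signed coefficient per feature from the final all-data refit; the
#' magnitude measures each variable's influence on the decision and the sign
#' its direction (positive pushes toward MM).
#'
#' @param model a `linear_svm` or `cv_report`.
#' @param feature_names optional names to attach.
#' @param sort_by_magnitude order by decreasing `|weight|` (default `TRUE`).
#' @return named numeric vector of signed weights.
#' @export
extract_weights <- function(model, feature_names = NULL,
                            sort_by_magnitude = TRUE) {
  if (inherits(model, "cv_report")) model <- model$final_model
  stopifnot(inherits(model, "linear_svm"))
  if (!identical(model$kernel, "linear"))
    stop("weight extraction requires a linear kernel", call. = FALSE)
  w <- model$weights
  if (!is.null(feature_names)) names(w) <- feature_names
  if (sort_by_magnitude) w <- w[order(abs(w), decreasing = TRUE)]
  w
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold linear SVM (C = %g) on %d instances\n",
              x$config$n_folds, x$config$regularization_C, x$n_total))
  cat(sprintf("  overall accuracy %.3f (%d/%d), mean AUC %.3f +/- %.3f\n",
              x$overall_accuracy, x$n_correct, x$n_total,
              x$mean_auc, x$auc_sd))
  cat("  per-sample correct proportions:\n")
  print(x$per_sample, row.names = FALSE)
  invisible(x)
}
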