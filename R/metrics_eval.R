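#' Classification metrics, ROC/AUC and stratified cross-validation
#'
#' Confusion-matrix scoring (accuracy, recall/TPR, FPR, precision,
#' TNR, F1, G-mean), trapezoidal ROC/AUC equal to the Mann-Whitney
#' concordance probability, and stratified k-fold cross-validation of
#' the swarm-trained network. Death is the positive class throughout.
#'
#' @name metrics_eval
NULL

.as_binary <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    ok <- y %in% c("live", "dead")
    if (!all(ok)) stop("labels must be live/dead or 0/1", call. = FALSE)
    return(as.numeric(y == "dead"))
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  y
}

#' Confusion matrix
#'
#' @param y_true,y_pred Binary vectors (0/1 with 1 = positive = dead,
#'   or live/dead factors/characters) of equal length.
#' @return A `confusion_matrix` list with integer `TP`, `FP`, `FN`,
#'   `TN`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- .as_binary(y_true); y_pred <- .as_binary(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ", call. = FALSE)
  }
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 FP = sum(y_true == 0 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0),
                 TN = sum(y_true == 0 & y_pred == 0)),
            class = "confusion_matrix")
}

#' Confusion-matrix scoring criteria
#'
#' Acc = (TP+TN)/total; REC = TPR = TP/(TP+FN); FPR = FP/(FP+TN);
#' TNR = TN/(FP+TN); PRE = TP/(TP+FP); F1 = 2 PRE REC/(PRE+REC);
#' G-mean = sqrt(TPR * TNR). A zero denominator yields `NA` (the
#' metric is undefined), except PRE/F1 which are 0 by convention when
#' TP = 0 but positive predictions or truths exist.
#'
#' @param cm A `confusion_matrix`.
#' @return Named list of metric values in \[0, 1\] (or `NA`).
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$FP + cm$FN + cm$TN
  div <- function(a, b) if (b > 0) a / b else NA_real_
  tpr <- div(cm$TP, cm$TP + cm$FN)
  fpr <- div(cm$FP, cm$FP + cm$TN)
  tnr <- div(cm$TN, cm$FP + cm$TN)
  pre <- if (cm$TP + cm$FP > 0) cm$TP / (cm$TP + cm$FP) else NA_real_
  f1 <- if (!is.na(pre) && !is.na(tpr)) {
    if (pre + tpr > 0) 2 * pre * tpr / (pre + tpr) else 0
  } else NA_real_
  gm <- if (!is.na(tpr) && !is.na(tnr)) sqrt(tpr * tnr) else NA_real_
  list(Acc = div(cm$TP + cm$TN, total), REC = tpr, TPR = tpr, FPR = fpr,
       PRE = pre, TNR = tnr, F1 = f1, GM = gm)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps thresholds over the unique scores (predicting positive when
#' score >= threshold) and integrates the ROC curve by the trapezoid
#' rule, which equals the Mann-Whitney concordance probability
#' P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param y_true Binary labels (1/"dead" = positive); both classes
#'   must be present.
#' @param scores Numeric scores, higher = more positive.
#' @return List with `roc` (data.frame fpr/tpr/threshold, from (0,0)
#'   to (1,1)) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  y <- .as_binary(y_true)
  stopifnot(length(y) == length(scores))
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0) {
    stop("ROC requires at least one positive and one negative",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # cumulative counts at the last occurrence of each distinct threshold
  cum_tp <- cumsum(ys); cum_fp <- cumsum(1 - ys)
  last <- which(!duplicated(ss, fromLast = TRUE))
  roc <- data.frame(
    fpr = c(0, cum_fp[last] / N),
    tpr = c(0, cum_tp[last] / P),
    threshold = c(Inf, ss[last])
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Mann-Whitney p-value for score separation
#'
#' Two-sided Wilcoxon rank-sum test of the scores between the two
#' classes (normal approximation with tie correction).
#'
#' @inheritParams roc_auc
#' @return p-value.
#' @export
auc_pvalue <- function(y_true, scores) {
  y <- .as_binary(y_true)
  suppressWarnings(
    stats::wilcox.test(scores[y == 1], scores[y == 0], exact = FALSE)
  )$p.value
}

#' Stratified fold assignment
#'
#' @param y Binary labels.
#' @param k Number of folds.
#' @param seed Optional seed.
#' @return Integer vector of fold ids 1..k, with each class split as
#'   evenly as possible (fold sizes differ by at most 1 per class).
#' @export
stratified_folds <- function(y, k = 5, seed = NULL) {
  y <- .as_binary(y)
  stopifnot(k >= 2)
  if (min(table(y)) < k) {
    stop("a class is too rare to stratify into ", k, " folds",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(y))
  # fill fold ids in opposite orders for the two classes so the
  # per-class remainders do not stack on the same folds (keeps total
  # fold sizes within +-1)
  for (cls in c(0, 1)) {
    idx <- sample(which(y == cls))
    ids <- if (cls == 0) seq_len(k) else rev(seq_len(k))
    folds[idx] <- rep_len(ids, length(idx))
  }
  folds
}

# standardize with training-fold statistics only; constant columns are
# left centered at zero
.standardize <- function(X_train, X_test) {
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(X_train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(X_test, 2, mu), 2, sdv, "/"))
}

#' Stratified k-fold cross-validation of the trained network
#'
#' For each fold: features are standardized with training-fold
#' statistics, the network is trained on the remaining folds by swarm
#' search ([train_network()]), and the held-out fold is scored. Death
#' is the positive class; class = score >= 0.5.
#'
#' @param cohort A `clinical_cohort`, or a list with elements `X`
#'   (feature matrix) and `y` (binary labels).
#' @param config A `trainer_config`. Per-fold seeds are derived from
#'   `seed` so folds are independent but reproducible.
#' @param k Number of folds (default 5).
#' @param seed Seed controlling fold assignment and per-fold training.
#' @return List with `folds` (per-fold metrics incl. AUC and p-value),
#'   `mean` (unweighted across-fold mean of each metric), `roc`
#'   (per-fold ROC data.frames) and `fold_id` (assignment vector).
#' @export
cross_validate <- function(cohort, config, k = 5, seed = 1) {
  if (inherits(cohort, "clinical_cohort")) {
    X <- cohort_features(cohort)
    y <- cohort_labels(cohort)
  } else {
    X <- as.matrix(cohort$X); y <- .as_binary(cohort$y)
  }
  fold_id <- stratified_folds(y, k, seed = seed)
  folds <- vector("list", k)
  rocs <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold_id != f; te <- !tr
    std <- .standardize(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    cfg <- config
    cfg$seed <- (if (is.null(config$seed)) seed else config$seed) + f
    model <- train_network(std$train, y[tr], cfg)
    scores <- predict_scores(model, std$test)
    pred <- as.numeric(scores >= 0.5)
    met <- classification_metrics(confusion(y[te], pred))
    ra <- roc_auc(y[te], scores)
    met$AUC <- ra$auc
    met$P <- auc_pvalue(y[te], scores)
    met$train_mse <- model$train_mse
    folds[[f]] <- met
    rocs[[f]] <- ra$roc
  }
  nm <- names(folds[[1]])
  mean_met <- stats::setNames(lapply(nm, function(m) {
    mean(vapply(folds, function(fl) as.numeric(fl[[m]]), 0), na.rm = TRUE)
  }), nm)
  list(folds = folds, mean = mean_met, roc = rocs, fold_id = fold_id)
}

#' Vertically averaged ROC curve across folds
#'
#' Interpolates each fold's ROC at a common FPR grid and averages the
#' TPRs, the usual way a mean ROC curve is drawn over CV folds.
#'
#' @param rocs List of ROC data.frames from [cross_validate()].
#' @param grid FPR grid (default 101 points on \[0, 1\]).
#' @return data.frame with `fpr` and mean `tpr`.
#' @export
mean_roc <- function(rocs, grid = seq(0, 1, length.out = 101)) {
  tprs <- vapply(rocs, function(r) {
    stats::approx(r$fpr, r$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(tprs))
}
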