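# SAP severity grading, the two binary prediction tasks, stratified 10-fold
# cross-validation of three classifier families, and L1-penalized
# feature-weight analysis.

#' @keywords internal
sap_levels <- function() c("none", "mild", "moderate", "severe")

#' Grade stroke-associated pneumonia from lung involvement
#'
#' Maps the chest-CT lung-involvement percentage to a severity category:
#' below 1 percent is `none`, 1-25 `mild`, above 25 up to 50 `moderate`,
#' above 50 up to 100 `severe`. The printed integer bands are extended to
#' half-open real intervals so every percentage in `[0, 100]` has a label.
#'
#' @param involvement_pct numeric vector of percentages in `[0, 100]`.
#' @return Factor with levels none, mild, moderate, severe.
#' @examples
#' grade_sap(c(0, 1, 25, 26, 50, 51, 100))
#' @export
grade_sap <- function(involvement_pct) {
  if (any(!is.finite(involvement_pct)) || any(involvement_pct < 0) ||
      any(involvement_pct > 100))
    hm_stop("involvement percentages must lie in [0, 100]",
            "hemomap_bad_percentage")
  out <- ifelse(involvement_pct < 1, "none",
         ifelse(involvement_pct <= 25, "mild",
         ifelse(involvement_pct <= 50, "moderate", "severe")))
  factor(out, levels = sap_levels())
}

#' Binary labels for the two prediction tasks
#'
#' `sap_any` asks whether the patient has pneumonia at all (positive =
#' mild/moderate/severe); `sap_moderate_plus` separates moderate-or-worse
#' pneumonia from the rest (positive = moderate/severe).
#'
#' @param categories character or factor vector of SAP categories.
#' @param task `"sap_any"` or `"sap_moderate_plus"`.
#' @return Integer vector of 0/1 labels.
#' @export
make_task_labels <- function(categories, task) {
  if (length(task) != 1 || !task %in% c("sap_any", "sap_moderate_plus"))
    hm_stop(sprintf("unknown task '%s'", paste(task, collapse = ",")),
            "hemomap_unknown_task")
  categories <- as.character(categories)
  if (!all(categories %in% sap_levels()))
    hm_stop("categories must be none/mild/moderate/severe",
            "hemomap_bad_category")
  pos <- if (task == "sap_any") c("mild", "moderate", "severe")
         else c("moderate", "severe")
  as.integer(categories %in% pos)
}

#' Z-score standardization with training statistics only
#'
#' Standardizes each column of `newdata` using the mean and standard
#' deviation of the corresponding `train` column, so no test-set information
#' leaks into the scaling. Columns constant in training map to 0.
#'
#' @param train numeric matrix of training rows (>= 2).
#' @param newdata matrix to standardize (defaults to `train`).
#' @return Standardized matrix with attributes `center` and `scale`.
#' @export
standardize <- function(train, newdata = train) {
  train <- as.matrix(train)
  newdata <- as.matrix(newdata)
  if (nrow(train) < 2)
    hm_stop("standardization needs at least 2 training rows",
            "hemomap_too_few_rows")
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  out <- sweep(newdata, 2, ctr, "-")
  keep <- scl > 0
  out[, keep] <- sweep(out[, keep, drop = FALSE], 2, scl[keep], "/")
  out[, !keep] <- 0
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

fit_and_score <- function(model, xtr, ytr, xte, seed, lambda_l2, ntree) {
  set.seed(seed)
  if (model == "logistic") {
    if (is.null(lambda_l2)) {
      # choose the ridge penalty by internal CV on the training fold only;
      # with very few minority cases internal folds degenerate, so fall
      # back to a fixed penalty
      if (min(table(ytr)) >= 8) {
        cvfit <- glmnet::cv.glmnet(xtr, ytr, family = "binomial", alpha = 0,
                                   nfolds = 5, standardize = FALSE)
        lambda_l2 <- cvfit$lambda.min
      } else {
        lambda_l2 <- 0.05
      }
    }
    fit <- glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                          lambda = lambda_l2, standardize = FALSE)
    as.numeric(stats::predict(fit, xte, type = "response"))
  } else if (model == "svm") {
    fit <- e1071::svm(xtr, factor(ytr, levels = c(0, 1)),
                      kernel = "radial", probability = TRUE)
    pr <- stats::predict(fit, xte, probability = TRUE)
    attr(pr, "probabilities")[, "1"]
  } else {
    fit <- randomForest::randomForest(xtr, factor(ytr, levels = c(0, 1)),
                                      ntree = ntree)
    stats::predict(fit, xte, type = "prob")[, "1"]
  }
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated SAP prediction
#'
#' Stratified k-fold (default 10) cross-validation of one classifier family
#' on the 43 features (35 bleeding-distribution + 8 bleeding-extrusion).
#' Each fold standardizes with training statistics only, fits, and scores
#' the held-out subjects; AUC is computed from the continuous positive-class
#' probabilities and accuracy/sensitivity/specificity at a 0.5 threshold
#' (sensitivity = TP/(TP+FN), specificity = TN/(TN+FP)). Reported metrics
#' are the means over folds.
#'
#' @param features an `sap_feature_table`.
#' @param task `"sap_any"` or `"sap_moderate_plus"`.
#' @param model `"logistic"` (ridge-penalized), `"svm"` (RBF kernel,
#'   probability-calibrated) or `"random_forest"`.
#' @param seed integer seed controlling fold assignment and the stochastic
#'   fits.
#' @param nfolds requested number of folds; reduced (with a warning) when a
#'   class has fewer members than folds.
#' @param threshold decision threshold on the positive-class probability.
#' @param lambda_l2 ridge penalty for the logistic model; `NULL` (default)
#'   selects it by 5-fold internal cross-validation on each training fold.
#' @param ntree trees for the random forest.
#' @param labels optional explicit 0/1 labels overriding
#'   `make_task_labels(features$sap_category, task)` (e.g. for permutation
#'   nulls).
#' @return An object of class `sap_cv`: mean `auc`, `accuracy`,
#'   `sensitivity`, `specificity`, plus `per_fold` (one row per fold),
#'   `nfolds`, `task`, `model`, `seed`.
#' @export
crossval <- function(features, task, model = c("logistic", "svm",
                                               "random_forest"),
                     seed = 1, nfolds = 10, threshold = 0.5,
                     lambda_l2 = NULL, ntree = 500, labels = NULL) {
  model <- match.arg(model)
  X <- feature_matrix(features)
  y <- if (is.null(labels)) make_task_labels(features$sap_category, task)
       else as.integer(labels)
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab < 2))
    hm_stop("cross-validation needs at least 2 subjects in each class",
            "hemomap_single_class")
  k <- min(nfolds, min(tab))
  if (k < nfolds)
    hm_warn(sprintf("smallest class has %d members; using %d folds",
                    min(tab), k), "hemomap_reduced_folds")
  fold <- stratified_folds(y, k, seed)
  per_fold <- data.frame(fold = seq_len(k), auc = NA_real_,
                         accuracy = NA_real_, sensitivity = NA_real_,
                         specificity = NA_real_)
  for (fd in seq_len(k)) {
    tr <- fold != fd
    xtr <- standardize(X[tr, , drop = FALSE])
    xte <- standardize(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
    p <- fit_and_score(model, xtr, y[tr], xte, seed + fd, lambda_l2, ntree)
    yte <- y[!tr]
    per_fold$auc[fd] <- as.numeric(pROC::auc(
      pROC::roc(yte, as.numeric(p), levels = c(0, 1), direction = "<",
                quiet = TRUE)))
    pred <- as.integer(p >= threshold)
    tp <- sum(pred == 1 & yte == 1); tn <- sum(pred == 0 & yte == 0)
    fp <- sum(pred == 1 & yte == 0); fn <- sum(pred == 0 & yte == 1)
    per_fold$accuracy[fd] <- (tp + tn) / length(yte)
    per_fold$sensitivity[fd] <- if (tp + fn > 0) tp / (tp + fn) else NA
    per_fold$specificity[fd] <- if (tn + fp > 0) tn / (tn + fp) else NA
  }
  structure(list(task = task, model = model, seed = seed, nfolds = k,
                 auc = mean(per_fold$auc),
                 accuracy = mean(per_fold$accuracy),
                 sensitivity = mean(per_fold$sensitivity, na.rm = TRUE),
                 specificity = mean(per_fold$specificity, na.rm = TRUE),
                 per_fold = per_fold),
            class = "sap_cv")
}

#' @exportS3Method base::print
print.sap_cv <- function(x, ...) {
  cat(sprintf("<sap_cv> %s on %s, %d-fold\n", x$model, x$task, x$nfolds))
  cat(sprintf("  AUC %.3f | accuracy %.3f | sensitivity %.3f | specificity %.3f\n",
              x$auc, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' @exportS3Method base::summary
summary.sap_cv <- function(object, ...) {
  print(object)
  cat("per fold:\n")
  print(object$per_fold, digits = 3, row.names = FALSE)
  invisible(object)
}

#' L1-penalized logistic feature weights
#'
#' Fits an L1-penalized (lasso) logistic regression on the standardized full
#' feature table and returns the coefficients sorted by absolute weight; at
#' sufficient penalty many weights are exactly zero, so the surviving
#' features are the ones the model leans on.
#'
#' @inheritParams crossval
#' @param penalty lasso penalty (glmnet `lambda`).
#' @return Data.frame of class `sap_feature_weights` with columns `feature`
#'   and `weight`, sorted by decreasing `|weight|`.
#' @export
feature_weights <- function(features, task, penalty = 0.02, seed = 1) {
  X <- feature_matrix(features)
  y <- make_task_labels(features$sap_category, task)
  if (length(unique(y)) < 2)
    hm_stop("feature weights need both classes present",
            "hemomap_single_class")
  Xs <- standardize(X)
  set.seed(seed)
  fit <- tryCatch(
    glmnet::glmnet(Xs, y, family = "binomial", alpha = 1, lambda = penalty,
                   standardize = FALSE),
    error = function(e)
      hm_stop(sprintf("L1 logistic fit failed to converge: %s",
                      conditionMessage(e)), "hemomap_no_convergence"))
  w <- as.numeric(fit$beta)
  out <- data.frame(feature = colnames(X), weight = w,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$weight)), ]
  rownames(out) <- NULL
  class(out) <- c("sap_feature_weights", "data.frame")
  attr(out, "task") <- task
  attr(out, "penalty") <- penalty
  out
}

#' @exportS3Method base::print
print.sap_feature_weights <- function(x, n = 10, ...) {
  cat(sprintf("<sap_feature_weights> task %s, penalty %g, %d non-zero of %d\n",
              attr(x, "task"), attr(x, "penalty"), sum(x$weight != 0),
              nrow(x)))
  print.data.frame(utils::head(x, n), digits = 3, row.names = FALSE)
  invisible(x)
}
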