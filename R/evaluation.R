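#' Confusion counts for +1/-1 predictions
#'
#' @param preds Vector of predicted +1/-1 labels.
#' @param labels Vector of true +1/-1 labels (same length, nonempty).
#' @return A `deepgam_confusion`: list with integer `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(preds, labels) {
  if (length(preds) == 0L) stop("empty predictions", call. = FALSE)
  if (length(preds) != length(labels)) stop("length mismatch", call. = FALSE)
  structure(
    list(TP = sum(preds == 1 & labels == 1),
         FP = sum(preds == 1 & labels == -1),
         FN = sum(preds == -1 & labels == 1),
         TN = sum(preds == -1 & labels == -1)),
    class = "deepgam_confusion")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall, F1 and specificity by the standard
#' confusion-matrix formulas. A ratio with zero denominator is reported as
#' 0 and flagged in `degenerate`, which keeps cross-fold averaging
#' well-defined.
#'
#' @param c A `deepgam_confusion` from [confusion()].
#' @return List with `accuracy`, `precision`, `recall`, `f1`,
#'   `specificity` and a character vector `degenerate` naming any metric
#'   whose denominator was zero.
#' @export
classification_metrics <- function(c) {
  stopifnot(inherits(c, "deepgam_confusion"))
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  acc <- safe(c$TP + c$TN, c$TP + c$TN + c$FP + c$FN, "accuracy")
  prec <- safe(c$TP, c$TP + c$FP, "precision")
  rec <- safe(c$TP, c$TP + c$FN, "recall")
  spec <- safe(c$TN, c$TN + c$FP, "specificity")
  f1 <- safe(2 * prec * rec, prec + rec, "f1")
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       specificity = spec, degenerate = degenerate)
}

#' ROC curve and AUC
#'
#' Sweeps all unique score thresholds, returning ROC points from (0, 0) to
#' (1, 1) that are monotone in both coordinates, and the trapezoidal AUC.
#' The trapezoid over tied-score groups gives each tied positive-negative
#' pair half credit, so the AUC equals the Mann-Whitney pair statistic.
#'
#' @param scores Real-valued scores (higher = more positive).
#' @param labels +1/-1 labels; both classes must be present.
#' @return List with `roc_points` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0L || n_neg == 0L) {
    stop("metric error: both classes required for ROC", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # one ROC point per unique threshold (group ties)
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y == 1)[last]
  fp <- cumsum(y == -1)[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Full classification evaluation of real-valued scores
#'
#' Thresholds the scores at `t` (strict inequality) for the
#' confusion-matrix metrics, and sweeps all thresholds for the ROC/AUC.
#'
#' @param scores Real-valued scores.
#' @param labels +1/-1 labels.
#' @param t Classification threshold (default 0).
#' @return A `deepgam_eval_report`: `auc`, `accuracy`, `f1`, `precision`,
#'   `recall`, `specificity`, `roc_points`, `confusion`, `degenerate`, `n`.
#' @export
evaluate_scores <- function(scores, labels, t = 0) {
  cm <- confusion(classify(scores, t), labels)
  met <- classification_metrics(cm)
  roc <- roc_and_auc(scores, labels)
  structure(
    list(auc = roc$auc, accuracy = met$accuracy, f1 = met$f1,
         precision = met$precision, recall = met$recall,
         specificity = met$specificity, roc_points = roc$roc_points,
         confusion = cm, degenerate = met$degenerate,
         n = length(labels)),
    class = "deepgam_eval_report")
}

#' @export
print.deepgam_eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval n=%d> AUC %.3f | acc %.3f | F1 %.3f | prec %.3f | rec %.3f | spec %.3f\n",
    x$n, x$auc, x$accuracy, x$f1, x$precision, x$recall, x$specificity))
  invisible(x)
}

#' Regression metrics: MSE and the coefficient of determination
#'
#' `MSE = mean((y - yhat)^2)`;
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. R2 can be negative
#' when the model is worse than predicting the mean.
#'
#' @param pred Predicted values.
#' @param y Observed targets (non-constant, n >= 2).
#' @return List with `mse` and `r2`.
#' @export
regression_metrics <- function(pred, y) {
  if (length(pred) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need n >= 2", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("r2 undefined for a constant target", call. = FALSE)
  sse <- sum((y - pred)^2)
  list(mse = mean((y - pred)^2), r2 = 1 - sse / sst)
}

# Fit one method on a (standardized) training split; returns a list with a
# $score function over raw feature matrices plus the fitted object.
fit_method <- function(method, train_std, valid_std, config, scaler) {
  switch(method,
    deepgam = {
      model <- init_model(ncol(train_std$features), C = config$C,
                          phi_init = config$phi_init, seed = config$seed,
                          mode = config$mode,
                          use_tanh = config$use_tanh,
                          feature_names = train_std$feature_names)
      fit <- train(model, train_std, valid_std, config)
      model <- fit$model
      model$scaler <- scaler
      list(fit = model, history = fit$history,
           score = function(Xraw) predict_scores(model, Xraw)$scores)
    },
    svm = {
      head <- train_linear(train_std, config, loss_kind = "hinge")
      list(fit = head,
           score = function(Xraw)
             predict_linear(head, standardize_matrix(Xraw, scaler)))
    },
    logistic = {
      head <- train_linear(train_std, config, loss_kind = "logistic")
      list(fit = head,
           score = function(Xraw)
             predict_linear(head, standardize_matrix(Xraw, scaler)))
    },
    mlp = {
      head <- train_mlp(train_std, config)
      list(fit = head,
           score = function(Xraw)
             predict_mlp(head, standardize_matrix(Xraw, scaler))$score)
    },
    stop(sprintf("unknown method '%s'", method), call. = FALSE)
  )
}

standardize_matrix <- function(X, scaler) {
  sweep(sweep(as.matrix(X), 2L, scaler$mean), 2L, scaler$sd, "/")
}

#' Stratified cross-validation of a classification method
#'
#' For each fold the standardizer is refit on that fold's training rows
#' only (no leakage), the method is trained on the standardized training
#' rows and evaluated on the held-out rows. Optionally a feature-selection
#' step (straight-through gates or L1 ranking) is refit inside each fold
#' before retraining on the selected columns.
#'
#' @param method One of `"deepgam"`, `"svm"`, `"logistic"`, `"mlp"`.
#' @param data A classification [deepgam_dataset()] (raw, unstandardized).
#' @param k Number of folds.
#' @param seed Integer seed (folds and per-fold training seeds derive from
#'   it).
#' @param config A [training_config()].
#' @param selection Optional selection method applied inside each fold:
#'   `"ste"` or `"lasso"`.
#' @param select_k Number of features kept when `selection` is given.
#' @param valid_fraction Fraction of each fold's training rows carved out
#'   as a validation split for per-epoch F1 tracking (0 disables).
#' @return A `deepgam_cv_report`: `fold_reports` (list of
#'   `deepgam_eval_report`), `mean_report` (unweighted metric means),
#'   `selected` (per-fold selected feature indices, if any), `folds`.
#' @export
cross_validate <- function(method, data, k = 5, seed = 1, config,
                           selection = NULL, select_k = 5,
                           valid_fraction = 0) {
  stopifnot(inherits(data, "deepgam_dataset"))
  plan <- make_folds(data, k, seed)
  fold_reports <- vector("list", k)
  selected <- vector("list", k)
  for (i in seq_len(k)) {
    tr_rows <- plan$folds[[i]]$train
    te_rows <- plan$folds[[i]]$test
    tr <- dataset_rows(data, tr_rows)
    te <- dataset_rows(data, te_rows)
    fold_cfg <- config
    fold_cfg$seed <- derive_seed(seed, i)

    valid <- NULL
    if (valid_fraction > 0) {
      sp <- split_dataset(tr, test_fraction = valid_fraction,
                          seed = derive_seed(seed, 100 + i))
      tr <- sp$train
      valid <- sp$test
    }

    if (!is.null(selection)) {
      sel <- select_features_on(tr, selection, select_k, fold_cfg)
      selected[[i]] <- sel
      tr <- dataset_cols(tr, sel)
      te <- dataset_cols(te, sel)
      if (!is.null(valid)) valid <- dataset_cols(valid, sel)
      if (identical(method, "deepgam")) fold_cfg$lambda2 <- 0
    }

    scaler <- fit_standardizer(tr)
    tr_std <- apply_standardizer(tr, scaler)
    valid_std <- if (is.null(valid)) NULL else apply_standardizer(valid, scaler)
    fitted <- if (identical(method, "deepgam") && !is.null(selection)) {
      # gates frozen alive when retraining on a pre-selected subset
      model <- init_model(ncol(tr_std$features), C = fold_cfg$C,
                          phi_init = fold_cfg$phi_init, seed = fold_cfg$seed,
                          use_tanh = fold_cfg$use_tanh,
                          feature_names = tr_std$feature_names)
      fit <- train(model, tr_std, valid_std, fold_cfg, freeze_gates = TRUE)
      model <- fit$model
      model$scaler <- scaler
      list(fit = model,
           score = function(Xraw) predict_scores(model, Xraw)$scores)
    } else {
      fit_method(method, tr_std, valid_std, fold_cfg, scaler)
    }
    fold_reports[[i]] <- evaluate_scores(fitted$score(te$features), te$labels)
  }
  metrics <- c("auc", "accuracy", "f1", "precision", "recall", "specificity")
  mean_report <- vapply(metrics, function(m)
    mean(vapply(fold_reports, `[[`, numeric(1), m)), numeric(1))
  structure(
    list(fold_reports = fold_reports,
         mean_report = as.list(mean_report),
         selected = selected, folds = plan, method = method,
         selection = selection),
    class = "deepgam_cv_report")
}

# Rank features on a training split only and return the top-k indices.
select_features_on <- function(tr, selection, k, config) {
  scaler <- fit_standardizer(tr)
  tr_std <- apply_standardizer(tr, scaler)
  ranking <- switch(selection,
    ste = {
      model <- init_model(ncol(tr_std$features), C = config$C,
                          phi_init = config$phi_init, seed = config$seed,
                          use_tanh = config$use_tanh,
                          feature_names = tr_std$feature_names)
      rank_by_gate(train(model, tr_std, NULL, config)$model)
    },
    lasso = rank_by_l1(tr_std, k = k),
    stop(sprintf("unknown selection method '%s'", selection), call. = FALSE))
  utils::head(ranking$feature_index, k)
}

#' Stratified train/test split
#'
#' @param data A [deepgam_dataset()].
#' @param test_fraction Fraction of rows held out (stratified by class for
#'   classification data).
#' @param seed Integer seed.
#' @return List with `train` and `test` datasets plus the held-out row
#'   indices `test_rows`.
#' @export
split_dataset <- function(data, test_fraction = 0.3, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- nrow(data$features)
  te <- with_seed(seed, {
    if (data$mode == "classification") {
      pos <- which(data$labels == 1)
      neg <- which(data$labels == -1)
      sort(c(sample(pos, max(1, round(length(pos) * test_fraction))),
             sample(neg, max(1, round(length(neg) * test_fraction)))))
    } else {
      sort(sample.int(n, max(1, round(n * test_fraction))))
    }
  })
  list(train = dataset_rows(data, setdiff(seq_len(n), te)),
       test = dataset_rows(data, te),
       test_rows = te)
}
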