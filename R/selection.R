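#' Rank features by straight-through gate logit
#'
#' Orders all features by their gate logit `phi` descending (ties broken
#' by lower index first); alive features necessarily precede dead ones.
#'
#' @param model A trained `deepgam_model`.
#' @return A `deepgam_ranking`: data frame with columns `rank`,
#'   `feature_index`, `feature_name`, `score` (the logit) and `method`.
#' @export
rank_by_gate <- function(model) {
  stopifnot(inherits(model, "deepgam_model"))
  ord <- order(-model$phi, seq_along(model$phi))
  ranking <- data.frame(
    rank = seq_along(ord),
    feature_index = ord,
    feature_name = model$feature_names[ord],
    score = model$phi[ord],
    method = "ste",
    stringsAsFactors = FALSE)
  class(ranking) <- c("deepgam_ranking", "data.frame")
  ranking
}

# Cyclic coordinate-descent lasso on standardized columns:
# minimize (1/2n) ||y - b0 - X w||^2 + lambda ||w||_1.
lasso_cd <- function(X, y, lambda, maxit = 2000, tol = 1e-9) {
  n <- nrow(X); m <- ncol(X)
  b0 <- mean(y)
  r <- y - b0
  w <- rep(0, m)
  xsq <- colMeans(X^2) # 1 for exactly standardized columns
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(m)) {
      if (xsq[j] == 0) next
      rho <- sum(X[, j] * r) / n + xsq[j] * w[j]
      wj <- soft(rho, lambda) / xsq[j]
      if (wj != w[j]) {
        r <- r - X[, j] * (wj - w[j])
        delta <- max(delta, abs(wj - w[j]))
        w[j] <- wj
      }
    }
    if (delta < tol) break
  }
  list(w = w, b0 = b0)
}

#' Rank features by L1-penalized linear-model coefficients
#'
#' Fits a lasso linear regression of the +1/-1 target on the standardized
#' features by cyclic coordinate descent and orders features by
#' coefficient magnitude. With `regularization_strength = 0` this reduces
#' to least-squares coefficient ranking. When `k` is given and no strength
#' is supplied, the strength is chosen by bisection as the largest value
#' keeping at least `k` coefficients nonzero.
#'
#' @param data A standardized classification [deepgam_dataset()].
#' @param regularization_strength Nonnegative lasso penalty `lambda`.
#' @param k Optional number of features that must remain nonzero.
#' @return A `deepgam_ranking` (columns as in [rank_by_gate()], `score` =
#'   absolute coefficient, `method = "lasso"`).
#' @export
rank_by_l1 <- function(data, regularization_strength = NULL, k = NULL) {
  stopifnot(inherits(data, "deepgam_dataset"))
  X <- data$features
  y <- data$labels
  n <- nrow(X)
  if (is.null(regularization_strength)) {
    if (is.null(k)) stop("supply regularization_strength or k", call. = FALSE)
    lam_max <- max(abs(crossprod(X, y - mean(y)) / n))
    lo <- 0; hi <- lam_max
    lam <- lam_max / 2
    for (it in seq_len(60)) {
      lam <- (lo + hi) / 2
      nz <- sum(lasso_cd(X, y, lam)$w != 0)
      if (nz >= k) lo <- lam else hi <- lam
    }
    regularization_strength <- lo
  }
  fit <- if (regularization_strength == 0) {
    list(w = stats::lm.fit(cbind(1, X), y)$coefficients[-1])
  } else {
    lasso_cd(X, y, regularization_strength)
  }
  w <- as.vector(fit$w)
  w[is.na(w)] <- 0
  if (all(w == 0)) {
    stop("ranking error: all coefficients are zero at this strength; use a smaller regularization_strength",
         call. = FALSE)
  }
  ord <- order(-abs(w), seq_along(w))
  ranking <- data.frame(
    rank = seq_along(ord),
    feature_index = ord,
    feature_name = data$feature_names[ord],
    score = abs(w)[ord],
    method = "lasso",
    stringsAsFactors = FALSE)
  class(ranking) <- c("deepgam_ranking", "data.frame")
  ranking
}

#' Serialize a feature ranking as CSV
#'
#' @param ranking A `deepgam_ranking`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.csv(as.data.frame(ranking), path, row.names = FALSE)
  invisible(path)
}

#' Retrain a model on the top-k features of a ranking
#'
#' Restricts the data to the top `k` ranked features and retrains the
#' chosen head from scratch with the shared config. For the DeepGAM head
#' the gates are frozen alive (`phi` excluded from optimization, `lambda2`
#' set to 0) so selection is not repeated during retraining.
#'
#' @param data A standardized [deepgam_dataset()] (training split).
#' @param ranking A `deepgam_ranking`.
#' @param k Number of top features to keep (1 <= k <= number ranked).
#' @param config A [training_config()].
#' @param head `"deepgam"`, `"svm"`, `"logistic"` or `"mlp"`.
#' @param valid_data Optional validation split (restricted identically).
#' @return List with `fit` (the trained head), `features` (kept indices,
#'   in rank order), `head`, and `history` for the DeepGAM head.
#' @export
select_and_retrain <- function(data, ranking, k, config,
                               head = c("deepgam", "svm", "logistic", "mlp"),
                               valid_data = NULL) {
  head <- match.arg(head)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k > nrow(ranking)) stop("k exceeds the ranking length", call. = FALSE)
  keep <- ranking$feature_index[seq_len(k)]
  sub <- dataset_cols(data, keep)
  sub_valid <- if (is.null(valid_data)) NULL else dataset_cols(valid_data, keep)
  if (head == "deepgam") {
    cfg <- config
    cfg$lambda2 <- 0
    model <- init_model(k, C = cfg$C, phi_init = cfg$phi_init,
                        seed = cfg$seed, mode = cfg$mode,
                        use_tanh = cfg$use_tanh,
                        feature_names = sub$feature_names)
    fit <- train(model, sub, sub_valid, cfg, freeze_gates = TRUE)
    list(fit = fit$model, features = keep, head = head,
         history = fit$history)
  } else if (head == "mlp") {
    list(fit = train_mlp(sub, config), features = keep, head = head)
  } else {
    list(fit = train_linear(sub, config,
                            loss_kind = if (head == "svm") "hinge"
                                        else "logistic"),
         features = keep, head = head)
  }
}
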