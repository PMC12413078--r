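#' Training configuration
#'
#' Bundles every hyperparameter of the DeepGAM objective
#' `L + lambda1 * R1 + lambda2 * R2` and its SGD optimizer. The defaults
#' are the reference settings: learning rate 0.01, batch size 16, 40
#' epochs, channel width `C = 128`, `lambda1 = 1`, `lambda2 = 0.005`,
#' gate-logit initialization 0.05, and L2 weight decay 0.001 (applied to
#' the shape weights and intercept, not to the gate logits).
#'
#' @param learning_rate SGD learning rate (>= 0).
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of passes (>= 1).
#' @param lambda1 Weight of the interpretability regularizer R1.
#' @param lambda2 Weight of the resource regularizer R2.
#' @param weight_decay L2 penalty weight on theta and beta0.
#' @param phi_init Initial gate logit.
#' @param C Shape-network channel width.
#' @param seed Integer seed driving initialization and batch sampling.
#' @param use_R1 Include R1 in the objective (ablation toggle).
#' @param use_tanh Apply the output tanh in every shape network.
#' @param rebalance Draw training batches with the class-rebalancing
#'   sampler (classification only).
#' @param mode `"classification"` or `"regression"`.
#' @return An object of class `deepgam_config`.
#' @export
training_config <- function(learning_rate = 0.01, batch_size = 16,
                            epochs = 40, lambda1 = 1, lambda2 = 0.005,
                            weight_decay = 0.001, phi_init = 0.05,
                            C = 128, seed = 1, use_R1 = TRUE,
                            use_tanh = TRUE, rebalance = TRUE,
                            mode = c("classification", "regression")) {
  mode <- match.arg(mode)
  stopifnot(learning_rate >= 0, batch_size >= 1, epochs >= 1,
            lambda1 >= 0, lambda2 >= 0, weight_decay >= 0, C >= 1)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), lambda1 = lambda1, lambda2 = lambda2,
         weight_decay = weight_decay, phi_init = phi_init,
         C = as.integer(C), seed = as.integer(seed),
         use_R1 = isTRUE(use_R1), use_tanh = isTRUE(use_tanh),
         rebalance = isTRUE(rebalance), mode = mode),
    class = "deepgam_config")
}

#' Mean-squared-error loss for +1/-1 classification (or regression)
#'
#' @param scores Numeric vector of model scores.
#' @param labels Numeric vector of targets (same length).
#' @return Mean over the batch of `(score - label)^2`.
#' @export
mse_loss <- function(scores, labels) {
  if (length(scores) == 0L) stop("empty batch", call. = FALSE)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  mean((scores - labels)^2)
}

#' Interpretability regularizer R1
#'
#' Discourages large offsetting per-feature effects: the mean over the
#' batch of the sum over features of squared contributions,
#' `R1 = mean_i sum_j f_j(z_ij)^2`.
#'
#' @param contributions Batch x M matrix of per-feature contributions.
#' @return The R1 penalty value.
#' @export
interpretability_penalty <- function(contributions) {
  contributions <- as.matrix(contributions)
  sum(contributions^2) / nrow(contributions)
}

#' Resource regularizer R2
#'
#' Forward value: the number of alive gates, `sum_j g(phi_j)`. In the
#' backward pass the gradient flows as if the value were
#' `sum_j sigma(phi_j)` (straight-through estimator; see
#' [gate_backward_surrogate()]), so the per-logit gradient is
#' `sigma'(phi_j)`.
#'
#' @param phi Vector of gate logits.
#' @return The alive-feature count.
#' @export
resource_penalty <- function(phi) {
  sum(gate_forward(phi))
}

#' Total training objective
#'
#' `L + lambda1 * R1 + lambda2 * R2`, with R1 dropped when the config's
#' `use_R1` toggle is off. The L2 weight decay is part of the optimizer
#' update (on theta and beta0 only), not of the reported objective value.
#'
#' @param scores,labels Batch scores and +/-1 targets.
#' @param contributions Batch x M contribution matrix.
#' @param phi Gate logits.
#' @param config A [training_config()].
#' @return The objective value.
#' @export
total_objective <- function(scores, labels, contributions, phi, config) {
  obj <- mse_loss(scores, labels)
  if (config$use_R1) {
    obj <- obj + config$lambda1 * interpretability_penalty(contributions)
  }
  obj + config$lambda2 * resource_penalty(phi)
}

#' Class-rebalancing sampler for imbalanced labels
#'
#' Draws row indices with replacement, each row weighted inversely to its
#' class frequency, so the expected positive fraction of a draw is 0.5
#' regardless of the class imbalance.
#'
#' @param labels +1/-1 label vector (both classes must be present).
#' @param seed Integer seed; the index stream is deterministic given it.
#' @param n_draws Number of indices to draw (default one epoch's worth,
#'   `length(labels)`).
#' @return Integer vector of row indices.
#' @export
balanced_sampler <- function(labels, seed, n_draws = length(labels)) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0L || n_neg == 0L) {
    stop("sampler error: both classes must be present", call. = FALSE)
  }
  w <- ifelse(labels == 1, 1 / n_pos, 1 / n_neg)
  with_seed(seed, sample.int(length(labels), n_draws, replace = TRUE,
                             prob = w))
}

# Build the epochs x N batch-index matrix consumed by the compiled core.
sampler_order <- function(labels, config, n) {
  with_seed(config$seed, {
    rows <- lapply(seq_len(config$epochs), function(e) {
      if (config$rebalance && config$mode == "classification") {
        n_pos <- sum(labels == 1)
        n_neg <- sum(labels == -1)
        if (n_pos == 0L || n_neg == 0L) {
          stop("sampler error: both classes must be present", call. = FALSE)
        }
        w <- ifelse(labels == 1, 1 / n_pos, 1 / n_neg)
        sample.int(n, n, replace = TRUE, prob = w)
      } else {
        sample.int(n)
      }
    })
    do.call(rbind, rows)
  })
}

#' Train a DeepGAM model by stochastic gradient descent
#'
#' Runs `epochs x ceiling(N / batch_size)` SGD steps on the objective
#' `L + lambda1 * R1 + lambda2 * R2` with straight-through gate gradients,
#' recording per-epoch objective components, alive-feature count and (if a
#' validation split is supplied) validation F1 at threshold 0. Training is
#' deterministic for a fixed config and input.
#'
#' @param model A `deepgam_model` whose M matches the data (typically from
#'   [init_model()] with the config's `C` and `phi_init`).
#' @param train_data A standardized [deepgam_dataset()] (the standardizer
#'   may also be attached to the model for later prediction).
#' @param valid_data Optional held-out `deepgam_dataset` for per-epoch F1
#'   tracking.
#' @param config A [training_config()].
#' @param freeze_gates If `TRUE`, gate logits are excluded from
#'   optimization (used when retraining on a pre-selected feature subset).
#' @return A list with `model` (trained `deepgam_model`) and `history`
#'   (data frame: epoch, objective, loss, r1, r2, alive_count, val_f1).
#' @export
train <- function(model, train_data, valid_data = NULL, config,
                  freeze_gates = FALSE) {
  stopifnot(inherits(model, "deepgam_model"),
            inherits(train_data, "deepgam_dataset"),
            inherits(config, "deepgam_config"))
  if (model$M != ncol(train_data$features)) {
    stop("model M does not match the data", call. = FALSE)
  }
  n <- nrow(train_data$features)
  ord <- sampler_order(train_data$labels, config, n)
  has_val <- !is.null(valid_data)
  Xval <- if (has_val) valid_data$features else matrix(0, 1, model$M)
  yval <- if (has_val) valid_data$labels else 0

  fit <- .deepgam_sgd_cpp(
    train_data$features, train_data$labels, Xval, yval, has_val,
    model$theta1, model$theta2, model$theta3, model$phi, model$beta0,
    ord, config$batch_size, config$learning_rate,
    config$lambda1, config$lambda2, config$weight_decay,
    config$use_R1, config$use_tanh, isTRUE(freeze_gates),
    config$mode == "classification")

  trained <- model
  trained$theta1 <- fit$theta1
  trained$theta2 <- fit$theta2
  trained$theta3 <- fit$theta3
  trained$phi <- as.vector(fit$phi)
  trained$beta0 <- fit$beta0
  trained$use_tanh <- config$use_tanh
  trained$mode <- config$mode

  history <- data.frame(
    epoch = seq_len(config$epochs),
    objective = as.vector(fit$objective),
    loss = as.vector(fit$loss),
    r1 = as.vector(fit$r1),
    r2 = as.vector(fit$r2),
    alive_count = as.integer(fit$alive),
    val_f1 = as.vector(fit$val_f1))
  list(model = trained, history = history)
}

#' Export a training history as CSV
#'
#' Columns: epoch, objective, loss, r1, r2, alive_count, val_f1 — enough
#' to reproduce alive-count and validation-F1 training curves.
#'
#' @param history The history data frame returned by [train()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
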