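#' Gradient-trained linear classifier heads (SVM and logistic regression)
#'
#' Both baselines are a single linear layer `score = w . x + b` trained by
#' SGD with the shared [training_config()] hyperparameters:
#' \describe{
#'   \item{hinge}{margin-based loss `mean(max(0, 1 - y * score))` — the
#'     SVM construction used for comparison.}
#'   \item{logistic}{cross-entropy loss `mean(log(1 + exp(-y * score)))`.}
#' }
#' L2 weight decay is applied to `w` and `b`; batches come from the same
#' class-rebalancing sampler as DeepGAM when `config$rebalance` is on.
#'
#' @param data A standardized classification [deepgam_dataset()].
#' @param config A [training_config()].
#' @param loss_kind `"hinge"` or `"logistic"`.
#' @return A `deepgam_linear_head`: list with `weights`, `bias`,
#'   `loss_kind`.
#' @export
train_linear <- function(data, config, loss_kind = c("hinge", "logistic")) {
  loss_kind <- match.arg(loss_kind)
  stopifnot(inherits(data, "deepgam_dataset"),
            inherits(config, "deepgam_config"))
  X <- data$features
  y <- data$labels
  n <- nrow(X); m <- ncol(X)
  ord <- sampler_order(y, config, n)
  w <- rep(0, m); b <- 0
  lr <- config$learning_rate; wd <- config$weight_decay
  bs <- config$batch_size
  steps <- ceiling(n / bs)
  for (e in seq_len(config$epochs)) {
    for (s in seq_len(steps)) {
      idx <- ord[e, ((s - 1) * bs + 1):min(s * bs, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      B <- length(idx)
      sc <- as.vector(Xb %*% w) + b
      if (loss_kind == "hinge") {
        active <- (yb * sc) < 1
        ds <- ifelse(active, -yb, 0) / B
      } else {
        ds <- -yb * sigmoid(-yb * sc) / B
      }
      gw <- as.vector(crossprod(Xb, ds))
      gb <- sum(ds)
      w <- w - lr * (gw + wd * w)
      b <- b - lr * (gb + wd * b)
    }
  }
  structure(list(weights = w, bias = b, loss_kind = loss_kind,
                 feature_names = data$feature_names),
            class = "deepgam_linear_head")
}

#' Scores from a linear head
#'
#' @param head A `deepgam_linear_head`.
#' @param X Standardized feature matrix.
#' @return Numeric score vector (threshold 0 separates the classes).
#' @export
predict_linear <- function(head, X) {
  as.vector(as.matrix(X) %*% head$weights) + head$bias
}

#' Hinge and logistic losses (exposed for testing and diagnostics)
#'
#' @param scores Numeric scores.
#' @param labels +1/-1 labels.
#' @return The mean loss over the batch.
#' @export
hinge_loss <- function(scores, labels) {
  mean(pmax(0, 1 - labels * scores))
}

#' @rdname hinge_loss
#' @export
logistic_loss <- function(scores, labels) {
  mean(log1p(exp(-labels * scores)))
}

#' Gradient-trained multilayer-perceptron baseline
#'
#' Three fully connected layers (with biases) and ReLU activations,
#' producing two class scores trained with softmax cross-entropy. Hidden
#' width, optimizer settings and the rebalancing sampler are shared with
#' the DeepGAM config.
#'
#' @param data A standardized classification [deepgam_dataset()].
#' @param config A [training_config()]; `config$C` is the hidden width.
#' @return A `deepgam_mlp_head` with weight matrices `W1`, `W2`, `W3` and
#'   biases `b1`, `b2`, `b3`.
#' @export
train_mlp <- function(data, config) {
  stopifnot(inherits(data, "deepgam_dataset"),
            inherits(config, "deepgam_config"))
  X <- data$features
  y01 <- as.integer(data$labels == 1) # 1 = positive class
  n <- nrow(X); m <- ncol(X); C <- config$C
  params <- with_seed(derive_seed(config$seed, 7), list(
    W1 = matrix(stats::runif(m * C, -1, 1) / sqrt(m), m, C),
    b1 = rep(0, C),
    W2 = matrix(stats::runif(C * C, -1, 1) / sqrt(C), C, C),
    b2 = rep(0, C),
    W3 = matrix(stats::runif(C * 2, -1, 1) / sqrt(C), C, 2),
    b3 = rep(0, 2)))
  W1 <- params$W1; b1 <- params$b1
  W2 <- params$W2; b2 <- params$b2
  W3 <- params$W3; b3 <- params$b3
  ord <- sampler_order(data$labels, config, n)
  lr <- config$learning_rate; wd <- config$weight_decay
  bs <- config$batch_size
  steps <- ceiling(n / bs)
  for (e in seq_len(config$epochs)) {
    for (s in seq_len(steps)) {
      idx <- ord[e, ((s - 1) * bs + 1):min(s * bs, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y01[idx]
      B <- length(idx)
      a1 <- sweep(Xb %*% W1, 2L, b1, "+"); h1 <- pmax(a1, 0)
      a2 <- sweep(h1 %*% W2, 2L, b2, "+"); h2 <- pmax(a2, 0)
      logits <- sweep(h2 %*% W3, 2L, b3, "+")
      mx <- pmax(logits[, 1], logits[, 2])
      lse <- mx + log(exp(logits[, 1] - mx) + exp(logits[, 2] - mx))
      p <- exp(logits - lse) # softmax, column 2 = positive class
      dlog <- p
      dlog[cbind(seq_len(B), yb + 1L)] <-
        dlog[cbind(seq_len(B), yb + 1L)] - 1
      dlog <- dlog / B
      gW3 <- crossprod(h2, dlog); gb3 <- colSums(dlog)
      dh2 <- tcrossprod(dlog, W3) * (a2 > 0)
      gW2 <- crossprod(h1, dh2); gb2 <- colSums(dh2)
      dh1 <- tcrossprod(dh2, W2) * (a1 > 0)
      gW1 <- crossprod(Xb, dh1); gb1 <- colSums(dh1)
      W3 <- W3 - lr * (gW3 + wd * W3); b3 <- b3 - lr * (gb3 + wd * b3)
      W2 <- W2 - lr * (gW2 + wd * W2); b2 <- b2 - lr * (gb2 + wd * b2)
      W1 <- W1 - lr * (gW1 + wd * W1); b1 <- b1 - lr * (gb1 + wd * b1)
    }
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3,
                 feature_names = data$feature_names),
            class = "deepgam_mlp_head")
}

#' Scores and class probabilities from an MLP head
#'
#' @param head A `deepgam_mlp_head`.
#' @param X Standardized feature matrix.
#' @return List with `score` (positive minus negative logit; threshold 0)
#'   and `prob` (softmax probability of the positive class, the continuous
#'   score used for ROC).
#' @export
predict_mlp <- function(head, X) {
  X <- as.matrix(X)
  h1 <- pmax(sweep(X %*% head$W1, 2L, head$b1, "+"), 0)
  h2 <- pmax(sweep(h1 %*% head$W2, 2L, head$b2, "+"), 0)
  logits <- sweep(h2 %*% head$W3, 2L, head$b3, "+")
  score <- logits[, 2] - logits[, 1]
  list(score = score, prob = sigmoid(score))
}
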