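# Shared test helpers: small fixtures built in code, plus independent
# oracles (naive implementations) that the package code is checked against.

# Tiny deterministic classification dataset.
tiny_dataset <- function(n = 40, m = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * m), n, m)
    y <- ifelse(X[, 1] + 0.5 * rnorm(n) > 0, 1, -1)
    if (all(y == y[1])) y[1] <- -y[1]
    deepgam_dataset(X, y)
  })
}

# Naive layer-by-layer forward of the shape network (independent of the
# half-line-collapsed fast path used by the package).
naive_shape_forward <- function(z, theta1, theta2, theta3, use_tanh = TRUE) {
  sapply(z, function(zi) {
    h1 <- pmax(theta1 * zi, 0)
    h2 <- pmax(as.vector(theta2 %*% h1), 0)
    p3 <- sum(theta3 * h2)
    if (use_tanh) tanh(p3) else p3
  })
}

# Brute-force confusion counting, one row at a time.
naive_confusion <- function(preds, labels) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(preds)) {
    if (preds[i] == 1 && labels[i] == 1) tp <- tp + 1L
    else if (preds[i] == 1 && labels[i] == -1) fp <- fp + 1L
    else if (preds[i] == -1 && labels[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# Mann-Whitney pair-counting AUC oracle (ties half-credited).
pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# One full-batch objective evaluation in plain R (direct composition),
# used for finite-difference gradient checks of the training core.
full_objective <- function(model, X, y, lambda1, lambda2, use_R1 = TRUE,
                           use_tanh = TRUE) {
  n <- nrow(X)
  g <- as.numeric(model$phi >= 0)
  contrib <- sapply(seq_len(model$M), function(j) {
    naive_shape_forward(X[, j] * g[j], model$theta1[, j],
                        matrix(model$theta2[, , j], model$C, model$C),
                        model$theta3[, j], use_tanh)
  })
  scores <- model$beta0 + rowSums(contrib)
  obj <- mean((scores - y)^2)
  if (use_R1) obj <- obj + lambda1 * sum(contrib^2) / n
  obj + lambda2 * sum(g)
}

# Run exactly one full-batch SGD step through the compiled core and return
# the recovered gradients (old - new) / lr for every parameter block.
one_step_gradients <- function(model, X, y, lambda1 = 0.7, lambda2 = 0.3,
                               use_R1 = TRUE, use_tanh = TRUE,
                               freeze_phi = FALSE, lr = 1e-7) {
  n <- nrow(X)
  cfg <- training_config(learning_rate = lr, batch_size = n, epochs = 1,
                         lambda1 = lambda1, lambda2 = lambda2,
                         weight_decay = 0, C = model$C, seed = 1,
                         use_R1 = use_R1, use_tanh = use_tanh,
                         rebalance = FALSE)
  fit <- train(model, deepgam_dataset(X, y), NULL, cfg,
               freeze_gates = freeze_phi)
  list(theta1 = (model$theta1 - fit$model$theta1) / lr,
       theta2 = (model$theta2 - fit$model$theta2) / lr,
       theta3 = (model$theta3 - fit$model$theta3) / lr,
       phi = (model$phi - fit$model$phi) / lr,
       beta0 = (model$beta0 - fit$model$beta0) / lr)
}

# Deterministic random model with non-degenerate weights in every layer
# (init_model starts theta3 at zero; tests of forward properties need
# nonzero output layers).
random_model <- function(M, C, seed, phi = NULL, use_tanh = TRUE) {
  m <- init_model(M, C = C, seed = seed, use_tanh = use_tanh)
  withr::with_seed(seed + 1000, {
    m$theta3 <- matrix(runif(C * M, -1 / sqrt(C), 1 / sqrt(C)), C, M)
    if (is.null(phi)) phi <- runif(M, -1, 1)
  })
  m$phi <- phi
  m
}
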