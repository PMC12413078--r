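#' Initialize a DeepGAM model
#'
#' A DeepGAM model is an additive model `score = beta0 + sum_j f_j(x_j *
#' g(phi_j))`: one bias-free three-layer shape network `f_j` per feature
#' (ReLU, ReLU, tanh activations), a binary straight-through gate `g` per
#' feature, and a learnable global intercept `beta0`.
#'
#' Gate logits are all set to `phi_init`; with the default 0.05 every
#' feature starts alive (`sigma(0.05) = 0.5125 >= 0.5`). Hidden-layer
#' weights are drawn uniformly in `+/- 1/sqrt(fan-in)`; the output layer
#' `theta3` and the intercept start at exactly 0, so every shape function
#' (and the whole model) starts as the null model `f_j == 0`. Zeroing the
#' output layer keeps the additive sum of many per-feature networks from
#' collectively overshooting in the first epochs, which with wide feature
#' sets would otherwise inject large random kicks into the gate logits.
#'
#' @param M Number of features (>= 1).
#' @param C Channel width of each shape network (>= 1); default 128.
#' @param phi_init Initial gate logit; default 0.05.
#' @param seed Integer seed for the weight draw.
#' @param mode `"classification"` or `"regression"`.
#' @param use_tanh Apply the output tanh (default `TRUE`); turning it off
#'   removes the (-1, 1) bound on each feature's contribution (ablation).
#' @param feature_names Optional feature names carried by the model.
#'
#' @return An object of class `deepgam_model`.
#' @export
init_model <- function(M, C = 128, phi_init = 0.05, seed = 1,
                       mode = c("classification", "regression"),
                       use_tanh = TRUE, feature_names = NULL) {
  mode <- match.arg(mode)
  stopifnot(M >= 1, C >= 1)
  M <- as.integer(M); C <- as.integer(C)
  with_seed(seed, {
    theta1 <- matrix(stats::runif(C * M, -1, 1), C, M)
    theta2 <- array(stats::runif(C * C * M, -1 / sqrt(C), 1 / sqrt(C)),
                    dim = c(C, C, M))
    theta3 <- matrix(0, C, M)
    structure(
      list(phi = rep(phi_init, M), theta1 = theta1, theta2 = theta2,
           theta3 = theta3, beta0 = 0, M = M, C = C, mode = mode,
           use_tanh = use_tanh, scaler = NULL,
           feature_names = feature_names %||% paste0("x", seq_len(M))),
      class = "deepgam_model")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.deepgam_model <- function(x, ...) {
  cat(sprintf("<deepgam_model> M=%d features, C=%d channels (%s%s)\n",
              x$M, x$C, x$mode, if (x$use_tanh) "" else ", no tanh"))
  cat(sprintf("  alive gates: %d / %d; beta0 = %.4g\n",
              sum(x$phi >= 0), x$M, x$beta0))
  invisible(x)
}

#' Straight-through gate: forward pass
#'
#' The forward gate is the rounded sigmoid of the logit: `g(phi) = 1` iff
#' `sigma(phi) >= 0.5`, i.e. iff `phi >= 0` (the tie at `sigma = 0.5`
#' resolves to alive). Vectorized over `phi`.
#'
#' @param phi Gate logit(s), finite.
#' @return 0/1 value(s).
#' @export
gate_forward <- function(phi) {
  as.numeric(phi >= 0)
}

#' Straight-through gate: backward surrogate
#'
#' In the backward pass the gate behaves as the sigmoid `sigma(phi)`, so
#' the returned gradient is `upstream * sigma(phi) * (1 - sigma(phi))`.
#' Dead gates keep receiving gradient and may revive.
#'
#' @param phi Gate logit(s).
#' @param upstream_gradient Upstream gradient(s).
#' @return Gradient(s) with respect to `phi`.
#' @export
gate_backward_surrogate <- function(phi, upstream_gradient) {
  upstream_gradient * sigmoid_grad(phi)
}

#' Extract one per-feature shape network
#'
#' @param model A `deepgam_model`.
#' @param j Feature index.
#' @return List with `theta1` (length-C), `theta2` (C x C), `theta3`
#'   (length-C), `C` and `use_tanh`.
#' @export
get_shape_network <- function(model, j) {
  stopifnot(inherits(model, "deepgam_model"), j >= 1, j <= model$M)
  list(theta1 = model$theta1[, j],
       theta2 = matrix(model$theta2[, , j], model$C, model$C),
       theta3 = model$theta3[, j], C = model$C, use_tanh = model$use_tanh)
}

#' Shape-network forward pass (direct composition)
#'
#' Evaluates `f(z) = tanh(theta3 . relu(theta2 . relu(theta1 z)))` by the
#' literal layer-by-layer composition. Because the network is bias-free,
#' `f(0) = 0` exactly, and with the tanh enabled every output lies in the
#' open interval (-1, 1).
#'
#' @param z Numeric vector of scalar inputs.
#' @param net A shape network from [get_shape_network()] (or any list with
#'   `theta1`, `theta2`, `theta3`).
#' @param use_tanh Apply the output tanh; defaults to the network's flag.
#' @return Numeric vector `f(z)`.
#' @export
shape_forward <- function(z, net, use_tanh = net$use_tanh %||% TRUE) {
  h1 <- pmax(outer(z, net$theta1), 0)
  h2 <- pmax(h1 %*% t(net$theta2), 0)
  pre3 <- as.vector(h2 %*% net$theta3)
  if (use_tanh) tanh(pre3) else pre3
}

# Half-line collapse of the bias-free shape network: positive homogeneity
# of ReLU gives f(z) = act(kp * max(z, 0) + km * max(-z, 0)) with
#   kp = theta3 . relu(theta2 relu(theta1))
#   km = theta3 . relu(theta2 relu(-theta1)).
# Returns a 2 x M matrix (rows kp, km). Used by the batch forward and the
# training core; equality with shape_forward is tested.
model_kappas <- function(model) {
  M <- model$M
  kap <- matrix(0, 2, M)
  for (j in seq_len(M)) {
    p <- pmax(model$theta1[, j], 0)
    m <- pmax(-model$theta1[, j], 0)
    t2 <- matrix(model$theta2[, , j], model$C, model$C)
    kap[1, j] <- sum(model$theta3[, j] * pmax(t2 %*% p, 0))
    kap[2, j] <- sum(model$theta3[, j] * pmax(t2 %*% m, 0))
  }
  kap
}

#' Batch prediction: scores and per-feature contributions
#'
#' @param model A `deepgam_model`.
#' @param X Numeric matrix (rows = samples, columns = the model's M
#'   features), already standardized if the model was trained on
#'   standardized inputs (see `model$scaler`).
#' @param apply_scaler If `TRUE` (default) and the model carries a scaler,
#'   `X` is standardized with it first.
#' @return List with `scores` (length-N) and `contributions` (N x M);
#'   `scores = beta0 + rowSums(contributions)` exactly.
#' @export
predict_scores <- function(model, X, apply_scaler = TRUE) {
  stopifnot(inherits(model, "deepgam_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$M) stop("dimension mismatch: X must have M columns",
                               call. = FALSE)
  if (apply_scaler && !is.null(model$scaler)) {
    X <- sweep(sweep(X, 2L, model$scaler$mean), 2L, model$scaler$sd, "/")
  }
  g <- gate_forward(model$phi)
  Z <- sweep(X, 2L, g, "*")
  kap <- model_kappas(model)
  pre3 <- sweep(pmax(Z, 0), 2L, kap[1, ], "*") +
          sweep(pmax(-Z, 0), 2L, kap[2, ], "*")
  contrib <- if (model$use_tanh) tanh(pre3) else pre3
  colnames(contrib) <- model$feature_names
  list(scores = model$beta0 + rowSums(contrib), contributions = contrib)
}

#' Forward pass for a single input row
#'
#' @param x Length-M numeric vector.
#' @param model A `deepgam_model`.
#' @param apply_scaler Standardize `x` with the model's scaler if present.
#' @return List with `score` (real) and `contributions` (length-M vector);
#'   `score = beta0 + sum(contributions)` exactly, and dead features
#'   contribute exactly 0.
#' @export
model_forward <- function(x, model, apply_scaler = TRUE) {
  if (length(x) != model$M) stop("dimension mismatch: x must have length M",
                                 call. = FALSE)
  p <- predict_scores(model, matrix(x, nrow = 1), apply_scaler = apply_scaler)
  list(score = p$scores[1], contributions = p$contributions[1, ])
}

#' Threshold a score into a class label
#'
#' Returns `+1` iff `score > t` (strict inequality), else `-1`. The
#' default threshold 0 is symmetric for +1/-1 targets with tanh-bounded
#' additive parts; ROC analysis sweeps all thresholds.
#'
#' @param score Numeric score(s).
#' @param t Threshold (default 0).
#' @return Vector of +1/-1.
#' @export
classify <- function(score, t = 0) {
  ifelse(score > t, 1, -1)
}

#' Alive features, ranked by gate logit
#'
#' @param model A `deepgam_model`.
#' @return Integer vector of feature indices with `phi >= 0`, ordered by
#'   `phi` descending (ties broken by lower index first).
#' @export
alive_features <- function(model) {
  idx <- which(model$phi >= 0)
  idx[order(-model$phi[idx], idx)]
}

MODEL_FORMAT_VERSION <- "deepgam-model/1"

# Verbatim JSON for a numeric vector at 17 significant digits, which
# round-trips IEEE doubles exactly.
json_num <- function(x) {
  structure(paste0("[", paste(sprintf("%.17g", x), collapse = ","), "]"),
            class = "json")
}

#' Save / load a DeepGAM model
#'
#' Models are stored as a single versioned JSON file with parameters at
#' full precision (17 significant digits), so a save/load round trip is
#' bit-faithful for all parameters, the attached scaler, and the mode.
#'
#' @param model A `deepgam_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model. A corrupt file or an unknown format version is a load error.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "deepgam_model"))
  obj <- list(
    format = MODEL_FORMAT_VERSION,
    M = model$M, C = model$C, mode = model$mode, use_tanh = model$use_tanh,
    phi = json_num(model$phi), beta0 = json_num(model$beta0),
    theta1 = json_num(as.vector(model$theta1)),
    theta2 = json_num(as.vector(model$theta2)),
    theta3 = json_num(as.vector(model$theta3)),
    feature_names = model$feature_names,
    scaler = if (is.null(model$scaler)) NULL else list(
      mean = json_num(unname(model$scaler$mean)),
      sd = json_num(unname(model$scaler$sd)),
      degenerate = unname(model$scaler$degenerate),
      feature_names = model$scaler$feature_names)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", json_verbatim = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop(sprintf("corrupt model file: %s", conditionMessage(e)),
                         call. = FALSE))
  if (is.null(obj$format) || !identical(obj$format, MODEL_FORMAT_VERSION)) {
    stop(sprintf("unsupported model format: %s",
                 obj$format %||% "<missing>"), call. = FALSE)
  }
  M <- as.integer(obj$M); C <- as.integer(obj$C)
  scaler <- NULL
  if (!is.null(obj$scaler)) {
    scaler <- structure(
      list(mean = stats::setNames(obj$scaler$mean, obj$scaler$feature_names),
           sd = stats::setNames(obj$scaler$sd, obj$scaler$feature_names),
           degenerate = stats::setNames(as.logical(obj$scaler$degenerate),
                                        obj$scaler$feature_names),
           feature_names = obj$scaler$feature_names),
      class = "deepgam_scaler")
  }
  structure(
    list(phi = as.numeric(obj$phi),
         theta1 = matrix(as.numeric(obj$theta1), C, M),
         theta2 = array(as.numeric(obj$theta2), dim = c(C, C, M)),
         theta3 = matrix(as.numeric(obj$theta3), C, M),
         beta0 = as.numeric(obj$beta0), M = M, C = C,
         mode = obj$mode, use_tanh = as.logical(obj$use_tanh),
         scaler = scaler, feature_names = obj$feature_names),
    class = "deepgam_model")
}
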