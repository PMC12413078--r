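#' Shape-function catalogue for synthetic ground truth
#'
#' Five named families of smooth univariate effects used by the synthetic
#' generator, each bounded on the sampled domain:
#' \describe{
#'   \item{linear}{`slope * x`}
#'   \item{saturating}{`amp * tanh(scale * x)`}
#'   \item{bump}{`amp * exp(-(x - center)^2 / (2 * width^2))`}
#'   \item{step}{`amp * (sigmoid(steep * (x - center)) - 0.5)`, a smooth
#'     step through `center`}
#'   \item{quadratic}{`coef * (x^2 - 1)`, mean-zero under a standard-normal
#'     input}
#' }
#'
#' @param name Family name.
#' @param ... Family parameters overriding the defaults above
#'   (`slope = 1`, `amp = 1.5`, `scale = 1.2`, `center`, `width = 0.6`,
#'   `steep = 3`, `coef = 0.8`).
#' @return A `deepgam_shape_spec`: list with `name`, `params` and `bound`,
#'   the maximum absolute value the family attains on \[-4, 4\].
#' @export
shape_spec <- function(name = c("linear", "saturating", "bump", "step",
                                "quadratic"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    linear     = list(slope = 1),
    saturating = list(amp = 1.5, scale = 1.2),
    bump       = list(amp = 1.5, center = 0, width = 0.8),
    step       = list(amp = 1.5, steep = 3, center = 0),
    quadratic  = list(coef = 0.8)
  )
  params <- utils::modifyList(defaults, list(...))
  bound <- switch(name,
    linear     = 4 * abs(params$slope),
    saturating = abs(params$amp),
    bump       = abs(params$amp),
    step       = abs(params$amp) / 2,
    quadratic  = 15 * abs(params$coef)
  )
  structure(list(name = name, params = params, bound = bound),
            class = "deepgam_shape_spec")
}

# Evaluate one catalogue shape at a numeric vector x.
eval_shape <- function(spec, x) {
  p <- spec$params
  switch(spec$name,
    linear     = p$slope * x,
    saturating = p$amp * tanh(p$scale * x),
    bump       = p$amp * exp(-(x - p$center)^2 / (2 * p$width^2)),
    step       = p$amp * (sigmoid(p$steep * (x - p$center)) - 0.5),
    quadratic  = p$coef * (x^2 - 1)
  )
}

# Exponential tilt: turns standard-normal z into a right-skewed column with
# zero mean and unit variance; a = 0 is the identity.
skew_transform <- function(z, a) {
  if (a <= 0) return(z)
  (exp(a * z) - exp(a^2 / 2)) / sqrt(exp(a^2) * (exp(a^2) - 1))
}

# Name of the multiplicative amplitude parameter of each family.
amp_param <- function(name) {
  switch(name, linear = "slope", quadratic = "coef", "amp")
}

# Rescale a shape spec so that its effect over the sampled column has the
# requested robust scale: unit standard deviation after trimming the most
# extreme 1% of effect values on each side (plain sd would be dominated by
# the heavy right tail of skewed features). Returns the adjusted spec.
normalize_effect <- function(spec, x, effect_scale) {
  f <- eval_shape(spec, x)
  q <- stats::quantile(f, c(0.01, 0.99), names = FALSE)
  s <- stats::sd(pmin(pmax(f, q[1]), q[2]))
  if (s <= 0) return(spec) # degenerate effect; leave untouched
  p <- amp_param(spec$name)
  do.call(shape_spec,
          c(list(name = spec$name),
            utils::modifyList(spec$params,
                              stats::setNames(list(spec$params[[p]] *
                                                     effect_scale / s), p))))
}

default_shape_assignment <- function(m_informative, shapes) {
  families <- c("linear", "saturating", "bump", "step", "quadratic")
  if (is.null(shapes)) shapes <- families
  if (is.character(shapes)) {
    shapes <- lapply(rep_len(shapes, m_informative), shape_spec)
  } else {
    stopifnot(all(vapply(shapes, inherits, logical(1), "deepgam_shape_spec")))
    shapes <- rep_len(shapes, m_informative)
  }
  shapes
}

#' Generate imbalanced classification data with known additive ground truth
#'
#' Features are drawn i.i.d. standard normal and passed through an
#' exponential tilt when `skew > 0`, producing right-skewed columns. A
#' latent score `s = intercept + sum_j f*_j(x_j) + eps`,
#' `eps ~ N(0, noise_sd)`, drives the label (`+1` iff `s > 0`); the
#' intercept is tuned by bisection on the sampled latent scores so the
#' realized positive fraction is within one percentage point of
#' `positive_rate`.
#'
#' @param n Number of rows (>= 20).
#' @param m_informative Number of features with nonzero effect (>= 1).
#' @param m_noise Number of features with identically zero effect.
#' @param skew Nonnegative tilt parameter `a`; 0 gives symmetric columns.
#' @param positive_rate Target positive-class fraction in (0, 1).
#' @param noise_sd Standard deviation of the latent noise.
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @param shapes Optional shape assignment for the informative features:
#'   a character vector of catalogue family names (recycled) or a list of
#'   [shape_spec()] objects. Defaults to cycling through the catalogue.
#' @param informative_first If `TRUE` the informative features occupy
#'   columns 1..m_informative; otherwise (default) their positions are
#'   drawn at random.
#' @param intercept Optional fixed latent intercept; when supplied the
#'   bisection tuning of the positive rate is skipped.
#' @param normalize_effects If `TRUE` (default) each informative effect is
#'   rescaled (via its family's amplitude parameter) to `effect_scale`
#'   times unit robust standard deviation over the sampled column (sd
#'   after trimming 1% of effect values per side), so that every
#'   informative feature carries a comparable, detectable signal share
#'   regardless of its family's tail behavior. The rescaled amplitudes are
#'   recorded in the returned ground truth.
#' @param effect_scale Robust standard deviation of each informative
#'   effect when `normalize_effects` is on.
#'
#' @return A list with `data` (a [deepgam_dataset()]) and `ground_truth`
#'   (class `deepgam_ground_truth`): informative indices, shape specs,
#'   intercept, noise_sd, target rate and skew.
#' @export
make_classification <- function(n, m_informative, m_noise,
                                skew = 0.8, positive_rate = 0.226,
                                noise_sd = 0.5, seed = 1, shapes = NULL,
                                informative_first = FALSE,
                                intercept = NULL,
                                normalize_effects = TRUE,
                                effect_scale = 1) {
  stopifnot(n >= 20, m_informative >= 1, m_noise >= 0,
            positive_rate > 0, positive_rate < 1, noise_sd >= 0, skew >= 0)
  m <- m_informative + m_noise
  shapes <- default_shape_assignment(m_informative, shapes)
  with_seed(seed, {
    informative <- if (informative_first) seq_len(m_informative)
                   else sort(sample.int(m, m_informative))
    X <- matrix(stats::rnorm(n * m), n, m)
    X <- skew_transform(X, skew)
    effect <- rep(0, n)
    for (i in seq_along(informative)) {
      if (normalize_effects) {
        shapes[[i]] <- normalize_effect(shapes[[i]], X[, informative[i]],
                                        effect_scale)
      }
      effect <- effect + eval_shape(shapes[[i]], X[, informative[i]])
    }
    eps <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else rep(0, n)
    base <- effect + eps
    if (is.null(intercept)) {
      intercept <- tune_intercept(base, positive_rate, tol = 0.01)
    }
    labels <- ifelse(base + intercept > 0, 1, -1)
    gt <- structure(
      list(informative_indices = informative,
           shapes = stats::setNames(shapes, paste0("x", informative)),
           intercept = intercept, noise_sd = noise_sd,
           target_positive_rate = positive_rate, skew = skew,
           mode = "classification"),
      class = "deepgam_ground_truth")
    list(data = deepgam_dataset(X, labels,
                                feature_names = paste0("x", seq_len(m))),
         ground_truth = gt)
  })
}

# Bisection on the empirical latent scores: pick b so that
# mean(base + b > 0) is within tol of rate.
tune_intercept <- function(base, rate, tol = 0.01) {
  frac <- function(b) mean(base + b > 0)
  lo <- -max(base) - 1e-9   # frac(lo) = 0
  hi <- -min(base) + 1e-9   # frac(hi) = 1
  for (iter in seq_len(200)) {
    mid <- (lo + hi) / 2
    f <- frac(mid)
    if (abs(f - rate) <= tol) return(mid)
    if (f < rate) lo <- mid else hi <- mid
  }
  stop(sprintf("generator error: positive rate %.3f unreachable within %.3f",
               rate, tol), call. = FALSE)
}

#' Evaluate a ground-truth shape function on a grid
#'
#' Exact, deterministic evaluation of the generator's additive effect for
#' one feature; non-informative features return zeros.
#'
#' @param gt A `deepgam_ground_truth` from [make_classification()] or
#'   [make_regression()].
#' @param feature Feature index (column position in the generated data).
#' @param grid Numeric vector of input values.
#' @return Numeric vector `f*_j(grid)`.
#' @export
true_shape_on_grid <- function(gt, feature, grid) {
  stopifnot(inherits(gt, "deepgam_ground_truth"))
  pos <- match(feature, gt$informative_indices)
  if (is.na(pos)) return(rep(0, length(grid)))
  eval_shape(gt$shapes[[pos]], grid)
}

#' Generate regression data with known additive ground truth
#'
#' As [make_classification()] but the target is the latent score itself
#' (no thresholding, no intercept tuning); the returned dataset is in
#' regression mode.
#'
#' @inheritParams make_classification
#' @return A list with `data` (regression-mode [deepgam_dataset()]) and
#'   `ground_truth`.
#' @export
make_regression <- function(n, m_informative, m_noise, skew = 0.8,
                            noise_sd = 0.5, seed = 1, shapes = NULL,
                            informative_first = FALSE,
                            normalize_effects = TRUE, effect_scale = 1) {
  stopifnot(n >= 20, m_informative >= 1, m_noise >= 0,
            noise_sd >= 0, skew >= 0)
  m <- m_informative + m_noise
  shapes <- default_shape_assignment(m_informative, shapes)
  with_seed(seed, {
    informative <- if (informative_first) seq_len(m_informative)
                   else sort(sample.int(m, m_informative))
    X <- matrix(stats::rnorm(n * m), n, m)
    X <- skew_transform(X, skew)
    effect <- rep(0, n)
    for (i in seq_along(informative)) {
      if (normalize_effects) {
        shapes[[i]] <- normalize_effect(shapes[[i]], X[, informative[i]],
                                        effect_scale)
      }
      effect <- effect + eval_shape(shapes[[i]], X[, informative[i]])
    }
    eps <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else rep(0, n)
    gt <- structure(
      list(informative_indices = informative,
           shapes = stats::setNames(shapes, paste0("x", informative)),
           intercept = 0, noise_sd = noise_sd,
           target_positive_rate = NA_real_, skew = skew,
           mode = "regression"),
      class = "deepgam_ground_truth")
    list(data = deepgam_dataset(X, effect + eps,
                                feature_names = paste0("x", seq_len(m)),
                                mode = "regression"),
         ground_truth = gt)
  })
}

#' Serialize ground truth to JSON (and read it back)
#'
#' @param gt A `deepgam_ground_truth`.
#' @param path JSON path.
#' @return Invisibly, `path` (write) or the ground truth (read).
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "deepgam_ground_truth"))
  jsonlite::write_json(
    list(informative_indices = gt$informative_indices,
         shapes = lapply(gt$shapes, function(s)
           list(name = s$name, params = s$params)),
         intercept = gt$intercept, noise_sd = gt$noise_sd,
         target_positive_rate = gt$target_positive_rate,
         skew = gt$skew, mode = gt$mode),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  shapes <- lapply(raw$shapes, function(s)
    do.call(shape_spec, c(list(name = s$name), s$params)))
  structure(
    list(informative_indices = vapply(raw$informative_indices,
                                      as.integer, integer(1)),
         shapes = stats::setNames(shapes, names(raw$shapes)),
         intercept = raw$intercept, noise_sd = raw$noise_sd,
         target_positive_rate = if (is.null(raw$target_positive_rate))
           NA_real_ else raw$target_positive_rate,
         skew = raw$skew, mode = raw$mode),
    class = "deepgam_ground_truth")
}
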