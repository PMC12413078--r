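#' Extract a per-feature shape curve
#'
#' Evaluates the learned additive contribution `f_j(grid * g(phi_j))` on a
#' grid spanning the \[0.5%, 99.5%\] quantiles of the observed
#' (standardized) feature, which avoids extrapolation artifacts in the
#' right-skewed tails. The curve is the model's global explanation for the
#' feature: with the tanh enabled all values lie in (-1, 1), and a dead
#' feature yields the identically-zero curve.
#'
#' @param model A trained `deepgam_model`.
#' @param feature Feature index.
#' @param data A [deepgam_dataset()] in the model's raw input space (used
#'   only for the grid quantiles).
#' @param n_points Number of grid points (default 100).
#' @return A `deepgam_shape_curve`: `feature`, `name`, `grid`
#'   (standardized units, strictly increasing), `grid_raw` (original
#'   units, when the model carries a scaler), `values`, `gate`
#'   (`"alive"` or `"dead"`).
#' @export
shape_curve <- function(model, feature, data, n_points = 100) {
  stopifnot(inherits(model, "deepgam_model"))
  if (feature < 1 || feature > model$M) {
    stop("invalid feature index", call. = FALSE)
  }
  x <- data$features[, feature]
  if (!is.null(model$scaler)) {
    x <- (x - model$scaler$mean[feature]) / model$scaler$sd[feature]
  }
  q <- stats::quantile(x, c(0.005, 0.995), names = FALSE, type = 7)
  if (q[1] >= q[2]) q <- c(q[1] - 0.5, q[1] + 0.5)
  grid <- seq(q[1], q[2], length.out = n_points)
  g <- gate_forward(model$phi[feature])
  values <- shape_forward(grid * g, get_shape_network(model, feature),
                          use_tanh = model$use_tanh)
  grid_raw <- if (!is.null(model$scaler)) {
    grid * model$scaler$sd[feature] + model$scaler$mean[feature]
  } else {
    grid
  }
  structure(
    list(feature = feature, name = model$feature_names[feature],
         grid = grid, grid_raw = grid_raw, values = values,
         gate = if (g == 1) "alive" else "dead"),
    class = "deepgam_shape_curve")
}

#' Histogram of an observed feature
#'
#' @param data A [deepgam_dataset()].
#' @param feature Feature index.
#' @param bins Number of equal-width bins (>= 1) spanning the observed
#'   min/max.
#' @return List with `edges` (length `bins + 1`) and `counts` (summing to
#'   N).
#' @export
feature_histogram <- function(data, feature, bins = 30) {
  stopifnot(bins >= 1)
  x <- data$features[, feature]
  lo <- min(x); hi <- max(x)
  if (lo == hi) {
    lo <- lo - 0.5; hi <- hi + 0.5
  }
  edges <- seq(lo, hi, length.out = bins + 1)
  counts <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                          bins), nbins = bins)
  list(edges = edges, counts = counts)
}

#' Export shape curves, histograms and a model summary
#'
#' Writes, into `out_dir`: one `shape_<name>.csv` per alive feature
#' (standardized grid, raw grid, contribution), a single
#' `histograms.csv` covering every feature, and `summary.json` (alive
#' set, gate logits, intercept). Re-export of the same model and data is
#' byte-identical.
#'
#' @param model A trained `deepgam_model`.
#' @param data A [deepgam_dataset()] in the model's raw input space.
#' @param out_dir Output directory (created if needed).
#' @param n_points Grid points per curve.
#' @param bins Histogram bins.
#' @return Invisibly, the character vector of files written.
#' @export
export_explanation <- function(model, data, out_dir, n_points = 100,
                               bins = 30) {
  stopifnot(inherits(model, "deepgam_model"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory %s", out_dir),
                  call. = FALSE)
  }
  alive <- alive_features(model)
  files <- character(0)
  for (j in alive) {
    curve <- shape_curve(model, j, data, n_points)
    path <- file.path(out_dir, sprintf("shape_%s.csv", model$feature_names[j]))
    utils::write.csv(
      data.frame(grid = curve$grid, grid_raw = curve$grid_raw,
                 value = curve$values),
      path, row.names = FALSE)
    files <- c(files, path)
  }
  hist_rows <- do.call(rbind, lapply(seq_len(model$M), function(j) {
    h <- feature_histogram(data, j, bins)
    data.frame(feature = model$feature_names[j],
               bin_lo = utils::head(h$edges, -1),
               bin_hi = utils::tail(h$edges, -1),
               count = h$counts)
  }))
  hist_path <- file.path(out_dir, "histograms.csv")
  utils::write.csv(hist_rows, hist_path, row.names = FALSE)
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(alive_features = model$feature_names[alive],
         alive_indices = alive,
         phi = stats::setNames(as.list(model$phi), model$feature_names),
         beta0 = model$beta0),
    summary_path, auto_unbox = TRUE, digits = NA)
  invisible(c(files, hist_path, summary_path))
}

#' Ablation suite over the R1 / tanh toggles
#'
#' Trains the four (R1, tanh) on/off variants of DeepGAM per seed on a
#' stratified train/test split and reports, per variant, mean held-out
#' classification metrics together with the mean of the maximum and mean
#' absolute per-feature contribution. The expected qualitative signatures:
#' the unconstrained variant saturates contributions beyond +/-1, R1 alone
#' shrinks their magnitude, and tanh bounds them in (-1, 1).
#'
#' @param data A classification [deepgam_dataset()] (raw).
#' @param base_config A [training_config()]; its R1/tanh toggles are
#'   overridden per variant.
#' @param seeds Integer vector of seeds (one split + training per seed).
#' @param test_fraction Held-out fraction per split.
#' @return A `deepgam_ablation`: `summary` (4-row data frame: use_R1,
#'   use_tanh, mean metrics, mean max/mean absolute contribution) and
#'   `detail` (per seed x variant).
#' @export
ablation_suite <- function(data, base_config, seeds = 1:5,
                           test_fraction = 0.3) {
  variants <- expand.grid(use_R1 = c(FALSE, TRUE),
                          use_tanh = c(FALSE, TRUE))
  detail <- list()
  for (seed in seeds) {
    sp <- split_dataset(data, test_fraction, seed = derive_seed(seed, 3))
    scaler <- fit_standardizer(sp$train)
    tr <- apply_standardizer(sp$train, scaler)
    te_X <- standardize_matrix(sp$test$features, scaler)
    for (v in seq_len(nrow(variants))) {
      cfg <- base_config
      cfg$use_R1 <- variants$use_R1[v]
      cfg$use_tanh <- variants$use_tanh[v]
      cfg$seed <- as.integer(seed)
      model <- init_model(ncol(tr$features), C = cfg$C,
                          phi_init = cfg$phi_init, seed = cfg$seed,
                          use_tanh = cfg$use_tanh,
                          feature_names = tr$feature_names)
      model <- train(model, tr, NULL, cfg)$model
      pr <- predict_scores(model, te_X, apply_scaler = FALSE)
      rep <- evaluate_scores(pr$scores, sp$test$labels)
      detail[[length(detail) + 1L]] <- data.frame(
        seed = seed, use_R1 = cfg$use_R1, use_tanh = cfg$use_tanh,
        auc = rep$auc, accuracy = rep$accuracy, f1 = rep$f1,
        max_abs_contribution = max(abs(pr$contributions)),
        mean_abs_contribution = mean(abs(pr$contributions)))
    }
  }
  detail <- do.call(rbind, detail)
  summary <- stats::aggregate(
    detail[c("auc", "accuracy", "f1", "max_abs_contribution",
             "mean_abs_contribution")],
    by = detail[c("use_R1", "use_tanh")], FUN = mean)
  structure(list(summary = summary, detail = detail),
            class = "deepgam_ablation")
}
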