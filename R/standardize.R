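#' Fit per-feature standardization statistics on a training split
#'
#' Computes per-column mean and standard deviation (population convention,
#' denominator N). Zero-variance columns get their standard deviation
#' replaced by 1 and are flagged as degenerate. Statistics must only ever
#' be fitted on training rows, never on held-out rows.
#'
#' @param train A [deepgam_dataset()] (the training split).
#' @return An object of class `deepgam_scaler` with `mean`, `sd` and
#'   logical `degenerate` vectors, one entry per feature.
#' @export
fit_standardizer <- function(train) {
  stopifnot(inherits(train, "deepgam_dataset"))
  X <- train$features
  mu <- colMeans(X)
  # population sd: sqrt(mean((x - mu)^2))
  sdev <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  degenerate <- sdev <= 0
  sdev[degenerate] <- 1
  structure(
    list(mean = mu, sd = sdev, degenerate = degenerate,
         feature_names = train$feature_names),
    class = "deepgam_scaler"
  )
}

#' Apply fitted standardization statistics to a dataset
#'
#' Transforms column j to (x_j - mean_j) / sd_j using statistics fitted by
#' [fit_standardizer()]. Applying train statistics to the training split
#' itself yields zero-mean, unit-sd columns (for non-degenerate features);
#' applied to a disjoint split the column means are in general nonzero.
#'
#' @param data A [deepgam_dataset()].
#' @param stats A `deepgam_scaler` from [fit_standardizer()].
#' @return A standardized `deepgam_dataset`.
#' @export
apply_standardizer <- function(data, stats) {
  stopifnot(inherits(data, "deepgam_dataset"), inherits(stats, "deepgam_scaler"))
  if (ncol(data$features) != length(stats$mean)) {
    stop("scaler dimension does not match the dataset", call. = FALSE)
  }
  X <- sweep(sweep(data$features, 2L, stats$mean), 2L, stats$sd, "/")
  deepgam_dataset(X, data$labels, feature_names = data$feature_names,
                  mode = data$mode)
}
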