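#' Stratified k-fold cross-validation plan
#'
#' Shuffles each class independently and deals rows round-robin into k test
#' folds, so every row appears in exactly one test set and each fold's
#' positive count differs from an even split by at most one sample.
#'
#' @param data A classification-mode [deepgam_dataset()].
#' @param k Number of folds (integer, >= 2).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return An object of class `deepgam_folds`: a list with `k`, `seed` and
#'   `folds`, where `folds[[i]]` has integer vectors `train` and `test`.
#' @export
make_folds <- function(data, k, seed) {
  stopifnot(inherits(data, "deepgam_dataset"))
  k <- as.integer(k)
  n <- nrow(data$features)
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= N", call. = FALSE)
  pos <- which(data$labels == 1)
  neg <- which(data$labels == -1)
  if (length(pos) < k || length(neg) < k) {
    stop(sprintf("stratification error: each class needs >= %d members", k),
         call. = FALSE)
  }
  assign_cls <- function(idx) {
    idx <- idx[sample.int(length(idx))]
    split(idx, rep_len(seq_len(k), length(idx)))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pos_f <- assign_cls(pos)
  neg_f <- assign_cls(neg)
  folds <- lapply(seq_len(k), function(i) {
    test <- sort(c(pos_f[[i]], neg_f[[i]]))
    list(train = setdiff(seq_len(n), test), test = test)
  })
  structure(list(k = k, seed = as.integer(seed), folds = folds),
            class = "deepgam_folds")
}

#' Serialize a fold plan to JSON (and read it back)
#'
#' @param plan A `deepgam_folds` object.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_folds <- function(plan, path) {
  stopifnot(inherits(plan, "deepgam_folds"))
  jsonlite::write_json(
    list(k = plan$k, seed = plan$seed,
         folds = lapply(plan$folds, function(f)
           list(train = f$train, test = f$test))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_folds
#' @export
read_folds <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  folds <- lapply(raw$folds, function(f)
    list(train = vapply(f$train, as.integer, integer(1)),
         test = vapply(f$test, as.integer, integer(1))))
  structure(list(k = as.integer(raw$k), seed = as.integer(raw$seed),
                 folds = folds),
            class = "deepgam_folds")
}
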