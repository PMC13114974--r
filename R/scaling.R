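#' Fit feature-wise min-max scaling parameters
#'
#' Parameters are fitted on the TRAINING rows only; applying them to test
#' rows therefore leaks no test information into the scaling (test rows may
#' fall outside the unit interval). Constant features are recorded with zero
#' range and later map to 0.
#'
#' @param train_rows numeric matrix or data frame of training feature rows
#'   (at least 2 rows).
#' @return An object of class `minmax_params` with `mins`, `maxs` and
#'   `features`.
#' @export
fit_minmax <- function(train_rows) {
  x <- as.matrix(train_rows)
  if (nrow(x) < 2L) stop("need at least 2 training rows")
  storage.mode(x) <- "double"
  structure(list(mins = apply(x, 2, min), maxs = apply(x, 2, max),
                 features = colnames(x)),
            class = "minmax_params")
}

#' Apply (or invert) min-max scaling
#'
#' `apply_minmax()` maps each feature through (x - min) / (max - min) using
#' the stored training-set parameters; zero-range features map to 0.
#' `invert_minmax()` undoes the transform (zero-range features are restored
#' to their stored constant value).
#'
#' @param params a fitted [fit_minmax()] object.
#' @param rows numeric matrix/data frame (or a single named vector) with the
#'   same feature columns.
#' @return A numeric matrix of the same shape.
#' @export
apply_minmax <- function(params, rows) {
  stopifnot(inherits(params, "minmax_params"))
  x <- .conform_rows(params, rows)
  rng <- params$maxs - params$mins
  out <- sweep(x, 2, params$mins, "-")
  for (j in seq_along(rng)) {
    out[, j] <- if (rng[j] == 0) 0 else out[, j] / rng[j]
  }
  out
}

#' @rdname apply_minmax
#' @export
invert_minmax <- function(params, rows) {
  stopifnot(inherits(params, "minmax_params"))
  x <- .conform_rows(params, rows)
  rng <- params$maxs - params$mins
  for (j in seq_along(rng)) {
    x[, j] <- if (rng[j] == 0) params$mins[j] else x[, j] * rng[j] + params$mins[j]
  }
  x
}

.conform_rows <- function(params, rows) {
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1,
                                         dimnames = list(NULL, names(rows)))
  x <- as.matrix(rows)
  storage.mode(x) <- "double"
  if (ncol(x) != length(params$mins)) {
    stop("feature dimension mismatch with fitted scaler")
  }
  if (!is.null(params$features) && !is.null(colnames(x))) {
    x <- x[, params$features, drop = FALSE]
  }
  x
}
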