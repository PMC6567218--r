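#' Sliding-interval segmentation
#'
#' Covers `[0, samples)` with windows of `Lw` samples advanced by `d`
#' samples: spans `[i*d, i*d + Lw)` for `i = 0 .. floor((samples - Lw)/d)`.
#'
#' @param samples Total sample count (must be at least `Lw`).
#' @param Lw Window length in samples.
#' @param d Sliding distance in samples.
#' @return List of [span()]s.
#' @examples
#' make_intervals(219, 155, 32)  # [0,155) [32,187) [64,219)
#' @export
make_intervals <- function(samples, Lw, d) {
  stopifnot(Lw > 2, d > 0, d <= Lw)
  if (samples < Lw)
    stop("recording too short: ", samples, " samples < Lw = ", Lw)
  n <- floor((samples - Lw) / d) + 1
  lapply(seq_len(n) - 1, function(i) span(i * d, i * d + Lw))
}

#' AR(2) coefficients of a signal window
#'
#' Fits a second-order autoregression to the mean-centred window with Burg's
#' method (stable on short EEG windows) and returns the two coefficients
#' `(a1, a2)` of `x_t = a1 x_{t-1} + a2 x_{t-2} + e_t`.  The coefficients are
#' scale- and location-invariant, which is what makes them portable artefact
#' features across subjects and gains.  A zero-variance (flat) window returns
#' `(0, 0)` by convention so dead channels do not abort detection.
#'
#' @param x Numeric vector, length at least 3.
#' @return Numeric vector `c(a1, a2)`.
#' @export
ar2_window <- function(x) {
  if (length(x) < 3) stop("window too short for AR(2): ", length(x))
  if (!all(is.finite(x))) stop("non-finite samples in window")
  if (stats::sd(x) == 0) return(c(0, 0))
  fit <- stats::ar.burg(x, aic = FALSE, order.max = 2, demean = TRUE)
  as.numeric(fit$ar)
}

#' Interval feature matrix
#'
#' One row per sliding interval; each row concatenates, channel by channel in
#' recording order, the AR(2) coefficients of that channel's window
#' (`2 * length(channels)` columns).
#'
#' @param rec A [recording()].
#' @param channels Channel indices to use; `NULL` means all.
#' @param Lw,d Window length and sliding distance in samples.
#' @return An object of class `uar_features`: list with `vectors` (matrix
#'   `n_intervals x 2*n_channels`), `starts` (0-based interval starts), `Lw`,
#'   `d`.
#' @export
feature_matrix <- function(rec, channels = NULL, Lw = 155, d = 32) {
  validate_recording(rec)
  if (is.null(channels)) channels <- seq_len(n_channels(rec))
  if (length(channels) == 0) stop("empty channel subset")
  if (any(channels < 1 | channels > n_channels(rec)))
    stop("channel index out of range")
  intervals <- make_intervals(n_samples(rec), Lw, d)
  vectors <- matrix(0, nrow = length(intervals), ncol = 2 * length(channels))
  for (i in seq_along(intervals)) {
    idx <- span_idx(intervals[[i]])
    for (j in seq_along(channels))
      vectors[i, c(2 * j - 1, 2 * j)] <- ar2_window(rec$data[channels[j], idx])
  }
  structure(list(
    vectors = vectors,
    starts = vapply(intervals, `[[`, numeric(1), "start"),
    Lw = as.integer(Lw), d = as.integer(d)),
    class = "uar_features")
}

#' @export
print.uar_features <- function(x, ...) {
  cat(sprintf("uar_features: %d intervals x %d features (Lw=%d, d=%d)\n",
              nrow(x$vectors), ncol(x$vectors), x$Lw, x$d))
  invisible(x)
}
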