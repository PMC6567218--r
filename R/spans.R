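#' Sample-coordinate spans
#'
#' A span is a 0-based, half-open interval of sample indices
#' `[start, end)`, the coordinate convention used throughout the package
#' (artefact portions `AT`, `ART`, the ICA window `ICA_P`, the reference
#' `REF`, ...).  Seconds are converted to samples with `floor(t * fs)`.
#'
#' @param start First sample index (0-based, inclusive).
#' @param end One past the last sample index (exclusive); must satisfy
#'   `start < end`.
#' @return An object of class `uar_span` with fields `start` and `end`.
#' @examples
#' span(0, 155)
#' span_length(span(32, 187))
#' @export
span <- function(start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(start) == 1, length(end) == 1, is.finite(start), is.finite(end))
  if (start < 0 || end <= start)
    stop("invalid span: need 0 <= start < end, got [", start, ", ", end, ")")
  structure(list(start = start, end = end), class = "uar_span")
}

#' @rdname span
#' @param x A `uar_span`.
#' @export
span_length <- function(x) x$end - x$start

#' @export
print.uar_span <- function(x, ...) {
  cat(sprintf("[%d, %d)  (%d samples)\n", x$start, x$end, span_length(x)))
  invisible(x)
}

#' @export
format.uar_span <- function(x, ...) sprintf("[%d, %d)", x$start, x$end)

# 1-based R column indices addressed by a 0-based half-open span.
span_idx <- function(x) seq.int(x$start + 1L, x$end)

# TRUE if inner lies fully inside outer.
span_within <- function(inner, outer) {
  inner$start >= outer$start && inner$end <= outer$end
}

spans_overlap <- function(a, b) a$start < b$end && b$start < a$end

# Number of samples shared by two spans.
span_overlap_length <- function(a, b) {
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

#' Convert seconds to a sample count
#'
#' Uses `floor(t * fs)` so that exact multiples of the sampling period map
#' to exact sample counts.
#'
#' @param t Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @return Integer number of samples.
#' @export
seconds_to_samples <- function(t, fs) {
  stopifnot(t >= 0, fs > 0)
  as.integer(floor(t * fs))
}

# Merge a list of spans into maximal non-overlapping spans (union).
merge_spans <- function(spans) {
  if (length(spans) == 0) return(list())
  ord <- order(vapply(spans, `[[`, numeric(1), "start"))
  spans <- spans[ord]
  out <- list(spans[[1]])
  for (sp in spans[-1]) {
    last <- out[[length(out)]]
    if (sp$start <= last$end) {
      if (sp$end > last$end) out[[length(out)]] <- span(last$start, sp$end)
    } else {
      out[[length(out) + 1]] <- sp
    }
  }
  out
}

spans_to_df <- function(spans) {
  data.frame(
    start = vapply(spans, `[[`, numeric(1), "start"),
    end = vapply(spans, `[[`, numeric(1), "end")
  )
}
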