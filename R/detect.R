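#' Distances of interval features to their centroid
#'
#' The centroid is the arithmetic mean of all interval feature vectors; each
#' interval's score is the Euclidean distance of its row to that centroid.
#' Intervals containing artefacts land in the extreme tail of the resulting
#' distance distribution.
#'
#' @param feats A [feature_matrix()] result.
#' @return An object of class `uar_distance_profile`: list with `distances`,
#'   `centroid`, `starts`, `Lw`, `d`.
#' @export
centroid_distances <- function(feats) {
  v <- feats$vectors
  if (nrow(v) < 2) stop("need at least 2 intervals to form a centroid")
  centroid <- colMeans(v)
  dev <- sweep(v, 2, centroid)
  structure(list(distances = sqrt(rowSums(dev^2)), centroid = centroid,
                 starts = feats$starts, Lw = feats$Lw, d = feats$d),
            class = "uar_distance_profile")
}

#' Lower detection threshold T1
#'
#' Either echoes a fixed value (the default operating point, `T1 = 1.33`,
#' portable across 64-electrode recordings because AR coefficients are scale-
#' and location-invariant), or reads a high quantile off a fitted GEV model
#' of the distances as an estimate of the onset of the extreme tail.
#'
#' @param distances Numeric vector of centroid distances.
#' @param mode `"fixed"` or `"gev_quantile"`.
#' @param value The fixed threshold, or the GEV probability (in `(0,1)`).
#' @return Threshold (scalar).
#' @export
threshold_T1 <- function(distances, mode = c("fixed", "gev_quantile"),
                         value = 1.33) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    stopifnot(is.numeric(value), length(value) == 1, value > 0)
    return(value)
  }
  if (value <= 0 || value >= 1)
    stop("gev_quantile mode needs a probability in (0, 1), got ", value)
  g <- fit_gev(distances)
  qgev(value, g$shape, g$location, g$scale)
}

#' Upper threshold T2 (tail balance point)
#'
#' `T2` is the median of the distances at or above `T1`, so that the number
#' of intervals beyond `T2` equals (within one) the number inside
#' `[T1, T2)`.  Used for reporting only; detection itself runs at `T = T1`.
#'
#' @param distances Numeric vector of centroid distances.
#' @param T1 Lower threshold.
#' @return Threshold (scalar).
#' @export
threshold_T2 <- function(distances, T1) {
  tail_d <- distances[distances >= T1]
  if (length(tail_d) < 2)
    stop("fewer than 2 distances at or above T1 = ", T1)
  stats::median(tail_d)
}

#' Extract above-threshold runs as artefact spans
#'
#' Finds maximal runs of consecutive intervals whose centroid distance is
#' `>= T`, keeps runs of at least `min_run` intervals, and maps each run to
#' the union of its member windows: `[first_start, last_start + Lw)`.
#'
#' @param profile A [centroid_distances()] result.
#' @param T Detection threshold.
#' @param min_run Minimum run length in intervals.
#' @param Lw,d Window length and sliding distance (default: taken from the
#'   profile).
#' @return List of [span()]s (possibly empty), the detected `AT` portions.
#' @export
detect_runs <- function(profile, T, min_run = 1, Lw = profile$Lw,
                        d = profile$d) {
  stopifnot(T > 0, min_run >= 1)
  flags <- profile$distances >= T
  starts <- profile$starts
  runs <- rle(flags)
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1
  out <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k] || runs$lengths[k] < min_run) next
    out[[length(out) + 1]] <-
      span(starts[begins[k]], starts[ends[k]] + Lw)
  }
  out
}

#' Widen detections and lay out the filtering geometry
#'
#' For each detected artefact `AT`, builds the portion actually filtered,
#' `ART = AT1 + AT + AT2` (margins of `at1_seconds` / `at2_seconds`,
#' clipped to the recording).  If the next artefact starts inside the current
#' `AT2`, the current `ART` is truncated at that start and the next
#' artefact's `AT1` begins there.  `ICA_P` is the trailing window of
#' `icap_seconds` ending with `ART` (clipped at the recording start and
#' always containing `ART`); the preliminary reference `REF` is the span of
#' the same length as `ART` immediately before it (re-derived against the
#' clean-sample mask during filtering, see [select_reference()]).
#'
#' @param at_spans Sorted, non-overlapping list of detected `AT` [span()]s.
#' @param cfg A [uar_config()].
#' @param fs Sampling rate in Hz.
#' @param total_samples Recording length in samples.
#' @return List of `uar_portion` objects with fields `at`, `art`, `icap`,
#'   `ref`, `truncated_at2`.
#' @export
widen_and_layout <- function(at_spans, cfg, fs, total_samples) {
  if (length(at_spans) == 0) return(list())
  starts <- vapply(at_spans, `[[`, numeric(1), "start")
  ends <- vapply(at_spans, `[[`, numeric(1), "end")
  if (is.unsorted(starts, strictly = TRUE) || any(starts[-1] < ends[-length(ends)]))
    stop("AT spans must be sorted and non-overlapping")
  at1 <- seconds_to_samples(cfg$at1_seconds, fs)
  at2 <- seconds_to_samples(cfg$at2_seconds, fs)
  icap_len <- seconds_to_samples(cfg$icap_seconds, fs)
  out <- vector("list", length(at_spans))
  prev_end <- 0
  for (i in seq_along(at_spans)) {
    at <- at_spans[[i]]
    art_start <- max(0, at$start - at1, prev_end)
    art_end <- min(at$end + at2, total_samples)
    truncated <- FALSE
    if (i < length(at_spans) && at_spans[[i + 1]]$start < art_end) {
      art_end <- at_spans[[i + 1]]$start
      truncated <- TRUE
    }
    art <- span(art_start, art_end)
    ic_start <- min(max(0, art_end - icap_len), art_start)
    icap <- span(ic_start, art_end)
    ref_start <- max(0, art_start - span_length(art))
    ref <- if (ref_start < art_start) span(ref_start, art_start) else NULL
    out[[i]] <- structure(
      list(at = at, art = art, icap = icap, ref = ref,
           truncated_at2 = truncated),
      class = "uar_portion")
    prev_end <- art_end
  }
  out
}

#' @export
print.uar_portion <- function(x, ...) {
  cat(sprintf("uar_portion: AT %s  ART %s  ICA_P %s  REF %s%s\n",
              format(x$at), format(x$art), format(x$icap),
              if (is.null(x$ref)) "<none>" else format(x$ref),
              if (x$truncated_at2) "  [AT2 truncated]" else ""))
  invisible(x)
}

#' Detection over a whole recording
#'
#' Convenience wrapper: feature extraction, centroid distances and run
#' extraction at the configured threshold.
#'
#' @param rec A [recording()].
#' @param cfg A [uar_config()].
#' @return List with `at_spans`, `profile`, `T1`, `T2` (`T2` is `NA` when
#'   fewer than two distances reach `T1`).
#' @export
uar_detect <- function(rec, cfg = uar_config()) {
  check_config_fs(cfg, rec$fs)
  feats <- feature_matrix(rec, cfg$n_detect, cfg$Lw, cfg$d)
  profile <- centroid_distances(feats)
  # distinct runs can still overlap in sample coordinates (windows overlap
  # whenever Lw > d); merged here so the layout sees disjoint AT spans
  at_spans <- merge_spans(detect_runs(profile, cfg$T, cfg$min_run))
  T2 <- tryCatch(threshold_T2(profile$distances, cfg$T), error = function(e) NA_real_)
  list(at_spans = at_spans, profile = profile, T1 = cfg$T, T2 = T2)
}

#' Detection on channel groups with fused results
#'
#' Runs detection separately on each channel group (smaller groups make the
#' Euclidean distance more sensitive to artefacts confined to few
#' electrodes) and merges the per-group spans into maximal spans.
#'
#' @param rec A [recording()].
#' @param groups List of channel-index vectors.
#' @param cfg A [uar_config()].
#' @return List of merged [span()]s.
#' @export
detect_grouped <- function(rec, groups, cfg = uar_config()) {
  if (length(groups) == 0) stop("groups must be non-empty")
  all_spans <- list()
  for (g in groups) {
    feats <- feature_matrix(rec, g, cfg$Lw, cfg$d)
    profile <- centroid_distances(feats)
    all_spans <- c(all_spans, detect_runs(profile, cfg$T, cfg$min_run))
  }
  merge_spans(all_spans)
}

#' Write a detection report
#'
#' Emits the detected spans either as BED-like tab-separated text
#' (`start`, `end`, peak distance within the span) or as JSON including the
#' thresholds.
#'
#' @param det A [uar_detect()] result.
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @export
write_detection_report <- function(det, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  peak <- function(sp) {
    in_span <- det$profile$starts >= sp$start & det$profile$starts < sp$end
    if (!any(in_span)) return(NA_real_)
    max(det$profile$distances[in_span])
  }
  df <- spans_to_df(det$at_spans)
  df$peak_distance <- if (nrow(df)) vapply(det$at_spans, peak, numeric(1)) else numeric(0)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(list(T1 = det$T1, T2 = det$T2, spans = df),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
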