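#' Mean squared error between two signal portions
#'
#' `mean((filtered - reference)^2)` over equal-length portions, the metric
#' used to compare filtered artefact portions with their clean
#' counterparts.
#'
#' @param filtered,reference Numeric vectors of equal length (>= 1).
#' @return Non-negative scalar.
#' @export
mse <- function(filtered, reference) {
  if (length(filtered) != length(reference))
    stop("length mismatch: ", length(filtered), " vs ", length(reference))
  if (length(filtered) < 1) stop("empty portions")
  mean((filtered - reference)^2)
}

#' Detection precision and recall against ground truth
#'
#' An event counts as hit when some predicted span overlaps at least
#' `min_overlap_fraction` of it; a predicted span counts as correct when it
#' overlaps at least that fraction of some event.  With no predictions,
#' precision is reported as 1 by convention (flagged
#' `no_predictions = TRUE`) and recall is 0 when events exist.
#'
#' @param predicted List of [span()]s (sorted).
#' @param truth Realised events from [build_seeg()] (or any list whose
#'   elements carry a `span`).
#' @param min_overlap_fraction Fraction of an event that must be covered
#'   (default 0.5).
#' @return List with `precision`, `recall`, `hits`, `no_predictions`.
#' @export
detection_scores <- function(predicted, truth, min_overlap_fraction = 0.5) {
  truth_spans <- lapply(truth, `[[`, "span")
  if (length(predicted) == 0) {
    return(list(precision = 1, recall = if (length(truth_spans)) 0 else 1,
                hits = logical(length(truth_spans)), no_predictions = TRUE))
  }
  hit <- vapply(truth_spans, function(ts) {
    need <- min_overlap_fraction * span_length(ts)
    any(vapply(predicted, function(ps) span_overlap_length(ps, ts) >= need,
               logical(1)))
  }, logical(1))
  correct <- vapply(predicted, function(ps) {
    any(vapply(truth_spans, function(ts)
      span_overlap_length(ps, ts) >= min_overlap_fraction * span_length(ts),
      logical(1)))
  }, logical(1))
  list(precision = mean(correct),
       recall = if (length(hit)) mean(hit) else 1,
       hits = hit, no_predictions = FALSE)
}

#' ICA-window-length sweep
#'
#' Re-runs the full filtering pipeline on the same simulated recordings for
#' each candidate `ICA_P` length and records the whole-channel MSE between
#' the filtered and clean signals (mean over channels), averaged across
#' seeds.  Reproduces the dependence of filtering quality on the ICA window
#' length: windows that are too short give poorly estimated components.
#'
#' @param scenario A [synth_scenario()]; its seed field is replaced by each
#'   element of `seeds` in turn.
#' @param icap_values ICA window lengths in seconds.
#' @param seeds Integer vector of scenario seeds.
#' @param cfg Base [uar_config()] (its `icap_seconds` is overridden).
#' @return Data frame with columns `icap_seconds`, `seed`, `mse`, plus the
#'   per-window mean as attribute `summary` (data frame `icap_seconds`,
#'   `mean_mse`).
#' @export
icap_sweep <- function(scenario, icap_values, seeds, cfg = uar_config()) {
  stopifnot(length(icap_values) >= 1, length(seeds) >= 1)
  for (v in icap_values)
    if (seconds_to_samples(v, scenario$fs) < cfg$Lw)
      stop("icap value ", v, " s holds fewer than Lw samples")
  rows <- list()
  for (v in icap_values) {
    for (s in seeds) {
      sc <- scenario; sc$seed <- as.integer(s)
      seeg <- build_seeg(sc)
      cfg_v <- cfg; cfg_v$icap_seconds <- v; cfg_v$seed <- as.integer(s)
      res <- uar_filter(seeg$contaminated, cfg_v)
      m <- mean(vapply(seq_len(n_channels(seeg$clean)), function(e)
        mse(res$recording$data[e, ], seeg$clean$data[e, ]), numeric(1)))
      rows[[length(rows) + 1]] <-
        data.frame(icap_seconds = v, seed = s, mse = m)
    }
  }
  out <- do.call(rbind, rows)
  summ <- stats::aggregate(mse ~ icap_seconds, out, mean)
  names(summ)[2] <- "mean_mse"
  attr(out, "summary") <- summ
  out
}
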