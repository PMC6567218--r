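#' Two-sample variance-equality test
#'
#' The stopping criterion of the filtering loop: an F-test of equal
#' variances between two sample vectors.  The statistic is the ratio of the
#' unbiased sample variances, `F = var(x1)/var(x2)`, referred to an F
#' distribution with `(n1 - 1, n2 - 1)` degrees of freedom; the two-sided
#' p-value is twice the smaller tail.  `reject = TRUE` (outcome "R1") when
#' `p < alpha`, otherwise "R0".  A zero-variance second sample is degenerate
#' and returns `F = Inf`, `p = 0`, `reject = TRUE` by convention.
#'
#' @param x1,x2 Numeric vectors, each of length at least 2.
#' @param alpha Significance level (default 1%).
#' @return List with `F`, `p`, `reject`, `df1`, `df2`.
#' @export
variance_test <- function(x1, x2, alpha = 0.01) {
  if (length(x1) < 2 || length(x2) < 2)
    stop("variance test needs at least 2 samples per group")
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  df1 <- length(x1) - 1L; df2 <- length(x2) - 1L
  if (v2 == 0) {
    if (v1 == 0)
      return(list(F = 1, p = 1, reject = FALSE, df1 = df1, df2 = df2))
    return(list(F = Inf, p = 0, reject = TRUE, df1 = df1, df2 = df2))
  }
  if (v1 == 0)
    return(list(F = 0, p = 0, reject = TRUE, df1 = df1, df2 = df2))
  # both tails via pf directly: var.test's 1 - pf() loses precision in the
  # far tail and would break the exact two-sided swap symmetry
  F <- v1 / v2
  p <- 2 * min(stats::pf(F, df1, df2),
               stats::pf(F, df1, df2, lower.tail = FALSE))
  list(F = F, p = p, reject = p < alpha, df1 = df1, df2 = df2)
}

#' Select the artefact-free reference span
#'
#' `REF` supplies the variance baseline for the stopping test: the most
#' recent span of the same length as `ART` that ends at or before the start
#' of `ART` and contains only clean samples (samples of previously filtered
#' artefacts count as clean).  When no full-length clean span exists, the
#' longest clean span ending exactly at the start of `ART` is returned,
#' flagged `short = TRUE`, provided it holds at least `min_len` samples;
#' otherwise a condition of class `uar_reference_unavailable` is signalled
#' (a fully contaminated history leaves nothing to compare against).
#'
#' @param portion A `uar_portion` from [widen_and_layout()].
#' @param clean_mask Logical vector, one flag per sample of the recording.
#' @param min_len Minimum acceptable reference length in samples (use the
#'   sliding-window length `Lw`).
#' @return List with `ref` ([span()]) and `short` flag.
#' @export
select_reference <- function(portion, clean_mask, min_len) {
  L <- span_length(portion$art)
  a0 <- portion$art$start
  csum <- c(0, cumsum(as.numeric(clean_mask)))
  clean_count <- function(s, e) csum[e + 1] - csum[s + 1]   # samples in [s, e)
  if (a0 >= L) {
    for (e in seq(a0, L, by = -1)) {
      if (clean_count(e - L, e) == L)
        return(list(ref = span(e - L, e), short = FALSE))
    }
  }
  # fall back: longest clean run ending exactly at the start of ART
  r <- 0
  while (r < a0 && clean_mask[a0 - r]) r <- r + 1
  if (r >= min_len)
    return(list(ref = span(a0 - r, a0), short = TRUE))
  stop(structure(class = c("uar_reference_unavailable", "error", "condition"),
                 list(message = paste0(
                   "no clean reference history of at least ", min_len,
                   " samples before sample ", a0), call = NULL)))
}

#' Filter one electrode's artefact portion
#'
#' The per-electrode filtering loop: starting from the raw `ART` samples,
#' the projection of each ordered component is subtracted in turn.  After
#' every subtraction the variance of the electrode's `REF` samples is
#' compared with the variance of the current residual via the two-sample
#' variance-equality test.  The loop stops when the reference variance
#' exceeds the residual variance *and* the test rejects equality (outcome
#' R1); the result is then the current residual - unless the immediately
#' preceding iterations were a consecutive run of non-rejections (R0), in
#' which case the residual rolls back to the state saved at the first R0 of
#' that run (the filtered signal had already reached the reference's
#' variance level; later subtractions were removing genuine signal).  If
#' every component is exhausted without a stop, the most recent R0 plateau
#' state is returned when one was recorded, otherwise the portion is left
#' unchanged (typically a false-positive detection).
#'
#' @param electrode_signal Full single-channel sample vector (1-based R
#'   indexing of 0-based sample coordinates).
#' @param electrode Channel index of that signal in the decomposition.
#' @param art,ref [span()]s of the artefact portion and reference.
#' @param dec A [run_fastica()] decomposition whose `icap` contains `art`.
#' @param order An [order_components()] result.
#' @param alpha Significance level of the stopping test.
#' @return List with `filtered` (the new `ART` samples) and `trace` (an
#'   `ElectrodeFilterTrace`: `n_components_subtracted`, `stop_reason`,
#'   per-iteration `F`/`p`/`reject`).
#' @export
filter_electrode <- function(electrode_signal, electrode, art, ref, dec,
                             order, alpha = 0.01) {
  if (!span_within(art, dec$icap)) stop("ART span outside ICA_P")
  if (ref$end > art$start) stop("REF must end at or before the start of ART")
  original <- electrode_signal[span_idx(art)]
  ref_x <- electrode_signal[span_idx(ref)]
  v_ref <- stats::var(ref_x)
  N <- length(order$order)
  n_art <- original
  old_art <- NULL; old_i <- NA_integer_
  first <- FALSE; before <- FALSE
  stopped <- FALSE
  out <- NULL; n_sub <- NA_integer_; reason <- NA_character_
  iters <- vector("list", N)
  i <- 1L
  while (!stopped && i <= N) {
    cmp <- order$order[i]
    n_art <- n_art - project_component(dec, electrode, cmp, art)
    tst <- variance_test(ref_x, n_art, alpha)
    iters[[i]] <- list(component = cmp, F = tst$F, p = tst$p,
                       reject = tst$reject)
    if (v_ref > stats::var(n_art) && tst$reject) {
      stopped <- TRUE
      out <- n_art; n_sub <- i; reason <- "significant_drop"
      if (before) {                      # roll back to the R0 plateau
        out <- old_art; n_sub <- old_i; reason <- "rollback_to_plateau"
      }
    }
    if (!tst$reject) {                   # R0: bookkeeping of the plateau
      if (!first) { old_art <- n_art; old_i <- i }
      first <- TRUE; before <- TRUE
    } else {
      first <- FALSE; before <- FALSE
    }
    i <- i + 1L
  }
  if (!stopped) {
    if (!is.null(old_art)) {
      out <- old_art; n_sub <- old_i; reason <- "rollback_to_plateau"
    } else {
      out <- original; n_sub <- 0L; reason <- "exhausted_unchanged"
    }
  }
  list(filtered = out,
       trace = list(n_components_subtracted = n_sub, stop_reason = reason,
                    iterations = iters[!vapply(iters, is.null, logical(1))]))
}

#' Unsupervised artefact removal over a whole recording
#'
#' The full pipeline: detect potential artefact portions from AR(2)
#' centroid distances, lay out the `ART`/`ICA_P`/`REF` geometry, then filter
#' each portion in detection order - FastICA on its `ICA_P` window of the
#' current (partially filtered) signal, components ordered by artefact
#' influence, every electrode's `ART` filtered independently under the
#' variance-equality stopping rule, and the filtered samples written back
#' before the next portion is processed.  Samples outside every `ART` span
#' are returned bit-identical to the input.  Portions without sufficient
#' clean reference history are skipped with a warning.
#'
#' @param rec A [recording()].
#' @param cfg A [uar_config()].
#' @param groups Optional list of channel-index vectors: detection runs per
#'   group and the detected spans are fused (see [detect_grouped()]).
#' @return List with `recording` (filtered) and `report` (class
#'   `uar_filter_report`): per-portion geometry, decomposition convergence,
#'   per-electrode traces, plus the detection profile and thresholds.
#' @export
uar_filter <- function(rec, cfg = uar_config(), groups = NULL) {
  validate_recording(rec)
  check_config_fs(cfg, rec$fs)
  det <- uar_detect(rec, cfg)
  at_spans <- if (is.null(groups)) det$at_spans else {
    merge_spans(detect_grouped(rec, groups, cfg))
  }
  portions <- widen_and_layout(at_spans, cfg, rec$fs, n_samples(rec))
  data <- rec$data
  clean_mask <- rep(TRUE, n_samples(rec))
  for (p in portions) clean_mask[span_idx(p$art)] <- FALSE
  entries <- vector("list", length(portions))
  for (k in seq_along(portions)) {
    p <- portions[[k]]
    refsel <- tryCatch(select_reference(p, clean_mask, cfg$Lw),
                       uar_reference_unavailable = function(e) e)
    if (inherits(refsel, "condition")) {
      warning("skipping artefact at ", format(p$art), ": ",
              conditionMessage(refsel))
      entries[[k]] <- list(portion = p, skipped = TRUE,
                           reason = conditionMessage(refsel))
      next                    # span stays flagged not-clean: still artefactual
    }
    cur <- rec; cur$data <- data
    dec <- run_fastica(cur, p$icap, seed = derive_seed(cfg$seed, k),
                       max_restarts = cfg$max_restarts,
                       tol = cfg$fastica_tol, maxit = cfg$fastica_maxit)
    ord <- order_components(dec, p$art, cfg$ordering_mode)
    traces <- vector("list", n_channels(rec))
    for (e in seq_len(n_channels(rec))) {
      fe <- filter_electrode(data[e, ], e, p$art, refsel$ref, dec, ord,
                             cfg$alpha)
      data[e, span_idx(p$art)] <- fe$filtered
      traces[[e]] <- fe$trace
    }
    clean_mask[span_idx(p$art)] <- TRUE   # filtered spans become usable history
    entries[[k]] <- list(portion = p, skipped = FALSE, ref = refsel$ref,
                         ref_short = refsel$short, converged = dec$converged,
                         electrode_traces = traces)
  }
  out <- rec; out$data <- data
  report <- structure(list(portions = entries, T1 = det$T1, T2 = det$T2,
                           profile = det$profile, config = cfg),
                      class = "uar_filter_report")
  list(recording = out, report = report)
}

#' @export
print.uar_filter_report <- function(x, ...) {
  cat(sprintf("uar_filter_report: %d artefact portion(s), T1=%g, T2=%s\n",
              length(x$portions), x$T1,
              if (is.na(x$T2)) "NA" else format(x$T2)))
  for (ent in x$portions) {
    if (ent$skipped) {
      cat("  ", format(ent$portion$art), " SKIPPED (", ent$reason, ")\n", sep = "")
    } else {
      ncomp <- vapply(ent$electrode_traces, `[[`, integer(1),
                      "n_components_subtracted")
      cat(sprintf("  ART %s: ICs subtracted per electrode: median %g (max %d)%s\n",
                  format(ent$portion$art), stats::median(ncomp), max(ncomp),
                  if (ent$converged) "" else "  [ICA not converged]"))
    }
  }
  invisible(x)
}

#' Serialise a filter report to JSON
#'
#' @param report A `uar_filter_report`.
#' @param path Output file.
#' @export
write_filter_report <- function(report, path) {
  ser <- lapply(report$portions, function(ent) {
    base <- list(at = unclass(ent$portion$at), art = unclass(ent$portion$art),
                 icap = unclass(ent$portion$icap),
                 truncated_at2 = ent$portion$truncated_at2,
                 skipped = ent$skipped)
    if (ent$skipped) return(c(base, list(reason = ent$reason)))
    c(base, list(
      ref = unclass(ent$ref), ref_short = ent$ref_short,
      converged = ent$converged,
      n_components = vapply(ent$electrode_traces, `[[`, integer(1),
                            "n_components_subtracted"),
      stop_reasons = vapply(ent$electrode_traces, `[[`, character(1),
                            "stop_reason")))
  })
  jsonlite::write_json(list(T1 = report$T1, T2 = report$T2, portions = ser),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
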