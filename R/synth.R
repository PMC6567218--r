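# Synthetic contaminated EEG: clean multichannel background, artefact
# templates (blink, eye movement, EMG burst), spatial projection over
# channels, and SEEG = clean + artefacts with ground-truth labels.

# 1/f-amplitude-weighted noise via spectral shaping of white noise.
pink_noise <- function(n, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]           # fold to physical frequency
  w <- 1 / sqrt(pmax(f, 1))                     # flat below 1 Hz, 1/f above
  Re(stats::fft(X * w, inverse = TRUE)) / n
}

#' Clean multichannel EEG background
#'
#' A statistical stand-in for resting EEG: spatially correlated
#' 1/f-weighted noise (a few shared latent sources mixed smoothly across
#' channels plus per-channel independent noise), a broadband white noise
#' floor (amplifier/sensor and high-frequency muscle-tone noise; about a
#' third of each channel's RMS, without it the 1/f component overstates the
#' lag-1 autocorrelation of real EEG), and a shared 10 Hz alpha-band
#' oscillation.  Per-channel RMS falls in 10-30 microvolts.  Deterministic
#' given the seed.
#'
#' @param n_channels Number of channels (>= 2).
#' @param fs Sampling rate in Hz.
#' @param duration Duration in seconds (> 0).
#' @param seed RNG seed.
#' @return A [recording()].
#' @export
gen_background <- function(n_channels, fs, duration, seed = 1L) {
  if (duration <= 0) stop("duration must be positive")
  stopifnot(n_channels >= 2, fs > 0)
  n <- seconds_to_samples(duration, fs)
  with_seed(seed, {
    n_latent <- max(4L, min(n_channels, 12L))
    latent <- t(vapply(seq_len(n_latent), function(i) pink_noise(n, fs),
                       numeric(n)))
    # smooth mixing so neighbouring channels share sources
    mix <- matrix(stats::rnorm(n_channels * n_latent), n_channels, n_latent)
    mix <- t(apply(mix, 1, function(r) r / sqrt(sum(r^2))))
    data <- mix %*% latent
    white_frac <- 0.35                          # broadband noise floor
    for (i in seq_len(n_channels)) {
      p <- data[i, ] + 0.5 * pink_noise(n, fs)
      data[i, ] <- sqrt(1 - white_frac^2) * p / stats::sd(p) +
        white_frac * stats::rnorm(n)
    }
    # shared alpha rhythm, random phase, amplitude graded across channels
    phase <- stats::runif(1, 0, 2 * pi)
    alpha <- sin(2 * pi * 10 * seq_len(n) / fs + phase)
    amp <- 0.3 + 0.4 * stats::runif(n_channels)
    data <- data + outer(amp, alpha)
    target_rms <- stats::runif(n_channels, 12, 25)   # microvolts
    for (i in seq_len(n_channels))
      data[i, ] <- data[i, ] * target_rms[i] / sqrt(mean(data[i, ]^2))
    recording(data, fs = fs)
  })
}

#' EMG burst template
#'
#' Muscle activity emulated as white noise band-pass filtered to 20-60 Hz
#' (4th-order Butterworth, zero-phase), cosine-tapered at both edges and
#' scaled to an exact target RMS.
#'
#' @param duration_s Burst duration in seconds.
#' @param fs Sampling rate in Hz (> 120 so the 60 Hz band edge is
#'   representable).
#' @param amplitude Target RMS in microvolts (0 gives all zeros).
#' @param seed RNG seed.
#' @return Numeric vector of `floor(duration_s * fs)` samples.
#' @export
gen_emg <- function(duration_s, fs, amplitude, seed = 1L) {
  if (fs <= 120) stop("fs must exceed 120 Hz for a 20-60 Hz EMG band")
  stopifnot(duration_s > 0, amplitude >= 0)
  n <- seconds_to_samples(duration_s, fs)
  if (amplitude == 0) return(numeric(n))
  with_seed(seed, {
    bp <- signal::butter(4, c(20, 60) / (fs / 2), type = "pass")
    x <- signal::filtfilt(bp, stats::rnorm(n + 2 * fs))
    x <- x[fs + seq_len(n)]                     # drop filter warm-up
    x <- x * cosine_taper(n, 0.1)
    x * amplitude / sqrt(mean(x^2))
  })
}

# Tukey-style taper: raised-cosine ramps over fraction `frac` of each end.
cosine_taper <- function(n, frac) {
  w <- rep(1, n)
  m <- max(1L, floor(frac * n))
  ramp <- 0.5 * (1 - cos(pi * seq_len(m) / (m + 1)))
  w[seq_len(m)] <- ramp
  w[n + 1 - seq_len(m)] <- ramp
  w
}

#' Eye-blink template
#'
#' A smooth unimodal raised-cosine pulse: zero at both ends, symmetric
#' about its midpoint, peak exactly `amplitude`.
#'
#' @param duration_s Blink duration in seconds (0.1 to 1.0).
#' @param fs Sampling rate in Hz.
#' @param amplitude Peak amplitude in microvolts.
#' @return Numeric vector of `floor(duration_s * fs)` samples.
#' @export
gen_blink <- function(duration_s, fs, amplitude) {
  if (duration_s < 0.1 || duration_s > 1.0)
    stop("blink duration must lie in [0.1, 1.0] s, got ", duration_s)
  n <- seconds_to_samples(duration_s, fs)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  amplitude * w / max(w)
}

#' Eye-movement template
#'
#' A smoothed rectangular deflection: raised-cosine ramp up over the first
#' fifth, plateau at `amplitude`, ramp back down over the last fifth (a
#' saccade-and-return emulation).  Zero at both ends.
#'
#' @param duration_s Duration in seconds (0.2 to 3).
#' @param fs Sampling rate in Hz.
#' @param amplitude Plateau amplitude in microvolts.
#' @return Numeric vector of `floor(duration_s * fs)` samples.
#' @export
gen_eye_move <- function(duration_s, fs, amplitude) {
  if (duration_s < 0.2 || duration_s > 3)
    stop("eye-movement duration must lie in [0.2, 3] s, got ", duration_s)
  n <- seconds_to_samples(duration_s, fs)
  m <- max(2L, floor(n / 5))
  w <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 1) / m))   # starts exactly at 0
  w[seq_len(m)] <- ramp
  w[n + 1 - seq_len(m)] <- ramp          # indices descend: mirrored ramp
  amplitude * w
}

#' Exponentially decaying channel topography
#'
#' Spatial weighting of an artefact over channels: weight 1 at the focus
#' channel, decaying exponentially with channel-index distance (a stand-in
#' for scalp distance on an abstract montage).
#'
#' @param n_channels Number of channels.
#' @param focus_channel Channel carrying the full artefact (weight 1).
#' @param decay Decay rate per channel-index step (> 0).
#' @return Numeric weight vector with `max(abs(.)) == 1`.
#' @export
frontal_topography <- function(n_channels, focus_channel, decay) {
  stopifnot(decay > 0, focus_channel >= 1, focus_channel <= n_channels)
  exp(-decay * abs(seq_len(n_channels) - focus_channel))
}

#' Artefact event specification
#'
#' @param kind `"blink"`, `"eye_move"` or `"emg"`.
#' @param onset_s Onset in seconds, relative to the end of the clean prefix.
#' @param duration_s Duration in seconds.
#' @param amplitude Microvolts: peak for ocular templates, RMS for EMG.
#' @param focus_channel Channel of maximal expression.
#' @param decay Topography decay rate per channel step.
#' @return List of class `uar_event_spec`.
#' @export
artefact_event <- function(kind = c("blink", "eye_move", "emg"), onset_s,
                           duration_s, amplitude, focus_channel, decay) {
  kind <- match.arg(kind)
  stopifnot(onset_s >= 0, duration_s > 0, amplitude >= 0)
  structure(list(kind = kind, onset_s = onset_s, duration_s = duration_s,
                 amplitude = amplitude, focus_channel = focus_channel,
                 decay = decay),
            class = "uar_event_spec")
}

default_events <- function(n_channels) {
  f <- function(x) max(1L, min(n_channels, x))
  list(
    artefact_event("blink",    5.0, 0.40, 120, f(4L),  0.015),
    artefact_event("eye_move", 14.0, 1.20,  90, f(6L),  0.015),
    artefact_event("emg",      23.0, 2.00,  45, f(50L), 0.030),
    artefact_event("blink",    33.0, 0.35, 140, f(5L),  0.015),
    artefact_event("emg",      41.0, 2.50,  50, f(58L), 0.030),
    artefact_event("eye_move", 51.0, 1.00, 100, f(10L), 0.015))
}

#' Synthetic contaminated-EEG scenario
#'
#' The default scenario mirrors the reference simulation conditions:
#' 64 channels at 256 Hz, 60 s of contaminated signal preceded by a 30 s
#' clean prefix (so artefacts near the start have enough history for the
#' ICA window and the reference span), and six ocular/EMG events whose peak
#' amplitudes are at least three times the background RMS.
#'
#' @param n_channels,fs,duration_seconds,clean_prefix_seconds Geometry.
#' @param events List of [artefact_event()]s; onsets are relative to the end
#'   of the clean prefix and events must not overlap.
#' @param seed RNG seed controlling background and EMG noise.
#' @return List of class `uar_scenario`.
#' @export
synth_scenario <- function(n_channels = 64, fs = 256, duration_seconds = 60,
                           clean_prefix_seconds = 30,
                           events = default_events(n_channels), seed = 1L) {
  stopifnot(n_channels >= 2, duration_seconds > 0, clean_prefix_seconds >= 0)
  if (fs <= 120)
    stop("fs must exceed 120 Hz so the 20-60 Hz EMG band is representable")
  for (ev in events) {
    if (ev$onset_s + ev$duration_s > duration_seconds)
      stop("event extends past the end of the scenario")
    if (ev$focus_channel > n_channels) stop("event focus channel out of range")
  }
  structure(list(n_channels = n_channels, fs = fs,
                 duration_seconds = duration_seconds,
                 clean_prefix_seconds = clean_prefix_seconds,
                 events = events, seed = as.integer(seed)),
            class = "uar_scenario")
}

#' Read a scenario from a YAML file
#'
#' Top-level keys mirror [synth_scenario()]; `events` is a list of records
#' with the [artefact_event()] fields.
#'
#' @param path YAML file.
#' @return A `uar_scenario`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$events)) y$events <- lapply(y$events, function(e) do.call(artefact_event, e))
  do.call(synth_scenario, y)
}

#' Build a simulated contaminated EEG (SEEG)
#'
#' Generates the clean background over prefix + body, renders each event's
#' template, projects it over channels with its topography and adds it at
#' its span.  Additivity is exact: `contaminated - clean` equals the summed
#' injected artefact signals bit-for-bit, and the clean prefix contains no
#' events.
#'
#' @param scenario A [synth_scenario()].
#' @return List with `clean` and `contaminated` ([recording()]s), and
#'   `events`: a list of realised events, each holding `kind`, `span`
#'   (absolute sample coordinates), `amplitude`, `topography`.
#' @export
build_seeg <- function(scenario) {
  stopifnot(inherits(scenario, "uar_scenario"))
  fs <- scenario$fs
  total_s <- scenario$clean_prefix_seconds + scenario$duration_seconds
  clean <- gen_background(scenario$n_channels, fs, total_s, scenario$seed)
  prefix <- seconds_to_samples(scenario$clean_prefix_seconds, fs)
  art <- matrix(0, nrow = scenario$n_channels, ncol = n_samples(clean))
  events <- vector("list", length(scenario$events))
  spans <- list()
  for (k in seq_along(scenario$events)) {
    ev <- scenario$events[[k]]
    template <- switch(ev$kind,
      blink = gen_blink(ev$duration_s, fs, ev$amplitude),
      eye_move = gen_eye_move(ev$duration_s, fs, ev$amplitude),
      emg = gen_emg(ev$duration_s, fs, ev$amplitude,
                    seed = derive_seed(scenario$seed, 100 + k)))
    start <- prefix + seconds_to_samples(ev$onset_s, fs)
    sp <- span(start, start + length(template))
    for (prev in spans) if (spans_overlap(sp, prev))
      stop("overlapping artefact events at ", format(sp), " and ", format(prev))
    spans[[k]] <- sp
    topo <- frontal_topography(scenario$n_channels, ev$focus_channel, ev$decay)
    art[, span_idx(sp)] <- art[, span_idx(sp)] + outer(topo, template)
    events[[k]] <- list(kind = ev$kind, span = sp, amplitude = ev$amplitude,
                        topography = topo)
  }
  contaminated <- clean
  contaminated$data <- clean$data + art
  list(clean = clean, contaminated = contaminated, events = events)
}

#' Write ground-truth event labels
#'
#' BED-like TSV (`start`, `end`, `kind`) or JSON including topographies.
#'
#' @param events Realised events from [build_seeg()].
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @export
write_events <- function(events, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- spans_to_df(lapply(events, `[[`, "span"))
  df$kind <- vapply(events, `[[`, character(1), "kind")
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(lapply(events, function(e)
      list(kind = e$kind, start = e$span$start, end = e$span$end,
           amplitude = e$amplitude, topography = e$topography)),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
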