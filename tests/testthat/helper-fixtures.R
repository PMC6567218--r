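# Shared fixtures and independent oracles for the test suite.

# Small random recording (white noise), deterministic given seed.
make_test_recording <- function(n_channels = 4, n = 600, fs = 256, seed = 1) {
  withr::with_seed(seed,
    recording(matrix(rnorm(n_channels * n, sd = 15), nrow = n_channels),
              fs = fs))
}

# Desk-scale synthetic scenario: 16 channels keep FastICA cheap; detection at
# the 64-channel operating threshold still flags the (strong) EMG events.
small_scenario <- function(seed = 1, n_channels = 16) {
  synth_scenario(
    n_channels = n_channels, fs = 256, duration_seconds = 30,
    clean_prefix_seconds = 15,
    events = list(
      artefact_event("blink", 4, 0.4, 120, 3, 0.015),
      artefact_event("emg", 12, 2.0, 45, min(n_channels, 12), 0.03),
      artefact_event("eye_move", 22, 1.0, 100, 5, 0.015)),
    seed = seed)
}

spans_df <- function(spans) {
  data.frame(start = vapply(spans, `[[`, numeric(1), "start"),
             end = vapply(spans, `[[`, numeric(1), "end"))
}

# Yule-Walker AR(2) from sample autocovariances: the estimator-independent
# oracle for ar2_window (which uses Burg).
yw_ar2 <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  r <- sapply(0:2, function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / n)
  solve(matrix(c(r[1], r[2], r[2], r[1]), 2), r[2:3])
}

# Naive run finder over a boolean vector: list of (first, last) index pairs.
naive_runs <- function(flags, min_run) {
  out <- list()
  i <- 1
  while (i <= length(flags)) {
    if (flags[i]) {
      j <- i
      while (j < length(flags) && flags[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run) out[[length(out) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# Hand-built decomposition object: known A (N x N), S (N x p, rows scaled to
# unit variance by the caller), icap span starting at 0.
make_fake_dec <- function(A, S, icap_start = 0) {
  structure(list(A = A, S = S, channel_means = rep(0, nrow(A)),
                 icap = span(icap_start, icap_start + ncol(S)),
                 converged = TRUE, iterations = 0L, seed_used = 0L),
            class = "uar_decomposition")
}

# Hand-built 3-component fixtures for the per-electrode filtering loop:
# icap [0, 2000); art [1200, 1700); ref [700, 1200).  Sources are unit
# variance over icap; the electrode signal is assembled explicitly so each
# stopping path of the loop is forced by construction.
build_filter_fixture <- function(kind, seed = 61) {
  withr::with_seed(seed, {
    n <- 2000
    art <- span(1200, 1700); ref <- span(700, 1200)
    art_rel <- 1201:1700
    base <- rnorm(n)                      # unit-variance background
    S <- matrix(rnorm(3 * n), 3, n)
    if (kind == "rollback") {
      # C3's waveform over ART is (almost) the background itself, so
      # subtracting it wipes genuine signal once C1 and C2 are gone
      S[3, art_rel] <- base[art_rel] * 3
    }
    S <- S / apply(S, 1, sd)
    A <- matrix(0, 3, 3)
    sig <- base
    if (kind == "one_component") {
      # ART = strong C1 + weak residual; removing C1 drops the variance far
      # below the reference level at once
      sig[art_rel] <- 0.1 * base[art_rel] + 10 * S[1, art_rel]
      A[1, ] <- c(10, 0.001, 0.001)
    } else if (kind == "rollback") {
      sig[art_rel] <- base[art_rel] + 5 * S[1, art_rel] + 2 * S[2, art_rel]
      A[1, ] <- c(5, 2, 0.93 / sd(S[3, art_rel]) * sd(base[art_rel]))
    } else if (kind == "noop") {
      A[1, ] <- 0                         # no influence on this electrode
    }
    list(signal = sig, dec = make_fake_dec(A, S), art = art, ref = ref,
         ord = list(order = 1:3, scores = c(3, 2, 1)))
  })
}

# Literal step-through of the per-electrode filtering pseudocode, kept
# deliberately naive and separate from filter_electrode.
pseudocode_filter <- function(signal, e, art, ref, dec, ord, alpha) {
  art_idx <- (art$start + 1):art$end
  ref_idx <- (ref$start + 1):ref$end
  ART <- signal[art_idx]
  REF <- signal[ref_idx]
  N_ART <- ART
  STOP <- 0; FIRST <- 0; BEFORE <- 0; i <- 1
  OLD_ART <- NULL
  result <- NULL
  while (STOP == 0 && i <= length(ord$order)) {
    C <- ord$order[i]
    rel <- (art$start - dec$icap$start + 1):(art$end - dec$icap$start)
    N_ART <- N_ART - dec$A[e, C] * dec$S[C, rel]
    FT <- var(REF) / var(N_ART)
    p <- 2 * min(pf(FT, length(REF) - 1, length(N_ART) - 1),
                 pf(FT, length(REF) - 1, length(N_ART) - 1, lower.tail = FALSE))
    R1 <- p < alpha
    if (var(REF) > var(N_ART) && R1) {
      STOP <- 1
      result <- N_ART
      if (BEFORE == 1) result <- OLD_ART
    }
    if (!R1) {
      if (FIRST == 0) OLD_ART <- N_ART
      FIRST <- 1; BEFORE <- 1
    } else {
      FIRST <- 0; BEFORE <- 0
    }
    i <- i + 1
  }
  if (STOP == 0) {
    result <- if (!is.null(OLD_ART)) OLD_ART else ART
  }
  result
}
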