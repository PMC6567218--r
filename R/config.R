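#' UAR pipeline configuration
#'
#' Bundles all tunable parameters of the detection / decomposition / removal
#' pipeline.  Defaults follow the reference operating point for 64-channel,
#' 256 Hz recordings: sliding window `Lw = 155` samples, sliding distance
#' `d = 32` samples, fixed detection threshold `T = 1.33`, 1 s widening
#' margins on either side of each detection, a 26 s ICA window and a 1%
#' significance level for the variance-equality stopping test.
#'
#' @param Lw Sliding window length in samples (> 2 so AR(2) is estimable).
#' @param d Sliding distance in samples, `0 < d <= Lw`.
#' @param n_detect Channel indices used for detection; `NULL` means all.
#' @param T Detection threshold on centroid distances (Option A uses the
#'   fixed tail-onset value 1.33).
#' @param at1_seconds,at2_seconds Widening margins prepended/appended to each
#'   detected artefact, in seconds.
#' @param icap_seconds Length of the local ICA window (`ICA_P`), seconds.
#' @param alpha Significance level of the two-sample variance-equality
#'   stopping test.
#' @param ordering_mode How independent components are ranked by artefact
#'   influence: `"max_abs"` (peak absolute projection) or `"max_var"`
#'   (projection variance).
#' @param min_run Minimum number of consecutive above-threshold intervals
#'   that constitute a detection.
#' @param seed Base RNG seed for FastICA initialisation.
#' @param max_restarts FastICA restarts on non-convergence.
#' @param fastica_tol,fastica_maxit FastICA convergence tolerance and
#'   iteration cap.
#' @return An object of class `uar_config`.
#' @export
uar_config <- function(Lw = 155, d = 32, n_detect = NULL, T = 1.33,
                       at1_seconds = 1, at2_seconds = 1, icap_seconds = 26,
                       alpha = 0.01, ordering_mode = c("max_abs", "max_var"),
                       min_run = 1, seed = 1L, max_restarts = 5,
                       fastica_tol = 1e-4, fastica_maxit = 500) {
  ordering_mode <- match.arg(ordering_mode)
  cfg <- structure(list(
    Lw = as.integer(Lw), d = as.integer(d), n_detect = n_detect, T = T,
    at1_seconds = at1_seconds, at2_seconds = at2_seconds,
    icap_seconds = icap_seconds, alpha = alpha,
    ordering_mode = ordering_mode, min_run = as.integer(min_run),
    seed = as.integer(seed), max_restarts = as.integer(max_restarts),
    fastica_tol = fastica_tol, fastica_maxit = as.integer(fastica_maxit)),
    class = "uar_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$Lw <= 2) stop("Lw must exceed 2 samples for AR(2) estimation")
  if (cfg$d <= 0 || cfg$d > cfg$Lw) stop("need 0 < d <= Lw")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cfg$T <= 0) stop("detection threshold T must be positive")
  if (cfg$min_run < 1) stop("min_run must be >= 1")
  if (cfg$at1_seconds < 0 || cfg$at2_seconds < 0)
    stop("widening margins must be non-negative")
  if (cfg$icap_seconds <= 0) stop("icap_seconds must be positive")
  cfg
}

# icap must be able to hold at least one sliding window; fs only known at
# use time, so this check runs when a recording is available.
check_config_fs <- function(cfg, fs) {
  if (seconds_to_samples(cfg$icap_seconds, fs) < cfg$Lw)
    stop("icap_seconds * fs must be at least Lw samples")
  invisible(cfg)
}

#' @export
print.uar_config <- function(x, ...) {
  cat("uar_config:\n")
  cat(sprintf("  Lw=%d d=%d T=%g min_run=%d ordering=%s\n",
              x$Lw, x$d, x$T, x$min_run, x$ordering_mode))
  cat(sprintf("  AT1=%gs AT2=%gs ICA_P=%gs alpha=%g seed=%d\n",
              x$at1_seconds, x$at2_seconds, x$icap_seconds, x$alpha, x$seed))
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [uar_config()]; unknown keys are an error.
#'
#' @param path YAML file.
#' @return A `uar_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(uar_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(uar_config, vals)
}
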