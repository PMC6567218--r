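# FastICA decomposition of the local ICA_P window around one artefact, plus
# component projections and influence ordering.
#
# The model is M = A %*% S for the mean-centred window M (channels x
# samples): A is the N x N mixing matrix, S holds N independent sources
# scaled to unit variance.  Channel means over ICA_P are kept separately and
# are never subtracted from the recording itself, so removing zero-mean
# component projections from the raw signal leaves the local baseline
# intact.

# One symmetric (parallel) FastICA pass with the cube nonlinearity on
# whitened data Z (N x p, identity sample covariance).  Returns the
# orthonormal unmixing matrix and the final convergence delta.
fastica_core <- function(Z, tol, maxit) {
  N <- nrow(Z); p <- ncol(Z)
  W <- qr.Q(qr(matrix(stats::rnorm(N * N), N, N)))
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), N) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  delta <- Inf
  for (it in seq_len(maxit)) {
    U <- W %*% Z
    W_new <- (U^3 %*% t(Z)) / p - 3 * W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (delta < tol) break
  }
  list(W = W, delta = delta, iterations = it, converged = delta < tol)
}

#' FastICA on an ICA window
#'
#' Decomposes the recording restricted to the `ICA_P` span into as many
#' independent components as channels: whitening by PCA retaining all
#' dimensions, then symmetric fixed-point iteration with the cube
#' nonlinearity.  FastICA runs are not always reproducible between random
#' initialisations, which does not harm the downstream filtering; on
#' non-convergence the decomposition restarts with fresh derived seeds up to
#' `max_restarts` times and keeps the best attempt (flagged
#' `converged = FALSE` if none met the tolerance).
#'
#' @param rec A [recording()].
#' @param icap A [span()] inside the recording; must contain at least as
#'   many samples as channels (a warning is issued below `10 * N`).
#' @param seed RNG seed for the initial unmixing matrix (bit-reproducible
#'   given the same input and seed).
#' @param max_restarts Restarts on non-convergence.
#' @param tol,maxit Fixed-point tolerance and iteration cap.
#' @return An object of class `uar_decomposition`: `A` (N x N mixing
#'   matrix), `S` (N x p sources, unit variance rows), `channel_means`,
#'   `icap`, `converged`, `iterations`, `seed_used`.  The reconstruction
#'   `channel_means + A %*% S` reproduces the window to near machine
#'   precision.
#' @export
run_fastica <- function(rec, icap, seed = 1L, max_restarts = 5,
                        tol = 1e-4, maxit = 500) {
  validate_recording(rec)
  if (icap$end > n_samples(rec)) stop("icap span exceeds recording length")
  M <- rec$data[, span_idx(icap), drop = FALSE]
  N <- nrow(M); p <- ncol(M)
  if (p < N) stop("ICA window has fewer samples (", p, ") than channels (", N, ")")
  if (p < 10 * N)
    warning("ICA window has fewer than 10 samples per channel; ",
            "components may be poorly estimated")
  channel_means <- rowMeans(M)
  Mc <- M - channel_means
  C <- (Mc %*% t(Mc)) / (p - 1)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) <= max(e$values) * 1e-10)
    stop("rank-deficient ICA window (duplicated or flat channels); ",
         "cannot decompose")
  K <- diag(1 / sqrt(e$values), N) %*% t(e$vectors)      # whitening
  Z <- K %*% Mc
  best <- NULL
  for (attempt in 0:max_restarts) {
    seed_k <- if (attempt == 0) as.integer(seed) else derive_seed(seed, attempt)
    res <- with_seed(seed_k, fastica_core(Z, tol, maxit))
    res$seed_used <- seed_k
    if (is.null(best) || res$delta < best$delta) best <- res
    if (res$converged) break
  }
  S <- best$W %*% Z
  # unit-variance source convention; fold the scale into the mixing matrix
  s_sd <- apply(S, 1, stats::sd)
  S <- S / s_sd
  A <- solve(best$W %*% K)
  A <- A * rep(s_sd, each = N)
  structure(list(A = A, S = S, channel_means = channel_means, icap = icap,
                 converged = best$converged, iterations = best$iterations,
                 seed_used = best$seed_used),
            class = "uar_decomposition")
}

#' @export
print.uar_decomposition <- function(x, ...) {
  cat(sprintf("uar_decomposition: %d components over ICA_P %s (%s, %d iterations)\n",
              nrow(x$S), format(x$icap),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Projection of one component onto one electrode
#'
#' The additive contribution of component `component` to electrode
#' `electrode` over `span`: `A[electrode, component] * S[component, ]`
#' restricted to the span.  Projections are zero-mean by construction (the
#' channel means live in `channel_means`), so subtracting them from the raw
#' signal does not shift the local baseline.
#'
#' @param dec A [run_fastica()] decomposition.
#' @param electrode Channel index.
#' @param component Component index.
#' @param span A [span()] inside `dec$icap`.
#' @return Numeric vector of `span_length(span)` samples.
#' @export
project_component <- function(dec, electrode, component, span) {
  if (!span_within(span, dec$icap))
    stop("projection span ", format(span), " lies outside ICA_P ",
         format(dec$icap))
  rel <- seq.int(span$start - dec$icap$start + 1, span$end - dec$icap$start)
  dec$A[electrode, component] * dec$S[component, rel]
}

#' Order components by artefact influence
#'
#' Scores every component by its strongest electrode projection over the
#' artefact portion - either the peak absolute value (`max_abs`, the
#' default) or the projection variance (`max_var`) - and returns the
#' components sorted by descending score, ties broken by ascending index.
#' The leading components are the ones subtracted first during filtering.
#'
#' @param dec A [run_fastica()] decomposition.
#' @param art The artefact [span()] (inside `dec$icap`).
#' @param mode `"max_abs"` or `"max_var"`.
#' @return List with `order` (permutation of component indices) and
#'   `scores` (per-component, in original component order).
#' @export
order_components <- function(dec, art, mode = c("max_abs", "max_var")) {
  mode <- match.arg(mode)
  if (!span_within(art, dec$icap))
    stop("artefact span lies outside ICA_P")
  if (span_length(art) < 1) stop("empty artefact span")
  rel <- seq.int(art$start - dec$icap$start + 1, art$end - dec$icap$start)
  N <- nrow(dec$S)
  scores <- vapply(seq_len(N), function(cmp) {
    s <- dec$S[cmp, rel]
    if (mode == "max_abs") {
      max(abs(dec$A[, cmp])) * max(abs(s))
    } else {
      max(dec$A[, cmp]^2) * stats::var(s)
    }
  }, numeric(1))
  list(order = order(-scores, seq_len(N)), scores = scores)
}
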