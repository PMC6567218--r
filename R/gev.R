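# Generalized Extreme Value distribution: density, CDF, quantile, RNG and
# maximum-likelihood fitting.  Parameterisation: shape xi, location mu,
# scale sigma; support 1 + xi*(x - mu)/sigma > 0 (all reals when xi = 0).

#' The Generalized Extreme Value distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the GEV with shape `shape`, location `location` and scale `scale`.
#' `shape = 0` is the Gumbel limit.
#'
#' @param x,q Quantiles.
#' @param p Probabilities.
#' @param n Number of draws.
#' @param shape,location,scale GEV parameters (`scale > 0`).
#' @param log Return log-density?
#' @return `dgev` density, `pgev` CDF, `qgev` inverse CDF, `rgev` draws.
#' @name gev
NULL

#' @rdname gev
#' @export
dgev <- function(x, shape, location, scale, log = FALSE) {
  stopifnot(scale > 0)
  z <- (x - location) / scale
  if (abs(shape) < 1e-12) {
    ld <- -z - exp(-z) - base::log(scale)
  } else {
    t <- 1 + shape * z
    ld <- ifelse(t > 0,
                 -(1 / shape + 1) * base::log(pmax(t, 1e-300)) -
                   pmax(t, 1e-300)^(-1 / shape) - base::log(scale),
                 -Inf)
  }
  if (log) ld else exp(ld)
}

#' @rdname gev
#' @export
pgev <- function(q, shape, location, scale) {
  stopifnot(scale > 0)
  z <- (q - location) / scale
  if (abs(shape) < 1e-12) return(exp(-exp(-z)))
  t <- 1 + shape * z
  out <- ifelse(t > 0, exp(-t^(-1 / shape)), NA_real_)
  # outside the support: CDF is 0 below a lower endpoint, 1 above an upper one
  out[is.na(out)] <- if (shape > 0) 0 else 1
  out
}

#' @rdname gev
#' @export
qgev <- function(p, shape, location, scale) {
  stopifnot(scale > 0, all(p > 0 & p < 1))
  if (abs(shape) < 1e-12) return(location - scale * base::log(-base::log(p)))
  location + scale * ((-base::log(p))^(-shape) - 1) / shape
}

#' @rdname gev
#' @export
rgev <- function(n, shape, location, scale) {
  qgev(stats::runif(n), shape, location, scale)
}

#' Fit a GEV distribution by maximum likelihood
#'
#' Used to model the histogram of interval-to-centroid distances, from which
#' a tail-onset detection threshold can be read off as a high quantile.
#' Starting values come from the method of moments (Gumbel approximation);
#' optimisation is Nelder-Mead on (location, log scale, shape).
#'
#' @param distances Numeric vector, at least 50 values.
#' @return List with `shape`, `location`, `scale`, `logLik`, `convergence`.
#' @export
fit_gev <- function(distances) {
  distances <- as.numeric(distances)
  if (length(distances) < 50)
    stop("need at least 50 distances to fit a GEV, got ", length(distances))
  if (stats::sd(distances) == 0)
    stop("degenerate (constant) distances: GEV fit is undefined")
  s0 <- stats::sd(distances) * sqrt(6) / pi
  m0 <- mean(distances) - 0.5772156649 * s0
  nll <- function(par) {
    ll <- dgev(distances, shape = par[3], location = par[1],
               scale = exp(par[2]), log = TRUE)
    if (any(!is.finite(ll))) return(1e10)
    -sum(ll)
  }
  fit <- stats::optim(c(m0, base::log(s0), 0.1), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (fit$convergence != 0 || fit$value >= 1e10)
    stop("GEV fit did not converge (code ", fit$convergence,
         ", nll ", format(fit$value), ")")
  list(shape = fit$par[3], location = fit$par[1], scale = exp(fit$par[2]),
       logLik = -fit$value, convergence = fit$convergence)
}
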