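# Belief states: probability distributions over a parameter represented on a
# dense grid, normalized by trapezoid quadrature. Point masses (a single
# support point) are permitted and behave as degenerate beliefs.

#' Construct a grid belief state
#'
#' A belief state is a probability distribution over a one-dimensional
#' parameter, held as log-density values on a strictly increasing grid and
#' normalized by trapezoid quadrature. It is the container for priors and
#' general-Bayes posteriors produced by [gibbs_update()].
#'
#' @param support Strictly increasing numeric vector of parameter values.
#'   A single point defines a point-mass (degenerate) belief.
#' @param log_density Numeric vector of log-density values at `support`;
#'   `-Inf` entries (zero density) are allowed, `+Inf`/`NaN` are not.
#' @param normalize Normalize so that the quadrature mass is one (default).
#' @return An object of class `belief_state` with fields `support`,
#'   `log_density`, `weights` (quadrature weights) and `normalized`.
#' @seealso [belief_normal()], [belief_uniform()], [gibbs_update()]
#' @export
belief_state <- function(support, log_density, normalize = TRUE) {
  support <- as.numeric(support)
  log_density <- as.numeric(log_density)
  if (length(support) != length(log_density)) {
    stop("`support` and `log_density` must have the same length")
  }
  if (length(support) > 1L && any(diff(support) <= 0)) {
    stop("`support` must be strictly increasing")
  }
  if (any(is.nan(log_density)) || any(log_density == Inf)) {
    stop("`log_density` must be finite or -Inf")
  }
  b <- structure(
    list(support = support, log_density = log_density,
         weights = trapezoid_weights(support), normalized = FALSE),
    class = "belief_state"
  )
  if (normalize) normalize_belief(b) else b
}

#' Normalize a belief state
#'
#' Rescales the log-density so the trapezoid-quadrature mass equals one.
#' A single-point support is treated as a point mass with total mass one.
#'
#' @param belief A `belief_state`.
#' @return The normalized `belief_state`.
#' @export
normalize_belief <- function(belief) {
  stopifnot(inherits(belief, "belief_state"))
  if (length(belief$support) == 1L) {
    belief$log_density <- 0
    belief$normalized <- TRUE
    return(belief)
  }
  logz <- logsumexp(belief$log_density + log(belief$weights))
  if (!is.finite(logz)) {
    stop("belief state has zero or non-finite total mass; cannot normalize")
  }
  belief$log_density <- belief$log_density - logz
  belief$normalized <- TRUE
  belief
}

#' Gaussian belief state on a grid
#'
#' @param mean,sd Mean and standard deviation of the Gaussian.
#' @param n Number of grid points (default 2048).
#' @param width Half-width of the grid in standard deviations (default 8).
#' @return A normalized `belief_state`.
#' @export
belief_normal <- function(mean = 0, sd = 1, n = 2048, width = 8) {
  stopifnot(sd > 0, n >= 2)
  g <- seq(mean - width * sd, mean + width * sd, length.out = n)
  belief_state(g, stats::dnorm(g, mean, sd, log = TRUE))
}

#' Uniform belief state on a bounded interval
#'
#' @param lower,upper Interval bounds.
#' @param n Number of grid points.
#' @return A normalized `belief_state`.
#' @export
belief_uniform <- function(lower, upper, n = 2048) {
  stopifnot(upper > lower, n >= 2)
  g <- seq(lower, upper, length.out = n)
  belief_state(g, rep(-log(upper - lower), n))
}

#' Belief state from a density function
#'
#' @param f Density (or log-density) function, vectorized over the parameter.
#' @param lower,upper Grid bounds.
#' @param n Number of grid points.
#' @param log Is `f` already a log-density?
#' @return A normalized `belief_state`.
#' @export
belief_from_density <- function(f, lower, upper, n = 2048, log = FALSE) {
  g <- seq(lower, upper, length.out = n)
  v <- f(g)
  belief_state(g, if (log) v else base::log(v))
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("<belief_state: %d grid points on [%g, %g]%s>\n",
              length(x$support), min(x$support), max(x$support),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Density values of a belief state
#' @param belief A `belief_state`.
#' @return Numeric vector `exp(log_density)`.
#' @export
belief_density <- function(belief) exp(belief$log_density)

#' Moments and summaries of a belief state
#'
#' `belief_mean()`, `belief_var()` and `belief_mode()` compute quadrature
#' moments and the grid mode; `belief_quantile()` inverts the quadrature
#' cumulative distribution by linear interpolation.
#'
#' @param belief A normalized `belief_state`.
#' @param probs Probabilities for `belief_quantile()`.
#' @return Numeric value(s).
#' @export
belief_mean <- function(belief) {
  b <- if (belief$normalized) belief else normalize_belief(belief)
  sum(b$support * exp(b$log_density) * b$weights)
}

#' @rdname belief_mean
#' @export
belief_var <- function(belief) {
  b <- if (belief$normalized) belief else normalize_belief(belief)
  m <- belief_mean(b)
  sum((b$support - m)^2 * exp(b$log_density) * b$weights)
}

#' @rdname belief_mean
#' @export
belief_mode <- function(belief) {
  belief$support[which.max(belief$log_density)]
}

#' @rdname belief_mean
#' @export
belief_quantile <- function(belief, probs) {
  b <- if (belief$normalized) belief else normalize_belief(belief)
  if (length(b$support) == 1L) return(rep(b$support, length(probs)))
  mass <- exp(b$log_density) * b$weights
  cdf <- cumsum(mass)
  cdf <- cdf / cdf[length(cdf)]
  vapply(probs, function(p) {
    i <- which(cdf >= p)[1]
    if (is.na(i)) return(b$support[length(b$support)])
    if (i == 1L) return(b$support[1])
    # linear interpolation between grid points
    p0 <- cdf[i - 1]; p1 <- cdf[i]
    if (p1 == p0) return(b$support[i])
    b$support[i - 1] + (p - p0) / (p1 - p0) * (b$support[i] - b$support[i - 1])
  }, numeric(1))
}

#' Draw samples from a belief state
#'
#' Samples grid points with probability proportional to their quadrature
#' mass. Adequate for Monte Carlo expectations on dense grids.
#'
#' @param belief A normalized `belief_state`.
#' @param n Number of draws.
#' @return Numeric vector of parameter values.
#' @export
belief_sample <- function(belief, n) {
  b <- if (belief$normalized) belief else normalize_belief(belief)
  if (length(b$support) == 1L) return(rep(b$support, n))
  p <- exp(b$log_density) * b$weights
  sample(b$support, n, replace = TRUE, prob = p)
}

#' Read and write belief states as TSV
#'
#' Serializes the grid as two tab-separated columns `parameter` and
#' `log_density`; reading reconstructs (and re-normalizes) the belief.
#'
#' @param belief A `belief_state`.
#' @param path File path.
#' @return `read_belief()` returns a `belief_state`; `write_belief()`
#'   returns `path` invisibly.
#' @export
write_belief <- function(belief, path) {
  utils::write.table(
    data.frame(parameter = belief$support, log_density = belief$log_density),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_belief
#' @export
read_belief <- function(path) {
  d <- utils::read.delim(path)
  if (!all(c("parameter", "log_density") %in% names(d))) {
    stop("belief TSV must have columns `parameter` and `log_density`")
  }
  belief_state(d$parameter, d$log_density)
}
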