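# Numerical helpers shared across modules. All density arithmetic in the
# package is done in the log domain; these primitives keep it overflow-safe.

#' Log-sum-exp
#'
#' Computes `log(sum(exp(x)))` with max-shift stabilisation.
#'
#' @param x Numeric vector; `-Inf` entries are allowed (zero mass).
#' @return A single numeric value.
#' @export
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m) # all -Inf, or a +Inf dominates
  m + log(sum(exp(x - m)))
}

# Running log-sum-exp: out[i] = logsumexp(x[1:i]). Safe even when early
# entries underflow relative to the global maximum.
logcumsumexp <- function(x) {
  n <- length(x)
  m <- max(x)
  if (!is.finite(m)) return(rep(m, n))
  s <- cumsum(exp(x - m))
  if (s[1] > 0) return(m + log(s))
  # fall back to a sequential accumulation when the first terms underflow
  out <- numeric(n)
  acc <- x[1]
  out[1] <- acc
  for (i in seq_len(n)[-1]) {
    a <- max(acc, x[i])
    acc <- a + log(exp(acc - a) + exp(x[i] - a))
    out[i] <- acc
  }
  out
}

# Trapezoid quadrature weights for a strictly increasing grid.
trapezoid_weights <- function(x) {
  n <- length(x)
  if (n == 1L) return(1)
  d <- diff(x)
  c(d[1] / 2, (d[-1] + d[-(n - 1)]) / 2, d[n - 1] / 2)
}

#' Gauss--Hermite nodes and weights
#'
#' Nodes and weights for the physicists' Gauss--Hermite rule
#' (weight function `exp(-x^2)`), computed by the Golub--Welsch
#' eigen-decomposition of the Jacobi matrix.
#'
#' @param n Number of nodes.
#' @return A list with `nodes` and `weights`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

#' Log Stirling numbers of the second kind
#'
#' `log S(n, k)`: the log number of ways to partition `n` labelled objects
#' into exactly `k` nonempty unlabelled blocks. Computed by the standard
#' recurrence in the log domain so large counts do not overflow.
#'
#' @param n,k Non-negative integers, `k <= n`.
#' @return `log S(n, k)` (`-Inf` when the count is zero).
#' @export
log_stirling2 <- function(n, k) {
  stopifnot(n >= 0, k >= 0)
  if (k > n) return(-Inf)
  if (n == 0L) return(if (k == 0L) 0 else -Inf)
  if (k == 0L) return(-Inf)
  # prev[j] = log S(i-1, j)
  prev <- c(0, rep(-Inf, k)) # row i = 1: S(1,1)=1
  prev[2] <- 0
  prev[1] <- -Inf
  if (n == 1L) return(prev[k + 1])
  for (i in 2:n) {
    cur <- rep(-Inf, k + 1)
    for (j in seq_len(min(i, k))) {
      cur[j + 1] <- logsumexp(c(log(j) + prev[j + 1], prev[j]))
    }
    prev <- cur
  }
  prev[k + 1]
}

# Uniform sample of a set partition of 1..n into exactly k nonempty blocks,
# via the Stirling recurrence S(n,k) = k S(n-1,k) + S(n-1,k-1): element n
# opens a singleton block with probability S(n-1,k-1)/S(n,k).
sample_set_partition <- function(n, k) {
  stopifnot(k >= 1, k <= n)
  labels <- integer(n)
  nn <- n
  kk <- k
  singleton <- logical(n)
  for (i in n:1) {
    if (kk == nn) {
      singleton[1:i] <- TRUE
      break
    }
    if (kk == 1L) {
      singleton[1:i] <- FALSE
      singleton[1] <- TRUE
      break
    }
    p_single <- exp(log_stirling2(nn - 1, kk - 1) - log_stirling2(nn, kk))
    if (stats::runif(1) < p_single) {
      singleton[i] <- TRUE
      kk <- kk - 1L
    }
    nn <- nn - 1L
  }
  # assign labels forward: singletons open new blocks, others join an
  # existing block uniformly at random
  nblocks <- 0L
  for (i in 1:n) {
    if (singleton[i]) {
      nblocks <- nblocks + 1L
      labels[i] <- nblocks
    } else {
      labels[i] <- sample.int(nblocks, 1)
    }
  }
  relabel_first_appearance(labels)
}

# Canonical labelling: groups numbered by order of first appearance.
relabel_first_appearance <- function(labels) {
  match(labels, unique(labels))
}

# Log multivariate normal density given mean and a cholesky factor of the
# covariance (upper triangular, as returned by chol()).
dmvnorm_chol_log <- function(x, mean, chol_cov) {
  d <- length(mean)
  if (d == 0L) return(0)
  z <- backsolve(chol_cov, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(chol_cov))) - 0.5 * sum(z^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
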