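# General-Bayes proportional-hazards inference via the partial-likelihood
# loss: the Cox log partial likelihood is the self-information loss of the
# partial information (event ordering), so exp{-l} with w = 1 plays the role
# of a likelihood that is free of the baseline hazard.

#' Construct a survival dataset
#'
#' @param time Positive event/censoring times.
#' @param event Event indicators in `{0, 1}` (1 = event, 0 = right-censored).
#' @param covariates Numeric matrix (n by p); genotype coding `{0, 1, 2}` or
#'   general real covariates. Missing values are not supported.
#' @return An object of class `survival_dataset`.
#' @export
survival_dataset <- function(time, event, covariates) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  covariates <- as.matrix(covariates)
  if (anyNA(time) || any(time <= 0)) stop("all times must be positive")
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0 or 1")
  if (length(time) != length(event) || nrow(covariates) != length(time)) {
    stop("time, event and covariates must have matching lengths")
  }
  if (anyNA(covariates)) stop("missing covariate values are not supported")
  if (ncol(covariates) < 1L) stop("at least one covariate column is required")
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("marker_", seq_len(ncol(covariates)))
  }
  structure(list(time = time, event = event, covariates = covariates,
                 n = length(time), p = ncol(covariates)),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("<survival_dataset: n = %d (%d events), p = %d markers>\n",
              x$n, sum(x$event), x$p))
  invisible(x)
}

#' Risk sets for a survival dataset
#'
#' For every event `i`, the risk set `R_i = {l : t_l >= t_i}` of subjects
#' still alive and uncensored at the event time. Tied event times share the
#' full joint risk set (Breslow convention).
#'
#' @param dataset A `survival_dataset`.
#' @return A list with `event_index` (indices of event subjects) and
#'   `risk_sets` (a list of integer index vectors, one per event).
#' @export
build_risk_sets <- function(dataset) {
  stopifnot(inherits(dataset, "survival_dataset"))
  ev <- which(dataset$event == 1)
  if (length(ev) == 0L) stop("dataset has no events; risk sets are undefined")
  rs <- lapply(ev, function(i) which(dataset$time >= dataset$time[i]))
  structure(list(event_index = ev, risk_sets = rs), class = "risk_set_index")
}

# Ordering and tie-run bookkeeping reused by the loss and its derivatives:
# subjects sorted by decreasing time; for sorted position i, the risk set is
# positions 1..run_end[i] (end of the tie run, Breslow).
risk_order <- function(dataset) {
  ord <- order(dataset$time, decreasing = TRUE)
  t_sorted <- dataset$time[ord]
  r <- rle(t_sorted)
  run_end <- rep(cumsum(r$lengths), r$lengths)
  list(ord = ord, run_end = run_end,
       event_sorted = dataset$event[ord] == 1)
}

#' Cox partial-likelihood loss
#'
#' The negative log partial likelihood
#' `l(beta) = -sum_{events i} [ x_i' beta - log sum_{l in R_i} exp(x_l' beta) ]`,
#' with Breslow handling of tied event times and log-domain accumulation of
#' the risk-set sums. This is the cumulative loss of the general-Bayes
#' survival model; small loss means good fit.
#'
#' @param beta Coefficient vector of length `p` (finite).
#' @param dataset A `survival_dataset` with at least one event.
#' @param risk_sets Optional `risk_set_index` from [build_risk_sets()]; when
#'   supplied the loss is evaluated by direct enumeration over the stored
#'   sets (same value, useful for cross-checking).
#' @return A single numeric loss value.
#' @export
cox_partial_loss <- function(beta, dataset, risk_sets = NULL) {
  stopifnot(inherits(dataset, "survival_dataset"))
  beta <- as.numeric(beta)
  if (length(beta) != dataset$p) stop("beta must have length p")
  if (any(!is.finite(beta))) stop("beta must be finite")
  if (sum(dataset$event) == 0L) stop("dataset has no events (all censored)")
  eta <- as.vector(dataset$covariates %*% beta)
  if (!is.null(risk_sets)) {
    stopifnot(inherits(risk_sets, "risk_set_index"))
    terms <- vapply(seq_along(risk_sets$event_index), function(k) {
      i <- risk_sets$event_index[k]
      eta[i] - logsumexp(eta[risk_sets$risk_sets[[k]]])
    }, numeric(1))
    return(-sum(terms))
  }
  ro <- risk_order(dataset)
  eta_s <- eta[ro$ord]
  lse <- logcumsumexp(eta_s)[ro$run_end]
  -sum(eta_s[ro$event_sorted] - lse[ro$event_sorted])
}

# Negative log partial likelihood with analytic gradient and Hessian for the
# included-column submatrix, via forward cumulative sums over the
# time-descending order (risk sets are nested).
cox_nll_derivs <- function(beta, X, ro) {
  eta <- as.vector(X %*% beta)
  eta_s <- eta[ro$ord]
  Xs <- X[ro$ord, , drop = FALSE]
  p <- ncol(X)
  m <- max(eta_s)
  e <- exp(eta_s - m)
  S0 <- cumsum(e)[ro$run_end]
  S1 <- apply(Xs * e, 2, cumsum)[ro$run_end, , drop = FALSE]
  # S2 rows hold the p x p cumulative sum of e * x x'
  XX <- Xs[, rep(seq_len(p), each = p), drop = FALSE] *
    Xs[, rep(seq_len(p), times = p), drop = FALSE]
  S2 <- apply(XX * e, 2, cumsum)[ro$run_end, , drop = FALSE]
  ev <- ro$event_sorted
  nll <- -sum(eta_s[ev] - (log(S0[ev]) + m))
  mu <- S1[ev, , drop = FALSE] / S0[ev]
  grad <- -colSums(Xs[ev, , drop = FALSE] - mu)
  # Hessian: sum over events of the risk-set weighted covariance of x
  Smat <- S2[ev, , drop = FALSE] / S0[ev]
  H <- matrix(colSums(Smat - mu[, rep(seq_len(p), each = p), drop = FALSE] *
                        mu[, rep(seq_len(p), times = p), drop = FALSE]), p, p)
  list(nll = nll, grad = grad, hess = H)
}

#' Maximum a posteriori fit and information matrix
#'
#' For a given inclusion state, maximizes the penalized objective
#' `-l(beta) - 0.5 * sum_j beta_j^2 / v_j` over the included markers by
#' Newton iteration (gradient sup-norm below `1e-8`), and returns the
#' inverse Hessian at the optimum as the approximate information matrix.
#' These are the centre and covariance of the independence proposal used by
#' [variable_selection_mcmc()] and of the Laplace importance proposal in
#' [gbf_scan()].
#'
#' @param dataset A `survival_dataset`.
#' @param delta Logical (or 0/1) inclusion vector of length `p`.
#' @param v Prior slab variance(s), scalar or length `p`.
#' @param w Loss weight (default 1: the partial likelihood is a partial
#'   self-information loss).
#' @return A list with `beta` (MAP over included markers), `cov` (inverse
#'   Hessian, symmetric positive definite), `included` (column indices) and
#'   `nll` (unpenalized loss at the MAP).
#' @export
map_and_information <- function(dataset, delta, v = 0.5, w = 1) {
  stopifnot(inherits(dataset, "survival_dataset"))
  delta <- as.logical(delta)
  stopifnot(length(delta) == dataset$p)
  v <- rep_len(v, dataset$p)
  stopifnot(all(v > 0), w > 0)
  inc <- which(delta)
  if (length(inc) == 0L) {
    nll0 <- cox_partial_loss(rep(0, dataset$p), dataset)
    return(list(beta = numeric(0), cov = matrix(0, 0, 0),
                included = integer(0), nll = nll0))
  }
  X <- dataset$covariates[, inc, drop = FALSE]
  if (qr(X)$rank < ncol(X)) {
    stop(sprintf("included columns are collinear: %s",
                 paste(colnames(dataset$covariates)[inc], collapse = ", ")))
  }
  ro <- risk_order(dataset)
  vv <- v[inc]
  beta <- rep(0, length(inc))
  obj <- function(b, d) w * d$nll + 0.5 * sum(b^2 / vv)
  d <- cox_nll_derivs(beta, X, ro)
  f <- obj(beta, d)
  for (iter in 1:100) {
    g <- w * d$grad + beta / vv
    H <- w * d$hess + diag(1 / vv, length(vv))
    if (max(abs(g)) < 1e-8) break
    step <- solve(H, g)
    t_step <- 1
    repeat {
      beta_new <- beta - t_step * step
      d_new <- cox_nll_derivs(beta_new, X, ro)
      f_new <- obj(beta_new, d_new)
      if (is.finite(f_new) && f_new <= f + 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-10) break
    }
    beta <- beta_new; d <- d_new; f <- f_new
  }
  H <- w * d$hess + diag(1 / vv, length(vv))
  cov <- solve(H)
  cov <- (cov + t(cov)) / 2
  list(beta = beta, cov = cov, included = inc, nll = d$nll)
}

# Partial loss for a single column at many beta values (vectorized over beta).
cox_loss_1d_vec <- function(xj, dataset, betas, ro = NULL) {
  if (is.null(ro)) ro <- risk_order(dataset)
  xs <- xj[ro$ord]
  ev <- ro$event_sorted
  vapply(betas, function(b) {
    eta_s <- xs * b
    lse <- logcumsumexp(eta_s)[ro$run_end]
    -sum(eta_s[ev] - lse[ev])
  }, numeric(1))
}

#' Marker-wise general Bayes factor scan
#'
#' For each marker `j`, the general Bayes factor of association
#' `gBF(j) = integral exp{-l(beta_j)} N(beta_j | 0, v) d beta_j / exp{-l(0)}`
#' under the univariate partial-likelihood loss, estimated by importance
#' sampling from the Laplace approximation at the one-dimensional MAP (the
#' proposal is widened and the draw repeated, at most three times, if
#' non-finite weights occur). A constant marker carries no information and
#' has `gBF = 1` exactly.
#'
#' @param dataset A `survival_dataset`.
#' @param v Slab prior variance (default 0.5).
#' @param n_importance Importance-sample size (>= 1000).
#' @param seed Integer seed.
#' @param w Loss weight (default 1).
#' @return A data frame with columns `marker`, `log_gbf` and `mc_se` (the
#'   Monte Carlo standard error of `log_gbf`, by the delta method).
#' @export
gbf_scan <- function(dataset, v = 0.5, n_importance = 10000, seed = 1, w = 1) {
  stopifnot(inherits(dataset, "survival_dataset"), v > 0, n_importance >= 1000)
  if (sum(dataset$event) == 0L) stop("dataset has no events (all censored)")
  set.seed(seed)
  ro <- risk_order(dataset)
  out <- lapply(seq_len(dataset$p), function(j) {
    xj <- dataset$covariates[, j]
    if (stats::var(xj) == 0) {
      return(data.frame(marker = colnames(dataset$covariates)[j],
                        log_gbf = 0, mc_se = 0))
    }
    delta <- rep(FALSE, dataset$p); delta[j] <- TRUE
    fit <- map_and_information(dataset, delta, v = v, w = w)
    l0 <- cox_loss_1d_vec(xj, dataset, 0, ro)
    sd_prop <- sqrt(fit$cov[1, 1])
    for (widen in 0:3) {
      if (widen == 3) stop(sprintf(
        "non-finite importance weights for marker %d after 3 widenings", j))
      sp <- sd_prop * 2^widen
      b <- stats::rnorm(n_importance, fit$beta, sp)
      lvals <- cox_loss_1d_vec(xj, dataset, b, ro)
      logw <- -w * (lvals - l0) +
        stats::dnorm(b, 0, sqrt(v), log = TRUE) -
        stats::dnorm(b, fit$beta, sp, log = TRUE)
      if (all(is.finite(logw))) break
    }
    m <- max(logw)
    ww <- exp(logw - m)
    log_gbf <- m + log(mean(ww))
    rel_se <- stats::sd(ww) / (mean(ww) * sqrt(n_importance))
    data.frame(marker = colnames(dataset$covariates)[j],
               log_gbf = log_gbf, mc_se = rel_se)
  })
  do.call(rbind, out)
}

#' Model evidence by adaptive Gauss--Hermite quadrature
#'
#' `log integral exp{-w l(beta)} prod_j N(beta_j | 0, v_j) d beta` for the
#' markers included in `delta`, by a product Gauss--Hermite rule centred at
#' the MAP with the Laplace covariance. Exact reference for small models;
#' used to enumerate posterior model probabilities at toy scale.
#'
#' @inheritParams map_and_information
#' @param nodes Gauss--Hermite nodes per dimension.
#' @return Log evidence (the empty model returns `-w * l(0)`).
#' @export
model_log_evidence <- function(dataset, delta, v = 0.5, w = 1, nodes = 32) {
  delta <- as.logical(delta)
  v <- rep_len(v, dataset$p)
  fit <- map_and_information(dataset, delta, v = v, w = w)
  if (length(fit$beta) == 0L) return(-w * fit$nll)
  d <- length(fit$beta)
  gh <- gauss_hermite(nodes)
  grids <- do.call(expand.grid, rep(list(seq_len(nodes)), d))
  Z <- as.matrix(grids)
  zpts <- matrix(gh$nodes[Z], ncol = d)
  logwts <- rowSums(matrix(log(gh$weights[Z]), ncol = d))
  L <- chol(fit$cov) # upper triangular
  pts <- sweep(sqrt(2) * zpts %*% L, 2, fit$beta, "+")
  vv <- v[fit$included]
  X <- dataset$covariates
  logint <- vapply(seq_len(nrow(pts)), function(i) {
    beta_full <- rep(0, dataset$p)
    beta_full[fit$included] <- pts[i, ]
    -w * cox_partial_loss(beta_full, dataset) +
      sum(stats::dnorm(pts[i, ], 0, sqrt(vv), log = TRUE))
  }, numeric(1))
  # integral = sqrt(2)^d |L| sum_k W_k exp(|z_k|^2) g(pts_k)
  logsumexp(logwts + rowSums(zpts^2) + logint) +
    d / 2 * log(2) + sum(log(diag(L)))
}

#' Enumerated posterior over inclusion states
#'
#' Exhaustive model posterior `P(delta | x)` over all `2^p` inclusion
#' states, combining the Bernoulli inclusion prior with quadrature evidence
#' from [model_log_evidence()]. Feasible for small `p` only; serves as the
#' exact reference for [variable_selection_mcmc()].
#'
#' @inheritParams map_and_information
#' @param a Prior inclusion probability(ies), scalar or length `p`.
#' @param nodes Gauss--Hermite nodes per dimension.
#' @return Data frame with columns `model` (comma-separated included
#'   indices, "" for the null model) and `prob`.
#' @export
enumerate_selection_posterior <- function(dataset, v = 0.5, a = NULL, w = 1,
                                          nodes = 32) {
  p <- dataset$p
  stopifnot(p <= 12)
  if (is.null(a)) a <- 1 / p
  a <- rep_len(a, p)
  states <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  logpost <- vapply(seq_len(nrow(states)), function(i) {
    delta <- as.logical(states[i, ])
    lp_delta <- sum(ifelse(delta, log(a), log(1 - a)))
    lp_delta + model_log_evidence(dataset, delta, v = v, w = w, nodes = nodes)
  }, numeric(1))
  probs <- exp(logpost - logsumexp(logpost))
  key <- apply(states, 1, function(d) paste(which(as.logical(d)),
                                            collapse = ","))
  data.frame(model = key, prob = probs, stringsAsFactors = FALSE)
}

# Proposal log-probability of the delta move: move type uniform among
# feasible {add, remove, swap}, marker(s) uniform within type.
delta_move_logq <- function(d_from, d_to, p) {
  nf <- sum(d_from)
  types <- c(add = nf < p, remove = nf > 0, swap = nf > 0 && nf < p)
  ltype <- -log(sum(types))
  nt <- sum(d_to)
  if (nt == nf + 1L) return(ltype - log(p - nf))            # add
  if (nt == nf - 1L) return(ltype - log(nf))                # remove
  ltype - log(nf) - log(p - nf)                             # swap
}

propose_delta <- function(delta, p) {
  nf <- sum(delta)
  feasible <- c(if (nf < p) "add", if (nf > 0) "remove",
                if (nf > 0 && nf < p) "swap")
  type <- if (length(feasible) == 1L) feasible else sample(feasible, 1)
  d2 <- delta
  if (type == "add") {
    j <- which(!delta); j <- if (length(j) == 1L) j else sample(j, 1)
    d2[j] <- TRUE
  } else if (type == "remove") {
    j <- which(delta); j <- if (length(j) == 1L) j else sample(j, 1)
    d2[j] <- FALSE
  } else {
    jin <- which(delta); jin <- if (length(jin) == 1L) jin else sample(jin, 1)
    jout <- which(!delta)
    jout <- if (length(jout) == 1L) jout else sample(jout, 1)
    d2[jin] <- FALSE; d2[jout] <- TRUE
  }
  d2
}

#' Spike-and-slab variable selection MCMC under the partial-likelihood loss
#'
#' Samples `(delta, beta)` from the general-Bayes posterior
#' `exp{-w l(beta)} prod_j [delta_j N(beta_j|0,v_j) + (1-delta_j) d_0]`
#' with Bernoulli(`a_j`) inclusion priors, using a joint proposal
#' `q(delta', beta' | delta) = q(delta' | delta) N(beta' | map, cov)`:
#' one add/remove/swap move per iteration and an independence draw from the
#' Laplace approximation of the proposed model (MAP fits are cached per
#' inclusion state). The acceptance ratio multiplies the exp-loss ratio, the
#' prior ratio and the full proposal-density ratio.
#'
#' @param dataset A `survival_dataset`.
#' @param v Slab variance(s), scalar or length `p`.
#' @param a Prior inclusion probability(ies); default `1/p`.
#' @param iterations Total iterations (> `burn_in`).
#' @param burn_in Burn-in length discarded from summaries.
#' @param seed Integer seed (fixed seed reproduces the trace exactly).
#' @param w Loss weight (default 1).
#' @return An object of class `vs_trace` with post-burn-in matrices `delta`
#'   (logical) and `beta` (zero where excluded), the acceptance rate, and
#'   bookkeeping fields.
#' @export
variable_selection_mcmc <- function(dataset, v = 0.5, a = NULL,
                                    iterations = 10000, burn_in = 1000,
                                    seed = 1, w = 1) {
  stopifnot(inherits(dataset, "survival_dataset"), iterations > burn_in)
  p <- dataset$p
  if (is.null(a)) a <- 1 / p
  v <- rep_len(v, p)
  a <- rep_len(a, p)
  stopifnot(all(v > 0), all(a > 0), all(a < 1))
  set.seed(seed)
  cache <- new.env(parent = emptyenv())
  get_fit <- function(delta) {
    key <- paste0("m", paste(which(delta), collapse = ","))
    if (is.null(cache[[key]])) {
      fit <- map_and_information(dataset, delta, v = v, w = w)
      fit$chol <- if (length(fit$beta)) chol(fit$cov) else matrix(0, 0, 0)
      cache[[key]] <- fit
    }
    cache[[key]]
  }
  lprior_delta <- function(delta) sum(ifelse(delta, log(a), log(1 - a)))
  lprior_beta <- function(beta, inc) {
    if (length(inc) == 0L) return(0)
    sum(stats::dnorm(beta, 0, sqrt(v[inc]), log = TRUE))
  }
  loss_at <- function(beta, inc) {
    bf <- rep(0, p); bf[inc] <- beta
    cox_partial_loss(bf, dataset)
  }
  # initial state: null model
  delta <- rep(FALSE, p)
  beta <- numeric(0)
  fit <- get_fit(delta)
  l_cur <- fit$nll
  keep <- iterations - burn_in
  delta_trace <- matrix(FALSE, keep, p)
  beta_trace <- matrix(0, keep, p)
  accept <- 0L
  for (it in seq_len(iterations)) {
    d2 <- propose_delta(delta, p)
    fit2 <- get_fit(d2)
    inc2 <- fit2$included
    z <- stats::rnorm(length(inc2))
    b2 <- if (length(inc2)) as.vector(fit2$beta + t(fit2$chol) %*% z) else
      numeric(0)
    l_new <- if (length(inc2)) loss_at(b2, inc2) else fit2$nll
    logq_fwd <- delta_move_logq(delta, d2, p) +
      (if (length(inc2)) dmvnorm_chol_log(b2, fit2$beta, fit2$chol) else 0)
    logq_rev <- delta_move_logq(d2, delta, p) +
      (if (length(beta)) dmvnorm_chol_log(beta, fit$beta, fit$chol) else 0)
    loga <- -w * (l_new - l_cur) +
      lprior_beta(b2, inc2) - lprior_beta(beta, fit$included) +
      lprior_delta(d2) - lprior_delta(delta) +
      logq_rev - logq_fwd
    if (is.finite(loga) && log(stats::runif(1)) < loga) {
      delta <- d2; beta <- b2; fit <- fit2; l_cur <- l_new
      accept <- accept + 1L
    }
    if (it > burn_in) {
      delta_trace[it - burn_in, ] <- delta
      if (length(beta)) beta_trace[it - burn_in, fit$included] <- beta
    }
  }
  structure(list(delta = delta_trace, beta = beta_trace,
                 acceptance_rate = accept / iterations,
                 iterations = iterations, burn_in = burn_in, seed = seed,
                 markers = colnames(dataset$covariates)),
            class = "vs_trace")
}

#' @export
print.vs_trace <- function(x, ...) {
  cat(sprintf(
    "<vs_trace: %d kept samples, p = %d, acceptance rate %.3f>\n",
    nrow(x$delta), ncol(x$delta), x$acceptance_rate))
  invisible(x)
}

#' Summaries of a variable-selection trace
#'
#' `inclusion_probabilities()` returns the post-burn-in mean of each
#' inclusion indicator; `model_probabilities()` the visit frequency of every
#' sampled inclusion state (keyed as comma-separated included indices).
#'
#' @param trace A `vs_trace`.
#' @return A named numeric vector, or a data frame of models and
#'   probabilities.
#' @export
inclusion_probabilities <- function(trace) {
  stopifnot(inherits(trace, "vs_trace"))
  stats::setNames(colMeans(trace$delta), trace$markers)
}

#' @rdname inclusion_probabilities
#' @export
model_probabilities <- function(trace) {
  stopifnot(inherits(trace, "vs_trace"))
  key <- apply(trace$delta, 1, function(d) paste(which(d), collapse = ","))
  tab <- table(key) / length(key)
  data.frame(model = names(tab), prob = as.numeric(tab),
             stringsAsFactors = FALSE)
}
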