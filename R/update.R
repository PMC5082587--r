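# The general Bayesian update: posterior log-density equals
# log prior - w * cumulative loss - log Z, evaluated on the belief grid.

# Cumulative loss over the data at every support point. Validates per-datum
# loss values: NaN or -Inf anywhere on the support is an error; +Inf is a
# hard constraint and yields zero posterior density.
cumulative_loss <- function(support, loss, data) {
  total <- numeric(length(support))
  for (x in data) {
    v <- loss$loss(support, x)
    if (length(v) != length(support)) {
      stop(sprintf("loss '%s' did not return one value per support point",
                   loss$name))
    }
    if (any(is.nan(v)) || any(v == -Inf)) {
      stop(sprintf("loss '%s' produced NaN or -Inf on the belief support",
                   loss$name))
    }
    total <- total + v
  }
  total
}

as_datum_list <- function(data) {
  if (is.null(data)) return(list())
  if (is.list(data)) data else as.list(data)
}

#' General Bayesian (Gibbs posterior) update
#'
#' Updates a prior belief state with data through a loss function:
#' the posterior log-density is
#' `log pi(theta) - w * sum_i l(theta, x_i) - log Z`,
#' normalized on the grid. With the self-information loss and `w = 1` this
#' is the classical Bayes update; with a constant loss the posterior equals
#' the prior; a point-mass prior is returned unchanged.
#'
#' @param prior A `belief_state` prior.
#' @param loss A `loss_spec`.
#' @param data List or vector of data; an empty set returns the prior.
#' @return A normalized `belief_state`; the prior object is not modified.
#' @examples
#' prior <- belief_normal(0, 1)
#' post <- gibbs_update(prior, loss_squared(weight = 1 / 2), data = 2)
#' c(belief_mean(post), belief_var(post)) # ~ (1, 1/2)
#' @export
gibbs_update <- function(prior, loss, data) {
  stopifnot(inherits(prior, "belief_state"), inherits(loss, "loss_spec"))
  data <- as_datum_list(data)
  if (length(data) == 0L) return(prior)
  if (length(prior$support) == 1L) return(prior) # degenerate prior: unchanged
  total <- cumulative_loss(prior$support, loss, data)
  ld <- prior$log_density - loss$weight * total
  logz <- logsumexp(ld + log(prior$weights))
  if (!is.finite(logz)) {
    stop(sprintf(
      "posterior under loss '%s' is not integrable on the belief support",
      loss$name))
  }
  out <- prior
  out$log_density <- ld - logz
  out$normalized <- TRUE
  out
}

#' Log normalizing constant of a general Bayesian update
#'
#' `log integral exp{-w * sum_i l(theta, x_i)} pi(d theta)`, accumulated in
#' the log domain so overflow/underflow cannot occur. Adding a constant `c`
#' to the loss shifts the result by exactly `-w * c * n`.
#'
#' @inheritParams gibbs_update
#' @return A single numeric value.
#' @export
log_partition <- function(prior, loss, data) {
  stopifnot(inherits(prior, "belief_state"), inherits(loss, "loss_spec"))
  p <- if (prior$normalized) prior else normalize_belief(prior)
  data <- as_datum_list(data)
  if (length(data) == 0L) return(0)
  if (length(p$support) == 1L) {
    return(-loss$weight * cumulative_loss(p$support, loss, data))
  }
  total <- cumulative_loss(p$support, loss, data)
  logsumexp(p$log_density - loss$weight * total + log(p$weights))
}

#' Sequential general Bayesian update
#'
#' Applies [gibbs_update()] batch by batch. Because the cumulative loss is a
#' sum over data, the result is identical (pointwise) to a single update on
#' the concatenated data, in any batch order: the coherence property of the
#' general Bayesian update.
#'
#' @param prior A `belief_state`.
#' @param loss A `loss_spec`.
#' @param batches List of datum lists/vectors; empty batches are allowed.
#' @return A normalized `belief_state`.
#' @export
sequential_update <- function(prior, loss, batches) {
  stopifnot(is.list(batches))
  Reduce(function(b, batch) gibbs_update(b, loss, batch), batches,
         init = prior)
}
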