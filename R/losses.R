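# Loss specifications: the object connecting data to the parameter of
# interest. A loss may be any real-valued function l(theta, datum); +Inf
# encodes a hard constraint (zero posterior density), -Inf is an error.

#' Specify a loss function
#'
#' Bundles a loss function `l(theta, datum)` with its weight `w > 0`. The
#' loss must be vectorized over `theta` (given one datum). Cumulative losses
#' over a dataset are always formed as the sum of per-datum losses, so
#' updates are coherent: batching the data in any way yields the same
#' posterior.
#'
#' @param loss Function `(theta, datum) -> numeric`, vectorized over `theta`.
#' @param weight Positive scalar loss weight `w` (data-vs-prior temperature).
#' @param name Label used in error messages and metadata.
#' @return An object of class `loss_spec`.
#' @seealso [loss_squared()], [loss_absolute()], [loss_self_information()]
#' @export
loss_spec <- function(loss, weight = 1, name = "custom") {
  stopifnot(is.function(loss), is.numeric(weight), length(weight) == 1L,
            is.finite(weight), weight > 0)
  structure(list(loss = loss, weight = weight, name = name),
            class = "loss_spec")
}

#' @export
print.loss_spec <- function(x, ...) {
  cat(sprintf("<loss_spec '%s', w = %g>\n", x$name, x$weight))
  invisible(x)
}

#' Re-weight a loss specification
#' @param loss A `loss_spec`.
#' @param weight New positive weight.
#' @return A `loss_spec` with the new weight.
#' @export
set_weight <- function(loss, weight) {
  loss_spec(loss$loss, weight, loss$name)
}

#' Built-in loss functions
#'
#' `loss_squared()` is the quadratic loss `(theta - x)^2` (targets a mean),
#' `loss_absolute()` the absolute loss `|theta - x|` (targets a median), and
#' `loss_self_information()` wraps a parametric log-density into the
#' self-information loss `-log f(x; theta)`, under which the general
#' Bayesian update with `w = 1` is exactly the classical Bayes update.
#'
#' @param weight Positive loss weight `w`.
#' @param log_density Function `(theta, x) -> log f(x; theta)`, vectorized
#'   over `theta`.
#' @return A `loss_spec`.
#' @export
loss_squared <- function(weight = 1) {
  loss_spec(function(theta, x) (theta - x)^2, weight, "squared")
}

#' @rdname loss_squared
#' @export
loss_absolute <- function(weight = 1) {
  loss_spec(function(theta, x) abs(theta - x), weight, "absolute")
}

#' @rdname loss_squared
#' @export
loss_self_information <- function(log_density, weight = 1) {
  stopifnot(is.function(log_density))
  loss_spec(function(theta, x) -log_density(theta, x), weight,
            "self_information")
}
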