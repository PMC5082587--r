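# Synthetic-data generators with the statistical structure each analysis
# assumes: i.i.d. location families for the calibration toys,
# proportional-hazards survival times with sparse genotype effects, and
# blocked mean-shift matrices with common column change points. Every
# generator is deterministic given its seed and records the generating truth
# alongside the data.

#' Generate i.i.d. observations from a location family
#'
#' @param n Sample size.
#' @param family `"normal"`, `"laplace"` or `"t"`.
#' @param params List of family parameters: `mean`/`sd` (normal),
#'   `location`/`scale` (laplace), `df`/`location` (t).
#' @param seed Integer seed.
#' @return A list with `data` (numeric vector) and `truth` (family,
#'   parameters, true mean/median/variance where finite, a heavy-tail flag,
#'   and the seed).
#' @export
gen_iid <- function(n, family = c("normal", "laplace", "t"),
                    params = list(), seed = 1) {
  stopifnot(n >= 1)
  family <- match.arg(family)
  set.seed(seed)
  if (family == "normal") {
    mean <- params$mean %||% 0
    sd <- params$sd %||% 1
    x <- stats::rnorm(n, mean, sd)
    truth <- list(family = family, mean = mean, median = mean,
                  variance = sd^2, heavy_tail = FALSE, seed = seed)
  } else if (family == "laplace") {
    location <- params$location %||% 0
    scale <- params$scale %||% 1
    u <- stats::runif(n, -0.5, 0.5)
    x <- location - scale * sign(u) * log(1 - 2 * abs(u))
    truth <- list(family = family, mean = location, median = location,
                  variance = 2 * scale^2, heavy_tail = FALSE, seed = seed)
  } else {
    df <- params$df %||% 3
    location <- params$location %||% 0
    x <- location + stats::rt(n, df)
    truth <- list(family = family, mean = if (df > 1) location else NA_real_,
                  median = location,
                  variance = if (df > 2) df / (df - 2) else NA_real_,
                  heavy_tail = TRUE, seed = seed)
  }
  list(data = x, truth = truth)
}

#' Generate proportional-hazards survival data with genotype covariates
#'
#' Genotypes are Binomial(2, maf) per marker (independent markers); event
#' times are exponential with hazard `baseline_rate * exp(x' beta_true)`;
#' censoring is independent exponential with its rate solved numerically so
#' the expected censored fraction equals `censor_rate`.
#'
#' @param n Number of subjects.
#' @param p Number of markers.
#' @param maf Minor-allele frequency in `(0, 0.5]`.
#' @param beta_true Sparse effect vector of length `p` (default all zero).
#' @param baseline_rate Baseline hazard rate.
#' @param censor_rate Target expected censored fraction in `[0, 1)`; zero
#'   yields no censoring.
#' @param seed Integer seed.
#' @return A list with `dataset` (a [survival_dataset()]) and `truth`.
#' @export
gen_survival <- function(n, p, maf = 0.3, beta_true = rep(0, p),
                         baseline_rate = 0.1, censor_rate = 0.3, seed = 1) {
  stopifnot(n >= 1, p >= 1, maf > 0, maf <= 0.5,
            length(beta_true) == p, baseline_rate > 0,
            censor_rate >= 0, censor_rate < 1)
  set.seed(seed)
  for (attempt in 1:5) {
    X <- matrix(stats::rbinom(n * p, 2, maf), n, p)
    colnames(X) <- paste0("marker_", seq_len(p))
    lambda <- baseline_rate * exp(as.vector(X %*% beta_true))
    times_event <- stats::rexp(n, lambda)
    if (censor_rate == 0) {
      time <- times_event
      event <- rep(1, n)
    } else {
      # P(censored | lambda_i) = c / (c + lambda_i) for exponential censoring
      f <- function(logc) mean(exp(logc) / (exp(logc) + lambda)) - censor_rate
      logc <- stats::uniroot(f, lower = log(min(lambda)) - 20,
                             upper = log(max(lambda)) + 20)$root
      cens <- stats::rexp(n, exp(logc))
      event <- as.numeric(times_event <= cens)
      time <- pmin(times_event, cens)
    }
    if (sum(event) > 0) {
      return(list(dataset = survival_dataset(time, event, X),
                  truth = list(beta = beta_true, maf = maf,
                               baseline_rate = baseline_rate,
                               censor_rate = censor_rate, seed = seed)))
    }
  }
  stop("all subjects censored in 5 consecutive draws; lower censor_rate")
}

#' Generate a blocked mean-shift matrix with common column change points
#'
#' `x_ij = mean[group(i), segment(j)] + N(0, sigma^2)` with `k_s` row groups
#' and segments defined by shared change points.
#'
#' @param n_rows,n_cols Matrix dimensions.
#' @param k_s Number of row groups; rows are assigned in balanced blocks.
#' @param change_points Strictly increasing columns in `1..(n_cols - 1)`.
#' @param group_segment_means Numeric `k_s` by `k_t + 1` matrix of cell
#'   means.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return A list with `X` (the matrix), `partition` (the true
#'   [bicluster_partition()]) and `truth`.
#' @export
gen_bicluster <- function(n_rows, n_cols, k_s, change_points,
                          group_segment_means, sigma = 1, seed = 1) {
  stopifnot(n_rows >= k_s, sigma >= 0)
  change_points <- as.integer(sort(change_points))
  k_t <- length(change_points)
  group_segment_means <- as.matrix(group_segment_means)
  if (nrow(group_segment_means) != k_s ||
      ncol(group_segment_means) != k_t + 1L) {
    stop("group_segment_means must be k_s by (k_t + 1)")
  }
  set.seed(seed)
  groups <- sort(rep_len(seq_len(k_s), n_rows))
  part <- bicluster_partition(groups, change_points, n_cols)
  seg <- segment_of_columns(part)
  mu <- group_segment_means[cbind(rep(groups, times = n_cols),
                                  rep(seg, each = n_rows))]
  X <- matrix(mu, n_rows, n_cols) +
    matrix(stats::rnorm(n_rows * n_cols, 0, sigma), n_rows, n_cols)
  rownames(X) <- paste0("row_", seq_len(n_rows))
  colnames(X) <- paste0("col_", seq_len(n_cols))
  list(X = X, partition = part,
       truth = list(row_groups = part$row_groups,
                    change_points = change_points,
                    means = group_segment_means, sigma = sigma, seed = seed))
}
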