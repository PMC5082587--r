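# General-Bayes biclustering: rows grouped into clusters, ordered columns cut
# at common change points, cells scored by a sum-of-squares loss, and the
# loss weight calibrated against the F distribution of a randomized
# allocation.

#' Construct a bicluster partition
#'
#' A partition of a data matrix into cells formed by row groups crossed with
#' contiguous column segments. A change point at column `c` places a segment
#' boundary between columns `c` and `c + 1` (1-based), so `k_t` change
#' points define `k_t + 1` time groupings.
#'
#' @param row_groups Integer group label per row; relabelled contiguously
#'   (1..k_s) in order of first appearance.
#' @param change_points Strictly increasing integers in `1..(n_cols - 1)`;
#'   may be empty.
#' @param n_cols Number of (ordered) columns of the matrix.
#' @return An object of class `bicluster_partition` with fields
#'   `row_groups`, `change_points`, `n_cols`, `k_s` and `k_t`.
#' @export
bicluster_partition <- function(row_groups, change_points, n_cols) {
  row_groups <- relabel_first_appearance(as.integer(row_groups))
  change_points <- as.integer(sort(unique(change_points)))
  stopifnot(n_cols >= 1)
  if (length(change_points) &&
      (min(change_points) < 1L || max(change_points) >= n_cols)) {
    stop("change points must lie in 1..(n_cols - 1)")
  }
  structure(list(row_groups = row_groups, change_points = change_points,
                 n_cols = as.integer(n_cols),
                 k_s = max(row_groups), k_t = length(change_points)),
            class = "bicluster_partition")
}

#' @export
print.bicluster_partition <- function(x, ...) {
  cat(sprintf(
    "<bicluster_partition: %d rows in %d groups, %d change point(s) at {%s}>\n",
    length(x$row_groups), x$k_s, x$k_t, paste(x$change_points, collapse = ",")))
  invisible(x)
}

# Segment label (1..k_t+1) for every column.
segment_of_columns <- function(partition) {
  cuts <- c(0L, partition$change_points, partition$n_cols)
  rep(seq_len(length(cuts) - 1L), diff(cuts))
}

#' Sum-of-squares loss of a bicluster partition
#'
#' The within-cell sum of squares
#' `sum_cells sum_{(i,j) in cell} (x_ij - mean_cell)^2` (unweighted: the
#' loss weight `w` enters the posterior separately). Zero exactly when every
#' cell is constant; splitting any cell can only decrease it.
#'
#' @param partition A `bicluster_partition`.
#' @param X Numeric matrix with as many rows as `row_groups` and `n_cols`
#'   columns.
#' @return Non-negative numeric value.
#' @export
sos_loss <- function(partition, X) {
  stopifnot(inherits(partition, "bicluster_partition"))
  X <- as.matrix(X)
  if (nrow(X) != length(partition$row_groups) ||
      ncol(X) != partition$n_cols) {
    stop("matrix shape does not match the partition")
  }
  if (anyNA(X)) stop("missing values are not supported")
  seg <- segment_of_columns(partition)
  cell <- (rep(partition$row_groups, times = ncol(X)) - 1L) *
    (partition$k_t + 1L) + rep(seg, each = nrow(X))
  xv <- as.vector(X)
  cnt <- tabulate(cell, nbins = partition$k_s * (partition$k_t + 1L))
  if (any(cnt == 0L)) stop("partition contains an empty cell")
  sums <- as.vector(rowsum(xv, cell))
  sum(xv^2) - sum(sums^2 / cnt)
}

#' Reference loss for a randomized k-group allocation
#'
#' The loss value a uniformly random allocation of the `n` observations into
#' `k` groups beats with probability `1 - alpha` on noise:
#' `l_null / (1 + f* (k - 1) / (n - k))` with `f*` the `alpha` quantile of
#' `F(k - 1, n - k)`. A partition reaching this loss is as good as the best
#' `alpha`-fraction of random allocations.
#'
#' @param l_null Loss of the single-cluster (null) partition: the total sum
#'   of squares about the grand mean.
#' @param k Reference number of clusters (`k >= 2`).
#' @param n Number of allocated observations (`n > k`); by convention the
#'   number of matrix cells.
#' @param alpha Tail level in `(0, 1)`.
#' @return Positive numeric reference loss.
#' @export
reference_loss <- function(l_null, k, n, alpha) {
  stopifnot(l_null >= 0, k >= 2, alpha > 0, alpha < 1)
  if (n <= k) stop("`n` must exceed `k`")
  fstar <- stats::qf(alpha, k - 1, n - k)
  l_null / (1 + fstar * (k - 1) / (n - k))
}

#' F-calibration of the biclustering loss weight
#'
#' Sets `w` from a reference posterior ratio `R` between the null partition
#' and a partition achieving the reference loss. The default (`"literal"`)
#' variant is `w = -log(R) / [l_null * f* (k - 1) / (n - k)]`; the
#' `"exact_ratio"` variant, `w = -log(R) / [l_null - reference_loss]`,
#' equates the posterior ratio to `R` exactly. The two agree closely
#' whenever `f* (k - 1) / (n - k)` is small.
#'
#' @inheritParams reference_loss
#' @param R Reference posterior ratio in `(0, 1)`.
#' @param variant `"literal"` or `"exact_ratio"`.
#' @return Positive numeric `w`.
#' @export
calibrate_w <- function(l_null, k, n, alpha, R,
                        variant = c("literal", "exact_ratio")) {
  stopifnot(l_null > 0, k >= 2, alpha > 0, alpha < 1)
  if (n <= k) stop("`n` must exceed `k`")
  if (!is.finite(R) || R <= 0) stop("`R` must be in (0, 1)")
  if (R >= 1) stop("`R` must be below 1 (the null must not be favoured)")
  variant <- match.arg(variant)
  fstar <- stats::qf(alpha, k - 1, n - k)
  if (variant == "literal") {
    -log(R) / (l_null * fstar * (k - 1) / (n - k))
  } else {
    -log(R) / (l_null - reference_loss(l_null, k, n, alpha))
  }
}

#' Partition prior on counts
#'
#' Poisson priors on the number of row groups (rate 3 by default) and on the
#' number of time groupings `k_t + 1` (rate 2), uniform over configurations
#' given the counts: all set partitions with exactly `k_s` blocks and all
#' change-point placements are equally likely.
#'
#' @param rate_groups Poisson rate for the number of row groups.
#' @param rate_time_groups Poisson rate for the number of time groupings.
#' @return An object of class `partition_prior`.
#' @export
partition_prior <- function(rate_groups = 3, rate_time_groups = 2) {
  stopifnot(rate_groups > 0, rate_time_groups > 0)
  structure(list(rate_groups = rate_groups,
                 rate_time_groups = rate_time_groups),
            class = "partition_prior")
}

# Log prior mass of a specific partition (up to the shared truncation
# constant): Poisson on counts divided by the number of configurations with
# those counts.
log_partition_prior <- function(partition, prior, n_rows) {
  stats::dpois(partition$k_s, prior$rate_groups, log = TRUE) -
    log_stirling2(n_rows, partition$k_s) +
    stats::dpois(partition$k_t + 1L, prior$rate_time_groups, log = TRUE) -
    lchoose(partition$n_cols - 1L, partition$k_t)
}

#' Log posterior of a bicluster partition
#'
#' `log pi(S) - w * sos_loss(S, X)` up to a constant shared across
#' partitions of the same matrix. Invariant to row-group label permutations.
#'
#' @param partition A `bicluster_partition`.
#' @param X Data matrix.
#' @param w Positive loss weight.
#' @param prior A [partition_prior()].
#' @return Numeric log posterior (unnormalized).
#' @export
partition_log_posterior <- function(partition, X, w, prior = partition_prior()) {
  stopifnot(w >= 0)
  log_partition_prior(partition, prior, nrow(as.matrix(X))) -
    w * sos_loss(partition, X)
}

# -- MCMC ------------------------------------------------------------------

# One proposal for the unrestricted sampler. Returns NULL when the drawn
# move is infeasible (counts as a rejected iteration), else the proposed
# partition and the log proposal ratio log q(rev) - log q(fwd).
propose_partition <- function(partition, n_rows, move_probs) {
  type <- sample.int(3L, 1L, prob = move_probs)
  g <- partition$row_groups
  cps <- partition$change_points
  nc <- partition$n_cols
  if (type == 1L) { # move one row to another or a new group
    i <- sample.int(n_rows, 1L)
    size_i <- sum(g == g[i])
    targets <- setdiff(seq_len(partition$k_s), g[i])
    if (size_i > 1L) targets <- c(targets, partition$k_s + 1L)
    if (length(targets) == 0L) return(NULL)
    tgt <- if (length(targets) == 1L) targets else sample(targets, 1L)
    m_fwd <- length(targets)
    g2 <- g
    g2[i] <- tgt
    newp <- bicluster_partition(g2, cps, nc)
    size_i2 <- sum(newp$row_groups == newp$row_groups[i])
    m_rev <- (newp$k_s - 1L) + (size_i2 > 1L)
    list(partition = newp, logq_ratio = log(m_fwd) - log(m_rev))
  } else if (type == 2L) { # add or remove a change point
    if (nc == 1L) return(NULL)
    add <- stats::runif(1) < 0.5
    if (add) {
      sites <- setdiff(seq_len(nc - 1L), cps)
      if (length(sites) == 0L) return(NULL)
      c_new <- if (length(sites) == 1L) sites else sample(sites, 1L)
      newp <- bicluster_partition(g, c(cps, c_new), nc)
      # reverse: remove that point among k_t + 1
      logq_ratio <- -log(newp$k_t) + log(length(sites))
      list(partition = newp, logq_ratio = logq_ratio)
    } else {
      if (length(cps) == 0L) return(NULL)
      drop <- if (length(cps) == 1L) cps else sample(cps, 1L)
      newp <- bicluster_partition(g, setdiff(cps, drop), nc)
      sites_after <- (nc - 1L) - newp$k_t
      logq_ratio <- -log(sites_after) + log(length(cps))
      list(partition = newp, logq_ratio = logq_ratio)
    }
  } else { # shift one change point by +/- 1 (symmetric)
    if (length(cps) == 0L) return(NULL)
    j <- if (length(cps) == 1L) 1L else sample.int(length(cps), 1L)
    shift <- if (stats::runif(1) < 0.5) -1L else 1L
    c_new <- cps[j] + shift
    if (c_new < 1L || c_new >= nc || c_new %in% cps) return(NULL)
    cps2 <- cps; cps2[j] <- c_new
    list(partition = bicluster_partition(g, cps2, nc), logq_ratio = 0)
  }
}

# Proposal for the count-restricted sampler (fixed k_s and k_t): row moves
# between existing groups (source must not empty), row-pair swaps, change
# point shifts and change point relocations; all symmetric.
propose_partition_fixed <- function(partition, n_rows) {
  g <- partition$row_groups
  cps <- partition$change_points
  nc <- partition$n_cols
  can_move <- partition$k_s > 1L
  can_cp <- partition$k_t > 0L
  opts <- c(if (can_move) c(1L, 2L), if (can_cp) c(3L, 4L))
  if (length(opts) == 0L) return(NULL)
  type <- if (length(opts) == 1L) opts else sample(opts, 1L)
  if (type == 1L) { # move a row (only if its group keeps a member)
    i <- sample.int(n_rows, 1L)
    if (sum(g == g[i]) == 1L) return(NULL)
    targets <- setdiff(seq_len(partition$k_s), g[i])
    tgt <- if (length(targets) == 1L) targets else sample(targets, 1L)
    g2 <- g; g2[i] <- tgt
    list(partition = bicluster_partition(g2, cps, nc), logq_ratio = 0)
  } else if (type == 2L) { # swap the groups of two rows
    ij <- sample.int(n_rows, 2L)
    if (g[ij[1]] == g[ij[2]]) return(NULL)
    g2 <- g
    g2[ij[1]] <- g[ij[2]]; g2[ij[2]] <- g[ij[1]]
    list(partition = bicluster_partition(g2, cps, nc), logq_ratio = 0)
  } else if (type == 3L) { # shift a change point
    j <- if (length(cps) == 1L) 1L else sample.int(length(cps), 1L)
    shift <- if (stats::runif(1) < 0.5) -1L else 1L
    c_new <- cps[j] + shift
    if (c_new < 1L || c_new >= nc || c_new %in% cps) return(NULL)
    cps2 <- cps; cps2[j] <- c_new
    list(partition = bicluster_partition(g, cps2, nc), logq_ratio = 0)
  } else { # relocate a change point to a uniformly chosen free boundary
    j <- if (length(cps) == 1L) 1L else sample.int(length(cps), 1L)
    free <- setdiff(seq_len(nc - 1L), cps)
    if (length(free) == 0L) return(NULL)
    c_new <- if (length(free) == 1L) free else sample(free, 1L)
    cps2 <- cps; cps2[j] <- c_new
    list(partition = bicluster_partition(g, cps2, nc), logq_ratio = 0)
  }
}

# Precomputation for fast SOS evaluation inside the sampler: per-row
# cumulative column sums; the total sum of squares is partition-free.
sos_precompute <- function(X) {
  list(cum = cbind(0, t(apply(X, 1, cumsum))), totsq = sum(X^2),
       n_rows = nrow(X), n_cols = ncol(X))
}

# Same value as sos_loss(), via the cumulative sums.
sos_loss_fast <- function(groups, cps, pre) {
  bounds <- c(0L, cps, pre$n_cols)
  nseg <- length(bounds) - 1L
  segsum <- pre$cum[, bounds[-1] + 1L, drop = FALSE] -
    pre$cum[, bounds[-length(bounds)] + 1L, drop = FALSE]
  gs <- rowsum(segsum, groups)
  cnt <- outer(as.vector(rowsum(rep(1, pre$n_rows), groups)), diff(bounds))
  pre$totsq - sum(gs^2 / cnt)
}

#' Metropolis sampler over bicluster partitions
#'
#' Samples partitions from `P(S | x) proportional to pi(S) exp{-w l(S, x)}`
#' with moves that (a) move one row to another or a new group, (b) add or
#' remove a change point at a uniformly chosen feasible column, and
#' (c) shift a change point by one column. With `fixed_counts = TRUE` the
#' counts `(k_s, k_t)` of the initial partition are held fixed and only
#' within-count moves (row move, row swap, change-point shift) are used.
#'
#' @param X Data matrix.
#' @param w Positive loss weight (e.g. from [calibrate_w()]).
#' @param prior A [partition_prior()].
#' @param iterations Total iterations (> `burn_in`).
#' @param burn_in Discarded initial iterations.
#' @param seed Integer seed; a fixed seed reproduces the trace exactly.
#' @param init Optional initial `bicluster_partition`; default: one group,
#'   no change points.
#' @param fixed_counts Hold `(k_s, k_t)` fixed at the initial values.
#' @param move_probs Probabilities of the three move types (unrestricted
#'   sampler).
#' @return An object of class `partition_trace`: post-burn-in `row_groups`
#'   matrix, list of `change_points`, vector of `loss` values, per-move-type
#'   acceptance counts and bookkeeping fields.
#' @export
partition_mcmc <- function(X, w, prior = partition_prior(),
                           iterations = 20000, burn_in = 5000, seed = 1,
                           init = NULL, fixed_counts = FALSE,
                           move_probs = c(0.5, 0.3, 0.2)) {
  X <- as.matrix(X)
  stopifnot(iterations > burn_in, w >= 0)
  n_rows <- nrow(X)
  set.seed(seed)
  cur <- init %||% bicluster_partition(rep(1L, n_rows), integer(0), ncol(X))
  pre <- sos_precompute(X)
  # memoized count-prior pieces
  ls2 <- vapply(seq_len(n_rows), function(k) log_stirling2(n_rows, k),
                numeric(1))
  lpois_ks <- stats::dpois(seq_len(n_rows), prior$rate_groups, log = TRUE)
  lpois_kt <- stats::dpois(seq_len(ncol(X)), prior$rate_time_groups,
                           log = TRUE)
  lprior_of <- function(p) {
    lpois_ks[p$k_s] - ls2[p$k_s] + lpois_kt[p$k_t + 1L] -
      lchoose(p$n_cols - 1L, p$k_t)
  }
  loss_cur <- sos_loss_fast(cur$row_groups, cur$change_points, pre)
  lp_cur <- lprior_of(cur) - w * loss_cur
  keep <- iterations - burn_in
  g_trace <- matrix(0L, keep, n_rows)
  cp_trace <- vector("list", keep)
  loss_trace <- numeric(keep)
  for (it in seq_len(iterations)) {
    prop <- if (fixed_counts) propose_partition_fixed(cur, n_rows) else
      propose_partition(cur, n_rows, move_probs)
    if (!is.null(prop)) {
      loss_new <- sos_loss_fast(prop$partition$row_groups,
                                prop$partition$change_points, pre)
      lp_new <- lprior_of(prop$partition) - w * loss_new
      loga <- lp_new - lp_cur + prop$logq_ratio
      if (is.finite(loga) && log(stats::runif(1)) < loga) {
        cur <- prop$partition
        lp_cur <- lp_new
        loss_cur <- loss_new
      }
    }
    if (it > burn_in) {
      g_trace[it - burn_in, ] <- cur$row_groups
      cp_trace[[it - burn_in]] <- cur$change_points
      loss_trace[it - burn_in] <- loss_cur
    }
  }
  structure(list(row_groups = g_trace, change_points = cp_trace,
                 loss = loss_trace, n_cols = ncol(X), w = w, seed = seed,
                 iterations = iterations, burn_in = burn_in,
                 fixed_counts = fixed_counts),
            class = "partition_trace")
}

#' @export
print.partition_trace <- function(x, ...) {
  cat(sprintf("<partition_trace: %d kept samples over %d rows x %d cols>\n",
              nrow(x$row_groups), ncol(x$row_groups), x$n_cols))
  invisible(x)
}

#' Pairwise co-clustering probabilities
#'
#' The posterior probability that two rows share a group, averaged over the
#' sampled partitions: a symmetric matrix with unit diagonal.
#'
#' @param trace A `partition_trace`.
#' @return An `n_rows` by `n_rows` numeric matrix with entries in `[0, 1]`.
#' @export
coclustering_matrix <- function(trace) {
  stopifnot(inherits(trace, "partition_trace"))
  T_kept <- nrow(trace$row_groups)
  if (T_kept == 0L) stop("empty trace")
  n <- ncol(trace$row_groups)
  M <- matrix(0, n, n)
  for (t in seq_len(T_kept)) {
    g <- trace$row_groups[t, ]
    M <- M + (outer(g, g, "=="))
  }
  M / T_kept
}

#' Posterior change-point location probabilities
#'
#' The per-boundary probability (columns `1..n_cols - 1`) of carrying a
#' change point, averaged over the sampled partitions. The probabilities sum
#' to the posterior expected number of change points.
#'
#' @param trace A `partition_trace`.
#' @return Numeric vector of length `n_cols - 1`.
#' @export
changepoint_posterior <- function(trace) {
  stopifnot(inherits(trace, "partition_trace"))
  T_kept <- length(trace$change_points)
  counts <- numeric(trace$n_cols - 1L)
  for (t in seq_len(T_kept)) {
    cps <- trace$change_points[[t]]
    if (length(cps)) counts[cps] <- counts[cps] + 1
  }
  counts / T_kept
}

#' Modal sampled configuration
#'
#' The most frequently visited partition (row grouping and change points) in
#' a trace.
#'
#' @param trace A `partition_trace`.
#' @return A `bicluster_partition`.
#' @export
modal_partition <- function(trace) {
  stopifnot(inherits(trace, "partition_trace"))
  key <- vapply(seq_len(nrow(trace$row_groups)), function(t) {
    paste(paste(trace$row_groups[t, ], collapse = ","),
          paste(trace$change_points[[t]], collapse = ","), sep = "|")
  }, character(1))
  best <- names(which.max(table(key)))
  idx <- match(best, key)
  bicluster_partition(trace$row_groups[idx, ], trace$change_points[[idx]],
                      trace$n_cols)
}

# Draw a uniform partition with exactly k_s row groups and k_t change points.
sample_partition_with_counts <- function(n_rows, n_cols, k_s, k_t) {
  g <- sample_set_partition(n_rows, k_s)
  cps <- if (k_t > 0) sort(sample.int(n_cols - 1L, k_t)) else integer(0)
  bicluster_partition(g, cps, n_cols)
}

#' Model-configuration grid summary
#'
#' For each configuration `(k_s, k_t)` on a grid, runs a count-restricted
#' sampler and reports the average (unweighted) loss across its samples,
#' together with the log posterior probability of the configuration. The
#' configuration probability combines the Poisson count priors with the
#' uniform-given-counts average of `exp{-w l(S, x)}`, estimated by
#' importance sampling from uniform partitions with those counts; the
#' `(k_s = 1, k_t = 0)` cell is a single partition and is deterministic.
#'
#' @param X Data matrix.
#' @param w Positive loss weight.
#' @param prior A [partition_prior()].
#' @param ks_grid,kt_grid Integer vectors of row-group counts and
#'   change-point counts.
#' @param iterations,burn_in Sampler lengths per configuration.
#' @param n_unif Uniform importance draws per configuration.
#' @param seed Integer seed.
#' @return A data frame with columns `k_s`, `k_t`, `avg_loss`,
#'   `log_posterior` (normalized over the grid) and `note`, sorted by
#'   decreasing log posterior. Infeasible cells are kept with a note and NA
#'   values.
#' @export
model_grid_summary <- function(X, w, prior = partition_prior(),
                               ks_grid = 1:4, kt_grid = 0:2,
                               iterations = 20000, burn_in = 5000,
                               n_unif = 2000, seed = 1) {
  X <- as.matrix(X)
  n_rows <- nrow(X); n_cols <- ncol(X)
  set.seed(seed)
  rows <- list()
  for (ks in ks_grid) for (kt in kt_grid) {
    if (ks > n_rows || kt > n_cols - 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        k_s = ks, k_t = kt, avg_loss = NA_real_, log_joint = NA_real_,
        note = "infeasible")
      next
    }
    lcount <- stats::dpois(ks, prior$rate_groups, log = TRUE) +
      stats::dpois(kt + 1L, prior$rate_time_groups, log = TRUE)
    if (ks == 1L && kt == 0L) {
      part <- bicluster_partition(rep(1L, n_rows), integer(0), n_cols)
      l0 <- sos_loss(part, X)
      rows[[length(rows) + 1L]] <- data.frame(
        k_s = ks, k_t = kt, avg_loss = l0, log_joint = lcount - w * l0,
        note = "deterministic")
      next
    }
    init <- sample_partition_with_counts(n_rows, n_cols, ks, kt)
    tr <- partition_mcmc(X, w, prior, iterations = iterations,
                         burn_in = burn_in,
                         seed = sample.int(.Machine$integer.max, 1),
                         init = init, fixed_counts = TRUE)
    # uniform-given-counts importance estimate of E[exp(-w l)]
    lvals <- vapply(seq_len(n_unif), function(i) {
      sos_loss(sample_partition_with_counts(n_rows, n_cols, ks, kt), X)
    }, numeric(1))
    log_mean_exp <- logsumexp(-w * lvals) - log(n_unif)
    rows[[length(rows) + 1L]] <- data.frame(
      k_s = ks, k_t = kt, avg_loss = mean(tr$loss),
      log_joint = lcount + log_mean_exp, note = "")
  }
  out <- do.call(rbind, rows)
  lz <- logsumexp(out$log_joint[!is.na(out$log_joint)])
  out$log_posterior <- out$log_joint - lz
  out$log_joint <- NULL
  out[order(-ifelse(is.na(out$log_posterior), -Inf, out$log_posterior)), ,
      drop = FALSE]
}
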