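test_that("partitions validate and canonicalize their labels", {
  p <- bicluster_partition(c(2, 2, 5, 5, 2), c(3L, 1L), 4)
  expect_identical(p$row_groups, c(1L, 1L, 2L, 2L, 1L))
  expect_identical(p$change_points, c(1L, 3L))
  expect_identical(p$k_s, 2L)
  expect_identical(p$k_t, 2L)
  expect_error(bicluster_partition(c(1, 2), 4L, 4), "1..\\(n_cols - 1\\)")
})

test_that("sum-of-squares loss matches hand computations and identities", {
  X <- matrix(c(0, 4, 2, 6), 2, 2)  # rows (0,2), (4,6)
  single <- bicluster_partition(c(1, 1), integer(0), 2)
  expect_equal(sos_loss(single, X), 20)
  expect_equal(sos_loss(single, X), sum((X - mean(X))^2))
  finest <- bicluster_partition(c(1, 2), 1L, 2)
  expect_equal(sos_loss(finest, X), 0)
  # decomposition: total SS = within + between, for random partitions
  set.seed(8)
  Y <- matrix(rnorm(60), 6, 10)
  total <- sum((Y - mean(Y))^2)
  for (i in 1:10) {
    part <- bicluster_partition(sample(1:3, 6, replace = TRUE),
                                sort(sample(1:9, 2)), 10)
    seg <- genbayes:::segment_of_columns(part)
    cell <- paste(part$row_groups[row(Y)], seg[col(Y)])
    between <- sum(tapply(as.vector(Y), cell, function(v)
      length(v) * (mean(v) - mean(Y))^2))
    expect_equal(sos_loss(part, Y) + between, total, tolerance = 1e-8)
  }
})

test_that("loss and posterior are invariant to row-group label permutation", {
  set.seed(3)
  X <- matrix(rnorm(40), 5, 8)
  p1 <- bicluster_partition(c(1, 2, 3, 2, 1), 4L, 8)
  p2 <- bicluster_partition(c(3, 1, 2, 1, 3), 4L, 8)
  expect_equal(sos_loss(p1, X), sos_loss(p2, X), tolerance = 1e-12)
  expect_equal(partition_log_posterior(p1, X, 0.3),
               partition_log_posterior(p2, X, 0.3), tolerance = 1e-12)
})

test_that("posterior ratios decompose into prior ratio and loss difference", {
  set.seed(4)
  X <- matrix(rnorm(40), 5, 8)
  pr <- partition_prior()
  p1 <- bicluster_partition(c(1, 1, 2, 2, 2), 3L, 8)
  p2 <- bicluster_partition(c(1, 2, 2, 1, 1), c(3L, 6L), 8)
  w <- 0.4
  lhs <- partition_log_posterior(p1, X, w, pr) -
    partition_log_posterior(p2, X, w, pr)
  rhs <- -w * (sos_loss(p1, X) - sos_loss(p2, X)) +
    (genbayes:::log_partition_prior(p1, pr, 5) -
       genbayes:::log_partition_prior(p2, pr, 5))
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # w = 0 orders by the prior alone
  expect_equal(partition_log_posterior(p1, X, 0, pr),
               genbayes:::log_partition_prior(p1, pr, 5), tolerance = 1e-12)
})

test_that("reference loss behaves as the F-quantile formula dictates", {
  expect_equal(reference_loss(100, 3, 288, 1e-12), 100, tolerance = 1e-6)
  fs <- qf(0.999, 2, 285)
  expect_equal(reference_loss(100, 3, 288, 0.999),
               100 / (1 + fs * 2 / 285), tolerance = 1e-10)
  expect_error(reference_loss(100, 5, 4, 0.9), "exceed")
})

test_that("weight calibration: variants, limits and scale consistency", {
  expect_error(calibrate_w(100, 3, 288, 0.99, 1), "below 1")
  expect_lt(calibrate_w(100, 3, 288, 0.99, 1 - 1e-9), 1e-6)
  w_lit <- calibrate_w(1e4, 3, 288, 0.99, 0.01)
  fs <- qf(0.99, 2, 285)
  expect_equal(w_lit, -log(0.01) / (1e4 * fs * 2 / 285), tolerance = 1e-12)
  # variants agree within 5% when f*(k-1)/(n-k) < 0.05
  stopifnot(qf(0.9, 2, 4997) * 2 / 4997 < 0.05)
  a <- calibrate_w(1e4, 3, 5000, 0.9, 0.01, variant = "literal")
  b <- calibrate_w(1e4, 3, 5000, 0.9, 0.01, variant = "exact_ratio")
  expect_lt(abs(a - b) / b, 0.05)
  # multiplying the data by c multiplies l_null by c^2 and divides w by c^2
  for (variant in c("literal", "exact_ratio")) {
    w1 <- calibrate_w(500, 3, 200, 0.99, 0.01, variant = variant)
    w2 <- calibrate_w(500 * 9, 3, 200, 0.99, 0.01, variant = variant)
    expect_equal(w2, w1 / 9, tolerance = 1e-10)
  }
})

test_that("partition sampler matches exhaustive enumeration on a tiny space", {
  set.seed(9)
  X <- matrix(rnorm(9), 3, 3)
  pr <- partition_prior()
  rps <- list(c(1, 1, 1), c(1, 1, 2), c(1, 2, 1), c(1, 2, 2), c(1, 2, 3))
  cpss <- list(integer(0), 1L, 2L, c(1L, 2L))
  parts <- list()
  for (g in rps) for (cc in cpss) {
    parts[[length(parts) + 1L]] <- bicluster_partition(g, cc, 3)
  }
  w <- 0.4
  lp <- vapply(parts, function(p) partition_log_posterior(p, X, w, pr),
               numeric(1))
  exact <- exp(lp - max(lp)); exact <- exact / sum(exact)
  names(exact) <- vapply(parts, function(p)
    partition_key(p$row_groups, p$change_points), character(1))
  tr <- partition_mcmc(X, w, pr, iterations = 60000, burn_in = 5000,
                       seed = 5)
  expect_lt(tv_distance(exact, trace_partition_probs(tr)), 0.03)
})

test_that("a fixed seed reproduces the partition trace exactly", {
  X <- matrix(rnorm(24), 4, 6)
  t1 <- partition_mcmc(X, 0.2, iterations = 2000, burn_in = 200, seed = 3)
  t2 <- partition_mcmc(X, 0.2, iterations = 2000, burn_in = 200, seed = 3)
  expect_identical(t1$row_groups, t2$row_groups)
  expect_identical(t1$change_points, t2$change_points)
})

test_that("co-clustering and change-point summaries obey their contracts", {
  # single-sample trace: a 0/1 matrix and an indicator vector
  X <- matrix(rnorm(24), 4, 6)
  tr <- partition_mcmc(X, 0.2, iterations = 2, burn_in = 1, seed = 1,
                       init = bicluster_partition(c(1, 1, 2, 2), 3L, 6))
  M1 <- coclustering_matrix(tr)
  expect_true(all(M1 %in% c(0, 1)))
  cp1 <- changepoint_posterior(tr)
  expect_true(all(cp1 %in% c(0, 1)))
  # longer trace: symmetry, unit diagonal, [0,1] entries, expected-count sum
  tr2 <- partition_mcmc(X, 0.2, iterations = 5000, burn_in = 500, seed = 2)
  M <- coclustering_matrix(tr2)
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(1, 4))
  expect_true(all(M >= 0 & M <= 1))
  cp <- changepoint_posterior(tr2)
  n_cp <- mean(lengths(tr2$change_points))
  expect_equal(sum(cp), n_cp, tolerance = 1e-10)
})

test_that("with zero weight the change-point locations follow the prior", {
  X <- matrix(rnorm(6 * 7), 6, 7)
  tr <- partition_mcmc(X, 0, iterations = 40000, burn_in = 5000, seed = 11)
  cp <- changepoint_posterior(tr)
  # conditional on carrying a point, boundaries are exchangeable
  expect_lt(max(cp) / max(min(cp), 1e-9), 1.3)
})

test_that("a single simulated change point is located by the sampler", {
  means <- matrix(c(0, 6), 1, 2)
  sim <- gen_bicluster(6, 12, 1, 7L, means, sigma = 1, seed = 13)
  l_null <- sum((sim$X - mean(sim$X))^2)
  w <- calibrate_w(l_null, 3, length(sim$X), 0.999, 0.01)
  tr <- partition_mcmc(sim$X, w, iterations = 8000, burn_in = 2000,
                       seed = 13)
  cp <- changepoint_posterior(tr)
  expect_identical(which.max(cp), 7L)
})

test_that("model grid summary: deterministic null cell and monotone fit", {
  means <- recovery_means()
  sim <- gen_bicluster(9, 12, 3, c(4, 8), means, sigma = 1, seed = 5)
  l_null <- sum((sim$X - mean(sim$X))^2)
  w <- calibrate_w(l_null, 3, length(sim$X), 0.999, 0.01)
  g <- model_grid_summary(sim$X, w, ks_grid = 1:3, kt_grid = 0:2,
                          iterations = 3000, burn_in = 500, n_unif = 500,
                          seed = 4)
  null_row <- g[g$k_s == 1 & g$k_t == 0, ]
  expect_equal(null_row$avg_loss, l_null, tolerance = 1e-10)
  expect_identical(null_row$note, "deterministic")
  first_row <- g[g$k_s == 1, ]
  first_row <- first_row[order(first_row$k_t), ]
  expect_true(all(diff(first_row$avg_loss) < 0.05 * l_null))
  expect_equal(sum(exp(g$log_posterior[!is.na(g$log_posterior)])), 1,
               tolerance = 1e-8)
  # infeasible cells are kept with a note
  g2 <- model_grid_summary(sim$X[1:2, ], w, ks_grid = c(1, 5),
                           kt_grid = 0, iterations = 500, burn_in = 100,
                           n_unif = 50, seed = 1)
  expect_identical(g2$note[g2$k_s == 5], "infeasible")
})
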