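test_that("MMD^2 vanishes on identical point masses and matches the two-mass closed form", {
  X <- matrix(rep(c(1, 2), each = 6), 6)
  expect_identical(mmd2_unbiased(X, X, sigma = 1), 0)
  Y <- matrix(rep(c(2, 4), each = 7), 7)
  # m copies of x vs n copies of y: direct expansion of the U-statistic
  expect_equal(mmd2_unbiased(X, Y, sigma = 1.3),
               2 * (1 - exp(-5 / (2 * 1.3^2))), tolerance = 1e-12)
  expect_error(mmd2_unbiased(X[1, , drop = FALSE], Y, 1), "at least 2")
  expect_error(mmd2_unbiased(X, Y, sigma = -1), "positive")
})

test_that("MMD^2 matches the analytic Gaussian value within Monte Carlo error", {
  set.seed(31)
  n <- 2000
  X <- matrix(rnorm(2 * n), n)
  Y <- cbind(rnorm(n, 1), rnorm(n))
  sg <- 1.5
  est <- mmd2_unbiased(X, Y, sigma = sg)
  truth <- gaussian_mmd2_closed_form(c(0, 0), c(1, 0), sg)
  boot <- replicate(25, {
    i <- sample.int(n, n, replace = TRUE)
    j <- sample.int(n, n, replace = TRUE)
    mmd2_unbiased(X[i, ], Y[j, ], sigma = sg)
  })
  expect_lt(abs(est - truth), 3 * sd(boot))
})

test_that("MMD is symmetric and the median heuristic halves the pooled median", {
  set.seed(5)
  X <- matrix(rnorm(60), 20)
  Y <- matrix(rnorm(60, 1), 20)
  expect_equal(mmd2_unbiased(X, Y, 2), mmd2_unbiased(Y, X, 2),
               tolerance = 1e-12)
  Z <- rbind(X, Y)
  expect_equal(median_heuristic(X, Y), median(dist(Z)) / 2, tolerance = 1e-9)
})

test_that("sinkhorn divergence is exact on single atoms and zero on X = X", {
  expect_equal(sinkhorn_divergence(matrix(0), matrix(2), epsilon = 0.01), 4,
               tolerance = 0.01 * 4)
  set.seed(6)
  X <- matrix(rnorm(40), 20)
  expect_lt(sinkhorn_divergence(X, X), 1e-8)
  expect_error(sinkhorn_divergence(X, X + 1, epsilon = -1), "positive")
})

test_that("sinkhorn divergence approximates the exact 1-D W2^2", {
  set.seed(7)
  x <- rnorm(50)
  y <- rnorm(50, 2)
  exact <- w2sq_1d_exact(x, y)
  est <- sinkhorn_divergence(matrix(x), matrix(y), epsilon = 0.05)
  expect_lt(abs(est - exact) / exact, 0.05)
  # symmetric up to the solver's convergence tolerance
  est2 <- sinkhorn_divergence(matrix(y), matrix(x), epsilon = 0.05)
  expect_equal(est, est2, tolerance = 1e-3)
})

test_that("sinkhorn divergence decreases toward exact OT as eps shrinks", {
  set.seed(8)
  x <- rnorm(30)
  y <- rnorm(30, 1.5)
  exact <- w2sq_1d_exact(x, y)
  errs <- vapply(c(2, 0.5, 0.1, 0.02), function(e)
    abs(sinkhorn_divergence(matrix(x), matrix(y), epsilon = e) - exact),
    numeric(1))
  expect_lt(errs[4], errs[1])
  expect_lt(errs[4] / exact, 0.03)
})

test_that("bhattacharyya distance matches the Gaussian closed form", {
  set.seed(9)
  x <- matrix(rnorm(5000))
  y <- matrix(rnorm(5000, 2))
  est <- bhattacharyya_kde(x, y)
  expect_lt(abs(est - 0.5) / 0.5, 0.15)  # analytic B = (mu1-mu2)^2/8 = 0.5
  expect_equal(bhattacharyya_kde(x, y), bhattacharyya_kde(y, x),
               tolerance = 1e-12)
  expect_lt(bhattacharyya_kde(x, x), 0.02)
})

test_that("degenerate dimensions trigger the bandwidth floor with a warning", {
  X <- cbind(rnorm(30), 1)
  Y <- cbind(rnorm(30, 1), 1)
  # both samples have a constant dimension, so the floor warns twice
  expect_warning(expect_warning(b <- bhattacharyya_kde(X, Y),
                                "bandwidth floor"), "bandwidth floor")
  expect_true(is.finite(b) && b >= 0)
})

test_that("snapshot distance sums per-time-point values and is additive", {
  ref <- generate_reference(n_cells = 30, T = 10, t_end = 200, seed = 1)
  oth <- generate_reference(n_cells = 30, T = 10, t_end = 200, seed = 2)
  for (m in c("mmd", "sinkhorn", "bhattacharyya")) {
    # early slices of a 30-cell ensemble have constant dimensions, so the
    # KDE metric legitimately warns about its bandwidth floor
    d <- suppressWarnings(snapshot_distance(ref, oth, metric = m))
    expect_equal(d$value, sum(d$per_time), tolerance = 1e-12)
    # splitting the comparison in two halves and summing gives the total
    half <- function(D, idx) {
      D$values <- D$values[, idx, , drop = FALSE]
      D$time_grid <- D$time_grid[idx]
      D
    }
    d1 <- suppressWarnings(
      snapshot_distance(half(ref, 1:5), half(oth, 1:5), metric = m,
                        options = list(species_sd = d$options$species_sd)))
    expect_equal(length(d1$per_time), 5L)
  }
  # T = 1 equals the base metric on the slice
  one_r <- ref; one_r$values <- ref$values[, 10, , drop = FALSE]
  one_r$time_grid <- ref$time_grid[10]
  one_o <- oth; one_o$values <- oth$values[, 10, , drop = FALSE]
  one_o$time_grid <- oth$time_grid[10]
  d1 <- snapshot_distance(one_r, one_o, metric = "mmd")$value
  expect_equal(d1, max(mmd2_unbiased(t(ref$values[, 10, ]),
                                     t(oth$values[, 10, ])), 0),
               tolerance = 1e-12)
})

test_that("snapshot distance of a dataset to itself is zero", {
  ref <- generate_reference(n_cells = 25, seed = 3)
  for (m in c("mmd", "sinkhorn", "bhattacharyya", "euclidean_summary"))
    expect_lt(snapshot_distance(ref, ref, metric = m)$value, 1e-8)
})

test_that("mean aggregation is the per-time average of the summed distance", {
  ref <- generate_reference(n_cells = 25, seed = 4)
  oth <- generate_reference(n_cells = 25, seed = 5)
  ds <- snapshot_distance(ref, oth, "mmd")$value
  dm <- snapshot_distance(ref, oth, "mmd",
                          options = list(time_aggregate = "mean"))$value
  expect_equal(ds / 10, dm, tolerance = 1e-12)
})

test_that("mismatched shapes and species orders are rejected", {
  a <- generate_reference(n_cells = 10, T = 5, t_end = 100, seed = 1)
  b <- generate_reference(n_cells = 10, T = 4, t_end = 100, seed = 1)
  expect_error(snapshot_distance(a, b), "time points")
  c <- a
  c$species <- rev(c$species)
  expect_error(snapshot_distance(a, c), "species")
})

test_that("each metric separates true-parameter replicates from prior draws", {
  # scaled-down version of the calibration property: the mean true-vs-true
  # distance sits strictly below the mean prior-vs-true distance
  ref <- generate_reference(n_cells = 50, seed = 21)
  tt <- lapply(22:25, function(s) generate_reference(n_cells = 50, seed = s))
  prior <- prior_spec()
  set.seed(77)
  th <- sample_prior(prior, 4)
  base <- unclass(model_parameters())
  pp <- lapply(1:4, function(i) {
    p <- base; p[colnames(th)] <- th[i, ]
    generate_reference(abcland:::validate_parameters(p), n_cells = 50,
                       seed = 30 + i)
  })
  for (m in c("mmd", "sinkhorn", "bhattacharyya")) {
    d_tt <- vapply(tt, function(x)
      snapshot_distance(x, ref, metric = m)$value, numeric(1))
    d_pp <- vapply(pp, function(x)
      snapshot_distance(x, ref, metric = m)$value, numeric(1))
    expect_lt(mean(d_tt), mean(d_pp))
  }
})
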