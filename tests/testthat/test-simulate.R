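pure_death <- function(gamma = 0.05) {
  ov <- as.list(rep(0, 15))
  names(ov) <- setdiff(abcland:::KINETIC_PARAMS, "gamma")
  do.call(model_parameters, c(ov, list(gamma = gamma, LIF = 0)))
}

test_that("a pure-death process is nonincreasing and absorbs at zero", {
  p <- pure_death(0.2)
  tr <- gillespie_trajectory(p, c(10, 10, 10, 10), t_end = 200, seed = 3)
  for (s in 1:4) {
    path <- tr$states[s, ]
    expect_true(all(diff(path) <= 0))
  }
  expect_equal(unname(tr$states[, ncol(tr$states)]), c(0, 0, 0, 0))
})

test_that("gillespie trajectories are bitwise reproducible by seed", {
  p <- model_parameters()
  a <- gillespie_trajectory(p, c(0, 0, 0, 0), 50, seed = 11)
  b <- gillespie_trajectory(p, c(0, 0, 0, 0), 50, seed = 11)
  c <- gillespie_trajectory(p, c(0, 0, 0, 0), 50, seed = 12)
  expect_identical(a$times, b$times)
  expect_identical(a$states, b$states)
  expect_false(identical(a$states, c$states))
})

test_that("gillespie events move by single stoichiometry columns", {
  tr <- gillespie_trajectory(model_parameters(), c(2, 5, 1, 1), 50, seed = 5)
  K <- ncol(tr$states)
  expect_gt(K, 50)  # the cascade fires plenty of events
  jumps <- tr$states[, 2:(K - 1), drop = FALSE] -
           tr$states[, 1:(K - 2), drop = FALSE]
  expect_true(all(colSums(abs(jumps)) == 1))
  expect_gte(max(tr$times), 20)
  expect_error(gillespie_trajectory(model_parameters(), c(0.5, 0, 0, 0), 10, 1),
               "integer")
})

gillespie_grid_cpp_wrap <- function(p, x0, t_end, i) {
  tr <- gillespie_trajectory(p, x0, t_end, seed = 1000 + i)
  tr$states[, ncol(tr$states)]
}

test_that("the gillespie ensemble mean tracks the ODE at large copy numbers", {
  p <- model_parameters()
  x0 <- c(0, 100, 0, 0)
  t_end <- 50
  n <- 500
  fin <- vapply(seq_len(n), function(i)
    gillespie_grid_cpp_wrap(p, x0, t_end, i), numeric(4))
  ode <- integrate_ode(p, x0 = x0, times = c(0, t_end))
  target <- ode[2, -1]
  m <- rowMeans(fin)
  se <- apply(fin, 1, sd) / sqrt(n)
  for (s in 1:4)
    expect_lt(abs(m[s] - target[s]), 3 * se[s] + 0.05 * max(1, target[s]))
})

test_that("zero-noise CLE equals the explicit Euler ODE solution", {
  p <- model_parameters()
  tr <- cle_trajectory(p, c(0, 1, 0, 0), t_end = 10, dt = 0.1, seed = 1,
                       noise_scale = 0)
  # independent explicit Euler in R
  x <- c(0, 1, 0, 0)
  for (k in 1:100) x <- pmax(x + 0.1 * unname(ode_rhs(x, p)), 0)
  expect_equal(unname(tr$states[, ncol(tr$states)]), x, tolerance = 1e-12)
  expect_identical(tr$states,
                   cle_trajectory(p, c(0, 1, 0, 0), 10, 0.1, 1, 0)$states)
  expect_error(cle_trajectory(p, c(0, 0, 0, 0), 10, dt = -1, seed = 1),
               "dt")
})

test_that("the CLE pure-death ensemble mean matches the exponential decay", {
  p <- pure_death(0.1)
  x0 <- c(40, 0, 0, 0)
  t_end <- 10
  n <- 2000
  fin <- vapply(seq_len(n), function(i) {
    tr <- cle_trajectory(p, x0, t_end, dt = 0.05, seed = 5000 + i)
    tr$states[1, ncol(tr$states)]
  }, numeric(1))
  expected <- x0[1] * exp(-0.1 * t_end)
  se <- sd(fin) / sqrt(n)
  expect_lt(abs(mean(fin) - expected), 3 * se + 0.05 * expected)
})

test_that("snapshot sampling uses the left-continuous hold convention", {
  tr <- structure(list(
    times = c(0, 5, 10),
    states = cbind(c(1, 0, 0, 0), c(2, 0, 0, 0), c(2, 0, 0, 0)),
    kind = "gillespie"), class = "trajectory")
  ds <- sample_snapshots(list(tr), c(4.9, 5.1))
  expect_equal(unname(ds$values[1, 1, 1]), 1)  # pre-event state
  expect_equal(unname(ds$values[1, 2, 1]), 2)  # post-event state
  ds0 <- sample_snapshots(list(tr), 0)
  expect_equal(unname(ds0$values[, 1, 1]), c(1, 0, 0, 0))
  expect_error(sample_snapshots(list(tr), c(5, 20)), "trajectory 1")
})

test_that("snapshot sampling is idempotent on grid-recorded trajectories", {
  tr <- gillespie_trajectory(model_parameters(), c(0, 0, 0, 0), 30, seed = 2)
  grid <- c(10, 20, 30)
  ds1 <- sample_snapshots(list(tr), grid)
  ds2 <- sample_snapshots(list(structure(list(
    times = grid, states = ds1$values[, , 1], kind = "gillespie"),
    class = "trajectory")), grid)
  expect_identical(ds1$values, ds2$values)
})

test_that("reference generation matches the snapshot-tensor contract", {
  ref <- generate_reference(n_cells = 300, T = 10, seed = 1)
  expect_equal(dim(ref$values), c(4L, 10L, 300L))
  expect_equal(ref$time_grid, (1:10) * 80)  # k * t_end / T
  expect_true(all(is.finite(ref$values)) && all(ref$values >= 0))
  one <- generate_reference(n_cells = 1, T = 4, seed = 1)
  expect_equal(dim(one$values), c(4L, 4L, 1L))
  again <- generate_reference(n_cells = 300, T = 10, seed = 1)
  expect_identical(ref$values, again$values)
  # grid sampler agrees with the event-path sampler cell by cell
  s <- child_seed(1, "reference", 7)
  tr <- gillespie_trajectory(model_parameters(), c(0, 0, 0, 2), 800, seed = s)
  expect_equal(unname(sample_snapshots(list(tr), ref$time_grid)$values[, , 1]),
               unname(ref$values[, , 7]))
})

test_that("the final-time fate scatter is bimodal at LIF = 50", {
  ref <- generate_reference(n_cells = 300, seed = 1)
  fin <- t(ref$values[c("Nanog", "Gata6"), 10, ])
  km <- abcland:::with_local_seed(4, kmeans(fin, 2, nstart = 10))
  frac <- min(table(km$cluster)) / 300
  expect_gt(frac, 0.05)  # both fates populated
  # one cluster is high-Nanog/low-Gata6, the other the reverse
  hi <- which.max(km$centers[, 1])
  lo <- 3 - hi
  expect_gt(km$centers[hi, 1], km$centers[hi, 2])
  expect_gt(km$centers[lo, 2], km$centers[lo, 1])
  expect_gt(km$centers[hi, 1], km$centers[lo, 1] + 20)
})

test_that("the pluripotent fraction increases with LIF", {
  frac_high <- vapply(c(5, 50, 200), function(L) {
    ref <- generate_reference(model_parameters(LIF = L), n_cells = 200,
                              seed = 7)
    fin <- t(ref$values[c("Nanog", "Gata6"), 10, ])
    mean(fin[, 1] > fin[, 2])
  }, numeric(1))
  expect_true(all(diff(frac_high) > 0))
})
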