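test_that("the default prior brackets the reference parameters by a factor of ten", {
  pr <- prior_spec()
  expect_equal(nrow(pr), 16L)
  a0 <- pr[pr$parameter == "a0", ]
  expect_equal(a0$lower, 0.001)
  expect_equal(a0$upper, 0.1)
  expect_true(all(pr$lower > 0 & pr$lower < pr$upper))
  expect_error(prior_from_bounds(c(a = 1), c(a = 1)), "lower < upper")
})

test_that("prior draws stay in bounds with uniform moments", {
  pr <- prior_spec()
  th <- sample_prior(pr, 1e4, seed = 1)
  expect_true(all(t(th) >= pr$lower & t(th) <= pr$upper))
  mid <- (pr$lower + pr$upper) / 2
  se <- (pr$upper - pr$lower) / sqrt(12 * 1e4)
  expect_true(all(abs(colMeans(th) - mid) < 3.5 * se))
})

test_that("rejection at infinite tolerance recovers the prior", {
  pr <- prior_from_bounds(c(mu = -5), c(mu = 5))
  set.seed(3)
  ref <- rnorm(20, 1, 1)
  pop <- abc_rejection(ref, toy_simulator(20), pr, toy_distance,
                       epsilon = Inf, N = 500, seed = 4)
  expect_equal(pop$n_sims, 500L)  # acceptance rate 1
  expect_equal(sum(pop$weights), 1, tolerance = 1e-12)
  ks <- suppressWarnings(ks.test(pop$theta[, "mu"], "punif", -5, 5))
  expect_gt(ks$p.value, 0.001)
})

test_that("rejection ABC recovers the conjugate Gaussian posterior", {
  n_obs <- 20
  set.seed(5)
  ref <- rnorm(n_obs, 1, 1)
  pr <- prior_from_bounds(c(mu = -5), c(mu = 5))
  pop <- abc_rejection(ref, toy_simulator(n_obs), pr, toy_distance,
                       epsilon = 0.05, N = 300, seed = 6)
  # wide-uniform prior: posterior ~ N(ybar, 1/n) truncated to [-5, 5]
  post <- truncnorm_moments(mean(ref), 1 / sqrt(n_obs), -5, 5)
  mc_se <- sd(pop$theta[, "mu"]) / sqrt(300)
  expect_lt(abs(mean(pop$theta[, "mu"]) - post$mean), 4 * mc_se + 0.05)
  expect_lt(abs(var(pop$theta[, "mu"]) - post$var), 0.5 * post$var)
  expect_true(all(pop$distances <= 0.05))
})

test_that("rejection is reproducible and reports budget exhaustion", {
  pr <- prior_from_bounds(c(mu = -5), c(mu = 5))
  set.seed(8)
  ref <- rnorm(10, 0, 1)
  a <- abc_rejection(ref, toy_simulator(10), pr, toy_distance, 0.5, 50, seed = 9)
  b <- abc_rejection(ref, toy_simulator(10), pr, toy_distance, 0.5, 50, seed = 9)
  expect_identical(a$theta, b$theta)
  partial <- abc_rejection(ref, toy_simulator(10), pr, toy_distance,
                           epsilon = 1e-6, N = 50, max_sims = 200, seed = 9)
  expect_equal(partial$status, "max_sims_reached")
  expect_lt(nrow(partial$theta), 50)
  expect_equal(partial$n_sims, 200L)
})

test_that("the perturbation kernel is zero-mean with variance-doubling scale", {
  pr <- prior_from_bounds(c(a = 0, b = 0), c(a = 10, b = 10))
  theta_mat <- cbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5))
  pop <- abcland:::new_population(theta_mat, rep(1, 4), rep(0.1, 4), 1, 0L,
                                  4L, pr)
  sds <- abcland:::kernel_sds(pop)
  expect_equal(unname(sds["a"]), sqrt(2 * mean((theta_mat[, 1] - 2.5)^2)))
  expect_equal(unname(sds["b"]), 0.1)  # 1% of prior range fallback
  set.seed(10)
  theta0 <- c(a = 2, b = 5)
  draws <- t(replicate(1e4, perturb(theta0, pop)))
  expect_lt(abs(mean(draws[, "a"]) - 2), 3 * sds["a"] / 100)
  expect_false(any(draws[, "b"] == 5))  # fallback jitter moves the particle
  # doubling the spread doubles the kernel sd
  pop2 <- abcland:::new_population(sweep(theta_mat, 2, c(2.5, 5)) * 2 +
                                     rep(c(2.5, 5), each = 4),
                                   rep(1, 4), rep(0.1, 4), 1, 0L, 4L, pr)
  expect_equal(unname(abcland:::kernel_sds(pop2)["a"]), 2 * unname(sds["a"]))
})

test_that("ABC-SMC tolerances decrease and weights stay normalized", {
  n_obs <- 15
  set.seed(11)
  ref <- rnorm(n_obs, 1, 1)
  pr <- prior_from_bounds(c(mu = -5), c(mu = 5))
  res <- abc_smc(ref, toy_simulator(n_obs), pr, toy_distance,
                 epsilon_target = 0.05, N = 150, seed = 12)
  expect_true(all(diff(res$tolerances) < 0))
  for (pop in res$generations) {
    expect_equal(sum(pop$weights), 1, tolerance = 1e-12)
    expect_true(all(pop$distances <= pop$tolerance))
    expect_true(all(pop$theta[, "mu"] >= -5 & pop$theta[, "mu"] <= 5))
  }
  expect_equal(res$status, "ok")

  # the final posterior matches the conjugate answer and is tighter than
  # the first generation
  fin <- final_population(res)
  post <- truncnorm_moments(mean(ref), 1 / sqrt(n_obs), -5, 5)
  m_fin <- sum(fin$weights * fin$theta[, "mu"])
  expect_lt(abs(m_fin - post$mean), 0.15)
  v_fin <- sum(fin$weights * (fin$theta[, "mu"] - m_fin)^2)
  v_gen0 <- var(res$generations[[1]]$theta[, "mu"])
  expect_lt(v_fin, v_gen0)
})

test_that("ABC-SMC respects the simulation budget with a status flag", {
  set.seed(13)
  ref <- rnorm(10, 0, 1)
  pr <- prior_from_bounds(c(mu = -5), c(mu = 5))
  res <- abc_smc(ref, toy_simulator(10), pr, toy_distance,
                 epsilon_target = 1e-9, N = 50, max_sims = 600, seed = 14)
  expect_equal(res$status, "max_sims_reached")
  expect_lte(res$n_sims, 600)
  expect_gt(length(res$generations), 0)
})

test_that("ABC-SMC is deterministic given the master seed", {
  set.seed(15)
  ref <- rnorm(10, 0.5, 1)
  pr <- prior_from_bounds(c(mu = -5), c(mu = 5))
  r1 <- abc_smc(ref, toy_simulator(10), pr, toy_distance, 0.2, 60, seed = 16)
  r2 <- abc_smc(ref, toy_simulator(10), pr, toy_distance, 0.2, 60, seed = 16)
  expect_identical(final_population(r1)$theta, final_population(r2)$theta)
  expect_identical(r1$tolerances, r2$tolerances)
})
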