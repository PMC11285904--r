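test_that("the overlap coefficient behaves at its extremes", {
  expect_equal(overlap_coefficient(rep(1, 50), rep(1, 50)), 1)
  expect_equal(overlap_coefficient(rnorm(100), rnorm(100, 100)), 0)
  set.seed(1)
  o <- overlap_coefficient(rnorm(2000), rnorm(2000))
  expect_gt(o, 0.8)
  expect_lte(o, 1)
})

test_that("the logit-pluripotency statistic matches hand-computed splits", {
  expect_equal(pluripotency_statistic(two_cluster_dataset(50, 50)), 0)
  expect_equal(pluripotency_statistic(two_cluster_dataset(90, 10)), log(9),
               tolerance = 1e-12)
  # all cells identical and pluripotent: p clips to 199/200
  all_plur <- two_cluster_dataset(100, 0)
  expect_equal(pluripotency_statistic(all_plur), log(199), tolerance = 1e-12)
  all_diff <- two_cluster_dataset(0, 100)
  expect_equal(pluripotency_statistic(all_diff), -log(199), tolerance = 1e-12)
})

test_that("the statistic is deterministic and leaves the RNG state alone", {
  ds <- two_cluster_dataset(60, 40, jitter = 0.5, seed = 2)
  s1 <- pluripotency_statistic(ds)
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(pluripotency_statistic(ds)); after <- runif(1)
  expect_identical(before, after)
  expect_identical(s1, pluripotency_statistic(ds))
  expect_equal(s1, log(0.6 / 0.4), tolerance = 1e-12)
})

test_that("euclidean summary distances match direct moment computation", {
  d1 <- two_cluster_dataset(3, 0)
  d2 <- d1
  d2$values[1, 1, 1] <- d1$values[1, 1, 1] + 0.7
  m1 <- c(apply(d1$values, c(1, 2), mean), apply(d1$values^2, c(1, 2), mean))
  m2 <- c(apply(d2$values, c(1, 2), mean), apply(d2$values^2, c(1, 2), mean))
  expect_equal(euclidean_summary_distance(d1, d2), sqrt(sum((m1 - m2)^2)),
               tolerance = 1e-12)
  expect_equal(euclidean_summary_distance(d1, d2),
               euclidean_summary_distance(d2, d1))
  expect_equal(euclidean_summary_distance(d1, d1), 0)
  a <- two_cluster_dataset(90, 10); b <- two_cluster_dataset(50, 50)
  expect_equal(euclidean_summary_distance(a, b, summary = "logit_p"),
               log(9), tolerance = 1e-12)
})

test_that("the separation experiment distinguishes truth from the prior", {
  sep <- separation_experiment(metric = "mmd", n_rep = 10, n_cells = 40,
                               seed = 3)
  expect_length(sep$distances_true_vs_true, 10)
  expect_length(sep$distances_prior_vs_true, 10)
  expect_true(all(sep$distances_true_vs_true >= 0))
  expect_lt(median(sep$distances_true_vs_true),
            median(sep$distances_prior_vs_true))
  expect_lt(sep$overlap, 0.5)
  expect_equal(suggest_epsilon(sep), median(sep$distances_true_vs_true))
  # reruns reproduce the same lists
  sep2 <- separation_experiment(metric = "mmd", n_rep = 10, n_cells = 40,
                                seed = 3)
  expect_identical(sep$distances_true_vs_true, sep2$distances_true_vs_true)
  expect_identical(sep$distances_prior_vs_true, sep2$distances_prior_vs_true)
})

test_that("a point-mass prior at the truth makes the two arms indistinguishable", {
  truth <- model_parameters()
  tight <- prior_spec(truth, lower_factor = 1 - 1e-9,
                      upper_factor = 1 + 1e-9)
  sep <- separation_experiment(prior = tight, metric = "mmd", n_rep = 25,
                               n_cells = 40, seed = 4)
  ks <- suppressWarnings(ks.test(sep$distances_true_vs_true,
                                 sep$distances_prior_vs_true))
  expect_gt(ks$p.value, 0.01)
  expect_gt(sep$overlap, 0.4)
})

test_that("posterior predictive checks are calibrated at the true parameters", {
  ref <- generate_reference(n_cells = 60, seed = 5)
  simfun <- stem_simulator(n_cells = 60, time_grid = ref$time_grid)
  truth <- unclass(model_parameters())[abcland:::KINETIC_PARAMS]
  pop <- abcland:::new_population(
    matrix(truth, 1, dimnames = list(NULL, names(truth))),
    1, 0, Inf, 0L, 0L, prior_spec())
  ppc <- posterior_predictive_check(pop, ref, simfun, n_draws = 50, seed = 6)
  expect_gte(ppc$tail_prob, 0.05)
  expect_lte(ppc$tail_prob, 0.95)
  expect_equal(ppc$n_failed, 0L)
  # deterministic given seed
  ppc2 <- posterior_predictive_check(pop, ref, simfun, n_draws = 50, seed = 6)
  expect_identical(ppc$S_posterior_draws, ppc2$S_posterior_draws)

  # a population at the prior's upper bound is much worse calibrated
  pr <- prior_spec()
  far <- setNames(pr$upper, pr$parameter)
  pop_far <- abcland:::new_population(
    matrix(far, 1, dimnames = list(NULL, names(far))),
    1, 0, Inf, 0L, 0L, pr)
  ppc_far <- posterior_predictive_check(pop_far, ref, simfun, n_draws = 20,
                                        seed = 6)
  expect_gt(ppc_far$mse, ppc$mse)
})
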