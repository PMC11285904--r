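# closed forms and small independent oracles shared across test files

# population MMD^2 between N(m1, I_d) and N(m2, I_d) under a Gaussian
# kernel of bandwidth sigma (analytic Gaussian integrals)
gaussian_mmd2_closed_form <- function(m1, m2, sigma) {
  d <- length(m1)
  s2 <- sigma^2
  ekpp <- (s2 / (s2 + 2))^(d / 2)
  ekpq <- ekpp * exp(-sum((m1 - m2)^2) / (2 * (s2 + 2)))
  2 * (ekpp - ekpq)
}

# exact 1-D squared 2-Wasserstein distance between empirical measures of
# equal size: sorted-quantile assignment
w2sq_1d_exact <- function(x, y) mean((sort(x) - sort(y))^2)

# moments of a normal truncated to [lo, hi]
truncnorm_moments <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  m <- mu + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
               ((dnorm(a) - dnorm(b)) / Z)^2)
  list(mean = m, var = v)
}

# toy conjugate setup used by the ABC tests: data are n draws from
# N(theta, 1), distance is |mean difference|, prior is uniform
toy_simulator <- function(n_obs) {
  function(theta, seed) {
    set.seed(seed)
    rnorm(n_obs, theta[["mu"]], 1)
  }
}
toy_distance <- function(x, ref) abs(mean(x) - mean(ref))

make_dataset <- function(values, time_grid = seq_len(dim(values)[2])) {
  abcland:::new_snapshot_dataset(values, time_grid)
}

# two clearly separated fate clusters in the (Nanog, Gata6) plane,
# embedded in the 4-species tensor at a single final time
two_cluster_dataset <- function(n_high, n_low, jitter = 0, seed = 1) {
  set.seed(seed)
  n <- n_high + n_low
  vals <- array(0, c(4, 1, n))
  nanog <- c(rep(10, n_high), rep(0.1, n_low)) + jitter * runif(n)
  gata6 <- c(rep(0.1, n_high), rep(10, n_low)) + jitter * runif(n)
  vals[1, 1, ] <- nanog
  vals[4, 1, ] <- gata6
  make_dataset(vals, time_grid = 1)
}
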