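#' Uniform prior specification over model parameters
#'
#' Independent uniform priors per inferred parameter. The default rule
#' brackets a reference parameter vector by a factor of 10 on each side:
#' `[theta*/10, 10 theta*]`.
#'
#' @param params reference `model_parameters` (or coercible).
#' @param infer names of the inferred parameters (default: the 16 kinetic
#'   constants including gamma; external signals stay fixed).
#' @param lower_factor,upper_factor multiplicative bounds.
#' @return object of class `prior_spec`: data frame with columns
#'   `parameter`, `lower`, `upper`.
#' @export
#' @examples
#' prior_spec()[1, ]  # a0 in [0.001, 0.1]
prior_spec <- function(params = model_parameters(), infer = KINETIC_PARAMS,
                       lower_factor = 1 / 10, upper_factor = 10) {
  params <- as_model_parameters(params)
  bad <- setdiff(infer, PARAM_NAMES)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  lo <- as.numeric(params[infer]) * lower_factor
  hi <- as.numeric(params[infer]) * upper_factor
  if (any(lo <= 0))
    stop("kinetic-constant priors need strictly positive lower bounds")
  new_prior_spec(infer, lo, hi)
}

new_prior_spec <- function(parameter, lower, upper) {
  if (any(lower >= upper)) stop("prior requires lower < upper for every parameter")
  structure(data.frame(parameter = parameter, lower = lower, upper = upper,
                       stringsAsFactors = FALSE),
            class = c("prior_spec", "data.frame"))
}

#' Uniform prior from explicit bounds
#'
#' @param lower,upper named numeric vectors of bounds (same names).
#' @return `prior_spec`.
#' @export
prior_from_bounds <- function(lower, upper) {
  stopifnot(identical(names(lower), names(upper)))
  new_prior_spec(names(lower), as.numeric(lower), as.numeric(upper))
}

prior_range <- function(prior) setNames(prior$upper - prior$lower, prior$parameter)

prior_contains <- function(prior, theta) {
  all(theta >= prior$lower & theta <= prior$upper)
}

#' Draw parameters from the prior
#'
#' @param prior a `prior_spec`.
#' @param n number of draws.
#' @param seed optional integer seed (uses the current RNG state if NULL).
#' @return `n` x p matrix with parameter-named columns.
#' @export
sample_prior <- function(prior, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(prior)
  th <- matrix(runif(n * p, rep(prior$lower, each = n),
                     rep(prior$upper, each = n)), nrow = n)
  colnames(th) <- prior$parameter
  th
}

new_population <- function(theta, weights, distances, tolerance, generation,
                           n_sims, prior, status = "ok") {
  weights <- weights / sum(weights)
  structure(list(theta = theta, weights = weights, distances = distances,
                 tolerance = tolerance, generation = generation,
                 n_sims = n_sims, prior = prior, status = status),
            class = "abc_population")
}

#' @export
print.abc_population <- function(x, ...) {
  cat(sprintf(
    "<ABC population: generation %d, %d particles, tolerance %.4g, %d simulations [%s]>\n",
    x$generation, nrow(x$theta), x$tolerance, x$n_sims, x$status))
  invisible(x)
}

#' ABC rejection sampling
#'
#' Draws candidates from the prior, simulates a dataset per candidate and
#' accepts those whose distance to the reference is at most `epsilon`,
#' until `N` particles are accepted or `max_sims` simulations are consumed
#' (in which case a partial population with status `"max_sims_reached"` is
#' returned, not an error).
#'
#' @param reference observed/reference dataset (any object the simulator
#'   output can be compared with).
#' @param simulator function `(theta, seed) -> data` simulating one dataset.
#' @param prior a `prior_spec`.
#' @param distance function `(candidate, reference) -> numeric`.
#' @param epsilon acceptance tolerance (> 0; may be `Inf`).
#' @param N number of particles to accept.
#' @param max_sims simulation budget (default 1e7).
#' @param seed master seed.
#' @return `abc_population` with equal weights `1/N`.
#' @export
abc_rejection <- function(reference, simulator, prior, distance, epsilon, N,
                          max_sims = 1e7, seed = 1) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (N < 1) stop("N must be >= 1")
  p <- nrow(prior)
  acc_theta <- matrix(NA_real_, N, p, dimnames = list(NULL, prior$parameter))
  acc_dist <- numeric(N)
  n_acc <- 0L; n_sims <- 0L
  set.seed(child_seed(seed, "prior", 0))
  while (n_acc < N && n_sims < max_sims) {
    theta <- sample_prior(prior, 1)[1, ]
    n_sims <- n_sims + 1L
    sim <- simulator(theta, child_seed(seed, "candidate", n_sims))
    d <- distance(sim, reference)
    if (d <= epsilon) {
      n_acc <- n_acc + 1L
      acc_theta[n_acc, ] <- theta
      acc_dist[n_acc] <- d
    }
  }
  status <- if (n_acc < N) "max_sims_reached" else "ok"
  keep <- seq_len(n_acc)
  new_population(acc_theta[keep, , drop = FALSE], rep(1, n_acc),
                 acc_dist[keep], epsilon, 0L, n_sims, prior, status)
}

weighted_var <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  sum(w * (x - m)^2)
}

kernel_sds <- function(population) {
  # marginal kernel scales, sd = sqrt(2 * weighted variance); degenerate
  # components fall back to 1% of the prior range
  v <- apply(population$theta, 2, weighted_var, w = population$weights)
  sds <- sqrt(2 * v)
  fallback <- 0.01 * prior_range(population$prior)
  ifelse(sds > 0, sds, fallback)
}

kernel_cov <- function(population, scale = 2) {
  # full-covariance Gaussian kernel, Sigma = 2 * weighted covariance of the
  # previous population: in a 16-parameter space with strongly correlated
  # pairs, component-wise kernels propose almost entirely off the posterior
  # ridge and the acceptance rate collapses; the multivariate kernel keeps
  # proposals on it. Degenerate directions get a 1%-of-prior-range jitter.
  S <- scale * posterior_covariance(population$theta, population$weights)
  jit <- (0.01 * prior_range(population$prior))^2
  d <- diag(S)
  bump <- pmax(jit - d, 0)
  S <- S + diag(bump + 1e-12 * pmax(d, jit), nrow(S))
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    S <- diag(pmax(d, jit), nrow(S))
    dimnames(S) <- list(colnames(population$theta), colnames(population$theta))
    R <- chol(S)
  }
  list(S = S, R = R)
}

mvn_propose <- function(theta, R) {
  theta + drop(rnorm(ncol(R)) %*% R)
}

mvn_log_density <- function(x, centers, R) {
  # log N(x; centers_j, R'R) for all rows of centers
  z <- backsolve(R, x - t(centers), transpose = TRUE)  # p x N rhs
  -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * ncol(R) * log(2 * pi)
}

#' Perturb a particle with the adaptive Gaussian kernel
#'
#' The kernel is a multivariate Gaussian with covariance twice the weighted
#' covariance of the previous population, so proposals follow the
#' population's correlation structure; degenerate directions fall back to a
#' jitter of 1% of the prior range.
#'
#' @param theta named parameter vector.
#' @param previous previous `abc_population`.
#' @param seed optional integer seed.
#' @return perturbed parameter vector (not support-checked; the SMC loop
#'   re-proposes draws that land outside the prior).
#' @export
perturb <- function(theta, previous, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mvn_propose(theta, kernel_cov(previous)$R)
}

smc_weights <- function(theta_new, previous, R) {
  # w_i proportional to prior(theta_i) / sum_j w_j K(theta_i | theta_j);
  # the uniform prior is constant on its support so only the kernel mixture
  # denominator matters
  lpw <- log(previous$weights)  # -Inf for numerically extinct particles
  lw <- vapply(seq_len(nrow(theta_new)), function(i) {
    lk <- lpw + mvn_log_density(theta_new[i, ], previous$theta, R)
    mx <- max(lk)  # finite: at least one previous weight is positive
    -(mx + log(sum(exp(lk - mx))))
  }, numeric(1))
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' ABC sequential Monte Carlo with adaptive quantile tolerance schedule
#'
#' Generation 0 is rejection sampling at an initial tolerance set to the
#' `quantile_alpha` quantile of distances from a pilot of
#' `pilot_factor * N` prior-predictive simulations; every subsequent
#' tolerance is the `quantile_alpha` quantile (default 30%) of the previous
#' generation's accepted distances. Particles are proposed by weighted
#' resampling of the previous population followed by the adaptive Gaussian
#' perturbation kernel of [perturb()]; proposals outside the prior support
#' are re-proposed. Importance weights follow the standard SMC correction
#' `w_i = prior(theta_i) / sum_j w_j K(theta_i | theta_j)`.
#'
#' The run terminates when the tolerance reaches `epsilon_target`, when the
#' simulation budget `max_sims` is exhausted (completed generations are
#' returned with a status flag) or after `max_generations`.
#'
#' @inheritParams abc_rejection
#' @param epsilon_target target final tolerance.
#' @param quantile_alpha quantile of the tolerance schedule, in (0, 1).
#' @param pilot_factor pilot simulations per particle for the initial
#'   tolerance.
#' @param kernel_scale multiplier on the weighted population covariance in
#'   the perturbation kernel (2 is the classical variance-doubling rule;
#'   smaller values raise late-generation acceptance in high-dimensional
#'   parameter spaces).
#' @param resample_ess if positive, resample the population to equal
#'   weights whenever the effective sample size falls below
#'   `N * resample_ess` (e.g. 0.2). Keeps credible intervals and the
#'   kernel covariance meaningful when weights degenerate, at some cost in
#'   particle diversity; 0 (default) disables it.
#' @param max_generations hard cap on the number of generations.
#' @param verbose print one line per generation.
#' @return object of class `abc_smc_result`: list of `abc_population`s plus
#'   `status` and the total simulation count.
#' @export
abc_smc <- function(reference, simulator, prior, distance, epsilon_target,
                    N, quantile_alpha = 0.3, max_sims = 1e7,
                    pilot_factor = 10, max_generations = 30,
                    kernel_scale = 2, resample_ess = 0, seed = 1,
                    verbose = FALSE) {
  if (N < 2) stop("N must be >= 2")
  if (quantile_alpha <= 0 || quantile_alpha >= 1)
    stop("quantile_alpha must be in (0, 1)")
  p <- nrow(prior)
  n_sims_total <- 0L

  # -- pilot: prior-predictive distances fix the initial tolerance --------
  n_pilot <- min(ceiling(pilot_factor * N), max_sims)
  set.seed(child_seed(seed, "pilot", 0))
  pilot_theta <- sample_prior(prior, n_pilot)
  pilot_dist <- vapply(seq_len(n_pilot), function(i) {
    sim <- simulator(pilot_theta[i, ], child_seed(seed, "pilot", i))
    distance(sim, reference)
  }, numeric(1))
  n_sims_total <- n_sims_total + n_pilot
  eps0 <- as.numeric(quantile(pilot_dist, quantile_alpha))
  ok <- which(pilot_dist <= eps0)
  if (length(ok) < N)
    ok <- order(pilot_dist)[seq_len(min(N, n_pilot))]
  keep <- ok[seq_len(min(N, length(ok)))]
  pop <- new_population(pilot_theta[keep, , drop = FALSE],
                        rep(1, length(keep)), pilot_dist[keep], eps0, 0L,
                        n_pilot, prior)
  generations <- list(pop)
  if (verbose)
    message(sprintf("generation 0: tolerance %.4g (%d pilot sims)",
                    eps0, n_pilot))
  status <- "ok"

  # -- SMC generations ----------------------------------------------------
  gen <- 0L
  while (pop$tolerance > epsilon_target && gen < max_generations) {
    gen <- gen + 1L
    eps_t <- as.numeric(quantile(pop$distances, quantile_alpha))
    eps_t <- max(eps_t, epsilon_target)
    kc <- kernel_cov(pop, scale = kernel_scale)
    acc_theta <- matrix(NA_real_, N, p,
                        dimnames = list(NULL, prior$parameter))
    acc_dist <- numeric(N)
    n_acc <- 0L
    set.seed(child_seed(seed, "generation", gen))
    budget_hit <- FALSE
    while (n_acc < N) {
      if (n_sims_total >= max_sims) { budget_hit <- TRUE; break }
      repeat {
        j <- sample.int(nrow(pop$theta), 1, prob = pop$weights)
        theta <- mvn_propose(pop$theta[j, ], kc$R)
        if (prior_contains(prior, theta)) break
      }
      n_sims_total <- n_sims_total + 1L
      sim <- simulator(theta, child_seed(seed, "candidate", n_sims_total))
      d <- distance(sim, reference)
      if (d <= eps_t) {
        n_acc <- n_acc + 1L
        acc_theta[n_acc, ] <- theta
        acc_dist[n_acc] <- d
      }
    }
    if (budget_hit) { status <- "max_sims_reached"; break }
    w <- smc_weights(acc_theta, pop, kc$R)
    # optional ESS-triggered resampling: when the importance weights
    # degenerate the population's effective size collapses and downstream
    # estimates (kernel covariance, credible intervals) become meaningless;
    # an equal-weight multinomial resample restores it without changing the
    # targeted distribution, at some cost in particle diversity (and hence
    # late-generation acceptance). Off by default: the classical sampler
    # carries the weights as they are.
    ess <- 1 / sum(w^2)
    if (resample_ess > 0 && ess < N * resample_ess) {
      idx <- sample.int(N, N, replace = TRUE, prob = w)
      acc_theta <- acc_theta[idx, , drop = FALSE]
      acc_dist <- acc_dist[idx]
      w <- rep(1 / N, N)
    }
    pop <- new_population(acc_theta, w, acc_dist, eps_t, gen,
                          n_sims_total, prior)
    generations <- c(generations, list(pop))
    if (verbose)
      message(sprintf("generation %d: tolerance %.4g (%d total sims)",
                      gen, eps_t, n_sims_total))
  }
  if (status == "ok" && pop$tolerance > epsilon_target)
    status <- "max_generations_reached"
  structure(list(generations = generations, status = status,
                 n_sims = n_sims_total,
                 tolerances = vapply(generations, `[[`, numeric(1),
                                     "tolerance")),
            class = "abc_smc_result")
}

#' @export
print.abc_smc_result <- function(x, ...) {
  cat(sprintf("<ABC-SMC: %d generations, final tolerance %.4g, %d simulations [%s]>\n",
              length(x$generations), utils::tail(x$tolerances, 1), x$n_sims,
              x$status))
  cat("tolerance schedule:", paste(signif(x$tolerances, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Final population of an ABC-SMC run
#' @param result `abc_smc_result`.
#' @return the last `abc_population`.
#' @export
final_population <- function(result) {
  result$generations[[length(result$generations)]]
}
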