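#' Overlap coefficient of two empirical distributions
#'
#' Histogram intersection over shared Freedman-Diaconis bins spanning the
#' pooled range: `sum_b min(p_b, q_b)` with `p`, `q` the per-sample bin
#' probabilities. 0 means perfectly separated, 1 identical.
#'
#' @param a,b numeric samples.
#' @return overlap in `[0, 1]`.
#' @export
overlap_coefficient <- function(a, b) {
  pooled <- c(a, b)
  iqr <- stats::IQR(pooled)
  bw <- if (iqr > 0) 2 * iqr / length(pooled)^(1 / 3) else diff(range(pooled)) / 30
  if (bw <= 0) return(1)  # all values identical
  breaks <- seq(min(pooled) - bw, max(pooled) + bw, by = bw)
  if (length(breaks) < 2) breaks <- range(pooled) + c(-bw, bw)
  ca <- tabulate(findInterval(a, breaks), nbins = length(breaks))
  cb <- tabulate(findInterval(b, breaks), nbins = length(breaks))
  sum(pmin(ca / length(a), cb / length(b)))
}

#' Distance-separation calibration experiment
#'
#' Checks that a distance metric can tell the true parameters apart from
#' prior draws: computes `n_rep` distances between independent replicate
#' reference datasets simulated at the true parameters (true-vs-true) and
#' `n_rep` distances between prior-predictive datasets and a fixed
#' true-parameter reference (prior-vs-true). Well-separated distributions
#' (small overlap coefficient) mean the ABC tolerance can be placed in the
#' true-vs-true range with few mistaken acceptances; the median true-vs-true
#' distance is the suggested final tolerance.
#'
#' @param params_true true model parameters.
#' @param prior `prior_spec` for the prior arm.
#' @param metric distance metric name (see [snapshot_distance()]).
#' @param n_rep replicates per arm (>= 2).
#' @param n_cells cells per dataset.
#' @param T,t_end,x0 snapshot scheme (defaults mirror the reference
#'   generator).
#' @param seed master seed.
#' @param options metric options.
#' @return object of class `separation_result` with both distance lists,
#'   the overlap coefficient and the suggested tolerance.
#' @export
separation_experiment <- function(params_true = model_parameters(), prior = prior_spec(params_true),
                                  metric = "mmd", n_rep = 50, n_cells = 100,
                                  T = 10, t_end = 800, x0 = c(0, 0, 0, 2),
                                  seed = 1, options = list()) {
  if (n_rep < 2) stop("n_rep must be >= 2")
  grid <- seq_len(T) * (t_end / T)
  sim <- function(theta_full, s)
    simulate_snapshots(theta_full, n_cells, grid, x0 = x0, seed = s,
                       stream = "separation")
  ref <- sim(params_true, child_seed(seed, "separation", 0))
  d_true <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    a <- sim(params_true, child_seed(seed, "separation", 2 * r))
    b <- sim(params_true, child_seed(seed, "separation", 2 * r + 1))
    d_true[r] <- snapshot_distance(a, b, metric = metric,
                                   options = options)$value
  }
  set.seed(child_seed(seed, "prior", 1))
  th <- sample_prior(prior, n_rep)
  d_prior <- numeric(n_rep)
  base <- unclass(as_model_parameters(params_true))
  for (r in seq_len(n_rep)) {
    p <- base
    p[colnames(th)] <- th[r, ]
    cand <- sim(validate_parameters(p),
                child_seed(seed, "separation", 2 * n_rep + 2 + r))
    d_prior[r] <- snapshot_distance(cand, ref, metric = metric,
                                    options = options)$value
  }
  structure(list(distances_true_vs_true = d_true,
                 distances_prior_vs_true = d_prior,
                 metric = metric, n_rep = n_rep,
                 overlap = overlap_coefficient(d_true, d_prior),
                 suggested_epsilon = median(d_true)),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf(
    "<%s separation: true-vs-true median %.4g, prior-vs-true median %.4g, overlap %.3f>\n",
    x$metric, median(x$distances_true_vs_true),
    median(x$distances_prior_vs_true), x$overlap))
  invisible(x)
}

#' Suggested final ABC tolerance from a separation experiment
#'
#' The median of the true-vs-true replicate distances: a tolerance at the
#' centre of the distance density attainable under the true parameters.
#'
#' @param x `separation_result`.
#' @return suggested epsilon.
#' @export
suggest_epsilon <- function(x) {
  stopifnot(inherits(x, "separation_result"))
  x$suggested_epsilon
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Logit-pluripotency statistic of a snapshot dataset
#'
#' K-means with 2 classes on the final-time `(Nanog, Gata6)` cells (or all
#' four species); the cluster with the higher Nanog centroid is the
#' pluripotent one, `p` its cell fraction, and the statistic is
#' `S = log(p / (1 - p))` with `p` clipped to `[1/(2n), 1 - 1/(2n)]` so S
#' stays finite. K-means uses a fixed internal seed and 10 restarts, and
#' clusters are identified by Nanog level, never by label index, so the
#' statistic is deterministic.
#'
#' @param data `snapshot_dataset` whose final time slice has >= 2 cells.
#' @param use_all_species cluster on all 4 species instead of
#'   `(Nanog, Gata6)`.
#' @return the logit-pluripotency statistic (scalar).
#' @export
pluripotency_statistic <- function(data, use_all_species = FALSE) {
  stopifnot(inherits(data, "snapshot_dataset"))
  T <- dim(data$values)[2]
  n <- dim(data$values)[3]
  if (n < 2) stop("final time slice needs at least 2 cells")
  M <- t(data$values[, T, , drop = TRUE])
  if (!use_all_species) M <- M[, c("Nanog", "Gata6"), drop = FALSE]
  nanog <- t(data$values[, T, , drop = TRUE])[, "Nanog"]
  if (nrow(unique(M)) < 2) {
    # degenerate ensemble: a single occupied state; pluripotent iff high
    # Nanog relative to Gata6
    p <- if (M[1, "Nanog"] >= M[1, ncol(M)]) 1 else 0
  } else {
    km <- with_local_seed(171717,
      kmeans(M, centers = 2, nstart = 10, iter.max = 50))
    high <- which.max(tapply(nanog, km$cluster, mean))
    p <- mean(km$cluster == as.integer(names(high)[1]))
  }
  p <- min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  log(p / (1 - p))
}

#' Posterior predictive check with the logit-pluripotency statistic
#'
#' Resamples `n_draws` particles by weight, simulates a dataset per
#' particle with the supplied simulator, computes the statistic for every
#' draw and for the reference, and reports the tail probability
#' `Pr(S(X) > S(D))` and the mean squared error of the draws around the
#' reference statistic.
#'
#' @param population `abc_population`.
#' @param reference reference `snapshot_dataset`.
#' @param simulator function `(theta, seed) -> snapshot_dataset` (use the
#'   one the ABC run used).
#' @param n_draws posterior predictive draws.
#' @param seed master seed.
#' @return object of class `ppc_result`: `S_reference`,
#'   `S_posterior_draws`, `tail_prob`, `mse`, `n_failed`.
#' @export
posterior_predictive_check <- function(population, reference, simulator,
                                       n_draws = 50, seed = 1) {
  stopifnot(inherits(population, "abc_population"))
  if (nrow(population$theta) < 1) stop("population is empty")
  S_ref <- pluripotency_statistic(reference)
  set.seed(child_seed(seed, "ppc", 0))
  idx <- sample.int(nrow(population$theta), n_draws, replace = TRUE,
                    prob = population$weights)
  S_draws <- rep(NA_real_, n_draws)
  n_failed <- 0L
  for (k in seq_len(n_draws)) {
    sim <- tryCatch(simulator(population$theta[idx[k], ],
                              child_seed(seed, "ppc", k)),
                    error = function(e) NULL)
    if (is.null(sim)) { n_failed <- n_failed + 1L; next }
    S_draws[k] <- pluripotency_statistic(sim)
  }
  S_draws <- S_draws[!is.na(S_draws)]
  # the statistic is discrete (p is a multiple of 1/n), so ties with the
  # reference are real; count them half (mid-p convention)
  structure(list(S_reference = S_ref, S_posterior_draws = S_draws,
                 tail_prob = mean(S_draws > S_ref) +
                   0.5 * mean(S_draws == S_ref),
                 mse = mean((S_draws - S_ref)^2),
                 n_failed = n_failed),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("<PPC: S(D) = %.3f, tail Pr(S(X) > S(D)) = %.3f, MSE = %.3f>\n",
              x$S_reference, x$tail_prob, x$mse))
  invisible(x)
}

#' Euclidean summary-statistic distance (baseline)
#'
#' The conventional summary-statistic ABC baseline: either the Euclidean
#' norm of the difference of stacked per-species, per-time-point first and
#' second moments (`"moments"`), or the absolute difference of the
#' logit-pluripotency statistics (`"logit_p"`).
#'
#' @param D1,D2 `snapshot_dataset`s of shared shape.
#' @param summary `"moments"` or `"logit_p"`.
#' @return nonnegative distance, symmetric in its arguments.
#' @export
euclidean_summary_distance <- function(D1, D2,
                                       summary = c("moments", "logit_p")) {
  summary <- match.arg(summary)
  stopifnot(inherits(D1, "snapshot_dataset"), inherits(D2, "snapshot_dataset"))
  if (!identical(dim(D1$values)[1:2], dim(D2$values)[1:2]))
    stop("datasets disagree on species/time shape")
  if (summary == "moments") {
    m1 <- c(apply(D1$values, c(1, 2), mean), apply(D1$values^2, c(1, 2), mean))
    m2 <- c(apply(D2$values, c(1, 2), mean), apply(D2$values^2, c(1, 2), mean))
    sqrt(sum((m1 - m2)^2))
  } else {
    abs(pluripotency_statistic(D1) - pluripotency_statistic(D2))
  }
}
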