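#' Weighted posterior covariance matrix
#'
#' Method-of-moments covariance of the particle cloud using the normalized
#' importance weights of the final population.
#'
#' @param samples n x p particle matrix.
#' @param weights particle weights (default equal); normalized internally.
#' @return p x p symmetric positive semidefinite matrix.
#' @export
posterior_covariance <- function(samples, weights = NULL) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 2) stop("need at least 2 samples for a covariance")
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("weights length must match sample count")
  w <- weights / sum(weights)
  mu <- colSums(samples * w)
  Xc <- sweep(samples, 2, mu)
  S <- crossprod(Xc * w, Xc)
  (S + t(S)) / 2
}

#' Per-parameter sensitivity scores from the posterior
#'
#' Eigendecomposes the posterior covariance `Sigma = Q Lambda Q^T` and
#' attributes to parameter k the fraction of total posterior variance it
#' carries, `s_k = sum_j q_{k,j}^2 lambda_j / sum_i lambda_i`
#' (algebraically `Sigma_kk / trace(Sigma)`); scores sum to 1. The index
#' convention is the one under which the scores partition 100% of the
#' posterior variance, which is what makes them interpretable as a
#' sensitivity spectrum. On the raw parameter scale a score partially
#' reflects parameter magnitude; with `standardize = TRUE` parameters are
#' first divided by their prior range, making scores unit-free.
#'
#' @param samples n x p particle matrix.
#' @param weights optional particle weights.
#' @param standardize divide each parameter by its prior range first.
#' @param prior `prior_spec`, required when `standardize = TRUE`.
#' @return named score vector summing to 1.
#' @export
sensitivity_scores <- function(samples, weights = NULL, standardize = FALSE,
                               prior = NULL) {
  samples <- as.matrix(samples)
  if (standardize) {
    if (is.null(prior)) stop("standardize = TRUE requires a prior")
    rng <- prior_range(prior)[colnames(samples)]
    samples <- sweep(samples, 2, rng, "/")
  }
  S <- posterior_covariance(samples, weights)
  if (!all(is.finite(S))) stop("non-finite covariance")
  eig <- eigen(S, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  Q <- eig$vectors
  s <- colSums(t(Q^2) * lam) / sum(lam)
  setNames(s, colnames(samples))
}

#' Classify parameters as sloppy or stiff
#'
#' A parameter is "sloppy" when it explains strictly more than `threshold`
#' (default 1%) of the total posterior variance, and "stiff" otherwise.
#' Sloppy parameters are inferred with higher uncertainty; stiff ones are
#' tightly constrained by the data.
#'
#' @param s sensitivity scores in `[0, 1]`.
#' @param threshold variance-share threshold (default 0.01).
#' @return named character vector of labels.
#' @export
classify_sloppy <- function(s, threshold = 0.01) {
  if (any(s < 0 | s > 1)) stop("scores must lie in [0, 1]")
  setNames(ifelse(s > threshold, "sloppy", "stiff"), names(s))
}

#' Full sensitivity report for a posterior population
#'
#' @param population `abc_population` (or an n x p matrix).
#' @param weights optional weights when a matrix is supplied.
#' @param standardize,prior see [sensitivity_scores()].
#' @param threshold sloppiness threshold.
#' @return object of class `sensitivity_report`: covariance, eigenvalues,
#'   eigenvectors, scores, labels and a tidy `table`.
#' @export
sensitivity_report <- function(population, weights = NULL,
                               standardize = FALSE, prior = NULL,
                               threshold = 0.01) {
  if (inherits(population, "abc_population")) {
    samples <- population$theta
    weights <- population$weights
    if (is.null(prior)) prior <- population$prior
  } else samples <- as.matrix(population)
  S <- posterior_covariance(samples, weights)
  eig <- eigen(S, symmetric = TRUE)
  s <- sensitivity_scores(samples, weights, standardize = standardize,
                          prior = prior)
  lab <- classify_sloppy(s, threshold)
  structure(list(covariance = S, eigenvalues = eig$values,
                 eigenvectors = eig$vectors, scores = s, labels = lab,
                 threshold = threshold, standardized = standardize,
                 table = data.frame(parameter = names(s), score = unname(s),
                                    percent = 100 * unname(s),
                                    label = unname(lab))),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity report: %d parameters, %d sloppy at %.3g%% threshold%s>\n",
              length(x$scores), sum(x$labels == "sloppy"), 100 * x$threshold,
              if (x$standardized) ", standardized scale" else ""))
  print(x$table[order(-x$table$score), ], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a sensitivity report as delimited text
#' @param report `sensitivity_report`.
#' @param path output path.
#' @export
write_sensitivity_report <- function(report, path) {
  write.csv(report$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pairwise posterior summary for corner plots
#'
#' Spearman rank-correlation matrix of the particles plus per-parameter
#' histogram bin data, the ingredients of the usual pairwise posterior
#' plot.
#'
#' @param samples n x p particle matrix (n >= 10).
#' @param bins histogram bin count per parameter.
#' @return list with `spearman` (p x p) and `histograms` (named list of
#'   `breaks` / `counts`).
#' @export
pairwise_posterior_summary <- function(samples, bins = 20) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 10) stop("need at least 10 samples")
  rho <- cor(samples, method = "spearman")
  hists <- lapply(seq_len(ncol(samples)), function(k) {
    h <- hist(samples[, k], breaks = bins, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  })
  names(hists) <- colnames(samples)
  list(spearman = rho, histograms = hists)
}

#' @importFrom graphics hist
NULL
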