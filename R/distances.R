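as_sample_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("sample matrix must be finite")
  X
}

#' Median-heuristic kernel bandwidth
#'
#' Half the median of all pairwise Euclidean distances over the pooled
#' sample, the standard median heuristic for Gaussian-kernel MMD.
#'
#' @param X,Y sample matrices (rows = points).
#' @return bandwidth sigma.
#' @export
median_heuristic <- function(X, Y) {
  Z <- rbind(as_sample_matrix(X), as_sample_matrix(Y))
  if (nrow(Z) > 128) {
    # deterministic stride subsample: the median of pairwise distances is
    # estimated to ample accuracy for a kernel bandwidth from ~100 points
    Z <- Z[seq(1, nrow(Z), length.out = 128), , drop = FALSE]
  }
  med <- median_pairwise_cpp(Z)
  if (med <= 0) {
    # degenerate pool (many duplicated points): fall back to the smallest
    # positive pairwise distance, if any
    d <- stats::dist(unique(Z, MARGIN = 1))
    d <- d[d > 0]
    if (!length(d)) return(0)
    med <- min(d)
  }
  med / 2
}

#' Unbiased squared maximum mean discrepancy
#'
#' The unbiased U-statistic estimator of MMD^2 between the empirical
#' distributions of `X` and `Y` under the Gaussian kernel
#' `k(x, y) = exp(-||x - y||^2 / (2 sigma^2))`. Being unbiased, the
#' estimate may be slightly negative when the distributions coincide.
#'
#' @param X,Y sample matrices with at least 2 rows each.
#' @param sigma kernel bandwidth, or `"median"` for the median heuristic on
#'   the pooled sample.
#' @return real MMD^2 estimate (symmetric in `X`, `Y`).
#' @export
#' @examples
#' X <- matrix(rnorm(100), ncol = 2)
#' mmd2_unbiased(X, X, sigma = 1)  # exactly 0
mmd2_unbiased <- function(X, Y, sigma = "median") {
  X <- as_sample_matrix(X); Y <- as_sample_matrix(Y)
  if (nrow(X) < 2 || nrow(Y) < 2)
    stop("unbiased MMD^2 needs at least 2 points per sample")
  if (ncol(X) != ncol(Y)) stop("X and Y must share dimensionality")
  if (identical(sigma, "median")) {
    sigma <- median_heuristic(X, Y)
    if (sigma <= 0) return(0)  # all points identical in both samples
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  mmd2_unbiased_cpp(X, Y, sigma)
}

#' Sinkhorn divergence (debiased entropic optimal transport)
#'
#' `S_eps(X, Y) = OT_eps(X, Y) - (OT_eps(X, X) + OT_eps(Y, Y)) / 2` with
#' squared Euclidean ground cost, uniform weights and entropic
#' regularization `eps`, computed by stabilized Sinkhorn scaling. The
#' debiasing removes the entropic blur so that `S_eps(X, X) = 0` and, for
#' small `eps`, `S_eps` approximates the squared 2-Wasserstein distance.
#'
#' @param X,Y sample matrices.
#' @param epsilon entropic regularization (> 0), or `"auto"` for
#'   `0.05 * median pairwise squared distance` of the pooled sample,
#'   floored at 1/100 of the squared pooled range so the scaling iteration
#'   stays well conditioned when most points coincide.
#' @param max_iter maximum Sinkhorn iterations per transport problem.
#' @param tol convergence tolerance (relative marginal violation).
#' @return nonnegative divergence (clamped at 0 against tiny negative
#'   round-off).
#' @export
sinkhorn_divergence <- function(X, Y, epsilon = "auto", max_iter = 20000,
                                tol = 1e-5) {
  X <- as_sample_matrix(X); Y <- as_sample_matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must share dimensionality")
  if (isTRUE(all.equal(X, Y, tolerance = 0))) return(0)  # debiasing cancels
  if (identical(epsilon, "auto")) {
    Z <- rbind(X, Y)
    med <- median_pairwise_cpp(Z)
    range_sq <- sum((apply(Z, 2, max) - apply(Z, 2, min))^2)
    epsilon <- max(0.05 * med^2, range_sq / 100)
    if (epsilon <= 0) return(0)  # fully degenerate pooled sample
  }
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be positive")
  check <- function(r) {
    if (!r$converged)
      stop(sprintf(
        "sinkhorn did not converge in %d iterations (residual %.3g)",
        max_iter, r$residual))
    r$cost
  }
  # collapse duplicated points to weighted atoms: an identical transport
  # problem, but much smaller and better conditioned for snapshot data
  # whose early time slices occupy only a handful of integer states
  ax <- collapse_atoms(X)
  ay <- collapse_atoms(Y)
  # cross term by annealed log-domain scaling; debias terms by the
  # symmetric fixed-point iteration (much faster on OT(X, X))
  xy <- check(sinkhorn_cost_cpp(ax$points, ax$weights, ay$points, ay$weights,
                                epsilon, as.integer(max_iter), tol))
  xx <- check(sinkhorn_sym_cost_cpp(ax$points, ax$weights, epsilon,
                                    as.integer(max_iter), tol))
  yy <- check(sinkhorn_sym_cost_cpp(ay$points, ay$weights, epsilon,
                                    as.integer(max_iter), tol))
  max(xy - 0.5 * xx - 0.5 * yy, 0)
}

collapse_atoms <- function(X) {
  key <- do.call(paste, c(lapply(seq_len(ncol(X)), function(k) X[, k]),
                          sep = "\r"))
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(points = X[first, , drop = FALSE], weights = w / nrow(X))
}

#' Per-dimension Silverman bandwidths
#'
#' Silverman's rule for a d-dimensional Gaussian product KDE:
#' `h_k = sd_k * (4 / ((d + 2) n))^(1 / (d + 4))`. A small floor replaces
#' zero bandwidths from degenerate (constant) dimensions.
#'
#' @param X sample matrix.
#' @return bandwidth per column.
#' @export
silverman_bandwidth <- function(X) {
  X <- as_sample_matrix(X)
  n <- nrow(X); d <- ncol(X)
  h <- apply(X, 2, sd) * (4 / ((d + 2) * n))^(1 / (d + 4))
  floor_h <- 1e-8 * pmax(1, abs(colMeans(X)))
  if (any(h <= 0)) {
    warning("degenerate sample dimension(s); bandwidth floor applied")
    h <- pmax(h, floor_h)
  }
  h
}

#' Bhattacharyya distance between samples via kernel density estimation
#'
#' Fits Gaussian product KDEs with Silverman-rule bandwidths to each sample
#' and estimates the Bhattacharyya coefficient `rho = integral sqrt(p q)`
#' by the mixture-form Monte Carlo estimator evaluated over the pooled
#' sample, `rho = E_[z ~ m] sqrt(p(z) q(z)) / m(z)` with mixture density
#' `m = (n p + m q) / (n + m)`. Every term is bounded by 1, so the
#' estimate stays stable even when the two supports barely overlap (where
#' plain importance-ratio estimators explode). Returns `-log(rho)`,
#' floored so the distance stays finite and nonnegative.
#'
#' @param X,Y sample matrices with at least 2 rows each.
#' @param rho_floor lower floor on the estimated coefficient.
#' @return nonnegative Bhattacharyya distance, symmetric in `X`, `Y`.
#' @export
bhattacharyya_kde <- function(X, Y, rho_floor = 1e-12) {
  X <- as_sample_matrix(X); Y <- as_sample_matrix(Y)
  if (nrow(X) < 2 || nrow(Y) < 2)
    stop("bhattacharyya_kde needs at least 2 points per sample")
  if (ncol(X) != ncol(Y)) stop("X and Y must share dimensionality")
  hx <- silverman_bandwidth(X)
  hy <- silverman_bandwidth(Y)
  rho <- bhatt_rho_cpp(X, Y, hx, hy)
  max(-log(max(rho, rho_floor)), 0)
}

#' Distance between two snapshot datasets
#'
#' The ABC distance: the chosen per-time-point metric applied to the
#' (cells x species) slices and summed over all time points,
#' `d = sum_t d(D1[, t, ], D2[, t, ])`. For MMD the per-slice value is the
#' unbiased MMD^2 floored at 0, so the sum stays nonnegative. The
#' `euclidean_summary` metric is the whole-dataset baseline of
#' [euclidean_summary_distance()].
#'
#' @param D1,D2 `snapshot_dataset`s sharing species order and time grid
#'   length.
#' @param metric one of `"mmd"`, `"sinkhorn"`, `"bhattacharyya"`,
#'   `"euclidean_summary"`.
#' @param options named list of metric options (`sigma`, `epsilon`,
#'   `max_iter`, `tol`, `summary`, `standardize`, `time_aggregate`).
#'   `time_aggregate = "mean"` reports the per-time-point average instead
#'   of the sum (a unit change only: both orderings of candidate datasets
#'   are identical). `standardize` divides
#'   every species by its pooled standard deviation before the comparison;
#'   it defaults to TRUE for the transport metric (whose squared-Euclidean
#'   ground cost is scale-sensitive) and FALSE otherwise.
#' @return object of class `distance_result`; use `$value` for the number.
#' @export
#' @examples
#' ref <- generate_reference(n_cells = 20, seed = 1)
#' snapshot_distance(ref, ref, metric = "mmd")$value
snapshot_distance <- function(D1, D2,
                              metric = c("mmd", "sinkhorn", "bhattacharyya",
                                         "euclidean_summary"),
                              options = list()) {
  metric <- match.arg(metric)
  stopifnot(inherits(D1, "snapshot_dataset"), inherits(D2, "snapshot_dataset"))
  if (!identical(D1$species, D2$species))
    stop("datasets disagree on species order")
  T1 <- dim(D1$values)[2]; T2 <- dim(D2$values)[2]
  if (T1 != T2) stop("datasets disagree on number of time points")
  opt <- options
  standardize <- if (is.null(opt$standardize)) metric == "sinkhorn"
                 else isTRUE(opt$standardize)
  if (standardize) {
    # symmetric per-species scaling by the pooled standard deviation: puts
    # all four factors on a common unit scale before the squared-Euclidean
    # ground cost (MMD and Bhattacharyya adapt their own bandwidths, so
    # only the transport metric needs this)
    sds <- apply(array(c(D1$values, D2$values), c(4, T1,
                 dim(D1$values)[3] + dim(D2$values)[3])), 1, sd)
    sds <- pmax(sds, 1e-12)
    D1$values <- D1$values / sds
    D2$values <- D2$values / sds
    opt$species_sd <- sds
  }
  if (metric == "euclidean_summary") {
    summary <- if (is.null(opt$summary)) "moments" else opt$summary
    val <- euclidean_summary_distance(D1, D2, summary = summary)
    per_t <- NULL
  } else if (metric == "mmd" && is.null(opt$sigma) &&
             dim(D1$values)[3] >= 2 && dim(D2$values)[3] >= 2) {
    # compiled fast path: all slices, median heuristic and flooring in one
    # call (identical contract to the per-slice route below)
    per_t <- as.numeric(snapshot_mmd_cpp(D1$values, D2$values, T1,
                                         dim(D1$values)[3],
                                         dim(D2$values)[3]))
    agg <- if (is.null(opt$time_aggregate)) "sum" else opt$time_aggregate
    val <- switch(agg, sum = sum(per_t), mean = mean(per_t),
                  stop("time_aggregate must be 'sum' or 'mean'"))
  } else {
    per_t <- vapply(seq_len(T1), function(t) {
      A <- t(D1$values[, t, , drop = TRUE])
      B <- t(D2$values[, t, , drop = TRUE])
      switch(metric,
        mmd = max(mmd2_unbiased(A, B,
                sigma = if (is.null(opt$sigma)) "median" else opt$sigma), 0),
        sinkhorn = {
          if (!is.null(opt$quantize) && opt$quantize > 0) {
            # merge cells into atoms on a lattice of the given resolution
            # (in standardized units): a numerical-resolution knob that
            # shrinks the transport problem at negligible cost to the value
            A <- round(A / opt$quantize) * opt$quantize
            B <- round(B / opt$quantize) * opt$quantize
          }
          sinkhorn_divergence(A, B,
                epsilon = if (is.null(opt$epsilon)) "auto" else opt$epsilon,
                max_iter = if (is.null(opt$max_iter)) 20000 else opt$max_iter,
                tol = if (is.null(opt$tol)) 1e-5 else opt$tol)
        },
        bhattacharyya = bhattacharyya_kde(A, B))
    }, numeric(1))
    agg <- if (is.null(opt$time_aggregate)) "sum" else opt$time_aggregate
    val <- switch(agg, sum = sum(per_t), mean = mean(per_t),
                  stop("time_aggregate must be 'sum' or 'mean'"))
  }
  structure(list(value = val, metric = metric, options = opt,
                 per_time = per_t),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<%s snapshot distance: %.6g>\n", x$metric, x$value))
  invisible(x)
}

#' Distance function factory for ABC
#'
#' Returns `function(candidate, reference) -> numeric` wrapping
#' [snapshot_distance()], the form consumed by [abc_rejection()] and
#' [abc_smc()].
#'
#' @inheritParams snapshot_distance
#' @export
snapshot_distance_fun <- function(metric = "mmd", options = list()) {
  force(metric); force(options)
  function(candidate, reference)
    snapshot_distance(candidate, reference, metric = metric,
                      options = options)$value
}
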