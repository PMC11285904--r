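#' Exact stochastic simulation of one cell (Gillespie direct method)
#'
#' Samples one trajectory of the jump process defined by the chemical master
#' equation of the network, recording every reaction event. The final
#' recorded time is `t_end` with the state held from the last event; a state
#' with zero total propensity freezes (valid, not an error).
#'
#' @param params model parameters.
#' @param x0 integer-valued nonnegative initial state `(N, O, F, G)`.
#' @param t_end simulation horizon (> 0).
#' @param seed integer seed; the same seed reproduces the trajectory
#'   bitwise.
#' @param max_events safety cap on the number of events.
#' @return object of class `trajectory`: list with `times` (event times,
#'   starting at 0, ending at `t_end`) and `states` (4 x K matrix, one
#'   column per recorded time).
#' @export
#' @examples
#' tr <- gillespie_trajectory(model_parameters(), c(0, 1, 0, 0), 10, seed = 1)
#' dim(tr$states)
gillespie_trajectory <- function(params, x0, t_end, seed,
                                 max_events = 1e7) {
  params <- as_model_parameters(params)
  x0 <- check_state(x0)
  if (any(x0 != round(x0)))
    stop("gillespie requires an integer-valued initial state")
  if (t_end <= 0) stop("t_end must be positive")
  out <- gillespie_path_cpp(as.numeric(params), x0, t_end,
                            as.double(seed), max_events)
  rownames(out$states) <- SPECIES
  structure(list(times = out$times, states = out$states,
                 kind = "gillespie"), class = "trajectory")
}

#' Approximate stochastic simulation via the chemical Langevin equation
#'
#' Euler-Maruyama discretization of the diffusion approximation
#' `dx = S a(x) dt + sum_i nu_i sqrt(a_i(x)) dW_i`: the propensities act as
#' the strength of multiplicative noise. States are clipped at 0 after
#' every step to preserve nonnegativity.
#'
#' @inheritParams gillespie_trajectory
#' @param dt time step (> 0).
#' @param noise_scale multiplier on the noise term; 0 gives the explicit
#'   Euler ODE solution.
#' @return `trajectory` object with states on the regular step grid.
#' @export
cle_trajectory <- function(params, x0, t_end, dt, seed, noise_scale = 1) {
  params <- as_model_parameters(params)
  x0 <- check_state(x0)
  if (dt <= 0) stop("dt must be positive")
  if (t_end <= 0) stop("t_end must be positive")
  out <- cle_path_cpp(as.numeric(params), x0, t_end, dt,
                      as.double(seed), noise_scale)
  rownames(out$states) <- SPECIES
  structure(list(times = out$times, states = out$states, kind = "cle"),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<%s trajectory: %d recorded times over [0, %g]>\n",
              x$kind, length(x$times), max(x$times)))
  invisible(x)
}

state_at <- function(trajectory, t) {
  # left-continuous hold: state of the last recorded time <= t
  idx <- findInterval(t, trajectory$times)
  if (any(idx < 1)) stop("requested time before trajectory start")
  trajectory$states[, idx, drop = FALSE]
}

new_snapshot_dataset <- function(values, time_grid, meta = list()) {
  stopifnot(length(dim(values)) == 3, dim(values)[1] == 4,
            dim(values)[2] == length(time_grid))
  dimnames(values) <- list(SPECIES, NULL, NULL)
  structure(list(values = values, time_grid = as.numeric(time_grid),
                 species = SPECIES, meta = meta),
            class = "snapshot_dataset")
}

#' @export
print.snapshot_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<snapshot dataset: %d species x %d time points x %d cells>\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Sample trajectories on a common snapshot time grid
#'
#' Builds the species x time x cell tensor used as the unit of comparison in
#' ABC. Gillespie trajectories are piecewise constant, so entry `(s, t, i)`
#' is the state of trajectory `i` at the last event time at or before
#' `time_grid[t]` (left-continuous hold); the same rule applies to the CLE
#' step grid.
#'
#' @param trajectories list of `trajectory` objects.
#' @param time_grid sample times; every trajectory must cover `max(time_grid)`.
#' @return a `snapshot_dataset`.
#' @export
sample_snapshots <- function(trajectories, time_grid) {
  time_grid <- as.numeric(time_grid)
  n <- length(trajectories)
  vals <- array(NA_real_, c(4, length(time_grid), n))
  for (i in seq_len(n)) {
    tr <- trajectories[[i]]
    if (max(tr$times) < max(time_grid))
      stop(sprintf("trajectory %d ends at %g, before max(time_grid) = %g",
                   i, max(tr$times), max(time_grid)))
    vals[, , i] <- state_at(tr, time_grid)
  }
  new_snapshot_dataset(vals, time_grid)
}

#' Simulate a snapshot dataset at given parameters
#'
#' Runs `n_cells` independent Gillespie trajectories (per-cell child seeds
#' derived from the master seed) and samples them on `time_grid`. This is
#' both the reference-data generator and the forward simulator used for ABC
#' candidates.
#'
#' @param params model parameters.
#' @param n_cells number of cells (trajectories).
#' @param time_grid snapshot times.
#' @param x0 initial state of every cell.
#' @param seed master seed.
#' @param stream seed stream name (see [child_seed()]).
#' @return a `snapshot_dataset` with full metadata.
#' @export
simulate_snapshots <- function(params, n_cells, time_grid,
                               x0 = c(0, 0, 0, 2), seed = 1,
                               stream = "reference") {
  params <- as_model_parameters(params)
  x0 <- check_state(x0)
  time_grid <- sort(as.numeric(time_grid))
  if (n_cells < 1) stop("n_cells must be >= 1")
  vals <- array(NA_real_, c(4, length(time_grid), n_cells))
  pv <- as.numeric(params)
  for (i in seq_len(n_cells)) {
    s <- child_seed(seed, stream, i)
    vals[, , i] <- gillespie_grid_cpp(pv, x0, time_grid, as.double(s))
  }
  new_snapshot_dataset(vals, time_grid,
                       meta = list(params = params, n_cells = n_cells,
                                   x0 = x0, seed = seed, stream = stream,
                                   LIF = params[["LIF"]]))
}

#' Generate reference snapshot data at the true parameters
#'
#' Emulates the study's reference scheme: `n_cells` Gillespie trajectories
#' of the four factors, sampled at `T` evenly spaced time points
#' `k * t_end / T`, k = 1..T (t = 0 is excluded since the initial state is
#' fixed and carries no parameter information). Defaults give the
#' 4 x 10 x 300 reference tensor at LIF = 50.
#'
#' @param params model parameters (defaults: published reference values).
#' @param n_cells number of cells (default 300).
#' @param T number of snapshot times (default 10).
#' @param t_end simulation horizon (default 800 = 8/gamma, long enough for
#'   nearly every cell to commit to one of the two fates).
#' @param x0 initial state (default `(0, 0, 0, 2)`: an undifferentiated
#'   start with a small Gata6 seed, so the fate decision is a genuinely
#'   stochastic race with both attractors reachable).
#' @param seed master seed.
#' @return a `snapshot_dataset`.
#' @export
#' @examples
#' ref <- generate_reference(n_cells = 5, seed = 1)
#' dim(ref$values)
generate_reference <- function(params = model_parameters(), n_cells = 300,
                               T = 10, t_end = 800, x0 = c(0, 0, 0, 2),
                               seed = 1) {
  if (T < 1) stop("T must be >= 1")
  if (n_cells < 1) stop("n_cells must be >= 1")
  grid <- seq_len(T) * (t_end / T)
  ds <- simulate_snapshots(params, n_cells, grid, x0 = x0, seed = seed,
                           stream = "reference")
  ds$meta$t_end <- t_end
  ds$meta$T <- T
  ds
}

#' Forward-simulator factory for ABC on the stem cell model
#'
#' Returns a function `(theta, seed) -> snapshot_dataset` that merges the
#' inferred parameter subset `theta` into `base_params` and simulates a
#' candidate dataset matching the reference sampling scheme.
#'
#' @param base_params full parameter vector supplying the fixed entries
#'   (e.g. LIF).
#' @param n_cells cells per candidate dataset.
#' @param time_grid snapshot times (use the reference's grid).
#' @param x0 initial state.
#' @return function of `(theta, seed)`.
#' @export
stem_simulator <- function(base_params = model_parameters(), n_cells = 300,
                           time_grid = seq_len(10) * 80, x0 = c(0, 0, 0, 2)) {
  base_params <- as_model_parameters(base_params)
  force(n_cells); force(time_grid); force(x0)
  function(theta, seed) {
    p <- unclass(base_params)
    p[names(theta)] <- as.numeric(theta)
    simulate_snapshots(validate_parameters(p), n_cells, time_grid, x0 = x0,
                       seed = seed, stream = "candidate")
  }
}

final_slice <- function(data, dims = c("Nanog", "Gata6")) {
  # n x length(dims) matrix of the final-time snapshot
  T <- dim(data$values)[2]
  t(data$values[dims, T, , drop = TRUE])
}
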