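default_config <- function() {
  list(
    parameters = as.list(unclass(model_parameters())),
    prior = list(infer = KINETIC_PARAMS, lower_factor = 0.1,
                 upper_factor = 10),
    simulation = list(n_cells = 300L, T = 10L, t_end = 800,
                      x0 = c(0, 0, 0, 2)),
    metric = list(name = "mmd", options = list()),
    abc = list(N = 100L, quantile_alpha = 0.3, epsilon_target = 0.06,
               max_sims = 1e7),
    seed = 1L,
    output_dir = "."
  )
}

check_scalar_num <- function(x, key, positive = FALSE) {
  x <- suppressWarnings(as.numeric(x))
  if (length(x) != 1 || is.na(x))
    stop(sprintf("config key '%s' must be a single number", key))
  if (positive && x <= 0)
    stop(sprintf("config key '%s' must be positive", key))
  x
}

#' Load / save a pipeline run configuration
#'
#' Structured-text (YAML) configuration covering model parameters, prior,
#' simulation scheme, metric, ABC settings, master seed and output
#' directory. Missing keys take the defaults (reference parameters,
#' LIF = 50, 300 cells, 10 time points, 30% quantile schedule, simulation
#' cap 1e7); unknown keys are rejected. Numbers are written at full double
#' precision, so a save/load round trip is exact.
#'
#' @param path config file path.
#' @return a validated config list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

#' @rdname load_config
#' @param cfg config list (possibly partial; validated and completed).
#' @export
save_config <- function(cfg, path) {
  cfg <- as_run_config(cfg)
  fmt <- function(x) {
    if (is.list(x)) lapply(x, fmt)
    else if (is.double(x)) sprintf("%.17g", x)
    else x
  }
  yaml::write_yaml(fmt(unclass(cfg)), path)
  invisible(path)
}

#' @rdname load_config
#' @export
as_run_config <- function(cfg) {
  if (inherits(cfg, "run_config")) return(cfg)
  def <- default_config()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in c("parameters", "prior", "simulation", "metric", "abc")) {
    if (is.null(cfg[[sec]])) next
    bad <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
    if (length(bad))
      stop(sprintf("unknown config key(s) under '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  out <- utils::modifyList(def, cfg)
  out$parameters <- as.list(unclass(as_model_parameters(out$parameters)))
  out$simulation$n_cells <- check_scalar_num(out$simulation$n_cells,
                                             "simulation.n_cells", TRUE)
  out$simulation$T <- check_scalar_num(out$simulation$T, "simulation.T", TRUE)
  out$simulation$t_end <- check_scalar_num(out$simulation$t_end,
                                           "simulation.t_end", TRUE)
  out$simulation$x0 <- check_state(as.numeric(out$simulation$x0))
  if (!out$metric$name %in% c("mmd", "sinkhorn", "bhattacharyya",
                              "euclidean_summary"))
    stop("config key 'metric.name' must be one of mmd, sinkhorn, ",
         "bhattacharyya, euclidean_summary")
  out$abc$N <- check_scalar_num(out$abc$N, "abc.N", TRUE)
  out$abc$quantile_alpha <- check_scalar_num(out$abc$quantile_alpha,
                                             "abc.quantile_alpha", TRUE)
  if (out$abc$quantile_alpha >= 1)
    stop("config key 'abc.quantile_alpha' must be in (0, 1)")
  out$abc$epsilon_target <- check_scalar_num(out$abc$epsilon_target,
                                             "abc.epsilon_target", TRUE)
  out$abc$max_sims <- check_scalar_num(out$abc$max_sims, "abc.max_sims", TRUE)
  out$seed <- as.integer(check_scalar_num(out$seed, "seed"))
  structure(out, class = "run_config")
}

#' Write / read a snapshot dataset as long-format delimited text
#'
#' Columns `cell_id, time_index, time, species, value` plus a YAML metadata
#' sidecar (`<path>.meta.yaml`) carrying the generating parameters and
#' seed. Values are written at full double precision, so the round trip is
#' bit-exact; files with arbitrary species row order are read back into the
#' canonical (Nanog, Oct4Sox2, Fgf4, Gata6) order.
#'
#' @param dataset a `snapshot_dataset`.
#' @param path CSV file path.
#' @return `read_snapshot` returns the `snapshot_dataset`.
#' @export
write_snapshot <- function(dataset, path) {
  stopifnot(inherits(dataset, "snapshot_dataset"))
  d <- dim(dataset$values)
  df <- data.frame(
    cell_id = rep(seq_len(d[3]), each = d[1] * d[2]),
    time_index = rep(rep(seq_len(d[2]), each = d[1]), d[3]),
    time = rep(rep(dataset$time_grid, each = d[1]), d[3]),
    species = rep(dataset$species, d[2] * d[3]),
    value = sprintf("%.17g", as.vector(dataset$values)))
  df$time <- sprintf("%.17g", df$time)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- dataset$meta
  meta_out <- list(
    species = dataset$species,
    time_grid = sprintf("%.17g", dataset$time_grid),
    n_cells = d[3])
  if (!is.null(meta$params))
    meta_out$params <- as.list(setNames(sprintf("%.17g",
                                                as.numeric(meta$params)),
                                        names(meta$params)))
  for (k in c("seed", "stream", "LIF", "t_end", "T"))
    if (!is.null(meta[[k]])) meta_out[[k]] <- meta[[k]]
  yaml::write_yaml(meta_out, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  df <- read.csv(path, colClasses = c(cell_id = "integer",
                                      time_index = "integer",
                                      time = "character",
                                      species = "character",
                                      value = "character"))
  need <- c("cell_id", "time_index", "time", "species", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("snapshot file missing column(s): ", paste(miss, collapse = ", "))
  bad_sp <- setdiff(unique(df$species), SPECIES)
  if (length(bad_sp))
    stop("unknown species in snapshot file: ", paste(bad_sp, collapse = ", "))
  df$value_num <- as.numeric(df$value)
  if (anyNA(df$value_num)) {
    bad <- which(is.na(df$value_num))[1]
    stop(sprintf("malformed value at data row %d of %s", bad, path))
  }
  T <- max(df$time_index); n <- max(df$cell_id)
  grid_df <- unique(df[, c("time_index", "time")])
  grid <- as.numeric(grid_df$time[order(grid_df$time_index)])
  vals <- array(NA_real_, c(4, T, n))
  si <- match(df$species, SPECIES)
  vals[cbind(si, df$time_index, df$cell_id)] <- df$value_num
  if (anyNA(vals)) stop("incomplete snapshot file: missing entries")
  meta <- list()
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    m <- yaml::read_yaml(meta_path)
    if (!is.null(m$params))
      meta$params <- as_model_parameters(lapply(m$params, as.numeric))
    for (k in c("seed", "stream", "LIF", "t_end", "T"))
      if (!is.null(m[[k]])) meta[[k]] <- m[[k]]
  }
  new_snapshot_dataset(vals, grid, meta)
}

#' Write a machine-readable run manifest
#'
#' Records the fully resolved configuration, package version and seeds next
#' to a run's outputs so any result can be regenerated.
#'
#' @param cfg `run_config` (or coercible).
#' @param path output path (YAML).
#' @param extra optional named list of extra fields (e.g. simulation
#'   counts).
#' @export
write_run_manifest <- function(cfg, path, extra = list()) {
  cfg <- as_run_config(cfg)
  m <- c(list(package = "abcland",
              version = as.character(packageVersion("abcland")),
              config = unclass(cfg)), extra)
  yaml::write_yaml(m, path)
  invisible(path)
}

#' Export an ABC population as structured text
#'
#' One CSV per generation: particles, weights and realized distances, with
#' the tolerance and generation index in a header comment line.
#'
#' @param population `abc_population`.
#' @param path output path.
#' @export
write_population <- function(population, path) {
  stopifnot(inherits(population, "abc_population"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# generation %d tolerance %.17g n_sims %d status %s",
                     population$generation, population$tolerance,
                     population$n_sims, population$status), con)
  df <- as.data.frame(population$theta)
  df$weight <- population$weights
  df$distance <- population$distances
  write.csv(format(df, digits = 17), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
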