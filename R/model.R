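#' Kinetic parameters of the four-gene differentiation network
#'
#' Constructs the full parameter set of the stem cell differentiation model:
#' sixteen nonnegative kinetic constants plus the external signals LIF
#' (leukaemia inhibitory factor, sustaining pluripotency), the inhibitor
#' level I3 and the reprogramming rate alpha. Defaults are the published
#' reference values of the Chickarmane-type network with LIF = 50 and
#' I3 = alpha = 0, under which the deterministic system is bistable: a
#' pluripotent (high Nanog / low Gata6) and a differentiated (low Nanog /
#' high Gata6) state coexist.
#'
#' @param ... named overrides of individual parameters, e.g. `LIF = 5`.
#' @return a named numeric vector of class `model_parameters`.
#' @export
#' @examples
#' p <- model_parameters()
#' p[["a0"]]
#' model_parameters(LIF = 200)[["LIF"]]
model_parameters <- function(...) {
  p <- c(a0 = 0.01, a1 = 1, b0 = 0.005, b1 = 0.005, b2 = 1, b3 = 1,
         c0 = 0.01, c1 = 0.4, c2 = 1, c3 = 0.1, c4 = 0.00135,
         e0 = 0.01, e1 = 1, e2 = 1, k0 = 0.005, gamma = 0.01,
         LIF = 50, I3 = 0, alpha = 0)
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("parameter overrides must be named")
    bad <- setdiff(names(ov), PARAM_NAMES)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- as.numeric(unlist(ov))
  }
  validate_parameters(p)
}

validate_parameters <- function(p) {
  p <- p[PARAM_NAMES]
  if (anyNA(p)) stop("parameters contain NA")
  if (any(p < 0)) stop("all model parameters must be nonnegative: ",
                       paste(PARAM_NAMES[p < 0], collapse = ", "))
  structure(p, class = "model_parameters")
}

#' Coerce a named vector or list to model parameters
#'
#' Missing entries are filled with the reference defaults.
#'
#' @param x named numeric vector or list.
#' @return `model_parameters` vector.
#' @export
as_model_parameters <- function(x) {
  if (inherits(x, "model_parameters")) return(validate_parameters(unclass(x)))
  x <- unlist(x)
  do.call(model_parameters, as.list(x))
}

check_state <- function(state) {
  state <- as.numeric(state)
  if (length(state) != 4) stop("state must have 4 components (N, O, F, G)")
  if (anyNA(state) || any(state < 0))
    stop("state components must be nonnegative")
  state
}

#' Deterministic right-hand side of the differentiation network
#'
#' Rate equations for the abundances of Nanog (N), Oct4-Sox2 (O), Fgf4 (F)
#' and Gata6 (G). Nanog production is a Hill-type function of its own level,
#' of Oct4-Sox2 (scaled by `k0`), of LIF, and of Fgf4-mediated repression
#' (`c3`), with an additional activation term `c4*O*G^2`; Oct4-Sox2 is
#' self-activating and repressed by Gata6; Fgf4 is driven by Oct4-Sox2; and
#' Gata6 is self-activating, driven by Oct4-Sox2 and repressed by Nanog.
#' Every species degrades linearly at rate `gamma`.
#'
#' @param state numeric state `(N, O, F, G)`, nonnegative.
#' @param params `model_parameters` (or coercible).
#' @return named 4-vector `(dN/dt, dO/dt, dF/dt, dG/dt)`.
#' @export
#' @examples
#' ode_rhs(c(0, 0, 0, 0), model_parameters())
ode_rhs <- function(state, params = model_parameters()) {
  state <- check_state(state)
  params <- as_model_parameters(params)
  a <- propensities_cpp(state, as.numeric(params))
  setNames(a[1:4] - a[5:8], SPECIES)
}

#' Reaction propensities of the jump-process interpretation
#'
#' Decomposes the rate equations into 8 elementary reactions: one production
#' and one linear degradation channel per species. Abundances are treated as
#' unit-scaled molecule counts (system size 1), so the printed rate laws are
#' used verbatim as propensities.
#'
#' @inheritParams ode_rhs
#' @return nonnegative 8-vector: productions of (N, O, F, G) then
#'   degradations `gamma * (N, O, F, G)`.
#' @export
propensities <- function(state, params = model_parameters()) {
  state <- check_state(state)
  params <- as_model_parameters(params)
  a <- propensities_cpp(state, as.numeric(params))
  names(a) <- c(paste0("prod_", SPECIES), paste0("deg_", SPECIES))
  a
}

#' Stoichiometric matrix of the reaction network
#'
#' @return 4 x 8 integer matrix: columns 1-4 are `+e_j` (production of
#'   species j), columns 5-8 are `-e_j` (degradation).
#' @export
stoichiometry <- function() {
  S <- cbind(diag(4L), -diag(4L))
  dimnames(S) <- list(SPECIES,
                      c(paste0("prod_", SPECIES), paste0("deg_", SPECIES)))
  S
}

#' Integrate the deterministic rate equations
#'
#' Thin wrapper around adaptive ODE integration (lsoda), used for oracle
#' checks of the stochastic simulators and for locating the deterministic
#' attractors.
#'
#' @param params model parameters.
#' @param x0 initial state.
#' @param times output time points (first entry is the initial time).
#' @param ... passed to [deSolve::ode()].
#' @return matrix with columns `time`, `Nanog`, `Oct4Sox2`, `Fgf4`, `Gata6`.
#' @export
integrate_ode <- function(params = model_parameters(), x0 = c(0, 0, 0, 0),
                          times = seq(0, 100, by = 1), ...) {
  params <- as_model_parameters(params)
  x0 <- check_state(x0)
  rhs <- function(t, y, parms) list(ode_rhs(pmax(y, 0), parms))
  out <- deSolve::ode(y = setNames(x0, SPECIES), times = times, func = rhs,
                      parms = params, ...)
  colnames(out) <- c("time", SPECIES)
  unclass(out)
}

#' Write / read model parameters as flat key-value text
#'
#' One `key: value` line per parameter, full double precision; the
#' write/read round trip is bit-exact.
#'
#' @param params model parameters.
#' @param path file path.
#' @return `read_parameters` returns a `model_parameters` vector.
#' @export
write_parameters <- function(params, path) {
  params <- as_model_parameters(params)
  writeLines(sprintf("%s: %.17g", names(params), as.numeric(params)), path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  do.call(model_parameters, as.list(setNames(vals, keys)))
}
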