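#' Built-in dynamical systems
#'
#' A `dynamical_system` bundles the local flow `f`, its Jacobian, the output
#' function `g` through which units interact (a constant linear selector
#' here), default parameters and an initial state on (or near) the
#' attractor.  Three systems are built in:
#'
#' * `rossler_system()` — the Roessler flow
#'   `f(x) = (-y - z, x + a*y, b + z*(x - c))` with output `g(x) = (0, y, 0)`
#'   (diffusive coupling through the y component).  Defaults
#'   `a = 0.1, b = 0.1, c = 18` give a chaotic attractor.
#' * `lorenz_system()` — the Lorenz flow
#'   `f(x) = (sigma*(y - x), x*(rho - z) - y, x*y - beta*z)` with output
#'   `g(x) = (x, 0, 0)`; defaults `sigma = 10, rho = 28, beta = 2` (chaotic).
#' * `linear_system()` — the one-dimensional analytic test case `f(x) = x`,
#'   `g(x) = x`, whose Master Stability Function is exactly
#'   `Lambda(nu) = 1 - nu`.
#'
#' @param a,b,c Roessler parameters.
#' @param sigma,rho,beta Lorenz parameters.
#' @return an object of class `dynamical_system`.
#' @name dynamical_systems
NULL

new_dynamical_system <- function(name, sysid, dimension, flow, flow_jacobian,
                                 output_jacobian, coupled_component, params,
                                 default_initial_state, var_func, var_event) {
  structure(list(name = name, sysid = sysid, dimension = dimension,
                 flow = flow, flow_jacobian = flow_jacobian,
                 output_jacobian = output_jacobian,
                 coupled_component = coupled_component,
                 params = params,
                 default_initial_state = default_initial_state,
                 var_func = var_func, var_event = var_event),
            class = "dynamical_system")
}

#' @rdname dynamical_systems
#' @export
rossler_system <- function(a = 0.1, b = 0.1, c = 18) {
  Jg <- diag(c(0, 1, 0))
  new_dynamical_system(
    name = "rossler", sysid = 1L, dimension = 3L,
    flow = function(x, p = c(a = a, b = b, c = c)) {
      c(-x[2] - x[3], x[1] + p[["a"]] * x[2], p[["b"]] + x[3] * (x[1] - p[["c"]]))
    },
    flow_jacobian = function(x, p = c(a = a, b = b, c = c)) {
      matrix(c(0, 1, x[3],
               -1, p[["a"]], 0,
               -1, 0, x[1] - p[["c"]]), 3L, 3L)
    },
    output_jacobian = Jg, coupled_component = 2L,
    params = c(a = a, b = b, c = c),
    default_initial_state = c(1, 1, 1),
    var_func = "derivs_rossler_var", var_event = "event_renorm3")
}

#' @rdname dynamical_systems
#' @export
lorenz_system <- function(sigma = 10, rho = 28, beta = 2) {
  Jg <- diag(c(1, 0, 0))
  new_dynamical_system(
    name = "lorenz", sysid = 2L, dimension = 3L,
    flow = function(x, p = c(sigma = sigma, rho = rho, beta = beta)) {
      c(p[["sigma"]] * (x[2] - x[1]),
        x[1] * (p[["rho"]] - x[3]) - x[2],
        x[1] * x[2] - p[["beta"]] * x[3])
    },
    flow_jacobian = function(x, p = c(sigma = sigma, rho = rho, beta = beta)) {
      matrix(c(-p[["sigma"]], p[["rho"]] - x[3], x[2],
               p[["sigma"]], -1, x[1],
               0, -x[1], -p[["beta"]]), 3L, 3L)
    },
    output_jacobian = Jg, coupled_component = 1L,
    params = c(sigma = sigma, rho = rho, beta = beta),
    default_initial_state = c(1, 1, 1),
    var_func = "derivs_lorenz_var", var_event = "event_renorm3")
}

#' @rdname dynamical_systems
#' @export
linear_system <- function() {
  new_dynamical_system(
    name = "linear", sysid = 3L, dimension = 1L,
    flow = function(x, p = NULL) x,
    flow_jacobian = function(x, p = NULL) matrix(1, 1L, 1L),
    output_jacobian = matrix(1, 1L, 1L), coupled_component = 1L,
    params = c(),
    default_initial_state = 1,
    var_func = "derivs_linear_var", var_event = "event_renorm1")
}

#' Look up a built-in system by name
#'
#' @param name one of `"rossler"`, `"lorenz"`, `"linear"`.
#' @param params optional named numeric overrides for the system parameters.
#' @return a `dynamical_system`.
#' @export
get_system <- function(name, params = NULL) {
  sys <- switch(name,
                rossler = rossler_system(), lorenz = lorenz_system(),
                linear = linear_system(),
                stop("unknown system: ", name))
  if (!is.null(params) && length(params)) {
    bad <- setdiff(names(params), names(sys$params))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p <- sys$params
    p[names(params)] <- params
    sys <- switch(name,
                  rossler = rossler_system(p[["a"]], p[["b"]], p[["c"]]),
                  lorenz = lorenz_system(p[["sigma"]], p[["rho"]], p[["beta"]]),
                  linear = linear_system())
  }
  sys
}

#' @export
print.dynamical_system <- function(x, ...) {
  cat(sprintf("dynamical_system '%s' (m = %d)", x$name, x$dimension))
  if (length(x$params)) {
    cat(": ", paste(sprintf("%s = %g", names(x$params), x$params),
                    collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Finite-difference check of a system's Jacobian
#'
#' Compares the analytic flow Jacobian with a central finite difference at
#' randomly drawn states; used as a structural sanity check of the built-in
#' systems.
#'
#' @param sys a `dynamical_system`.
#' @param n_states number of random evaluation states.
#' @param seed RNG seed for the states.
#' @return maximum relative error observed (invisibly errors if > 1e-5).
#' @export
check_jacobian <- function(sys, n_states = 10L, seed = 1L) {
  m <- sys$dimension
  states <- with_seed(seed, matrix(stats::runif(n_states * m, -5, 5),
                                   n_states, m))
  h <- 1e-6
  worst <- 0
  for (s in seq_len(n_states)) {
    x <- states[s, ]
    J <- sys$flow_jacobian(x)
    Jnum <- matrix(0, m, m)
    for (k in seq_len(m)) {
      e <- numeric(m); e[k] <- h
      Jnum[, k] <- (sys$flow(x + e) - sys$flow(x - e)) / (2 * h)
    }
    scale <- max(abs(J), 1)
    worst <- max(worst, max(abs(J - Jnum)) / scale)
  }
  if (worst > 1e-5) stop("flow_jacobian disagrees with finite differences")
  invisible(worst)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
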