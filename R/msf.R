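#' Settings for Lyapunov-exponent estimation
#'
#' Controls for the Benettin estimate of the largest Lyapunov exponent of
#' the parametric variational equation: a transient is discarded, then the
#' tangent vector is renormalized at fixed intervals and the average log
#' growth over the remaining window is the exponent.
#'
#' @param transient_time time units discarded before averaging.
#' @param total_time total integration time (`total_time - transient_time`
#'   is the averaging window).
#' @param renormalization_interval interval between tangent renormalizations.
#' @param rtol,atol integrator tolerances.
#' @param seed seed for the initial-condition jitter.
#' @param ic_jitter amplitude of the uniform jitter applied to the system's
#'   default initial state (lands on the attractor after the transient).
#' @return an object of class `lyapunov_settings`.
#' @export
lyapunov_settings <- function(transient_time = 200, total_time = 2200,
                              renormalization_interval = 1,
                              rtol = 1e-9, atol = 1e-9,
                              seed = 1L, ic_jitter = 1e-3) {
  stopifnot(total_time > transient_time, transient_time > 0,
            renormalization_interval > 0)
  structure(list(transient_time = transient_time, total_time = total_time,
                 renormalization_interval = renormalization_interval,
                 rtol = rtol, atol = atol, seed = as.integer(seed),
                 ic_jitter = ic_jitter),
            class = "lyapunov_settings")
}

#' Largest Lyapunov exponent of the variational equation
#'
#' Estimates the largest Lyapunov exponent of
#' `eta' = [Jf(x_s) - nu * Jg(x_s)] eta` driven by the isolated trajectory
#' `x_s(t)`, by Benettin's method: the base system and one tangent vector
#' are co-integrated (compiled right-hand side, adaptive integrator at the
#' settings' tolerances), the tangent is renormalized at fixed intervals,
#' and the exponent is the mean log growth after the transient.  Evaluated
#' over a grid of `nu` this is the Master Stability Function; `Lambda(0)` is
#' the maximum Lyapunov exponent of the isolated unit.
#'
#' Because the base trajectory does not depend on `nu`, estimates at equal
#' seeds share the trajectory and `Lambda(nu)` is a smooth function of `nu`,
#' which makes the bisection in [classify_msf()] well-posed.
#'
#' @param sys a [dynamical_systems] object.
#' @param nu the variational parameter `nu = d * lambda` (>= 0).
#' @param settings a [lyapunov_settings()] object.
#' @return the estimated exponent (scalar).
#' @export
max_lyapunov <- function(sys, nu, settings = lyapunov_settings()) {
  stopifnot(inherits(sys, "dynamical_system"),
            inherits(settings, "lyapunov_settings"),
            is.numeric(nu), length(nu) == 1L, nu >= 0)
  m <- sys$dimension
  x0 <- sys$default_initial_state +
    with_seed(settings$seed,
              stats::runif(m, -settings$ic_jitter, settings$ic_jitter))
  eta0 <- rep(1, m) / sqrt(m)
  y0 <- c(x0, eta0, 0)
  tau <- settings$renormalization_interval
  ev_times <- seq(tau, settings$total_time, by = tau)
  times <- c(0, ev_times)
  parms <- c(nu, unname(sys$params), numeric(3L))[1:4]
  out <- deSolve::ode(y = y0, times = times, func = sys$var_func,
                      parms = parms, dllname = "syncpath",
                      initfunc = "initmod_var",
                      events = list(func = sys$var_event, time = ev_times),
                      method = "lsoda",
                      rtol = settings$rtol, atol = settings$atol,
                      maxsteps = 50000)
  if (nrow(out) < length(times) || anyNA(out[nrow(out), ]) ||
      any(!is.finite(out[nrow(out), ]))) {
    stop(sprintf("trajectory diverged or integration failed at nu = %g", nu))
  }
  acc_col <- 1L + 2L * m + 1L   # time column + state + tangent, then acc
  acc <- out[, acc_col]
  i_trans <- which.min(abs(times - settings$transient_time))
  window <- settings$total_time - times[i_trans]
  (acc[length(acc)] - acc[i_trans]) / window
}

#' Sample the Master Stability Function on a grid
#'
#' One [max_lyapunov()] evaluation per grid point, all sharing the settings
#' (and hence the base trajectory).
#'
#' @param sys a [dynamical_systems] object.
#' @param nu_grid sorted nonnegative grid of `nu` values.
#' @param settings a [lyapunov_settings()] object.
#' @return an object of class `msf_curve` with `nu_values`, `lambda_values`
#'   and the settings used.
#' @export
msf_curve <- function(sys, nu_grid, settings = lyapunov_settings()) {
  stopifnot(is.numeric(nu_grid), length(nu_grid) >= 2L, all(nu_grid >= 0),
            !is.unsorted(nu_grid, strictly = TRUE))
  lambda <- vapply(nu_grid, function(nu) max_lyapunov(sys, nu, settings), 0.0)
  structure(list(nu_values = nu_grid, lambda_values = lambda,
                 system = sys$name, settings = settings),
            class = "msf_curve")
}

#' @export
print.msf_curve <- function(x, ...) {
  cat(sprintf("msf_curve (%s): %d points on [%g, %g], Lambda(0-end) = %.4g .. %.4g\n",
              x$system, length(x$nu_values), min(x$nu_values),
              max(x$nu_values), x$lambda_values[1L],
              x$lambda_values[length(x$lambda_values)]))
  invisible(x)
}

#' Export an MSF curve as a two-column CSV
#'
#' @param curve an [msf_curve()] result.
#' @param path output file.
#' @export
msf_curve_to_csv <- function(curve, path) {
  stopifnot(inherits(curve, "msf_curve"))
  utils::write.csv(data.frame(nu = curve$nu_values,
                              lambda = curve$lambda_values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Classify a Master Stability Function and locate its intercepts
#'
#' From the sign pattern of the sampled curve: Class I (never negative,
#' synchronization impossible), Class II (single `+ -> -` intercept
#' `nu*`; threshold `d_c = nu*/lambda_2`), Class III (sign pattern
#' `+, -, +` with two intercepts `nu1* < nu2*`; synchronization requires
#' `d*lambda_2 > nu1*` and `d*lambda_N < nu2*` simultaneously).  Any other
#' pattern (multiple stability intervals) is outside the three-class
#' first-transition scenario and raises an error.
#'
#' Each bracketed root is refined by bisection on fresh [max_lyapunov()]
#' evaluations (sharing the curve's settings, hence its base trajectory)
#' until the bracket is narrower than `refine_tol`; when `sys` is `NULL`
#' the intercepts are linearly interpolated from the tabulated curve
#' instead.
#'
#' @param curve an [msf_curve()] result sampled densely enough to bracket
#'   all sign changes.
#' @param sys the [dynamical_systems] object to refine with, or `NULL`.
#' @param settings optional [lyapunov_settings()] override for refinement.
#' @param refine_tol absolute bisection tolerance on `nu`.
#' @return an object of class `msf_classification` with `class_label`
#'   (`"I"`, `"II"` or `"III"`), `nu_star` or `nu1_star`/`nu2_star`, and
#'   the input curve.
#' @export
classify_msf <- function(curve, sys = NULL, settings = NULL,
                         refine_tol = 1e-4) {
  stopifnot(inherits(curve, "msf_curve"))
  if (is.null(settings)) settings <- curve$settings
  nu <- curve$nu_values
  lam <- curve$lambda_values
  neg <- lam < 0
  flips <- which(neg[-1L] != neg[-length(neg)])
  cls <- if (!any(neg)) "I"
  else if (length(flips) == 1L && !neg[1L]) "II"
  else if (length(flips) == 2L && !neg[1L] && !neg[length(neg)]) "III"
  else {
    stop("MSF sign pattern is outside the three-class scenario ",
         "(the stability region may be a union of several intervals)")
  }
  root <- function(i) {
    lo <- nu[i]; hi <- nu[i + 1L]
    flo <- lam[i]; fhi <- lam[i + 1L]
    if (is.null(sys)) {
      return(lo + (hi - lo) * flo / (flo - fhi))  # linear interpolation
    }
    if (flo == 0) return(lo)      # a grid point sits exactly on the root
    if (fhi == 0) return(hi)
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      fm <- max_lyapunov(sys, mid, settings)
      if (fm == 0) return(mid)
      if ((fm > 0) == (flo > 0)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  res <- list(class_label = cls, nu_star = NULL, nu1_star = NULL,
              nu2_star = NULL, curve = curve)
  if (cls == "II") res$nu_star <- root(flips[1L])
  if (cls == "III") {
    res$nu1_star <- root(flips[1L])
    res$nu2_star <- root(flips[2L])
  }
  structure(res, class = "msf_classification")
}

#' @export
print.msf_classification <- function(x, ...) {
  cat(sprintf("msf_classification: Class %s", x$class_label))
  if (x$class_label == "II") cat(sprintf(", nu* = %.6g", x$nu_star))
  if (x$class_label == "III") {
    cat(sprintf(", nu1* = %.6g, nu2* = %.6g", x$nu1_star, x$nu2_star))
  }
  cat("\n")
  invisible(x)
}

#' Locate nu* for a built-in system with a standard protocol
#'
#' Convenience wrapper: samples the MSF on a coarse grid, classifies, and
#' refines the first intercept by bisection.  This is the protocol used to
#' reproduce the critical parameters of the built-in chaotic flows.
#'
#' @param sys a [dynamical_systems] object.
#' @param nu_max upper end of the scan grid (the grid is 11 equispaced
#'   points on `[0, nu_max]`).
#' @param settings a [lyapunov_settings()] object.
#' @param refine_tol bisection tolerance on `nu`.
#' @return an `msf_classification`.
#' @export
find_nu_star <- function(sys, nu_max, settings = lyapunov_settings(),
                         refine_tol = 1e-4) {
  grid <- seq(0, nu_max, length.out = 11L)
  classify_msf(msf_curve(sys, grid, settings), sys = sys,
               settings = settings, refine_tol = refine_tol)
}
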