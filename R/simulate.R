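#' Simulation configuration
#'
#' @param t_end positive end time. Defaults, when a parameter set is supplied
#'   at integration time, to two oscillation periods.
#' @param n_points number of output points (>= 2); default 200 per period
#'   when resolved against a parameter set, else 400.
#' @param rtol,atol integrator tolerances. The defaults (1e-13) keep the
#'   absolute integration error below 1e-8 even at concentration scales of a
#'   few hundred, so closed-form-vs-simulation agreement checks measure the
#'   model, not the solver.
#' @return An object of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(t_end = NULL, n_points = NULL,
                             rtol = 1e-13, atol = 1e-13) {
  if (!is.null(t_end)) stopifnot(t_end > 0)
  if (!is.null(n_points)) stopifnot(n_points >= 2)
  structure(list(t_end = t_end, n_points = n_points,
                 rtol = rtol, atol = atol),
            class = "SimulationConfig")
}

.resolveTimes <- function(p, cfg) {
  period <- 2 * pi / oscillationFrequency(p)
  t_end <- cfg$t_end %||% (2 * period)
  n_points <- cfg$n_points %||% max(2L, ceiling(200 * t_end / period))
  seq(0, t_end, length.out = n_points)
}

#' Numerically integrate the oscillator ODE
#'
#' Independent oracle for the closed-form solution: integrates
#' `xdot = A x + u` with `deSolve::lsoda` directly from the state-space form.
#' Concentrations are *not* clamped at zero — an infeasible parameter set
#' legitimately produces negative values, and the integration must expose
#' that rather than mask it.
#'
#' @param p a [kineticParameters()] object.
#' @param x0 an [initialState()] (or length-2 numeric).
#' @param cfg a [simulationConfig()].
#' @return A `"Trajectory"` with attribute `source = "ode"`.
#' @export
integrateODE <- function(p, x0, cfg = simulationConfig()) {
  stopifnot(inherits(p, "KineticParameters"), inherits(cfg, "SimulationConfig"))
  x0 <- as.numeric(x0)
  sys <- linearSystem(p)
  times <- .resolveTimes(p, cfg)
  deriv <- function(t, x, parms) list(as.numeric(parms$A %*% x + parms$u))
  out <- deSolve::lsoda(y = x0, times = times, func = deriv,
                        parms = list(A = sys$A, u = sys$u),
                        rtol = cfg$rtol, atol = cfg$atol)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed; istate = ", attr(out, "istate")[1],
         call. = FALSE)
  }
  trajectory(out[, 1], out[, 2], out[, 3], source = "ode")
}

#' Maximum deviation between closed form and numerical integration
#'
#' Verification protocol for the analytic solution: the closed-form waveform
#' is evaluated on the integrator's own time grid and the maximum absolute
#' deviation across both species is returned.
#'
#' @inheritParams integrateODE
#' @return Non-negative scalar, `max over n,t of |closed_form - ode|`.
#' @examples
#' p <- kineticParameters(1, 3.91, 10.09, k4 = 41.75, k6 = 92.2)
#' verifyAgreement(p, initialState(5, 10.49)) < 1e-8
#' @export
verifyAgreement <- function(p, x0, cfg = simulationConfig()) {
  ode <- integrateODE(p, x0, cfg)
  oc <- solveClosedForm(p, x0)
  cf <- evaluateWaveform(oc, ode$time)
  max(abs(cf$S1 - ode$S1), abs(cf$S2 - ode$S2))
}
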