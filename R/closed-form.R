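#' Oscillation characteristics container
#'
#' Bundles the four oscillation characteristics (OCs) of each species: shared
#' angular frequency `theta`, per-species amplitude `alpha_n >= 0`, phase
#' `phi_n` in `(-pi, pi]`, and DC offset `omega_n`. Two phase conventions are
#' supported for the waveform:
#' cosine, `x_n(t) = alpha_n cos(theta t + phi_n) + omega_n`, and
#' sine, `x_n(t) = alpha_n sin(theta t + phi_n) + omega_n`.
#'
#' @param theta positive angular frequency (rad/time).
#' @param alpha length-2 non-negative amplitudes (concentration).
#' @param phi length-2 phases in `(-pi, pi]` (rad).
#' @param omega length-2 DC offsets (concentration).
#' @param convention `"cos"` or `"sin"`.
#' @return An object of class `"OscillationCharacteristics"`.
#' @export
oscillationCharacteristics <- function(theta, alpha, phi, omega,
                                       convention = c("cos", "sin")) {
  convention <- match.arg(convention)
  stopifnot(length(theta) == 1L, theta > 0,
            length(alpha) == 2L, all(alpha >= 0),
            length(phi) == 2L, length(omega) == 2L)
  phi <- wrapPhase(phi)
  structure(
    list(theta = theta,
         alpha = stats::setNames(as.numeric(alpha), c("x1", "x2")),
         phi = stats::setNames(as.numeric(phi), c("x1", "x2")),
         omega = stats::setNames(as.numeric(omega), c("x1", "x2")),
         convention = convention),
    class = "OscillationCharacteristics"
  )
}

#' Closed-form solution of the oscillator initial value problem
#'
#' Solves `xdot = A x + u` exactly. Each species follows
#' `x_n(t) = alpha_n cos(theta t + phi_n) + omega_n`: the DC offset is the
#' fixed point of the system, and the homogeneous remainder
#' `h(t) = x(t) - omega` is a pure sinusoid at `theta = sqrt(k2*kd)` fully
#' determined by `h(0) = x(0) - omega` and `h'(0) = A x(0) + u`. From these,
#' \deqn{\alpha_n = \sqrt{h_n(0)^2 + (h_n'(0)/\theta)^2}, \qquad
#'       \phi_n = \mathrm{atan2}(-h_n'(0)/\theta,\ h_n(0)).}
#' When `alpha_n = 0` (start exactly at the fixed point) the phase is 0 by
#' convention. The arctangent branch structure implied by atan2 agrees with
#' the sign rules of the explicit correction terms, see [phaseCorrections()].
#'
#' @param p a [kineticParameters()] object.
#' @param x0 an [initialState()] (or length-2 non-negative numeric).
#' @param convention phase convention of the returned OCs, `"cos"` (default)
#'   or `"sin"`.
#' @return An [oscillationCharacteristics()] object.
#' @examples
#' p <- kineticParameters(1, 3.91, 10.09, k4 = 41.75, k6 = 92.2)
#' oc <- solveClosedForm(p, initialState(5, 10.49), convention = "sin")
#' oc$alpha  # ~ (3.00, 5.67)
#' oc$phi    # ~ (0.00, 2.13)
#' @export
solveClosedForm <- function(p, x0, convention = c("cos", "sin")) {
  convention <- match.arg(convention)
  stopifnot(inherits(p, "KineticParameters"))
  x0 <- as.numeric(x0)
  stopifnot(length(x0) == 2L)
  sys <- linearSystem(p)
  if (sys$determinant <= 0) {
    stop("no oscillation: det(A) = k2*kd must be positive", call. = FALSE)
  }
  theta <- sqrt(sys$determinant)
  omega <- fixedPoint(p)
  h0 <- x0 - omega
  hdot0 <- as.numeric(sys$A %*% x0 + sys$u)
  alpha <- sqrt(h0^2 + (hdot0 / theta)^2)
  phi <- ifelse(alpha == 0, 0, atan2(-hdot0 / theta, h0))
  oc <- oscillationCharacteristics(theta, alpha, phi, omega, "cos")
  if (convention == "sin") oc <- convertPhaseConvention(oc, "sin")
  oc
}

#' Arctangent branch-correction terms of the phase formulas
#'
#' The explicit phase formulas are built from an arctangent whose principal
#' branch must be corrected by `pi_n` in half of the plane. The correction is
#' governed by two condition terms evaluated verbatim:
#' `pi_1 = pi` iff `cond1 < 0` and `pi_2 = pi` iff `cond2 > 0`. Also returns
#' `T`, the envelope term of the large-`k2` feasibility limits, whose squared
#' value simplifies to `(k4 - k6)^2 + theta^2 (x1(0) + x2(0))^2`.
#'
#' Algebraically `cond1 = h_1'(0)/theta` and `cond2 = -h_2'(0)/theta`, so the
#' corrections fire exactly when the sine-convention phase of the species
#' falls outside `(-pi/2, pi/2]` — the consistency checked in the tests.
#'
#' @param p a [kineticParameters()] object.
#' @param x0 an [initialState()] (or length-2 numeric).
#' @param theta positive angular frequency; defaults to
#'   [oscillationFrequency()] of `p`.
#' @return An object of class `"PhaseCorrectionTerms"`: list with `cond1`,
#'   `cond2`, `pi1`, `pi2` and `T`.
#' @export
phaseCorrections <- function(p, x0, theta = oscillationFrequency(p)) {
  stopifnot(inherits(p, "KineticParameters"))
  x0 <- as.numeric(x0)
  if (theta == 0) stop("theta must be non-zero", call. = FALSE)
  k2 <- p$k2; kd <- p$kd; k4 <- p$k4; k6 <- p$k6
  x1 <- x0[1]; x2 <- x0[2]

  # term-by-term as printed; no algebraic simplification
  cond1 <- k2^2 * x1 / (k2 * theta + kd * theta) +
    k2^2 * x2 / (k2 * theta + kd * theta) +
    k2 * k4 * theta / (k2 * theta^2 + kd * theta^2) -
    2 * k2 * k4 / (k2 * theta + kd * theta) -
    k2 * k6 * theta / (k2 * theta^2 + kd * theta^2) +
    k2 * k6 / (k2 * theta + kd * theta) +
    k2 * kd * x1 / (k2 * theta + kd * theta) +
    k4 * kd * theta / (k2 * theta^2 + kd * theta^2) -
    2 * k4 * kd / (k2 * theta + kd * theta) +
    theta * x2 / (k2 + kd)
  cond2 <- k2 * x1 / theta + k2 * x2 / theta - k6 / theta + kd * x1 / theta

  structure(
    list(cond1 = cond1,
         cond2 = cond2,
         pi1 = if (cond1 < 0) pi else 0,
         pi2 = if (cond2 > 0) pi else 0,
         T = sqrt(k4^2 - 2 * k4 * k6 + k6^2 +
                    theta^2 * x1^2 + 2 * theta^2 * x1 * x2 + theta^2 * x2^2)),
    class = "PhaseCorrectionTerms"
  )
}

#' Sample the closed-form waveform on a time grid
#'
#' @param oc an [oscillationCharacteristics()] object.
#' @param times strictly increasing numeric time grid.
#' @return A `"Trajectory"`: data frame with columns `time`, `S1`, `S2` and
#'   attribute `source = "closed_form"`.
#' @export
evaluateWaveform <- function(oc, times) {
  stopifnot(inherits(oc, "OscillationCharacteristics"),
            is.numeric(times), !is.unsorted(times, strictly = TRUE))
  carrier <- if (oc$convention == "cos") cos else sin
  x1 <- oc$alpha[1] * carrier(times * oc$theta + oc$phi[1]) + oc$omega[1]
  x2 <- oc$alpha[2] * carrier(times * oc$theta + oc$phi[2]) + oc$omega[2]
  trajectory(times, x1, x2, source = "closed_form")
}

#' @rdname evaluateWaveform
#' @param x1,x2 concentration vectors aligned with `times`.
#' @param source `"closed_form"` or `"ode"`.
#' @export
trajectory <- function(times, x1, x2, source = c("closed_form", "ode")) {
  source <- match.arg(source)
  stopifnot(length(times) == length(x1), length(x1) == length(x2),
            !is.unsorted(times, strictly = TRUE))
  structure(
    data.frame(time = times, S1 = as.numeric(x1), S2 = as.numeric(x2)),
    source = source,
    class = c("Trajectory", "data.frame")
  )
}

#' Convert an OC set between phase conventions
#'
#' `cos(x) = sin(x + pi/2)`, so the sine-convention phase is the cosine
#' phase plus `pi/2`, renormalized to `(-pi, pi]`. The waveform is unchanged.
#'
#' @param oc an [oscillationCharacteristics()] object.
#' @param to target convention, `"cos"` or `"sin"`.
#' @return The converted object (identity if already in `to`).
#' @export
convertPhaseConvention <- function(oc, to = c("cos", "sin")) {
  to <- match.arg(to)
  stopifnot(inherits(oc, "OscillationCharacteristics"))
  if (oc$convention == to) return(oc)
  shift <- if (to == "sin") pi / 2 else -pi / 2
  oscillationCharacteristics(oc$theta, oc$alpha, wrapPhase(oc$phi + shift),
                             oc$omega, convention = to)
}

#' Biological feasibility of an oscillation
#'
#' Concentrations stay non-negative for all time iff the DC offset of each
#' species is at least its amplitude, `omega_n >= alpha_n`. A relative
#' tolerance admits boundary-grazing oscillators whose minimum concentration
#' touches zero (the worked nominal parameter set is one such case).
#'
#' @param oc an [oscillationCharacteristics()] object.
#' @param tol non-negative relative tolerance (default `1e-9`).
#' @return `TRUE` iff `omega_n >= alpha_n - tol * max(1, |omega_n|)` for both
#'   species.
#' @export
feasibilityCheck <- function(oc, tol = 1e-9) {
  stopifnot(inherits(oc, "OscillationCharacteristics"), tol >= 0)
  all(oc$omega >= oc$alpha - tol * pmax(1, abs(oc$omega)))
}

#' Signs of the feasibility margins in the large-k2 limit
#'
#' As `k2` grows without bound (with `theta` held fixed), the feasibility
#' margins diverge with definite signs:
#' `omega_1 - alpha_1 -> sign(-k4 + k6 - T) * Inf` and
#' `omega_2 - alpha_2 -> sign(k4 - k6 - T) * Inf`, with `T` the envelope term
#' of [phaseCorrections()]. Since `T >= |k4 - k6|`, at most one sign can be
#' positive: making one species comfortably feasible in this limit drives
#' the other infeasible.
#'
#' @param k4,k6 zeroth-order rates.
#' @param theta positive angular frequency.
#' @param x0 an [initialState()] (or length-2 numeric).
#' @return Named numeric vector `c(s1, s2)` of signs in `{-1, 0, 1}`.
#' @export
largeK2LimitSigns <- function(k4, k6, theta, x0) {
  stopifnot(theta > 0)
  x0 <- as.numeric(x0)
  Tt <- sqrt(k4^2 - 2 * k4 * k6 + k6^2 +
               theta^2 * x0[1]^2 + 2 * theta^2 * x0[1] * x0[2] +
               theta^2 * x0[2]^2)
  c(s1 = sign(-k4 + k6 - Tt), s2 = sign(k4 - k6 - Tt))
}

#' @export
print.OscillationCharacteristics <- function(x, ...) {
  cat(sprintf("Oscillation characteristics (%s convention)\n", x$convention))
  cat(sprintf("  theta = %.6g rad/time (period %.6g)\n",
              x$theta, 2 * pi / x$theta))
  for (n in 1:2) {
    cat(sprintf("  S%d: alpha = %.6g, phi = %.6g rad, omega = %.6g\n",
                n, x$alpha[n], x$phi[n], x$omega[n]))
  }
  cat(sprintf("  feasible (omega_n >= alpha_n): %s\n", feasibilityCheck(x)))
  invisible(x)
}

# wrap into (-pi, pi]
wrapPhase <- function(phi) {
  w <- (phi + pi) %% (2 * pi)
  w[w == 0] <- 2 * pi
  w - pi
}
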