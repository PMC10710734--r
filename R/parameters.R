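#' Kinetic parameters of the two-species harmonic oscillator
#'
#' Constructs the full set of kinetic constants for the six-reaction network.
#' The network has five first-order mass-action reactions and two zeroth-order
#' (fixed-rate) reactions; sustained oscillation forces two dependency
#' constraints among the rate constants, so `k3` and `k5` are *dependent*
#' parameters and are always computed here:
#'
#' \deqn{k_3 = k_1 + k_2, \qquad k_5 = k_3 + k_d,}
#'
#' where `kd > 0` is the excess of negative over positive feedback. The
#' independent parameters are `k1`, `k2`, `k4`, `k6`, `kd` (plus the two
#' initial concentrations held in [initialState()]).
#'
#' Units are abstract: `k1`, `k2`, `k3`, `k5` and `kd` are first-order rates
#' (1/time); `k4` and `k6` are zeroth-order rates (concentration/time).
#'
#' @param k1 non-negative first-order rate of the S1 -> S2 conversion. It does
#'   not influence any oscillation characteristic (it cancels through the
#'   `k3 = k1 + k2` constraint) and may be 0.
#' @param k2 positive first-order rate of the S2 -> S1 conversion.
#' @param kd positive derived rate, the margin `k5 - k3`. Exactly one of `kd`
#'   and `k5` must be supplied.
#' @param k4 non-negative zeroth-order degradation rate of S1.
#' @param k6 non-negative zeroth-order synthesis rate of S2.
#' @param k3,k5 optional. If supplied they are verified against the dependency
#'   constraints to relative tolerance `tol` and rejected otherwise; they are
#'   never taken at face value.
#' @param tol relative tolerance used to verify supplied `k3`/`k5`.
#'
#' @return An object of class `"KineticParameters"`: a list with elements
#'   `k1`...`k6` and `kd`.
#' @seealso [deriveDependentParameters()], [linearSystem()], [solveClosedForm()]
#' @examples
#' p <- kineticParameters(k1 = 1, k2 = 3.91, kd = 10.09, k4 = 41.75, k6 = 92.2)
#' p$k3  # 4.91
#' p$k5  # 15
#' @export
kineticParameters <- function(k1, k2, kd = NULL, k4 = 0, k6 = 0,
                              k3 = NULL, k5 = NULL, tol = 1e-9) {
  stopifnot(is.numeric(k1), length(k1) == 1L, is.finite(k1),
            is.numeric(k2), length(k2) == 1L, is.finite(k2),
            is.numeric(k4), length(k4) == 1L, is.finite(k4),
            is.numeric(k6), length(k6) == 1L, is.finite(k6))
  if (k1 < 0) stop("k1 must be non-negative", call. = FALSE)
  if (k2 <= 0) stop("constraint violation: k2 must be strictly positive", call. = FALSE)
  if (k4 < 0 || k6 < 0) stop("k4 and k6 must be non-negative", call. = FALSE)

  k3_derived <- k1 + k2
  if (!is.null(k3) && !.relEqual(k3, k3_derived, tol)) {
    stop(sprintf("supplied k3 = %g violates k3 = k1 + k2 = %g", k3, k3_derived),
         call. = FALSE)
  }
  if (is.null(kd)) {
    if (is.null(k5)) stop("one of `kd` or `k5` must be supplied", call. = FALSE)
    kd <- k5 - k3_derived
  } else if (!is.null(k5) && !.relEqual(k5, k3_derived + kd, tol)) {
    stop(sprintf("supplied k5 = %g violates k5 = k3 + kd = %g",
                 k5, k3_derived + kd), call. = FALSE)
  }
  if (!is.finite(kd) || kd <= 0) {
    stop("constraint violation: kd = k5 - k3 must be strictly positive",
         call. = FALSE)
  }
  structure(
    list(k1 = k1, k2 = k2, k3 = k3_derived, k4 = k4,
         k5 = k3_derived + kd, k6 = k6, kd = kd),
    class = "KineticParameters"
  )
}

#' Derive the dependent rate constants
#'
#' Thin wrapper over [kineticParameters()] emphasising the dependency
#' structure: given the independent rates `k1`, `k2`, `kd` it returns the full
#' parameter set with `k3 = k1 + k2` and `k5 = k3 + kd`.
#'
#' @inheritParams kineticParameters
#' @return A `"KineticParameters"` object.
#' @examples
#' deriveDependentParameters(1, 3.91, 10.09)$k5  # 15
#' @export
deriveDependentParameters <- function(k1, k2, kd, k4 = 0, k6 = 0) {
  kineticParameters(k1 = k1, k2 = k2, kd = kd, k4 = k4, k6 = k6)
}

#' Initial concentrations of the two species
#'
#' @param x1,x2 non-negative initial concentrations of S1 and S2.
#' @return An object of class `"InitialState"`: named numeric vector
#'   `c(x1, x2)`.
#' @examples
#' initialState(5, 10.49)
#' @export
initialState <- function(x1 = 0, x2 = 0) {
  stopifnot(is.numeric(x1), length(x1) == 1L, is.finite(x1),
            is.numeric(x2), length(x2) == 1L, is.finite(x2))
  if (x1 < 0 || x2 < 0) stop("initial concentrations must be non-negative",
                             call. = FALSE)
  structure(c(x1 = x1, x2 = x2), class = "InitialState")
}

#' Read independent parameters from a JSON or YAML file
#'
#' The on-disk schema carries the independent parameters only:
#' `{k1, k2, k4, k6, kd, x1_0, x2_0}`. Dependent constants are derived on
#' load, so a file can never encode an inconsistent parameter set.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `parameters` ([kineticParameters()]) and
#'   `state` ([initialState()]).
#' @export
readParameters <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported parameter file format: ", ext, call. = FALSE)
  )
  needed <- c("k1", "k2", "k4", "k6", "kd")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("parameter file is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  list(
    parameters = kineticParameters(k1 = raw$k1, k2 = raw$k2, kd = raw$kd,
                                   k4 = raw$k4, k6 = raw$k6),
    state = initialState(x1 = raw$x1_0 %||% 0, x2 = raw$x2_0 %||% 0)
  )
}

#' Check the oscillation constraints of a parameter set
#'
#' The network oscillates harmonically iff its Jacobian has zero trace and
#' positive determinant. Four constraints govern the construction: C1 (all
#' rate laws linear in the concentrations) holds structurally for this
#' network; C3 (`trace(A) = 0`) and C4 (`det(A) = k2*kd > 0`) are checked
#' numerically here. C2 (non-negative concentrations for all t) depends on
#' the initial state and is assessed by [feasibilityCheck()] on the
#' closed-form solution.
#'
#' @param p a [kineticParameters()] object.
#' @param x0 optional [initialState()]; recorded in the report but C2 is
#'   deferred to [feasibilityCheck()].
#' @return An object of class `"ConstraintReport"`: list with logical
#'   elements `C1`, `C3`, `C4`, plus `trace`, `determinant` and `all_pass`.
#' @examples
#' validateConstraints(kineticParameters(1, 3.91, 10.09))
#' @export
validateConstraints <- function(p, x0 = NULL) {
  stopifnot(inherits(p, "KineticParameters"))
  sys <- linearSystem(p)
  rep <- list(
    C1 = TRUE,                      # structural: mass-action + zeroth order
    C3 = sys$trace == 0,
    C4 = sys$determinant > 0,
    trace = sys$trace,
    determinant = sys$determinant,
    C2 = NA                          # see feasibilityCheck()
  )
  rep$all_pass <- rep$C1 && rep$C3 && rep$C4
  structure(rep, class = "ConstraintReport")
}

#' @export
print.KineticParameters <- function(x, ...) {
  cat("Two-species harmonic oscillator kinetic parameters\n")
  cat(sprintf("  k1 = %g  k2 = %g  k3 = %g (dependent)\n", x$k1, x$k2, x$k3))
  cat(sprintf("  k4 = %g  k5 = %g (dependent)  k6 = %g\n", x$k4, x$k5, x$k6))
  cat(sprintf("  kd = k5 - k3 = %g ; frequency sqrt(k2*kd) = %g rad/time\n",
              x$kd, sqrt(x$k2 * x$kd)))
  invisible(x)
}

#' @export
print.ConstraintReport <- function(x, ...) {
  cat("2SHO constraint report\n")
  cat(sprintf("  C1 linear rate laws : %s\n", ifelse(x$C1, "pass", "FAIL")))
  cat(sprintf("  C3 trace(A) = 0     : %s (trace = %g)\n",
              ifelse(x$C3, "pass", "FAIL"), x$trace))
  cat(sprintf("  C4 det(A) > 0       : %s (det = %g)\n",
              ifelse(x$C4, "pass", "FAIL"), x$determinant))
  cat("  C2 x(t) >= 0        : assessed via feasibilityCheck()\n")
  invisible(x)
}

.relEqual <- function(a, b, tol) {
  abs(a - b) <= tol * max(1, abs(a), abs(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
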