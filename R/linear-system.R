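#' Linear system representation of the oscillator network
#'
#' Assembles the state-space form `xdot = A x + u` of the reaction network.
#' After substituting the dependency constraints the Jacobian and forcing
#' vector are
#' \deqn{A = \begin{pmatrix} k_2 & k_2 \\ -k_2 - k_d & -k_2 \end{pmatrix},
#'       \qquad u = \begin{pmatrix} -k_4 \\ k_6 \end{pmatrix},}
#' so the trace is exactly zero, the determinant is `k2 * kd > 0`, and the
#' eigenvalues are the pure imaginary pair `+/- i sqrt(k2*kd)`.
#'
#' @param p a [kineticParameters()] object.
#' @return An object of class `"LinearSystem"`: list with `A` (2x2 matrix),
#'   `u` (length-2 vector), `trace`, `determinant`, `eigenvalues` (complex
#'   pair, computed numerically from `A`), and the originating `parameters`.
#' @examples
#' sys <- linearSystem(kineticParameters(1, 3.91, 10.09, k4 = 41.75, k6 = 92.2))
#' sys$A
#' sys$eigenvalues
#' @export
linearSystem <- function(p) {
  stopifnot(inherits(p, "KineticParameters"))
  A <- matrix(c(p$k2, -p$k2 - p$kd,
                p$k2, -p$k2), nrow = 2L, ncol = 2L)
  u <- c(-p$k4, p$k6)
  structure(
    list(A = A,
         u = u,
         trace = A[1, 1] + A[2, 2],
         determinant = A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1],
         eigenvalues = eigen(A, only.values = TRUE)$values,
         parameters = p),
    class = "LinearSystem"
  )
}

#' Angular frequency of oscillation
#'
#' The oscillation frequency is the square root of the Jacobian determinant,
#' `theta = sqrt(k2 * kd)` (radians per unit time). Of the two roots
#' `+/- sqrt(k2*kd)` the non-negative one is returned; the sign ambiguity is
#' carried by the phase, which is treated as a separate oscillation
#' characteristic.
#'
#' @param k2 positive first-order rate constant, or a
#'   [kineticParameters()] object (in which case `kd` is ignored).
#' @param kd positive rate margin `k5 - k3`.
#' @return The angular frequency, a positive scalar.
#' @examples
#' oscillationFrequency(3.91, 10.09)  # ~6.28
#' oscillationFrequency(4, 9)         # 6
#' @export
oscillationFrequency <- function(k2, kd = NULL) {
  if (inherits(k2, "KineticParameters")) {
    kd <- k2$kd
    k2 <- k2$k2
  }
  stopifnot(is.numeric(k2), is.numeric(kd))
  if (k2 * kd <= 0) {
    stop("no oscillation: k2 * kd must be strictly positive", call. = FALSE)
  }
  sqrt(k2 * kd)
}

#' Fixed point (DC offsets) of the oscillator
#'
#' The constant particular solution of `xdot = A x + u`, i.e. the point about
#' which both species oscillate. For this network it has the closed form
#' `x1* = (k6 - k4)/kd`, `x2* = k4/k2 - x1*`; for a generic
#' [linearSystem()] it is obtained by solving `A x = -u`.
#'
#' @param x a [kineticParameters()] or [linearSystem()] object.
#' @param ... unused.
#' @return Named numeric vector `c(x1, x2)` of stationary concentrations.
#'   Components may be negative, in which case no feasible oscillation around
#'   this point exists.
#' @examples
#' p <- kineticParameters(1, 3.91, 10.09, k4 = 41.75, k6 = 92.2)
#' fixedPoint(p)  # c(5.00, 5.68)
#' @export
fixedPoint <- function(x, ...) UseMethod("fixedPoint")

#' @rdname fixedPoint
#' @export
fixedPoint.KineticParameters <- function(x, ...) {
  x1 <- (x$k6 - x$k4) / x$kd
  c(x1 = x1, x2 = x$k4 / x$k2 - x1)
}

#' @rdname fixedPoint
#' @export
fixedPoint.LinearSystem <- function(x, ...) {
  if (abs(x$determinant) < .Machine$double.eps) {
    stop("singular Jacobian: no unique fixed point", call. = FALSE)
  }
  fp <- solve(x$A, -x$u)
  c(x1 = fp[1], x2 = fp[2])
}

#' @export
print.LinearSystem <- function(x, ...) {
  cat("Linear system xdot = A x + u\n")
  cat("A:\n")
  print(x$A)
  cat("u:", format(x$u), "\n")
  cat(sprintf("trace = %g, det = %g, eigenvalues = %s\n",
              x$trace, x$determinant,
              paste(format(x$eigenvalues, digits = 6), collapse = ", ")))
  invisible(x)
}
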