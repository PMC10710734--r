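#' Standard study fixtures
#'
#' Generates the parameter sets and target grids used by the accuracy,
#' design-error and sensitivity studies. Generation is pure: the same
#' arguments always yield the same fixtures.
#'
#' * `"verification_regimes"` — four diverse valid oscillators (slow/fast,
#'   small/large amplitude) for closed-form-vs-integration verification.
#' * `"design_grid"` — the design study grid: `theta*` and `alpha*`
#'   geometrically spaced over three decades `[0.1, 100]` in 8 increments,
#'   crossed with `phi* in {0, pi/2, pi, 2pi/3}` and `omega* = alpha*`.
#'   `scale` shrinks the number of increments per axis (e.g. `scale = 0.25`
#'   gives a 2 x 2 x 4 grid) while preserving geometric spacing and the
#'   `[0.1, 100]` endpoints.
#' * `"sensitivity_nominal"` — nominal parameter sets for the Monte-Carlo
#'   study: `$reconciled` (k4 chosen so the S1 DC offset is 5.00; a feasible,
#'   boundary-grazing oscillator used as the study nominal) and `$printed`
#'   (the k4 = 4.77 variant, retained for reference; it is *infeasible* —
#'   its fixed point has a negative component — see the package vignette).
#'
#' @param study one of `"verification_regimes"`, `"design_grid"`,
#'   `"sensitivity_nominal"`.
#' @param scale grid scale factor in `(0, 1]` (design grid only).
#' @param theta_max,alpha_max optional upper endpoints of the design grid
#'   axes (default 100); a reduced study over e.g. `[0.1, 10]` keeps the
#'   geometric spacing between the 0.1 lower endpoint and the cap.
#' @return For `"verification_regimes"` and `"sensitivity_nominal"`, a named
#'   list of `list(parameters, state)` entries; for `"design_grid"`, a data
#'   frame with columns `theta_star`, `alpha_star`, `phi_star`, `omega_star`.
#' @examples
#' nrow(generateFixtures("design_grid"))          # 256
#' nrow(generateFixtures("design_grid", 0.25))    # 16
#' @export
generateFixtures <- function(study = c("verification_regimes", "design_grid",
                                       "sensitivity_nominal"),
                             scale = 1, theta_max = NULL, alpha_max = NULL) {
  study <- match.arg(study)
  stopifnot(scale > 0, scale <= 1)
  switch(study,
    verification_regimes = list(
      # offsets sit above the amplitudes in all four (feasible oscillators)
      slow_small = list(
        parameters = kineticParameters(k1 = 0, k2 = 0.5, kd = 0.5,
                                       k4 = 2, k6 = 3),
        state = initialState(2.5, 2)),
      fast = list(
        parameters = kineticParameters(k1 = 1, k2 = 10, kd = 10,
                                       k4 = 80, k6 = 130),
        state = initialState(6, 3)),
      large_amplitude = list(
        parameters = kineticParameters(k1 = 2, k2 = 2, kd = 8,
                                       k4 = 110, k6 = 350),
        state = initialState(35, 25)),
      nominal_like = list(
        parameters = kineticParameters(k1 = 1, k2 = 3.91, kd = 10.09,
                                       k4 = 41.75, k6 = 92.2),
        state = initialState(5, 10.49))
    ),
    design_grid = {
      n_inc <- max(2L, round(8 * scale))
      gaxis <- function(top) 10^seq(-1, log10(top), length.out = n_inc)
      theta_axis <- gaxis(theta_max %||% 100)
      alpha_axis <- gaxis(alpha_max %||% 100)
      grid <- expand.grid(theta_star = theta_axis,
                          alpha_star = alpha_axis,
                          phi_star = c(0, pi / 2, pi, 2 * pi / 3),
                          KEEP.OUT.ATTRS = FALSE)
      grid$omega_star <- grid$alpha_star
      grid
    },
    sensitivity_nominal = {
      base <- list(k1 = 1.00, k2 = 3.91, k5 = 15.00, k6 = 92.2)
      kd <- base$k5 - (base$k1 + base$k2)
      list(
        reconciled = list(
          parameters = kineticParameters(k1 = base$k1, k2 = base$k2, kd = kd,
                                         k4 = base$k6 - kd * 5.00,
                                         k6 = base$k6),
          state = initialState(5.00, 10.49)),
        printed = list(
          parameters = kineticParameters(k1 = base$k1, k2 = base$k2, kd = kd,
                                         k4 = 4.77, k6 = base$k6),
          state = initialState(5.00, 10.49))
      )
    }
  )
}
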