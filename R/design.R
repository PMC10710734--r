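#' Desired oscillation characteristics for design
#'
#' A design target is a single desired sinusoid in the sine convention,
#' `x*(t) = alpha* sin(theta* t + phi*) + omega*`, that one of the two
#' species should follow.
#'
#' @param theta desired angular frequency, > 0 (rad/time).
#' @param alpha desired amplitude, > 0 (concentration).
#' @param phi desired phase in `(-pi, pi]` (rad); values outside are wrapped.
#' @param omega desired DC offset, >= 0 (concentration). Non-negative
#'   concentrations require `omega >= alpha`; `omega = alpha` is the grazing
#'   case used throughout the design studies.
#' @return An object of class `"DesignTarget"`.
#' @export
designTarget <- function(theta, alpha, phi = 0, omega = alpha) {
  stopifnot(is.numeric(theta), theta > 0,
            is.numeric(alpha), alpha > 0,
            is.numeric(phi), is.numeric(omega), omega >= 0)
  structure(list(theta = theta, alpha = alpha, phi = wrapPhase(phi),
                 omega = omega),
            class = "DesignTarget")
}

#' Configuration of the design optimization
#'
#' @param w penalty weight applied to negative concentrations in the relaxed
#'   loss; "large" relative to the squared residual scale (default 1e3).
#' @param n_periods number of target periods spanned by the fitting grid
#'   (default 2; at least two full sinusoids).
#' @param points_per_period samples per period on the fitting grid
#'   (default 10).
#' @param n_restarts number of random multi-start initializations per species
#'   (default 10).
#' @param seed integer seed making the multi-start draws reproducible.
#' @param k_max upper bound on the kinetic constants searched (default 1000).
#' @param c_max upper bound on initial concentrations searched; defaults at
#'   fit time to `2 * (alpha* + omega*)`.
#' @return An object of class `"LossConfig"`.
#' @export
lossConfig <- function(w = 1e3, n_periods = 2, points_per_period = 10,
                       n_restarts = 10, seed = 1, k_max = 1000, c_max = NULL) {
  stopifnot(w > 0, n_periods >= 2, points_per_period >= 2, n_restarts >= 1,
            k_max > 0)
  structure(list(w = w, n_periods = n_periods,
                 points_per_period = points_per_period,
                 n_restarts = n_restarts, seed = seed,
                 k_max = k_max, c_max = c_max),
            class = "LossConfig")
}

#' Fitting time grid matched to the target frequency
#'
#' The grid density tracks `theta*` so the optimizer always sees
#' `n_periods` complete sinusoids sampled at `points_per_period` phases.
#'
#' @param target a [designTarget()].
#' @param cfg a [lossConfig()].
#' @return Increasing numeric vector of times starting at 0.
#' @export
designTimeGrid <- function(target, cfg = lossConfig()) {
  period <- 2 * pi / target$theta
  seq(0, cfg$n_periods * period,
      length.out = cfg$n_periods * cfg$points_per_period + 1L)
}

#' Target waveform values
#'
#' @param target a [designTarget()].
#' @param times numeric time grid.
#' @return `alpha* sin(theta* t + phi*) + omega*` at each time.
#' @export
targetWaveform <- function(target, times) {
  target$alpha * sin(target$theta * times + target$phi) + target$omega
}

#' Expand a search point into a full parameter set
#'
#' The design search runs over the reduced 5-dimensional space
#' `(k2, k4, k6, x1_0, x2_0)`. Two reductions pin the remaining independent
#' parameters: `k1 = 1` (it affects no oscillation characteristic) and
#' `kd = theta*^2 / k2` (which forces the achieved frequency to equal the
#' desired frequency by construction).
#'
#' @param target a [designTarget()].
#' @param point named numeric vector or list with `k2 > 0`, `k4`, `k6`,
#'   `x1_0`, `x2_0`.
#' @return A list with `parameters` ([kineticParameters()]) and `state`
#'   ([initialState()]).
#' @export
reduceSearchSpace <- function(target, point) {
  point <- as.list(point)
  if (point$k2 <= 0) stop("k2 must be strictly positive", call. = FALSE)
  list(
    parameters = kineticParameters(k1 = 1, k2 = point$k2,
                                   kd = target$theta^2 / point$k2,
                                   k4 = point$k4, k6 = point$k6),
    state = initialState(point$x1_0, point$x2_0)
  )
}

.pointTrajectory <- function(target, point, times) {
  m <- reduceSearchSpace(target, point)
  oc <- solveClosedForm(m$parameters, m$state)
  evaluateWaveform(oc, times)
}

#' Design loss of a candidate search point
#'
#' Sum of squared deviations between the target sinusoid and the candidate's
#' closed-form waveform for the given species on the time grid.
#'
#' @param point candidate search point (see [reduceSearchSpace()]).
#' @param target a [designTarget()].
#' @param species 1 or 2, the species compared against the target.
#' @param times fitting time grid.
#' @return Non-negative scalar loss.
#' @export
ocLoss <- function(point, target, species, times) {
  traj <- .pointTrajectory(target, point, times)
  xs <- targetWaveform(target, times)
  sum((xs - traj[[species + 1L]])^2)
}

#' Relaxed design loss with soft non-negativity penalties
#'
#' Adds to [ocLoss()] a heavily weighted penalty for every grid point at
#' which either species' concentration goes negative:
#' `sum_t (1[x1 < 0] w x1)^2 + (1[x2 < 0] w x2)^2`. This relaxation keeps
#' the hard constraint `x_n(t) >= 0` differentiable so derivative-based
#' least squares is steered away from infeasible regions.
#'
#' @inheritParams ocLoss
#' @param cfg a [lossConfig()] supplying the weight `w`.
#' @return Non-negative scalar; always `>= ocLoss()`, with equality iff the
#'   candidate's concentrations are non-negative on the grid.
#' @export
relaxedLoss <- function(point, target, species, times, cfg = lossConfig()) {
  traj <- .pointTrajectory(target, point, times)
  xs <- targetWaveform(target, times)
  sum((xs - traj[[species + 1L]])^2) +
    sum((cfg$w * pmin(traj$S1, 0))^2) +
    sum((cfg$w * pmin(traj$S2, 0))^2)
}

# lean closed-form evaluation of both species on the design grid; identical
# algebra to solveClosedForm + evaluateWaveform, without object construction
# (the optimizer calls this thousands of times)
.waveformRaw <- function(theta, k2, k4, k6, x1_0, x2_0, times) {
  kd <- theta^2 / k2
  omega1 <- (k6 - k4) / kd
  omega2 <- k4 / k2 - omega1
  hd1 <- k2 * (x1_0 + x2_0) - k4
  hd2 <- -(k2 + kd) * x1_0 - k2 * x2_0 + k6
  ct <- cos(theta * times)
  st <- sin(theta * times)
  list(S1 = omega1 + (x1_0 - omega1) * ct + (hd1 / theta) * st,
       S2 = omega2 + (x2_0 - omega2) * ct + (hd2 / theta) * st)
}

# residual vector whose sum of squares is relaxedLoss; used by nls.lm
.relaxedResiduals <- function(par, target, species, times, xs, w) {
  traj <- .waveformRaw(target$theta, par[1], par[2], par[3], par[4], par[5],
                       times)
  c(xs - traj[[species]],
    w * pmin(traj$S1, 0),
    w * pmin(traj$S2, 0))
}

# One random restart point. k2 (and hence kd = theta*^2/k2) sets the
# conditioning of the problem and is drawn log-uniformly over the range the
# bounds allow; one initial concentration is drawn uniformly. The remaining
# parameters enter the waveform linearly at fixed k2, so they are initialized
# by inverting the target sinusoid (x*(t) = omega* + alpha* sin(phi*) cos(th t)
# + alpha* cos(phi*) sin(th t)) for the fitted species, then clipped to the
# bounds. The subsequent bounded least squares refines all five jointly.
.designStart <- function(target, species, cfg, c_max) {
  th <- target$theta
  k2 <- 10^stats::runif(1, log10(max(th^2 / cfg$k_max, 1e-3)),
                        log10(cfg$k_max))
  kd <- th^2 / k2
  c0 <- target$omega
  c1 <- target$alpha * sin(target$phi)
  c2 <- target$alpha * cos(target$phi)
  clipk <- function(v) min(max(v, 0), cfg$k_max)
  clipc <- function(v) min(max(v, 0), c_max)
  if (species == 1L) {
    x2_0 <- stats::runif(1, 0, c_max)
    x1_0 <- clipc(c0 + c1)
    k4 <- clipk(k2 * (x1_0 + x2_0) - th * c2)
    k6 <- clipk(k4 + kd * c0)
  } else {
    x1_0 <- stats::runif(1, 0, c_max)
    x2_0 <- clipc(c0 + c1)
    k6 <- clipk(th * c2 + (k2 + kd) * x1_0 + k2 * x2_0)
    k4 <- clipk((c0 + k6 / kd) * k2 * kd / (k2 + kd))
  }
  c(k2 = k2, k4 = k4, k6 = k6, x1_0 = x1_0, x2_0 = x2_0)
}

.fitSpecies <- function(target, species, times, xs, cfg, starts) {
  lower <- c(k2 = 1e-8, k4 = 0, k6 = 0, x1_0 = 0, x2_0 = 0)
  c_max <- cfg$c_max %||% (2 * (target$alpha + target$omega))
  upper <- c(k2 = cfg$k_max, k4 = cfg$k_max, k6 = cfg$k_max,
             x1_0 = c_max, x2_0 = c_max)
  # run each restart essentially to stationarity; restarts are cheap and the
  # ill-conditioned large-k2 region stalls under looser tolerances
  ctrl <- minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-15,
                                     ptol = 1e-15, maxfev = 20000)
  best <- NULL
  n_converged <- 0L
  for (i in seq_len(nrow(starts))) {
    par0 <- pmin(pmax(unlist(starts[i, ]), lower), upper)
    fit <- tryCatch(
      suppressWarnings(   # restarts that stall at maxiter are expected
        minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                           fn = .relaxedResiduals, control = ctrl,
                           target = target, species = species, times = times,
                           xs = xs, w = cfg$w)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    n_converged <- n_converged + 1L
    loss <- fit$deviance
    if (is.null(best) || loss < best$loss) {
      best <- list(par = fit$par, loss = loss)
    }
  }
  if (is.null(best)) {
    # every restart failed: best-effort fall-back to the first start
    par0 <- pmin(pmax(unlist(starts[1, ]), lower), upper)
    best <- list(par = par0,
                 loss = relaxedLoss(as.list(par0), target, species, times, cfg))
  }
  best$converged <- n_converged > 0L
  best$point <- as.list(best$par)
  names(best$point) <- c("k2", "k4", "k6", "x1_0", "x2_0")
  best
}

#' Parameterize the oscillator to achieve desired oscillation characteristics
#'
#' The design algorithm: for each species in turn, run multi-start bounded
#' Levenberg-Marquardt least squares over the reduced search space
#' `(k2, k4, k6, x1_0, x2_0)` minimizing the relaxed loss
#' ([relaxedLoss()]) against the target sinusoid, then return the species
#' whose minimized loss is smaller (ties go to S1). The achieved frequency
#' equals `theta*` by construction of the search-space reduction, so only
#' amplitude, phase and feasibility design errors can arise.
#'
#' Each restart draws `k2` log-uniformly over the bound-respecting range
#' (together with `kd = theta*^2/k2` it fixes the conditioning of the
#' problem) and one initial concentration uniformly on `[0, c_max]`; the
#' parameters that enter the waveform linearly at fixed `k2` are initialized
#' by inverting the target sinusoid and clipping to the bounds. All draws
#' are seeded by `cfg$seed`, so the result is deterministic for a fixed
#' configuration.
#'
#' @param target a [designTarget()] (sine convention).
#' @param cfg a [lossConfig()].
#' @param species `"auto"` (default: pick the smaller loss), or 1 or 2 to
#'   force the chosen oscillating species.
#' @return An object of class `"DesignResult"`: list with `chosen_species`,
#'   `best_point`, `parameters`, `state`, `losses` (per species, `NA` for a
#'   species not fitted), `achieved` (sine-convention
#'   [oscillationCharacteristics()]), `feasible`, `amplitude_design_error`,
#'   `phase_design_error`, `converged`, `target`, `times`.
#' @examples
#' \donttest{
#' res <- parameterizeOscillator(designTarget(1, 1, 0, 1),
#'                               lossConfig(n_restarts = 5, seed = 7))
#' res$amplitude_design_error
#' }
#' @export
parameterizeOscillator <- function(target, cfg = lossConfig(),
                                   species = c("auto", "1", "2")) {
  stopifnot(inherits(target, "DesignTarget"), inherits(cfg, "LossConfig"))
  species <- match.arg(as.character(species), c("auto", "1", "2"))
  times <- designTimeGrid(target, cfg)
  xs <- targetWaveform(target, times)
  c_max <- cfg$c_max %||% (2 * (target$alpha + target$omega))

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  draw_starts <- function(sp) {
    as.data.frame(t(vapply(seq_len(cfg$n_restarts),
                           function(i) .designStart(target, sp, cfg, c_max),
                           numeric(5))))
  }
  fit_for <- c("auto" = list(1:2), "1" = list(1L), "2" = list(2L))[[species]]
  fits <- list()
  losses <- c(NA_real_, NA_real_)
  for (sp in fit_for) {
    fits[[sp]] <- .fitSpecies(target, sp, times, xs, cfg, draw_starts(sp))
    losses[sp] <- fits[[sp]]$loss
  }
  chosen <- if (length(fit_for) == 1L) fit_for else {
    if (losses[2] < losses[1]) 2L else 1L   # tie -> species 1
  }
  best <- fits[[chosen]]
  model <- reduceSearchSpace(target, best$point)
  achieved <- solveClosedForm(model$parameters, model$state,
                              convention = "sin")
  traj <- evaluateWaveform(convertPhaseConvention(achieved, "cos"), times)
  result <- structure(
    list(chosen_species = chosen,
         best_point = best$point,
         parameters = model$parameters,
         state = model$state,
         losses = stats::setNames(losses, c("L1", "L2")),
         achieved = achieved,
         # feasibility design error: any negative concentration on the
         # evaluation grid (scale-aware numerical tolerance)
         feasible = all(c(traj$S1, traj$S2) >=
                          -1e-9 * max(1, target$alpha + target$omega)),
         converged = best$converged,
         target = target,
         times = times),
    class = "DesignResult"
  )
  err <- designErrors(result, target)
  result$amplitude_design_error <- err[["amplitude"]]
  result$phase_design_error <- err[["phase"]]
  result
}

#' Amplitude and phase design errors
#'
#' Relative deviation of the achieved oscillation from the target:
#' amplitude error `(alpha_hat - alpha*) / alpha*` (so -1 means the chosen
#' species never oscillates) and phase error `(phi_hat - phi*) / 2pi`, the
#' deviation as a fraction of a cycle, wrapped into `(-0.5, 0.5]`. Frequency
#' carries no design error: it is pinned to `theta*` by construction.
#'
#' @param result a `"DesignResult"` from [parameterizeOscillator()].
#' @param target the [designTarget()] it was fitted to.
#' @return Named numeric vector `c(amplitude, phase)`.
#' @export
designErrors <- function(result, target) {
  stopifnot(inherits(result, "DesignResult"), inherits(target, "DesignTarget"))
  if (target$alpha <= 0) stop("target amplitude must be positive", call. = FALSE)
  sp <- result$chosen_species
  achieved <- convertPhaseConvention(result$achieved, "sin")
  c(amplitude = unname((achieved$alpha[sp] - target$alpha) / target$alpha),
    phase = unname(wrapPhase(achieved$phi[sp] - target$phi) / (2 * pi)))
}

#' Run the design algorithm over a grid of targets
#'
#' Reproduces the design-error study protocol: for each grid cell
#' (`theta*`, `alpha*`, `phi*`, with `omega* = alpha*`) run
#' [parameterizeOscillator()] and record the chosen species, design errors,
#' feasibility and fitted parameter values (the latter feed parameter-value
#' histograms). Cells use seeds derived deterministically from `cfg$seed`.
#'
#' @param grid data frame with columns `theta_star`, `alpha_star`,
#'   `phi_star` and optionally `omega_star` (defaults to `alpha_star`); see
#'   [generateFixtures()] for the standard grids.
#' @param cfg a [lossConfig()].
#' @param s1_only if `TRUE`, force S1 as the chosen oscillating species (the
#'   restricted variant of the study); default `FALSE` allows either species.
#' @return Data frame, one row per cell: targets, `chosen_species`
#'   (`"a"` = S1, `"b"` = S2), `loss`, `amplitude_error`, `phase_error`,
#'   `feasible`, and fitted `k2`, `k4`, `k6`, `x1_0`, `x2_0`.
#' @export
runStudyGrid <- function(grid, cfg = lossConfig(), s1_only = FALSE) {
  stopifnot(all(c("theta_star", "alpha_star", "phi_star") %in% names(grid)))
  if (is.null(grid$omega_star)) grid$omega_star <- grid$alpha_star
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    cell_cfg <- cfg
    cell_cfg$seed <- (cfg$seed %||% 0) + i
    res <- parameterizeOscillator(
      designTarget(cell$theta_star, cell$alpha_star, cell$phi_star,
                   cell$omega_star),
      cell_cfg,
      species = if (s1_only) "1" else "auto")
    data.frame(theta_star = cell$theta_star, alpha_star = cell$alpha_star,
               phi_star = cell$phi_star, omega_star = cell$omega_star,
               chosen_species = c("a", "b")[res$chosen_species],
               loss = res$losses[res$chosen_species],
               amplitude_error = res$amplitude_design_error,
               phase_error = res$phase_design_error,
               feasible = res$feasible,
               k2 = res$best_point$k2, k4 = res$best_point$k4,
               k6 = res$best_point$k6, x1_0 = res$best_point$x1_0,
               x2_0 = res$best_point$x2_0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.DesignResult <- function(x, ...) {
  cat("2SHO design result\n")
  cat(sprintf("  chosen oscillating species: S%d (losses L1 = %s, L2 = %s)\n",
              x$chosen_species, format(x$losses[1]), format(x$losses[2])))
  cat(sprintf("  amplitude design error: %.4g, phase design error: %.4g cycles\n",
              x$amplitude_design_error, x$phase_design_error))
  cat(sprintf("  feasible: %s, converged: %s\n", x$feasible, x$converged))
  cat(sprintf("  point: k2 = %.4g, k4 = %.4g, k6 = %.4g, x0 = (%.4g, %.4g)\n",
              x$best_point$k2, x$best_point$k4, x$best_point$k6,
              x$best_point$x1_0, x$best_point$x2_0))
  invisible(x)
}
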