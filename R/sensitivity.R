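#' Analytic relative sensitivity of the frequency to a rate constant
#'
#' The relative (logarithmic) sensitivity `S_k^theta = (dtheta/dk)(k/theta)`
#' of the frequency `theta = sqrt(k2 (k5 - k3))`, treating `k3` and `k5` as
#' independent perturbations of the Jacobian:
#' `S_k2 = 1/2`, `S_k3 = -k3 / (2 (k5 - k3))`, `S_k5 = k5 / (2 (k5 - k3))`,
#' and 0 for every other constant. `S_k3 + S_k5 = 1/2` identically.
#'
#' @param p a [kineticParameters()] object.
#' @param which one of `"k1"`..`"k6"`, `"kd"`.
#' @return The unitless relative sensitivity (a 1% change in the constant
#'   produces an `S`% change in frequency).
#' @examples
#' p <- kineticParameters(1, 3.91, 10.09)
#' analyticFrequencySensitivity(p, "k2")  # 0.5
#' analyticFrequencySensitivity(p, "k5")  # ~0.743
#' @export
analyticFrequencySensitivity <- function(p, which) {
  stopifnot(inherits(p, "KineticParameters"))
  which <- match.arg(which, c("k1", "k2", "k3", "k4", "k5", "k6", "kd"))
  margin <- p$k5 - p$k3
  if (which %in% c("k3", "k5") && margin == 0) {
    stop("singular: k5 = k3 gives zero frequency", call. = FALSE)
  }
  switch(which,
         k2 = 0.5,
         k3 = -p$k3 / (2 * margin),
         k5 = p$k5 / (2 * margin),
         0)
}

#' Finite-difference relative sensitivity of the frequency
#'
#' Central-difference oracle for [analyticFrequencySensitivity()]:
#' perturbs a single constant in `theta(k2, k3, k5) = sqrt(k2 (k5 - k3))`
#' (with `k3`, `k5` treated as independent) and estimates
#' `(dtheta/dk)(k/theta)`.
#'
#' @inheritParams analyticFrequencySensitivity
#' @param step relative step size of the central difference.
#' @return Numeric estimate of the relative sensitivity.
#' @export
numericFrequencySensitivity <- function(p, which, step = 1e-6) {
  stopifnot(inherits(p, "KineticParameters"), step > 0)
  which <- match.arg(which, c("k1", "k2", "k3", "k4", "k5", "k6", "kd"))
  theta_of <- function(k) sqrt(k[["k2"]] * (k[["k5"]] - k[["k3"]]))
  k <- unlist(p[c("k1", "k2", "k3", "k4", "k5", "k6")])
  k0 <- if (which == "kd") p$kd else k[[which]]
  if (which == "kd") k <- c(k, kd = p$kd)
  h <- step * max(abs(k0), 1)
  up <- k; up[[which]] <- k0 + h
  dn <- k; dn[[which]] <- k0 - h
  if (which == "kd") {  # kd enters only through k5 = k3 + kd
    up[["k5"]] <- k[["k3"]] + k0 + h
    dn[["k5"]] <- k[["k3"]] + k0 - h
  }
  dtheta <- (theta_of(up) - theta_of(dn)) / (2 * h)
  dtheta * k0 / theta_of(k)
}

#' Configuration of the Monte-Carlo parameter-sensitivity study
#'
#' @param parameters nominal [kineticParameters()].
#' @param state nominal [initialState()].
#' @param cv_grid coefficients of variation (normalized standard deviations)
#'   at which to run the study; default `c(0.01, 0.05, 0.1, 0.2)`, spanning
#'   the empirical 1-20% variability of kinetic-constant estimates.
#' @param n_samples truncated-normal draws per coefficient of variation
#'   (default 400).
#' @param seed integer seed.
#' @param tol feasibility tolerance passed to [feasibilityCheck()].
#' @return An object of class `"SensitivityStudyConfig"`.
#' @export
sensitivityStudyConfig <- function(parameters, state,
                                   cv_grid = c(0.01, 0.05, 0.1, 0.2),
                                   n_samples = 400, seed = 1, tol = 1e-9) {
  stopifnot(inherits(parameters, "KineticParameters"),
            all(cv_grid >= 0), n_samples >= 1, tol >= 0)
  structure(list(parameters = parameters, state = initialState(
                   as.numeric(state)[1], as.numeric(state)[2]),
                 cv_grid = cv_grid, n_samples = as.integer(n_samples),
                 seed = seed, tol = tol),
            class = "SensitivityStudyConfig")
}

# one truncated-normal column: rejection sampling, redraw negatives
.rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Draw perturbed parameter sets around the nominal
#'
#' Each of `k1, k2, k4, k5, k6, x1(0), x2(0)` is drawn independently from a
#' normal centered on its nominal value with standard deviation
#' `cv * nominal`, truncated at zero by rejection (negative draws are
#' redrawn, not clipped). `k3 = k1 + k2` is recomputed per draw — the
#' biochemical design enforces that constraint — while `kd = k5 - k3` may
#' come out non-positive, making the draw an infeasible oscillator.
#'
#' @param cfg a [sensitivityStudyConfig()].
#' @param cv coefficient of variation, >= 0.
#' @return Data frame with `n_samples` rows and columns `k1, k2, k3, k4, k5,
#'   k6, kd, x1_0, x2_0`.
#' @export
sampleParameters <- function(cfg, cv) {
  stopifnot(inherits(cfg, "SensitivityStudyConfig"))
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  p <- cfg$parameters
  n <- cfg$n_samples
  x0 <- as.numeric(cfg$state)
  draws <- data.frame(
    k1 = .rtruncnorm0(n, p$k1, cv * p$k1),
    k2 = .rtruncnorm0(n, p$k2, cv * p$k2),
    k4 = .rtruncnorm0(n, p$k4, cv * p$k4),
    k5 = .rtruncnorm0(n, p$k5, cv * p$k5),
    k6 = .rtruncnorm0(n, p$k6, cv * p$k6),
    x1_0 = .rtruncnorm0(n, x0[1], cv * x0[1]),
    x2_0 = .rtruncnorm0(n, x0[2], cv * x0[2])
  )
  draws$k3 <- draws$k1 + draws$k2
  draws$kd <- draws$k5 - draws$k3
  draws[, c("k1", "k2", "k3", "k4", "k5", "k6", "kd", "x1_0", "x2_0")]
}

#' Monte-Carlo feasibility and OC-deviation study
#'
#' For each coefficient of variation in the grid, draws `n_samples`
#' perturbed parameter sets ([sampleParameters()]) and measures
#' (a) the *feasibility* fraction — draws with `kd = k5 - k3 > 0` and
#' `omega_n >= alpha_n` for both species — with its binomial standard error,
#' and (b) for the feasible draws, the deviation of each oscillation
#' characteristic from the nominal: absolute fractional deviation
#' `|z_hat - z| / z` for `theta`, `alpha_n`, `omega_n`, and the unnormalized
#' absolute deviation in radians for the phases (the nominal S1 phase is 0,
#' so a fractional measure is undefined there).
#'
#' @param cfg a [sensitivityStudyConfig()]; its nominal must be a valid
#'   oscillator.
#' @return An object of class `"SensitivityStudyResult"`: list with
#'   `feasibility` (data frame `cv, n, n_feasible, feasibility, se`),
#'   `deviations` (data frame `cv, oc, mean, sd, n`), `nominal_oc`, `config`.
#' @examples
#' \donttest{
#' nom <- kineticParameters(1, 3.91, 10.09, k4 = 41.75, k6 = 92.2)
#' study <- feasibilityStudy(sensitivityStudyConfig(
#'   nom, initialState(5, 10.49), cv_grid = c(0.01, 0.2), seed = 11))
#' study$feasibility
#' }
#' @export
feasibilityStudy <- function(cfg) {
  stopifnot(inherits(cfg, "SensitivityStudyConfig"))
  nominal_oc <- solveClosedForm(cfg$parameters, cfg$state, convention = "sin")
  if (!feasibilityCheck(nominal_oc, cfg$tol)) {
    stop("nominal parameter set is not a feasible oscillator", call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  oc_names <- c("theta", "alpha1", "alpha2", "phi1", "phi2", "omega1", "omega2")
  feas_rows <- list()
  dev_rows <- list()
  for (cv in cfg$cv_grid) {
    draws <- sampleParameters(cfg, cv)
    devs <- matrix(NA_real_, nrow = nrow(draws), ncol = length(oc_names),
                   dimnames = list(NULL, oc_names))
    feasible <- logical(nrow(draws))
    for (i in seq_len(nrow(draws))) {
      d <- draws[i, ]
      if (d$kd <= 0 || d$k2 <= 0) next
      p <- kineticParameters(k1 = d$k1, k2 = d$k2, kd = d$kd,
                             k4 = d$k4, k6 = d$k6)
      oc <- solveClosedForm(p, c(d$x1_0, d$x2_0), convention = "sin")
      if (!feasibilityCheck(oc, cfg$tol)) next
      feasible[i] <- TRUE
      devs[i, ] <- c(
        abs(oc$theta - nominal_oc$theta) / nominal_oc$theta,
        abs(oc$alpha - nominal_oc$alpha) / nominal_oc$alpha,
        abs(wrapPhase(oc$phi - nominal_oc$phi)),
        abs(oc$omega - nominal_oc$omega) / nominal_oc$omega
      )  # order matches oc_names
    }
    f <- mean(feasible)
    feas_rows[[length(feas_rows) + 1L]] <- data.frame(
      cv = cv, n = nrow(draws), n_feasible = sum(feasible),
      feasibility = f, se = sqrt(f * (1 - f) / nrow(draws)))
    for (ocn in oc_names) {
      v <- devs[feasible, ocn]
      dev_rows[[length(dev_rows) + 1L]] <- data.frame(
        cv = cv, oc = ocn,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        n = length(v))
    }
  }
  structure(
    list(feasibility = do.call(rbind, feas_rows),
         deviations = do.call(rbind, dev_rows),
         nominal_oc = nominal_oc,
         config = cfg),
    class = "SensitivityStudyResult"
  )
}

#' Probability of obtaining a feasible oscillator within m attempts
#'
#' With per-attempt feasibility `f`, the chance of at least one feasible
#' oscillator in `m` independent attempts is `p(m, f) = 1 - (1 - f)^m`.
#'
#' @param m positive integer number of attempts.
#' @param f per-attempt feasibility in `[0, 1]`.
#' @return Probability in `[0, 1]`; monotone non-decreasing in both
#'   arguments.
#' @examples
#' successProbability(4, 0.57)  # ~0.966
#' successProbability(6, 0.33)  # ~0.910
#' @export
successProbability <- function(m, f) {
  stopifnot(is.numeric(m), all(m >= 1), all(m == round(m)))
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]", call. = FALSE)
  1 - (1 - f)^m
}

#' @export
print.SensitivityStudyResult <- function(x, ...) {
  cat(sprintf("2SHO sensitivity study (n = %d draws per cv, seed = %s)\n",
              x$config$n_samples, format(x$config$seed)))
  cat("Feasibility by coefficient of variation (+/- 2 SE):\n")
  f <- x$feasibility
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  cv = %-5g f = %.3f +/- %.3f\n",
                f$cv[i], f$feasibility[i], 2 * f$se[i]))
  }
  invisible(x)
}
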