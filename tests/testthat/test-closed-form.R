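test_that("closed form reproduces the worked-example oscillation characteristics", {
  nom <- reconciledNominal()
  oc <- solveClosedForm(nom$parameters, nom$state, convention = "sin")
  expect_equal(oc$theta, NOMINAL_OC$theta, tolerance = 1e-6)
  expect_equal(unname(oc$alpha), NOMINAL_OC$alpha, tolerance = 1e-6)
  expect_equal(unname(oc$omega), NOMINAL_OC$omega, tolerance = 1e-6)
  expect_equal(unname(oc$phi), NOMINAL_OC$phi_sin, tolerance = 1e-6)
  # matches the printed list at its rounding: theta 6.28, alpha (3.00, 5.67),
  # omega (5.00, 5.67-5.68), phi (0.00, ~2.12)
  expect_equal(signif(oc$theta, 3), 6.28)
  expect_equal(unname(signif(oc$alpha, 3)), c(3.00, 5.67))
})

test_that("starting at the fixed point yields the constant solution", {
  nom <- reconciledNominal()
  fp <- fixedPoint(nom$parameters)
  oc <- solveClosedForm(nom$parameters, fp)
  expect_equal(unname(oc$alpha), c(0, 0))
  expect_equal(unname(oc$phi), c(0, 0))   # phase convention for alpha = 0
  expect_equal(unname(oc$omega), unname(fp))
})

test_that("closed-form trajectories satisfy the ODE and the t=0 condition", {
  for (fx in randomOscillators(20, seed = 3)) {
    p <- fx$parameters
    oc <- solveClosedForm(p, fx$state)
    # initial condition reproduced
    t0 <- evaluateWaveform(oc, c(0, 1e-3))
    expect_equal(c(t0$S1[1], t0$S2[1]), as.numeric(fx$state),
                 tolerance = 1e-9)
    # ODE residual by central differences at sample times
    theta <- oc$theta
    period <- 2 * pi / theta
    times <- seq(0, 2 * period, length.out = 101)
    h <- 1e-4 * period
    grid <- function(ts) {
      tr <- evaluateWaveform(oc, ts)
      rbind(tr$S1, tr$S2)
    }
    xm <- grid(times)
    xdot <- (grid(times + h) - grid(times - h)) / (2 * h)
    sys <- linearSystem(p)
    rhs <- sys$A %*% xm + sys$u
    expect_lt(max(abs(xdot - rhs)), 1e-7 * max(1, max(abs(rhs))))
  }
})

test_that("waveform evaluation is periodic with period-mean equal to the offset", {
  nom <- reconciledNominal()
  oc <- solveClosedForm(nom$parameters, nom$state)
  period <- 2 * pi / oc$theta
  t1 <- evaluateWaveform(oc, c(0.1, 0.4, 0.9))
  t2 <- evaluateWaveform(oc, c(0.1, 0.4, 0.9) + period)
  expect_equal(t1$S1, t2$S1, tolerance = 1e-9)
  expect_equal(t1$S2, t2$S2, tolerance = 1e-9)
  # mean over one exact period (endpoint excluded) recovers the DC offset
  grid <- seq(0, period, length.out = 513)[-513]
  tr <- evaluateWaveform(oc, grid)
  expect_equal(mean(tr$S1), unname(oc$omega[1]), tolerance = 1e-9)
  expect_equal(mean(tr$S2), unname(oc$omega[2]), tolerance = 1e-9)
})

test_that("phase-convention conversion preserves the waveform exactly", {
  oc <- oscillationCharacteristics(2, c(1, 3), c(0, 2.5), c(4, 5), "cos")
  osin <- convertPhaseConvention(oc, "sin")
  expect_equal(unname(osin$phi[1]), pi / 2)  # cos(x) = sin(x + pi/2)
  expect_equal(convertPhaseConvention(osin, "cos"), oc)  # round trip
  times <- seq(0, 10, length.out = 101)
  a <- evaluateWaveform(oc, times)
  b <- evaluateWaveform(osin, times)
  expect_equal(a$S1, b$S1, tolerance = 1e-12)
  expect_equal(a$S2, b$S2, tolerance = 1e-12)
})

test_that("feasibility requires omega_n >= alpha_n with boundary grazing allowed", {
  nom <- reconciledNominal()
  expect_true(feasibilityCheck(solveClosedForm(nom$parameters, nom$state)))
  graze <- oscillationCharacteristics(1, c(2, 3), c(0, 0), c(2, 3))
  expect_true(feasibilityCheck(graze))
  bad <- oscillationCharacteristics(1, c(2.5, 3), c(0, 0), c(2, 3))
  expect_false(feasibilityCheck(bad))
})

test_that("pi_n corrections agree with the atan2 phase branches", {
  nom <- reconciledNominal()
  cases <- c(list(nom), randomOscillators(20, seed = 9))
  for (fx in cases) {
    oc <- solveClosedForm(fx$parameters, fx$state, convention = "sin")
    pc <- phaseCorrections(fx$parameters, fx$state)
    # correction fires exactly when the sin-convention phase needs the other
    # arctangent branch, i.e. cos(phi_sin) < 0
    if (oc$alpha[1] > 1e-12) {
      expect_equal(pc$pi1 == pi, unname(cos(oc$phi[1]) < 0))
    }
    if (oc$alpha[2] > 1e-12) {
      expect_equal(pc$pi2 == pi, unname(cos(oc$phi[2]) < 0))
    }
    # T reduces to sqrt((k4-k6)^2 + theta^2 (x1+x2)^2)
    p <- fx$parameters
    th <- oscillationFrequency(p)
    expect_equal(pc$T,
                 sqrt((p$k4 - p$k6)^2 + th^2 * sum(as.numeric(fx$state))^2),
                 tolerance = 1e-12)
  }
  # dominant -k6 drives cond2 negative, so no correction for species 2
  p <- kineticParameters(1, 2, 2, k4 = 1, k6 = 1e6)
  pc <- phaseCorrections(p, initialState(1, 1))
  expect_lt(pc$cond2, 0)
  expect_identical(pc$pi2, 0)
  # every radicand term of T vanishes
  pT <- kineticParameters(1, 2, 2, k4 = 3, k6 = 3)
  expect_equal(phaseCorrections(pT, initialState(0, 0))$T, 0)
})

test_that("large-k2 limit signs are non-positive and match the closed form", {
  # T >= |k4 - k6| identically, so neither margin can diverge to +Inf
  s <- largeK2LimitSigns(k4 = 2, k6 = 2, theta = 1, x0 = initialState(1, 1))
  expect_equal(unname(s), c(-1, -1))
  s2 <- largeK2LimitSigns(k4 = 1, k6 = 100, theta = 2, x0 = initialState(3, 4))
  expect_true(all(s2 <= 0))
  # numeric agreement: sign(omega_n - alpha_n) at k2 = 1e6
  for (cs in list(list(k4 = 1, k6 = 10, x0 = c(1, 1)),
                  list(k4 = 20, k6 = 3, x0 = c(2, 5)))) {
    theta <- 2
    p <- kineticParameters(1, 1e6, theta^2 / 1e6, k4 = cs$k4, k6 = cs$k6)
    oc <- solveClosedForm(p, cs$x0)
    lim <- largeK2LimitSigns(cs$k4, cs$k6, theta, cs$x0)
    expect_equal(unname(sign(oc$omega - oc$alpha)), unname(lim))
  }
})

test_that("oscillation characteristics are invariant to k1 and phases align as k2 grows", {
  # k1-irrelevance: k3 absorbs k1, nothing else changes
  base <- solveClosedForm(kineticParameters(0, 3.91, 10.09, k4 = 41.75,
                                            k6 = 92.2),
                          initialState(5, 10.49))
  for (k1 in c(1, 10)) {
    oc <- solveClosedForm(kineticParameters(k1, 3.91, 10.09, k4 = 41.75,
                                            k6 = 92.2),
                          initialState(5, 10.49))
    expect_equal(oc, base, tolerance = 1e-12)
  }
  # large-k2 limit: x1 + x2 is nearly conserved, so the two species become
  # exactly antiphase -- their arctangent phase arguments converge (phases
  # equal mod pi) while the branch corrections keep them pi apart
  gap_from_pi <- function(k2) {
    p <- kineticParameters(1, k2, 4 / k2, k4 = 3, k6 = 8)
    oc <- solveClosedForm(p, initialState(2, 1))
    abs(abs(wrapPi(oc$phi[1] - oc$phi[2])) - pi)
  }
  expect_lt(gap_from_pi(1e6), gap_from_pi(1e2))
  expect_lt(gap_from_pi(1e6), 1e-2)
})
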