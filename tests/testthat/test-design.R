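test_that("search-space reduction pins the frequency exactly", {
  tg <- designTarget(6.28, 3, 0, 5)
  m <- reduceSearchSpace(tg, list(k2 = 3.91, k4 = 10, k6 = 50,
                                  x1_0 = 1, x2_0 = 1))
  expect_equal(m$parameters$kd, 6.28^2 / 3.91)
  expect_equal(m$parameters$k1, 1)
  expect_equal(reduceSearchSpace(designTarget(1, 1), list(
    k2 = 1, k4 = 0, k6 = 0, x1_0 = 0, x2_0 = 0))$parameters$kd, 1)
  expect_error(reduceSearchSpace(tg, list(k2 = 0, k4 = 0, k6 = 0,
                                          x1_0 = 0, x2_0 = 0)), "k2")
  for (k2 in c(0.05, 1, 37, 900)) {
    m <- reduceSearchSpace(tg, list(k2 = k2, k4 = 1, k6 = 1,
                                    x1_0 = 1, x2_0 = 1))
    expect_equal(oscillationFrequency(m$parameters), tg$theta,
                 tolerance = 1e-14)
  }
})

test_that("loss is the squared deviation summed over the grid", {
  # a candidate whose own species-1 waveform is used as the target has zero
  # loss against itself
  point <- list(k2 = 2, k4 = 10, k6 = 14, x1_0 = 3, x2_0 = 4)
  m <- reduceSearchSpace(designTarget(2, 1), point)
  oc <- solveClosedForm(m$parameters, m$state, convention = "sin")
  self_target <- designTarget(oc$theta, oc$alpha[1], oc$phi[1], oc$omega[1])
  times <- designTimeGrid(self_target)
  expect_lt(ocLoss(point, self_target, 1, times), 1e-18)
  # shifting the target offset by c adds M*c^2
  shifted <- designTarget(oc$theta, oc$alpha[1], oc$phi[1], oc$omega[1] + 0.3)
  expect_equal(ocLoss(point, shifted, 1, times), length(times) * 0.3^2,
               tolerance = 1e-9)
  # random candidate: matches an independent brute-force re-summation
  tg <- designTarget(1.7, 2.5, 0.8, 2.5)
  times <- designTimeGrid(tg)
  pt <- list(k2 = 5, k4 = 7, k6 = 11, x1_0 = 2, x2_0 = 6)
  m <- reduceSearchSpace(tg, pt)
  oc2 <- solveClosedForm(m$parameters, m$state)
  brute <- 0
  for (t in times) {
    xt <- oc2$alpha[2] * cos(oc2$theta * t + oc2$phi[2]) + oc2$omega[2]
    brute <- brute + (tg$alpha * sin(tg$theta * t + tg$phi) + tg$omega - xt)^2
  }
  expect_equal(ocLoss(pt, tg, 2, times), unname(brute), tolerance = 1e-10)
})

test_that("relaxed loss adds the negativity penalty and never undercuts the loss", {
  tg <- designTarget(1, 1, 0, 1)
  times <- designTimeGrid(tg)
  cfg <- lossConfig(w = 1e3)
  # non-negative trajectories: relaxation is inactive
  pt_ok <- list(k2 = 1, k4 = 3, k6 = 4, x1_0 = 1, x2_0 = 3)
  expect_equal(relaxedLoss(pt_ok, tg, 1, times, cfg),
               ocLoss(pt_ok, tg, 1, times))
  # a candidate with negative excursions: penalty equals w^2 * sum(min(x,0)^2)
  pt_neg <- list(k2 = 1, k4 = 10, k6 = 1, x1_0 = 1, x2_0 = 1)
  m <- reduceSearchSpace(tg, pt_neg)
  tr <- evaluateWaveform(solveClosedForm(m$parameters, m$state), times)
  pen <- cfg$w^2 * (sum(pmin(tr$S1, 0)^2) + sum(pmin(tr$S2, 0)^2))
  expect_gt(pen, 0)
  expect_equal(relaxedLoss(pt_neg, tg, 1, times, cfg),
               ocLoss(pt_neg, tg, 1, times) + pen, tolerance = 1e-9)
  # penalty grows with the excursion depth (deeper via larger k4)
  pt_deeper <- within(as.list(pt_neg), k4 <- 20)
  expect_gt(relaxedLoss(pt_deeper, tg, 1, times, cfg) -
              ocLoss(pt_deeper, tg, 1, times), pen)
})

test_that("the design algorithm achieves a simple target and is deterministic", {
  tg <- designTarget(1, 1, 0, 1)
  res <- parameterizeOscillator(tg, lossConfig(seed = 7))
  expect_true(res$converged)
  expect_true(res$feasible)
  expect_lt(abs(res$amplitude_design_error), 0.01)
  expect_lt(abs(res$phase_design_error), 0.01)
  # frequency is pinned exactly by construction
  expect_identical(res$achieved$theta, tg$theta)
  expect_equal(oscillationFrequency(res$parameters), tg$theta,
               tolerance = 1e-12)
  expect_equal(res$parameters$k3, 1 + res$parameters$k2)
  expect_equal(res$parameters$k5, res$parameters$k3 + res$parameters$kd)
  # same seed, same result
  res2 <- parameterizeOscillator(tg, lossConfig(seed = 7))
  expect_equal(res, res2)
})

test_that("design errors are relative, wrapped, and -1 for a dead species", {
  tg <- designTarget(1, 2, 0.5, 2)
  res <- parameterizeOscillator(tg, lossConfig(seed = 3, n_restarts = 4))
  expect_equal(designErrors(res, tg)[["amplitude"]],
               (convertPhaseConvention(res$achieved, "sin")$alpha[[
                 res$chosen_species]] - 2) / 2)
  # a full-cycle phase offset wraps to zero error
  sp <- res$chosen_species
  shifted <- res
  shifted$achieved <- oscillationCharacteristics(
    res$achieved$theta, res$achieved$alpha,
    res$achieved$phi + 2 * pi,     # constructor wraps back into (-pi, pi]
    res$achieved$omega, res$achieved$convention)
  expect_equal(designErrors(shifted, tg)[["phase"]],
               designErrors(res, tg)[["phase"]], tolerance = 1e-12)
  # zero achieved amplitude is a -1 amplitude design error
  dead <- res
  dead$achieved <- oscillationCharacteristics(
    res$achieved$theta, c(0, 0), c(0, 0), res$achieved$omega,
    res$achieved$convention)
  expect_equal(designErrors(dead, tg)[["amplitude"]], -1)
})

test_that("free species choice never loses to the S1-only restriction", {
  for (tg in list(designTarget(1, 1, 0, 1),
                  designTarget(0.5, 4, pi / 2, 4),
                  designTarget(3, 0.5, pi, 0.5))) {
    cfg <- lossConfig(seed = 13, n_restarts = 5)
    free <- parameterizeOscillator(tg, cfg)
    s1 <- parameterizeOscillator(tg, cfg, species = "1")
    expect_lte(free$losses[free$chosen_species], s1$losses[1] + 1e-12)
    expect_identical(s1$chosen_species, 1L)
  }
})

test_that("study grids record species letters, errors and parameters", {
  grid <- generateFixtures("design_grid", scale = 0.25, theta_max = 10,
                           alpha_max = 10)[1:6, ]
  tab <- suppressWarnings(runStudyGrid(grid, lossConfig(seed = 5,
                                                        n_restarts = 5)))
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$chosen_species %in% c("a", "b")))
  expect_true(all(tab$omega_star == tab$alpha_star))
  expect_true(all(abs(tab$amplitude_error) < 0.05))
  s1tab <- suppressWarnings(runStudyGrid(grid, lossConfig(seed = 5,
                                                          n_restarts = 5),
                                         s1_only = TRUE))
  expect_true(all(s1tab$chosen_species == "a"))
})
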