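# Debye/Cole-Cole evaluation and anchor calibration.

test_that("Debye evaluation matches closed-form values", {
  m <- debyeModel(epsInf = 6, deltaEps = 36.14, tau = 10e-12, sigmaS = 0.5)
  sp <- evaluatePermittivity(m, 1e9)
  # frozen from an independent closed-form evaluation:
  # omega*tau = 0.0628319, conduction term sigma/(omega*eps0) = 8.98756
  expect_equal(Re(epsilonAt(sp, 1e9)), 41.997886, tolerance = 1e-6)
  expect_equal(-Im(epsilonAt(sp, 1e9)), 11.249366, tolerance = 1e-6)

  # no relaxation, no conduction: flat eps_inf
  m0 <- debyeModel(epsInf = 6)
  expect_equal(epsilonValues(evaluatePermittivity(m0, tinyGrid())),
               rep(6 + 0i, 5))

  # static limit eps_inf + delta_eps
  m1 <- debyeModel(epsInf = 6, deltaEps = 36.14, tau = 10e-12, sigmaS = 0)
  expect_equal(Re(epsilonAt(evaluatePermittivity(m1, 1e3), 1e3)),
               42.14, tolerance = 1e-6)
})

test_that("evaluation rejects non-positive frequencies", {
  expect_error(evaluatePermittivity(healthyLiverModel(), c(1e9, 0)),
               "finite and > 0")
  expect_error(evaluatePermittivity(healthyLiverModel(), -1e9),
               "finite and > 0")
})

test_that("Cole-Cole broadening keeps the spectrum passive and distinct", {
  f <- defaultFrequencyGrid()
  cc <- debyeModel(epsInf = 6, deltaEps = 36, tau = 10e-12, sigmaS = 0.3,
                   alpha = 0.15)
  d <- debyeModel(epsInf = 6, deltaEps = 36, tau = 10e-12, sigmaS = 0.3)
  epsCc <- epsilonValues(evaluatePermittivity(cc, f))
  expect_true(all(-Im(epsCc) >= 0))
  expect_gt(max(Mod(epsCc - epsilonValues(evaluatePermittivity(d, f)))), 0.01)
})

test_that("anchor calibration inverts the closed-form relations", {
  h <- calibrateAnchor(6, 10e-12, 1e9, 42, 11.249)
  expect_equal(h@deltaEps, 36.1421, tolerance = 1e-4)
  expect_equal(h@sigmaS, 0.49997, tolerance = 1e-4)

  f <- calibrateAnchor(6, 10e-12, 1e9, 31, 0.65 * 11.249)
  expect_equal(f@deltaEps, 25.0987, tolerance = 1e-4)
  expect_equal(f@sigmaS, 0.31939, tolerance = 1e-4)
})

test_that("infeasible anchors are rejected", {
  expect_error(calibrateAnchor(6, 10e-12, 1e9, 5, 3), "infeasible")
  # relaxation loss of the real-part solution alone exceeds the target
  expect_error(calibrateAnchor(6, 10e-12, 1e9, 42, 0.1), "infeasible")
})

test_that("calibration round trip reproduces anchors to 1e-9 relative", {
  set.seed(42)
  for (i in 1:20) {
    er <- runif(1, 10, 80)
    ei <- runif(1, er * 2 * pi * 1e9 * 10e-12 * 1.01, 30)
    m <- calibrateAnchor(6, 10e-12, 1e9, er, ei)
    got <- epsilonAt(evaluatePermittivity(m, 1e9), 1e9)
    expect_equal(Re(got), er, tolerance = 1e-9)
    expect_equal(-Im(got), ei, tolerance = 1e-9)
  }
})

test_that("passivity and conductivity monotonicity hold for random models", {
  set.seed(7)
  f <- defaultFrequencyGrid()
  for (i in 1:20) {
    s0 <- runif(1, 0, 1)
    m <- debyeModel(epsInf = runif(1, 1, 10), deltaEps = runif(1, 0, 60),
                    tau = 10^runif(1, -12, -10), sigmaS = s0,
                    alpha = runif(1, 0, 0.3))
    e1 <- epsilonValues(evaluatePermittivity(m, f))
    expect_true(all(-Im(e1) >= 0))
    m2 <- debyeModel(epsInf = m@epsInf, deltaEps = m@deltaEps, tau = m@tau,
                     sigmaS = s0 + 0.2, alpha = m@alpha)
    e2 <- epsilonValues(evaluatePermittivity(m2, f))
    expect_true(all(-Im(e2) > -Im(e1)))       # loss strictly increases
    expect_equal(Re(e2), Re(e1))              # real part untouched
  }
})

test_that("canonical models hit their 1 GHz group anchors", {
  eh <- epsilonAt(evaluatePermittivity(healthyLiverModel(), 1e9), 1e9)
  ef <- epsilonAt(evaluatePermittivity(fattyLiverModel(), 1e9), 1e9)
  expect_equal(Re(eh), 42, tolerance = 1e-3)
  expect_equal(Re(ef), 31, tolerance = 1e-3)
  # fatty loss part is 65% of healthy (35% diminution)
  expect_equal(Im(ef) / Im(eh), 0.65, tolerance = 1e-4)
})

test_that("model config YAML round-trips losslessly", {
  p <- withr::local_tempfile(fileext = ".yaml")
  m <- debyeModel(epsInf = 6, deltaEps = c(36.14, 2), tau = c(1e-11, 1e-9),
                  sigmaS = 0.5, alpha = c(0, 0.1))
  writeModelConfig(m, p, name = "two_pole")
  back <- readModelConfig(p)
  expect_identical(back$name, "two_pole")
  expect_equal(back$model@deltaEps, m@deltaEps)
  expect_equal(back$model@tau, m@tau)
  expect_equal(back$model@alpha, m@alpha)
  expect_equal(back$model@sigmaS, m@sigmaS)
  expect_error(readModelConfig(withr::local_tempfile(lines = "poles: []",
                                                     fileext = ".yaml")),
               "missing field")
})
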