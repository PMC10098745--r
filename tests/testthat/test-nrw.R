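# Nicolson-Ross extraction: root selection, branch handling, round trips.

test_that("reflection root of the eps = 4 example is -1/3", {
  sw <- sampleSParams(permittivitySpectrum(1e9, 4 + 0i), 0.003)
  G <- selectReflectionRoot(sParam(sw, "s11"), sParam(sw, "s21"))
  expect_equal(G, -1/3 + 0i, tolerance = 1e-9)
})

test_that("matched sample raises the dedicated signal", {
  expect_error(selectReflectionRoot(0 + 0i, 1 + 0i), "matched sample")
})

test_that("candidate roots are reciprocal; exactly one is physical", {
  set.seed(5)
  for (i in 1:20) {
    eps <- randomEps()
    eps <- eps - 1i * 0.5   # guarantee real loss
    sw <- sampleSParams(permittivitySpectrum(1e9, eps), 0.003)
    cand <- coaxperm:::.gammaFromX(sParam(sw, "s11"), sParam(sw, "s21"))
    expect_equal(cand[, 1] * cand[, 2], 1 + 0i, tolerance = 1e-9)
    expect_equal(sum(Mod(cand) <= 1), 1)
  }
})

test_that("product-form and quadratic-form roots agree to 1e-12", {
  set.seed(9)
  for (i in 1:20) {
    eps <- randomEps()
    f <- runif(1, 1e8, 2e9)
    sw <- sampleSParams(permittivitySpectrum(f, eps), 0.003)
    gX <- coaxperm:::.pickRoot(
      coaxperm:::.gammaFromX(sParam(sw, "s11"), sParam(sw, "s21")))
    gC <- coaxperm:::.pickRoot(
      coaxperm:::.gammaFromC(sParam(sw, "s11"), sParam(sw, "s21")))
    expect_equal(gX, gC, tolerance = 1e-12)
  }
})

test_that("empty holder extracts to vacuum permittivity", {
  f <- tinyGrid()
  sw <- twoPortSweep(f, s11 = rep(0 + 0i, 5),
                     s21 = exp(-1i * 2 * pi * f / 299792458 * 0.003))
  eps <- extractPermittivity(sw, 0.003)
  expect_equal(epsilonValues(eps), rep(1 + 0i, 5), tolerance = 1e-9)
})

test_that("worked eps = 4 example inverts on the principal branch", {
  sw <- sampleSParams(permittivitySpectrum(1e9, 4 + 0i), 0.003)
  eps <- extractPermittivity(sw, 0.003)
  expect_equal(epsilonValues(eps), 4 + 0i, tolerance = 1e-6)
  expect_identical(eps@branch, 0L)
})

test_that("full pipeline recovers the liver anchors at 1 GHz", {
  f <- defaultFrequencyGrid()
  rec <- recoverSpectrum(evaluatePermittivity(healthyLiverModel(), f))
  expect_equal(Re(epsilonAt(rec, 1e9)), 42, tolerance = 1e-2)
  expect_equal(-Im(epsilonAt(rec, 1e9)), 11.25, tolerance = 1e-2)
})

test_that("forward -> extract round trip is exact across the band", {
  set.seed(21)
  f <- seq(1e8, 2e9, length.out = 41)
  L <- 0.003
  for (i in 1:8) {
    eps <- permittivitySpectrum(f, vapply(f, function(.) randomEps(),
                                          complex(1)))
    # precondition of the principal branch: phase below half-wavelength
    nRe <- Re(sqrt(epsilonValues(eps)))
    expect_true(all(2 * pi * f / 299792458 * nRe * L < pi))
    got <- extractPermittivity(sampleSParams(eps, L), L)
    expect_equal(epsilonValues(got), epsilonValues(eps),
                 tolerance = 1e-6)
  }
})

test_that("branch n = 0 fails on an electrically long sample; continuity recovers it", {
  f <- defaultFrequencyGrid()
  L <- 0.024  # 8x the real holder: phase exceeds 2*pi at the top of the band
  eps <- evaluatePermittivity(healthyLiverModel(), f)
  nRe <- Re(sqrt(epsilonValues(eps)))
  phase <- 2 * pi * f / 299792458 * nRe * L
  expect_gt(max(phase), 2 * pi)
  expect_lt(phase[1], pi)  # continuity seed at the lowest frequency is safe
  sw <- sampleSParams(eps, L)
  fixed0 <- extractPermittivity(sw, L, nrwOptions(branchMode = "fixed"))
  errFixed <- max(Mod(epsilonValues(fixed0) - epsilonValues(eps)) /
                    Mod(epsilonValues(eps)))
  expect_gt(errFixed, 0.1)
  cont <- extractPermittivity(sw, L, nrwOptions(branchMode = "continuity"))
  expect_equal(epsilonValues(cont), epsilonValues(eps), tolerance = 1e-6)
  # phase accumulates downward (e^{-i phi}), so the unwrap uses negative n
  expect_lt(min(cont@branch), 0L)
})

test_that("reciprocal-mean port averaging is the identity on symmetric data", {
  f <- tinyGrid()
  eps <- evaluatePermittivity(fattyLiverModel(), f)
  sw <- sampleSParams(eps, 0.003)
  a <- extractPermittivity(sw, 0.003, nrwOptions())
  b <- extractPermittivity(sw, 0.003,
                           nrwOptions(portAverage = "reciprocal-mean"))
  expect_equal(epsilonValues(a), epsilonValues(b), tolerance = 1e-12)
})

test_that("non-physical |T| >= 1 is flagged, not fatal", {
  f <- tinyGrid()
  sw <- twoPortSweep(f, s11 = rep(0.2 + 0i, 5),
                     s21 = 1.05 * exp(-1i * 2 * pi * f / 299792458 * 0.003))
  expect_warning(eps <- extractPermittivity(sw, 0.003), "\\|T\\| >= 1")
  expect_true(any(eps@flags == 1L))
})
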