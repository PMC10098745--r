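# Cohort generator: structure, determinism, noise model, recovery.

test_that("default cohort has 6 control and 10 HFS animals, all valid", {
  co <- generateCohort(cohortConfig(seed = 1, nPoints = 20L))
  expect_length(co, 16)
  grp <- vapply(co, function(s) s@group, character(1))
  expect_equal(sum(grp == "control"), 6)
  expect_equal(sum(grp == "HFS"), 10)
  ids <- vapply(co, function(s) s@animalId, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  for (s in co) {
    expect_true(validObject(s, test = TRUE))
    expect_true(all(s@biochemistry > 0))
  }
})

test_that("degenerate generator (sd = 0, noise = 0) hits the anchors exactly", {
  cfg <- cohortConfig(seed = 2, sdControl = 0, sdHfs = 0, magSd = 0,
                      phaseSdDeg = 0, nPoints = 20L)
  co <- generateCohort(cfg)
  spectra <- extractCohortSpectra(co)
  for (s in co) {
    e <- Re(epsilonAt(spectra[[s@animalId]], 1e9))
    target <- if (s@group == "control") 42 else 31
    expect_equal(e, target, tolerance = 1e-6)
  }
})

test_that("noiseless pipeline recovers each animal's model spectrum to 1e-6", {
  cfg <- cohortConfig(seed = 5, magSd = 0, phaseSdDeg = 0, nPoints = 20L)
  co <- generateCohort(cfg)
  spectra <- extractCohortSpectra(co)
  f <- configFrequencyGrid(cfg)
  for (s in co) {
    truth <- epsilonValues(evaluatePermittivity(s@tissueModel, f))
    got <- epsilonValues(spectra[[s@animalId]])
    expect_lt(max(Mod(got - truth) / Mod(truth)), 1e-6)
  }
})

test_that("same config and seed give byte-identical fixture files", {
  cfg <- cohortConfig(seed = 9, nPoints = 20L, nControl = 2L, nHfs = 2L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  saveCohortFixtures(generateCohort(cfg), d1)
  saveCohortFixtures(generateCohort(cfg), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (fn in f1)
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
})

test_that("pooled TG-permittivity association is negative by construction", {
  co <- generateCohort(cohortConfig(seed = 1, nPoints = 20L))
  a <- associationAtFrequency(co, 1e9,
                              suppressWarnings(extractCohortSpectra(co)))
  expect_lt(a$pearson[["tg_liver"]], 0)
  tg <- a$table$tg_liver_mmol_per_100g
  hfs <- a$table$group == "HFS"
  expect_true(all(tg[hfs] >= 20 & tg[hfs] <= 40))
  expect_true(all(tg[!hfs] < 20))
  glu <- a$table$glucose_liver_mg_per_mg_protein
  expect_true(all(glu >= 0.4 & glu <= 0.6))
})

test_that("instrument noise: identity at zero sds, deterministic under a seed", {
  sw <- sampleSParams(constSpectrum(4), 0.003)
  expect_identical(addInstrumentNoise(sw, 0, 0), sw)
  n1 <- addInstrumentNoise(sw, 0.01, 0.5, seed = 33)
  n2 <- addInstrumentNoise(sw, 0.01, 0.5, seed = 33)
  expect_identical(n1@s21, n2@s21)
  expect_false(identical(n1@s21, sw@s21))
})

test_that("1% magnitude noise keeps 1 GHz extraction error mostly under 5%", {
  sw <- sampleSParams(permittivitySpectrum(1e9, 4 + 0i), 0.003)
  errs <- vapply(1:100, function(s) {
    noisy <- addInstrumentNoise(sw, 0.01, 0, seed = s)
    got <- suppressWarnings(
      Re(epsilonValues(extractPermittivity(noisy, 0.003))))
    abs(got - 4) / 4
  }, numeric(1))
  expect_lt(unname(quantile(errs, 0.9)), 0.05)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(cohortConfig(nControl = 1), "n >= 2")
  expect_error(cohortConfig(sdControl = -1), "sds must be >= 0")
  expect_error(cohortConfig(fStart = 2e9, fStop = 1e9), "frequency grid")
  # anchors far below eps_inf cannot be drawn
  expect_error(generateCohort(cohortConfig(meanControl = 6.5, sdControl = 0,
                                           seed = 1, nPoints = 20L)),
               "feasible")
})
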