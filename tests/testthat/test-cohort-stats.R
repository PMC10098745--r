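# Group summaries, diminutions, test chain, association table.

test_that("identical spectra summarize to zero spread and a +/-10% band", {
  sp <- constSpectrum(40 - 5i)
  s <- summarizeGroupSpectra(list(sp, sp, sp), "control")
  expect_equal(s$n, 3)
  expect_equal(s$table$sd_real, rep(0, 5))
  expect_equal(s$table$sem_imag, rep(0, 5))
  expect_equal(s$table$band_lo_real, rep(36, 5))
  expect_equal(s$table$band_hi_real, rep(44, 5))
})

test_that("two-spectrum summary matches hand arithmetic (n-1 sd, sem)", {
  s <- summarizeGroupSpectra(list(constSpectrum(40 - 0i),
                                  constSpectrum(44 - 0i)), "control")
  expect_equal(s$table$mean_real, rep(42, 5))
  expect_equal(s$table$sd_real, rep(2 * sqrt(2), 5))
  expect_equal(s$table$sem_real, rep(2, 5))
})

test_that("mismatched grids are rejected", {
  expect_error(
    summarizeGroupSpectra(list(constSpectrum(40), constSpectrum(40, 1e9)),
                          "g"),
    "common frequency grid")
})

test_that("percent diminution reproduces the noiseless group contrast", {
  f <- defaultFrequencyGrid()
  ctrl <- recoverSpectrum(evaluatePermittivity(healthyLiverModel(), f))
  hfs <- recoverSpectrum(evaluatePermittivity(fattyLiverModel(), f))
  sc <- summarizeGroupSpectra(list(ctrl, ctrl), "control")
  sh <- summarizeGroupSpectra(list(hfs, hfs), "HFS")
  expect_equal(percentDiminution(sc, sh, 1e9, "imag"), 35, tolerance = 1e-3)
  # the 1 GHz real-part anchors give (42-31)/42 = 26.19%
  expect_equal(percentDiminution(sc, sh, 1e9, "real"), 26.19,
               tolerance = 1e-3)
  expect_equal(percentDiminution(sc, sc, 1e9, "real"), 0)
  expect_equal(percentDiminution(sc, sc, 1e9, "imag"), 0)
})

test_that("comparison chain matches hand-computed pooled t-test", {
  r <- compareGroups(c(1, 2, 3, 4), c(3, 4, 5, 6))
  # closed form: sp^2 = 5/3, t = -2/0.912871 = -2.190890, p = 2*pt(t, 6)
  expect_equal(r$t_test$statistic, -2.190890, tolerance = 1e-6)
  expect_equal(r$t_test$df, 6)
  expect_equal(r$t_test$p_value, 0.070988, tolerance = 1e-5)
  expect_equal(r$normality_a$method, "shapiro-wilk")
  expect_true(r$normality_a$p_value >= 0 && r$normality_a$p_value <= 1)

  # swapping groups negates t, leaves p unchanged
  r2 <- compareGroups(c(3, 4, 5, 6), c(1, 2, 3, 4))
  expect_equal(r2$t_test$statistic, -r$t_test$statistic)
  expect_equal(r2$t_test$p_value, r$t_test$p_value)
})

test_that("degenerate variances are handled as specified", {
  r <- compareGroups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$t_test$statistic, 0)
  expect_equal(r$t_test$p_value, 1)
  expect_error(compareGroups(c(2, 2, 2), c(3, 3, 3)),
               "degenerate variance")
})

test_that("Welch option changes df but not the two-tailed symmetry", {
  a <- c(1, 2, 3, 4, 8)
  b <- c(3, 4, 5, 6)
  rp <- compareGroups(a, b)
  rw <- compareGroups(a, b, welch = TRUE)
  expect_false(isTRUE(all.equal(rp$t_test$df, rw$t_test$df)))
})

test_that("association table recovers exact linear covariates", {
  # 20-point grid keeps 1 GHz on the grid (100 MHz spacing)
  co <- generateCohort(cohortConfig(seed = 4, magSd = 0, phaseSdDeg = 0,
                                    nPoints = 20L))
  spectra <- extractCohortSpectra(co)
  a <- associationAtFrequency(co, 1e9, spectra)
  expect_equal(nrow(a$table), 16)
  expect_true(all(c("animal_id", "group", "eps_real") %in% names(a$table)))
  # replace covariates with exact +/- linear functions of eps'
  co2 <- lapply(co, function(s) {
    sp <- spectra[[s@animalId]]
    e <- Re(epsilonAt(sp, 1e9))
    b <- s@biochemistry
    b[["tg_liver_mmol_per_100g"]] <- 100 - e
    b[["glucose_liver_mg_per_mg_protein"]] <- 2 * e
    cohortSample(s@animalId, s@group, s@tissueModel, b, s@measurementSet)
  })
  a2 <- associationAtFrequency(co2, 1e9, spectra)
  expect_equal(unname(a2$pearson["tg_liver"]), -1)
  expect_equal(unname(a2$pearson["glucose_liver"]), 1)
  # constant covariate: undefined correlation reported as NA
  co3 <- lapply(co, function(s) {
    b <- s@biochemistry
    b[["tg_liver_mmol_per_100g"]] <- 30
    cohortSample(s@animalId, s@group, s@tissueModel, b, s@measurementSet)
  })
  a3 <- associationAtFrequency(co3, 1e9, spectra)
  expect_true(is.na(a3$pearson["tg_liver"]))
})

test_that("default synthetic control group recovers its anchor mean", {
  co <- generateCohort(cohortConfig(seed = 1))
  spectra <- suppressWarnings(extractCohortSpectra(co))
  grp <- vapply(co, function(s) s@group, character(1))
  sc <- summarizeGroupSpectra(spectra[grp == "control"], "control")
  i <- which(sc$frequencies == 1e9)
  expect_lt(abs(sc$table$mean_real[i] - 42), 2 * sc$table$sem_real[i] + 1e-9)
})

test_that("t-test rejection rate under the null is near alpha", {
  set.seed(123)
  rej <- 0
  nrep <- 400
  for (i in seq_len(nrep)) {
    r <- compareGroups(rnorm(6), rnorm(10))
    if (r$t_test$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / nrep, 0.02)
  expect_lt(rej / nrep, 0.09)
})
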