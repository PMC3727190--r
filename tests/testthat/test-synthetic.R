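# Synthetic reaction-monitoring generator: peaks, kinetics, determinism,
# Beer-Lambert exactness, and the benchmark scenario calibration.

test_that("generatePureSpectra evaluates peak profiles on the axis", {
  axis <- seq(100, 300, by = 10)
  K <- generatePureSpectra(list(p = list(list(center = 200, width = 20,
                                              amplitude = 1.5))), axis)
  expect_equal(dim(K), c(1L, length(axis)))
  expect_equal(unname(K[1, axis == 200]), 1.5)              # peak amplitude
  expect_equal(unname(K[1, axis == 220]), 1.5 * exp(-0.5), tolerance = 1e-12)
  # empty peak list: zero spectrum
  K0 <- generatePureSpectra(list(z = list()), axis)
  expect_equal(unname(K0[1, ]), numeric(length(axis)))
  # lorentzian half-maximum at one width from the center
  Kl <- generatePureSpectra(list(l = list(list(center = 200, width = 20,
                                               amplitude = 1, shape = "lorentzian"))),
                            axis)
  expect_equal(unname(Kl[1, axis == 220]), 0.5)
  expect_error(generatePureSpectra(list(list(list(center = 999, width = 5,
                                                  amplitude = 1))), axis),
               "outside")
})

test_that("kineticProfiles follows the closed-form sequential solution", {
  out <- kineticProfiles(1, 1, 0.5, c(0, 1))
  expect_equal(unname(out[1, ]), c(1, 0, 0))                # initial condition
  expect_equal(unname(out[2, "A"]), exp(-1))
  expect_equal(unname(out[2, "B"]), 1 / (0.5 - 1) * (exp(-1) - exp(-0.5)),
               tolerance = 1e-12)
  expect_equal(unname(rowSums(out)), c(1, 1))               # mass conservation
  expect_error(kineticProfiles(1, 2, 2, 0:1), "differ")
  expect_error(kineticProfiles(-1, 1, 2, 0:1), "positive")
})

test_that("kinetic profiles have the expected shapes over a long horizon", {
  tt <- seq(0, 50, length.out = 200)
  out <- kineticProfiles(0.46, 1.6, 0.055, tt)
  expect_true(all(diff(out[, "A"]) < 0))                    # reactant decays
  expect_true(all(diff(out[, "C"]) > 0))                    # product grows
  b <- out[, "B"]
  peak <- which.max(b)
  expect_true(all(diff(b[seq_len(peak)]) > 0))              # unimodal rise
  expect_true(all(diff(b[peak:length(b)]) < 0))             # then fall
  expect_equal(unname(rowSums(out)), rep(0.46, 200), tolerance = 1e-12)
})

test_that("the paperlike axis matches the stated grid arithmetic", {
  sc <- benchmarkScenario("paperlike")
  axis <- seq(sc@axisStart, sc@axisStop, by = sc@axisStep)
  expect_equal(length(axis), 1636L)
  expect_equal(axis[1], 230)
  expect_equal(axis[length(axis)], 3500)
})

test_that("generateDataset is deterministic given scenario and seed", {
  sc <- benchmarkScenario("demo", seed = 5L)
  r1 <- generateDataset(sc)
  r2 <- generateDataset(sc)
  expect_equal(intensities(r1), intensities(r2))
  expect_equal(concentrations(r1), concentrations(r2))
  r3 <- generateDataset(sc, seed = 6L)
  expect_false(isTRUE(all.equal(intensities(r1), intensities(r3))))
})

test_that("clean-scenario spectra are exact Beer-Lambert mixtures", {
  re <- generateDataset(benchmarkScenario("clean"))
  gt <- S4Vectors::metadata(re)$groundTruth
  expect_equal(intensities(re), unname(concentrations(re) %*% gt$K),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(gt$C), unname(concentrations(re)))
})

test_that("benchmark layout: 110 samples in 7 batches, concentrations in range", {
  re <- generateDataset(benchmarkScenario("paperlike"))
  expect_equal(ncol(re), 110L)
  expect_equal(nrow(re), 1636L)
  b <- SummarizedExperiment::colData(re)$batch
  expect_equal(length(unique(b)), 7L)
  C <- concentrations(re)
  expect_equal(colnames(C), c("PA", "ST", "EB"))
  expect_true(all(C >= -1e-12))
  expect_true(all(abs(apply(C, 2, max) - c(0.46, 0.41, 0.38)) < 0.06))
})

test_that("the target's correlation with the other species sits in the study window", {
  C <- concentrations(generateDataset(benchmarkScenario("paperlike")))
  expect_lt(abs(cor(C[, "PA"], C[, "ST"])^2 - 0.24), 0.15)
  expect_lt(abs(cor(C[, "PA"], C[, "EB"])^2 - 0.44), 0.15)
})

test_that("the spectral residual of an interferent scenario points along its pure spectrum", {
  sc <- benchmarkScenario("paperlike")
  sc@noiseSd <- 0
  sc@interferents <- sc@interferents[1]   # keep only the spectral component
  re <- generateDataset(sc)
  gt <- S4Vectors::metadata(re)$groundTruth
  resid <- intensities(re) - concentrations(re) %*% gt$K[1:3, ]
  sv <- svd(resid, nu = 0, nv = 1)
  ki <- gt$K["interferent1", ]
  cosine <- abs(sum(sv$v * ki)) / sqrt(sum(ki^2))
  expect_gt(cosine, 0.99)
})

test_that("scenario validity catches inconsistent designs", {
  expect_error(syntheticScenario("x", samplesPerBatch = 10L,
                                 peaks = vector("list", 3L), k1 = 1, k2 = 1),
               "k1 and k2")
  expect_error(syntheticScenario("x", samplesPerBatch = c(5L, 1L),
                                 peaks = vector("list", 3L)),
               "at least 2 samples")
  expect_error(syntheticScenario("x", samplesPerBatch = 10L,
                                 peaks = vector("list", 2L)),
               "peak set per analyte")
})

test_that("interferent concentration profiles have their designed shapes", {
  u <- seq(0, 1, length.out = 101)
  expect_equal(augCLS:::.interferentProfile(list(profile = "increasing"), u), u)
  bell <- augCLS:::.interferentProfile(list(profile = "bell"), u)
  expect_equal(max(bell), 1)
  expect_equal(bell[u == 0.5], 1)
  osc <- augCLS:::.interferentProfile(list(profile = "oscillating", cycles = 2), u)
  expect_true(all(osc >= 0 & osc <= 1))
  expect_equal(osc[1], 0.5)
  expect_error(augCLS:::.interferentProfile(list(profile = "sawtooth"), u),
               "unknown interferent profile")
})
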