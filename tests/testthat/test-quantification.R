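test_that("bucketing partitions the axis and conserves the integral", {
  ## grid step chosen so buckets align with the axis
  x <- seq(0, 10, by = 0.0005)
  y <- 1 + sin(x)
  sp <- nmrSpectrum(x, complex(real = y, imaginary = 0), smallAcq())
  bins <- binSpectrum(sp, 0.002)
  total <- trapzIntegral(x, y)
  expect_equal(sum(bins$value), total, tolerance = 1e-9)
  expect_equal(unique(round(bins$hi - bins$lo, 12)), 0.002)
  ## constant intensity: every full bucket holds c * width
  spc <- nmrSpectrum(x, complex(real = rep(3, length(x))), smallAcq())
  bc <- binSpectrum(spc, 0.002)
  full <- bc$value[bc$hi <= 10]
  expect_equal(full, rep(3 * 0.002, length(full)), tolerance = 1e-9)
  expect_error(binSpectrum(sp, 20), "span")
})

test_that("region integration matches the Lorentzian closed form", {
  gamma <- 0.01                     # HWHM in ppm
  x <- seq(-3, 3, length.out = 200001)
  y <- (1 / pi) * gamma / (x^2 + gamma^2)   # unit-area Lorentzian
  sp <- nmrSpectrum(x, complex(real = y), smallAcq())
  a <- integrateRegion(sp, c(-20 * gamma, 20 * gamma))
  expect_equal(a, (2 / pi) * atan(20), tolerance = 1e-4)
  expect_equal(integrateRegion(sp, c(0.5, 0.5)), 0)    # empty region
  expect_error(integrateRegion(sp, c(2, 5)), "outside")
  ## tiny negative integrals floored at zero with a warning
  spn <- nmrSpectrum(x, complex(real = rep(-1e-9, length(x))), smallAcq())
  expect_warning(v <- integrateRegion(spn, c(-1, 1)), "floored")
  expect_equal(v, 0)
})

test_that("saturation factor and relaxation correction match closed forms", {
  expect_equal(saturationFactor(0, 1), 0)
  expect_equal(saturationFactor(1e9, 1), 1, tolerance = 1e-12)
  expect_equal(saturationFactor(1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_error(saturationFactor(1, 0), "T1")
  expect_equal(relaxationCorrection(1, 2, 1),
               (1 - exp(-1)) / (1 - exp(-0.5)), tolerance = 1e-12)
  expect_equal(relaxationCorrection(5, 1.7, 1.7), 1)
  expect_error(relaxationCorrection(0, 1, 1), "t = 0")
  ## fully relaxed regime: t = 26 s keeps the correction within 0.15% of 1
  for (t1m in seq(0.5, 4, by = 0.5))
    expect_lt(abs(relaxationCorrection(26, t1m, 3) - 1), 1.5e-3)
})

test_that("the internal-standard equation recovers known concentrations", {
  ref <- referenceStandard()
  ## the reference quantified against itself returns its own concentration
  expect_identical(absoluteConcentration(1, 1, 9, ref, T1m = ref@t1, t = 26),
                   0.2915)
  ## area ratio 2 with 4 protons, fully relaxed
  expect_equal(absoluteConcentration(2, 1, 4, ref, T1m = ref@t1, t = 1e6),
               9 * 0.2915 / 4 * 2, tolerance = 1e-12)
  expect_equal(absoluteConcentration(0, 1, 4, ref, T1m = 1.5), 0)
  expect_error(absoluteConcentration(1, 0, 4, ref, T1m = 1.5),
               "reference integral")
  ## monotonicity: increasing in Am, decreasing in Nm
  a <- vapply(c(1, 2, 3), function(Am)
    absoluteConcentration(Am, 1, 4, ref, T1m = 1.5), numeric(1))
  expect_true(all(diff(a) > 0))
  b <- vapply(c(1, 2, 9), function(Nm)
    absoluteConcentration(1, 1, Nm, ref, T1m = 1.5), numeric(1))
  expect_true(all(diff(b) < 0))
})

test_that("tissue conversion is the volume/mass ratio", {
  expect_equal(tissueConcentration(1, 0.6, 0.05), 12)
  expect_equal(tissueConcentration(0, 0.6, 0.05), 0)
  expect_equal(tissueConcentration(1, 0.6, 0.1),
               tissueConcentration(1, 0.6, 0.05) / 2)
  expect_error(tissueConcentration(1, 0, 0.05), "> 0")
})

test_that("a simulated sample is quantified back to its true concentration", {
  lib <- defaultLibrary()
  rec <- concRecord(Succinate = 0.589, Lactate = 3.367, Glucose = 3.166)
  sp <- processFid(simulateFid(rec, lib, acq = smallAcq(),
                               noise = quietNoise()), smallProc())
  q <- suppressWarnings(quantifySample(sp, lib))
  expect_equal(q$Succinate, 0.589, tolerance = 0.01)
  expect_equal(q$units, "umol_per_g")
  qc <- attr(q, "qc")
  expect_gt(qc$reference_integral, 0)
  ## all-zero metabolites stay at the noise floor
  rec0 <- concRecord(Succinate = 0, Lactate = 0)
  sp0 <- processFid(simulateFid(rec0, lib, acq = smallAcq(),
                                noise = quietNoise()), smallProc())
  q0 <- suppressWarnings(quantifySample(sp0, lib))
  expect_lt(q0$Succinate, 0.01)
})

test_that("the T1 correction is exercised at short relaxation times", {
  ## at t = 0.8 s signals are far from relaxed; supplying the correct T1
  ## restores the concentration, forcing the correction to 1 leaves the
  ## known saturation bias
  lib <- metaboliteLibrary(list(
    metaboliteSpec("Succinate", 2.41, "singlet", protons = 4, t1 = 1.8)))
  rec <- concRecord(Succinate = 0.589)
  acq <- smallAcq(relaxTime = 0.8)
  sp <- processFid(simulateFid(rec, lib, acq = acq, noise = quietNoise()),
                   smallProc())
  q <- quantifySample(sp, lib)
  expect_equal(q$Succinate, 0.589, tolerance = 0.02)
  ## uncorrected: biased by sat(t, T1_ref)/sat(t, T1_m)
  ref <- reference(lib)
  Aref <- integrateRegion(sp, ref@quantRegion)
  Am <- integrateRegion(sp, libraryEntries(lib)$Succinate@quantRegion)
  raw <- tissueConcentration((ref@protons * ref@concentration / 4) * Am / Aref)
  expectedBias <- saturationFactor(0.8, 1.8) / saturationFactor(0.8, ref@t1)
  expect_equal(raw / 0.589, expectedBias, tolerance = 0.02)
})

test_that("recovered concentration is linear in truth over a 100x range", {
  lib <- defaultLibrary()
  truth <- 0.03 * 100^seq(0, 1, length.out = 5)  # 0.03 to 3 umol/g
  rec0 <- concRecord(Succinate = 1, Lactate = 3.367)
  got <- vapply(truth, function(v) {
    r <- rec0
    r$Succinate <- v
    sp <- processFid(simulateFid(r, lib, acq = smallAcq(),
                                 noise = quietNoise()), smallProc())
    suppressWarnings(quantifySample(sp, lib))$Succinate
  }, numeric(1))
  fit <- stats::lm(got ~ truth)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.02)
  expect_lt(abs(unname(coef(fit)[1])), 0.01)
})
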