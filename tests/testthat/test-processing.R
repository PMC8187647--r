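test_that("exponential apodization matches its closed form", {
  ## dwell of exactly 1 ms so t = 1 s falls on sample 1001
  acq <- acquisitionParams(frequency = 100, sweepWidth = 10, nPoints = 2048L)
  expect_equal(dwellTime(acq), 1e-3)
  fid <- nmrFid(rep(1 + 0i, 2048), acq)
  ap <- apodize(fid, 1)
  expect_equal(Re(fidData(ap)[1]), 1)                      # t = 0 unchanged
  expect_equal(Re(fidData(ap)[1001]), exp(-pi), tolerance = 1e-12)
  expect_identical(fidData(apodize(fid, 0)), fidData(fid)) # LB = 0 identity
  expect_error(apodize(fid, -1), ">= 0")
  expect_true("apodize" %in% provenance(ap))
})

test_that("zero-filling appends exact zeros and preserves the integral", {
  lib <- defaultLibrary()
  fid <- simulateFid(concRecord(Succinate = 1), lib, acq = smallAcq(),
                     noise = quietNoise())
  zf <- zeroFill(fid, 16384L)
  expect_equal(length(fidData(zf)), 16384L)
  expect_identical(fidData(zf)[8193:16384], complex(8192))
  expect_error(zeroFill(zf, 1024L), "smaller")
  expect_identical(fidData(zeroFill(fid, length(fidData(fid)))),
                   fidData(fid))
  ## total spectral integral unchanged by interpolation
  s0 <- fourierTransform(fid)
  s1 <- fourierTransform(zf)
  i0 <- trapzIntegral(ppm(s0), intensities(s0))
  i1 <- trapzIntegral(ppm(s1), intensities(s1))
  expect_equal(i1 / i0, 1, tolerance = 1e-3)
})

test_that("the transform yields a Lorentzian at the right shift and width", {
  acq <- smallAcq()
  dt <- dwellTime(acq)
  tvec <- (0:8191) * dt
  t2 <- 0.1
  delta <- 7.2                       # ppm
  f <- (delta - acq@carrierPpm) * acq@frequency
  fid <- nmrFid(exp(2i * pi * f * tvec - tvec / t2), acq)
  sp <- fourierTransform(zeroFill(fid, 65536L))
  y <- intensities(sp)
  pk <- which.max(y)
  step <- ppm(sp)[2] - ppm(sp)[1]
  expect_lt(abs(ppm(sp)[pk] - delta), step * 1.5)
  ## FWHM = 1/(pi T2) Hz
  half <- y[pk] / 2
  above <- which(y >= half)
  fwhmHz <- (ppm(sp)[max(above)] - ppm(sp)[min(above)]) * acq@frequency
  expect_equal(fwhmHz, 1 / (pi * t2), tolerance = 0.1)
  ## zero FID transforms to a zero spectrum
  expect_true(all(intensities(fourierTransform(nmrFid(complex(64), acq))) == 0))
})

test_that("the transform satisfies the discrete Parseval identity", {
  acq <- smallAcq()
  set.seed(3)
  s <- complex(real = rnorm(8192), imaginary = rnorm(8192))
  fid <- nmrFid(s, acq)
  sp <- fourierTransform(fid, halveFirstPoint = FALSE)
  eTime <- sum(Mod(s)^2)
  eFreq <- sum(Mod(complexIntensities(sp))^2) / length(s)
  expect_equal(eFreq / eTime, 1, tolerance = 1e-9)
})

test_that("phase correction: manual is exact and invertible, auto recovers", {
  lib <- defaultLibrary()
  fid <- simulateFid(concRecord(Succinate = 0.6, Lactate = 3), lib,
                     acq = smallAcq(), noise = quietNoise())
  sp <- fourierTransform(zeroFill(apodize(fid, 1), 16384L))
  ## manual(0, 0) is the identity
  expect_equal(complexIntensities(phaseCorrect(sp, "manual")),
               complexIntensities(sp))
  ## manual(phi) then manual(-phi) restores the spectrum
  ph <- phaseCorrect(sp, "manual", ph0 = 37, ph1 = -12)
  back <- phaseCorrect(ph, "manual", ph0 = -37, ph1 = 12)
  expect_equal(complexIntensities(back), complexIntensities(sp),
               tolerance = 1e-10)
  ## auto phasing recovers an injected zero-order error within 1 degree
  fidP <- simulateFid(concRecord(Succinate = 0.6, Lactate = 3), lib,
                      acq = smallAcq(),
                      noise = noiseModel(noiseSd = 0.002, ph0 = 30), seed = 2)
  spP <- processFid(fidP, smallProc())
  expect_lt(abs(spP@meta$phase[["ph0"]] - 30), 1)
  ## all-zero spectra cannot be phased automatically
  zero <- nmrSpectrum(ppm(sp), complex(length(ppm(sp))), smallAcq())
  expect_error(phaseCorrect(zero, "auto"), "unphaseable")
})

test_that("baseline correction removes offsets and restores integrals", {
  lib <- defaultLibrary()
  reg <- libraryEntries(lib)$Succinate@quantRegion
  rec <- concRecord(Succinate = 0.589, Lactate = 3.367)
  ## flat input is (nearly) untouched
  spFlat <- processFid(simulateFid(rec, lib, acq = smallAcq(),
                                   noise = quietNoise()), smallProc())
  corrected <- baselineCorrect(spFlat, 1)
  expect_lt(max(abs(intensities(corrected) - intensities(spFlat))),
            1e-6 * max(intensities(spFlat)))
  ## pure constant offset removed essentially exactly
  x <- seq(0, 10, length.out = 4096)
  off <- nmrSpectrum(x, rep(5 + 0i, 4096), smallAcq())
  expect_lt(max(abs(intensities(baselineCorrect(off, 0)))), 1e-6 * 5)
  ## injected linear baseline: quant integrals restored within 1%
  noiseBl <- noiseModel(noiseSd = 0.002, baselineCoeffs = c(2, 1))
  spBl <- processFid(simulateFid(rec, lib, acq = smallAcq(),
                                 noise = noiseBl, seed = 3),
                     smallProc(baselineDegree = 1L))
  spRef <- processFid(simulateFid(rec, lib, acq = smallAcq(),
                                  noise = noiseModel(noiseSd = 0.002),
                                  seed = 3), smallProc())
  expect_equal(integrateRegion(spBl, reg) / integrateRegion(spRef, reg), 1,
               tolerance = 0.01)
  expect_error(baselineCorrect(spFlat, 9), "cap")
})

test_that("axis referencing centres the reference and flags its absence", {
  lib <- defaultLibrary()
  rec <- concRecord(Succinate = 0.6)
  fid <- simulateFid(rec, lib, acq = smallAcq(), noise = quietNoise())
  sp <- baselineCorrect(phaseCorrect(
    fourierTransform(zeroFill(apodize(fid, 1), 16384L)), "manual"), 1)
  ## simulate a 0.05 ppm referencing error by shifting the axis
  shifted <- nmrSpectrum(ppm(sp) + 0.05, complexIntensities(sp), smallAcq())
  refd <- referenceShift(shifted, reference(lib))
  step <- ppm(refd)[2] - ppm(refd)[1]
  win <- which(ppm(refd) >= -0.05 & ppm(refd) <= 0.05)
  pk <- ppm(refd)[win[which.max(intensities(refd)[win])]]
  expect_lte(abs(pk), step * 1.5)                     # within one bin
  expect_lt(abs(refd@meta$referenceShift - 0.05), 1.5 * step)
  ## an already-referenced spectrum moves by at most one axis step (the
  ## maximum is ambiguous by one bin when the line straddles two samples)
  again <- referenceShift(refd, reference(lib))
  expect_lte(abs(again@meta$referenceShift), step)
  ## no reference signal -> error
  noref <- nmrSpectrum(ppm(sp), complex(length(ppm(sp))), smallAcq())
  expect_error(referenceShift(noref, reference(lib)), "reference not found")
})

test_that("the processing chain runs in fixed order and deterministically", {
  lib <- defaultLibrary()
  fid <- simulateFid(concRecord(Succinate = 0.6), lib, acq = smallAcq(),
                     noise = noiseModel(noiseSd = 0.002), seed = 4)
  sp1 <- processFid(fid, smallProc())
  expect_identical(tail(provenance(sp1), 6),
                   c("apodize", "zero_fill", "transform", "phase_correct",
                     "baseline_correct", "reference_shift"))
  sp2 <- processFid(fid, smallProc())
  expect_identical(complexIntensities(sp1), complexIntensities(sp2))
  expect_identical(ppm(sp1), ppm(sp2))
})

test_that("apodization leaves equal-T2 integral ratios invariant", {
  ## underwrites the metabolite/reference area ratio: peaks with equal T2
  ## (and commensurate integration regions) keep their integral ratio
  ## under any line broadening
  lib <- defaultLibrary()
  rec <- concRecord(Succinate = 0.589, Creatine = 1.062)
  regS <- libraryEntries(lib)$Succinate@quantRegion
  regC <- libraryEntries(lib)$Creatine@quantRegion
  ratioAt <- function(lb) {
    sp <- processFid(simulateFid(rec, lib, acq = smallAcq(),
                                 noise = quietNoise()),
                     smallProc(lineBroadening = lb))
    integrateRegion(sp, regS) / integrateRegion(sp, regC)
  }
  r0 <- ratioAt(0)
  for (lb in c(1, 3, 5)) expect_equal(ratioAt(lb) / r0, 1, tolerance = 5e-3)
})

test_that("global gain cancels out of concentration estimates", {
  lib <- defaultLibrary()
  rec <- concRecord(Succinate = 0.589)
  q1 <- suppressWarnings(
    quantifySample(processFid(simulateFid(rec, lib, acq = smallAcq(),
                                          noise = quietNoise()),
                              smallProc()), lib))
  q7 <- suppressWarnings(
    quantifySample(processFid(simulateFid(rec, lib, acq = smallAcq(),
                                          noise = quietNoise(gain = 7.3)),
                              smallProc()), lib))
  expect_equal(q7$Succinate, q1$Succinate, tolerance = 1e-9)
})
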