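#' @include AllClasses.R AllGenerics.R simulate.R
NULL

#' Exponential apodization
#'
#' Multiplies sample \code{k} of the FID by \code{exp(-pi * LB * t_k)}
#' with \code{t_k = k * dwell}, the exponential window whose line
#' broadening parameter LB (Hz) adds LB to the Lorentzian full width at
#' half maximum of every line. \code{LB = 0} is the identity.
#'
#' @param fid an [NMRFid-class].
#' @param lineBroadening line broadening in Hz (>= 0).
#' @return The apodized [NMRFid-class], with \code{"apodize"} appended to
#'   its provenance.
#' @rdname apodize
#' @export
setMethod("apodize", "NMRFid", function(fid, lineBroadening = 1) {
  if (lineBroadening < 0) stop("'lineBroadening' must be >= 0")
  tvec <- (seq_along(fid@samples) - 1) * dwellTime(fid)
  nmrFid(fid@samples * exp(-pi * lineBroadening * tvec), fid@acquisition,
         c(fid@provenance, "apodize"))
})

#' Zero-filling
#'
#' Appends exactly-zero samples to the FID up to \code{target} points,
#' interpolating the frequency axis after transformation without changing
#' integrals.
#'
#' @param fid an [NMRFid-class].
#' @param target target length; must be at least the current length.
#' @return The zero-filled [NMRFid-class] with \code{"zero_fill"} appended
#'   to its provenance.
#' @rdname zeroFill
#' @export
setMethod("zeroFill", "NMRFid", function(fid, target = 131072L) {
  n <- length(fid@samples)
  if (target < n)
    stop("zero-fill target (", target, ") is smaller than the FID (", n, ")")
  s <- c(fid@samples, complex(target - n))
  nmrFid(s, fid@acquisition, c(fid@provenance, "zero_fill"))
})

#' Discrete Fourier transformation to a ppm axis
#'
#' Transforms the (apodized, zero-filled) FID and maps the result onto an
#' ascending chemical-shift axis centred at the carrier. The first time
#' point is halved before transformation (the standard correction for the
#' half-sample offset of the discrete integral), which keeps the baseline
#' of the transformed spectrum flat and makes the total spectral integral
#' equal \code{sweepWidth x fid[0]/2} regardless of zero-filling.
#' Intensities stay complex until phased.
#'
#' @param fid an [NMRFid-class].
#' @param halveFirstPoint halve the first FID sample before the transform.
#' @return An [NMRSpectrum-class] with \code{"transform"} appended to its
#'   provenance.
#' @rdname fourierTransform
#' @export
setMethod("fourierTransform", "NMRFid", function(fid, halveFirstPoint = TRUE) {
  acq <- fid@acquisition
  s <- fid@samples
  if (halveFirstPoint) s[1] <- s[1] / 2
  n <- length(s)
  raw <- stats::fft(s)
  ord <- order(.fftFreqs(n, dwellTime(acq)))
  nmrSpectrum(.ppmAxis(acq, n), raw[ord], acq,
              c(fid@provenance, "transform"))
})

.applyPhase <- function(spec, ph0, ph1) {
  x <- (spec@ppm - spec@acquisition@carrierPpm) / spec@acquisition@sweepWidth
  spec@intensity * exp(-1i * (.deg2rad(ph0) + .deg2rad(ph1) * x))
}

#' Phase correction
#'
#' Manual mode applies exactly the given zero- and first-order phases (in
#' degrees; the first-order phase is linear across the sweep and pivots at
#' the carrier). Auto mode minimizes a negative-intensity penalty (sum of
#' squared negative real points, normalized by the total squared real
#' intensity, with a mild quadratic penalty on the first-order term to
#' resolve the near-degeneracy between the two phases) by a coarse grid
#' search followed by Nelder-Mead refinement.
#'
#' @param spec an [NMRSpectrum-class] with complex intensities.
#' @param mode \code{"auto"} or \code{"manual"}.
#' @param ph0,ph1 phases in degrees (manual mode).
#' @param searchPh1 in auto mode, also optimize the first-order phase.
#' @param decimate evaluate the auto objective on every \code{decimate}-th
#'   point for speed.
#' @param ... unused.
#' @return The phased [NMRSpectrum-class]; the applied (or recovered)
#'   phases are stored in \code{meta$phase} and \code{"phase_correct"} is
#'   appended to the provenance.
#' @rdname phaseCorrect
#' @export
setMethod("phaseCorrect", "NMRSpectrum",
  function(spec, mode = c("auto", "manual"), ph0 = 0, ph1 = 0,
           searchPh1 = TRUE, decimate = 8L, ...) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    out <- spec
    out@intensity <- .applyPhase(spec, ph0, ph1)
    out@provenance <- c(spec@provenance, "phase_correct")
    out@meta$phase <- c(ph0 = ph0, ph1 = ph1)
    return(out)
  }
  y <- spec@intensity
  if (all(Mod(y) == 0)) stop("unphaseable: all-zero spectrum")
  idx <- seq(1L, length(y), by = max(1L, as.integer(decimate)))
  ys <- y[idx]
  x <- (spec@ppm[idx] - spec@acquisition@carrierPpm) / spec@acquisition@sweepWidth
  denom <- sum(Mod(ys)^2)
  obj <- function(p) {
    r <- Re(ys * exp(-1i * (.deg2rad(p[1]) + .deg2rad(p[2]) * x)))
    neg <- pmin(r, 0)
    sum(neg^2) / denom + 1e-4 * (p[2] / 180)^2
  }
  grid0 <- seq(-170, 180, by = 10)
  grid1 <- if (searchPh1) seq(-60, 60, by = 20) else 0
  best <- NULL; bestVal <- Inf
  for (g1 in grid1) for (g0 in grid0) {
    v <- obj(c(g0, g1))
    if (v < bestVal) { bestVal <- v; best <- c(g0, g1) }
  }
  fit <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  p <- fit$par
  if (!searchPh1) p[2] <- 0
  out <- spec
  out@intensity <- .applyPhase(spec, p[1], p[2])
  out@provenance <- c(spec@provenance, "phase_correct")
  out@meta$phase <- c(ph0 = p[1], ph1 = p[2])
  out
})

#' Baseline correction
#'
#' Fits a polynomial through the signal-free points of the real channel by
#' iterative clipping: at each iteration the polynomial is refitted to the
#' points whose residual lies below \code{k} times the median absolute
#' deviation of the residuals (peaks, being large and positive, are
#' excluded after a few iterations), and the converged polynomial is
#' subtracted.
#'
#' @param spec an [NMRSpectrum-class] (phased).
#' @param degree polynomial degree (0 = constant offset); capped at 6.
#' @param k clipping threshold in MAD units.
#' @param maxIter maximum clipping iterations.
#' @param ... unused.
#' @return The corrected [NMRSpectrum-class]; fitted coefficients are in
#'   \code{meta$baseline} and \code{"baseline_correct"} is appended to the
#'   provenance.
#' @rdname baselineCorrect
#' @export
setMethod("baselineCorrect", "NMRSpectrum",
  function(spec, degree = 3L, k = 3, maxIter = 20L, ...) {
  degree <- as.integer(degree)
  if (degree < 0L) stop("'degree' must be >= 0")
  if (degree > 6L) stop("'degree' exceeds the supported cap of 6")
  y <- Re(spec@intensity)
  x <- (spec@ppm - mean(spec@ppm)) / (diff(range(spec@ppm)) / 2)
  X <- matrix(1, length(y), 1L)
  if (degree > 0L)
    X <- cbind(X, stats::poly(x, degree = degree, raw = FALSE, simple = TRUE))
  keep <- rep(TRUE, length(y))
  base <- numeric(length(y))
  for (it in seq_len(maxIter)) {
    fit <- stats::lm.fit(X[keep, , drop = FALSE], y[keep])
    base <- drop(X %*% fit$coefficients)
    res <- y - base
    sc <- stats::mad(res[keep])
    if (sc == 0) break
    newKeep <- res < k * sc & res > -2 * k * sc
    if (all(newKeep == keep)) break
    keep <- newKeep
    if (sum(keep) <= degree + 1L) break
  }
  out <- spec
  out@intensity <- complex(real = y - base, imaginary = Im(spec@intensity))
  out@provenance <- c(spec@provenance, "baseline_correct")
  out@meta$baseline <- list(degree = degree, fitted = base[c(1, length(base))],
                            nKept = sum(keep))
  out
})

#' Chemical-shift referencing
#'
#' Translates the ppm axis so that the intensity maximum inside the
#' reference search window sits at the reference's nominal shift (0.00 ppm
#' for TSP).
#'
#' @param spec an [NMRSpectrum-class] (phased, baseline-corrected).
#' @param ref a [ReferenceStandard-class].
#' @param minSnr minimum peak height, in units of the spectrum's median
#'   absolute deviation, below which the reference is declared missing.
#' @param ... unused.
#' @return The referenced [NMRSpectrum-class]; the applied shift is stored
#'   in \code{meta$referenceShift} and \code{"reference_shift"} appended to
#'   the provenance.
#' @rdname referenceShift
#' @export
setMethod("referenceShift", "NMRSpectrum",
  function(spec, ref = referenceStandard(), minSnr = 5, ...) {
  y <- Re(spec@intensity)
  win <- which(spec@ppm >= ref@searchWindow[1] & spec@ppm <= ref@searchWindow[2])
  if (length(win) == 0L) stop("reference not found: empty search window")
  noise <- stats::mad(y)
  peak <- max(y[win])
  if (!(peak > 0) || (noise > 0 && peak < minSnr * noise))
    stop("reference not found: no peak above threshold in search window")
  delta <- spec@ppm[win[which.max(y[win])]] - ref@shift
  out <- spec
  out@ppm <- spec@ppm - delta
  out@provenance <- c(spec@provenance, "reference_shift")
  out@meta$referenceShift <- delta
  out
})

#' Full FID-to-spectrum processing chain
#'
#' Applies, in fixed order: exponential apodization, zero-filling, Fourier
#' transformation, phase correction, baseline correction and
#' chemical-shift referencing. The order is recorded in the spectrum's
#' provenance.
#'
#' @param fid an [NMRFid-class].
#' @param params a [ProcessingParams-class].
#' @param ref a [ReferenceStandard-class] for axis referencing.
#' @return A referenced, absorptive [NMRSpectrum-class].
#' @examples
#' lib <- defaultLibrary()
#' rec <- sampleCohort(data.frame(metabolite = "Succinate",
#'                                mean = 0.589, sd = 0), 1, seed = 1)[1, ]
#' fid <- simulateFid(rec, lib, seed = 1)
#' sp <- processFid(fid)
#' provenance(sp)
#' @export
processFid <- function(fid, params = processingParams(),
                       ref = referenceStandard()) {
  stopifnot(is(fid, "NMRFid"), is(params, "ProcessingParams"))
  fid <- apodize(fid, params@lineBroadening)
  fid <- zeroFill(fid, max(params@zeroFillTo, length(fid@samples)))
  spec <- fourierTransform(fid)
  spec <- phaseCorrect(spec, mode = params@phaseMode,
                       ph0 = params@ph0, ph1 = params@ph1)
  spec <- baselineCorrect(spec, degree = params@baselineDegree)
  referenceShift(spec, ref)
}
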