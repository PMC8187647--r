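#' @import methods
NULL

## ---------------------------------------------------------------------------
## Acquisition parameters
## ---------------------------------------------------------------------------

#' Acquisition parameters for a 1D 1H-NMR experiment
#'
#' Holds the spectrometer and pulse-program settings that determine the time
#' and frequency axes of a free-induction decay: proton frequency,
#' spectral width, number of complex points, number of co-added transients
#' and the total relaxation time (recycle delay plus acquisition time) that
#' governs T1 saturation of the signal integrals.
#'
#' @slot frequency spectrometer proton frequency in MHz.
#' @slot sweepWidth spectral width in ppm.
#' @slot nPoints number of complex time-domain points acquired.
#' @slot nTransients number of co-added transients (affects noise scaling
#'   only; transients are not simulated individually).
#' @slot relaxTime total relaxation time in seconds between excitations; a
#'   resonance with spin-lattice time T1 is attenuated by
#'   \code{1 - exp(-relaxTime/T1)}.
#' @slot carrierPpm chemical shift (ppm) at the centre of the sweep.
#'
#' @seealso [acquisitionParams()]
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
  representation(
    frequency   = "numeric",
    sweepWidth  = "numeric",
    nPoints     = "integer",
    nTransients = "integer",
    relaxTime   = "numeric",
    carrierPpm  = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character(0)
  for (s in c("frequency", "sweepWidth", "relaxTime")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive finite number", s))
  }
  if (length(object@nPoints) != 1L || object@nPoints < 2L)
    msg <- c(msg, "'nPoints' must be >= 2")
  if (length(object@nTransients) != 1L || object@nTransients < 1L)
    msg <- c(msg, "'nTransients' must be >= 1")
  if (length(object@carrierPpm) != 1L || !is.finite(object@carrierPpm))
    msg <- c(msg, "'carrierPpm' must be a single finite number")
  if (length(msg) == 0L) {
    dw <- 1 / (object@sweepWidth * object@frequency)
    if (!is.finite(dw) || dw <= 0)
      msg <- c(msg, "dwell time must be finite and positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct acquisition parameters
#'
#' Defaults correspond to a standard 600 MHz tissue-extract acquisition:
#' 64 transients of 32k complex points over a 20 ppm sweep with a total
#' relaxation time of 26 s, long enough that all signals are essentially
#' fully relaxed.
#'
#' @param frequency spectrometer proton frequency (MHz).
#' @param sweepWidth spectral width (ppm).
#' @param nPoints number of complex points.
#' @param nTransients number of transients.
#' @param relaxTime total relaxation time (s), i.e. recycle delay plus
#'   acquisition time.
#' @param carrierPpm chemical shift at the centre of the sweep (ppm).
#' @return An [AcquisitionParams-class] object.
#' @examples
#' acq <- acquisitionParams()
#' dwellTime(acq)   # 1/(20 * 600.13) seconds
#' @export
acquisitionParams <- function(frequency = 600.13, sweepWidth = 20,
                              nPoints = 32768L, nTransients = 64L,
                              relaxTime = 26, carrierPpm = 4.7) {
  new("AcquisitionParams",
      frequency = as.numeric(frequency), sweepWidth = as.numeric(sweepWidth),
      nPoints = as.integer(nPoints), nTransients = as.integer(nTransients),
      relaxTime = as.numeric(relaxTime), carrierPpm = as.numeric(carrierPpm))
}

## ---------------------------------------------------------------------------
## Processing parameters
## ---------------------------------------------------------------------------

#' Processing parameters for the FID-to-spectrum chain
#'
#' @slot lineBroadening exponential apodization line broadening in Hz.
#' @slot zeroFillTo target length (complex points) after zero-filling.
#' @slot baselineDegree polynomial degree for automated baseline correction.
#' @slot binWidth bucket width in ppm for binned export.
#' @slot phaseMode either \code{"auto"} or \code{"manual"}.
#' @slot ph0,ph1 zero- and first-order phases in degrees (used when
#'   \code{phaseMode == "manual"}).
#' @seealso [processingParams()], [processFid()]
#' @exportClass ProcessingParams
setClass("ProcessingParams",
  representation(
    lineBroadening = "numeric",
    zeroFillTo     = "integer",
    baselineDegree = "integer",
    binWidth       = "numeric",
    phaseMode      = "character",
    ph0            = "numeric",
    ph1            = "numeric"
  )
)

setValidity("ProcessingParams", function(object) {
  msg <- character(0)
  if (object@lineBroadening < 0) msg <- c(msg, "'lineBroadening' must be >= 0")
  if (object@zeroFillTo < 2L) msg <- c(msg, "'zeroFillTo' must be >= 2")
  if (object@baselineDegree < 0L) msg <- c(msg, "'baselineDegree' must be >= 0")
  if (object@binWidth <= 0) msg <- c(msg, "'binWidth' must be > 0")
  if (!object@phaseMode %in% c("auto", "manual"))
    msg <- c(msg, "'phaseMode' must be \"auto\" or \"manual\"")
  if (length(msg)) msg else TRUE
})

#' Construct processing parameters
#'
#' Defaults follow common quantitative practice: 1 Hz exponential line
#' broadening, zero-filling to 128k points, automated phasing, cubic
#' baseline model and 0.002 ppm buckets for the binned export.
#'
#' @param lineBroadening exponential line broadening (Hz).
#' @param zeroFillTo zero-fill target length (complex points).
#' @param baselineDegree baseline polynomial degree.
#' @param binWidth bucket width (ppm).
#' @param phaseMode \code{"auto"} or \code{"manual"}.
#' @param ph0,ph1 manual zero-/first-order phase (degrees).
#' @return A [ProcessingParams-class] object.
#' @export
processingParams <- function(lineBroadening = 1, zeroFillTo = 131072L,
                             baselineDegree = 3L, binWidth = 0.002,
                             phaseMode = c("auto", "manual"),
                             ph0 = 0, ph1 = 0) {
  phaseMode <- match.arg(phaseMode)
  new("ProcessingParams",
      lineBroadening = as.numeric(lineBroadening),
      zeroFillTo = as.integer(zeroFillTo),
      baselineDegree = as.integer(baselineDegree),
      binWidth = as.numeric(binWidth), phaseMode = phaseMode,
      ph0 = as.numeric(ph0), ph1 = as.numeric(ph1))
}

## ---------------------------------------------------------------------------
## Reference standard and metabolite library
## ---------------------------------------------------------------------------

#' Internal concentration reference standard
#'
#' Describes the chemical-shift and concentration reference added to every
#' sample (by default TSP, trimethylsilyl propionate: nine equivalent methyl
#' protons resonating at 0.00 ppm).
#'
#' @slot name reference compound name.
#' @slot concentration in-tube concentration in mM.
#' @slot protons number of protons contributing to the reference signal
#'   (nine for the TSP methyl groups).
#' @slot t1 spin-lattice relaxation time (s) of the reference protons.
#' @slot shift nominal chemical shift (ppm).
#' @slot searchWindow ppm interval searched for the reference maximum when
#'   referencing the axis.
#' @slot quantRegion ppm interval integrated for the reference area.
#' @seealso [referenceStandard()]
#' @exportClass ReferenceStandard
setClass("ReferenceStandard",
  representation(
    name          = "character",
    concentration = "numeric",
    protons       = "integer",
    t1            = "numeric",
    shift         = "numeric",
    searchWindow  = "numeric",
    quantRegion   = "numeric"
  )
)

setValidity("ReferenceStandard", function(object) {
  msg <- character(0)
  if (object@concentration <= 0) msg <- c(msg, "'concentration' must be > 0")
  if (object@protons < 1L) msg <- c(msg, "'protons' must be >= 1")
  if (object@t1 <= 0) msg <- c(msg, "'t1' must be > 0")
  for (s in c("searchWindow", "quantRegion")) {
    v <- slot(object, s)
    if (length(v) != 2L || v[1] >= v[2])
      msg <- c(msg, sprintf("'%s' must be an interval c(lo, hi) with lo < hi", s))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a reference standard
#'
#' @param name compound name.
#' @param concentration in-tube concentration (mM).
#' @param protons number of contributing protons.
#' @param t1 spin-lattice relaxation time (s).
#' @param shift nominal chemical shift (ppm).
#' @param searchWindow ppm window searched during axis referencing.
#' @param quantRegion ppm region integrated for the reference area.
#' @return A [ReferenceStandard-class] object. Defaults describe TSP at
#'   0.2915 mM with nine methyl protons at 0.00 ppm.
#' @export
referenceStandard <- function(name = "TSP", concentration = 0.2915,
                              protons = 9L, t1 = 3.0, shift = 0,
                              searchWindow = c(-0.05, 0.05),
                              quantRegion = c(-0.03, 0.03)) {
  new("ReferenceStandard", name = name,
      concentration = as.numeric(concentration), protons = as.integer(protons),
      t1 = as.numeric(t1), shift = as.numeric(shift),
      searchWindow = as.numeric(searchWindow),
      quantRegion = as.numeric(quantRegion))
}

#' Per-metabolite quantification specification
#'
#' @slot name metabolite name.
#' @slot peaks data.frame with one row per multiplet: columns \code{center}
#'   (ppm), \code{pattern} (singlet/doublet/triplet/quartet), \code{j}
#'   (coupling constant, Hz) and \code{protons}.
#' @slot quantRegion half-open ppm interval \code{[lo, hi)} integrated for
#'   quantification.
#' @slot protons number of protons giving rise to the quantified signal.
#' @slot t1 spin-lattice relaxation time (s).
#' @seealso [metaboliteSpec()], [MetaboliteLibrary-class]
#' @exportClass MetaboliteSpec
setClass("MetaboliteSpec",
  representation(
    name        = "character",
    peaks       = "data.frame",
    quantRegion = "numeric",
    protons     = "integer",
    t1          = "numeric"
  )
)

.patterns <- c("singlet", "doublet", "triplet", "quartet")

setValidity("MetaboliteSpec", function(object) {
  msg <- character(0)
  pk <- object@peaks
  need <- c("center", "pattern", "j", "protons")
  if (!all(need %in% names(pk)))
    msg <- c(msg, "peaks must have columns center, pattern, j, protons")
  else {
    if (!all(pk$pattern %in% .patterns))
      msg <- c(msg, "peak pattern must be singlet, doublet, triplet or quartet")
    if (any(pk$protons < 1)) msg <- c(msg, "peak protons must be >= 1")
    if (any(pk$j < 0)) msg <- c(msg, "J couplings must be >= 0")
  }
  if (length(object@quantRegion) != 2L ||
      object@quantRegion[1] >= object@quantRegion[2])
    msg <- c(msg, "'quantRegion' must be c(lo, hi) with lo < hi")
  if (object@protons < 1L) msg <- c(msg, "'protons' must be >= 1")
  if (object@t1 <= 0)
    msg <- c(msg, sprintf("missing or non-positive T1 for '%s'", object@name))
  if (length(msg)) msg else TRUE
})

#' Construct a metabolite quantification spec
#'
#' If \code{quantRegion} is omitted it is derived from the (single) peak as
#' the multiplet span plus a symmetric margin, which keeps Lorentzian tail
#' truncation commensurate with the reference region.
#'
#' @param name metabolite name.
#' @param center multiplet centre (ppm).
#' @param pattern multiplicity: "singlet", "doublet", "triplet" or "quartet".
#' @param j scalar coupling (Hz); ignored for singlets.
#' @param protons proton count of the quantified signal.
#' @param t1 spin-lattice relaxation time (s).
#' @param quantRegion optional explicit ppm interval \code{c(lo, hi)}.
#' @param margin region margin (ppm) beyond the outermost multiplet lines
#'   when \code{quantRegion} is derived.
#' @param frequency spectrometer frequency (MHz) used to convert J to ppm
#'   when deriving the region.
#' @return A [MetaboliteSpec-class] object.
#' @examples
#' metaboliteSpec("Succinate", 2.41, "singlet", protons = 4, t1 = 1.8)
#' @export
metaboliteSpec <- function(name, center, pattern = "singlet", j = 0,
                           protons = 1L, t1 = 1.5, quantRegion = NULL,
                           margin = 0.03, frequency = 600.13) {
  pattern <- match.arg(pattern, .patterns)
  pk <- data.frame(center = as.numeric(center), pattern = pattern,
                   j = as.numeric(j), protons = as.numeric(protons),
                   stringsAsFactors = FALSE)
  if (is.null(quantRegion)) {
    nlines <- match(pattern, .patterns)           # 1..4 lines
    halfspan <- (nlines - 1) * j / 2 / frequency  # ppm
    quantRegion <- c(center - halfspan - margin, center + halfspan + margin)
  }
  new("MetaboliteSpec", name = name, peaks = pk,
      quantRegion = as.numeric(quantRegion), protons = as.integer(protons),
      t1 = as.numeric(t1))
}

#' Library of metabolite quantification specs plus the reference standard
#'
#' Validity enforces unique names and pairwise-disjoint quantification
#' regions (also disjoint from the reference search window), i.e. the
#' resolved-resonance assumption that plain region integration requires.
#'
#' @slot entries named list of [MetaboliteSpec-class] objects.
#' @slot reference the [ReferenceStandard-class].
#' @seealso [metaboliteLibrary()], [defaultLibrary()], [loadLibrary()]
#' @exportClass MetaboliteLibrary
setClass("MetaboliteLibrary",
  representation(entries = "list", reference = "ReferenceStandard")
)

.regionsOverlap <- function(a, b) a[1] < b[2] && b[1] < a[2]

setValidity("MetaboliteLibrary", function(object) {
  msg <- character(0)
  if (!all(vapply(object@entries, is, logical(1), class2 = "MetaboliteSpec")))
    msg <- c(msg, "all entries must be MetaboliteSpec objects")
  else {
    nms <- vapply(object@entries, function(e) e@name, character(1))
    if (anyDuplicated(nms))
      msg <- c(msg, sprintf("duplicated metabolite names: %s",
                            paste(unique(nms[duplicated(nms)]), collapse = ", ")))
    regs <- lapply(object@entries, function(e) e@quantRegion)
    n <- length(regs)
    if (n > 1L) {
      ## order-independent pairwise check
      for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
        if (.regionsOverlap(regs[[i]], regs[[k]]))
          msg <- c(msg, sprintf(
            "quantification regions of '%s' and '%s' overlap",
            nms[i], nms[k]))
      }
    }
    for (i in seq_len(n)) {
      if (.regionsOverlap(regs[[i]], object@reference@searchWindow))
        msg <- c(msg, sprintf(
          "quantification region of '%s' overlaps the reference search window",
          nms[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a metabolite library
#'
#' @param entries list of [MetaboliteSpec-class] objects.
#' @param reference a [ReferenceStandard-class].
#' @return A validated [MetaboliteLibrary-class]; overlapping quantification
#'   regions are rejected with an error naming both metabolites.
#' @export
metaboliteLibrary <- function(entries, reference = referenceStandard()) {
  if (is(entries, "MetaboliteSpec")) entries <- list(entries)
  names(entries) <- vapply(entries, function(e) e@name, character(1))
  new("MetaboliteLibrary", entries = entries, reference = reference)
}

## ---------------------------------------------------------------------------
## FID and Spectrum
## ---------------------------------------------------------------------------

#' Complex free-induction decay
#'
#' @slot samples complex time-domain samples.
#' @slot acquisition the [AcquisitionParams-class] the FID was recorded with.
#' @slot provenance character vector of applied processing stage labels.
#' @exportClass NMRFid
setClass("NMRFid",
  representation(samples = "complex", acquisition = "AcquisitionParams",
                 provenance = "character")
)

setValidity("NMRFid", function(object) {
  msg <- character(0)
  if (length(object@samples) < 2L) msg <- c(msg, "FID must have >= 2 samples")
  if (any(!is.finite(Re(object@samples))) || any(!is.finite(Im(object@samples))))
    msg <- c(msg, "FID samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an FID
#' @param samples complex vector of time-domain samples.
#' @param acquisition an [AcquisitionParams-class] object.
#' @param provenance processing stage labels already applied.
#' @return An [NMRFid-class] object.
#' @export
nmrFid <- function(samples, acquisition = acquisitionParams(),
                   provenance = character(0)) {
  new("NMRFid", samples = as.complex(samples), acquisition = acquisition,
      provenance = provenance)
}

#' Frequency-domain spectrum on a ppm axis
#'
#' Intensities are stored as complex values until phased; the real channel
#' (accessible via [intensities()]) is the absorptive spectrum used for
#' integration.
#'
#' @slot ppm strictly increasing chemical-shift axis (ppm).
#' @slot intensity complex intensities, same length as \code{ppm}.
#' @slot acquisition originating [AcquisitionParams-class].
#' @slot provenance processing stage labels.
#' @slot meta list of per-stage processing records (recovered phases,
#'   baseline coefficients, reference shift).
#' @exportClass NMRSpectrum
setClass("NMRSpectrum",
  representation(ppm = "numeric", intensity = "complex",
                 acquisition = "AcquisitionParams",
                 provenance = "character", meta = "list")
)

setValidity("NMRSpectrum", function(object) {
  msg <- character(0)
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "'ppm' and 'intensity' must have equal length")
  if (is.unsorted(object@ppm, strictly = TRUE))
    msg <- c(msg, "'ppm' axis must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a spectrum
#' @param ppm ascending ppm axis.
#' @param intensity complex (or real) intensities.
#' @param acquisition an [AcquisitionParams-class] object.
#' @param provenance processing stage labels.
#' @param meta list of processing records.
#' @return An [NMRSpectrum-class] object.
#' @export
nmrSpectrum <- function(ppm, intensity, acquisition = acquisitionParams(),
                        provenance = character(0), meta = list()) {
  new("NMRSpectrum", ppm = as.numeric(ppm), intensity = as.complex(intensity),
      acquisition = acquisition, provenance = provenance, meta = meta)
}

## ---------------------------------------------------------------------------
## Noise model
## ---------------------------------------------------------------------------

#' Instrumental distortion model for the simulator
#'
#' @slot noiseSd standard deviation of the complex Gaussian time-domain
#'   noise at the reference transient count of 64; the effective value
#'   scales as \code{1/sqrt(nTransients/64)}.
#' @slot baselineCoeffs polynomial coefficients (intensity units, ascending
#'   powers of the centred, scaled ppm axis) of an injected baseline.
#' @slot ph0,ph1 injected zero-/first-order phase errors (degrees).
#' @slot gain global dimensionless amplitude scale.
#' @seealso [noiseModel()], [simulateFid()]
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(noiseSd = "numeric", baselineCoeffs = "numeric",
                 ph0 = "numeric", ph1 = "numeric", gain = "numeric")
)

setValidity("NoiseModel", function(object) {
  msg <- character(0)
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (object@gain <= 0) msg <- c(msg, "'gain' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a noise model
#'
#' The default is a low-noise, distortion-free instrument: complex Gaussian
#' time-domain noise with standard deviation 0.005 (in the amplitude units
#' of a 1 mM singlet proton, at 64 transients), no baseline, no phase error,
#' unit gain.
#'
#' @param noiseSd time-domain complex Gaussian noise SD at 64 transients.
#' @param baselineCoeffs injected baseline polynomial coefficients
#'   (ascending powers; \code{numeric(0)} for none).
#' @param ph0,ph1 injected phase errors (degrees).
#' @param gain global amplitude scale.
#' @return A [NoiseModel-class] object.
#' @export
noiseModel <- function(noiseSd = 0.005, baselineCoeffs = numeric(0),
                       ph0 = 0, ph1 = 0, gain = 1) {
  new("NoiseModel", noiseSd = as.numeric(noiseSd),
      baselineCoeffs = as.numeric(baselineCoeffs),
      ph0 = as.numeric(ph0), ph1 = as.numeric(ph1), gain = as.numeric(gain))
}
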