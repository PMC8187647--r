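#' @include AllClasses.R library.R utils.R
NULL

#' Build a group distribution from a summary table
#'
#' Extracts the per-metabolite (mean, SD) pairs of one group of a two-group
#' summary table (as read by [readSummaryTable()]) into the distribution
#' format consumed by [sampleCohort()].
#'
#' @param summary summary data.frame with \code{metabolite, mean1, sd1,
#'   mean2, sd2} columns.
#' @param group which group to extract (1 or 2).
#' @param label group label attached to sampled cohorts; defaults to
#'   \code{"group1"}/\code{"group2"}.
#' @return A data.frame with columns \code{metabolite, mean, sd} and
#'   attribute \code{"label"}.
#' @export
groupDistribution <- function(summary, group = 1L,
                              label = paste0("group", group)) {
  stopifnot(group %in% c(1L, 2L))
  m <- summary[[paste0("mean", group)]]
  s <- summary[[paste0("sd", group)]]
  if (any(s < 0)) stop("standard deviations must be >= 0")
  if (any(m < 0)) stop("means must be >= 0")
  out <- data.frame(metabolite = summary$metabolite, mean = m, sd = s,
                    stringsAsFactors = FALSE)
  attr(out, "label") <- label
  out
}

#' Sample a cohort of tissue concentrations
#'
#' Draws \code{n} samples per metabolite from normal distributions with the
#' given means and SDs (in umol/g tissue), truncated below at zero because
#' concentrations are nonnegative. Sampling uses the inverse-CDF of the
#' truncated normal, so results are deterministic given the seed and
#' independent of truncation mass.
#'
#' @param dist distribution data.frame from [groupDistribution()] (columns
#'   \code{metabolite, mean, sd}).
#' @param n number of samples.
#' @param seed integer RNG seed; \code{NULL} uses the current RNG state.
#' @param group group label column value; defaults to the distribution's
#'   label attribute.
#' @param tissueMass tissue mass per sample (g).
#' @param extractVolume reconstitution volume per sample (mL).
#' @param idPrefix prefix for generated sample identifiers.
#' @return A concentration table: data.frame with columns
#'   \code{sample_id, group, tissue_mass, extract_volume, units} and one
#'   column per metabolite (umol/g).
#' @examples
#' d <- data.frame(metabolite = "Succinate", mean = 0.589, sd = 0.121)
#' tab <- sampleCohort(d, n = 5, seed = 1)
#' @export
sampleCohort <- function(dist, n, seed = NULL,
                         group = attr(dist, "label") %||% "group1",
                         tissueMass = 0.05, extractVolume = 0.6,
                         idPrefix = group) {
  stopifnot(n >= 1)
  if (any(dist$sd < 0)) stop("standard deviations must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(sample_id = sprintf("%s_%02d", idPrefix, seq_len(n)),
                    group = group, tissue_mass = tissueMass,
                    extract_volume = extractVolume, units = "umol_per_g",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(dist)))
    out[[dist$metabolite[i]]] <- .rtruncnorm0(n, dist$mean[i], dist$sd[i])
  out
}

## Multiplet line offsets (Hz) and first-order binomial weights.
.multipletLines <- function(pattern, j) {
  switch(pattern,
    singlet = list(offsets = 0, weights = 1),
    doublet = list(offsets = c(-j, j) / 2, weights = c(1, 1) / 2),
    triplet = list(offsets = c(-j, 0, j), weights = c(1, 2, 1) / 4),
    quartet = list(offsets = c(-1.5, -0.5, 0.5, 1.5) * j,
                   weights = c(1, 3, 3, 1) / 8),
    stop("unknown multiplet pattern: ", pattern))
}

## Ascending ppm axis of a spectrum derived from an FID of length n.
.ppmAxis <- function(acq, n) {
  sw <- acq@sweepWidth
  acq@carrierPpm + seq(-sw / 2, sw / 2 - sw / n, length.out = n)
}

## fft-order frequencies (Hz) for n points at dwell dt.
.fftFreqs <- function(n, dt) {
  f <- (seq_len(n) - 1) / (n * dt)
  nyq <- 1 / (2 * dt)
  f[f >= nyq] <- f[f >= nyq] - 1 / dt
  f
}

#' Simulate a free-induction decay for one sample
#'
#' Builds the complex time-domain signal of a tissue-extract sample: one
#' exponentially decaying complex sinusoid per multiplet line, with line
#' amplitude proportional to \code{gain x C(mM) x protons x (1 -
#' exp(-relaxTime/T1))} (the T1 saturation factor that the downstream
#' relaxation correction undoes), multiplet lines split by J with binomial
#' intensity ratios, plus the reference standard, complex Gaussian noise
#' (scaled by \code{1/sqrt(nTransients/64)}), and optional zero-/first-order
#' phase error and polynomial baseline distortion.
#'
#' @param record one row of a concentration table (see [sampleCohort()]);
#'   umol/g values are converted to in-tube mM as
#'   \code{umol/g x tissue_mass / extract_volume}.
#' @param library a [MetaboliteLibrary-class]; every metabolite column of
#'   \code{record} must be present in it.
#' @param acq an [AcquisitionParams-class].
#' @param noise a [NoiseModel-class].
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @param linewidthHz natural linewidth (Lorentzian FWHM, Hz) of every
#'   line; \code{T2 = 1/(pi x FWHM)}.
#' @return An [NMRFid-class].
#' @examples
#' lib <- defaultLibrary()
#' d <- data.frame(metabolite = "Succinate", mean = 0.589, sd = 0)
#' rec <- sampleCohort(d, 1, seed = 1)[1, ]
#' fid <- simulateFid(rec, lib, seed = 1)
#' @export
simulateFid <- function(record, library, acq = acquisitionParams(),
                        noise = noiseModel(), seed = NULL,
                        linewidthHz = 1) {
  stopifnot(is(library, "MetaboliteLibrary"))
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    mets <- .metaboliteCols(record)
    conc <- as.numeric(record[1, mets]); names(conc) <- mets
    units <- record$units %||% "umol_per_g"
    if (identical(units, "umol_per_g")) {
      conc <- conc * record$tissue_mass / record$extract_volume
    } else if (!identical(units, "mM")) stop("unknown units: ", units)
  } else {
    conc <- record  # named numeric, already mM
    mets <- names(conc)
  }
  missing <- setdiff(mets, libraryNames(library))
  if (length(missing))
    stop("metabolite(s) absent from library: ", paste(missing, collapse = ", "))

  dt <- dwellTime(acq)
  n <- acq@nPoints
  tvec <- (seq_len(n) - 1) * dt
  t2 <- 1 / (pi * linewidthHz)
  decay <- exp(-tvec / t2)
  trel <- acq@relaxTime

  addPeak <- function(fid, centerPpm, pattern, j, protons, t1, cmM) {
    amp <- noise@gain * cmM * protons * (1 - exp(-trel / t1))
    if (amp == 0) return(fid)
    ml <- .multipletLines(pattern, j)
    for (k in seq_along(ml$offsets)) {
      f <- (centerPpm - acq@carrierPpm) * acq@frequency + ml$offsets[k]
      fid <- fid + (amp * ml$weights[k]) * exp(2i * pi * f * tvec) * decay
    }
    fid
  }

  fid <- complex(n)
  ref <- library@reference
  fid <- addPeak(fid, ref@shift, "singlet", 0, ref@protons, ref@t1,
                 ref@concentration)
  for (nm in mets) {
    e <- library@entries[[nm]]
    for (i in seq_len(nrow(e@peaks)))
      fid <- addPeak(fid, e@peaks$center[i], e@peaks$pattern[i],
                     e@peaks$j[i], e@peaks$protons[i], e@t1, conc[[nm]])
  }

  if (noise@noiseSd > 0) {
    sdEff <- noise@noiseSd / sqrt(acq@nTransients / 64)
    fid <- fid + complex(real = stats::rnorm(n, sd = sdEff),
                         imaginary = stats::rnorm(n, sd = sdEff))
  }
  if (noise@ph0 != 0) fid <- fid * exp(1i * .deg2rad(noise@ph0))
  if (noise@ph1 != 0) {
    ## first-order phase error applied across the frequency axis
    f <- .fftFreqs(n, dt)
    x <- f * dt                         # (-0.5, 0.5) fractional position
    fid <- stats::fft(stats::fft(fid) * exp(1i * .deg2rad(noise@ph1) * x),
                      inverse = TRUE) / n
  }
  if (length(noise@baselineCoeffs) && any(noise@baselineCoeffs != 0)) {
    axis <- .ppmAxis(acq, n)
    x <- (axis - mean(axis)) / (diff(range(axis)) / 2)
    b <- rep(0, n)
    for (p in seq_along(noise@baselineCoeffs))
      b <- b + noise@baselineCoeffs[p] * x^(p - 1)
    ## place baseline on the fft-ordered grid, then back to time domain
    ord <- order(.fftFreqs(n, dt))
    bFft <- numeric(n); bFft[ord] <- b
    fid <- fid + stats::fft(bFft, inverse = TRUE) / n
  }
  nmrFid(fid, acq, provenance = "simulated")
}

#' Simulate a two-group study
#'
#' Samples one cohort per group and simulates one FID per sample, keeping
#' the ground-truth concentration table for parameter-recovery checks.
#'
#' @param distA,distB group distributions (see [groupDistribution()]); must
#'   cover the same metabolite set.
#' @param nPerGroup samples per group.
#' @param library a [MetaboliteLibrary-class].
#' @param acq an [AcquisitionParams-class].
#' @param noise a [NoiseModel-class].
#' @param seed integer seed controlling both cohort sampling and FID noise.
#' @param tissueMass,extractVolume sample preparation parameters.
#' @return A list with \code{fids} (named list of [NMRFid-class]) and
#'   \code{truth} (the ground-truth concentration table, 2 x nPerGroup
#'   rows).
#' @export
generateStudy <- function(distA, distB, nPerGroup, library,
                          acq = acquisitionParams(), noise = noiseModel(),
                          seed = 1L, tissueMass = 0.05, extractVolume = 0.6) {
  if (!setequal(distA$metabolite, distB$metabolite))
    stop("distributions cover different metabolite sets: ",
         paste(union(setdiff(distA$metabolite, distB$metabolite),
                     setdiff(distB$metabolite, distA$metabolite)),
               collapse = ", "))
  set.seed(seed)
  labA <- attr(distA, "label") %||% "A"
  labB <- attr(distB, "label") %||% "B"
  if (identical(labA, labB)) { labA <- paste0(labA, "_1"); labB <- paste0(labB, "_2") }
  cohA <- sampleCohort(distA, nPerGroup, seed = NULL, group = labA,
                       tissueMass = tissueMass, extractVolume = extractVolume)
  cohB <- sampleCohort(distB, nPerGroup, seed = NULL, group = labB,
                       tissueMass = tissueMass, extractVolume = extractVolume)
  truth <- rbind(cohA, cohB)
  fids <- lapply(seq_len(nrow(truth)), function(i)
    simulateFid(truth[i, ], library, acq, noise, seed = NULL))
  names(fids) <- truth$sample_id
  list(fids = fids, truth = truth)
}
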