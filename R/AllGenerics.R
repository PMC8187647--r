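#' @include AllClasses.R
NULL

#' @rdname apodize
#' @export
setGeneric("apodize", function(fid, lineBroadening = 1) standardGeneric("apodize"))

#' @rdname zeroFill
#' @export
setGeneric("zeroFill", function(fid, target = 131072L) standardGeneric("zeroFill"))

#' @rdname fourierTransform
#' @export
setGeneric("fourierTransform", function(fid, halveFirstPoint = TRUE)
  standardGeneric("fourierTransform"))

#' @rdname phaseCorrect
#' @export
setGeneric("phaseCorrect", function(spec, mode = c("auto", "manual"),
                                    ph0 = 0, ph1 = 0, ...)
  standardGeneric("phaseCorrect"))

#' @rdname baselineCorrect
#' @export
setGeneric("baselineCorrect", function(spec, degree = 3L, ...)
  standardGeneric("baselineCorrect"))

#' @rdname referenceShift
#' @export
setGeneric("referenceShift", function(spec, ref = referenceStandard(), ...)
  standardGeneric("referenceShift"))

#' @rdname binSpectrum
#' @export
setGeneric("binSpectrum", function(spec, width = 0.002) standardGeneric("binSpectrum"))

#' @rdname integrateRegion
#' @export
setGeneric("integrateRegion", function(spec, region) standardGeneric("integrateRegion"))

## -- simple accessors --------------------------------------------------------

#' Accessors for FIDs, spectra and libraries
#'
#' \code{fidData} returns the complex time-domain samples; \code{ppm} the
#' chemical-shift axis; \code{intensities} the real (absorptive) channel;
#' \code{complexIntensities} the full complex intensities;
#' \code{acquisition} the acquisition parameters; \code{provenance} the
#' ordered labels of applied processing stages; \code{dwellTime} the
#' sampling interval in seconds; \code{libraryNames} the metabolite names
#' of a library; \code{libraryEntries} its [MetaboliteSpec-class] list and
#' \code{reference} its [ReferenceStandard-class].
#'
#' @param object an [NMRFid-class], [NMRSpectrum-class],
#'   [AcquisitionParams-class] or [MetaboliteLibrary-class] as appropriate.
#' @return See description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fidData", function(object) standardGeneric("fidData"))
#' @rdname accessors
#' @export
setGeneric("ppm", function(object) standardGeneric("ppm"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("complexIntensities", function(object) standardGeneric("complexIntensities"))
#' @rdname accessors
#' @export
setGeneric("acquisition", function(object) standardGeneric("acquisition"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("dwellTime", function(object) standardGeneric("dwellTime"))
#' @rdname accessors
#' @export
setGeneric("libraryNames", function(object) standardGeneric("libraryNames"))
#' @rdname accessors
#' @export
setGeneric("libraryEntries", function(object) standardGeneric("libraryEntries"))
#' @rdname accessors
#' @export
setGeneric("reference", function(object) standardGeneric("reference"))

#' @rdname accessors
#' @export
setMethod("fidData", "NMRFid", function(object) object@samples)
#' @rdname accessors
#' @export
setMethod("ppm", "NMRSpectrum", function(object) object@ppm)
#' @rdname accessors
#' @export
setMethod("intensities", "NMRSpectrum", function(object) Re(object@intensity))
#' @rdname accessors
#' @export
setMethod("complexIntensities", "NMRSpectrum", function(object) object@intensity)
#' @rdname accessors
#' @export
setMethod("acquisition", "NMRFid", function(object) object@acquisition)
#' @rdname accessors
#' @export
setMethod("acquisition", "NMRSpectrum", function(object) object@acquisition)
#' @rdname accessors
#' @export
setMethod("provenance", "NMRFid", function(object) object@provenance)
#' @rdname accessors
#' @export
setMethod("provenance", "NMRSpectrum", function(object) object@provenance)
#' @rdname accessors
#' @export
setMethod("dwellTime", "AcquisitionParams",
          function(object) 1 / (object@sweepWidth * object@frequency))
#' @rdname accessors
#' @export
setMethod("dwellTime", "NMRFid", function(object) dwellTime(object@acquisition))
#' @rdname accessors
#' @export
setMethod("libraryNames", "MetaboliteLibrary",
          function(object) vapply(object@entries, function(e) e@name, character(1)))
#' @rdname accessors
#' @export
setMethod("libraryEntries", "MetaboliteLibrary", function(object) object@entries)
#' @rdname accessors
#' @export
setMethod("reference", "MetaboliteLibrary", function(object) object@reference)

## -- show methods ------------------------------------------------------------

setMethod("show", "AcquisitionParams", function(object) {
  cat("AcquisitionParams:", object@frequency, "MHz,",
      object@sweepWidth, "ppm sweep,", object@nPoints, "points,",
      object@nTransients, "transients, relaxation time",
      object@relaxTime, "s\n")
})

setMethod("show", "NMRFid", function(object) {
  cat("NMRFid with", length(object@samples), "complex points (",
      format(length(object@samples) * dwellTime(object), digits = 4),
      "s acquisition )\n")
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "NMRSpectrum", function(object) {
  cat("NMRSpectrum:", length(object@ppm), "points,",
      format(min(object@ppm), digits = 4), "to",
      format(max(object@ppm), digits = 4), "ppm\n")
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "MetaboliteLibrary", function(object) {
  cat("MetaboliteLibrary with", length(object@entries), "metabolites;",
      "reference", object@reference@name,
      sprintf("(%.4f mM, %d protons)\n", object@reference@concentration,
              object@reference@protons))
})

setMethod("show", "NoiseModel", function(object) {
  cat("NoiseModel: noise SD", object@noiseSd, "; phase error (",
      object@ph0, ",", object@ph1, ") deg; gain", object@gain, ";",
      length(object@baselineCoeffs), "baseline coefficients\n")
})
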