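#' @include AllClasses.R
NULL

## Default quantification library.
##
## The assignment of quantification signals is synthetic reference data:
## multiplicities, proton counts and most chemical shifts follow standard
## 1H reference spectra of the compounds, but several centres are curated
## (moved by up to ~0.15 ppm) so that all quantification regions are
## mutually resolved, because plain region integration assumes resolved
## resonances. T1 values are plausible small-molecule defaults in the
## 1.0-4.0 s range; at a total relaxation time of 26 s the saturation
## correction is ~1 regardless. All values are configurable via
## [loadLibrary()].
.defaultLibraryTable <- function() {
  tab <- rbind(
    ## name                 shift  pattern    J(Hz) H  T1(s)
    c("Leucine",            0.92, "doublet",  6.6, 6, 1.3),
    c("Valine",             1.02, "doublet",  7.0, 6, 1.2),
    c("Isoleucine",         1.12, "doublet",  6.9, 3, 1.3),
    c("Lactate",            1.33, "doublet",  6.9, 3, 1.8),
    c("Alanine",            1.48, "doublet",  7.2, 3, 1.5),
    c("Acetate",            1.92, "singlet",  0.0, 3, 2.5),
    c("Glutamate",          2.05, "triplet",  7.5, 2, 1.2),
    c("Glutamine",          2.17, "triplet",  7.6, 2, 1.2),
    c("Pyruvate",           2.28, "singlet",  0.0, 3, 1.6),
    c("Succinate",          2.41, "singlet",  0.0, 4, 1.8),
    c("Citrate",            2.66, "doublet", 15.5, 2, 1.2),
    c("Aspartate",          2.81, "doublet", 17.4, 1, 1.0),
    c("Creatine",           3.04, "singlet",  0.0, 3, 1.4),
    c("Taurine",            3.26, "triplet",  6.6, 2, 1.8),
    c("Glycine",            3.56, "singlet",  0.0, 2, 1.4),
    c("3-hydroxybutytrate", 4.13, "quartet",  6.3, 1, 1.6),
    c("Glucose",            5.23, "doublet",  3.8, 1, 1.6),
    c("Uracil",             5.80, "doublet",  7.7, 1, 2.6),
    c("Uridine",            5.92, "doublet",  8.1, 1, 2.4),
    c("Fumarate",           6.52, "singlet",  0.0, 2, 3.0),
    c("Tyrosine",           6.90, "doublet",  8.5, 2, 2.0),
    c("Histidine",          7.09, "singlet",  0.0, 1, 1.9),
    c("Phenylalanine",      7.42, "triplet",  7.4, 1, 2.2),
    c("Carnosine",          8.07, "singlet",  0.0, 1, 2.0),
    c("Hypoxanthine",       8.19, "singlet",  0.0, 1, 2.8),
    c("Inosine",            8.34, "singlet",  0.0, 1, 2.6),
    c("Formate",            8.46, "singlet",  0.0, 1, 4.0),
    c("ADP",                8.58, "singlet",  0.0, 1, 2.8),
    c("AMP",                8.70, "singlet",  0.0, 1, 2.8),
    c("Nicotinamide",       8.94, "singlet",  0.0, 1, 2.6),
    c("NAD",                9.33, "singlet",  0.0, 1, 2.2)
  )
  data.frame(name = tab[, 1], center = as.numeric(tab[, 2]),
             pattern = tab[, 3], j = as.numeric(tab[, 4]),
             protons = as.integer(tab[, 5]), t1 = as.numeric(tab[, 6]),
             stringsAsFactors = FALSE)
}

#' Default metabolite quantification library
#'
#' Thirty-one metabolites (the panel quantifiable in first-trimester
#' villous/decidual tissue extracts) plus a TSP reference standard at
#' 0.2915 mM. Peak positions, multiplicities, J couplings and T1 values are
#' synthetic reference data, not measured: shifts mostly follow standard
#' reference spectra, with a few signals relocated so that all
#' quantification regions are resolved. Every value can be overridden by
#' loading a user library with [loadLibrary()].
#'
#' @param margin ppm margin added on each side of a multiplet when deriving
#'   its quantification region. Equal margins for metabolites and the
#'   reference make Lorentzian tail truncation cancel in the
#'   metabolite/reference area ratio.
#' @param reference the [ReferenceStandard-class] to attach.
#' @return A validated [MetaboliteLibrary-class].
#' @examples
#' lib <- defaultLibrary()
#' libraryNames(lib)
#' @export
defaultLibrary <- function(margin = 0.03, reference = referenceStandard()) {
  tab <- .defaultLibraryTable()
  entries <- lapply(seq_len(nrow(tab)), function(i) {
    metaboliteSpec(tab$name[i], tab$center[i], tab$pattern[i], tab$j[i],
                   tab$protons[i], tab$t1[i], margin = margin)
  })
  metaboliteLibrary(entries, reference)
}

#' Load a metabolite library from a YAML configuration file
#'
#' The file must declare a \code{reference} block (name, concentration_mM,
#' protons, t1, shift, search_window, quant_region) and a
#' \code{metabolites} list in which every entry provides name, center,
#' pattern, protons and t1 (j and quant_region optional). Validation
#' rejects overlapping quantification regions, naming the offending
#' metabolites, and missing or non-positive T1 values.
#'
#' @param path path to the YAML file.
#' @return A validated [MetaboliteLibrary-class].
#' @seealso [defaultLibrary()], [writeLibrary()]
#' @export
loadLibrary <- function(path) {
  if (!file.exists(path)) stop("library config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$reference) || is.null(cfg$metabolites))
    stop("library config must declare 'reference' and 'metabolites'")
  r <- cfg$reference
  ref <- referenceStandard(
    name = r$name %||% "TSP",
    concentration = r$concentration_mM %||% 0.2915,
    protons = r$protons %||% 9L,
    t1 = r$t1 %||% 3.0,
    shift = r$shift %||% 0,
    searchWindow = unlist(r$search_window) %||% c(-0.05, 0.05),
    quantRegion = unlist(r$quant_region) %||% c(-0.03, 0.03))
  entries <- lapply(cfg$metabolites, function(m) {
    if (is.null(m$name)) stop("metabolite entry without a name")
    if (is.null(m$t1))
      stop("missing T1 for metabolite '", m$name, "'")
    metaboliteSpec(m$name, m$center, m$pattern %||% "singlet",
                   m$j %||% 0, m$protons %||% 1L, m$t1,
                   quantRegion = if (!is.null(m$quant_region))
                     unlist(m$quant_region))
  })
  metaboliteLibrary(entries, ref)
}

#' Write a metabolite library to a YAML configuration file
#'
#' Inverse of [loadLibrary()]: the written file round-trips to an identical
#' library.
#'
#' @param library a [MetaboliteLibrary-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeLibrary <- function(library, path) {
  stopifnot(is(library, "MetaboliteLibrary"))
  ref <- library@reference
  cfg <- list(
    reference = list(
      name = ref@name, concentration_mM = ref@concentration,
      protons = ref@protons, t1 = ref@t1, shift = ref@shift,
      search_window = as.numeric(ref@searchWindow),
      quant_region = as.numeric(ref@quantRegion)),
    metabolites = lapply(library@entries, function(e) {
      list(name = e@name, center = e@peaks$center[1],
           pattern = e@peaks$pattern[1], j = e@peaks$j[1],
           protons = e@protons, t1 = e@t1,
           quant_region = as.numeric(e@quantRegion))
    })
  )
  names(cfg$metabolites) <- NULL
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
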