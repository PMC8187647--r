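#' @include AllClasses.R
NULL

.fmtNum <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

#' Read a two-group summary-statistics table
#'
#' Reads a UTF-8 tab-separated file with one row per metabolite and at
#' least the columns \code{metabolite, mean1, sd1, n1, mean2, sd2, n2}
#' (group means, standard deviations and sample sizes). Additional columns
#' (such as printed P values) are kept. The printed character
#' representation of every numeric cell is preserved in the
#' \code{"printed"} attribute so that printed-precision intervals can be
#' propagated through recomputed statistics.
#'
#' @param path path to the TSV file.
#' @return A data.frame of group summaries, in file order, with attribute
#'   \code{"printed"} holding the original strings.
#' @examples
#' t1 <- readSummaryTable(system.file("extdata", "table1_villi_rsa.tsv",
#'                                    package = "quantNMR"))
#' nrow(t1)   # 31 metabolites
#' @export
readSummaryTable <- function(path) {
  if (!file.exists(path)) stop("summary table not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("metabolite", "mean1", "sd1", "n1", "mean2", "sd2", "n2")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("summary table is missing required column(s): ",
         paste(missing, collapse = ", "))
  out <- raw
  numcols <- setdiff(names(raw), "metabolite")
  for (cn in numcols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & nzchar(trimws(raw[[cn]])))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                   raw[[cn]][bad[1]], cn, bad[1]))
    out[[cn]] <- v
  }
  out$n1 <- as.integer(out$n1); out$n2 <- as.integer(out$n2)
  attr(out, "printed") <- raw
  out
}

#' Write and read a differential comparison table
#'
#' \code{writeComparisonTable} writes a tab-separated file with the fixed
#' column order \code{metabolite, mean1, sd1, n1, mean2, sd2, n2,
#' test_mode, t, df, p, adjusted_p, percent_change}; numbers are written
#' with 15 significant digits so a write/read round trip preserves every
#' value to better than 1e-12 relative. \code{readComparisonTable} reads
#' such a file back.
#'
#' @param table a comparison data.frame as produced by
#'   [differentialTable()].
#' @param path output (input) file path.
#' @return \code{writeComparisonTable} returns \code{path} invisibly;
#'   \code{readComparisonTable} returns the data.frame.
#' @export
writeComparisonTable <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("comparison table must be a non-empty data.frame")
  cols <- c("metabolite", "mean1", "sd1", "n1", "mean2", "sd2", "n2",
            "test_mode", "t", "df", "p", "adjusted_p", "percent_change")
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("comparison table is missing column(s): ",
         paste(missing, collapse = ", "))
  out <- table[, cols]
  for (cn in cols) if (is.numeric(out[[cn]])) out[[cn]] <- .fmtNum(out[[cn]])
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write comparison table: ",
                              conditionMessage(e)))
  invisible(path)
}

#' @rdname writeComparisonTable
#' @export
readComparisonTable <- function(path) {
  if (!file.exists(path)) stop("comparison table not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  tab$n1 <- as.integer(tab$n1); tab$n2 <- as.integer(tab$n2)
  tab
}

#' Write and read concentration tables
#'
#' Concentration tables are plain data.frames with the metadata columns
#' \code{sample_id, group, tissue_mass, extract_volume, units} followed by
#' one column per metabolite (concentrations in \code{umol_per_g} tissue or
#' in-tube \code{mM}, as flagged by \code{units}). Stored as UTF-8 TSV.
#'
#' @param table the concentration data.frame.
#' @param path file path.
#' @return \code{writeConcentrationTable} returns \code{path} invisibly;
#'   \code{readConcentrationTable} returns the data.frame.
#' @export
writeConcentrationTable <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (cn in names(out)) if (is.numeric(out[[cn]])) out[[cn]] <- .fmtNum(out[[cn]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeConcentrationTable
#' @export
readConcentrationTable <- function(path) {
  if (!file.exists(path)) stop("concentration table not found: ", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write and read spectra as two-column text
#'
#' Spectra are stored as a two-column (ppm, intensity) tab-separated file
#' plus a YAML metadata sidecar (\code{<path>.meta.yaml}) carrying the
#' acquisition parameters and processing provenance. Only the real
#' (absorptive) channel is stored.
#'
#' @param spec an [NMRSpectrum-class].
#' @param path output file path (sidecar written next to it).
#' @return \code{writeSpectrum} returns \code{path} invisibly;
#'   \code{readSpectrum} returns the [NMRSpectrum-class].
#' @export
writeSpectrum <- function(spec, path) {
  stopifnot(is(spec, "NMRSpectrum"))
  df <- data.frame(ppm = .fmtNum(spec@ppm),
                   intensity = .fmtNum(intensities(spec)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  acq <- spec@acquisition
  meta <- list(
    acquisition = list(frequency = acq@frequency, sweep_width = acq@sweepWidth,
                       n_points = acq@nPoints, n_transients = acq@nTransients,
                       relax_time = acq@relaxTime, carrier_ppm = acq@carrierPpm),
    provenance = as.list(spec@provenance))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 12L)
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  metaPath <- paste0(path, ".meta.yaml")
  acq <- acquisitionParams()
  prov <- character(0)
  if (file.exists(metaPath)) {
    meta <- yaml::read_yaml(metaPath)
    a <- meta$acquisition
    acq <- acquisitionParams(a$frequency, a$sweep_width, a$n_points,
                             a$n_transients, a$relax_time, a$carrier_ppm)
    prov <- as.character(unlist(meta$provenance))
  }
  nmrSpectrum(df$ppm, complex(real = df$intensity, imaginary = 0),
              acquisition = acq, provenance = prov)
}
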