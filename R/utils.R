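## Internal helpers shared across modules.

## Trapezoidal integral of y over x (x ascending).
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n])) / 2
}

## Half of the last printed decimal unit of a number given as a string,
## e.g. "0.09" -> 0.005, "3.166" -> 0.0005, "1.48e-06" -> 0.005e-6.
## Used to propagate printed-precision uncertainty through recomputed
## statistics.
.printedHalfUlp <- function(s) {
  s <- trimws(as.character(s))
  vapply(s, function(x) {
    m <- regmatches(x, regexec("^[-+]?([0-9]*)(?:\\.([0-9]*))?(?:[eE]([-+]?[0-9]+))?$", x))[[1]]
    if (length(m) == 0L) stop("cannot parse printed number: ", x)
    ndec <- nchar(m[3])
    expo <- if (nzchar(m[4])) as.numeric(m[4]) else 0
    0.5 * 10^(-ndec + expo)
  }, numeric(1), USE.NAMES = FALSE)
}

## Deterministic draws from a normal truncated below at zero, via the
## inverse-CDF so the draw count is independent of the truncation mass.
.rtruncnorm0 <- function(n, mean, sd) {
  if (sd < 0) stop("standard deviation must be >= 0")
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(0, mean = mean, sd = sd)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnorm(u, mean = mean, sd = sd)
}

.deg2rad <- function(x) x * pi / 180

## Metadata columns of a concentration table; everything else is a
## metabolite concentration column.
.concMetaCols <- c("sample_id", "group", "tissue_mass", "extract_volume", "units")

.metaboliteCols <- function(tab) setdiff(names(tab), .concMetaCols)
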