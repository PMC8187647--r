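## Shared fixtures: a reduced acquisition (8k points, 16k zero-fill) keeps
## unit tests fast; statistical tolerances are unchanged.

smallAcq <- function(...) acquisitionParams(nPoints = 8192L, ...)
smallProc <- function(...) processingParams(zeroFillTo = 16384L, ...)

quietNoise <- function(...) noiseModel(noiseSd = 0, ...)

table1Path <- function() system.file("extdata", "table1_villi_rsa.tsv",
                                     package = "quantNMR")
table2Path <- function() system.file("extdata", "table2_decidua_villi.tsv",
                                     package = "quantNMR")

## one-row concentration record with the given umol/g values
concRecord <- function(...) {
  vals <- list(...)
  d <- data.frame(metabolite = names(vals),
                  mean = as.numeric(unlist(vals)), sd = 0)
  sampleCohort(d, 1, seed = 1)[1, ]
}

metaboliteColumns <- function(tab)
  setdiff(names(tab), c("sample_id", "group", "tissue_mass",
                        "extract_volume", "units"))

trapzIntegral <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n])) / 2
}
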