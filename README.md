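# quantNMR

Absolute quantitative 1D ¹H-NMR metabolomics for tissue extracts, as a
tested R pipeline.

## What this is for

Cohort studies that quantify tissue metabolites by one-dimensional proton
NMR — the motivating setting is first-trimester chorionic villous and
decidual tissue, where villous **succinate** concentration distinguishes
healthy from failing pregnancies — need three things to be right at once:

1. **Spectral processing**: FID → spectrum via exponential apodization,
   zero-filling, Fourier transformation, phase and baseline correction,
   and chemical-shift referencing to TSP (δ 0.00).
2. **Absolute quantification** against the internal standard with
   spin-lattice (T1) saturation correction. For a metabolite signal with
   proton count *N<sub>m</sub>* and relaxation time *T1<sup>m</sup>*,
   observed with total relaxation time *t*:

   *C<sub>m</sub>* = (*N*<sub>TSP</sub>·*C*<sub>TSP</sub>/*N<sub>m</sub>*) ·
   (*A<sup>m</sup>*/*A*<sup>TSP</sup>) ·
   (1 − e<sup>−t/T1<sup>TSP</sup></sup>)/(1 − e<sup>−t/T1<sup>m</sup></sup>),

   converted to tissue units by μmol/g = mM × V<sub>extract</sub>(mL) /
   m<sub>tissue</sub>(g).
3. **Differential statistics** on the resulting concentration tables:
   a variance-gated unpaired t test per metabolite (pooled when an F test
   accepts equal SDs, Welch otherwise), Benjamini–Hochberg adjustment
   across the panel, percent change, two-sample power analysis, one-way
   ANOVA, and the embryo-resorption rate R/(R+V)×100 for the companion
   mouse experiments.

Because raw instrument data cannot be assumed available, the package
carries a first-class synthetic-data generator: cohorts are sampled from
the packaged summary tables (31 metabolites, mean ± SD, n≈30/group) and
rendered into FIDs under the study acquisition (600.13 MHz, 20 ppm sweep,
32k complex points, 64 transients, total relaxation time 26 s, TSP at
0.2915 mM), with configurable noise, phase error, baseline distortion and
gain. Every downstream stage is verified by parameter recovery against
that generator.

## Worked example

```r
library(quantNMR)

table1 <- readSummaryTable(system.file("extdata", "table1_villi_rsa.tsv",
                                       package = "quantNMR"))
cmp <- differentialTable(table1)
cmp[cmp$metabolite == "Succinate",
    c("metabolite", "test_mode", "t", "df", "p", "adjusted_p", "percent_change")]
#>   metabolite test_mode     t df         p adjusted_p percent_change
#> 5  Succinate    pooled 5.381 58 1.391e-06  4.311e-05          27.16
```

Succinate is 27.2% lower in the case group, t = 5.38 on 58 df (pooled,
because the F gate accepts equal SDs), raw p = 1.4×10⁻⁶ — the smallest of
the 31-metabolite panel — and survives Benjamini–Hochberg adjustment.
The design's power for this effect at n = 30/group:

```r
powerTwoSample(0.589, 0.121, 0.429, 0.109, nPerGroup = 30)
#> [1] 0.9996
```

The full synthetic pipeline — sample a cohort, simulate FIDs, process,
quantify, compare:

```r
dN <- groupDistribution(table1, 1, "normal")
dR <- groupDistribution(table1, 2, "rsa")
res <- endToEndRecovery(dN, dR, nPerGroup = 30, seed = 1)
res$recovery[res$recovery$metabolite == "Succinate", ]
res$comparison$metabolite[which.min(res$comparison$p)]   # "Succinate"
```

See `vignettes/quantitative-hnmr.Rmd` for the model, the assumptions
behind the synthetic generator and metabolite library, and the numerical
design choices.

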