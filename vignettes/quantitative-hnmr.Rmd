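---
title: "Absolute quantitative 1H-NMR metabolomics: model, assumptions and design"
author: "quantNMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute quantitative 1H-NMR metabolomics: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantNMR)
```

## The problem

Tissue-extract metabolomics by one-dimensional proton NMR asks two
questions: *how much* of each metabolite is in a sample (absolute
quantification), and *whether two cohorts differ* in those amounts
(differential statistics). The motivating application is the
maternal--fetal interface in early pregnancy: chorionic villous and
decidual tissues from first-trimester cohorts, where villous succinate
concentration is the metabolite of principal interest — its depletion is
associated with recurrent spontaneous abortion, and it rises in villi
relative to decidua during normal implantation.

This package implements that entire measurement chain as tested code,
driven by its own synthetic-data generator so that every stage can be
verified by parameter recovery without any instrument data.

## The quantification model

A resonance of metabolite $m$ observed with total relaxation time $t$
(recycle delay plus acquisition time) is attenuated by incomplete
spin-lattice relaxation:

$$A^m = A_0^m\left[1 - e^{-t/T_1^m}\right],$$

where $A_0^m$ is the fully relaxed integral. Taking the ratio to the
internal standard (TSP, trimethylsilyl propionate: nine equivalent methyl
protons at $\delta$ 0.00, at a known concentration $C_\mathrm{TSP}$ =
0.2915 mM) cancels the spectrometer gain, and correcting each side by its
saturation factor yields the absolute concentration:

$$C_m = \frac{N_\mathrm{TSP}\,C_\mathrm{TSP}}{N_m}\cdot
  \frac{A^m}{A^\mathrm{TSP}}\cdot
  \frac{1-e^{-t/T_1^\mathrm{TSP}}}{1-e^{-t/T_1^m}},$$

with $N$ the proton counts of the integrated signals. These are
`saturationFactor()`, `relaxationCorrection()` and
`absoluteConcentration()`. At the default $t = 26$ s every plausible
small-molecule $T_1$ (\(\le\) 4 s) gives a correction within 0.15% of 1 —
the acquisition is designed to be fully relaxed — but the correction is
implemented and exercised in tests at short $t$, where it matters.

In-tube molarity is converted to tissue concentration by the single
unit-bridging assumption

$$\mu\mathrm{mol/g} = C\,(\mathrm{mM}) \times
  \frac{V_\mathrm{extract}\,(\mathrm{mL})}{m_\mathrm{tissue}\,(\mathrm{g})},$$

with defaults $V = 0.6$ mL and $m = 0.05$ g (a ~50 mg tissue piece
reconstituted in 600 uL of buffer). This conversion is stated nowhere as
an equation in typical methods sections; it is the one assumption a user
must check against their own extraction protocol
(`tissueConcentration()`).

## Processing chain

`processFid()` applies, in fixed, provenance-recorded order:

1. **Exponential apodization** (`apodize`, default LB = 1 Hz): multiplies
   the FID by $e^{-\pi \cdot \mathrm{LB} \cdot t_k}$, adding LB to every
   Lorentzian FWHM.
2. **Zero-filling** (`zeroFill`, default to 128k points): appends exact
   zeros, interpolating the frequency axis. With the first-point-halving
   convention used by the transform, the total spectral integral is
   unchanged.
3. **Fourier transformation** (`fourierTransform`): FFT mapped to an
   ascending ppm axis about the carrier (default 4.7 ppm); intensities
   stay complex until phased.
4. **Phase correction** (`phaseCorrect`): manual mode applies exact
   zero-/first-order phases; the default automated mode minimizes the
   normalized squared negative intensity over $(\varphi_0, \varphi_1)$
   with a coarse grid followed by Nelder--Mead refinement (relative
   tolerance $10^{-12}$, objective decimated 8-fold for speed). A mild
   quadratic penalty ($10^{-4}(\varphi_1/180)^2$) resolves the
   near-degeneracy between the two phase orders; zero-order errors are
   recovered to well under a degree. Manual phasing remains available,
   but an algorithmic default is what makes runs reproducible.
5. **Baseline correction** (`baselineCorrect`, default cubic): iterative
   polynomial fitting with MAD clipping (points above 3 MAD of the
   residual are dropped, refit until stable), so peaks are excluded from
   the baseline estimate. Degree is capped at 6.
6. **Referencing** (`referenceShift`): the axis is translated so the
   maximum within the TSP search window ([-0.05, 0.05] ppm) sits at
   0.00; a missing reference raises an error rather than silently
   misreferencing.

Integration is trapezoidal at full resolution over half-open regions
(`integrateRegion`); 0.002 ppm bucket tables are available separately
(`binSpectrum`), with each discrete segment assigned to the bucket
containing its left edge so buckets sum exactly to the total integral.

## The metabolite library is reference data, not measurement

Region integration needs to know, per metabolite: where to integrate,
how many protons the signal carries, and its $T_1$. None of that is
derivable from a summary table, and resonance assignment (2D NMR) is out
of scope, so the default library (`defaultLibrary()`,
`inst/extdata/metabolite_library.yaml`) is **synthetic reference data**:
multiplicities and proton counts follow standard reference spectra of
the 31 compounds; most chemical shifts do too, but a handful (pyruvate,
valine, isoleucine, the purine-nucleotide aromatic protons, and the
3-hydroxybutyrate signal, which uses the downfield methine rather than
the methyl doublet) are curated by up to ~0.15 ppm so that all
quantification regions are mutually resolved. $T_1$ values are plausible
defaults in 1.0--4.0 s. Every value is overridable via `loadLibrary()`;
analyses of real spectra must supply a library measured for their field
and matrix.

Quantification regions are derived as the multiplet span plus a 0.03 ppm
margin per side, the same margin as the TSP integration region. This is
deliberate: with equal linewidths, the Lorentzian tail fraction lost
outside a region of commensurate width cancels in the
metabolite-to-reference area ratio, which is what makes plain bucket
integration accurate to ~1% for well-resolved singlets despite the slowly
decaying tails.

## The synthetic-data generator

`sampleCohort()` draws per-sample tissue concentrations from normal
distributions with the cohort means and SDs of the packaged summary
tables, truncated at zero (concentrations are nonnegative, and several
printed SDs are large relative to their means, e.g. 3-hydroxybutyrate),
via the inverse CDF so runs are bit-reproducible given a seed.

`simulateFid()` renders a sample as a sum of exponentially decaying
complex sinusoids: one line per multiplet component, first-order
(binomial) multiplet intensities, amplitude proportional to
$C_m(\mathrm{mM}) \times \mathrm{protons} \times (1-e^{-t/T_1^m})$ — so
the saturation physics the correction undoes is actually present in the
data. Defaults emulate the study acquisition: 600.13 MHz, 20 ppm sweep,
32k complex points, 64 transients, $t = 26$ s. The noise model adds
complex Gaussian time-domain noise (SD 0.005 at 64 transients, scaling as
$1/\sqrt{n_\mathrm{transients}/64}$; transients are not simulated
individually), and optionally injects zero-/first-order phase errors,
polynomial baselines and a global gain, because those are the distortions
manual phasing/baselining exists to remove. The natural linewidth
defaults to 1 Hz FWHM for every line ($T_2 = 1/(\pi\,\mathrm{FWHM})$);
no linewidth table exists for these extracts, and a uniform choice is
what makes the reference-ratio cancellation exact.

What the generator does **not** emulate: strong coupling (multiplets are
first-order), peak overlap between metabolites (the library's disjoint
regions enforce the resolved-resonance assumption), chemical-shift
variation with pH/ionic strength, solvent and water-suppression
artifacts, 13C satellites, and between-sample shift misalignment.
Passing recovery tests therefore demonstrates the correctness of the
*computation* — processing, integration, the relaxation-corrected
internal-standard equations, and the statistics — not robustness to
crowded real spectra, for which peak fitting or alignment would be
needed.

## Differential statistics

The published tables gate each metabolite on equality of the two group
SDs, using the ordinary t test when they agree and Welch's form when they
do not. The gating criterion itself is not specified in such captions;
this package uses the conventional reading, a two-sided F test on the
summary variances at $\alpha = 0.05$ (`varianceGate()`), with the level
configurable and the verdict logged per row. `tTestSummary()` computes
the routed two-tailed t test directly from (mean, SD, n) — fractional
Welch--Satterthwaite degrees of freedom are not rounded — and is
cross-checked against `t.test()` on raw vectors in the test suite.
`bhAdjust()` applies Benjamini--Hochberg across exactly the metabolites
supplied ($m$ = number of rows; for the packaged tables $m = 31$).
Recomputing the printed adjusted P values of the first table requires
$m = 35$, which cannot be reconciled with its 31 printed rows; the
standard definition is implemented and printed adjusted values are
compared only qualitatively. Percent change is
$(\bar{x}_\mathrm{ref}-\bar{x}_\mathrm{other})/\bar{x}_\mathrm{ref}
\times 100$, positive when the case group is lower, matching the usage
"succinate levels were 27.1% lower". Power analysis
(`powerTwoSample()`) uses the noncentral-t power of the two-sided
two-sample test at the pooled SD. One-way ANOVA and the embryo-resorption
rate $R/(R+V)\times 100$ round out the statistics the cohort data
require.

### Reproducing printed p values from rounded tables

A p value recomputed from 3-decimal summary statistics is only determined
up to the rounding of its inputs. `pValueInterval()` propagates half of
the last printed digit of each mean and SD (parsed from the preserved
printed strings — `"0.09"` carries five times the uncertainty of
`"0.090"`) through the routed t test and returns the attainable
interval. `reproduceTableStats()` reports, per row, the recomputed
statistics side by side with the printed values and whether the printed
p lies in its interval; for both packaged tables all 31 rows are
covered. Well-conditioned rows (lactate, glutamate, alanine, valine,
uracil, phenylalanine, the decidua-villi succinate row) reproduce the
printed value to the printed precision; rows like pyruvate and citrate
are inherently not point-recoverable from rounded inputs and are covered
by the interval check instead.

## Numerical choices and degenerate inputs

* Half-open `[lo, hi)` intervals everywhere make binning a partition.
* The first FID point is halved before the FFT (discrete-integral
  convention), keeping baselines flat and integrals invariant under
  zero-filling.
* Negative region integrals (noise in empty regions) are floored at zero
  with a warning rather than propagated into concentrations.
* Two zero SDs gate as "equal" (logged); a zero pooled SD with unequal
  means yields power 1 (logged); the relaxation correction refuses
  $t = 0$ (0/0); automated phasing refuses an all-zero spectrum; a
  missing reference peak is an error.
* Library validation is order-independent and names both offenders when
  regions overlap.

## Problem sizes used by the tests

Unit tests run the simulator at 8k points with 16k zero-fill, which
preserves every numerical property at a fraction of the cost; the
end-to-end cohort tests and the acceptance script use the full
32k/128k geometry with $n = 30$ per group, the study's design size.
Statistical calibration uses 2000 null metabolite tests at $n = 10$ per
group (type-I error within 0.05 +- 0.01, BH false-rejection fraction
below 0.05) and 250 replicate null studies for the
Kolmogorov--Smirnov uniformity check of the p-value distribution.

## Worked example

```{r example, eval = FALSE}
library(quantNMR)

table1 <- readSummaryTable(system.file("extdata", "table1_villi_rsa.tsv",
                                       package = "quantNMR"))

## statistics straight from the printed summary data
cmp <- differentialTable(table1)
cmp[cmp$metabolite == "Succinate",
    c("test_mode", "t", "p", "adjusted_p", "percent_change")]

## full synthetic pipeline: simulate -> process -> quantify -> compare
dN <- groupDistribution(table1, 1, "normal")
dR <- groupDistribution(table1, 2, "rsa")
res <- endToEndRecovery(dN, dR, nPerGroup = 30, seed = 1)
head(res$recovery)
res$comparison$metabolite[which.min(res$comparison$p)]  # "Succinate"
```

## Known limitations

* No peak deconvolution: overlapped multiplets cannot be quantified;
  the library's disjoint-region constraint makes the limitation explicit
  instead of silent.
* No cross-sample alignment or solvent-region handling; synthetic
  spectra do not need them, real ones often do.
* Equivalence with any vendor processing software is not claimed — only
  with the stated mathematical operations.
* The truncated-normal cohort model slightly inflates the mean of
  metabolites whose printed SD approaches their mean; for the succinate
  recovery target the truncation mass is negligible.
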