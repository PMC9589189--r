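---
title: "Methods: receptor-library screening, dose-response and panel models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptor-library screening, dose-response and panel models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orscreen)
```

This vignette documents the models behind each pipeline stage, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The assay chain

A deorphanization campaign of this design proceeds in four stages. A
library of OR variants is expressed in HEK-293 cells in 96-well plates and
challenged with a candidate odorant while a cAMP luciferase reporter is
read three times before and three times after stimulus (60 s intervals).
Variants that exceed a screen-wide 2σ threshold are re-tested in
concentration series and their EC50s estimated by Hill fits. In parallel,
the chemistry the receptor should explain is quantified by GC-MS against a
spiked internal standard, and human relevance is assessed with
forced-choice sensory panels whose members are genotyped at the candidate
OR loci.

## Screening model

Each well's signal is `Δ = mean(post) − mean(basal)`; negative values are
retained, never clipped. Per plate, signals are divided by the summarized
signal of the OR1A1 + 30 µmol/L R-(−)-carvone positive-control wells, which
cancels plate-to-plate scale (a tested invariance). Duplicate wells are
normalized first and averaged per variant afterwards. Mock
(receptor-free-plasmid) wells are normalized identically and reported
alongside, but are excluded, together with the positive control, from the
screen statistics: the mock is a plotted reference level, not part of the
library distribution.

**Threshold statistics.** Hits are variants whose duplicate-averaged
normalized value strictly exceeds `mean + 2·SD`. Two choices are explicit
arguments rather than hidden conventions:

* `sd_convention`: sample (n−1, the default — the library is treated as a
  sample) or population SD.
* `stat_level`: whether mean and SD are computed over per-well normalized
  signals (`"wells"`, the default when per-well data are available) or
  over the per-variant averages (`"variants"`).

The `stat_level` default deserves its own paragraph, because it is a real
design decision. If the dispersion is estimated from the per-variant
duplicate averages themselves, then for any near-Gaussian noise the
expected fraction of a null (no-responder) library beyond `mean + 2·SD` is
the Gaussian tail mass at 2σ, about 2.3%, *independent of the noise
magnitude* — a 616-variant screen with no true ligand would hand you ~14
"hits" every time, incompatible with the sub-2% false-positive rate such
screens are engineered for. Estimating the dispersion from the individual
replicate wells instead means duplicate averages (whose sampling SD is
smaller by √2) are compared against a threshold at effectively 2√2 σ of
their own distribution, putting the null exceedance near 0.24%. The
package therefore uses well-level dispersion for full screens; calling
`call_hits()` on a bare per-variant table (as in quick interactive use)
falls back to variant-level statistics. Both are available, the choice is
printed with the result, and the calibration is verified by a test that
runs null screens through the pipeline.

False positives are hits that fail concentration-response validation; the
fraction is reported over all screened variants, not over hits.

## Dose-response model

Responses are `Δsignal` minus the matched mock `Δsignal` of the same
odorant and concentration, normalized either to the plate positive control
or to the curve maximum (`normalize_mode`). Each replicate is fit
separately with

`f(x) = (min − max) / (1 + (x/EC50)^Hillslope) + max`

and EC50s are summarized as mean ± sample SD across replicates — a
per-replicate-then-summarize scheme, matching how such assays report
"mean ± SD (n = 3)", rather than one pooled fit.

**Numerics.** The fit is bounded Levenberg–Marquardt (`minpack.lm`),
with EC50 parameterized as log10(EC50). Initialization: `min`/`max` at the
smallest/largest response, EC50 at the geometric mean of tested
concentrations, Hillslope 1. Bounds: EC50 in `[min(conc)/100,
max(conc)·100]`, Hillslope in `[0.1, 10]`; convergence tolerances 1e-12 on
the objective and parameters. A fit is non-converged if the optimizer
fails or EC50 lands on a bound. `min` is free rather than fixed at 0 (the
mock subtraction already centers the baseline, but residual offsets are
absorbed by `min`); both the bounds and this choice are visible arguments
of the result, and a grid-search oracle test confirms the optimizer finds
the global least-squares solution on small curves. Zero concentrations
cannot enter a log-space fit and are excluded from fitting.

**Nonresponder (ND) rule.** The assay convention "no response detected up
to 1000 µmol/L" needs an operational criterion. A replicate votes ND when
its fit failed, its fitted amplitude `max − min` is below 3× the SD of
mock-subtracted mock responses (the assay's noise floor), or its fitted
EC50 exceeds the highest tested concentration. A strict majority of ND
votes — 2 of 3 at the standard replicate count — yields status
`nonresponder` with ND values.

## Headspace quantification

Amounts are single-point internal-standard estimates, `ng = is_ng ·
area(analyte) / area(IS)`, with a unit response factor (no per-analyte
calibration curves; the factor is a visible constant). The strain
statistic is the mean ± sample SD of *per-sample* ratios, not the ratio of
mean amounts: a reported "fold-amount ± SD (n = 10)" implies per-sample
variability. The ratio cancels the internal standard entirely, which is
tested as an invariance.

## Panel statistics and the genotype-expectation model

Forced-choice trials are scored against their chance probability — 1/3 for
triangle and odd-one-out formats, 1/2 for binary resemblance judgements —
with a Pearson chi-square goodness of fit (1 df); the Yates correction is
available by flag but off by default. Printed chi-square values in the
source study's figure legends do not back-solve to integer correct counts
under either form, so the package implements the standard forms and does
not chase those statistics.

The genotype-expectation model assumes carriers of a functional haplotype
answer correctly with probability `p_detect` and everyone else guesses at
`p_chance`; the number correct is then `Binomial(n_carriers, p_detect) +
Binomial(n − n_carriers, p_chance)`, computed exactly by convolution and
verified against brute-force enumeration for small panels. With 14 of 29
panelists carrying the functional haplotype, perfect detection and 1/3
chance, the expectation is 19 correct answers.

Two carrier definitions coexist and are kept distinct on purpose:
`is_carrier()`/`carrier_summary()` use the *site-based* definition (any
haplotype containing the variant's site counts, composites included),
while the panel generator conditions detection on carrying a *functional*
haplotype (for OR10A6, only L287P alone — composite haplotypes containing
the L287P site are annotated non-functional in the shipped table). In the
population the site-based OR10A6 L287P carrier rate is far higher than the
functional-haplotype carrier rate, so conflating the two would distort the
expectation model.

Molar masses come from molecular formulas and IUPAC 2021 standard atomic
weights, so 1 ng/mL of C11H20O prints as 0.006 µmol/L without any
hard-coded mass.

## Genotyping

Diplotypes are assigned by enumerating all unordered pairs of defined
haplotypes and keeping those whose per-site alternate-allele dosage
matches every call — a computational stand-in for manual chromatogram
haplotyping, which likewise cannot phase. When several pairs are
consistent (e.g. heterozygous at all three OR10A6 sites), the pair
maximizing the product of population frequencies is returned with an
ambiguity flag. The haplotype table ships as a versioned CSV with both
database frequency columns (minor-allele and haplotype frequencies);
callers choose via `freq_source`, defaulting to the haplotype-frequency
column. Haplotypes missing from the chosen column receive a 0.01% floor so
they remain assignable but never beat an observed haplotype in the prior.

## The synthetic-data generator

The generator exists so every stage can be exercised end to end with known
ground truth. Its defaults are the study conditions, chosen once:

* **Library layout**: 616 variants in duplicate, one mock and one
  positive-control well set per 96-well plate, three basal and three post
  reads per well; screening at 30 µmol/L Z4-11Al with OR10A6 L287P
  (EC50 28.21 µmol/L) planted as the sole responder.
* **Noise model**: multiplicative Gaussian with CV `noise_cv = 0.05` on
  every read (luminescence noise scales with signal) and a per-plate scale
  factor with SD `plate_scale_sd = 0.10`. No published noise magnitudes
  exist for this assay; these values are plausible for plate luminescence
  and, with the well-level threshold statistics above, keep null screens
  below the 2% false-positive bound (a tested property). Because
  normalization cancels the plate factor, the false-positive rate is
  insensitive to `plate_scale_sd`.
* **Signal scale**: basal mean 1000 LU, positive-control amplitude
  5000 LU; responder amplitudes are expressed as fractions of the
  positive-control amplitude. Amplitude fractions and the Hill slope
  (1.2) for the reference parameter sets are package defaults taken from
  the screens' relative response magnitudes; the source assay reports
  EC50s only.
* **Headspace**: the Zimbabwe preset draws per-batch fold ratios from a
  lognormal *moment-matched* to arithmetic mean 2.6 and SD 0.7 — the
  reported statistic is an arithmetic mean ± SD, so matching the median
  instead would bias per-batch means upward by ~3%. The cosmopolitan
  preset emits zero Z4-9Al. Batch Z4-11Al amounts default to a mean of
  50 ng per 60-female 24 h collection (sub-ng/h per female emission times
  collection efficiency; the exact value only sets a scale that cancels in
  the ratio).
* **Panels**: diplotypes drawn independently per gene at the table
  frequencies (no linkage model — no joint frequencies are published);
  carrier detection probabilities default to 1.0 at 10 ng, 0.9 at 1 ng
  and chance at 0.1 ng Z4-11Al, a minimal psychometric stand-in
  consistent with significance emerging between 0.1 and 1 ng.

Fixed seeds give byte-identical output; a seed is mandatory in every
config.

**What the generator does not emulate**: luminescence kinetics beyond the
3 + 3 read design; receptor surface-expression differences (so passing
tests say nothing about expression-driven amplitude artifacts in real
screens); chromatogram waveforms (peak areas only); panelist-level
response correlation across trials, fatigue, or learning; linkage between
the two OR loci. Tests passing on synthetic data demonstrate the
*analysis* is correct under the stated statistical structure, not that
real assays satisfy that structure.

## Problem sizes and test design

The package's own test suite runs full-size screens (616 variants, 14
plates) in Monte-Carlo loops of 100 seeds for the hit-calling and
false-positive calibration checks, 25–30 seeds for EC50-recovery and
fold-ratio checks, 10,000 simulated individuals for haplotype-frequency
recovery, and brute-force enumeration oracles on small instances (≤10
variants for screening, 2^7 outcome vectors for the panel distribution,
a 7,700-node grid for the Hill fit). These sizes make every stochastic
assertion stable at fixed seeds while the whole suite stays fast.

## Known limitations

* The 2σ rule is a screen-relative criterion; it cannot detect a ligand
  that activates many library members weakly (the threshold would rise
  with the mean).
* Single-point internal-standard quantification assumes equal detector
  response for analyte and standard; with a true response factor far from
  1 the *ratio* statistic is still correct only if both aldehydes share
  their factor.
* The ND rule depends on mock replicate spread; with noise-free synthetic
  mocks (`noise_cv = 0`) the amplitude criterion degenerates and only the
  EC50-range criterion distinguishes nonresponders.
* Phase-ambiguous diplotypes are resolved by a frequency prior, which is
  a point estimate; the ambiguity flag should be consulted before any
  carrier-level inference on ambiguous individuals.
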