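---
title: "An integrated untargeted-to-targeted GC-MS workflow for wine volatiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated untargeted-to-targeted GC-MS workflow for wine volatiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinomix)
```

## The problem

Targeted quantitation of wine volatiles measures only the compounds you
thought to calibrate. Subtle viticultural treatments — the rootstock a vine
is grafted to, or its irrigation regime — shift many volatiles by modest
amounts (tens of percent), and a targeted panel can simply miss the
compounds that respond. `vinomix` implements the complementary strategy: an
*untargeted* survey of scan-mode GC-MS features first, statistical selection
of the features that respond to treatment, spectral identification of the
selected features, and only then *targeted* quantitation of the identified
compounds against authentic-standard calibration — finishing with odor
activity values (OAV = concentration / odor threshold) to rank the compounds
by likely sensory relevance.

The funnel is:

```
runs (mzML) -> peaks -> aligned features -> ANOVA + FDR -> PCA / PLS-DA
            -> pseudo-spectra -> library match + retention index
            -> calibration -> concentration -> OAV
```

Every stage is an exported function; `run_pipeline()` orchestrates them and
writes each intermediate table plus a JSON manifest of funnel counts.

## The synthetic study generator

Real wine GC-MS studies cannot ship inside a package, so `vinomix` includes
a generator whose output has the statistical structure the workflow assumes.
`default_study_recipe()` defines the reference study:

* **Design**: 4 root systems (own-rooted, 1103P, 3309C, SO4) x 3 irrigation
  regimes (full, regulated deficit, none) x 2 vines, each wine injected
  twice — 48 runs, 24 biological samples.
* **Compound panel**: 60 volatiles — 24 curated wine volatiles with
  plausible unit-mass EI fragments, polar-column retention indices, typical
  concentrations and literature odor thresholds, padded with procedurally
  generated "unknowns". Twelve compounds carry a rootstock effect on the
  own-rooted level; see *Effect sizes* below.
* **Biological noise**: per-compound, per-biological-sample log-normal with
  CV 15%, mean-preserving. Technical replicates share the biological draw —
  a duplicate injection re-measures the same wine.
* **Instrument model**: each compound elutes as a Gaussian (sigma 2.5 s,
  chosen inside the 5–20 s half-height-width acceptance window so the width
  filter is exercised but not marginal); a fragment channel's apex
  contribution is concentration x response x relative intensity. Per-run
  nuisances: retention drift (sd 0.02 min) and a global response factor
  (log-normal, CV 5%) that internal-standard normalisation must cancel.
  Counting noise is Poisson with mean signal + floor (floor 5 counts);
  `noise_floor = 0` switches all noise off for exact-recovery tests.
* **Internal standards**: 2-octanol at 50 ug/L (the response normaliser),
  4-methyl-2-pentanol at 100 and 3-octanone at 50 ug/L.
* **Acquisition grid**: 240 scans/min over m/z 29–300 and 1.5–38 min, with a
  C7–C30 alkane ladder from 2.4 to 36.8 min. These sizes are the package's
  choice of a representative desk-scale study: large enough that feature
  counts land in the hundreds — the order of magnitude untargeted wine
  studies report — while a full pipeline run stays in the low minutes.

What the generator deliberately does **not** emulate: chromatographic
tailing and fronting, co-elution-dependent ion suppression, column bleed,
high-resolution m/z, or between-batch instrument drift beyond a smooth
per-run shift. Passing tests therefore demonstrate that the algorithms are
correct on data obeying their stated model, not that the pipeline is robust
to every artefact of a real instrument.

### Effect sizes

The planted rootstock effects are drawn uniformly from 35–50% shifts
(alternating up/down) on the own-rooted level. A truth-level power analysis
for this design (6 own-rooted vs 18 grafted biological samples, one-way
ANOVA over 4 groups at 15% CV, Benjamini–Hochberg across ~300 features)
shows that shifts of exactly 25% sit on the edge of detectability — a
recovery test at that size would measure F-test power, not pipeline
correctness — while 35%+ shifts are recovered with probability above 0.9.
The generator therefore plants comfortably detectable effects; smaller ones
(e.g. the ~10% own-rooted contrast typical of a norisoprenoid) can be
planted explicitly via `compound_spec(effect_multiplier = c(Own = 1.105))`.

## Feature detection and alignment

Unit-mass quadrupole data puts every nominal m/z in its own channel (the
configured m/z tolerances, 0.01–0.015, are far below unit spacing), so
detection runs per integer-m/z extracted ion chromatogram rather than on
high-resolution regions of interest:

1. channels are smoothed with a Gaussian kernel (sigma = min peak width /
   2.355);
2. smoothed local maxima become candidates near stretches passing the
   prefilter (>= 3 consecutive scans >= 100 counts);
3. the full width at half height is measured **on the raw EIC** above a
   linear baseline between the window ends — measuring on the smoothed trace
   would widen narrow peaks past the 5 s minimum and defeat the width gate;
4. signal-to-noise is apex height over 1.4826 x MAD of the channel outside
   candidate windows (floored at 1), threshold 6;
5. the area is the trapezoidal integral above the baseline, clipped at zero,
   in counts x seconds.

Retention-time correction uses peak-group warping: groups present in >= 90%
of runs with one peak per run anchor a per-run loess fit of deviation vs
retention time; the fitted warp is clamped to strict monotonicity (scans are
never reordered) and extrapolated with unit slope beyond the anchor range.
With fewer than five anchors a per-run alkane ladder can substitute; with
none the warp is the identity plus a warning. This replaces raw-profile
dynamic warping with a method that serves the same purpose, is testable
against constructed drifts, and is orders of magnitude simpler.

Grouping follows the kernel-density convention: per channel, a Gaussian
density (bandwidth 5 s) over corrected retention times; density maxima
define groups; one peak per run per group (largest area wins). A group is
kept when detected in at least `minfrac` (inclusive — a fraction exactly at
the threshold passes) of some metadata class's runs, or in `minsamp` runs
overall. Undetected cells are filled by integrating the raw warped EIC over
the group's median window (a non-positive integral falls back to a
noise-floor area so log transforms stay defined), and technical replicates
are averaged arithmetically.

## Statistics

Preprocessing is the standard chain: divide each sample by its
internal-standard response (cancelling per-run response drift exactly), then
log(x + 1), then per-feature autoscaling. Internal-standard features and
zero-variance features are dropped. Calling `preprocess()` twice errors — the
state machine guards against double scaling.

* **Univariate**: one-way fixed-effects ANOVA per feature per factor
  (rootstock, irrigation), computed vectorised from sums of squares and
  cross-checked against `aov()` in the tests; Benjamini–Hochberg q-values
  within each factor's family. The two factors are tested one-way at the
  feature stage and two-way with interaction only at the compound stage,
  mirroring the split between screening and quantitation.
* **PCA**: singular value decomposition; variance fractions denominated over
  all components; the largest-magnitude loading of each component is made
  positive so signs are reproducible.
* **PLS-DA**: NIPALS PLS2 against centred one-hot class membership, two
  components by default. R2Y is the cumulative explained class-matrix
  variance; Q2 = 1 - PRESS/TSS with PRESS from leave-one-out refits (one
  biological sample per fold, after replicate averaging). VIP_j =
  sqrt(p x sum_a ssy_a w_ja^2 / sum_a ssy_a) with unit-norm weight vectors,
  so mean(VIP^2) = 1 identically — the tests assert this on every fit.
  Permutation validation refits the LOOCV Q2 under B label permutations and
  reports (1 + #{perm >= observed}) / (B + 1); the smallest attainable
  p-value is therefore 1/(B+1) — with B = 1000 about 0.1%, which is why
  "probability of chance below 0.0001%" claims are not reproducible with
  this estimator and are not made here. Q2 is used as the permutation
  statistic; it is the quantity the model is judged by.
* **Variance partition**: per principal component (up to 20), the linear
  model score ~ rootstock + irrigation + interaction with type-I sums of
  squares in that order — equal to type-III on this balanced design — giving
  each term's variance fraction and F-test p-value.

A note on realized FDR: features inherit their compound's biological draw,
so the ~5 fragments of one compound are nearly perfectly correlated. Under
the null a compound occasionally reaches the BH threshold by chance and
brings all its fragments along; realized feature-level false discovery is
therefore lumpy across seeds (usually 0%, occasionally a block) even though
the per-compound test is exactly calibrated. This is the same behaviour
real feature tables show.

## Identification

Significant features are clustered into pseudo-spectra by single-linkage on
retention time with a 3 s gap (the window is not dictated by any standard;
3 s spans typical apex scatter of one compound's fragments and is exposed in
the configuration). Identification is two-step:

1. **Match factor**: a weighted-cosine identity score on the 0–999 scale
   with weights intensity^0.5 x m/z — the common choice for EI identity
   search; both exponents are configurable since library vendors do not
   publish theirs. Only scores >= 700 proceed.
2. **Retention index**: calculated in the van den Dool–Kratz linear form
   (the run is temperature-programmed; the isothermal logarithmic Kovats
   form is available behind `form = "kovats"`), refusing to extrapolate
   outside the C7–C30 ladder. The calculated index must fall within 15
   units of the library value — a default chosen to accept the classic
   ~12-unit gap between a calculated and a literature index on a polar
   column, with margin.

Ties between library entries are broken by the smaller RI gap. Entries that
match well spectrally but sit > 15 RI units away are `rejected`; spectra
with no library match >= 700 are `orphan` — both outcomes occur in real
studies and in the synthetic decoy tests, where perturbed-spectrum decoys
with 30–80-unit RI shifts must never be accepted. Optional confirmation
against a simulated authentic-standard run requires retention agreement
within 3 s *and* a spectral match >= 700.

## Quantitation

Response ratios (analyte area / 2-octanol area on the quantifier ion) are
converted to concentrations via 1/x-weighted least-squares calibration —
the appropriate weighting when calibration noise grows with concentration;
the tests verify the weighted fit beats the unweighted one on
heteroscedastic data and matches a normal-equations oracle. R2 is computed
in its weighted form (no standard defines it otherwise for weighted fits);
curves below R2 = 0.99 are flagged unusable rather than silently applied.
Compounds without a usable curve fall back to semi-quantitation at an
assumed response factor of 1 (concentration = ratio x 50 ug/L); when the
true response factor is exactly 1 and the curve passes through the origin
the two coincide, which the tests assert.

Per-compound inference is a two-way fixed-effects ANOVA (rootstock,
irrigation, interaction) followed by all-pairwise comparison of the 12
interaction cells. Tukey's HSD is the default post-hoc — it controls
family-wise error — with Duncan's multiple range test available behind
`posthoc = "duncan"` for comparability with tables that use it; the two
tests disagree in exactly the way their error-rate philosophies predict.
Letters come from the insert-and-absorb compact-letter-display algorithm
and are verified against the brute-force pairwise p matrix: two cells share
a letter exactly when their pairwise p >= 0.05. Concentrations are averaged
over injections before the ANOVA, consistent with feature-stage replicate
averaging.

Odor thresholds ship as an editable CSV
(`system.file("extdata/odor_thresholds.csv", package = "vinomix")`) of
literature values; they are user-supplied data, not asserted truth, and a
missing threshold yields a missing OAV, never zero.

## Numerical choices and degenerate inputs

* Retention times are stored in minutes everywhere; widths and bandwidths
  are specified in seconds and converted at one point.
* A feature's identifier is `M{mz}T{rt}` with retention time to two
  decimals; collisions get a numeric suffix.
* BH q-values: `q_i = min over ranks j >= rank(i) of p_(j) n / j`, capped at
  1 — verified against a brute-force oracle and `p.adjust`.
* Zero within- and between-group variance gives p = 1, not NaN; a constant
  compound table gives a single shared letter and p = 1.
* A flat calibration series has slope 0, R2 defined as 0, and is flagged.
* Warps are strictly monotone by construction (cummax plus an epsilon ramp
  applied only where flats occur).
* All simulation randomness flows from a single recipe seed; the pipeline
  re-seeds from its configuration, so a full run is byte-reproducible.

## Known limitations

* Detection is not a continuous-wavelet method: heavily overlapping peaks
  on one channel are split only if the smoothed trace has two maxima.
* Pseudo-spectrum construction is retention-gap clustering, not model-peak
  deconvolution; co-eluting compounds closer than the gap merge and
  typically surface as `orphan` or depressed match factors.
* The NIST "match probability" field is not reproduced — it requires a
  proprietary in-library ambiguity model; the match factor is the gate.
* Cross-year feature matching is by identifier string with an optional
  retention tolerance; no claim is made about which convention any given
  external tool uses.
* MS/MS (MRM) data are out of scope; transitions are metadata only.
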