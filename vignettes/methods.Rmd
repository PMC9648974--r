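---
title: "Models and methods behind hepatoxim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hepatoxim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepatoxim)
```

hepatoxim implements the quantitative core of a mouse-liver oxygen-challenge
MRI + isotope-tracing + label-free omics workflow. This vignette documents
the models, the tunable parameters, the synthetic-data generators that stand
in for animal data, and the numerical and design choices, including the
limitations we measured ourselves.

## Oxygen-challenge MRI

### Variable-flip-angle T1 mapping

A spoiled gradient-echo (SPGR/FLASH) cine acquired at two flip angles
$\alpha_1, \alpha_2$ determines the apparent longitudinal relaxation time
pixel by pixel. The full steady-state signal is

$$S(\alpha) = M_0 \sin\alpha \, \frac{1 - e^{-TR/T_1}}{1 - e^{-TR/T_1}\cos\alpha},$$

and for small angles and $TR \ll T_1$ it linearizes to
$S/\alpha = M_0 - \frac{T_1}{2\,TR}\, S\,\alpha$, a line in
$(x, y) = (S\alpha,\ S/\alpha)$ whose slope gives
$T_{1,\mathrm{app}} = -2\,TR\,(y_1 - y_2)/(x_1 - x_2)$ from exactly two
angles. `fit_t1_vfa()` implements that closed form. It is *apparent* T1:
no B1 correction is attempted, because the challenge statistic
$\Delta T_1 = 100\,(T_{1,\mathrm{O_2}} - T_{1,\mathrm{air}})/T_{1,\mathrm{air}}$
(in percent, `relative_delta_map()`) cancels static spatial scale factors.
Angles are stored in degrees in metadata and converted to radians before
fitting. Pixels with a degenerate local design ($x_1 = x_2$), non-positive
or non-finite estimates, or estimates above a ceiling (default 10 s) are
masked invalid rather than propagated.

On data generated from the linearized forward model the estimator is exact
to floating point; on data from the full SPGR equation at $\alpha$ = 5°/20°,
TR = 10 ms and liver-like T1 (500–2500 ms), the small-angle approximation
contributes a median bias of roughly 1–2%, which the phantom tests measure
directly.

Cines reach steady state after an initial transient; `average_frames()`
averages a closed 1-based frame interval (the acquisition convention, e.g.
frames 55–65 of 65) before fitting.

### Vessel exclusion and ROI statistics

Blood T1 at high field is much longer than liver tissue T1, so vessels are
outliers of the ROI's T1 distribution. `exclude_vessels()` computes the ROI
mean and *sample* SD once (a single pass, no iteration) and removes pixels
outside mean ± k·SD with k = 2 by default, boundaries inclusive. On a
Gaussian T1 field this removes the two-sided 2-SD tail mass, 4.55% of
pixels, which the tests verify within binomial error; on a uniform field
nothing is removed (SD = 0 keeps every pixel at the mean). Re-running on
the reduced region with the statistics implied by that region is idempotent
in the constructed-outlier case. `masked_mean()` reports mean, sample SD
(n − 1), and pixel count; a single-pixel mask yields an `NA` SD rather
than a fabricated zero.

### Multi-echo T2* relaxometry

Sixteen gradient echoes at 2.5 ms spacing are fit per pixel to the offset
exponential $s(TE) = A e^{-B\,TE} + C$ with $T_2^* = 1/B$ in ms, by
bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm` with an
analytic Jacobian; B constrained to $(10^{-6}, 10)$ /ms, at most 200
iterations, `ftol = ptol = 1e-12`). Starting values come from a log-linear
regression of the early echoes after subtracting the last-echo signal as a
crude offset. Pixels are masked invalid — never extrapolated — when the
signal has zero variance (A = 0 leaves B unidentifiable), the solver does
not converge, or the relative residual (RMSE divided by mean absolute
signal) exceeds a configurable ceiling (default 0.5, i.e. only gross
failures are dropped). Since the decay rate does not depend on amplitude,
estimates with C = 0 are invariant to global signal scaling, which the
tests assert.

**A precision limitation worth knowing.** The three-parameter offset
exponential is poorly conditioned when the echo train covers only ~2.4
decay constants. At A = 100, C = 5, T2* = 20 ms and Gaussian noise
SD = A/50 ("SNR 50"), the Cramér–Rao bound for this design gives a
relative T2* standard deviation of 7.3%, i.e. a minimum achievable median
absolute relative error near 4.9% for any unbiased fitter of this model.
Our fitter measures ~4.7–4.9% median error on that phantom — essentially
efficient — so sub-3% precision at SNR 50 is not reachable without either
dropping the offset term (a two-parameter fit would reach ~1.6%) or more
averaging; we keep the three-parameter model because the offset is part of
the stated acquisition model.

### FAIR perfusion index

Flow-sensitive alternating inversion recovery compares a slice-selective
inversion (inflowing spins are un-inverted, adding an apparent relaxation
rate $f/\lambda$) against a global inversion, with a reference image
(no inversion) supplying $M_0$. Assuming perfect inversion and a single
inversion time TI, each inverted image gives
$R_{1,\mathrm{app}}(s) = -\ln\!\big((1 - s/M_0)/2\big)/TI$, and the
perfusion index is $f = \lambda\,(R_{1,\mathrm{sel}} - R_{1,\mathrm{glob}})$
with the blood–tissue partition coefficient $\lambda$ = 0.9 mL/g by
default. This is deliberately an *index* in institutional units — a
single-TI, perfect-inversion two-compartment simplification, not an
absolute CBF-style quantification. Pixels where the reference is
non-positive or the log argument is non-positive ($s/M_0 \ge 1$) are
masked. Composed with its generator the estimator is the identity on $f$
to solver precision, and $f = 0$ yields an identically zero map.

The delta-map analysis assumes the air and O2 images are co-registered;
per-pixel differencing followed by ROI averaging is used (sub-ROI
averaging before differencing would also be defensible; the per-pixel
order preserves the pixel-level distribution for the vessel filter).

## Isotope tracing

### Natural-abundance correction

GC-MS measures methoxime-TBDMS derivatized fragments, so the measured ion
carries many atoms beyond the metabolite backbone — notably silicon, whose
heavy isotopes (4.68% ²⁹Si, 3.09% ³⁰Si per atom) dominate the mass
broadening. A `fragment_spec` therefore lists the *complete* elemental
composition of the measured ion plus the number of labelable backbone
carbons. The correction matrix column for labeling state $j$ is the
predicted observed mass distribution of a molecule with exactly $j$ tracer
carbons: the per-atom isotope mass-shift distributions of every atom
except the $j$ labeled carbons are convolved, shifted up by $j$, truncated
to the measured window, and renormalized. Truncation-plus-renormalization
is what makes each column a probability vector over the measured
isotopologues. `correct_mid()` then solves $M x = \mathrm{observed}$ by
non-negative least squares (`pracma::lsqnonneg`) and renormalizes — the
referenced correction-matrix practice; negativity from noise is clipped
before the solve, and matrices with 2-norm condition number above $10^8$
are rejected with a diagnostic rather than silently inverted. Round trips
(convolve, then correct) recover arbitrary labeling distributions to
better than $10^{-8}$ for fragments up to 20 carbons, checked against an
independent atom-by-atom convolution oracle.

Default abundances (¹³C 0.0107, ²H 0.000115, ¹⁵N 0.00364, ¹⁷O/¹⁸O
0.00038/0.00205, ²⁹Si/³⁰Si 0.0468/0.0309, ³³S/³⁴S/³⁶S standard) are all
overridable through `isotope_table()`. The packaged fragment library
carries glucose methoxime-penta-TBDMS [M−57]⁺ (C₃₃H₇₆NO₆Si₅, 6 labelable
carbons) and lactate di-TBDMS [M−57]⁺ (C₁₁H₂₅O₃Si₂, 3 labelable carbons),
derived from standard derivatization chemistry; no automatic adduct
inference is attempted.

### Tracer statistics

`labeled_fraction()` is $1 - m{+}0$; `normalize_enrichment()` divides by a
precursor-pool enrichment (e.g. liver glucose m+6 during a [U-¹³C]glucose
infusion). Fractional gluconeogenesis from a labeled lactate/pyruvate
bolus is

$$\mathrm{GNG} = \frac{M_1^{glc} + M_2^{glc} + M_3^{glc}}
{2\, M_0^{lac}\,(M_1^{lac} + M_2^{lac} + M_3^{lac})},$$

where $M_x$ are natural-abundance-corrected fractional enrichments.
The fractions are consumed *as given* (validated non-negative, summing to
at most 1) rather than renormalized: the glucose terms are a truncated
window (m+1..m+3 of a six-carbon molecule) that legitimately sums below 1,
and renormalizing would change the printed formula's value. Scale
invariance to raw ion intensities is instead guaranteed upstream: readers
(`read_mid_csv()`) normalize intensities to fractions, so multiplying any
sample's raw counts by a constant leaves GNG unchanged. Plasma MIDs are
assumed for the tolerance-test statistic. A fully unlabeled lactate pool
makes the statistic undefined and raises an error.

## Label-free omics statistics

### Normalization

`log2_normalize()` log2-transforms and standardizes each sample by its own
mean and distribution width, then rescales all columns by the grand mean
and pooled width so values remain in log2-intensity units; afterwards every
column has identical mean and SD. "Width" is the sample SD by default,
switchable to MAD. `tic_normalize()` (metabolomics) equalizes column sums
to their grand mean instead. A consequence of column standardization worth
knowing: when a nontrivial fraction of features genuinely changes in one
group, those features inflate that group's column widths, and true fold
changes shrink accordingly (measured below).

### MNAR imputation

Missing label-free intensities are censored at the detection limit, i.e.
missing-not-at-random. `impute_mnar()` fills each missing cell with a draw
from a Gaussian centered `shift_sd` = 2.5 column SDs *below* the column
mean with width `width_sd` = 0.3 column SDs, computed from present values.
The downshift is part of the stated procedure; the width is not stated
anywhere, so 0.3 follows common left-shifted-Gaussian practice and is
configurable. Present values are never altered; imputation is a pure
function of (table, seed); features whose statistics involve imputed cells
are flagged in the output.

### Adaptive two-group testing

Per feature: if both groups have more than 4 replicates, each group is
screened by Shapiro–Wilk at 0.05; if either screen rejects, a two-sided
Mann–Whitney test is used. Otherwise an F-test of variance equality at
0.05 selects the pooled t-test or Welch's t-test. Groups of ≤4 replicates
skip the normality screen (it has essentially no power there) and go
straight to the F-gate. Two groups forming a single shared constant get
p = 1 by convention, flagged degenerate, rather than NaN. Mann–Whitney
uses the normal approximation with continuity correction: at the default
group sizes its accept/reject decisions at 0.05 coincide with the exact
test, and the approximation tolerates the ties that occur in real
intensity data. Bonferroni (`adjust_pvalues()`, family = all features in
the run, the only built-in method by design) and the volcano caller
(`call_significant()`, strict inequalities: |log2FC| > 1 *and* adjusted
p < 0.05) complete the pipeline. Fold changes are means of normalized
log2 values, second design group minus first, computed after imputation.

### Measured operating characteristics

The acceptance tests run the full pipeline on synthetic data at the study
scale (2000 features, n = 6 per group; 200 replicate datasets for the null,
5 for the spike recovery — sizes chosen to make the Monte-Carlo error small
at desk scale). Three findings are worth stating plainly:

- **Null calibration.** The fraction of raw p < 0.05 on null data is
  ≈ 0.0496 — inside the 99% binomial band around 0.05, but genuinely
  slightly conservative, because choosing the pooled t-test conditional on
  an accepted F-gate perturbs the conditional null distribution. This is a
  property of the published two-stage recipe, not of the implementation.
  Family-wise error after Bonferroni stays below 0.05.
- **A recall ceiling.** With truly normal data the Shapiro–Wilk screen
  still rejects ~5% per group, routing ≈ 9.6% of features to
  Mann–Whitney — whose smallest achievable two-sided p at n = 6/6 (2/924
  exact) can never pass a Bonferroni-adjusted 0.05 for families larger
  than ~23 features. Those features are unrecoverable regardless of effect
  size.
- **Normalization shrinkage.** With 2% of 2000 features spiked at
  |log2FC| = 2 (balanced up/down, mirroring the sparsity of real
  differential proteomes), column standardization shrinks the realized
  fold changes to ≈ 1.75, and combined with t-statistic sampling variance
  at n = 6 this leaves some truly changed features above the adjusted
  threshold. Measured recall of the full pipeline is ≈ 72–85% (seed
  dependent) with a false-call rate of ≈ 0 — the |log2FC| > 1 gate makes
  false positives essentially impossible at replicate SD 0.3. Users who
  need higher recall at this design should weigh a larger n, a
  less-aggressive family correction, or normalization robust to dense
  regulation; the package deliberately reproduces the published recipe.

### Clustering, ratios, annotation

`zscore_rows()` standardizes feature rows (constant rows are excluded with
a warning — they carry no clustering signal); `cluster_rows()` performs
deterministic agglomerative clustering (average linkage, Euclidean
distance by default) via `stats::hclust`, so permuting input rows permutes
labels but not topology. `redox_ratios()` builds per-sample metabolite
ratio panels (pyruvate/lactate for cytosolic, acetoacetate/β-hydroxy-
butyrate for mitochondrial NAD⁺/NADH state), optionally normalized to a
control-group mean of 1; zero denominators flag the sample rather than
producing infinities. `annotate_mito()` flags features present in a
packaged, case-insensitively matched list of canonical mouse mitochondrial
gene symbols — a small synthetic stand-in for a full localization
inventory, not a database copy.

## Synthetic-data generators

Every generator is a pure function of (spec, seed) — identical inputs give
bit-identical outputs, and each forward model is exactly the model its
fitter inverts, so noiseless round trips recover truth to solver
tolerance. What they emulate, and what they do not:

- **MR phantoms** (`gen_vfa_phantom`, `gen_mge_phantom`,
  `gen_fair_phantom`): true parameter fields with additive Gaussian noise
  on magnitude signals. Rician noise, B1 maps, slice profiles and
  respiratory motion are *not* modeled; at the SNRs used the
  Gaussian/Rician difference is negligible, and Gaussian noise keeps
  noiseless round trips exact. The in vivo acquisition geometry
  (two-angle cine, 16 echoes at 2.5 ms, TI 2000 ms with a reference image)
  is the default. Phantom noise levels are free parameters, since no noise
  statistics are published for the modality.
- **Isotopomer data** (`gen_mid_dataset`): forward convolution of a true
  labeling distribution with the fragment's natural abundance, plus
  fractional Gaussian noise, clipped and renormalized. Chromatographic
  peak shape and integration are out of scope.
- **Omics matrices** (`gen_omics_dataset`): per-feature log2 intensities
  $\mathcal{N}(\mathrm{base\_mean} + \mathrm{group}\cdot\log_2 FC,\
  \mathrm{base\_sd})$, returned on the raw intensity scale; dropout
  probability follows a logistic curve decreasing with intensity, centered
  `mnar_shift` SDs below the grand mean (logistic scale fixed at half the
  replicate SD), with the center offset calibrated by root finding so the
  *expected* overall missingness equals `missing_rate` exactly. Defaults —
  2000 features, 6 per group, base mean 25, replicate SD 0.3, 10%
  missingness — are the study-like conditions; peptide-level structure,
  shared-peptide rollup and intensity-dependent variance are not emulated.
  Passing tests on these generators therefore demonstrates correctness of
  the *computations*, not robustness to every pathology of real data.

## Pipeline and reproducibility

`run_pipeline()` executes one stage (`synth`, `mri`, `tracer`, `omics`)
from a configuration list or YAML file. Configurations are validated
against a per-stage key schema before any computation (unknown keys are
rejected), every stochastic stage requires an explicit seed, and no global
random state is touched (`withr::with_seed` everywhere). Each run writes a
JSON report with the package version, seed, parameters, MD5 hashes of the
inputs and a stage summary; identical configuration and inputs reproduce
every output byte for byte, which the tests assert on the omics CSVs.
Units ride in key names (`tr_ms`, `ti_ms`, `te_ms`). Logs go to stderr;
results never to stdout. Image stacks travel as NIfTI (lossless) or
multi-page TIFF (scaled to [0, 1] with the scale factor recorded in the
JSON sidecar); tables as CSV with `NA`/empty cells for missingness, dot
decimals, and duplicate-id rejection on read.
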