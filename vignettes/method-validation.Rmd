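---
title: "Total-error validation statistics for targeted LC-MS/MS assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Total-error validation statistics for targeted LC-MS/MS assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msval)
```

## The problem

Quantifying a drug and its metabolites in plasma by multiple-reaction-
monitoring (MRM) LC-MS/MS requires demonstrating, before any clinical
sample is measured, that the whole procedure -- extraction, chromatography,
ionization, calibration, inverse prediction -- returns concentrations close
enough to the truth over the intended range. `msval` implements the
statistical machinery of such a validation in the *total-error* framework:
instead of judging systematic error (trueness) and random error (precision)
against separate cut-offs, it asks where future single measurements are
expected to fall, and validates the concentration range over which that
prediction stays inside an acceptance band.

The package was built around a six-analyte benzothiazinone panel (an
antituberculosis drug candidate and five active metabolites, quantified in
citrated human plasma against deuterated and structural-analogue internal
standards), which ships as the ready-made `pbtz169_design()`. Every
computation is generic: any panel described by an `assay_design()` works.

## The model

### Response functions and inverse prediction

The response of an analyte is the analyte/ISTD peak-area ratio $y$ as a
function of concentration $x$ (ng/mL). Over a four-decade calibration range
a single straight line rarely holds, so three candidate families are fitted
(`fit_response()`):

* quadratic, weighted least squares with weights $1/x$:
  $y = a + b x + c x^2$ on raw scales;
* log-log linear: $\log_{10} y = a + b \log_{10} x$;
* log-log quadratic: $\log_{10} y = a + b \log_{10} x + c (\log_{10} x)^2$.

Base-10 logarithms are used throughout; the base cancels in inverse
prediction but fixes the meaning of reported coefficients. The $1/x$
weights use the nominal concentration, the conventional bioanalytical
choice. Inverse prediction (`back_calculate()`) is closed-form for the
linear family; for the quadratic families both roots are examined and
exactly one must fall inside the fitted domain extended by a factor 2.5 on
both ends. The headroom supports quantifying above-range samples (a
5000 ng/mL sample on a 2000 ng/mL curve) while failing loudly -- with both
candidate roots attached to the condition -- when a fold-back makes the
response ambiguous. Concentrations inside the headroom but outside the
fitted domain carry an `out_of_range` flag rather than an error.

Calibration is daily: each validation day's standards fit their own curve,
and validation standards are back-calculated only with their own day's
curve (`daily_quantification()`).

### Variance components and the tolerance interval

Each validation level is measured on $p$ days with $n$ replicates per day
(default $3 \times 3$). `variance_components()` decomposes the
back-calculated concentrations by one-way random-effects ANOVA:

$$ MSW = \frac{\sum_{j}\sum_{r}(z_{jr}-\bar z_j)^2}{p(n-1)}, \qquad
   MSB = \frac{n \sum_j (\bar z_j - \bar z)^2}{p-1}, $$

with repeatability variance $s_r^2 = MSW$ and between-day variance
$s_B^2 = \max(0, (MSB-MSW)/n)$; negative estimates truncate to zero, the
standard ANOVA practice (the printed validation tables that show identical
repeatability and intermediate precision at some levels are exactly this
truncation). Intermediate precision is $s_{IT}^2 = s_r^2 + s_B^2$. Both
components are reported as RSDs **of the nominal concentration**, not of
the observed mean -- a deliberate convention that keeps precision and
trueness decoupled.

The accuracy profile needs an interval expected to contain a proportion
$\beta$ (default 0.90) of *future single measurements*. `beta_eti()`
implements the Mee two-component $\beta$-expectation tolerance interval
with Satterthwaite degrees of freedom: with $R = s_B^2/s_r^2$,

$$ B^2 = \frac{R+1}{nR+1}, \qquad
   \nu = \frac{(R+1)^2}{\dfrac{(R+1/n)^2}{p-1} + \dfrac{1-1/n}{pn}}, $$

$$ \bar z \pm t_{\nu,(1+\beta)/2}\; s_{IT} \sqrt{1 + \frac{1}{p\,n\,B^2}}. $$

The harmonized SFSTP literature that defines the accuracy-profile
methodology cites this interval without printing it, so the formula is a
design decision of this package; it is accepted by *behaviour*, not
provenance: the test suite replays the validation experiment 10,000 times
under the generative noise model and checks that the fraction of
independent future observations inside the interval matches $\beta$ within
1.5 percentage points, for $\beta \in \{0.80, 0.90, 0.95\}$ and both
$3\times3$ and $5\times4$ designs. Degenerate inputs are taken at their
limits: $s_r^2 = 0$ gives $B^2 = 1/n$, $\nu = p-1$; both components zero
give the point interval.

### Accuracy profile and quantification limits

`accuracy_profile()` expresses the interval bounds per level relative to
nominal, computes the per-level total error
$\max(|rel_{low}|, |rel_{high}|)$, and flags levels whose bounds leave the
acceptance band $\pm\lambda$ (default 30% for biological samples). The
LLOQ/ULOQ (`determine_limits()`) are the outermost concentrations at which
both bounds stay inside the band. When the crossing falls between two
adjacent levels the violating bound is interpolated linearly against
$\log_{10}$ concentration (relative mode) -- calibration levels are
log-spaced, so straight lines in log space are the natural reading of a
graphical determination -- or against concentration with the limit lines
$x(1\pm\lambda/100)$ in absolute mode, which resolves the LLOQ more sharply
when relative errors blow up at the bottom of the range. With the
LLOQ-level interval just over the band, the interpolated limit lands
slightly above the lowest level (e.g. +10%), rather than discarding the
level entirely.

### Model selection

`run_validation()` evaluates all three families and selects
lexicographically: (iii) largest validation domain -- lowest LLOQ, then
highest ULOQ -- then (ii) narrowest mean tolerance interval, then (i) best
combined trueness/precision score (mean absolute bias plus mean
intermediate-precision RSD over the levels). The ordering favours the
widest defensible claim first and uses the sharper statistical criteria
only to break ties; it is deterministic and recorded in the report.

### Matrix effects (Matuszewski design)

Three sample sets at three levels: neat standards (A), blank plasma from
several donors spiked *after* extraction (B), and the same donors spiked
*before* extraction (C). `compute_me_er_pe()` computes the matrix effect
per set B replicate as $B/\bar A \times 100$ (reported as deviation from
100), the process efficiency per set C replicate as $C/\bar A \times 100$,
and the extraction recovery per donor as
$\bar C_{donor}/\bar B_{donor} \times 100$. ER pairs within donor because
replicate-level pairing across separately processed samples is physically
undefined -- a choice this package states explicitly. With `by = "donor"`
all three statistics use per-donor means, and $PE = ME \times ER / 100$
holds exactly; the replicate-level path (the reporting convention) is the
default. IS-normalized variants replace every area by the analyte/ISTD
ratio. Regular and lipemic donors are summarized separately, with lipemic
replicates pooled across donors.

### Detection limits

`signal_to_noise()` follows the peak-to-peak convention: noise is the
max-minus-min excursion in a baseline window of at least 30 s immediately
before or after the peak; both sides are evaluated and the *larger* noise
is selected (conservative). Height is the in-window maximum minus the
median of the chosen noise window -- the baseline subtraction is assumed,
and S/N is height over the full peak-to-peak amplitude (not half), matching
the named vendor convention; a halved convention can be configured by
scaling. A zero-noise trace is an error, not an infinite ratio. The LOD is
the lowest tested level with S/N $\ge$ 3 per matrix (`lod_from_scan()`).

The instrument detection limit uses replicate-injection precision instead
of S/N: $IDL = t_{n-1,0.99} \times (RSD/100) \times \text{injected
amount}$, with the one-sided Student factor 2.821 at $n = 10$
(`t_confidence_factor()`, `idl()`).

### QC decision rules

Carryover is the blank-after-high-standard area as a percent of the mean
LLOQ-standard area; the default flag threshold of 20% is the regulatory
convention, stated here explicitly because observed carryover is reported
either way. Ion-ratio confirmation compares qualifier/base product-area
ratios against the calibration-standard mean with a *relative* ±20%
tolerance. Stability verdicts compare time-point means against a t0 mean
or the nominal value at ±15% (±20% at LLOQ); the identical computation
accepts analyte/ISTD response ratios for processed-sample monitoring.
Alternate-anticoagulant and serum QCs quantified on the validated
calibration are judged by the same bias/RSD rules. The whole-blood
correction multiplies plasma concentrations by
$(blood + anticoagulant)/blood$ -- 1.1 for a 10:1 citrate collection.

## The synthetic data generator

No instrument raw data ship with the package; every pipeline stage is
exercised on synthetic measurements with known ground truth
(`ground_truth()`, `generate_design_dataset()`, `generate_matrix_sets()`,
`generate_sequence_with_carryover()`, `simulate_chromatogram()`).

Design choices, and what they imply for the tests:

* **Noise is multiplicative (lognormal).** Precision in this field is
  reported as CV across a four-decade range, so the generative CVs are
  defined on the log scale: a measurement carries
  $\exp(\delta_j + \varepsilon)$ with day effect $\delta_j$ at
  `cv_between` and residual at `cv_repeat`
  ($\sigma = \sqrt{\log(1+cv^2)}$, so the lognormal CV equals the stated
  value). Defaults are `cv_repeat = 0.025`, `cv_between = 0.02`,
  matching the mid- and high-level precision a validated assay of this
  type achieves; both accept a concentration-dependent profile
  (`pbtz169_cv_profiles()` rises to 17% repeatability at the 0.1 ng/mL
  LLOQ), since constant CV is the one feature of real data the scalar
  default clearly lacks.
* **Day effects are shared across levels within a day** (one draw per
  analyte and day), emulating run-level drift; with a level-dependent CV
  profile the shared draw is scaled per level. Because the variance
  estimator must not depend on this sharing, `day_effects = "per_level"`
  generates independent day effects instead -- parameter-recovery tests
  use it so per-level estimates are independent.
* **ISTD noise is shared into the analyte area.** Both signals come from
  the same processed sample, so the ISTD log-noise term multiplies both;
  the analyte/ISTD ratio then carries exactly the stated CVs (making
  recovery tests sharp) while raw areas are realistically correlated. In
  the matrix sets the ISTD experiences the donor's matrix and recovery
  factors raised to `istd_matrix_power` (default 0.8): at 1 the ISTD
  tracks the analyte exactly and IS-normalization cancels the matrix
  effect identically, at 0 normalization does nothing -- the default
  produces the visible-but-partial improvement real ISTDs give.
* **True response curves are gently saturating quadratics**
  ($y = 5\times10^{-4} + 0.025x - 1.25\times10^{-6}x^2$ by default,
  ~11% droop at the top calibrator), so the weighted quadratic family is
  exactly specified and the log families are useful approximations --
  the same situation the model-selection rules face in practice.
* **Carryover** multiplies the previous injection's effective area by a
  fixed fraction into each blank, so successive blanks decay
  geometrically. **Chromatograms** are Gaussians over a constant baseline
  plus bounded uniform noise of stated peak-to-peak amplitude on a fixed
  0.2 s cycle; every peak must leave a 30 s clear window on one side or
  generation refuses, since the S/N estimator would be undefined.

What the generator does *not* emulate -- and hence what passing tests do
not show about real data: chromatographic peak-shape pathology (tailing,
co-elution), inter-batch calibration drift beyond the day effect,
concentration-dependent matrix effects, autosampler-position effects, and
any vendor-specific peak integration. Tests against this generator
validate the *statistics*, not the chromatography.

## Problem sizes and numerical choices

The test suite and the acceptance script use 10,000 Monte-Carlo replays
for coverage checks (Monte-Carlo SE ~0.3 percentage points at
$\beta = 0.9$), a $p = 50 \times n = 10$ design for parameter recovery
(repeatability is then determined to ~3% per level; the between-day SD
still carries ~11% Monte-Carlo spread per level, so recovery is judged on
the across-level mean), and 200,001-point grids for inverse-prediction
oracles (0.1% agreement). Grid density and replay counts were sized so
Monte-Carlo error sits well below the tolerances being checked.

Other numerical conventions: quadratic root selection requires exactly one
admissible root within the 2.5-fold headroom (with a $10^{-9}$ relative
slack at the boundary); `trim_range()` is idempotent and order-independent;
ties in the widest compliant run of an accuracy profile resolve toward
lower concentrations; weighted-fit residuals satisfy the weighted normal
equations to numerical precision (asserted in tests).

## Known limitations

* Only balanced $p \times n$ designs are supported; unbalanced day
  counts are an explicit error, not an approximation.
* $\beta$-expectation (not $\beta$-content/$\gamma$-confidence) intervals
  only.
* The weighted family offers $1/x$ weights only; $1/x^2$ variants and
  4/5-parameter logistic curves are out of scope.
* The response-curve assumption in the generator is quadratic; assays with
  genuinely sigmoidal responses are outside the generator's remit.
* Whether the weighted quadratic should be fitted on the area ratio or the
  raw area is ambiguous in parts of the validation literature; this
  package fits the ratio, consistent with the response-function
  definition, and says so rather than guessing silently.

## A worked run

```{r, eval = FALSE}
design <- pbtz169_design(seed = 42L)
cvs <- pbtz169_cv_profiles()
truth <- ground_truth(design$analytes, cv_repeat = cvs$cv_repeat,
                      cv_between = cvs$cv_between)
measurements <- generate_design_dataset(design, truth)
report <- run_validation(measurements, design)
report
trueness_precision_table(report)
profile_export(report)
```

The `analysis/` directory of the source repository runs this workflow as
numbered scripts (simulation, calibration, validation, matrix effects,
detection limits, QC rules) and writes its tables under `results/`.
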