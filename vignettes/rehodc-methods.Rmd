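---
title: "Methods: simulated rTMS resting-state cohorts, ReHo/DC change maps, and PAIR SVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated rTMS resting-state cohorts, ReHo/DC change maps, and PAIR SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Repetitive transcranial magnetic stimulation (rTMS) of the motor cortex can
change spontaneous activity in remote brain regions. Two voxel-level
resting-state fMRI metrics capture complementary aspects of such changes:

* **Regional homogeneity (ReHo)** — Kendall's coefficient of concordance (W)
  between a voxel's time course and those of its nearest neighbors; a measure
  of local temporal synchronization.
* **Degree centrality (DC)** — the summed suprathreshold correlation of a
  voxel with every other gray-matter voxel; a measure of global (hub)
  connectivity.

The design emulated here is within-subject: each subject receives three
stimulation conditions (High = 10 Hz, Low = 1 Hz, Sham) on separate days, with
resting runs before and after each. Per subject, condition and metric, the
analysis forms a *change map* (post − pre). Group inference proceeds along two
complementary routes:

1. **Univariate** — voxelwise repeated-measures one-way ANOVA across the three
   conditions, cluster-corrected under Gaussian-random-field (GRF) theory
   (voxel p < 0.001, cluster p < 0.05), followed by pairwise paired t tests at
   the peak voxels with Bonferroni control (0.05 / 15).
2. **Multivariate** — a PAIR support-vector machine: feature selection on the
   uncorrected F map (p < 0.05), signed-difference samples per subject,
   linear SVM, and 100 repetitions of split-half validation.

Because the real cohort is not publicly deposited, the package ships a
synthetic-data module with known ground truth; every stage is validated by
oracle equalities, statistical calibration on null cohorts, and recovery of
the injected effect.

# The synthetic cohort generator

`sim_config()` fixes the study conditions. Per voxel $v$ and volume $t$ a
resting run is

$$y_v(t) = 100 + a_s\, g_v(t)\,\mathbb{1}[\text{effect}]
         + b_s\, h(t)\,\mathbb{1}[\text{effect}]
         + c\, h(t)\,\mathbb{1}[\text{mask}]
         + \delta_v\, t + M(t)\,\gamma_v + \varepsilon_v(t),$$

with the following ingredients and defaults:

* **Noise** $\varepsilon$: white Gaussian noise (SD 1), spatially smoothed to
  6 mm FWHM and AR(1)-filtered over time with $\rho = 0.3$, then rescaled to
  unit temporal SD per voxel. This is the simplest field with the spatial and
  temporal correlation the metrics assume.
* **Global signal** $h$: one band-limited (0.01–0.08 Hz) signal carried by
  every in-mask voxel with amplitude $c = 0.45$. This coupling floor gives
  pairwise correlations of roughly 0.17 — below the DC threshold of 0.25 —
  and is what makes a *hub* effect expressible: a voxel can only have high
  degree if the rest of the brain carries something it can correlate with.
* **DC effect**: effect voxels receive an extra coupling $b_s$ to $h$
  (default mean 1), lifting their correlation with all mask voxels to ~0.34,
  above the threshold.
* **ReHo effect**: a band-limited random field $g$ with a spatial coherence
  scale of 2 voxels (neighbors share ~94% of its variance) is added with
  amplitude $a_s$ (default mean 1) inside the effect region. The coherence
  must exceed the neighborhood correlation of the baseline (smoothed noise
  plus the perfectly-shared global signal), otherwise injecting "local
  synchrony" would *dilute* concordance rather than raise it. The field
  extends one voxel beyond the declared region so that every region voxel
  has a fully synchronized 7-voxel neighborhood; without this completion the
  declared ground truth under-covers the injected effect.
* **Per-subject amplitudes** $a_s, b_s$ are drawn once per subject around the
  configured means with SD = 30% of the mean (truncated at zero), so paired
  tests and the SVM face realistic between-subject heterogeneity. They are
  nonzero only in the configured (condition, phase) cell — by default
  (High, post).
* **Drift and motion**: a small per-voxel linear drift (total drift SD 2 over
  the run) and six motion parameters simulated as random walks, coupled into
  the data with per-voxel Gaussian coefficients — so detrending and the
  Friston-24 regression are genuinely exercised.
* **Gray-matter mask**: a smooth tissue-probability blob thresholded at 0.2,
  largest connected component, covering 30–60% of the grid; the effect region
  must lie (at least 90%) inside it.
* **Task runs**: 120 volumes of alternating 30-s rest/task blocks
  (rest first), a boxcar ⊗ canonical-HRF response on a Gaussian spatial bump
  at the configured target, amplitude 1.5, on the same noise model.

**Grid and run-length choices.** The generator defaults to a 24 × 24 × 18 grid
at 3 mm and 240 volumes at TR = 2 s — a desk-scale stand-in for a whole-brain
64 × 64 × 43 acquisition that keeps the full pipeline in minutes. The analysis
drivers and the acceptance script keep the study's 31 subjects but use an
18 × 18 × 14 grid with 160 raw volumes; calibration suites use 14 × 14 × 10
and 10 × 10 × 8 grids with 6–10 subjects. These sizes are the package's own
validation-study design: large enough for the inferential machinery to behave
asymptotically, small enough to iterate on.

**Effect-region geometry.** The default region is a radius-4-voxel ellipsoid
(~257 voxels) in the right-posterior-inferior octant (the "right cerebellum"
of the phantom). The radius is deliberately large relative to the 6-mm map
smoothing: local-synchrony effects are *genuinely* suppressed in a roughly
one-voxel-deep boundary zone — voxels just outside a synchronized region have
mixed neighborhoods and so lose concordance, and mask-mean normalization plus
smoothing pulls the change map through zero just inside the boundary. A small
region is therefore unrecoverable at its edges at any sample size; with
radius 4 the interior dominates. This is a property real ReHo analyses share:
compact synchronization effects appear eroded and ringed by weak negative
change.

**What the generator does not emulate**: anatomy, physiological (cardiac /
respiratory) noise, scanner drift nonlinearity, susceptibility dropout,
multi-site effects, or imperfect registration — sessions are born aligned on
one grid. Passing tests therefore show the *analysis machinery* is correct
and calibrated for data satisfying its assumptions, not that it is robust to
every artifact of real acquisitions.

# Preprocessing

The per-session cleaning chain is fixed: discard the first 10 volumes;
regress out the Friston-24 motion expansion (six parameters, their one-volume
lag, and both squared) together with an intercept and linear trend; band-pass
0.01–0.08 Hz. Detrending is folded into the nuisance regression as a linear
column — numerically identical to running the two steps separately, since OLS
residuals against a joint design equal sequential residuals for nested
orthogonalized steps, and exactly idempotent.

The band-pass is an ideal frequency-domain boxcar (bins outside the band,
including DC, zeroed). An ideal filter is exactly testable (pass-band
identity to 1e-6, stop-band suppression to 1e-10) and matches the convention
of the standard resting-state toolchains rather than an IIR design.
Spatial smoothing is applied **only to metric maps, never to the series**:
ReHo measures neighborhood synchrony and would be trivially inflated by
pre-smoothing.

# Metrics

**Kendall's W.** For $K$ series of length $n$, each ranked over time
(average ranks on ties), with rank sums $R_t$:
$$W = \frac{\sum_t (R_t - \bar R)^2}{K^2 (n^3 - n) / 12},
\qquad \bar R = K(n+1)/2 .$$
No tie-correction term is applied — ties have measure zero in floating-point
data; constant series are flagged. `reho_map()` computes W over each in-mask
voxel's neighborhood (7 = center + faces, 19 = + edges, 27 = + corners; the
7-voxel cluster is the default, chosen for small subcortical structures).
Edge voxels use their available in-mask members (minimum 2) rather than being
dropped.

**Degree centrality.** `dc_map()` computes the Pearson correlation of every
in-mask voxel pair over time and sums, per voxel, the correlations strictly
above 0.25 ("weighted positive"); negative connections are excluded as
ambiguous; self-correlation is excluded; the computation is confined to the
gray-matter mask. Zero-variance voxels contribute nothing and are flagged.

**Normalization, smoothing, change.** Metric maps are divided by their
gray-matter mean (mask-mean 1 by construction), smoothed at 6 mm FWHM with a
mask-normalized kernel (out-of-mask values excluded, result re-masked), and
differenced post − pre. The order — metrics on unsmoothed filtered series,
then normalization, then smoothing — is fixed.

# Univariate inference

The design is within-subject, so the default voxelwise ANOVA is the
repeated-measures decomposition (two-way subject × condition without
replication): $F = MS_\text{cond} / MS_\text{error}$ with
df = (k−1, (k−1)(n−1)). A between-groups variant is available behind a flag
for sensitivity analysis; with k = 2 the F map equals the squared paired t
map, which the tests verify numerically.

**GRF cluster correction.** Smoothness is estimated from the standardized
repeated-measures residual maps by inverting the Gaussian autocorrelation of
spatial first differences (floored at the voxel size). The voxel threshold
p < 0.001 is converted to a Gaussian-equivalent height $u$; the expected
number of clusters comes from the Euler-characteristic density of a 3D
stationary field in resel units; the extent tail uses the standard
exponential form $P(S \ge s) = \exp(-\beta s^{2/3})$ with
$\beta = (\Gamma(5/2)\,E[m]/E[N])^{2/3}$, and the corrected cluster p is
$1 - \exp(-E[m]\,P(S \ge s))$. The F field is handled through the Gaussian
equivalent of its voxel threshold — a standard simplification; the package
therefore also provides `permutation_max_extents()` (within-subject
condition-label permutation) as an assumption-free cross-check, and the test
suite requires both routes to flag the same clusters on an effect cohort and
a family-wise rate ≤ 0.10 at nominal 0.05 over 200 simulated null fields.
Clusters are formed by face (6) connectivity, configurable to 18/26.

Paired t tests are two-tailed (negative differences are meaningful);
`t_from_summary()` reproduces a printed t from printed mean ± SD summaries.
Bonferroni control across 5 regions × 3 condition pairs gives
0.05 / 15 ≈ 0.0033.

# PAIR SVM

For a condition pair (X, Y), subjects are randomly split into group A
(⌊n/2⌋, labeled +1, samples = X−Y change at the feature voxels) and group B
(⌈n/2⌉, labeled −1, samples = Y−X). This signed-difference construction is
the within-subject ("paired") analogue of a two-group classification: the
classes differ only through the sign convention, so any separating direction
reflects a consistent within-subject condition difference.

Features are the voxels of the uncorrected ANOVA F map at p < 0.05. Note the
deliberate circularity: selection and validation share the cohort, matching
the emulated analysis; selection inside each training fold would be the safer
default for new data and is trivially arranged by calling
`feature_mask_from_f()` per fold. The simulations show this circularity is
not benign: on a *null* cohort, the selected voxels have condition
differences that are consistent across subjects by construction of the F
test, and the PAIR signed-difference geometry then separates the groups
almost perfectly — near-100% apparent accuracy with no effect present
(a property test documents this). Chance-level calibration of the
classifier itself is therefore assessed with selection-independent features
(the whole gray-matter mask), where null accuracy sits at 0.5 as it should.

The classifier is a linear soft-margin SVM (C = 1 by default, exposed),
solved by SMO (libsvm via e1071) behind a surface that returns the primal
weight vector and bias with signs aligned to the +1 class; tests verify the
closed-form max-margin solution on a two-point toy and agreement with an
independent quadratic-program solution of the dual to 1e-4. No feature
standardization is applied by default — change maps are already on a common
normalized scale.

A second calibration subtlety: on null data the *dataset-level* held-out
accuracy (averaged over splits, for one fixed cohort) is extremely variable
at small n — simulations with iid Gaussian features give a spread of roughly
0.28–0.75 at n = 8 and ±0.15 at n = 31 around a chance-centered mean. A
single small null cohort can therefore sit far from 0.5 without anything
being wrong; chance-level statements are meaningful for study-sized cohorts
or averaged over datasets, and the tests are constructed accordingly.

Validation is 100 random stratified split-half repetitions: half of each
group (⌊n_g/2⌋) trains, the rest tests; mean held-out accuracy and the mean
of the signed per-repetition weight vectors are reported (absolute-mean
behind a flag). Weights are back-projected to a brain map for inspection.
`voxel_auc()` computes the single-voxel ROC AUC via the Mann–Whitney
identity (ties count 1/2), quantifying how far any single peak voxel falls
short of the multivariate classifier.

# Numerical and degenerate-input policy

* Identical-series ranks, constant voxels, zero-variance differences and
  empty suprathreshold sets are all defined outcomes (flagged, not errors);
  genuinely contradictory inputs (empty masks, k ≥ t discards, rank-deficient
  GLM designs, single-class training sets) raise errors.
* Rank-deficient nuisance designs drop collinear columns with a warning.
* GLM t maps never produce NaN: zero-residual voxels give ±Inf (0 where the
  estimate is also 0).
* Peak ties break to the lowest linear index, deterministically.
* Every stochastic step takes an explicit seed; identical configuration +
  seed is bit-identical.

# Calibration measurement choices

The null false-positive-rate check aggregates suprathreshold counts over a
coarse voxel lattice (spacing 3 voxels = 9 mm > the 6-mm noise FWHM) so that
a binomial confidence interval is valid; pooling all voxels of a smooth field
would understate the variance of the count. The pooled Kolmogorov–Smirnov
uniformity check on null ANOVA p-values is reported with that caveat: spatial
dependence inflates its statistic, so it is an indicative, not exact, test.

# Dose-response and saturation

Both metrics are bounded (W by 1; DC by the suprathreshold mask sum), so the
measured change is monotone in the injected amplitude only below saturation —
roughly amplitudes up to the noise SD on the desk-scale grids. Above that,
the concordance gain flattens while the boundary-suppression ring deepens,
and the normalized smoothed change inside the region can even decline
slightly with amplitude. The dose-response property tests therefore probe
amplitudes in the responsive regime (0.25–1), and the vignette flags the
saturated regime as a feature of bounded metrics, not a generator defect.

# Known limitations

* GRF correction assumes a stationary smooth Gaussian field; at the coarse
  desk-scale grid the resel counts are small and the correction leans
  conservative. The permutation route is the reference when they disagree.
* The generator's effect amplitudes are calibrated only to reproduce the
  qualitative ordering High > Low > Sham — raw-signal effect sizes for rTMS
  are not established quantities.
* The Low condition carries no injected effect by default, so Low-vs-Sham
  classification sits at chance in the synthetic world; in real data both
  conditions may modulate activity.
* Repeated-measures ANOVA assumes sphericity; no correction is applied, as
  k = 3 with the dominant contrasts checked by paired t tests.
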