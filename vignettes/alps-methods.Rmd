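---
title: "Methods: phantom design, tensor fitting and the ALPS statistics chain"
author: "alpsdti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom design, tensor fitting and the ALPS statistics chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the measurement model,
the phantom that emulates a three-group clinical cohort, the estimator
choices, and the statistical chain — including every place where the design
was genuinely open and what we chose.

## 1. Measurement model

A diffusion-weighted measurement with b-value $b$ (s/mm²) and unit gradient
direction $g$ of a voxel with diffusion tensor $D$ (mm²/s) follows the
monoexponential Stejskal–Tanner model

$$ S(b, g) = S_0 \exp(-b\, g^\top D g). $$

Magnitude MRI data carry Rician noise: the observed value is
$|S + n_1 + i\,n_2|$ with $n_1, n_2 \sim \mathcal N(0, \sigma^2)$. We define
SNR as $S_0/\sigma$; the default of 20 is a typical b0 white-matter SNR for a
3 T protocol of this kind. The acquisition scheme mirrors the emulated
protocol: 12 b-values (0, 300, 350, 650, 950, 1000, 1350, 1650, 1700, 2000,
2700, 3000 s/mm²) with 99 directions per non-zero shell. Directions are a
spherical Fibonacci lattice under a seed-determined random rotation:
quasi-uniform, deterministic, and cheap; electrostatic-repulsion optimisation
would change nothing the tensor fit can see at 99 directions.

## 2. Tensor estimation

* **Shell selection.** The analysis convention for ALPS is to use the DTI
  regime only. The protocol description reads "b-values below 1000", which we
  take literally: the default retains shells `{0, 300, 350, 650, 950}`
  (strict `b < 1000`). Because the convention in the field is often *up to
  and including* 1000, an `inclusive` switch keeps the 1000 shell too; both
  modes are tested.
* **Estimator.** Weighted linear least squares on log-signals: an OLS pass on
  $\log S$ gives predicted signals whose squares become the weights for one
  refinement iteration. This is the standard accuracy/cost compromise between
  plain log-linear fitting (biased at low SNR) and full nonlinear estimation.
  Multiple b0 volumes are averaged before fitting. On noise-free data the fit
  is exact to numerical precision — the basis of the package's exactness
  tests.
* **Degenerate voxels.** Voxels with non-positive signals cannot enter the
  log domain; they are flagged and excluded rather than imputed. Negative
  eigenvalues after fitting are clamped to zero with a per-voxel flag; a full
  SPD projection was rejected as unnecessary at the tested SNR (clamping
  events are essentially absent at SNR 20 with 397 retained measurements).
* **Maps.** FA uses
  $\sqrt{3/2}\,\lVert\lambda-\bar\lambda\rVert/\lVert\lambda\rVert$; MD is the
  eigenvalue mean (identically trace/3); AD is $\lambda_1$; RD is
  $(\lambda_2+\lambda_3)/2$. An all-zero tensor gets FA = 0 and a flag rather
  than NaN.

## 3. ALPS ROIs and index

The four ROIs are 5 mm-diameter spheres at the published template
coordinates — left projection (116, 109, 99), left association (126, 109, 99),
right projection (64, 109, 101), right association (54, 109, 101) —
interpreted as 0-based voxel indices into the 182×218×182 1 mm template grid
in its stored orientation. The indexing
convention is not standardised across tools, and the printed centres are not exactly mirror-symmetric about
either convention (65 vs 64 and 55 vs 54 after reflection), so we implement
the coordinates as printed, provide a `oneBased` switch, and *test* only the
within-one-voxel reflection property. Sphere membership is voxel-centre
distance ≤ radius, which makes the voxel count bit-stable (exactly 81 voxels
on a 1 mm grid). ROI means use all sphere voxels by default; an optional
mask-intersection mode warns when the sphere is not fully inside the mask.
No FA threshold or manual ROI adjustment is applied — the index is computed
from the printed coordinates alone.

Per hemisphere, `Dxproj` and `Dxassoc` are the `dxx` means over the
projection and association ROI, `Dyproj` the `dyy` mean over the projection
ROI, `Dzassoc` the `dzz` mean over the association ROI, and

$$ \mathrm{ALPS} = \frac{\mathrm{mean}(D_{x,proj}, D_{x,assoc})}
                        {\mathrm{mean}(D_{y,proj}, D_{z,assoc})}, $$

with the average index the mean of the two sides. The index is scale-invariant
(any global rescaling of diffusivities cancels) and mirror-covariant
(x-reflecting the maps with re-derived ROIs swaps left and right exactly);
both are tested as exact invariants.

## 4. Phantom design

Phantoms are generated directly in template space (the real-data steps this
replaces — distortion correction, skull stripping, nonlinear normalisation —
are out of scope; interfaces accept pre-corrected, pre-masked, normalised
input).

* **Geometry.** The default analysis grid is the full 182×218×182 1 mm
  template. Cohort-scale simulation and the test suite use a *reduced*
  64×64×32 grid with re-homed, template-proportional ROI centres (preserving
  the one-voxel z-asymmetry between hemispheres), two ellipsoidal hippocampal
  labels under the conventional bilateral-hippocampus IDs 37/38, and a
  brain-ellipsoid support mask of ~12,000 voxels; a 32×32×16 smoke grid
  serves the fastest tests. Structures are required to be pairwise disjoint —
  overlapping paint would silently pollute the ground truth.
* **Tensors.** Each structure carries one tensor: projection fibers have
  their large eigenvalue along z, association fibers along y, with the
  perivascular (x) diffusivity set by the subject's drawn ALPS value times
  the perpendicular diffusivity (0.6e-3 mm²/s; fiber diffusivity
  1.5e-3 mm²/s; isotropic background 0.75e-3 mm²/s). Hippocampal tensors are
  axisymmetric with FA/MD drawn around 0.17 / 0.88e-3 mm²/s — grey-matter
  values; whole-hippocampus
  metrics show no group differences in cohorts of this design, so the
  hippocampal population is shared across groups.
* **Subject variation.** Subject-to-subject variation enters at the
  ROI-diffusivity level as lognormal jitter of the per-side ALPS value (with
  a shared left/right component, correlation 0.5, plus a 5% lognormal jitter
  of the overall diffusivity scale, which the ratio cancels); voxel-level
  variation comes only from the Rician channel. This makes group means and
  SDs directly calibratable.
* **Calibration.** The published group values are *estimates from a
  magnitude-MRI pipeline*, so the presets are calibrated such that the
  *pipeline-recovered* distribution matches them: `scripts/calibrate_presets.R`
  measures, at a fixed calibration seed, the location recovery factor
  (recovered/painted, ≈1.0001 at SNR 20 — the magnitude noise floor is
  negligible here) and the per-subject measurement SD (≈0.005), then solves
  the lognormal jitter by 1-D bisection so biological plus measurement
  variance reproduces the printed SD (mean ± SD groups) or IQR (median (IQR)
  group). Groups printed as mean ± SD are location-matched on the mean,
  the median-printed group on the median. 25 zero-jitter replicates per group
  suffice: the measurement SD is ~2% of the table SDs, so its estimation
  error is far below the reported precision of the frozen constants.
* **Covariates.** The demographic/clinical/cognitive table is emulated
  per group: rows printed as mean ± SD are sampled normally; right-skewed
  laboratory values and timed tests as lognormals matched to median/IQR;
  roughly symmetric scores as normals matched to median/IQR (with a small
  spread floor so a degenerate printed IQR still yields a non-constant
  column); gender as Bernoulli with the group male fraction; disease duration
  is absent for controls. Cognitive scores are rounded and clamped to their
  instrument ranges, and the MoCA respects the groups' screening windows
  (≥26 for cognitively normal groups, 17–25 for the impaired group).
* **What the phantom does not emulate.** Susceptibility/eddy distortion and
  motion; spatially correlated noise; partial-volume gradients at structure
  boundaries (the field is piecewise constant); any coupling between ALPS
  and hippocampal metrics or cognition (covariates and imaging are drawn
  independently). Passing tests therefore certify the *estimation chain* and
  the statistics under known truth — not robustness to real-world artefacts,
  nor any real-data correlational findings.

Ground truth stored with each subject is recomputed from the painted field
itself, so it is exact by construction, and every subject's seed derives
deterministically from (cohort seed, group, index): a single-group cohort is
bit-identical to the matching subset of the full three-group cohort at the
same seed.

## 5. The statistics chain

* **Gating.** Shapiro–Wilk per group and Levene's test (centred on the mean),
  both at α = 0.05 with mean centring — the common defaults, since neither
  choice is standardised. All groups normal *and* variances
  homogeneous routes to ANOVA (then Tukey's HSD), otherwise Kruskal–Wallis
  (then Dunn's z-tests on midranks with tie-corrected variance). Constant or
  too-small groups count as failing normality rather than erroring.
* **FDR.** Benjamini–Hochberg is applied within each family of three pairwise
  comparisons, not across analyses; both raw and adjusted p-values are
  reported, since analysts interpret both.
* **Adjusted two-group comparison.** A linear model of the outcome on the
  group indicator plus duration, fasting glucose and LDL, complete-case with
  dropped-row counts logged; collinear or ill-conditioned designs error with
  the offending columns named.
* **Logistic regression.** The "percentage form" of the ALPS-index is
  implemented as predictor × 100, so the odds ratio is per 0.01 ALPS
  increment — the wording is ambiguous and the scaling is behind a flag.
  Complete separation is an error, never a silently huge OR.
* **Partial correlation.** Residualize both variables on the covariates (with
  intercept) by least squares; Pearson correlation of residuals; p from a t
  distribution on $n - 2 - k$ df; Fisher-z CI. Residuals numerically zero
  relative to the input scale are treated as constant (exact collinearity).
* **Descriptives.** Mean ± SD when the gate passes, median (IQR) otherwise —
  the standard clinical reporting convention.
* **Roster.** `runFullStats()` reproduces the full analysis set (group
  comparisons of every clinical/cognitive column, ALPS omnibus + post hocs,
  the within-group comparison of the three ALPS variants, the adjusted
  DMNC-vs-DMMCI models, MCI logistic models, diabetic-vs-control hippocampal
  comparisons, and the partial-correlation batteries) under fixed,
  documented keys. Two deliberate scope notes: the printed duration statistic
  (H = 161.02 over two non-null groups) is not reproducible from its stated
  family and is reported as a plain two-group Kruskal–Wallis; the cognitive
  covariate list names "LBP", which we read as DBP.

## 6. Numerical and reproducibility choices

Sphere membership, eigenvalue sorting, clamp-and-flag handling and b0
averaging are all deterministic; every random draw flows from an explicit
seed through a hash that keeps derived seeds in 32-bit range, and library
code saves/restores the caller's RNG state. Pipeline outputs (cohort CSV,
JSON/Markdown reports, provenance) are byte-identical across runs of the
same configuration. The run configuration format is YAML (`yaml` is the
established R parser for a human-editable config; TOML has no comparable
standard R reader), overridable by CLI flags.

Problem sizes in the shipped tests: single-voxel and 32×32×16 phantoms for
exactness and property tests; the reduced 64×64×32 grid with the full
12-shell/99-direction protocol for the end-to-end cohort checks (113
subjects at SNR 20); 200–2000 replicates for the simulation-based oracle
suites. These sizes were chosen so the whole suite certifies each claim at
meaningful statistical resolution while remaining routine to run.

## 7. Known limitations

Single-tensor voxels only (no multi-compartment or kurtosis models); no
distortion, motion or free-water modelling; whole-label hippocampal means
(subfield parcellation deliberately deferred — whole-hippocampus averaging
masks subfield heterogeneity); the real JHU/AAL
atlas files are never bundled — the shipped atlas is a synthetic stand-in,
and real-data users supply their own label volumes and pre-normalised input.
With per-subject SDs calibrated to the published tables, cohort-mean
recovery at n≈37 has an SEM of ~0.045, so single-seed cohort means scatter
accordingly — the acceptance machinery reports them as the stochastic
quantities they are.
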