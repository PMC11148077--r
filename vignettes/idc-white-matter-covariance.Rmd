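---
title: "Linking isodendritic-core microstructure to white-matter NODDI metrics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking isodendritic-core microstructure to white-matter NODDI metrics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

The isodendritic core (IdC) is a set of neuromodulatory nuclei — locus
coeruleus (LC), dorsal raphe (DR), ventral tegmental area (VTA) and
nucleus basalis of Meynert (NbM) — whose long, thinly myelinated axons
project throughout the brain's white matter and which are among the
earliest sites of tau pathology in Alzheimer's disease. `idcwm`
implements, at desk scale, an analysis pipeline that asks how the
microstructure of these nuclei covaries with whole-brain white-matter
microstructure, and whether the resulting covariance patterns relate to
CSF biomarkers of Alzheimer pathology.

Two imaging modalities feed the analysis:

* **Multiparametric mapping (MPM)** yields four quantitative maps per
  subject — R1 (longitudinal relaxation rate, 1/s), MTsat
  (magnetization-transfer saturation, percent units), R2\* (effective
  transverse relaxation rate, 1/s) and PD (proton density, percent
  units). ROI means over the four nuclei give 16 "behavior" variables
  per subject.
* **NODDI** (neurite orientation dispersion and density imaging) yields
  three voxelwise white-matter maps — NDI (neurite density index), ODI
  (orientation dispersion index) and FW (free-water fraction), each in
  [0, 1].

The statistical core is a **multi-condition behavioral PLS
correlation**: the Pearson correlation matrix between the 16 IdC metrics
and every white-matter voxel, computed separately for each NODDI
condition and stacked into one 48 x p matrix, is decomposed by SVD into
latent variables (LVs). Each LV has behavior saliences (one per metric
per condition), one shared voxel-salience map, a singular value
(summarized as percent crossblock covariance, $100 s_l^2 / \sum_k
s_k^2$), and per-subject brain scores (projections of the z-scored voxel
data onto the voxel saliences). Inference uses 1000 row permutations
(LV significance, add-one rule) and 1000 subject bootstraps (voxel
bootstrap ratios and behavior-correlation CIs).

Because the cohort that motivated this pipeline is under governed
access, the package ships a **synthetic phantom generator** that
emulates the cohort's structure with planted ground truth, so every
stage has a recovery target and the pipeline is testable end to end.

# Pipeline stages and the models behind them

## Quantitative map estimation (`fit_mpm_maps`)

Each contrast (T1-, PD-, MT-weighted) is a multi-echo FLASH train;
echoes decay as $S(TE) = S_0 e^{-R2^* TE}$. The package fits the
**joint log-linear model** ("ESTATICS"-style): one shared R2\* per voxel
with a TE = 0 intercept per contrast. The first pass is OLS on log
signals; one reweighting pass with weights equal to squared
model-predicted signals ("WLS1") compensates the noise distortion of the
log transform. On noiseless data the fit is exact (tested to 1e-6 1/s).

R1 and the amplitude A come from the dual-flip-angle **rational
approximation** of the spoiled steady state,
$S_c = A\,\alpha_c\,TR_c R1 / (\alpha_c^2/2 + TR_c R1)$, inverted in
closed form from the T1w/PDw intercepts. The closed form is verified in
the test suite against direct root-finding of the same 2 x 2 system, and
against signals generated from the *exact* steady-state equation
$S_0 = A \sin\alpha\,(1-E_1)/(1-\cos\alpha\,E_1)$, where the
approximation error stays below 2% for R1 in [0.5, 1.2] 1/s at the
acquisition's TR/flip settings.

MT saturation is the extra per-TR saturation of the MT-weighted train:
$\delta = (A\,\alpha/S_{MT} - 1)\,R1\,TR - \alpha^2/2$, reported as
percent units ($\times 100$). Transmit-field (B1) inhomogeneity enters
twice: effective flip angles $\alpha_{eff} = f\,\alpha_{nom}$ in all
formulas, and the empirical MTsat correction
$\delta_{corr} = \delta (1 - C)/(1 - C f)$ with $C = 0.4$ (exposed as
`corr_C`). The simulator deposits the inverse-corrected saturation so
that the stored tissue property round-trips; recovery stays within 5%
under the exact-equation simulation.

The B1 map uses the **double-angle method**: $f = \arccos(S_{2\alpha} /
(2 S_\alpha)) / \alpha_{nom}$ voxelwise, then a 3-D polynomial surface
of total degree 6 fitted within the mask (per-axis degree capped at the
number of distinct slice coordinates minus one, which keeps the design
full rank on thin slabs). PD is A rescaled so that mean white-matter
PD equals 69 p.u. (`pd_target`, the conventional calibration; the
phantom's background tissue is constructed consistently with it).

## NODDI forward model and dictionary fit (`predict_noddi_signal`, `fit_noddi_volume`)

The three-compartment Watson model:

$$S/S_0 = (1-f_{iso})\left(f_{ic} A_{ic} + (1-f_{ic}) A_{ec}\right)
          + f_{iso} e^{-b d_{iso}}$$

* $A_{ic}$: sticks with $d_\parallel = 1.7\ \mu m^2/ms$, orientations
  Watson($\mu$, $\kappa$)-distributed; the spherical average is computed
  on a fixed 1000-point Fibonacci lattice with equal weights (the same
  deterministic quadrature everywhere — no runtime randomness in the
  forward model).
* $A_{ec}$: axially symmetric tensor with the tortuosity constraint
  $d_\perp = d_\parallel (1 - f_{ic})$, its axis averaged over the same
  Watson weights (via the quadrature moment $\tau = \langle (\mu \cdot
  n)^2 \rangle$).
* ball: $d_{iso} = 3.0\ \mu m^2/ms$. b-values are converted to
  ms/µm² internally. $ODI = (2/\pi)\arctan(1/\kappa)$.

Fitting is a linearized dictionary approach in the spirit of
convex-optimization microstructure fitters: per voxel, the fiber
direction is estimated by a log-linear tensor fit restricted to b ≤ 1000
s/mm² (principal eigenvector, sign-normalized to positive z; degenerate
tensors fall back to the most-attenuated gradient direction and are
flagged), a dictionary of tissue atoms on a 12 x 12 `f_ic` x ODI grid
plus one ball atom is built with the same quadrature, and nonnegative
least squares with a Tikhonov penalty (`lambda = 1e-3`, Lawson–Hanson
via `pracma::lsqnonneg`) assigns atom weights. NDI and ODI are
tissue-weight-weighted means of the atoms' parameters; FW is the ball's
weight share. On-grid noiseless voxels with known orientation are
recovered exactly; 100 random off-grid truths are recovered well within
one grid spacing (max |error| ≈ 0.02 observed vs the 0.075 spacing
bound); under Rician noise at SNR 30 the median |ΔNDI| stays below 0.1.
The fit is validated by parameter recovery, not bit-compatibility with
any particular external fitter, whose exact regularization defaults are
not public.

## Preparation (`build_voxel_dataset` and friends)

* Probabilistic ROI masks are thresholded inclusively (≥): LC at 10%,
  VTA at 25%, NbM at 60% in the intended application; the DR ROI is a
  3 mm-radius sphere at MNI (0, −30, −13) (123 voxels on a 1 mm grid).
  The inclusive boundary is a deterministic choice where the convention
  was unspecified. An optional exclusion mask can trim the DR sphere
  toward the ~32 mm³ ROI that aqueduct trimming produces; the trim
  shape itself is not published, so the default is the pure sphere.
* The group white-matter mask keeps voxels that are white matter in at
  least 95% of subjects (inclusive).
* Every condition map is residualized voxelwise (OLS, QR-based) on age
  plus the pontine control region's 4 MPM and 3 NODDI means — the
  control region guards against globally shared variance — and then
  smoothed with a 1 mm FWHM masked Gaussian ($\sigma = FWHM /
  \sqrt{8\ln 2}$ per axis, kernel renormalized over in-mask voxels).
  Residuals are returned mean-centered; the PLS z-scores columns anyway.
  Smoothing after residualization mirrors the stated processing order
  of the pipeline this reimplements.

## PLS inference details

* **Stacking**: conditions (and groups, for the APOE4-split analysis)
  are stacked on the behavior side, giving one shared voxel-salience map
  per LV and per-condition behavior saliences. This is the only
  arrangement consistent with per-condition "design score" summaries
  over a common voxel map.
* **Permutation**: subject rows of the behavior block are permuted
  (within group when grouped) against all conditions jointly; only
  singular values are compared (no procrustes inside the permutation
  loop), with the add-one rule $p = (\#\{s^{perm} \ge s^{obs}\} + 1) /
  (n_{perm} + 1)$, so p is never 0.
* **Bootstrap**: subjects are resampled with replacement within group
  (resamples with < 3 distinct subjects per group are redrawn and
  counted); each resample's SVD is aligned to the original by an
  orthogonal procrustes rotation of the behavior saliences, guarding
  against axis reordering and reflection when singular values are
  close — the test suite shows the alignment strictly reduces bootstrap
  SDs on a phantom with a near-degenerate latent pair. Bootstrap ratios
  are $v / SD_{boot}(v)$, reported as ±Inf where the SD is 0. Whether
  the original toolbox also rotates inside the permutation loop is
  unknown; the choice is recorded in the output metadata.
* **Cluster filtering**: voxels with |BSR| > 2, connected components
  labeled at 26-connectivity separately per sign (touching blobs of
  opposite sign are distinct clusters), components smaller than 32
  voxels dropped.
* **Condition contributions** sum *absolute* behavior saliences per
  condition; signed sums could cancel within a condition.

## Downstream models

Brain scores of each LV's driving condition (largest contribution) are
regressed on each CSF biomarker analog (pTau181, Aβ42) with sex and
years of education as covariates; age is never included because the
maps were already age-residualized. Continuous variables are z-scored so
the biomarker coefficient is a standardized β (sex stays 0/1 — the
convention is explicit in the output since the printed cohort value's
scale was not stated). The two tests per score are Bonferroni-corrected
(m = 2). The CSF-to-MRI delay enters only as a screen: a single
product term (z-scored biomarker × z-scored delay) is added and kept
only if it lowers the AIC — one extra parameter, so pure-noise
interactions are dropped with probability $P(\chi^2_1 < 2) \approx
0.84$. Partial correlations (IdC metrics vs demographics/CSF) use
two-stage OLS residualization with $t = r\sqrt{df/(1-r^2)}$,
$df = n - 2 - k$.

# The phantom: what it emulates and what it does not

`phantom_spec()` defaults encode the emulated study conditions: n = 133
subjects; 16 IdC metrics with published cohort means/SDs (e.g. LC R1
0.61 ± 0.03 1/s, pontine PD 68.8 p.u.); age 67.9 ± 5.3 years; 29% male;
15.4 ± 3.5 years of education; CSF-to-MRI delay 768 ± 375 days; an
APOE4+ fraction of 50/132.

Planted structure: latent scores $Z$ (column-centered, mutually
orthogonalized, unit SD) drive both sides. The behavior block is
$B = \mu + (ZW + \epsilon)\,\sigma_{target}/\sigma_{total}$, scaled so
each metric's population SD matches its target. Condition maps are
$X_c = \text{baseline}_c + a\,(g\,Z\,\text{diag}(s_{\cdot c})V^\top +
\sigma_{brain}\epsilon)$, clipped to [0, 1]; $V$ holds smooth
orthonormal voxel patterns (white noise smoothed at 4 mm FWHM, then
QR-orthonormalized, unit Frobenius norm), $a$ = `map_amplitude` = 0.12
converts the standardized covariance scale to NODDI units, and $g$ is a
per-subject group multiplier (neutral by default). Defaults plant two
latents — NDI-dominant (strengths 10/5/1.25 for NDI/ODI/FW) and
ODI-dominant (2.5/7.5/1.25) — with `noise_sd_brain = 0.5` and
`noise_sd_behavior = 0.5`. These strengths were chosen once, at design
time, so that the planted patterns sit clearly above the sampling noise
of a 48 x 6912 correlation matrix at n = 150 (the regime in which the
pipeline is expected to operate: both patterns recovered with |corr| >
0.9 and permutation p < 0.01); weaker plantings degrade gracefully and
the null (all strengths 0) is used to check calibration. The exact
orthogonalization of the latent scores is a deliberate identifiability
choice: with random scores, sample correlation between latents of order
$1/\sqrt{n}$ rotates the recovered axes within the planted subspace,
which would conflate generator variance with estimator error in
recovery tests.

The pTau181 analog is `intercept + slope * latent2 + noise` (defaults
50 + 6 Z₂ + N(0, 19²) pg/ml, a standardized effect of ≈ 0.3); Aβ42 is
independent of the latents (1000 ± 200 pg/ml). The pontine control
region is drawn independently of the latents, so the residualization
stage removes only incidental sample correlation.

Raw-signal ground truth lives on a separate brainstem slab (12 x 12 x 6
voxels): per-subject parameter volumes whose nucleus/pontine ROI voxels
carry the subject's table values (±0.2% within-ROI jitter), a smooth
low-order B1 field (±6%), background tissue with mean PD 69 p.u., and
smooth NODDI parameter fields with a smoothly rotating fiber direction.
MPM fitting runs on all subjects (cheap); raw-DWI refitting runs on a
validation subset (default 2 subjects) because the per-voxel NNLS is
the costly stage — the cohort-level PLS consumes the phantom's condition
maps, which mirrors the real pipeline's split into ROI extraction (MPM)
and voxelwise maps (NODDI).

Not emulated: head motion, susceptibility/eddy distortion, bias fields,
registration error, spatially varying receive fields, within-nucleus
MPM correlation beyond what the shared latents induce (no within-block
covariance was published), non-Gaussian biomarker distributions, and
missingness (every phantom subject has complete CSF data). Passing
recovery tests therefore demonstrates the estimators and inference
machinery are correct, not that the pipeline is robust to acquisition
artifacts — those stages (registration, denoising, distortion
correction) are explicitly outside this package's scope.

# Numerical choices

* Clipping NODDI maps to [0, 1] *after* adding noise keeps maps
  physically interpretable; with the default FW baseline (0.20 ± 0.05)
  about 0.1% of values clip, a negligible attenuation of planted
  effects. (A lower FW baseline measurably attenuates pattern recovery
  — the clipped tail is correlated with the planted effect — which is
  why the baseline sits at 0.20.)
* Rician noise is the magnitude of complex Gaussian noise (standard MR
  convention).
* The SVD sign convention flips each (u, v) pair so the
  largest-magnitude voxel salience is positive.
* Zero-variance columns are an error in the observed crossblock and a
  redraw in bootstrap resamples; brain-score projection treats
  zero-variance columns as contributing 0.
* `fwhm = 0` smoothing is the identity; unmasked smoothing renormalizes
  at the grid edge.
* Residual "dust" (variables fully explained by covariates) is rejected
  in partial correlations rather than correlated.

# Problem sizes in the test suite

The suite exercises the study-scale regime directly: 20 phantoms at
n = 150 with p = 6912 voxels (199 permutations each — the add-one floor
1/200 sits below the 0.01 significance requirement); 200 null phantoms
at n = 60, p = 1000 with 200 permutations each for calibration; 100
biomarker replicates at n = 93; 100 off-grid NODDI voxels plus a
500-voxel Rician Monte Carlo; and one complete pipeline run (133
subjects, 250/250 resamples) that writes every declared output file.
The numbered scripts under `analysis/` run the same pipeline at the full
default 1000/1000 resampling.

# Known limitations

* The dictionary fitter quantizes (f_ic, ODI) to grid resolution; NNLS
  interpolation between atoms recovers off-grid truth to ~0.02, but
  heavy noise can push weight to distant atoms.
* The desk-scale phantom grid (6912 voxels) is ~10⁴ smaller than a real
  1 mm white-matter mask; absolute cluster sizes and BSR maps are not
  comparable to cohort-scale outputs, only their logic is.
* Brain scores are computed on globally z-scored condition matrices
  even in the grouped analysis (one shared scale), a simplification
  recorded here because group-wise standardization is equally
  defensible.
* Cohort-scale printed quantities (LV covariance fractions of 26.9% /
  10.2%, β = 0.295 for pTau181) depend on the governed cohort data and
  are not reproduced by the phantom; the package's claims are the
  property-based ones its tests compute.
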