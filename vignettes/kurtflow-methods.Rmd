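---
title: "Models and methods behind kurtflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kurtflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kurtflow)
```

`kurtflow` couples three quantitative MRI models — diffusion kurtosis
imaging (DKI), parametric DSC perfusion with a gamma transit-time family,
and an extended flow–diffusion model of oxygen transport — with the mask
logic and adjusted statistics needed to compare white-matter lesions and
normal-appearing tissue across a patient cohort. Because the package is
validated entirely by parameter recovery on synthetic data, this vignette
records the modelling assumptions, the conventions we had to fix, and what
the passing tests do and do not establish.

## The diffusion kurtosis model

The signal model is the standard quadratic-in-b expansion of the log
signal,
$$\ln S(b,n) = \ln S_0 - b\,D(n) + \tfrac{b^2}{6}\,\bar{MD}^2\,W(n),$$
valid for b-values up to about 2.5 ms/µm² in brain. Diffusivities are
carried in µm²/ms (numerically equal to the conventional
$\times 10^{-3}$ mm²/s display units) and b-values in s/mm² at the
interface, converted internally.

**Fitting.** The 22 parameters enter the log signal linearly if the
kurtosis block is parameterized as $\bar{MD}^2 W$, so we use two-stage
linear weighted least squares: an ordinary solve, then one reweighting
iteration with weights equal to the squared predicted signal (the
first-order variance correction for log-transformed Rician-dominated
data). The kurtosis tensor is recovered by dividing out the fitted
$\bar{MD}^2$. This estimator is deterministic, needs no starting values,
and recovers noiseless signals to machine precision, which is what the
recovery tests rely on. No regularizer is applied; instead constraints are
enforced by projection after the fit — diffusion eigenvalues are clipped
at $10^{-6}$ µm²/ms and apparent kurtosis is clamped to $[0, 10]$ when
metrics are evaluated, each with a flag in the result. A voxel with any
non-positive signal is marked unfittable and excluded from maps.

**Metric conventions.** Published DKI studies differ silently in how MK
and RK are computed (analytic closed forms vs directional averages). We
fix the convention: MK is the mean of apparent kurtosis over a
1000-point Fibonacci sphere sample, RK the mean over 64 equatorial
directions, AK the value along the principal eigenvector, and AWF uses the
kurtosis-maximum form $K_{max}/(K_{max}+3)$. Crucially the sphere sample
is *anchored to the diffusion eigenframe*: directions are generated in the
eigenvector basis. This makes every scalar metric exactly rotation
equivariant (verified to $10^{-8}$) rather than equivariant only up to
quadrature error, and it lets the phantom define ground-truth MK under the
identical convention, so recovery is self-consistent. Refining the sphere
from 1000 to 10000 points moves MK by less than $10^{-3}$, so the sample
size is not a material tuning knob. Near-degenerate principal eigenvalues
are flagged; eigenvector sign is fixed by making the first non-negligible
component positive.

## The DSC perfusion model

Concentration is the standard gradient-echo relation
$C(t) = -\ln(S/S_0)/TE$ with $S_0$ the pre-bolus baseline mean.
Relaxivity and hematocrit proportionality constants are deliberately
absorbed into CBF's arbitrary units: the analysis only ever consumes
NAWM-relative rCBF/rCBV and the transit-time quantities, which are
invariant to common scaling (tested as a scale-equivariance property).

The capillary transit-time distribution is a gamma family with
$\alpha = MTT^2/CTH^2$, $\beta = CTH^2/MTT$, so MTT and CTH are exactly
its mean and SD. The tissue curve is
$$C_t(t) = CBF\,(AIF \circledast R)(t-\delta) + K_2 \int_0^t AIF(u-\delta)\,du,$$
a parametric (model-based) deconvolution with an additive cumulative-AIF
leakage term of the Boxerman type — our concrete realization of a
leakage-insensitive estimation scheme; $K_2$ can be pinned to zero for
non-enhancing analyses. A Bayesian estimator over the same family would be
a drop-in extension; we chose bounded nonlinear least squares for
determinism.

**Numerics.** Convolution is evaluated trapezoidally on the TR grid
(checked against a 100×-oversampled oracle); the delay is a fractional
frame shift by linear interpolation. The optimizer works in
$(\log MTT, \log CTH, \delta)$ with L-BFGS-B inside the box
MTT ∈ [0.3, 30] s, CTH ∈ [0.02, 30] s, δ ∈ [0, 8] s, from a multistart
grid MTT ∈ {2, 4, 8} s × CTH ∈ {0.5, 1}·MTT; the two linear parameters
(CBF and K₂) are profiled out exactly at each step, which removes the main
source of multistart failures. A Nelder–Mead polish refines the optimum;
the convergence flag combines the optimizer status with a relative
residual threshold. Noiseless recovery is far inside the 1 % acceptance
band, and co-estimating $K_2 \le 0.02$ s⁻¹ perturbs MTT by well under 3 %.

The AIF is an input, never estimated: in synthetic runs it is the
generating gamma-variate bolus itself. Automatic AIF detection is out of
scope.

## The oxygen transport model

Oxygen content $B(x)$ along a normalized capillary obeys
$$\frac{dB}{dx} = -k\,\alpha_{O_2}\,\tau\,(P(B) - P_t)_+, \qquad
P(B) = P_{50}\left(\frac{s}{1-s}\right)^{1/h},\; s = B/C_A,$$
with Hill constants $P_{50} = 26$ mmHg, $h = 2.8$, carrying capacity
$C_A = 0.19$ mL O₂/mL, transfer rate $k = 118$ s⁻¹, and arterial tension
$P_a = 95$ mmHg. We express the transmural driving gradient as a
dissolved-plasma concentration difference via the standard oxygen
solubility $\alpha_{O_2} = 3.1\times10^{-5}$ mL O₂/mL/mmHg; this makes
the units of the rate law coherent and places capillary equilibration on
the 1–2 s timescale, the partial-equilibration regime in which transit
times of 0.2–8 s matter and flow heterogeneity genuinely shunts oxygen
(with instantaneous equilibration OEF would collapse to a function of
$P_t$ alone and the model would have nothing to say about CTH). The
one-sided clamp $(\cdot)_+$ encodes one-way extraction and keeps
$Q \in [0,1]$. All constants are configuration-exposed.

Because the ODE is autonomous once capillary position is rescaled to
physical time, a single dense integration (deSolve/lsoda, rtol $10^{-8}$)
yields the extraction $Q(\tau, P_t)$ for *every* transit time
simultaneously; the gamma-weighted
$OEF = \int h(\tau)\,Q(\tau, P_t)\,d\tau$ then costs one ODE solve per
tension. The integral uses 96 Gauss–Legendre nodes mapped through the
gamma quantile function (so the density integrates exactly to one), with
an optional node-doubling convergence check; agreement with 10⁶-sample
Monte Carlo is within 3 standard errors. With this structure the
interpolation table we had originally planned for map-scale evaluation is
unnecessary — direct evaluation is already O(one solve) per voxel
tension query.

`solve_pto2()` exploits that CMRO2 $= C_A \cdot CBF \cdot OEF(P_t)$ is
strictly decreasing in $P_t$: bisection on $[0, P_a]$ runs until the
forward CMRO2 matches the resting target (2.5 ml/100 ml/min) to $10^{-6}$
relative. If even $P_t = 0$ cannot meet the demand the voxel is flagged
infeasible with $P_t = 0$ and the achievable CMRO2 reported.

DSC yields only relative CBF, and no calibration to absolute units is
universally agreed; the package scales rCBF by a configurable deep-NAWM
reference (default 22 ml/100 ml/min), recorded in the outputs. Both that
calibration and the choice to evaluate PtO2 under each voxel's measured
flow (rather than a fixed flow convention) are declared assumptions,
switchable in the configuration.

## Masks, partial volume, ROI records

Lesion masks live on the 1 mm grid. A connected component (26-connectivity)
is retained only if some slice-contiguous pair of slices each contains a
run of ≥ 3 collinear in-plane voxels (≥ 3 mm); this is the stricter
two-slice reading of the minimum-size rule, and the 3-voxel floor follows
from it. In-plane extent is measured as the longest run along either
in-plane axis — the paper-style pixel-count rule does not specify
connectivity, so this choice is documented and oracle-tested. When masks
move to the 2 mm (DKI) or 3 mm (DSC) grids, a coarse voxel keeps the label
only if its lesion fill fraction is ≥ 50 %, computed by exact sub-voxel
counting for integer-ratio grids and by 5³ supersampling otherwise;
misaligned world transforms are an error, never silently resampled.
Normal-appearing ROIs take the tissue mask as inclusion and every lesion
mask as exclusion; records carry mean, SD and voxel count per
subject × region × metric, and empty effective masks suppress the record
rather than emitting NaNs. Lesion volumes are normalized to whole-brain
volume.

## Statistics

Group contrasts are ordinary least squares of the ROI outcome on group,
age and sex. Percent differences are reported against the
covariate-adjusted reference-group mean (the raw-mean version is emitted
alongside, since published percent contrasts rarely state their
denominator). Logistic biomarker models standardize the predictor and
report odds ratios per SD with Wald intervals; perfect separation returns
an explicit infinite-OR sentinel instead of a silently divergent estimate.
Spearman correlations use average ranks and the conventional strength
bins (none < 0.1 ≤ weak < 0.4 ≤ moderate < 0.7 ≤ strong < 1 = perfect).
Paired regional tests use the paired t-test or the Wilcoxon signed-rank
test (exact for n ≤ 25 without ties); the `"auto"` gate uses Shapiro–Wilk
at 0.05 because visual normality inspection is not reproducible. No
multiple-comparison correction is applied by default, matching
exploratory-analysis practice for panels of interrelated vascular
measures; a Benjamini–Hochberg helper is provided but off by default.
Under 5000 null replicates the adjusted contrast rejects at 5.0 ± 1 %.

## The synthetic cohort: what it does and does not emulate

The phantom is a 64 × 64 × 24 voxel grid at 1 mm with seven box-shaped
compartments: deep NAWM, corpus-callosum NAWM, cortical and thalamic NAGM,
an unspecific T2-FLAIR lesion, an MS T2-FLAIR lesion, and an enhancing T1
lesion (the latter two present only in MS subjects). Normal-appearing
ground truths are set to the reported tissue means (deep NAWM MD
0.96 µm²/ms, MK 1.04, RK 1.31; callosal RK 1.65; NAGM MD 0.99, MK 0.88)
and lesions are defined by exact multiplicative contrasts on them
(unspecific = NAWM × 1.13 in MD, × 0.933 in kurtosis; MS lesion =
unspecific × 1.13 in MD, × 0.84 in kurtosis, × 1.32 in MTT, × 1.31 in
CTH). Absolute hemodynamics are not published for these tissues, so deep
NAWM uses plausible white-matter values (CBF 22 ml/100 ml/min, MTT 3.5 s,
CTH 3.0 s) and only ratios are ever asserted; all of it is
configuration-exposed. Lesion extents are aligned to the coarse-grid
blocks and satisfy the minimum-size rule by construction.

Cohorts default to 54 MS and 26 symptomatic controls with the reported
demographics (age 38 ± 11 vs 36 ± 13, 61 %/69 % female, phenotype mix
CIS/RIS/RRMS/PPMS = 8/7/32/7). MS subjects carry the group effect
(deep-NAWM MD × 1.024, kurtosis × 0.972); between-subject variation is
multiplicative Gaussian with CVs matched to the reported cohort SDs
(MD 5.2 %, MK 3.8 %, CBF 15 %, MTT 10 %, CTH 12 %). With those SDs and
n = 54/26, the adjusted NAWM MD contrast is estimated with a sampling SE
of roughly 1.2 percentage points — the recovery test therefore asserts
agreement within 3 SE, not equality, and individual seeds scatter
accordingly around +2.4 %.

The diffusion acquisition is a three-shell Fibonacci-sphere scheme
(6 × b0, 30 × b1000, 60 × b2500 s/mm²) — a desk-scale stand-in for a
dense 201-direction protocol; DKI noise is Rician with a single
σ = S0/SNR (default SNR 30), and the b0 noise calibration is verified by
moment checks. The DSC series uses TR/TE = 0.8 s/32 ms, 80 frames, a
gamma-variate bolus $A\,(t-t_0)^3 e^{-(t-t_0)/1.5}$ arriving at 8 s with
10 baseline frames, and additive Gaussian signal noise.

Deliberately not emulated: realistic anatomy, partial-volume mixing at
compartment borders beyond the resampling rule itself, susceptibility/EPI
artifacts, motion, AIF measurement error, and spatially varying noise.
Passing recovery tests therefore demonstrate correctness of the estimators
under the stated models, not robustness to the full messiness of clinical
acquisitions — conclusions about real data still require the preprocessing
chain (denoising, Gibbs and eddy-current correction, segmentation,
registration) that is explicitly outside this package.

## Orchestration and problem sizes

`run_pipeline()` validates a single YAML/list configuration (unknown keys
rejected, stage dependencies checked before anything runs), executes
simulate → fit-dki → fit-dsc → oxygen → roi-extract → stats in order, and
writes a manifest with the resolved configuration, the seed and an MD5
checksum per artifact; rerunning with the same configuration and seed
reproduces every artifact bit-identically. In the cohort stage the DSC
model is fitted to the ROI-mean concentration curve per compartment — the
statistics consume ROI means, so voxelwise deconvolution (available as
`perfusion_maps()`) would add nothing at phantom scale. The shipped demo
configuration runs 4 + 4 subjects through every stage in well under a
minute; the cohort recovery experiment uses the full 54 + 26 subjects
with voxelwise DKI fitting of the deep-NAWM ROI (~2000 voxels per
subject), a couple of minutes on one core. These sizes are the package's
validation choices: large enough for the moment checks and contrasts to
converge, small enough to run routinely.

## Known limitations

- The DKI estimator is the uncorrected WLS path: at SNR 30 the residual
  Rician bias on MD is below 2 % (regression-tested) but grows at lower
  SNR; no Rician likelihood or noise-floor correction is implemented.
- The oxygen model treats each voxel independently: no inter-capillary
  diffusion, tissue oxygen gradients, Bohr-shift modulation, or dynamic
  CMRO2.
- The leakage term is the linear Boxerman form; genuinely pharmacokinetic
  (Tofts-type) extravasation is out of scope.
- Absolute CBF calibration (and hence absolute CMRO2/PtO2 levels) rests on
  the declared deep-NAWM reference value; only NAWM-relative statements
  are calibration-free.
- SVD-based nonparametric deconvolution and automatic AIF search are not
  provided.
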