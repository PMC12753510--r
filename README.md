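# kurtflow

Combined microstructure–microvasculature analysis of white-matter disease,
reimplemented end to end on synthetic data.

In multiple sclerosis (MS), loss of tissue integrity and disturbed capillary
flow may both contribute to a cerebral energy deficit. Two MRI arms probe
the two sides: **diffusion kurtosis imaging (DKI)** quantifies non-Gaussian
water diffusion as an indirect index of microstructural integrity, and
**dynamic susceptibility contrast (DSC)** perfusion MRI characterises the
capillary transit-time distribution, whose heterogeneity limits how much
oxygen tissue can extract. `kurtflow` implements the full analysis chain —
tissue model, fitting, masks and statistics — and, because clinical imaging
data of this kind cannot be shared, pairs it with a seeded digital phantom
cohort so that every stage is testable by parameter recovery.

For researchers in quantitative neuroimaging: the package is a working
reference implementation of each model, a simulation lab for protocol and
power questions, and a template for lesion/partial-volume handling.

## The models

**DKI.** The signal along gradient direction $n$ at b-value $b$ follows

$$\ln S(b, n) = \ln S_0 - b\, D(n) + \tfrac{b^2}{6}\, \bar{MD}^2\, W(n),$$

with $D(n) = n^T D n$, $W(n) = \sum_{ijkl} W_{ijkl} n_i n_j n_k n_l$, and
apparent kurtosis $K(n) = \bar{MD}^2 W(n) / D(n)^2$. The 22 unknowns
(log S0, 6 diffusion, 15 kurtosis components) are estimated by two-stage
weighted linear least squares on the log signal; scalar metrics are
MD/AD/RD from the diffusion eigenvalues and MK/AK/RK/AWF from directional
averages of $K(n)$ over an eigenframe-anchored sphere sample
(AWF $= K_{max}/(K_{max}+3)$).

**DSC.** Signal is converted to concentration by
$C(t) = -\ln(S/S_0)/TE$ and fitted with a parametric residue model: the
capillary transit-time distribution is a gamma family
$h(\tau;\alpha,\beta)$ with mean $MTT = \alpha\beta$ and standard deviation
$CTH = \sqrt{\alpha}\beta$, the residue function is
$R(t) = 1 - \int_0^t h$, and the tissue curve is

$$C_t(t) = CBF \cdot (AIF \circledast R)(t-\delta) + K_2 \int_0^t AIF,$$

with the additive cumulative-AIF term absorbing contrast-agent
extravasation (leakage-insensitive fitting). CBV $=$ CBF·MTT by the
central volume theorem; CBF and CBV are reported relative to deep
normal-appearing white matter (rCBF, rCBV).

**Oxygen transport.** Along one capillary with transit time $\tau$, blood
oxygen content $B$ relaxes toward the tissue tension $P_t$ through the
Hill dissociation curve ($P_{50} = 26$ mmHg, $h = 2.8$); extraction is
averaged over the gamma transit-time distribution to give
$OEF(MTT, CTH, P_t)$, and CMRO2 $= C_A \cdot CBF \cdot OEF$. `solve_pto2()`
returns the tension at which extraction exactly meets the resting demand
CMRO2 $= 2.5$ ml/100 ml/min — elevated CTH "shunts" oxygenated blood
through fast capillaries and drives the solved PtO2 down.

**Masks and statistics.** Lesions must span ≥ 3 collinear in-plane voxels
in ≥ 2 contiguous slices; coarse-grid voxels keep a lesion label only when
≥ 50 % filled by the fine-grid mask; normal-appearing ROIs exclude all
lesion masks. Group contrasts are age- and sex-adjusted linear models with
percent differences against the covariate-adjusted reference mean,
logistic biomarker models report ORs per SD, Spearman correlations carry
the conventional strength labels, and paired regional comparisons use
t or signed-rank tests.

## Worked example

One deep-NAWM voxel through all three models:

```r
library(kurtflow)

truth <- build_phantom()$truth
nawm  <- truth[truth$name == "deep_nawm", ]

# DKI: noiseless forward signal, fit, metric set
sig <- predict_dki_signal(1000, nawm$d6[[1]], nawm$w15[[1]], default_scheme())
dki_metrics(fit_dki_wls(sig, default_scheme()))
#>      md    ad    rd    mk    ak    rk   awf degenerate clamped_k
#> 1 0.960  1.40 0.740  1.04  0.75  1.31 0.304 FALSE      FALSE

# DSC: synthetic bolus passage, parametric deconvolution
times <- (0:79) * 0.8
aif   <- gamma_variate_aif(times)
curve <- predict_tissue_curve(aif, times, nawm$cbf / 6000,
                              transit_distribution(nawm$mtt, nawm$cth))
tidy(fit_perfusion_voxel(curve, aif, times))
#>       cbf    cbv   mtt   cth    delay       k2      rss converged
#> 1 0.00367 0.0128  3.50  3.00 1.22e-11 1.47e-16 1.07e-25 TRUE

# oxygenation under the resting-demand constraint
tidy(solve_pto2(nawm$cbf, nawm$mtt, nawm$cth))
#>     oef  pto2 cmro2 feasible
#> 1 0.598  16.6  2.50 TRUE
```

The fitted MD (0.96 × 10⁻³ mm²/s) and MK (1.04) equal the white-matter
ground truth by round trip; MTT (3.5 s) and CTH (3.0 s) are recovered from
the bolus curve to machine precision; and at CBF = 22 ml/100 ml/min the
tissue would need to sit at PtO2 ≈ 16.6 mmHg (OEF ≈ 0.60) to cover the
resting oxygen demand given that flow pattern.

A whole synthetic cohort runs through one call (or the
`inst/cli/kurtflow-pipeline` script):

```r
run_pipeline(default_config(), out_dir = "runs/demo", seed = 1)
```

which writes demographics, ground truth, per-subject DKI/DSC/oxygen ROI
records, adjusted contrasts, correlations and a checksummed manifest.

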