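---
title: "Reference-tissue kinetics and cluster-based discrimination of tauopathy binding profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-tissue kinetics and cluster-based discrimination of tauopathy binding profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taurefkin)
```

## The problem

Second-generation tau-PET tracers such as [18F]PI-2620 bind both the mixed
3-repeat/4-repeat (3/4R) tau aggregates of the Alzheimer continuum and the
4-repeat (4R) aggregates of progressive supranuclear palsy and corticobasal
syndrome — but with different affinity and, consequently, different
kinetics.  In 4R disease the tracer washes out of cortical target tissue
faster: delivery-corrected binding (DVR) is lower, apparent efflux (k2a) is
higher, and the late-phase target-to-cerebellum ratio curve is flat where
the 3/4R curve keeps rising.  This package implements the full
quantification chain that turns a dynamic 0–60 min scan into those
discriminating read-outs, and a synthetic-cohort generator with known
ground truth so every stage is testable without clinical data.

The pipeline operates in a pre-aligned common space on a fixed frame
schedule (six 30 s, four 60 s, four 120 s and nine 300 s frames; 23 frames
covering 0–60 min).  Acquisition, reconstruction, motion correction,
scanner harmonisation and spatial normalisation are out of scope: inputs
are decay-corrected dynamic images (or region time–activity tables) plus an
atlas label image on the same 2 mm grid.

## The kinetic models

All three solvers assume one-tissue kinetics in target and reference
tissue, sharing the plasma input that is never measured:

* reference: $dC_R/dt = K_1' C_p - k_2' C_R$
* target: $dC_T/dt = K_1 C_p - k_{2a} C_T$, with apparent efflux
  $k_{2a} = k_2 / (1 + BP_{ND})$ and $DVR = BP_{ND} + 1$.

**SRTM** eliminates $C_p$ and fits the operational equation

$$C_T(t) = R_1 C_R(t) + (k_2 - R_1 k_{2a})\,(C_R \otimes e^{-k_{2a} t})(t)$$

by a basis-function search: for each candidate $k_{2a}$ on a 100-point
log-spaced grid spanning the admissible range $[0.006, 0.6]$/min, the two
linear coefficients are solved by weighted least squares; the grid optimum
is refined by bounded one-dimensional minimisation.  A grid-edge optimum is
flagged, never silently accepted.

**SRTM2** couples $k_2 = R_1 k_2'$ with the reference efflux $k_2'$ fixed
per subject, leaving $R_1$ (linear) and $k_{2a}$ (1-D search).

**MRTM2** is the two-parameter multilinear form

$$C_T(T) = \gamma_1 \left[\int_0^T C_R + \frac{C_R(T)}{k_2'}\right] +
\gamma_2 \int_0^T C_T, \qquad DVR = -\gamma_1/\gamma_2 .$$

For one-tissue data with the true $k_2'$ this identity is exact at all
times, with $\gamma_1 = DVR \cdot k_{2a}$ and $\gamma_2 = -k_{2a}$; a
non-negative $\gamma_2$ is non-physical and marks the fit invalid.  Only
DVR (and $BP_{ND}$) are treated as contractual MRTM2 outputs; $R_1 =
\gamma_1 / k_2'$ and $k_{2a} = -\gamma_2$ follow the same identity and are
reported for completeness.  The model literature offers more than one
multilinear arrangement of these terms; the form above was selected because
it is the one that is exactly solved by one-tissue curves (verified
analytically and against an independent ODE integration in the test
suite), and because its sign convention matches the validity rule
$\gamma_2 < 0$.

### Fixing $k_2'$ and $t^*$

The reference efflux is fixed per subject as the median of $k_2 / R_1$
over first-pass SRTM fits — of all atlas target regions at the parametric-
map stage (clusters do not exist yet, and control subjects never have
any), optionally re-estimated from the subject's clusters afterwards.  The
equilibration time $t^*$ defaults to 0 min (all frames enter the
multilinear fit) because the simulated data are one-tissue-consistent from
injection; for real data it is configurable, and frames enter by midpoint
($\bar t_k \ge t^*$).

### Numerical choices

* **Weights.** All fits weight frames by duration: under count statistics
  the frame variance scales with activity over duration, and duration is
  the dominant, signal-independent part.
* **Integrals.** A frame average times its duration is the *exact*
  integral of the curve over that frame, so cumulative integrals are
  computed as exact frame sums plus half of the current frame, evaluated
  at frame midpoints.  A trapezoid through midpoint samples was measurably
  worse on the peaked early kinetics and was rejected.
* **Convolution.** $C_R \otimes e^{-k_{2a} t}$ is evaluated on a fine grid
  (0.005 min in the generator, 0.01 min inside the solvers) by an $O(n)$
  recursive trapezoidal update run in C through `stats::filter`.  When a
  curve carries its fine-grid version (everything the generator produces
  does), the solvers use it; otherwise the reference is rebuilt by linear
  interpolation of the frame values at midpoints, anchored at the origin.
  With fine-grid references the noise-free recovery error is below
  $10^{-6}$ relative; with interpolation it stays below about 1% for fast
  efflux ($k_{2a} \approx 0.2$/min) — the bolus peak cannot be fully
  recovered from 30 s frames.
* **Identifiability.** The convolution coefficient is
  $k_{2a}(DVR - R_1)$: when $DVR = R_1$ the target is an exactly scaled
  reference and $k_{2a}$ drops out of the model.  Recovery tests therefore
  keep $DVR$ and $R_1$ apart; real fits near this degeneracy return an
  arbitrary admissible $k_{2a}$ with correct $R_1$ and near-zero residual.
* **Parameter limits.** Fits with $k_{2a} \notin [0.006, 0.6]$/min or
  $DVR \notin (0, 5)$ — or fits that *reach* the search boundary — carry
  `within_limits = FALSE` and are excluded from group statistics; the
  excluded fraction is reported by the pipeline.
* **Missing values.** Invalid voxels in parametric maps carry `NA`
  (written as NaN in NIfTI).

## Cluster definition

Normative maps are the voxelwise mean and SD of the control DVR maps
(sample SD, $n-1$; the population variant is available — the choice is not
dictated by the method and matters little at $n = 11$).  The patient
z-map is $(\text{patient} - \text{mean}) / \text{SD}$, with zero-SD voxels
set missing.  Within each atlas target region *independently*, voxels with
$z \ge 2.5$ are binarised and connected components are labelled with
26-neighbour connectivity (6 and 18 are available; the choice is not
dictated either).  Components are kept when their voxel count strictly
exceeds 20 ("exceeding 20 voxels" read literally; a 20-voxel component is
rejected), i.e. at least 168 mm³ on the 2 mm grid.  Region-scoped
labelling means clusters never merge across a region boundary even when
touching — consistent with per-region, per-side cluster reporting.
Control-group read-outs are computed from whole atlas regions, not
clusters (controls have none).

## Cluster read-outs

Per cluster: $R_1$, $k_2$, $k_{2a}$ from SRTM and SRTM2; DVR from MRTM2;
the duration-weighted late-window ratio SUVR$_{30\text{–}60}$ (frames
fully inside 30–60 min); and the post-perfusion slope family — ordinary
least-squares slopes of the framewise SUVR curve against frame midpoint
over intervals $[i, 60]$ min for $i \in \{9, 11, 13, 15, 20, 25, 30, 35,
40, 45\}$.  The interval list beyond "9–60, 11–60, …" is configurable; the
default enumerates the starts the slope analysis plots label.  Slopes are
unweighted (a simple linear fit is the declared method, imperfect for
inverted-U curves by design); frame membership is by midpoint, and
intervals with fewer than three frames are flagged rather than fitted.

A note on scales: a slowly clearing high-binding target approaches its
late ratio plateau from below, and that plateau exceeds DVR whenever
plasma clearance is slow relative to $k_{2a}$.  Late-window SUVR above DVR
(e.g. $\approx 1.6$ vs $\approx 1.4$ in the 3/4R-like group) is therefore
genuine transient behaviour, not an inconsistency.

## Group discrimination

Cortical clusters are the statistical unit (the subcortical binding
profile does not separate the groups; patient-level averaging is offered
as an option).  Per read-out: group means/SDs, a two-sample t-test
(pooled-variance Student by default, Welch by configuration) and an
empirical ROC AUC by the rank (Mann–Whitney) formulation with ties counted
one half, oriented to be at least 0.5 with the orientation reported.  No
multiple-testing correction is applied across read-outs.

The principal component block follows the SPSS-style recipe on five
variables — the delivery, efflux and slope read-outs with the highest AUC
plus DVR and SUVR$_{30\text{–}60}$: z-standardise; discard variables whose
maximum absolute correlation with the rest falls below 0.3 (the filter
phrase is ambiguous; "no linear relationship with any other item" is the
reading that matches PCA-suitability practice, and with fewer than three
survivors the analysis refuses rather than degrades); compute KMO (from
anti-image partial correlations) and Bartlett's sphericity
($-(n-1-(2p+5)/6)\ln|R|$); retain eigenvalue-above-1 components of the
correlation matrix; varimax-rotate; score by the regression method; report
an oriented AUC per component.

The power utility computes two-sided two-sample t-test power through the
noncentral t distribution with effect size
$d = (\mu_1 - \mu_2)/\sqrt{(\sigma_1^2 + \sigma_2^2)/2}$, noncentrality
$d\sqrt{n/2}$ and $2n-2$ degrees of freedom; at the published design
values (n = 6 per group, $\alpha = 0.05$, 1.17 ± 0.20 vs 0.89 ± 0.07) it
returns 0.83, and a 50 000-experiment Monte-Carlo rejection rate agrees
within 0.01.

## The synthetic cohort

The generator is the package's study design, not a tuning knob.  It
emulates:

* the acquisition: the 23-frame 0–60 min schedule; activity in kBq/ml;
  a Feng-type four-exponential bolus input (amplitudes chosen so the
  reference curve peaks inside 0–10 min) driving one-tissue reference
  kinetics ($K_1' = 0.1$ ml/min/ml, $k_2' = 0.12$/min, jittered mildly per
  subject);
* the cohort: 11 healthy controls, 10 3/4R-like and 29 4R-like subjects;
* the binding contrast: per-lesion $R_1$ and DVR drawn from the published
  cluster read-out distributions per group and region class (cortical
  3/4R 0.83 ± 0.10 / 1.38 ± 0.18; cortical 4R 0.92 ± 0.21 / 1.13 ± 0.10;
  subcortical analogues), healthy tissue with near-zero specific binding;
* the lesion topography: cortical lesions in every region for 3/4R
  subjects vs 72% of regions for 4R; subcortical lesions in 35% vs 77%;
  contiguous blobs grown by random face-connected accretion, sized as
  fractions of their host region (3/4R cortical 40–80%, 4R cortical
  2–20%, subcortical 15–60%) to preserve the roughly tenfold cortical
  volume contrast on a phantom whose lobes are necessarily smaller than
  real ones;
* measurement noise: independent Gaussian per frame and voxel with
  SD $= s\sqrt{\max(C,\varepsilon)/\Delta t}$, the standard frame-count
  heuristic, at scale $s = 0.05$.

Three generator decisions deserve emphasis:

1. **One-tissue consistency.**  Efflux is derived, not drawn:
   $k_2 = R_1 k_2' e^{N(0, 0.1)}$.  All three models assume equal
   nondisplaceable distribution volumes ($k_2 = R_1 k_2'$); drawing $k_2$
   independently of $R_1$ breaks that assumption arbitrarily badly and
   makes MRTM2 DVR unbounded in error for slow-efflux draws.  The mild
   lognormal factor models real violations of volume equality.  The cost
   is that the absolute efflux contrast between groups is compressed
   relative to the published tables (the direction survives, driven by
   delivery and binding); the published $k_2$ spread largely reflects
   estimation noise, which re-emerges here in the fitted read-outs.
2. **Supra-threshold lesions by construction.**  Lesion DVR draws are
   truncated at the healthy mean plus 2.5 healthy SDs plus a 0.06 margin
   (`lesion_dvr_floor()`).  The margin absorbs fit noise inflating the
   *measured* control SD so that cluster recovery exercises the pipeline,
   not threshold-grazing draws.
3. **Healthy DVR ≥ 1.**  A forward one-tissue model with $BP_{ND} \ge 0$
   cannot produce the slightly sub-unity control DVR seen clinically;
   healthy tissue uses $DVR = 1 + |N(0, 0.02)|$ instead.

What the generator does **not** emulate — and what passing tests therefore
do not show about clinical data: the inverted-U (late-declining)
subcortical SUVR curves, which arise from kinetics outside the one-tissue
family (off-target binding, secondary sites); scanner point-spread and
harmonisation filtering, partial-volume effects and registration error;
spatially correlated noise; cross-scanner variance (a single effective
noise level is used).  Late washout itself is within the model family
(any $k_{2a} > k_2'$ clears faster than the reference and shows negative
late slopes) and is covered by explicitly constructed truths in the tests,
but the default cohort's subcortical slopes stay positive.

## Problem sizes

The default phantom grid is 40 × 48 × 40 voxels at 2 mm — large enough for
eight cortical regions of ~4700–5900 voxels, four subcortical nuclei and a
1536-voxel cerebellar reference block, small enough that the full
50-subject pipeline (forward simulation, voxelwise MRTM2 maps, cluster
extraction, all read-outs) completes in a few minutes on one core.
Solver validation uses a 27-point noise-free truth grid and 500 noisy
TACs; the power Monte-Carlo uses 50 000 simulated experiments.

## Known limitations

* MRTM2 R1/k2a (and SRTM2 DVR) inherit bias from a mis-specified $k_2'$;
  the sensitivity is characterised in `analysis/02_kinetics_validation.R`
  (roughly −2% to +6% DVR bias across a ±50% $k_2'$ error at mid-range
  kinetics) and kept small in practice by the median-based subject
  estimate.
* The cluster search is purely voxelwise-threshold based; no spatial
  smoothing, no multiple-comparison control — matching the quantification
  recipe it implements, which relies on the strict 2.5 SD / >20 voxel rule
  instead.
* Whole-region control read-outs and cluster-based patient read-outs are
  not like-for-like volumes; the package mirrors that asymmetry
  deliberately because it is how the normative comparison is defined.
* AUCs treat clusters, not patients, as exchangeable units; clusters from
  one subject are correlated, so cluster-level AUCs are optimistic about
  subject-level discrimination.  Patient-level averaging is available.
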