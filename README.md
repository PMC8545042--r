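# taurefkin

Reference-tissue kinetic modelling and cluster-based group discrimination
for dynamic tau-PET.

## What this is for

Dynamic [¹⁸F]PI-2620 tau-PET separates mixed 3/4-repeat tauopathies (the
Alzheimer continuum) from 4-repeat tauopathies (PSP, CBS) not only by how
much tracer binds but by *how* it binds: 4R cortex shows faster apparent
efflux, lower distribution volume ratio (DVR), lower late-window SUVR and
flatter post-perfusion SUVR slopes.  `taurefkin` implements the complete
non-invasive quantification chain for users working with dynamic PET in a
pre-aligned common space — imaging scientists who need reference-tissue
kinetics without arterial sampling, and methodologists who want every
stage testable against ground truth:

* **Kinetics** — from-scratch solvers for the simplified reference tissue
  model (SRTM, basis-function search over k2a with bounded refinement),
  SRTM2 (reference efflux k2′ fixed per subject) and the multilinear
  reference tissue model 2 (MRTM2), plus voxelwise MRTM2 DVR parametric
  maps.  The shared one-tissue model family:

  C_T(t) = R1·C_R(t) + (k2 − R1·k2a)·(C_R ⊗ e^(−k2a·t))(t),
  k2a = k2/(1 + BPND), DVR = BPND + 1,

  with MRTM2 as C_T(T) = γ1·[∫₀ᵀC_R + C_R(T)/k2′] + γ2·∫₀ᵀC_T and
  DVR = −γ1/γ2.  Fits outside k2a ∈ [0.006, 0.6]/min or DVR ∈ (0, 5) are
  flagged and excluded from statistics.
* **Maps** — normative mean/SD DVR maps from controls, patient z-score
  maps, and extraction of tracer-positive clusters (z ≥ 2.5, strictly
  more than 20 voxels, 26-connectivity, region-scoped) within atlas
  target regions.
* **Read-outs** — per-cluster R1, k2, k2a, DVR, SUVR₃₀₋₆₀ and the
  post-perfusion slope family slope_i–60 for i ∈ {9, 11, …, 45} min.
* **Discrimination** — two-sample t-tests, rank-based ROC/AUC, a
  five-parameter PCA with correlation filtering, KMO and Bartlett gating
  and varimax rotation, and noncentral-t power for the two-sample design.
* **Simulation** — a seedable synthetic-cohort generator (forward
  compartment models on a fine grid, lesion phantoms grown inside a
  synthetic atlas, frame-count noise) parameterised to emulate the
  published group contrasts, so the full pipeline runs end-to-end with
  known truth.

Images travel as NIfTI-1 (via `RNifti`) with TSV sidecars for frame
timing and label tables; all tabular outputs are TSV.

## Worked example

Fit one noisy cortical 3/4R-like curve, then push a small synthetic
cohort through the whole pipeline:

```r
library(taurefkin)

sched <- default_frame_schedule()           # 6x30s, 4x60s, 4x120s, 9x300s
ref <- simulate_reference_tac(sched, K1prime = 0.1, k2prime = 0.12)
truth <- kinetic_truth(R1 = 0.83, k2 = 0.83 * 0.12, BPND = 0.38)
target <- add_tac_noise(simulate_target_tac(ref, truth), scale = 0.05,
                        seed = 7)

fit_srtm(target, ref)
#> <SRTM fit: R1=0.834 k2=0.1036 k2a=0.0748 DVR=1.385>
fit_mrtm2(target, ref, global_kinetic_constants(k2prime = 0.12))
#> <MRTM2 fit: R1=0.841 k2=0.1009 k2a=0.0728 DVR=1.387>
suvr_30_60(target, ref)
#> [1] 1.603
```

The true DVR is 1.38: both models land within 0.5% despite 5% frame
noise.  The late-window SUVR of 1.60 sits well above DVR — the expected
transient overshoot of a slowly clearing, high-binding target.

```r
res <- run_cohort_pipeline(cohort_spec(n_per_group =
         c("HC" = 4, "3/4R" = 3, "4R" = 3)), seed = 7)
cohort_discrimination(res)
#> <discrimination_report: 3/4R vs 4R (24 vs 17 clusters)>
#>       readout   mean_1   mean_2        p   auc
#> 1     R1_srtm 0.852570 8.85e-01 3.70e-01 0.576
#> ...
#> 6   DVR_mrtm2 1.349347 1.16e+00 5.85e-05 0.850
#> 7  SUVR_30_60 1.538278 1.26e+00 7.85e-05 0.841
#> 8  slope_9_60 0.010503 5.33e-03 2.41e-03 0.779
```

Even at this toy size the published ordering appears: binding read-outs
(DVR, SUVR₃₀₋₆₀) discriminate best, the 9–60 min slope follows, delivery
(R1) barely discriminates — and the group means sit where the generator
put them (cortical DVR ≈ 1.35 vs 1.16).

The `analysis/` directory holds the numbered drivers for the full-size
study — `01_simulate_cohort.R` (default 50-subject cohort and its ground
truth), `02_kinetics_validation.R` (solver recovery, cross-model
agreement, k2′ sensitivity), `03_cluster_pipeline.R` (maps → z-scores →
clusters → read-outs) and `04_discrimination.R` (t/ROC/PCA report) — each
writing its tables under `results/`.

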