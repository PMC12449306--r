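# rsdpet

Voxel-level detection and semi-quantification of task-induced striatal
dopamine (DA) release from dynamic [11C]raclopride PET.

In a single-bolus scan, a task started 30–40 minutes in raises synaptic
DA, which competes with the tracer at D2/D3 receptors and transiently
depresses the voxel time-activity curve (TAC). `rsdpet` detects that dip
by predicting each voxel's release-free **baseline TAC** and analyzing
the percent-difference residuals — a workflow for PET methodologists and
neuroimaging researchers studying motor, cognitive or reward tasks in
health and Parkinson's disease.

## What it implements

**Kinetic models** (weighted linear least squares, cerebellar reference
region):

- MRTM: `C_T = R1·C_R + k2·∫C_R − k2a·∫C_T`
- lp-ntPET: MRTM plus a release term `−γ·∫C_T·h`, with `h(t)` a
  unit-peak gamma-variate response from a discretized library
  (tD = 36 min, tP = 37–51 min, α = 1), detected by F-test against the
  nested MRTM fit
- Iterative MRTM (IMRTM): pre-task MRTM extrapolated by self-substitution
  of its own integral term, converging to a release-free baseline

**The RSD-Hybrid-IMRTM pipeline** (`run_rsd_hybrid()`): z-scored
pre-task kinetic coordinates → non-local-means weights
`w_ij = exp(−‖d_j − d_i‖²/h²)`, `h² = 0.5` → lp-ntPET pass replaces
flagged voxels (`p_F < 0.05`) with IMRTM baselines → NLM-weighted
baseline average → nonnegative scale + spill-in fit
`C ≈ θ_NLM·C_NLM + θ_R·C_R` on pre-task frames → percent residuals
`R_pct = 100·(1 − C/Ĉ)` → single-predictor GLM `R_pct = β·P(t) + ε`.
`β` reads as a voxel's maximal percent TAC decrease from baseline.

**Residual lp-ntPET and occupancy** (`run_residual_lpntpet()`):
`R_abs = γ·∫C·h − k2a·∫R_abs`, plus `BPND(t) = k2/(k2a + γh) − 1` and
peak occupancy `pOcc = 100·(BPND0 − BPND(h=1))/BPND0`.

**A digital-phantom simulator** (`simulate_study()`): the
receptor-competition ODE model (free tracer, bound tracer, DA-occupied
receptors) on a 64×64×12 striatal phantom with heterogeneous Bmax,
fixed release clusters (46/85/69 voxels; localized / mid-sized / global
scenarios; release-free right caudate), calibrated frame-scaled noise
and a spatio-temporal smoothing stand-in for scanner-side denoising.

**Evaluation** (`roc_from_maps()`, `tpr_at_fpr()`, `tracking_curve()`,
`sparsity_binarize()`, `dice()`, `one_sample_tmap()`) and a simplified
RSD-k-means comparator reproducing the earlier data-driven pipeline's
failure mode under wide-spread release.

NIfTI images with CSV/JSON frame timing are read and written via
`load_dynamic_image()` / `save_nifti()`. A thin CLI wrapper lives at
`inst/exec/rsdpet` (subcommands `simulate`, `fit`, `rsd`, `occupancy`,
`roc`).

## Worked example

```r
library(rsdpet)

study <- simulate_study(scenario = "localized", DA_peak = 100,
                        n_realizations = 1, seed = 1)
img <- study$studies[[1]]$image
ph  <- study$noise_free$phantom

res <- run_rsd_hybrid(img, ph$striatum, ph$cerebellum)
res$diagnostics
#> $n_voxels        [1] 1264
#> $frac_replaced   [1] 0.483
#> $frac_theta_r_pos [1] 0.512
#> $n_isolated      [1] 0
#> $n_failed        [1] 0

truth <- study$noise_free$release_mask
mean(res$beta$values[truth], na.rm = TRUE)                  # 7.03
mean(res$beta$values[ph$striatum & !truth], na.rm = TRUE)   # 0.95

occ <- run_residual_lpntpet(res, img)
mean(occ$values$pOcc[truth[cbind(res$index)]], na.rm = TRUE) # 22.5
```

Reading: about half the striatal voxels were flagged by the lp-ntPET
pass and contributed model-derived baselines; voxels inside the true
100 nM release clusters show a mean ≈7% peak TAC decrease versus ≈1%
elsewhere, and a cluster-mean peak D2 occupancy change of ≈22%.

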