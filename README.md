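# probereg

Spatial coregistration and error metrics for neuroimaging probes
(fNIRS optodes, EEG electrodes) localized on infrared 3D head scans.

When a measurement cap is placed "by eye" according to the 10-20/10-10
proportional systems, the fixed 30 mm inter-optode spacing of fNIRS caps
means probe positions can differ by tens of millimeters between heads.
Labeling the probes on a quick infrared 3D scan and rigidly registering
them to each participant's anatomy (or to a template montage) removes most
of that error. `probereg` implements the full validation pipeline around
that idea, for researchers who digitize probe positions with depth
cameras, photogrammetry or MRI:

- **IO** — MeshLab PickPoints (`.pp`) XML, `label,x,y,z` marker CSV,
  positions TSV, and a bundled idealized spherical 10-05 template montage
  (all coordinates in millimeters).
- **Registration** — anatomical head frames from the nasion/LPA/RPA
  fiducials, and closed-form rigid control-point registration
  (orthogonal Procrustes / Kabsch): for corresponded point sets
  $X, Y$ the rotation is $R = V\,\mathrm{diag}(1,1,d)\,U^\top$ with
  $U\Sigma V^\top = \mathrm{svd}(X_c^\top Y_c)$ and
  $d = \mathrm{sign}\,\det(VU^\top)$ (reflections corrected to proper
  rotations), translation $t = \bar y - sR\bar x$, and an optional
  least-squares uniform scale $s$ (Umeyama). Correspondences are always
  known by label — no iterative closest point.
  Two alignment strategies: *landmark-based* (fit on the three fiducials)
  and *landmark-free* (fiducials excluded, fit on all shared probe
  labels).
- **Metrics** — the four validation analyses, each summarized per optode
  and pooled: between-subject **cap-fixation variability**, scan-vs-MRI
  **accuracy**, scan-rescan **reproducibility**, and **inter-optode
  channel distances**, plus a Welch t comparison between analyses.
- **Synthetic cohorts** — ellipsoidal scalps over a realistic head
  circumference range, a 25-optode / 24-channel layout at exactly 30 mm
  chord spacing, cap-placement jitter between subjects and digitization
  noise within subjects, so the whole pipeline is testable without any
  data download.
- **Defacing** — OBJ head-mesh anonymization (reorient, plane cut,
  face-region removal) that provably preserves the three landmark
  regions, archiving the applied transform.
- **CLI** — `inst/cli/probereg.R` with `simulate`, `align`, `metrics`,
  `anonymize` and `benchmark` subcommands.

## Worked example

```r
library(probereg)

cohort  <- simulate_cohort(cohort_config(seed = 2026))
battery <- metric_battery(cohort)
for (nm in setdiff(names(battery), "welch_cap_vs_accuracy")) {
  r <- battery[[nm]]
  cat(sprintf("%-31s %6.2f (%.2f) mm over %d distances\n",
              nm, r$pooled_mean, r$pooled_sd, r$n_distances))
}
w <- battery$welch_cap_vs_accuracy
cat(sprintf("Welch t = %.2f, p = %.3g\n", w$statistic, w$p_value))
```

```
cap_fixation                     20.20 (14.42) mm over 250 distances
accuracy_landmark_based           3.80 (1.72) mm over 375 distances
accuracy_landmark_free            1.89 (0.81) mm over 375 distances
reproducibility_landmark_based    3.73 (1.56) mm over 375 distances
reproducibility_landmark_free     2.77 (1.13) mm over 375 distances
inter_optode_mri                 30.09 (1.04) mm over 120 distances
inter_optode_scan                30.19 (2.01) mm over 360 distances
Welch t = 17.91, p = 6.37e-47
```

Reading the output: with no registration, the same optode sits ~20 mm
apart on different heads (worst single pairs reach 40+ mm); registering
each scan to the subject's MRI reference shrinks the error to ~3.8 mm
anchored to anatomy (landmark-based) and ~1.9 mm of pure device/labeling
error (landmark-free); repeat scans agree to a few millimeters; and the
measured channel separations recover the cap's 30 mm construction value.
The Welch test confirms the registration improvement over standard cap
fixation is highly significant. Per-optode breakdowns are in each
report's `per_label` table; `battery_to_tsv()` writes the combined
summary table.

Command-line equivalent:

```sh
Rscript inst/cli/probereg.R simulate --seed 2026 --out cohort/
Rscript inst/cli/probereg.R metrics --cohort cohort/ --out reports/
```

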