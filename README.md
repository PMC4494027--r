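# blockmvpa

Simulation and multivoxel pattern analysis (MVPA) of block-design fMRI
experiments with per-block awareness reports, in R.

## What this is for

A recurring design in the cognitive neuroscience of unconscious processing:
stimuli (here, meaningful sentences vs. unpronounceable nonwords) are shown
in 10 s blocks under continuous flash suppression, and after every block the
participant gives an objective forced choice and a subjective
"knew"/"guessed" confidence report. The analysis asks whether, restricted to
subjectively invisible ("guessed") blocks whose objective accuracy sits at
chance, the *spatial pattern* of BOLD responses in language-selective cortex
still discriminates the two conditions — and whether the information is
multivoxel rather than a regional mean-signal difference.

Because such datasets are rarely shared, `blockmvpa` pairs the full analysis
chain with a forward generator that produces synthetic 4D BOLD runs, block
timelines, and awareness reports with the statistical structure the analysis
assumes. Everything is testable end to end without any download.

## The method in brief

For each simulated (or loaded) subject:

1. **Design / generator** — sessions of 12 blocks (6 per condition, 10 s
   each, 7.5 s fixation, 10 s lead-in; 220 s = 88 volumes at TR 2.5 s);
   voxelwise timecourses `baseline + Σ_c (pattern_c + offset_c) ·
   (boxcar_c ∗ HRF) + drift + AR(1) noise` with the canonical double-gamma
   HRF; per-block awareness reports (~80% "guessed", objective accuracy
   51.7% on those).
2. **Localizer GLM** — concatenated visible-localizer sessions, OLS with
   boxcar∗HRF regressors, per-session intercept/drift; per-voxel
   `sentences > nonwords` contrast mapped to z through the exact t CDF.
3. **ROI** — within a named parcel, the contiguous cluster of highest-z
   voxels at exactly N voxels (greedy growth, 26-connectivity,
   deterministic tie-breaks); N = 100 by default (1200 mm³ at 2×2×3 mm),
   with a 50/100/150 sweep.
4. **Pattern preparation** — per session: linear detrend + z-score each
   voxel, 3-TR hemodynamic lag shift, average each block's 4 volumes to one
   row, keep "guessed" blocks, balance classes, then subtract the
   per-session per-condition scalar grand mean ("cocktail" subtraction) so
   global activation level cannot drive classification.
5. **Decoding** — leave-one-session-out cross-validation with a linear
   soft-margin classifier (C = 1); a univariate control repeats the chain
   with the single ROI-mean feature and no subtraction.
6. **Group inference** — one-tailed one-sample t vs. 50% per ROI with
   Bonferroni families (7 temporal → threshold 0.0071, 4 frontal → 0.0125),
   paired t between regions, and a 2×2 within-subject ANOVA
   (region × hemisphere).

See `vignettes/decoding-methods.Rmd` for the model, parameter meanings,
calibration, and limitations.

## Worked example

Eight simulated subjects, two signal-carrying regions, 6 main + 3 localizer
sessions each (a few minutes on one CPU):

```r
library(blockmvpa)
cfg <- default_config(seed = 42, n_subjects = 8,
                      regions = c("L_post_STS", "L_mid_frontal_gyrus"),
                      grid_dim = c(21, 14, 12))
cfg$sessions <- list(main = 6L, localizer = 3L)
cfg$roi$sizes <- 100L
out <- run_pipeline(cfg)
out$group$multivariate_100
out$group$univariate_100
```

prints (columns abbreviated):

```
== multivariate, 100-voxel ROIs ==
                  roi n mean_accuracy  sem    t df      p significant
1          L_post_STS 8          57.4 3.00 2.45  7 0.0219        TRUE
2 L_mid_frontal_gyrus 8          56.3 4.99 1.27  7 0.1220       FALSE
== univariate control ==
                  roi n mean_accuracy  sem     t df     p significant
1          L_post_STS 8          42.0 4.49 -1.77  7 0.940       FALSE
2 L_mid_frontal_gyrus 8          45.1 4.04 -1.22  7 0.869       FALSE
```

Reading it: both regions carry a calibrated multivoxel pattern difference
(true subject-mean accuracy ≈ 56%), and the leave-one-session-out decoder
recovers it, while the univariate control — which can only use the regional
mean signal — stays at chance, because the generator's invisible-experiment
world contains no condition-wise global-level difference. With only 8
subjects the per-region t tests are noisy; at n = 15 the group test at the
family threshold rejects in well over half of simulated experiments.

`significant` compares each one-tailed p to its Bonferroni family threshold
(here each family has one member, so the threshold is 0.05).

## Command line

```sh
Rscript inst/cli/blockmvpa.R simulate --config cfg.yaml --out out/ --subject 1
Rscript inst/cli/blockmvpa.R localize --config cfg.yaml --out out/ --subject 1
Rscript inst/cli/blockmvpa.R roi --zmap out/sub01_zmap.nii --mask mask.nii --size 100
Rscript inst/cli/blockmvpa.R decode --config cfg.yaml --out out/ --subject 1
Rscript inst/cli/blockmvpa.R all --config cfg.yaml --out out/
```

Volumes are single-file NIfTI-1, events are BIDS-style TSV, configs are
YAML (seed mandatory), results are TSV plus a JSON manifest of seeds and
config hash.

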