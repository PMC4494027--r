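---
title: "Simulating and decoding subliminal block-design fMRI experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding subliminal block-design fMRI experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockmvpa)
```

## The problem

In continuous-flash-suppression (CFS) experiments, written stimuli —
meaningful sentences versus unpronounceable nonwords — are presented in 10 s
blocks while rendered subjectively invisible, and after every block the
participant reports an objective forced choice (sentences/nonwords) and a
subjective confidence judgment ("knew"/"guessed"). The scientific question
is whether the *spatial pattern* of BOLD responses in language-selective
cortex still discriminates the two conditions on blocks the participant
reports as guessed — i.e., whether linguistic information is processed
without awareness — and whether that information is carried by multivoxel
patterns rather than by the regional mean signal.

`blockmvpa` implements the complete analysis chain for this question, and —
because such datasets are rarely shared — a forward generator that produces
synthetic 4D BOLD runs, block timelines, and awareness reports with the
statistical structure the analysis assumes. Every stage is exercisable and
testable without any data download.

## The experimental world the generator emulates

One session is: 10 s fixation, then 12 experimental blocks (6 per
condition, order a seeded uniform permutation) of 10 s each, separated by
7.5 s fixation — 220 s total, exactly 88 volumes at TR = 2.5 s. A block
contains 4 sentences of 6 words at 0.4 s per word; this micro-structure is
carried as timeline metadata only, because the analysis operates at block
resolution and the neural regressor is the block boxcar. Subjects complete
7–11 invisible-experiment sessions and 3–5 visible localizer sessions.

Behavior is modelled per block: `P(guessed)` is 0.803 for sentences and
0.826 for nonwords; objective accuracy is 0.517 given "guessed" (chance-level
invisibility) and 0.624/0.865 given "knew". These are the marginal rates the
analysis conditions on when it restricts itself to guessed blocks.

The BOLD forward model per voxel is

```
y(t) = baseline
     + sum_c (pattern_c + offset_c) * (boxcar_c * HRF)(t)
     + drift(t) + AR(1) noise
```

with the canonical double-gamma HRF (gamma(6,1) response minus gamma(16,1)/6
undershoot, peak ~5 s, 32 s support, sampled at the TR, unit peak). The two
signal components are deliberately separable because the analyses dissociate
them:

* **pattern component** — a per-voxel, per-condition amplitude map, drawn
  once per subject as `pattern_sd` times a standard normal field inside the
  signal regions and held fixed across sessions. This is what multivoxel
  decoding can use after global-level information is removed.
* **global component** — a per-condition scalar applied to every voxel
  (`global_offset`, plus the region-level mean amplitudes). This is what the
  univariate control can use.

In the default world the visible localizer has a strong region-level mean
contrast (1.5 vs 0.6 signal units) in all language regions except the
superior frontal parcel (kept non-selective, as functional localizers find),
while the invisible main experiment has *equal* mean amplitudes across
conditions — the univariate control is null by construction, matching the
phenomenon the package models — and carries only the pattern component.

Noise defaults: white innovation SD 1, AR(1) coefficient 0.3, sinusoidal
scanner drift of amplitude 0.5 and period 128 s shared by all voxels. These
are not reported quantities; they were chosen to give realistic temporal
autocorrelation at controllable effect size, and every effect-size statement
below is relative to them.

### Calibration of the pattern amplitude

`pattern_sd = 0.035` (signal units per unit HRF response) was fixed by a
one-time pilot: across 40 simulated subjects it yields subject-mean
leave-one-session-out accuracy of ~56.4% with between-subject SD ~7.8
(SEM ~2 at n = 15), the regime the analysis is designed to detect. The
between-subject spread is dominated by binomial counting noise over ~77
analysed blocks, exactly as in real data of this size. The calibration was
not revisited after acceptance outcomes were observed.

### Synthetic parcels and volume margins

`language_mask_set()` ships eleven disjoint rectangular parcels (~240 voxels
each) named after the language-network regions; they are a synthetic naming
convention, not real published parcels. Parcels keep a 5-voxel in-plane
background margin from the volume edge. This matters: spatial smoothing with
edge renormalization leaves inflated noise variance within one kernel radius
of the volume boundary, and parcels placed there get measurably worse
z-based voxel selection. A normalized brain never abuts the volume edge, so
the margin is the realistic geometry.

## The analysis chain

1. **Discard** the first 4 volumes (10 s) of every session; onsets shift
   accordingly, so the first block starts at 0 s.
2. **Smooth** (6 mm FWHM separable Gaussian, edge-renormalized) — applied to
   the localizer by default; for the main experiment smoothing is a config
   switch defaulting to off, keeping pattern information crisp.
3. **Localizer GLM** — sessions concatenated with shared condition
   regressors (boxcar convolved with the HRF) and per-session intercept and
   linear drift columns; OLS per voxel; the contrast t statistic is mapped
   to z through the exact t CDF (small localizer df make the normal
   approximation noticeably wrong in the tails). Voxels whose residual
   variance is at numerical-noise level get z = 0 (constant voxels) or a
   signed capped z (noiseless pure-signal voxels) so ROI growth never feeds
   on degenerate values.
4. **ROI growth** — within each parcel, seed at the maximum-z voxel and
   greedily add the highest-z frontier voxel under 26-connectivity until
   exactly the requested size (100 by default; 50/100/150 in the sweep).
   Ties break on the lowest linear index, so the result is deterministic,
   and the greedy trace makes the size-k ROI a prefix of the size-(k+1) ROI.
   Greedy growth is a documented heuristic, not a maximum-sum-subgraph
   solver (that problem is NP-hard); on tiny masks it is tested to reach at
   least 90% of the exhaustively enumerated optimum.
5. **Pattern preparation** — per session: linear detrend then z-score each
   voxel's full timecourse (linear, matching the generator's slow drift at
   220 s sessions; zero-variance voxels map to zeros); shift every block's
   analysis window forward by 3 TRs (label-window shift, not a data roll, so
   there are no wraparound artifacts; order is detrend → shift, which
   differs from the alternative only at session edges); average the 4
   volumes of each shifted window into one row per block; keep only
   "guessed" blocks; balance classes by seeded uniform down-sampling of the
   larger condition (once per subject, before cross-validation); finally
   subtract, per session and condition, the scalar grand mean over that
   condition's blocks and voxels ("cocktail" subtraction). The scalar
   reading follows from the subtraction's purpose — removing arousal-like
   global-level differences; a per-voxel mean-pattern variant is available
   via `per_voxel = TRUE` for sensitivity analysis. Computing the
   subtraction within session only means no statistic ever crosses the
   train/test boundary; this is verified by perturbing a held-out session
   and observing bit-identical patterns elsewhere.
6. **Decoding** — leave-one-session-out cross-validation with a linear
   soft-margin classifier, C = 1 (the classical default of linear SVM
   implementations; nothing in the modelled analysis pins it down, so it is
   declared, exposed in config, and not tuned). Because no pre-installed R
   package provides an SVM, the package implements the L2-regularized
   squared-hinge primal minimized by BFGS with the analytic gradient —
   convex and deterministic; it differs from the hinge-loss SVM only in the
   squaring, which does not change the separable solution and behaves
   equivalently at this data scale. Decision-boundary ties resolve to the
   first condition label. Fold accuracy is percent correct; the subject
   statistic is the unweighted fold mean.
7. **Univariate control** — identical chain except no cocktail subtraction
   and the single feature is the ROI-mean timecourse value per block. On
   pattern-only data it stays at chance while the multivariate route
   succeeds; on global-offset data the roles reverse (until subtraction
   removes the offset). Both directions are asserted against a
   within-session label-permutation null band.
8. **Group inference** — per ROI, a one-tailed one-sample t versus 50%
   (chance for balanced two-class decoding); Bonferroni families of 7
   temporal and 4 frontal regions give thresholds 0.0071 and 0.0125.
   Between-region comparisons use a two-tailed paired t, and the
   region-by-hemisphere question a 2x2 within-subject ANOVA where each
   effect is tested against its own subject-by-effect error term on
   (1, n-1) df — with two-level factors sphericity is not at issue. The
   one-tailed choice applies only to the versus-chance test, where the
   direction is prespecified. Zero-error degenerate ANOVA cells report
   F = Inf with p = 0 and a warning rather than an error.

## What a green test does and does not establish

The generator produces stationary Gaussian AR(1) noise on a rectangular
grid with box-shaped parcels and no head motion, physiological noise,
susceptibility dropout, or spatial noise correlation beyond smoothing.
Passing tests therefore establish that the *pipeline machinery* is correct
(arithmetic, ordering, leakage-freedom, calibration of its statistics under
its stated null) and that the dissociation logic behaves as designed — not
that real cortex behaves this way, and not that the effect sizes reported
from real data are reproduced, which would require the original scans.

Statistical power at the stated world deserves a note: with true accuracy
~56% and SEM ~2 at n = 15, the one-tailed test at the 0.0071 family
threshold has true power around 0.6. The acceptance suite asserts the
rejection rate exceeds 0.5 over replicate simulated experiments; that is a
property of this marginal regime, faithfully reproduced rather than
inflated.

## Numerical choices

* Time is continuous seconds internally; a block occupies the volumes whose
  acquisition time falls in `[onset, onset + duration)`; volume index =
  `floor(onset / TR)` (0-based).
* Boxcar-HRF convolution is direct (not FFT) so regressors are exactly zero
  before stimulus onset.
* Degenerate-voxel thresholds are relative: a voxel is degenerate when its
  residual (or detrended) variation is below 1e-8–1e-10 of its signal
  scale, covering constants and pure ramps without misclassifying real data.
* The t-to-z map works on the log scale in the tails, so |t| up to ~1e15
  converts without overflow; |z| is capped at 38 for exactly-zero residuals.
* Seeds: every stochastic stage derives its seed from the master seed by
  stable integer arithmetic modulo 2^31 - 1; the full pipeline is
  byte-reproducible from the config alone.

## Known limitations

* Rectangular parcels make ROI contiguity easy; irregular real parcels
  would stress the greedy growth differently (the enumeration bound is only
  tested on small fixtures).
* The localizer GLM does no prewhitening; with AR(1) noise its z values are
  mildly miscalibrated (conservative ROI ranking is unaffected, and the
  null-calibration test uses white noise where the z null is exact).
  Whether the modelled analysis included drift regressors is unknowable
  from its description; drift inclusion is a config flag defaulting to on.
* No inter-block randomization constraints (e.g., maximum consecutive
  same-condition blocks) are imposed, as none are specified.
* The NIfTI-1 reader/writer is deliberately minimal (single-file, axis-
  aligned sform, datatypes uint8/int16/int32/float32/float64); it is not a
  general neuroimaging I/O library.
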