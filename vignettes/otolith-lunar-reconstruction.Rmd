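---
title: "Reconstructing lunar birth timing from otolith growth histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing lunar birth timing from otolith growth histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otolunar)
```

## The inference chain

Otoliths accrete one increment per day, so a radius-at-age series
$R_1, R_2, \dots$ is a daily diary of larval growth. Moonlight
modulates the food and predation environment of pelagic larvae on the
synodic cycle, leaving a periodic signature in growth whose *phase*
is set by the day of birth. `otolunar` turns that signature into a
classifier of lunar quarter of birth, then uses birth-quarter
distributions per life stage to measure selection on birth timing.
The chain is:

1. **Lunar clock.** An idealized linear clock: phase angle
   $\phi(t) = 360 \cdot ((t - t_0) \bmod s)/s$ with synodic length
   $s = 29.53$ d (configurable; the astronomical synodic month,
   rather than the rounded 29.5 sometimes quoted, so the clock stays
   phase-true over a year of simulated spawning). Quarters are
   $\pm 45^\circ$ windows around the four principal phases, boundary
   values assigned to the higher window. Ephemeris accuracy is not
   needed at quarter (7.4 d) resolution — linear-clock error is below
   a day — but `lunar_calendar(new_moons = ...)` accepts an observed
   new-moon table for real collections.

2. **Detrending.** Radius is regressed on age *as a factor* over the
   pooled cohort, which reduces to age-specific mean radii; residuals
   are de-trended size-at-age, and their first differences are
   *residual growth*. The pool is all stages together, matching how a
   mixed sample of settlers, juveniles and adults would be processed.

3. **Traits.** Twelve per-fish features: trend strength, linearity
   and curvature of the normalized + smoothed residual-growth series;
   OLS slope and intercept over ages 28–34, 35–41 and 42–48 days
   post-hatch; amplitude $a$ and offset $d$ of
   $a\sin(\theta \pi/180 + c) + d$ fitted to the *raw* residual
   growth over ages 25–47 ($\theta$ = lunar phase angle at that age);
   and pelagic larval duration (PLD), the increment count between the
   hatch and settlement marks.

4. **Classification.** Linear discriminant analysis over the 12
   traits, leave-one-out cross-validated, with an equal
   ("uninformative") prior when assigning stages whose composition
   differs from the training pool.

5. **Selection.** For stages $j \to j+1$ and quarter $i$, the index
   $\log_{10}(P_{j+1,i}/P_{j,i})$ of birth-quarter proportions;
   positive values mean that quarter's cohort survived the transition
   relatively well. The stage graph is egg → settler → juvenile →
   {female, primary male} → terminal-phase male, 14 ordered pairs in
   total including skip-level composites (which equal path sums
   exactly, by log additivity).

## Design decisions in the open points

**What is $\theta$?** The periodic growth model's phase argument is
not fully pinned down by its usual presentation. We define it as the
fish's lunar phase angle at age $x$:
$\theta(x) = (\beta + 360x/s) \bmod 360$, with $\beta$ the phase at
birth. For fish of unknown birthdate the fit uses $\beta = 0$; this
changes nothing that matters, because
$a\sin(\theta\pi/180 + c) + d$ with $\theta$ shifted by $\beta$ is
the same curve with $c$ shifted by $\beta\pi/180$ — $a$ and $d$, the
two traits actually used, are invariant. $c$ is excluded as a trait
precisely because under a known-$\beta$ parameterization it is nearly
constant across fish (it estimates the environmental phase offset of
the moonlight effect), and under the blind parameterization it would
leak the label through a quantity unavailable for adults.

**Processing order.** "Normalize and smooth the residuals" is
ambiguous about whether sizes or growth rates are normalized. We
difference first, then z-score (sample sd) per fish, then apply the
3-day centred rolling mean, because all downstream traits consume
growth; `process_residuals(order = "smooth-normalize")` is the
sensitivity switch. Rolling-mean edges use shrunken windows rather
than trimming so the 42–48 d window keeps support for typical PLDs.

**Sinusoid solver.** $a\sin(x + c) + d = A\sin x + B\cos x + d$ is
linear in $(A, B, d)$, so the least-squares problem is solved exactly
by linear algebra and converted back ($a = \sqrt{A^2+B^2} \ge 0$,
$c = \mathrm{atan2}(B, A) \bmod 2\pi$). No starting values, no
convergence failures. A multi-start `nls` path is retained only for
use with settlement-correction hooks that break linearity.

**Settlement-effect growth correction.** Some workflows adjust
increments spanning the settlement check for a settlement-related
growth disruption. That adjustment is *not* reproduced here: the
exact form belongs to a different analysis and guessing it would be
worse than omitting it. `to_growth(correction = )` is a documented
hook with identity default.

**Short records.** A fish with PLD 40 has no growth observations at
ages 42–48. Window traits with fewer than 3 supporting points are
`NA` with a missingness flag, and the classifier imputes them as the
column mean (exactly 0 in its standardized trait space). This keeps
every fish classifiable — adults must never be dropped for a short
larval record — at the cost of shrinking their discriminant
information toward the pooled centroid.

**Numerics in the classifier.** Traits are standardized inside every
LOOCV fold (no leakage); population (maximum-likelihood) denominators
are used for the standardization and the pooled covariance so the
fitted model is an exact function of sufficient statistics
(duplicating every observation leaves it unchanged); a ridge of
$10^{-8}\,\mathrm{tr}(S)/p$ rescues singular covariances; prediction
ties break deterministically in the fixed quarter order NEW, WAXING,
FULL, WANING.

**Zeros in selection.** $\log_{10}$ of a zero proportion is reported
as a non-finite value with `finite = FALSE` — faithful to the formula
— with optional Laplace smoothing (+0.5 per quarter count) behind a
flag, since the index is undefined rather than zero when a stage has
no fish from some quarter.

## What the simulator emulates

`sim_params()` defaults state the world the pipeline is tested in:

- **Spawning**: birth phase von Mises around the new moon,
  concentration 1 (≈47% of eggs in the NEW quarter, ≈8% in FULL).
  Concentration 2 was rejected as a default because it starves the
  full-moon quarter (≈2%) below anything usable for stage
  distributions at desk scale.
- **PLD**: latent truncated normal, mean 46 d, sd 5, range 37–61 d.
- **Settlement**: pulled (strength 0.8) toward a target tied to a new
  moon. The reference new moon is the candidate whose
  priority-adjusted target is closest to the mean PLD — a
  deterministic function of birth phase — and the target leads the
  new moon by 0.25 d per day of "competency surplus" (time since the
  minimum PLD), so new-moon-born fish, competent longest, arrive
  earliest, oldest and largest: the priority-effect ordering. A
  global offset is solved by deterministic quadrature + root-finding
  at parameter-construction time so that the *realized* population
  mean PLD equals `pld_mean` exactly in expectation. This
  calibration is part of the generator's contract, not a fit to any
  measured outcome: the stated facts "spawning peaks at new moon",
  "settlement is moon-cued" and "mean PLD 46 in [37, 61]" are
  mutually constraining (46 d is mid-cycle for a new-moon birth),
  and the offset is what makes them jointly true.
- **Growth**: daily increment = declining base curve
  ($5e^{-0.015\,\mathrm{age}}$ µm/d) + $0.4\sin(\theta\pi/180)$ µm/d
  moonlight modulation + Gaussian noise (sd 0.2 µm/d, i.e. half the
  amplitude: "moderate"), floored at 0.05 µm/d so radii stay strictly
  increasing. The modulation is additive on increment width, the
  quantity otoliths actually record.
- **Survival**: egg→settler lowest for NEW/WANING births (0.10 /
  0.08) and highest for FULL (0.30); settler→juvenile roughly flat
  with a WANING penalty; juvenile→adult *counteracting*, favouring
  NEW/WANING (0.60 / 0.55) — the reversal the selection matrix is
  expected to recover.
- **Sex determination**: among adults, log-odds of maturing directly
  as a primary male = $-6 + 5\,\mathrm{rank} + 5\,\mathrm{grouped} +
  1\,\mathrm{offshore}$, with rank scaled to [0, 1] within the
  settlement group (PLD as the size proxy). A grouped largest fish
  matures male with p ≈ 0.98; a solitary fish with p ≈ 0.003,
  matching the experimental observation that social groups, not
  isolation, produce primary males. 15% of females and 40% of
  primary males progress to terminal phase.
- **Reproducibility**: every fish draws from its own substream
  derived from the global seed, so enlarging a cohort extends it
  without reshuffling earlier fish.

### What a green test does *not* establish

The simulator omits increment-reading error, within-quarter
environmental heterogeneity, between-year variation in the
moonlight–growth coupling, and any hydrodynamics of larval transport.
Its lunar growth signal is a clean single-harmonic sinusoid. LOOCV
accuracies near 0.9 on synthetic cohorts therefore say the *pipeline*
is correct, not that real otoliths support that accuracy — on real
material the same workflow achieves roughly half that, and the
meaningful validations are the qualitative ones: above-chance
accuracy, misclassifications confined to adjacent quarters, and
distribution-level agreement between predicted and true birth
quarters.

One measured artifact deserves note: with age-as-factor detrending on
an unbalanced panel, the age means at old ages are computed only from
long-PLD survivors, whose lunar phases are not balanced; this
contaminates the residuals and inflates the fitted sinusoid amplitude
by ~8–12% at simulator defaults even with zero noise. On an equal-PLD
balanced panel the amplitude is recovered within ~3% at noise equal
to half the amplitude. The real-data analogue of this artifact is
intrinsic to the method, not a bug in either implementation.

## Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `synodic_length` | 29.53 | d | astronomical synodic month |
| `spawn_concentration` | 1 | — | new-moon spawning peak without starving FULL |
| `pld_mean`, `pld_sd` | 46, 5 | d | documented larval duration |
| `pld_min`, `pld_max` | 37, 61 | d | documented range (hard truncation) |
| `settle_snap` | 0.8 | — | strength of the lunar settlement cue |
| `settle_priority_rate` | 0.25 | d/d | arrival lead per day of competency surplus |
| `moon_amp` | 0.4 | µm/d | moonlight growth modulation |
| `noise_sd` | 0.2 | µm/d | "moderate" daily noise (= amp/2) |
| smoothing `window` | 3 | d | rolling-average span |
| sinusoid `age_range` | 25–47 | dph | ages with stable lunar signal |
| LDA `ridge` | 1e-8 | — | relative covariance regularization |

## Known limitations

- The lunar clock is linear; for multi-year real data supply a
  new-moon table.
- Selection indices on classifier-predicted (rather than true)
  quarters are attenuated toward zero by misclassification; output
  provenance should record which labels were used.
- Bootstrap confidence intervals for selection indices are out of
  scope; the resampling hooks exist but no calibrated inference on
  real collections is attempted.
- The sex-determination rule is a phenomenological logistic stand-in
  for a qualitative mechanism; its coefficients are configuration,
  not estimates.
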