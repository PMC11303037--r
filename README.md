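# otolunar

Reconstructing the lunar timing of birth from fish otoliths, and
measuring how selection on birth timing plays out across the life
cycle.

## The problem

Many reef fishes time their spawning to the lunar cycle, and
moonlight modulates the growth and survival of their pelagic larvae
on the same 29.5-day rhythm. Otoliths (ear stones) record one growth
increment per day, so the larval history of any fish — settler,
juvenile or adult — can be read back at daily resolution. For young
fish, counting increments from a known capture date dates the birth
directly. For adults this fails: even a 1% increment-counting error
on an 8-year-old fish implies a birthdate window of
`round(0.01 * 8 * 365.25)` = **29 days**, a full lunar cycle, so a
direct count carries no lunar information.

`otolunar` implements the indirect route: because moonlight leaves a
periodic signature in larval growth whose phase is set by the birth
date, the *shape* of a fish's detrended larval growth history encodes
its lunar quarter of birth (new, waxing, full, waning). The package

1. simulates cohorts of daily otolith radius series with known birth
   quarters, lunar-cued settlement, quarter-dependent survival and a
   social-context sex-determination rule (`sim_params()`,
   `simulate_cohort()`, `apply_life_history()`);
2. removes ontogenetic growth trends with an age-as-factor model and
   forms normalized, smoothed residual-growth series
   (`fit_age_detrend()`, `process_residuals()`);
3. extracts twelve growth-history traits per fish — trend, linearity
   and curvature of the residual-growth series; slope and intercept
   over ages 28–34, 35–41 and 42–48 days post-hatch; the amplitude
   *a* and offset *d* of the periodic model
   `growth = a sin(theta * pi/180 + c) + d`, where theta is the
   fish's lunar phase angle at each age; and pelagic larval duration
   (`cohort_traits()`, `fit_sinusoid()`);
4. classifies lunar quarter of birth by linear discriminant analysis
   with leave-one-out cross-validation and an uninformative prior for
   adults (`fit_lda()`, `loocv_lda()`, `assign_cohort()`);
5. quantifies selection between life stages *j* and *j+1* as
   `log10(P_{j+1,i} / P_{j,i})` per lunar quarter *i*, over the stage
   graph egg → settler → juvenile → {female, primary male} →
   terminal-phase male (`stage_distribution()`, `selection_matrix()`).

## Worked example

Simulate a balanced cohort (200 fish per birth quarter), extract the
12 traits, and cross-validate the birth-quarter classifier:

```r
library(otolunar)

params <- sim_params(n_spawned = 400, spawn = "balanced", seed = 42)
cohort <- simulate_cohort(params)
traits <- cohort_traits(cohort)

X <- traits[, c("trend", "linearity", "curvature",
                "slope_28_34", "intercept_28_34", "slope_35_41",
                "intercept_35_41", "slope_42_48", "intercept_42_48",
                "sin_a", "sin_d", "pld_days")]
y <- cohort$truth$birth_quarter[match(traits$fish_id,
                                      cohort$truth$fish_id)]
cv <- loocv_lda(X, y)
cv
#> <loocv_result> accuracy 0.902 (0 unclassifiable)
#>         predicted
#> true     NEW WAXING FULL WANING
#>   NEW     94      3    0      3
#>   WAXING   5     92    3      0
#>   FULL     0      1   94      5
#>   WANING  11      0    8     81

adjacency_fraction(cv$confusion)
#> [1] 1
pred <- stage_distribution(cv$predicted, "settler")
total_variation(pred$P, stage_distribution(y, "settler")$P)
#> [1] 0.0375
```

90% of fish are assigned their true lunar quarter of birth; every
misclassification lands on a cyclically adjacent quarter (as expected
when the only confusable feature is a continuous phase), and the
predicted birth-quarter distribution is within total-variation 0.04
of the truth. On real otoliths, accuracy is far lower — the simulator
omits increment-reading error and between-year variation — but the
qualitative structure (above-chance accuracy, adjacent-quarter
errors, distribution-level agreement) is the validation signature the
workflow is built to check.

A command-line wrapper around the same functions is installed at
`inst/cli/otolunar` (`simulate`, `residuals`, `traits`, `classify`,
`select`).

## Layout

- `R/` — lunar clock, simulator, residual-growth pipeline, trait
  extraction, discriminant classifier, selection indices.
- `tests/testthat/` — unit, property and acceptance tests (oracle
  comparisons against brute-force Bayes posteriors and hand-built
  orthogonal regressions).
- `vignettes/otolith-lunar-reconstruction.Rmd` — the model, its
  assumptions, parameter choices and known limitations.
- `scripts/acceptance.R` — the acceptance report.
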