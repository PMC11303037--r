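#' Simulation parameters for a synthetic otolith cohort
#'
#' Bundles and validates all knobs of the synthetic data generator.
#' Defaults encode the study system they emulate: spawning
#' concentrated at the new moon, a pelagic larval duration (PLD)
#' averaging 46 days with range 37-61, settlement cued to the dark
#' nights around the new moon, a moonlight-modulated additive signal
#' on daily increment widths, egg-to-settler survival lowest for new-
#' and waning-moon births, later survival favouring those same
#' quarters, and a logistic primary-male determination rule driven by
#' social group membership, within-group size rank and site quality.
#'
#' @param n_spawned Number of spawned larvae (> 0).
#' @param spawn Either `"lunar"` (birth phase drawn from a von
#'   Mises-type distribution centred on the new moon with
#'   concentration `spawn_concentration`) or `"balanced"` (equal
#'   numbers per quarter, phase uniform within each quarter; used for
#'   classifier calibration experiments).
#' @param spawn_concentration Von Mises concentration of birth phase
#'   around the new moon (0 = uniform).
#' @param n_cycles Number of synodic cycles in the spawning season.
#' @param pld_mean,pld_sd,pld_min,pld_max Target mean, spread and
#'   truncation bounds (days) of realized PLD.
#' @param settle_snap Strength in `[0, 1]` of the pull of settlement
#'   toward the nearest feasible new moon (0 = none, 1 = fully
#'   moon-cued).
#' @param settle_priority_rate Days of settlement lead (arrival before
#'   the new moon) per day of competency surplus; generates priority
#'   effects whereby long-PLD fish arrive earliest.
#' @param settle_rel_sd SD (days) of individual noise on settlement
#'   timing.
#' @param base_growth_curve Numeric vector of mean daily increment
#'   widths (micrometres/day) indexed by age in days post-hatch;
#'   must cover ages up to `pld_max`.
#' @param moon_amp Amplitude (micrometres/day) of the sinusoidal
#'   moonlight modulation of daily increment width.
#' @param moon_phase_offset Phase offset (degrees) of the moonlight
#'   modulation; 0 places peak growth a quarter cycle after new moon.
#' @param noise_sd SD (micrometres/day) of daily increment noise.
#' @param min_increment Floor (micrometres) on daily increments so
#'   radii stay strictly increasing.
#' @param survival_by_quarter Egg-to-settler survival probability per
#'   birth quarter (order NEW, WAXING, FULL, WANING).
#' @param settler_survival_by_quarter Settler-to-juvenile survival per
#'   birth quarter.
#' @param juvenile_survival_by_quarter Juvenile-to-adult survival per
#'   birth quarter.
#' @param p_offshore_given_quarter Probability of settling to an
#'   offshore (high-quality) site per birth quarter.
#' @param p_group_given_quarter Probability of settling into a social
#'   group per birth quarter.
#' @param group_size_mean Mean of the Poisson count of extra group
#'   members for grouped settlers (group size = 2 + Poisson).
#' @param sex_logit_coefs Named coefficients `(intercept, size_rank,
#'   grouped, offshore)` of the logistic primary-male determination
#'   rule; `size_rank` is scaled to `[0, 1]` (1 = largest in group,
#'   0 = smallest or solitary).
#' @param tp_fraction Named fractions `(female, primary_male)` of each
#'   initial sex phenotype progressing to terminal-phase male.
#' @param cal A [lunar_calendar()].
#' @param seed Integer seed; with the per-fish stream-splitting used
#'   by [simulate_cohort()], identical params + seed reproduce the
#'   cohort exactly and earlier fish are unchanged by increasing
#'   `n_spawned`.
#' @return A validated object of class `sim_params`.
#' @export
sim_params <- function(n_spawned = 1000,
                       spawn = c("lunar", "balanced"),
                       spawn_concentration = 1,
                       n_cycles = 13,
                       pld_mean = 46, pld_sd = 5,
                       pld_min = 37, pld_max = 61,
                       settle_snap = 0.8,
                       settle_priority_rate = 0.25,
                       settle_rel_sd = 2,
                       base_growth_curve = 5 * exp(-0.015 * seq_len(90)),
                       moon_amp = 0.4,
                       moon_phase_offset = 0,
                       noise_sd = 0.2,
                       min_increment = 0.05,
                       survival_by_quarter =
                         c(NEW = 0.10, WAXING = 0.25, FULL = 0.30, WANING = 0.08),
                       settler_survival_by_quarter =
                         c(NEW = 0.50, WAXING = 0.50, FULL = 0.50, WANING = 0.35),
                       juvenile_survival_by_quarter =
                         c(NEW = 0.60, WAXING = 0.30, FULL = 0.25, WANING = 0.55),
                       p_offshore_given_quarter =
                         c(NEW = 0.70, WAXING = 0.40, FULL = 0.50, WANING = 0.40),
                       p_group_given_quarter =
                         c(NEW = 0.45, WAXING = 0.45, FULL = 0.25, WANING = 0.25),
                       group_size_mean = 1.2,
                       sex_logit_coefs =
                         c(intercept = -6, size_rank = 5, grouped = 5, offshore = 1),
                       tp_fraction = c(female = 0.15, primary_male = 0.40),
                       cal = lunar_calendar(),
                       seed = 1L) {
  spawn <- match.arg(spawn)
  p <- list(n_spawned = n_spawned, spawn = spawn,
            spawn_concentration = spawn_concentration, n_cycles = n_cycles,
            pld_mean = pld_mean, pld_sd = pld_sd,
            pld_min = pld_min, pld_max = pld_max,
            settle_snap = settle_snap,
            settle_priority_rate = settle_priority_rate,
            settle_rel_sd = settle_rel_sd,
            base_growth_curve = base_growth_curve,
            moon_amp = moon_amp, moon_phase_offset = moon_phase_offset,
            noise_sd = noise_sd, min_increment = min_increment,
            survival_by_quarter = survival_by_quarter,
            settler_survival_by_quarter = settler_survival_by_quarter,
            juvenile_survival_by_quarter = juvenile_survival_by_quarter,
            p_offshore_given_quarter = p_offshore_given_quarter,
            p_group_given_quarter = p_group_given_quarter,
            group_size_mean = group_size_mean,
            sex_logit_coefs = sex_logit_coefs,
            tp_fraction = tp_fraction, cal = cal, seed = as.integer(seed))
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  bad <- character()
  chk <- function(ok, field) if (!isTRUE(ok)) bad <<- c(bad, field)
  chk(is.numeric(p$n_spawned) && length(p$n_spawned) == 1L &&
        p$n_spawned > 0 && p$n_spawned == round(p$n_spawned), "n_spawned")
  chk(p$spawn %in% c("lunar", "balanced"), "spawn")
  chk(is.numeric(p$spawn_concentration) && p$spawn_concentration >= 0,
      "spawn_concentration")
  chk(is.numeric(p$n_cycles) && p$n_cycles >= 1, "n_cycles")
  chk(is.numeric(p$pld_mean) && is.numeric(p$pld_min) &&
        is.numeric(p$pld_max) &&
        p$pld_min <= p$pld_mean && p$pld_mean <= p$pld_max, "pld bounds")
  chk(is.numeric(p$pld_sd) && p$pld_sd > 0, "pld_sd")
  chk(is.numeric(p$settle_snap) && p$settle_snap >= 0 && p$settle_snap <= 1,
      "settle_snap")
  chk(is.numeric(p$settle_priority_rate) && p$settle_priority_rate >= 0 &&
        p$settle_priority_rate < 1, "settle_priority_rate")
  chk(is.numeric(p$settle_rel_sd) && p$settle_rel_sd >= 0, "settle_rel_sd")
  chk(is.numeric(p$base_growth_curve) &&
        length(p$base_growth_curve) >= p$pld_max &&
        all(p$base_growth_curve > 0), "base_growth_curve")
  chk(is.numeric(p$moon_amp) && p$moon_amp >= 0, "moon_amp")
  chk(is.numeric(p$noise_sd) && p$noise_sd >= 0, "noise_sd")
  chk(is.numeric(p$min_increment) && p$min_increment > 0, "min_increment")
  for (f in c("survival_by_quarter", "settler_survival_by_quarter",
              "juvenile_survival_by_quarter", "p_offshore_given_quarter",
              "p_group_given_quarter")) {
    v <- p[[f]]
    chk(is.numeric(v) && length(v) == 4L && all(v >= 0) && all(v <= 1), f)
  }
  chk(is.numeric(p$group_size_mean) && p$group_size_mean >= 0,
      "group_size_mean")
  chk(is.numeric(p$sex_logit_coefs) && length(p$sex_logit_coefs) == 4L,
      "sex_logit_coefs")
  chk(is.numeric(p$tp_fraction) && length(p$tp_fraction) == 2L &&
        all(p$tp_fraction >= 0) && all(p$tp_fraction <= 1), "tp_fraction")
  chk(inherits(p$cal, "lunar_calendar"), "cal")
  chk(is.numeric(p$seed) && length(p$seed) == 1L && is.finite(p$seed),
      "seed")
  if (length(bad)) {
    stop("invalid sim_params field(s): ", paste(bad, collapse = ", "))
  }
  invisible(p)
}

#' Default simulation parameters
#'
#' Convenience wrapper returning [sim_params()] evaluated at its
#' documented defaults (mean PLD 46 d, range 37-61 d, spawning mode at
#' the new moon).
#'
#' @param ... Overrides passed to [sim_params()].
#' @return A `sim_params` object.
#' @export
default_params <- function(...) sim_params(...)

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>", x$n_spawned, "spawned larvae |", x$spawn,
      "spawning (kappa", x$spawn_concentration, ")\n")
  cat("  PLD ~", x$pld_mean, "d (sd", x$pld_sd, ", range",
      paste0("[", x$pld_min, ", ", x$pld_max, "]"),
      ") | settlement snap", x$settle_snap, "\n")
  cat("  moon amplitude", x$moon_amp, "um/d | noise sd", x$noise_sd,
      "um/d | seed", x$seed, "\n")
  invisible(x)
}
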