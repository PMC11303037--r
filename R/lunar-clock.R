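#' Lunar calendar
#'
#' A minimal idealized lunar clock: phase advances linearly with time
#' from a reference new moon, with a configurable synodic period.
#' Quarter-level analyses tolerate the <1 day error of a linear clock
#' relative to true ephemeris phase; for real collections an explicit
#' table of observed new-moon dates can be supplied and is used by
#' [days_from_new_moon()] in preference to the linear rule.
#'
#' @param epoch_new_moon Continuous day of a reference new moon.
#' @param synodic_length Length of the synodic month in days
#'   (default 29.53).
#' @param new_moons Optional numeric vector of new-moon days
#'   (ephemeris hook for real data).
#' @return An object of class `lunar_calendar`.
#' @examples
#' cal <- lunar_calendar()
#' phase_angle(14.765, cal) # half cycle -> 180 degrees
#' @export
lunar_calendar <- function(epoch_new_moon = 0, synodic_length = 29.53,
                           new_moons = NULL) {
  stopifnot(is.numeric(epoch_new_moon), length(epoch_new_moon) == 1L,
            is.finite(epoch_new_moon))
  if (!is.numeric(synodic_length) || length(synodic_length) != 1L ||
      !is.finite(synodic_length) || synodic_length <= 0) {
    stop("`synodic_length` must be a single positive number")
  }
  if (!is.null(new_moons)) {
    stopifnot(is.numeric(new_moons), all(is.finite(new_moons)))
    new_moons <- sort(new_moons)
  }
  structure(
    list(epoch_new_moon = epoch_new_moon,
         synodic_length = synodic_length,
         new_moons = new_moons),
    class = "lunar_calendar"
  )
}

#' @export
print.lunar_calendar <- function(x, ...) {
  cat("<lunar_calendar> epoch new moon at day", x$epoch_new_moon,
      "| synodic month", x$synodic_length, "d\n")
  if (!is.null(x$new_moons)) {
    cat("  ephemeris table:", length(x$new_moons), "new moons\n")
  }
  invisible(x)
}

#' Ordered lunar quarter labels
#'
#' The four principal phases in cyclic order. All quarter factors in
#' the package use these levels, so `which.max` tie-breaking and
#' adjacency are deterministic.
#'
#' @return Character vector `c("NEW", "WAXING", "FULL", "WANING")`.
#' @export
lunar_quarters <- function() c("NEW", "WAXING", "FULL", "WANING")

#' Lunar phase angle at a time point
#'
#' @param t Continuous day (vectorized).
#' @param cal A [lunar_calendar()].
#' @return Phase angle in degrees in `[0, 360)`; 0 = new moon,
#'   180 = full moon.
#' @export
phase_angle <- function(t, cal = lunar_calendar()) {
  stopifnot(inherits(cal, "lunar_calendar"), is.numeric(t))
  ((t - cal$epoch_new_moon) %% cal$synodic_length) /
    cal$synodic_length * 360
}

#' Bin a phase angle to its nearest lunar quarter
#'
#' Quarter windows are +/-45 degrees around the four principal
#' phases; a boundary angle is assigned to the higher window, so
#' `[315, 360) U [0, 45)` is NEW, `[45, 135)` WAXING, `[135, 225)`
#' FULL and `[225, 315)` WANING.
#'
#' @param angle Phase angle(s) in degrees, in `[0, 360)`.
#' @return Factor with levels [lunar_quarters()].
#' @export
nearest_quarter <- function(angle) {
  stopifnot(is.numeric(angle))
  if (any(!is.finite(angle)) || any(angle < 0) || any(angle >= 360)) {
    stop("`angle` must be finite and in [0, 360)")
  }
  q <- lunar_quarters()[1L + (floor((angle + 45) / 90) %% 4L)]
  factor(q, levels = lunar_quarters())
}

#' Signed day offset to the nearest new moon
#'
#' Negative values mean the time point falls before the nearest new
#' moon; the offset lies in `(-synodic/2, synodic/2]`. When the
#' calendar carries an ephemeris table of new-moon days the offset is
#' computed against the closest tabulated new moon instead of the
#' linear clock.
#'
#' @inheritParams phase_angle
#' @return Signed days (vectorized over `t`).
#' @export
days_from_new_moon <- function(t, cal = lunar_calendar()) {
  stopifnot(inherits(cal, "lunar_calendar"), is.numeric(t))
  if (!is.null(cal$new_moons)) {
    return(vapply(t, function(ti) {
      d <- ti - cal$new_moons
      d[which.min(abs(d))]
    }, numeric(1L)))
  }
  s <- cal$synodic_length
  s / 2 - ((s / 2 - (t - cal$epoch_new_moon)) %% s)
}

#' Lunar phase angle of a fish at a given larval age
#'
#' The phase argument of the periodic growth model: a fish born at
#' phase angle `birth_angle` has advanced by `age_dph * 360 / synodic`
#' degrees at age `age_dph` days post-hatch.
#'
#' @param age_dph Age in days post-hatch (vectorized, >= 0).
#' @param birth_angle Phase angle at birth, degrees.
#' @param cal A [lunar_calendar()].
#' @return Phase angle in degrees in `[0, 360)`.
#' @export
lunar_theta <- function(age_dph, birth_angle = 0, cal = lunar_calendar()) {
  stopifnot(inherits(cal, "lunar_calendar"),
            is.numeric(age_dph), is.numeric(birth_angle))
  if (any(age_dph < 0)) stop("`age_dph` must be >= 0")
  (birth_angle + age_dph * 360 / cal$synodic_length) %% 360
}

#' Are two lunar quarters cyclically adjacent?
#'
#' Adjacency on the cycle NEW - WAXING - FULL - WANING - NEW.
#' Used to score near-miss classifications: a misassignment to a
#' neighbouring quarter is a one-bin error on the lunar cycle.
#'
#' @param q1,q2 Quarter labels (character or factor), vectorized.
#' @return Logical vector; `FALSE` for identical quarters.
#' @export
quarter_is_adjacent <- function(q1, q2) {
  lv <- lunar_quarters()
  i <- match(as.character(q1), lv)
  j <- match(as.character(q2), lv)
  if (any(is.na(i)) || any(is.na(j))) stop("unknown quarter label")
  d <- abs(i - j) %% 4L
  d == 1L | d == 3L
}

#' Birthdate uncertainty implied by an increment-counting error rate
#'
#' Direct daily-increment ageing of old fish fails because even small
#' increment-counting error rates translate into birthdate windows
#' wider than a lunar cycle. This helper returns the implied error
#' range in whole days: `round(error_rate * age_years * year_length)`.
#' A 1% error rate on an 8-year-old fish gives 29 days, about one full
#' synodic month, which is why adult birth quarters must be inferred
#' from larval growth-history traits instead of raw increment counts.
#'
#' @param age_years Age of the fish in years.
#' @param error_rate Proportional increment-counting error rate
#'   (default 0.01).
#' @param year_length Days per year (default 365.25).
#' @return Error range in whole days.
#' @examples
#' birthdate_error_days(8) # 29
#' @export
birthdate_error_days <- function(age_years, error_rate = 0.01,
                                 year_length = 365.25) {
  stopifnot(is.numeric(age_years), age_years >= 0,
            is.numeric(error_rate), error_rate >= 0)
  round(error_rate * age_years * year_length)
}
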