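# The 12 growth-history traits: STL-style trend/linearity/curvature,
# slopes and intercepts over three larval age windows, sinusoid
# amplitude and offset of the lunar-periodic growth model, and
# pelagic larval duration.

trait_names <- function() {
  c("trend", "linearity", "curvature",
    "slope_28_34", "intercept_28_34",
    "slope_35_41", "intercept_35_41",
    "slope_42_48", "intercept_42_48",
    "sin_a", "sin_d", "pld_days")
}

#' Trend, linearity and curvature of a processed growth series
#'
#' A non-seasonal decomposition: the trend component is a loess
#' smooth of the series on its time index (the larval record is far
#' too short to extract a seasonal component at the synodic period,
#' so the decomposition reduces to trend + remainder). Trend strength
#' is `max(0, 1 - Var(remainder) / Var(series))`. Linearity and
#' curvature are the first- and second-order coefficients of an
#' orthogonal quadratic regression of the trend component on the time
#' index; curvature is reported as the raw second coefficient, with
#' no sign flip.
#'
#' @param x Normalized, smoothed residual-growth series (length >= 5).
#' @param span Loess span (default 0.75).
#' @return Named numeric: `trend`, `linearity`, `curvature`.
#' @export
stl_traits <- function(x, span = 0.75) {
  if (length(x) < 5) stop("series too short for trend decomposition")
  tt <- seq_along(x)
  fit <- stats::loess(x ~ tt, span = span, degree = 2,
                      family = "gaussian")
  trend_c <- stats::fitted(fit)
  rem <- x - trend_c
  vx <- stats::var(x)
  strength <- if (vx > 0) max(0, 1 - stats::var(rem) / vx) else 0
  pc <- stats::coef(stats::lm(trend_c ~ stats::poly(tt, 2)))
  c(trend = unname(strength),
    linearity = unname(pc[2]),
    curvature = unname(pc[3]))
}

#' Windowed slopes and intercepts of residual growth on age
#'
#' Per window (inclusive integer age bounds), the OLS slope and
#' intercept of the processed residual-growth series against age,
#' over whatever ages of the window are present in the record.
#' Windows with fewer than 3 available points yield `NA` traits plus
#' a missingness flag; the discriminant step later imputes them as
#' the column mean (0 in standardized space) so that fish with short
#' larval records remain classifiable. Intercepts are reported at age
#' 0 (raw regression intercept); set `center_age` to use
#' window-centred intercepts instead.
#'
#' @param ages Ages (days post-hatch) of the growth values.
#' @param growth Processed residual-growth values.
#' @param windows List of inclusive `(lo, hi)` age pairs.
#' @param center_age If `TRUE`, intercepts are evaluated at each
#'   window's midpoint.
#' @return Named numeric of `2 * length(windows)` values with a
#'   logical `missing` attribute (one flag per window).
#' @export
window_fits <- function(ages, growth,
                        windows = list(c(28, 34), c(35, 41), c(42, 48)),
                        center_age = FALSE) {
  stopifnot(length(ages) == length(growth))
  vals <- numeric(0)
  miss <- logical(length(windows))
  for (k in seq_along(windows)) {
    w <- windows[[k]]
    sel <- ages >= w[1] & ages <= w[2]
    nm <- paste0(c("slope_", "intercept_"), w[1], "_", w[2])
    if (sum(sel) < 3) {
      miss[k] <- TRUE
      vals <- c(vals, stats::setNames(c(NA_real_, NA_real_), nm))
      next
    }
    a <- ages[sel]
    if (center_age) a <- a - mean(w)
    fit <- stats::lm(growth[sel] ~ a)
    vals <- c(vals, stats::setNames(unname(stats::coef(fit)[c(2, 1)]), nm))
  }
  if (all(miss)) stop("no trait window contains any growth observations")
  attr(vals, "missing") <- miss
  vals
}

#' Fit the lunar-periodic growth model to raw residual growth
#'
#' Least-squares fit of `growth = a * sin(theta * pi/180 + c) + d`,
#' where `theta` is the fish's lunar phase angle at each age from
#' [lunar_theta()]. When the birth phase is unknown (the adult
#' assignment case) `birth_angle = 0` is used; this leaves the fitted
#' amplitude `a` and offset `d` unchanged and absorbs the birth phase
#' into `c`, which is why `c` is not used as a trait. The default
#' solver reparameterizes `a * sin(x + c) = A * sin(x) + B * cos(x)`,
#' linear in `(A, B, d)`, and solves exactly by linear least squares
#' (no initialization or convergence concerns); `method = "nls"`
#' retains a multi-start nonlinear path for use with growth
#' corrections that break linearity.
#'
#' @param ages Ages (days post-hatch); the fit is restricted to
#'   `age_range`.
#' @param growth Raw (unnormalized, unsmoothed) residual growth.
#' @param birth_angle Lunar phase at birth in degrees, if known.
#' @param cal A [lunar_calendar()].
#' @param age_range Inclusive age window for the fit (default 25-47).
#' @param method `"linear"` (exact) or `"nls"` (multi-start
#'   Levenberg-style path).
#' @return List of class `sinusoid_fit`: `a >= 0`, `c` in `[0, 2*pi)`,
#'   `d`, `sse`, `n`, `converged`.
#' @export
fit_sinusoid <- function(ages, growth, birth_angle = 0,
                         cal = lunar_calendar(), age_range = c(25, 47),
                         method = c("linear", "nls")) {
  method <- match.arg(method)
  stopifnot(length(ages) == length(growth))
  sel <- ages >= age_range[1] & ages <= age_range[2] &
    is.finite(growth)
  if (sum(sel) < 6) {
    stop("need at least 6 growth observations in the sinusoid window")
  }
  x <- lunar_theta(ages[sel], birth_angle, cal) * pi / 180
  y <- growth[sel]
  out <- list(converged = TRUE)
  if (method == "linear") {
    X <- cbind(sin = sin(x), cos = cos(x), one = 1)
    cf <- stats::coef(stats::lm.fit(X, y))
    A <- cf[["sin"]]; B <- cf[["cos"]]; d <- cf[["one"]]
    a <- sqrt(A^2 + B^2)
    cc <- atan2(B, A) %% (2 * pi)
    sse <- sum((y - (a * sin(x + cc) + d))^2)
  } else {
    best <- NULL
    for (c0 in seq(0, 2 * pi - 1e-9, length.out = 8)) {
      fit <- tryCatch(
        stats::nls(y ~ a * sin(x + c) + d,
                   start = list(a = stats::sd(y), c = c0, d = mean(y)),
                   control = stats::nls.control(warnOnly = TRUE)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse_i <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse_i < best$sse) {
        cf <- stats::coef(fit)
        best <- list(a = cf[["a"]], c = cf[["c"]], d = cf[["d"]],
                     sse = sse_i)
      }
    }
    if (is.null(best)) {
      return(structure(list(a = 0, c = 0, d = mean(y),
                            sse = sum((y - mean(y))^2),
                            n = length(y), converged = FALSE),
                       class = "sinusoid_fit"))
    }
    a <- best$a; cc <- best$c; d <- best$d; sse <- best$sse
    if (a < 0) { # canonicalize: -a sin(x + c) = a sin(x + c + pi)
      a <- -a
      cc <- cc + pi
    }
    cc <- cc %% (2 * pi)
  }
  structure(list(a = unname(a), c = unname(cc), d = unname(d),
                 sse = unname(sse), n = length(y), converged = TRUE),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sinusoid_fit> a = %.4g, c = %.4g rad, d = %.4g (n = %d, sse = %.3g)%s\n",
    x$a, x$c, x$d, x$n, x$sse,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Pelagic larval duration of one fish
#'
#' The increment count between hatch and settlement check marks, read
#' directly off the series' settlement index.
#'
#' @param series One fish's rows of an increments data frame (must
#'   carry a `settlement_index` column), or a single numeric index.
#' @return PLD in days.
#' @export
pld_trait <- function(series) {
  si <- if (is.numeric(series)) series else unique(series$settlement_index)
  si <- si[!is.na(si)]
  if (length(si) != 1L) stop("settlement check missing or ambiguous")
  as.numeric(si)
}

#' Extract the 12 growth-history traits for one fish
#'
#' Runs the residual-growth pipeline for a single fish against a
#' pooled detrending model and computes, in order: trend, linearity
#' and curvature of the normalized + smoothed residual-growth series;
#' slope and intercept of that series over ages 28-34, 35-41 and
#' 42-48; the amplitude `a` and offset `d` of the lunar sinusoid
#' fitted to the raw residual-growth series over ages 25-47 (the
#' phase `c` is deliberately not a trait); and pelagic larval
#' duration. Window traits a short record cannot support are `NA`
#' with a missingness flag (imputed in standardized space by the
#' classifier).
#'
#' @param series One fish's increment rows (`age_dph`, `radius_um`,
#'   `settlement_index`).
#' @param model A pooled [fit_age_detrend()] model.
#' @param cal A [lunar_calendar()].
#' @param window Smoothing window for the processed series.
#' @param correction Optional settlement-correction hook (see
#'   [to_growth()]); when supplied, the sinusoid falls back to the
#'   nonlinear fit path.
#' @return Named numeric vector of the 12 traits, with a logical
#'   `missing` attribute flagging imputable window traits.
#' @export
extract_traits <- function(series, model, cal = lunar_calendar(),
                           window = 3, correction = NULL) {
  stopifnot(is.data.frame(series), nrow(series) >= 2)
  r <- series[order(series$age_dph), ]
  rs <- residual_size(r$age_dph, r$radius_um, model)
  si <- pld_trait(r)
  g_raw <- to_growth(rs, r$age_dph, si, correction)
  g_ages <- r$age_dph[-nrow(r)]
  g_proc <- smooth_growth(normalize_growth(g_raw), window)

  stl <- stl_traits(g_proc)
  wf <- window_fits(g_ages, g_proc)
  sf <- fit_sinusoid(g_ages, g_raw, birth_angle = 0, cal = cal,
                     method = if (is.null(correction)) "linear" else "nls")
  out <- c(stl, wf, sin_a = sf$a, sin_d = sf$d, pld_days = si)
  stopifnot(identical(names(out), trait_names()))
  attr(out, "missing") <- attr(wf, "missing")
  out
}

#' Trait table for a whole cohort
#'
#' @param cohort An `otl_cohort` or increments data frame.
#' @param model Optional pooled detrend model (fitted on the cohort
#'   when `NULL`); pass a shared model when settlers, juveniles and
#'   adults are processed together.
#' @param cal A [lunar_calendar()].
#' @param ... Passed to [extract_traits()].
#' @return Data frame: `fish_id`, `stage`, the 12 trait columns, and
#'   three logical `miss_*` flags (one per age window).
#' @export
cohort_traits <- function(cohort, model = NULL, cal = lunar_calendar(),
                          ...) {
  inc <- if (inherits(cohort, "otl_cohort")) cohort$increments else cohort
  stopifnot(is.data.frame(inc), nrow(inc) > 0)
  if (is.null(model)) model <- fit_age_detrend(inc)
  rows <- lapply(split(inc, inc$fish_id), function(r) {
    tv <- extract_traits(r, model, cal, ...)
    miss <- attr(tv, "missing")
    cbind(data.frame(fish_id = r$fish_id[1],
                     stage = if ("stage" %in% names(r)) r$stage[1]
                             else NA_character_,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(tv)),
          data.frame(miss_28_34 = miss[1], miss_35_41 = miss[2],
                     miss_42_48 = miss[3]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
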