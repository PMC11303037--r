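# Residual-growth processing: age-as-factor detrending of radius at
# age, first differences, per-fish normalization, rolling smoothing.

#' Fit the age-detrending model (age as a factor)
#'
#' An ordinary least squares fit of otolith radius on age with age as
#' a factor reduces to the age-specific mean radius over the training
#' pool; residuals within each observed age sum to zero by
#' construction. The pool should contain every fish whose series will
#' later be detrended (all stages together).
#'
#' @param increments Long data frame with columns `fish_id`,
#'   `age_dph`, `radius_um` (an `otl_cohort$increments`).
#' @return Object of class `age_detrend` with `ages`,
#'   `mean_radius_at_age` and `n_obs_at_age`.
#' @export
fit_age_detrend <- function(increments) {
  if (inherits(increments, "otl_cohort")) increments <- increments$increments
  stopifnot(is.data.frame(increments))
  if (nrow(increments) == 0) stop("empty increment pool")
  stopifnot(all(c("age_dph", "radius_um") %in% names(increments)))
  agg <- stats::aggregate(increments$radius_um,
                          by = list(age = increments$age_dph),
                          FUN = function(v) c(mean(v), length(v)))
  ages <- agg$age
  m <- agg$x[, 1]
  nobs <- agg$x[, 2]
  o <- order(ages)
  structure(list(ages = ages[o],
                 mean_radius_at_age = m[o],
                 n_obs_at_age = as.integer(nobs[o])),
            class = "age_detrend")
}

#' @export
print.age_detrend <- function(x, ...) {
  cat("<age_detrend>", length(x$ages), "ages,",
      sum(x$n_obs_at_age), "fish-age observations\n")
  invisible(x)
}

#' De-trended size-at-age residuals for one fish
#'
#' @param ages Integer ages (days post-hatch) of the fish's record.
#' @param radii Otolith radius at each age (micrometres).
#' @param model An [fit_age_detrend()] model covering every age in
#'   `ages`.
#' @return Numeric vector of residual size (radius minus the pool
#'   mean radius at that age), in `ages` order.
#' @export
residual_size <- function(ages, radii, model) {
  stopifnot(inherits(model, "age_detrend"),
            length(ages) == length(radii))
  idx <- match(ages, model$ages)
  if (anyNA(idx)) {
    stop("age(s) not in detrend model: ",
         paste(ages[is.na(idx)], collapse = ", "))
  }
  radii - model$mean_radius_at_age[idx]
}

#' Residual growth: first differences of residual size
#'
#' `residual_growth[i] = residual_size[i+1] - residual_size[i]`,
#' labelled at the first age of each pair. The optional `correction`
#' hook receives `(growth, ages, settlement_index)` and may adjust
#' increments spanning the settlement check (a settlement-effect
#' growth correction is deliberately not built in; the default is the
#' identity).
#'
#' @param rs Residual size vector.
#' @param ages Ages corresponding to `rs` (default `seq_along(rs)`).
#' @param settlement_index Age of the settlement check, passed to the
#'   hook.
#' @param correction Optional function hook; `NULL` means identity.
#' @return Numeric vector of length `length(rs) - 1`.
#' @export
to_growth <- function(rs, ages = seq_along(rs), settlement_index = NA,
                      correction = NULL) {
  if (length(rs) < 2) stop("residual size series too short to difference")
  g <- diff(rs)
  if (!is.null(correction)) {
    g <- correction(g, ages[-length(ages)], settlement_index)
    stopifnot(length(g) == length(rs) - 1)
  }
  g
}

#' Per-fish z-score normalization of a growth series
#'
#' Centres and scales to mean 0, sd 1 (sample sd, denominator n-1).
#'
#' @param x Numeric series.
#' @return Normalized series.
#' @export
normalize_growth <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot normalize a degenerate (zero variance) series")
  }
  (x - mean(x)) / s
}

#' Centred rolling-mean smoothing
#'
#' A centred rolling average with an odd window; edge values use
#' shrunken (partial) windows rather than being trimmed, so age
#' coverage is preserved for the trait windows near the end of the
#' larval record.
#'
#' @param x Numeric series.
#' @param window Odd window width, default 3; `window = 1` is the
#'   identity.
#' @return Smoothed series, same length as `x`.
#' @export
smooth_growth <- function(x, window = 3) {
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window %% 2 != 1 || window > length(x)) {
    stop("`window` must be an odd integer in [1, length(x)]")
  }
  if (window == 1) return(x)
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Full residual-growth pipeline for a cohort
#'
#' For each fish: detrend radius-at-age against the pooled
#' age-specific means, difference to residual growth, and (for the
#' processed variant) normalize per fish then smooth with a centred
#' rolling mean. Both the raw (unnormalized, unsmoothed) and the
#' processed growth series are returned, since downstream trait
#' extraction needs both: the sinusoid fit uses the raw series to
#' preserve each fish's inherent variability, every other trait uses
#' the processed one.
#'
#' @param cohort An `otl_cohort` or its `increments` data frame.
#' @param model Optional [fit_age_detrend()] model; fitted on the
#'   cohort itself when `NULL`.
#' @param window Smoothing window (odd, default 3).
#' @param order Processing order for the processed variant:
#'   `"normalize-smooth"` (default) or `"smooth-normalize"`
#'   (sensitivity switch).
#' @param correction Optional settlement-correction hook passed to
#'   [to_growth()].
#' @return Long data frame: `fish_id`, `age_dph`, `residual_size_um`,
#'   `residual_growth_raw`, `residual_growth` (processed); growth
#'   rows span ages 1..(n-1) of each fish.
#' @export
process_residuals <- function(cohort, model = NULL, window = 3,
                              order = c("normalize-smooth",
                                        "smooth-normalize"),
                              correction = NULL) {
  order <- match.arg(order)
  inc <- if (inherits(cohort, "otl_cohort")) cohort$increments else cohort
  stopifnot(is.data.frame(inc), nrow(inc) > 0)
  if (is.null(model)) model <- fit_age_detrend(inc)
  out <- lapply(split(inc, inc$fish_id), function(r) {
    r <- r[order(r$age_dph), ]
    rs <- residual_size(r$age_dph, r$radius_um, model)
    if (nrow(r) < 2) return(NULL)
    g <- to_growth(rs, r$age_dph, r$settlement_index[1], correction)
    gp <- if (order == "normalize-smooth") {
      smooth_growth(normalize_growth(g), window)
    } else {
      normalize_growth(smooth_growth(g, window))
    }
    data.frame(fish_id = r$fish_id[1],
               age_dph = r$age_dph[-nrow(r)],
               residual_size_um = rs[-length(rs)],
               residual_growth_raw = g,
               residual_growth = gp,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
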