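# Birth-quarter distributions per life stage and log10-ratio
# selection indices between stages.

stage_order <- function() {
  c("egg", "settler", "juvenile", "female", "primary_male", "tp_male")
}

stage_rank <- function(stage) {
  r <- c(egg = 1, settler = 2, juvenile = 3,
         female = 4, primary_male = 4, tp_male = 5)
  out <- r[stage]
  if (anyNA(out)) stop("unknown stage label: ",
                       paste(stage[is.na(out)], collapse = ", "))
  unname(out)
}

#' Construct a stage cohort from explicit per-quarter values
#'
#' Used for exogenously supplied distributions, e.g. a spawning
#' (egg-stage) distribution estimated from an external spawning
#' survey rather than from classified fish.
#'
#' @param x Numeric vector of 4 counts or proportions in quarter
#'   order NEW, WAXING, FULL, WANING.
#' @param stage Stage label (one of `"egg"`, `"settler"`,
#'   `"juvenile"`, `"female"`, `"primary_male"`, `"tp_male"`).
#' @param n Total count; required when `x` is proportions, inferred
#'   when `x` is counts.
#' @return Object of class `stage_cohort`: `stage`, `n`, `counts`
#'   (may be `NA` for purely proportional input), `P` (proportions
#'   summing to 1).
#' @export
stage_cohort <- function(x, stage, n = NULL) {
  stopifnot(is.numeric(x), length(x) == 4L, all(x >= 0), sum(x) > 0)
  stage <- match.arg(stage, stage_order())
  P <- x / sum(x)
  counts <- NULL
  if (abs(sum(x) - 1) < 1e-9 && !is.null(n)) {
    counts <- rep(NA_real_, 4)
  } else if (all(x == round(x))) {
    counts <- x
    if (is.null(n)) n <- sum(x)
  }
  if (is.null(n)) stop("`n` required when `x` is not a count vector")
  structure(list(stage = stage, n = n,
                 counts = if (is.null(counts)) rep(NA_real_, 4) else counts,
                 P = stats::setNames(P, lunar_quarters())),
            class = "stage_cohort")
}

#' Birth-quarter distribution of one life stage
#'
#' @param quarters Vector of quarter labels (true or predicted) for
#'   every fish sampled in the stage.
#' @param stage Stage label.
#' @return A [stage_cohort()] with exact count bookkeeping.
#' @export
stage_distribution <- function(quarters, stage = "settler") {
  q <- factor(as.character(quarters), levels = lunar_quarters())
  if (length(q) == 0 || anyNA(q)) {
    stop("`quarters` must be non-empty valid quarter labels")
  }
  cnt <- as.numeric(table(q))
  out <- stage_cohort(cnt, stage = stage, n = length(q))
  out
}

#' @export
print.stage_cohort <- function(x, ...) {
  cat("<stage_cohort>", x$stage, "(n =", x$n, "):",
      paste(sprintf("%s %.3f", lunar_quarters(), x$P), collapse = ", "),
      "\n")
  invisible(x)
}

#' Selection index between two life stages
#'
#' For each lunar quarter `i`, `log10(P_to_i / P_from_i)`, where `P`
#' is the proportion of that stage's fish born in quarter `i`. Values
#' above 0 mean fish born in that quarter survived the transition
#' relatively well; below 0, they were selected against. Quarters
#' with a zero proportion yield non-finite values flagged
#' `finite = FALSE`; optional Laplace smoothing (+0.5 to every
#' quarter's count) avoids zeros but requires count bookkeeping.
#'
#' @param to,from [stage_cohort()] objects for the later and earlier
#'   stage.
#' @param smooth If `TRUE`, apply +0.5 Laplace smoothing to both
#'   stages' counts before forming proportions.
#' @return Data frame: `from_stage`, `to_stage`, `quarter`, `value`,
#'   `finite`.
#' @export
selection_index <- function(to, from, smooth = FALSE) {
  stopifnot(inherits(to, "stage_cohort"), inherits(from, "stage_cohort"))
  pt <- to$P; pf <- from$P
  if (smooth) {
    if (anyNA(to$counts) || anyNA(from$counts)) {
      stop("Laplace smoothing needs count bookkeeping in both cohorts")
    }
    pt <- (to$counts + 0.5) / sum(to$counts + 0.5)
    pf <- (from$counts + 0.5) / sum(from$counts + 0.5)
  }
  v <- log10(pt / pf)
  data.frame(from_stage = from$stage, to_stage = to$stage,
             quarter = factor(lunar_quarters(),
                              levels = lunar_quarters()),
             value = as.numeric(v), finite = is.finite(v),
             stringsAsFactors = FALSE)
}

#' Selection indices for every stage transition
#'
#' Computes [selection_index()] for every ordered stage pair allowed
#' by the life-history graph egg -> settler -> juvenile ->
#' {female, primary_male} -> terminal-phase male, including composite
#' (skip-level) transitions; the two sex pathways at rank four are
#' alternatives, not successive stages, so no pair is formed between
#' them. For the full six-stage graph this yields 14 transitions.
#' Composite values equal the quarter-wise sum of the sequential
#' values along any path, by log additivity.
#'
#' @param cohorts List of [stage_cohort()] objects (any subset of the
#'   six stages, at least 2).
#' @param smooth Passed to [selection_index()].
#' @return Data frame of stacked [selection_index()] rows, with a
#'   `sequential` flag marking single-step transitions.
#' @export
selection_matrix <- function(cohorts, smooth = FALSE) {
  stopifnot(is.list(cohorts), length(cohorts) >= 2,
            all(vapply(cohorts, inherits, logical(1), "stage_cohort")))
  stg <- vapply(cohorts, function(x) x$stage, character(1))
  if (anyDuplicated(stg)) stop("duplicate stage in `cohorts`")
  names(cohorts) <- stg
  rk <- stage_rank(stg)
  ord <- order(rk, match(stg, stage_order()))
  stg <- stg[ord]; rk <- rk[ord]
  out <- list()
  for (i in seq_along(stg)) for (j in seq_along(stg)) {
    if (rk[j] <= rk[i]) next
    si <- selection_index(cohorts[[stg[j]]], cohorts[[stg[i]]],
                          smooth = smooth)
    si$sequential <- rk[j] - rk[i] == 1
    out[[length(out) + 1L]] <- si
  }
  do.call(rbind, out)
}

#' Settler rearing-environment summary by lunar quarter of birth
#'
#' Per birth quarter of the settler stage: mean settlement day
#' relative to the new moon, mean otolith radius at settlement (the
#' size proxy), mean age at settlement (PLD), and the proportions
#' settling offshore and in social groups. Quarters with no settlers
#' get `NA` cells and are flagged.
#'
#' @param cohort An `otl_cohort` whose truth table has stages
#'   assigned ([apply_life_history()]); stages `settler` and above
#'   all passed through settlement and are included.
#' @return Data frame with one row per quarter.
#' @export
settler_summary <- function(cohort) {
  stopifnot(inherits(cohort, "otl_cohort"))
  tr <- cohort$truth
  sel <- tr$stage_reached %in% c("settler", "juvenile", "adult")
  if (!any(sel)) stop("no settler records in cohort")
  tr <- tr[sel, ]
  rad <- NULL
  if (!is.null(cohort$increments)) {
    inc <- cohort$increments
    at_settle <- inc[inc$age_dph == inc$settlement_index, ]
    rad <- stats::setNames(at_settle$radius_um, at_settle$fish_id)
  }
  rows <- lapply(lunar_quarters(), function(q) {
    d <- tr[as.character(tr$birth_quarter) == q, ]
    if (nrow(d) == 0) {
      return(data.frame(quarter = q, n = 0L,
                        mean_settle_day_rel_new_moon = NA_real_,
                        mean_radius_at_settlement = NA_real_,
                        mean_age_at_settlement = NA_real_,
                        prop_offshore = NA_real_,
                        prop_grouped = NA_real_, empty = TRUE))
    }
    data.frame(quarter = q, n = nrow(d),
               mean_settle_day_rel_new_moon =
                 mean(d$settle_day_rel_new_moon),
               mean_radius_at_settlement =
                 if (is.null(rad)) NA_real_
                 else mean(rad[d$fish_id], na.rm = TRUE),
               mean_age_at_settlement = mean(d$pld),
               prop_offshore = mean(d$offshore),
               prop_grouped = mean(d$grouped), empty = FALSE)
  })
  out <- do.call(rbind, rows)
  out$quarter <- factor(out$quarter, levels = lunar_quarters())
  out
}
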