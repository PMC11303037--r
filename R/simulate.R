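# Synthetic cohort generator: lunar-concentrated spawning, moon-cued
# settlement, moonlight-modulated daily otolith increments, and a
# quarter-dependent life-history / sex-determination path.

# Deterministic per-fish substream seed. Arithmetic stays below 2^53
# so the modulus is exact in double precision; increasing n_spawned
# never changes the draws of earlier fish.
fish_stream <- function(seed, i, salt) {
  s <- (abs(as.numeric(seed)) %% 2147483647) * 69069 +
    as.numeric(i) * 1000003 + as.numeric(salt) * 10007
  as.integer(s %% 2147483629) + 1L
}

# Inverse-CDF sampler grid for a von Mises distribution centred on 0
# degrees (the new moon). Returns a function mapping u in (0,1) to an
# angle in degrees.
vm_inverse <- function(kappa) {
  if (kappa == 0) return(function(u) u * 360 - 180)
  ang <- seq(-180, 180, by = 0.25)
  dens <- exp(kappa * cos(ang * pi / 180))
  cdf <- cumsum(dens)
  cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  function(u) stats::approx(cdf, ang, xout = u, ties = "ordered")$y
}

# Settlement model: a larva with birth phase angle phi and latent
# duration pld0 is pulled (strength settle_snap) toward a settlement
# target tied to a new moon: the target sits settle_priority_rate
# days before the new moon per day of competency surplus (time the
# fish has been past pld_min), generating priority effects in which
# long-surplus (new-moon-born) fish arrive earliest, plus a global
# offset solved so the population expectation of realized PLD equals
# pld_mean (see settle_offset). The reference new moon is the
# candidate whose target lies closest to pld_mean, a deterministic
# function of birth phase, which keeps each quarter's settlement
# timing unimodal.
settle_pld <- function(phi, pld0, rel, p, offset) {
  syn <- p$cal$synodic_length
  s <- p$settle_snap
  nm0 <- (-phi / 360 * syn) %% syn
  cand <- nm0 + syn * (0:4)
  targ <- cand - p$settle_priority_rate * pmax(0, cand - p$pld_min)
  k <- which.min(abs(targ - p$pld_mean)) # offset-free: unique root below
  pc <- (1 - s) * pld0 + s * (targ[k] + offset) + rel
  as.integer(round(min(max(pc, p$pld_min), p$pld_max)))
}

.settle_cache <- new.env(parent = emptyenv())

# Solve the global settlement offset so that E[realized PLD] equals
# pld_mean under the configured birth-phase distribution. Uses a
# deterministic quadrature grid (no RNG) and caches per parameter
# combination.
settle_offset <- function(p) {
  if (p$settle_snap == 0) return(0)
  key <- paste(p$spawn, p$spawn_concentration, p$pld_mean, p$pld_sd,
               p$pld_min, p$pld_max, p$settle_snap,
               p$settle_priority_rate, p$settle_rel_sd,
               p$cal$synodic_length, sep = "|")
  hit <- .settle_cache[[key]]
  if (!is.null(hit)) return(hit)
  ang <- seq(0, 355, by = 5)
  w <- if (p$spawn == "lunar") {
    exp(p$spawn_concentration * cos(ang * pi / 180))
  } else rep(1, length(ang))
  w <- w / sum(w)
  pld0g <- p$pld_mean + p$pld_sd * stats::qnorm((seq_len(11) - 0.5) / 11)
  relg <- p$settle_rel_sd * stats::qnorm((seq_len(7) - 0.5) / 7)
  exp_pld <- function(off) {
    m <- 0
    for (i in seq_along(ang)) {
      acc <- 0
      for (x0 in pld0g) for (r in relg) {
        acc <- acc + settle_pld(ang[i], x0, r, p, off)
      }
      m <- m + w[i] * acc / (length(pld0g) * length(relg))
    }
    m
  }
  # The response is only monotone locally (large offsets wrap targets
  # to another cycle), so bracket on a grid near 0 before root-finding.
  grid <- seq(-10, 10, by = 1)
  fg <- vapply(grid, function(o) exp_pld(o) - p$pld_mean, numeric(1))
  br <- which(fg[-length(fg)] * fg[-1] <= 0)
  if (length(br)) {
    br <- br[which.min(abs(grid[br]))]
    off <- stats::uniroot(function(o) exp_pld(o) - p$pld_mean,
                          interval = grid[c(br, br + 1)],
                          tol = 5e-3)$root
  } else {
    off <- grid[which.min(abs(fg))]
  }
  assign(key, off, envir = .settle_cache)
  off
}

#' Simulate a cohort of otolith increment series with known truth
#'
#' Generates `n_spawned` larvae. Each fish receives a birth day drawn
#' from the configured lunar spawning distribution, a pelagic larval
#' duration produced by the moon-cued settlement model (truncated to
#' `[pld_min, pld_max]`, population mean calibrated to `pld_mean`),
#' and a daily otolith radius series in which increment width is the
#' age-declining base curve plus a sinusoidal moonlight term whose
#' phase tracks the fish's position in the lunar cycle, plus Gaussian
#' noise. Identical `params` (including `seed`) reproduce the cohort
#' exactly, and per-fish random streams mean a larger cohort extends,
#' rather than reshuffles, a smaller one.
#'
#' @param params A [sim_params()] object.
#' @param increments If `FALSE`, skip generating radius series (truth
#'   table only; useful for demographic experiments).
#' @return An object of class `otl_cohort`: a list with
#'   `increments` (long data frame: `fish_id`, `age_dph`, `radius_um`,
#'   `settlement_index`, `stage`, `capture_day`) and `truth` (one row
#'   per fish: `fish_id`, `birth_day`, `birth_quarter`, `pld`,
#'   `settle_day_rel_new_moon`, `offshore`, `grouped`, `group_size`,
#'   `stage_reached`, `sex_path`). Stage and sex fields are filled by
#'   [apply_life_history()]; here all fish are at stage `"egg"`.
#' @seealso [apply_life_history()], [write_cohort()]
#' @export
simulate_cohort <- function(params, increments = TRUE) {
  validate_sim_params(params)
  n <- params$n_spawned
  cal <- params$cal
  syn <- cal$synodic_length
  offset <- settle_offset(params)
  vinv <- vm_inverse(params$spawn_concentration)
  off_rad <- params$moon_phase_offset * pi / 180

  fish_id <- sprintf("F%05d", seq_len(n))
  birth_day <- numeric(n)
  birth_angle <- numeric(n)
  pld <- integer(n)
  rel_day <- numeric(n)
  offshore <- logical(n)
  grouped <- logical(n)
  group_size <- integer(n)
  inc_list <- if (increments) vector("list", n)

  for (i in seq_len(n)) {
    set.seed(fish_stream(params$seed, i, 1L))
    u <- stats::runif(4)
    pld0 <- stats::rnorm(1, params$pld_mean, params$pld_sd)
    rel <- stats::rnorm(1, 0, params$settle_rel_sd)
    g_extra <- stats::rpois(1, params$group_size_mean)
    eps <- stats::rnorm(params$pld_max, 0, params$noise_sd)

    ang <- if (params$spawn == "balanced") {
      (((i - 1) %% 4) * 90 - 45 + 90 * u[2]) %% 360
    } else {
      vinv(u[1]) %% 360
    }
    cyc <- floor(u[2] * params$n_cycles)
    if (params$spawn == "balanced") cyc <- floor(u[1] * params$n_cycles)
    birth_angle[i] <- ang
    birth_day[i] <- cal$epoch_new_moon + cyc * syn + ang / 360 * syn
    pld[i] <- settle_pld(ang, pld0, rel, params, offset)
    settle_day <- birth_day[i] + pld[i]
    rel_day[i] <- days_from_new_moon(settle_day, cal)
    q <- as.integer(nearest_quarter(ang))
    offshore[i] <- u[3] < params$p_offshore_given_quarter[q]
    grouped[i] <- u[4] < params$p_group_given_quarter[q]
    group_size[i] <- if (grouped[i]) 2L + g_extra else 1L

    if (increments) {
      ages <- seq_len(pld[i])
      inc <- params$base_growth_curve[ages] +
        params$moon_amp *
          sin(lunar_theta(ages, ang, cal) * pi / 180 + off_rad) +
        eps[ages]
      inc <- pmax(inc, params$min_increment)
      inc_list[[i]] <- data.frame(
        fish_id = fish_id[i], age_dph = ages, radius_um = cumsum(inc),
        settlement_index = pld[i], stage = "egg",
        capture_day = settle_day + 10,
        stringsAsFactors = FALSE)
    }
  }

  truth <- data.frame(
    fish_id = fish_id, birth_day = birth_day,
    birth_quarter = nearest_quarter(birth_angle),
    pld = pld, settle_day_rel_new_moon = rel_day,
    offshore = offshore, grouped = grouped, group_size = group_size,
    stage_reached = "egg", sex_path = "none",
    stringsAsFactors = FALSE)

  out <- list(
    increments = if (increments) do.call(rbind, inc_list) else NULL,
    truth = truth, params = params)
  class(out) <- "otl_cohort"
  out
}

#' @export
print.otl_cohort <- function(x, ...) {
  cat("<otl_cohort>", nrow(x$truth), "fish")
  if (!is.null(x$increments)) {
    cat(",", nrow(x$increments), "daily increments")
  }
  cat("\n  stages:")
  print(table(x$truth$stage_reached))
  invisible(x)
}

logit_term <- function(coef, x) if (x == 0) 0 else coef * x

#' Apply quarter-dependent survival and sex determination
#'
#' Walks each fish through the stage transitions egg -> settler ->
#' juvenile -> adult with survival probabilities that depend on lunar
#' quarter of birth, then determines the initial sexual phenotype of
#' adults with a logistic rule: the log-odds of maturing directly as a
#' primary male are a linear function of within-group size rank
#' (scaled to `[0, 1]`, using pelagic larval duration as the size
#' proxy against simulated group peers), a grouped-settlement
#' indicator, and an offshore (high site quality) indicator. A
#' configurable fraction of females and of primary males progresses
#' to terminal-phase male. All draws come from per-fish random
#' substreams keyed by `params$seed`.
#'
#' @param x An `otl_cohort` from [simulate_cohort()], or just its
#'   `truth` data frame.
#' @param params The [sim_params()] used to generate the cohort.
#' @return Same shape as `x`, with `stage_reached` and `sex_path`
#'   filled in (and, for a cohort, increment `stage`/`capture_day`
#'   updated: settlers are captured 10 d, juveniles 90 d and adults
#'   730 d after settlement).
#' @export
apply_life_history <- function(x, params) {
  validate_sim_params(params)
  truth <- if (inherits(x, "otl_cohort")) x$truth else x
  stopifnot(is.data.frame(truth), nrow(truth) >= 1)
  n <- nrow(truth)
  qi <- as.integer(factor(as.character(truth$birth_quarter),
                          levels = lunar_quarters()))
  cf <- params$sex_logit_coefs
  tpf <- params$tp_fraction
  a <- stats::pnorm((params$pld_min - params$pld_mean) / params$pld_sd)
  b <- stats::pnorm((params$pld_max - params$pld_mean) / params$pld_sd)

  stage <- character(n)
  sex <- rep("none", n)
  for (i in seq_len(n)) {
    set.seed(fish_stream(params$seed, i, 2L))
    u <- stats::runif(5)
    s <- "egg"
    if (u[1] < params$survival_by_quarter[qi[i]]) s <- "settler"
    if (s == "settler" &&
        u[2] < params$settler_survival_by_quarter[qi[i]]) s <- "juvenile"
    if (s == "juvenile" &&
        u[3] < params$juvenile_survival_by_quarter[qi[i]]) s <- "adult"
    stage[i] <- s
    if (s != "adult") next

    g <- truth$group_size[i]
    rank01 <- 0
    if (isTRUE(truth$grouped[i]) && g > 1) {
      # peers drawn from the marginal truncated-normal PLD pool;
      # longer larval duration => larger at settlement in this model
      peers <- stats::qnorm(a + stats::runif(g - 1) * (b - a)) *
        params$pld_sd + params$pld_mean
      rnk <- 1 + sum(peers > truth$pld[i])
      rank01 <- (g - rnk) / (g - 1)
    }
    eta <- logit_term(cf[[1]], 1) + logit_term(cf[[2]], rank01) +
      logit_term(cf[[3]], as.numeric(truth$grouped[i])) +
      logit_term(cf[[4]], as.numeric(truth$offshore[i]))
    pm <- u[4] < stats::plogis(eta)
    sex[i] <- if (pm) "primary_male" else "female"
    if ((pm && u[5] < tpf[["primary_male"]]) ||
        (!pm && u[5] < tpf[["female"]])) {
      sex[i] <- "terminal_phase_male"
    }
  }
  truth$stage_reached <- stage
  truth$sex_path <- sex

  if (inherits(x, "otl_cohort")) {
    x$truth <- truth
    if (!is.null(x$increments)) {
      idx <- match(x$increments$fish_id, truth$fish_id)
      x$increments$stage <- stage[idx]
      hold <- c(egg = 10, settler = 10, juvenile = 90, adult = 730)
      settle_day <- truth$birth_day[idx] + truth$pld[idx]
      x$increments$capture_day <- settle_day + hold[stage[idx]]
    }
    return(x)
  }
  truth
}
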