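test_that("default parameters encode the documented larval biology", {
  p <- default_params()
  expect_equal(p$pld_mean, 46)
  expect_equal(c(p$pld_min, p$pld_max), c(37, 61))
  # spawning mode at the new moon: the phase density is centred on 0
  expect_equal(p$spawn, "lunar")
  expect_gt(p$spawn_concentration, 0)
  # egg-to-settler survival lowest for NEW/WANING births
  sv <- p$survival_by_quarter
  expect_true(all(sv[c("NEW", "WANING")] < sv[c("WAXING", "FULL")]))
})

test_that("invalid parameters are rejected naming the offending field", {
  expect_error(sim_params(n_spawned = 0), "n_spawned")
  expect_error(sim_params(pld_min = 50, pld_mean = 46), "pld bounds")
  expect_error(sim_params(survival_by_quarter = c(0.5, 0.5, 0.5, 1.2)),
               "survival_by_quarter")
  expect_error(sim_params(settle_snap = 2), "settle_snap")
})

test_that("simulation is deterministic and per-fish streams are stable", {
  p <- sim_params(n_spawned = 12, seed = 99)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$truth, b$truth)
  expect_identical(a$increments, b$increments)
  # growing the cohort extends it without reshuffling earlier fish
  big <- simulate_cohort(sim_params(n_spawned = 20, seed = 99))
  expect_identical(big$truth[1:12, ], a$truth)
})

test_that("cohort bookkeeping and invariants hold", {
  p <- sim_params(n_spawned = 60, seed = 4)
  co <- cached_cohort("small60", p)
  expect_equal(nrow(co$truth), 60)
  expect_setequal(unique(co$increments$fish_id), co$truth$fish_id)
  # radii strictly increasing; PLDs inside truncation bounds
  for (id in co$truth$fish_id[1:10]) {
    r <- co$increments[co$increments$fish_id == id, ]
    expect_true(all(diff(r$radius_um[order(r$age_dph)]) > 0))
  }
  expect_true(all(co$truth$pld >= 37 & co$truth$pld <= 61))
  lh <- apply_life_history(co, p)
  cnt <- table(factor(lh$truth$stage_reached,
                      levels = c("egg", "settler", "juvenile", "adult")))
  n_at_least <- rev(cumsum(rev(cnt)))
  expect_true(all(diff(n_at_least) <= 0))
  expect_true(all(lh$truth$sex_path[lh$truth$stage_reached != "adult"] ==
                    "none"))
  expect_true(all(lh$truth$sex_path[lh$truth$stage_reached == "adult"] !=
                    "none"))
})

test_that("no lunar signal means identical growth regardless of quarter", {
  p <- sim_params(n_spawned = 16, moon_amp = 0, noise_sd = 0, seed = 2)
  co <- simulate_cohort(p)
  r5 <- co$increments[co$increments$age_dph == 5, "radius_um"]
  expect_equal(diff(range(r5)), 0)
  r40 <- co$increments[co$increments$age_dph == 40, "radius_um"]
  expect_equal(diff(range(r40)), 0)
})

test_that("spawn phase histogram peaks at the NEW quarter", {
  p <- sim_params(n_spawned = 400, seed = 8)
  co <- cached_cohort("spawn400", p)
  tab <- table(co$truth$birth_quarter)
  expect_equal(names(which.max(tab)), "NEW")
})

test_that("life-history degenerate configurations behave as contracts", {
  ones <- rep(1, 4)
  # all survive + sex logit forced hard negative -> all adults female
  p1 <- sim_params(n_spawned = 40, seed = 5,
                   survival_by_quarter = ones,
                   settler_survival_by_quarter = ones,
                   juvenile_survival_by_quarter = ones,
                   sex_logit_coefs = c(-Inf, 0, 0, 0),
                   tp_fraction = c(female = 0, primary_male = 0))
  t1 <- apply_life_history(simulate_cohort(p1, increments = FALSE), p1)$truth
  expect_true(all(t1$stage_reached == "adult"))
  expect_true(all(t1$sex_path == "female"))
  # zero survival at the first transition -> no settlers
  p2 <- sim_params(n_spawned = 40, seed = 5,
                   survival_by_quarter = rep(0, 4))
  t2 <- apply_life_history(simulate_cohort(p2, increments = FALSE), p2)$truth
  expect_true(all(t2$stage_reached == "egg"))
  # grouping is what makes primary males: all-solitary cohort has none
  p3 <- sim_params(n_spawned = 40, seed = 5,
                   survival_by_quarter = ones,
                   settler_survival_by_quarter = ones,
                   juvenile_survival_by_quarter = ones,
                   p_group_given_quarter = rep(0, 4),
                   sex_logit_coefs = c(-20, 0, 40, 0),
                   tp_fraction = c(female = 0, primary_male = 0))
  t3 <- apply_life_history(simulate_cohort(p3, increments = FALSE), p3)$truth
  expect_true(all(t3$sex_path == "female"))
})

test_that("cohort CSV round trip preserves the structures", {
  p <- sim_params(n_spawned = 8, seed = 21)
  co <- apply_life_history(simulate_cohort(p), p)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$truth$birth_quarter, co$truth$birth_quarter)
  expect_equal(back$truth$pld, co$truth$pld)
  expect_equal(back$truth$birth_day, co$truth$birth_day, tolerance = 1e-9)
  expect_equal(back$increments$radius_um, co$increments$radius_um,
               tolerance = 1e-9)
  expect_equal(back$increments$stage, co$increments$stage)
})

test_that("cohort reader validates structure with helpful errors", {
  dir <- withr::local_tempdir()
  # empty cohort round-trips
  empty <- structure(list(increments = NULL,
                          truth = data.frame(
                            fish_id = character(0), birth_day = numeric(0),
                            birth_quarter = character(0), pld = integer(0),
                            settle_day_rel_new_moon = numeric(0),
                            offshore = logical(0), grouped = logical(0),
                            group_size = integer(0),
                            stage_reached = character(0),
                            sex_path = character(0))),
                     class = "otl_cohort")
  write_cohort(empty, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$truth), 0)
  expect_equal(nrow(back$increments), 0)

  # non-monotone radii are a validation error
  p <- sim_params(n_spawned = 3, seed = 1)
  co <- simulate_cohort(p)
  bad <- co
  i <- which(bad$increments$fish_id == "F00002" &
               bad$increments$age_dph == 10)
  bad$increments$radius_um[i] <- 0
  write_cohort(bad, dir)
  expect_error(read_cohort(dir), "strictly increasing.*F00002")

  # malformed numeric cells are reported with their line number
  write_cohort(co, dir)
  lines <- readLines(file.path(dir, "increments.csv"))
  parts <- strsplit(lines[4], ",")[[1]]
  parts[3] <- "\"oops\""
  lines[4] <- paste(parts, collapse = ",")
  writeLines(lines, file.path(dir, "increments.csv"))
  expect_error(read_cohort(dir), "radius_um.*line 4")
})

test_that("realized PLD distribution honors its generator contract", {
  p <- sim_params(n_spawned = 300, seed = 13)
  co <- simulate_cohort(p, increments = FALSE)
  expect_lt(abs(mean(co$truth$pld) - 46), 1)
  expect_true(all(co$truth$pld >= 37 & co$truth$pld <= 61))
  # settlement is pulled into the dark-night window before the new
  # moon: every quarter's mean arrival is pre-new-moon, and the
  # spread of arrival days is far narrower than without the lunar cue
  rel <- tapply(co$truth$settle_day_rel_new_moon, co$truth$birth_quarter,
                mean)
  expect_true(all(rel < 0))
  p_free <- sim_params(n_spawned = 300, seed = 13, settle_snap = 0,
                       settle_rel_sd = 0)
  free <- simulate_cohort(p_free, increments = FALSE)
  by_q <- function(tr) tapply(tr$settle_day_rel_new_moon,
                              tr$birth_quarter, sd)
  expect_true(all(by_q(co$truth) < by_q(free$truth)))
})

test_that("settler environments are shaped by birth quarter", {
  p <- sim_params(n_spawned = 400, seed = 8)
  co <- cached_cohort("spawn400", p)
  lh <- apply_life_history(co, p)
  ss <- settler_summary(lh)
  # new-moon-born settlers arrive earliest relative to the new moon,
  # oldest, and largest (priority effect ordering)
  expect_equal(which.min(ss$mean_settle_day_rel_new_moon), 1L)
  expect_equal(which.max(ss$mean_age_at_settlement), 1L)
  expect_equal(which.max(ss$mean_radius_at_settlement), 1L)
  expect_true(all(ss$prop_offshore >= 0 & ss$prop_offshore <= 1,
                  na.rm = TRUE))
  expect_true(all(ss$prop_grouped >= 0 & ss$prop_grouped <= 1,
                  na.rm = TRUE))
})
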