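geom <- maze_geometry()

test_that("behavior and design constructors validate their invariants", {
  expect_error(behavior_params("x", p_alternate = 1.5), "p_alternate")
  expect_error(behavior_params("x", mean_speed = -1), "non-negative")
  expect_error(study_design(trial_duration = 0), "trial_duration")
  expect_error(study_design(n_fish_per_group = 0), "n_fish_per_group")
  expect_error(simulate_track(behavior_params("x"), geom, duration = -5),
               "invalid-argument")
})

test_that("simulated tracks have the contracted sample count and stay inside the maze", {
  bp <- behavior_params("x", p_alternate = 0.6)
  tr <- simulate_track(bp, geom, duration = 97, rate = 7, seed = 3)
  expect_equal(nrow(tr), ceiling(97 * 7))
  z <- assign_zones(tr, geom)
  expect_false(any(z$snapped))  # point-in-polygon over every sample
})

test_that("a stationary fish never leaves the start position", {
  bp <- behavior_params("x", mean_speed = 0, speed_sd = 0, freeze_rate = 0)
  tr <- simulate_track(bp, geom, 60, 10, seed = 1)
  expect_equal(nrow(unique(tr[, c("x_cm", "y_cm")])), 1L)
  expect_equal(locomotor_endpoints(tr)$distance_cm, 0)
})

test_that("forced alternation yields SAB -> 100 and planted order round-trips", {
  bp <- behavior_params("x", p_alternate = 1)
  tr <- simulate_track(bp, geom, 600, 5, seed = 2)
  sab <- compute_sab(extract_arm_entries(assign_zones(tr, geom)))
  expect_gt(sab$n_entries, 10)
  expect_equal(sab$sab_percent, 100)

  forced <- c("A", "B", "C", "A")
  trf <- simulate_track(behavior_params("x", turn_noise = 0), geom,
                        duration = 120, rate = 10, seed = 5,
                        forced_entries = forced)
  got <- extract_arm_entries(assign_zones(trf, geom))
  expect_identical(got$arms, forced)
})

test_that("chance-level p_alternate gives mean SAB ~ 50% over a large cohort", {
  # 2-choice rule: analytic chance rate of alternation is p_alternate itself;
  # at the chance level 0.5 downstream SAB% must average ~50.
  bp <- behavior_params("x", p_alternate = 0.5)
  sabs <- vapply(1:200, function(i) {
    tr <- simulate_track(bp, geom, 300, 5, seed = 1000 + i)
    compute_sab(extract_arm_entries(assign_zones(tr, geom)))$sab_percent
  }, numeric(1))
  expect_equal(mean(sabs, na.rm = TRUE), 50, tolerance = 0.05)
})

test_that("decreasing p_alternate strictly decreases mean cohort SAB", {
  mean_sab <- function(p, off) {
    mean(vapply(1:60, function(i) {
      tr <- simulate_track(behavior_params("x", p_alternate = p), geom,
                           300, 5, seed = off + i)
      compute_sab(extract_arm_entries(assign_zones(tr, geom)))$sab_percent
    }, numeric(1)), na.rm = TRUE)
  }
  s <- c(mean_sab(0.25, 10), mean_sab(0.5, 20), mean_sab(0.85, 30))
  expect_true(all(diff(s) > 0))
})

test_that("simulate_cohort counts, ids and determinism honour the contract", {
  design <- study_design(doses = c("a", "b", "c"), days = c("Day1", "Day2"),
                         n_fish_per_group = 10, trial_duration = 20,
                         sample_rate = 5, seed = 9)
  params <- sapply(c("a", "b", "c"), function(d) behavior_params(d),
                   simplify = FALSE)
  st1 <- simulate_cohort(design, params, geom)
  expect_equal(length(unique(paste(st1$tracks$fish_id, st1$tracks$day))), 60L)
  expect_equal(length(unique(st1$tracks$fish_id)), 30L)
  st2 <- simulate_cohort(design, params, geom)
  expect_identical(st1$tracks, st2$tracks)  # bitwise reproducibility
  expect_error(simulate_cohort(design, params[1:2], geom), "configuration")
})

test_that("mortality simulation obeys the probit model and determinism", {
  expect_error(simulate_mortality(probit_slope = 0), "probit_slope")
  # probit median: huge n at the true LD50, no control mortality
  mt <- simulate_mortality(doses_ug = c(0, 292), n_per_group = 200000,
                           true_ld50 = 292, probit_slope = 2,
                           control_rate = 0, seed = 4)
  expect_equal(mt$deaths[2] / mt$n[2], 0.5, tolerance = 0.01)
  m1 <- simulate_mortality(seed = 11)
  m2 <- simulate_mortality(seed = 11)
  expect_identical(m1, m2)
})

test_that("IAT simulation plants the paired effect and the non-avoiders", {
  # null case: no learning, no noise -> identical pairs
  r0 <- simulate_iat(10, learned_delta = 0, noise_sd = 0, seed = 2)
  expect_equal(r0$train_latency_s, r0$test_latency_s)
  # planted non-avoiders exceed the 180-s cutoff on the training phase
  r1 <- simulate_iat(10, nonavoider_rate = 0.2, seed = 3)
  expect_equal(sum(r1$nonavoider), 2L)
  expect_true(all(r1$train_latency_s[r1$nonavoider] > 180))
  expect_true(all(r1$train_latency_s[!r1$nonavoider] <= 180))
})

test_that("planted learned_delta powers the paired t-test", {
  hits <- vapply(1:100, function(i) {
    r <- simulate_iat(15, learned_delta = 40, noise_sd = 10, seed = 100 + i)
    compare_paired(r$train_latency_s, r$test_latency_s)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("track tables round-trip through the CSV dialect", {
  design <- study_design(doses = "a", days = "Day1", n_fish_per_group = 2,
                         trial_duration = 10, sample_rate = 5, seed = 3)
  st <- simulate_cohort(design, list(a = behavior_params("a")), geom)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracks(st, f)
  back <- read_tracks(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$x_cm,
               st$tracks[fish_id == attr(back[[1]], "fish_id")]$x_cm)
})
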