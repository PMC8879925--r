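geom <- maze_geometry()

make_zone_df <- function(zones, dt = 0.1) {
  data.frame(time_s = seq_along(zones) * dt, zone = zones,
             snapped = FALSE)
}

test_that("read_tracks groups, sorts, drops NA rows and reports", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(time_s = c(0.2, 0.1, 0.1, 0.2, 0.3),
                   x_cm = c(1, 2, 3, NA, 5), y_cm = c(1, 2, 3, 4, 5),
                   fish_id = c("f1", "f1", "f2", "f2", "f2"),
                   day = "Day1", dose = "control")
  write.csv(df, f, row.names = FALSE)
  tracks <- read_tracks(f)
  expect_length(tracks, 2L)
  expect_equal(attr(tracks, "report")$dropped, 1L)
  expect_equal(tracks[["f1|Day1"]]$time_s, c(0.1, 0.2))  # time-sorted
  expect_error(read_tracks(withr::local_tempfile()), "format error")
  # missing column
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, -2], f2, row.names = FALSE)
  expect_error(read_tracks(f2), "missing column")
  # header-only file
  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[0, ], f3, row.names = FALSE)
  expect_warning(out <- read_tracks(f3), "empty")
  expect_length(out, 0L)
})

test_that("arm entries require dwell and collapse duplicates", {
  z <- make_zone_df(c(rep("A", 20), "junction", rep("B", 20)))
  expect_identical(extract_arm_entries(z, min_dwell = 0.5)$arms, c("A", "B"))
  # 1-sample flicker into C between A and B is ignored
  z2 <- make_zone_df(c(rep("A", 20), "C", rep("B", 20)))
  expect_identical(extract_arm_entries(z2, min_dwell = 0.5)$arms, c("A", "B"))
  # junction dip back into the same arm does not recount
  z3 <- make_zone_df(c(rep("A", 20), rep("junction", 5), rep("A", 20),
                       rep("B", 20)))
  expect_identical(extract_arm_entries(z3, min_dwell = 0.5)$arms, c("A", "B"))
  expect_error(extract_arm_entries(z, min_dwell = -1), "min_dwell")
})

test_that("compute_sab matches the hand-enumerated cases", {
  expect_equal(compute_sab(c("A", "B", "C", "A", "B", "C"))$sab_percent, 100)
  expect_equal(compute_sab(c("A", "B", "A", "B", "A"))$sab_percent, 0)
  expect_equal(compute_sab(c("A", "B", "C", "A", "C", "B"))$sab_percent, 75)
  short <- compute_sab(c("A", "B"))
  expect_false(short$defined)
  expect_true(is.na(short$sab_percent))
})

test_that("compute_sab equals the brute-force window enumerator on random sequences", {
  withr::local_seed(42)
  for (i in 1:300) {
    arms <- random_arm_sequence(sample(3:50, 1))
    expect_equal(compute_sab(arms)$sab_percent, brute_force_sab(arms))
  }
})

test_that("SAB is invariant under arm relabeling", {
  withr::local_seed(7)
  perms <- list(c(A = "B", B = "C", C = "A"), c(A = "C", B = "A", C = "B"),
                c(A = "A", B = "C", C = "B"))
  for (i in 1:50) {
    arms <- random_arm_sequence(sample(5:40, 1))
    base <- compute_sab(arms)$sab_percent
    for (p in perms) {
      expect_equal(compute_sab(unname(p[arms]))$sab_percent, base)
    }
  }
})

test_that("locomotor endpoints match closed forms", {
  # stationary 600-s track: zero distance, one bout covering the track
  tr0 <- data.frame(time_s = seq(0, 600, by = 1), x_cm = 3, y_cm = 3)
  l0 <- locomotor_endpoints(tr0)
  expect_equal(l0$distance_cm, 0)
  expect_equal(l0$n_freezing_bouts, 1L)
  expect_equal(l0$total_freeze_s, 600)
  # straight line at constant 5 cm/s
  tr1 <- data.frame(time_s = seq(0, 10, by = 0.1),
                    x_cm = 5 * seq(0, 10, by = 0.1), y_cm = 0)
  l1 <- locomotor_endpoints(tr1, freeze_speed_thresh = 1)
  expect_equal(l1$mean_speed_cm_s, 5, tolerance = 1e-9)
  expect_equal(l1$n_freezing_bouts, 0L)
  # single-sample track is flagged undefined
  expect_false(locomotor_endpoints(tr1[1, ])$defined)
})

test_that("planted freezing rate is recovered within binomial noise", {
  bp <- behavior_params("x", freeze_rate = 2, freeze_duration = 4,
                        turn_noise = 0.3)
  got <- vapply(1:30, function(i) {
    tr <- simulate_track(bp, geom, 600, 5, seed = 200 + i)
    c(locomotor_endpoints(tr, freeze_speed_thresh = 0.5,
                          freeze_min_dur = 2)$n_freezing_bouts,
      attr(tr, "truth")$n_freezes)
  }, numeric(2))
  # ~20 planted bouts per 10-min trial; detection may merge overlaps
  expect_equal(mean(got[1, ]), mean(got[2, ]), tolerance = 0.15)
  expect_equal(mean(got[2, ]), 20, tolerance = 0.2)
})

test_that("SAB and locomotion are uncorrelated in a shared-kinematics cohort", {
  # same kinematics, varying alternation propensity: r(SAB, distance) ~ 0
  withr::local_seed(1)
  ps <- runif(40, 0.3, 0.9)
  rows <- t(vapply(seq_along(ps), function(i) {
    tr <- simulate_track(behavior_params("x", p_alternate = ps[i]), geom,
                         300, 5, seed = 400 + i)
    c(compute_sab(extract_arm_entries(assign_zones(tr, geom)))$sab_percent,
      locomotor_endpoints(tr)$distance_cm)
  }, numeric(2)))
  ct <- correlate(rows[, 1], rows[, 2])
  expect_lt(abs(ct$r), 0.35)
  expect_gt(ct$p_value, 0.05)
})

test_that("score_tracks summarises a cohort with undefined-SAB accounting", {
  design <- study_design(doses = "a", days = "Day1", n_fish_per_group = 3,
                         trial_duration = 60, sample_rate = 5, seed = 5)
  st <- simulate_cohort(design, list(a = behavior_params("a")), geom)
  ep <- score_tracks(st, geom)
  expect_equal(nrow(ep), 3L)
  expect_true(all(c("fish_id", "day", "dose", "n_entries", "sab_percent",
                    "distance_cm", "mean_speed", "n_freezes") %in% names(ep)))
  expect_identical(attr(ep, "n_undefined_sab"), sum(is.na(ep$sab_percent)))
})
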