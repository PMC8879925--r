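#' Behavioural parameter set for one dose group
#'
#' Encodes the planted effect structure of a simulated dose group: swim
#' kinematics (speed distribution, freezing bouts) and the spontaneous
#' alternation propensity `p_alternate` — the probability that, at a
#' junction crossing with two distinct previously visited arms, the fish
#' enters the arm different from both. By construction the expected
#' downstream SAB% of a group equals `100 * p_alternate`.
#'
#' @param dose_label group label, e.g. `"control"`, `"100ug"`, `"200ug"`.
#' @param mean_speed mean swim speed, cm/s, > 0 (or 0 for a stationary fish).
#' @param speed_sd per-sample speed SD, cm/s, >= 0.
#' @param freeze_rate freezing bouts per minute, >= 0.
#' @param freeze_duration duration of one freezing bout, s, >= 0.
#' @param p_alternate alternation probability in `[0, 1]`.
#' @param turn_noise heading noise, radians, >= 0; controls lateral
#'   wobble of the swim path around the arm axis.
#' @return an object of class `behavior_params`.
#' @export
behavior_params <- function(dose_label, mean_speed = 6, speed_sd = 2,
                            freeze_rate = 0.5, freeze_duration = 3,
                            p_alternate = 0.7, turn_noise = 0.5) {
  if (!is.numeric(p_alternate) || p_alternate < 0 || p_alternate > 1) {
    stop_invalid("invalid-argument: p_alternate must be in [0, 1]")
  }
  vals <- c(mean_speed = mean_speed, speed_sd = speed_sd,
            freeze_rate = freeze_rate, freeze_duration = freeze_duration,
            turn_noise = turn_noise)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_invalid("invalid-argument: rates, speeds and noise must be finite and non-negative")
  }
  structure(list(dose_label = as.character(dose_label),
                 mean_speed = mean_speed, speed_sd = speed_sd,
                 freeze_rate = freeze_rate, freeze_duration = freeze_duration,
                 p_alternate = p_alternate, turn_noise = turn_noise),
            class = "behavior_params")
}

#' Study design for a simulated cohort
#'
#' @param doses character vector of dose labels.
#' @param days character vector of day labels (default `c("Day1","Day2")`).
#' @param n_fish_per_group fish per dose group (>= 1); the same fish are
#'   re-tested on every day.
#' @param trial_duration trial length, s, > 0 (default 600 = 10 min).
#' @param sample_rate positional sampling rate, Hz, > 0 (default 25).
#' @param seed master seed for the cohort.
#' @return an object of class `study_design`.
#' @export
study_design <- function(doses = c("control", "100ug", "200ug"),
                         days = c("Day1", "Day2"),
                         n_fish_per_group = 10,
                         trial_duration = 600, sample_rate = 25,
                         seed = 1L) {
  if (trial_duration <= 0 || sample_rate <= 0) {
    stop_invalid("invalid-argument: trial_duration and sample_rate must be > 0")
  }
  if (n_fish_per_group < 1) stop_invalid("invalid-argument: n_fish_per_group must be >= 1")
  structure(list(doses = as.character(doses), days = as.character(days),
                 n_fish_per_group = as.integer(n_fish_per_group),
                 trial_duration = trial_duration, sample_rate = sample_rate,
                 seed = as.integer(seed)),
            class = "study_design")
}

# Draw an arm-entry sequence of length n_visits under the alternation rule:
# with two distinct previous arms, the alternating arm (different from both)
# is chosen with probability p, otherwise the fish returns to the previous
# arm; with fewer than two distinct previous arms the choice is uniform over
# the two non-current arms. E[SAB%] = 100 * p exactly.
draw_entry_sequence <- function(n_visits, p_alternate, labels) {
  if (n_visits <= 0) return(character(0))
  out <- character(n_visits)
  out[1] <- sample(labels, 1L)
  if (n_visits >= 2) out[2] <- sample(setdiff(labels, out[1]), 1L)
  if (n_visits >= 3) {
    for (k in 3:n_visits) {
      prev <- out[k - 1]; prev2 <- out[k - 2]
      if (prev != prev2) {
        alt <- setdiff(labels, c(prev, prev2))
        out[k] <- if (stats::runif(1) < p_alternate) alt else prev2
      } else {
        out[k] <- sample(setdiff(labels, prev), 1L)
      }
    }
  }
  out
}

#' Simulate one Y-maze swim track
#'
#' Discrete-time path-following model: the fish shuttles between the
#' junction centroid and arm way-points (at 90% of the arm length), with a
#' per-sample speed process (Gaussian speed, Poisson freezing bouts of
#' fixed duration) and an AR(1) lateral wobble clamped inside the maze
#' polygons. Arm choice at each junction crossing follows the alternation
#' rule of [behavior_params()], so the planted `p_alternate` is the ground
#' truth for downstream SAB scoring.
#'
#' @param params a [behavior_params()].
#' @param geometry a [maze_geometry()].
#' @param duration trial length, s, > 0.
#' @param rate sampling rate, Hz, > 0.
#' @param seed integer seed; the track is a pure function of its arguments.
#' @param forced_entries optional character vector of arm labels forcing
#'   the exact visit order (used for round-trip testing); overrides the
#'   stochastic arm choice.
#' @return a `data.frame` (`time_s`, `x_cm`, `y_cm`) of
#'   `ceiling(duration * rate)` rows with attributes `truth` (a list with
#'   the planted `entry_arms`, number of freezing bouts `n_freezes`, and
#'   per-sample speeds) and class `fish_track`.
#' @export
simulate_track <- function(params, geometry, duration = 600, rate = 25,
                           seed = 1L, forced_entries = NULL) {
  stopifnot(inherits(params, "behavior_params"),
            inherits(geometry, "maze_geometry"))
  if (!is.numeric(duration) || duration <= 0 || !is.numeric(rate) || rate <= 0) {
    stop_invalid("invalid-argument: duration and rate must be > 0")
  }
  n <- ceiling(duration * rate)
  dt <- 1 / rate
  with_seed(seed, {
    ## speed process
    v <- stats::rnorm(n, params$mean_speed, params$speed_sd)
    v <- pmax(v, 0)
    n_bouts <- if (params$freeze_rate > 0) {
      stats::rpois(1, params$freeze_rate * duration / 60)
    } else 0L
    if (n_bouts > 0 && params$freeze_duration > 0) {
      starts <- sort(stats::runif(n_bouts, 0, max(duration - params$freeze_duration, 0)))
      t_s <- (seq_len(n) - 1) * dt
      for (s0 in starts) v[t_s >= s0 & t_s < s0 + params$freeze_duration] <- 0
    } else {
      starts <- numeric(0)
    }
    s <- cumsum(v * dt)  # path distance at each sample

    ## way-point path from the arm-entry process
    leg <- geometry$apothem + 0.9 * geometry$arm_length
    n_visits_needed <- max(ceiling(s[n] / (2 * leg)) + 2L, 1L)
    entries <- if (!is.null(forced_entries)) {
      as.character(forced_entries)
    } else {
      draw_entry_sequence(n_visits_needed, params$p_alternate,
                          geometry$arm_labels)
    }
    path_len <- length(entries) * 2 * leg
    s <- pmin(s, path_len - 1e-9)

    visit_idx <- pmin(floor(s / (2 * leg)) + 1L, length(entries))
    d_in_visit <- s - (visit_idx - 1L) * 2 * leg
    r <- ifelse(d_in_visit <= leg, d_in_visit, 2 * leg - d_in_visit)  # radial dist
    arm_i <- match(entries[visit_idx], geometry$arm_labels)

    ## lateral wobble: AR(1) over moving samples only (a frozen or
    ## stationary fish holds its position exactly), clamped to the local
    ## corridor width
    margin <- 0.06 * geometry$arm_width
    off <- numeric(n)
    moving <- v > 0
    if (params$turn_noise > 0 && any(moving)) {
      rho <- 0.95
      sd_stat <- min(params$turn_noise, 1.2) * (geometry$arm_width / 2 - margin) * 0.6
      innov <- stats::rnorm(sum(moving), 0, sd_stat * sqrt(1 - rho^2))
      off_m <- as.numeric(stats::filter(innov, rho, method = "recursive"))
      off <- c(0, off_m)[cumsum(moving) + 1L]  # last-observation carry-forward
    }
    half <- lateral_halfwidth(geometry, r, margin)
    off <- pmin(pmax(off, -half), half)
    ## clamp radial coordinate inside the arm (waypoint already at 0.9 L)
    r <- pmin(r, geometry$apothem + geometry$arm_length - margin)

    x <- r * geometry$axes[arm_i, 1] + off * geometry$perps[arm_i, 1]
    y <- r * geometry$axes[arm_i, 2] + off * geometry$perps[arm_i, 2]

    ## arms actually penetrated beyond the mouth (ground truth for entries)
    reached <- unique(visit_idx[r > geometry$apothem + 0.5])
    truth_entries <- entries[sort(reached)]

    tr <- data.frame(time_s = (seq_len(n) - 1) * dt, x_cm = x, y_cm = y)
    attr(tr, "truth") <- list(entry_arms = truth_entries,
                              planned_entries = entries,
                              n_freezes = length(starts),
                              freeze_starts = starts,
                              speeds = v)
    class(tr) <- c("fish_track", "data.frame")
    tr
  })
}

#' Simulate a full multi-day cohort
#'
#' One track per fish per day. Fish identities are stable across days and
#' per-fish random streams are derived deterministically from the master
#' seed and the fish index, so enlarging the cohort does not reshuffle
#' existing fish.
#'
#' @param design a [study_design()].
#' @param params_by_group named list of [behavior_params()], one per dose
#'   label in `design$doses`. A configuration error is raised if a dose has
#'   no parameter set.
#' @param geometry a [maze_geometry()] (default standard maze).
#' @return an object of class `study_dataset`: `$tracks` is a
#'   `data.table` with columns `time_s, x_cm, y_cm, fish_id, day, dose`;
#'   `$truth` a per-fish/day list of planted ground truth; plus the design,
#'   params and geometry.
#' @export
simulate_cohort <- function(design, params_by_group, geometry = maze_geometry()) {
  stopifnot(inherits(design, "study_design"))
  missing_doses <- setdiff(design$doses, names(params_by_group))
  if (length(missing_doses)) {
    stop_invalid("configuration error: no behavior_params for dose(s) %s",
                 paste(missing_doses, collapse = ", "))
  }
  pieces <- list()
  truth <- list()
  fish_counter <- 0L
  for (dose in design$doses) {
    for (f in seq_len(design$n_fish_per_group)) {
      fish_counter <- fish_counter + 1L
      fish_id <- sprintf("%s_f%02d", dose, f)
      for (di in seq_along(design$days)) {
        day <- design$days[di]
        seed_f <- derive_seed(design$seed, fish_counter * 1000L + di)
        tr <- simulate_track(params_by_group[[dose]], geometry,
                             duration = design$trial_duration,
                             rate = design$sample_rate, seed = seed_f)
        key <- paste(fish_id, day, sep = "|")
        truth[[key]] <- attr(tr, "truth")
        dtab <- data.table::as.data.table(unclass(tr)[c("time_s", "x_cm", "y_cm")])
        dtab[, `:=`(fish_id = fish_id, day = day, dose = dose)]
        pieces[[length(pieces) + 1L]] <- dtab
      }
    }
  }
  tracks <- data.table::rbindlist(pieces)
  structure(list(tracks = tracks, truth = truth, design = design,
                 params_by_group = params_by_group, geometry = geometry),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("study_dataset: %d doses x %d days x %d fish/group, %d samples\n",
              length(x$design$doses), length(x$design$days),
              x$design$n_fish_per_group, nrow(x$tracks)))
  invisible(x)
}

#' Simulate a dose-group mortality table
#'
#' Deaths are binomial with per-dose probability from a probit model on
#' log10 dose, composed with a baseline control lethality as independent
#' risks: `p_total = control_rate + (1 - control_rate) * p_dose`, so an
#' Abbott-style correction recovers `p_dose` exactly in expectation. Dose 0
#' uses `control_rate` alone. Doses are in ug per ~1-g fish, i.e.
#' numerically equal to mg/kg.
#'
#' @param doses_ug numeric doses (ug/fish), >= 0; may include 0 (control).
#' @param n_per_group fish per dose group (recycled if scalar), >= 1.
#' @param true_ld50 true LD50 in mg/kg, > 0.
#' @param probit_slope probit units per log10 dose, > 0.
#' @param control_rate baseline lethality fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return a `data.frame` with columns
#'   `dose_ug, dose_mg_per_kg, n, deaths` (class `mortality_table`).
#' @export
simulate_mortality <- function(doses_ug = c(0, 50, 100, 200, 400),
                               n_per_group = 20, true_ld50 = 292,
                               probit_slope = 2, control_rate = 0.05,
                               seed = 1L) {
  if (probit_slope <= 0) stop_invalid("invalid-argument: probit_slope must be > 0")
  if (control_rate < 0 || control_rate >= 1) {
    stop_invalid("invalid-argument: control_rate must be in [0, 1)")
  }
  if (any(doses_ug < 0) || any(n_per_group < 1)) {
    stop_invalid("invalid-argument: doses must be >= 0 and n >= 1")
  }
  n_per_group <- rep_len(as.integer(n_per_group), length(doses_ug))
  p_dose <- ifelse(doses_ug > 0,
                   stats::pnorm(probit_slope * (log10(doses_ug) - log10(true_ld50))),
                   0)
  p_tot <- control_rate + (1 - control_rate) * p_dose
  deaths <- with_seed(seed, stats::rbinom(length(doses_ug), n_per_group, p_tot))
  mortality_table(dose_ug = doses_ug, n = n_per_group, deaths = deaths)
}

#' Simulate paired inhibitory-avoidance latencies
#'
#' Each fish gets a training-phase latency and a testing-phase latency
#' `test = train + learned_delta + noise`, clipped at 0. A
#' `nonavoider_rate` fraction of fish are planted as non-avoiders whose
#' training latency exceeds the 180-s cutoff (they never enter the deep
#' zone in time and are expected to be excluded downstream).
#'
#' @param n number of fish, >= 1.
#' @param learned_delta mean latency increase after training, s.
#' @param noise_sd SD of the paired noise, s, >= 0.
#' @param nonavoider_rate fraction of planted non-avoiders in `[0, 1]`.
#' @param base_latency mean (and shape) of the baseline training latency, s.
#' @param group group label attached to all records.
#' @param seed integer seed.
#' @return a `data.frame` `fish_id, group, train_latency_s, test_latency_s,
#'   nonavoider` (class `iat_records`). `nonavoider` is the planted flag.
#' @export
simulate_iat <- function(n, learned_delta = 40, noise_sd = 10,
                         nonavoider_rate = 0, base_latency = 30,
                         group = "control", seed = 1L) {
  if (n < 1) stop_invalid("invalid-argument: n must be >= 1")
  if (noise_sd < 0) stop_invalid("invalid-argument: noise_sd must be >= 0")
  if (nonavoider_rate < 0 || nonavoider_rate > 1) {
    stop_invalid("invalid-argument: nonavoider_rate must be in [0, 1]")
  }
  with_seed(seed, {
    n_na <- round(nonavoider_rate * n)
    flags <- rep(FALSE, n)
    if (n_na > 0) flags[sample.int(n, n_na)] <- TRUE
    train <- pmax(stats::rnorm(n, base_latency, base_latency / 3), 0.5)
    train[flags] <- stats::runif(sum(flags), 181, 300)
    test <- pmax(train + learned_delta + stats::rnorm(n, 0, noise_sd), 0)
    data.frame(fish_id = sprintf("%s_f%02d", group, seq_len(n)),
               group = group,
               train_latency_s = train, test_latency_s = test,
               nonavoider = flags) |>
      structure(class = c("iat_records", "data.frame"))
  })
}

#' Write a cohort's tracks as a flat CSV (EthoVision-export-like dialect)
#'
#' Header: `time_s,x_cm,y_cm,fish_id,day,dose`.
#' @param study a `study_dataset` (or its `$tracks` table).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(study, path) {
  tab <- if (inherits(study, "study_dataset")) study$tracks else study
  data.table::fwrite(tab[, c("time_s", "x_cm", "y_cm", "fish_id", "day", "dose")],
                     path)
  invisible(path)
}

#' Write a mortality table as CSV (`dose_ug,dose_mg_per_kg,n,deaths`)
#' @param table a `mortality_table`.
#' @param path output CSV path.
#' @export
write_mortality <- function(table, path) {
  data.table::fwrite(table, path)
  invisible(path)
}

#' Write IAT records as CSV (`fish_id,group,train_latency_s,test_latency_s`)
#' @param records an `iat_records` data frame.
#' @param path output CSV path.
#' @export
write_iat <- function(records, path) {
  data.table::fwrite(records[, c("fish_id", "group", "train_latency_s",
                                 "test_latency_s")], path)
  invisible(path)
}
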