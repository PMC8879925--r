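#' Read a flat track CSV into a list of per-fish/day tracks
#'
#' Expects the dialect written by [write_tracks()]:
#' `time_s,x_cm,y_cm,fish_id,day,dose`. Rows are grouped by
#' `fish_id` x `day`, time-sorted within each track, and rows with missing
#' coordinates are dropped and counted in the parse report.
#'
#' @param path CSV file path.
#' @return a list of `fish_track` data frames (attributes `fish_id`,
#'   `day`, `dose`), with an attribute `report` = `list(n_tracks, dropped)`.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop_invalid("format error: file not found: %s", path)
  tab <- data.table::fread(path)
  required <- c("time_s", "x_cm", "y_cm", "fish_id", "day", "dose")
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop_invalid("format error: missing column(s) %s", paste(miss, collapse = ", "))
  }
  bad <- !is.finite(tab$x_cm) | !is.finite(tab$y_cm) | !is.finite(tab$time_s)
  dropped <- sum(bad)
  if (dropped > 0) tab <- tab[!bad]
  if (nrow(tab) == 0L) {
    warning("empty track table (header only)")
    return(structure(list(), report = list(n_tracks = 0L, dropped = dropped)))
  }
  data.table::setorderv(tab, c("fish_id", "day", "time_s"))
  keys <- paste(tab$fish_id, tab$day, sep = "|")
  out <- lapply(split(seq_len(nrow(tab)), keys), function(idx) {
    sub <- tab[idx]
    if (anyDuplicated(sub$time_s)) {
      stop_invalid("data error: non-monotone or duplicated times for %s/%s",
                   sub$fish_id[1], sub$day[1])
    }
    tr <- data.frame(time_s = sub$time_s, x_cm = sub$x_cm, y_cm = sub$y_cm)
    attr(tr, "fish_id") <- sub$fish_id[1]
    attr(tr, "day") <- sub$day[1]
    attr(tr, "dose") <- sub$dose[1]
    class(tr) <- c("fish_track", "data.frame")
    tr
  })
  attr(out, "report") <- list(n_tracks = length(out), dropped = dropped)
  out
}

#' Assign a maze zone to every track sample
#'
#' Point-in-polygon over the junction triangle and the three arm
#' rectangles. Samples falling outside all polygons (numerical jitter,
#' tracking noise) are snapped to the nearest zone boundary and flagged.
#'
#' @param track a track data frame with `x_cm`, `y_cm`.
#' @param geometry a [maze_geometry()].
#' @return a `data.frame` `time_s, zone, snapped`; `zone` is `"junction"`
#'   or an arm label.
#' @export
assign_zones <- function(track, geometry) {
  stopifnot(inherits(geometry, "maze_geometry"))
  x <- track$x_cm; y <- track$y_cm
  zone <- rep(NA_character_, length(x))
  # arms first so that boundary points shared with the junction edge
  # resolve to the junction only when in no arm
  for (lab in geometry$arm_labels) {
    inside <- points_in_polygon(x, y, geometry$arms[[lab]])
    zone[is.na(zone) & inside] <- lab
  }
  inj <- points_in_polygon(x, y, geometry$junction)
  zone[is.na(zone) & inj] <- "junction"
  snapped <- is.na(zone)
  if (any(snapped)) {
    polys <- c(list(junction = geometry$junction), geometry$arms)
    d <- sapply(polys, function(p) dist_to_polygon(x[snapped], y[snapped], p))
    d <- matrix(d, nrow = sum(snapped))
    zone[snapped] <- names(polys)[max.col(-d, ties.method = "first")]
  }
  data.frame(time_s = track$time_s, zone = zone, snapped = snapped)
}

#' Extract the arm-entry sequence from a zone series
#'
#' An entry is recorded when the fish, arriving from the junction or
#' another arm, remains inside one arm for at least `min_dwell` seconds
#' (hysteresis against junction jitter); consecutive duplicate entries are
#' collapsed, so re-entering the same arm after a junction dip does not
#' count.
#'
#' @param zones output of [assign_zones()] (or a data frame with `time_s`,
#'   `zone`).
#' @param min_dwell minimum dwell time inside an arm, s, >= 0 (default 0.5).
#' @return an object of class `arm_sequence`: `list(arms, entry_times)`.
#' @export
extract_arm_entries <- function(zones, min_dwell = 0.5) {
  if (min_dwell < 0) stop_invalid("invalid-argument: min_dwell must be >= 0")
  z <- as.character(zones$zone)
  t_s <- zones$time_s
  if (length(z) == 0L) {
    return(structure(list(arms = character(0), entry_times = numeric(0)),
                     class = "arm_sequence"))
  }
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # dwell of run i: time from run start to start of next run (last run: to end)
  nxt <- c(t_s[starts[-1]], t_s[length(t_s)] + if (length(t_s) > 1)
    stats::median(diff(t_s)) else min_dwell)
  dwell <- nxt - t_s[starts]
  keep <- r$values != "junction" & dwell >= min_dwell
  arms <- r$values[keep]
  times <- t_s[starts[keep]]
  if (length(arms) > 1) {
    dup <- c(FALSE, arms[-1] == arms[-length(arms)])
    arms <- arms[!dup]; times <- times[!dup]
  }
  structure(list(arms = arms, entry_times = times), class = "arm_sequence")
}

#' @export
print.arm_sequence <- function(x, ...) {
  cat(sprintf("arm_sequence: %d entries [%s]\n", length(x$arms),
              paste(x$arms, collapse = ",")))
  invisible(x)
}

#' Score spontaneous alternation behaviour (SAB)
#'
#' An alternation is a sliding window of 3 consecutive arm entries that are
#' pairwise distinct (continuous-SAB convention). The score is
#' `SAB% = 100 * alternations / (entries - 2)`; with fewer than 3 entries
#' the score is undefined (`NA`, flagged), which is a value rather than an
#' error.
#'
#' @param seq an `arm_sequence` (or a bare character vector of arm labels).
#' @return a list of class `sab_result`: `n_entries`, `n_alternations`,
#'   `sab_percent` (`NA` if undefined), `defined`.
#' @examples
#' compute_sab(c("A","B","C","A","B","C"))$sab_percent  # 100
#' compute_sab(c("A","B","A","B","A"))$sab_percent      # 0
#' @export
compute_sab <- function(seq) {
  arms <- if (inherits(seq, "arm_sequence")) seq$arms else as.character(seq)
  n <- length(arms)
  if (n < 3) {
    return(structure(list(n_entries = n, n_alternations = 0L,
                          sab_percent = NA_real_, defined = FALSE),
                     class = "sab_result"))
  }
  a1 <- arms[1:(n - 2)]; a2 <- arms[2:(n - 1)]; a3 <- arms[3:n]
  alt <- sum(a1 != a2 & a2 != a3 & a1 != a3)
  structure(list(n_entries = n, n_alternations = as.integer(alt),
                 sab_percent = 100 * alt / (n - 2), defined = TRUE),
            class = "sab_result")
}

#' Locomotor endpoints of one track
#'
#' Distance is the sum of consecutive-point Euclidean steps; mean speed is
#' distance over elapsed time; a freezing bout is a maximal run of samples
#' with instantaneous speed below `freeze_speed_thresh` lasting at least
#' `freeze_min_dur` seconds.
#'
#' @param track a track data frame (`time_s`, `x_cm`, `y_cm`).
#' @param freeze_speed_thresh speed threshold, cm/s (default 0.5).
#' @param freeze_min_dur minimum bout duration, s (default 2).
#' @return a list of class `locomotor_summary`: `distance_cm`,
#'   `mean_speed_cm_s`, `n_freezing_bouts`, `total_freeze_s`, `defined`.
#' @export
locomotor_endpoints <- function(track, freeze_speed_thresh = 0.5,
                                freeze_min_dur = 2) {
  if (freeze_speed_thresh < 0 || freeze_min_dur < 0) {
    stop_invalid("invalid-argument: thresholds must be >= 0")
  }
  n <- nrow(track)
  if (n < 2) {
    return(structure(list(distance_cm = 0, mean_speed_cm_s = NA_real_,
                          n_freezing_bouts = NA_integer_,
                          total_freeze_s = NA_real_, defined = FALSE),
                     class = "locomotor_summary"))
  }
  dx <- diff(track$x_cm); dy <- diff(track$y_cm); dt <- diff(track$time_s)
  step <- sqrt(dx^2 + dy^2)
  distance <- sum(step)
  elapsed <- track$time_s[n] - track$time_s[1]
  speed <- step / dt
  slow <- speed < freeze_speed_thresh
  r <- rle(slow)
  run_dur <- tapply(dt, rep(seq_along(r$lengths), r$lengths), sum)
  bouts <- r$values & as.numeric(run_dur) >= freeze_min_dur
  structure(list(distance_cm = distance,
                 mean_speed_cm_s = distance / elapsed,
                 n_freezing_bouts = as.integer(sum(bouts)),
                 total_freeze_s = as.numeric(sum(run_dur[bouts])),
                 defined = TRUE),
            class = "locomotor_summary")
}

#' Score a whole cohort: per-fish SAB and locomotor endpoints
#'
#' @param study a `study_dataset` from [simulate_cohort()], a list of
#'   tracks from [read_tracks()], or a flat track `data.table`.
#' @param geometry a [maze_geometry()].
#' @param min_dwell arm-entry dwell threshold, s.
#' @param freeze_speed_thresh,freeze_min_dur see [locomotor_endpoints()].
#' @return a `data.frame` with one row per fish x day:
#'   `fish_id, day, dose, n_entries, sab_percent, distance_cm, mean_speed,
#'   n_freezes`. Fish with undefined SAB (< 3 entries) carry `NA` and the
#'   count of such tracks is in attribute `n_undefined_sab`.
#' @export
score_tracks <- function(study, geometry = maze_geometry(), min_dwell = 0.5,
                         freeze_speed_thresh = 0.5, freeze_min_dur = 2) {
  tab <- if (inherits(study, "study_dataset")) study$tracks
         else if (is.data.frame(study)) data.table::as.data.table(study)
         else NULL
  if (is.null(tab)) {  # list of tracks from read_tracks()
    rows <- lapply(study, function(tr) {
      one_track_endpoints(tr, attr(tr, "fish_id"), attr(tr, "day"),
                          attr(tr, "dose"), geometry, min_dwell,
                          freeze_speed_thresh, freeze_min_dur)
    })
  } else {
    keys <- paste(tab$fish_id, tab$day, sep = "|")
    rows <- lapply(split(seq_len(nrow(tab)), keys), function(idx) {
      sub <- tab[idx]
      tr <- data.frame(time_s = sub$time_s, x_cm = sub$x_cm, y_cm = sub$y_cm)
      one_track_endpoints(tr, sub$fish_id[1], sub$day[1], sub$dose[1],
                          geometry, min_dwell, freeze_speed_thresh,
                          freeze_min_dur)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_undefined_sab") <- sum(is.na(out$sab_percent))
  out
}

one_track_endpoints <- function(tr, fish_id, day, dose, geometry, min_dwell,
                                freeze_speed_thresh, freeze_min_dur) {
  zones <- assign_zones(tr, geometry)
  seq <- extract_arm_entries(zones, min_dwell)
  sab <- compute_sab(seq)
  loco <- locomotor_endpoints(tr, freeze_speed_thresh, freeze_min_dur)
  data.frame(fish_id = fish_id, day = day, dose = dose,
             n_entries = sab$n_entries, sab_percent = sab$sab_percent,
             distance_cm = loco$distance_cm,
             mean_speed = loco$mean_speed_cm_s,
             n_freezes = loco$n_freezing_bouts)
}
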