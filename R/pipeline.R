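#' Default demonstration configuration
#'
#' A planted-effect study mirroring the modelled in-vivo design: three
#' dose groups (control, 100 ug, 200 ug MPTP per ~1-g fish) tested on two
#' days, 10-min Y-maze trials. Control and 100-ug fish share behavioural
#' parameters; the 200-ug group has markedly altered kinematics (slower,
#' more freezing) and reduced alternation, the planted analogue of a
#' high-dose parkinsonian phenotype. Mortality covers doses 0-400 ug with
#' a true LD50 of 292 mg/kg.
#'
#' @param n_fish fish per dose group (default 10).
#' @param sample_rate track sampling rate, Hz (default 25; lower it to
#'   trade fidelity for speed).
#' @param trial_duration trial length, s (default 600).
#' @param image_size rasterized image side, pixels (default 64).
#' @param epochs CNN training epochs (default 15).
#' @param experiments which experiment designs to run (default all five).
#' @param seed master seed.
#' @return a nested configuration list understood by [run_study()].
#' @export
demo_config <- function(n_fish = 10, sample_rate = 25, trial_duration = 600,
                        image_size = 64, epochs = 15,
                        experiments = c("E1", "E2A", "E2B", "E3A", "E3B"),
                        seed = 1L) {
  list(
    seed = as.integer(seed),
    design = list(doses = c("control", "100ug", "200ug"),
                  days = c("Day1", "Day2"),
                  n_fish_per_group = n_fish,
                  trial_duration = trial_duration,
                  sample_rate = sample_rate),
    groups = list(
      control = list(mean_speed = 6, speed_sd = 2, freeze_rate = 0.5,
                     freeze_duration = 3, p_alternate = 0.70, turn_noise = 0.5),
      `100ug` = list(mean_speed = 6, speed_sd = 2, freeze_rate = 0.5,
                     freeze_duration = 3, p_alternate = 0.70, turn_noise = 0.5),
      `200ug` = list(mean_speed = 2.5, speed_sd = 1.2, freeze_rate = 4,
                     freeze_duration = 5, p_alternate = 0.50, turn_noise = 0.5)),
    maze = list(arm_length = 25, arm_width = 8),
    mortality = list(doses_ug = c(0, 50, 100, 200, 400), n_per_group = 30,
                     true_ld50 = 292, probit_slope = 2, control_rate = 0.05),
    iat = list(n = 19, learned_delta = 40, noise_sd = 15,
               nonavoider_rate = 0.1),
    imaging = list(window_s = 30, image_size = image_size, binary = FALSE),
    classifier = list(channels = 8, epochs = epochs, batch_size = 16,
                      lr = 3e-3, holdout_frac = 0.25),
    permutation = list(reps = 1000, alpha = 0.05),
    community = list(resolution = 1, restarts = 10),
    experiments = experiments,
    stats = list(sab_pair = c("control", "200ug"))
  )
}

#' Read a run configuration from JSON or YAML
#' @param path a `.json`, `.yaml` or `.yml` file mirroring [demo_config()].
#' @return the configuration list.
#' @export
read_config <- function(path) {
  if (grepl("\\.(yaml|yml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_invalid("config error: the yaml package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

validate_config <- function(config) {
  for (field in c("seed", "design", "groups", "imaging", "classifier",
                  "permutation", "community", "experiments")) {
    if (is.null(config[[field]])) {
      stop_invalid("config error: missing field '%s'", field)
    }
  }
  miss <- setdiff(config$design$doses, names(config$groups))
  if (length(miss)) {
    stop_invalid("config error: groups: no parameters for dose(s) %s",
                 paste(miss, collapse = ", "))
  }
  invisible(config)
}

#' Run the full analysis pipeline from one configuration
#'
#' Stage DAG: simulate cohort -> score tracks (SAB + locomotion) ->
#' simulate mortality -> LD50 -> rasterize -> per-experiment classifier
#' (train, evaluate, confusion, permutation baseline) -> similarity graph
#' -> Louvain partition -> conventional statistics (SAB contrast,
#' SAB-vs-distance correlation, paired IAT with non-avoider exclusion).
#' One master seed is fanned out to named substreams (synth / split /
#' train / permute / louvain / mortality / iat), all recorded in the
#' report.
#'
#' @param config a configuration list ([demo_config()]) or a path readable
#'   by [read_config()].
#' @param out_dir optional directory for artifacts (endpoint CSV, LD50
#'   JSON, per-experiment JSON, report JSON).
#' @param images optional precomputed `image_set` (stage cache): when
#'   supplied, the synth/rasterize stages for the Y-maze branch are
#'   skipped and the classifier branch runs from the cached images.
#' @param verbose print stage progress?
#' @return an object of class `run_report`.
#' @export
run_study <- function(config, out_dir = NULL, images = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  seed <- as.integer(config$seed)
  seeds <- list(synth = derive_seed(seed, "synth"),
                split = derive_seed(seed, "split"),
                train = derive_seed(seed, "train"),
                permute = derive_seed(seed, "permute"),
                louvain = derive_seed(seed, "louvain"),
                mortality = derive_seed(seed, "mortality"),
                iat = derive_seed(seed, "iat"))
  say <- function(...) if (verbose) message(sprintf(...))

  geometry <- maze_geometry(config$maze$arm_length %||% 25,
                            config$maze$arm_width %||% 8)
  design <- study_design(doses = config$design$doses,
                         days = config$design$days,
                         n_fish_per_group = config$design$n_fish_per_group,
                         trial_duration = config$design$trial_duration,
                         sample_rate = config$design$sample_rate,
                         seed = seeds$synth)
  params <- lapply(names(config$groups), function(g) {
    do.call(behavior_params, c(list(dose_label = g), config$groups[[g]]))
  })
  names(params) <- names(config$groups)

  ## synth + tracking branch
  say("stage: simulate cohort")
  study <- NULL
  endpoints <- NULL
  if (is.null(images)) {
    study <- simulate_cohort(design, params, geometry)
    say("stage: score tracks")
    endpoints <- score_tracks(study, geometry)
  }

  ## toxicology branch
  ld50 <- NULL
  if (!is.null(config$mortality)) {
    say("stage: mortality / LD50")
    mt <- simulate_mortality(doses_ug = config$mortality$doses_ug,
                             n_per_group = config$mortality$n_per_group,
                             true_ld50 = config$mortality$true_ld50,
                             probit_slope = config$mortality$probit_slope,
                             control_rate = config$mortality$control_rate,
                             seed = seeds$mortality)
    ld50 <- fit_ld50(mt)
  }

  ## imaging + classify + community branch
  say("stage: rasterize")
  if (is.null(images)) {
    images <- rasterize_cohort(study, geometry,
                               window_s = config$imaging$window_s %||% 30,
                               size = config$imaging$image_size %||% 64,
                               binary = isTRUE(config$imaging$binary))
  }
  experiments <- list()
  for (eid in config$experiments) {
    say("stage: experiment %s", eid)
    des <- experiment_design(eid, doses = config$design$doses,
                             days = config$design$days)
    split <- assemble_dataset(images, des,
                              holdout_frac = config$classifier$holdout_frac %||% 0.25,
                              seed = derive_seed(seeds$split, eid))
    model <- train_classifier(split$train,
                              channels = config$classifier$channels %||% 8,
                              epochs = config$classifier$epochs %||% 15,
                              batch_size = config$classifier$batch_size %||% 16,
                              lr = config$classifier$lr %||% 3e-3,
                              seed = derive_seed(seeds$train, eid))
    ev <- evaluate(model, split$validation)
    cm <- confusion(ev$predictions, pred_levels = model$classes,
                    true_levels = sort(unique(split$validation$meta$class)))
    # In cross-day designs the train and test label sets are disjoint by
    # construction (Day1-X vs Day2-X), so prediction accuracy and its
    # permutation baseline are scored on the dose component of the label;
    # the confusion matrix and the similarity graph keep the full
    # day-by-dose labels.
    acc_preds <- ev$predictions
    accuracy <- ev$accuracy
    if (des$split_mode == "cross-day") {
      acc_preds$true_class <- sub("^[^-]+-", "", acc_preds$true_class)
      acc_preds$predicted_class <- sub("^[^-]+-", "", acc_preds$predicted_class)
      accuracy <- mean(acc_preds$predicted_class == acc_preds$true_class)
    }
    perm <- permutation_baseline(acc_preds,
                                 reps = config$permutation$reps %||% 1000,
                                 alpha = config$permutation$alpha %||% 0.05,
                                 seed = derive_seed(seeds$permute, eid))
    graph <- build_similarity_graph(cm)
    part <- louvain(graph,
                    resolution = config$community$resolution %||% 1,
                    seed = derive_seed(seeds$louvain, eid),
                    restarts = config$community$restarts %||% 10)
    experiments[[eid]] <- list(design = des, accuracy = accuracy,
                               threshold = perm$threshold,
                               significant = perm$significant,
                               p_value = perm$p_value,
                               confusion = cm, graph = graph,
                               partition = part,
                               n_train = nrow(split$train$meta),
                               n_validation = nrow(split$validation$meta))
  }

  ## conventional statistics branch
  say("stage: statistics")
  stats_out <- list()
  if (!is.null(endpoints)) {
    pair <- config$stats$sab_pair %||% c(config$design$doses[1],
                                         config$design$doses[length(config$design$doses)])
    day1 <- config$design$days[1]
    e1 <- endpoints[endpoints$day == day1, ]
    sa <- e1$sab_percent[e1$dose == pair[1]]
    sb <- e1$sab_percent[e1$dose == pair[2]]
    stats_out$sab_contrast <- compare_unpaired(sa, sb)
    ok <- is.finite(e1$sab_percent) & is.finite(e1$distance_cm)
    stats_out$sab_vs_distance <- correlate(e1$sab_percent[ok], e1$distance_cm[ok])
    stats_out$n_undefined_sab <- attr(endpoints, "n_undefined_sab")
  }
  if (!is.null(config$iat)) {
    iat <- simulate_iat(n = config$iat$n %||% 19,
                        learned_delta = config$iat$learned_delta %||% 40,
                        noise_sd = config$iat$noise_sd %||% 10,
                        nonavoider_rate = config$iat$nonavoider_rate %||% 0,
                        seed = seeds$iat)
    kept <- filter_nonavoiders(iat)
    stats_out$iat <- compare_paired(kept$train_latency_s, kept$test_latency_s)
    stats_out$iat_excluded <- attr(kept, "n_excluded")
  }

  report <- structure(list(
    config = config,
    config_hash = stable_hash(stable_json(config)),
    seeds = seeds,
    endpoints = endpoints,
    ld50 = ld50,
    experiments = experiments,
    stats = stats_out
  ), class = "run_report")
  report$report_hash <- report_hash(report)

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Deterministic hash of every numerical outcome of a run (not of the raw
# tracks): endpoints, LD50, per-experiment accuracy/threshold/confusion/
# partition, statistics.
report_hash <- function(report) {
  payload <- list(
    config_hash = report$config_hash,
    endpoints = if (!is.null(report$endpoints)) {
      lapply(report$endpoints[, c("n_entries", "sab_percent", "distance_cm",
                                  "mean_speed", "n_freezes")], round, 9)
    },
    ld50 = if (!is.null(report$ld50)) {
      round(c(report$ld50$ld50, report$ld50$slope, report$ld50$intercept), 9)
    },
    experiments = lapply(report$experiments, function(e) {
      list(acc = round(e$accuracy, 12), thr = round(e$threshold, 12),
           cm = round(as.numeric(e$confusion), 12),
           part = as.integer(e$partition$membership),
           q = round(e$partition$modularity, 9))
    }),
    stats = lapply(report$stats, function(s) {
      if (inherits(s, "group_comparison")) {
        round(c(s$statistic, s$df %||% NA_real_, s$p_value), 9)
      } else if (inherits(s, "correlation_result")) {
        round(c(s$r, s$df, s$p_value), 9)
      } else s
    })
  )
  stable_hash(stable_json(payload))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report %s (config %s)\n", x$report_hash, x$config_hash))
  if (!is.null(x$ld50)) {
    cat(sprintf("  LD50: %.1f mg/kg\n", x$ld50$ld50))
  }
  if (!is.null(x$endpoints)) {
    agg <- stats::aggregate(sab_percent ~ dose + day, data = x$endpoints,
                            FUN = function(v) mean(v, na.rm = TRUE))
    cat("  mean SAB% by group:\n")
    for (i in seq_len(nrow(agg))) {
      cat(sprintf("    %s %s: %.1f\n", agg$day[i], agg$dose[i],
                  agg$sab_percent[i]))
    }
  }
  for (eid in names(x$experiments)) {
    e <- x$experiments[[eid]]
    cat(sprintf("  %s: accuracy %.3f (perm. threshold %.3f, %s), %d communities, Q = %.3f\n",
                eid, e$accuracy, e$threshold,
                if (e$significant) "significant" else "n.s.",
                e$partition$n_communities, e$partition$modularity))
  }
  if (!is.null(x$stats$sab_contrast)) {
    s <- x$stats$sab_contrast
    cat(sprintf("  SAB contrast: %s = %.3f, p = %.4f\n", s$test, s$statistic,
                s$p_value))
  }
  if (!is.null(x$stats$iat)) {
    s <- x$stats$iat
    cat(sprintf("  IAT paired: t(%d) = %.3f, p = %.4f (%d non-avoider(s) excluded)\n",
                s$df, s$statistic, s$p_value, x$stats$iat_excluded))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$endpoints)) {
    utils::write.csv(report$endpoints, file.path(out_dir, "endpoints.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$ld50)) {
    jsonlite::write_json(
      list(ld50 = report$ld50$ld50, slope = report$ld50$slope,
           intercept = report$ld50$intercept,
           r_squared = report$ld50$r_squared),
      file.path(out_dir, "ld50.json"), auto_unbox = TRUE, digits = NA)
  }
  for (eid in names(report$experiments)) {
    e <- report$experiments[[eid]]
    jsonlite::write_json(
      list(accuracy = e$accuracy, threshold = e$threshold,
           significant = e$significant, p_value = e$p_value,
           confusion = as.data.frame(unclass(e$confusion)),
           partition = as.list(e$partition$membership),
           modularity = e$partition$modularity),
      file.path(out_dir, sprintf("experiment_%s.json", eid)),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(config_hash = report$config_hash, report_hash = report$report_hash,
         seeds = report$seeds),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
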