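# Orchestration: simulate -> preprocess -> detect -> metrics -> stats for a
# whole group, from one config, with a deterministic seed tree and a
# report bundle whose every statistic is recomputable from the bundled
# intermediate tables.

#' Build a pipeline configuration
#'
#' Collects the per-module settings into one validated list. Either pass a
#' simulation block (the default) or input paths to recordings and trial
#' tables produced elsewhere in the same dialect.
#'
#' @param experiment 1 or 2.
#' @param n_participants Group size (default 25).
#' @param sim A [sim_config()] (one per participant; per-participant seeds
#'   are derived from `seed`). Mutually exclusive with `paths`.
#' @param paths Optional data frame/list with `recording` and `trials`
#'   file paths per participant.
#' @param pad_ms,gaze_limit_units,rt_sd_mult Preprocessing settings.
#' @param baseline_ms,epoch_ms Half-open windows, ms relative to cue.
#' @param lambda,min_dur_ms,merge_ms,min_magnitude_units,smooth_ms,mag_bins
#'   Saccade-detection settings.
#' @param delay_window_ms Window for scalar delay-period averages.
#' @param n_permutations,cluster_alpha,side_alpha,bf_scales Group-stats
#'   settings.
#' @param seed Master seed governing every stochastic stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = 1, n_participants = 25,
                            sim = sim_config(experiment = experiment),
                            paths = NULL,
                            pad_ms = 50, gaze_limit_units = 50,
                            rt_sd_mult = 4,
                            baseline_ms = c(-500, 0),
                            epoch_ms = c(-500, 1500),
                            lambda = 5, min_dur_ms = 6, merge_ms = 20,
                            min_magnitude_units = 1, smooth_ms = 100,
                            mag_bins = seq(2, 110, 4),
                            delay_window_ms = c(0, 1500),
                            n_permutations = 10000, cluster_alpha = 0.05,
                            side_alpha = 0.025,
                            bf_scales = c(0.5, 0.707, 1, 2),
                            seed = 1L) {
  abort_if(!is.null(paths) && !is.null(sim) && !inherits(sim, "sim_config"),
           "sim must be a sim_config")
  abort_if(is.null(paths) && is.null(sim),
           "exactly one of 'sim' or 'paths' must be given")
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `sim`
#' key holds [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  if (!is.null(y$experiment) && is.null(sim_args$experiment)) {
    sim_args$experiment <- y$experiment
  }
  y$sim <- do.call(sim_config, lapply(sim_args, unlist))
  do.call(pipeline_config, y)
}

# One participant: simulate (or load), preprocess, detect, summarise.
process_participant <- function(cfg, p) {
  pid <- sprintf("p%02d", p)
  if (!is.null(cfg$paths)) {
    rec <- read_recording(cfg$paths$recording[p])
    trials <- read_trials(cfg$paths$trials[p])
    trials$participant <- pid
    truth <- NULL
  } else {
    sess <- simulate_session(cfg$sim, seed = derive_seed(cfg$seed, p),
                             participant = pid)
    rec <- sess$recording
    trials <- sess$trials
    truth <- sess$truth
  }
  rec <- interpolate_blinks(rec, pad_ms = cfg$pad_ms)
  map <- fit_calibration(rec)
  rec <- normalize_gaze(rec, map)
  epochs <- epoch_and_baseline(rec, trials, epoch_window = cfg$epoch_ms,
                               baseline_window = cfg$baseline_ms)
  ex <- exclude_trials(epochs, gaze_limit = cfg$gaze_limit_units,
                       rt_sd_mult = cfg$rt_sd_mult)

  conds <- sort(unique(trials$condition))
  tw <- list(); sacc_rate <- list(); mag <- list()
  for (cond in conds) {
    ep_c <- subset_epochs(ex$epochs, cond)
    tw[[cond]] <- towardness(ep_c)
    ev <- detect_saccades(ep_c, lambda = cfg$lambda,
                          min_dur_ms = cfg$min_dur_ms,
                          merge_ms = cfg$merge_ms,
                          min_magnitude = cfg$min_magnitude_units)
    ev <- classify_direction(ev, ep_c$trials)
    sacc_rate[[cond]] <- rate_timecourses(ev, ep_c,
                                          smooth_ms = cfg$smooth_ms)
    ep_m <- subset_epochs(ex$epochs_magnitude, cond)
    ev_m <- detect_saccades(ep_m, lambda = cfg$lambda,
                            min_dur_ms = cfg$min_dur_ms,
                            merge_ms = cfg$merge_ms,
                            min_magnitude = cfg$min_magnitude_units)
    ev_m <- classify_direction(ev_m, ep_m$trials)
    mag[[cond]] <- magnitude_bias_map(ev_m, ep_m, edges = cfg$mag_bins,
                                      smooth_ms = cfg$smooth_ms)
  }
  list(participant = pid, towardness = tw, saccade_rate = sacc_rate,
       magnitude = mag, behaviour = behaviour_summary(ex$epochs$trials),
       exclusion = ex$report, truth = truth, calibration = map)
}

#' Run the full group analysis pipeline
#'
#' For every participant: simulate (or load) a session, interpolate
#' blinks, fit and apply the calibration, epoch around the retro-cue,
#' apply both exclusion rules, compute towardness and toward/away saccade
#' rates per condition, and the magnitude-resolved bias map. At the group
#' level: cluster-based permutation tests of each condition's towardness
#' and saccade-effect time courses against zero and of the
#' condition difference, plus scalar delay-period condition contrasts
#' (paired t, Cohen's d, and the JZS Bayes-factor sensitivity analysis).
#' Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `report_bundle`: tidy time-course tables,
#'   behaviour and exclusion tables, cluster results, the Bayes-factor
#'   table, scalar test results, and provenance (seed + config echo).
#' @export
run_pipeline <- function(config) {
  abort_if(!inherits(config, "pipeline_config"),
           "config must be a pipeline_config")
  cfg <- config
  parts <- lapply(seq_len(cfg$n_participants),
                  function(p) process_participant(cfg, p))
  conds <- names(parts[[1]]$towardness)
  abort_if(length(conds) != 2, "expected exactly two conditions, got %d",
           length(conds))
  time <- parts[[1]]$towardness[[1]]$time

  # group matrices: participants x time, per condition and metric
  stack <- function(metric, cond) {
    do.call(rbind, lapply(parts, function(pp) {
      tc <- pp[[metric]][[cond]]
      if (!is.null(tc$value)) tc$value else tc$effect_hz
    }))
  }
  mats <- list()
  for (m in c("towardness", "saccade_rate")) {
    for (cond in conds) mats[[paste(m, cond, sep = ".")]] <- stack(m, cond)
  }

  # cluster tests: each condition vs 0, and the condition difference
  cluster_results <- list()
  k <- 0L
  for (m in c("towardness", "saccade_rate")) {
    for (cond in conds) {
      k <- k + 1L
      cluster_results[[paste(m, cond, sep = ".")]] <-
        cluster_permutation_test(
          mats[[paste(m, cond, sep = ".")]],
          n_permutations = cfg$n_permutations,
          cluster_alpha = cfg$cluster_alpha,
          side_alpha = cfg$side_alpha, time = time,
          seed = derive_seed(cfg$seed, 900 + k))
    }
    k <- k + 1L
    cluster_results[[paste(m, "difference", sep = ".")]] <-
      cluster_permutation_test(
        mats[[paste(m, conds[1], sep = ".")]],
        mats[[paste(m, conds[2], sep = ".")]],
        n_permutations = cfg$n_permutations,
        cluster_alpha = cfg$cluster_alpha,
        side_alpha = cfg$side_alpha, time = time,
        seed = derive_seed(cfg$seed, 900 + k))
  }

  # scalar delay-period condition contrasts
  delay_means <- function(m, cond) {
    vapply(parts, function(pp) {
      delay_average(pp[[m]][[cond]], cfg$delay_window_ms)
    }, numeric(1))
  }
  stat_table <- NULL
  bf_table <- NULL
  for (m in c("towardness", "saccade_rate")) {
    a <- delay_means(m, conds[1])
    b <- delay_means(m, conds[2])
    st <- paired_stats(a, b)
    stat_table <- rbind(stat_table, data.frame(
      metric = m, contrast = paste(conds[1], "vs", conds[2]),
      t = st$t, df = st$df, p = st$p, d = st$d, mean_diff = st$mean_diff,
      ci_low = st$ci_low, ci_high = st$ci_high))
    bf <- bf_sensitivity(st$t, st$n, cfg$bf_scales)
    bf$metric <- m
    bf$contrast <- paste(conds[1], "vs", conds[2])
    bf_table <- rbind(bf_table, bf)
  }

  tidy_tc <- function(metric) {
    do.call(rbind, lapply(parts, function(pp) {
      do.call(rbind, lapply(conds, function(cond) {
        tc <- pp[[metric]][[cond]]
        data.frame(participant = pp$participant, condition = cond,
                   time_ms = time,
                   value = if (!is.null(tc$value)) tc$value else
                     tc$effect_hz)
      }))
    }))
  }
  behaviour <- do.call(rbind, lapply(parts, `[[`, "behaviour"))
  exclusions <- do.call(rbind, lapply(parts, function(pp) {
    cbind(participant = pp$participant, pp$exclusion)
  }))

  clusters_df <- do.call(rbind, lapply(names(cluster_results), function(nm) {
    cl <- cluster_results[[nm]]$clusters
    if (nrow(cl) == 0) return(NULL)
    cbind(test = nm, cl)
  }))
  if (is.null(clusters_df)) {
    clusters_df <- data.frame(test = character(0), start_ms = numeric(0),
                              end_ms = numeric(0), sign = numeric(0),
                              mass = numeric(0), p = numeric(0),
                              significant = logical(0))
  }

  structure(list(
    towardness = tidy_tc("towardness"),
    saccade_effect = tidy_tc("saccade_rate"),
    behaviour = behaviour, exclusions = exclusions,
    clusters = clusters_df, cluster_results = cluster_results,
    stat_table = stat_table, bf_table = bf_table,
    magnitude = lapply(parts, `[[`, "magnitude"),
    conditions = conds, time = time,
    provenance = list(seed = cfg$seed, experiment = cfg$experiment,
                      n_participants = cfg$n_participants,
                      n_permutations = cfg$n_permutations)),
    class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> experiment %d, %d participants\n",
              x$provenance$experiment, x$provenance$n_participants))
  cat("scalar condition contrasts:\n")
  print(x$stat_table, row.names = FALSE)
  invisible(x)
}

#' Serialise a report bundle to CSV tables plus summary JSON
#'
#' Writes the tidy time-course, behaviour, exclusion, cluster and
#' Bayes-factor tables as CSV under `dir`, and the scalar statistics with
#' provenance as `summary.json`. Identical seeds give byte-identical
#' summaries.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_bundle <- function(bundle, dir) {
  abort_if(!inherits(bundle, "report_bundle"),
           "'bundle' must be a report_bundle")
  summary <- list(
    provenance = bundle$provenance,
    scalar_contrasts = bundle$stat_table,
    bayes_factors = bundle$bf_table,
    clusters = bundle$clusters)
  write_report(
    tables = list(towardness = bundle$towardness,
                  saccade_effect = bundle$saccade_effect,
                  behaviour = bundle$behaviour,
                  exclusions = bundle$exclusions,
                  clusters = bundle$clusters,
                  bf_table = bundle$bf_table,
                  stat_table = bundle$stat_table),
    summary = summary, dir = dir)
}
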