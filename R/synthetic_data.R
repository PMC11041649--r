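# Generative model of fixational gaze during a retro-cue working-memory
# session: slow drift + white measurement noise + Poisson microsaccades
# whose direction becomes biased toward the cued item's encoded side after
# the cue, plus return saccades, blinks with artifact pads, and per-block
# calibration sweeps. Emits the gaze_io dialect plus ground truth so every
# downstream stage can be scored against what was injected.

#' Configuration for the synthetic session generator
#'
#' Defaults reproduce the study conditions being emulated: 1000 Hz
#' binocular tracking, stimulus centres at +/-100 normalized units (8 deg),
#' Experiment 1 with 500 trials (100 per each of five presentation
#' subtypes, 10 blocks of 50) or Experiment 2 with 480 trials (10 blocks of
#' 48, colour/order blocks alternating), intertrial interval 500-800 ms,
#' 250 ms encoding displays separated by a 750 ms interstimulus interval,
#' 250 ms retro-cue after a 1250 ms delay, and a second 1250 ms delay
#' before the go signal. The post-cue microsaccade direction bias rises
#' from `bias_latency_ms`, peaks at `bias_peak_ms` (probability
#' `bias_peak_p_toward` that a microsaccade heads toward the cued side) and
#' decays by `bias_end_ms`.
#'
#' @param experiment 1 or 2.
#' @param n_trials Total trials (default 500 for E1, 480 for E2).
#' @param block_size Trials per block (50 for E1, 48 for E2); a calibration
#'   sweep follows each block.
#' @param eccentricity_units Stimulus-centre eccentricity in normalized
#'   units (100 = 8 visual degrees).
#' @param iti_range_ms,encoding_ms,isi_ms,delay1_ms,cue_ms,delay2_ms,response_window_ms
#'   Trial timing, ms.
#' @param bias_latency_ms,bias_peak_ms,bias_end_ms,bias_peak_p_toward
#'   Direction-bias profile (see [bias_profile()]).
#' @param base_msacc_rate_hz Baseline microsaccade rate (Hz).
#' @param amp_median_units,amp_sdlog Lognormal amplitude distribution of
#'   injected saccades (median 5 units, sdlog 0.6 keeps ~94% below 12.5
#'   units, i.e. below 1 degree).
#' @param return_prob,return_delay_mean_ms Probability that a saccade is
#'   followed by a return saccade toward fixation, and the mean of the
#'   exponential delay before it.
#' @param drift_sd,drift_theta Ornstein-Uhlenbeck fixational drift:
#'   innovation SD (units per sample) and mean-reversion rate.
#' @param noise_sd Per-eye white measurement noise SD (units).
#' @param blink_rate_hz,blink_dur_ms Poisson blink onsets and blink length;
#'   blinked samples are missing and 50 ms pads either side carry eyelid
#'   artifacts.
#' @param gain_x,offset_x,gain_y,offset_y True raw-to-normalized affine per
#'   axis (`normalized = gain * (raw - offset)`), used to emit tracker
#'   units and to score calibration recovery.
#' @param calib_point_ms Dwell per calibration point, ms.
#' @param report_sd_deg SD of Gaussian report noise in 180-degree
#'   orientation space.
#' @param rt_meanlog,rt_sdlog Lognormal response-onset parameters (ms).
#' @param seed Default seed used when `simulate_session()` is called
#'   without one.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(experiment = 1,
                       n_trials = if (experiment == 1) 500L else 480L,
                       block_size = if (experiment == 1) 50L else 48L,
                       eccentricity_units = 100,
                       iti_range_ms = c(500, 800),
                       encoding_ms = 250, isi_ms = 750, delay1_ms = 1250,
                       cue_ms = 250, delay2_ms = 1250,
                       response_window_ms = 1500,
                       bias_latency_ms = 300, bias_peak_ms = 600,
                       bias_end_ms = 800, bias_peak_p_toward = 0.75,
                       base_msacc_rate_hz = 1.5,
                       amp_median_units = 5, amp_sdlog = 0.6,
                       return_prob = 1.0, return_delay_mean_ms = 100,
                       drift_sd = 0.02, drift_theta = 0.002,
                       noise_sd = 0.15,
                       blink_rate_hz = 0.1, blink_dur_ms = 150,
                       gain_x = 0.05, offset_x = 512,
                       gain_y = 0.05, offset_y = 384,
                       calib_point_ms = 1200,
                       report_sd_deg = 17,
                       rt_meanlog = log(220), rt_sdlog = 0.25,
                       seed = 1L) {
  cfg <- as.list(environment())
  abort_if(!experiment %in% c(1, 2), "experiment must be 1 or 2")
  abort_if(n_trials < 1, "n_trials must be positive")
  abort_if(bias_peak_p_toward < 0 || bias_peak_p_toward > 1,
           "bias_peak_p_toward must lie in [0, 1]")
  abort_if(return_prob < 0 || return_prob > 1,
           "return_prob must lie in [0, 1]")
  abort_if(base_msacc_rate_hz < 0 || blink_rate_hz < 0, "rates must be >= 0")
  abort_if(bias_latency_ms >= bias_peak_ms,
           "bias_latency_ms must be below bias_peak_ms")
  abort_if(bias_peak_ms >= bias_end_ms,
           "bias_peak_ms must be below bias_end_ms")
  structure(cfg, class = "sim_config")
}

#' Post-cue microsaccade direction-bias profile
#'
#' Probability that a microsaccade launched `t_rel` ms after cue onset is
#' directed toward the cued item's encoded side. 0.5 (unbiased) before
#' `bias_latency_ms` and after `bias_end_ms`; in between, a smooth
#' raised-cosine bump rising to `bias_peak_p_toward` at `bias_peak_ms`.
#'
#' @param t_rel Time since cue onset, ms (vectorised; `NA` allowed).
#' @param config A [sim_config()].
#' @return Vector of toward-probabilities.
#' @export
bias_profile <- function(t_rel, config) {
  L <- config$bias_latency_ms
  P <- config$bias_peak_ms
  E <- config$bias_end_ms
  b <- numeric(length(t_rel))
  t <- as.numeric(t_rel)
  up <- !is.na(t) & t >= L & t < P
  dn <- !is.na(t) & t >= P & t <= E
  b[up] <- (1 - cos(pi * (t[up] - L) / (P - L))) / 2
  b[dn] <- (1 + cos(pi * (t[dn] - P) / (E - P))) / 2
  0.5 + (config$bias_peak_p_toward - 0.5) * b
}

#' Nominal calibration-target layout
#'
#' Seven targets in normalized coordinates: central fixation, the two
#' stimulus centres at +/-100 horizontal, two vertical and two diagonal
#' points. The calibration fit only assumes these nominal coordinates are
#' known.
#'
#' @return Data frame with columns `point`, `x`, `y`.
#' @export
calib_targets <- function() {
  data.frame(point = 1:7,
             x = c(0, -100, 100, 0, 0, -70, 70),
             y = c(0, 0, 0, 60, -60, -45, 45))
}

# Trial schedule: subtype/condition/cued-side assignment, timing draws.
build_trial_schedule <- function(cfg) {
  n <- cfg$n_trials
  if (cfg$experiment == 1) {
    subtypes <- rep_len(rep(c("sim_early", "sim_late", "sim_both",
                              "seq_LR", "seq_RL"), each = ceiling(n / 5)), n)
    subtypes <- subtypes[sample.int(n)]
    condition <- ifelse(startsWith(subtypes, "sim"),
                        "simultaneous", "sequential")
    block <- rep(seq_len(ceiling(n / cfg$block_size)),
                 each = cfg$block_size)[seq_len(n)]
  } else {
    n_blocks <- ceiling(n / cfg$block_size)
    cond_block <- rep_len(c("colour", "order"), n_blocks)
    cond_block <- cond_block[sample.int(n_blocks)]
    block <- rep(seq_len(n_blocks), each = cfg$block_size)[seq_len(n)]
    condition <- cond_block[block]
    subtypes <- condition
  }
  cued_side <- character(n)
  for (cond in unique(condition)) {
    idx <- which(condition == cond)
    sides <- rep_len(c("left", "right"), length(idx))
    cued_side[idx] <- sides[sample.int(length(idx))]
  }
  iti <- sample(seq(cfg$iti_range_ms[1], cfg$iti_range_ms[2]), n,
                replace = TRUE)
  target <- stats::runif(n, 0, 180)
  reported <- (target + stats::rnorm(n, 0, cfg$report_sd_deg)) %% 180
  rt <- pmax(1, round(stats::rlnorm(n, cfg$rt_meanlog, cfg$rt_sdlog)))
  data.frame(trial_id = seq_len(n), experiment = cfg$experiment,
             condition = condition, trial_subtype = subtypes,
             cued_side = cued_side, iti = iti,
             target_orientation = target, reported_orientation = reported,
             response_onset_ms = rt, block = block,
             stringsAsFactors = FALSE)
}

#' Simulate a full experimental session for one participant
#'
#' Produces a raw-unit binocular recording (trials interleaved with
#' per-block calibration sweeps), the trial table, and ground truth: every
#' injected saccade (onset, displacement, toward/away/base/return label),
#' blink intervals, and the raw-to-normalized affine. Post-cue
#' microsaccades are direction-biased per [bias_profile()]; each saccade is
#' followed (with probability `return_prob`) by a return saccade toward
#' fixation after an exponential delay, which produces the late
#' away-directed rate rebound and keeps simulated gaze stationary.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`). Identical seeds
#'   give identical output.
#' @param participant Participant label stored in the trial table.
#' @param flip_cued_sides If `TRUE`, regenerate with every cued side
#'   mirrored while consuming the identical random stream; direction-biased
#'   ground-truth displacements are negated exactly (mirror symmetry).
#' @return List with elements `recording` ([gaze_recording()], raw units),
#'   `trials` (data frame) and `truth` (list: `saccades`, `blinks`,
#'   `affine`, `config`).
#' @export
simulate_session <- function(config, seed = config$seed,
                             participant = "p1", flip_cued_sides = FALSE) {
  abort_if(!inherits(config, "sim_config"), "config must be a sim_config")
  with_seed(seed, {
    cfg <- config
    tr <- build_trial_schedule(cfg)
    if (flip_cued_sides) {
      tr$cued_side <- ifelse(tr$cued_side == "left", "right", "left")
    }
    n <- nrow(tr)
    pre_cue <- 2 * cfg$encoding_ms + cfg$isi_ms + cfg$delay1_ms  # 2500
    post_cue <- cfg$cue_ms + cfg$delay2_ms                       # 1500
    trial_len <- tr$iti + pre_cue + post_cue + cfg$response_window_ms
    sweep_len <- 7L * cfg$calib_point_ms
    n_blocks <- max(tr$block)

    # Absolute start of every trial, with a calibration sweep after each
    # block.
    start <- integer(n)
    cursor <- 0L
    sweep_start <- integer(n_blocks)
    for (b in seq_len(n_blocks)) {
      idx <- which(tr$block == b)
      for (i in idx) {
        start[i] <- cursor
        cursor <- cursor + trial_len[i]
      }
      sweep_start[b] <- cursor
      cursor <- cursor + sweep_len
    }
    N <- cursor
    tr$cue_onset <- start + tr$iti + pre_cue
    go_time <- tr$cue_onset + post_cue

    # Calibration sweeps: point order randomized per sweep.
    targets <- calib_targets()
    calib_events <- NULL
    calib_x <- numeric(N)
    calib_y <- numeric(N)
    in_calib <- logical(N)
    for (b in seq_len(n_blocks)) {
      ord <- sample.int(7)
      for (k in seq_len(7)) {
        t0 <- sweep_start[b] + (k - 1L) * cfg$calib_point_ms
        idx <- (t0 + 1L):(t0 + cfg$calib_point_ms)
        pt <- ord[k]
        calib_x[idx] <- targets$x[pt]
        calib_y[idx] <- targets$y[pt]
        in_calib[idx] <- TRUE
        calib_events <- rbind(calib_events,
                              data.frame(time = t0, label = "CALIB_POINT",
                                         arg = as.character(pt)))
      }
    }

    # Microsaccade onsets: homogeneous Poisson over trial time only.
    trial_dur_total <- sum(trial_len)
    K <- stats::rpois(1, trial_dur_total / 1000 * cfg$base_msacc_rate_hz)
    cum_len <- cumsum(as.numeric(trial_len))
    u <- sort(stats::runif(K, 0, trial_dur_total))
    trial_of <- findInterval(u, c(0, cum_len), rightmost.closed = TRUE)
    offset_in_trial <- u - c(0, cum_len)[trial_of]
    t_on <- floor(start[trial_of] + offset_in_trial)
    rel <- t_on - tr$cue_onset[trial_of]

    p_toward <- bias_profile(rel, cfg)
    biased <- p_toward != 0.5
    toward_draw <- stats::rbinom(K, 1, p_toward) == 1
    base_dir <- sample(c(-1, 1), K, replace = TRUE)
    amp <- stats::rlnorm(K, log(cfg$amp_median_units), cfg$amp_sdlog)
    dy <- stats::rnorm(K, 0, 0.2) * amp
    ret_occur <- stats::runif(K) < cfg$return_prob
    ret_delay <- stats::rexp(K, 1 / cfg$return_delay_mean_ms)

    side_sign <- ifelse(tr$cued_side[trial_of] == "right", 1, -1)
    dir <- ifelse(biased,
                  ifelse(toward_draw, side_sign, -side_sign),
                  base_dir)
    dx <- dir * amp
    type <- ifelse(biased, ifelse(toward_draw, "toward", "away"), "base")

    sacc <- data.frame(t_onset = t_on, trial_id = tr$trial_id[trial_of],
                       rel_onset = rel, dx = dx, dy = dy,
                       amplitude = amp, type = type,
                       stringsAsFactors = FALSE)
    # Return saccades.
    ri <- which(ret_occur)
    if (length(ri)) {
      t_ret <- floor(t_on[ri] + 20 + ret_delay[ri])
      keep <- t_ret < N - 25
      ri <- ri[keep]; t_ret <- t_ret[keep]
      ret <- data.frame(t_onset = t_ret, trial_id = tr$trial_id[trial_of[ri]],
                        rel_onset = t_ret - tr$cue_onset[trial_of[ri]],
                        dx = -dx[ri], dy = -dy[ri], amplitude = amp[ri],
                        type = "return", stringsAsFactors = FALSE)
      sacc <- rbind(sacc, ret)
    }
    sacc <- sacc[order(sacc$t_onset), , drop = FALSE]
    # Epoch membership: only saccades inside [-500, 1500) of their trial's
    # cue carry a trial_id in the ground truth.
    outside <- is.na(sacc$rel_onset) | sacc$rel_onset < -500 |
      sacc$rel_onset >= 1500
    sacc$trial_id[outside] <- NA_integer_

    # Displacement track from waveform increments.
    inc_x <- numeric(N)
    inc_y <- numeric(N)
    wf <- saccade_waveform(1:20, 20) - saccade_waveform(0:19, 20)
    for (j in seq_len(nrow(sacc))) {
      i0 <- sacc$t_onset[j] + 1L
      if (i0 + 19L > N) next
      ii <- i0:(i0 + 19L)
      inc_x[ii] <- inc_x[ii] + sacc$dx[j] * wf
      inc_y[ii] <- inc_y[ii] + sacc$dy[j] * wf
    }
    disp_x <- cumsum(inc_x)
    disp_y <- cumsum(inc_y)

    drift_x <- as.numeric(stats::filter(stats::rnorm(N, 0, cfg$drift_sd),
                                        1 - cfg$drift_theta, "recursive"))
    drift_y <- as.numeric(stats::filter(stats::rnorm(N, 0, cfg$drift_sd),
                                        1 - cfg$drift_theta, "recursive"))

    x0 <- disp_x + drift_x
    y0 <- disp_y + drift_y
    x0[in_calib] <- calib_x[in_calib] + drift_x[in_calib]
    y0[in_calib] <- calib_y[in_calib] + drift_y[in_calib]

    lx <- x0 + stats::rnorm(N, 0, cfg$noise_sd)
    ly <- y0 + stats::rnorm(N, 0, cfg$noise_sd)
    rx <- x0 + stats::rnorm(N, 0, cfg$noise_sd)
    ry <- y0 + stats::rnorm(N, 0, cfg$noise_sd)

    # Blinks: missing samples plus eyelid artifacts in 50 ms pads.
    Kb <- stats::rpois(1, N / 1000 * cfg$blink_rate_hz)
    blink_events <- NULL
    blinks <- data.frame(start = integer(0), end = integer(0))
    if (Kb > 0) {
      b_on <- sort(sample.int(max(1L, N - cfg$blink_dur_ms - 200L), Kb))
      b_on <- b_on[c(TRUE, diff(b_on) > cfg$blink_dur_ms + 300L)]
      for (t0 in b_on) {
        t1 <- t0 + cfg$blink_dur_ms
        pad0 <- max(1L, t0 - 50L + 1L)
        pre <- pad0:t0
        post <- (t1 + 1L):min(N, t1 + 50L)
        ramp_pre <- seq(0, 1, length.out = length(pre))
        ramp_post <- seq(1, 0, length.out = length(post))
        for (ch in c("ly", "ry")) {
          v <- get(ch); v[pre] <- v[pre] - 15 * ramp_pre
          v[post] <- v[post] - 15 * ramp_post; assign(ch, v)
        }
        for (ch in c("lx", "rx")) {
          v <- get(ch); v[pre] <- v[pre] - 6 * ramp_pre
          v[post] <- v[post] - 6 * ramp_post; assign(ch, v)
        }
        na_idx <- (t0 + 1L):min(N, t1)
        lx[na_idx] <- NA; ly[na_idx] <- NA
        rx[na_idx] <- NA; ry[na_idx] <- NA
        blink_events <- rbind(blink_events,
                              data.frame(time = c(t0, t1),
                                         label = c("BLINK_START",
                                                   "BLINK_END"),
                                         arg = NA_character_))
        blinks <- rbind(blinks, data.frame(start = t0, end = t1))
      }
    }

    events <- rbind(
      calib_events,
      data.frame(time = tr$cue_onset, label = "CUE_ONSET",
                 arg = as.character(tr$trial_id)),
      data.frame(time = go_time + tr$response_onset_ms,
                 label = "RESPONSE_ONSET", arg = as.character(tr$trial_id)),
      blink_events)
    events <- events[order(events$time), , drop = FALSE]

    to_raw <- function(v, gain, off) v / gain + off
    rec <- gaze_recording(
      time = 0:(N - 1L),
      left_x = to_raw(lx, cfg$gain_x, cfg$offset_x),
      left_y = to_raw(ly, cfg$gain_y, cfg$offset_y),
      right_x = to_raw(rx, cfg$gain_x, cfg$offset_x),
      right_y = to_raw(ry, cfg$gain_y, cfg$offset_y),
      events = events, sampling_rate = 1000, units = "raw")

    tr$participant <- participant
    tr$iti <- NULL
    truth <- list(
      saccades = sacc, blinks = blinks,
      affine = list(gain_x = cfg$gain_x, offset_x = cfg$offset_x,
                    gain_y = cfg$gain_y, offset_y = cfg$offset_y),
      config = cfg)
    list(recording = rec, trials = tr, truth = truth)
  })
}

#' Simulate one calibration sweep
#'
#' Emits a recording segment with the seven `CALIB_POINT` targets (random
#' order), gaze settled on each affine-mapped target plus drift and noise,
#' together with the generating affine as the true calibration map.
#'
#' @inheritParams simulate_session
#' @return List with `recording` (raw units) and `map`
#'   (a [calibration_map] containing the generating affine).
#' @export
simulate_calibration <- function(config, seed = config$seed) {
  abort_if(!inherits(config, "sim_config"), "config must be a sim_config")
  with_seed(seed, {
    cfg <- config
    targets <- calib_targets()
    N <- 7L * cfg$calib_point_ms
    ord <- sample.int(7)
    x0 <- numeric(N); y0 <- numeric(N)
    events <- NULL
    for (k in seq_len(7)) {
      t0 <- (k - 1L) * cfg$calib_point_ms
      idx <- (t0 + 1L):(t0 + cfg$calib_point_ms)
      x0[idx] <- targets$x[ord[k]]
      y0[idx] <- targets$y[ord[k]]
      events <- rbind(events,
                      data.frame(time = t0, label = "CALIB_POINT",
                                 arg = as.character(ord[k])))
    }
    drift_x <- as.numeric(stats::filter(stats::rnorm(N, 0, cfg$drift_sd),
                                        1 - cfg$drift_theta, "recursive"))
    drift_y <- as.numeric(stats::filter(stats::rnorm(N, 0, cfg$drift_sd),
                                        1 - cfg$drift_theta, "recursive"))
    mk <- function(base, drift) base + drift + stats::rnorm(N, 0, cfg$noise_sd)
    to_raw <- function(v, gain, off) v / gain + off
    rec <- gaze_recording(
      time = 0:(N - 1L),
      left_x = to_raw(mk(x0, drift_x), cfg$gain_x, cfg$offset_x),
      left_y = to_raw(mk(y0, drift_y), cfg$gain_y, cfg$offset_y),
      right_x = to_raw(mk(x0, drift_x), cfg$gain_x, cfg$offset_x),
      right_y = to_raw(mk(y0, drift_y), cfg$gain_y, cfg$offset_y),
      events = events, sampling_rate = 1000, units = "raw")
    map <- new_calibration_map(
      gain = c(x = cfg$gain_x, y = cfg$gain_y),
      offset = c(x = cfg$offset_x, y = cfg$offset_y),
      residuals = data.frame(point = integer(0), axis = character(0),
                             resid = numeric(0)),
      targets = targets)
    list(recording = rec, map = map)
  })
}

#' Simulate a null group of paired condition time courses
#'
#' Per-participant time-course pairs of i.i.d. Gaussian noise with zero
#' true condition difference, for type-I-error calibration of the cluster
#' permutation test.
#'
#' @param n_participants Number of participants.
#' @param n_time Number of time samples per course.
#' @param seed Integer seed.
#' @param sd Noise standard deviation.
#' @return List of class `null_group`: matrices `x` and `y`
#'   (participants x time) and the `time` axis.
#' @export
simulate_null_group <- function(n_participants, n_time, seed = 1L, sd = 1) {
  with_seed(seed, {
    structure(list(
      x = matrix(stats::rnorm(n_participants * n_time, 0, sd),
                 n_participants, n_time),
      y = matrix(stats::rnorm(n_participants * n_time, 0, sd),
                 n_participants, n_time),
      time = seq_len(n_time) - 1L), class = "null_group")
  })
}
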