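# Shared fixtures: small simulation configs, hand-built epoch sets, and the
# ground-truth scoring helper for detector recall.

quick_config <- function(...) {
  args <- list(experiment = 1, n_trials = 40L, block_size = 40L,
               blink_rate_hz = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Run the preprocessing chain on a simulated session.
preprocess_session <- function(sess, pad_ms = 50) {
  rec <- interpolate_blinks(sess$recording, pad_ms = pad_ms)
  rec <- normalize_gaze(rec, fit_calibration(rec))
  epoch_and_baseline(rec, sess$trials)
}

# Minimal trial table for hand-built epoch sets.
make_trials <- function(n, cued_side = rep(c("left", "right"),
                                           length.out = n),
                        condition = "a", response_onset_ms = 300,
                        participant = "p1") {
  data.frame(trial_id = seq_len(n), experiment = 1, condition = condition,
             trial_subtype = condition, cued_side = cued_side,
             cue_onset = 1000L, target_orientation = 45,
             reported_orientation = 45,
             response_onset_ms = rep_len(response_onset_ms, n),
             block = 1L, participant = participant,
             stringsAsFactors = FALSE)
}

# Epoch set directly from matrices (trials x time).
make_epochs <- function(x, y = NULL, time = NULL, trials = NULL) {
  if (is.null(y)) y <- matrix(0, nrow(x), ncol(x))
  if (is.null(time)) time <- seq_len(ncol(x)) - 501L
  if (is.null(trials)) trials <- make_trials(nrow(x))
  structure(list(x = x, y = y, time = time, trials = trials,
                 participant = trials$participant[1],
                 baseline_window = c(-500, 0), sampling_rate = 1000,
                 dropped_edge = integer(0)),
            class = "epoch_set")
}

# Score detected events against injected ground truth: recall and onset
# error over isolated truth saccades (no neighbour within `isolation_ms`)
# with amplitude inside `amp_range`, restricted to epochs.
score_detection <- function(truth, events, amp_range = c(3, 30),
                            tol_ms = 20, isolation_ms = 50) {
  iso <- vapply(seq_len(nrow(truth)), function(i) {
    same <- truth$trial_id[-i] %in% truth$trial_id[i]
    others <- truth$t_onset[-i][same]
    length(others) == 0 || min(abs(others - truth$t_onset[i])) >=
      isolation_ms
  }, logical(1))
  tt <- truth[iso & !is.na(truth$trial_id) &
                truth$amplitude >= amp_range[1] &
                truth$amplitude <= amp_range[2] &
                truth$rel_onset > -480 & truth$rel_onset < 1470, ,
              drop = FALSE]
  hits <- 0L
  err <- numeric(0)
  for (i in seq_len(nrow(tt))) {
    cand <- events[events$trial_id == tt$trial_id[i] &
                     abs(events$onset_ms - tt$rel_onset[i]) <= tol_ms, ,
                   drop = FALSE]
    if (nrow(cand)) {
      hits <- hits + 1L
      err <- c(err, min(abs(cand$onset_ms - tt$rel_onset[i])))
    }
  }
  list(n = nrow(tt), recall = hits / nrow(tt),
       mean_onset_err = mean(err))
}

# Expected (noise-free) towardness from ground-truth events: each injected
# saccade contributes its displacement through the saccade waveform;
# baseline-corrected like the real epochs.
oracle_towardness <- function(truth, trials, time = -500:1499) {
  keep <- trials$trial_id
  xdet <- matrix(0, length(keep), length(time))
  sac <- truth$saccades
  for (j in seq_len(nrow(sac))) {
    i <- match(sac$trial_id[j], keep)
    if (is.na(i)) next
    u <- time - sac$rel_onset[j]
    xdet[i, ] <- xdet[i, ] + sac$dx[j] * saccade_waveform(u, 20)
  }
  bl <- time >= -500 & time < 0
  xdet <- xdet - rowMeans(xdet[, bl, drop = FALSE])
  side <- trials$cued_side
  (colMeans(xdet[side == "right", , drop = FALSE]) -
      colMeans(xdet[side == "left", , drop = FALSE])) / 2
}
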