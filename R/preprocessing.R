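# From raw recordings to normalized, baseline-corrected, exclusion-filtered
# epochs: blink interpolation, calibration-based affine normalization,
# epoching around the retro-cue, and the two trial-exclusion rules.

new_calibration_map <- function(gain, offset, residuals, targets) {
  structure(list(gain = gain, offset = offset, residuals = residuals,
                 targets = targets), class = "calibration_map")
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf(paste0("<calibration_map> gain (x, y) = (%.6g, %.6g), ",
                     "offset = (%.6g, %.6g)\n"),
              x$gain["x"], x$gain["y"], x$offset["x"], x$offset["y"]))
  if (nrow(x$residuals)) {
    cat(sprintf("  max |residual| = %.4g normalized units\n",
                max(abs(x$residuals$resid))))
  }
  invisible(x)
}

#' Interpolate blinks with a padded cubic spline
#'
#' Blink intervals are taken from `BLINK_START`/`BLINK_END` markers and
#' from runs of missing samples, padded by `pad_ms` on either side to cover
#' pre/post-blink eyelid artifacts. Each padded gap is replaced by a cubic
#' spline fitted to `anchor_ms` of clean samples on both flanks. Gaps
#' longer than `max_gap_ms` are filled by nearest-value fill instead and
#' recorded in the `long_gaps` attribute so downstream exclusion can flag
#' the affected trials; gaps abutting the recording edge also fall back to
#' nearest-value fill.
#'
#' @param recording A [gaze_recording()].
#' @param pad_ms Pad either side of each blink, ms (default 50).
#' @param anchor_ms Length of the anchor windows outside the padded gap
#'   used to fit the spline (default 100).
#' @param max_gap_ms Longest gap interpolated by spline (default 500).
#' @return The recording with all gaze channels gap-free; attributes
#'   `long_gaps` (data frame of start/end ms) and `edge_fills` record the
#'   fallback fills.
#' @export
interpolate_blinks <- function(recording, pad_ms = 50, anchor_ms = 100,
                               max_gap_ms = 500) {
  abort_if(!inherits(recording, "gaze_recording"),
           "'recording' must be a gaze_recording")
  n <- length(recording$time)
  bad <- is.na(recording$left_x) | is.na(recording$left_y) |
    is.na(recording$right_x) | is.na(recording$right_y)
  ev <- recording$events
  starts <- ev$time[ev$label == "BLINK_START"]
  ends <- ev$time[ev$label == "BLINK_END"]
  if (length(starts)) {
    for (k in seq_along(starts)) {
      i0 <- match(starts[k], recording$time)
      i1 <- match(ends[k], recording$time)
      if (!is.na(i0) && !is.na(i1)) bad[i0:i1] <- TRUE
    }
  }
  if (!any(bad)) return(recording)

  # Pad and merge runs.
  r <- rle(bad)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  runs <- cbind(starts_i[r$values], ends_i[r$values])
  runs[, 1] <- pmax(1L, runs[, 1] - pad_ms)
  runs[, 2] <- pmin(n, runs[, 2] + pad_ms)
  if (nrow(runs) > 1) {
    merged <- list(runs[1, ])
    for (k in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs[k, 1] <= last[2] + 1L) {
        merged[[length(merged)]][2] <- max(last[2], runs[k, 2])
      } else merged[[length(merged) + 1]] <- runs[k, ]
    }
    runs <- do.call(rbind, merged)
  }

  long_gaps <- NULL
  edge_fills <- NULL
  out <- recording
  for (ch in c("left_x", "left_y", "right_x", "right_y")) {
    v <- out[[ch]]
    for (k in seq_len(nrow(runs))) {
      a <- runs[k, 1]; b <- runs[k, 2]
      left_anchor <- seq(max(1L, a - anchor_ms), a - 1L)
      right_anchor <- seq(b + 1L, min(n, b + anchor_ms))
      left_anchor <- left_anchor[left_anchor >= 1 & !is.na(v[left_anchor])]
      right_anchor <- right_anchor[right_anchor <= n &
                                     !is.na(v[right_anchor])]
      gap_len <- b - a + 1L
      if (length(left_anchor) == 0 || length(right_anchor) == 0) {
        # blink abuts the recording edge: nearest-value fill
        src <- if (length(left_anchor)) max(left_anchor) else
          if (length(right_anchor)) min(right_anchor) else NA
        v[a:b] <- if (is.na(src)) 0 else v[src]
        if (ch == "left_x") {
          edge_fills <- rbind(edge_fills,
                              data.frame(start = recording$time[a],
                                         end = recording$time[b]))
        }
      } else if (gap_len > max_gap_ms) {
        half <- floor(gap_len / 2)
        v[a:(a + half - 1L)] <- v[max(left_anchor)]
        v[(a + half):b] <- v[min(right_anchor)]
        if (ch == "left_x") {
          long_gaps <- rbind(long_gaps,
                             data.frame(start = recording$time[a],
                                        end = recording$time[b]))
        }
      } else {
        xs <- c(left_anchor, right_anchor)
        fit <- stats::spline(xs, v[xs], xout = a:b, method = "natural")
        v[a:b] <- fit$y
      }
    }
    out[[ch]] <- v
  }
  attr(out, "long_gaps") <- if (is.null(long_gaps))
    data.frame(start = integer(0), end = integer(0)) else long_gaps
  attr(out, "edge_fills") <- if (is.null(edge_fills))
    data.frame(start = integer(0), end = integer(0)) else edge_fills
  out
}

#' Fit the calibration map from calibration sweeps
#'
#' For each of the 7 calibration points, the median binocular gaze in the
#' window 400-1000 ms after `CALIB_POINT` onset is computed (pooled over
#' all sweeps), and a per-axis least-squares affine is fitted from the raw
#' medians to the nominal target coordinates, mapping central fixation to 0
#' and the left/right stimulus centres to -100/+100.
#'
#' @param recording A [gaze_recording()] in raw units containing
#'   `CALIB_POINT` events.
#' @param nominal_targets Data frame `point`, `x`, `y`; defaults to
#'   [calib_targets()].
#' @param window_ms Post-onset window used for the per-point median.
#' @return A `calibration_map` (per-axis `gain`, `offset`, per-point
#'   `residuals` in normalized units, and the nominal target table).
#' @export
fit_calibration <- function(recording, nominal_targets = calib_targets(),
                            window_ms = c(400, 1000)) {
  abort_if(!inherits(recording, "gaze_recording"),
           "'recording' must be a gaze_recording")
  ev <- recording$events
  cal <- ev[ev$label == "CALIB_POINT", , drop = FALSE]
  abort_if(nrow(cal) == 0, "recording has no CALIB_POINT events")
  pts <- sort(unique(as.integer(cal$arg)))
  med <- data.frame(point = pts, x = NA_real_, y = NA_real_)
  cx <- rowMeans(cbind(recording$left_x, recording$right_x), na.rm = TRUE)
  cy <- rowMeans(cbind(recording$left_y, recording$right_y), na.rm = TRUE)
  for (j in seq_along(pts)) {
    onsets <- cal$time[as.integer(cal$arg) == pts[j]]
    idx <- unlist(lapply(onsets, function(t0) {
      i0 <- match(t0 + window_ms[1], recording$time)
      i1 <- match(t0 + window_ms[2] - 1L, recording$time)
      if (is.na(i0) || is.na(i1)) return(integer(0))
      i0:i1
    }))
    med$x[j] <- stats::median(cx[idx], na.rm = TRUE)
    med$y[j] <- stats::median(cy[idx], na.rm = TRUE)
  }
  tg <- nominal_targets[match(pts, nominal_targets$point), , drop = FALSE]
  fit_axis <- function(raw, nominal, axis) {
    ok <- !is.na(raw)
    abort_if(sum(ok) < 2 || stats::sd(raw[ok]) == 0,
             "degenerate calibration targets on %s axis", axis)
    co <- stats::coef(stats::lm(nominal[ok] ~ raw[ok]))
    gain <- unname(co[2]); off <- unname(-co[1] / co[2])
    abort_if(!is.finite(gain) || gain == 0,
             "calibration fit failed on %s axis", axis)
    resid <- gain * (raw - off) - nominal
    list(gain = gain, offset = off, resid = resid)
  }
  fx <- fit_axis(med$x, tg$x, "x")
  fy <- fit_axis(med$y, tg$y, "y")
  new_calibration_map(
    gain = c(x = fx$gain, y = fy$gain),
    offset = c(x = fx$offset, y = fy$offset),
    residuals = rbind(
      data.frame(point = pts, axis = "x", resid = fx$resid),
      data.frame(point = pts, axis = "y", resid = fy$resid)),
    targets = nominal_targets)
}

#' Normalize a raw recording with a calibration map
#'
#' Applies the per-axis affine `normalized = gain * (raw - offset)` to all
#' four gaze channels and flags the recording as normalized. 100 units
#' correspond to 8 visual degrees. Normalizing an already-normalized
#' recording is an error.
#'
#' @param recording A raw-unit [gaze_recording()].
#' @param map A `calibration_map` from [fit_calibration()].
#' @return The normalized recording.
#' @export
normalize_gaze <- function(recording, map) {
  abort_if(!inherits(recording, "gaze_recording"),
           "'recording' must be a gaze_recording")
  abort_if(!inherits(map, "calibration_map"),
           "'map' must be a calibration_map")
  abort_if(recording$units == "normalized",
           "recording is already normalized")
  out <- recording
  out$left_x <- map$gain["x"] * (recording$left_x - map$offset["x"])
  out$right_x <- map$gain["x"] * (recording$right_x - map$offset["x"])
  out$left_y <- map$gain["y"] * (recording$left_y - map$offset["y"])
  out$right_y <- map$gain["y"] * (recording$right_y - map$offset["y"])
  out$units <- "normalized"
  for (a in c("long_gaps", "edge_fills")) attr(out, a) <- attr(recording, a)
  out
}

#' Epoch a recording around each retro-cue and baseline-correct
#'
#' Cuts one epoch per trial spanning `epoch_window` (default -500 to
#' 1500 ms, half-open) around `cue_onset`, averages the two eyes per axis,
#' and subtracts each trial's mean over `baseline_window` (default the
#' 500 ms preceding the cue) from both channels. Trials whose epoch would
#' extend beyond the recording are dropped and listed in the
#' `dropped_edge` attribute.
#'
#' @param recording A normalized, blink-interpolated [gaze_recording()].
#' @param trials Trial table with `cue_onset` in absolute recording ms.
#' @param epoch_window,baseline_window Half-open `[start, end)` windows in
#'   ms relative to cue onset.
#' @return Object of class `epoch_set`: matrices `x`, `y`
#'   (trials x time, normalized units), the relative `time` axis, the
#'   retained `trials` (with a `long_gap` flag), `participant` and window
#'   metadata.
#' @export
epoch_and_baseline <- function(recording, trials,
                               epoch_window = c(-500, 1500),
                               baseline_window = c(-500, 0)) {
  abort_if(!inherits(recording, "gaze_recording"),
           "'recording' must be a gaze_recording")
  validate_trials(trials)
  offs <- epoch_window[1]:(epoch_window[2] - 1L)
  idx0 <- match(trials$cue_onset, recording$time)
  n_samp <- length(recording$time)
  ok <- !is.na(idx0) & (idx0 + epoch_window[1]) >= 1 &
    (idx0 + epoch_window[2] - 1L) <= n_samp
  dropped <- trials$trial_id[!ok]
  trials <- trials[ok, , drop = FALSE]
  idx0 <- idx0[ok]
  abort_if(nrow(trials) == 0, "no trial epoch fits inside the recording")

  cx <- rowMeans(cbind(recording$left_x, recording$right_x), na.rm = TRUE)
  cy <- rowMeans(cbind(recording$left_y, recording$right_y), na.rm = TRUE)
  im <- outer(idx0, offs, `+`)
  X <- matrix(cx[im], nrow = nrow(trials))
  Y <- matrix(cy[im], nrow = nrow(trials))
  bl <- offs >= baseline_window[1] & offs < baseline_window[2]
  X <- X - rowMeans(X[, bl, drop = FALSE])
  Y <- Y - rowMeans(Y[, bl, drop = FALSE])

  lg <- attr(recording, "long_gaps")
  trials$long_gap <- FALSE
  if (!is.null(lg) && nrow(lg)) {
    e0 <- trials$cue_onset + epoch_window[1]
    e1 <- trials$cue_onset + epoch_window[2]
    for (k in seq_len(nrow(lg))) {
      trials$long_gap <- trials$long_gap |
        (lg$start[k] < e1 & lg$end[k] >= e0)
    }
  }
  structure(list(x = X, y = Y, time = offs, trials = trials,
                 participant = trials$participant[1],
                 baseline_window = baseline_window,
                 sampling_rate = recording$sampling_rate,
                 dropped_edge = dropped),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d samples (%d..%d ms)\n",
              nrow(x$x), length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Subset an epoch set
#'
#' @param epochs An `epoch_set`.
#' @param keep Logical or integer row index, or a condition label.
#' @return The subsetted `epoch_set`.
#' @export
subset_epochs <- function(epochs, keep) {
  abort_if(!inherits(epochs, "epoch_set"), "'epochs' must be an epoch_set")
  if (is.character(keep)) keep <- epochs$trials$condition %in% keep
  out <- epochs
  out$x <- epochs$x[keep, , drop = FALSE]
  out$y <- epochs$y[keep, , drop = FALSE]
  out$trials <- epochs$trials[keep, , drop = FALSE]
  out
}

#' Apply the two trial-exclusion rules
#'
#' Rule 1 (gaze): drop any trial whose horizontal gaze exceeds
#' `gaze_limit` normalized units (absolute value) at any sample in
#' `gaze_window` (default the post-cue analysis window, 0-1500 ms), or
#' whose epoch overlaps an uninterpolatable long blink gap. Rule 2
#' (attentiveness): iteratively drop trials with response onset above the
#' mean + `rt_sd_mult` standard deviations of the remaining trials until no
#' outlier is left. The gaze rule is applied first; the RT rule operates on
#' the gaze-surviving set. `epochs_magnitude` keeps gaze-rule violators
#' (only RT outliers removed), the trial set used for the
#' magnitude-resolved saccade analysis.
#'
#' @param epochs An `epoch_set`.
#' @param gaze_limit Exclusion threshold, normalized units (default 50).
#' @param rt_sd_mult SD multiplier for the response-onset rule (default 4).
#' @param gaze_window Window inspected by the gaze rule, ms relative to
#'   cue.
#' @return List: `epochs` (both rules applied), `epochs_magnitude` (RT rule
#'   only), `report` (per-condition `exclusion_report` data frame) and
#'   `excluded` (trial_id + reason).
#' @export
exclude_trials <- function(epochs, gaze_limit = 50, rt_sd_mult = 4,
                           gaze_window = c(0, 1500)) {
  abort_if(!inherits(epochs, "epoch_set"), "'epochs' must be an epoch_set")
  tr <- epochs$trials
  n <- nrow(tr)
  win <- epochs$time >= gaze_window[1] & epochs$time < gaze_window[2]
  gaze_bad <- apply(abs(epochs$x[, win, drop = FALSE]) > gaze_limit, 1, any)
  if (!is.null(tr$long_gap)) gaze_bad <- gaze_bad | tr$long_gap

  # Iterative response-onset rule on the gaze-surviving set.
  rt_bad <- rep(FALSE, n)
  active <- which(!gaze_bad)
  repeat {
    rts <- tr$response_onset_ms[active]
    if (length(rts) < 2) break
    thr <- mean(rts) + rt_sd_mult * stats::sd(rts)
    out <- rts > thr
    if (!any(out)) break
    rt_bad[active[out]] <- TRUE
    active <- active[!out]
  }
  keep <- !gaze_bad & !rt_bad
  abort_if(!any(keep), "all trials excluded")

  agg <- function(flag) {
    tapply(flag, tr$condition, sum)
  }
  conds <- sort(unique(tr$condition))
  n_total <- as.integer(table(factor(tr$condition, levels = conds)))
  n_gaze <- as.integer(agg(gaze_bad)[conds])
  n_rt <- as.integer(agg(rt_bad)[conds])
  report <- data.frame(
    condition = conds, n_total = n_total,
    n_excluded_gaze = n_gaze, n_excluded_rt = n_rt,
    pct_gaze = 100 * n_gaze / n_total,
    pct_rt = 100 * n_rt / n_total,
    pct_total = 100 * (n_gaze + n_rt) / n_total,
    stringsAsFactors = FALSE)

  excluded <- data.frame(
    trial_id = c(tr$trial_id[gaze_bad], tr$trial_id[rt_bad]),
    reason = c(rep("gaze", sum(gaze_bad)), rep("rt", sum(rt_bad))),
    stringsAsFactors = FALSE)
  list(epochs = subset_epochs(epochs, keep),
       epochs_magnitude = subset_epochs(epochs, !rt_bad),
       report = report, excluded = excluded)
}
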