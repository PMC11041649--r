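# Velocity-threshold detection of gaze shifts (microsaccades), toward/away
# classification against the cued side, and rate / magnitude-resolved
# time courses.

#' Detect gaze shifts by adaptive velocity thresholding
#'
#' Velocity is estimated per axis with a 5-sample symmetric difference
#' filter; the detection threshold per axis is `lambda` times a
#' median-based velocity SD estimated per trial, combined elliptically
#' across the two axes. Supra-threshold runs separated by less than
#' `merge_ms` are merged; runs shorter than `min_dur_ms` are discarded, as
#' are events overlapping the epoch edges (displacement undefined) and
#' events whose horizontal magnitude does not exceed `min_magnitude`
#' normalized units.
#'
#' @param epochs An `epoch_set` (normalized, blink-free).
#' @param lambda Threshold multiplier (default 5).
#' @param min_dur_ms Minimum supra-threshold duration (default 6).
#' @param merge_ms Events closer than this are merged (default 20).
#' @param min_magnitude Retain only events with `|dx| >` this (default 1).
#' @return Data frame of saccade events: `trial_id`, `onset_ms`,
#'   `offset_ms` (relative to cue), `dx` (signed horizontal displacement),
#'   `magnitude`, `peak_velocity` (units/s).
#' @export
detect_saccades <- function(epochs, lambda = 5, min_dur_ms = 6,
                            merge_ms = 20, min_magnitude = 1) {
  abort_if(!inherits(epochs, "epoch_set"), "'epochs' must be an epoch_set")
  nt <- length(epochs$time)
  abort_if(nt < 5, "epoch shorter than the velocity filter window")
  dt <- 1 / epochs$sampling_rate
  out <- vector("list", nrow(epochs$x))
  for (i in seq_len(nrow(epochs$x))) {
    x <- epochs$x[i, ]
    y <- epochs$y[i, ]
    vx <- c(NA, NA, (x[5:nt] + x[4:(nt - 1)] - x[2:(nt - 3)] -
                       x[1:(nt - 4)]) / (6 * dt), NA, NA)
    vy <- c(NA, NA, (y[5:nt] + y[4:(nt - 1)] - y[2:(nt - 3)] -
                       y[1:(nt - 4)]) / (6 * dt), NA, NA)
    msd <- function(v) {
      v <- v[!is.na(v)]
      s <- sqrt(stats::median(v^2) - stats::median(v)^2)
      max(s, 1e-6)
    }
    ex <- lambda * msd(vx)
    ey <- lambda * msd(vy)
    crit <- (vx / ex)^2 + (vy / ey)^2 > 1
    crit[is.na(crit)] <- FALSE
    if (!any(crit)) { out[[i]] <- NULL; next }
    r <- rle(crit)
    e_i <- cumsum(r$lengths)
    s_i <- e_i - r$lengths + 1L
    runs <- cbind(s_i[r$values], e_i[r$values])
    # merge runs whose gap is below merge_ms
    if (nrow(runs) > 1) {
      merged <- list(runs[1, ])
      for (k in 2:nrow(runs)) {
        last <- merged[[length(merged)]]
        if (runs[k, 1] - last[2] < merge_ms) {
          merged[[length(merged)]][2] <- runs[k, 2]
        } else merged[[length(merged) + 1]] <- runs[k, ]
      }
      runs <- do.call(rbind, merged)
    }
    dur <- runs[, 2] - runs[, 1] + 1L
    runs <- runs[dur >= min_dur_ms, , drop = FALSE]
    if (nrow(runs) == 0) { out[[i]] <- NULL; next }
    # drop events touching the epoch edges (velocity undefined there)
    edge <- runs[, 1] <= 3L | runs[, 2] >= nt - 2L
    runs <- runs[!edge, , drop = FALSE]
    if (nrow(runs) == 0) { out[[i]] <- NULL; next }
    dx <- x[runs[, 2]] - x[runs[, 1]]
    pv <- vapply(seq_len(nrow(runs)), function(k) {
      ii <- runs[k, 1]:runs[k, 2]
      max(sqrt(vx[ii]^2 + vy[ii]^2), na.rm = TRUE)
    }, numeric(1))
    ev <- data.frame(trial_id = epochs$trials$trial_id[i],
                     onset_ms = epochs$time[runs[, 1]],
                     offset_ms = epochs$time[runs[, 2]],
                     dx = dx, magnitude = abs(dx), peak_velocity = pv)
    out[[i]] <- ev[ev$magnitude > min_magnitude, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(trial_id = integer(0), onset_ms = integer(0),
                      offset_ms = integer(0), dx = numeric(0),
                      magnitude = numeric(0), peak_velocity = numeric(0))
  }
  rownames(res) <- NULL
  res
}

#' Classify saccades as toward or away from the cued side
#'
#' A saccade is `toward` iff the sign of its horizontal displacement
#' points to the hemifield where the cued item was encoded, `away`
#' otherwise.
#'
#' @param events Saccade events from [detect_saccades()].
#' @param trials Trial table with `trial_id` and `cued_side`.
#' @return `events` with `cued_side` and `direction` columns added.
#' @export
classify_direction <- function(events, trials) {
  abort_if(!all(events$trial_id %in% trials$trial_id),
           "events reference trials absent from the trial table")
  side <- trials$cued_side[match(events$trial_id, trials$trial_id)]
  side_sign <- ifelse(side == "right", 1, -1)
  events$cued_side <- side
  events$direction <- ifelse(sign(events$dx) == side_sign, "toward", "away")
  events
}

#' Toward / away saccade-rate time courses
#'
#' Counts saccade onsets per 1-ms bin across trials, converts to Hz
#' (`count / n_trials * sampling_rate`) and smooths with a mass-conserving
#' 100 ms moving average (see [spread_smooth()]); the time-integral of each
#' rate equals the mean event count per trial exactly. The saccade effect
#' is the toward-minus-away rate.
#'
#' @param events Classified events (with a `direction` column).
#' @param epochs The `epoch_set` the events were detected in (supplies the
#'   time axis and trial count).
#' @param smooth_ms Moving-average window, ms (default 100).
#' @return Data frame of class `saccade_rate`: `time`, `toward_hz`,
#'   `away_hz`, `effect_hz`.
#' @export
rate_timecourses <- function(events, epochs, smooth_ms = 100) {
  abort_if(!inherits(epochs, "epoch_set"), "'epochs' must be an epoch_set")
  n_trials <- nrow(epochs$x)
  abort_if(n_trials == 0, "epoch set has zero trials")
  abort_if(!is.null(events) && nrow(events) > 0 &&
             is.null(events$direction),
           "events must be classified first (see classify_direction)")
  tv <- epochs$time
  rate_of <- function(dir) {
    counts <- numeric(length(tv))
    sel <- events$direction == dir
    if (any(sel)) {
      pos <- match(events$onset_ms[sel], tv)
      tb <- table(pos[!is.na(pos)])
      counts[as.integer(names(tb))] <- as.numeric(tb)
    }
    spread_smooth(counts, smooth_ms) / n_trials * epochs$sampling_rate
  }
  toward <- rate_of("toward")
  away <- rate_of("away")
  structure(data.frame(time = tv, toward_hz = toward, away_hz = away,
                       effect_hz = toward - away),
            class = c("saccade_rate", "data.frame"),
            smooth_ms = smooth_ms, n_trials = n_trials)
}

#' Magnitude-resolved toward-minus-away rate map
#'
#' Sorts saccades into half-open magnitude bins (default edges 2 to 110
#' normalized units, width 4) and computes the toward-minus-away rate per
#' (time, magnitude-bin) cell with the same smoothing as the 1-D time
#' courses. Per the analysis design this is computed on trials filtered
#' only by the response-onset rule, not the gaze-position rule.
#'
#' @param events Classified events.
#' @param epochs The `epoch_set` the events were detected in.
#' @param edges Bin edges, normalized units (default `seq(2, 110, 4)`).
#' @param smooth_ms Moving-average window, ms.
#' @return List of class `magnitude_map`: `time`, `edges`, and `effect`
#'   (time x bin matrix, Hz).
#' @export
magnitude_bias_map <- function(events, epochs, edges = seq(2, 110, 4),
                               smooth_ms = 100) {
  abort_if(!inherits(epochs, "epoch_set"), "'epochs' must be an epoch_set")
  n_trials <- nrow(epochs$x)
  abort_if(n_trials == 0, "epoch set has zero trials")
  tv <- epochs$time
  nb <- length(edges) - 1L
  eff <- matrix(0, length(tv), nb)
  if (!is.null(events) && nrow(events)) {
    bin <- findInterval(events$magnitude, edges, rightmost.closed = FALSE)
    bin[events$magnitude >= edges[length(edges)]] <- NA
    bin[bin == 0] <- NA
    for (b in seq_len(nb)) {
      sel <- !is.na(bin) & bin == b
      if (!any(sel)) next
      counts <- numeric(length(tv))
      pos <- match(events$onset_ms[sel], tv)
      sgn <- ifelse(events$direction[sel] == "toward", 1, -1)
      ok <- !is.na(pos)
      for (k in which(ok)) counts[pos[k]] <- counts[pos[k]] + sgn[k]
      eff[, b] <- spread_smooth(counts, smooth_ms) / n_trials *
        epochs$sampling_rate
    }
  }
  structure(list(time = tv, edges = edges, effect = eff),
            class = "magnitude_map")
}
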