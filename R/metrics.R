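# The towardness gaze-bias statistic and the behavioural measures
# (orientation reproduction error, response onset).

#' Towardness time course
#'
#' The standardized gaze-bias metric: at each sample, the mean horizontal
#' gaze position over right-cued trials minus the mean over left-cued
#' trials, divided by two. Positive values mean gaze is biased toward the
#' cued item's encoded side (rightward positive). Mirroring the epochs
#' (negating x and swapping cued sides) negates towardness exactly.
#'
#' @param epochs A baseline-corrected, exclusion-filtered `epoch_set`
#'   containing both cue sides.
#' @return Data frame of class `cond_timecourse`: `time`, `value`
#'   (normalized units).
#' @export
towardness <- function(epochs) {
  abort_if(!inherits(epochs, "epoch_set"), "'epochs' must be an epoch_set")
  side <- epochs$trials$cued_side
  abort_if(!all(c("left", "right") %in% side),
           "towardness needs trials from both cue sides")
  tw <- (colMeans(epochs$x[side == "right", , drop = FALSE]) -
           colMeans(epochs$x[side == "left", , drop = FALSE])) / 2
  structure(data.frame(time = epochs$time, value = tw),
            class = c("cond_timecourse", "data.frame"),
            metric = "towardness")
}

#' Average a time course over the post-cue delay period
#'
#' Scalar summary used for condition contrasts: the mean of the metric
#' over the delay window (default 0-1500 ms after cue onset, half-open).
#'
#' @param tc A data frame with `time` plus a value column, or a
#'   `saccade_rate` (its `effect_hz` is used).
#' @param window Half-open averaging window, ms.
#' @return Scalar mean.
#' @export
delay_average <- function(tc, window = c(0, 1500)) {
  val <- if (!is.null(tc$value)) tc$value else tc$effect_hz
  abort_if(is.null(val), "no value column found")
  sel <- tc$time >= window[1] & tc$time < window[2]
  abort_if(!any(sel), "window outside the time axis")
  mean(val[sel])
}

#' Orientation reproduction error
#'
#' Minimal angular distance between reported and true orientation in
#' 180-degree circular space: `min(|a - b|, 180 - |a - b|)`, in `[0, 90]`.
#' Uniform random responses give a mean error of 45 degrees (chance
#' level).
#'
#' @param reported,target Orientations in degrees, `[0, 180)` (vectorised).
#' @return Absolute errors in degrees.
#' @export
reproduction_error <- function(reported, target) {
  ok <- function(v) all(v >= 0 & v < 180)
  abort_if(!ok(reported) || !ok(target),
           "orientations must lie in [0, 180)")
  d <- abs(reported - target)
  pmin(d, 180 - d)
}

#' Per-participant, per-condition behavioural summary
#'
#' Mean orientation reproduction error and mean response onset for each
#' participant x condition cell. Empty cells are marked with `NA`.
#'
#' @param trials Trial table (filtered like the gaze analysis), with a
#'   `participant` column (a single unnamed participant is assumed if
#'   absent).
#' @return Data frame: `participant`, `condition`, `n_trials`,
#'   `mean_error_deg`, `mean_response_onset_ms`.
#' @export
behaviour_summary <- function(trials) {
  if (is.null(trials$participant)) trials$participant <- "p1"
  err <- reproduction_error(trials$reported_orientation,
                            trials$target_orientation)
  cells <- expand.grid(participant = unique(trials$participant),
                       condition = sort(unique(trials$condition)),
                       stringsAsFactors = FALSE)
  cells$n_trials <- 0L
  cells$mean_error_deg <- NA_real_
  cells$mean_response_onset_ms <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sel <- trials$participant == cells$participant[i] &
      trials$condition == cells$condition[i]
    if (any(sel)) {
      cells$n_trials[i] <- sum(sel)
      cells$mean_error_deg[i] <- mean(err[sel])
      cells$mean_response_onset_ms[i] <- mean(trials$response_onset_ms[sel])
    }
  }
  cells
}
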