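# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed.
#'
#' @param seed Integer seed (must be below 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(code)
}

# Derive a deterministic per-participant sub-seed from a master seed,
# kept within the 32-bit integer range R requires.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

#' Mass-conserving moving-average smoothing of count time courses
#'
#' Spreads each 1-sample count uniformly over a `window_ms`-wide window
#' centred on it (left-heavy by one sample for even windows), truncating at
#' the series edges. Away from the edges this equals a centred moving
#' average; unlike a plain shrinking-window average it conserves total mass
#' exactly, so the time-integral of a smoothed rate still equals events per
#' trial.
#'
#' @param counts Numeric vector of per-sample counts (or rates).
#' @param window_ms Window length in samples (default 100).
#' @return Smoothed numeric vector of the same length.
#' @keywords internal
spread_smooth <- function(counts, window_ms = 100) {
  n <- length(counts)
  if (window_ms <= 1 || n == 0) return(counts)
  left <- floor(window_ms / 2)
  right <- window_ms - left - 1
  out <- numeric(n)
  idx <- which(counts != 0)
  for (j in idx) {
    a <- max(1L, j - left)
    b <- min(n, j + right)
    out[a:b] <- out[a:b] + counts[j] / (b - a + 1L)
  }
  out
}

#' Saccade displacement waveform
#'
#' Smooth sigmoidal (raised-cosine) position profile used by the synthetic
#' generator for injected saccades: 0 before onset, 1 after `dur_ms`, with
#' the velocity peak at mid-flight. C1-continuous, so velocity-threshold
#' detectors see a single clean velocity pulse.
#'
#' @param u_ms Time since saccade onset, ms (vectorised).
#' @param dur_ms Saccade duration in ms (default 20).
#' @return Fraction of total displacement completed at `u_ms`, in `[0, 1]`.
#' @export
saccade_waveform <- function(u_ms, dur_ms = 20) {
  u <- pmin(pmax(u_ms / dur_ms, 0), 1)
  (1 - cos(pi * u)) / 2
}

# Stop unless cond is TRUE; msg is sprintf-style.
abort_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
  invisible(NULL)
}
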