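# Blink interpolation, calibration fitting and normalization, epoching,
# and the two exclusion rules.

blank_recording <- function(x, events = NULL) {
  n <- length(x)
  if (is.null(events)) events <- data.frame(time = integer(0),
                                            label = character(0),
                                            arg = character(0))
  gaze_recording(0:(n - 1), x, x, x, x, events = events,
                 units = "normalized")
}

test_that("recordings without blinks pass through untouched", {
  rec <- blank_recording(sin(seq(0, 2, length.out = 500)))
  expect_identical(interpolate_blinks(rec)$left_x, rec$left_x)
})

test_that("spline interpolation restores a linear ramp exactly", {
  x <- seq(0, 10, length.out = 1000)
  x[400:500] <- NA
  rec <- blank_recording(x)
  out <- interpolate_blinks(rec, pad_ms = 50)
  truth <- seq(0, 10, length.out = 1000)
  expect_equal(out$left_x, truth, tolerance = 1e-8)
  expect_false(anyNA(out$right_y))
})

test_that("spline error on a slow sinusoid stays below the analytic bound", {
  t <- 0:2999
  truth <- 10 * sin(2 * pi * t / 2000)
  x <- truth
  gap <- 1400:1600
  x[gap] <- NA
  out <- interpolate_blinks(blank_recording(x), pad_ms = 50)
  # cubic-spline bound (5/384) h^4 max|f''''| over the padded gap width
  h <- (diff(range(gap)) + 100)
  bound <- 5 / 384 * h^4 * 10 * (2 * pi / 2000)^4
  expect_lt(max(abs(out$left_x[gap] - truth[gap])), max(bound, 1e-6))
})

test_that("edge blinks fall back to nearest-value fill and are logged", {
  x <- c(rep(NA, 30), rep(5, 470))
  out <- interpolate_blinks(blank_recording(x), pad_ms = 10)
  expect_equal(out$left_x[1:30], rep(5, 30))
  expect_gt(nrow(attr(out, "edge_fills")), 0)
})

test_that("gaps beyond the spline limit are flagged as long gaps", {
  x <- rep(1, 2000)
  x[500:1200] <- NA
  out <- interpolate_blinks(blank_recording(x), max_gap_ms = 500)
  expect_false(anyNA(out$left_x))
  expect_equal(nrow(attr(out, "long_gaps")), 1)
})

test_that("calibration fit recovers identity and synthetic affines", {
  # medians already in normalized coordinates -> gain 1, offset 0
  cfg <- quick_config(noise_sd = 0, drift_sd = 0, gain_x = 1, offset_x = 0,
                      gain_y = 1, offset_y = 0)
  cal <- simulate_calibration(cfg, seed = 2)
  m <- fit_calibration(cal$recording)
  expect_equal(unname(m$gain), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(m$offset), c(0, 0), tolerance = 1e-9)

  # noise-free recovery of gain 0.05 / offset 512 to <= 1e-6
  cfg2 <- quick_config(noise_sd = 0, drift_sd = 0)
  cal2 <- simulate_calibration(cfg2, seed = 2)
  m2 <- fit_calibration(cal2$recording)
  expect_equal(unname(m2$gain["x"]), 0.05, tolerance = 1e-6)
  expect_equal(unname(m2$offset["x"]), 512, tolerance = 1e-6)
  expect_lt(max(abs(m2$residuals$resid)), 1e-6)

  # the fitted map sends fixation to 0 and the left stimulus to -100
  rec_n <- normalize_gaze(cal2$recording, m2)
  ev <- rec_n$events
  t_fix <- ev$time[ev$arg == "1"]
  t_left <- ev$time[ev$arg == "2"]
  med_at <- function(t0) {
    idx <- match(t0 + 400:999, rec_n$time)
    median(rec_n$left_x[idx])
  }
  expect_equal(med_at(t_fix), 0, tolerance = 1e-6)
  expect_equal(med_at(t_left), -100, tolerance = 1e-6)
})

test_that("degenerate calibration targets raise a fit error", {
  x <- rep(100, 3000)
  ev <- data.frame(time = c(0L, 1200L), label = "CALIB_POINT",
                   arg = c("1", "2"))
  rec <- gaze_recording(0:2999, x, x, x, x, events = ev, units = "raw")
  expect_error(fit_calibration(rec), "degenerate")
})

test_that("normalization is the stated affine and refuses double application", {
  m <- gazebias:::new_calibration_map(
    gain = c(x = 0.05, y = 0.1), offset = c(x = 512, y = 384),
    residuals = data.frame(point = integer(0), axis = character(0),
                           resid = numeric(0)),
    targets = calib_targets())
  raw <- gaze_recording(0:2, c(512, 612, 412), rep(384, 3),
                        c(512, 612, 412), rep(384, 3), units = "raw")
  nm <- normalize_gaze(raw, m)
  expect_equal(nm$left_x, c(0, 5, -5))
  expect_equal(nm$left_y, c(0, 0, 0))
  expect_equal(nm$units, "normalized")
  # invertibility to machine precision
  expect_equal(nm$left_x / m$gain["x"] + m$offset["x"], raw$left_x,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(normalize_gaze(nm, m), "already normalized")
})

test_that("epoching slices, baselines and drops edge trials", {
  n <- 6000
  x <- seq_len(n) * 0.01  # ramp: nonzero baseline per trial
  ev <- data.frame(time = c(1000L, 3000L, 5800L), label = "CUE_ONSET",
                   arg = c("1", "2", "3"))
  rec <- gaze_recording(0:(n - 1), x, x, x, x, events = ev,
                        units = "normalized")
  tr <- make_trials(3)
  tr$cue_onset <- c(1000L, 3000L, 5800L)  # third extends past the end
  ep <- epoch_and_baseline(rec, tr)
  expect_equal(nrow(ep$x), 2)
  expect_equal(ep$dropped_edge, 3L)
  expect_equal(length(ep$time), 2000)
  expect_equal(range(ep$time), c(-500, 1499))
  bl <- ep$time >= -500 & ep$time < 0
  expect_lt(max(abs(rowMeans(ep$x[, bl]))), 1e-12)
  # constant channel -> all-zero epochs
  rec2 <- gaze_recording(0:(n - 1), rep(7, n), rep(7, n), rep(7, n),
                         rep(7, n), events = ev, units = "normalized")
  ep2 <- epoch_and_baseline(rec2, tr)
  expect_equal(max(abs(ep2$x)), 0)
})

test_that("gaze rule drops exactly the trials that surpass 50 units", {
  x <- matrix(0, 4, 2000)
  x[2, 900] <- 60    # post-cue excursion -> dropped
  x[3, 100] <- 80    # pre-cue (baseline window) -> kept
  x[4, 1200] <- 49.9 # below threshold -> kept
  ep <- make_epochs(x, trials = make_trials(4, condition = "a"))
  res <- exclude_trials(ep)
  expect_equal(res$report$n_excluded_gaze, 1)
  expect_equal(res$excluded$trial_id[res$excluded$reason == "gaze"], 2L)
  expect_equal(nrow(res$epochs$x), 3)
  # magnitude set keeps the gaze violator
  expect_equal(nrow(res$epochs_magnitude$x), 4)
})

test_that("iterative response-onset rule matches hand iteration", {
  # single clear outlier
  tr <- make_trials(20, response_onset_ms = c(rep(300, 19), 10000))
  ep <- make_epochs(matrix(0, 20, 2000), trials = tr)
  res <- exclude_trials(ep)
  expect_equal(res$excluded$trial_id[res$excluded$reason == "rt"], 20L)

  # removal of the extreme outlier exposes a second one
  rts <- c(rep(100, 20), 190, 1000)
  tr2 <- make_trials(22, response_onset_ms = rts)
  ep2 <- make_epochs(matrix(0, 22, 2000), trials = tr2)
  res2 <- exclude_trials(ep2)
  # independent oracle: explicit loop
  active <- seq_along(rts)
  repeat {
    thr <- mean(rts[active]) + 4 * sd(rts[active])
    out <- rts[active] > thr
    if (!any(out)) break
    active <- active[!out]
  }
  oracle_excluded <- sort(setdiff(seq_along(rts), active))
  expect_equal(sort(res2$excluded$trial_id[res2$excluded$reason == "rt"]),
               oracle_excluded)
  expect_equal(oracle_excluded, c(21L, 22L))  # two iterations needed
})

test_that("exclusion is idempotent and errors when nothing survives", {
  set.seed(1)
  x <- matrix(rnorm(10 * 2000), 10, 2000)
  tr <- make_trials(10, response_onset_ms = rlnorm(10, log(300), 0.2))
  ep <- make_epochs(x, trials = tr)
  res1 <- exclude_trials(ep)
  res2 <- exclude_trials(res1$epochs)
  expect_equal(res2$report$n_excluded_gaze, rep(0, nrow(res2$report)))
  expect_equal(res2$report$n_excluded_rt, rep(0, nrow(res2$report)))
  expect_equal(nrow(res2$epochs$x), nrow(res1$epochs$x))

  xall <- matrix(100, 3, 2000)
  expect_error(exclude_trials(make_epochs(xall, trials = make_trials(3))),
               "all trials excluded")
})

test_that("simulated sessions stay in the single-digit exclusion corridor", {
  sess <- simulate_session(quick_config(n_trials = 80, block_size = 40,
                                        blink_rate_hz = 0.1), seed = 31)
  res <- exclude_trials(preprocess_session(sess))
  total_pct <- 100 * sum(res$report$n_excluded_gaze +
                           res$report$n_excluded_rt) /
    sum(res$report$n_total)
  expect_lt(total_pct, 10)
})
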