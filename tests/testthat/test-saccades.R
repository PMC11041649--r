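# Velocity-threshold detection, direction classification, rate time
# courses and the magnitude-resolved bias map.

step_trace <- function(onset, dx, n = 2000, dur = 20) {
  saccade_waveform(seq_len(n) - 1 - onset, dur) * dx
}

test_that("pure noise produces no events (threshold adapts)", {
  set.seed(4)
  x <- matrix(rnorm(3 * 2000, 0, 0.2), 3, 2000)
  y <- matrix(rnorm(3 * 2000, 0, 0.2), 3, 2000)
  ev <- detect_saccades(make_epochs(x, y, trials = make_trials(3)))
  expect_equal(nrow(ev), 0)
})

test_that("a single smooth step is detected once with its displacement", {
  set.seed(5)
  x <- matrix(step_trace(1100, 10), 1, 2000)  # onset at t = 600 ms
  x <- x + rnorm(2000, 0, 0.15)
  ev <- detect_saccades(make_epochs(x, trials = make_trials(1)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$dx, 10, tolerance = 0.1)
  expect_lt(abs(ev$onset_ms - 600), 6)
  expect_gt(ev$peak_velocity, 0)
  expect_gt(ev$offset_ms, ev$onset_ms)
})

test_that("detector recovers injected saccades from simulator noise", {
  cfg <- quick_config(n_trials = 60, block_size = 60, return_prob = 0)
  sess <- simulate_session(cfg, seed = 42)
  ep <- preprocess_session(sess)
  ev <- detect_saccades(ep)
  sc <- score_detection(sess$truth$saccades, ev)
  expect_gt(sc$n, 50)
  expect_gte(sc$recall, 0.95)
  expect_lte(sc$mean_onset_err, 5)
})

test_that("direction classification follows the cued side", {
  ev <- data.frame(trial_id = c(1L, 2L), onset_ms = c(100, 100),
                   offset_ms = c(120, 120), dx = c(5, 5),
                   magnitude = c(5, 5), peak_velocity = c(400, 400))
  tr <- make_trials(2, cued_side = c("right", "left"))
  cl <- classify_direction(ev, tr)
  expect_equal(cl$direction, c("toward", "away"))
  expect_error(classify_direction(transform(ev, trial_id = 9L), tr),
               "absent")
})

test_that("simulated biased sessions carry the injected toward surplus", {
  cfg <- quick_config(n_trials = 60, block_size = 60, return_prob = 0)
  sess <- simulate_session(cfg, seed = 13)
  ep <- preprocess_session(sess)
  ev <- classify_direction(detect_saccades(ep), ep$trials)
  truth <- sess$truth$saccades
  true_toward <- sum(truth$type == "toward")
  true_away <- sum(truth$type == "away")
  win <- ev$onset_ms >= cfg$bias_latency_ms & ev$onset_ms <= cfg$bias_end_ms
  det_toward <- sum(ev$direction[win] == "toward")
  det_away <- sum(ev$direction[win] == "away")
  # detected surplus tracks the ground-truth surplus (within detector loss)
  expect_gt(true_toward, true_away)
  expect_gt(det_toward, det_away)
  expect_equal(det_toward / (det_toward + det_away),
               true_toward / (true_toward + true_away), tolerance = 0.12)
})

test_that("one toward event per trial gives a flat 10 Hz smoothed window", {
  n_tr <- 100
  ev <- data.frame(trial_id = 1:n_tr, onset_ms = 600, offset_ms = 620,
                   dx = 5, magnitude = 5, peak_velocity = 400,
                   cued_side = "right", direction = "toward")
  ep <- make_epochs(matrix(0, n_tr, 2000),
                    trials = make_trials(n_tr, cued_side = "right"))
  rt <- rate_timecourses(ev, ep, smooth_ms = 100)
  inwin <- rt$time >= 550 & rt$time <= 649
  expect_equal(rt$toward_hz[inwin], rep(10, 100))
  expect_equal(sum(rt$toward_hz[!inwin]), 0)
  expect_equal(rt$away_hz, rep(0, 2000))
  expect_equal(rt$effect_hz, rt$toward_hz)
})

test_that("no events gives all-zero rates; zero trials is an error", {
  ep <- make_epochs(matrix(0, 5, 2000), trials = make_trials(5))
  ev <- detect_saccades(ep)
  rt <- rate_timecourses(classify_direction(ev, ep$trials), ep)
  expect_equal(sum(abs(rt$toward_hz)) + sum(abs(rt$away_hz)), 0)
  empty <- subset_epochs(ep, rep(FALSE, 5))
  expect_error(rate_timecourses(ev, empty), "zero trials")
})

test_that("smoothed rates conserve events per trial exactly", {
  set.seed(8)
  n_tr <- 20
  ev <- data.frame(trial_id = sample(1:n_tr, 57, replace = TRUE),
                   onset_ms = sample(-450:1450, 57, replace = TRUE),
                   offset_ms = 0, dx = 5, magnitude = 5,
                   peak_velocity = 400, cued_side = "right",
                   direction = sample(c("toward", "away"), 57,
                                      replace = TRUE))
  ev$offset_ms <- ev$onset_ms + 20
  ep <- make_epochs(matrix(0, n_tr, 2000),
                    trials = make_trials(n_tr, cued_side = "right"))
  rt <- rate_timecourses(ev, ep, smooth_ms = 100)
  # sum(rate) * dt = events / trial, exactly
  expect_equal(sum(rt$toward_hz) * 1e-3,
               sum(ev$direction == "toward") / n_tr, tolerance = 1e-12)
  expect_equal(sum(rt$away_hz) * 1e-3,
               sum(ev$direction == "away") / n_tr, tolerance = 1e-12)
})

test_that("Poisson onsets at 2 Hz are estimated within sampling error", {
  set.seed(9)
  n_tr <- 150
  lam <- 2 * 2  # 2 Hz over the 2 s epoch
  counts <- rpois(n_tr, lam)
  ev <- data.frame(trial_id = rep(1:n_tr, counts))
  ev$onset_ms <- sample(-500:1499, nrow(ev), replace = TRUE)
  ev$offset_ms <- ev$onset_ms + 20
  ev$dx <- 5; ev$magnitude <- 5; ev$peak_velocity <- 400
  ev$cued_side <- "right"; ev$direction <- "toward"
  ep <- make_epochs(matrix(0, n_tr, 2000),
                    trials = make_trials(n_tr, cued_side = "right"))
  rt <- rate_timecourses(ev, ep)
  est <- mean(rt$toward_hz)
  se <- sqrt(lam / n_tr) / 2  # SE of the mean rate in Hz
  expect_lt(abs(est - 2), 3 * se)
})

test_that("lowering the magnitude floor never loses events", {
  cfg <- quick_config(n_trials = 30, block_size = 30)
  ep <- preprocess_session(simulate_session(cfg, seed = 17))
  n1 <- nrow(detect_saccades(ep, min_magnitude = 2))
  n2 <- nrow(detect_saccades(ep, min_magnitude = 1))
  n3 <- nrow(detect_saccades(ep, min_magnitude = 0.5))
  expect_true(n3 >= n2 && n2 >= n1)
})

test_that("mirror flip swaps labels and negates the rate effect exactly", {
  cfg <- quick_config(n_trials = 40, block_size = 40)
  ep <- preprocess_session(simulate_session(cfg, seed = 19))
  ev <- detect_saccades(ep)
  tr <- ep$trials
  trf <- transform(tr, cued_side = ifelse(cued_side == "left", "right",
                                          "left"))
  a <- classify_direction(ev, tr)
  b <- classify_direction(ev, trf)
  expect_true(all((a$direction == "toward") == (b$direction == "away")))
  ra <- rate_timecourses(a, ep)
  rb <- rate_timecourses(b, ep)
  expect_equal(rb$effect_hz, -ra$effect_hz)
})

test_that("magnitude map bins at 2:4:110 and sums back to the 1-D effect", {
  set.seed(10)
  n_tr <- 15
  ev <- data.frame(trial_id = sample(1:n_tr, 80, replace = TRUE),
                   onset_ms = sample(0:1400, 80, replace = TRUE),
                   dx = runif(80, 2.1, 100) *
                     sample(c(-1, 1), 80, replace = TRUE))
  ev$offset_ms <- ev$onset_ms + 20
  ev$magnitude <- abs(ev$dx)
  ev$peak_velocity <- 400
  ep <- make_epochs(matrix(0, n_tr, 2000),
                    trials = make_trials(n_tr))
  ev <- classify_direction(ev, ep$trials)
  mp <- magnitude_bias_map(ev, ep)
  expect_equal(mp$edges, seq(2, 110, 4))
  expect_equal(ncol(mp$effect), 27)
  rt <- rate_timecourses(ev, ep)
  expect_equal(rowSums(mp$effect), rt$effect_hz, tolerance = 1e-12)

  # all events of one magnitude occupy exactly one bin
  ev5 <- transform(ev, dx = sign(dx) * 5, magnitude = 5)
  mp5 <- magnitude_bias_map(ev5, ep)
  nz <- which(colSums(abs(mp5$effect)) > 0)
  expect_equal(unname(nz), 1L)  # magnitude 5 falls in bin [2, 6) only
})
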