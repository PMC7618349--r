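test_that("RPE traces follow their definitions", {
  s <- make_session(c(1L, 1L, 0L), c(1L, 0L, 1L))
  lat_q <- data.frame(trial = 0:2, p_left = 0.5, p_right = 0.5,
                      q_left = c(0.5, 0.5, 0.5), q_right = c(0.5, 0.75, 0.4),
                      belief_R = 0.5, rpe = 0)
  lat_si <- lat_q
  lat_si$belief_R <- c(0.5, 0.77, 0.1)
  rpe <- rpe_trace(s, lat_q, lat_si)
  expect_equal(rpe$q_rpe, c(1 - 0.5, 0 - 0.75, 1 - 0.5))
  # belief 0.77 on right-high, chose right: E = 0.77*0.7 + 0.23*0.1
  expect_equal(rpe$si_rpe[2], 0 - (0.77 * 0.7 + 0.23 * 0.1),
               tolerance = 1e-12)
  # certain and correct on the high side, omission: -0.7
  s3 <- make_session(0L, 0L, high_side = 0L)
  l3 <- lat_q[1, ]; l3$belief_R <- 0
  expect_equal(rpe_trace(s3, l3, l3)$si_rpe, -0.7, tolerance = 1e-12)
  expect_error(rpe_trace(s, lat_q[1:2, ], lat_si), "lengths differ")
})

test_that("a noiseless single-trial synthetic trace is the scaled sensor
           kernel", {
  s <- make_session(1L, 1L)
  set.seed(61)
  ph <- synth_photometry(s, rpe = 0.8, noise_sd = 0, drift_amp = 0,
                         motion_sd = 0)
  fs <- ph$sample_rate
  i0 <- floor(ph$events$outcome_cue * fs) + 1
  kt <- (0:(2 * fs - 1)) / fs
  expect_equal(ph$signal_470[i0:(i0 + 2 * fs - 1)],
               0.8 * banditSI:::sensor_kernel(kt), tolerance = 1e-12)
  expect_true(all(ph$signal_470[1:(i0 - 1)] == 0))
})

test_that("preprocessing removes artifacts and recovers the embedded
           transient", {
  set.seed(62)
  s <- run_session(task_config(n_trials = 60), function(t) c(0.5, 0.5))
  amp <- stats::rnorm(60, 0, 0.5)
  ph <- synth_photometry(s, amp)
  out <- preprocess_photometry(ph)
  expect_equal(mean(out), 0, tolerance = 1e-8)
  expect_equal(stats::sd(out), 1, tolerance = 1e-8)
  expect_gt(stats::cor(out, ph$ground_truth), 0.8)
  # pure shared artifact: the corrected output is uncorrelated with it
  ph0 <- synth_photometry(s, rep(0, 60), noise_sd = 0.01)
  out0 <- preprocess_photometry(ph0)
  expect_lt(abs(stats::cor(out0, ph0$control_405)), 0.1)
  expect_error(preprocess_photometry(
    structure(list(signal_470 = rep(1, 1000), control_405 = rep(1, 1000),
                   sample_rate = 100), class = "photometry_session")))
})

test_that("event summaries are baselined means, invariant to constant
           offsets", {
  fs <- 100
  tr <- rep(0, 10 * fs)
  expect_equal(event_summary(tr, 5, fs), 0)
  # unit step at the event
  tr2 <- c(rep(0, 5 * fs), rep(1, 5 * fs))
  expect_equal(event_summary(tr2, 5, fs), 1)
  expect_equal(event_summary(tr2 + 3.7, 5, fs), 1, tolerance = 1e-12)
  # kernel transient: numeric quadrature oracle
  tt <- (0:(10 * fs - 1)) / fs
  k <- banditSI:::sensor_kernel(tt - 5)
  expected <- mean(k[(5 * fs + 1):(9 * fs)])
  expect_equal(event_summary(k, 5, fs), expected, tolerance = 1e-6)
  # out-of-bounds events are skipped with a warning
  expect_warning(v <- event_summary(tr, 9.9, fs), "outside")
  expect_true(is.na(v))
})

test_that("history splits label trials per the worked examples", {
  # choices L,L,R with middle trial rewarded status varying
  s1 <- make_session(c(0L, 0L, 1L), c(1L, 1L, 1L))
  h1 <- history_split(s1, c(0, 0, 5))
  # trial 3: switched (O), previous rewarded (+), current rewarded (+)
  expect_equal(h1$n[h1$group == "O+/cur+"], 1)
  s2 <- make_session(c(0L, 0L, 1L), c(1L, 0L, 1L))
  h2 <- history_split(s2, c(0, 0, 5))
  expect_equal(h2$n[h2$group == "O-/cur+"], 1)
  # all-stay session: no O groups
  s3 <- make_session(rep(1L, 20), rep(c(1L, 0L), 10))
  h3 <- history_split(s3, rep(1, 20))
  expect_false(any(grepl("^O", h3$group)))
  expect_equal(sum(h3$n), 19)
})

test_that("group-mean regression attributes variance to the generating
           RPE", {
  set.seed(63)
  g <- run_generative(exemplar_specs()$si, list(c = 0.8, gamma = 0.9,
                                                bias = 0),
                      task_config(n_trials = 400))
  s <- g$session
  rpe <- rpe_trace(s, g$latents, g$latents)
  gr_si <- history_split(s, rpe$si_rpe)
  gr_q <- history_split(s, rpe$q_rpe)
  # dopamine identical to the SI-RPE group means: R2(SI) = 1
  r2 <- rpe_group_regression(gr_si, list(q = gr_q, si = gr_si))
  expect_equal(r2$r2[r2$model == "si"], 1, tolerance = 1e-12)
  expect_lte(r2$r2[r2$model == "q"], 1)
  # uncorrelated noise explains nothing
  noise <- gr_si; noise$mean <- stats::rnorm(nrow(noise))
  r2n <- rpe_group_regression(noise, list(q = gr_q, si = gr_si))
  expect_lt(max(r2n$r2), 0.8)
  few <- gr_si[1:2, ]
  expect_error(rpe_group_regression(few, list(si = gr_si)), "3")
})

test_that("time warping preserves anchored structure", {
  fs <- 200
  events <- data.frame(initiation = c(1, 6), lever_press = c(1.4, 6.9),
                       outcome_cue = c(1.7, 7.1))
  tt <- (0:(13 * fs - 1)) / fs
  # linear trace stays linear under a piecewise-linear warp
  w <- timewarp(tt, events, fs)
  for (i in 1:2) {
    seg <- w$mat[i, w$time >= 0.8]        # post-outcome: identity speed
    expect_equal(diff(seg), rep(diff(seg)[1], length(seg) - 1),
                 tolerance = 1e-9)
  }
  # a kernel at the outcome lands on the same warped samples in both trials
  k <- banditSI:::sensor_kernel(tt - events$outcome_cue[1]) +
       banditSI:::sensor_kernel(tt - events$outcome_cue[2])
  wk <- timewarp(k, events, fs)
  post <- w$time >= 0.8
  expect_equal(wk$mat[1, post], wk$mat[2, post], tolerance = 1e-3)
  # identity case: anchors already on the template
  ev_id <- data.frame(initiation = 2, lever_press = 2.6, outcome_cue = 2.8)
  tr <- sin(2 * pi * tt / 3)
  wi <- timewarp(tr, ev_id, fs)
  expect_equal(wi$mat[1, ], sin(2 * pi * (wi$time + 2) / 3),
               tolerance = 1e-4)
  bad <- data.frame(initiation = 2, lever_press = 1.9, outcome_cue = 2.5)
  expect_error(timewarp(tr, bad, fs), "monotone")
})

test_that("ridge CPD credits the generating RPE and flags degenerate
           designs", {
  set.seed(64)
  run <- rpe_signature_run("si", n_sessions = 1, n_trials = 300,
                           n_restarts = 10)
  expect_gt(run$n_trials_used, 10)
  expect_true(is.finite(run$cpd_si) && is.finite(run$cpd_q))
  # constant predictor after filtering is reported
  g <- run_generative(exemplar_specs()$si, list(c = 0.8, gamma = 0.9,
                                                bias = 0),
                      task_config(n_trials = 200))
  s <- g$session
  s$reward <- 1L   # outcome becomes constant
  rpe <- rpe_trace(s, g$latents, g$latents)
  W <- list(mat = matrix(stats::rnorm(200 * 4), 200, 4), time = 0:3 / 25,
            outcome_index = 1)
  expect_error(ridge_cpd(W, s, rpe), "constant predictor")
})
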