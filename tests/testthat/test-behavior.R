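test_that("reversal curves recover the expected shapes for degenerate
           agents", {
  set.seed(51)
  cfg <- task_config(n_trials = 300)
  # random agent: flat near 0.5 away from the boundary trial; the
  # reversal-triggering press itself is incorrect by definition (it is
  # labelled into the new block), so offset 0 is exactly 0
  rnd <- lapply(1:20, function(i) run_session(cfg, function(t) c(0.5, 0.5)))
  cv <- reversal_curve(rnd)
  expect_equal(cv$p_high_choice[cv$offset == 0], 0)
  expect_true(all(abs(cv$p_high_choice[cv$offset != 0] - 0.5) < 0.15,
                  na.rm = TRUE))
  # SI exemplar: pre-reversal accuracy above the first post-reversal trial
  g <- run_generative(exemplar_specs()$si, list(c = 0.8, gamma = 0.9,
                                                bias = 0), cfg)
  cv2 <- reversal_curve(g$session)
  expect_gt(cv2$p_high_choice[cv2$offset == -1],
            cv2$p_high_choice[cv2$offset == 0])
  # no reversals -> error
  one_block <- make_session(rep(0L, 30), rep(1L, 30))
  expect_error(reversal_curve(one_block), "reversal")
})

test_that("trials_to_switch inverts a known exponential and honours the
           boundary conventions", {
  # p(t) = 1 - exp(-t / 2) crosses 0.5 at 2 log 2
  cv <- data.frame(offset = 0:15, p_high_choice = 1 - exp(-(0:15) / 2),
                   n_blocks = 10)
  expect_equal(trials_to_switch(cv), 2 * log(2), tolerance = 1e-6)
  # already above 0.5 everywhere -> 0; never crossing -> Inf
  flat_hi <- data.frame(offset = 0:10, p_high_choice = rep(0.9, 11),
                        n_blocks = 5)
  expect_equal(trials_to_switch(flat_hi), 0)
  flat_lo <- data.frame(offset = 0:10, p_high_choice = rep(0.3, 11),
                        n_blocks = 5)
  expect_equal(trials_to_switch(flat_lo), Inf)
  # invariant to prepending pre-reversal offsets
  cv_pre <- rbind(data.frame(offset = -4:-1, p_high_choice = 0.9,
                             n_blocks = 10), cv)
  expect_equal(trials_to_switch(cv_pre), trials_to_switch(cv),
               tolerance = 1e-6)
})

test_that("history regression attributes behavior to the correct
           regressors", {
  set.seed(52)
  cfg <- task_config(n_trials = 400)
  # win-stay/lose-shift: positive rewarded-choice and negative
  # unrewarded-choice first-lag weights
  g <- run_generative(model_spec("wsls"), list(eps = 0.1), cfg)
  hr <- history_logistic_regression(g$session)
  expect_gt(hr$coef$R[1], 0)
  expect_lt(hr$coef$N[1], 0)
  expect_equal(nrow(hr$coef), 5)
  # pure perseverator: choice history dominates, reward terms near zero
  g2 <- run_generative(model_spec("choice_kernel"),
                       list(alpha_c = 0.5, beta_c = 3), cfg)
  hr2 <- history_logistic_regression(g2$session)
  expect_gt(hr2$coef$C[1], abs(hr2$coef$R[1]))
  expect_gt(hr2$coef$C[1], abs(hr2$coef$N[1]))
  # single-class target errors out
  stuck <- make_session(rep(1L, 60), rep(c(0L, 1L), 30))
  expect_error(history_logistic_regression(stuck), "single-class")
})

test_that("history regression is equivariant under a left-right relabel", {
  # flipping the lever coding negates the target log-odds AND every
  # regressor, so the slope coefficients are invariant while the intercept
  # (the lateral bias) flips sign
  set.seed(53)
  g <- run_generative(model_spec("wsls"), list(eps = 0.15),
                      task_config(n_trials = 300))
  s <- g$session
  flip <- s; flip$choice <- 1L - flip$choice
  flip$high_side <- 1L - flip$high_side
  set.seed(99); hr <- history_logistic_regression(s)
  set.seed(99); hrf <- history_logistic_regression(flip)
  expect_equal(hrf$coef$R, hr$coef$R, tolerance = 1e-6)
  expect_equal(hrf$coef$N, hr$coef$N, tolerance = 1e-6)
  expect_equal(hrf$coef$C, hr$coef$C, tolerance = 1e-6)
  expect_equal(hrf$intercept, -hr$intercept, tolerance = 1e-6)
})

test_that("switch tables follow their tautologies and count every eligible
           trial", {
  # stay-forever agent
  stay <- make_session(rep(1L, 40), rep(c(1L, 0L), 20))
  st <- switch_probability_by_history(stay)
  expect_true(all(st$p_switch == 0))
  expect_equal(sum(st$n), 40 - 3)
  # random agent: near 0.5 overall
  set.seed(54)
  s <- run_session(task_config(n_trials = 3000), function(t) c(0.5, 0.5))
  st2 <- switch_probability_by_history(s)
  expect_lt(abs(sum(st2$p_switch * st2$n) / sum(st2$n) - 0.5), 0.05)
  # SI exemplar: repeated omissions raise switching above repeated rewards
  set.seed(55)
  sims <- lapply(1:10, function(i)
    run_generative(exemplar_specs()$si, list(c = 0.8, gamma = 0.9, bias = 0),
                   task_config(n_trials = 300))$session)
  st3 <- switch_probability_by_history(sims)
  expect_gt(st3$p_switch[st3$history == "S-S-S-"],
            st3$p_switch[st3$history == "S+S+S+"])
})

test_that("model-derived switch probabilities use the mass on the
           non-previous lever", {
  set.seed(56)
  g <- run_generative(exemplar_specs()$si, list(c = 0.8, gamma = 0.9,
                                                bias = 0),
                      task_config(n_trials = 300))
  st <- switch_probability_by_history(g$session, latents = g$latents)
  expect_true(all(st$p_switch >= 0 & st$p_switch <= 1))
  # the model's S-S-S- switch estimate also exceeds its S+S+S+ one
  if (all(c("S-S-S-", "S+S+S+") %in% st$history))
    expect_gt(st$p_switch[st$history == "S-S-S-"],
              st$p_switch[st$history == "S+S+S+"])
})

test_that("strategy consistency credits the model that predicts the
           choice", {
  set.seed(57)
  ex <- exemplar_specs()
  g <- run_generative(ex$si, list(c = 0.8, gamma = 0.9, bias = 0),
                      task_config(n_trials = 300))
  fit_si <- list(spec = ex$si, params = list(c = 0.8, gamma = 0.9, bias = 0))
  fit_q <- list(spec = ex$q, params = list(alpha_r = 0.6, alpha_ur = 0.3,
                                           beta = 5, bias = 0))
  cons <- strategy_consistency(g$session, fit_q, fit_si)
  expect_gt(cons$consistent[cons$model == "si"], 0.5)
  # identical models give identical proportions
  cons2 <- strategy_consistency(g$session, fit_si, fit_si)
  expect_equal(cons2$consistent[1], cons2$consistent[2])
  # ties at exactly 0.5 are excluded and counted
  rnd <- list(spec = model_spec("random"), params = list(b = 0.5))
  cons3 <- strategy_consistency(g$session, rnd, fit_si)
  expect_equal(cons3$n_eligible[cons3$model == "q"], 0)
  expect_equal(cons3$n_tied[cons3$model == "q"], 300)
})
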