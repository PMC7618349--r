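test_that("choice probabilities match hand-evaluated softmax/WSLS values", {
  # symmetric Q values give 0.5 regardless of beta
  sp <- model_spec("q")
  st <- init_state(sp, list(alpha = 0.2, beta = 7))
  expect_equal(choice_probs(sp, list(alpha = 0.2, beta = 7), st),
               c(0.5, 0.5))
  # beta = 5, Q = (0.3, 0.7): p(right) = 1 / (1 + exp(-2))
  st$Q <- c(0.3, 0.7)
  expect_equal(choice_probs(sp, list(alpha = 0.2, beta = 5), st)[2],
               1 / (1 + exp(-2)), tolerance = 1e-12)
  # WSLS, eps = 0.2, last trial right and rewarded: p(right) = 0.9
  sw <- model_spec("wsls")
  stw <- init_state(sw, list(eps = 0.2))
  expect_equal(choice_probs(sw, list(eps = 0.2), stw), c(0.5, 0.5))
  stw$last_choice <- 1L; stw$last_reward <- 1L
  expect_equal(choice_probs(sw, list(eps = 0.2), stw)[2], 0.9)
  stw$last_reward <- 0L          # lose-shift: now prefers left
  expect_equal(choice_probs(sw, list(eps = 0.2), stw)[1], 0.9)
  # SI, belief (right high) = 0.8: p(right) = 1 / (1 + exp(-10 * 0.6))
  ss <- model_spec("si")
  sts <- init_state(ss, list(c = 0.6, gamma = 0.9))
  sts$belief <- c(0.2, 0.8)
  expect_equal(choice_probs(ss, list(c = 0.6, gamma = 0.9), sts)[2],
               1 / (1 + exp(-6)), tolerance = 1e-12)
})

test_that("state updates match hand-evaluated update rules", {
  # plain Q: 0.5 + 0.2 * (1 - 0.5) = 0.6
  sp <- model_spec("q"); pv <- list(alpha = 0.2, beta = 5)
  st <- update_state(sp, pv, init_state(sp, pv), 0, 1)
  expect_equal(st$Q, c(0.6, 0.5))
  # counterfactual: unchosen moves toward 1 - r
  sc <- model_spec("q", q_variant = "cf_diff")
  pc <- list(alpha = 0.2, alpha_cf = 0.2, beta = 5)
  st <- update_state(sc, pc, init_state(sc, pc), 0, 1)
  expect_equal(st$Q, c(0.6, 0.4))
  # forget reset: unchosen jumps to the across-action mean after the
  # chosen update
  sf <- model_spec("q", q_variant = "forget_reset")
  pf <- list(alpha = 0.8, beta = 5)
  stf <- init_state(sf, pf); stf$Q <- c(0.9, 0.3)
  stf <- update_state(sf, pf, stf, 0, 1)      # chosen L: 0.9 + .8*.1 = 0.98
  expect_equal(stf$Q[1], 0.98)
  expect_equal(stf$Q[2], mean(c(0.98, 0.3)))
  # forget gradual never overshoots the mean
  sg <- model_spec("q", q_variant = "forget_gradual")
  pg <- list(alpha = 0, delta = 0.9, beta = 5)
  stg <- init_state(sg, pg); stg$Q <- c(0.5, 0.52)
  stg <- update_state(sg, pg, stg, 0, 0)
  expect_equal(stg$Q[2], mean(c(0.5, 0.52)))  # clamped at the mean
  # Pearce-Hall associability: 0.5 * (1 - 0.4) + 0.4 * |rpe|
  sd_ <- model_spec("q", q_variant = "dynamic")
  pd <- list(kappa = 1, gamma_ph = 0.4, alpha0 = 0.5, beta = 5)
  std <- init_state(sd_, pd)
  expect_equal(std$assoc, 0.5)
  std <- update_state(sd_, pd, std, 0, 1)     # rpe = 0.5
  expect_equal(std$Q[1], 0.5 + 1 * 0.5 * 0.5)
  expect_equal(std$assoc, 0.5 * 0.6 + 0.4 * 0.5)
  # SI forward filter: uniform belief, c = 0.6, chose right (= right-high
  # evidence), rewarded, gamma = 0.9 -> posterior (0.2, 0.8), belief
  # (0.23, 0.77)
  ss <- model_spec("si"); ps <- list(c = 0.6, gamma = 0.9)
  sts <- update_state(ss, ps, init_state(ss, ps), 1, 1)
  expect_equal(sts$belief, c(0.23, 0.77), tolerance = 1e-12)
  # d = 0: omissions leave the posterior untouched (transition only)
  sts2 <- update_state(ss, ps, init_state(ss, ps), 1, 0)
  expect_equal(sts2$belief, c(0.5, 0.5))
  # gamma = 0: transition is uniform, belief resets to 0.5 after any trial
  ps0 <- list(c = 0.6, gamma = 0)
  sts3 <- update_state(ss, ps0, init_state(ss, ps0), 1, 1)
  expect_equal(sts3$belief, c(0.5, 0.5))
  # reward outside {0,1} rejected
  expect_error(update_state(sp, pv, init_state(sp, pv), 0, 0.5), "reward")
})

test_that("conditioned forward pass matches independent manual oracles on
           the worked session", {
  s <- worked_session()
  cases <- list(
    list(spec = model_spec("random"), pars = list(b = 0.7),
         oracle = manual_probs$random(0.7, s)),
    list(spec = model_spec("wsls"), pars = list(eps = 0.2),
         oracle = manual_probs$wsls(0.2, s)),
    list(spec = model_spec("choice_kernel"),
         pars = list(alpha_c = 0.3, beta_c = 2),
         oracle = manual_probs$choice_kernel(0.3, 2, s)),
    list(spec = model_spec("q"), pars = list(alpha = 0.5, beta = 2),
         oracle = manual_probs$q(0.5, 2, s)),
    list(spec = model_spec("si"), pars = list(c = 0.6, gamma = 0.9),
         oracle = manual_probs$si(0.6, 0.9, s)))
  for (cs in cases) {
    l <- run_conditioned(cs$spec, cs$pars, s)
    p_chosen <- ifelse(s$choice == 1, l$p_right, l$p_left)
    expect_equal(p_chosen, cs$oracle, tolerance = 1e-10,
                 label = cs$spec$label)
    expect_equal(negative_log_likelihood(cs$spec, cs$pars, s),
                 -sum(log(cs$oracle)), tolerance = 1e-10,
                 label = paste("nll", cs$spec$label))
  }
})

test_that("R reference and compiled forward passes agree across all model
           structures", {
  set.seed(11)
  cfg <- task_config(n_trials = 120)
  s <- run_session(cfg, function(t) c(0.5, 0.5))
  for (spec in model_zoo_small()) {
    pars <- random_params(spec)
    l <- run_conditioned(spec, pars, s)
    m <- banditSI:::forward_fast(spec, pars, s)
    expect_equal(l$p_right, unname(m[, "p_right"]), tolerance = 1e-10,
                 label = spec$label)
    expect_equal(l$rpe, unname(m[, "rpe"]), tolerance = 1e-10,
                 label = paste("rpe", spec$label))
  }
})

test_that("probabilities, beliefs and values respect their invariants under
           random parameter draws", {
  set.seed(12)
  cfg <- task_config(n_trials = 150)
  s <- run_session(cfg, function(t) c(0.5, 0.5))
  for (spec in model_zoo_small()) {
    for (rep in 1:3) {
      pars <- random_params(spec)
      l <- run_conditioned(spec, pars, s)
      expect_true(all(l$p_left > 0 & l$p_left < 1), label = spec$label)
      expect_equal(l$p_left + l$p_right, rep(1, nrow(s)), tolerance = 1e-12)
      expect_true(all(l$q_left >= -1e-12 & l$q_left <= 1 + 1e-12),
                  label = paste("Q bounds", spec$label))
      expect_true(all(l$belief_R >= -1e-12 & l$belief_R <= 1 + 1e-12))
    }
  }
})

test_that("degenerate parameter limits behave as closed forms predict", {
  set.seed(13)
  cfg <- task_config(n_trials = 100)
  s <- run_session(cfg, function(t) c(0.5, 0.5))
  # q with alpha = 0: probabilities constant
  l <- run_conditioned(model_spec("q"), list(alpha = 0, beta = 5), s)
  expect_equal(l$p_right, rep(0.5, 100))
  # si with c = 0: likelihood flat, belief pinned at 0.5
  l <- run_conditioned(model_spec("si"), list(c = 0, gamma = 0.9), s)
  expect_equal(l$p_right, rep(0.5, 100))
  # wsls with eps = 1: uniform random
  l <- run_conditioned(model_spec("wsls"), list(eps = 1), s)
  expect_equal(l$p_right, rep(0.5, 100))
  # random model with b = 0.5
  l <- run_conditioned(model_spec("random"), list(b = 0.5), s)
  expect_equal(l$p_right, rep(0.5, 100))
})

test_that("generative play is reproducible and self-consistent with the
           conditioned pass", {
  spec <- model_spec("si", bias = TRUE)
  pars <- list(c = 0.8, gamma = 0.9, bias = 0.1)
  cfg <- task_config(n_trials = 200)
  set.seed(21); a <- run_generative(spec, pars, cfg)
  set.seed(21); b <- run_generative(spec, pars, cfg)
  expect_identical(a$session, b$session)
  l <- run_conditioned(spec, pars, a$session)
  expect_equal(l$p_right, a$latents$p_right, tolerance = 1e-12)
  expect_equal(l$belief_R, a$latents$belief_R, tolerance = 1e-12)
})

test_that("deterministic WSLS locks onto the rewarded lever", {
  set.seed(22)
  cfg <- task_config(p_high = 1, p_low = 0, block_min = 15, block_max = 15,
                     n_trials = 40)
  g <- run_generative(model_spec("wsls"), list(eps = 0), cfg)
  s <- g$session
  first_win <- which(s$reward == 1)[1]
  run_end <- first_win + 10
  expect_true(all(s$choice[first_win:run_end][
    s$block_index[first_win:run_end] == s$block_index[first_win]] ==
      s$choice[first_win]))
})

test_that("an SI agent outperforms a random agent at the end of blocks", {
  set.seed(23)
  cfg <- task_config(n_trials = 300)
  acc <- function(spec, pars) {
    g <- run_generative(spec, pars, cfg)
    s <- g$session
    # last 8 trials of each completed block
    ends <- tapply(seq_len(nrow(s)), s$block_index, max)
    ends <- ends[-length(ends)]
    late <- unlist(lapply(ends, function(e) max(1, e - 7):e))
    mean((s$choice == s$high_side)[late])
  }
  d <- replicate(15, acc(model_spec("si"), list(c = 0.8, gamma = 0.9)) -
                     acc(model_spec("random"), list(b = 0.5)))
  expect_gt(mean(d), 0)
  expect_gt(mean(d > 0), 0.8)
})

test_that("model specs validate their parameter sets and augment rules", {
  expect_error(model_spec("random", bias = TRUE), "augments")
  expect_error(model_spec("si", rp = TRUE), "si_variant")
  expect_error(init_state(model_spec("q"), list(beta = 2)), "missing")
  expect_error(init_state(model_spec("q"), list(alpha = 2, beta = 2)),
               "bounds")
  expect_equal(n_params(exemplar_specs()$q), 4)   # alpha_r, alpha_ur, beta, b
  expect_equal(n_params(exemplar_specs()$si), 3)  # c, gamma, b
  expect_equal(n_params(model_spec("q", q_variant = "cf_diff", rp = TRUE)), 5)
  expect_equal(n_params(model_spec("q", q_variant = "dynamic")), 4)
})
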