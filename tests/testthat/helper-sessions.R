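# small builders used across test files

make_session <- function(choice, reward,
                         high_side = rep(1L, length(choice)),
                         block_index = rep(0L, length(choice))) {
  banditSI:::new_session(choice, reward, high_side, block_index,
                         trial_in_block = seq_along(choice) - 1L)
}

# the 3-trial worked session used by the likelihood oracles
worked_session <- function() make_session(choice = c(1L, 1L, 0L),
                                          reward = c(1L, 0L, 1L))

# independent manual forward passes (plain arithmetic, no package state
# machinery) returning per-trial p(chosen choice)
manual_probs <- list(
  random = function(b, s) ifelse(s$choice == 1, b, 1 - b),
  wsls = function(eps, s) {
    n <- nrow(s); p <- numeric(n); p[1] <- 0.5
    for (t in 2:n) {
      stay <- if (s$reward[t - 1] == 1) s$choice[t - 1] else 1 - s$choice[t - 1]
      p[t] <- if (s$choice[t] == stay) 1 - eps / 2 else eps / 2
    }
    p
  },
  choice_kernel = function(alpha_c, beta_c, s) {
    n <- nrow(s); ck <- c(0, 0); p <- numeric(n)
    for (t in 1:n) {
      pr <- 1 / (1 + exp(-beta_c * (ck[2] - ck[1])))
      p[t] <- if (s$choice[t] == 1) pr else 1 - pr
      ck <- ck + alpha_c * (c(s$choice[t] == 0, s$choice[t] == 1) - ck)
    }
    p
  },
  q = function(alpha, beta, s) {
    n <- nrow(s); q <- c(0.5, 0.5); p <- numeric(n)
    for (t in 1:n) {
      pr <- 1 / (1 + exp(-beta * (q[2] - q[1])))
      p[t] <- if (s$choice[t] == 1) pr else 1 - pr
      i <- s$choice[t] + 1
      q[i] <- q[i] + alpha * (s$reward[t] - q[i])
    }
    p
  },
  si = function(cc, gamma, s) {
    n <- nrow(s); b <- c(0.5, 0.5); p <- numeric(n)  # (left high, right high)
    stay <- 0.5 + 0.5 * gamma
    for (t in 1:n) {
      pr <- 1 / (1 + exp(-10 * (b[2] - b[1])))
      p[t] <- if (s$choice[t] == 1) pr else 1 - pr
      if (s$reward[t] == 1) {
        lik <- 0.5 + 0.5 * c(if (s$choice[t] == 0) cc else -cc,
                             if (s$choice[t] == 1) cc else -cc)
        post <- lik * b; post <- post / sum(post)
      } else post <- b                              # d = 0: omissions flat
      b <- c(stay * post[1] + (1 - stay) * post[2],
             (1 - stay) * post[1] + stay * post[2])
    }
    p
  })

model_zoo_small <- function() list(
  model_spec("random"),
  model_spec("wsls"),
  model_spec("choice_kernel"),
  model_spec("q"),
  model_spec("q", rp = TRUE, bias = TRUE),
  model_spec("q", q_variant = "cf_diff", rp = TRUE),
  model_spec("q", q_variant = "forget_reset"),
  model_spec("q", q_variant = "forget_gradual"),
  model_spec("q", q_variant = "dynamic", ck = TRUE),
  model_spec("si", si_variant = "d_zero", bias = TRUE),
  model_spec("si", si_variant = "full_d", ck = TRUE))

random_params <- function(spec) {
  info <- param_info(spec)
  as.list(stats::setNames(stats::runif(nrow(info), info$lower, info$upper),
                          info$name))
}
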