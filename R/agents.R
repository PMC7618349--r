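#' Specify a behavioral model
#'
#' Constructs a model specification for the agent families used to analyse
#' 2-armed bandit behavior: random choice with bias, noisy
#' win-stay/lose-shift, choice kernel, Q-learning (with counterfactual,
#' forgetting and Pearce-Hall dynamic-learning-rate variants), and Bayesian
#' hidden-state inference (SI) implemented as an HMM forward filter over the
#' two latent lever contingencies.
#'
#' Augments: `bias` adds a lateral choice bias inside the softmax; `ck` adds
#' a choice kernel tracking recent choice frequency (perseveration); `rp`
#' splits learning rates by outcome (reward/punishment sensitivity). For the
#' SI family the reward/punishment analogue is structural: `si_variant
#' = "full_d"` frees a separate omission compatibility `d`, while `"d_zero"`
#' fixes `d = 0` so that only rewarded trials inform the observation
#' likelihood.
#'
#' @param family One of `"random"`, `"wsls"`, `"choice_kernel"`, `"q"`, `"si"`.
#' @param q_variant Q-family variant: `"plain"`, `"cf_same"` (counterfactual,
#'   shared learning rates), `"cf_diff"` (counterfactual, separate unchosen
#'   rates), `"forget_reset"`, `"forget_gradual"`, `"dynamic"` (Pearce-Hall).
#' @param si_variant `"d_zero"` (omission likelihood flat at 0.5) or
#'   `"full_d"` (free omission compatibility).
#' @param bias,ck,rp Logical augment flags (see Details).
#' @param label Optional display label; derived from the structure if `NULL`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("q", "si", "random", "wsls", "choice_kernel"),
                       q_variant = c("plain", "cf_same", "cf_diff",
                                     "forget_reset", "forget_gradual",
                                     "dynamic"),
                       si_variant = c("d_zero", "full_d"),
                       bias = FALSE, ck = FALSE, rp = FALSE, label = NULL) {
  family <- match.arg(family)
  q_variant <- match.arg(q_variant)
  si_variant <- match.arg(si_variant)
  if (family %in% c("random", "wsls", "choice_kernel") && (bias || ck || rp))
    stop("bias/ck/rp augments apply only to the q and si families")
  if (family == "si" && rp)
    stop("for SI models reward/punishment sensitivity is expressed by ",
         "si_variant ('full_d' frees d, 'd_zero' fixes d = 0), not `rp`")
  spec <- structure(list(family = family, q_variant = q_variant,
                         si_variant = si_variant, bias = bias, ck = ck,
                         rp = rp),
                    class = "model_spec")
  spec$label <- if (is.null(label)) spec_label(spec) else label
  spec
}

spec_label <- function(spec) {
  base <- switch(spec$family,
                 random = "random", wsls = "wsls", choice_kernel = "ck",
                 q = paste0("q_", spec$q_variant),
                 si = paste0("si_", spec$si_variant))
  aug <- c(if (spec$rp) "rp", if (spec$bias) "bias", if (spec$ck) "ck")
  if (length(aug)) paste(c(base, aug), collapse = "+") else base
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$label, "\n  parameters:",
      paste(param_info(x)$name, collapse = ", "), "\n")
  invisible(x)
}

#' Parameter names and bounds implied by a model specification
#'
#' Probability-scale parameters (learning rates, compatibilities, stay
#' probability, forgetting factor, associability) live in \[0, 1\]; inverse
#' temperatures in \[0, 20\]; the Q/SI lateral bias in \[-1, 1\]; the random
#' model's bias (probability of the right lever) in \[0, 1\].
#'
#' @param spec A [model_spec()].
#' @return Data frame with columns `name`, `lower`, `upper`.
#' @export
param_info <- function(spec) {
  p <- function(name, lower, upper) data.frame(name = name, lower = lower,
                                               upper = upper)
  rows <- switch(spec$family,
    random = p("b", 0, 1),
    wsls = p("eps", 0, 1),
    choice_kernel = rbind(p("alpha_c", 0, 1), p("beta_c", 0, 20)),
    q = {
      lr <- if (spec$rp) rbind(p("alpha_r", 0, 1), p("alpha_ur", 0, 1))
            else p("alpha", 0, 1)
      extra <- switch(spec$q_variant,
        plain = NULL, cf_same = NULL, forget_reset = NULL,
        cf_diff = if (spec$rp)
            rbind(p("alpha_cf_r", 0, 1), p("alpha_cf_ur", 0, 1))
          else p("alpha_cf", 0, 1),
        forget_gradual = p("delta", 0, 1),
        dynamic = NULL)
      if (spec$q_variant == "dynamic") {
        lr <- if (spec$rp) rbind(p("kappa_r", 0, 1), p("kappa_ur", 0, 1))
              else p("kappa", 0, 1)
        extra <- rbind(p("gamma_ph", 0, 1), p("alpha0", 0, 1))
      }
      rbind(lr, extra, p("beta", 0, 20))
    },
    si = {
      rows <- rbind(p("c", 0, 1), p("gamma", 0, 1))
      if (spec$si_variant == "full_d") rows <- rbind(rows, p("d", 0, 1))
      rows
    })
  if (spec$family %in% c("q", "si")) {
    if (spec$bias) rows <- rbind(rows, p("bias", -1, 1))
    if (spec$ck) rows <- rbind(rows, p("alpha_c", 0, 1), p("beta_c", 0, 20))
  }
  rows
}

#' Number of free parameters of a model
#' @param spec A [model_spec()].
#' @return Integer count.
#' @export
n_params <- function(spec) nrow(param_info(spec))

check_params <- function(spec, params) {
  info <- param_info(spec)
  missing <- setdiff(info$name, names(params))
  if (length(missing))
    stop("missing parameter(s) for ", spec$label, ": ",
         paste(missing, collapse = ", "))
  v <- unlist(params[info$name])
  bad <- v < info$lower - 1e-9 | v > info$upper + 1e-9
  if (any(bad))
    stop("parameter(s) out of bounds: ", paste(info$name[bad], collapse = ", "))
  invisible(v)
}

#' Initialize an agent's internal state
#'
#' Action values start at 0.5 (the midpoint of the binary reward scale),
#' choice kernels at 0, the belief over latent contingencies uniform, and
#' for the Pearce-Hall variant the associability at its free initial value
#' `alpha0`.
#'
#' @param spec A [model_spec()].
#' @param params Named list/vector of parameters (see [param_info()]).
#' @return An `agent_state` list.
#' @export
init_state <- function(spec, params) {
  check_params(spec, params)
  structure(list(Q = c(0.5, 0.5), CK = c(0, 0), belief = c(0.5, 0.5),
                 assoc = if (spec$family == "q" && spec$q_variant == "dynamic")
                           unname(unlist(params)[["alpha0"]]) else NA_real_,
                 last_choice = NA_integer_, last_reward = NA_integer_),
            class = "agent_state")
}

softmax2 <- function(d_left, d_right) {
  pr <- 1 / (1 + exp(-(d_right - d_left)))
  c(1 - pr, pr)
}

#' Choice probabilities of an agent in its current state
#'
#' Returns `c(p_left, p_right)`. Q-family drives are `beta * (Q + bias)` plus
#' `beta_c * CK` when the choice kernel is active; SI drives are `10 *
#' (belief(s) + bias)` (the softmax steepness over beliefs is the fixed
#' constant 10, and the lateral bias enters inside it, as the Q-model bias
#' enters inside `beta`) plus the choice-kernel term. The belief entering
#' the right lever's drive is the belief that the right lever is currently
#' the high-probability one.
#'
#' @inheritParams init_state
#' @param state An `agent_state` from [init_state()] / [update_state()].
#' @return Numeric length-2 probability vector summing to 1.
#' @export
choice_probs <- function(spec, params, state) {
  pv <- as.list(params)
  switch(spec$family,
    random = c(1 - pv$b, pv$b),
    wsls = {
      if (is.na(state$last_choice)) return(c(0.5, 0.5))
      stay <- if (state$last_reward == 1) state$last_choice
              else 1L - state$last_choice
      p <- c(pv$eps / 2, pv$eps / 2)
      p[stay + 1L] <- 1 - pv$eps / 2
      p
    },
    choice_kernel = softmax2(pv$beta_c * state$CK[1], pv$beta_c * state$CK[2]),
    q = {
      b <- if (spec$bias) pv$bias else 0
      d <- pv$beta * c(state$Q[1], state$Q[2] + b)
      if (spec$ck) d <- d + pv$beta_c * state$CK
      softmax2(d[1], d[2])
    },
    si = {
      b <- if (spec$bias) pv$bias else 0
      # bias enters inside the fixed steepness, as the Q-model bias enters
      # inside beta; belief[2] = P(right lever high)
      d <- 10 * (state$belief + c(0, b))
      if (spec$ck) d <- d + pv$beta_c * state$CK
      softmax2(d[1], d[2])
    })
}

#' Update an agent's state from an observed choice and outcome
#'
#' Applies the value/belief update of the active family and variant, then the
#' choice-kernel update for both actions, then records the trial. For
#' Q-learning: the chosen value moves toward the outcome at the effective
#' learning rate (split by outcome under `rp`; scaled by associability for
#' the Pearce-Hall variant); counterfactual variants move the unchosen value
#' toward `1 - r`; forgetting variants pull the unchosen value to (reset) or
#' toward (gradual, never overshooting) the across-action mean. For SI: the
#' belief is passed through one HMM forward-filter step — multiply by the
#' observation likelihood `0.5 + 0.5 * (+/- c)` (`+/- d` on omissions),
#' normalize, then mix through the symmetric sticky transition matrix with
#' stay probability `0.5 + 0.5 * gamma`.
#'
#' @inheritParams choice_probs
#' @param choice 0 (left) or 1 (right).
#' @param reward 0 or 1.
#' @return The updated `agent_state`.
#' @export
update_state <- function(spec, params, state, choice, reward) {
  if (!choice %in% c(0, 1)) stop("choice must be 0 or 1")
  if (!reward %in% c(0, 1))
    stop("reward must be 0 or 1 (likelihood undefined otherwise)")
  pv <- as.list(params)
  ch <- choice + 1L
  un <- 2L - choice
  if (spec$family == "q") {
    rpe <- reward - state$Q[ch]
    if (spec$q_variant == "dynamic") {
      kap <- if (spec$rp) { if (reward == 1) pv$kappa_r else pv$kappa_ur }
             else pv$kappa
      state$Q[ch] <- state$Q[ch] + kap * state$assoc * rpe
      # associability carries |RPE| of this trial into the next one
      state$assoc <- state$assoc * (1 - pv$gamma_ph) + pv$gamma_ph * abs(rpe)
    } else {
      alp <- if (spec$rp) { if (reward == 1) pv$alpha_r else pv$alpha_ur }
             else pv$alpha
      state$Q[ch] <- state$Q[ch] + alp * rpe
      if (spec$q_variant %in% c("cf_same", "cf_diff")) {
        acf <- if (spec$q_variant == "cf_same") alp
               else if (spec$rp) { if (reward == 1) pv$alpha_cf_r
                                   else pv$alpha_cf_ur }
               else pv$alpha_cf
        state$Q[un] <- state$Q[un] + acf * ((1 - reward) - state$Q[un])
      } else if (spec$q_variant %in% c("forget_reset", "forget_gradual")) {
        qbar <- mean(state$Q)
        if (spec$q_variant == "forget_reset") {
          state$Q[un] <- qbar
        } else {
          q <- state$Q[un]
          state$Q[un] <- if (q > qbar) max((1 - pv$delta) * q, qbar)
                         else if (q < qbar) min((1 + pv$delta) * q, qbar)
                         else qbar
        }
      }
    }
  } else if (spec$family == "si") {
    dd <- if (spec$si_variant == "full_d") pv$d else 0
    # states: 1 = left lever high, 2 = right lever high
    match_s <- c(choice == 0, choice == 1)
    lik <- if (reward == 1) 0.5 + 0.5 * ifelse(match_s, pv$c, -pv$c)
           else 0.5 + 0.5 * ifelse(match_s, -dd, dd)
    post <- lik * state$belief
    post <- post / sum(post)
    stay <- 0.5 + 0.5 * pv$gamma
    state$belief <- c(stay * post[1] + (1 - stay) * post[2],
                      (1 - stay) * post[1] + stay * post[2])
  }
  if (spec$family == "choice_kernel" || spec$ck) {
    ind <- c(choice == 0, choice == 1)
    state$CK <- state$CK + pv$alpha_c * (ind - state$CK)
  }
  state$last_choice <- as.integer(choice)
  state$last_reward <- as.integer(reward)
  state
}

#' Run an agent conditioned on an observed session
#'
#' The reference (pure R) forward pass: for each trial the choice
#' probabilities are computed from the state *before* observing that trial,
#' then the state is updated with the session's actual choice and outcome.
#' Snapshots are pre-update, so `rpe` is the chosen-action prediction error
#' `r_t - Q_t(c_t)` evaluated at the pre-update value.
#'
#' @inheritParams init_state
#' @param session A `bandit_session`.
#' @return An `agent_latents` data frame with columns `trial`, `p_left`,
#'   `p_right`, `q_left`, `q_right`, `belief_R` (belief that the right lever
#'   is high, pre-update), `rpe`.
#' @export
run_conditioned <- function(spec, params, session) {
  n <- nrow(session)
  st <- init_state(spec, params)
  p_left <- p_right <- q_left <- q_right <- belief_R <- rpe <- numeric(n)
  for (t in seq_len(n)) {
    p <- choice_probs(spec, params, st)
    ch <- session$choice[t]; rw <- session$reward[t]
    p_left[t] <- p[1]; p_right[t] <- p[2]
    q_left[t] <- st$Q[1]; q_right[t] <- st$Q[2]
    belief_R[t] <- st$belief[2]
    rpe[t] <- rw - st$Q[ch + 1L]
    st <- update_state(spec, params, st, ch, rw)
  }
  structure(data.frame(trial = session$trial, p_left = p_left,
                       p_right = p_right, q_left = q_left, q_right = q_right,
                       belief_R = belief_R, rpe = rpe),
            class = c("agent_latents", "data.frame"))
}

#' Let an agent play the bandit task
#'
#' The agent samples each choice from its own probabilities; the environment
#' supplies rewards and reversals under the task config.
#'
#' @inheritParams init_state
#' @param config A [task_config()].
#' @param high_side_init Optional initial high side (0/1).
#' @return List with elements `session` (a `bandit_session`) and `latents`
#'   (the `agent_latents` realized during play).
#' @export
run_generative <- function(spec, params, config, high_side_init = NULL) {
  n <- config$n_trials
  st <- init_state(spec, params)
  env <- new_env_state(config, high_side_init)
  choice <- reward <- high_side <- block_index <- trial_in_block <- integer(n)
  p_left <- p_right <- q_left <- q_right <- belief_R <- rpe <- numeric(n)
  in_block <- 0L
  for (t in seq_len(n)) {
    p <- choice_probs(spec, params, st)
    ch <- as.integer(stats::runif(1) < p[2])
    out <- step_environment(config, env, ch)
    if (out$flipped) in_block <- 0L
    rw <- out$reward
    p_left[t] <- p[1]; p_right[t] <- p[2]
    q_left[t] <- st$Q[1]; q_right[t] <- st$Q[2]
    belief_R[t] <- st$belief[2]
    rpe[t] <- rw - st$Q[ch + 1L]
    choice[t] <- ch; reward[t] <- rw
    high_side[t] <- out$state$high_side
    block_index[t] <- out$state$block
    trial_in_block[t] <- in_block
    in_block <- in_block + 1L
    st <- update_state(spec, params, st, ch, rw)
    env <- out$state
  }
  list(session = new_session(choice, reward, high_side, block_index,
                             trial_in_block),
       latents = structure(data.frame(trial = seq_len(n) - 1L,
                                      p_left = p_left, p_right = p_right,
                                      q_left = q_left, q_right = q_right,
                                      belief_R = belief_R, rpe = rpe),
                           class = c("agent_latents", "data.frame")))
}

#' Export agent latents to CSV
#' @param latents An `agent_latents` data frame.
#' @param path File path.
#' @export
write_latents <- function(latents, path) {
  utils::write.csv(as.data.frame(latents), path, row.names = FALSE)
  invisible(path)
}
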