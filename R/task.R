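#' Task configuration for the 2-armed bandit
#'
#' Probabilistic serial reversal learning: one lever is rewarded with
#' probability `p_high`, the other with `p_low`, and the contingency reverses
#' after a criterion number of high-probability-lever choices drawn uniformly
#' from `[block_min, block_max]`.
#'
#' @param p_high Reward probability of the high-probability lever (default 0.7).
#' @param p_low Reward probability of the low-probability lever (default 0.1).
#' @param block_min,block_max Inclusive range of the number of
#'   high-probability-lever choices that triggers a reversal (defaults 10, 32).
#' @param n_trials Number of trials in a session (default 300).
#' @return An object of class `task_config`.
#' @export
task_config <- function(p_high = 0.7, p_low = 0.1, block_min = 10L,
                        block_max = 32L, n_trials = 300L) {
  stopifnot(p_low >= 0, p_high <= 1, p_low < p_high,
            block_min >= 1, block_min <= block_max, n_trials >= 0)
  structure(list(p_high = p_high, p_low = p_low,
                 block_min = as.integer(block_min),
                 block_max = as.integer(block_max),
                 n_trials = as.integer(n_trials)),
            class = "task_config")
}

#' Draw a block-length threshold
#'
#' The number of high-probability-lever choices after which the contingency
#' reverses, uniform on the inclusive integer range of the config.
#'
#' @param config A [task_config()].
#' @return Integer threshold.
#' @export
draw_block_length <- function(config) {
  config$block_min + sample.int(config$block_max - config$block_min + 1L, 1L) - 1L
}

#' Advance the bandit environment by one lever press
#'
#' Draws the reward for `choice` under the current contingency, increments the
#' high-probability-choice counter when the press is on the high side, and
#' flips the contingency once the counter reaches the drawn threshold. The
#' reward of the reversal-triggering press is drawn under the old contingency
#' (the press preceded the flip), but that trial is labelled as belonging to
#' the new block.
#'
#' @param config A [task_config()].
#' @param state List with `high_side` (0/1), `count` (high-side presses so
#'   far this block), `threshold` (drawn block length), `block` (0-based).
#' @param choice 0 (left) or 1 (right).
#' @return List `reward` (0/1), `state` (next state), `flipped` (logical).
#' @export
step_environment <- function(config, state, choice) {
  if (!(is.numeric(choice) && length(choice) == 1L && choice %in% c(0, 1)))
    stop("`choice` must be 0 (left) or 1 (right)")
  on_high <- choice == state$high_side
  p <- if (on_high) config$p_high else config$p_low
  reward <- as.integer(stats::runif(1) < p)
  flipped <- FALSE
  if (on_high) {
    state$count <- state$count + 1L
    if (state$count >= state$threshold) {
      state$high_side <- 1L - state$high_side
      state$count <- 0L
      state$threshold <- draw_block_length(config)
      state$block <- state$block + 1L
      flipped <- TRUE
    }
  }
  list(reward = reward, state = state, flipped = flipped)
}

new_env_state <- function(config, high_side = NULL) {
  if (is.null(high_side)) high_side <- sample(0:1, 1L)
  list(high_side = as.integer(high_side), count = 0L,
       threshold = draw_block_length(config), block = 0L)
}

#' Run a session of the bandit task under a choice policy
#'
#' @param config A [task_config()].
#' @param policy Function of the 0-based trial index returning a length-2
#'   probability vector `c(p_left, p_right)` summing to 1.
#' @param high_side_init Optional initial high-probability side (0/1);
#'   random if `NULL`.
#' @return A `bandit_session` data frame with columns `trial`, `choice`,
#'   `reward`, `high_side`, `block_index`, `trial_in_block`.
#' @export
run_session <- function(config, policy, high_side_init = NULL) {
  n <- config$n_trials
  choice <- reward <- high_side <- block_index <- trial_in_block <- integer(n)
  st <- new_env_state(config, high_side_init)
  in_block <- 0L
  for (t in seq_len(n)) {
    p <- policy(t - 1L)
    if (!(is.numeric(p) && length(p) == 2L && all(p >= 0) &&
          abs(sum(p) - 1) < 1e-8))
      stop("policy must return a probability pair summing to 1")
    ch <- as.integer(stats::runif(1) < p[2L])
    # label the trial BEFORE stepping: the reversal-triggering press belongs
    # to the NEW block, so label after the step when a flip occurred
    out <- step_environment(config, st, ch)
    if (out$flipped) in_block <- 0L
    choice[t] <- ch
    reward[t] <- out$reward
    high_side[t] <- out$state$high_side
    block_index[t] <- out$state$block
    trial_in_block[t] <- in_block
    in_block <- in_block + 1L
    st <- out$state
  }
  new_session(choice, reward, high_side, block_index, trial_in_block)
}

new_session <- function(choice, reward, high_side, block_index,
                        trial_in_block) {
  structure(data.frame(trial = seq_along(choice) - 1L,
                       choice = as.integer(choice),
                       reward = as.integer(reward),
                       high_side = as.integer(high_side),
                       block_index = as.integer(block_index),
                       trial_in_block = as.integer(trial_in_block)),
            class = c("bandit_session", "data.frame"))
}

session_cols <- c("trial", "choice", "reward", "high_side", "block_index",
                  "trial_in_block")

#' Read / write a session CSV
#'
#' Lossless round-trip of the session schema: columns
#' `trial,choice,reward,high_side,block_index,trial_in_block`, one row per
#' trial, 0-based trial index.
#'
#' @param path File path.
#' @return `read_session` returns a `bandit_session`; `write_session`
#'   invisibly returns `path`.
#' @export
read_session <- function(path) {
  df <- utils::read.csv(path)
  missing <- setdiff(session_cols, names(df))
  if (length(missing))
    stop("session file missing columns: ", paste(missing, collapse = ", "))
  if (nrow(df) && (!all(df$choice %in% c(0, 1)) || !all(df$reward %in% c(0, 1)) ||
                   !all(df$high_side %in% c(0, 1))))
    stop("choice, reward and high_side must be coded 0/1")
  new_session(df$choice, df$reward, df$high_side, df$block_index,
              df$trial_in_block)
}

#' @param session A `bandit_session`.
#' @rdname read_session
#' @export
write_session <- function(session, path) {
  utils::write.csv(as.data.frame(session)[, session_cols], path,
                   row.names = FALSE)
  invisible(path)
}
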