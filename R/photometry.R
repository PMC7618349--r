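#' Model-derived reward prediction errors
#'
#' Q-RPE on trial `t` is the outcome minus the pre-update value of the
#' chosen action. SI-RPE is the outcome minus the expected reward under the
#' pre-update belief and a reward-probability matrix: `r_t - sum_s b_t(s) *
#' M[c_t, s]`. By default `M` is the true task contingency matrix, rows
#' indexed by choice (left, right) and columns by state (left lever high,
#' right lever high).
#'
#' @param session A `bandit_session`.
#' @param latents_q,latents_si `agent_latents` from [run_conditioned()] for
#'   the exemplar Q and SI fits on this session.
#' @param reward_matrix 2x2 matrix of reward probabilities by
#'   (choice, state); default `rbind(c(0.7, 0.1), c(0.1, 0.7))`.
#' @return An `rpe_trace` data frame: `trial`, `q_rpe`, `si_rpe`.
#' @export
rpe_trace <- function(session, latents_q, latents_si,
                      reward_matrix = rbind(c(0.7, 0.1), c(0.1, 0.7))) {
  n <- nrow(session)
  if (nrow(latents_q) != n || nrow(latents_si) != n)
    stop("latents and session lengths differ")
  q_rpe <- session$reward -
    ifelse(session$choice == 1, latents_q$q_right, latents_q$q_left)
  b_R <- latents_si$belief_R
  expected <- (1 - b_R) * reward_matrix[cbind(session$choice + 1L, 1L)] +
    b_R * reward_matrix[cbind(session$choice + 1L, 2L)]
  structure(data.frame(trial = session$trial, q_rpe = q_rpe,
                       si_rpe = session$reward - expected),
            class = c("rpe_trace", "data.frame"))
}

#' Event times for a simulated session
#'
#' Draws within-trial event times following the task's timing: trial
#' initiation, lever press after a 0.1-1 s delay (0.1 s steps), outcome cue
#' shortly after the press, then a 0.5 s cue and a 3 s inter-trial interval.
#'
#' @param n_trials Number of trials.
#' @return Data frame `initiation`, `lever_press`, `outcome_cue` (seconds).
#' @keywords internal
draw_event_times <- function(n_trials) {
  delay <- sample(seq(0.1, 1, by = 0.1), n_trials, replace = TRUE)
  initiation <- lever_press <- outcome_cue <- numeric(n_trials)
  t0 <- 2
  for (i in seq_len(n_trials)) {
    initiation[i] <- t0
    lever_press[i] <- t0 + delay[i]
    outcome_cue[i] <- lever_press[i] + 0.2
    t0 <- outcome_cue[i] + 0.5 + 3.0
  }
  data.frame(initiation = initiation, lever_press = lever_press,
             outcome_cue = outcome_cue)
}

sensor_kernel <- function(t, rise = 0.05, decay = 0.5) {
  ifelse(t < 0, 0, (1 - exp(-t / rise)) * exp(-t / decay))
}

#' Synthesize a two-channel photometry session from model RPEs
#'
#' The ground-truth dopamine trace is the sum over trials of the SI-RPE (or
#' any supplied per-trial amplitude) times an exponential-rise/decay sensor
#' kernel placed at the outcome cue. The signal channel adds slow drift (to
#' exercise detrending), a shared low-frequency motion artifact and white
#' noise; the control channel carries the same motion artifact plus its own
#' drift and noise, but no dopamine-dependent component.
#'
#' @param session A `bandit_session`.
#' @param rpe Numeric per-trial RPE amplitudes (e.g. `rpe_trace$si_rpe`).
#' @param sample_rate Hz (default 500).
#' @param kernel_rise,kernel_decay Sensor kernel time constants, s.
#' @param noise_sd White-noise SD per channel (default 0.1).
#' @param drift_amp Slow drift amplitude (default 0.5).
#' @param motion_sd Shared motion-artifact SD (default 0.3).
#' @return A `photometry_session` list: `signal_470`, `control_405`,
#'   `ground_truth`, `events` (data frame), `sample_rate`, `session`.
#' @export
synth_photometry <- function(session, rpe, sample_rate = 500,
                             kernel_rise = 0.05, kernel_decay = 0.5,
                             noise_sd = 0.1, drift_amp = 0.5,
                             motion_sd = 0.3) {
  n <- nrow(session)
  stopifnot(length(rpe) == n)
  events <- draw_event_times(n)
  dur <- max(events$outcome_cue) + 6
  ns <- ceiling(dur * sample_rate)
  tt <- (seq_len(ns) - 1) / sample_rate
  truth <- numeric(ns)
  klen <- ceiling(4 * sample_rate)
  kt <- (seq_len(klen) - 1) / sample_rate
  kern <- sensor_kernel(kt, kernel_rise, kernel_decay)
  for (i in seq_len(n)) {
    i0 <- floor(events$outcome_cue[i] * sample_rate) + 1
    idx <- i0:min(i0 + klen - 1, ns)
    truth[idx] <- truth[idx] + rpe[i] * kern[seq_along(idx)]
  }
  # slow drift: photobleaching-like decay plus a sub-cycle oscillation,
  # both removable by the 4th-order polynomial detrend
  drift <- drift_amp * (exp(-tt / (0.7 * dur)) + 0.4 * sin(pi * tt / dur))
  # motion: smoothed gaussian noise shared by both channels
  raw <- stats::rnorm(ns, sd = motion_sd)
  win <- max(1L, as.integer(sample_rate * 0.2))
  motion <- stats::filter(raw, rep(1 / win, win), sides = 2, circular = TRUE)
  motion <- as.numeric(motion) * sqrt(win)
  signal <- truth + drift + motion + stats::rnorm(ns, sd = noise_sd)
  control_drift <- 0.6 * drift_amp * exp(-tt / (0.5 * dur))
  control <- motion + control_drift + stats::rnorm(ns, sd = noise_sd)
  structure(list(signal_470 = signal, control_405 = control,
                 ground_truth = truth, events = events,
                 sample_rate = sample_rate, session = session),
            class = "photometry_session")
}

poly_detrend <- function(x, order = 4) {
  t <- seq_along(x)
  stats::residuals(stats::lm(x ~ stats::poly(t, order)))
}

#' Preprocess a two-channel photometry recording
#'
#' Lowpass filter both channels (4th-order zero-phase Butterworth), subtract
#' a 4th-order polynomial trend from each, estimate the movement artifact by
#' a least-squares linear fit of the control channel to the signal channel,
#' subtract the fitted artifact, and z-score.
#'
#' @param photometry A `photometry_session`.
#' @param cutoff Lowpass cutoff, Hz (default 10).
#' @return Numeric z-scored corrected trace, same length as the input.
#' @export
preprocess_photometry <- function(photometry, cutoff = 10) {
  fs <- photometry$sample_rate
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  sig <- signal::filtfilt(bf, photometry$signal_470)
  ctl <- signal::filtfilt(bf, photometry$control_405)
  sig <- poly_detrend(sig)
  ctl <- poly_detrend(ctl)
  fit <- stats::lm(sig ~ ctl)
  corrected <- sig - stats::fitted(fit)
  if (stats::sd(corrected) < 1e-10 * max(1, abs(mean(photometry$signal_470))))
    stop("constant trace cannot be z-scored")
  as.numeric(scale(corrected))
}

#' Baselined event summary
#'
#' Mean of the trace over `[event, event + summary_window]` after
#' subtracting the mean over `[event - baseline_window, event]`.
#'
#' @param trace Numeric trace.
#' @param event_times Event times in seconds.
#' @param sample_rate Hz.
#' @param baseline_window,summary_window Seconds (defaults 1 and 4).
#' @return Numeric vector of per-event summaries (`NA` for events whose
#'   windows fall outside the trace, with a warning).
#' @export
event_summary <- function(trace, event_times, sample_rate,
                          baseline_window = 1, summary_window = 4) {
  ns <- length(trace)
  vapply(event_times, function(ev) {
    i0 <- round(ev * sample_rate) + 1
    b0 <- i0 - round(baseline_window * sample_rate)
    i1 <- i0 + round(summary_window * sample_rate) - 1
    if (b0 < 1 || i1 > ns) {
      warning("event at ", ev, " s outside trace bounds; skipped")
      return(NA_real_)
    }
    mean(trace[i0:i1]) - mean(trace[b0:(i0 - 1)])
  }, numeric(1))
}

#' Split per-trial summaries by recent choice-outcome history
#'
#' Labels each trial `t >= 2` by three binary facts: whether the previous
#' press was on the same (S) or opposite (O) lever, whether it was rewarded
#' (+/-), and whether the current press was rewarded (+/-) - eight groups.
#' The O+/O- comparison of rewarded switch trials corresponds to the groups
#' with current reward and previous lever opposite.
#'
#' @param session A `bandit_session`.
#' @param summaries Per-trial scalars aligned to the session (e.g. from
#'   [event_summary()] at the outcome cue, or an RPE column).
#' @return Data frame `group` (e.g. "O+/cur+"), `prev_side`, `prev_outcome`,
#'   `cur_outcome`, `mean`, `n`.
#' @export
history_split <- function(session, summaries) {
  n <- nrow(session)
  stopifnot(length(summaries) == n)
  t <- 2:n
  prev_side <- ifelse(session$choice[t] == session$choice[t - 1], "S", "O")
  prev_out <- ifelse(session$reward[t - 1] == 1, "+", "-")
  cur_out <- ifelse(session$reward[t] == 1, "+", "-")
  d <- data.frame(prev_side = prev_side, prev_outcome = prev_out,
                  cur_outcome = cur_out, val = summaries[t])
  out <- stats::aggregate(val ~ prev_side + prev_outcome + cur_outcome, d,
                          function(v) c(mean(v[!is.na(v)]), sum(!is.na(v))))
  res <- data.frame(group = paste0(out$prev_side, out$prev_outcome, "/cur",
                                   out$cur_outcome),
                    prev_side = out$prev_side, prev_outcome = out$prev_outcome,
                    cur_outcome = out$cur_outcome,
                    mean = out$val[, 1], n = out$val[, 2])
  res[order(res$group), ]
}

#' Variance in history-group dopamine means explained by model RPEs
#'
#' Ordinary least squares of the group-mean dopamine summaries on the
#' corresponding group-mean RPEs, one model at a time.
#'
#' @param dopamine_groups Output of [history_split()] on dopamine summaries.
#' @param rpe_groups Named list of [history_split()] outputs on model RPEs
#'   (e.g. `list(q = ..., si = ...)`).
#' @return Data frame `model`, `r2`.
#' @export
rpe_group_regression <- function(dopamine_groups, rpe_groups) {
  y <- dopamine_groups$mean
  key <- dopamine_groups$group
  if (sum(!is.na(y)) < 3) stop("need at least 3 non-empty history groups")
  do.call(rbind, lapply(names(rpe_groups), function(nm) {
    x <- rpe_groups[[nm]]$mean[match(key, rpe_groups[[nm]]$group)]
    ok <- !is.na(x) & !is.na(y)
    fit <- stats::lm(y[ok] ~ x[ok])
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y[ok] - mean(y[ok]))^2)
    data.frame(model = nm, r2 = r2)
  }))
}

#' Linearly time-warp a trace onto a fixed within-trial template
#'
#' Each trial's anchors (initiation, lever press, outcome cue) are mapped
#' onto fixed template latencies; the trace is resampled by linear
#' interpolation under the piecewise-linear time map, with a fixed-duration
#' post-outcome segment.
#'
#' @param trace Numeric trace.
#' @param events Data frame with `initiation`, `lever_press`, `outcome_cue`
#'   (seconds), one row per trial.
#' @param sample_rate Hz of `trace`.
#' @param template Named numeric template latencies in seconds:
#'   `c(initiation = 0, lever_press = 0.6, outcome_cue = 0.8, end = 4.8)`.
#' @param warp_rate Sampling rate of the warped grid, Hz (default 25).
#' @return List: `mat` (trials x timepoints matrix), `time` (template grid,
#'   s), `outcome_index` (first grid index at/after the outcome anchor).
#' @export
timewarp <- function(trace, events, sample_rate,
                     template = c(initiation = 0, lever_press = 0.6,
                                  outcome_cue = 0.8, end = 4.8),
                     warp_rate = 25) {
  grid <- seq(template[["initiation"]], template[["end"]], by = 1 / warp_rate)
  n <- nrow(events)
  mat <- matrix(NA_real_, n, length(grid))
  ns <- length(trace)
  tmpl_anchor <- unname(template[c("initiation", "lever_press",
                                   "outcome_cue", "end")])
  for (i in seq_len(n)) {
    a <- c(events$initiation[i], events$lever_press[i], events$outcome_cue[i],
           events$outcome_cue[i] +
             (template[["end"]] - template[["outcome_cue"]]))
    if (any(diff(a) <= 0)) stop("non-monotone event anchors in trial ", i)
    src_t <- stats::approx(tmpl_anchor, a, xout = grid)$y
    # interpolate within the trial's slice of the trace only
    i0 <- max(1L, floor(a[1] * sample_rate))
    i1 <- min(ns, ceiling(a[4] * sample_rate) + 2L)
    tt <- (seq.int(i0, i1) - 1) / sample_rate
    mat[i, ] <- stats::approx(tt, trace[i0:i1], xout = src_t, rule = 2)$y
  }
  list(mat = mat, time = grid,
       outcome_index = which(grid >= template[["outcome_cue"]])[1])
}

ridge_solve <- function(X, y, lambda) {
  Xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, Xm); yc <- y - ym
  A <- crossprod(Xc) + diag(lambda, ncol(X))
  b <- solve(A, crossprod(Xc, yc))
  list(coef = b, intercept = ym - sum(Xm * b))
}

ridge_pred <- function(fit, X) as.numeric(X %*% fit$coef) + fit$intercept

#' Cross-validated ridge regression with coefficients of partial
#' determination
#'
#' At each warped timepoint, regresses dopamine across trials on six
#' predictors - outcome, past outcome, choice and past choice (binary,
#' coded +/-0.5) plus the continuous Q-RPE and SI-RPE - using k-fold
#' cross-validated ridge regression with the penalty chosen on a grid by the
#' full model's held-out error. `CPD_j = 100 * (SSE_without_j - SSE_full) /
#' SSE_without_j` on held-out folds; single-predictor explained variance is
#' `100 * (SSE_mean - SSE_j) / SSE_mean`. Only trials within
#' `switch_window` trials of a contingency switch enter (those trials
#' dissociate the two RPE predictors best); the first trial of the session
#' is dropped (no past trial), and folds are split by alternating blocks to
#' avoid leakage.
#'
#' @param warped Output of [timewarp()].
#' @param session The linked `bandit_session`.
#' @param rpe An `rpe_trace` for the session.
#' @param switch_window Trials after a switch to keep (default 6).
#' @param folds Number of CV folds (default 2).
#' @param penalty_grid Ridge penalties (default `10^(-3:3)`).
#' @return A `cpd_result` list: `cpd` (predictors x timepoints matrix, %),
#'   `single_r2` (same shape, %), `time`, `outcome_index`, `predictors`,
#'   `n_trials_used`, `penalty`.
#' @export
ridge_cpd <- function(warped, session, rpe, switch_window = 6, folds = 2,
                      penalty_grid = 10^(-3:3)) {
  n <- nrow(session)
  # trials within `switch_window` of a contingency switch, on either side
  switches <- which(diff(session$block_index) != 0) + 1L
  if (length(switches)) {
    dist <- vapply(seq_len(n), function(t) min(abs(t - switches)),
                   numeric(1))
    keep <- dist < switch_window & seq_len(n) > 1
  } else {
    keep <- rep(FALSE, n)
  }
  if (sum(keep) < 2 * folds)
    stop("need at least ", 2 * folds, " eligible trials")
  idx <- which(keep)
  X <- cbind(outcome = session$reward[idx] - 0.5,
             past_outcome = session$reward[idx - 1] - 0.5,
             choice = session$choice[idx] - 0.5,
             past_choice = session$choice[idx - 1] - 0.5,
             q_rpe = rpe$q_rpe[idx],
             si_rpe = rpe$si_rpe[idx])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant predictor(s) after filtering: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  Y <- warped$mat[idx, , drop = FALSE]
  foldid <- (session$block_index[idx] %% folds) + 1
  if (length(unique(foldid)) < folds)
    foldid <- rep_len(seq_len(folds), length(idx))
  p <- ncol(X); nt <- ncol(Y)
  cpd <- single <- matrix(NA_real_, p, nt,
                          dimnames = list(colnames(X), NULL))
  penalty <- numeric(nt)
  for (ti in seq_len(nt)) {
    y <- Y[, ti]
    sse_cv <- function(cols, lambda) {
      s <- 0
      for (f in seq_len(folds)) {
        tr <- foldid != f
        fit <- ridge_solve(X[tr, cols, drop = FALSE], y[tr], lambda)
        res <- y[!tr] - ridge_pred(fit, X[!tr, cols, drop = FALSE])
        s <- s + sum(res^2)
      }
      s
    }
    full_sse <- vapply(penalty_grid, function(l) sse_cv(seq_len(p), l),
                       numeric(1))
    lam <- penalty_grid[which.min(full_sse)]
    penalty[ti] <- lam
    sse_full <- min(full_sse)
    sse_mean <- sum(vapply(seq_len(folds), function(f) {
      sum((y[foldid == f] - mean(y[foldid != f]))^2)
    }, numeric(1)))
    for (j in seq_len(p)) {
      sse_wo <- sse_cv(setdiff(seq_len(p), j), lam)
      cpd[j, ti] <- 100 * (sse_wo - sse_full) / sse_wo
      sse_j <- sse_cv(j, lam)
      single[j, ti] <- 100 * (sse_mean - sse_j) / sse_mean
    }
  }
  structure(list(cpd = cpd, single_r2 = single, time = warped$time,
                 outcome_index = warped$outcome_index,
                 predictors = colnames(X), n_trials_used = length(idx),
                 penalty = penalty),
            class = "cpd_result")
}

#' Write a CPD result to CSV
#' @param result A `cpd_result`.
#' @param path File path.
#' @export
write_cpd <- function(result, path) {
  long <- do.call(rbind, lapply(result$predictors, function(pr) {
    data.frame(predictor = pr, timepoint = result$time,
               cpd_pct = result$cpd[pr, ],
               single_r2_pct = result$single_r2[pr, ])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' End-to-end reward-prediction-error signature run
#'
#' The module's headline property, run as one unit: simulate behavioral
#' sessions from a generating agent (the exemplar SI or Q model), build
#' synthetic photometry from the generating agent's own RPE trace, then run
#' preprocessing, time-warping and cross-validated ridge CPD on the pooled
#' sessions. Sessions are pooled in groups of `n_sessions` (3 simulation
#' runs of 300 trials per parameter set, the package's simulation unit).
#'
#' The Q-RPE and SI-RPE predictors are computed by conditioning the two
#' exemplar agents, at fixed reference parameters, on each session - the
#' same use of average fitted parameters for trial-by-trial model
#' predictions as in the behavioral analyses. Refitting both exemplars to
#' each simulated session (`refit = TRUE`) is also supported, but on
#' agent-generated (near-deterministic) choices the refitted Q model can
#' mimic the SI latents almost exactly, which leaves the two RPE predictors
#' nearly collinear and the CPD split between them undetermined.
#'
#' @param generator `"si"` or `"q"`: which exemplar agent produces both the
#'   behavior and the dopamine-generating RPE.
#' @param si_params,q_params Generating parameters of the exemplar agents.
#' @param n_sessions Sessions pooled per run (default 3).
#' @param n_trials Trials per session (default 300).
#' @param refit Refit both exemplars to each session instead of using the
#'   fixed reference parameters (default FALSE; see Details).
#' @param n_restarts Fit restarts when `refit = TRUE` (default 50).
#' @param outcome_window Seconds after the outcome anchor over which the
#'   CPD is averaged (default 1, the sensor kernel's support).
#' @return List: `cpd_si`, `cpd_q` (mean CPD, %, in the outcome window),
#'   `cpd` (the full `cpd_result`), `n_trials_used`.
#' @export
rpe_signature_run <- function(generator = c("si", "q"),
                              si_params = list(c = 0.8, gamma = 0.9,
                                               bias = 0),
                              q_params = list(alpha_r = 0.6, alpha_ur = 0.3,
                                              beta = 5, bias = 0),
                              n_sessions = 3, n_trials = 300,
                              refit = FALSE, n_restarts = 50,
                              outcome_window = 1) {
  generator <- match.arg(generator)
  ex <- exemplar_specs()
  cfg <- task_config(n_trials = n_trials)
  gen_spec <- if (generator == "si") ex$si else ex$q
  gen_par <- if (generator == "si") si_params else q_params
  sess <- list(); rpes <- list(); warps <- list()
  for (k in seq_len(n_sessions)) {
    g <- run_generative(gen_spec, gen_par, cfg)
    s <- g$session
    # dopamine generator: the generating agent's own (ground-truth) RPE
    amp <- if (generator == "si")
      rpe_trace(s, g$latents, g$latents)$si_rpe
    else
      s$reward - ifelse(s$choice == 1, g$latents$q_right, g$latents$q_left)
    ph <- synth_photometry(s, amp)
    tr <- preprocess_photometry(ph)
    warps[[k]] <- timewarp(tr, ph$events, ph$sample_rate)
    # analysis RPEs: both exemplar agents conditioned on the session
    pq <- if (refit) fit_session(ex$q, s, n_restarts = n_restarts)$params
          else q_params
    ps <- if (refit) fit_session(ex$si, s, n_restarts = n_restarts)$params
          else si_params
    rpes[[k]] <- rpe_trace(s, run_conditioned(ex$q, pq, s),
                           run_conditioned(ex$si, ps, s))
    sess[[k]] <- s
  }
  pooled <- do.call(rbind, lapply(seq_len(n_sessions), function(k) {
    s <- as.data.frame(sess[[k]])
    s$block_index <- s$block_index + (k - 1L) * 10000L
    s
  }))
  class(pooled) <- c("bandit_session", "data.frame")
  pooled_rpe <- do.call(rbind, lapply(rpes, as.data.frame))
  W <- list(mat = do.call(rbind, lapply(warps, `[[`, "mat")),
            time = warps[[1]]$time,
            outcome_index = warps[[1]]$outcome_index)
  cpd <- ridge_cpd(W, pooled, pooled_rpe)
  oi <- cpd$outcome_index
  warp_rate <- 1 / diff(cpd$time[1:2])
  win <- oi:min(oi + round(outcome_window * warp_rate), ncol(cpd$cpd))
  list(cpd_si = mean(cpd$cpd["si_rpe", win]),
       cpd_q = mean(cpd$cpd["q_rpe", win]),
       cpd = cpd, n_trials_used = cpd$n_trials_used)
}
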