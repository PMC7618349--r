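#' Choice accuracy around contingency reversals
#'
#' For each reversal, collects the indicator `choice == current high side`
#' at offsets relative to the first trial of the new block (offset 0), and
#' averages over blocks within session, then over sessions.
#'
#' @param sessions A `bandit_session` or list thereof.
#' @param window Integer offsets, default `-8:15`.
#' @return A `reversal_curve` data frame: `offset`, `p_high_choice`,
#'   `n_blocks`.
#' @export
reversal_curve <- function(sessions, window = -8:15) {
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  per_sess <- lapply(sessions, function(s) {
    starts <- which(diff(s$block_index) != 0) + 1L   # first trial of block
    if (!length(starts)) return(NULL)
    correct <- as.numeric(s$choice == s$high_side)
    sapply(window, function(off) {
      idx <- starts + off
      ok <- idx >= 1 & idx <= nrow(s)
      # keep offsets within the adjacent blocks only
      if (!any(ok)) return(NA_real_)
      mean(correct[idx[ok]])
    })
  })
  per_sess <- Filter(Negate(is.null), per_sess)
  if (!length(per_sess)) stop("no completed reversals in the input sessions")
  m <- do.call(rbind, per_sess)
  nb <- sum(vapply(sessions, function(s)
    max(0L, length(unique(s$block_index)) - 1L), integer(1)))
  structure(data.frame(offset = window,
                       p_high_choice = colMeans(m, na.rm = TRUE),
                       n_blocks = nb),
            class = c("reversal_curve", "data.frame"))
}

#' Trials to re-reach 50% choice of the new high-probability lever
#'
#' Fits `p(t) = p_inf - (p_inf - p0) * exp(-t / tau)` by least squares to the
#' post-reversal part of a reversal curve (offsets `t >= 0`) and returns the
#' `t` at which the fitted curve crosses 0.5. Returns 0 when the curve starts
#' above 0.5 and `Inf` when it never crosses.
#'
#' @param curve A `reversal_curve`.
#' @return Scalar crossing time in trials (possibly 0 or `Inf`).
#' @export
trials_to_switch <- function(curve) {
  post <- curve[curve$offset >= 0 & !is.na(curve$p_high_choice), ]
  if (nrow(post) < 8) stop("need at least 8 post-reversal offsets")
  t <- post$offset; y <- post$p_high_choice
  p0_init <- y[1]; pinf_init <- mean(utils::tail(y, 3))
  fit <- tryCatch(suppressWarnings(
    stats::nls(y ~ pinf - (pinf - p0) * exp(-t / tau),
               start = list(p0 = p0_init,
                            pinf = max(pinf_init, p0_init + 1e-3),
                            tau = 2),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # flat-curve degenerate case: report by level
    lvl <- mean(y)
    return(if (lvl >= 0.5) 0 else Inf)
  }
  cf <- stats::coef(fit)
  p0 <- cf[["p0"]]; pinf <- cf[["pinf"]]; tau <- cf[["tau"]]
  if (p0 >= 0.5) return(0)
  if (pinf <= 0.5) return(Inf)
  unname(-tau * log((pinf - 0.5) / (pinf - p0)))
}

history_regressors <- function(session, n_lags) {
  n <- nrow(session)
  ch <- ifelse(session$choice == 1, 1, -1)     # +1 right, -1 left
  R <- ch * (session$reward == 1)
  N <- ch * (session$reward == 0)
  idx <- (n_lags + 1):n
  X <- matrix(0, length(idx), 3 * n_lags)
  cn <- character(3 * n_lags)
  for (j in seq_len(n_lags)) {
    X[, j] <- R[idx - j];              cn[j] <- paste0("R", j)
    X[, n_lags + j] <- N[idx - j];     cn[n_lags + j] <- paste0("N", j)
    X[, 2 * n_lags + j] <- ch[idx - j]; cn[2 * n_lags + j] <- paste0("C", j)
  }
  colnames(X) <- cn
  list(X = X, y = session$choice[idx])
}

#' Trial-history logistic regression with elastic-net regularization
#'
#' Models the log-odds of a right-lever choice from three lagged history
#' regressor families: rewarded choice `R(i-j)` (+1 rewarded right, -1
#' rewarded left, 0 otherwise), unrewarded choice `N(i-j)`, and
#' outcome-independent choice `C(i-j)`, for lags `1..n_lags`, plus an
#' intercept. Hyperparameters (inverse regularization strength and L1 ratio)
#' are grid-searched by k-fold cross-validated deviance R-squared; the
#' winning pair is refit on the full session.
#'
#' @param session A `bandit_session`.
#' @param n_lags Number of history lags (default 5).
#' @param inv_strength_grid Inverse-regularization-strength grid (default
#'   `c(0.01, 0.03, 0.1, 0.25, 0.5, 1, 3)`); the glmnet penalty is
#'   `lambda = 1 / (n * C)`.
#' @param l1_ratio_grid L1-ratio grid (default `seq(0, 1, by = 0.1)`).
#' @param folds Number of CV folds (default 5).
#' @return A `history_regression` list: `coef` (data frame `lag, R, N, C`),
#'   `intercept`, `cv_r2`, `inv_strength`, `l1_ratio`.
#' @export
history_logistic_regression <- function(session, n_lags = 5,
                                        inv_strength_grid =
                                          c(0.01, 0.03, 0.1, 0.25, 0.5, 1, 3),
                                        l1_ratio_grid = seq(0, 1, by = 0.1),
                                        folds = 5) {
  if (nrow(session) <= n_lags + folds)
    stop("session too short for ", n_lags, " lags and ", folds, " folds")
  hr <- history_regressors(session, n_lags)
  X <- hr$X; y <- hr$y
  if (length(unique(y)) < 2)
    stop("single-class target: the subject never switched side")
  n <- length(y)
  foldid <- sample(rep_len(seq_len(folds), n))
  cv_r2 <- function(alpha, lambda) {
    devs <- vapply(seq_len(folds), function(f) {
      tr <- foldid != f
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                            alpha = alpha, lambda = lambda,
                            standardize = FALSE)
      p <- as.numeric(stats::predict(fit, X[!tr, , drop = FALSE],
                                     type = "response", s = lambda))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      yt <- y[!tr]
      dev <- -2 * sum(yt * log(p) + (1 - yt) * log(1 - p))
      p0 <- mean(y[tr])
      null <- -2 * sum(yt * log(p0) + (1 - yt) * log(1 - p0))
      1 - dev / null
    }, numeric(1))
    mean(devs)
  }
  best <- list(r2 = -Inf)
  for (a in l1_ratio_grid) for (C in inv_strength_grid) {
    lam <- 1 / (n * C)
    r2 <- cv_r2(a, lam)
    if (r2 > best$r2) best <- list(r2 = r2, alpha = a, C = C, lambda = lam)
  }
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = best$alpha,
                        lambda = best$lambda, standardize = FALSE)
  b <- as.numeric(stats::coef(fit, s = best$lambda))
  names(b) <- c("(Intercept)", colnames(X))
  co <- data.frame(lag = seq_len(n_lags),
                   R = b[paste0("R", seq_len(n_lags))],
                   N = b[paste0("N", seq_len(n_lags))],
                   C = b[paste0("C", seq_len(n_lags))],
                   row.names = NULL)
  structure(list(coef = co, intercept = unname(b[1]), cv_r2 = best$r2,
                 inv_strength = best$C, l1_ratio = best$alpha),
            class = "history_regression")
}

history_label <- function(choices, rewards, t, depth) {
  ref <- choices[t - 1L]
  paste(vapply(seq_len(depth), function(j) {
    side <- if (choices[t - j] == ref) "S" else "O"
    paste0(side, if (rewards[t - j] == 1) "+" else "-")
  }, character(1)), collapse = "")
}

#' Switch probability conditioned on recent choice-outcome history
#'
#' Labels each eligible trial by its previous `depth` trials, each coded
#' same/opposite lever (relative to the choice at `t-1`, the reference
#' lever) and rewarded/unrewarded, reading backwards from `t-1`. For
#' observed sessions `p(switch)` is the empirical probability that the
#' choice at `t` differs from `t-1`; when `latents` are supplied the model's
#' probability mass on the non-previous lever is averaged within label.
#'
#' @param sessions A `bandit_session` or list thereof.
#' @param depth History depth (default 3).
#' @param latents Optional `agent_latents` (or list matching `sessions`):
#'   use model switch probabilities instead of empirical switches.
#' @return A `switch_table` data frame: `history`, `p_switch`, `n`.
#' @export
switch_probability_by_history <- function(sessions, depth = 3,
                                          latents = NULL) {
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  if (!is.null(latents) && inherits(latents, "agent_latents"))
    latents <- list(latents)
  acc <- list()
  for (si in seq_along(sessions)) {
    s <- sessions[[si]]
    n <- nrow(s)
    if (n <= depth) next
    for (t in (depth + 1L):n) {
      lab <- history_label(s$choice, s$reward, t, depth)
      val <- if (is.null(latents)) as.numeric(s$choice[t] != s$choice[t - 1L])
             else {
               l <- latents[[si]]
               if (s$choice[t - 1L] == 1) l$p_left[t] else l$p_right[t]
             }
      acc[[length(acc) + 1L]] <- data.frame(history = lab, val = val)
    }
  }
  if (!length(acc)) stop("no eligible trials at depth ", depth)
  d <- do.call(rbind, acc)
  out <- stats::aggregate(val ~ history, d, mean)
  out$n <- stats::aggregate(val ~ history, d, length)$val
  names(out) <- c("history", "p_switch", "n")
  structure(out[order(out$history), ],
            class = c("switch_table", "data.frame"))
}

#' Proportion of choices consistent with fitted Q and SI strategies
#'
#' Runs each fitted model conditioned on the session; a trial is consistent
#' with a model when the model assigns the actually made choice probability
#' strictly above 0.5. Trials at exactly 0.5 are excluded from that model's
#' denominator.
#'
#' @param session A `bandit_session`.
#' @param fitted_q,fitted_si `fit_result` objects (or lists with `spec`,
#'   `params`).
#' @param switch_window Optional integer: restrict to trials within this
#'   many trials after a reversal (`NULL` = all trials).
#' @return A data frame with one row per model: `model`, `consistent`,
#'   `n_eligible`, `n_tied`.
#' @export
strategy_consistency <- function(session, fitted_q, fitted_si,
                                 switch_window = NULL) {
  keep <- rep(TRUE, nrow(session))
  if (!is.null(switch_window))
    keep <- session$trial_in_block < switch_window & session$block_index > 0
  one <- function(fit, name) {
    l <- run_conditioned(fit$spec, fit$params, session)
    p_actual <- ifelse(session$choice == 1, l$p_right, l$p_left)
    tied <- abs(p_actual - 0.5) < 1e-12
    elig <- keep & !tied
    data.frame(model = name,
               consistent = mean(p_actual[elig] > 0.5),
               n_eligible = sum(elig), n_tied = sum(keep & tied))
  }
  rbind(one(fitted_q, "q"), one(fitted_si, "si"))
}
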