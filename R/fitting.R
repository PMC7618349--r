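cpp_layout <- c("b", "eps", "alpha_c", "beta_c", "alpha_r", "alpha_ur",
                "alpha_cf_r", "alpha_cf_ur", "beta", "delta", "kappa_r",
                "kappa_ur", "gamma_ph", "alpha0", "c", "d", "gamma", "bias")

family_code <- c(random = 0L, wsls = 1L, choice_kernel = 2L, q = 3L, si = 4L)
qvar_code <- c(plain = 0L, cf_same = 1L, cf_diff = 2L, forget_reset = 3L,
               forget_gradual = 4L, dynamic = 5L)

# Canonicalize named params into the fixed C++ layout: rp-off models get
# their single rate copied into both outcome slots; absent augments become 0.
canon_par <- function(spec, params) {
  pv <- as.list(params)
  out <- stats::setNames(numeric(length(cpp_layout)), cpp_layout)
  for (nm in intersect(names(pv), cpp_layout)) out[nm] <- pv[[nm]]
  if (spec$family == "q") {
    if (!spec$rp) {
      if (spec$q_variant == "dynamic") {
        out["kappa_r"] <- out["kappa_ur"] <- pv$kappa
      } else {
        out["alpha_r"] <- out["alpha_ur"] <- pv$alpha
        if (spec$q_variant == "cf_diff")
          out["alpha_cf_r"] <- out["alpha_cf_ur"] <- pv$alpha_cf
      }
    }
  }
  if (spec$family == "si" && spec$si_variant == "d_zero") out["d"] <- 0
  if (!spec$bias) out["bias"] <- 0
  out
}

forward_fast <- function(spec, params, session) {
  m <- agent_forward_cpp(family_code[[spec$family]],
                         qvar_code[[spec$q_variant]],
                         isTRUE(spec$ck) || spec$family == "choice_kernel",
                         canon_par(spec, params),
                         as.integer(session$choice),
                         as.integer(session$reward))
  colnames(m) <- c("p_right", "q_left", "q_right", "belief_R", "rpe")
  m
}

#' Negative log-likelihood of a session under a model
#'
#' `-sum_t log p(c_t | history, params)`, with per-trial probabilities from
#' the model's forward pass and floored at `floor_p` for log-safety.
#'
#' @param spec A [model_spec()].
#' @param params Named parameters (see [param_info()]).
#' @param session A `bandit_session`.
#' @param floor_p Probability floor (default 1e-12).
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(spec, params, session, floor_p = 1e-12) {
  if (nrow(session) == 0) stop("session is empty")
  check_params(spec, params)
  agent_nll_cpp(family_code[[spec$family]], qvar_code[[spec$q_variant]],
                isTRUE(spec$ck) || spec$family == "choice_kernel",
                canon_par(spec, params), as.integer(session$choice),
                as.integer(session$reward), floor_p)
}

#' Bayesian Information Criterion
#'
#' `BIC = 2 * nll + k * log(N)` where `nll` is the minimized negative
#' log-likelihood, `k` the number of free parameters and `N` the number of
#' trials.
#'
#' @param nll Negative log-likelihood at the best fit.
#' @param k Number of free parameters.
#' @param n Number of trials.
#' @return Scalar BIC.
#' @export
bic <- function(nll, k, n) {
  stopifnot(n >= 1)
  2 * nll + k * log(n)
}

#' Fit a model to a session by multi-restart maximum likelihood
#'
#' Bounded quasi-Newton (`L-BFGS-B`) minimization of the negative
#' log-likelihood from `n_restarts` uniform-random starting points within
#' the parameter bounds; the restart attaining the lowest NLL wins.
#'
#' @inheritParams negative_log_likelihood
#' @param n_restarts Number of random restarts (default 50).
#' @param min_trials Minimum session length accepted (default 20).
#' @return A `fit_result` list: `spec`, `params` (named best parameters),
#'   `nll`, `bic`, `n_restarts`, `restart_nlls`, `converged`.
#' @export
fit_session <- function(spec, session, n_restarts = 50, min_trials = 20) {
  n <- nrow(session)
  if (n < min_trials)
    stop("session has ", n, " trials; need at least ", min_trials)
  info <- param_info(spec)
  k <- nrow(info)
  ch <- as.integer(session$choice); rw <- as.integer(session$reward)
  fam <- family_code[[spec$family]]; qv <- qvar_code[[spec$q_variant]]
  uck <- isTRUE(spec$ck) || spec$family == "choice_kernel"
  obj <- function(x) {
    names(x) <- info$name
    v <- agent_nll_cpp(fam, qv, uck, canon_par(spec, as.list(x)), ch, rw,
                       1e-12)
    if (!is.finite(v)) 1e10 else v
  }
  # shrink starts slightly inside the box so finite-difference gradients
  # at the boundary stay defined
  lo <- info$lower; hi <- info$upper
  eps <- 1e-6 * (hi - lo)
  best <- NULL
  restart_nlls <- numeric(n_restarts)
  any_conv <- FALSE
  for (i in seq_len(n_restarts)) {
    x0 <- stats::runif(k, lo + eps, hi - eps)
    res <- tryCatch(
      stats::optim(x0, obj, method = "L-BFGS-B", lower = lo, upper = hi),
      error = function(e) NULL)
    if (is.null(res)) { restart_nlls[i] <- NA_real_; next }
    restart_nlls[i] <- res$value
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all ", n_restarts, " restarts failed for ", spec$label)
  pars <- as.list(stats::setNames(best$par, info$name))
  structure(list(spec = spec, params = pars, nll = best$value,
                 bic = bic(best$value, k, n), n_restarts = n_restarts,
                 restart_nlls = restart_nlls, converged = any_conv),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$spec$label,
      sprintf(" nll=%.3f bic=%.3f\n", x$nll, x$bic))
  print(unlist(x$params))
  invisible(x)
}

#' Fit a set of models to a set of sessions and compare by BIC
#'
#' Each model is fit to each session; per-session `dbic` is the difference
#' from that session's most parsimonious (lowest-BIC) model, with ties
#' broken toward the model with fewer parameters, then declaration order.
#'
#' @param specs List of [model_spec()] objects.
#' @param sessions List of `bandit_session` objects.
#' @param grouping Optional vector mapping each session to a subject id;
#'   per-subject mean BIC/dbic are reported when given.
#' @param n_restarts Restarts per fit.
#' @return A `comparison_table` list: `table` (data frame `session, mouse,
#'   model, k, nll, bic, dbic, best`), `fits` (nested list), `by_mouse`
#'   (mean dbic per subject x model, or NULL).
#' @export
compare_models <- function(specs, sessions, grouping = NULL,
                           n_restarts = 50) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  if (is.null(grouping)) grouping <- rep("m1", length(sessions))
  labels <- vapply(specs, function(s) s$label, character(1))
  ks <- vapply(specs, n_params, numeric(1))
  rows <- list(); fits <- vector("list", length(sessions))
  for (si in seq_along(sessions)) {
    fr <- lapply(specs, fit_session, session = sessions[[si]],
                 n_restarts = n_restarts)
    fits[[si]] <- stats::setNames(fr, labels)
    bics <- vapply(fr, `[[`, numeric(1), "bic")
    # best: lowest BIC, ties toward fewer parameters, then declaration order
    ord <- order(bics, ks, seq_along(specs))
    best_i <- ord[1]
    rows[[si]] <- data.frame(session = si, mouse = grouping[si],
                             model = labels, k = ks,
                             nll = vapply(fr, `[[`, numeric(1), "nll"),
                             bic = bics, dbic = bics - bics[best_i],
                             best = seq_along(specs) == best_i)
  }
  tab <- do.call(rbind, rows)
  by_mouse <- if (length(unique(grouping)) >= 1)
    stats::aggregate(cbind(bic, dbic) ~ mouse + model, tab, mean)
  structure(list(table = tab, fits = fits, by_mouse = by_mouse),
            class = "comparison_table")
}

#' Exemplar Q and SI models
#'
#' The matched pair used for the headline strategy comparison: both carry
#' reward/punishment sensitivity and a lateral choice bias. For Q this means
#' asymmetric learning rates (`alpha_r`, `alpha_ur`) plus `beta` and `bias`;
#' for SI the omission compatibility is fixed at zero (`d = 0`, i.e. only
#' rewarded trials inform the observation likelihood), leaving `c`, `gamma`
#' and `bias`.
#'
#' @return List with elements `q` and `si`, each a [model_spec()].
#' @export
exemplar_specs <- function() {
  list(q = model_spec("q", q_variant = "plain", bias = TRUE, rp = TRUE,
                      label = "q_exemplar"),
       si = model_spec("si", si_variant = "d_zero", bias = TRUE,
                       label = "si_exemplar"))
}

#' Write a comparison table to CSV
#' @param comparison A `comparison_table`.
#' @param path File path.
#' @export
write_comparison <- function(comparison, path) {
  utils::write.csv(comparison$table, path, row.names = FALSE)
  invisible(path)
}
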