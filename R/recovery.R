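#' Simulate sessions from fitted parameter sets
#'
#' For each fit, runs the fitted model generatively for `runs_per_fit`
#' sessions of `n_trials` trials, labelling each with the generating model.
#'
#' @param fits List of `fit_result` objects (from [fit_session()]).
#' @param config A [task_config()]; its `n_trials` is overridden by
#'   `n_trials`.
#' @param runs_per_fit Simulation runs per parameter set (default 3).
#' @param n_trials Trials per run (default 300).
#' @return List of `list(spec_label, session)` entries.
#' @export
simulate_from_fits <- function(fits, config = task_config(),
                               runs_per_fit = 3, n_trials = 300) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  cfg <- config; cfg$n_trials <- as.integer(n_trials)
  out <- list()
  for (f in fits) {
    for (r in seq_len(runs_per_fit)) {
      g <- run_generative(f$spec, f$params, cfg)
      out[[length(out) + 1L]] <- list(spec_label = f$spec$label,
                                      session = g$session)
    }
  }
  out
}

#' Model recovery: confusion and inversion matrices
#'
#' Fits every candidate model to every labelled session; the winner per
#' session is the lowest BIC (ties toward fewer parameters). The confusion
#' matrix is `p(fit model | simulated model)` (rows sum to 1); the inversion
#' matrix is `p(simulated model | fit model)`, computed by Bayes' rule under
#' a uniform prior over generating models.
#'
#' @param specs List of candidate [model_spec()] objects.
#' @param labelled_sessions Output of [simulate_from_fits()].
#' @param n_restarts Restarts per fit (default 50).
#' @return A `recovery_matrices` list: `confusion`, `inversion`, `counts`,
#'   `n_failed`.
#' @export
recover_models <- function(specs, labelled_sessions, n_restarts = 50) {
  labels <- vapply(specs, function(s) s$label, character(1))
  ks <- vapply(specs, n_params, numeric(1))
  gen_labels <- sort(unique(vapply(labelled_sessions, `[[`, character(1),
                                   "spec_label")))
  counts <- matrix(0, length(gen_labels), length(labels),
                   dimnames = list(simulated = gen_labels, fit = labels))
  n_failed <- 0L
  for (ls in labelled_sessions) {
    bics <- rep(NA_real_, length(specs))
    for (i in seq_along(specs)) {
      f <- tryCatch(fit_session(specs[[i]], ls$session,
                                n_restarts = n_restarts),
                    error = function(e) NULL)
      if (!is.null(f)) bics[i] <- f$bic
    }
    if (all(is.na(bics))) { n_failed <- n_failed + 1L; next }
    ord <- order(bics, ks, seq_along(specs), na.last = TRUE)
    counts[ls$spec_label, ord[1]] <- counts[ls$spec_label, ord[1]] + 1
  }
  recovery_from_counts(counts, n_failed)
}

recovery_from_counts <- function(counts, n_failed = 0L) {
  confusion <- counts / pmax(rowSums(counts), 1)
  # Bayes under a uniform prior over generating models:
  # p(sim | fit) = confusion[sim, fit] / sum_sim confusion[sim, fit]
  colsum <- colSums(confusion)
  inversion <- sweep(confusion, 2, ifelse(colsum > 0, colsum, 1), "/")
  structure(list(confusion = confusion, inversion = inversion,
                 counts = counts, n_failed = n_failed),
            class = "recovery_matrices")
}

#' Collapse recovery matrices over model classes
#'
#' Sums confusion mass within classes (e.g. the Q family vs the SI family)
#' and renormalizes rows.
#'
#' @param matrices A `recovery_matrices` object.
#' @param class_map Named character vector mapping each model label to a
#'   class name.
#' @return A `recovery_matrices` object over classes.
#' @export
collapse_by_class <- function(matrices, class_map) {
  labs <- rownames(matrices$counts)
  labs_f <- colnames(matrices$counts)
  unmapped <- setdiff(union(labs, labs_f), names(class_map))
  if (length(unmapped))
    stop("class_map missing entries for: ", paste(unmapped, collapse = ", "))
  classes <- sort(unique(unname(class_map[union(labs, labs_f)])))
  counts <- matrix(0, length(classes), length(classes),
                   dimnames = list(simulated = classes, fit = classes))
  for (i in labs) for (j in labs_f)
    counts[class_map[[i]], class_map[[j]]] <-
      counts[class_map[[i]], class_map[[j]]] + matrices$counts[i, j]
  recovery_from_counts(counts, matrices$n_failed)
}

#' Write recovery matrices to CSV
#' @param matrices A `recovery_matrices`.
#' @param path File path (confusion); the inversion matrix goes to
#'   `<path>` with suffix `_inversion` before the extension.
#' @export
write_recovery <- function(matrices, path) {
  utils::write.csv(as.data.frame(matrices$confusion), path)
  inv_path <- if (grepl("\\.", basename(path)))
    sub("\\.([^.]*)$", "_inversion.\\1", path)
  else paste0(path, "_inversion")
  utils::write.csv(as.data.frame(matrices$inversion), inv_path)
  invisible(path)
}
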