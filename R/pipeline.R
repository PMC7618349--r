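#' Default pipeline configuration
#'
#' Bundles the knobs of the end-to-end synthetic analysis: task settings,
#' candidate models, fitting, recovery, photometry and population options,
#' and an output directory. Seeds are explicit; one global seed fans out to
#' per-stage seeds via fixed offsets so stages rerun reproducibly.
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @param n_mice,sessions_per_mouse,n_trials Synthetic cohort size.
#' @param n_restarts Fit restarts.
#' @param si_params,q_params Generating parameters of the exemplar agents.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("banditSI_run_"), seed = 1,
                            n_mice = 2, sessions_per_mouse = 3,
                            n_trials = 300, n_restarts = 50,
                            si_params = list(c = 0.8, gamma = 0.9, bias = 0),
                            q_params = list(alpha_r = 0.6, alpha_ur = 0.3,
                                            beta = 5, bias = 0)) {
  structure(list(out_dir = out_dir, seed = seed, n_mice = n_mice,
                 sessions_per_mouse = sessions_per_mouse,
                 n_trials = n_trials, n_restarts = n_restarts,
                 si_params = si_params, q_params = q_params,
                 task = task_config(n_trials = n_trials)),
            class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a cohort of SI-agent sessions, fits and compares the exemplar Q
#' and SI models, runs model recovery on the exemplar pair, computes
#' behavioral metrics, the photometry RPE regression, and the population
#' analyses, writing CSV/JSON artifacts and a manifest to the output
#' directory.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ex <- exemplar_specs()
  manifest <- list(seed = config$seed, stages = list())
  stage_seed <- function(k) config$seed + 1000L * k

  # 1. simulate cohort (SI agents, as mouse stand-ins)
  set.seed(stage_seed(1))
  sessions <- list(); grouping <- character(0)
  for (m in seq_len(config$n_mice)) {
    for (s in seq_len(config$sessions_per_mouse)) {
      g <- run_generative(ex$si, config$si_params, config$task)
      sessions[[length(sessions) + 1L]] <- g$session
      grouping <- c(grouping, paste0("m", m))
      write_session(g$session, file.path(config$out_dir,
        sprintf("session_m%d_s%d.csv", m, s)))
    }
  }

  # 2. fit and compare exemplar models
  set.seed(stage_seed(2))
  comparison <- compare_models(list(ex$q, ex$si), sessions,
                               grouping = grouping,
                               n_restarts = config$n_restarts)
  write_comparison(comparison, file.path(config$out_dir, "comparison.csv"))

  # 3. model recovery on the exemplar pair (one run per fitted session)
  set.seed(stage_seed(3))
  first_fits <- list(comparison$fits[[1]][[ex$q$label]],
                     comparison$fits[[1]][[ex$si$label]])
  labelled <- simulate_from_fits(first_fits, config$task, runs_per_fit = 3,
                                 n_trials = config$n_trials)
  recovery <- recover_models(list(ex$q, ex$si), labelled,
                             n_restarts = config$n_restarts)
  write_recovery(recovery, file.path(config$out_dir, "recovery.csv"))

  # 4. behavioral metrics
  set.seed(stage_seed(4))
  curve <- reversal_curve(sessions)
  utils::write.csv(curve, file.path(config$out_dir, "reversal_curve.csv"),
                   row.names = FALSE)
  swt <- switch_probability_by_history(sessions)
  utils::write.csv(swt, file.path(config$out_dir, "switch_table.csv"),
                   row.names = FALSE)

  # 5. photometry on the first session
  set.seed(stage_seed(5))
  s1 <- sessions[[1]]
  fits1 <- comparison$fits[[1]]
  lat_q <- run_conditioned(ex$q, fits1[[ex$q$label]]$params, s1)
  lat_si <- run_conditioned(ex$si, fits1[[ex$si$label]]$params, s1)
  rpe <- rpe_trace(s1, lat_q, lat_si)
  phot <- synth_photometry(s1, rpe$si_rpe)
  trace <- preprocess_photometry(phot)
  warped <- timewarp(trace, phot$events, phot$sample_rate)
  cpd <- ridge_cpd(warped, s1, rpe)
  write_cpd(cpd, file.path(config$out_dir, "cpd.csv"))

  # 6. population analyses on the first session
  set.seed(stage_seed(6))
  pop <- synth_population(s1)
  sel <- selectivity_index(pop, "context", n_shuffles = 200)
  utils::write.csv(sel, file.path(config$out_dir, "selectivity.csv"),
                   row.names = FALSE)
  dec <- decode(pop, "choice", reps = 20)

  manifest$stages <- list(
    n_sessions = length(sessions),
    si_best = mean(comparison$table$best[comparison$table$model ==
                                           ex$si$label]),
    recovery_diag = unname(diag(recovery$confusion)),
    cpd_si_at_outcome = cpd$cpd["si_rpe", cpd$outcome_index],
    choice_decode = dec$accuracy)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sessions = sessions, comparison = comparison,
                 recovery = recovery, curve = curve, switch_table = swt,
                 rpe = rpe, cpd = cpd, population = pop,
                 selectivity = sel, decode = dec, manifest = manifest))
}

#' Hand-checkable fixtures used in the tests
#'
#' Builds the small deterministic objects the unit tests reason about: a
#' 3-trial worked session, a single-transient photometry trace, and a
#' 4-class linearly separable population.
#'
#' @param seed Seed for the separable population.
#' @return A list with `worked_session`, `single_kernel` (list `trace`,
#'   `sample_rate`, `events`) and `separable_population`.
#' @export
make_fixtures <- function(seed = 1) {
  worked <- new_session(choice = c(1L, 1L, 0L), reward = c(1L, 0L, 1L),
                        high_side = c(1L, 1L, 0L), block_index = c(0L, 0L, 1L),
                        trial_in_block = c(0L, 1L, 0L))
  fs <- 100
  events <- data.frame(initiation = 1, lever_press = 1.6, outcome_cue = 1.8)
  tt <- (0:(8 * fs - 1)) / fs
  trace <- sensor_kernel(tt - events$outcome_cue)
  set.seed(seed)
  cfg <- task_config(n_trials = 80)
  sess <- run_session(cfg, function(t) c(0.5, 0.5))
  pop <- synth_population(sess, n_neurons = 40,
                          tuning_mix = c(choice = 0.4, outcome = 0.3,
                                         context = 0.3, time = 0,
                                         untuned = 0),
                          gain = 3, noise = 0.05)
  list(worked_session = worked,
       single_kernel = list(trace = trace, sample_rate = fs, events = events),
       separable_population = pop)
}
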