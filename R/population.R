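#' Trial-type labels from a behavioral session
#'
#' Each trial is labelled by the choice (L/R) and whether the chosen lever
#' was the current high- or low-probability one: `RH`, `RL`, `LH`, `LL`.
#' Context A is `{RH, LL}` (right lever high) and context B `{RL, LH}`.
#'
#' @param session A `bandit_session`.
#' @return Character vector of labels.
#' @export
trial_type_labels <- function(session) {
  side <- ifelse(session$choice == 1, "R", "L")
  hl <- ifelse(session$choice == session$high_side, "H", "L")
  paste0(side, hl)
}

label_dichotomy <- function(labels, variable) {
  switch(variable,
         choice = substr(labels, 1, 1) == "R",
         expected_outcome = substr(labels, 2, 2) == "H",
         context = labels %in% c("RH", "LL"),
         stop("unknown variable: ", variable))
}

tuning_temporal_field <- function(n_time) {
  centre <- stats::runif(1, 0.2, 0.8) * n_time
  width <- stats::runif(1, 0.15, 0.4) * n_time
  exp(-0.5 * ((seq_len(n_time) - centre) / width)^2)
}

#' Synthesize a trial-labelled neural population
#'
#' Each neuron is assigned a tuning class - choice, (expected) outcome,
#' context, time or untuned - a preferred condition and a within-trial
#' temporal field. Rates are `baseline + gain * tuning(label) * field(time)`
#' plus truncated gaussian noise, mimicking deconvolved spike probabilities.
#' Context cells respond equally on both trial types of their preferred
#' context (abstract by construction); an alternative `conjunction` class
#' (via `tuning_mix`) responds to a single trial type only.
#'
#' @param session A `bandit_session` (supplies the trial labels).
#' @param n_neurons Number of neurons.
#' @param tuning_mix Named proportions over `choice`, `outcome`, `context`,
#'   `conjunction`, `time`, `untuned`; defaults mirror the recorded class
#'   shares `c(choice = 0.4, outcome = 0.2, context = 0.3, time = 0.05,
#'   untuned = 0.05)`.
#' @param gain Tuned-rate gain (default 1).
#' @param noise SD of the activity noise (default 0.3).
#' @param n_time Within-trial timepoints (default 20).
#' @return A `neural_session` list: `activity` (neurons x trials x time
#'   array), `labels`, `classes`, `preferred`, `session`.
#' @export
synth_population <- function(session, n_neurons = 60,
                             tuning_mix = c(choice = 0.4, outcome = 0.2,
                                            context = 0.3, time = 0.05,
                                            untuned = 0.05),
                             gain = 1, noise = 0.3, n_time = 20) {
  stopifnot(abs(sum(tuning_mix) - 1) < 1e-8)
  labels <- trial_type_labels(session)
  n_trials <- length(labels)
  classes <- sample(names(tuning_mix), n_neurons, replace = TRUE,
                    prob = tuning_mix)
  activity <- array(0, c(n_neurons, n_trials, n_time))
  preferred <- character(n_neurons)
  baseline <- 0.2
  for (i in seq_len(n_neurons)) {
    field <- tuning_temporal_field(n_time)
    drive <- switch(classes[i],
      choice = {
        preferred[i] <- sample(c("R", "L"), 1)
        as.numeric(substr(labels, 1, 1) == preferred[i])
      },
      outcome = {
        preferred[i] <- sample(c("H", "L"), 1)
        as.numeric(substr(labels, 2, 2) == preferred[i])
      },
      context = {
        preferred[i] <- sample(c("A", "B"), 1)
        pair <- if (preferred[i] == "A") c("RH", "LL") else c("RL", "LH")
        as.numeric(labels %in% pair)
      },
      conjunction = {
        preferred[i] <- sample(c("RH", "RL", "LH", "LL"), 1)
        as.numeric(labels == preferred[i])
      },
      time = { preferred[i] <- "time"; rep(1, n_trials) },
      untuned = { preferred[i] <- "none"; rep(0, n_trials) })
    m <- baseline + gain * outer(drive, field)
    activity[i, , ] <- pmax(m + stats::rnorm(n_trials * n_time, sd = noise), 0)
  }
  structure(list(activity = activity, labels = labels, classes = classes,
                 preferred = preferred, session = session),
            class = "neural_session")
}

window_features <- function(activity) {
  # mean over within-trial timepoints -> trials x neurons
  t(apply(activity, c(1, 2), mean))
}

#' Selectivity index with a permutation test
#'
#' `SI = (f+ - f-) / (f+ + f-)` where `f+` and `f-` are the neuron's mean
#' window-averaged activity on the two trial classes. Significance is
#' assessed against `n_shuffles` label permutations with add-one smoothing:
#' `p = (1 + #{|SI_shuffle| >= |SI|}) / (1 + n_shuffles)`.
#'
#' @param population A `neural_session`.
#' @param split Logical vector over trials defining the positive class (see
#'   [label_dichotomy()]), or a variable name (`"choice"`,
#'   `"expected_outcome"`, `"context"`).
#' @param n_shuffles Number of permutations (default 1000).
#' @return Data frame `neuron`, `si`, `p`, `defined` (`FALSE` where
#'   `f+ + f- = 0`, with `si = NA`).
#' @export
selectivity_index <- function(population, split, n_shuffles = 1000) {
  if (is.character(split)) split <- label_dichotomy(population$labels, split)
  if (all(split) || !any(split)) stop("both classes must be non-empty")
  feat <- window_features(population$activity)   # trials x neurons
  si_of <- function(s) {
    fp <- colMeans(feat[s, , drop = FALSE])
    fm <- colMeans(feat[!s, , drop = FALSE])
    tot <- fp + fm
    ifelse(tot > 0, (fp - fm) / tot, NA_real_)
  }
  si_obs <- si_of(split)
  count <- integer(ncol(feat))
  for (k in seq_len(n_shuffles)) {
    s <- sample(split)
    count <- count + as.integer(abs(si_of(s)) >= abs(si_obs))
  }
  data.frame(neuron = seq_len(ncol(feat)), si = si_obs,
             p = (1 + count) / (1 + n_shuffles), defined = !is.na(si_obs))
}

#' Cross-trial-type demeaned PCA of population trajectories
#'
#' Computes each neuron's timepoint-wise mean per trial type, subtracts the
#' cross-type mean (the non-selective component), baselines each condition
#' trajectory to its first timepoint, concatenates the four types into a
#' neurons x (types * time) matrix, and projects the per-type trajectories
#' onto the principal axes of that matrix.
#'
#' @param population A `neural_session`.
#' @param n_components Number of components to retain (default 3).
#' @return List: `projections` (named list per trial type of time x
#'   component matrices), `var_explained`, `types`, `rotation`.
#' @export
trial_type_pca <- function(population, n_components = 3) {
  types <- sort(unique(population$labels))
  if (length(types) < 2) stop("need at least 2 trial types")
  act <- population$activity
  n_time <- dim(act)[3]
  cond_mean <- lapply(types, function(ty) {
    sel <- population$labels == ty
    apply(act[, sel, , drop = FALSE], c(1, 3), mean)  # neurons x time
  })
  grand <- Reduce(`+`, cond_mean) / length(types)
  dem <- lapply(cond_mean, function(m) {
    d <- m - grand
    d - d[, 1]                       # baseline to trial start
  })
  X <- do.call(cbind, dem)           # neurons x (types * time)
  pc <- stats::prcomp(t(X), center = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  proj <- lapply(dem, function(m) t(m) %*% pc$rotation[, seq_len(k),
                                                       drop = FALSE])
  names(proj) <- types
  list(projections = proj,
       var_explained = pc$sdev^2 / sum(pc$sdev^2), types = types,
       rotation = pc$rotation[, seq_len(k), drop = FALSE])
}

balanced_resample <- function(feat, cls, per_class) {
  i1 <- sample(which(cls), per_class, replace = TRUE)
  i0 <- sample(which(!cls), per_class, replace = TRUE)
  list(X = feat[c(i1, i0), , drop = FALSE],
       y = factor(rep(c(1, 0), each = per_class)))
}

# stratified split of unique trials, then balanced resampling with
# replacement within each side (keeps held-out trials truly unseen)
split_resample <- function(feat, cls, per_class, split) {
  pick <- function(idx, n) sample(idx, n, replace = TRUE)
  tr1 <- sample(which(cls), max(1L, round(split * sum(cls))))
  tr0 <- sample(which(!cls), max(1L, round(split * sum(!cls))))
  te1 <- setdiff(which(cls), tr1); te0 <- setdiff(which(!cls), tr0)
  if (!length(te1)) { te1 <- tr1[1]; tr1 <- tr1[-1] }
  if (!length(te0)) { te0 <- tr0[1]; tr0 <- tr0[-1] }
  n_tr <- round(split * per_class); n_te <- per_class - n_tr
  list(Xtr = feat[c(pick(tr1, n_tr), pick(tr0, n_tr)), , drop = FALSE],
       ytr = factor(rep(c(1, 0), each = n_tr)),
       Xte = feat[c(pick(te1, n_te), pick(te0, n_te)), , drop = FALSE],
       yte = factor(rep(c(1, 0), each = n_te)))
}

svm_cv_fit <- function(X, y, cost_grid, cv_folds = 5) {
  best_cost <- cost_grid[1]
  if (length(cost_grid) > 1) {
    n <- nrow(X)
    fid <- sample(rep_len(seq_len(cv_folds), n))
    acc <- vapply(cost_grid, function(co) {
      mean(vapply(seq_len(cv_folds), function(f) {
        tr <- fid != f
        if (length(unique(y[tr])) < 2) return(NA_real_)
        m <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = co, scale = FALSE)
        mean(stats::predict(m, X[!tr, , drop = FALSE]) == y[!tr])
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    best_cost <- cost_grid[which.max(acc)]
  }
  e1071::svm(X, y, kernel = "linear", cost = best_cost, scale = FALSE)
}

#' Balanced linear decoding of a trial variable
#'
#' Window-averages activity, splits the unique trials of each class 75/25
#' into train and test, balanced-resamples each side with replacement (to
#' `resample` pseudo-trials per class in total, so held-out trials stay
#' unseen during training), grid-searches the linear SVM regularization by
#' cross-validation on the training split, and reports held-out accuracy
#' averaged over `reps` random splits. A shuffle control repeats the
#' pipeline with permuted labels.
#'
#' @param population A `neural_session`.
#' @param variable `"choice"`, `"expected_outcome"` or `"context"`.
#' @param resample Per-class resample count (default 250).
#' @param split Train fraction (default 0.75).
#' @param reps Number of repetitions (default 100).
#' @param cost_grid SVM regularization grid (default `c(0.01, 0.1, 1, 10)`).
#' @param shuffle Also run the label-shuffle control (default TRUE).
#' @return A `decode_result` list: `variable`, `accuracy`, `accuracy_sd`,
#'   `shuffle_accuracy`, `shuffle_sd`, `reps`.
#' @export
decode <- function(population, variable, resample = 250, split = 0.75,
                   reps = 100, cost_grid = c(0.01, 0.1, 1, 10),
                   shuffle = TRUE) {
  cls <- label_dichotomy(population$labels, variable)
  if (!any(cls) || !any(!cls)) stop("a class is absent for ", variable)
  feat <- window_features(population$activity)
  run <- function(cls) {
    vapply(seq_len(reps), function(r) {
      rs <- split_resample(feat, cls, resample, split)
      m <- svm_cv_fit(rs$Xtr, rs$ytr, cost_grid)
      mean(stats::predict(m, rs$Xte) == rs$yte)
    }, numeric(1))
  }
  acc <- run(cls)
  sh <- if (shuffle) run(sample(cls)) else NA_real_
  structure(list(variable = variable, accuracy = mean(acc),
                 accuracy_sd = stats::sd(acc),
                 shuffle_accuracy = mean(sh), shuffle_sd = stats::sd(sh),
                 reps = reps),
            class = "decode_result")
}

ccgp_splits <- function(variable) {
  # train on one condition pair of the dichotomy, test on the held-out pair
  switch(variable,
    context = list(list(train = c("RH", "LH"), test = c("LL", "RL")),
                   list(train = c("LL", "RL"), test = c("RH", "LH"))),
    choice = list(list(train = c("RH", "LH"), test = c("RL", "LL")),
                  list(train = c("RL", "LL"), test = c("RH", "LH"))),
    expected_outcome = list(list(train = c("RH", "RL"), test = c("LH", "LL")),
                            list(train = c("LH", "LL"), test = c("RH", "RL"))),
    stop("unknown variable: ", variable))
}

#' Cross-condition generalization performance (CCGP)
#'
#' For each train/test split consistent with the variable's dichotomy, a
#' linear SVM is trained to discriminate the two training conditions and
#' tested on the two held-out conditions (e.g. for context: train RH vs LH,
#' test LL vs RL). High CCGP indicates an abstract (condition-general)
#' representation.
#'
#' @inheritParams decode
#' @param reps Resampling repetitions per split (default 20).
#' @return A `decode_result` list with `accuracy` (mean over splits and
#'   reps), `per_split` accuracies, `variable`.
#' @export
ccgp <- function(population, variable, resample = 250, reps = 20,
                 cost_grid = c(0.01, 0.1, 1, 10)) {
  labs <- population$labels
  if (!all(c("RH", "RL", "LH", "LL") %in% labs))
    stop("all four trial types must be present")
  feat <- window_features(population$activity)
  pos <- label_dichotomy(labs, variable)
  per_split <- vapply(ccgp_splits(variable), function(sp) {
    mean(vapply(seq_len(reps), function(r) {
      # balanced resample within each training/testing condition
      take <- function(conds) {
        idx <- unlist(lapply(conds, function(cd)
          sample(which(labs == cd), resample, replace = TRUE)))
        list(X = feat[idx, , drop = FALSE],
             y = factor(as.integer(pos[idx])))
      }
      trs <- take(sp$train); tes <- take(sp$test)
      m <- svm_cv_fit(trs$X, trs$y, cost_grid)
      mean(stats::predict(m, tes$X) == tes$y)
    }, numeric(1)))
  }, numeric(1))
  structure(list(variable = variable, accuracy = mean(per_split),
                 per_split = per_split, reps = reps),
            class = "decode_result")
}

#' Build a pseudo-population across sessions
#'
#' Samples `n_neurons` neurons without replacement from the pooled sessions;
#' within each trial condition, each neuron's trials are resampled
#' independently (destroying noise correlations) to a fixed count per
#' condition.
#'
#' @param populations A `neural_session` or list thereof.
#' @param n_neurons Neurons to sample.
#' @param resample Pseudo-trials per condition (default 250).
#' @return A `neural_session` with balanced pseudo-trials; `source` records
#'   which (session, neuron) each row was drawn from.
#' @export
pseudo_population <- function(populations, n_neurons, resample = 250) {
  if (inherits(populations, "neural_session")) populations <- list(populations)
  pool <- do.call(rbind, lapply(seq_along(populations), function(si)
    data.frame(sess = si, neuron = seq_len(dim(populations[[si]]$activity)[1]))))
  if (n_neurons > nrow(pool))
    stop("requested ", n_neurons, " neurons but only ", nrow(pool),
         " available")
  pick <- pool[sample(nrow(pool), n_neurons), ]
  conds <- c("RH", "RL", "LH", "LL")
  n_time <- dim(populations[[1]]$activity)[3]
  labels <- rep(conds, each = resample)
  activity <- array(NA_real_, c(n_neurons, length(labels), n_time))
  for (i in seq_len(n_neurons)) {
    pop <- populations[[pick$sess[i]]]
    for (ci in seq_along(conds)) {
      src <- which(pop$labels == conds[ci])
      if (!length(src)) stop("condition ", conds[ci], " absent in session ",
                             pick$sess[i])
      draw <- sample(src, resample, replace = TRUE)
      activity[i, (ci - 1) * resample + seq_len(resample), ] <-
        pop$activity[pick$neuron[i], draw, ]
    }
  }
  structure(list(activity = activity, labels = labels,
                 classes = NULL, preferred = NULL, session = NULL,
                 source = pick),
            class = "neural_session")
}
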