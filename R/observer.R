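#' Synthetic observer parameters
#'
#' A shifted-lognormal reaction-time model with an additive participant
#' effect on the log scale, standing in for human participants in the
#' odd-one-out search task.  For participant p on a trial of condition c
#' where the changed variant is v:
#'
#' \deqn{RT = shift + \exp( N( \log(\mu_c - a_c 1[v = nonaccidental]) + u_p,\ \sigma_t ) )}
#'
#' with participant effect `u_p ~ N(0, sigma_p)`.  Medians are the
#' natural per-cell summary of this model: the within-cell median RT is
#' `shift + (mu_c - a_c 1[v]) exp(u_p)`, so the per-participant
#' median-RT advantage (metric minus nonaccidental) recovers `a_c`
#' up to the participant's multiplicative factor.  Accuracy is Bernoulli
#' near ceiling, higher for nonaccidental targets; errors choose a wrong
#' quadrant uniformly.
#'
#' @param n_participants number of simulated participants (default 10).
#' @param rt_shift non-decision time in ms.
#' @param participant_mean_sd between-participant s.d. on the log scale.
#' @param trial_sd within-participant lognormal scale.
#' @param condition_baseline named vector, median-scale baseline (ms)
#'   per condition for metric trials.
#' @param nap_advantage named vector, reduction (ms) of the lognormal
#'   median on nonaccidental trials; may be 0 for a null model.
#' @param p_correct_metric,p_correct_nap response accuracy by changed
#'   variant.
#' @return list of class `observer_params`.
#' @export
observer_params <- function(n_participants = 10, rt_shift = 200,
                            participant_mean_sd = 0.1, trial_sd = 0.25,
                            condition_baseline = NULL,
                            nap_advantage = NULL,
                            p_correct_metric = 0.90,
                            p_correct_nap = 0.97) {
  base <- c(alignment = 880, collinearity_between = 900,
            generic_to_L = 920, generic_to_T = 940, generic_to_X = 900,
            T_to_L = 960, X_to_T = 950, cotermination = 860,
            expansion_constant = 980, collinearity_within = 900,
            curvature_edges = 840, curvature_axis = 880,
            curvature_control = 820)
  adv <- c(alignment = 60, collinearity_between = 60, generic_to_L = 60,
           generic_to_T = 60, generic_to_X = 60, T_to_L = 60,
           X_to_T = 60, cotermination = 60, expansion_constant = 15,
           collinearity_within = 60, curvature_edges = 60,
           curvature_axis = 60, curvature_control = 60)
  if (!is.null(condition_baseline)) {
    if (length(condition_baseline) == 1L && is.null(names(condition_baseline)))
      base[] <- condition_baseline
    else base[names(condition_baseline)] <- condition_baseline
  }
  if (!is.null(nap_advantage)) {
    if (length(nap_advantage) == 1L && is.null(names(nap_advantage)))
      adv[] <- nap_advantage
    else adv[names(nap_advantage)] <- nap_advantage
  }
  stopifnot(n_participants >= 2, rt_shift >= 0, trial_sd >= 0,
            participant_mean_sd >= 0, all(base - pmax(adv, 0) > 0),
            p_correct_metric > 0, p_correct_metric <= 1,
            p_correct_nap > 0, p_correct_nap <= 1)
  structure(list(n_participants = as.integer(n_participants),
                 rt_shift = rt_shift,
                 participant_mean_sd = participant_mean_sd,
                 trial_sd = trial_sd, condition_baseline = base,
                 nap_advantage = adv,
                 p_correct_metric = p_correct_metric,
                 p_correct_nap = p_correct_nap),
            class = "observer_params")
}

#' Simulate responses of synthetic participants
#'
#' Each participant completes every trial of the table.  Reaction times
#' follow the shifted-lognormal model of [observer_params()];
#' correctness is Bernoulli with the accuracy of the changed variant,
#' and error trials get a uniformly random wrong quadrant.  Fully
#' reproducible under `set.seed()`.
#'
#' @param trials a trial table from [build_trial_table()].
#' @param params an [observer_params()].
#' @return data.frame of `ResponseRecord`s: `participant`, `trial_id`,
#'   `triplet_id`, `condition`, `variant_changed`, `role`, `rt` (ms),
#'   `chosen_quadrant`, `correct`.
#' @export
simulate_responses <- function(trials, params = observer_params()) {
  stopifnot(inherits(params, "observer_params"))
  n_tr <- nrow(trials)
  u <- stats::rnorm(params$n_participants, 0, params$participant_mean_sd)
  out <- vector("list", params$n_participants)
  for (p in seq_len(params$n_participants)) {
    mu_med <- params$condition_baseline[trials$condition] -
      params$nap_advantage[trials$condition] *
        (trials$variant_changed == "nonaccidental")
    rt <- params$rt_shift +
      exp(stats::rnorm(n_tr, log(mu_med) + u[p], params$trial_sd))
    p_ok <- ifelse(trials$variant_changed == "nonaccidental",
                   params$p_correct_nap, params$p_correct_metric)
    ok <- stats::runif(n_tr) < p_ok
    chosen <- trials$target_quadrant
    if (any(!ok)) {
      wrong <- which(!ok)
      # uniformly random wrong quadrant
      shift <- sample.int(3, length(wrong), replace = TRUE)
      chosen[wrong] <- ((chosen[wrong] - 1L + shift) %% 4L) + 1L
    }
    out[[p]] <- data.frame(
      participant = sprintf("p%02d", p), trial_id = trials$trial_id,
      triplet_id = trials$triplet_id, condition = trials$condition,
      variant_changed = trials$variant_changed, role = trials$role,
      rt = rt, chosen_quadrant = chosen, correct = ok,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a response table CSV
#' @param responses result of [simulate_responses()].
#' @param path file path.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' Write observer parameters as YAML
#' @param params an [observer_params()].
#' @param path file path.
#' @export
write_observer_params <- function(params, path) {
  x <- unclass(params)
  x$condition_baseline <- as.list(x$condition_baseline)
  x$nap_advantage <- as.list(x$nap_advantage)
  yaml::write_yaml(x, path)
  invisible(path)
}
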