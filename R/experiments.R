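#' Per-trial summary metrics
#'
#' Computes the metric family used by the batch experiments from a single
#' trial: the tongue-center position at the final sample, the condyle
#' angle/length at the final sample, and the state prediction error (mean
#' over the trial of the Euclidean distance between the estimated and true
#' articulatory state, positions and velocities).
#'
#' @param trial An `sfc_trial`.
#' @return A one-row tibble.
#' @export
trial_metrics <- function(trial) {
  tr <- trial$trajectory
  last <- tr[nrow(tr), ]
  a_last <- setNames(as.numeric(last[paste0("a_", articulator_inventory())]),
                     articulator_inventory())
  tc <- tongue_center(a_last)
  est <- as.matrix(tr[, c(paste0("est_", articulator_inventory()),
                          paste0("estv_", articulator_inventory()))])
  tru <- as.matrix(tr[, c(paste0("a_", articulator_inventory()),
                          paste0("ad_", articulator_inventory()))])
  tibble::tibble(
    condition = trial$condition,
    seed = trial$seed,
    diverged = trial$diverged,
    tc_x = tc[["x"]], tc_y = tc[["y"]],
    CA = a_last[["CA"]], CL = a_last[["CL"]],
    pred_error = mean(sqrt(rowSums((est - tru)^2)))
  )
}

run_trial_batch <- function(score, config, seeds, map, norms) {
  purrr::map(seeds, function(s) run_trial(score, config, seed = s, map = map,
                                          norms = norms))
}

boot_sd_ci <- function(x, y, n_boot = 1000, seed = 1L, level = 0.95) {
  stat <- function(idx) sqrt(stats::var(x[idx]) + stats::var(y[idx]))
  n <- length(x)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) stat(sample.int(n, n, replace = TRUE)),
           numeric(1))
  })
  alpha <- (1 - level) / 2
  c(quantile(reps, alpha, names = FALSE), quantile(reps, 1 - alpha, names = FALSE))
}

#' Feedback-availability experiment
#'
#' Runs `n_per_condition` trials of the vowel-sequence score under each
#' feedback condition (both channels, somatosensory only, auditory only,
#' none) at the baseline noise levels, and summarizes endpoint variability
#' (between-trial s.d. of the tongue-center coordinates at the final
#' sample, with a bootstrap confidence interval), articulator variability
#' (s.d. of condyle angle and length at the endpoint), mean prediction
#' error, and the count of divergent trials (excluded from the metrics).
#'
#' @param score Gestural score (vowel sequence by default).
#' @param config Baseline configuration (feedback field is overridden per
#'   condition).
#' @param n_per_condition Trials per condition.
#' @param seed Base seed; per-trial seeds are derived deterministically.
#' @param map Trained auditory map.
#' @param conditions Subset of `c("both", "somat", "aud", "none")`.
#' @param n_boot Bootstrap resamples for the endpoint-variability interval.
#' @return An object of class `sfc_feedback_summary`: list with `summary`
#'   (one row per condition) and `trials` (per-trial metrics).
#' @export
feedback_conditions <- function(score = score_vowel_sequence(),
                                config = sfc_config(),
                                n_per_condition = 100, seed = 1L, map = NULL,
                                conditions = c("both", "somat", "aud", "none"),
                                n_boot = 1000) {
  norms <- calibrate_norms(score, config)
  rows <- list(); per_trial <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    cfg <- config
    cfg$feedback <- cond
    seeds <- vapply(seq_len(n_per_condition),
                    function(i) derive_seed(seed, ci * 100000 + i), integer(1))
    trials <- run_trial_batch(score, cfg, seeds, map, norms)
    met <- dplyr::bind_rows(lapply(trials, trial_metrics))
    ok <- met[!met$diverged, ]
    ci95 <- if (nrow(ok) >= 3) {
      boot_sd_ci(ok$tc_x, ok$tc_y, n_boot = n_boot, seed = derive_seed(seed, ci))
    } else c(NA_real_, NA_real_)
    rows[[ci]] <- tibble::tibble(
      condition = cond, n = n_per_condition, n_divergent = sum(met$diverged),
      endpoint_sd = sqrt(stats::var(ok$tc_x) + stats::var(ok$tc_y)),
      endpoint_sd_lo = ci95[1], endpoint_sd_hi = ci95[2],
      sd_CA = sd(ok$CA), sd_CL = sd(ok$CL),
      pred_error = mean(ok$pred_error)
    )
    per_trial[[ci]] <- met
  }
  structure(list(summary = dplyr::bind_rows(rows),
                 trials = dplyr::bind_rows(per_trial)),
            class = "sfc_feedback_summary")
}

#' @export
print.sfc_feedback_summary <- function(x, ...) {
  cat("<sfc_feedback_summary>\n")
  print(x$summary, ...)
  invisible(x)
}

#' Single-channel sensory-noise sweep
#'
#' Runs trials with a single feedback channel while sweeping that channel's
#' noise level; the observer's internal estimate of the noise is varied in
#' tandem (they are equal by construction unless overridden in the
#' configuration). Reports prediction error, articulator variability and
#' divergence counts per level.
#'
#' @param channel `"aud"` or `"somat"`: the only feedback channel.
#' @param levels Noise levels to sweep.
#' @param n Trials per level.
#' @param score,config,seed,map As in [feedback_conditions()].
#' @return A tibble of class `sfc_sweep`, one row per level.
#' @export
noise_sweep <- function(channel = c("aud", "somat"),
                        levels = 10^-c(2, 4, 6, 8), n = 25,
                        score = score_vowel_sequence(),
                        config = sfc_config(), seed = 1L, map = NULL) {
  channel <- match.arg(channel)
  norms <- calibrate_norms(score, config)
  rows <- list()
  for (li in seq_along(levels)) {
    cfg <- config
    cfg$feedback <- channel
    if (channel == "aud") cfg$noise$aud_level <- levels[li]
    else cfg$noise$somat_level <- levels[li]
    cfg$noise_internal <- NULL  # internal estimate tracks the true level
    seeds <- vapply(seq_len(n),
                    function(i) derive_seed(seed, li * 1000 + i), integer(1))
    trials <- run_trial_batch(score, cfg, seeds, map, norms)
    met <- dplyr::bind_rows(lapply(trials, trial_metrics))
    ok <- met[!met$diverged, ]
    rows[[li]] <- tibble::tibble(
      channel = channel, level = levels[li], n = n,
      n_divergent = sum(met$diverged),
      pred_error = if (nrow(ok) > 0) mean(ok$pred_error) else NA_real_,
      sd_CA = if (nrow(ok) > 1) sd(ok$CA) else NA_real_,
      sd_CL = if (nrow(ok) > 1) sd(ok$CL) else NA_real_,
      endpoint_sd = if (nrow(ok) > 1) sqrt(stats::var(ok$tc_x) + stats::var(ok$tc_y))
      else NA_real_
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sfc_sweep", class(out))
  out
}

#' Mechanical jaw-perturbation experiment
#'
#' Simulates a vowel-consonant-vowel utterance twice — unperturbed, and
#' with the jaw fixed in place (simulating a downward load) from midway
#' through the consonant closure to the end of the utterance — and
#' contrasts the lip and tongue trajectories. The observer is not informed
#' of the clamp; compensation arises from somatosensory prediction errors
#' feeding the task-level controller. The default configuration is
#' noiseless with somatosensory feedback, making the result deterministic.
#'
#' @param consonant `"b"` (bilabial closure, lip-aperture task) or `"d"`
#'   (tongue-tip closure).
#' @param score Optional score override; it must contain a closure gesture
#'   (target below `closure_criterion`) on the consonant's task variable,
#'   otherwise a validation error is raised.
#' @param config Configuration; defaults to zero noise, somatosensory
#'   feedback.
#' @param closure_criterion Aperture (cm) below which the constriction
#'   counts as closed.
#' @param map Auditory map (only needed if `config` enables auditory
#'   feedback).
#' @param seed Seed (irrelevant at zero noise).
#' @return An object of class `sfc_jaw_result`: `summary` (upper-lip
#'   lowering and lower-lip raising differences at gesture offset, final
#'   constriction value), plus both trials and the clamp window.
#' @export
jaw_perturbation <- function(consonant = c("b", "d"), score = NULL,
                             config = NULL, closure_criterion = 0.1,
                             map = NULL, seed = 1L) {
  consonant <- match.arg(consonant)
  if (is.null(score)) {
    score <- if (consonant == "b") score_aba() else score_ada()
  }
  task_var <- if (consonant == "b") "LA" else "TTCD"
  g <- score$gestures
  closure <- which(g$task == task_var & g$target < closure_criterion)
  if (length(closure) == 0) {
    abort(paste0("jaw clamp scheduled but the score has no closure gesture on ",
                 task_var, " (no target below ", closure_criterion, " cm)"))
  }
  closure <- closure[1]
  t_on <- (g$onset[closure] + g$offset[closure]) / 2  # midway through closure
  t_off <- g$offset[closure]
  if (is.null(config)) {
    config <- sfc_config(noise = sfc_noise_config(0, 0, 0), feedback = "somat")
  }
  norms <- calibrate_norms(score, config)
  cfg_pert <- config
  cfg_pert$jaw_clamp <- utils::modifyList(config$jaw_clamp,
                                          list(on = TRUE, t_on = t_on,
                                               t_off = score$duration))
  unpert <- run_trial(score, config, seed = seed, map = map, norms = norms)
  pert <- run_trial(score, cfg_pert, seed = seed, map = map, norms = norms)

  at_offset <- function(trial, col) {
    tr <- trial$trajectory
    idx <- which.min(abs(tr$t - t_off))
    tr[[col]][idx]
  }
  summary <- tibble::tibble(
    consonant = consonant,
    clamp_on = t_on, gesture_offset = t_off,
    ul_lowering_diff = at_offset(unpert, "a_ULV") - at_offset(pert, "a_ULV"),
    ll_raising_diff = at_offset(pert, "a_LLV") - at_offset(unpert, "a_LLV"),
    constriction_final = at_offset(pert, paste0("x_", task_var)),
    constriction_final_unpert = at_offset(unpert, paste0("x_", task_var)),
    closure_achieved = at_offset(pert, paste0("x_", task_var)) < closure_criterion
  )
  structure(list(summary = summary, perturbed = pert, unperturbed = unpert,
                 task = task_var),
            class = "sfc_jaw_result")
}

#' @export
print.sfc_jaw_result <- function(x, ...) {
  cat("<sfc_jaw_result> consonant task ", x$task, "\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}

#' Auditory F1-perturbation experiment
#'
#' Simulates a sustained schwa; after a stabilization window a constant
#' shift is added to the perceived F1 (the auditory observation only). For
#' each seed the experiment runs a perturbed and an unperturbed trial and
#' measures compensation as the drop in *produced* F1, averaged over the
#' final steady portion of the trial:
#' `compensation = mean(F1 baseline) - mean(F1 perturbed)`, reported in Hz
#' and as a percentage of the shift.
#'
#' @param shift Perceived-F1 shift (Hz), +100 by default.
#' @param config Baseline configuration (baseline noise levels).
#' @param n_seeds Number of seed pairs to average over.
#' @param seed Base seed.
#' @param score Sustained-vowel score.
#' @param map Trained auditory map (required: the auditory channel drives
#'   the effect).
#' @param stabilization Time (s) before the shift switches on.
#' @param steady_frac Final fraction of the trial over which produced F1 is
#'   averaged.
#' @return An object of class `sfc_f1_result`: `summary` (mean compensation
#'   in Hz and %), `per_seed`, and one example trial pair.
#' @export
f1_perturbation <- function(shift = 100, config = sfc_config(), n_seeds = 20,
                            seed = 1L, score = score_sustained_schwa(),
                            map = NULL, stabilization = 0.2,
                            steady_frac = 0.25) {
  if (is.null(map) && feedback_mask(config$feedback)[21]) {
    abort("f1_perturbation requires a trained auditory map")
  }
  norms <- calibrate_norms(score, config)
  cfg_pert <- config
  cfg_pert$f1_shift <- list(hz = shift, t_on = stabilization)
  window_start <- score$duration * (1 - steady_frac)
  rows <- list()
  example <- NULL
  for (i in seq_len(n_seeds)) {
    s <- derive_seed(seed, 500000 + i)
    base <- run_trial(score, config, seed = s, map = map, norms = norms)
    pert <- run_trial(score, cfg_pert, seed = s, map = map, norms = norms)
    f1b <- mean(base$trajectory$F1[base$trajectory$t >= window_start])
    f1p <- mean(pert$trajectory$F1[pert$trajectory$t >= window_start])
    rows[[i]] <- tibble::tibble(seed = s, f1_baseline = f1b, f1_perturbed = f1p,
                                comp_hz = f1b - f1p,
                                diverged = base$diverged || pert$diverged)
    if (i == 1) example <- list(baseline = base, perturbed = pert)
  }
  per_seed <- dplyr::bind_rows(rows)
  ok <- per_seed[!per_seed$diverged, ]
  summary <- tibble::tibble(
    shift_hz = shift, n_seeds = nrow(ok),
    comp_hz = mean(ok$comp_hz), comp_pct = 100 * mean(ok$comp_hz) / shift,
    comp_hz_sd = sd(ok$comp_hz),
    window_start = window_start, stabilization = stabilization
  )
  structure(list(summary = summary, per_seed = per_seed, example = example),
            class = "sfc_f1_result")
}

#' @export
print.sfc_f1_result <- function(x, ...) {
  cat("<sfc_f1_result>\n")
  print(x$summary, ...)
  invisible(x)
}
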