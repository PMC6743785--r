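#' Run one closed-loop trial
#'
#' Executes the full perception-action loop for one utterance: at each
#' control step the task state is estimated from the current articulatory
#' estimate (forward kinematics), the task control law issues task
#' accelerations toward the active gestural goals, the articulatory control
#' law inverts them through the weighted Jacobian pseudoinverse, the plant
#' integrates the noisy motor command (applying any scheduled jaw clamp),
#' a noisy sensory observation is emitted (applying any scheduled perceived-
#' F1 shift), and the unscented-Kalman-filter observer fuses the efference
#' copy of the command with the gated feedback channels to produce the next
#' articulatory estimate. The trial is fully reproducible from
#' `(score, config, seed)`.
#'
#' A trial is flagged divergent (and stopped) when any true or estimated
#' articulator position strays more than `config$divergence_factor` times
#' its range-box extent from the box center, or any state becomes
#' non-finite. Divergence is an outcome, not an error.
#'
#' @param score An `sfc_score`.
#' @param config An [sfc_config()].
#' @param seed Integer seed for all noise draws in this trial.
#' @param map Trained auditory map; required unless the auditory channel is
#'   gated off.
#' @param norms Channel norms from [calibrate_norms()]; computed on the fly
#'   (noiseless calibration run of the same score) when `NULL`. Pass
#'   precomputed norms when running many trials of one score.
#' @return An object of class `sfc_trial`: list with `trajectory` (a tibble,
#'   one row per step: time, true articulator positions `a_*` and
#'   velocities `ad_*`, task variables `x_*`, produced formants `F1`-`F3`,
#'   estimated positions `est_*` and velocities `estv_*`, sensory
#'   predictions `yhat_*`, perturbation flags), `seed`, `diverged`,
#'   `condition`, and the full configuration echo.
#' @export
run_trial <- function(score, config = sfc_config(), seed = 1L, map = NULL,
                      norms = NULL) {
  stopifnot(inherits(score, "sfc_score"), inherits(config, "sfc_config"))
  if (is.null(norms)) norms <- calibrate_norms(score, config)
  noise <- config$noise
  noise$norms <- norms
  mask <- feedback_mask(config$feedback)
  if (any(mask[21:23]) && is.null(map)) {
    abort("auditory feedback is active but no trained auditory map was supplied")
  }
  dt <- config$dt
  n_steps <- max(1L, round(score$duration / dt))
  arts <- articulator_inventory()
  tasks <- task_inventory()
  box <- articulator_range_box()
  extent <- box["hi", ] - box["lo", ]
  center <- (box["hi", ] + box["lo", ]) / 2
  bound <- config$divergence_factor * extent

  state <- plant_init()
  obs_state <- observer_init(noise, config)
  est <- list(a = state$a, a_dot = state$a_dot)

  cols <- c("t", paste0("a_", arts), paste0("ad_", arts), paste0("x_", tasks),
            c("F1", "F2", "F3"), paste0("est_", arts), paste0("estv_", arts),
            paste0("yhat_", arts), paste0("yhatv_", arts),
            paste0("yhat_", c("F1", "F2", "F3")),
            "jaw_clamp", "f1_shift")
  traj <- matrix(NA_real_, n_steps, length(cols), dimnames = list(NULL, cols))
  diverged <- FALSE

  with_seed(seed, {
    for (k in seq_len(n_steps)) {
      t_now <- (k - 1) * dt
      t_next <- k * dt

      tstate <- task_state_estimate(est, geom = config$geom)
      goals <- active_set(score, t_now)
      xdd <- task_command(tstate, goals)
      add <- articulatory_command(xdd, est, mask = goals$mask, W = config$W,
                                  null_attractor = config$null_attractor,
                                  geom = config$geom, eps = config$pinv_eps)

      jc <- config$jaw_clamp
      clamp_now <- isTRUE(jc$on) && jc$mode == "clamp" &&
        t_now >= jc$t_on && t_now < jc$t_off
      bias_now <- isTRUE(jc$on) && jc$mode == "bias" &&
        t_now >= jc$t_on && t_now < jc$t_off
      state$jaw_clamp <- clamp_now
      cmd_true <- add
      if (bias_now) cmd_true["JA"] <- cmd_true["JA"] + jc$bias

      state <- plant_step(state, cmd_true, noise, dt)
      state$f1_shift <- if (t_next >= config$f1_shift$t_on) config$f1_shift$hz else 0
      y <- observe(state, noise, geom = config$geom)

      # efference copy: the issued command, without motor noise or external bias
      upd <- tryCatch(ukf_step(obs_state, add, y, mask, dt, map = map),
                      error = function(e) NULL)
      if (is.null(upd)) {
        # filter covariance lost positive definiteness beyond repair:
        # count the trial as divergent rather than raising
        diverged <- TRUE
        traj <- traj[seq_len(max(1, k - 1)), , drop = FALSE]
        break
      }
      obs_state <- upd$obs_state
      est <- upd$estimate

      form <- synthesize(state$a, geom = config$geom)
      yh <- predict_sensory_row(est, map)
      traj[k, ] <- c(t_next, state$a, state$a_dot,
                     forward_kinematics(state$a, geom = config$geom,
                                        warn_clamp = FALSE),
                     form, est$a, est$a_dot, yh,
                     as.numeric(clamp_now), state$f1_shift)

      if (!all(is.finite(c(state$a, state$a_dot, est$a, est$a_dot))) ||
          any(abs(state$a - center) > bound) ||
          any(abs(est$a - center) > bound)) {
        diverged <- TRUE
        traj <- traj[seq_len(k), , drop = FALSE]
        break
      }
    }
  })

  structure(list(
    trajectory = tibble::as_tibble(as.data.frame(traj)),
    seed = seed,
    diverged = diverged,
    condition = config$feedback,
    config = config_echo(config)
  ), class = "sfc_trial")
}

# sensory prediction at the current estimate for the trajectory record;
# auditory part only when a map is available
predict_sensory_row <- function(est, map) {
  yh <- rep(NA_real_, 23)
  yh[1:20] <- c(est$a, est$a_dot)
  if (!is.null(map)) {
    yh[21:23] <- drop(predict_formants(map, matrix(est$a, nrow = 1),
                                       localize = TRUE))
  }
  yh
}

#' @export
print.sfc_trial <- function(x, ...) {
  cat("<sfc_trial> ", nrow(x$trajectory), " steps, feedback = ", x$condition,
      if (x$diverged) ", DIVERGED" else "", "\n", sep = "")
  invisible(x)
}

#' Write a trial trajectory to disk
#'
#' Writes the tidy per-step trajectory as CSV and the full configuration
#' echo (including calibrated channel norms and geometry constants) as a
#' JSON sidecar `<path>.json`.
#'
#' @param trial An `sfc_trial`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trial, path) {
  stopifnot(inherits(trial, "sfc_trial"))
  utils::write.csv(trial$trajectory, path, row.names = FALSE)
  sidecar <- c(trial$config, list(seed = trial$seed, diverged = trial$diverged,
                                  condition = trial$condition))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
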