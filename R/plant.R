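#' Sensory noise configuration
#'
#' Noise levels are dimensionless standard deviations expressed as a
#' fraction of each channel group's nominal signal norm: the realized
#' standard deviation on a channel is `level * norm` where the norms are
#' RMS values of a noiseless, unperturbed calibration run of the same score
#' (see [calibrate_norms()]). Channel groups are: motor command, articulator
#' positions, articulator velocities, and formants.
#'
#' @param motor_level,aud_level,somat_level Noise levels (>= 0). Defaults
#'   are the baseline configuration: 1e-4 motor/process, 1e-2 auditory,
#'   1e-6 somatosensory.
#' @param norms List with `motor`, `pos`, `vel`, `formant` nominal norms;
#'   `NULL` until calibrated.
#' @return An object of class `sfc_noise`.
#' @export
sfc_noise_config <- function(motor_level = 1e-4, aud_level = 1e-2,
                             somat_level = 1e-6, norms = NULL) {
  stopifnot(motor_level >= 0, aud_level >= 0, somat_level >= 0)
  structure(list(motor_level = motor_level, aud_level = aud_level,
                 somat_level = somat_level, norms = norms),
            class = "sfc_noise")
}

noise_sds <- function(noise) {
  if (is.null(noise$norms)) {
    abort("noise config has no channel norms; run calibrate_norms() first")
  }
  list(
    motor = noise$motor_level * noise$norms$motor,
    pos = noise$somat_level * noise$norms$pos,
    vel = noise$somat_level * noise$norms$vel,
    aud = noise$aud_level * noise$norms$formant
  )
}

#' Initial plant state
#'
#' @param a,a_dot Initial articulator positions/velocities (neutral posture
#'   at rest by default).
#' @return An `sfc_plant_state`: articulatory ground truth, time, and
#'   perturbation flags (jaw clamp, auditory F1 shift in Hz).
#' @export
plant_init <- function(a = neutral_posture(),
                       a_dot = setNames(rep(0, 10), articulator_inventory())) {
  structure(list(a = a, a_dot = a_dot, t = 0,
                 jaw_clamp = FALSE, f1_shift = 0),
            class = "sfc_plant_state")
}

# Classical 4th-order Runge-Kutta step of the double integrator
# d[a; v]/dt = [v; acc] with constant commanded acceleration over the step.
# `a`, `v` are 10-vectors or 10 x n matrices (columns advance in parallel,
# used for sigma-point propagation); `acc` matches.
rk4_double_integrator <- function(a, v, acc, dt) {
  # k1 = (v, acc); k2 = (v + acc dt/2, acc); k3 = k2; k4 = (v + acc dt, acc)
  k1a <- v
  k2a <- v + acc * (dt / 2)
  k3a <- k2a
  k4a <- v + acc * dt
  a_new <- a + (dt / 6) * (k1a + 2 * k2a + 2 * k3a + k4a)
  v_new <- v + acc * dt
  list(a = a_new, a_dot = v_new)
}

# clamp positions into the range box, zeroing velocity at the boundary
clamp_to_box <- function(a, a_dot) {
  box <- articulator_range_box()
  if (is.matrix(a)) {
    lo <- box["lo", rownames(a)]; hi <- box["hi", rownames(a)]
    below <- a < lo; above <- a > hi
    if (any(below) || any(above)) {
      a[below] <- lo[row(a)[below]]
      a[above] <- hi[row(a)[above]]
      a_dot[below | above] <- 0
    }
  } else {
    lo <- box["lo", names(a)]; hi <- box["hi", names(a)]
    hit <- a < lo | a > hi
    if (any(hit)) {
      a <- pmin(pmax(a, lo), hi)
      a_dot[hit] <- 0
    }
  }
  list(a = a, a_dot = a_dot)
}

#' Advance the plant by one control step
#'
#' Adds zero-mean Gaussian motor noise to the commanded articulator
#' accelerations (standard deviation `motor_level * motor norm`), then
#' integrates positions and velocities with a classical 4th-order
#' Runge-Kutta step. If the jaw clamp perturbation is active, the jaw angle
#' is frozen at its current value with zero velocity regardless of the
#' command. Positions are clamped to the articulator range box with
#' velocity zeroed at the boundary. Draws from the R random number
#' generator; with all noise levels zero the step is deterministic and
#' RNG-independent.
#'
#' @param state An `sfc_plant_state`.
#' @param cmd Commanded articulator accelerations (length 10).
#' @param noise An `sfc_noise` with calibrated norms.
#' @param dt Step duration in seconds (> 0).
#' @return The advanced `sfc_plant_state`.
#' @export
plant_step <- function(state, cmd, noise, dt) {
  stopifnot(dt > 0)
  if (!all(is.finite(cmd))) abort("non-finite motor command in plant_step()")
  sds <- noise_sds(noise)
  acc <- cmd
  if (sds$motor > 0) acc <- acc + rnorm(length(cmd), 0, sds$motor)
  out <- rk4_double_integrator(state$a, state$a_dot, acc, dt)
  out <- clamp_to_box(out$a, out$a_dot)
  if (isTRUE(state$jaw_clamp)) {
    out$a["JA"] <- state$a[["JA"]]
    out$a_dot["JA"] <- 0
  }
  state$a <- out$a
  state$a_dot <- out$a_dot
  state$t <- state$t + dt
  state
}

#' Articulatory-to-acoustic map of the surrogate plant
#'
#' Closed-form formant map standing in for tube-based acoustic synthesis.
#' With `d = max(TBCD, 0)` (cm; contact clamps to 0), `l = TBCL` (rad) and
#' constriction coupling `c(d) = exp(-d / 0.5)`:
#' \deqn{F1 = 500 + 180\cos(l)c - 190\sin(l)c}
#' \deqn{F2 = 1500 + 700\sin(l)c - 570\cos(l)c}
#' \deqn{F3 = 2500 + 200\sin(l)c - 150\,PRO}
#' A tight palatal constriction (`l = pi/2, d -> 0`) gives (F1, F2) ->
#' (310, 2200) Hz and a wide neutral tract gives (500, 1500) Hz. The map
#' depends on the articulators only through (TBCD, TBCL, PRO), so it is
#' smooth and many-to-one in `a`.
#'
#' @param a Named articulator position vector, or 10 x n matrix.
#' @param geom Geometry constants.
#' @return Named numeric `c(F1, F2, F3)` in Hz (or 3 x n matrix).
#' @export
synthesize <- function(a, geom = geometry_constants()) {
  x <- forward_kinematics(a, geom = geom, warn_clamp = FALSE)
  if (is.matrix(x)) {
    d <- pmax(x["TBCD", ], 0); l <- x["TBCL", ]; pro <- x["PRO", ]
  } else {
    d <- max(x[["TBCD"]], 0); l <- x[["TBCL"]]; pro <- x[["PRO"]]
  }
  cc <- exp(-d / 0.5)
  f1 <- 500 + 180 * cos(l) * cc - 190 * sin(l) * cc
  f2 <- 1500 + 700 * sin(l) * cc - 570 * cos(l) * cc
  f3 <- 2500 + 200 * sin(l) * cc - 150 * pro
  if (is.matrix(x)) rbind(F1 = f1, F2 = f2, F3 = f3) else c(F1 = f1, F2 = f2, F3 = f3)
}

#' Noisy sensory observation of the plant
#'
#' Emits the somatosensory channel (articulator positions and velocities,
#' 20 dimensions) and the auditory channel (F1-F3, 3 dimensions), each with
#' additive zero-mean Gaussian noise scaled by the channel-group norms. An
#' active auditory perturbation adds `f1_shift` Hz to the *perceived* F1
#' after noise; the produced acoustics are unchanged.
#'
#' @param state An `sfc_plant_state`.
#' @param noise An `sfc_noise` with calibrated norms.
#' @param geom Geometry constants.
#' @return List with `y_somat` (length 20, positions then velocities) and
#'   `y_aud` (length 3).
#' @export
observe <- function(state, noise, geom = geometry_constants()) {
  sds <- noise_sds(noise)
  pos <- state$a
  vel <- state$a_dot
  if (sds$pos > 0) pos <- pos + rnorm(10, 0, sds$pos)
  if (sds$vel > 0) vel <- vel + rnorm(10, 0, sds$vel)
  y_aud <- synthesize(state$a, geom = geom)
  if (sds$aud > 0) y_aud <- y_aud + rnorm(3, 0, sds$aud)
  if (state$f1_shift != 0) y_aud[1] <- y_aud[1] + state$f1_shift
  list(y_somat = c(pos, vel), y_aud = y_aud)
}

#' Calibrate channel norms from a noiseless reference run
#'
#' Runs the closed loop once on `score` with all noise off, no
#' perturbations, and an ideal observer (estimate set to the true state),
#' then records the RMS of each channel group over the run: articulator
#' positions, articulator velocities, formants, and the motor command.
#' These norms anchor the dimensionless noise levels; they are computed
#' once per score/configuration and reused for every trial.
#'
#' @param score An `sfc_score`.
#' @param config An [sfc_config()].
#' @return List with `motor`, `pos`, `vel`, `formant` RMS norms.
#' @export
calibrate_norms <- function(score, config = sfc_config()) {
  dt <- config$dt
  n_steps <- max(1L, round(score$duration / dt))
  state <- plant_init()
  noise0 <- sfc_noise_config(0, 0, 0,
                             norms = list(motor = 1, pos = 1, vel = 1, formant = 1))
  ss_pos <- 0; ss_vel <- 0; ss_form <- 0; ss_cmd <- 0
  for (k in seq_len(n_steps)) {
    t <- (k - 1) * dt
    est <- list(a = state$a, a_dot = state$a_dot)
    goals <- active_set(score, t)
    tstate <- task_state_estimate(est, geom = config$geom)
    xdd <- task_command(tstate, goals)
    add <- articulatory_command(xdd, est, mask = goals$mask, W = config$W,
                                null_attractor = config$null_attractor,
                                geom = config$geom, eps = config$pinv_eps)
    state <- plant_step(state, add, noise0, dt)
    ss_pos <- ss_pos + sum(state$a^2)
    ss_vel <- ss_vel + sum(state$a_dot^2)
    ss_form <- ss_form + sum(synthesize(state$a, geom = config$geom)^2)
    ss_cmd <- ss_cmd + sum(add^2)
  }
  rms <- function(ss, m) max(sqrt(ss / (n_steps * m)), 1e-9)
  list(motor = rms(ss_cmd, 10), pos = rms(ss_pos, 10),
       vel = rms(ss_vel, 10), formant = rms(ss_form, 3))
}
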