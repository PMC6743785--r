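#' Simulation configuration
#'
#' Collects every tunable of the closed-loop simulator: the control/
#' integration step, plant and sensory noise levels (with optional separate
#' internal estimates for the observer), UKF settings, feedback-channel
#' gating, the articulatory null-space attractor, perturbation schedules,
#' and the surrogate geometry constants. All defaults are echoed into
#' results for provenance.
#'
#' @param dt Control and integration step (s). 5 ms by default, so a
#'   1.0-1.5 s utterance is a few hundred steps.
#' @param noise An [sfc_noise_config()]: true plant/sensory noise levels.
#' @param noise_internal Optional `sfc_noise_config` used by the observer's
#'   internal noise model when it should differ from the true noise;
#'   `NULL` (default) means internal estimates equal the true levels.
#' @param feedback One of `"both"`, `"somat"`, `"aud"`, `"none"`: which
#'   sensory channels the observer receives. Gated channels are removed
#'   categorically (row deletion), not modeled as infinite noise.
#' @param ukf List: `alpha`, `kappa`, `beta` of the scaled unscented
#'   transform and `state_cov_init` (initial state covariance scale).
#' @param null_attractor List `on`, `k` (1/s^2), `b` (1/s): null-space
#'   restoration of uncontrolled articulators toward the neutral posture.
#' @param W Articulator weight matrix of the pseudoinverse (identity:
#'   no preferential articulators).
#' @param pinv_eps Tikhonov term of the weighted pseudoinverse.
#' @param jaw_clamp List `on` (logical), `t_on`, `t_off` (s): freeze the
#'   jaw angle during `[t_on, t_off)`. `mode = "clamp"` fixes the jaw in
#'   place; `mode = "bias"` instead adds constant acceleration `bias`
#'   (rad/s^2) to the jaw, for the downward-load reading of the paradigm.
#' @param f1_shift List `hz`, `t_on`: add `hz` to the perceived F1 from
#'   `t_on` onward (the produced acoustics are unchanged).
#' @param divergence_factor A trial is flagged divergent when any true or
#'   estimated articulator position strays more than this multiple of its
#'   range-box extent from the box center.
#' @param geom Geometry constants, see [geometry_constants()].
#' @return An object of class `sfc_config`.
#' @export
sfc_config <- function(dt = 0.005,
                       noise = sfc_noise_config(),
                       noise_internal = NULL,
                       feedback = c("both", "somat", "aud", "none"),
                       ukf = list(alpha = 1e-3, kappa = 0, beta = 2,
                                  state_cov_init = 1e-2),
                       null_attractor = list(on = TRUE, k = 10, b = 2 * sqrt(10)),
                       W = diag(10),
                       pinv_eps = 1e-8,
                       jaw_clamp = list(on = FALSE, t_on = Inf, t_off = Inf,
                                        mode = "clamp", bias = 0),
                       f1_shift = list(hz = 0, t_on = Inf),
                       divergence_factor = 5,
                       geom = geometry_constants()) {
  feedback <- match.arg(feedback)
  ukf_def <- list(alpha = 1e-3, kappa = 0, beta = 2, state_cov_init = 1e-2)
  ukf <- utils::modifyList(ukf_def, ukf)
  na_def <- list(on = TRUE, k = 10, b = 2 * sqrt(10))
  null_attractor <- utils::modifyList(na_def, null_attractor)
  jc_def <- list(on = FALSE, t_on = Inf, t_off = Inf, mode = "clamp", bias = 0)
  jaw_clamp <- utils::modifyList(jc_def, jaw_clamp)
  f1_def <- list(hz = 0, t_on = Inf)
  f1_shift <- utils::modifyList(f1_def, f1_shift)
  structure(list(dt = dt, noise = noise, noise_internal = noise_internal,
                 feedback = feedback, ukf = ukf,
                 null_attractor = null_attractor, W = W, pinv_eps = pinv_eps,
                 jaw_clamp = jaw_clamp, f1_shift = f1_shift,
                 divergence_factor = divergence_factor, geom = geom),
            class = "sfc_config")
}

#' Read a configuration file
#'
#' Reads a YAML (or JSON) configuration with any subset of the
#' [sfc_config()] fields; unspecified fields keep their defaults. Noise
#' blocks are given as `noise: {motor_level: ..., aud_level: ...,
#' somat_level: ...}`.
#'
#' @param path Path to a YAML or JSON file.
#' @return An `sfc_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  simple <- intersect(names(raw), c("dt", "feedback", "pinv_eps",
                                    "divergence_factor"))
  args[simple] <- raw[simple]
  for (blk in c("ukf", "null_attractor", "jaw_clamp", "f1_shift", "geom")) {
    if (!is.null(raw[[blk]])) args[[blk]] <- as.list(raw[[blk]])
  }
  for (blk in c("noise", "noise_internal")) {
    if (!is.null(raw[[blk]])) {
      nb <- as.list(raw[[blk]])
      args[[blk]] <- sfc_noise_config(
        motor_level = nb$motor_level %||% 1e-4,
        aud_level = nb$aud_level %||% 1e-2,
        somat_level = nb$somat_level %||% 1e-6
      )
    }
  }
  do.call(sfc_config, args)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# serializable echo of a config (numeric-only view for sidecar files)
config_echo <- function(config) {
  list(dt = config$dt,
       feedback = config$feedback,
       noise = config$noise[c("motor_level", "aud_level", "somat_level")],
       noise_internal = if (is.null(config$noise_internal)) NULL else
         config$noise_internal[c("motor_level", "aud_level", "somat_level")],
       norms = config$noise$norms,
       ukf = config$ukf,
       null_attractor = config$null_attractor,
       pinv_eps = config$pinv_eps,
       jaw_clamp = config$jaw_clamp,
       f1_shift = config$f1_shift,
       divergence_factor = config$divergence_factor,
       geom = config$geom)
}
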