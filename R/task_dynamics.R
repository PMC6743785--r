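#' Task state feedback control law
#'
#' Each active gesture drives its task variable as an independent damped
#' second-order point attractor:
#' \deqn{\ddot x_i = m_i^{-1}\,(-b_i\,\dot{\tilde x}_i - k_i\,(\tilde x_i - x_{0,i})),}
#' evaluated on the *estimated* task state. With the `"critical"` damping
#' sentinel (`b = 2 sqrt(m k)`) the step response converges to the target
#' without overshoot. Inactive tasks receive a zero task-space command;
#' restoration of uncontrolled degrees of freedom happens in articulatory
#' space (see [articulatory_command()]).
#'
#' @param est List with `x` (estimated task positions, length 7) and
#'   `x_dot` (estimated task velocities).
#' @param goals Output of [active_set()]: mask and per-task `x0`, `m`, `b`, `k`.
#' @return Named length-7 vector of commanded task accelerations (zero on
#'   inactive tasks).
#' @export
task_command <- function(est, goals) {
  x <- est$x; x_dot <- est$x_dot
  if (!all(is.finite(x)) || !all(is.finite(x_dot))) {
    abort("non-finite task state estimate in task_command()")
  }
  tasks <- task_inventory()
  acc <- setNames(rep(0, length(tasks)), tasks)
  act <- goals$mask
  if (any(act)) {
    acc[act] <- (-goals$b[act] * x_dot[act] -
                   goals$k[act] * (x[act] - goals$x0[act])) / goals$m[act]
  }
  acc
}

#' Task state estimator (forward kinematics of the articulatory estimate)
#'
#' Maps the observer's articulatory state estimate into task coordinates:
#' positions through the forward kinematics `x = f(a)` and velocities
#' through its Jacobian `x_dot = J(a) a_dot`.
#'
#' @param artic_est List with `a` (estimated articulator positions) and
#'   `a_dot` (estimated velocities).
#' @param geom Geometry constants.
#' @param f,J Optional overrides of the kinematic map and its Jacobian
#'   (used with linear stand-ins in tests).
#' @return List with `x` and `x_dot`, named length-7 vectors.
#' @export
task_state_estimate <- function(artic_est, geom = geometry_constants(),
                                f = NULL, J = NULL) {
  a <- artic_est$a; a_dot <- artic_est$a_dot
  if (!all(is.finite(a)) || !all(is.finite(a_dot))) {
    abort("non-finite articulatory estimate in task_state_estimate()")
  }
  if (is.null(f)) {
    x <- forward_kinematics(a, geom = geom, warn_clamp = FALSE)
    Jm <- jacobian(a, geom = geom)
  } else {
    x <- f(a)
    Jm <- if (is.function(J)) J(a) else J
  }
  list(x = x, x_dot = drop(Jm %*% a_dot))
}
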