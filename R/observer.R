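#' Sigma points of the scaled unscented transform
#'
#' Generates the `2L + 1` sigma points `X = [m, m + cols(sqrt((L +
#' lambda) P)), m - cols(...)]` via Cholesky factorization, together with
#' mean weights `Wm` and covariance weights `Wc`. The weighted mean and
#' covariance of the points reconstruct the inputs exactly. If `P` is not
#' positive semi-definite up to round-off it is repaired by symmetrization
#' and an eigenvalue floor; failure beyond repair is an error.
#'
#' @param mean Length-L mean vector.
#' @param P L x L covariance matrix (symmetric PSD).
#' @param lambda Scaling factor; with the scaled parameterization
#'   `lambda = alpha^2 (L + kappa) - L`.
#' @param alpha,beta Optional scaled-transform parameters used only for the
#'   zeroth covariance weight `Wc0 = Wm0 + 1 - alpha^2 + beta`; defaults
#'   (`alpha = 1`, `beta = 0`) make `Wc = Wm`.
#' @return List of class `sfc_sigma`: `X` (L x (2L+1)), `Wm`, `Wc`, `L`,
#'   `lambda`.
#' @export
sigma_points <- function(mean, P, lambda, alpha = 1, beta = 0) {
  L <- length(mean)
  P <- (P + t(P)) / 2
  S <- tryCatch(chol((L + lambda) * P), error = function(e) NULL)
  if (!is.null(S)) {
    dev <- t(S)  # columns are the sigma-point offsets
  } else {
    # round-off pushed P off the PSD cone (or P is singular PSD): repair,
    # then take an eigenvalue square root
    P <- repair_psd(P)
    ev <- eigen((L + lambda) * P, symmetric = TRUE)
    dev <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(mean))
  }
  X <- cbind(mean, mean + dev, mean - dev)
  dimnames(X) <- NULL
  Wm <- c(lambda / (L + lambda), rep(1 / (2 * (L + lambda)), 2 * L))
  Wc <- Wm
  Wc[1] <- Wm[1] + 1 - alpha^2 + beta
  structure(list(X = X, Wm = Wm, Wc = Wc, L = L, lambda = lambda),
            class = "sfc_sigma")
}

# symmetrize and floor eigenvalues at a small non-negative value; used only
# when a Cholesky factorization reveals loss of positive semi-definiteness.
# A matrix that is indefinite beyond round-off (not merely grazing zero) is
# an upstream numerical failure and raises an error instead of being bent
# back onto the PSD cone.
repair_psd <- function(P, floor_frac = 1e-12) {
  P <- (P + t(P)) / 2
  ev <- eigen(P, symmetric = TRUE)
  top <- max(ev$values, 0)
  if (min(ev$values) < -1e-6 * top - 1e-300) {
    abort("covariance is not positive semi-definite after repair")
  }
  lo <- top * floor_frac
  if (all(ev$values >= lo)) return(P)
  vals <- pmax(ev$values, lo)
  P2 <- ev$vectors %*% (vals * t(ev$vectors))
  (P2 + t(P2)) / 2
}

ut_mean <- function(Y, Wm) drop(Y %*% Wm)

ut_cov <- function(Ya, Yb, Wc, mean_a, mean_b) {
  da <- Ya - mean_a
  db <- Yb - mean_b
  (da * rep(Wc, each = nrow(da))) %*% t(db)
}

#' Unscented transform through the process model
#'
#' Propagates the articulatory-state part of each augmented sigma point
#' through the efference-copy integrator `F`, adding each point's
#' process-noise component to the commanded acceleration, and returns the
#' weighted posterior mean and covariance of the predicted state along with
#' the propagated sigma set.
#'
#' @param sig An augmented `sfc_sigma` whose rows are ordered state (20),
#'   process noise (10), observation noise (23).
#' @param efference Commanded articulator accelerations (length 10).
#' @param dt Step duration (s).
#' @param n_state,n_proc Row partition sizes (defaults 20 and 10).
#' @param F_fun Optional override of the process model for tests: called as
#'   `F_fun(Xstate, Xproc, efference)` on matrices with points in columns
#'   and returning the propagated state matrix.
#' @return List with `a_hat` (predicted state mean, length `n_state`),
#'   `P_prior` (its covariance), and `X_prop` (propagated state sigma
#'   points).
#' @export
ut_process <- function(sig, efference, dt, n_state = 20L, n_proc = 10L,
                       F_fun = NULL) {
  X <- sig$X
  Xs <- X[seq_len(n_state), , drop = FALSE]
  Xv <- X[n_state + seq_len(n_proc), , drop = FALSE]
  if (is.null(F_fun)) {
    arts <- articulator_inventory()
    A <- Xs[seq_len(n_proc), , drop = FALSE]
    Vel <- Xs[n_proc + seq_len(n_proc), , drop = FALSE]
    rownames(A) <- arts
    rownames(Vel) <- arts
    acc <- Xv + efference
    out <- predict_state(list(a = A, a_dot = Vel), acc, dt)
    Xp <- rbind(out$a, out$a_dot)
    rownames(Xp) <- NULL
  } else {
    Xp <- F_fun(Xs, Xv, efference)
  }
  a_hat <- ut_mean(Xp, sig$Wm)
  P_prior <- ut_cov(Xp, Xp, sig$Wc, a_hat, a_hat)
  list(a_hat = a_hat, P_prior = (P_prior + t(P_prior)) / 2, X_prop = Xp)
}

#' Unscented transform through the observation model
#'
#' Maps propagated state sigma points through the sensory prediction model
#' `H` (identity somatosensory branch plus the trained auditory map), adds
#' each point's observation-noise component, restricts to the active
#' feedback channels, and returns the expected observation with the
#' innovation and cross covariances.
#'
#' @param X_prop Propagated state sigma points (n_state x (2L+1)).
#' @param sig The augmented `sfc_sigma` that produced `X_prop` (supplies
#'   weights and the observation-noise rows).
#' @param map Trained auditory map (may be `NULL` when the auditory channel
#'   is masked out).
#' @param mask Logical length-23 vector of active observation channels
#'   (20 somatosensory then 3 auditory).
#' @param n_state,n_proc Row partition sizes.
#' @param H_fun Optional override for tests: called as `H_fun(X_prop)` and
#'   returning the 23 x (2L+1) noise-free observation matrix.
#' @return List with `y_hat`, `P_yy`, `P_ay` (all restricted to active
#'   channels) and the active-channel index.
#' @export
ut_observe <- function(X_prop, sig, map = NULL, mask = rep(TRUE, 23),
                       n_state = 20L, n_proc = 10L, H_fun = NULL) {
  active <- which(mask)
  if (length(active) == 0) {
    return(list(y_hat = numeric(0), P_yy = matrix(0, 0, 0),
                P_ay = matrix(0, nrow(X_prop), 0), active = integer(0)))
  }
  n_obs <- length(mask)
  Xn <- sig$X[n_state + n_proc + seq_len(n_obs), , drop = FALSE]
  if (is.null(H_fun)) {
    need_aud <- any(active > n_state)
    Ysom <- X_prop
    if (need_aud) {
      A <- X_prop[seq_len(n_proc), , drop = FALSE]
      aud <- t(predict_formants(map, t(A), localize = TRUE))
      Y0 <- rbind(Ysom, aud)
    } else {
      Y0 <- rbind(Ysom, matrix(0, 3, ncol(X_prop)))
    }
  } else {
    Y0 <- H_fun(X_prop)
  }
  Y <- (Y0 + Xn)[active, , drop = FALSE]
  dimnames(Y) <- NULL
  a_hat <- ut_mean(X_prop, sig$Wm)
  y_hat <- ut_mean(Y, sig$Wm)
  P_yy <- ut_cov(Y, Y, sig$Wc, y_hat, y_hat)
  P_ay <- ut_cov(X_prop, Y, sig$Wc, a_hat, y_hat)
  list(y_hat = y_hat, P_yy = (P_yy + t(P_yy)) / 2, P_ay = P_ay, active = active)
}

#' Kalman gain and state correction
#'
#' Computes `K = P_ay P_yy^-1`, corrects the predicted state with the
#' innovation `delta_y = y - y_hat`, and updates the covariance as
#' `P <- P - K P_yy K'`. (The innovation is the standard observation-minus-
#' prediction convention; the equivalent prediction-minus-observation form
#' with a negated gain gives the identical estimate.) An ill-conditioned
#' innovation covariance falls back to an eigenvalue-truncated pseudo-solve
#' and records the condition number on the result as attribute
#' `condition_number`.
#'
#' @param a_hat Predicted state mean.
#' @param P_prior Predicted state covariance.
#' @param obs Output of [ut_observe()].
#' @param delta_y Innovation on active channels (`y - y_hat`).
#' @return List with corrected mean `a_tilde`, updated covariance `P`, and
#'   the gain `K`.
#' @export
gain_and_correct <- function(a_hat, P_prior, obs, delta_y) {
  if (length(obs$active) == 0) {
    return(list(a_tilde = a_hat, P = P_prior, K = matrix(0, length(a_hat), 0)))
  }
  P_yy <- obs$P_yy
  cn <- tryCatch(1 / rcond(P_yy), error = function(e) Inf)
  if (is.finite(cn) && cn < 1e12) {
    K <- t(solve(P_yy, t(obs$P_ay)))
  } else {
    ev <- eigen((P_yy + t(P_yy)) / 2, symmetric = TRUE)
    tol <- max(ev$values) * 1e-13
    inv_vals <- ifelse(ev$values > tol, 1 / ev$values, 0)
    Pinv <- ev$vectors %*% (inv_vals * t(ev$vectors))
    K <- obs$P_ay %*% Pinv
  }
  a_tilde <- a_hat + drop(K %*% delta_y)
  P <- P_prior - K %*% P_yy %*% t(K)
  P <- (P + t(P)) / 2
  out <- list(a_tilde = a_tilde, P = P, K = K)
  attr(out, "condition_number") <- cn
  out
}

#' Initialize the articulatory observer
#'
#' Builds the observer state: the augmented-filter mean (articulatory
#' estimate), its covariance (identity scaled by `state_cov_init`), and the
#' internal process/observation noise estimates. The internal noise
#' estimates equal the true plant noise levels unless overridden.
#'
#' @param noise An `sfc_noise` with calibrated norms (true plant noise).
#' @param config An [sfc_config()] (UKF settings and any internal noise
#'   overrides `config$noise_internal`).
#' @param a,a_dot Initial articulatory estimate (neutral posture at rest by
#'   default).
#' @return An object of class `sfc_observer`.
#' @export
observer_init <- function(noise, config = sfc_config(),
                          a = neutral_posture(),
                          a_dot = setNames(rep(0, 10), articulator_inventory())) {
  internal <- config$noise_internal
  if (is.null(internal)) {
    internal <- noise
  } else {
    internal$norms <- noise$norms
  }
  # internal noise variances are floored at (1e-8)^2 so that the filter
  # covariance stays resolvable in double precision under zero-noise
  # configurations (sigma-point deviations must clear round-off)
  sds <- noise_sds(internal)
  Q <- diag(rep(max(sds$motor, 1e-8)^2, 10))
  R <- diag(c(rep(max(sds$pos, 1e-8)^2, 10),
              rep(max(sds$vel, 1e-8)^2, 10),
              rep(max(sds$aud, 1e-8)^2, 3)))
  structure(list(
    mean = c(a, a_dot),
    P = diag(rep(config$ukf$state_cov_init, 20)),
    Q = Q, R = R,
    alpha = config$ukf$alpha, kappa = config$ukf$kappa, beta = config$ukf$beta
  ), class = "sfc_observer")
}

#' One full observer update
#'
#' Composes sigma-point generation on the augmented state (articulatory
#' state, process noise, observation noise), the unscented transforms
#' through the process and observation models, and the Kalman correction.
#' The estimate at each step uses the efference copy issued one control
#' step earlier, so the loop carries a one-step delay. With an empty
#' channel mask the update reduces to dead reckoning on the efference copy
#' (pure feedforward prediction).
#'
#' @param obs_state An `sfc_observer`.
#' @param efference Motor command issued at the previous step (length 10).
#' @param observation List with `y_somat` (20) and `y_aud` (3) from
#'   [observe()]; `y_aud` may be `NULL` when the auditory channel is masked.
#' @param mask Logical length-23 active-channel vector, or one of
#'   `"both"`, `"somat"`, `"aud"`, `"none"`.
#' @param dt Step duration (s).
#' @param map Trained auditory map (required when auditory channels are
#'   active).
#' @return List with the updated `obs_state` and `estimate` (a list with
#'   `a` and `a_dot` for the controllers).
#' @export
ukf_step <- function(obs_state, efference, observation, mask, dt, map = NULL) {
  if (is.character(mask)) mask <- feedback_mask(mask)
  if (length(mask) != 23) abort("observation mask must have 23 channels")
  lambda <- obs_state$alpha^2 * (53 + obs_state$kappa) - 53
  mean_aug <- c(obs_state$mean, rep(0, 10), rep(0, 23))
  P_aug <- matrix(0, 53, 53)
  P_aug[1:20, 1:20] <- obs_state$P
  P_aug[21:30, 21:30] <- obs_state$Q
  P_aug[31:53, 31:53] <- obs_state$R
  sig <- sigma_points(mean_aug, P_aug, lambda,
                      alpha = obs_state$alpha, beta = obs_state$beta)
  pr <- ut_process(sig, efference, dt)
  ob <- ut_observe(pr$X_prop, sig, map = map, mask = mask)
  if (length(ob$active) == 0) {
    obs_state$mean <- pr$a_hat
    obs_state$P <- pr$P_prior
  } else {
    y <- c(observation$y_somat, observation$y_aud)[ob$active]
    if (length(y) != length(ob$y_hat) || anyNA(y)) {
      abort("observation does not match the active channel mask")
    }
    corr <- gain_and_correct(pr$a_hat, pr$P_prior, ob, y - ob$y_hat)
    obs_state$mean <- corr$a_tilde
    obs_state$P <- corr$P
  }
  arts <- articulator_inventory()
  est <- list(a = setNames(obs_state$mean[1:10], arts),
              a_dot = setNames(obs_state$mean[11:20], arts))
  list(obs_state = obs_state, estimate = est)
}

#' Feedback-channel mask
#'
#' @param condition One of `"both"`, `"somat"`, `"aud"`, `"none"`.
#' @return Logical length-23 vector (20 somatosensory channels, then 3
#'   auditory channels).
#' @export
feedback_mask <- function(condition = c("both", "somat", "aud", "none")) {
  condition <- match.arg(condition)
  som <- condition %in% c("both", "somat")
  aud <- condition %in% c("both", "aud")
  c(rep(som, 20), rep(aud, 3))
}
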