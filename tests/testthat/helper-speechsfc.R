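# Shared fixtures, built in code and cached for the session.

sfc_test_cache <- new.env(parent = emptyenv())

# small babble + auditory map for unit tests (seconds to train)
test_babble_small <- function() {
  if (is.null(sfc_test_cache$babble_small)) {
    bb <- babble(6000, seed = 101)
    sfc_test_cache$babble_small <- babble_split(bb, 0.9, seed = 102)
  }
  sfc_test_cache$babble_small
}

test_map_small <- function() {
  if (is.null(sfc_test_cache$map_small)) {
    sp <- test_babble_small()
    sfc_test_cache$map_small <- train_auditory_map(sp$train, n_centers = 400,
                                                   seed = 103)
  }
  sfc_test_cache$map_small
}

# full-size babble + map at the study-condition training size (5e4)
test_map_full <- function() {
  if (is.null(sfc_test_cache$map_full)) {
    bb <- babble(50000, seed = 7)
    sfc_test_cache$split_full <- babble_split(bb, 0.9, seed = 11)
    sfc_test_cache$map_full <- train_auditory_map(sfc_test_cache$split_full$train,
                                                  seed = 3)
  }
  sfc_test_cache$map_full
}

test_split_full <- function() {
  test_map_full()
  sfc_test_cache$split_full
}

# random posture strictly inside the articulator range box
random_posture <- function(margin = 0.1) {
  box <- articulator_range_box()
  lo <- box["lo", ]; hi <- box["hi", ]
  setNames(lo + (margin + (1 - 2 * margin) * runif(10)) * (hi - lo),
           articulator_inventory())
}

zero_noise_config <- function(feedback = "somat", ...) {
  sfc_config(noise = sfc_noise_config(0, 0, 0), feedback = feedback, ...)
}

# classic textbook Kalman filter step (oracle for the UKF equivalence test)
kf_step <- function(m, P, A, B, u, H, Q, R, y) {
  mp <- drop(A %*% m + B * u)
  Pp <- A %*% P %*% t(A) + Q
  S <- H %*% Pp %*% t(H) + R
  K <- Pp %*% t(H) %*% solve(S)
  list(m = mp + drop(K %*% (y - drop(H %*% mp))), P = Pp - K %*% H %*% Pp)
}

# one generic augmented-UKF step built from the package's observer operations
generic_ukf_step <- function(m, P, A, B, u, H, Q, R, y, alpha = 1e-3, beta = 2) {
  nx <- length(m); nq <- nrow(Q); ny <- nrow(R)
  L <- nx + nq + ny
  mean_aug <- c(m, rep(0, nq), rep(0, ny))
  P_aug <- matrix(0, L, L)
  P_aug[seq_len(nx), seq_len(nx)] <- P
  P_aug[nx + seq_len(nq), nx + seq_len(nq)] <- Q
  P_aug[nx + nq + seq_len(ny), nx + nq + seq_len(ny)] <- R
  sig <- sigma_points(mean_aug, P_aug, alpha^2 * L - L, alpha = alpha, beta = beta)
  pr <- ut_process(sig, efference = u, dt = NA, n_state = nx, n_proc = nq,
                   F_fun = function(Xs, Xv, eff) A %*% Xs + B * eff + Xv)
  ob <- ut_observe(pr$X_prop, sig, mask = rep(TRUE, ny), n_state = nx,
                   n_proc = nq, H_fun = function(Xp) H %*% Xp)
  corr <- gain_and_correct(pr$a_hat, pr$P_prior, ob, y - ob$y_hat)
  list(m = corr$a_tilde, P = corr$P)
}
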