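random_psd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + 0.1 * diag(n)
}

test_that("sigma points reconstruct their inputs and follow the closed form", {
  set.seed(41)
  for (L in c(1, 3, 8)) {
    m <- rnorm(L)
    P <- random_psd(L)
    sig <- sigma_points(m, P, lambda = 3 - L)
    expect_equal(ncol(sig$X), 2 * L + 1)
    # weighted mean and covariance reproduce the inputs exactly
    m_rec <- drop(sig$X %*% sig$Wm)
    dev <- sig$X - m_rec
    P_rec <- (dev * rep(sig$Wc, each = L)) %*% t(dev)
    expect_lt(max(abs(m_rec - m)), 1e-12)
    expect_lt(max(abs(P_rec - P)), 1e-12)
  }
  # one dimension, P = sigma^2, lambda = 2: points at mu, mu +- sigma sqrt(3)
  sig <- sigma_points(5, matrix(4), lambda = 2)
  expect_equal(sort(drop(sig$X)), sort(c(5, 5 + 2 * sqrt(3), 5 - 2 * sqrt(3))))
  # a non-PSD input beyond repair errors
  expect_error(sigma_points(c(0, 0), matrix(c(1, 2, 2, 1), 2), lambda = 0),
               "positive semi-definite")
})

test_that("the unscented transform is exact for linear maps and scalar quadratics", {
  set.seed(43)
  nx <- 3; nq <- 3; ny <- 2
  A <- matrix(rnorm(9), 3); B <- rnorm(3); u <- 0.7
  H <- matrix(rnorm(6), 2, 3)
  Q <- random_psd(nq); R <- random_psd(ny)
  m <- rnorm(3); P <- random_psd(3)
  L <- nx + nq + ny
  mean_aug <- c(m, rep(0, nq + ny))
  P_aug <- matrix(0, L, L)
  P_aug[1:3, 1:3] <- P; P_aug[4:6, 4:6] <- Q; P_aug[7:8, 7:8] <- R
  sig <- sigma_points(mean_aug, P_aug, 1e-6 * L - L, alpha = 1e-3, beta = 2)
  pr <- ut_process(sig, efference = u, dt = NA, n_state = nx, n_proc = nq,
                   F_fun = function(Xs, Xv, eff) A %*% Xs + B * eff + Xv)
  expect_equal(pr$a_hat, drop(A %*% m + B * u), tolerance = 1e-10)
  expect_equal(pr$P_prior, A %*% P %*% t(A) + Q, tolerance = 1e-9)
  ob <- ut_observe(pr$X_prop, sig, mask = rep(TRUE, ny), n_state = nx,
                   n_proc = nq, H_fun = function(Xp) H %*% Xp)
  expect_equal(ob$y_hat, drop(H %*% pr$a_hat), tolerance = 1e-9)
  expect_equal(ob$P_yy, H %*% pr$P_prior %*% t(H) + R, tolerance = 1e-8)
  expect_equal(ob$P_ay, pr$P_prior %*% t(H), tolerance = 1e-8)

  # scalar quadratic: transformed mean is mu^2 + sigma^2, exactly
  mu <- 1.3; s2 <- 0.49
  sig1 <- sigma_points(mu, matrix(s2), lambda = 2)
  expect_equal(sum(sig1$Wm * drop(sig1$X)^2), mu^2 + s2, tolerance = 1e-12)

  # zero covariance: all sigma points coincide
  sig0 <- sigma_points(c(1, 2), matrix(0, 2, 2), lambda = 1)
  expect_equal(sig0$X, matrix(c(1, 2), 2, 5))
})

test_that("channel gating deletes observation rows categorically", {
  map <- test_map_small()
  noise <- sfc_noise_config(norms = list(motor = 1, pos = 1, vel = 1,
                                         formant = 1000))
  obs <- observer_init(noise, sfc_config())
  lambda <- 1e-6 * 53 - 53
  P_aug <- matrix(0, 53, 53)
  P_aug[1:20, 1:20] <- obs$P; P_aug[21:30, 21:30] <- obs$Q
  P_aug[31:53, 31:53] <- obs$R
  sig <- sigma_points(c(obs$mean, rep(0, 33)), P_aug, lambda,
                      alpha = obs$alpha, beta = obs$beta)
  pr <- ut_process(sig, setNames(rep(0, 10), articulator_inventory()), 0.005)
  ob_full <- ut_observe(pr$X_prop, sig, map = map, mask = rep(TRUE, 23))
  ob_somat <- ut_observe(pr$X_prop, sig, map = map, mask = feedback_mask("somat"))
  expect_equal(dim(ob_full$P_yy), c(23, 23))
  expect_equal(dim(ob_somat$P_yy), c(20, 20))
  expect_equal(ob_somat$P_yy, ob_full$P_yy[1:20, 1:20], tolerance = 1e-10)
  expect_equal(ob_somat$P_ay, ob_full$P_ay[, 1:20], tolerance = 1e-10)
  # empty mask yields a pure prediction in the full step
  y <- list(y_somat = rnorm(20), y_aud = rnorm(3))
  upd <- ukf_step(obs, setNames(rep(0, 10), articulator_inventory()), y,
                  feedback_mask("none"), 0.005, map = map)
  pure <- predict_state(list(a = obs$mean[1:10], a_dot = obs$mean[11:20]),
                        rep(0, 10), 0.005)
  expect_equal(unname(upd$estimate$a), unname(pure$a), tolerance = 1e-9)
})

test_that("corrections behave like a Kalman update in its limits", {
  # zero innovation leaves the estimate unchanged
  set.seed(47)
  P <- random_psd(4)
  obs <- list(P_yy = random_psd(2), P_ay = matrix(rnorm(8), 4, 2),
              active = 1:2)
  m <- rnorm(4)
  out <- gain_and_correct(m, P, obs, c(0, 0))
  expect_equal(out$a_tilde, m)

  # the auditory gain block vanishes as the auditory noise estimate grows,
  # and shrinks monotonically along the way
  map <- test_map_small()
  norms <- list(motor = 1, pos = 1, vel = 1, formant = 1000)
  gains <- sapply(c(1e-2, 1e-1, 1, 10), function(lvl) {
    noise <- sfc_noise_config(aud_level = lvl, norms = norms)
    ob_state <- observer_init(noise, sfc_config())
    P_aug <- matrix(0, 53, 53)
    P_aug[1:20, 1:20] <- ob_state$P; P_aug[21:30, 21:30] <- ob_state$Q
    P_aug[31:53, 31:53] <- ob_state$R
    sig <- sigma_points(c(ob_state$mean, rep(0, 33)), P_aug, 1e-6 * 53 - 53,
                        alpha = 1e-3, beta = 2)
    pr <- ut_process(sig, setNames(rep(0, 10), articulator_inventory()), 0.005)
    ob <- ut_observe(pr$X_prop, sig, map = map, mask = rep(TRUE, 23))
    corr <- gain_and_correct(pr$a_hat, pr$P_prior, ob, rep(0, 23))
    sqrt(sum(corr$K[, 21:23]^2))
  })
  expect_true(all(diff(gains) < 0))
  expect_lt(gains[4] / gains[1], 1e-3)
})

test_that("the augmented filter reproduces a classic Kalman filter on a linear-Gaussian system", {
  A <- matrix(c(1, 0.1, 0, 0.9), 2, 2); B <- c(0.05, 0.1)
  H <- matrix(c(1, 0, 0.5, 1), 2, 2, byrow = TRUE)
  Q <- diag(c(0.02, 0.01)); R <- diag(c(0.04, 0.09))
  set.seed(4)
  x <- c(0, 0)
  m_u <- m_k <- c(0, 0); P_u <- P_k <- diag(2) * 0.5
  maxd <- 0
  for (k in 1:500) {
    u <- sin(k / 20)
    x <- drop(A %*% x + B * u) + drop(chol(Q) %*% rnorm(2))
    y <- drop(H %*% x) + drop(chol(R) %*% rnorm(2))
    su <- generic_ukf_step(m_u, P_u, A, B, u, H, Q, R, y)
    sk <- kf_step(m_k, P_k, A, B, u, H, Q, R, y)
    m_u <- su$m; P_u <- su$P
    m_k <- sk$m; P_k <- sk$P
    maxd <- max(maxd, max(abs(m_u - m_k)))
    # covariance stays symmetric PSD throughout
    expect_true(isSymmetric(P_u))
  }
  expect_lt(maxd, 1e-8)
  expect_gt(min(eigen(P_u, symmetric = TRUE)$values), 0)
})

test_that("covariances stay PSD over long runs and after repair", {
  # long generic run exercising the repair path
  set.seed(49)
  A <- diag(2) * 0.99; B <- c(0, 0); H <- diag(2)
  Q <- diag(2) * 1e-10; R <- diag(2) * 1e-10
  m <- c(0, 0); P <- diag(2)
  for (k in 1:2000) {
    s <- generic_ukf_step(m, P, A, B, 0, H, Q, R, c(0, 0))
    m <- s$m; P <- s$P
  }
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE)$values
  expect_gt(min(ev), -1e-12)
  # explicit repair floors negative eigenvalues
  bad <- diag(c(1, -1e-6))
  sig <- sigma_points(c(0, 0), bad, lambda = 1)   # repaired internally
  dev <- sig$X - drop(sig$X %*% sig$Wm)
  P_rec <- (dev * rep(sig$Wc, each = 2)) %*% t(dev)
  expect_gt(min(eigen(P_rec, symmetric = TRUE)$values), -1e-12)
})

test_that("a perceived-F1 shift pulls the estimate toward configurations with higher predicted F1", {
  map <- test_map_small()
  sc <- score_sustained_schwa(0.3)
  cfg <- sfc_config(noise = sfc_noise_config(0, 0, 0), feedback = "aud")
  norms <- calibrate_norms(sc, cfg)
  noise <- cfg$noise; noise$norms <- norms
  obs <- observer_init(noise, cfg)
  st <- plant_init()
  cmd <- setNames(rep(0, 10), articulator_inventory())
  y <- observe(st, noise)
  y$y_aud[1] <- y$y_aud[1] + 100
  upd <- ukf_step(obs, cmd, y, feedback_mask("aud"), cfg$dt, map = map)
  f1_before <- predict_formants(map, matrix(st$a, 1))[1, "F1"]
  f1_after <- predict_formants(map, matrix(upd$estimate$a, 1))[1, "F1"]
  expect_gt(f1_after, f1_before)
})
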