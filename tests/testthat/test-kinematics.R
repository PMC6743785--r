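test_that("the analytic Jacobian matches central finite differences", {
  set.seed(11)
  h <- 1e-6
  for (i in 1:20) {
    a <- random_posture()
    J <- jacobian(a)
    Jfd <- matrix(0, 7, 10)
    for (j in 1:10) {
      ap <- a; am <- a
      ap[j] <- ap[j] + h; am[j] <- am[j] - h
      Jfd[, j] <- (forward_kinematics(ap, warn_clamp = FALSE) -
                     forward_kinematics(am, warn_clamp = FALSE)) / (2 * h)
    }
    expect_lt(max(abs(J - Jfd) / pmax(abs(Jfd), 1)), 1e-4)
  }
})

test_that("Jacobian sparsity reflects the geometry", {
  a <- random_posture()
  J <- jacobian(a)
  # lip aperture does not involve the tongue
  expect_equal(unname(J["LA", c("CA", "CL", "TTA", "TTL")]), rep(0, 4))
  # tongue-body constriction does not involve the lips or velum
  expect_equal(unname(J["TBCD", c("ULV", "LLV", "ULH", "LLH", "VEL")]), rep(0, 5))
  # perturbing only the velum changes only the velic task variable
  a2 <- a; a2["VEL"] <- a2["VEL"] + 0.05
  dx <- forward_kinematics(a2, warn_clamp = FALSE) -
    forward_kinematics(a, warn_clamp = FALSE)
  expect_equal(unname(dx[setdiff(task_inventory(), "VEL")]), rep(0, 6))
  expect_equal(dx[["VEL"]], 0.05)
})

test_that("the Jacobian time derivative matches differentiation along a trajectory", {
  arts <- articulator_inventory()
  a <- neutral_posture()
  expect_equal(jacobian_dot(a, setNames(rep(0, 10), arts)),
               matrix(0, 7, 10, dimnames = list(task_inventory(), arts)))
  set.seed(3)
  for (i in 1:5) {
    a <- random_posture()
    ad <- setNames(rnorm(10, 0, 0.5), arts)
    Jd <- jacobian_dot(a, ad)
    # independent route: finite difference of J along the time parameterization
    delta <- 1e-4
    Jd_t <- (jacobian(a + delta * ad) - jacobian(a - delta * ad)) / (2 * delta)
    expect_lt(max(abs(Jd - Jd_t)), 1e-4 * max(1, max(abs(Jd_t))))
    # linear in the velocity
    expect_equal(jacobian_dot(a, 2 * ad), 2 * Jd, tolerance = 1e-6)
  }
})

test_that("the weighted pseudoinverse inverts, right-inverts, and minimizes the W-norm", {
  # square nonsingular case reduces to the matrix inverse
  set.seed(5)
  Jsq <- matrix(rnorm(9), 3, 3) + 3 * diag(3)
  Jstar <- weighted_pseudoinverse(Jsq, W = diag(3), mask = rep(TRUE, 3), eps = 0)
  expect_equal(unname(Jstar), solve(Jsq), tolerance = 1e-10)

  # full-row-rank active rows of the real geometry: right inverse
  J <- jacobian(random_posture())
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  Jstar <- weighted_pseudoinverse(J, mask = mask)
  expect_lt(max(abs(J[mask, ] %*% Jstar[, mask] - diag(sum(mask)))), 1e-6)
  # inactive tasks map to zero columns
  expect_equal(unname(Jstar[, !mask]), matrix(0, 10, 2))

  # redundant case: one task, W-weighted minimum-norm solution.
  # Oracle: minimize 0.5 a' W a subject to Ja a = xdd via a null-space
  # parameterization (different computational route).
  Ja <- J["LA", , drop = FALSE]
  Wd <- diag(runif(10, 0.5, 3))
  xdd <- 2.5
  Jstar <- weighted_pseudoinverse(J, W = Wd, mask = c(TRUE, rep(FALSE, 6)),
                                  eps = 0)
  a_pkg <- Jstar[, "LA"] * xdd
  a0 <- qr.solve(Ja, xdd)                       # any particular solution
  N <- qr.Q(qr(t(Ja)), complete = TRUE)[, -1]   # null-space basis (10 x 9)
  z <- -solve(t(N) %*% Wd %*% N, t(N) %*% Wd %*% a0)
  a_opt <- a0 + drop(N %*% z)
  expect_equal(unname(a_pkg), unname(a_opt), tolerance = 1e-8)

  # rank-deficient active set errors with the offending rows named
  Jbad <- J
  Jbad["PRO", ] <- Jbad["LA", ]
  expect_error(weighted_pseudoinverse(Jbad, mask = c(TRUE, TRUE, rep(FALSE, 5)),
                                      eps = 0),
               "rank deficient")
})

test_that("the articulatory control law achieves commanded task accelerations", {
  arts <- articulator_inventory()
  tasks <- task_inventory()
  # at neutral, at rest, with no command: nothing moves
  est <- list(a = neutral_posture(), a_dot = setNames(rep(0, 10), arts))
  add <- articulatory_command(setNames(rep(0, 7), tasks), est)
  expect_equal(unname(add), rep(0, 10), tolerance = 1e-12)

  # task-space closure: J add + Jdot adot = xdd on active tasks
  set.seed(9)
  for (i in 1:5) {
    est <- list(a = random_posture(),
                a_dot = setNames(rnorm(10, 0, 0.3), arts))
    xdd <- setNames(rnorm(7), tasks)
    mask <- setNames(rep(TRUE, 7), tasks)
    add <- articulatory_command(xdd, est, mask = mask)
    J <- jacobian(est$a)
    Jd <- jacobian_dot(est$a, est$a_dot)
    resid <- J %*% add + Jd %*% est$a_dot - xdd
    expect_lt(max(abs(resid)), 1e-6)
  }

  # deterministic: identical inputs give bitwise-identical commands
  est <- list(a = random_posture(), a_dot = setNames(rnorm(10), arts))
  xdd <- setNames(rnorm(7), tasks)
  expect_identical(articulatory_command(xdd, est),
                   articulatory_command(xdd, est))

  # the null-space attractor pulls uncontrolled articulators toward neutral
  est <- list(a = random_posture(), a_dot = setNames(rep(0, 10), arts))
  add <- articulatory_command(setNames(rep(0, 7), tasks), est,
                              mask = setNames(rep(FALSE, 7), tasks))
  expect_equal(unname(add), unname(-10 * (est$a - neutral_posture())),
               tolerance = 1e-10)
})
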