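unit_norms <- function() list(motor = 1, pos = 1, vel = 1, formant = 1)

test_that("the integrator advances constant-acceleration motion exactly", {
  arts <- articulator_inventory()
  st <- plant_init()
  st$a_dot <- setNames(rep(0.3, 10), arts)
  cmd <- setNames(seq(-0.5, 0.4, length.out = 10), arts)
  noise0 <- sfc_noise_config(0, 0, 0, norms = unit_norms())
  dt <- 0.01
  out <- plant_step(st, cmd, noise0, dt)
  expect_equal(out$a, st$a + st$a_dot * dt + cmd * dt^2 / 2, tolerance = 1e-14)
  expect_equal(out$a_dot, st$a_dot + cmd * dt, tolerance = 1e-14)
  expect_equal(out$t, dt)
  # zero command at rest: unchanged
  st0 <- plant_init()
  out0 <- plant_step(st0, setNames(rep(0, 10), arts), noise0, dt)
  expect_equal(out0$a, st0$a)
  expect_equal(unname(out0$a_dot), rep(0, 10))
  # zero noise levels do not consume random numbers
  set.seed(123); before <- .Random.seed
  plant_step(st, cmd, noise0, dt)
  expect_identical(.Random.seed, before)
  expect_error(plant_step(st, c(NaN, cmd[-1]), noise0, dt), "non-finite")
})

test_that("the jaw clamp freezes the jaw and nothing else", {
  arts <- articulator_inventory()
  noise0 <- sfc_noise_config(0, 0, 0, norms = unit_norms())
  st <- plant_init()
  st$jaw_clamp <- TRUE
  cmd <- setNames(rep(2, 10), arts)
  cmd["JA"] <- -50     # hard downward jaw command
  out <- plant_step(st, cmd, noise0, 0.01)
  expect_equal(out$a[["JA"]], st$a[["JA"]])
  expect_equal(out$a_dot[["JA"]], 0)
  # all other degrees of freedom integrate exactly as without the clamp
  st2 <- st; st2$jaw_clamp <- FALSE
  out2 <- plant_step(st2, cmd, noise0, 0.01)
  other <- setdiff(arts, "JA")
  expect_identical(out$a[other], out2$a[other])
  expect_identical(out$a_dot[other], out2$a_dot[other])
})

test_that("positions clamp to the range box with velocity zeroed at the wall", {
  arts <- articulator_inventory()
  box <- articulator_range_box()
  noise0 <- sfc_noise_config(0, 0, 0, norms = unit_norms())
  st <- plant_init()
  st$a["VEL"] <- box["hi", "VEL"] - 1e-4
  cmd <- setNames(rep(0, 10), arts)
  cmd["VEL"] <- 500
  out <- plant_step(st, cmd, noise0, 0.05)
  expect_equal(out$a[["VEL"]], box["hi", "VEL"])
  expect_equal(out$a_dot[["VEL"]], 0)
})

test_that("the formant map hits its calibration anchors and depends only on (TBCD, TBCL, PRO)", {
  # tight palatal constriction: theta = pi/2 and contact (d = 0)
  a <- neutral_posture()
  a["JA"] <- 0.1; a["CA"] <- pi / 2 - 0.1
  a["CL"] <- outline_radius(pi / 2) - geometry_constants()$r_tongue
  f <- synthesize(a)
  expect_equal(f[["F1"]], 310, tolerance = 1e-8)
  expect_equal(f[["F2"]], 2200, tolerance = 1e-8)
  # wide vocal tract: formants approach the neutral values
  a2 <- neutral_posture(); a2["CL"] <- 1.8
  f2 <- synthesize(a2)
  expect_lt(abs(f2[["F1"]] - 500), 10)
  expect_lt(abs(f2[["F2"]] - 1500), 20)
  # many-to-one: same constriction triple from different articulators
  a3 <- random_posture()
  a4 <- a3
  a4["TTA"] <- a3[["TTA"]] + 0.2; a4["TTL"] <- a3[["TTL"]] - 0.3
  a4["VEL"] <- a3[["VEL"]] + 0.1
  a4["ULV"] <- a3[["ULV"]] + 0.1; a4["LLV"] <- a3[["LLV"]] + 0.1
  expect_equal(synthesize(a3), synthesize(a4))
})

test_that("the formant map is Lipschitz over sampled nearby pairs", {
  set.seed(21)
  worst <- 0
  for (i in 1:10000) {
    a <- random_posture(margin = 0.02)
    da <- rnorm(10, 0, 1e-3)
    a2 <- pmin(pmax(a + da, articulator_range_box()["lo", ]),
               articulator_range_box()["hi", ])
    num <- sqrt(sum((synthesize(a2) - synthesize(a))^2))
    den <- sqrt(sum((a2 - a)^2))
    if (den > 0) worst <- max(worst, num / den)
  }
  # empirically recorded bound for the default map over the range box
  expect_lt(worst, 4000)
})

test_that("observation noise honors the level-times-norm contract", {
  norms <- list(motor = 1, pos = 2, vel = 0.5, formant = 1000)
  noise <- sfc_noise_config(motor_level = 0, aud_level = 1e-2,
                            somat_level = 1e-3, norms = norms)
  st <- plant_init()
  # zero noise: observation is exact
  y0 <- observe(st, sfc_noise_config(0, 0, 0, norms = norms))
  expect_equal(y0$y_somat, c(st$a, st$a_dot))
  expect_equal(y0$y_aud, synthesize(st$a))
  # Monte-Carlo standard deviations match level x group norm within 5%
  set.seed(31)
  n <- 10000
  pos1 <- numeric(n); vel1 <- numeric(n); aud1 <- numeric(n)
  for (i in seq_len(n)) {
    y <- observe(st, noise)
    pos1[i] <- y$y_somat[[1]]; vel1[i] <- y$y_somat[[11]]; aud1[i] <- y$y_aud[[1]]
  }
  expect_equal(sd(pos1), 1e-3 * 2, tolerance = 0.05)
  expect_equal(sd(vel1), 1e-3 * 0.5, tolerance = 0.05)
  expect_equal(sd(aud1), 1e-2 * 1000, tolerance = 0.05)
  # the perceived-F1 shift adds to the auditory channel only, after noise
  st$f1_shift <- 100
  y1 <- observe(st, sfc_noise_config(0, 0, 0, norms = norms))
  expect_equal(y1$y_aud[[1]] - synthesize(st$a)[["F1"]], 100)
  expect_equal(y1$y_aud[2:3], synthesize(st$a)[2:3])
  expect_equal(y1$y_somat, c(st$a, st$a_dot))
})

test_that("channel norms come from a reproducible noiseless calibration run", {
  sc <- score_sustained_schwa(0.3)
  cfg <- sfc_config()
  n1 <- calibrate_norms(sc, cfg)
  n2 <- calibrate_norms(sc, cfg)
  expect_identical(n1, n2)
  expect_true(all(unlist(n1) > 0))
  # formants live in the hundreds-to-thousands of Hz
  expect_gt(n1$formant, 500)
})
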