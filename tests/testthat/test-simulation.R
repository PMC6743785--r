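test_that("trials are bitwise reproducible from (score, config, seed)", {
  sc <- score_sustained_schwa(0.3)
  cfg <- sfc_config(feedback = "somat")
  norms <- calibrate_norms(sc, cfg)
  t1 <- run_trial(sc, cfg, seed = 5, norms = norms)
  t2 <- run_trial(sc, cfg, seed = 5, norms = norms)
  expect_identical(t1$trajectory, t2$trajectory)
  t3 <- run_trial(sc, cfg, seed = 6, norms = norms)
  expect_false(identical(t1$trajectory, t3$trajectory))
  # one row per control step
  expect_equal(nrow(t1$trajectory), round(sc$duration / cfg$dt))
})

test_that("the noiseless loop attains targets and the estimate tracks the plant", {
  sc <- score_vowel_sequence()
  cfg <- zero_noise_config()
  tr <- run_trial(sc, cfg, seed = 1)
  expect_false(tr$diverged)
  traj <- tr$trajectory
  # estimate equals truth to numerical precision (self-consistency)
  est_err <- max(abs(as.matrix(traj[, paste0("est_", articulator_inventory())]) -
                       as.matrix(traj[, paste0("a_", articulator_inventory())])))
  expect_lt(est_err, 1e-6)
  # each gesture's target reached within 2% of target-to-start distance
  g <- sc$gestures
  for (i in seq_len(nrow(g))) {
    col <- paste0("x_", g$task[i])
    onset_idx <- max(1, which.min(abs(traj$t - g$onset[i])))
    off_idx <- which.min(abs(traj$t - g$offset[i]))
    start <- traj[[col]][onset_idx]
    final <- traj[[col]][off_idx]
    expect_lt(abs(final - g$target[i]), 0.02 * abs(start - g$target[i]) + 1e-9)
  }
  # tongue lowers into the open vowel, then raises and fronts
  arts <- articulator_inventory()
  A <- t(as.matrix(traj[, paste0("a_", arts)])); rownames(A) <- arts
  tc <- tongue_center(A)
  i1 <- which.min(abs(traj$t - 0.35)); i2 <- which.min(abs(traj$t - 0.75))
  i3 <- nrow(traj)
  expect_lt(tc["y", i2], tc["y", i1])       # lowers
  expect_gt(tc["y", i3], tc["y", i2])       # raises
  expect_lt(tc["x", i3], tc["x", i2])       # fronts (anterior = negative x)
})

test_that("divergence is an outcome, not an error", {
  sc <- score_sustained_schwa(0.3)
  cfg <- zero_noise_config()
  cfg$divergence_factor <- 1e-4
  tr <- run_trial(sc, cfg, seed = 1)
  expect_true(tr$diverged)
  expect_lt(nrow(tr$trajectory), round(sc$duration / cfg$dt))
})

test_that("trajectories and config echo round-trip through the writers", {
  sc <- score_sustained_schwa(0.25)
  tr <- run_trial(sc, zero_noise_config(), seed = 2)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(tr$trajectory))
  expect_equal(back$a_JA, tr$trajectory$a_JA, tolerance = 1e-12)
  sidecar <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(sidecar$dt, 0.005)
  expect_equal(sidecar$noise$somat_level, 0)
  expect_true(all(c("geom", "ukf", "null_attractor") %in% names(sidecar)))
  unlink(c(path, paste0(path, ".json")))
})

test_that("configuration files read with defaults filled in", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "dt: 0.004",
    "feedback: aud",
    "noise:",
    "  aud_level: 0.05",
    "ukf:",
    "  alpha: 0.01",
    "f1_shift:",
    "  hz: 100",
    "  t_on: 0.2"
  ), path)
  cfg <- read_config(path)
  expect_equal(cfg$dt, 0.004)
  expect_equal(cfg$feedback, "aud")
  expect_equal(cfg$noise$aud_level, 0.05)
  expect_equal(cfg$noise$somat_level, 1e-6)   # default preserved
  expect_equal(cfg$ukf$alpha, 0.01)
  expect_equal(cfg$ukf$beta, 2)               # default preserved
  expect_equal(cfg$f1_shift$hz, 100)
  unlink(path)
})

test_that("jaw-clamp compensation is task-specific and validated", {
  jb <- jaw_perturbation("b")
  expect_gt(jb$summary$ul_lowering_diff, 1e-3)
  expect_gt(jb$summary$ll_raising_diff, 1e-3)
  expect_true(jb$summary$closure_achieved)
  jd <- jaw_perturbation("d")
  expect_lt(abs(jd$summary$ul_lowering_diff), 1e-4)
  expect_true(jd$summary$closure_achieved)
  # a score without the consonant's closure gesture is rejected
  expect_error(jaw_perturbation("b", score = score_sustained_schwa(1)),
               "closure gesture")
})

test_that("perceived-F1 compensation is positive, partial, and trades off with sensory precision", {
  # run in a regime where somatosensory and auditory precision are comparable,
  # so the effect is resolvable above trial noise
  map <- test_map_small()
  base <- function(somat, aud) {
    sfc_config(noise = sfc_noise_config(somat_level = somat, aud_level = aud))
  }
  comp <- function(cfg) {
    f1_perturbation(shift = 100, config = cfg, n_seeds = 4, seed = 11,
                    map = map, score = score_sustained_schwa(1.0))$summary
  }
  mid <- comp(base(0.1, 1e-2))
  expect_gt(mid$comp_hz, 0)            # lowers produced F1
  expect_lt(mid$comp_pct, 100)         # but only partially
  hi_aud <- comp(base(0.1, 2e-2))      # doubled auditory noise: smaller response
  expect_lt(hi_aud$comp_hz, mid$comp_hz)
  lo_somat <- comp(base(0.03, 1e-2))   # reduced somatosensory noise: smaller
  expect_lt(lo_somat$comp_hz, mid$comp_hz)
})

test_that("plot methods return ggplot objects", {
  sc <- score_sustained_schwa(0.25)
  tr <- run_trial(sc, zero_noise_config(), seed = 3)
  expect_s3_class(autoplot(tr), "ggplot")
  map <- test_map_small()
  res <- f1_perturbation(shift = 100, n_seeds = 2, seed = 2, map = map,
                         config = sfc_config(noise = sfc_noise_config(somat_level = 0.05)),
                         score = score_sustained_schwa(0.5))
  expect_s3_class(autoplot(res), "ggplot")
  sw <- noise_sweep("somat", levels = c(1e-3, 1e-5), n = 2,
                    score = score_sustained_schwa(0.3), map = map, seed = 4)
  expect_s3_class(autoplot(sw), "ggplot")
})
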