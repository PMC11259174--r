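test_that("noise SDs and reward covariance are derived from the config", {
  cfg <- task_config(alpha_a = 0.2, alpha_o = 0.1)
  expect_equal(process_noise_sd(cfg), c(40, 18))
  expect_equal(obs_noise_sd(cfg), c(20, 9))
  # gain-task scaling: noise scales with the multiplier
  cfg2 <- task_config(alpha_a = 0.2, alpha_o = 0.1, gain_multiplier = 2)
  expect_equal(process_noise_sd(cfg2), c(80, 36))
  expect_equal(reward_cov(cfg), diag((65 / 1.5)^2, 2))
  expect_error(task_config(dt = 0), "dt")
  expect_error(task_config(gain = c(-1, 90)), "gain")
})

test_that("config JSON round-trips", {
  cfg <- task_config(alpha_a = 0.3, gain_multiplier = 1.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_task_config(cfg, path)
  expect_equal(read_task_config(path), cfg)
})

test_that("targets are uniform over the annular sector", {
  set.seed(42)
  tg <- sample_target(1e5)
  r <- sqrt(rowSums(tg^2))
  ang <- atan2(tg[, 2], tg[, 1]) * 180 / pi
  expect_true(all(r >= 100 & r <= 400))
  expect_true(all(tg[, 2] > 0))
  expect_true(all(ang >= 55 - 1e-9 & ang <= 125 + 1e-9))
  # 2-D uniformity: equal-area bins in (r^2, angle) should be equally filled
  rbin <- cut(r^2, breaks = seq(100^2, 400^2, length.out = 6))
  abin <- cut(ang, breaks = seq(55, 125, length.out = 6))
  tab <- table(rbin, abin)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("forced boundary target lands straight ahead at 100 cm", {
  # u forced to 100^2 and angle to 90 deg via a degenerate sampling range
  tg <- sample_target(1, r_range = c(100, 100), ang_range = c(90, 90))
  expect_equal(as.numeric(tg), c(0, 100), tolerance = 1e-12)
})

test_that("perturbation envelope peaks exactly and vanishes outside 1 s", {
  pr <- perturbation_profile(t_p = 1.0, p_v_peak = 100, p_omega_peak = -50)
  expect_equal(as.numeric(perturbation_velocity(1.0, pr)), c(100, -50))
  expect_equal(as.numeric(perturbation_velocity(1.6, pr)), c(0, 0))
  expect_equal(as.numeric(perturbation_velocity(0.3, pr)), c(0, 0))
  expect_equal(unname(perturbation_velocity(1.2, pr)[1, 1]), 100 * exp(-0.5),
               tolerance = 1e-12)
  expect_equal(unname(perturbation_velocity(seq(0, 2, 0.1), pr)[11, 1]), 100)
})

test_that("environment step follows the stated integration order", {
  cfg <- noise_free_config()
  s0 <- initial_state(c(0, 200))
  # fixed point at rest
  expect_equal(env_step(s0, c(0, 0), cfg), s0)
  # position uses the pre-update velocity: full throttle moves nothing yet
  s1 <- env_step(s0, c(1, 0), cfg)
  expect_equal(unname(s1[c("x", "y", "v")]), c(0, 0, 200))
  # next step the new velocity moves the agent along heading 90 deg
  s2 <- env_step(s1, c(1, 0), cfg)
  expect_equal(unname(s2[c("x", "y")]), c(0, 20), tolerance = 1e-12)
  # target fields never change
  expect_equal(unname(s2[c("gx", "gy")]), c(0, 200))
  expect_error(env_step(s0, c(0, 0), task_config(dt = -1)))
})

test_that("process and observation noise have the configured SDs", {
  cfg <- task_config(alpha_a = 0.2, alpha_o = 0.1)
  s0 <- initial_state(c(0, 200))
  set.seed(7)
  S <- env_step(matrix(rep(s0, each = 1e5), 1e5), matrix(0.5, 1e5, 2), cfg)
  expect_equal(stats::sd(S[, 4]), 40, tolerance = 0.02 * 40)
  expect_equal(stats::sd(S[, 5]), 18, tolerance = 0.02 * 18)
  O <- observe(matrix(rep(s0, each = 1e5), 1e5), t = 0.5, cfg)
  expect_equal(stats::sd(O[, 1]), 20, tolerance = 0.02 * 20)
  expect_equal(stats::sd(O[, 2]), 9, tolerance = 0.02 * 9)
})

test_that("observation masks the target after 0.3 s and is noiseless at t=0", {
  cfg <- task_config()
  s <- initial_state(c(50, 150))
  s[4] <- 120
  set.seed(1)
  o0 <- observe(s, 0, cfg)
  expect_equal(unname(o0), c(120, 0, 50, 150, 1))
  o3 <- observe(s, 0.3, cfg) # inclusive visibility boundary
  expect_equal(unname(o3[3:5]), c(50, 150, 1))
  o4 <- observe(s, 0.4, cfg)
  expect_equal(unname(o4[3:5]), c(0, 0, 0))
})

test_that("reward and termination implement the start/stop criteria", {
  cfg <- task_config()
  s_at_target <- c(x = 0, y = 200, theta = 90, v = 0, omega = 0,
                   gx = 0, gy = 200)
  # stop at distance 0 -> full reward
  rd <- reward_and_done(s_at_target, c(0, 0), t = 1, started = TRUE, cfg)
  expect_equal(rd$reward, 10)
  expect_equal(rd$done, 1)
  # not started yet: small action is not a stop
  rd0 <- reward_and_done(s_at_target, c(0, 0), t = 1, started = FALSE, cfg)
  expect_equal(rd0$done, 0)
  expect_false(rd0$started)
  # stop at 97.5 cm: the Gaussian partial reward, evaluated directly
  s_off <- s_at_target
  s_off["y"] <- 200 + 97.5
  rd2 <- reward_and_done(s_off, c(0.05, 0), t = 1, started = TRUE, cfg)
  expect_equal(rd2$reward, 10 * exp(-0.5 * (97.5 * 1.5 / 65)^2),
               tolerance = 1e-12)
  # timeout while still moving: done with zero reward
  rd3 <- reward_and_done(s_off, c(1, 0), t = 3.4, started = TRUE, cfg)
  expect_equal(rd3$done, 1)
  expect_equal(rd3$reward, 0)
})

test_that("episodes have consistent shapes and a single terminal flag", {
  cfg <- task_config()
  ep <- run_episode(scripted_controller(cfg), cfg, seed = 11)
  expect_s3_class(ep, "firefly_episode")
  expect_true(all(ep$done[-nrow(ep)] == 0))
  expect_equal(ep$done[nrow(ep)], 1)
  expect_lte(nrow(ep) * cfg$dt, cfg$max_duration + cfg$dt + 1e-9)
  expect_true(all(ep$gx == ep$gx[1]))
  # determinism: same seed, bit-identical episode
  ep2 <- run_episode(scripted_controller(cfg), cfg, seed = 11)
  expect_identical(as.data.frame(ep), as.data.frame(ep2))
})

test_that("episode CSV round-trips with metadata", {
  cfg <- task_config()
  ep <- run_episode(scripted_controller(cfg), cfg, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_episode(ep, path)
  ep2 <- read_episode(path)
  expect_equal(ep2[, ], ep[, ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(ep2, "config"), cfg)
})

test_that("mirroring is an involution, fixes symmetric trials, and is
           dynamically consistent", {
  cfg <- noise_free_config()
  # symmetric trial: target straight ahead, pure-forward actions
  acts <- matrix(c(rep(1, 8), rep(0, 8)), ncol = 2)
  ep_sym <- fixed_action_episode(acts, target = c(0, 200))
  expect_equal(as.data.frame(mirror_episode(ep_sym)), as.data.frame(ep_sym))
  # generic trial: involution
  acts2 <- cbind(seq(1, 0.2, length.out = 8), seq(0.5, -0.5, length.out = 8))
  ep <- fixed_action_episode(acts2, target = c(80, 180))
  expect_equal(as.data.frame(mirror_episode(mirror_episode(ep))),
               as.data.frame(ep))
  # dynamical consistency: replaying mirrored actions on the mirrored
  # target reproduces the mirrored state sequence exactly
  m <- mirror_episode(ep)
  ep_replay <- fixed_action_episode(cbind(m$a_v, m$a_omega),
                                    target = c(m$gx[1], m$gy[1]))
  expect_equal(ep_replay$x, m$x, tolerance = 1e-10)
  expect_equal(ep_replay$y, m$y, tolerance = 1e-10)
  expect_equal(ep_replay$theta, m$theta, tolerance = 1e-10)
  expect_equal(ep_replay$r, m$r, tolerance = 1e-10)
})

test_that("gain covariance: scaling gain and noise scales linear trajectories", {
  acts <- matrix(c(rep(1, 10), rep(0, 10)), ncol = 2) # straight ahead
  ep1 <- fixed_action_episode(acts, target = c(0, 200),
                              config = noise_free_config())
  ep2 <- fixed_action_episode(acts, target = c(0, 400),
                              config = noise_free_config(gain_multiplier = 2))
  expect_equal(ep2$y, 2 * ep1$y, tolerance = 1e-10)
})

test_that("noise-off replay reconstructs a stored trajectory exactly", {
  cfg <- noise_free_config()
  ep <- run_episode(scripted_controller(cfg), cfg, target = c(60, 250),
                    noise = FALSE)
  re <- no_generalization_replay(cbind(ep$a_v, ep$a_omega)[-nrow(ep), ,
                                                           drop = FALSE],
                                 c(60, 250), cfg)
  expect_equal(re$x, ep$x, tolerance = 1e-10)
  expect_equal(re$y, ep$y, tolerance = 1e-10)
})
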