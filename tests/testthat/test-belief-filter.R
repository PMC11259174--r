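test_that("initial belief is minus the target with epsilon covariance", {
  b <- ekf_init(c(0, 100))
  expect_equal(b$mean, c(0, -100, 90, 0, 0))
  expect_equal(b$P, diag(1e-8, 5))
  expect_equal(sum(diag(ekf_init(c(50, 200))$P)), 5e-8)
  expect_equal(ekf_init(c(50, 200))$mean[1:2], c(-50, -200))
})

test_that("noise model floors zero variances at epsilon", {
  nm <- noise_model(c(0, 0), c(0, 0))
  expect_equal(diag(nm$Sigma_a)[4:5], c(1e-8, 1e-8))
  expect_equal(diag(nm$Sigma_o), c(1e-8, 1e-8))
  nm2 <- noise_model(c(40, 18), c(20, 9))
  expect_equal(nm2$Sigma_a[4, 4], 1600)
  expect_equal(nm2$Sigma_a[5, 5], 324)
  expect_true(all(nm2$Sigma_a[-c(19, 25)] == 0))
})

test_that("prediction resets velocity variances to the process noise", {
  cfg <- task_config()
  nm <- noise_model(c(40, 18), c(20, 9))
  b <- ekf_init(c(0, 100))
  bp <- ekf_predict(b, c(0, 0), nm, cfg)
  expect_equal(bp$mean, b$mean) # at rest, mean unchanged
  expect_equal(bp$P[4, 4], 1600)
  expect_equal(bp$P[5, 5], 324)
  # predicted velocity variances are independent of the prior covariance
  b_wide <- fireflynav:::new_belief(b$mean, diag(c(100, 100, 25, 900, 400)))
  bp2 <- ekf_predict(b_wide, c(0.3, -0.2), nm, cfg)
  expect_equal(bp2$P[4, 4], 1600)
  expect_equal(bp2$P[5, 5], 324)
  expect_error(ekf_predict(fireflynav:::new_belief(b$mean,
                                                   diag(c(-1, 1, 1, 1, 1))),
                           c(0, 0), nm, cfg),
               "positive semidefinite")
})

test_that("prediction matches Monte-Carlo propagation of the dynamics", {
  cfg <- task_config()
  nm <- noise_model(c(40, 18), c(20, 9))
  mean0 <- c(-30, -150, 80, 120, 10)
  P0 <- diag(c(25, 25, 4, 100, 25))
  b <- fireflynav:::new_belief(mean0, P0)
  a <- c(0.6, -0.3)
  bp <- ekf_predict(b, a, nm, cfg)
  set.seed(99)
  n <- 1e6
  X <- cbind(stats::rnorm(n, mean0[1], 5), stats::rnorm(n, mean0[2], 5),
             stats::rnorm(n, mean0[3], 2), stats::rnorm(n, mean0[4], 10),
             stats::rnorm(n, mean0[5], 5))
  th <- X[, 3] * pi / 180
  Xn <- cbind(X[, 1] + 0.1 * X[, 4] * cos(th),
              X[, 2] + 0.1 * X[, 4] * sin(th),
              X[, 3] + 0.1 * X[, 5],
              200 * a[1] + stats::rnorm(n, 0, 40),
              90 * a[2] + stats::rnorm(n, 0, 18))
  se <- apply(Xn, 2, stats::sd) / sqrt(n)
  expect_true(all(abs(colMeans(Xn) - bp$mean) < 3 * se + 1e-9))
  expect_equal(diag(stats::cov(Xn)), diag(bp$P), tolerance = 0.02)
})

test_that("update fuses velocities with the closed-form gain", {
  cfg <- task_config()
  nm <- noise_model(c(40, 18), c(20, 9))
  b <- ekf_init(c(0, 100))
  bp <- ekf_predict(b, c(0.5, 0), nm, cfg)
  # huge observation noise: posterior equals prior
  nm_inf <- noise_model(c(40, 18), c(1e9, 1e9))
  bu <- ekf_update(bp, c(500, 100), nm_inf)
  expect_equal(bu$mean, bp$mean, tolerance = 1e-4)
  # equal precision: posterior velocity is the midpoint
  nm_eq <- noise_model(c(40, 18), c(40, 18))
  bu2 <- ekf_update(bp, c(bp$mean[4] + 10, bp$mean[5] + 4), nm_eq)
  expect_equal(bu2$mean[4], bp$mean[4] + 5, tolerance = 1e-6)
  expect_equal(bu2$mean[5], bp$mean[5] + 2, tolerance = 1e-6)
  # sigma_o = 0.1 G against sigma_a = 0.2 G: observation weight 0.8
  K <- kalman_gain_schedule(nm)
  expect_equal(K[4, 1], 0.8)
  expect_equal(K[5, 2], 0.8)
  expect_true(all(K[1:3, ] == 0))
})

test_that("Kalman gain is constant and independent of the prior covariance", {
  cfg <- task_config()
  nm <- noise_model(c(40, 18), c(20, 9))
  K_sched <- kalman_gain_schedule(nm)
  H <- matrix(0, 2, 5); H[1, 4] <- 1; H[2, 5] <- 1
  gain_from <- function(P) {
    bp <- ekf_predict(fireflynav:::new_belief(c(-10, -120, 85, 50, 5), P),
                      c(0.4, 0.1), nm, cfg)
    bp$P %*% t(H) %*% solve(H %*% bp$P %*% t(H) + nm$Sigma_o)
  }
  set.seed(5)
  for (i in 1:5) {
    A <- matrix(rnorm(25), 5)
    P <- crossprod(A) + diag(0.1, 5)
    expect_lt(max(abs(gain_from(P) - K_sched)), 1e-12)
  }
  # noiseless observation: full trust in it
  K0 <- kalman_gain_schedule(noise_model(c(40, 18), c(0, 0)))
  expect_equal(K0[4, 1], 1, tolerance = 1e-8)
  expect_equal(K0[5, 2], 1, tolerance = 1e-8)
})

test_that("covariance stays PSD and fusing never loses velocity information", {
  cfg <- task_config()
  nm <- config_noise_model(cfg)
  ep <- run_episode(scripted_controller(cfg), cfg, seed = 21)
  b <- ekf_init(c(ep$gx[1], ep$gy[1]))
  for (i in 2:nrow(ep)) {
    bp <- ekf_predict(b, c(ep$a_v[i - 1], ep$a_omega[i - 1]), nm, cfg)
    b <- ekf_update(bp, c(ep$o_v[i], ep$o_omega[i]), nm)
    ev <- eigen(b$P, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
    expect_lte(b$P[4, 4], min(bp$P[4, 4], nm$Sigma_o[1, 1]) + 1e-9)
    expect_lte(b$P[5, 5], min(bp$P[5, 5], nm$Sigma_o[2, 2]) + 1e-9)
  }
})

test_that("relative belief plus target recovers the true pose, noise-free", {
  cfg <- noise_free_config()
  ep <- run_episode(scripted_controller(cfg), cfg, target = c(40, 220),
                    noise = FALSE)
  bf <- ekf_run(ep)
  expect_equal(bf$s_hat_1 + ep$gx[1], ep$x, tolerance = 1e-6)
  expect_equal(bf$s_hat_2 + ep$gy[1], ep$y, tolerance = 1e-6)
  expect_equal(bf$s_hat_3, ep$theta, tolerance = 1e-6)
})

test_that("packed covariance round-trips", {
  set.seed(8)
  A <- matrix(rnorm(25), 5)
  P <- crossprod(A)
  expect_equal(unpack_cov(pack_cov(P)), P)
  expect_equal(pack_cov(P)[1:5], P[1, ])
})

test_that("fast rollout belief equals the generic EKF step for step", {
  # deterministic environment, nontrivial frozen gain: the vectorized
  # pose-block propagation must reproduce ekf_predict/ekf_update exactly
  cfg_env <- noise_free_config()
  cfg_agent <- task_config() # training-time model (alpha_a=.2, alpha_o=.1)
  nm <- config_noise_model(cfg_agent)
  target <- matrix(c(70, 230), 1)
  ro <- rollout_ekf_trials(scripted_policy(cfg_agent), targets = target,
                           env_config = cfg_env, agent_config = cfg_agent,
                           agent_noise = nm, record = "full")
  n_steps <- ro$steps[1]
  feats <- matrix(ro$feats[seq_len(n_steps), 1, ], nrow = n_steps)
  acts <- matrix(ro$actions[seq_len(n_steps), 1, ], nrow = n_steps)
  # generic filter on the same (deterministic) observation stream
  b <- ekf_init(target[1, ])
  s <- initial_state(target[1, ])
  scales <- fireflynav:::belief_scales(cfg_agent)
  for (i in seq_len(n_steps - 1)) {
    f_ref <- belief_features(b$mean, pack_cov(b$P), cfg_agent)[1, ]
    expect_equal(unname(feats[i, ]), unname(f_ref), tolerance = 1e-9)
    a <- acts[i, ]
    s <- env_step(s, a, cfg_env, noise = FALSE)
    o <- observe(s, i * cfg_env$dt, cfg_env, noise = FALSE)
    b <- ekf_update(ekf_predict(b, a, nm, cfg_agent), o, nm)
  }
})

test_that("particle filter agrees with the EKF on low-noise episodes and
           collapses to the truth without noise", {
  cfg <- task_config(alpha_a = 0.05, alpha_o = 0.05)
  nm <- config_noise_model(cfg)
  set.seed(31)
  ep <- run_episode(scripted_controller(cfg), cfg, target = c(0, 250))
  bf <- ekf_run(ep, noise = nm)
  set.seed(32)
  pf <- particle_filter_oracle(ep, nm, n_particles = 2e4)
  expect_true(all(pf$ess >= 10))
  for (i in seq_len(nrow(ep))) {
    expect_gte(sum(diag(pf$cov[[i]])), 0)
  }
  # invariant: mean discrepancy < 5% of target distance
  disc <- sqrt(rowSums((pf$mean[, 1:2] -
                          as.matrix(bf[, c("s_hat_1", "s_hat_2")]))^2))
  expect_lt(max(disc), 0.05 * 250)
  # zero-noise: the PF collapses onto the true relative state
  cfg0 <- noise_free_config()
  ep0 <- run_episode(scripted_controller(cfg0), cfg0, target = c(0, 250),
                     noise = FALSE)
  pf0 <- particle_filter_oracle(ep0, config_noise_model(cfg0),
                                n_particles = 2000)
  expect_lt(max(abs(pf0$mean[, 1] - (ep0$x - ep0$gx))), 0.1)
  expect_lt(max(abs(pf0$mean[, 2] - (ep0$y - ep0$gy))), 0.1)
})
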