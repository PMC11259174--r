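# Extended Kalman filter over the 5-dim relative state (x - gx, y - gy,
# theta, v, omega). Means are stored in degrees; Jacobian trigonometry is in
# radians, with the deg<->rad factor carried in the d/dtheta entries so that
# covariances in degree units propagate correctly.

EKF_EPS <- 1e-8

#' Gaussian noise model for the belief filter
#'
#' Process noise enters only the two velocity components (the position rows of
#' the transition carry no noise of their own), so `Sigma_a` is a 5x5 matrix
#' that is zero except for the velocity variances; `Sigma_o` is the 2x2
#' diagonal covariance of the velocity observation. Zero variances are floored
#' at a minimal variance of 1e-8 so every update stays well posed.
#'
#' @param sigma_a length-2 process-noise SD `(cm/s, deg/s)`.
#' @param sigma_o length-2 observation-noise SD `(cm/s, deg/s)`.
#' @return object of class `firefly_noise` with `Sigma_a` (5x5), `Sigma_o`
#'   (2x2) and the SD vectors.
#' @export
noise_model <- function(sigma_a, sigma_o) {
  va <- pmax(sigma_a^2, EKF_EPS)
  vo <- pmax(sigma_o^2, EKF_EPS)
  Sigma_a <- matrix(0, 5, 5)
  Sigma_a[4, 4] <- va[1]
  Sigma_a[5, 5] <- va[2]
  structure(list(Sigma_a = Sigma_a, Sigma_o = diag(vo, 2),
                 sigma_a = sqrt(va), sigma_o = sqrt(vo)),
            class = "firefly_noise")
}

#' Noise model implied by a task configuration
#' @param config a [task_config()].
#' @return a [noise_model()].
#' @export
config_noise_model <- function(config) {
  noise_model(process_noise_sd(config), obs_noise_sd(config))
}

new_belief <- function(mean, P) {
  structure(list(mean = as.numeric(mean), P = P), class = "firefly_belief")
}

#' Initial belief for a trial
#'
#' In relative coordinates the agent starts at minus the target location,
#' heading 90 degrees, at rest; the initial covariance is `1e-8 * I5` (the
#' start pose is known, the target was just seen).
#'
#' @param target length-2 `(gx, gy)` in cm.
#' @return object of class `firefly_belief` with `mean` (length 5) and `P`
#'   (5x5).
#' @export
ekf_init <- function(target) {
  new_belief(c(-target[1], -target[2], 90, 0, 0), diag(EKF_EPS, 5))
}

check_psd <- function(P, tol = 1e-10) {
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) stop("covariance is not positive semidefinite")
  invisible(TRUE)
}

ekf_fenv <- function(mean, action, config) {
  dt <- config$dt
  nG <- config$gain_multiplier * config$gain
  th <- deg2rad(mean[3])
  c(mean[1] + dt * mean[4] * cos(th),
    mean[2] + dt * mean[4] * sin(th),
    mean[3] + dt * mean[5],
    nG[1] * action[1],
    nG[2] * action[2])
}

ekf_jacobian <- function(mean, config) {
  dt <- config$dt
  th <- deg2rad(mean[3])
  d2r <- pi / 180
  A <- matrix(0, 5, 5)
  A[1, 1] <- 1
  A[2, 2] <- 1
  A[3, 3] <- 1
  A[1, 3] <- -dt * mean[4] * sin(th) * d2r
  A[2, 3] <- dt * mean[4] * cos(th) * d2r
  A[1, 4] <- dt * cos(th)
  A[2, 4] <- dt * sin(th)
  A[3, 5] <- dt
  # velocity rows are all zero: the action fully resets the velocities
  A
}

#' EKF prediction step
#'
#' Propagates the mean through the noise-free 5-dim dynamics and the
#' covariance through the local linearization `A P A' + Sigma_a`. Because the
#' velocity rows of `A` are identically zero (the commanded velocity is the
#' whole prior on the next velocity), the predicted velocity variances equal
#' the process-noise variances exactly, independent of the prior covariance.
#'
#' @param belief a `firefly_belief`.
#' @param action length-2 action at the previous step.
#' @param noise a [noise_model()].
#' @param config a [task_config()] describing the agent's internal model.
#' @return predicted `firefly_belief`.
#' @export
ekf_predict <- function(belief, action, noise, config) {
  check_psd(belief$P)
  A <- ekf_jacobian(belief$mean, config)
  P <- A %*% belief$P %*% t(A) + noise$Sigma_a
  new_belief(ekf_fenv(belief$mean, action, config), (P + t(P)) / 2)
}

#' EKF update step
#'
#' Standard Kalman update with the 2x5 observation matrix selecting the two
#' velocity components (the target enters only through [ekf_init()]; position
#' is never directly observed, so position uncertainty can only grow).
#'
#' @param belief predicted `firefly_belief`.
#' @param obs observation: uses components `o_v`, `o_omega` (anything with
#'   those first two velocity entries works).
#' @param noise a [noise_model()].
#' @return posterior `firefly_belief`.
#' @export
ekf_update <- function(belief, obs, noise) {
  H <- matrix(0, 2, 5)
  H[1, 4] <- 1
  H[2, 5] <- 1
  P <- belief$P
  S <- H %*% P %*% t(H) + noise$Sigma_o
  K <- P %*% t(H) %*% solve(S)
  o <- as.numeric(obs[1:2])
  mean <- belief$mean + as.numeric(K %*% (o - H %*% belief$mean))
  P_new <- (diag(5) - K %*% H) %*% P
  new_belief(mean, (P_new + t(P_new)) / 2)
}

#' The constant Kalman gain implied by the noise model
#'
#' With zero velocity rows in the Jacobian, the predicted velocity block of
#' the covariance equals `Sigma_a`'s velocity block and all cross terms with
#' position vanish, so for every step `t >= 1` the gain is the same 5x2
#' matrix: zero everywhere except the two velocity weights
#' `sigma_a^2 / (sigma_a^2 + sigma_o^2)`. Observations therefore never
#' correct position directly; they only reweight the velocity estimate.
#'
#' @param noise a [noise_model()].
#' @return 5x2 matrix.
#' @export
kalman_gain_schedule <- function(noise) {
  K <- matrix(0, 5, 2)
  va <- diag(noise$Sigma_a)[4:5]
  vo <- diag(noise$Sigma_o)
  K[4, 1] <- va[1] / (va[1] + vo[1])
  K[5, 2] <- va[2] / (va[2] + vo[2])
  K
}

#' Run the EKF along a recorded episode
#'
#' Replays the episode's actions and observations through predict/update,
#' starting from [ekf_init()] at the episode's target. Returns one row per
#' step: the belief held when the step's action was taken.
#'
#' @param episode a `firefly_episode`.
#' @param noise a [noise_model()]; defaults to the episode config's
#'   ground-truth noise.
#' @param config internal-model config; defaults to the episode's config.
#' @return data.frame with columns `s_hat_1..5` and the packed
#'   upper-triangular covariance `P_1..15` (row-major over the upper
#'   triangle).
#' @export
ekf_run <- function(episode, noise = NULL, config = NULL) {
  if (is.null(config)) config <- attr(episode, "config")
  if (is.null(noise)) noise <- config_noise_model(config)
  n <- nrow(episode)
  out <- matrix(NA_real_, n, 20)
  colnames(out) <- c(paste0("s_hat_", 1:5), paste0("P_", 1:15))
  b <- ekf_init(c(episode$gx[1], episode$gy[1]))
  out[1, ] <- c(b$mean, pack_cov(b$P))
  if (n > 1) {
    for (i in 2:n) {
      a <- c(episode$a_v[i - 1], episode$a_omega[i - 1])
      b <- ekf_predict(b, a, noise, config)
      b <- ekf_update(b, c(episode$o_v[i], episode$o_omega[i]), noise)
      out[i, ] <- c(b$mean, pack_cov(b$P))
    }
  }
  as.data.frame(out)
}

#' Pack/unpack a symmetric 5x5 covariance as its 15 upper-triangle entries
#' @param P 5x5 symmetric matrix.
#' @return `pack_cov`: length-15 vector (row-major upper triangle).
#' @export
pack_cov <- function(P) {
  t(P)[lower.tri(P, diag = TRUE)]
}

#' @param v length-15 packed vector.
#' @rdname pack_cov
#' @export
unpack_cov <- function(v) {
  P <- matrix(0, 5, 5)
  P[lower.tri(P, diag = TRUE)] <- v
  P <- t(P)
  P[lower.tri(P)] <- t(P)[lower.tri(P)]
  P
}

#' Bootstrap particle filter oracle for the belief
#'
#' An independent check on the EKF: a plain bootstrap filter over the 5-dim
#' relative state, propagating particles through the exact stochastic
#' dynamics and weighting them by the Gaussian velocity-observation
#' likelihood. Systematic resampling is triggered below half the particle
#' count; degeneracy (effective sample size under 10) is an error. With
#' enough particles its posterior moments agree with the EKF on low-curvature
#' trajectories, where the linearization is benign.
#'
#' @param episode a `firefly_episode` generated with known noise.
#' @param noise a [noise_model()] (the generating noise).
#' @param n_particles number of particles.
#' @param config internal-model config; defaults to the episode's.
#' @return list of per-step `mean` (n x 5 matrix) and `cov` (list of 5x5),
#'   plus `ess` (per-step effective sample size).
#' @export
particle_filter_oracle <- function(episode, noise, n_particles = 1e4,
                                   config = NULL) {
  if (is.null(config)) config <- attr(episode, "config")
  n <- nrow(episode)
  dt <- config$dt
  nG <- config$gain_multiplier * config$gain
  sd_a <- noise$sigma_a
  sd_o <- noise$sigma_o
  m0 <- c(-episode$gx[1], -episode$gy[1], 90, 0, 0)
  X <- matrix(rep(m0, each = n_particles), n_particles, 5)
  X <- X + matrix(stats::rnorm(n_particles * 5, 0, sqrt(EKF_EPS)),
                  n_particles, 5)
  means <- matrix(NA_real_, n, 5)
  covs <- vector("list", n)
  ess <- numeric(n)
  w <- rep(1 / n_particles, n_particles)
  wmoments <- function(X, w) {
    mu <- colSums(X * w)
    Xc <- sweep(X, 2, mu)
    list(mean = mu, cov = crossprod(Xc * sqrt(w), Xc * sqrt(w)) / sum(w))
  }
  mm <- wmoments(X, w)
  means[1, ] <- mm$mean
  covs[[1]] <- mm$cov
  ess[1] <- n_particles
  if (n > 1) {
    for (i in 2:n) {
      a <- c(episode$a_v[i - 1], episode$a_omega[i - 1])
      th <- deg2rad(X[, 3])
      X <- cbind(X[, 1] + dt * X[, 4] * cos(th),
                 X[, 2] + dt * X[, 4] * sin(th),
                 X[, 3] + dt * X[, 5],
                 nG[1] * a[1] + stats::rnorm(n_particles, 0, sd_a[1]),
                 nG[2] * a[2] + stats::rnorm(n_particles, 0, sd_a[2]))
      lw <- stats::dnorm(episode$o_v[i], X[, 4], sd_o[1], log = TRUE) +
        stats::dnorm(episode$o_omega[i], X[, 5], sd_o[2], log = TRUE)
      lw <- lw - max(lw)
      w <- w * exp(lw)
      w <- w / sum(w)
      ess[i] <- 1 / sum(w^2)
      if (ess[i] < 10) stop("particle degeneracy (effective sample size < 10)")
      mm <- wmoments(X, w)
      means[i, ] <- mm$mean
      covs[[i]] <- mm$cov
      if (ess[i] < n_particles / 2) {
        u <- (stats::runif(1) + seq_len(n_particles) - 1) / n_particles
        idx <- findInterval(u, cumsum(w)) + 1L
        idx[idx > n_particles] <- n_particles
        X <- X[idx, , drop = FALSE]
        w <- rep(1 / n_particles, n_particles)
      }
    }
  }
  list(mean = means, cov = covs, ess = ess)
}
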