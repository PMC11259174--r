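deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Task configuration for the firefly navigation POMDP
#'
#' Bundles every tunable of the task: integration step, joystick gain, gain
#' multiplier for the gain task, process/observation noise levels in units of
#' the gain, reward geometry, stop detection threshold, trial duration, target
#' visibility window, and the temporal discount.
#'
#' Noise standard deviations are derived, never stored: the process noise SD is
#' `alpha_a * gain_multiplier * gain` and the observation noise SD is
#' `alpha_o * gain_multiplier * gain`, so scaling the gain scales the noise
#' with it (the gain-task convention). The reward covariance used for the
#' partial (Gaussian) reward is `(reward_radius / 1.5)^2 * I2` and is likewise
#' always derived.
#'
#' @param dt integration time step in seconds.
#' @param gain joystick gain, length-2 `(linear cm/s, angular deg/s)`; maps
#'   dimensionless joystick deflections in `[-1, 1]` to velocities.
#' @param gain_multiplier dimensionless multiplier `n >= 1` applied to the
#'   gain (and therefore to the noise SDs) in the gain task.
#' @param alpha_a process-noise level in units of the (multiplied) gain.
#' @param alpha_o observation-noise level in units of the (multiplied) gain.
#' @param reward_radius radius of the reward zone, cm.
#' @param reward_amplitude reward delivered for a stop inside the zone.
#' @param action_threshold joystick magnitude separating "moving" from
#'   "stopped" (the start/stop criterion threshold).
#' @param max_duration maximum trial duration in seconds.
#' @param target_visible_duration the target is observable for trial times
#'   `t <= target_visible_duration` (inclusive).
#' @param gamma per-step temporal discount factor.
#' @param arena_radius radius of the ground plane, cm. Tracked (an episode
#'   flags exits) but not enforced as a wall.
#' @return An object of class `firefly_config` (a named list).
#' @export
task_config <- function(dt = 0.1,
                        gain = c(200, 90),
                        gain_multiplier = 1,
                        alpha_a = 0.2,
                        alpha_o = 0.1,
                        reward_radius = 65,
                        reward_amplitude = 10,
                        action_threshold = 0.1,
                        max_duration = 3.4,
                        target_visible_duration = 0.3,
                        gamma = 0.97,
                        arena_radius = 7000) {
  if (dt <= 0) stop("dt must be positive")
  if (any(gain <= 0)) stop("gain components must be positive")
  if (gain_multiplier < 1) stop("gain_multiplier must be >= 1")
  if (alpha_a < 0 || alpha_o < 0) stop("noise levels must be non-negative")
  cfg <- list(
    dt = dt, gain = as.numeric(gain), gain_multiplier = gain_multiplier,
    alpha_a = alpha_a, alpha_o = alpha_o,
    reward_radius = reward_radius, reward_amplitude = reward_amplitude,
    action_threshold = action_threshold, max_duration = max_duration,
    target_visible_duration = target_visible_duration, gamma = gamma,
    arena_radius = arena_radius
  )
  class(cfg) <- "firefly_config"
  cfg
}

#' @export
print.firefly_config <- function(x, ...) {
  cat("firefly task config\n")
  cat(sprintf("  dt = %g s, gain = (%g cm/s, %g deg/s) x %g\n",
              x$dt, x$gain[1], x$gain[2], x$gain_multiplier))
  cat(sprintf("  alpha_a = %g, alpha_o = %g  (sigma_a = %g, %g; sigma_o = %g, %g)\n",
              x$alpha_a, x$alpha_o,
              process_noise_sd(x)[1], process_noise_sd(x)[2],
              obs_noise_sd(x)[1], obs_noise_sd(x)[2]))
  cat(sprintf("  reward radius %g cm, max duration %g s, gamma %g\n",
              x$reward_radius, x$max_duration, x$gamma))
  invisible(x)
}

#' Derived noise standard deviations
#'
#' `sigma_a = alpha_a * n * G` and `sigma_o = alpha_o * n * G`: both noise SDs
#' are expressed in units of the multiplied joystick gain, so the gain task
#' scales them together with the dynamics.
#'
#' @param config a [task_config()] object.
#' @return length-2 numeric `(linear, angular)` SD.
#' @export
process_noise_sd <- function(config) {
  config$alpha_a * config$gain_multiplier * config$gain
}

#' @rdname process_noise_sd
#' @export
obs_noise_sd <- function(config) {
  config$alpha_o * config$gain_multiplier * config$gain
}

#' Reward covariance of the partial (Gaussian) reward
#'
#' `(reward_radius / 1.5)^2 * I2`; derived from the config, never stored.
#' @param config a [task_config()] object.
#' @return 2x2 matrix.
#' @export
reward_cov <- function(config) {
  diag((config$reward_radius / 1.5)^2, 2)
}

#' Read/write a task configuration as JSON
#'
#' @param config a [task_config()] object.
#' @param path file path.
#' @return `read_task_config` returns a `firefly_config`.
#' @export
write_task_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(task_config, x)
}

#' Sample target locations uniformly over the annular sector
#'
#' Targets lie ahead of the agent at a distance of 100 to 400 cm and a polar
#' angle within +/- 35 degrees of straight ahead (90 degrees). To obtain a
#' spatially uniform 2-D density over this sector, the squared radius is
#' sampled uniformly on `[100^2, 400^2]` (so `r = sqrt(u)`) and the angle
#' uniformly on `[55, 125]` degrees.
#'
#' @param n number of targets.
#' @param config a [task_config()] object (unused fields reserved).
#' @param r_range radial range in cm.
#' @param ang_range angular range in degrees.
#' @return an `n x 2` matrix with columns `gx`, `gy`.
#' @export
sample_target <- function(n = 1, config = task_config(),
                          r_range = c(100, 400), ang_range = c(55, 125)) {
  u <- stats::runif(n, r_range[1]^2, r_range[2]^2)
  r <- sqrt(u)
  th <- deg2rad(stats::runif(n, ang_range[1], ang_range[2]))
  cbind(gx = r * cos(th), gy = r * sin(th))
}

#' Gaussian-profile perturbation velocity
#'
#' The perturbation task adds a passive velocity with a Gaussian temporal
#' envelope of SD 0.2 s, truncated to the one-second window
#' `[t_p - 0.5, t_p + 0.5]`, and zero outside it. At `t = t_p` the envelope
#' equals 1 so the peak values are attained exactly.
#'
#' @param t_p peak time, s.
#' @param p_v_peak linear peak, cm/s.
#' @param p_omega_peak angular peak, deg/s.
#' @return an object of class `firefly_perturbation`.
#' @export
perturbation_profile <- function(t_p, p_v_peak, p_omega_peak) {
  structure(list(t_p = t_p, p_v_peak = p_v_peak, p_omega_peak = p_omega_peak),
            class = "firefly_perturbation")
}

#' @param t time (s), scalar or vector.
#' @param profile a [perturbation_profile()] or `NULL` (no perturbation).
#' @return `perturbation_velocity`: a matrix with columns `p_v`, `p_omega`.
#' @rdname perturbation_profile
#' @export
perturbation_velocity <- function(t, profile) {
  if (is.null(profile)) {
    return(cbind(p_v = numeric(length(t)), p_omega = numeric(length(t))))
  }
  env <- exp(-0.5 * ((t - profile$t_p) / 0.2)^2)
  env[t < profile$t_p - 0.5 | t > profile$t_p + 0.5] <- 0
  cbind(p_v = profile$p_v_peak * env, p_omega = profile$p_omega_peak * env)
}

#' Initial world state for a trial
#'
#' The agent starts at the origin heading straight ahead (90 degrees) at rest;
#' the target fields hold the trial's target and stay constant within a trial.
#'
#' @param target length-2 `(gx, gy)` in cm.
#' @return named numeric vector `(x, y, theta, v, omega, gx, gy)`.
#' @export
initial_state <- function(target) {
  c(x = 0, y = 0, theta = 90, v = 0, omega = 0,
    gx = unname(target[1]), gy = unname(target[2]))
}

#' One step of the unicycle environment dynamics
#'
#' Positions and heading advance with the current (pre-update) velocities:
#' `x += dt * v * cos(theta)`, `y += dt * v * sin(theta)`,
#' `theta += dt * omega`. The new velocities are set by the action through the
#' multiplied gain, plus any perturbation velocity, and then zero-mean
#' Gaussian process noise with SD `sigma_a` is added to the two velocity
#' components only (so noise first affects position one step later). Target
#' fields are unchanged. Operates row-wise on a state matrix.
#'
#' @param state named length-7 state vector, or an `n x 7` matrix.
#' @param action length-2 action in `[-1, 1]^2`, or `n x 2` matrix.
#' @param config a [task_config()] object.
#' @param t current trial time (s); used to evaluate the perturbation.
#' @param profile optional [perturbation_profile()].
#' @param noise logical; set `FALSE` for a deterministic step.
#' @return state(s) at `t + dt`, same shape as `state`.
#' @export
env_step <- function(state, action, config, t = 0, profile = NULL,
                     noise = TRUE) {
  vec_in <- is.null(dim(state))
  s <- if (vec_in) matrix(state, nrow = 1) else state
  a <- if (is.null(dim(action))) matrix(action, nrow = 1) else action
  a <- pmin(pmax(a, -1), 1)
  dt <- config$dt
  th <- deg2rad(s[, 3])
  p <- perturbation_velocity(t, profile)
  nG <- config$gain_multiplier * config$gain
  out <- s
  out[, 1] <- s[, 1] + dt * s[, 4] * cos(th)
  out[, 2] <- s[, 2] + dt * s[, 4] * sin(th)
  out[, 3] <- s[, 3] + dt * s[, 5]
  out[, 4] <- nG[1] * a[, 1] + p[, 1]
  out[, 5] <- nG[2] * a[, 2] + p[, 2]
  if (noise) {
    sd_a <- process_noise_sd(config)
    if (any(sd_a > 0)) {
      n <- nrow(out)
      out[, 4] <- out[, 4] + stats::rnorm(n, 0, sd_a[1])
      out[, 5] <- out[, 5] + stats::rnorm(n, 0, sd_a[2])
    }
  }
  if (vec_in) {
    v <- out[1, ]
    names(v) <- c("x", "y", "theta", "v", "omega", "gx", "gy")
    v
  } else out
}

#' Observe the world state
#'
#' The observation is `o = H_t s + zeta`: linear and angular velocity are
#' always observed (optic flow); the target position is included only while
#' visible (`t <= target_visible_duration`). Observation noise is zero-mean
#' Gaussian with SD `sigma_o` on the two velocity components, and exactly zero
#' at `t = 0`. When the target is invisible its observation components are 0.
#'
#' @inheritParams env_step
#' @param t trial time, s.
#' @return named length-5 vector `(o_v, o_omega, o_gx, o_gy, target_visible)`
#'   or an `n x 5` matrix.
#' @export
observe <- function(state, t, config, noise = TRUE) {
  vec_in <- is.null(dim(state))
  s <- if (vec_in) matrix(state, nrow = 1) else state
  n <- nrow(s)
  vis <- as.numeric(t <= config$target_visible_duration)
  o_v <- s[, 4]
  o_om <- s[, 5]
  if (noise && t > 0) {
    sd_o <- obs_noise_sd(config)
    if (any(sd_o > 0)) {
      o_v <- o_v + stats::rnorm(n, 0, sd_o[1])
      o_om <- o_om + stats::rnorm(n, 0, sd_o[2])
    }
  }
  out <- cbind(o_v = o_v, o_omega = o_om,
               o_gx = vis * s[, 6], o_gy = vis * s[, 7],
               target_visible = rep(vis, n))
  if (vec_in) out[1, ] else out
}

#' Reward and termination for the current step
#'
#' A trial ends when the agent stops (both joystick components below the
#' action threshold `a*`, recognized only after the start criterion -- some
#' earlier action component above `a*` -- has been met) or when `t` exceeds
#' the maximum trial duration. A nonzero reward is delivered only at a stop:
#' the full amplitude if the stop lies within the reward radius of the target,
#' otherwise the Gaussian partial reward
#' `amplitude * exp(-d' solve(reward_cov) d / 2)`. Timeouts earn nothing.
#'
#' @param state state at the current step (position used as stop location).
#' @param action action taken at the current step.
#' @param t trial time at the current step, s.
#' @param started logical: has the start criterion been met before this step?
#' @param config a [task_config()] object.
#' @return list with `reward`, `done`, `stopped`, and updated `started`.
#' @export
reward_and_done <- function(state, action, t, started, config) {
  a_star <- config$action_threshold
  below <- abs(action[1]) < a_star && abs(action[2]) < a_star
  stopped <- started && below
  timeout <- (t + config$dt) > config$max_duration + 1e-9
  done <- stopped || timeout
  reward <- 0
  if (stopped) {
    d <- c(state[1] - state[6], state[2] - state[7])
    dist <- sqrt(sum(d^2))
    reward <- if (dist < config$reward_radius) config$reward_amplitude else
      config$reward_amplitude *
        exp(-0.5 * sum(d^2) / (config$reward_radius / 1.5)^2)
  }
  list(reward = reward, done = as.numeric(done), stopped = stopped,
       started = started || !below)
}

episode_columns <- c("t", "x", "y", "theta", "v", "omega", "gx", "gy",
                     "a_v", "a_omega", "o_v", "o_omega", "o_gx", "o_gy",
                     "target_visible", "r", "done")

#' Run one trial of the firefly task
#'
#' Rolls out a controller in the simulator and records the full trial as an
#' episode table: per-step state, observation, action, reward and done flag
#' (all sequences share one length; the done flag is 1 only at the final row).
#'
#' The controller is a function `f(obs, t)` returning a length-2 action in
#' `[-1, 1]^2`; controllers that carry internal state (beliefs, recurrent
#' activity) should be closures created fresh per trial, e.g. by
#' [scripted_controller()] or an agent's policy factory.
#'
#' @param controller function `(obs, t) -> c(a_v, a_omega)`.
#' @param config a [task_config()] object.
#' @param target length-2 target; sampled from [sample_target()] if `NULL`.
#' @param profile optional [perturbation_profile()].
#' @param noise logical; `FALSE` switches off process and observation noise.
#' @param seed optional integer seed set before the trial.
#' @return a `data.frame` of class `firefly_episode` with columns
#'   `r episode_columns` and attributes `config`, `profile`, `seed`, and
#'   `left_arena` (flag: did the trajectory exit the arena radius).
#' @export
run_episode <- function(controller, config = task_config(), target = NULL,
                        profile = NULL, noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(target)) target <- sample_target(1, config)[1, ]
  s <- initial_state(target)
  max_steps <- floor(config$max_duration / config$dt) + 1L
  rec <- matrix(NA_real_, nrow = max_steps, ncol = length(episode_columns))
  colnames(rec) <- episode_columns
  started <- FALSE
  for (i in seq_len(max_steps)) {
    t <- (i - 1L) * config$dt
    o <- observe(s, t, config, noise = noise)
    a <- controller(o, t)
    a <- pmin(pmax(as.numeric(a), -1), 1)
    rd <- reward_and_done(s, a, t, started, config)
    started <- rd$started
    rec[i, ] <- c(t, s, a, o, rd$reward, rd$done)
    if (rd$done == 1) {
      rec <- rec[seq_len(i), , drop = FALSE]
      break
    }
    s <- env_step(s, a, config, t = t + config$dt, profile = profile,
                  noise = noise)
  }
  ep <- as.data.frame(rec)
  attr(ep, "config") <- config
  attr(ep, "profile") <- profile
  attr(ep, "seed") <- seed
  attr(ep, "left_arena") <-
    any(sqrt(ep$x^2 + ep$y^2) > config$arena_radius)
  class(ep) <- c("firefly_episode", "data.frame")
  ep
}

#' Mirror an episode across the y axis
#'
#' Reflection across the y axis negates `x`, `gx` and `o_gx`, reflects the
#' heading about 90 degrees (`theta -> 180 - theta`), and negates the angular
#' velocity, angular action and angular observation. Linear components,
#' rewards and done flags are unchanged. The mirrored episode is itself
#' dynamically consistent: replaying the mirrored actions against the mirrored
#' target (noise off) reproduces the mirrored state sequence. Mirroring is an
#' involution.
#'
#' @param episode a `firefly_episode`.
#' @return the mirrored episode (attributes preserved).
#' @export
mirror_episode <- function(episode) {
  m <- episode
  m$x <- -episode$x
  m$gx <- -episode$gx
  m$o_gx <- -episode$o_gx
  m$theta <- 180 - episode$theta
  m$omega <- -episode$omega
  m$a_omega <- -episode$a_omega
  m$o_omega <- -episode$o_omega
  m
}

#' Write or read episode tables as CSV
#'
#' One table per trial with exactly the spec'd column order; metadata
#' (config, perturbation, seed) goes to a JSON sidecar when `sidecar = TRUE`.
#'
#' @param episode a `firefly_episode`.
#' @param path CSV file path.
#' @param sidecar write `<path>.json` with config/profile/seed metadata.
#' @export
write_episode <- function(episode, path, sidecar = TRUE) {
  utils::write.csv(as.data.frame(episode)[, episode_columns], path,
                   row.names = FALSE)
  if (sidecar) {
    cfg <- attr(episode, "config")
    prof <- attr(episode, "profile")
    meta <- list(config = if (!is.null(cfg)) unclass(cfg),
                 profile = if (!is.null(prof)) unclass(prof),
                 seed = attr(episode, "seed"))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_episode
#' @export
read_episode <- function(path) {
  ep <- utils::read.csv(path)
  stopifnot(identical(names(ep), episode_columns))
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$config)) attr(ep, "config") <- do.call(task_config, meta$config)
    if (!is.null(meta$profile)) attr(ep, "profile") <- do.call(perturbation_profile, meta$profile)
    attr(ep, "seed") <- meta$seed
  }
  class(ep) <- c("firefly_episode", "data.frame")
  ep
}
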