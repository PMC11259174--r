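# Training driver and the vectorized multi-trial rollout engine for
# belief-input (EKF) policies.
#
# Structure exploited throughout (and cross-checked against the generic
# predict/update in the tests): because the velocity rows of the transition
# Jacobian are zero and only velocities are observed, the posterior
# covariance always has a zero pose-velocity block and a constant velocity
# block (I - K) Sigma_a_vel, while the 3x3 pose/heading block grows by dead
# reckoning. Only that pose block differs across trials.

# constant posterior velocity variances and Kalman gain
ekf_constants <- function(noise) {
  K <- kalman_gain_schedule(noise)
  k <- c(K[4, 1], K[5, 2])
  va <- diag(noise$Sigma_a)[4:5]
  list(k = k, d_post = (1 - k) * va, va = va)
}

# order of the packed 3x3 pose-block entries within the 15-entry packed P:
# (1,1),(1,2),(1,3) -> 1,2,3 ; (2,2),(2,3) -> 6,7 ; (3,3) -> 10
POSE_PACK_IDX <- c(1L, 2L, 3L, 6L, 7L, 10L)
VEL_PACK_IDX <- c(13L, 15L) # (4,4) and (5,5)

# advance the packed pose covariance (n x 6: p11,p12,p13,p22,p23,p33) one
# prediction step; v, th are the belief's current velocity (cm/s) and heading
# (deg); d22 length-2: the velocity variances feeding the step.
pose_cov_step <- function(Ppose, v, th_deg, dt, d22) {
  thr <- deg2rad(th_deg)
  d2r <- pi / 180
  b1 <- -dt * v * sin(thr) * d2r
  b2 <- dt * v * cos(thr) * d2r
  p11 <- Ppose[, 1]; p12 <- Ppose[, 2]; p13 <- Ppose[, 3]
  p22 <- Ppose[, 4]; p23 <- Ppose[, 5]; p33 <- Ppose[, 6]
  cv <- cos(thr); sv <- sin(thr)
  cbind(
    p11 + 2 * b1 * p13 + b1^2 * p33 + dt^2 * cv^2 * d22[1],
    p12 + b1 * p23 + b2 * p13 + b1 * b2 * p33 + dt^2 * cv * sv * d22[1],
    p13 + b1 * p33,
    p22 + 2 * b2 * p23 + b2^2 * p33 + dt^2 * sv^2 * d22[1],
    p23 + b2 * p33,
    p33 + dt^2 * d22[2]
  )
}

#' Vectorized rollout of a belief-input policy over many trials
#'
#' Runs `n` independent trials simultaneously: the environment (possibly a
#' gain/perturbation/test-uncertainty variant) advances under the policy's
#' actions while the agent's internal EKF -- defined by `agent_config` and
#' `agent_noise`, i.e. the *training-time* model when testing under novel
#' conditions -- tracks the belief whose features feed the policy.
#'
#' @param policy function mapping an `n x 20` belief-feature matrix to an
#'   `n x 2` action matrix (e.g. a trained actor or [scripted_controller()]).
#' @param n number of trials (ignored when `targets` given).
#' @param env_config [task_config()] governing the true environment.
#' @param agent_config internal-model config (defaults to `env_config`);
#'   the belief always uses this gain and dt.
#' @param agent_noise [noise_model()] used for the Kalman gain and
#'   covariance features; defaults to `agent_config`'s ground truth. Pass
#'   the training-time model to freeze the gain at its training value.
#' @param targets optional `n x 2` target matrix.
#' @param profiles optional perturbation parameters: a list with vectors
#'   `t_p`, `p_v_peak`, `p_omega_peak` of length `n`.
#' @param sigma_exp exploration noise SD (0 = deterministic testing).
#' @param record `"none"`, `"traj"` (states), or `"full"` (states +
#'   belief features + actions + rewards, for TD-error and decoding work).
#' @return list of class `ekf_rollout`: per-trial summary `trials`
#'   (data.frame: target, stop, reward, rewarded, stopped, steps,
#'   duration_s) and, if recorded, `traj` / `feats` / `actions` arrays with
#'   attribute `steps` giving each trial's length.
#' @export
rollout_ekf_trials <- function(policy, n = 100,
                               env_config = task_config(),
                               agent_config = env_config,
                               agent_noise = config_noise_model(agent_config),
                               targets = NULL, profiles = NULL,
                               sigma_exp = 0, record = "none") {
  cfg <- env_config
  if (is.null(targets)) targets <- sample_target(n, cfg)
  n <- nrow(targets)
  dt <- cfg$dt
  max_steps <- floor(cfg$max_duration / dt) + 1L
  nG_env <- cfg$gain_multiplier * cfg$gain
  nG_agent <- agent_config$gain_multiplier * agent_config$gain
  sd_a <- process_noise_sd(cfg)
  sd_o <- obs_noise_sd(cfg)
  kc <- ekf_constants(agent_noise)
  a_star <- cfg$action_threshold

  # environment state
  S <- cbind(x = numeric(n), y = numeric(n), theta = rep(90, n),
             v = numeric(n), omega = numeric(n),
             gx = targets[, 1], gy = targets[, 2])
  # belief: mean (relative coords) + pose covariance block
  Bm <- cbind(-targets[, 1], -targets[, 2], rep(90, n), numeric(n), numeric(n))
  Ppose <- matrix(EKF_EPS, n, 6)
  Ppose[, c(2, 3, 5)] <- 0
  vel_var <- rep(EKF_EPS, 2) # at t=0 the velocity variance is epsilon

  started <- rep(FALSE, n)
  active <- rep(TRUE, n)
  stop_xy <- matrix(NA_real_, n, 2)
  reward <- numeric(n)
  rewarded <- logical(n)
  stopped_flag <- logical(n)
  steps <- rep(max_steps, n)

  rec_traj <- record %in% c("traj", "full")
  rec_full <- record == "full"
  if (rec_traj) traj <- array(NA_real_, c(max_steps, n, 5),
                              dimnames = list(NULL, NULL,
                                              c("x", "y", "theta", "v", "omega")))
  if (rec_full) {
    feats_arr <- array(NA_real_, c(max_steps, n, 20))
    act_arr <- array(NA_real_, c(max_steps, n, 2))
    rew_arr <- matrix(0, max_steps, n)
    done_arr <- matrix(0, max_steps, n)
  }

  pscale <- belief_scales(agent_config)
  pack_scale <- pscale[pack_index[, "row"]] * pscale[pack_index[, "col"]]

  for (ti in seq_len(max_steps)) {
    t_now <- (ti - 1) * dt
    idx <- which(active)
    if (!length(idx)) break
    # features for active trials
    P_packed <- matrix(0, length(idx), 15)
    P_packed[, POSE_PACK_IDX] <- Ppose[idx, , drop = FALSE]
    vv <- if (ti == 1L) rep(EKF_EPS, 2) else kc$d_post
    P_packed[, VEL_PACK_IDX[1]] <- vv[1]
    P_packed[, VEL_PACK_IDX[2]] <- vv[2]
    feats <- belief_features(Bm[idx, , drop = FALSE], P_packed, agent_config)
    a_hat <- policy(feats)
    a <- if (sigma_exp > 0) explore_action(a_hat, sigma_exp, a_star) else
      pmin(pmax(a_hat, -1), 1)
    if (rec_traj) traj[ti, idx, ] <- S[idx, 1:5]
    if (rec_full) {
      feats_arr[ti, idx, ] <- feats
      act_arr[ti, idx, ] <- a
    }
    # stop / timeout bookkeeping
    below <- abs(a[, 1]) < a_star & abs(a[, 2]) < a_star
    stopping <- started[idx] & below
    timeout <- (t_now + dt) > cfg$max_duration + 1e-9
    ending <- stopping | timeout
    if (any(ending)) {
      eidx <- idx[ending]
      stop_xy[eidx, ] <- S[eidx, 1:2, drop = FALSE]
      d2 <- (S[eidx, 1] - S[eidx, 6])^2 + (S[eidx, 2] - S[eidx, 7])^2
      r <- ifelse(sqrt(d2) < cfg$reward_radius, cfg$reward_amplitude,
                  cfg$reward_amplitude *
                    exp(-0.5 * d2 / (cfg$reward_radius / 1.5)^2))
      r[!stopping[ending]] <- 0 # timeouts earn nothing
      reward[eidx] <- r
      rewarded[eidx] <- stopping[ending] &
        sqrt(d2) < cfg$reward_radius
      stopped_flag[eidx] <- stopping[ending]
      steps[eidx] <- ti
      if (rec_full) {
        rew_arr[ti, eidx] <- r
        done_arr[ti, eidx] <- 1
      }
      active[eidx] <- FALSE
    }
    started[idx] <- started[idx] | !below
    live <- idx[!ending]
    if (!length(live)) next
    la <- a[!ending, , drop = FALSE]
    # environment step
    thr <- deg2rad(S[live, 3])
    S[live, 1] <- S[live, 1] + dt * S[live, 4] * cos(thr)
    S[live, 2] <- S[live, 2] + dt * S[live, 4] * sin(thr)
    S[live, 3] <- S[live, 3] + dt * S[live, 5]
    pv <- c(0, 0)
    if (!is.null(profiles)) {
      envl <- exp(-0.5 * ((t_now + dt - profiles$t_p[live]) / 0.2)^2)
      envl[abs(t_now + dt - profiles$t_p[live]) > 0.5] <- 0
      S[live, 4] <- nG_env[1] * la[, 1] + profiles$p_v_peak[live] * envl
      S[live, 5] <- nG_env[2] * la[, 2] + profiles$p_omega_peak[live] * envl
    } else {
      S[live, 4] <- nG_env[1] * la[, 1]
      S[live, 5] <- nG_env[2] * la[, 2]
    }
    if (sd_a[1] > 0) {
      S[live, 4] <- S[live, 4] + stats::rnorm(length(live), 0, sd_a[1])
      S[live, 5] <- S[live, 5] + stats::rnorm(length(live), 0, sd_a[2])
    }
    # observation of the new state's velocities (t+dt > 0, so noisy)
    o_v <- S[live, 4]
    o_om <- S[live, 5]
    if (sd_o[1] > 0) {
      o_v <- o_v + stats::rnorm(length(live), 0, sd_o[1])
      o_om <- o_om + stats::rnorm(length(live), 0, sd_o[2])
    }
    # belief predict (internal model: agent's own gain, no perturbation)
    d22 <- if (ti == 1L) rep(EKF_EPS, 2) else kc$d_post
    Ppose[live, ] <- pose_cov_step(Ppose[live, , drop = FALSE],
                                   Bm[live, 4], Bm[live, 3], dt, d22)
    thb <- deg2rad(Bm[live, 3])
    Bm[live, 1] <- Bm[live, 1] + dt * Bm[live, 4] * cos(thb)
    Bm[live, 2] <- Bm[live, 2] + dt * Bm[live, 4] * sin(thb)
    Bm[live, 3] <- Bm[live, 3] + dt * Bm[live, 5]
    v_pred <- nG_agent[1] * la[, 1]
    om_pred <- nG_agent[2] * la[, 2]
    # belief update (frozen constant gain)
    Bm[live, 4] <- v_pred + kc$k[1] * (o_v - v_pred)
    Bm[live, 5] <- om_pred + kc$k[2] * (o_om - om_pred)
  }

  trials <- data.frame(
    gx = targets[, 1], gy = targets[, 2],
    stop_x = stop_xy[, 1], stop_y = stop_xy[, 2],
    reward = reward, rewarded = rewarded, stopped = stopped_flag,
    steps = steps, duration_s = steps * dt
  )
  out <- list(trials = trials)
  if (rec_traj) out$traj <- traj
  if (rec_full) {
    out$feats <- feats_arr
    out$actions <- act_arr
    out$rewards <- rew_arr
    out$dones <- done_arr
  }
  out$steps <- steps
  class(out) <- "ekf_rollout"
  out
}

## ---- training --------------------------------------------------------------

actor_policy <- function(actor) {
  if (actor$kind == "ekf") {
    flat <- mlp_flat(actor$modules$mlp)
    function(feats) cpp_mlp3_fwd(feats, flat, TRUE)
  } else {
    stop("use run_episode() with an actor controller for recurrent policies")
  }
}

#' Controller closure wrapping a recurrent actor for [run_episode()]
#'
#' Maintains the hidden state and the efference copy across the trial
#' (both reset to zeros at trial start, per the reset contract).
#'
#' @param actor a recurrent `ff_actor`.
#' @param config [task_config()] used for input normalization.
#' @param sigma_exp exploration SD (0 for testing).
#' @param a_star action threshold.
#' @return function `(obs, t) -> action`.
#' @export
actor_controller <- function(actor, config, sigma_exp = 0, a_star = 0.1) {
  hidden <- NULL
  a_prev <- c(0, 0)
  function(obs, t) {
    feats <- obs_features(obs, a_prev, config)
    fw <- actor_forward(actor, feats, hidden)
    hidden <<- fw$hidden
    a_hat <- fw$action[1, ]
    a <- if (sigma_exp > 0) explore_action(a_hat, sigma_exp, a_star) else a_hat
    a_prev <<- a
    a
  }
}

phase_config <- function(config, schedule, phase) {
  cfg <- config
  if (!schedule$sigma_o_on[phase]) cfg$alpha_o <- 0
  cfg
}

validate_learner <- function(L, config, n_trials, record = "none") {
  if (L$mode == "ekf") {
    ro <- rollout_ekf_trials(actor_policy(L$actor), n = n_trials,
                             env_config = config, record = record)
    ro
  } else {
    res <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      ctrl <- actor_controller(L$actor, config, sigma_exp = 0)
      res[[i]] <- run_episode(ctrl, config)
    }
    trials <- do.call(rbind, lapply(res, function(ep) {
      last <- nrow(ep)
      data.frame(gx = ep$gx[1], gy = ep$gy[1],
                 stop_x = ep$x[last], stop_y = ep$y[last],
                 reward = ep$r[last],
                 rewarded = ep$r[last] >= attr(ep, "config")$reward_amplitude - 1e-9,
                 stopped = ep$r[last] > 0 ||
                   (abs(ep$a_v[last]) < config$action_threshold &&
                    abs(ep$a_omega[last]) < config$action_threshold),
                 steps = last, duration_s = last * config$dt)
    }))
    list(trials = trials, episodes = res)
  }
}

# mean |TD error| of critic 1 on freshly recorded validation data (ekf mode)
td_error_from_rollout <- function(L, ro) {
  stopifnot(L$mode == "ekf")
  n <- nrow(ro$trials)
  deltas <- c()
  feats <- ro$feats
  acts <- ro$actions
  F_list <- list(); A_list <- list(); R <- c(); D <- c(); NF_list <- list()
  for (i in seq_len(n)) {
    Tn <- ro$steps[i]
    f <- matrix(feats[seq_len(Tn), i, ], nrow = Tn)
    a <- matrix(acts[seq_len(Tn), i, ], nrow = Tn)
    nf <- rbind(f[-1, , drop = FALSE], f[Tn, , drop = FALSE])
    F_list[[i]] <- f; A_list[[i]] <- a; NF_list[[i]] <- nf
    R <- c(R, ro$rewards[seq_len(Tn), i])
    D <- c(D, ro$dones[seq_len(Tn), i])
  }
  Fm <- do.call(rbind, F_list)
  Am <- do.call(rbind, A_list)
  NFm <- do.call(rbind, NF_list)
  a_next <- mlp_forward(L$actor$modules$mlp, NFm)
  q_next <- as.numeric(mlp_forward(L$critic1$modules$mlp, cbind(NFm, a_next)))
  q <- as.numeric(mlp_forward(L$critic1$modules$mlp, cbind(Fm, Am)))
  mean(abs(R + (1 - D) * L$gamma * q_next - q))
}

learner_checkpoint <- function(L, trial, phase) {
  list(trial = trial, phase = phase,
       actor = net_params(L$actor),
       critic1 = net_params(L$critic1),
       critic2 = net_params(L$critic2))
}

#' Train a TD3 agent on the firefly task
#'
#' Runs the interaction/update loop with the three-phase schedule: phases
#' advance when validation accuracy (fraction of rewarded trials) crosses
#' 20% then 80%; observation noise is off in phase 1; exploration and
#' learning rates step at the phase boundaries. Critics update once per
#' `critic_period` environment steps (recurrent agents accumulate the due
#' updates and apply them at trial boundaries), the actor and targets once
#' per `actor_delay` critic updates. Every `checkpoint_every` trials the
#' agent is validated and its parameters checkpointed. Training stops
#' `trials_past_phase1` trials after phase 1 ends (or earlier if
#' `stop_accuracy` is reached, or at `max_trials`).
#'
#' @param spec an [agent_spec()].
#' @param config training-task [task_config()].
#' @param schedule a [train_schedule()].
#' @param seed integer; governs weight init, environment noise, exploration
#'   and buffer sampling.
#' @param max_trials hard cap on total trials.
#' @param verbose print per-validation progress lines.
#' @return object of class `td3_training`: the final `learner`,
#'   `checkpoints`, learning-`curve` data.frame
#'   (trial, phase, frac_rewarded, reward_rate, td_error), `phase_starts`.
#' @export
train_agent <- function(spec, config = task_config(),
                        schedule = train_schedule(), seed = spec$seed,
                        max_trials = 2e4, verbose = FALSE) {
  set.seed(seed)
  L <- td3_learner(spec, schedule, gamma = config$gamma,
                   a_star = config$action_threshold)
  is_ekf <- L$mode == "ekf"
  buf <- if (is_ekf) step_buffer(schedule$buffer_steps, BELIEF_INPUT_DIM)
         else traj_buffer(schedule$buffer_traj)
  phase <- 1L
  phase_starts <- c(1L, NA_integer_, NA_integer_)
  trials_in_phase2plus <- 0L
  curve <- list()
  checkpoints <- list()
  step_count <- 0L
  updates_done <- 0L
  batch_size <- if (is_ekf) schedule$batch_steps else schedule$batch_traj
  noise <- NULL
  refresh_noise <- function(phase) {
    cfgp <- phase_config(config, schedule, phase)
    config_noise_model(cfgp)
  }
  noise <- refresh_noise(phase)
  kc <- ekf_constants(noise)
  trial <- 0L
  divergence <- function(x, where, trial) {
    if (!all(is.finite(x))) {
      stop(sprintf("training diverged (%s non-finite) at trial %d", where,
                   trial))
    }
  }
  do_updates <- function(k) {
    for (u in seq_len(k)) {
      if ((if (is_ekf) buf$size else buf$size) < batch_size) return(invisible())
      batch <- if (is_ekf) buffer_sample(buf, batch_size)
               else traj_sample(buf, batch_size)
      loss <- td3_critic_update(L, batch)
      divergence(loss, "critic loss", trial)
      if (L$critic_updates %% schedule$actor_delay == 0L) {
        obj <- td3_actor_update(L, batch)
        divergence(obj, "actor objective", trial)
        td3_soft_updates(L)
      }
    }
  }

  repeat {
    trial <- trial + 1L
    cfgp <- phase_config(config, schedule, phase)
    sig_exp <- schedule$sigma_exp[phase]
    if (is_ekf) {
      res <- train_trial_ekf(L, buf, cfgp, noise, kc, sig_exp,
                             function(nsteps) {
                               step_count <<- step_count + nsteps
                               due <- step_count %/% schedule$critic_period
                               k <- due - updates_done
                               updates_done <<- due
                               do_updates(k)
                             })
    } else {
      res <- train_trial_rnn(L, buf, cfgp, sig_exp)
      step_count <- step_count + res$steps
      due <- step_count %/% schedule$critic_period
      do_updates(due - updates_done)
      updates_done <- due
    }
    if (phase > 1L) trials_in_phase2plus <- trials_in_phase2plus + 1L

    if (trial %% schedule$checkpoint_every == 0L) {
      val <- validate_learner(L, cfgp, schedule$validation_trials,
                              record = if (is_ekf) "full" else "none")
      acc <- mean(val$trials$rewarded)
      rrate <- sum(val$trials$rewarded) / sum(val$trials$duration_s)
      tde <- if (is_ekf) td_error_from_rollout(L, val) else NA_real_
      curve[[length(curve) + 1L]] <-
        data.frame(trial = trial, phase = phase, frac_rewarded = acc,
                   reward_rate = rrate, td_error = tde)
      checkpoints[[length(checkpoints) + 1L]] <-
        learner_checkpoint(L, trial, phase)
      if (verbose) {
        message(sprintf("trial %6d phase %d acc %.3f rate %.3f td %.3f",
                        trial, phase, acc, rrate, tde))
      }
      # phase transitions (monotone; lr never increases)
      new_phase <- phase
      if (phase == 1L && acc >= schedule$phase_thresholds[1]) new_phase <- 2L
      if (phase <= 2L && acc >= schedule$phase_thresholds[2]) new_phase <- 3L
      if (new_phase != phase) {
        phase <- new_phase
        phase_starts[phase] <- trial
        set_learning_rate(L, schedule$learning_rates[phase])
        noise <- refresh_noise(phase)
        kc <- ekf_constants(noise)
      }
      if (!is.null(schedule$stop_accuracy) && phase > 1L &&
          acc >= schedule$stop_accuracy) break
    }
    if (phase > 1L && trials_in_phase2plus >= schedule$trials_past_phase1) break
    if (trial >= max_trials) break
  }
  structure(list(spec = spec, config = config, schedule = schedule,
                 learner = L, checkpoints = checkpoints,
                 curve = do.call(rbind, curve), phase_starts = phase_starts,
                 seed = seed, trials = trial),
            class = "td3_training")
}

# one training trial, feedforward mode: sequential steps with belief
# tracking, buffer insertion (with mirrors) and periodic updates via hook.
train_trial_ekf <- function(L, buf, cfg, noise, kc, sig_exp, update_hook) {
  dt <- cfg$dt
  max_steps <- floor(cfg$max_duration / dt) + 1L
  target <- sample_target(1, cfg)[1, ]
  s <- initial_state(target)
  bm <- c(-target[1], -target[2], 90, 0, 0)
  Ppose <- c(EKF_EPS, 0, 0, EKF_EPS, 0, EKF_EPS)
  nG_a <- cfg$gain_multiplier * cfg$gain
  sd_a <- process_noise_sd(cfg)
  sd_o <- obs_noise_sd(cfg)
  started <- FALSE
  feats <- matrix(NA_real_, max_steps, 20)
  acts <- matrix(NA_real_, max_steps, 2)
  bs <- belief_scales(cfg)
  m_inv <- 1 / bs
  m_center <- c(0, 0, 90, 0, 0)
  pk_inv <- 1 / (bs[pack_index[, "row"]] * bs[pack_index[, "col"]])
  finish <- function(ti, r) {
    # transitions (i_t, a_t, r_t, i_{t+1}, D_t); the terminal next input is
    # the terminal input itself (its bootstrap is truncated by D = 1)
    F <- feats[seq_len(ti), , drop = FALSE]
    NF <- rbind(F[-1, , drop = FALSE], F[ti, , drop = FALSE])
    rew <- c(rep(0, ti - 1), r)
    don <- c(rep(0, ti - 1), 1)
    buffer_insert_chunk(buf, F, acts[seq_len(ti), , drop = FALSE], rew, NF,
                        don)
    update_hook(ti)
  }
  for (ti in seq_len(max_steps)) {
    t_now <- (ti - 1) * dt
    vv <- if (ti == 1L) rep(EKF_EPS, 2) else kc$d_post
    P_packed <- numeric(15)
    P_packed[POSE_PACK_IDX] <- Ppose
    P_packed[VEL_PACK_IDX] <- vv
    feat <- c((bm - m_center) * m_inv, P_packed * pk_inv)
    a_hat <- cpp_mlp3_fwd(matrix(feat, 1), mlp_flat(L$actor$modules$mlp),
                          TRUE)[1, ]
    a <- explore_action(a_hat, sig_exp, cfg$action_threshold)
    feats[ti, ] <- feat
    acts[ti, ] <- a
    below <- abs(a[1]) < cfg$action_threshold && abs(a[2]) < cfg$action_threshold
    stopping <- started && below
    timeout <- (t_now + dt) > cfg$max_duration + 1e-9
    if (stopping || timeout) {
      r <- 0
      if (stopping) {
        d2 <- (s[1] - s[6])^2 + (s[2] - s[7])^2
        r <- if (sqrt(d2) < cfg$reward_radius) cfg$reward_amplitude else
          cfg$reward_amplitude * exp(-0.5 * d2 / (cfg$reward_radius / 1.5)^2)
      }
      finish(ti, r)
      return(list(steps = ti, reward = r,
                  rewarded = stopping && r >= cfg$reward_amplitude - 1e-9))
    }
    started <- started || !below
    # env step
    thr <- deg2rad(s[3])
    s[1] <- s[1] + dt * s[4] * cos(thr)
    s[2] <- s[2] + dt * s[4] * sin(thr)
    s[3] <- s[3] + dt * s[5]
    s[4] <- nG_a[1] * a[1] + if (sd_a[1] > 0) stats::rnorm(1, 0, sd_a[1]) else 0
    s[5] <- nG_a[2] * a[2] + if (sd_a[2] > 0) stats::rnorm(1, 0, sd_a[2]) else 0
    o_v <- s[4] + if (sd_o[1] > 0) stats::rnorm(1, 0, sd_o[1]) else 0
    o_om <- s[5] + if (sd_o[2] > 0) stats::rnorm(1, 0, sd_o[2]) else 0
    # belief predict + update
    d22 <- if (ti == 1L) rep(EKF_EPS, 2) else kc$d_post
    Ppose <- pose_cov_step(matrix(Ppose, 1), bm[4], bm[3], dt, d22)[1, ]
    thb <- deg2rad(bm[3])
    bm[1] <- bm[1] + dt * bm[4] * cos(thb)
    bm[2] <- bm[2] + dt * bm[4] * sin(thb)
    bm[3] <- bm[3] + dt * bm[5]
    v_pred <- nG_a[1] * a[1]
    om_pred <- nG_a[2] * a[2]
    bm[4] <- v_pred + kc$k[1] * (o_v - v_pred)
    bm[5] <- om_pred + kc$k[2] * (o_om - om_pred)
  }
  list(steps = max_steps, reward = 0, rewarded = FALSE)
}

# one training trial, recurrent mode: run the exploring actor, store the
# whole trajectory (+ mirror) in the buffer.
train_trial_rnn <- function(L, buf, cfg, sig_exp) {
  hidden <- NULL
  a_prev <- c(0, 0)
  feats <- list(); acts <- list()
  ctrl <- function(obs, t) {
    f <- obs_features(obs, a_prev, cfg)
    fw <- actor_forward(L$actor, f, hidden)
    hidden <<- fw$hidden
    a <- explore_action(fw$action[1, ], sig_exp, cfg$action_threshold)
    feats[[length(feats) + 1L]] <<- f
    acts[[length(acts) + 1L]] <<- a
    a_prev <<- a
    a
  }
  ep <- run_episode(ctrl, cfg)
  traj <- list(feat = do.call(rbind, feats),
               action = do.call(rbind, acts),
               reward = ep$r, done = ep$done)
  traj_insert(buf, traj)
  last <- nrow(ep)
  list(steps = last, reward = ep$r[last],
       rewarded = ep$r[last] >= cfg$reward_amplitude - 1e-9)
}

#' Rebuild an actor from a stored checkpoint
#' @param training a `td3_training`.
#' @param checkpoint one element of `training$checkpoints`.
#' @return an `ff_actor` with the checkpoint's weights.
#' @export
checkpoint_actor <- function(training, checkpoint) {
  net_set_params(training$learner$actor, checkpoint$actor)
}

#' Select the best checkpoint by mean reward rate across test sets
#'
#' Every stored checkpoint is evaluated (without exploration noise) on each
#' test set; the checkpoint with the highest reward rate averaged across the
#' sets wins. Ties break deterministically to the earliest checkpoint.
#'
#' @param training a `td3_training` (EKF-mode).
#' @param test_sets list of test sets, each a list with `config` (a
#'   [task_config()]) and optional `profiles` (as in
#'   [rollout_ekf_trials()]).
#' @param trials_per_set evaluation trials per set.
#' @return list: `index`, `checkpoint`, `actor`, `rates` (checkpoint x set).
#' @export
select_checkpoint <- function(training, test_sets = list(list(config = training$config)),
                              trials_per_set = 500) {
  cps <- training$checkpoints
  if (!length(cps)) stop("no checkpoints to select from")
  rates <- matrix(NA_real_, length(cps), length(test_sets))
  for (i in seq_along(cps)) {
    actor <- checkpoint_actor(training, cps[[i]])
    pol <- actor_policy(actor)
    for (j in seq_along(test_sets)) {
      ts <- test_sets[[j]]
      ro <- rollout_ekf_trials(pol, n = trials_per_set, env_config = ts$config,
                               agent_config = training$config,
                               profiles = ts$profiles)
      rates[i, j] <- sum(ro$trials$rewarded) / sum(ro$trials$duration_s)
    }
  }
  mean_rate <- rowMeans(rates)
  best <- which(mean_rate >= max(mean_rate) - 1e-12)[1]
  list(index = best, checkpoint = cps[[best]],
       actor = checkpoint_actor(training, cps[[best]]), rates = rates)
}
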