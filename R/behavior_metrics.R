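# Behavioral analyses: psychometric/ROC stopping accuracy, signed radial
# error via idealized circular arcs, trajectory geometry, reward rate,
# test-time TD errors, and no-generalization counterfactual replays.

#' Arc length of the idealized circular trajectory to a point
#'
#' The circle through the origin with initial heading straight ahead (90
#' degrees) that passes through `(x, y)` has radius
#' `r = (x^2 + y^2) / (2 x)`; the arc from the origin to the point has length
#' `L = 2 r asin(sqrt(x^2 + y^2) / (2 r))`. The formula is even in `x`
#' (mirror trajectories have equal length) and approaches the straight-line
#' limit `L -> y` as `x -> 0`, which is handled explicitly.
#'
#' @param x,y endpoint coordinates, cm (vectorized).
#' @return arc length(s), cm.
#' @export
arc_length <- function(x, y) {
  if (any(x == 0 & y == 0)) stop("arc length undefined at the origin")
  ax <- abs(x)
  chord <- sqrt(x^2 + y^2)
  r <- chord^2 / (2 * ax)
  # asin argument chord / (2 r) = ax / chord
  L <- ifelse(ax < 1e-12 * pmax(chord, 1), abs(y),
              2 * r * asin(pmin(ax / chord, 1)))
  as.numeric(L)
}

#' Classify a stop as over- or undershooting the target
#'
#' Overshoot iff the stop's idealized arc length strictly exceeds the
#' target's; ties count as undershoot.
#'
#' @param stop,target length-2 points (or n x 2 matrices).
#' @return character vector `"overshoot"` / `"undershoot"`.
#' @export
classify_shoot <- function(stop, target) {
  S <- if (is.null(dim(stop))) matrix(stop, ncol = 2) else stop
  G <- if (is.null(dim(target))) matrix(target, ncol = 2) else target
  ifelse(arc_length(S[, 1], S[, 2]) > arc_length(G[, 1], G[, 2]),
         "overshoot", "undershoot")
}

#' Signed radial error
#'
#' Magnitude: Euclidean distance between stop and target. Sign: positive for
#' overshoot, negative for undershoot (idealized-arc comparison).
#'
#' @param stop,target `n x 2` matrices.
#' @return numeric vector, cm.
#' @export
radial_error <- function(stop, target) {
  S <- if (is.null(dim(stop))) matrix(stop, ncol = 2) else stop
  G <- if (is.null(dim(target))) matrix(target, ncol = 2) else target
  d <- sqrt(rowSums((S - G)^2))
  sgn <- ifelse(classify_shoot(S, G) == "overshoot", 1, -1)
  sgn * d
}

#' Psychometric curve, shuffled control, and ROC/AUC
#'
#' The psychometric curve is the fraction of trials whose stop lies within a
#' hypothetical reward boundary of the target, as a function of the boundary
#' radius. The control recomputes it after permuting targets across trials
#' (breaking any stop-target association). Plotting the true fraction
#' against the shuffled fraction over the same boundary grid traces an ROC
#' curve; its area (trapezoid rule, endpoints (0,0) and (1,1) appended) is 1
#' for a perfect stopper and 0.5 when stops are independent of targets.
#'
#' Trials that never stopped count as unrewarded at every boundary.
#'
#' @param stops `n x 2` stop locations (rows may be NA for no-stop trials).
#' @param targets `n x 2` target locations.
#' @param boundaries boundary grid, cm; default 60 log-spaced radii from 5
#'   to 400 cm.
#' @param perm optional permutation of `1:n` for the shuffle (defaults to a
#'   random permutation drawn from the current RNG state).
#' @return list of class `roc_result`: `boundaries`, `true_frac`,
#'   `shuffled_frac`, `auc`.
#' @export
psychometric_and_roc <- function(stops, targets,
                                 boundaries = exp(seq(log(5), log(400),
                                                      length.out = 60)),
                                 perm = sample.int(nrow(targets))) {
  if (!length(boundaries)) stop("empty boundary grid")
  S <- as.matrix(stops)
  G <- as.matrix(targets)
  d_true <- sqrt(rowSums((S - G)^2))
  d_shuf <- sqrt(rowSums((S - G[perm, , drop = FALSE])^2))
  d_true[is.na(d_true)] <- Inf
  d_shuf[is.na(d_shuf)] <- Inf
  true_frac <- vapply(boundaries, function(b) mean(d_true < b), numeric(1))
  shuf_frac <- vapply(boundaries, function(b) mean(d_shuf < b), numeric(1))
  xs <- c(0, shuf_frac, 1)
  ys <- c(0, true_frac, 1)
  o <- order(xs, ys)
  xs <- xs[o]; ys <- ys[o]
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  structure(list(boundaries = boundaries, true_frac = true_frac,
                 shuffled_frac = shuf_frac, auc = auc),
            class = "roc_result")
}

#' Trajectory length
#' @param xy `n x 2` matrix of positions.
#' @return total length (sum of segment norms), cm.
#' @export
trajectory_length <- function(xy) {
  d <- diff(as.matrix(xy))
  sum(sqrt(rowSums(d^2)))
}

#' Per-step trajectory curvature
#'
#' `k_t = |x' y'' - y' x''| / (x'^2 + y'^2)^(3/2)` with first-order one-sided
#' differences at the endpoints and second-order central differences inside.
#' Steps with (near) zero speed have undefined curvature; they are returned
#' as `NA` and their count is attached as attribute `dropped`.
#'
#' @param xy `n x 2` positions (resampled to a uniform time step upstream).
#' @param dt time step, s (cancels in the ratio; kept for clarity).
#' @return numeric vector of curvatures (1/cm) with attribute `dropped`.
#' @export
trajectory_curvature <- function(xy, dt = 0.1) {
  P <- as.matrix(xy)
  n <- nrow(P)
  if (n < 3) stop("need at least 3 points for curvature")
  d1 <- matrix(NA_real_, n, 2)
  d2 <- matrix(NA_real_, n, 2)
  d1[1, ] <- (P[2, ] - P[1, ]) / dt
  d1[n, ] <- (P[n, ] - P[n - 1, ]) / dt
  d1[2:(n - 1), ] <- (P[3:n, ] - P[1:(n - 2), ]) / (2 * dt)
  d2[1, ] <- (P[3, ] - 2 * P[2, ] + P[1, ]) / dt^2
  d2[n, ] <- (P[n, ] - 2 * P[n - 1, ] + P[n - 2, ]) / dt^2
  d2[2:(n - 1), ] <- (P[3:n, ] - 2 * P[2:(n - 1), ] + P[1:(n - 2), ]) / dt^2
  speed2 <- rowSums(d1^2)
  k <- abs(d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]) / speed2^1.5
  zero <- speed2 < 1e-12
  k[zero] <- NA_real_
  attr(k, "dropped") <- sum(zero)
  k
}

#' Trial-mean curvature with the 95th-percentile outlier rule
#'
#' Within each trial, step curvatures above that trial's 95th percentile are
#' excluded before averaging (undefined steps are dropped first).
#'
#' @param xy `n x 2` positions.
#' @param dt time step, s.
#' @return scalar mean curvature, 1/cm.
#' @export
curvature_trial_mean <- function(xy, dt = 0.1) {
  k <- trajectory_curvature(xy, dt)
  k <- k[!is.na(k)]
  q <- stats::quantile(k, 0.95, type = 7, names = FALSE)
  mean(k[k <= q])
}

#' Rewarded trials per second
#' @param trials data.frame with logical `rewarded` and `duration_s`.
#' @return rewarded count divided by total time, 1/s.
#' @export
reward_rate <- function(trials) {
  tot <- sum(trials$duration_s)
  if (tot <= 0) stop("zero total duration")
  sum(trials$rewarded) / tot
}

#' Test-time temporal-difference errors along a trajectory
#'
#' `|r_t + (1 - D_t) gamma Q1(i_{t+1}, a_{t+1}) - Q1(i_t, a_t)|` using only
#' the first critic and the trained actor for the next action -- no target
#' networks, no exploration noise. The bootstrap is truncated at the
#' terminal step, whose contribution is `|r - Q|`.
#'
#' @param traj list with `feat` (T x d), `action` (T x 2), `reward` (T),
#'   `done` (T).
#' @param actor an `ff_actor`, or a function `feat_matrix -> action matrix`.
#' @param critic an `ff_critic`, or a function
#'   `(feat_matrix, action_matrix) -> q vector`.
#' @param gamma temporal discount.
#' @return numeric vector of per-step absolute TD errors.
#' @export
td_error_eval <- function(traj, actor, critic, gamma = 0.97) {
  Tn <- nrow(traj$feat)
  nfeat <- rbind(traj$feat[-1, , drop = FALSE],
                 traj$feat[Tn, , drop = FALSE])
  feat_seq <- lapply(seq_len(Tn), function(t) traj$feat[t, , drop = FALSE])
  nfeat_seq <- lapply(seq_len(Tn), function(t) nfeat[t, , drop = FALSE])
  act_seq <- lapply(seq_len(Tn), function(t) traj$action[t, , drop = FALSE])
  if (inherits(actor, "ff_actor")) {
    a_next <- if (actor$kind == "ekf") {
      lapply(nfeat_seq, function(f) mlp_forward(actor$modules$mlp, f))
    } else actor_seq_eval(actor, nfeat_seq)
  } else {
    a_next <- lapply(nfeat_seq, function(f) {
      a <- actor(f)
      if (is.null(dim(a))) matrix(a, nrow = 1) else a
    })
  }
  q_of <- function(fs, as) {
    if (inherits(critic, "ff_critic")) {
      if (critic$kind == "ekf") {
        vapply(seq_along(fs), function(t)
          as.numeric(mlp_forward(critic$modules$mlp, cbind(fs[[t]], as[[t]]))),
          numeric(1))
      } else {
        vapply(critic_seq_eval(critic, fs, as), function(q) q[1], numeric(1))
      }
    } else {
      vapply(seq_along(fs), function(t)
        as.numeric(critic(fs[[t]], as[[t]])), numeric(1))
    }
  }
  q <- q_of(feat_seq, act_seq)
  q_next <- q_of(nfeat_seq, a_next)
  abs(traj$reward + (1 - traj$done) * gamma * q_next - q)
}

#' No-generalization counterfactual replay
#'
#' Replays a recorded training-task action sequence open loop through the
#' noise-free environment dynamics of a *novel* task configuration (higher
#' gain, or a perturbation profile): the trajectory a non-adapting agent
#' would produce.
#'
#' @param actions `N x 2` recorded actions `(a_v, a_omega)`.
#' @param target length-2 target for the regenerated trial.
#' @param config the novel task's [task_config()].
#' @param profile optional [perturbation_profile()].
#' @return data.frame with `t, x, y, theta, v, omega` of length `N + 1`.
#' @export
no_generalization_replay <- function(actions, target, config,
                                     profile = NULL) {
  A <- as.matrix(actions)
  s <- initial_state(target)
  n <- nrow(A)
  out <- matrix(NA_real_, n + 1, 6)
  colnames(out) <- c("t", "x", "y", "theta", "v", "omega")
  out[1, ] <- c(0, s[1:5])
  for (i in seq_len(n)) {
    s <- env_step(s, A[i, ], config, t = i * config$dt, profile = profile,
                  noise = FALSE)
    out[i + 1, ] <- c(i * config$dt, s[1:5])
  }
  as.data.frame(out)
}

#' Per-trial behavioral outcome table
#'
#' Convenience wrapper turning a rollout's trial summary into outcome rows:
#' signed radial error, over/undershoot class, reward flag and duration.
#'
#' @param trials trial summary (as in [rollout_ekf_trials()]`$trials`).
#' @return data.frame of per-trial outcomes.
#' @export
trial_outcomes <- function(trials) {
  stops <- cbind(trials$stop_x, trials$stop_y)
  targets <- cbind(trials$gx, trials$gy)
  ok <- !is.na(stops[, 1])
  err <- rep(NA_real_, nrow(trials))
  shoot <- rep(NA_character_, nrow(trials))
  if (any(ok)) {
    err[ok] <- radial_error(stops[ok, , drop = FALSE],
                            targets[ok, , drop = FALSE])
    shoot[ok] <- classify_shoot(stops[ok, , drop = FALSE],
                                targets[ok, , drop = FALSE])
  }
  data.frame(gx = trials$gx, gy = trials$gy,
             stop_x = trials$stop_x, stop_y = trials$stop_y,
             radial_error = err, shoot = shoot,
             rewarded = trials$rewarded, steps = trials$steps,
             duration_s = trials$duration_s)
}
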