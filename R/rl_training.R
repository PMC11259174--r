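# Twin-delayed deterministic policy gradient (TD3) in two flavors:
# feedforward on EKF beliefs (step-tuple replay) and recurrent with
# whole-trajectory replay and backpropagation through time.
#
# The feedforward path runs on single-precision C++ kernels (src/) for
# speed; the base-R implementations in nn_core.R are the reference and the
# tests hold the two routes together.

#' @useDynLib fireflynav, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# flat parameter layout (W1, b1, W2, b2, W3, b3) used by the C++ kernels
mlp_flat <- function(net) {
  l <- net$layers
  list(l[[1]]$W, l[[1]]$b, l[[2]]$W, l[[2]]$b, l[[3]]$W, l[[3]]$b)
}

mlp_set_flat <- function(net, flat) {
  for (i in 1:3) {
    net$layers[[i]]$W <- flat[[2 * i - 1]]
    b <- flat[[2 * i]]
    dim(b) <- NULL
    net$layers[[i]]$b <- b
  }
  net
}

#' Training schedule and hyperparameters
#'
#' Three phases split by validation accuracy (20% and 80% on 300 validation
#' trials): phase 1 has learning rate 3e-4, exploration SD 0.8 and the
#' observation noise switched off; phase 2 keeps the learning rate, lowers
#' exploration to 0.5 and switches observation noise on; phase 3 anneals the
#' learning rate to 5e-5 with exploration 0.4. Critics update once every
#' `critic_period = 4` environment interactions; the actor (and the target
#' networks) once every two critic updates; targets track online networks
#' with rate `tau = 0.005`. Batches: 256 step tuples (feedforward) or 16
#' equal-length trajectories (recurrent).
#'
#' @param learning_rates per-phase Adam learning rates.
#' @param sigma_exp per-phase exploration noise SD.
#' @param sigma_o_on per-phase flag: is observation noise active?
#' @param phase_thresholds accuracies that open phases 2 and 3.
#' @param critic_period environment steps per critic update.
#' @param actor_delay critic updates per actor/target update.
#' @param tau soft-update rate.
#' @param batch_steps step-tuple batch size (feedforward TD3).
#' @param batch_traj trajectory batch size (recurrent TD3).
#' @param buffer_steps step-tuple buffer capacity.
#' @param buffer_traj trajectory buffer capacity.
#' @param trials_past_phase1 stop this many trials after leaving phase 1.
#' @param checkpoint_every checkpoint/validation cadence in trials.
#' @param validation_trials trials per validation set.
#' @param smooth_sd,smooth_clip target-policy smoothing noise SD and clip.
#' @param grad_clip global-norm gradient clip for recurrent training
#'   (`Inf` disables; feedforward training never clips).
#' @param stop_accuracy optional early stop: end training at the first
#'   validation whose accuracy reaches this level (desk-scale budget guard).
#' @return list of class `train_schedule`.
#' @export
train_schedule <- function(learning_rates = c(3e-4, 3e-4, 5e-5),
                           sigma_exp = c(0.8, 0.5, 0.4),
                           sigma_o_on = c(FALSE, TRUE, TRUE),
                           phase_thresholds = c(0.2, 0.8),
                           critic_period = 4L,
                           actor_delay = 2L,
                           tau = 0.005,
                           batch_steps = 256L,
                           batch_traj = 16L,
                           buffer_steps = 1.6e6,
                           buffer_traj = 1e5,
                           trials_past_phase1 = 1e4,
                           checkpoint_every = 500L,
                           validation_trials = 300L,
                           smooth_sd = 0.05,
                           smooth_clip = 0.1,
                           grad_clip = 1,
                           stop_accuracy = NULL) {
  structure(as.list(environment()), class = "train_schedule")
}

#' Exploration noise around the actor's action
#'
#' Adds zero-mean Gaussian noise with SD `sigma_exp` and clips to
#' `[-1, 1]`, except that noise is suppressed whenever both components of
#' the deterministic action are already below the action threshold, so
#' intended stops stay stops.
#'
#' @param a_hat `M x 2` deterministic actions (or length-2 vector).
#' @param sigma_exp exploration SD.
#' @param a_star action threshold.
#' @return actions of the same shape.
#' @export
explore_action <- function(a_hat, sigma_exp, a_star = 0.1) {
  A <- if (is.null(dim(a_hat))) matrix(a_hat, nrow = 1) else a_hat
  stopping <- abs(A[, 1]) < a_star & abs(A[, 2]) < a_star
  noise <- matrix(stats::rnorm(length(A), 0, sigma_exp), nrow(A), 2)
  noise[stopping, ] <- 0
  out <- pmin(pmax(A + noise, -1), 1)
  if (is.null(dim(a_hat))) out[1, ] else out
}

#' Target-policy smoothing noise
#'
#' Clipped Gaussian noise (`SD 0.05`, clipped to `[-0.1, 0.1]`) added to the
#' target actor's action; the sum is clipped back to `[-1, 1]`.
#'
#' @param a_target `M x 2` target-actor actions.
#' @param sd,clip noise SD and clip bound.
#' @return smoothed actions, same shape.
#' @export
target_smoothed_action <- function(a_target, sd = 0.05, clip = 0.1) {
  A <- if (is.null(dim(a_target))) matrix(a_target, nrow = 1) else a_target
  noise <- matrix(stats::rnorm(length(A), 0, sd), nrow(A), 2)
  noise <- pmin(pmax(noise, -clip), clip)
  out <- pmin(pmax(A + noise, -1), 1)
  if (is.null(dim(a_target))) out[1, ] else out
}

## ---- replay buffers --------------------------------------------------------

#' Step-tuple replay buffer (FIFO)
#'
#' Circular buffer of `(i, a, r, i', D)` tuples. Every insertion stores the
#' tuple and its mirror image (reflection across the y axis), so the
#' insertion count is exactly twice the number of transitions seen. Storage
#' is split into fixed-size blocks so that R's copy-on-modify only ever
#' touches one small block per write (a single flat matrix in an environment
#' would be copied wholesale on every insertion).
#'
#' @param capacity maximum number of stored tuples.
#' @param feat_dim input feature dimension.
#' @return an environment (class `step_buffer`).
#' @export
step_buffer <- function(capacity = 1.6e6, feat_dim = 20L) {
  b <- new.env(parent = emptyenv())
  b$capacity <- as.integer(capacity)
  b$feat_dim <- as.integer(feat_dim)
  b$width <- feat_dim + 2L + 1L + feat_dim + 1L # feat, a, r, feat', D
  b$block_size <- 8192L
  b$n_blocks <- as.integer(ceiling(capacity / b$block_size))
  b$blocks <- vector("list", b$n_blocks)
  b$size <- 0L
  b$ptr <- 0L
  b$inserted <- 0L
  class(b) <- "step_buffer"
  b
}

buffer_put_rows <- function(b, rows) {
  n <- nrow(rows)
  done_rows <- 0L
  while (done_rows < n) {
    blk <- (b$ptr %/% b$block_size) + 1L
    off <- b$ptr %% b$block_size
    take <- min(n - done_rows, b$block_size - off, b$capacity - b$ptr)
    if (is.null(b$blocks[[blk]])) {
      b$blocks[[blk]] <- matrix(NA_real_, b$block_size, b$width)
    }
    b$blocks[[blk]][off + seq_len(take), ] <-
      rows[done_rows + seq_len(take), , drop = FALSE]
    done_rows <- done_rows + take
    b$ptr <- (b$ptr + take) %% b$capacity
  }
  b$size <- min(b$size + n, b$capacity)
  b$inserted <- b$inserted + n
  invisible(b)
}

# chunk insertion used by the training loop: a trial's worth of transitions
# plus their mirrors in one write.
buffer_insert_chunk <- function(b, feat, action, reward, next_feat, done) {
  mf <- belief_feature_mirror(feat)
  mn <- belief_feature_mirror(next_feat)
  ma <- sweep(action, 2, mirror_signs$action, "*")
  rows <- cbind(rbind(feat, mf), rbind(action, ma), c(reward, reward),
                rbind(next_feat, mn), c(done, done))
  buffer_put_rows(b, rows)
}

#' @param b a [step_buffer()].
#' @param feat,action,reward,next_feat,done one transition (vectors/scalars).
#' @rdname step_buffer
#' @export
buffer_insert <- function(b, feat, action, reward, next_feat, done) {
  buffer_insert_chunk(b, matrix(feat, 1), matrix(action, 1), reward,
                      matrix(next_feat, 1), done)
}

#' @param M batch size.
#' @rdname step_buffer
#' @export
buffer_sample <- function(b, M) {
  idx <- sample.int(b$size, M, replace = b$size < M) - 1L
  blk <- (idx %/% b$block_size) + 1L
  off <- (idx %% b$block_size) + 1L
  out <- matrix(NA_real_, M, b$width)
  for (k in unique(blk)) {
    sel <- blk == k
    out[sel, ] <- b$blocks[[k]][off[sel], , drop = FALSE]
  }
  d <- b$feat_dim
  list(feat = out[, seq_len(d), drop = FALSE],
       action = out[, d + (1:2), drop = FALSE],
       reward = out[, d + 3L],
       next_feat = out[, d + 3L + seq_len(d), drop = FALSE],
       done = out[, 2L * d + 4L])
}

#' Whole-trajectory replay buffer (FIFO)
#'
#' Stores complete trials (and their mirrors) keyed by duration. Sampling
#' first draws a duration with probability proportional to how many stored
#' trajectories have it, then draws a batch of equal-length trajectories
#' uniformly within that bucket.
#'
#' @param capacity maximum number of stored trajectories.
#' @return an environment; trajectories are lists with elements `feat`
#'   (T x d), `action` (T x 2), `reward` (T), `done` (T).
#' @export
traj_buffer <- function(capacity = 1e5) {
  b <- new.env(parent = emptyenv())
  b$capacity <- as.integer(capacity)
  b$items <- vector("list", capacity)
  b$len <- integer(capacity)
  b$size <- 0L
  b$ptr <- 0L
  b$inserted <- 0L
  class(b) <- "traj_buffer"
  b
}

#' @param b a [traj_buffer()].
#' @param traj a trajectory list (see [traj_buffer()]).
#' @param mirror_traj its mirror image.
#' @rdname traj_buffer
#' @export
traj_insert <- function(b, traj,
                        mirror_traj = mirror_trajectory(traj)) {
  for (tr in list(traj, mirror_traj)) {
    b$ptr <- (b$ptr %% b$capacity) + 1L
    b$items[[b$ptr]] <- tr
    b$len[b$ptr] <- nrow(tr$feat)
    b$size <- min(b$size + 1L, b$capacity)
    b$inserted <- b$inserted + 1L
  }
  invisible(b)
}

mirror_trajectory <- function(traj) {
  list(feat = obs_feature_mirror(traj$feat),
       action = sweep(traj$action, 2, mirror_signs$action, "*"),
       reward = traj$reward, done = traj$done)
}

#' @param M batch size (trajectories).
#' @rdname traj_buffer
#' @export
traj_sample <- function(b, M) {
  lens <- b$len[seq_len(b$size)]
  pick_len <- lens[sample.int(b$size, 1L)]
  pool <- which(lens == pick_len)
  idx <- pool[sample.int(length(pool), M, replace = length(pool) < M)]
  b$items[idx]
}

## ---- TD3 learner -----------------------------------------------------------

#' Create a TD3 learner
#'
#' Holds the actor, twin critics, their target copies, and Adam states in a
#' mutable environment. `mode` is `"ekf"` (feedforward networks on belief
#' features, step-tuple batches) or `"rnn"` (recurrent networks,
#' equal-length trajectory batches).
#'
#' @param spec an [agent_spec()].
#' @param schedule a [train_schedule()].
#' @param gamma temporal discount.
#' @param a_star action threshold (for exploration suppression).
#' @return learner environment of class `td3_learner`.
#' @export
td3_learner <- function(spec, schedule = train_schedule(), gamma = 0.97,
                        a_star = 0.1) {
  L <- new.env(parent = emptyenv())
  L$spec <- spec
  L$mode <- if (spec$actor_kind == "ekf") "ekf" else "rnn"
  L$schedule <- schedule
  L$gamma <- gamma
  L$a_star <- a_star
  L$actor <- build_actor(spec)
  L$critic1 <- build_critic(spec)
  L$critic2 <- build_critic(spec)
  L$t_actor <- L$actor
  L$t_critic1 <- L$critic1
  L$t_critic2 <- L$critic2
  lr <- schedule$learning_rates[1]
  if (L$mode == "ekf") {
    # flat layout consumed by the C++ kernels
    L$opt_actor <- adam_init(mlp_flat(L$actor$modules$mlp), lr = lr)
    L$opt_c1 <- adam_init(mlp_flat(L$critic1$modules$mlp), lr = lr)
    L$opt_c2 <- adam_init(mlp_flat(L$critic2$modules$mlp), lr = lr)
  } else {
    L$opt_actor <- adam_init(net_params(L$actor), lr = lr)
    L$opt_c1 <- adam_init(net_params(L$critic1), lr = lr)
    L$opt_c2 <- adam_init(net_params(L$critic2), lr = lr)
  }
  L$critic_updates <- 0L
  L$actor_updates <- 0L
  L$last_min_ok <- TRUE
  class(L) <- "td3_learner"
  L
}

set_learning_rate <- function(L, lr) {
  L$opt_actor$lr <- lr
  L$opt_c1$lr <- lr
  L$opt_c2$lr <- lr
  invisible(L)
}

clip_global_norm <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  nrm <- sqrt(sum(tree_flatten(grads)^2))
  if (nrm > max_norm) grads <- tree_map(function(g) g * (max_norm / nrm), grads)
  grads
}

## ---- feedforward (EKF) updates --------------------------------------------

#' One critic update (both twin critics)
#'
#' Regresses both critics onto the shared learning target
#' `y = r + (1 - D) * gamma * min_j Q'_j(i', a')`, where `a'` is the target
#' actor's smoothed action. The minimum over the twin target critics counters
#' maximization bias; the bootstrap is truncated at terminal transitions.
#' Recurrent mode unrolls full equal-length trajectories and averages the
#' squared error over time and batch.
#'
#' @param L a [td3_learner()].
#' @param batch from [buffer_sample()] (`"ekf"` mode) or [traj_sample()]
#'   (`"rnn"` mode).
#' @return the TD loss (mean squared error against the target), invisibly
#'   also recorded in the learner.
#' @export
td3_critic_update <- function(L, batch) {
  loss <- if (L$mode == "ekf") critic_update_ekf(L, batch)
          else critic_update_rnn(L, batch)
  L$critic_updates <- L$critic_updates + 1L
  loss
}

#' Bootstrap learning targets for a step-tuple batch
#'
#' `y = r + (1 - D) gamma min_j Q'_j(i', a')` with the target actor's
#' smoothed action: the twin minimum counters maximization bias and the
#' bootstrap is truncated at terminal transitions.
#'
#' @param L a [td3_learner()] in `"ekf"` mode.
#' @param batch from [buffer_sample()].
#' @return numeric vector of targets.
#' @export
td3_targets <- function(L, batch) {
  a_tgt <- cpp_mlp3_fwd(batch$next_feat, mlp_flat(L$t_actor$modules$mlp),
                        TRUE)
  a_smooth <- target_smoothed_action(a_tgt, L$schedule$smooth_sd,
                                     L$schedule$smooth_clip)
  Xn <- cbind(batch$next_feat, a_smooth)
  q1p <- cpp_mlp3_fwd(Xn, mlp_flat(L$t_critic1$modules$mlp), FALSE)
  q2p <- cpp_mlp3_fwd(Xn, mlp_flat(L$t_critic2$modules$mlp), FALSE)
  qmin <- pmin(q1p, q2p)
  L$last_min_ok <- all(qmin <= q1p + 1e-12) && all(qmin <= q2p + 1e-12)
  batch$reward + (1 - batch$done) * L$gamma * as.numeric(qmin)
}

# one Adam step through the C++ kernel; returns new flat params
flat_adam <- function(L, opt_nm, flat, grads, maximize = FALSE) {
  opt <- get(opt_nm, envir = L)
  opt$t <- opt$t + 1L
  st <- cpp_adam_step(flat, grads, opt$m, opt$v, opt$t, opt$lr,
                      opt$beta1, opt$beta2, opt$eps, maximize)
  opt$m <- st$m
  opt$v <- st$v
  assign(opt_nm, opt, envir = L)
  st$params
}

critic_update_ekf <- function(L, batch) {
  y <- td3_targets(L, batch)
  X <- cbind(batch$feat, batch$action)
  loss <- 0
  for (nm in c("critic1", "critic2")) {
    cr <- get(nm, envir = L)
    flat <- mlp_flat(cr$modules$mlp)
    res <- cpp_critic_loss_grads(X, y, flat)
    loss <- loss + res$loss
    opt_nm <- if (nm == "critic1") "opt_c1" else "opt_c2"
    new_flat <- flat_adam(L, opt_nm, flat, res$grads)
    cr$modules$mlp <- mlp_set_flat(cr$modules$mlp, new_flat)
    assign(nm, cr, envir = L)
  }
  loss / 2
}

#' One actor update (and nothing else)
#'
#' Gradient ascent on the first critic's value of the actor's own action;
#' the critic's weights are left untouched. In recurrent mode the gradient
#' is backpropagated through time through both the critic's and the actor's
#' recurrences.
#'
#' @inheritParams td3_critic_update
#' @return the objective `mean(Q1)` before the update.
#' @export
td3_actor_update <- function(L, batch) {
  obj <- if (L$mode == "ekf") actor_update_ekf(L, batch)
         else actor_update_rnn(L, batch)
  L$actor_updates <- L$actor_updates + 1L
  obj
}

actor_update_ekf <- function(L, batch) {
  flat <- mlp_flat(L$actor$modules$mlp)
  res <- cpp_actor_obj_grads(batch$feat, flat,
                             mlp_flat(L$critic1$modules$mlp))
  new_flat <- flat_adam(L, "opt_actor", flat, res$grads, maximize = TRUE)
  L$actor$modules$mlp <- mlp_set_flat(L$actor$modules$mlp, new_flat)
  res$objective
}

#' Soft-update all target networks
#' @param L a [td3_learner()].
#' @export
td3_soft_updates <- function(L) {
  tau <- L$schedule$tau
  L$t_actor <- net_set_params(L$t_actor,
    soft_update(net_params(L$actor), net_params(L$t_actor), tau))
  L$t_critic1 <- net_set_params(L$t_critic1,
    soft_update(net_params(L$critic1), net_params(L$t_critic1), tau))
  L$t_critic2 <- net_set_params(L$t_critic2,
    soft_update(net_params(L$critic2), net_params(L$t_critic2), tau))
  invisible(L)
}

## ---- recurrent sequence forward/backward ----------------------------------

# Stack a list of T matrices (M x d) into (T*M) x d.
stack_seq <- function(seq) do.call(rbind, seq)
unstack_seq <- function(X, Tn) {
  M <- nrow(X) / Tn
  lapply(seq_len(Tn), function(t) X[((t - 1) * M + 1):(t * M), , drop = FALSE])
}

actor_seq_forward <- function(actor, feat_seq) {
  m <- actor$modules
  Tn <- length(feat_seq)
  switch(actor$kind,
    holistic = {
      fw <- lstm_forward_seq(m$rnn, feat_seq, cache = TRUE)
      Hs <- stack_seq(fw$hs)
      hf <- mlp_forward(m$head, Hs, cache = TRUE)
      list(actions = unstack_seq(hf$out, Tn), rnn = fw, head = hf, Tn = Tn)
    },
    two_recurrent = {
      f1 <- lstm_forward_seq(m$rnn1, feat_seq, cache = TRUE)
      f2 <- lstm_forward_seq(m$rnn2, f1$hs, cache = TRUE)
      Hs <- stack_seq(f2$hs)
      hf <- mlp_forward(m$head, Hs, cache = TRUE)
      list(actions = unstack_seq(hf$out, Tn), rnn1 = f1, rnn2 = f2,
           head = hf, Tn = Tn)
    },
    modular = {
      fw <- lstm_forward_seq(m$rnn, feat_seq, cache = TRUE)
      Hs <- stack_seq(fw$hs)
      hf <- mlp_forward(m$mlp, Hs, cache = TRUE)
      list(actions = unstack_seq(hf$out, Tn), rnn = fw, head = hf, Tn = Tn)
    },
    stop("ekf actors have no sequence mode"))
}

# dA_seq: list of M x 2 gradients on each action. Returns parameter grads.
actor_seq_backward <- function(actor, fw, dA_seq) {
  m <- actor$modules
  dAs <- stack_seq(dA_seq)
  switch(actor$kind,
    holistic = ,
    modular = {
      head_nm <- if (actor$kind == "holistic") "head" else "mlp"
      bh <- mlp_backward(m[[head_nm]], fw$head, dAs)
      dH_seq <- unstack_seq(bh$dX, fw$Tn)
      br <- lstm_backward_seq(m$rnn, fw$rnn$caches, dH_seq)
      out <- list(rnn = br$grads)
      out[[head_nm]] <- bh$grads
      out
    },
    two_recurrent = {
      bh <- mlp_backward(m$head, fw$head, dAs)
      dH2 <- unstack_seq(bh$dX, fw$Tn)
      b2 <- lstm_backward_seq(m$rnn2, fw$rnn2$caches, dH2)
      b1 <- lstm_backward_seq(m$rnn1, fw$rnn1$caches, b2$dX_seq)
      list(rnn1 = b1$grads, rnn2 = b2$grads, head = bh$grads)
    })
}

critic_seq_forward <- function(critic, feat_seq, action_seq) {
  m <- critic$modules
  Tn <- length(feat_seq)
  switch(critic$kind,
    holistic = {
      xs <- Map(cbind, feat_seq, action_seq)
      fw <- lstm_forward_seq(m$rnn, xs, cache = TRUE)
      hf <- mlp_forward(m$head, stack_seq(fw$hs), cache = TRUE)
      list(q = unstack_seq(hf$out, Tn), rnn = fw, head = hf, Tn = Tn)
    },
    two_recurrent = {
      xs <- Map(cbind, feat_seq, action_seq)
      f1 <- lstm_forward_seq(m$rnn1, xs, cache = TRUE)
      f2 <- lstm_forward_seq(m$rnn2, f1$hs, cache = TRUE)
      hf <- mlp_forward(m$head, stack_seq(f2$hs), cache = TRUE)
      list(q = unstack_seq(hf$out, Tn), rnn1 = f1, rnn2 = f2, head = hf,
           Tn = Tn)
    },
    rnn_mlp_action_both = {
      xs <- Map(cbind, feat_seq, action_seq)
      fw <- lstm_forward_seq(m$rnn, xs, cache = TRUE)
      ha <- Map(cbind, fw$hs, action_seq)
      hf <- mlp_forward(m$mlp, stack_seq(ha), cache = TRUE)
      list(q = unstack_seq(hf$out, Tn), rnn = fw, head = hf, Tn = Tn)
    },
    two_recurrent_action_second = {
      f1 <- lstm_forward_seq(m$rnn1, feat_seq, cache = TRUE)
      xs2 <- Map(cbind, f1$hs, action_seq)
      f2 <- lstm_forward_seq(m$rnn2, xs2, cache = TRUE)
      hf <- mlp_forward(m$head, stack_seq(f2$hs), cache = TRUE)
      list(q = unstack_seq(hf$out, Tn), rnn1 = f1, rnn2 = f2, head = hf,
           Tn = Tn)
    },
    modular = {
      fw <- lstm_forward_seq(m$rnn, feat_seq, cache = TRUE)
      ha <- Map(cbind, fw$hs, action_seq)
      hf <- mlp_forward(m$mlp, stack_seq(ha), cache = TRUE)
      list(q = unstack_seq(hf$out, Tn), rnn = fw, head = hf, Tn = Tn)
    })
}

# dq_seq: list of M x 1 gradients on q_t. Returns grads + dAction_seq.
critic_seq_backward <- function(critic, fw, dq_seq) {
  m <- critic$modules
  dqs <- stack_seq(dq_seq)
  w <- function(x) ncol(x) # helper
  switch(critic$kind,
    holistic = {
      bh <- mlp_backward(m$head, fw$head, dqs)
      br <- lstm_backward_seq(m$rnn, fw$rnn$caches, unstack_seq(bh$dX, fw$Tn))
      dA <- lapply(br$dX_seq, function(dx)
        dx[, OBS_INPUT_DIM + (1:2), drop = FALSE])
      list(grads = list(rnn = br$grads, head = bh$grads), dA_seq = dA)
    },
    two_recurrent = {
      bh <- mlp_backward(m$head, fw$head, dqs)
      b2 <- lstm_backward_seq(m$rnn2, fw$rnn2$caches, unstack_seq(bh$dX, fw$Tn))
      b1 <- lstm_backward_seq(m$rnn1, fw$rnn1$caches, b2$dX_seq)
      dA <- lapply(b1$dX_seq, function(dx)
        dx[, OBS_INPUT_DIM + (1:2), drop = FALSE])
      list(grads = list(rnn1 = b1$grads, rnn2 = b2$grads, head = bh$grads),
           dA_seq = dA)
    },
    rnn_mlp_action_both = {
      H <- m$rnn$hidden_size
      bh <- mlp_backward(m$mlp, fw$head, dqs)
      dHA <- unstack_seq(bh$dX, fw$Tn)
      dH_seq <- lapply(dHA, function(x) x[, 1:H, drop = FALSE])
      dA_mlp <- lapply(dHA, function(x) x[, H + (1:2), drop = FALSE])
      br <- lstm_backward_seq(m$rnn, fw$rnn$caches, dH_seq)
      dA <- Map(function(dx, da) dx[, OBS_INPUT_DIM + (1:2), drop = FALSE] + da,
                br$dX_seq, dA_mlp)
      list(grads = list(rnn = br$grads, mlp = bh$grads), dA_seq = dA)
    },
    two_recurrent_action_second = {
      H <- m$rnn1$hidden_size
      bh <- mlp_backward(m$head, fw$head, dqs)
      b2 <- lstm_backward_seq(m$rnn2, fw$rnn2$caches, unstack_seq(bh$dX, fw$Tn))
      dH1 <- lapply(b2$dX_seq, function(x) x[, 1:H, drop = FALSE])
      dA <- lapply(b2$dX_seq, function(x) x[, H + (1:2), drop = FALSE])
      b1 <- lstm_backward_seq(m$rnn1, fw$rnn1$caches, dH1)
      list(grads = list(rnn1 = b1$grads, rnn2 = b2$grads, head = bh$grads),
           dA_seq = dA)
    },
    modular = {
      H <- m$rnn$hidden_size
      bh <- mlp_backward(m$mlp, fw$head, dqs)
      dHA <- unstack_seq(bh$dX, fw$Tn)
      dH_seq <- lapply(dHA, function(x) x[, 1:H, drop = FALSE])
      dA <- lapply(dHA, function(x) x[, H + (1:2), drop = FALSE])
      br <- lstm_backward_seq(m$rnn, fw$rnn$caches, dH_seq)
      list(grads = list(rnn = br$grads, mlp = bh$grads), dA_seq = dA)
    })
}

# run a recurrent net over a sequence without caches; returns q_seq or a_seq
critic_seq_eval <- function(critic, feat_seq, action_seq) {
  lapply(critic_seq_forward(critic, feat_seq, action_seq)$q, as.numeric)
}
actor_seq_eval <- function(actor, feat_seq) {
  actor_seq_forward(actor, feat_seq)$actions
}

## ---- recurrent updates -----------------------------------------------------

# batch: list of trajectories with equal length T.
rnn_batch_arrays <- function(batch) {
  Tn <- nrow(batch[[1]]$feat)
  if (!all(vapply(batch, function(tr) nrow(tr$feat), integer(1)) == Tn)) {
    stop("recurrent batch requires equal-length trajectories")
  }
  M <- length(batch)
  feat_seq <- lapply(seq_len(Tn), function(t)
    do.call(rbind, lapply(batch, function(tr) tr$feat[t, , drop = FALSE])))
  act_seq <- lapply(seq_len(Tn), function(t)
    do.call(rbind, lapply(batch, function(tr) tr$action[t, , drop = FALSE])))
  rew <- vapply(batch, function(tr) tr$reward, numeric(Tn))
  don <- vapply(batch, function(tr) tr$done, numeric(Tn))
  if (Tn == 1L) { rew <- matrix(rew, 1); don <- matrix(don, 1) }
  list(feat_seq = feat_seq, act_seq = act_seq,
       reward = rew, done = don, Tn = Tn, M = M)
}

critic_update_rnn <- function(L, batch) {
  ba <- rnn_batch_arrays(batch)
  Tn <- ba$Tn; M <- ba$M
  # next-step inputs: shift by one; the terminal next step is a zero pad
  # (its bootstrap is truncated by the done flag).
  zero_feat <- ba$feat_seq[[1]] * 0
  zero_act <- ba$act_seq[[1]] * 0
  nfeat_seq <- c(ba$feat_seq[-1], list(zero_feat))
  # target actions along the shifted sequence: unroll the target actor over
  # the full next-input sequence (hidden state advanced from t = 0).
  a_tgt_full <- actor_seq_eval(L$t_actor, nfeat_seq)
  a_smooth <- lapply(a_tgt_full, function(a)
    target_smoothed_action(a, L$schedule$smooth_sd, L$schedule$smooth_clip))
  q1p <- critic_seq_eval(L$t_critic1, nfeat_seq, a_smooth)
  q2p <- critic_seq_eval(L$t_critic2, nfeat_seq, a_smooth)
  y <- matrix(0, Tn, M)
  for (t in seq_len(Tn)) {
    qmin <- pmin(q1p[[t]], q2p[[t]])
    y[t, ] <- ba$reward[t, ] + (1 - ba$done[t, ]) * L$gamma * qmin
  }
  loss <- 0
  for (nm in c("critic1", "critic2")) {
    cr <- get(nm, envir = L)
    fw <- critic_seq_forward(cr, ba$feat_seq, ba$act_seq)
    err <- matrix(0, Tn, M)
    for (t in seq_len(Tn)) err[t, ] <- as.numeric(fw$q[[t]]) - y[t, ]
    loss <- loss + mean(err^2)
    dq_seq <- lapply(seq_len(Tn), function(t)
      matrix(2 * err[t, ] / (Tn * M), ncol = 1))
    bk <- critic_seq_backward(cr, fw, dq_seq)
    grads <- clip_global_norm(bk$grads, L$schedule$grad_clip)
    opt_nm <- if (nm == "critic1") "opt_c1" else "opt_c2"
    st <- adam_step(get(opt_nm, envir = L), net_params(cr), grads)
    assign(opt_nm, st$opt, envir = L)
    assign(nm, net_set_params(cr, st$params), envir = L)
  }
  loss / 2
}

actor_update_rnn <- function(L, batch) {
  ba <- rnn_batch_arrays(batch)
  Tn <- ba$Tn; M <- ba$M
  fa <- actor_seq_forward(L$actor, ba$feat_seq)
  fq <- critic_seq_forward(L$critic1, ba$feat_seq, fa$actions)
  obj <- mean(vapply(fq$q, mean, numeric(1)))
  dq_seq <- lapply(seq_len(Tn), function(t) matrix(1 / (Tn * M), M, 1))
  bq <- critic_seq_backward(L$critic1, fq, dq_seq)
  ga <- actor_seq_backward(L$actor, fa, bq$dA_seq)
  ga <- clip_global_norm(ga, L$schedule$grad_clip)
  st <- adam_step(L$opt_actor, net_params(L$actor), ga, maximize = TRUE)
  L$opt_actor <- st$opt
  L$actor <- net_set_params(L$actor, st$params)
  obj
}
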