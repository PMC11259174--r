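# Actor and critic families with graded module specialization. Specialization
# is structural, enforced by wiring: memory (and therefore belief computation)
# exists only in recurrent modules, and in critics 4/5 the action enters only
# the second module, so value computation cannot occur before action
# injection -- the interface offers no path for it.

ACTOR_KINDS <- c("holistic", "two_recurrent", "modular", "ekf")
CRITIC_KINDS <- c("holistic", "two_recurrent", "rnn_mlp_action_both",
                  "two_recurrent_action_second", "modular", "ekf")

#' Agent architecture descriptor
#'
#' Actors: 1 = holistic (one gated-recurrent module), 2 = two recurrent
#' modules in sequence, 3 = modular (recurrent module followed by a
#' feedforward module), `"ekf"` = feedforward on the EKF belief (mean +
#' packed covariance). Critics: 1 = holistic, 2 = two recurrent modules
#' (action into the first), 3 = recurrent + feedforward with the action
#' visible to both modules, 4 = two recurrent modules with the action routed
#' only into the second, 5 = modular (recurrent + feedforward, action only
#' into the feedforward module), `"ekf"` = feedforward on belief + action.
#'
#' Default widths: holistic networks use a single 220-unit gated-recurrent
#' module; all multi-module variants use 128-unit recurrent modules and
#' two-layer feedforward modules of 300 rectified units, which keeps total
#' trainable parameter counts within about 10% across critic variants.
#'
#' @param actor_kind actor architecture: 1:3 or one of
#'   `"holistic"`, `"two_recurrent"`, `"modular"`, `"ekf"`.
#' @param critic_kind critic architecture: 1:5 or a name above, or `"ekf"`.
#' @param holistic_width recurrent units in holistic networks.
#' @param recurrent_width recurrent units per module in multi-module nets.
#' @param ff_widths hidden sizes of feedforward modules.
#' @param seed integer; seeds weight initialization (and, in training, all
#'   randomness tied to this agent).
#' @return object of class `agent_spec`.
#' @export
agent_spec <- function(actor_kind = "modular", critic_kind = "modular",
                       holistic_width = 220, recurrent_width = 128,
                       ff_widths = c(300, 300), seed = 1L) {
  if (is.numeric(actor_kind)) actor_kind <- ACTOR_KINDS[actor_kind]
  if (is.numeric(critic_kind)) critic_kind <- CRITIC_KINDS[critic_kind]
  actor_kind <- match.arg(actor_kind, ACTOR_KINDS)
  critic_kind <- match.arg(critic_kind, CRITIC_KINDS)
  structure(list(actor_kind = actor_kind, critic_kind = critic_kind,
                 holistic_width = holistic_width,
                 recurrent_width = recurrent_width,
                 ff_widths = ff_widths, seed = as.integer(seed)),
            class = "agent_spec")
}

# input dims: recurrent nets see {o_t (4), a_{t-1} (2)}; EKF nets see the
# belief mean (5) + packed upper-triangular covariance (15).
OBS_INPUT_DIM <- 6L
BELIEF_INPUT_DIM <- 20L
ACTION_DIM <- 2L

linear_head <- function(nin, nout, tanh_out) {
  mlp_create(c(nin, nout), out_act = if (tanh_out) "tanh" else "linear")
}

#' Build an actor network from a spec
#'
#' Weights are initialized fan-in uniform under the spec's seed (actors and
#' critics consume independent substreams).
#'
#' @param spec an [agent_spec()].
#' @return object of class `ff_actor` with a `modules` list.
#' @export
build_actor <- function(spec) {
  k <- spec$actor_kind
  w <- spec$recurrent_width
  mods <- switch(k,
    holistic = list(
      rnn = lstm_create(OBS_INPUT_DIM, spec$holistic_width),
      head = linear_head(spec$holistic_width, ACTION_DIM, TRUE)),
    two_recurrent = list(
      rnn1 = lstm_create(OBS_INPUT_DIM, w),
      rnn2 = lstm_create(w, w),
      head = linear_head(w, ACTION_DIM, TRUE)),
    modular = list(
      rnn = lstm_create(OBS_INPUT_DIM, w),
      mlp = mlp_create(c(w, spec$ff_widths, ACTION_DIM), out_act = "tanh")),
    ekf = list(
      mlp = mlp_create(c(BELIEF_INPUT_DIM, spec$ff_widths, ACTION_DIM),
                       out_act = "tanh"))
  )
  structure(list(kind = k, modules = mods, spec = spec), class = "ff_actor")
}

#' Build a critic network from a spec
#' @param spec an [agent_spec()].
#' @return object of class `ff_critic`.
#' @export
build_critic <- function(spec) {
  k <- spec$critic_kind
  w <- spec$recurrent_width
  mods <- switch(k,
    holistic = list(
      rnn = lstm_create(OBS_INPUT_DIM + ACTION_DIM, spec$holistic_width),
      head = linear_head(spec$holistic_width, 1, FALSE)),
    two_recurrent = list(
      rnn1 = lstm_create(OBS_INPUT_DIM + ACTION_DIM, w),
      rnn2 = lstm_create(w, w),
      head = linear_head(w, 1, FALSE)),
    rnn_mlp_action_both = list(
      rnn = lstm_create(OBS_INPUT_DIM + ACTION_DIM, w),
      mlp = mlp_create(c(w + ACTION_DIM, spec$ff_widths, 1))),
    two_recurrent_action_second = list(
      rnn1 = lstm_create(OBS_INPUT_DIM, w),
      rnn2 = lstm_create(w + ACTION_DIM, w),
      head = linear_head(w, 1, FALSE)),
    modular = list(
      rnn = lstm_create(OBS_INPUT_DIM, w),
      mlp = mlp_create(c(w + ACTION_DIM, spec$ff_widths, 1))),
    ekf = list(
      mlp = mlp_create(c(BELIEF_INPUT_DIM + ACTION_DIM, spec$ff_widths, 1)))
  )
  structure(list(kind = k, modules = mods, spec = spec), class = "ff_critic")
}

net_params <- function(net) {
  lapply(net$modules, function(m) {
    if (inherits(m, "ff_mlp")) list(layers = m$layers)
    else list(W = m$W, b = m$b)
  })
}

net_set_params <- function(net, params) {
  for (nm in names(net$modules)) {
    if (inherits(net$modules[[nm]], "ff_mlp")) {
      net$modules[[nm]]$layers <- params[[nm]]$layers
    } else {
      net$modules[[nm]]$W <- params[[nm]]$W
      net$modules[[nm]]$b <- params[[nm]]$b
    }
  }
  net
}

#' Fresh (all-zero) hidden state for a network
#'
#' At the start of a trial the hidden state of every recurrent module and the
#' previous action are zeros; feedforward networks have no state (`NULL`
#' entries).
#'
#' @param net an `ff_actor` or `ff_critic`.
#' @param batch batch size.
#' @return named list with `h`/`c` matrices per recurrent module.
#' @export
init_hidden <- function(net, batch = 1L) {
  out <- list()
  for (nm in names(net$modules)) {
    m <- net$modules[[nm]]
    if (inherits(m, "ff_lstm")) {
      out[[nm]] <- list(h = matrix(0, batch, m$hidden_size),
                        c = matrix(0, batch, m$hidden_size))
    }
  }
  out
}

check_dim <- function(x, expected, what) {
  if (ncol(x) != expected) {
    stop(sprintf("%s: expected %d input columns, got %d", what, expected,
                 ncol(x)))
  }
}

#' Actor forward pass
#'
#' Recurrent actors take `inputs = cbind(o_t, a_{t-1})` (normalized) and a
#' hidden state; the EKF actor takes belief features and ignores the hidden
#' state. Outputs are bounded to `(-1, 1)` by a hyperbolic tangent and are
#' deterministic given weights, inputs and hidden state.
#'
#' @param actor an `ff_actor`.
#' @param inputs `M x d` input matrix (or a vector for `M = 1`).
#' @param hidden state from [init_hidden()] / a previous call.
#' @return list `action` (`M x 2`), `hidden`.
#' @export
actor_forward <- function(actor, inputs, hidden = NULL) {
  X <- if (is.null(dim(inputs))) matrix(inputs, nrow = 1) else inputs
  if (is.null(hidden) || !length(hidden)) hidden <- init_hidden(actor, nrow(X))
  m <- actor$modules
  switch(actor$kind,
    ekf = {
      check_dim(X, BELIEF_INPUT_DIM, "ekf actor")
      list(action = mlp_forward(m$mlp, X), hidden = hidden)
    },
    holistic = {
      check_dim(X, OBS_INPUT_DIM, "holistic actor")
      st <- lstm_step(m$rnn, X, hidden$rnn$h, hidden$rnn$c)
      list(action = mlp_forward(m$head, st$h),
           hidden = list(rnn = list(h = st$h, c = st$c)))
    },
    two_recurrent = {
      check_dim(X, OBS_INPUT_DIM, "two-recurrent actor")
      s1 <- lstm_step(m$rnn1, X, hidden$rnn1$h, hidden$rnn1$c)
      s2 <- lstm_step(m$rnn2, s1$h, hidden$rnn2$h, hidden$rnn2$c)
      list(action = mlp_forward(m$head, s2$h),
           hidden = list(rnn1 = list(h = s1$h, c = s1$c),
                         rnn2 = list(h = s2$h, c = s2$c)))
    },
    modular = {
      check_dim(X, OBS_INPUT_DIM, "modular actor")
      st <- lstm_step(m$rnn, X, hidden$rnn$h, hidden$rnn$c)
      list(action = mlp_forward(m$mlp, st$h),
           hidden = list(rnn = list(h = st$h, c = st$c)))
    }
  )
}

#' Critic forward pass
#'
#' For critic kinds 1-3 the action joins the first module's input (kind 3
#' additionally feeds it to the feedforward module); for kinds 4 and 5 the
#' action is routed only into the second module -- by construction there is
#' no input path for it into the first. The value is produced by a linear
#' unit without any nonlinearity.
#'
#' @param critic an `ff_critic`.
#' @param inputs `M x d` state-related inputs.
#' @param action `M x 2` actions.
#' @param hidden recurrent state.
#' @return list `q` (length-M numeric), `hidden`.
#' @export
critic_forward <- function(critic, inputs, action, hidden = NULL) {
  X <- if (is.null(dim(inputs))) matrix(inputs, nrow = 1) else inputs
  A <- if (is.null(dim(action))) matrix(action, nrow = 1) else action
  if (is.null(hidden) || !length(hidden)) hidden <- init_hidden(critic, nrow(X))
  m <- critic$modules
  res <- switch(critic$kind,
    ekf = {
      check_dim(X, BELIEF_INPUT_DIM, "ekf critic")
      list(q = mlp_forward(m$mlp, cbind(X, A)), hidden = hidden)
    },
    holistic = {
      st <- lstm_step(m$rnn, cbind(X, A), hidden$rnn$h, hidden$rnn$c)
      list(q = mlp_forward(m$head, st$h),
           hidden = list(rnn = list(h = st$h, c = st$c)))
    },
    two_recurrent = {
      s1 <- lstm_step(m$rnn1, cbind(X, A), hidden$rnn1$h, hidden$rnn1$c)
      s2 <- lstm_step(m$rnn2, s1$h, hidden$rnn2$h, hidden$rnn2$c)
      list(q = mlp_forward(m$head, s2$h),
           hidden = list(rnn1 = list(h = s1$h, c = s1$c),
                         rnn2 = list(h = s2$h, c = s2$c)))
    },
    rnn_mlp_action_both = {
      st <- lstm_step(m$rnn, cbind(X, A), hidden$rnn$h, hidden$rnn$c)
      list(q = mlp_forward(m$mlp, cbind(st$h, A)),
           hidden = list(rnn = list(h = st$h, c = st$c)))
    },
    two_recurrent_action_second = {
      check_dim(X, OBS_INPUT_DIM, "critic 4 first module (no action path)")
      s1 <- lstm_step(m$rnn1, X, hidden$rnn1$h, hidden$rnn1$c)
      s2 <- lstm_step(m$rnn2, cbind(s1$h, A), hidden$rnn2$h, hidden$rnn2$c)
      list(q = mlp_forward(m$head, s2$h),
           hidden = list(rnn1 = list(h = s1$h, c = s1$c),
                         rnn2 = list(h = s2$h, c = s2$c)))
    },
    modular = {
      check_dim(X, OBS_INPUT_DIM, "modular critic first module (no action path)")
      st <- lstm_step(m$rnn, X, hidden$rnn$h, hidden$rnn$c)
      list(q = mlp_forward(m$mlp, cbind(st$h, A)),
           hidden = list(rnn = list(h = st$h, c = st$c)))
    }
  )
  res$q <- as.numeric(res$q)
  res
}

lstm_param_count <- function(nin, H) 4 * ((nin + H) * H + H)
mlp_param_count <- function(sizes) {
  sum(vapply(seq_len(length(sizes) - 1),
             function(i) sizes[i] * sizes[i + 1] + sizes[i + 1], numeric(1)))
}

#' Count trainable parameters of an architecture
#'
#' Closed-form count (weights + biases) from the architecture description;
#' agrees with the element count of a built network's parameter tree. Critic
#' variants 1-5 are designed to land within about 10% of each other.
#'
#' @param x an [agent_spec()], `ff_actor`, or `ff_critic`.
#' @param which for a spec: `"actor"` or `"critic"`.
#' @return integer parameter count.
#' @export
count_parameters <- function(x, which = c("critic", "actor")) {
  if (inherits(x, c("ff_actor", "ff_critic"))) {
    return(as.integer(tree_count(net_params(x))))
  }
  which <- match.arg(which)
  w <- x$recurrent_width
  hw <- x$holistic_width
  ff <- x$ff_widths
  n <- if (which == "actor") {
    switch(x$actor_kind,
      holistic = lstm_param_count(OBS_INPUT_DIM, hw) +
        mlp_param_count(c(hw, ACTION_DIM)),
      two_recurrent = lstm_param_count(OBS_INPUT_DIM, w) +
        lstm_param_count(w, w) + mlp_param_count(c(w, ACTION_DIM)),
      modular = lstm_param_count(OBS_INPUT_DIM, w) +
        mlp_param_count(c(w, ff, ACTION_DIM)),
      ekf = mlp_param_count(c(BELIEF_INPUT_DIM, ff, ACTION_DIM)))
  } else {
    switch(x$critic_kind,
      holistic = lstm_param_count(OBS_INPUT_DIM + ACTION_DIM, hw) +
        mlp_param_count(c(hw, 1)),
      two_recurrent = lstm_param_count(OBS_INPUT_DIM + ACTION_DIM, w) +
        lstm_param_count(w, w) + mlp_param_count(c(w, 1)),
      rnn_mlp_action_both = lstm_param_count(OBS_INPUT_DIM + ACTION_DIM, w) +
        mlp_param_count(c(w + ACTION_DIM, ff, 1)),
      two_recurrent_action_second = lstm_param_count(OBS_INPUT_DIM, w) +
        lstm_param_count(w + ACTION_DIM, w) + mlp_param_count(c(w, 1)),
      modular = lstm_param_count(OBS_INPUT_DIM, w) +
        mlp_param_count(c(w + ACTION_DIM, ff, 1)),
      ekf = mlp_param_count(c(BELIEF_INPUT_DIM + ACTION_DIM, ff, 1)))
  }
  as.integer(n)
}

## ---- input construction ----------------------------------------------------

# normalization scales: positions by 400 cm, angle (centered on 90 deg) by
# 90 deg, velocities by the multiplied gain. Covariance entries are scaled by
# the products of the corresponding scales.
belief_scales <- function(config) {
  nG <- config$gain_multiplier * config$gain
  c(400, 400, 90, nG[1], nG[2])
}

pack_index <- local({
  idx <- which(upper.tri(matrix(0, 5, 5), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, "row"], idx[, "col"]), ]
})

#' Belief features for EKF-input networks
#'
#' Normalized belief mean (5) plus the packed upper-triangular covariance
#' (15), 20 inputs total. Operates on batches: `means` is `N x 5`, `P_packed`
#' is `N x 15` (see [pack_cov()]).
#'
#' @param means belief means (`N x 5` or length-5 vector).
#' @param P_packed packed covariances (`N x 15` or length-15).
#' @param config the agent's internal-model [task_config()].
#' @return `N x 20` feature matrix.
#' @export
belief_features <- function(means, P_packed, config) {
  M <- if (is.null(dim(means))) matrix(means, nrow = 1) else means
  P <- if (is.null(dim(P_packed))) matrix(P_packed, nrow = 1) else P_packed
  s <- belief_scales(config)
  Mn <- cbind(M[, 1] / s[1], M[, 2] / s[2], (M[, 3] - 90) / s[3],
              M[, 4] / s[4], M[, 5] / s[5])
  pscale <- s[pack_index[, "row"]] * s[pack_index[, "col"]]
  Pn <- P * rep(1 / pscale, each = nrow(P))
  cbind(Mn, Pn)
}

# sign flips implementing reflection across the y axis, in feature space:
# x and the centered heading and angular velocity flip sign; covariance
# entries flip by the product of their coordinate signs; the angular action
# flips.
mirror_signs <- local({
  ms <- c(-1, 1, -1, 1, -1)
  list(mean = ms,
       P = ms[pack_index[, "row"]] * ms[pack_index[, "col"]],
       action = c(1, -1))
})

belief_feature_mirror <- function(feats) {
  sweep(feats, 2, c(mirror_signs$mean, mirror_signs$P), "*")
}

#' Observation features for recurrent networks
#'
#' `cbind(o_v, o_omega, o_gx, o_gy, a_prev)` normalized: velocities by the
#' multiplied gain, positions by 400 cm; the efference copy is already
#' dimensionless.
#'
#' @param obs observation row(s) from [observe()] (`N x 5` or length-5).
#' @param a_prev previous action(s) (`N x 2` or length-2).
#' @param config a [task_config()].
#' @return `N x 6` feature matrix.
#' @export
obs_features <- function(obs, a_prev, config) {
  O <- if (is.null(dim(obs))) matrix(obs, nrow = 1) else obs
  A <- if (is.null(dim(a_prev))) matrix(a_prev, nrow = 1) else a_prev
  nG <- config$gain_multiplier * config$gain
  cbind(O[, 1] / nG[1], O[, 2] / nG[2], O[, 3] / 400, O[, 4] / 400, A)
}

obs_feature_mirror <- function(feats) {
  sweep(feats, 2, c(1, -1, -1, 1, 1, -1), "*")
}
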