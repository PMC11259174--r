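tiny_spec <- function(actor = "ekf", critic = "ekf", seed = 1) {
  agent_spec(actor_kind = actor, critic_kind = critic, holistic_width = 10,
             recurrent_width = 8, ff_widths = c(24, 24), seed = seed)
}
tiny_schedule <- function(...) {
  train_schedule(batch_steps = 32L, batch_traj = 4L, checkpoint_every = 10L,
                 validation_trials = 20L, ...)
}

test_that("exploration noise respects the stop-suppression rule and bounds", {
  set.seed(11)
  # below-threshold actions pass through unchanged
  expect_equal(explore_action(c(0.05, -0.02), sigma_exp = 0.8), c(0.05, -0.02))
  # saturated actions stay within the box
  A <- matrix(1, 1e4, 2)
  out <- explore_action(A, sigma_exp = 0.8)
  expect_true(all(out <= 1 & out >= -1))
  # moment check in a clip-free regime
  A2 <- matrix(0.2, 1e5, 2)
  out2 <- explore_action(A2, sigma_exp = 0.1)
  expect_equal(stats::sd(out2[, 1]), 0.1, tolerance = 0.02)
  expect_equal(mean(out2[, 1]), 0.2, tolerance = 0.01)
})

test_that("target-policy smoothing adds clipped noise with the analytic SD", {
  set.seed(12)
  # degenerate SD: output unchanged
  expect_equal(target_smoothed_action(c(0.3, -0.4), sd = 1e-12), c(0.3, -0.4))
  # clipped-Gaussian SD via numeric integration (independent oracle)
  sd0 <- 0.05; cl <- 0.1
  ex2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, 0, sd0),
                          -cl, cl)$value + 2 * cl^2 * stats::pnorm(-cl / sd0)
  A <- matrix(0, 1e5, 2)
  out <- target_smoothed_action(A)
  expect_equal(stats::sd(out[, 1]), sqrt(ex2), tolerance = 0.02)
  expect_equal(sqrt(ex2), 0.0485, tolerance = 0.02)
  expect_true(all(abs(out) <= cl))
})

test_that("step buffer: mirror doubling, FIFO eviction, sane sampling", {
  b <- step_buffer(capacity = 6, feat_dim = 20)
  f1 <- seq_len(20) / 20
  buffer_insert(b, f1, c(0.5, 0.25), 1, f1 * 2, 0)
  expect_equal(b$inserted, 2L) # the tuple and its mirror
  expect_equal(b$size, 2L)
  s <- buffer_sample(b, 2)
  expect_equal(dim(s$feat), c(2, 20))
  # mirrored row: feature signs flipped per the reflection, a_omega negated
  rows <- b$blocks[[1]][1:2, ]
  expect_equal(rows[2, 1:20],
               as.numeric(fireflynav:::belief_feature_mirror(rbind(f1))))
  expect_equal(rows[2, 21:22], c(0.5, -0.25))
  # FIFO: capacity 6 keeps only the 6 newest of 8 inserted
  for (i in 2:4) buffer_insert(b, f1 * i, c(0, 0), i, f1, 0)
  expect_equal(b$size, 6L)
  expect_equal(b$inserted, 8L)
})

test_that("trajectory buffer stores mirrors and samples equal lengths", {
  b <- traj_buffer(capacity = 50)
  set.seed(13)
  mk <- function(Tn) list(feat = matrix(rnorm(Tn * 6), Tn),
                          action = matrix(runif(Tn * 2, -1, 1), Tn),
                          reward = rep(0, Tn), done = c(rep(0, Tn - 1), 1))
  for (Tn in c(3, 3, 5, 5, 5, 8)) traj_insert(b, mk(Tn))
  expect_equal(b$inserted, 12L)
  for (i in 1:20) {
    batch <- traj_sample(b, 4)
    lens <- vapply(batch, function(tr) nrow(tr$feat), integer(1))
    expect_true(all(lens == lens[1]))
  }
  # mirrored trajectory flips the angular action and observation features
  tr <- mk(3)
  m <- fireflynav:::mirror_trajectory(tr)
  expect_equal(m$action[, 1], tr$action[, 1])
  expect_equal(m$action[, 2], -tr$action[, 2])
  expect_equal(m$feat[, 2], -tr$feat[, 2])
  expect_equal(m$reward, tr$reward)
})

test_that("bootstrap targets truncate at done and use the twin minimum", {
  set.seed(14)
  L <- td3_learner(tiny_spec(), tiny_schedule(smooth_sd = 1e-12))
  # force constant target critics: zero weights, known biases 3 and 5
  for (nm in c("t_critic1", "t_critic2")) {
    net <- get(nm, envir = L)
    nl <- length(net$modules$mlp$layers)
    for (li in seq_len(nl)) {
      net$modules$mlp$layers[[li]]$W[] <- 0
      net$modules$mlp$layers[[li]]$b[] <- 0
    }
    net$modules$mlp$layers[[nl]]$b <- if (nm == "t_critic1") 3 else 5
    assign(nm, net, envir = L)
  }
  batch <- list(feat = matrix(rnorm(4 * 20), 4),
                action = matrix(0.5, 4, 2),
                reward = c(0, 1, 10, 2),
                next_feat = matrix(rnorm(4 * 20), 4),
                done = c(0, 0, 1, 0))
  y <- td3_targets(L, batch)
  expect_equal(y, c(0 + 0.97 * 3, 1 + 0.97 * 3, 10, 2 + 0.97 * 3))
  expect_true(L$last_min_ok)
})

test_that("critic updates converge to the tabular optimum on a 2-step MDP", {
  set.seed(15)
  L <- td3_learner(tiny_spec(), tiny_schedule())
  # deterministic chain: s0 -> s1 -> terminal, rewards 0 then 10,
  # independent of the action, so Q*(s1) = 10, Q*(s0) = 9.7
  f0 <- rep(0.1, 20); f1 <- rep(-0.2, 20)
  batch <- list(feat = rbind(matrix(f0, 16, 20, byrow = TRUE),
                             matrix(f1, 16, 20, byrow = TRUE)),
                action = matrix(runif(64, -1, 1), 32),
                reward = c(rep(0, 16), rep(10, 16)),
                next_feat = rbind(matrix(f1, 16, 20, byrow = TRUE),
                                  matrix(f1, 16, 20, byrow = TRUE)),
                done = c(rep(0, 16), rep(1, 16)))
  for (i in 1:3500) {
    td3_critic_update(L, batch)
    td3_soft_updates(L)
  }
  fireflynav:::set_learning_rate(L, 3e-5) # settle the fit
  for (i in 1:2000) {
    td3_critic_update(L, batch)
    td3_soft_updates(L)
  }
  q0 <- critic_forward(L$critic1, matrix(f0, 1), matrix(0.3, 1, 2))$q
  q1 <- critic_forward(L$critic1, matrix(f1, 1), matrix(0.3, 1, 2))$q
  expect_equal(q1, 10, tolerance = 1e-2)
  expect_equal(q0, 9.7, tolerance = 1e-2)
})

test_that("actor ascent: quadratic-bowl oracle drives the action to 0.3", {
  set.seed(16)
  actor <- build_actor(tiny_spec())
  opt <- adam_init(fireflynav:::net_params(actor), lr = 3e-3)
  X <- matrix(rnorm(8 * 20), 8)
  for (i in 1:800) {
    fw <- fireflynav:::mlp_forward(actor$modules$mlp, X, cache = TRUE)
    dA <- -2 * (fw$out - 0.3) / nrow(X) # d/da of -(a - 0.3)^2
    bk <- fireflynav:::mlp_backward(actor$modules$mlp, fw, dA)
    st <- adam_step(opt, fireflynav:::net_params(actor),
                    list(mlp = bk$grads), maximize = TRUE)
    opt <- st$opt
    actor <- fireflynav:::net_set_params(actor, st$params)
  }
  out <- actor_forward(actor, X)$action
  expect_equal(as.numeric(out), rep(0.3, 16), tolerance = 0.01)
})

test_that("actor update leaves the critic untouched (frozen-critic contract)", {
  set.seed(17)
  L <- td3_learner(tiny_spec(), tiny_schedule())
  batch <- list(feat = matrix(rnorm(32 * 20), 32),
                action = matrix(runif(64, -1, 1), 32),
                reward = runif(32), next_feat = matrix(rnorm(32 * 20), 32),
                done = rbinom(32, 1, 0.2))
  before <- fireflynav:::net_params(L$critic1)
  obj <- td3_actor_update(L, batch)
  expect_true(is.finite(obj))
  expect_identical(fireflynav:::net_params(L$critic1), before)
  expect_equal(L$actor_updates, 1L)
})

test_that("recurrent critic/actor updates run and decrease the TD loss", {
  set.seed(18)
  for (critic in c("holistic", "two_recurrent", "rnn_mlp_action_both",
                   "two_recurrent_action_second", "modular")) {
    L <- td3_learner(tiny_spec(actor = "modular", critic = critic),
                     tiny_schedule())
    Tn <- 5
    mk <- function() list(feat = matrix(rnorm(Tn * 6), Tn),
                          action = matrix(runif(Tn * 2, -1, 1), Tn),
                          reward = c(rep(0, Tn - 1), 10),
                          done = c(rep(0, Tn - 1), 1))
    batch <- replicate(4, mk(), simplify = FALSE)
    l1 <- td3_critic_update(L, batch)
    for (i in 1:60) l2 <- td3_critic_update(L, batch)
    expect_true(is.finite(l2))
    expect_lt(l2, l1)
    obj <- td3_actor_update(L, batch)
    expect_true(is.finite(obj))
  }
  # unequal lengths are rejected
  L <- td3_learner(tiny_spec(actor = "modular", critic = "modular"),
                   tiny_schedule())
  bad <- list(list(feat = matrix(0, 3, 6), action = matrix(0, 3, 2),
                   reward = rep(0, 3), done = c(0, 0, 1)),
              list(feat = matrix(0, 4, 6), action = matrix(0, 4, 2),
                   reward = rep(0, 4), done = c(0, 0, 0, 1)))
  expect_error(td3_critic_update(L, bad), "equal-length")
})

test_that("recurrent BPTT gradients match finite differences through the
           composite critic", {
  set.seed(19)
  spec <- agent_spec(actor_kind = "modular", critic_kind = "modular",
                     recurrent_width = 4, ff_widths = c(5, 5), seed = 3)
  cr <- build_critic(spec)
  Tn <- 4; M <- 2
  feat_seq <- lapply(1:Tn, function(t) matrix(rnorm(M * 6), M))
  act_seq <- lapply(1:Tn, function(t) matrix(runif(M * 2, -1, 1), M))
  loss_of <- function(cr) {
    q <- fireflynav:::critic_seq_eval(cr, feat_seq, act_seq)
    sum(vapply(q, sum, numeric(1)))
  }
  fw <- fireflynav:::critic_seq_forward(cr, feat_seq, act_seq)
  dq <- lapply(1:Tn, function(t) matrix(1, M, 1))
  bk <- fireflynav:::critic_seq_backward(cr, fw, dq)
  # recurrent module weights
  g_num <- vapply(1:20, function(i) {
    eps <- 1e-5
    c1 <- cr; c1$modules$rnn$W[i] <- c1$modules$rnn$W[i] + eps
    c2 <- cr; c2$modules$rnn$W[i] <- c2$modules$rnn$W[i] - eps
    (loss_of(c1) - loss_of(c2)) / (2 * eps)
  }, numeric(1))
  expect_equal(as.numeric(bk$grads$rnn$W)[1:20], g_num, tolerance = 1e-5)
  # action gradient at an interior step
  g_act <- vapply(1:2, function(i) {
    eps <- 1e-5
    a1 <- act_seq; a1[[2]][1, i] <- a1[[2]][1, i] + eps
    a2 <- act_seq; a2[[2]][1, i] <- a2[[2]][1, i] - eps
    (sum(vapply(fireflynav:::critic_seq_eval(cr, feat_seq, a1), sum,
                numeric(1))) -
       sum(vapply(fireflynav:::critic_seq_eval(cr, feat_seq, a2), sum,
                  numeric(1)))) / (2 * eps)
  }, numeric(1))
  expect_equal(as.numeric(bk$dA_seq[[2]][1, ]), g_act, tolerance = 1e-5)
})

test_that("a tiny feedforward training run is deterministic and keeps the
           actor/critic update cadence", {
  sch <- tiny_schedule(trials_past_phase1 = 30, stop_accuracy = NULL)
  tr1 <- train_agent(tiny_spec(), task_config(), sch, seed = 5,
                     max_trials = 25)
  tr2 <- train_agent(tiny_spec(), task_config(), sch, seed = 5,
                     max_trials = 25)
  expect_identical(tr1$curve, tr2$curve)
  expect_identical(fireflynav:::net_params(tr1$learner$actor),
                   fireflynav:::net_params(tr2$learner$actor))
  L <- tr1$learner
  expect_equal(L$actor_updates, L$critic_updates %/% 2L)
  expect_true(L$last_min_ok)
  expect_gte(nrow(tr1$curve), 2)
  expect_true(all(diff(tr1$curve$phase) >= 0)) # phase monotone
})

test_that("a tiny recurrent training run executes end to end", {
  sch <- train_schedule(batch_steps = 32L, batch_traj = 4L,
                        checkpoint_every = 8L, validation_trials = 5L)
  tr <- train_agent(tiny_spec(actor = "modular", critic = "modular"),
                    task_config(), sch, seed = 6, max_trials = 12)
  expect_s3_class(tr, "td3_training")
  expect_gte(length(tr$checkpoints), 1)
  expect_true(all(is.finite(tr$curve$frac_rewarded)))
})

test_that("checkpoint selection maximizes mean reward rate with the earliest
           tie-break", {
  sch <- tiny_schedule(trials_past_phase1 = 20)
  tr <- train_agent(tiny_spec(), task_config(), sch, seed = 7,
                    max_trials = 20)
  set.seed(1)
  sel <- select_checkpoint(tr, trials_per_set = 30)
  expect_gte(sel$index, 1)
  expect_equal(dim(sel$rates), c(length(tr$checkpoints), 1))
  best <- which(rowMeans(sel$rates) >= max(rowMeans(sel$rates)) - 1e-12)[1]
  expect_equal(sel$index, best)
  # single checkpoint selects trivially
  tr1 <- tr; tr1$checkpoints <- tr$checkpoints[1]
  set.seed(2)
  expect_equal(select_checkpoint(tr1, trials_per_set = 10)$index, 1)
  tr0 <- tr; tr0$checkpoints <- list()
  expect_error(select_checkpoint(tr0), "no checkpoints")
})
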