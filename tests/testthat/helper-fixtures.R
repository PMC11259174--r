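# Shared fixtures. Trained agents are expensive, so they are built lazily
# once per test session and reused across test files (acceptance criteria 7
# and 8 share the default-uncertainty agent).

noise_free_config <- function(...) task_config(alpha_a = 0, alpha_o = 0, ...)

# a short, deterministic episode driven by a fixed action sequence
fixed_action_episode <- function(actions, target = c(0, 200),
                                 config = noise_free_config(), ...) {
  i <- 0L
  ctrl <- function(obs, t) {
    i <<- i + 1L
    if (i <= nrow(actions)) actions[i, ] else c(0, 0)
  }
  run_episode(ctrl, config, target = target, ...)
}

# dense numeric arc-length oracle: sample the circle through the origin
# (initial heading +y, center on the x axis) and sum chord lengths
arc_length_numeric <- function(x, y, n = 2e4) {
  x <- abs(x)
  if (x < 1e-9) return(abs(y))
  r <- (x^2 + y^2) / (2 * x)
  S <- atan2(y / r, 1 - x / r) %% (2 * pi)
  s <- seq(0, S, length.out = n)
  px <- r * (1 - cos(s))
  py <- r * sin(s)
  sum(sqrt(diff(px)^2 + diff(py)^2))
}

.trained_cache <- new.env(parent = emptyenv())

# Desk-scale trained EKF agent for the stated uncertainty pair. Training is
# scaled down relative to the full protocol (stop once validation accuracy
# is comfortably above the 80% criterion; cap well under the 3000
# trials-past-phase-1 budget) to fit the suite's runtime budget.
trained_ekf_agent <- function(alpha_a = 0.2, alpha_o = 0.1, seed = 1L) {
  key <- sprintf("a%.2f_o%.2f_s%d", alpha_a, alpha_o, seed)
  if (!is.null(.trained_cache[[key]])) return(.trained_cache[[key]])
  cfg <- task_config(alpha_a = alpha_a, alpha_o = alpha_o)
  sch <- train_schedule(checkpoint_every = 250L, validation_trials = 300L,
                        trials_past_phase1 = 3000, stop_accuracy = 0.85)
  tr <- train_agent(agent_spec(actor_kind = "ekf", critic_kind = "ekf",
                               seed = seed),
                    cfg, sch, seed = seed, max_trials = 6000)
  sel <- select_checkpoint(tr, trials_per_set = 300)
  out <- list(training = tr, actor = sel$actor, config = cfg)
  .trained_cache[[key]] <- out
  out
}
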