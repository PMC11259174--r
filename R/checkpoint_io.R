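# Checkpoint archives: all module weights, optimizer state, trial counter,
# and the architecture spec embedded in one JSON file (text-only storage).
# Arrays are serialized explicitly as {dim, data} so shapes and element
# order are unambiguous.

ser_tree <- function(x) {
  if (is.list(x)) {
    lapply(x, ser_tree)
  } else if (is.numeric(x) && (length(x) > 1 || !is.null(dim(x)))) {
    list(`.arr` = TRUE, dim = dim(x), data = as.numeric(x))
  } else x
}

deser_tree <- function(x) {
  if (is.list(x)) {
    if (isTRUE(x$.arr)) {
      a <- as.numeric(x$data)
      if (!is.null(x$dim) && length(x$dim)) dim(a) <- as.integer(x$dim)
      return(a)
    }
    return(lapply(x, deser_tree))
  }
  x
}

#' Save a training checkpoint archive
#'
#' Writes one JSON archive holding the actor and twin-critic weights, the
#' Adam optimizer states, the trial counter and the embedded [agent_spec()].
#'
#' @param training a `td3_training` (or a [td3_learner()]).
#' @param path file path (`.json`).
#' @param trial trial counter stored in the archive.
#' @return the path, invisibly.
#' @export
save_checkpoint <- function(training, path, trial = NULL) {
  L <- if (inherits(training, "td3_training")) training$learner else training
  if (is.null(trial)) {
    trial <- if (inherits(training, "td3_training")) training$trials else 0L
  }
  arch <- list(
    spec = ser_tree(unclass(L$spec)),
    trial = trial,
    actor = ser_tree(net_params(L$actor)),
    critic1 = ser_tree(net_params(L$critic1)),
    critic2 = ser_tree(net_params(L$critic2)),
    opt_actor = ser_tree(L$opt_actor),
    opt_c1 = ser_tree(L$opt_c1),
    opt_c2 = ser_tree(L$opt_c2)
  )
  jsonlite::write_json(arch, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint archive into a fresh learner
#'
#' @param path archive written by [save_checkpoint()].
#' @param schedule a [train_schedule()] for the revived learner.
#' @return a [td3_learner()] with restored weights, optimizer state and
#'   attribute `trial`.
#' @export
load_checkpoint <- function(path, schedule = train_schedule()) {
  arch <- jsonlite::read_json(path, simplifyVector = FALSE)
  spec <- do.call(agent_spec, deser_tree(arch$spec))
  L <- td3_learner(spec, schedule)
  L$actor <- net_set_params(L$actor, deser_tree(arch$actor))
  L$critic1 <- net_set_params(L$critic1, deser_tree(arch$critic1))
  L$critic2 <- net_set_params(L$critic2, deser_tree(arch$critic2))
  L$t_actor <- L$actor
  L$t_critic1 <- L$critic1
  L$t_critic2 <- L$critic2
  for (nm in c("opt_actor", "opt_c1", "opt_c2")) {
    opt <- deser_tree(arch[[nm]])
    opt$t <- as.integer(opt$t)
    assign(nm, opt, envir = L)
  }
  attr(L, "trial") <- as.integer(arch$trial)
  L
}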