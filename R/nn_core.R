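# Minimal dense/LSTM neural-network core in base R. Parameters live in nested
# lists of numeric arrays ("trees"); forward passes return caches consumed by
# the matching backward passes. Gradients are checked against central finite
# differences in the test suite.

## ---- parameter trees -------------------------------------------------------

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else f(x, y)
}

tree_zeros_like <- function(x) tree_map(function(a) a * 0, x)

tree_count <- function(x) {
  if (is.list(x)) sum(vapply(x, tree_count, numeric(1))) else length(x)
}

tree_flatten <- function(x) {
  if (is.list(x)) unlist(lapply(x, tree_flatten), use.names = FALSE)
  else as.numeric(x)
}

#' Polyak (soft) update of a parameter tree
#'
#' `target <- tau * online + (1 - tau) * target`, applied to every parameter.
#'
#' @param online,target parameter trees of identical shape.
#' @param tau averaging rate.
#' @return the updated target tree.
#' @export
soft_update <- function(online, target, tau = 0.005) {
  tree_map2(function(o, tg) tau * o + (1 - tau) * tg, online, target)
}

## ---- Adam ------------------------------------------------------------------

#' Adam optimizer state for a parameter tree
#'
#' Moment decay rates 0.9 / 0.999, denominator stability constant 1.5e-4 and
#' zero weight decay, matching the training setup.
#'
#' @param params parameter tree (shapes are copied).
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps denominator stability constant.
#' @return optimizer state list.
#' @export
adam_init <- function(params, lr = 3e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1.5e-4) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

#' One Adam step
#' @param opt state from [adam_init()].
#' @param params parameter tree.
#' @param grads gradient tree (same shape); minimizes by default.
#' @param maximize ascend instead of descend.
#' @return list `params`, `opt`.
#' @export
adam_step <- function(opt, params, grads, maximize = FALSE) {
  opt$t <- opt$t + 1L
  sgn <- if (maximize) -1 else 1
  opt$m <- tree_map2(function(m, g) opt$beta1 * m + (1 - opt$beta1) * sgn * g,
                     opt$m, grads)
  opt$v <- tree_map2(function(v, g) opt$beta2 * v + (1 - opt$beta2) * g^2,
                     opt$v, grads)
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + opt$eps),
                   opt$m, opt$v)
  params <- tree_map2(function(p, u) p - opt$lr * u, params, upd)
  list(params = params, opt = opt)
}

## ---- dense layers ----------------------------------------------------------

# fan-in uniform init, the standard default for dense/recurrent layers
init_mat <- function(nin, nout) {
  lim <- 1 / sqrt(nin)
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

mlp_create <- function(sizes, out_act = c("linear", "tanh")) {
  out_act <- match.arg(out_act)
  layers <- vector("list", length(sizes) - 1)
  for (i in seq_along(layers)) {
    layers[[i]] <- list(W = init_mat(sizes[i], sizes[i + 1]),
                        b = stats::runif(sizes[i + 1], -1 / sqrt(sizes[i]),
                                         1 / sqrt(sizes[i])))
  }
  structure(list(layers = layers, out_act = out_act, sizes = sizes),
            class = "ff_mlp")
}

# X: M x in. Hidden layers ReLU, output linear or tanh.
mlp_forward <- function(net, X, cache = FALSE) {
  acts <- list(X)
  n <- length(net$layers)
  H <- X
  M <- nrow(X)
  for (i in seq_len(n)) {
    Z <- H %*% net$layers[[i]]$W
    Z <- Z + rep(net$layers[[i]]$b, each = M) # column-major bias add
    H <- if (i < n) pmax(Z, 0)
         else if (net$out_act == "tanh") tanh(Z) else Z
    if (cache) acts[[i + 1]] <- H
  }
  if (cache) list(out = H, acts = acts) else H
}

# dY: gradient wrt output. Returns grads tree (layers) and dX.
mlp_backward <- function(net, cache, dY) {
  n <- length(net$layers)
  grads <- vector("list", n)
  delta <- dY
  out <- cache$acts[[n + 1]]
  if (net$out_act == "tanh") delta <- delta * (1 - out^2)
  for (i in n:1) {
    A_prev <- cache$acts[[i]]
    grads[[i]] <- list(W = crossprod(A_prev, delta), b = colSums(delta))
    dA <- tcrossprod(delta, net$layers[[i]]$W)
    if (i > 1) delta <- dA * (cache$acts[[i]] > 0)
  }
  list(grads = list(layers = grads), dX = if (n >= 1) dA else dY)
}

## ---- LSTM ------------------------------------------------------------------

# Combined-weight LSTM. Gate order in the 4H block: input, forget, cell, out.
lstm_create <- function(input_size, hidden_size) {
  lim_in <- 1 / sqrt(input_size)
  structure(list(
    W = init_mat(input_size + hidden_size, 4 * hidden_size),
    b = stats::runif(4 * hidden_size, -lim_in, lim_in),
    input_size = input_size, hidden_size = hidden_size
  ), class = "ff_lstm")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# x: M x input. h, c: M x H. Returns h, c (and cache when requested).
lstm_step <- function(net, x, h, c, cache = FALSE) {
  H <- net$hidden_size
  z <- cbind(x, h) %*% net$W
  z <- z + rep(net$b, each = nrow(z))
  i_g <- sigmoid(z[, 1:H, drop = FALSE])
  f_g <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
  g_g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
  o_g <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
  c_new <- f_g * c + i_g * g_g
  tc <- tanh(c_new)
  h_new <- o_g * tc
  if (cache) {
    list(h = h_new, c = c_new,
         cache = list(x = x, h_prev = h, c_prev = c, i = i_g, f = f_g,
                      g = g_g, o = o_g, tc = tc))
  } else list(h = h_new, c = c_new)
}

# One-step backward. dh: grad wrt h_new (incl. recurrent inflow), dc: grad wrt
# c_new inflow. Returns dx, dh_prev, dc_prev, and parameter grads.
lstm_step_backward <- function(net, cache, dh, dc) {
  H <- net$hidden_size
  do <- dh * cache$tc
  dcx <- dc + dh * cache$o * (1 - cache$tc^2)
  di <- dcx * cache$g
  df <- dcx * cache$c_prev
  dg <- dcx * cache$i
  dc_prev <- dcx * cache$f
  dz <- cbind(di * cache$i * (1 - cache$i),
              df * cache$f * (1 - cache$f),
              dg * (1 - cache$g^2),
              do * cache$o * (1 - cache$o))
  inp <- cbind(cache$x, cache$h_prev)
  gW <- crossprod(inp, dz)
  gb <- colSums(dz)
  dinp <- tcrossprod(dz, net$W)
  nin <- net$input_size
  list(dx = dinp[, 1:nin, drop = FALSE],
       dh_prev = dinp[, (nin + 1):(nin + H), drop = FALSE],
       dc_prev = dc_prev, grads = list(W = gW, b = gb))
}

# Full-sequence forward. X_seq: list over time of M x input matrices.
lstm_forward_seq <- function(net, X_seq, cache = FALSE) {
  M <- nrow(X_seq[[1]])
  H <- net$hidden_size
  h <- matrix(0, M, H)
  c <- matrix(0, M, H)
  hs <- vector("list", length(X_seq))
  caches <- if (cache) vector("list", length(X_seq)) else NULL
  for (t in seq_along(X_seq)) {
    st <- lstm_step(net, X_seq[[t]], h, c, cache = cache)
    h <- st$h
    c <- st$c
    hs[[t]] <- h
    if (cache) caches[[t]] <- st$cache
  }
  list(hs = hs, caches = caches)
}

# BPTT. dH_seq: list of grads wrt each h_t output. Returns grads and dX_seq.
lstm_backward_seq <- function(net, caches, dH_seq) {
  Tn <- length(caches)
  M <- nrow(dH_seq[[Tn]])
  H <- net$hidden_size
  gW <- net$W * 0
  gb <- net$b * 0
  dh_next <- matrix(0, M, H)
  dc_next <- matrix(0, M, H)
  dX_seq <- vector("list", Tn)
  for (t in Tn:1) {
    bk <- lstm_step_backward(net, caches[[t]], dH_seq[[t]] + dh_next, dc_next)
    gW <- gW + bk$grads$W
    gb <- gb + bk$grads$b
    dh_next <- bk$dh_prev
    dc_next <- bk$dc_prev
    dX_seq[[t]] <- bk$dx
  }
  list(grads = list(W = gW, b = gb), dX_seq = dX_seq)
}
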