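# Probing internal representations: spatial tuning maps, ridge decoding of
# task variables from unit activities, decoding error, and the
# uncertainty-sweep fingerprint of an agent's learned Kalman gain.

#' Spatial tuning map of one unit
#'
#' Grids the plane at `cell` resolution, interpolates the unit's activity
#' onto the grid from the scattered `(x, y, activity)` samples (cell-wise
#' averaging of a dense sample cloud, the piecewise-constant limit of linear
#' interpolation; empty in-hull cells are filled from their neighbors), then
#' smooths with a boxcar filter of `boxcar` cm width and height. Cells
#' outside the convex hull of the samples are `NA`.
#'
#' @param activity numeric vector, one value per sample (time step).
#' @param positions `n x 2` matrix of `(x, y)` locations, cm.
#' @param cell grid cell size, cm.
#' @param boxcar boxcar side length, cm.
#' @param xlim,ylim grid extents; default spans the samples.
#' @return list of class `tuning_map`: `z` (matrix, rows = y), `x`, `y`
#'   cell-center coordinates.
#' @export
spatial_tuning <- function(activity, positions, cell = 5, boxcar = 40,
                           xlim = NULL, ylim = NULL) {
  P <- as.matrix(positions)
  if (nrow(P) < 3 || nrow(unique(P)) < 3) stop("degenerate sample set")
  if (qr(cbind(1, P))$rank < 3) stop("degenerate (collinear) sample set")
  if (is.null(xlim)) xlim <- range(P[, 1])
  if (is.null(ylim)) ylim <- range(P[, 2])
  xs <- seq(xlim[1], xlim[2] + cell, by = cell)
  ys <- seq(ylim[1], ylim[2] + cell, by = cell)
  ix <- findInterval(P[, 1], xs, rightmost.closed = TRUE)
  iy <- findInterval(P[, 2], ys, rightmost.closed = TRUE)
  nx <- length(xs) - 1L
  ny <- length(ys) - 1L
  keep <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  idx <- (ix[keep] - 1L) * ny + iy[keep]
  sums <- tapply(activity[keep], idx, sum)
  cnts <- tapply(rep(1, sum(keep)), idx, sum)
  Z <- matrix(NA_real_, ny, nx)
  Z[as.integer(names(sums))] <- sums / cnts
  # convex-hull mask on cell centers
  cx <- xs[-length(xs)] + cell / 2
  cy <- ys[-length(ys)] + cell / 2
  hull <- P[grDevices::chull(P), , drop = FALSE]
  inside <- point_in_poly(rep(cx, each = ny), rep(cy, nx), hull)
  mask <- matrix(inside, ny, nx)
  # fill empty in-hull cells by repeated neighbor averaging
  for (it in 1:50) {
    nas <- which(is.na(Z) & mask)
    if (!length(nas)) break
    Zf <- Z
    for (cellii in nas) {
      r <- ((cellii - 1L) %% ny) + 1L
      cc <- ((cellii - 1L) %/% ny) + 1L
      nb <- c(if (r > 1) Z[r - 1, cc], if (r < ny) Z[r + 1, cc],
              if (cc > 1) Z[r, cc - 1], if (cc < nx) Z[r, cc + 1])
      if (any(!is.na(nb))) Zf[r, cc] <- mean(nb, na.rm = TRUE)
    }
    Z <- Zf
  }
  Z <- boxcar_smooth(Z, max(1L, round(boxcar / cell)))
  Z[!mask] <- NA_real_
  structure(list(z = Z, x = cx, y = cy, cell = cell), class = "tuning_map")
}

# even-sided boxcar handled by an odd window of the nearest size
boxcar_smooth <- function(Z, w) {
  if (w %% 2 == 0) w <- w + 1L
  h <- (w - 1L) %/% 2L
  ny <- nrow(Z); nx <- ncol(Z)
  out <- Z
  V <- Z; V[is.na(V)] <- 0
  C <- !is.na(Z)
  # separable moving sum with NA-aware renormalization
  msum <- function(M, h, along) {
    n <- if (along == 1) nrow(M) else ncol(M)
    acc <- M * 0
    for (d in -h:h) {
      if (along == 1) {
        src <- pmin(pmax(seq_len(nrow(M)) + d, 1), nrow(M))
        valid <- seq_len(nrow(M)) + d >= 1 & seq_len(nrow(M)) + d <= nrow(M)
        Md <- M[src, , drop = FALSE]
        Md[!valid, ] <- 0
      } else {
        src <- pmin(pmax(seq_len(ncol(M)) + d, 1), ncol(M))
        valid <- seq_len(ncol(M)) + d >= 1 & seq_len(ncol(M)) + d <= ncol(M)
        Md <- M[, src, drop = FALSE]
        Md[, !valid] <- 0
      }
      acc <- acc + Md
    }
    acc
  }
  num <- msum(msum(V, h, 1), h, 2)
  den <- msum(msum(C + 0, h, 1), h, 2)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Ridge decoding of task variables from unit activities
#'
#' Closed-form ridge estimator `W = (X'X + lambda I)^-1 X'S` with the
#' penalty chosen from a small grid by k-fold cross-validation *within the
#' training trials*; trials are split 70/30 at the trial level so no time
#' step leaks between splits.
#'
#' @param X activity matrix (rows = time steps, columns = units).
#' @param S target matrix (rows = time steps, columns = variables).
#' @param trial_ids integer vector assigning each row to a trial.
#' @param lambdas penalty grid.
#' @param train_frac fraction of trials used for fitting.
#' @param folds cross-validation folds within the training trials.
#' @return list of class `ridge_decoder`: `W`, `lambda`, `train_trials`,
#'   `test_trials`, `pred` (test-set predictions), `test_rows`.
#' @export
ridge_decode <- function(X, S, trial_ids = rep(1L, nrow(X)),
                         lambdas = c(0.1, 1, 10), train_frac = 0.7,
                         folds = 5) {
  X <- as.matrix(X)
  S <- as.matrix(S)
  stopifnot(nrow(X) == nrow(S), nrow(X) == length(trial_ids),
            !anyNA(X), !anyNA(S))
  trials <- unique(trial_ids)
  ntr <- max(1L, round(train_frac * length(trials)))
  train_trials <- sort(sample(trials, ntr))
  test_trials <- setdiff(trials, train_trials)
  tr_rows <- trial_ids %in% train_trials
  fit <- function(Xt, St, lambda) {
    solve(crossprod(Xt) + diag(lambda, ncol(Xt)), crossprod(Xt, St))
  }
  # choose lambda by CV over training trials
  if (length(lambdas) > 1 && length(train_trials) >= folds) {
    fold_of <- rep(seq_len(folds), length.out = length(train_trials))
    fold_of <- fold_of[sample.int(length(train_trials))]
    cv_err <- vapply(lambdas, function(lm) {
      errs <- numeric(folds)
      for (f in seq_len(folds)) {
        hold <- train_trials[fold_of == f]
        rows_fit <- trial_ids %in% setdiff(train_trials, hold)
        rows_val <- trial_ids %in% hold
        W <- fit(X[rows_fit, , drop = FALSE], S[rows_fit, , drop = FALSE], lm)
        e <- X[rows_val, , drop = FALSE] %*% W - S[rows_val, , drop = FALSE]
        errs[f] <- mean(e^2)
      }
      mean(errs)
    }, numeric(1))
    lambda <- lambdas[which.min(cv_err)]
  } else lambda <- lambdas[1]
  W <- fit(X[tr_rows, , drop = FALSE], S[tr_rows, , drop = FALSE], lambda)
  te_rows <- which(!tr_rows)
  pred <- X[te_rows, , drop = FALSE] %*% W
  structure(list(W = W, lambda = lambda, train_trials = train_trials,
                 test_trials = test_trials, pred = pred,
                 test_rows = te_rows),
            class = "ridge_decoder")
}

#' Mean Euclidean decoding error
#'
#' Per trial, the mean step-wise Euclidean distance between predicted and
#' true `(x, y)`; the reported value is the mean over trials.
#'
#' @param pred,truth `n x 2` matrices of aligned positions.
#' @param trial_ids optional per-row trial labels; if omitted the whole
#'   input is one trial.
#' @return mean decoding error, cm.
#' @export
decoding_error <- function(pred, truth, trial_ids = rep(1L, nrow(pred))) {
  P <- as.matrix(pred)
  Tr <- as.matrix(truth)
  if (nrow(P) != nrow(Tr)) stop("length mismatch between predictions and truth")
  d <- sqrt(rowSums((P - Tr)^2))
  mean(tapply(d, trial_ids, mean))
}

#' Uncertainty sweep: AUC drop under test uncertainties above training
#'
#' Evaluates a frozen agent on a grid of test uncertainty pairs
#' `(sigma_a, sigma_o) = training + {+0, +0.2, +0.4, +0.6, +0.8} G`,
#' computing for each cell the AUC drop relative to the training-uncertainty
#' baseline (the `(+0, +0)` cell, whose drop is 0 by construction). For EKF
#' reference agents the Kalman gain (and covariance features) stay frozen at
#' the training values -- the belief model does not know the test noise.
#'
#' @param policy belief-feature policy (see [rollout_ekf_trials()]).
#' @param train_config training [task_config()] (its `alpha_a`, `alpha_o`
#'   define the training uncertainties and the frozen belief model).
#' @param increments added uncertainty levels in units of G.
#' @param n_trials trials per cell.
#' @param boundaries ROC boundary grid.
#' @return object of class `auc_drop_table`: `drop` (5x5 matrix, rows =
#'   sigma_a increments, cols = sigma_o increments), `auc`, `baseline_auc`,
#'   `increments`.
#' @export
uncertainty_sweep <- function(policy, train_config = task_config(),
                              increments = c(0, 0.2, 0.4, 0.6, 0.8),
                              n_trials = 500,
                              boundaries = exp(seq(log(5), log(400),
                                                   length.out = 60))) {
  frozen_noise <- config_noise_model(train_config)
  k <- length(increments)
  auc <- matrix(NA_real_, k, k,
                dimnames = list(paste0("+", increments, "G_a"),
                                paste0("+", increments, "G_o")))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      cfg <- train_config
      cfg$alpha_a <- train_config$alpha_a + increments[i]
      cfg$alpha_o <- train_config$alpha_o + increments[j]
      ro <- rollout_ekf_trials(policy, n = n_trials, env_config = cfg,
                               agent_config = train_config,
                               agent_noise = frozen_noise)
      roc <- psychometric_and_roc(cbind(ro$trials$stop_x, ro$trials$stop_y),
                                  cbind(ro$trials$gx, ro$trials$gy),
                                  boundaries = boundaries)
      auc[i, j] <- roc$auc
    }
  }
  drop <- auc[1, 1] - auc
  structure(list(drop = drop, auc = auc, baseline_auc = auc[1, 1],
                 increments = increments),
            class = "auc_drop_table")
}

#' Correlate two AUC-drop tables (Kalman-gain fingerprint)
#'
#' Pearson correlation of the flattened grid entries, with a bootstrap 95%
#' confidence interval (resampling entries) and a shuffled-entry null.
#'
#' @param table,reference `auc_drop_table`s (or plain matrices) on the same
#'   grid.
#' @param n_boot bootstrap resamples.
#' @return list: `r`, `ci` (2.5/97.5 percentiles), `null_r` (mean shuffled
#'   correlation), `boot_r`.
#' @export
gain_fingerprint_correlation <- function(table, reference, n_boot = 1e4) {
  a <- as.numeric(if (inherits(table, "auc_drop_table")) table$drop else table)
  b <- as.numeric(if (inherits(reference, "auc_drop_table")) reference$drop
                  else reference)
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant table: correlation undefined")
  }
  r <- stats::cor(a, b)
  n <- length(a)
  boot_r <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(a[idx]) == 0 || stats::sd(b[idx]) == 0) return(NA_real_)
    stats::cor(a[idx], b[idx])
  }, numeric(1))
  null_r <- vapply(seq_len(min(n_boot, 2000L)), function(i)
    stats::cor(a[sample.int(n)], b), numeric(1))
  list(r = r,
       ci = stats::quantile(boot_r, c(0.025, 0.975), na.rm = TRUE,
                            names = FALSE),
       null_r = mean(null_r), boot_r = boot_r)
}
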