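#' Hidden-layer size rule
#'
#' The network topology rule `N_hidden = ceiling(log2(N_input))`: eight inputs
#' (four features x two muscles) give three hidden neurons. The ceiling makes
#' the rule well defined for input counts that are not powers of two.
#'
#' @param n_input Number of input neurons (>= 2).
#' @return Integer hidden-layer size.
#' @export
#' @examples
#' hidden_size(8)  # 3
hidden_size <- function(n_input) {
  if (n_input < 2) stop("n_input must be >= 2")
  as.integer(ceiling(log2(n_input)))
}

#' Training configuration for the force estimator
#'
#' @param split Train/validation/test fractions (must sum to 1). The default
#'   70/15/15 keeps an untouched test share next to the early-stopping
#'   validation share; `c(0.7, 0.3)` gives the literal two-way split (the
#'   validation share then doubles as the held-out set).
#' @param lr Learning rate of batch gradient descent.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param seed Seed for weight initialization and the window split.
#' @param tol Minimum decrease of validation loss counted as improvement.
#' @return An object of class `train_config`.
#' @export
train_config <- function(split = c(0.70, 0.15, 0.15), lr = 0.2,
                         max_epochs = 5000, patience = 200, seed = 42L,
                         tol = 1e-9) {
  stopifnot(length(split) %in% c(2, 3), all(split > 0),
            abs(sum(split) - 1) < 1e-8, lr > 0, max_epochs >= 1,
            patience >= 1)
  if (length(split) == 2) split <- c(split, 0)
  structure(list(split = split, lr = lr, max_epochs = max_epochs,
                 patience = patience, seed = as.integer(seed), tol = tol),
            class = "train_config")
}

#' Min--max target normalization and its inverse
#'
#' Maps `min -> 0`, `max -> 1` affinely; the inverse ("anti-normalization")
#' maps network outputs back to newtons.
#'
#' @param force Numeric series (N).
#' @param norm List with `min` and `max`.
#' @return Normalized (or denormalized) series.
#' @export
normalize_targets <- function(force, norm) {
  if (!(norm$max > norm$min)) stop("degenerate normalization range")
  (force - norm$min) / (norm$max - norm$min)
}

#' @rdname normalize_targets
#' @export
denormalize_targets <- function(force, norm) {
  if (!(norm$max > norm$min)) stop("degenerate normalization range")
  force * (norm$max - norm$min) + norm$min
}

minmax_fit <- function(x) {
  if (is.matrix(x)) list(min = apply(x, 2, min), max = apply(x, 2, max))
  else list(min = min(x), max = max(x))
}

minmax_apply <- function(x, norm) {
  rng <- norm$max - norm$min
  rng[rng == 0] <- 1          # constant feature: map to 0
  sweep(sweep(x, 2, norm$min), 2, rng, "/")
}

#' Initialize an untrained estimator network
#'
#' One hidden layer of `n_hidden` symmetric-sigmoid (tanh) units and a linear
#' output neuron; weights and thresholds drawn uniformly from (-0.5, 0.5).
#'
#' @param n_input Number of inputs (8 for the two-muscle multi-feature set).
#' @param n_hidden Hidden units; defaults to [hidden_size()] of `n_input`.
#' @param seed Seed for the draw; `NULL` uses the current RNG state.
#' @return An object of class `bpnn_model` (untrained: identity
#'   normalizations).
#' @export
bpnn_init <- function(n_input = 8, n_hidden = hidden_size(n_input),
                      seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  structure(list(
    w_in = matrix(stats::runif(n_hidden * n_input, -0.5, 0.5),
                  n_hidden, n_input),
    t = stats::runif(n_hidden, -0.5, 0.5),
    w_out = stats::runif(n_hidden, -0.5, 0.5),
    b_out = stats::runif(1, -0.5, 0.5),
    feat_norm = list(min = rep(0, n_input), max = rep(1, n_input)),
    force_norm = list(min = 0, max = 1),
    feature_order = if (n_input == 8) feature_names() else NULL,
    activation = "tanh"), class = "bpnn_model")
}

# Hidden activations (rows = samples) for a normalized input matrix.
bpnn_hidden <- function(model, Xn) {
  Z <- Xn %*% t(model$w_in)
  tanh(sweep(Z, 2, model$t))
}

#' Forward pass: features to estimated force
#'
#' Each hidden unit computes the symmetric sigmoid
#' \eqn{h_j = 2 / (1 + e^{-2 z_j}) - 1} (i.e. `tanh(z_j)`) of
#' \eqn{z_j = \sum_i w^{in}_{ji} x_i - t_j}; the output neuron is linear,
#' \eqn{y = \sum_j w^{out}_j h_j + b^{out}}, and the result is
#' anti-normalized to newtons with the stored force range. Inputs are
#' normalized with the stored per-feature min/max before the pass.
#'
#' @param model A `bpnn_model`.
#' @param x An 8-vector or an n x 8 matrix of raw feature values.
#' @return Estimated force, N (vector of length n).
#' @export
bpnn_forward <- function(model, x) {
  stopifnot(inherits(model, "bpnn_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$w_in))
    stop(sprintf("expected %d features, got %d", ncol(model$w_in), ncol(x)))
  Xn <- minmax_apply(x, model$feat_norm)
  H <- bpnn_hidden(model, Xn)
  yn <- drop(H %*% model$w_out) + model$b_out
  denormalize_targets(yn, model$force_norm)
}

# Deterministic stratified split of window indices by trial id.
split_windows <- function(trial, split, seed) {
  set.seed(seed)
  idx <- list(train = integer(), val = integer(), test = integer())
  for (id in unique(trial)) {
    rows <- sample(which(trial == id))
    n <- length(rows)
    n_tr <- max(1L, round(split[1] * n))
    n_va <- max(1L, round(split[2] * n))
    if (split[3] > 0) {
      n_te <- n - n_tr - n_va
      if (n_te < 1) { n_tr <- n_tr - (1 - n_te); n_te <- 1 }
    } else n_te <- 0
    idx$train <- c(idx$train, rows[seq_len(n_tr)])
    idx$val <- c(idx$val, rows[n_tr + seq_len(n_va)])
    if (n_te > 0) idx$test <- c(idx$test, rows[n_tr + n_va + seq_len(n_te)])
  }
  if (length(idx$test) == 0) idx$test <- idx$val  # literal two-way split
  idx
}

#' Train the force estimator by backpropagation
#'
#' Plain batch gradient descent on the mean squared error of min--max
#' normalized targets, with early stopping on a validation share and
#' restoration of the best-validation weights. The split is stratified by
#' trial so every trial contributes held-out windows. Deterministic under a
#' fixed `cfg$seed`.
#'
#' @param features A `feature_series` (usually pooled with
#'   [bind_features()]), >= 50 windows.
#' @param cfg A [train_config()].
#' @param n_hidden Hidden-layer size; defaults to the topology rule.
#' @return A `bpnn_model` with the learned weights, the normalization
#'   constants, the split indices (`$split`), and the loss history
#'   (`$history`).
#' @export
bpnn_train <- function(features, cfg = train_config(),
                       n_hidden = hidden_size(ncol(features$X))) {
  stopifnot(inherits(features, "feature_series"))
  X <- features$X
  y <- features$y
  if (nrow(X) < 50) stop("need at least 50 windows to train")
  if (max(y) - min(y) <= 0) stop("degenerate targets: zero range")
  trial <- if (length(features$trial) == nrow(X)) features$trial
           else rep(1L, nrow(X))
  idx <- split_windows(trial, cfg$split, cfg$seed)

  model <- bpnn_init(ncol(X), n_hidden, seed = cfg$seed)
  model$feat_norm <- minmax_fit(X[idx$train, , drop = FALSE])
  model$force_norm <- minmax_fit(y[idx$train])
  Xn <- minmax_apply(X, model$feat_norm)
  yn <- normalize_targets(y, model$force_norm)

  Xtr <- Xn[idx$train, , drop = FALSE]; ytr <- yn[idx$train]
  Xva <- Xn[idx$val, , drop = FALSE];   yva <- yn[idx$val]
  m <- nrow(Xtr)

  mse <- function(W, t, w, b, A, target) {
    H <- tanh(sweep(A %*% t(W), 2, t))
    mean((drop(H %*% w) + b - target)^2)
  }
  W <- model$w_in; th <- model$t; w <- model$w_out; b <- model$b_out
  best <- list(W = W, t = th, w = w, b = b,
               val = mse(W, th, w, b, Xva, yva), epoch = 0L)
  hist_tr <- hist_va <- numeric(cfg$max_epochs)
  stall <- 0L
  for (ep in seq_len(cfg$max_epochs)) {
    H <- tanh(sweep(Xtr %*% t(W), 2, th))
    err <- drop(H %*% w) + b - ytr            # d(0.5*mse)/d(out) * 2
    dH <- (err %o% w) * (1 - H^2)
    W <- W - cfg$lr * (t(dH) %*% Xtr) * (2 / m)
    th <- th + cfg$lr * colSums(dH) * (2 / m)
    w <- w - cfg$lr * drop(t(H) %*% err) * (2 / m)
    b <- b - cfg$lr * 2 * mean(err)
    hist_tr[ep] <- mean(err^2)
    hist_va[ep] <- mse(W, th, w, b, Xva, yva)
    if (hist_va[ep] < best$val - cfg$tol) {
      best <- list(W = W, t = th, w = w, b = b, val = hist_va[ep],
                   epoch = ep)
      stall <- 0L
    } else stall <- stall + 1L
    if (stall >= cfg$patience) break
  }
  model$w_in <- best$W; model$t <- best$t
  model$w_out <- best$w; model$b_out <- best$b
  model$split <- idx
  model$history <- list(train = hist_tr[seq_len(ep)],
                        val = hist_va[seq_len(ep)],
                        best_epoch = best$epoch, best_val = best$val)
  model$seed <- cfg$seed
  model
}

#' @export
print.bpnn_model <- function(x, ...) {
  cat(sprintf("<bpnn_model> %d-%d-1 (%s hidden units)\n",
              ncol(x$w_in), nrow(x$w_in), x$activation))
  if (!is.null(x$history))
    cat(sprintf("  best validation MSE %.3g at epoch %d\n",
                x$history$best_val, x$history$best_epoch))
  cat(sprintf("  force range: %.3g-%.3g N\n",
              x$force_norm$min, x$force_norm$max))
  invisible(x)
}

#' Online validation gate for a trained estimator
#'
#' Streams a fresh recording through the full pipeline (conditioning, feature
#' extraction, forward pass), compares the per-window estimates with the
#' measured force, and accepts the model when the squared correlation reaches
#' the threshold -- the safety gate before any model is used for assist
#' control. A poor model is rejected (to be retrained).
#'
#' @param model A trained `bpnn_model`.
#' @param recording An [emg_recording()].
#' @param threshold R-squared floor for acceptance (default 0.90).
#' @param filter A [filter_spec()].
#' @param window A [window_spec()].
#' @param mvc Per-channel MVC reference (mV); defaults to the values stored in
#'   the model (the offline MVC test), else recomputed from this recording.
#' @return List with `accept`, `r2`, `rmse`, `n`, `estimate`, `actual`, `t`.
#' @export
validate_online <- function(model, recording, threshold = 0.90,
                            filter = filter_spec(), window = window_spec(),
                            mvc = model$mvc) {
  stopifnot(inherits(model, "bpnn_model"), inherits(recording, "emg_recording"))
  processed <- preprocess_chain(recording, filter, mvc = mvc)
  feats <- feature_matrix(processed, spec = window)
  est <- bpnn_forward(model, feats$X)
  r2 <- r_squared(est, feats$y)
  list(accept = r2 >= threshold, r2 = r2, rmse = rmse(est, feats$y),
       n = length(est), threshold = threshold,
       estimate = est, actual = feats$y, t = feats$t)
}

#' Serialize / restore an estimator model as JSON
#'
#' The JSON file stores shapes, weights, thresholds, both normalizations, the
#' frozen feature ordering, the activation label, the MVC reference, and the
#' training seed, so a trained model is portable across sessions.
#'
#' @param model A `bpnn_model`.
#' @param path JSON file path.
#' @return `bpnn_save()` returns `path` invisibly; `bpnn_load()` the model.
#' @export
bpnn_save <- function(model, path) {
  stopifnot(inherits(model, "bpnn_model"))
  payload <- list(
    n_input = ncol(model$w_in), n_hidden = nrow(model$w_in),
    w_in = model$w_in, t = model$t, w_out = model$w_out,
    b_out = model$b_out, feat_norm = model$feat_norm,
    force_norm = model$force_norm, feature_order = model$feature_order,
    activation = model$activation, mvc = as.list(model$mvc),
    seed = model$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' @rdname bpnn_save
#' @export
bpnn_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("w_in", "t", "w_out", "b_out", "feat_norm", "force_norm",
              "activation"))
    if (is.null(p[[f]])) stop("corrupt model file: missing field '", f, "'")
  w_in <- if (is.matrix(p$w_in)) p$w_in
          else matrix(unlist(p$w_in), nrow = p$n_hidden, ncol = p$n_input,
                      byrow = TRUE)
  if (!identical(dim(w_in), c(as.integer(p$n_hidden), as.integer(p$n_input))))
    stop("corrupt model file: inconsistent shapes")
  structure(list(w_in = w_in, t = as.numeric(p$t),
                 w_out = as.numeric(p$w_out), b_out = as.numeric(p$b_out),
                 feat_norm = list(min = as.numeric(p$feat_norm$min),
                                  max = as.numeric(p$feat_norm$max)),
                 force_norm = list(min = as.numeric(p$force_norm$min),
                                   max = as.numeric(p$force_norm$max)),
                 feature_order = p$feature_order,
                 activation = p$activation,
                 mvc = if (length(p$mvc)) unlist(p$mvc) else NULL,
                 seed = p$seed),
            class = "bpnn_model")
}
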