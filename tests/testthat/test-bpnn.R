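test_that("the topology rule gives ceil(log2(n_input)) hidden units", {
  expect_identical(hidden_size(8), 3L)
  expect_identical(hidden_size(2), 1L)
  expect_identical(hidden_size(10), 4L)
  expect_error(hidden_size(1))
})

test_that("target normalization round-trips and rejects degenerate ranges", {
  norm <- list(min = 2, max = 12)
  expect_equal(normalize_targets(2, norm), 0)
  expect_equal(normalize_targets(12, norm), 1)
  set.seed(2)
  y <- runif(50, -5, 40)
  expect_equal(denormalize_targets(normalize_targets(y, norm), norm), y,
               tolerance = 1e-9)
  expect_error(normalize_targets(1, list(min = 3, max = 3)))
  expect_error(denormalize_targets(1, list(min = 3, max = 3)))
})

test_that("forward pass equals the independent equation oracle", {
  set.seed(42)
  for (rep in 1:100) {
    model <- bpnn_init(8, 3, seed = rep)
    model$feat_norm <- list(min = rep(0, 8), max = rep(1, 8) + runif(8))
    model$force_norm <- list(min = 0, max = 30)
    x <- runif(8, 0, 1.5)
    expect_equal(bpnn_forward(model, x), oracle_forward(model, x),
                 tolerance = 1e-12)
  }
})

test_that("degenerate networks behave per the closed-form corner cases", {
  model <- bpnn_init(8, 3, seed = 1)
  model$force_norm <- list(min = 0, max = 30)
  beta <- 0.4
  zeroed <- model
  zeroed$w_in[] <- 0; zeroed$w_out[] <- 0; zeroed$t[] <- 0
  zeroed$b_out <- beta
  expect_equal(bpnn_forward(zeroed, runif(8)), beta * 30)
  # a single hidden unit whose net input hits the threshold exactly
  one <- bpnn_init(2, 1, seed = 1)
  one$force_norm <- list(min = 0, max = 10)
  one$w_in <- matrix(c(1, 1), 1, 2); one$t <- 2; one$b_out <- 0.25
  expect_equal(bpnn_forward(one, c(1, 1)), 0.25 * 10)
  # hidden activations are inside (-1, 1) for bounded weights
  H <- semgforce:::bpnn_hidden(model, matrix(runif(80), 10, 8))
  expect_true(all(H > -1 & H < 1))
  expect_error(bpnn_forward(model, runif(5)), "features")
})

make_linear_features <- function(n = 400, seed = 5) {
  set.seed(seed)
  X <- matrix(runif(n * 8), n, 8, dimnames = list(NULL, NULL))
  colnames(X) <- c("b_mav", "b_rms", "b_dasdv", "b_wl",
                   "t_mav", "t_rms", "t_dasdv", "t_wl")
  beta <- c(3, 2, 1, 0.5, -1, 0.2, 0, 1.5)
  structure(list(t = seq_len(n) * 0.1, X = X,
                 y = drop(X %*% beta) + 2, trial = rep(1:4, each = n / 4)),
            class = "feature_series")
}

test_that("training recovers an exactly-linear feature-force mapping", {
  feats <- make_linear_features()
  model <- bpnn_train(feats, train_config(seed = 11))
  held <- model$split$test
  expect_gte(r_squared(bpnn_forward(model, feats$X[held, ]), feats$y[held]),
             0.99)
})

test_that("training is deterministic and respects its preconditions", {
  feats <- make_linear_features(n = 200, seed = 8)
  m1 <- bpnn_train(feats, train_config(seed = 4, max_epochs = 200))
  m2 <- bpnn_train(feats, train_config(seed = 4, max_epochs = 200))
  expect_identical(m1$w_in, m2$w_in)
  expect_identical(m1$w_out, m2$w_out)
  expect_identical(m1$b_out, m2$b_out)
  small <- feats; small$X <- feats$X[1:30, ]; small$y <- feats$y[1:30]
  small$trial <- feats$trial[1:30]
  expect_error(bpnn_train(small), "at least 50")
  flat <- feats; flat$y <- rep(5, nrow(feats$X))
  expect_error(bpnn_train(flat), "degenerate")
})

test_that("near-constant targets yield near-constant predictions", {
  feats <- make_linear_features(n = 200, seed = 9)
  feats$y <- 5 + 1e-3 * sin(seq_len(200))
  model <- bpnn_train(feats, train_config(seed = 2, max_epochs = 300))
  pred <- bpnn_forward(model, feats$X[model$split$test, ])
  expect_true(all(abs(pred - 5) < 0.05))
})

test_that("validation loss improves from initialization to best epoch", {
  feats <- make_linear_features()
  model <- bpnn_train(feats, train_config(seed = 3))
  hist <- model$history
  expect_lte(hist$best_val, hist$val[1])
  expect_lt(hist$train[length(hist$train)], hist$train[1])
  expect_gte(hist$best_epoch, 1)
})

test_that("the online gate accepts a good model and rejects a random one", {
  cfg <- quick_synth(duration_s = 6, seed = 30)
  ds <- make_dataset(3, cfg)
  mvc <- vapply(c("biceps", "triceps"),
                function(ch) compute_mvc(ds[[1]], ch), numeric(1))
  suppressMessages(feats <- bind_features(lapply(ds, function(r)
    feature_matrix(preprocess_chain(r, mvc = mvc)))))
  model <- bpnn_train(feats, train_config(seed = 30))
  model$mvc <- mvc
  suppressMessages(ok <- validate_online(model, ds[[1]]))
  expect_true(ok$accept)
  expect_gte(ok$r2, 0.9)
  rand <- bpnn_init(8, 3, seed = 99)
  rand$force_norm <- model$force_norm
  rand$feat_norm <- model$feat_norm
  rand$mvc <- mvc
  suppressMessages(bad <- validate_online(rand, ds[[1]]))
  expect_false(bad$accept)
  suppressMessages(vac <- validate_online(rand, ds[[1]], threshold = 0))
  expect_true(vac$accept)   # a zero threshold is a vacuous gate
})

test_that("model JSON serialization round-trips the forward pass", {
  feats <- make_linear_features(n = 200, seed = 6)
  model <- bpnn_train(feats, train_config(seed = 6, max_epochs = 100))
  model$mvc <- c(biceps = 0.5, triceps = 0.4)
  path <- withr::local_tempfile(fileext = ".json")
  bpnn_save(model, path)
  back <- bpnn_load(path)
  X <- feats$X[1:10, ]
  expect_equal(bpnn_forward(back, X), bpnn_forward(model, X),
               tolerance = 1e-12)
  expect_equal(back$mvc, model$mvc)
  # corrupt files are diagnosed
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(w_in = 1), bad, auto_unbox = TRUE)
  expect_error(bpnn_load(bad), "corrupt model file")
})
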