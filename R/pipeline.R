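#' Run configuration for the three-phase protocol
#'
#' Bundles every stage configuration plus paths and the protocol-level knobs.
#' All randomness flows from `seed`: the synthetic generator uses it as master
#' seed, training derives its split/initialization seed from it, and the
#' fresh trials of the online and assist phases use fixed offsets (+1000,
#' +2000, +3000) so no phase reuses another's random stream.
#'
#' @param out_dir Directory for all artifacts (model, reports, CSVs).
#' @param data_dir Optional directory of recorded trial CSVs; when `NULL` the
#'   synthetic generator supplies the trials.
#' @param seed Master seed.
#' @param n_trials Number of offline training trials.
#' @param synth A [synth_config()]; its seed is overridden by `seed`.
#' @param filter A [filter_spec()].
#' @param window A [window_spec()].
#' @param train A [train_config()]; its seed is overridden by `seed`.
#' @param plant A [plant_params()].
#' @param gains A [controller_gains()].
#' @param accept_threshold R-squared floor of the online validation gate.
#' @param impairment Fraction of healthy output the simulated affected limb
#'   still produces in the assist phase (0 = plegic, 1 = healthy).
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, data_dir = NULL, seed = 42L, n_trials = 5,
                       synth = synth_config(), filter = filter_spec(),
                       window = window_spec(), train = train_config(),
                       plant = plant_params(), gains = controller_gains(),
                       accept_threshold = 0.90, impairment = 0.3) {
  stopifnot(is.character(out_dir), length(out_dir) == 1)
  synth$seed <- as.integer(seed)
  train$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, data_dir = data_dir,
                 seed = as.integer(seed), n_trials = n_trials, synth = synth,
                 filter = filter, window = window, train = train,
                 plant = plant, gains = gains,
                 accept_threshold = accept_threshold,
                 impairment = impairment),
            class = "run_config")
}

model_path <- function(cfg) file.path(cfg$out_dir, "model.json")
validation_path <- function(cfg) file.path(cfg$out_dir, "validation.json")

load_or_make_trials <- function(cfg) {
  if (!is.null(cfg$data_dir)) {
    if (!dir.exists(cfg$data_dir))
      stop("data directory not found: ", cfg$data_dir)
    files <- sort(list.files(cfg$data_dir, pattern = "^trial_.*\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0) stop("no trial CSVs in ", cfg$data_dir)
    lapply(seq_along(files), function(k)
      read_trial_csv(files[k], meta = list(trial = k, file = files[k])))
  } else {
    make_dataset(cfg$n_trials, cfg$synth)
  }
}

#' Offline learning phase
#'
#' Runs the training leg of the protocol: load (or synthesize) the training
#' trials, take the MVC reference from the first trial (the MVC test),
#' condition every trial, extract sliding-window features, train the
#' estimator, and persist the model JSON plus a training report with split
#' sizes and per-trial held-out metrics.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `model`, `report`, `features`, `trials`.
#' @export
offline_phase <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- load_or_make_trials(cfg)
  chans <- names(trials[[1]]$channels)
  mvc <- vapply(chans, function(ch)
    compute_mvc(trials[[1]], ch, cfg$filter), numeric(1))
  feats <- bind_features(lapply(trials, function(tr)
    feature_matrix(preprocess_chain(tr, cfg$filter, mvc = mvc),
                   spec = cfg$window)))
  model <- bpnn_train(feats, cfg$train)
  model$mvc <- mvc
  bpnn_save(model, model_path(cfg))

  est <- bpnn_forward(model, feats$X)
  test_idx <- model$split$test
  held <- lapply(sort(unique(feats$trial)), function(id) {
    rows <- intersect(test_idx, which(feats$trial == id))
    list(id = id, est = est[rows], act = feats$y[rows])
  })
  metrics <- summarize_trials(held)
  report <- list(phase = "offline", seed = cfg$seed,
                 n_trials = length(trials),
                 n_windows = nrow(feats$X),
                 split_sizes = lapply(model$split, length),
                 mvc = as.list(mvc),
                 best_epoch = model$history$best_epoch,
                 held_out = metrics$summary,
                 per_trial = metrics$per_trial)
  jsonlite::write_json(report, file.path(cfg$out_dir, "training_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = model, report = report, features = feats,
                 trials = trials, metrics = metrics))
}

#' Online validation phase
#'
#' Streams a fresh trial (seed offset +1000 when synthetic) through the full
#' pipeline with the trained model and applies the acceptance gate: the model
#' is accepted when the trial's squared correlation reaches
#' `cfg$accept_threshold`, otherwise rejected for retraining. Refuses to run
#' when the offline model artifact is missing, unless `model` is supplied.
#'
#' @param cfg A [run_config()].
#' @param model Optional `bpnn_model`; by default loaded from the offline
#'   artifact in `cfg$out_dir`.
#' @param recording Optional validation recording; by default one fresh
#'   synthetic trial.
#' @return Invisibly, the validation report list (with `accept`).
#' @export
online_phase <- function(cfg, model = NULL, recording = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(model)) {
    if (!file.exists(model_path(cfg)))
      stop("offline model artifact not found (run offline_phase first): ",
           model_path(cfg))
    model <- bpnn_load(model_path(cfg))
  }
  if (is.null(recording)) {
    synth <- cfg$synth
    synth$seed <- cfg$seed + 1000L
    recording <- make_dataset(1, synth)[[1]]
  }
  res <- validate_online(model, recording, cfg$accept_threshold,
                         cfg$filter, cfg$window)
  report <- list(phase = "online", seed = cfg$seed, accept = res$accept,
                 r2 = res$r2, rmse = res$rmse, n_windows = res$n,
                 threshold = res$threshold)
  jsonlite::write_json(report, validation_path(cfg), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  est_df <- data.frame(t_s = res$t, est_n = res$estimate, act_n = res$actual)
  utils::write.csv(est_df, file.path(cfg$out_dir, "online_estimates.csv"),
                   row.names = FALSE)
  invisible(c(report, list(estimate = res$estimate, actual = res$actual,
                           t = res$t)))
}

#' Real-time assist phase (simulated)
#'
#' Runs the mirror bilateral assist loop in replay mode: the healthy-side
#' force of a fresh synthetic trial is the tracking reference; the simulated
#' affected limb contributes `impairment` times a healthy effort (its sEMG
#' envelope and force scaled accordingly); the PID loop commands the actuator
#' so the measured affected-side force tracks the reference. In parallel the
#' affected-side sEMG is streamed through the validated estimator to produce
#' the participation-assessment overlay (estimated active force per window),
#' which is independent of the assist itself.
#'
#' Refuses to run before a passing online validation unless `force = TRUE`.
#'
#' @param cfg A [run_config()].
#' @param model Optional `bpnn_model` (default: offline artifact).
#' @param force Skip the validation-gate check.
#' @return Invisibly, a list with `sim` (an `assist_sim`), `overlay`
#'   (data.frame `t_s, est_active_n, true_active_n`), and `report`.
#' @export
assist_phase <- function(cfg, model = NULL, force = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (!force) {
    if (!file.exists(validation_path(cfg)))
      stop("online validation artifact not found (run online_phase first): ",
           validation_path(cfg))
    val <- jsonlite::read_json(validation_path(cfg), simplifyVector = TRUE)
    if (!isTRUE(val$accept))
      stop("estimation model was rejected in online validation; ",
           "retrain before the assist phase (or use force = TRUE)")
  }
  if (is.null(model)) {
    if (!file.exists(model_path(cfg)))
      stop("offline model artifact not found: ", model_path(cfg))
    model <- bpnn_load(model_path(cfg))
  }
  healthy_cfg <- cfg$synth; healthy_cfg$seed <- cfg$seed + 2000L
  healthy <- make_dataset(1, healthy_cfg)[[1]]
  # the affected limb: same effort pattern, scaled envelope and force
  aff_cfg <- cfg$synth
  aff_cfg$seed <- cfg$seed + 3000L
  aff_cfg$A_mvc <- aff_cfg$A_rest +
    cfg$impairment * (aff_cfg$A_mvc - aff_cfg$A_rest)
  aff_cfg$F_max <- max(1e-6, cfg$impairment * aff_cfg$F_max)
  affected <- make_dataset(1, aff_cfg)[[1]]

  tau_human <- affected$force * cfg$plant$lever_arm
  sim <- simulate_assist(healthy$force, tau_human, cfg$plant, cfg$gains)

  processed <- preprocess_chain(affected, cfg$filter, mvc = model$mvc)
  feats <- feature_matrix(processed, spec = cfg$window)
  overlay <- data.frame(t_s = feats$t,
                        est_active_n = bpnn_forward(model, feats$X),
                        true_active_n = feats$y)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_assist_csv(sim, file.path(cfg$out_dir, "assist_sim.csv"))
  utils::write.csv(overlay, file.path(cfg$out_dir, "assist_overlay.csv"),
                   row.names = FALSE)
  tail_idx <- seq.int(max(1, floor(0.5 * length(sim$t))), length(sim$t))
  report <- list(phase = "assist", seed = cfg$seed,
                 impairment = cfg$impairment,
                 mae_tracking = bilateral_mae(sim$F_ref, sim$F_aff),
                 tail_mean_abs_err = mean(abs(sim$F_err[tail_idx])),
                 max_current = max(abs(sim$i_cmd)),
                 i_max = cfg$gains$i_max)
  jsonlite::write_json(report, file.path(cfg$out_dir, "assist_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, overlay = overlay, report = report))
}
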