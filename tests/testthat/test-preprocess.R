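fs <- 1000
spec <- filter_spec()
tgrid <- (0:(4 * fs - 1)) / fs

test_that("remove_dc centers a series and preserves shape", {
  expect_equal(remove_dc(c(2, 2, 2, 2)), c(0, 0, 0, 0))
  x <- sin(2 * pi * 5 * tgrid) + 0.7
  expect_equal(remove_dc(x), sin(2 * pi * 5 * tgrid), tolerance = 1e-10)
  z <- sin(2 * pi * 5 * tgrid)   # mean-free over full periods
  expect_equal(remove_dc(z), z, tolerance = 1e-10)
  expect_error(remove_dc(numeric(0)))
})

test_that("notch rejects 50 Hz by >= 20 dB and passes 100 Hz within 10%", {
  expect_equal(notch_50hz(rep(0, 1000), fs, spec), rep(0, 1000))
  # time-domain (implementation) route
  expect_lte(steady_amp(notch_50hz(sin(2 * pi * 50 * tgrid), fs, spec)), 0.1)
  expect_gte(steady_amp(notch_50hz(sin(2 * pi * 100 * tgrid), fs, spec)), 0.9)
  # independent magnitude-response oracle on the designed coefficients
  sos <- semgforce:::notch_sos(spec$notch_hz, spec$notch_q, fs)
  expect_lte(oracle_sos_gain(sos, 50, fs), 0.1)
  expect_gte(oracle_sos_gain(sos, 100, fs), 0.9)
  expect_error(notch_50hz(rep(0, 100), fs = 90, spec))
})

test_that("band-pass kills DC/sub-bass and passes mid-band near unity", {
  bp <- function(x) butterworth_bandpass(x, fs, spec, quiet = TRUE)
  const <- bp(rep(1, 3000))
  expect_lt(max(abs(const[2500:3000])), 1e-6)   # DC decays away
  expect_true(steady_amp(bp(sin(2 * pi * 100 * tgrid))) >= 0.95)
  expect_true(steady_amp(bp(sin(2 * pi * 100 * tgrid))) <= 1.05)
  expect_lte(steady_amp(bp(sin(2 * pi * 2 * tgrid))), 0.1)
  # same contracts through the independent frequency-response oracle
  sos <- semgforce:::butter_bandpass_sos(spec$bp_order, spec$bp_low,
                                         0.99 * fs / 2, fs)
  expect_true(abs(oracle_sos_gain(sos, 100, fs) - 1) <= 0.05)
  expect_lte(oracle_sos_gain(sos, 2, fs), 0.1)
  expect_lte(oracle_sos_gain(sos, 0, fs), 1e-10)
  # unrealizable edges error out
  bad <- filter_spec(bp_low = 400, bp_high = 500)
  expect_error(butterworth_bandpass(rep(0, 100), fs = 700, bad, quiet = TRUE),
               "band edges")
})

test_that("the printed 500 Hz upper edge is clamped with a message", {
  expect_message(butterworth_bandpass(sin(2 * pi * 100 * tgrid), fs, spec),
                 "clamped to 495")
})

test_that("full-wave rectification is the elementwise absolute value", {
  expect_equal(full_wave_rectify(c(-1, 2, -3)), c(1, 2, 3))
  expect_equal(full_wave_rectify(c(0.5, 0, 2)), c(0.5, 0, 2))
  expect_equal(full_wave_rectify(c(-0.5, 0, 0.5)), c(0.5, 0, 0.5))
})

test_that("MVC matches a brute-force window scan and rejects silence", {
  cfg <- quick_synth(duration_s = 5, seed = 21)
  rec <- make_dataset(1, cfg)[[1]]
  mvc <- compute_mvc(rec, "biceps", spec)
  expect_gt(mvc, 0)
  # oracle: rectified conditioned signal, max over every 0.2 s mean
  y <- abs(butterworth_bandpass(
    notch_50hz(remove_dc(rec$channels$biceps), rec$fs, spec),
    rec$fs, spec, quiet = TRUE))
  w <- round(0.2 * rec$fs)
  brute <- max(vapply(seq_len(length(y) - w + 1),
                      function(s) mean(y[s:(s + w - 1)]), numeric(1)))
  expect_equal(mvc, brute, tolerance = 0.15)
  # and it sits near the plateau envelope RMS-derived level
  expect_gt(mvc, 0.5 * cfg$A_mvc)
  zero <- emg_recording(fs, list(biceps = rep(0, 1000)), rep(0, 1000))
  expect_error(compute_mvc(zero, "biceps", spec), "all-zero")
  expect_error(compute_mvc(rec, "deltoid", spec), "unknown channel")
})

test_that("MVC normalization is an affine clamp to [0, 1]", {
  expect_equal(mvc_normalize(0.6, 0.6), 1.0)
  expect_equal(mvc_normalize(0, 0.6), 0.0)
  expect_equal(mvc_normalize(0.3, 0.6), 0.5)
  expect_equal(mvc_normalize(1.2, 0.6), 1.0)   # clamped
  expect_error(mvc_normalize(0.3, 0))
  expect_error(mvc_normalize(0.3, -1))
})

test_that("the full chain suppresses the mains line by >= 20 dB", {
  cfg <- quick_synth(duration_s = 4, mains_amp = 0.3, seed = 9)
  rec <- make_dataset(1, cfg)[[1]]
  suppressMessages(p <- preprocess_chain(rec))
  n <- length(rec$channels$biceps)
  bin <- 1 + 50 * (n / fs)                  # 50 Hz bin
  before <- Mod(fft(rec$channels$biceps))[bin]
  # drop the transient before measuring the settled spectrum
  after <- Mod(fft(p$filtered$biceps * c(rep(0, fs), rep(1, n - fs))))[bin]
  before_w <- Mod(fft(rec$channels$biceps * c(rep(0, fs), rep(1, n - fs))))[bin]
  expect_lt(after / before_w, 10^(-20 / 20))
  # structural invariants
  expect_true(all(p$rectified$biceps >= 0))
  expect_true(all(p$normalized$biceps >= 0 & p$normalized$biceps <= 1))
  expect_length(p$filtered$triceps, n)       # stages preserve sample count
})

test_that("the chain is linear up to rectification and causal", {
  cfg <- quick_synth(duration_s = 2, seed = 5)
  rec <- make_dataset(1, cfg)[[1]]
  mvc <- c(biceps = 1, triceps = 1)
  suppressMessages({
    p1 <- preprocess_chain(rec, mvc = mvc)
    rec3 <- rec
    rec3$channels <- lapply(rec$channels, function(x) 3 * x)
    p3 <- preprocess_chain(rec3, mvc = mvc)
  })
  expect_equal(p3$filtered$biceps, 3 * p1$filtered$biceps, tolerance = 1e-9)
  # causality: truncating the input does not change earlier output
  x <- rec$channels$biceps
  full <- butterworth_bandpass(x, fs, spec, quiet = TRUE)
  half <- butterworth_bandpass(x[1:1000], fs, spec, quiet = TRUE)
  expect_equal(full[1:1000], half, tolerance = 1e-12)
})

test_that("externally supplied MVC maps a zero recording to zero output", {
  zero <- emg_recording(fs, list(biceps = rep(0, 1000),
                                 triceps = rep(0, 1000)), rep(0, 1000))
  suppressMessages(
    p <- preprocess_chain(zero, mvc = c(biceps = 0.5, triceps = 0.5)))
  expect_true(all(p$normalized$biceps == 0))
  expect_error(preprocess_chain(zero))   # MVC undefined from silence
})
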