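rms <- function(x) sqrt(mean(x^2))

test_that("band-pass rejects the stop band and preserves the pass band", {
  rate <- 2000
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  core <- 2001:6000 # away from filtfilt edge transients
  rec50 <- make_recording(sin(2 * pi * 50 * t), rate)
  out50 <- bandpass_filter(rec50, 0.1, 30)
  expect_lt(rms(out50$data[1, core]) / rms(rec50$data[1, core]), 0.05)

  rec10 <- make_recording(sin(2 * pi * 10 * t), rate)
  out10 <- bandpass_filter(rec10, 0.1, 30)
  expect_equal(rms(out10$data[1, core]) / rms(rec10$data[1, core]),
               1, tolerance = 0.1)

  recdc <- make_recording(rep(3.7, length(t)), rate)
  expect_lt(abs(mean(bandpass_filter(recdc)$data[1, ])), 1e-9)

  expect_error(bandpass_filter(rec10, 0.1, 1500), "Nyquist")
  expect_error(bandpass_filter(rec10, 30, 0.1), "Nyquist|low < high")
})

test_that("notch filter removes line noise", {
  rate <- 2000
  t <- seq(0, 2 - 1 / rate, by = 1 / rate)
  rec <- make_recording(sin(2 * pi * 50 * t), rate,
                        events = data.frame(onset_sample = 2000L,
                                            symbol = "A", is_target = 1L))
  out <- notch_filter(rec, 50, 2)
  expect_lt(rms(out$data[1, 1001:3000]) / rms(rec$data[1, 1001:3000]), 0.05)
})

test_that("downsampling decimates by an integer factor and rescales events", {
  rate <- 2000
  sig <- sin(2 * pi * 2 * seq(0, 2 - 1 / rate, by = 1 / rate))
  rec <- make_recording(sig, rate,
                        events = data.frame(onset_sample = 2000L,
                                            symbol = "A", is_target = 1L))
  ds <- downsample(rec, 200)
  expect_equal(ncol(ds$data), 400)
  expect_equal(ds$rate, 200)
  expect_equal(ds$events$onset_sample, 200L)
  expect_equal(ds$data[1, ], rec$data[1, seq(1, 4000, by = 10)])

  expect_identical(downsample(rec, 2000), rec) # factor 1 = identity
  expect_error(downsample(rec, 300), "integer multiple")
})

test_that("epoching honors the window/baseline contract", {
  rate <- 200
  n <- 1000
  onset <- 500L
  # constant signal: baseline correction yields all-zero epochs
  rec_c <- make_recording(rep(2.5, n), rate,
                          events = data.frame(onset_sample = onset,
                                              symbol = "A", is_target = 1L))
  ep_c <- epoch_and_baseline(rec_c, c(-200, 800), c(-200, 0))
  expect_equal(dim(ep_c$data), c(1, 2, 200)) # 200 samples at 200 Hz
  expect_true(all(ep_c$data == 0))

  # step at onset: epoch is a step of height 1 at stimulus onset
  sig <- c(rep(0, onset - 1), rep(1, n - onset + 1))
  rec_s <- make_recording(sig, rate,
                          events = data.frame(onset_sample = onset,
                                              symbol = "A", is_target = 1L))
  ep_s <- epoch_and_baseline(rec_s, c(-200, 800), c(-200, 0))
  t <- epoch_times(ep_s)
  expect_true(all(ep_s$data[1, 1, t < 0] == 0))
  expect_true(all(ep_s$data[1, 1, t >= 0] == 1))

  # window exceeding the record names the offending event
  rec_e <- make_recording(rep(0, 400), rate,
                          events = data.frame(onset_sample = c(150L, 390L),
                                              symbol = c("A", "B"),
                                              is_target = c(1L, 0L)))
  expect_error(epoch_and_baseline(rec_e, c(-200, 800), c(-200, 0)),
               "event 2.*symbol B|symbol B")
})

test_that("baseline correction is idempotent", {
  set.seed(4)
  arr <- array(rnorm(5 * 2 * 100, mean = 3), c(5, 2, 100))
  ep <- make_epochs(arr, labels = c(1, 0, 0, 1, 0), rate = 200,
                    window = c(-200, 300))
  b1 <- baseline_correct(ep, c(-200, 0))
  b2 <- baseline_correct(b1, c(-200, 0))
  expect_equal(b1$data, b2$data)
  # baseline segment mean is (numerically) zero afterwards
  t <- epoch_times(b1)
  expect_lt(max(abs(apply(b1$data[, , t < 0], c(1, 2), mean))), 1e-12)
})

test_that("channel selection restricts, reorders, and errors on unknowns", {
  set.seed(5)
  arr <- array(rnorm(3 * 4 * 10), c(3, 4, 10))
  ep <- make_epochs(arr, labels = c(1, 0, 0), rate = 1000, window = c(0, 10))
  sel <- select_channels(ep, c("CH03", "CH01"))
  expect_equal(sel$channel_names, c("CH03", "CH01"))
  expect_equal(sel$data[, 1, ], arr[, 3, ])
  expect_equal(sel$data[, 2, ], arr[, 1, ])
  expect_identical(select_channels(ep, ep$channel_names)$data, ep$data)
  expect_error(select_channels(ep, c("CH01", "XX")), "XX")
})

test_that("decimation commutes with epoching for on-grid events", {
  rate <- 2000
  k <- 10L
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  sig <- 3 * sin(2 * pi * 5 * t) + sin(2 * pi * 11 * t)
  onset <- 4001L # on the decimation grid (== 1 mod k)
  rec <- bandpass_filter(make_recording(
    sig, rate, events = data.frame(onset_sample = onset, symbol = "A",
                                   is_target = 1L)))
  # path A: decimate then epoch at 200 Hz
  a <- epoch_and_baseline(downsample(rec, 200), c(-200, 800), c(-200, 0))
  # path B: epoch at 2000 Hz, then decimate the epoch samples and
  # re-baseline on the decimated grid
  b_full <- epoch_and_baseline(rec, c(-200, 800), c(-200, 0))
  keep <- seq(1, dim(b_full$data)[3], by = k)
  bsamp <- b_full$data[, , keep, drop = FALSE]
  tb <- epoch_times(a)
  base <- apply(bsamp[, , tb < 0, drop = FALSE], c(1, 2), mean)
  bsamp <- bsamp - as.vector(base)
  expect_lt(max(abs(a$data - bsamp)) / max(abs(sig)), 1e-6)
})

test_that("the default pipeline yields 6 x 200 epochs from a 64-channel record", {
  rate <- 2000
  n <- rate * 6
  set.seed(11)
  chans <- c(analysis_channels(),
             sprintf("X%02d", seq_len(58)))
  data <- matrix(rnorm(64 * n), nrow = 64)
  events <- data.frame(onset_sample = c(4001L, 6001L, 8001L),
                       symbol = c("A", "B", "C"),
                       is_target = c(1L, 0L, 0L))
  rec <- raw_recording(data, rate, chans, events)
  ep <- preprocess_recording(rec)
  expect_equal(dim(ep$data), c(3, 6, 200))
  expect_equal(ep$channel_names, analysis_channels())
  expect_equal(ep$rate, 200)
})
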