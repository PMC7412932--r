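# Preprocessing chain: re-reference -> band-pass -> (notch) -> downsample ->
# epoch + baseline -> channel selection. All filters are zero-phase
# (forward-backward) so ERP latencies are not distorted.

#' Zero-phase Butterworth band-pass filter
#'
#' Removes each channel's mean, then applies a 2nd-order high-pass at `low`
#' and a 4th-order low-pass at `high`, each forward-backward
#' ([signal::filtfilt()]) for zero phase. The cascade is used instead of a
#' single band-pass section because the low edge (0.1 Hz at a 2000 Hz rate)
#' makes a direct high-order band-pass numerically unstable.
#'
#' @param rec A [raw_recording()].
#' @param low,high Band edges in Hz; `0 < low < high < rate/2`.
#' @return A [raw_recording()] with filtered data (same shape and rate).
#' @export
bandpass_filter <- function(rec, low = 0.1, high = 30) {
  stopifnot(inherits(rec, "raw_recording"))
  nyq <- rec$rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop2(sprintf("band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
                  low, high, nyq))
  hp <- signal::butter(2, low / nyq, type = "high")
  lp <- signal::butter(4, high / nyq, type = "low")
  out <- rec$data - rowMeans(rec$data)
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- signal::filtfilt(lp, signal::filtfilt(hp, out[ch, ]))
  }
  rec$data <- out
  rec
}

#' Zero-phase notch filter for line noise
#'
#' 2nd-order Butterworth band-stop around `freq`, applied forward-backward.
#' Optional stage; line noise is usually removed at acquisition.
#'
#' @param rec A [raw_recording()].
#' @param freq Center frequency in Hz (default 50, mains in 50 Hz regions).
#' @param width Half-width of the stop band in Hz.
#' @return A filtered [raw_recording()].
#' @export
notch_filter <- function(rec, freq = 50, width = 2) {
  stopifnot(inherits(rec, "raw_recording"))
  nyq <- rec$rate / 2
  if (freq - width <= 0 || freq + width >= nyq)
    stop2("notch band must lie strictly inside (0, Nyquist)")
  bs <- signal::butter(2, c(freq - width, freq + width) / nyq, type = "stop")
  for (ch in seq_len(nrow(rec$data)))
    rec$data[ch, ] <- signal::filtfilt(bs, rec$data[ch, ])
  rec
}

#' Re-reference a recording to the mean of reference channels
#'
#' Subtracts the average of the named channels (e.g. ear/mastoid electrodes)
#' from every channel. Applied only when such channels exist; simulated
#' cohorts are generated reference-free and skip this stage.
#'
#' @param rec A [raw_recording()].
#' @param ref_channels Character vector of reference channel names.
#' @return A re-referenced [raw_recording()].
#' @export
rereference <- function(rec, ref_channels) {
  stopifnot(inherits(rec, "raw_recording"))
  miss <- setdiff(ref_channels, rec$channel_names)
  if (length(miss))
    stop2("unknown reference channel(s): ", paste(miss, collapse = ", "))
  idx <- match(ref_channels, rec$channel_names)
  ref <- colMeans(rec$data[idx, , drop = FALSE])
  rec$data <- sweep(rec$data, 2L, ref)
  rec
}

#' Downsample a recording by an integer factor
#'
#' Pure decimation (every k-th sample kept); the signal must already be
#' low-passed below `target_rate / 2` (as [bandpass_filter()] with
#' `high < target_rate / 2` guarantees), so no further anti-alias filter is
#' applied. Event onsets are rescaled onto the decimated grid.
#'
#' @param rec A [raw_recording()].
#' @param target_rate Target rate in Hz; `rate / target_rate` must be a
#'   whole number.
#' @return A [raw_recording()] at `target_rate`.
#' @export
downsample <- function(rec, target_rate) {
  stopifnot(inherits(rec, "raw_recording"))
  factor <- rec$rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop2(sprintf("rate %g Hz is not an integer multiple of target %g Hz",
                  rec$rate, target_rate))
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  keep <- seq(1L, ncol(rec$data), by = factor)
  rec$data <- rec$data[, keep, drop = FALSE]
  rec$rate <- target_rate
  rec$events$onset_sample <- (rec$events$onset_sample - 1L) %/% factor + 1L
  rec
}

#' Cut epochs around stimulus events and baseline-correct them
#'
#' Extracts the half-open window `[window[1], window[2])` ms around each
#' event onset and subtracts, per epoch and channel, the mean of the
#' baseline segment `[baseline[1], baseline[2])` ms. Extra event columns
#' `block`, `trial`, `round` are carried into the epoch set.
#'
#' @param rec A [raw_recording()].
#' @param window Epoch window in ms relative to stimulus onset.
#' @param baseline Baseline segment in ms; must lie within `window`.
#' @param subject_id Identifier stored on the resulting epoch set.
#' @return An [epoch_set()] with one epoch per event.
#' @export
epoch_and_baseline <- function(rec, window = c(-200, 800),
                               baseline = c(-200, 0), subject_id = "S01") {
  stopifnot(inherits(rec, "raw_recording"))
  if (baseline[1L] < window[1L] || baseline[2L] > window[2L])
    stop2("baseline segment must lie within the epoch window")
  rate <- rec$rate
  off0 <- round(window[1L] * rate / 1000)
  n_samp <- round((window[2L] - window[1L]) * rate / 1000)
  b0 <- round(baseline[1L] * rate / 1000)
  b1 <- round(baseline[2L] * rate / 1000)
  base_idx <- seq.int(b0 - off0 + 1L, b1 - off0) # within-epoch samples
  ev <- rec$events
  n_ev <- nrow(ev)
  n_ch <- nrow(rec$data)
  arr <- array(0, c(n_ev, n_ch, n_samp))
  for (j in seq_len(n_ev)) {
    s0 <- ev$onset_sample[j] + off0
    s1 <- s0 + n_samp - 1L
    if (s0 < 1L || s1 > ncol(rec$data))
      stop2(sprintf(
        "epoch window for event %d (symbol %s, onset sample %d) exceeds the recording",
        j, ev$symbol[j], ev$onset_sample[j]))
    ep <- rec$data[, s0:s1, drop = FALSE]
    ep <- ep - rowMeans(ep[, base_idx, drop = FALSE])
    arr[j, , ] <- ep
  }
  epoch_set(arr, labels = as.integer(ev$is_target), symbols = ev$symbol,
            rate = rate, window = window, channel_names = rec$channel_names,
            subject_id = subject_id,
            block = ev$block, trial = ev$trial, round = ev$round)
}

#' Apply (or re-apply) baseline correction to an epoch set
#'
#' Subtracts the per-epoch, per-channel mean of the baseline segment.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param epochs An [epoch_set()].
#' @param baseline Baseline segment in ms within the epoch window.
#' @return A baseline-corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, baseline = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  t <- epoch_times(epochs)
  idx <- which(t >= baseline[1L] & t < baseline[2L])
  if (!length(idx)) stop2("baseline segment contains no samples")
  means <- apply(epochs$data[, , idx, drop = FALSE], c(1L, 2L), mean)
  epochs$data <- epochs$data - as.vector(means) # recycles over sample axis
  epochs
}

#' Restrict and reorder the channels of an epoch set
#'
#' @param epochs An [epoch_set()].
#' @param names Channel names to keep, in the desired order.
#' @return An [epoch_set()] whose channel axis is exactly `names`.
#' @export
select_channels <- function(epochs, names) {
  stopifnot(inherits(epochs, "epoch_set"))
  miss <- setdiff(names, epochs$channel_names)
  if (length(miss))
    stop2("unknown channel(s): ", paste(miss, collapse = ", "))
  idx <- match(names, epochs$channel_names)
  epochs$data <- epochs$data[, idx, , drop = FALSE]
  epochs$channel_names <- as.character(names)
  epochs
}

#' Standard preprocessing pipeline for a raw recording
#'
#' Band-pass, downsample, epoch + baseline, select analysis channels, in
#' that order, with the standard defaults (0.1-30 Hz, 200 Hz, -200..800 ms
#' window, -200..0 ms baseline, six midline/occipital channels).
#'
#' @param rec A [raw_recording()].
#' @param low,high Band edges, Hz.
#' @param target_rate Analysis rate, Hz.
#' @param window,baseline Epoch window and baseline segment, ms.
#' @param channels Channels to keep (`NULL` keeps all).
#' @param subject_id Identifier for the resulting epoch set.
#' @return An [epoch_set()].
#' @export
preprocess_recording <- function(rec, low = 0.1, high = 30,
                                 target_rate = 200,
                                 window = c(-200, 800),
                                 baseline = c(-200, 0),
                                 channels = DEFAULT_CHANNELS,
                                 subject_id = "S01") {
  rec <- bandpass_filter(rec, low, high)
  rec <- downsample(rec, target_rate)
  ep <- epoch_and_baseline(rec, window, baseline, subject_id)
  if (!is.null(channels)) ep <- select_channels(ep, channels)
  ep
}
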