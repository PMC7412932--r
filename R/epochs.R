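#' Labeled single-trial epoch container
#'
#' Holds one subject's epoched EEG: a numeric array of dimension
#' `n_epochs x n_channels x n_samples` (microvolts), a binary target label
#' and a symbol identity per epoch, the sampling rate and the epoch window
#' relative to stimulus onset. Optional block/trial/round indices carry the
#' speller session structure needed for symbol-level decoding and
#' calibration splits.
#'
#' The sample axis covers the half-open window `[window[1], window[2])` ms:
#' sample `k` (1-based) sits at `window[1] + (k-1) * 1000/rate` ms relative
#' to stimulus onset.
#'
#' @param data Numeric array `n_epochs x n_channels x n_samples`.
#' @param labels Integer/logical vector, 1 = target epoch, 0 = nontarget.
#' @param symbols Character vector of presented symbols, one per epoch.
#' @param rate Sampling rate in Hz.
#' @param window Length-2 numeric, epoch window in ms relative to onset.
#' @param channel_names Character vector naming the channel axis.
#' @param subject_id Subject identifier string.
#' @param block,trial,round Optional integer vectors (one per epoch) giving
#'   the session position of each presentation.
#' @param epoch_ids Optional character ids; defaults to
#'   `"<subject>#<index>"`. Used for provenance assertions downstream.
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, labels, symbols, rate, window, channel_names,
                      subject_id = "S01", block = NULL, trial = NULL,
                      round = NULL, epoch_ids = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop2("`data` must be a 3-d array (epochs x channels x samples)")
  d <- dim(data)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop2("`labels` must be binary (0/1)")
  if (length(labels) != d[1L]) stop2("length(labels) must equal n_epochs")
  if (length(symbols) != d[1L]) stop2("length(symbols) must equal n_epochs")
  if (length(channel_names) != d[2L])
    stop2("length(channel_names) must equal n_channels")
  if (anyDuplicated(channel_names)) stop2("channel names must be unique")
  assert_scalar_number(rate, "rate", lower = 1e-9)
  if (length(window) != 2L || window[2L] <= window[1L])
    stop2("`window` must be (start_ms, end_ms) with end > start")
  n_expect <- (window[2L] - window[1L]) / 1000 * rate
  if (abs(n_expect - d[3L]) > 1e-6)
    stop2(sprintf("n_samples (%d) != window span x rate (%g)", d[3L], n_expect))
  for (nm in c("block", "trial", "round")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != d[1L])
      stop2(sprintf("`%s` must have one entry per epoch", nm))
  }
  if (is.null(epoch_ids))
    epoch_ids <- sprintf("%s#%d", subject_id, seq_len(d[1L]))
  structure(list(
    subject_id = subject_id,
    data = data,
    labels = labels,
    symbols = as.character(symbols),
    rate = rate,
    window = as.numeric(window),
    channel_names = as.character(channel_names),
    block = if (is.null(block)) NULL else as.integer(block),
    trial = if (is.null(trial)) NULL else as.integer(trial),
    round = if (is.null(round)) NULL else as.integer(round),
    epoch_ids = as.character(epoch_ids)
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> subject %s: %d epochs (%d targets) x %d channels x %d samples\n",
    x$subject_id, d[1L], sum(x$labels), d[2L], d[3L]))
  cat(sprintf("  %g Hz, window [%g, %g) ms, channels: %s\n", x$rate,
              x$window[1L], x$window[2L],
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Sample times of an epoch set
#'
#' @param epochs An [epoch_set()] (or an `erp_waveform`).
#' @return Numeric vector of per-sample times in ms relative to stimulus
#'   onset (start of the half-open window per sample).
#' @export
epoch_times <- function(epochs) {
  ns <- if (inherits(epochs, "epoch_set")) dim(epochs$data)[3L] else
    ncol(epochs$target_mean)
  epochs$window[1L] + (seq_len(ns) - 1L) * 1000 / epochs$rate
}

#' Subset an epoch set by epoch index
#'
#' @param epochs An [epoch_set()].
#' @param i Integer or logical index over epochs.
#' @return An [epoch_set()] with the selected epochs; session structure and
#'   epoch ids follow the subset.
#' @export
subset_epochs <- function(epochs, i) {
  stopifnot(inherits(epochs, "epoch_set"))
  epoch_set(
    data = epochs$data[i, , , drop = FALSE],
    labels = epochs$labels[i],
    symbols = epochs$symbols[i],
    rate = epochs$rate, window = epochs$window,
    channel_names = epochs$channel_names,
    subject_id = epochs$subject_id,
    block = epochs$block[i], trial = epochs$trial[i],
    round = epochs$round[i], epoch_ids = epochs$epoch_ids[i])
}

#' Continuous multichannel recording with stimulus events
#'
#' Minimal raw-recording container for the preprocessing chain: a
#' `channels x samples` matrix in microvolts plus an event table tying
#' stimulus onsets (1-based sample indices) to symbols and target flags.
#'
#' @param data Numeric matrix `n_channels x n_samples` (microvolts).
#' @param rate Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param events `data.frame` with columns `onset_sample` (1-based),
#'   `symbol`, `is_target`; optional extra columns (e.g. `block`, `trial`,
#'   `round`) are carried through epoching.
#' @return A `raw_recording` object.
#' @export
raw_recording <- function(data, rate, channel_names, events) {
  if (!is.matrix(data)) stop2("`data` must be a channels x samples matrix")
  if (length(channel_names) != nrow(data))
    stop2("one channel name per data row required")
  if (anyDuplicated(channel_names)) stop2("channel names must be unique")
  assert_scalar_number(rate, "rate", lower = 1e-9)
  req <- c("onset_sample", "symbol", "is_target")
  if (!is.data.frame(events) || !all(req %in% names(events)))
    stop2("`events` needs columns onset_sample, symbol, is_target")
  if (nrow(events) > 0 &&
      (min(events$onset_sample) < 1 || max(events$onset_sample) > ncol(data)))
    stop2("event onset samples must lie within the recording")
  structure(list(
    data = data, rate = rate,
    channel_names = as.character(channel_names),
    events = events
  ), class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$rate, nrow(x$events)))
  invisible(x)
}
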