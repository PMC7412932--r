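# Shared fixtures and independent oracles for the test suite.

# A small session: 2 blocks x 2 trials x 2 rounds x 6 symbols = 48 epochs.
small_paradigm <- function(n_symbols = 6L, ...) {
  paradigm_config(n_symbols = n_symbols, rounds_per_trial = 2L,
                  trials_per_block = 2L, n_blocks = 2L, ...)
}

# Build an erp_waveform directly from a channels x samples target mean.
fake_erp <- function(target_mean, subject_id = "S01", rate = 200,
                     window = NULL) {
  target_mean <- as.matrix(target_mean)
  if (is.null(window)) window <- c(0, ncol(target_mean) * 1000 / rate)
  structure(list(
    subject_id = subject_id,
    target_mean = target_mean,
    nontarget_mean = target_mean * 0,
    n_target_epochs = 1L, n_nontarget_epochs = 1L,
    rate = rate, window = window,
    channel_names = sprintf("CH%02d", seq_len(nrow(target_mean)))
  ), class = "erp_waveform")
}

# Minimal epoch_set from an epochs x channels x samples array.
make_epochs <- function(arr, labels, symbols = NULL, rate = 1000,
                        window = NULL, ...) {
  if (is.null(window)) window <- c(0, dim(arr)[3] * 1000 / rate)
  if (is.null(symbols)) symbols <- LETTERS[(seq_len(dim(arr)[1]) - 1) %% 26 + 1]
  epoch_set(arr, labels, symbols, rate, window,
            sprintf("CH%02d", seq_len(dim(arr)[2])), ...)
}

# Brute-force AUC: count target/nontarget pairs, ties 1/2.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Brute-force match counts: double loop over subject pairs.
match_counts_oracle <- function(vecs, threshold) {
  n <- length(vecs)
  counts <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cs <- sum(vecs[[i]] * vecs[[j]]) /
      (sqrt(sum(vecs[[i]]^2)) * sqrt(sum(vecs[[j]]^2)))
    if (cs > threshold) counts[i] <- counts[i] + 1L
  }
  counts
}

# Hand evaluation of the (n-1)-denominator correlation formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sum(((x - mean(x)) / sd(x)) * ((y - mean(y)) / sd(y))) / (n - 1)
}

# Recording with a sinusoidal (or supplied) signal and events on the
# decimation grid, for preprocessing tests.
make_recording <- function(signal, rate = 2000, n_channels = 2,
                           events = data.frame(onset_sample = 4001L,
                                               symbol = "A",
                                               is_target = 1L)) {
  data <- matrix(rep(signal, each = n_channels), nrow = n_channels)
  raw_recording(data, rate, sprintf("CH%02d", seq_len(n_channels)), events)
}
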