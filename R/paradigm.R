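#' RSVP speller paradigm configuration
#'
#' Session structure and timing constants for a rapid serial visual
#' presentation (RSVP) speller. Defaults reproduce a standard alphabetic
#' RSVP session: 26 symbols flashed for 200 ms with a 100 ms off period
#' (300 ms stimulus-onset asynchrony), 5 rounds per trial (one trial spells
#' one target letter), 8 trials per block and 20 blocks per session,
#' acquired at 2000 Hz.
#'
#' @param n_symbols Number of spellable symbols (classes). Symbols are the
#'   first `n_symbols` capital letters for `n_symbols <= 26`, otherwise
#'   `"S01"`, `"S02"`, ....
#' @param flash_duration Stimulus-on duration in ms.
#' @param off_duration Inter-stimulus off duration in ms.
#' @param rounds_per_trial Complete symbol sweeps per target selection.
#' @param trials_per_block Target letters per block.
#' @param n_blocks Blocks per session.
#' @param acquisition_rate EEG acquisition sampling rate in Hz.
#' @param symbol_order `"sequential"` presents symbols in fixed A-to-Z order
#'   within each round; `"random"` permutes each round.
#' @return A `paradigm_config` object (list with the fields above plus
#'   `symbols`).
#' @examples
#' p <- paradigm_config()
#' soa(p)                 # 300 ms
#' n_session_epochs(p)    # 20800
#' @export
paradigm_config <- function(n_symbols = 26L,
                            flash_duration = 200,
                            off_duration = 100,
                            rounds_per_trial = 5L,
                            trials_per_block = 8L,
                            n_blocks = 20L,
                            acquisition_rate = 2000,
                            symbol_order = c("sequential", "random")) {
  symbol_order <- match.arg(symbol_order)
  counts <- c(n_symbols = n_symbols, rounds_per_trial = rounds_per_trial,
              trials_per_block = trials_per_block, n_blocks = n_blocks)
  for (nm in names(counts)) {
    if (counts[[nm]] < 1 || counts[[nm]] != round(counts[[nm]]))
      stop2(sprintf("`%s` must be a positive integer", nm))
  }
  assert_scalar_number(flash_duration, "flash_duration")
  assert_scalar_number(off_duration, "off_duration")
  assert_scalar_number(acquisition_rate, "acquisition_rate")
  if (flash_duration <= 0 || off_duration <= 0)
    stop2("flash_duration and off_duration must be > 0")
  if (acquisition_rate <= 0) stop2("acquisition_rate must be > 0")
  if (trials_per_block > n_symbols)
    stop2("trials_per_block cannot exceed n_symbols (distinct targets per block)")
  symbols <- if (n_symbols <= 26L) LETTERS[seq_len(n_symbols)] else
    sprintf("S%02d", seq_len(n_symbols))
  structure(list(
    n_symbols = as.integer(n_symbols),
    flash_duration = flash_duration,
    off_duration = off_duration,
    rounds_per_trial = as.integer(rounds_per_trial),
    trials_per_block = as.integer(trials_per_block),
    n_blocks = as.integer(n_blocks),
    acquisition_rate = acquisition_rate,
    symbol_order = symbol_order,
    symbols = symbols
  ), class = "paradigm_config")
}

#' Stimulus-onset asynchrony of a paradigm
#'
#' @param paradigm A [paradigm_config()].
#' @return SOA in ms (flash + off duration).
#' @export
soa <- function(paradigm) {
  stopifnot(inherits(paradigm, "paradigm_config"))
  paradigm$flash_duration + paradigm$off_duration
}

#' Total epochs in one session under a paradigm
#'
#' @param paradigm A [paradigm_config()].
#' @return Named integer vector with `total` (blocks x trials x rounds x
#'   symbols) and `targets` (blocks x trials x rounds).
#' @export
n_session_epochs <- function(paradigm) {
  stopifnot(inherits(paradigm, "paradigm_config"))
  tg <- paradigm$n_blocks * paradigm$trials_per_block * paradigm$rounds_per_trial
  c(total = tg * paradigm$n_symbols, targets = tg)
}

#' @export
print.paradigm_config <- function(x, ...) {
  cat(sprintf(
    "RSVP paradigm: %d symbols (%s), %g ms flash + %g ms off (SOA %g ms)\n",
    x$n_symbols, x$symbol_order, x$flash_duration, x$off_duration, soa(x)))
  cat(sprintf("  %d blocks x %d trials x %d rounds; acquisition %g Hz\n",
              x$n_blocks, x$trials_per_block, x$rounds_per_trial,
              x$acquisition_rate))
  invisible(x)
}
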