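# Speller-level performance: symbol selection accuracy and information
# transfer rate (Wolpaw-style bits per minute).

#' Stimulus time of one symbol selection
#'
#' One selection (trial) presents every symbol once per round for
#' `rounds_per_trial` rounds, each presentation occupying one
#' stimulus-onset asynchrony. Pauses between trials are not included; the
#' value can be overridden wherever a `T` is accepted.
#'
#' @param paradigm A [paradigm_config()].
#' @return Selection time in minutes:
#'   `rounds_per_trial * n_symbols * SOA / 60000`.
#' @examples
#' selection_time(paradigm_config()) # 5 * 26 * 300 ms = 0.65 min
#' @export
selection_time <- function(paradigm) {
  stopifnot(inherits(paradigm, "paradigm_config"))
  paradigm$rounds_per_trial * paradigm$n_symbols * soa(paradigm) / 60000
}

#' Symbol selection accuracy from classifier scores
#'
#' For every trial, each candidate symbol's decision scores are summed
#' across its `rounds_per_trial` presentations and the symbol with the
#' largest sum is predicted (ties broken toward the alphabetically first
#' symbol). Accuracy `P` is the fraction of trials whose predicted symbol
#' is the true target.
#'
#' @param epochs An [epoch_set()] carrying `block`, `trial`, `round` and
#'   symbol identities.
#' @param clf An `lda_classifier` from [fit_lda()].
#' @param cfg The [feature_config()] the classifier was trained with.
#' @return List with `P` (accuracy), `n_trials`, and a data.frame
#'   `per_trial` (`block`, `trial`, `target`, `predicted`, `correct`).
#' @export
symbol_accuracy <- function(epochs, clf, cfg = feature_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(epochs$block) || is.null(epochs$trial))
    stop2("epochs lack block/trial structure required for symbol decoding")
  scores <- predict(clf, extract_features(epochs, cfg))
  key <- paste(epochs$block, epochs$trial, sep = ".")
  trials <- unique(key)
  per_trial <- do.call(rbind, lapply(trials, function(k) {
    idx <- which(key == k)
    sym <- epochs$symbols[idx]
    tot <- tapply(scores[idx], sym, sum)
    tot <- tot[order(names(tot))] # alphabetical tie-break via which.max
    predicted <- names(tot)[which.max(tot)]
    target <- unique(sym[epochs$labels[idx] == 1L])
    if (length(target) != 1L)
      stop2("trial ", k, " does not have exactly one target symbol")
    data.frame(block = epochs$block[idx][1L], trial = epochs$trial[idx][1L],
               target = target, predicted = predicted,
               correct = predicted == target, stringsAsFactors = FALSE)
  }))
  list(P = mean(per_trial$correct), n_trials = nrow(per_trial),
       per_trial = per_trial)
}

#' Information transfer rate of a speller
#'
#' Wolpaw-style ITR: with `N` classes, selection accuracy `P` and selection
#' time `T` minutes, the bits per selection are
#' `log2(N) + P log2(P) + (1 - P) log2((1 - P)/(N - 1))`
#' (with `p log2 p` taken as 0 at `p = 0` by continuity) and the rate is
#' bits per selection divided by `T`. At `P = 1` this is `log2(N)/T`; at
#' chance (`P = 1/N`) it is exactly 0. Below-chance `P` is rejected: the
#' formula would go negative and has no operational meaning there.
#'
#' @param N Number of classes (>= 2).
#' @param P Selection accuracy in `[1/N, 1]`.
#' @param T Selection time in minutes (> 0), e.g. from
#'   [selection_time()].
#' @return An `itr_result`: list with `N`, `P`, `T`, `bits_per_selection`
#'   and `itr` (bits/min).
#' @examples
#' compute_itr(26, 1, 0.65)$itr   # log2(26)/0.65 = 7.231 bits/min
#' @export
compute_itr <- function(N, P, T) {
  if (N < 2 || N != round(N)) stop2("N must be an integer >= 2")
  assert_scalar_number(T, "T")
  if (T <= 0) stop2("selection time T must be > 0")
  assert_scalar_number(P, "P", lower = 0, upper = 1)
  if (P < 1 / N - 1e-12)
    stop2(sprintf("P (%g) is below chance (1/%d); ITR is undefined there", P, N))
  plog2p <- function(p) if (p <= 0) 0 else p * log2(p)
  bits <- log2(N) + plog2p(P) +
    (if (P >= 1) 0 else (1 - P) * log2((1 - P) / (N - 1)))
  structure(list(N = as.integer(N), P = P, T = T,
                 bits_per_selection = bits, itr = bits / T),
            class = "itr_result")
}

#' @export
print.itr_result <- function(x, ...) {
  cat(sprintf(
    "<itr_result> N = %d, P = %.3f, T = %.4g min: %.3f bits/selection, %.3f bits/min\n",
    x$N, x$P, x$T, x$bits_per_selection, x$itr))
  invisible(x)
}
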