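# Synthetic multi-subject RSVP cohort generator.
#
# Signal model per epoch: x = topography (x) p300_template + pink noise for
# target presentations, pure pink noise for nontargets. Subjects are drawn
# around cluster centers so inter-subject ERP similarity has a recoverable
# structure for donor-ranking experiments.

DEFAULT_CHANNELS <- c("FZ", "CZ", "PZ", "O1", "O2", "OZ")
# Centro-parietal dominant weights for the six analysis channels, max-normed.
DEFAULT_TOPOGRAPHY <- c(FZ = 0.6, CZ = 0.85, PZ = 1.0,
                        O1 = 0.45, O2 = 0.45, OZ = 0.55)

#' Single-channel P300 template waveform
#'
#' A smooth unimodal positive deflection modeled as a Gaussian bump, the
#' evoked component added to target epochs by the cohort simulator. The
#' bump peaks at `latency` with value `amplitude` and has full width at
#' half maximum `width`; it is numerically zero throughout a pre-stimulus
#' baseline that is more than a couple of widths away from the peak.
#'
#' @param latency Peak time in ms relative to stimulus onset.
#' @param amplitude Peak amplitude in microvolts (>= 0).
#' @param width Full width at half maximum, ms (> 0).
#' @param window Epoch window (start_ms, end_ms); must contain `latency`.
#' @param rate Sampling rate in Hz.
#' @return Numeric vector of `diff(window)/1000 * rate` samples.
#' @examples
#' w <- p300_template(350, 5, 70)
#' which.max(w)   # sample nearest 350 ms
#' @export
p300_template <- function(latency, amplitude, width,
                          window = c(-200, 800), rate = 200) {
  assert_scalar_number(latency, "latency")
  assert_scalar_number(amplitude, "amplitude", lower = 0)
  assert_scalar_number(width, "width", lower = 1e-9)
  assert_scalar_number(rate, "rate", lower = 1e-9)
  if (latency < window[1L] || latency >= window[2L])
    stop2(sprintf("latency %g ms lies outside the epoch window [%g, %g) ms",
                  latency, window[1L], window[2L]))
  n <- round((window[2L] - window[1L]) / 1000 * rate)
  t <- window[1L] + (seq_len(n) - 1L) * 1000 / rate
  sigma <- width / (2 * sqrt(2 * log(2))) # FWHM -> Gaussian sd
  amplitude * exp(-0.5 * ((t - latency) / sigma)^2)
}

# 1/f^alpha ("pink" for alpha = 1) noise by spectral shaping: white Gaussian
# noise is filtered in the frequency domain with |H(f)| = f^(-alpha/2), the DC
# bin is zeroed, and the shaping gains are scaled so each series has expected
# variance sd^2. Columns are independent series. Consumes the RNG stream.
pink_noise <- function(n_samples, n_series, rate, sd = 1, exponent = 1) {
  if (sd == 0) return(matrix(0, n_samples, n_series))
  w <- matrix(stats::rnorm(n_samples * n_series), n_samples, n_series)
  if (exponent == 0) return(w * sd)
  k <- seq_len(n_samples) - 1L
  freq <- k * rate / n_samples
  # mirror frequencies above Nyquist onto their aliases
  freq <- pmin(freq, rate - freq)
  gain <- c(0, freq[-1L]^(-exponent / 2))
  gain <- gain * sd / sqrt(sum(gain^2) / n_samples) # E[var] = sd^2
  f <- stats::mvfft(w) * gain
  Re(stats::mvfft(f, inverse = TRUE)) / n_samples
}

#' Subject archetype: latent ERP parameters of one simulated subject
#'
#' @param subject_id Identifier string.
#' @param p300_latency Peak latency, ms.
#' @param p300_amplitude Peak amplitude, microvolts (>= 0).
#' @param p300_width Full width at half maximum, ms (> 0).
#' @param topography Per-channel weight vector; rescaled so the maximum
#'   absolute weight is 1 (unless all-zero).
#' @param noise_sd Per-sample noise standard deviation, microvolts (> 0).
#' @param pink_exponent Spectral slope alpha of the 1/f^alpha noise.
#' @param cluster_id Optional cluster label (ground truth for donor-ranking
#'   experiments).
#' @return A `subject_archetype` object.
#' @export
subject_archetype <- function(subject_id, p300_latency = 350,
                              p300_amplitude = 5, p300_width = 70,
                              topography = DEFAULT_TOPOGRAPHY,
                              noise_sd = 8, pink_exponent = 1,
                              cluster_id = NA_integer_) {
  assert_scalar_number(p300_amplitude, "p300_amplitude", lower = 0)
  assert_scalar_number(p300_width, "p300_width", lower = 1e-9)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0) # 0 = noiseless limit
  m <- max(abs(topography))
  if (m > 0) topography <- topography / m
  structure(list(
    subject_id = subject_id, cluster_id = cluster_id,
    p300_latency = p300_latency, p300_amplitude = p300_amplitude,
    p300_width = p300_width, topography = topography,
    noise_sd = noise_sd, pink_exponent = pink_exponent
  ), class = "subject_archetype")
}

#' Simulate one subject's epoched RSVP session
#'
#' Generates every symbol presentation of a session directly as an epoch
#' (no continuous-record synthesis): target epochs are the subject's
#' topography-weighted P300 template plus 1/f noise, nontarget epochs are
#' noise only. Each block presents `trials_per_block` distinct target
#' letters; within a trial every symbol appears once per round.
#'
#' @param archetype A [subject_archetype()].
#' @param paradigm A [paradigm_config()].
#' @param seed Integer seed; fully determines the output.
#' @param window Epoch window in ms (half-open).
#' @param rate Sampling rate of the generated epochs, Hz. Epochs are
#'   generated at the analysis rate directly (default 200 Hz); raw-rate
#'   simulation is a non-goal.
#' @param channel_names Channels to generate; must index `topography` (by
#'   name if it is named, by position otherwise).
#' @return An [epoch_set()] with
#'   `n_blocks * trials_per_block * rounds_per_trial * n_symbols` epochs
#'   and block/trial/round structure attached.
#' @export
generate_subject_epochs <- function(archetype, paradigm, seed,
                                    window = c(-200, 800), rate = 200,
                                    channel_names = NULL) {
  stopifnot(inherits(archetype, "subject_archetype"),
            inherits(paradigm, "paradigm_config"))
  topo <- archetype$topography
  if (is.null(channel_names))
    channel_names <- if (!is.null(names(topo))) names(topo) else
      sprintf("CH%02d", seq_along(topo))
  topo <- if (!is.null(names(topo))) {
    if (!all(channel_names %in% names(topo)))
      stop2("topography lacks weights for requested channels")
    topo[channel_names]
  } else {
    if (length(topo) != length(channel_names))
      stop2("topography length must match channel_names")
    topo
  }
  n_ch <- length(channel_names)
  n_samp <- round((window[2L] - window[1L]) / 1000 * rate)
  set.seed(derive_seed(seed, "epochs", archetype$subject_id))

  p <- paradigm
  n_per_round <- p$n_symbols
  n_rounds_total <- p$n_blocks * p$trials_per_block * p$rounds_per_trial
  n_epochs <- n_rounds_total * n_per_round

  # session layout: targets per block, symbol order per round
  targets <- vapply(seq_len(p$n_blocks), function(b)
    sample(p$symbols, p$trials_per_block), character(p$trials_per_block))
  targets <- matrix(targets, nrow = p$trials_per_block) # trials x blocks

  block <- rep(seq_len(p$n_blocks),
               each = p$trials_per_block * p$rounds_per_trial * n_per_round)
  trial <- rep(rep(seq_len(p$trials_per_block),
                   each = p$rounds_per_trial * n_per_round), p$n_blocks)
  round_i <- rep(rep(seq_len(p$rounds_per_trial), each = n_per_round),
                 p$n_blocks * p$trials_per_block)
  symbol <- if (p$symbol_order == "sequential") {
    rep(p$symbols, n_rounds_total)
  } else {
    as.vector(replicate(n_rounds_total, sample(p$symbols)))
  }
  labels <- as.integer(symbol == targets[cbind(trial, block)])

  noise <- pink_noise(n_samp, n_epochs * n_ch, rate,
                      sd = archetype$noise_sd,
                      exponent = archetype$pink_exponent)
  arr <- aperm(array(noise, c(n_samp, n_ch, n_epochs)), c(3L, 2L, 1L))

  if (archetype$p300_amplitude > 0) {
    tmpl <- p300_template(archetype$p300_latency, archetype$p300_amplitude,
                          archetype$p300_width, window, rate)
    sig <- outer(as.numeric(topo), tmpl) # channels x samples
    idx <- which(labels == 1L)
    if (length(idx))
      arr[idx, , ] <- arr[idx, , , drop = FALSE] +
        aperm(array(sig, c(n_ch, n_samp, length(idx))), c(3L, 1L, 2L))
  }

  epoch_set(arr, labels, symbol, rate, window, channel_names,
            subject_id = archetype$subject_id,
            block = block, trial = trial, round = round_i)
}

#' Specification of a synthetic multi-subject cohort
#'
#' Subjects are drawn around `n_clusters` cluster centers: centers are
#' perturbations of a common base archetype by the `between_*` standard
#' deviations, and each subject perturbs its center by the `within_*`
#' standard deviations. `style = "matrix"` emulates a matrix-speller cohort
#' by tripling the between-subject dispersion (larger individual
#' differences); it is an emulation knob, not a physiological model of the
#' matrix paradigm.
#'
#' @param n_subjects,n_clusters Cohort size and number of latent clusters
#'   (`n_clusters <= n_subjects`); subjects are assigned round-robin so
#'   clusters are balanced.
#' @param seed Integer seed; fully determines the cohort.
#' @param paradigm A [paradigm_config()].
#' @param base_latency,base_amplitude,base_width,base_noise_sd,pink_exponent
#'   Base archetype: P300 peak latency (ms), amplitude (uV), FWHM (ms),
#'   epoch noise sd (uV) and noise spectral slope.
#' @param between_sd_latency,between_sd_amplitude,between_sd_topography
#'   Cluster-center dispersion (ms, uV, unitless weight).
#' @param within_sd_latency,within_sd_amplitude,within_sd_topography
#'   Within-cluster subject dispersion (same units).
#' @param cluster_latencies Optional explicit cluster-center latencies (ms),
#'   length `n_clusters`; overrides the random draw (used to place
#'   well-separated clusters deterministically).
#' @param channel_names Channels to simulate.
#' @param style `"rsvp"` (default) or `"matrix"` (between-cluster sds x 3).
#' @param window,rate Epoch window (ms) and sampling rate (Hz).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects, n_clusters = 1L, seed = 1L,
                        paradigm = paradigm_config(),
                        base_latency = 350, base_amplitude = 5,
                        base_width = 70, base_noise_sd = 8,
                        pink_exponent = 1,
                        between_sd_latency = 40, between_sd_amplitude = 1,
                        between_sd_topography = 0.15,
                        within_sd_latency = 10, within_sd_amplitude = 0.5,
                        within_sd_topography = 0.05,
                        cluster_latencies = NULL,
                        channel_names = DEFAULT_CHANNELS,
                        style = c("rsvp", "matrix"),
                        window = c(-200, 800), rate = 200) {
  style <- match.arg(style)
  if (n_clusters > n_subjects) stop2("n_clusters must be <= n_subjects")
  if (!is.null(cluster_latencies) && length(cluster_latencies) != n_clusters)
    stop2("cluster_latencies must have one entry per cluster")
  if (style == "matrix") {
    between_sd_latency <- 3 * between_sd_latency
    between_sd_amplitude <- 3 * between_sd_amplitude
    between_sd_topography <- 3 * between_sd_topography
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_clusters = as.integer(n_clusters),
    seed = as.integer(seed), paradigm = paradigm,
    base_latency = base_latency, base_amplitude = base_amplitude,
    base_width = base_width, base_noise_sd = base_noise_sd,
    pink_exponent = pink_exponent,
    between_sd_latency = between_sd_latency,
    between_sd_amplitude = between_sd_amplitude,
    between_sd_topography = between_sd_topography,
    within_sd_latency = within_sd_latency,
    within_sd_amplitude = within_sd_amplitude,
    within_sd_topography = within_sd_topography,
    cluster_latencies = cluster_latencies,
    channel_names = channel_names, style = style,
    window = as.numeric(window), rate = rate
  ), class = "cohort_spec")
}

#' Generate a synthetic multi-subject cohort
#'
#' Draws per-subject archetypes around cluster centers per the spec, then
#' simulates each subject's epoched session. The archetype table records
#' ground-truth cluster memberships and ERP parameters.
#'
#' @param spec A [cohort_spec()].
#' @return An `erp_cohort`: list with `subjects` (named list of
#'   [epoch_set()]s), `archetypes` (data.frame of ground-truth parameters),
#'   and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_ch <- length(spec$channel_names)
  base_topo <- if (identical(spec$channel_names, DEFAULT_CHANNELS))
    DEFAULT_TOPOGRAPHY else
    stats::setNames(rep(1, n_ch), spec$channel_names)

  set.seed(derive_seed(spec$seed, "archetypes"))
  K <- spec$n_clusters
  centers <- lapply(seq_len(K), function(k) list(
    latency = if (!is.null(spec$cluster_latencies)) spec$cluster_latencies[k]
      else spec$base_latency + stats::rnorm(1, 0, spec$between_sd_latency),
    amplitude = max(0, spec$base_amplitude +
                      stats::rnorm(1, 0, spec$between_sd_amplitude)),
    topography = as.numeric(base_topo) +
      stats::rnorm(n_ch, 0, spec$between_sd_topography)))
  cluster_of <- rep_len(seq_len(K), spec$n_subjects)

  ids <- sprintf("S%02d", seq_len(spec$n_subjects))
  archetypes <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    ce <- centers[[cluster_of[i]]]
    topo <- ce$topography + stats::rnorm(n_ch, 0, spec$within_sd_topography)
    names(topo) <- spec$channel_names
    archetypes[[i]] <- subject_archetype(
      subject_id = ids[i], cluster_id = cluster_of[i],
      p300_latency = ce$latency + stats::rnorm(1, 0, spec$within_sd_latency),
      p300_amplitude = max(0, ce$amplitude +
                             stats::rnorm(1, 0, spec$within_sd_amplitude)),
      p300_width = spec$base_width,
      topography = topo,
      noise_sd = spec$base_noise_sd,
      pink_exponent = spec$pink_exponent)
  }

  subjects <- lapply(archetypes, function(a)
    generate_subject_epochs(a, spec$paradigm, seed = spec$seed,
                            window = spec$window, rate = spec$rate,
                            channel_names = spec$channel_names))
  names(subjects) <- ids

  tab <- do.call(rbind, lapply(archetypes, function(a) {
    d <- data.frame(subject_id = a$subject_id, cluster_id = a$cluster_id,
                    p300_latency = a$p300_latency,
                    p300_amplitude = a$p300_amplitude,
                    p300_width = a$p300_width, noise_sd = a$noise_sd,
                    pink_exponent = a$pink_exponent,
                    stringsAsFactors = FALSE)
    topo <- as.data.frame(as.list(a$topography))
    names(topo) <- paste0("topo_", names(a$topography))
    cbind(d, topo)
  }))
  rownames(tab) <- NULL

  structure(list(subjects = subjects, archetypes = tab, spec = spec),
            class = "erp_cohort")
}

#' @export
print.erp_cohort <- function(x, ...) {
  cat(sprintf("<erp_cohort> %d subjects in %d clusters (%s style), seed %d\n",
              x$spec$n_subjects, x$spec$n_clusters, x$spec$style,
              x$spec$seed))
  d <- dim(x$subjects[[1L]]$data)
  cat(sprintf("  per subject: %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$spec$rate))
  invisible(x)
}
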