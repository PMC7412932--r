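# ERP extraction and inter-subject similarity: coherent averaging, angle
# cosine with threshold matching, Pearson correlation and CAR donor ranking.

#' Coherent average of an epoch set
#'
#' Element-wise mean over epochs, separately for target and nontarget
#' labels. Averaging M time-locked epochs attenuates zero-mean noise by
#' 1/sqrt(M) while leaving the evoked component intact, which is what makes
#' the P300 visible above single-trial noise.
#'
#' @param epochs An [epoch_set()] with at least one epoch in each class.
#' @return An `erp_waveform`: list with `target_mean` and `nontarget_mean`
#'   (`channels x samples` matrices, microvolts), epoch counts, `rate`,
#'   `window`, `channel_names` and `subject_id`.
#' @export
coherent_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx_t <- which(epochs$labels == 1L)
  idx_n <- which(epochs$labels == 0L)
  if (!length(idx_t)) stop2("no target epochs to average")
  if (!length(idx_n)) stop2("no nontarget epochs to average")
  avg <- function(i) colMeans(epochs$data[i, , , drop = FALSE])
  structure(list(
    subject_id = epochs$subject_id,
    target_mean = avg(idx_t), nontarget_mean = avg(idx_n),
    n_target_epochs = length(idx_t), n_nontarget_epochs = length(idx_n),
    rate = epochs$rate, window = epochs$window,
    channel_names = epochs$channel_names
  ), class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf(
    "<erp_waveform> subject %s: %d channels x %d samples (%d target / %d nontarget epochs)\n",
    x$subject_id, nrow(x$target_mean), ncol(x$target_mean),
    x$n_target_epochs, x$n_nontarget_epochs))
  invisible(x)
}

#' Flatten an ERP waveform into a similarity vector
#'
#' Restricts the target-ERP matrix to a time segment and concatenates the
#' channels in `channel_names` order into one vector — the form in which
#' waveforms enter cosine and Pearson similarity. The default segment is
#' the post-stimulus part of the epoch, excluding the (zero-mean) baseline.
#'
#' @param erp An `erp_waveform` from [coherent_average()].
#' @param segment Half-open time segment in ms, within the epoch window.
#' @param which `"target"` (default) or `"nontarget"` mean.
#' @return Numeric vector of length `n_channels * n_segment_samples`.
#' @export
vectorize_erp <- function(erp, segment = c(0, 800), which = "target") {
  stopifnot(inherits(erp, "erp_waveform"))
  if (segment[1L] < erp$window[1L] || segment[2L] > erp$window[2L] ||
      segment[2L] <= segment[1L])
    stop2(sprintf("segment [%g, %g) ms must lie within the window [%g, %g) ms",
                  segment[1L], segment[2L], erp$window[1L], erp$window[2L]))
  m <- if (which == "target") erp$target_mean else erp$nontarget_mean
  t <- epoch_times(erp)
  keep <- t >= segment[1L] & t < segment[2L]
  as.vector(t(m[, keep, drop = FALSE])) # channel blocks in channel order
}

#' Angle cosine similarity of two vectors
#'
#' `dot(a, b) / (||a|| ||b||)`, in `[-1, 1]`; larger values mean a smaller
#' angle between the waveform vectors, i.e. more similar ERP shapes.
#'
#' @param a,b Numeric vectors of equal length, neither all-zero.
#' @return Cosine of the angle between `a` and `b`.
#' @examples
#' cosine_similarity(c(3, 4), c(4, 3)) # 24/25
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop2("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop2("cosine similarity is undefined for a zero-norm vector")
  sum(a * b) / (na * nb)
}

#' Pearson correlation coefficient of two vectors
#'
#' Sample correlation with (n-1)-denominator standard deviations:
#' `r = 1/(n-1) * sum(((x - mean(x))/sd(x)) * ((y - mean(y))/sd(y)))`.
#'
#' @param x,y Numeric vectors of equal length >= 2, each with nonzero
#'   sample standard deviation.
#' @return `r` in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop2("vectors must have equal length")
  if (length(x) < 2L) stop2("need at least two observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop2("Pearson correlation is undefined for a zero-variance vector")
  stats::cor(x, y)
}

#' Pairwise inter-subject ERP similarity matrix
#'
#' @param erps List of `erp_waveform` objects (one per subject).
#' @param metric `"cosine"` or `"pearson"`.
#' @param segment Time segment passed to [vectorize_erp()].
#' @return A `similarity_matrix`: list with `values` (symmetric `n x n`
#'   matrix, unit diagonal), `subject_ids`, `metric` and a `vectorization`
#'   descriptor.
#' @export
similarity_matrix <- function(erps, metric = c("cosine", "pearson"),
                              segment = c(0, 800)) {
  metric <- match.arg(metric)
  if (length(erps) < 2L) stop2("need at least two subjects")
  ids <- vapply(erps, function(e) e$subject_id, character(1))
  vecs <- lapply(erps, vectorize_erp, segment = segment)
  n <- length(vecs)
  v <- diag(1, n)
  f <- if (metric == "cosine") cosine_similarity else pearson_correlation
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v[i, j] <- v[j, i] <- tryCatch(
      f(vecs[[i]], vecs[[j]]),
      error = function(e) stop2(sprintf("subject pair (%s, %s): %s",
                                        ids[i], ids[j], conditionMessage(e))))
  }
  dimnames(v) <- list(ids, ids)
  structure(list(
    subject_ids = ids, values = v, metric = metric,
    vectorization = sprintf("target ERP, segment [%g, %g) ms, channels %s",
                            segment[1L], segment[2L],
                            paste(erps[[1L]]$channel_names, collapse = ","))
  ), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d subjects, metric %s\n  %s\n",
              length(x$subject_ids), x$metric, x$vectorization))
  invisible(x)
}

#' Per-subject count of similarity matches above a threshold
#'
#' Binarizes the pairwise cosine similarity at `threshold` (strictly
#' greater-than; self-similarity excluded) and counts, for each subject,
#' how many other subjects it matches. High counts indicate small
#' inter-individual ERP differences across the cohort.
#'
#' @param erps List of `erp_waveform` objects (>= 2 subjects).
#' @param threshold Match threshold on the cosine value (default 0.5).
#' @param segment Time segment passed to [vectorize_erp()].
#' @return List with `counts` (named integer vector), `binary` (logical
#'   matrix, diagonal `FALSE`) and the underlying [similarity_matrix()].
#' @export
match_counts <- function(erps, threshold = 0.5, segment = c(0, 800)) {
  sim <- similarity_matrix(erps, metric = "cosine", segment = segment)
  bin <- sim$values > threshold
  diag(bin) <- FALSE
  counts <- rowSums(bin)
  storage.mode(counts) <- "integer"
  list(counts = counts, binary = bin, similarity = sim)
}

#' Rank donor subjects by ERP correlation with a test subject (CAR)
#'
#' The Correlation Analysis Rank: each candidate donor's averaged target
#' ERP is correlated (Pearson) with the test subject's, and donors are
#' sorted by descending `r`, so the most similar subject comes first. The
#' top-N of this ranking forms the cross-subject training set.
#'
#' @param test_erp `erp_waveform` of the test subject (typically computed
#'   from calibration blocks only).
#' @param donor_erps List of donor `erp_waveform`s (test subject excluded).
#' @param segment Time segment passed to [vectorize_erp()].
#' @return A `subject_ranking`: list with `test_subject` and
#'   `ranked_donors` (data.frame `subject_id`, `r`, non-increasing in `r`;
#'   ties broken by ascending subject id).
#' @export
rank_donors <- function(test_erp, donor_erps, segment = c(0, 800)) {
  stopifnot(inherits(test_erp, "erp_waveform"))
  if (length(donor_erps) < 1L) stop2("need at least one donor")
  ids <- vapply(donor_erps, function(e) e$subject_id, character(1))
  if (test_erp$subject_id %in% ids)
    stop2("donor list must not contain the test subject")
  v0 <- vectorize_erp(test_erp, segment)
  r <- vapply(seq_along(donor_erps), function(i) tryCatch(
    pearson_correlation(v0, vectorize_erp(donor_erps[[i]], segment)),
    error = function(e) stop2(sprintf("donor %s: %s", ids[i],
                                      conditionMessage(e)))), numeric(1))
  ord <- order(-r, ids)
  structure(list(
    test_subject = test_erp$subject_id,
    ranked_donors = data.frame(subject_id = ids[ord], r = r[ord],
                               stringsAsFactors = FALSE),
    metric = "pearson", segment = segment
  ), class = "subject_ranking")
}

#' @export
print.subject_ranking <- function(x, ...) {
  cat(sprintf("<subject_ranking> test subject %s, %d donors (Pearson r)\n",
              x$test_subject, nrow(x$ranked_donors)))
  print(utils::head(x$ranked_donors, 5L))
  invisible(x)
}
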