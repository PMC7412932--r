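# Target/nontarget classification: binned time-window features, shrinkage
# LDA, and rank-based AUC.

#' Feature extraction configuration
#'
#' Epoch features are the per-channel means of consecutive non-overlapping
#' time bins within a post-stimulus segment, concatenated channel by
#' channel. Defaults (0-800 ms, 50 ms bins, six analysis channels) give
#' 6 x 16 = 96 features per epoch.
#'
#' @param segment Half-open feature segment in ms.
#' @param bin_width Bin width in ms; must divide the segment length.
#' @param channels Channels used, in order; `NULL` means all channels of
#'   the epoch set at extraction time.
#' @return A `feature_config` object.
#' @export
feature_config <- function(segment = c(0, 800), bin_width = 50,
                           channels = DEFAULT_CHANNELS) {
  span <- segment[2L] - segment[1L]
  if (span <= 0) stop2("segment must have positive length")
  if (bin_width <= 0 || abs(span / bin_width - round(span / bin_width)) > 1e-9)
    stop2(sprintf("bin_width (%g ms) must divide the segment length (%g ms)",
                  bin_width, span))
  structure(list(segment = as.numeric(segment), bin_width = bin_width,
                 channels = channels), class = "feature_config")
}

#' Extract binned time-window features from epochs
#'
#' @param epochs An [epoch_set()].
#' @param cfg A [feature_config()]; its channels must be present in
#'   `epochs`.
#' @return List with `x` (matrix `n_epochs x n_features`), `y` (integer
#'   labels), `feature_names`, and `epoch_ids` carried from the epoch set.
#' @export
extract_features <- function(epochs, cfg = feature_config()) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(cfg, "feature_config"))
  if (!is.null(cfg$channels)) epochs <- select_channels(epochs, cfg$channels)
  t <- epoch_times(epochs)
  keep <- which(t >= cfg$segment[1L] & t < cfg$segment[2L])
  if (!length(keep)) stop2("feature segment contains no samples")
  spb <- cfg$bin_width * epochs$rate / 1000 # samples per bin
  if (abs(spb - round(spb)) > 1e-9)
    stop2(sprintf("bin_width (%g ms) is not a whole number of samples at %g Hz",
                  cfg$bin_width, epochs$rate))
  spb <- as.integer(round(spb))
  n_bins <- length(keep) %/% spb
  if (n_bins * spb != length(keep))
    stop2("segment does not divide into whole bins at this rate")
  d <- dim(epochs$data)
  n <- d[1L]; n_ch <- d[2L]
  # (epoch, channel) rows x sample columns; bin means via one matrix product
  m <- matrix(epochs$data[, , keep, drop = FALSE], nrow = n * n_ch)
  binmat <- matrix(0, length(keep), n_bins)
  binmat[cbind(seq_along(keep), rep(seq_len(n_bins), each = spb))] <- 1 / spb
  f <- m %*% binmat # (n * n_ch) x n_bins
  x <- matrix(aperm(array(f, c(n, n_ch, n_bins)), c(1L, 3L, 2L)), nrow = n)
  colnames(x) <- as.vector(t(outer(epochs$channel_names,
                                   seq_len(n_bins), paste, sep = "_bin")))
  list(x = x, y = epochs$labels, feature_names = colnames(x),
       epoch_ids = epochs$epoch_ids)
}

#' Fit a shrinkage-regularized linear discriminant classifier
#'
#' Two-class LDA with discriminant direction `w` proportional to
#' `solve(Sigma, mu1 - mu0)`, where `Sigma` is the pooled within-class
#' covariance shrunk toward a scaled identity:
#' `Sigma = (1 - lambda) * S + lambda * nu * I` with `nu = mean(diag(S))`.
#' `lambda = "auto"` uses the Ledoit-Wolf analytic shrinkage intensity,
#' which keeps the fit well-conditioned when the feature dimension
#' approaches the epoch count (the usual ERP regime). The decision score is
#' `w . x + b` with `b` placing the boundary midway between class means;
#' scores are unnormalized discriminants, suitable for ranking (AUC) and
#' symbol-level score summation.
#'
#' @param x Feature matrix, epochs in rows.
#' @param y Binary labels (0/1), both classes present, >= 2 each.
#' @param shrinkage `"auto"` (Ledoit-Wolf) or a number in `[0, 1]`.
#' @return An `lda_classifier`: list with `w`, `b`, class means, the
#'   shrinkage used and the feature dimension.
#' @export
fit_lda <- function(x, y, shrinkage = "auto") {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop2("labels must be binary (0/1)")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 2L || n0 < 2L)
    stop2("need at least two epochs in each class")
  mu0 <- colMeans(x[y == 0L, , drop = FALSE])
  mu1 <- colMeans(x[y == 1L, , drop = FALSE])
  xc <- x
  xc[y == 0L, ] <- sweep(x[y == 0L, , drop = FALSE], 2L, mu0)
  xc[y == 1L, ] <- sweep(x[y == 1L, , drop = FALSE], 2L, mu1)
  n <- nrow(xc); p <- ncol(xc)
  s <- crossprod(xc) / n
  nu <- mean(diag(s))
  if (nu == 0) {
    # zero within-class scatter (noiseless data): fall back to the identity
    # metric, i.e. the class-mean difference direction
    w <- mu1 - mu0
    return(structure(list(w = as.numeric(w),
                          b = -sum(w * (mu0 + mu1)) / 2,
                          mu0 = mu0, mu1 = mu1,
                          shrinkage = 1, n_features = p),
                     class = "lda_classifier"))
  }
  lambda <- if (identical(shrinkage, "auto")) {
    # Ledoit-Wolf (2004) intensity toward nu * I
    d2 <- sum((s - diag(nu, p))^2)
    if (d2 < .Machine$double.eps) 0 else {
      q <- rowSums(xc^2)
      b2 <- (sum(q^2) - 2 * sum((xc %*% s) * xc) + n * sum(s^2)) / n^2
      min(1, max(0, min(b2, d2) / d2))
    }
  } else {
    assert_scalar_number(shrinkage, "shrinkage", lower = 0, upper = 1)
    shrinkage
  }
  sigma <- (1 - lambda) * s + diag(lambda * nu, p)
  w <- tryCatch(solve(sigma, mu1 - mu0),
                error = function(e) stop2("covariance is singular; ",
                                          "use shrinkage > 0: ",
                                          conditionMessage(e)))
  structure(list(w = as.numeric(w),
                 b = -sum(w * (mu0 + mu1)) / 2,
                 mu0 = mu0, mu1 = mu1,
                 shrinkage = lambda, n_features = p),
            class = "lda_classifier")
}

#' @export
print.lda_classifier <- function(x, ...) {
  cat(sprintf("<lda_classifier> %d features, shrinkage %.4f\n",
              x$n_features, x$shrinkage))
  invisible(x)
}

#' Decision scores of a fitted LDA classifier
#'
#' @param object An `lda_classifier`.
#' @param newdata Feature matrix (or the list returned by
#'   [extract_features()]).
#' @param ... Unused.
#' @return Numeric vector of discriminant scores (higher = more
#'   target-like).
#' @export
predict.lda_classifier <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.null(newdata$x)) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop2(sprintf("feature dimension %d does not match classifier (%d)",
                  ncol(newdata), object$n_features))
  as.numeric(newdata %*% object$w + object$b)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen target epoch outscores a randomly
#' chosen nontarget epoch, with ties counted 1/2 — computed from midranks,
#' so it is invariant under any strictly increasing transform of the
#' scores.
#'
#' @param scores Numeric decision scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop2("scores and labels must have equal length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop2("both classes must be present")
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
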