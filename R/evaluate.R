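# Cross-subject donor-selection experiment: random vs CAR donor training
# sets, leave-one-subject-out AUC, and the paired statistical comparison.

#' Evaluate a donor-selection model on a synthetic cohort
#'
#' Leave-one-subject-out cross-subject evaluation: each subject is the test
#' subject once. Donors are chosen either uniformly at random (`"random"`,
#' repeated `reps` times with derived seeds) or as the top-N of the CAR
#' ranking (`"car"`), where the test subject's ranking ERP is computed from
#' its first `calibration_blocks` blocks only. An LDA classifier is trained
#' on the pooled epochs of the chosen donors and scored on the test
#' subject's non-calibration epochs; calibration epochs are never scored
#' and the test subject's own epochs are never trained on (asserted via
#' epoch ids on every run).
#'
#' @param cohort An `erp_cohort` from [generate_cohort()].
#' @param model `"random"` or `"car"`.
#' @param N Number of donor subjects in the training set
#'   (`1 <= N <= n_subjects - 1`).
#' @param calibration_blocks Leading blocks of the test subject reserved
#'   for CAR ranking (and excluded from evaluation under both models, so
#'   the two models are scored on identical epochs).
#' @param reps Random-model repetitions per test subject (CAR is
#'   deterministic and uses one).
#' @param seed Integer seed for the random donor draws.
#' @param cfg A [feature_config()].
#' @param segment Time segment used for the CAR ERP vectorization, ms.
#' @param shrinkage Passed to [fit_lda()].
#' @return An `evaluation_result`: data.frame with columns `test_subject`,
#'   `model`, `N`, `rep`, `auc`, plus attributes `leakage_checked`,
#'   `donors` (list of donor id sets) and the call parameters.
#' @export
evaluate_model <- function(cohort, model = c("random", "car"), N,
                           calibration_blocks = 2L, reps = 10L, seed = 1L,
                           cfg = feature_config(), segment = c(0, 800),
                           shrinkage = "auto") {
  model <- match.arg(model)
  stopifnot(inherits(cohort, "erp_cohort"))
  subjects <- cohort$subjects
  ids <- names(subjects)
  n_sub <- length(subjects)
  if (N < 1L || N >= n_sub)
    stop2(sprintf("N (%d) must be in [1, n_subjects - 1 = %d]", N, n_sub - 1L))
  if (calibration_blocks < 1L)
    stop2("calibration_blocks must be >= 1")
  n_blocks <- cohort$spec$paradigm$n_blocks
  if (calibration_blocks >= n_blocks)
    stop2("calibration_blocks must leave at least one evaluation block")

  # one-time per-subject features and full-data ERP vectors
  feats <- lapply(subjects, extract_features, cfg = cfg)
  donor_vecs <- if (model == "car")
    lapply(subjects, function(s) coherent_average(s)) else NULL

  rows <- list()
  donor_sets <- list()
  for (s in ids) {
    test <- subjects[[s]]
    if (is.null(test$block)) stop2("cohort epochs lack block structure")
    calib_mask <- test$block <= calibration_blocks
    if (!any(calib_mask) || !any(!calib_mask))
      stop2("calibration split leaves an empty partition for subject ", s)
    eval_idx <- which(!calib_mask)
    eval_feat <- list(x = feats[[s]]$x[eval_idx, , drop = FALSE],
                      y = feats[[s]]$y[eval_idx],
                      epoch_ids = feats[[s]]$epoch_ids[eval_idx])
    calib_ids <- feats[[s]]$epoch_ids[calib_mask]
    donors_pool <- setdiff(ids, s)

    chosen_sets <- if (model == "car") {
      calib_erp <- coherent_average(subset_epochs(test, which(calib_mask)))
      ranking <- rank_donors(calib_erp, donor_vecs[donors_pool], segment)
      list(ranking$ranked_donors$subject_id[seq_len(N)])
    } else {
      lapply(seq_len(reps), function(r) {
        set.seed(derive_seed(seed, "random-donors", s, r))
        sample(donors_pool, N)
      })
    }

    for (rep_i in seq_along(chosen_sets)) {
      donors <- chosen_sets[[rep_i]]
      train_x <- do.call(rbind, lapply(donors, function(d) feats[[d]]$x))
      train_y <- unlist(lapply(donors, function(d) feats[[d]]$y),
                        use.names = FALSE)
      train_ids <- unlist(lapply(donors, function(d) feats[[d]]$epoch_ids),
                          use.names = FALSE)
      # leakage guard: training must not touch the test subject, and no
      # scored epoch may appear in the training set or the calibration set
      stopifnot(!(s %in% donors),
                length(intersect(train_ids, feats[[s]]$epoch_ids)) == 0L,
                length(intersect(eval_feat$epoch_ids, train_ids)) == 0L,
                length(intersect(eval_feat$epoch_ids, calib_ids)) == 0L)
      clf <- fit_lda(train_x, train_y, shrinkage)
      scores <- predict(clf, eval_feat$x)
      rows[[length(rows) + 1L]] <- data.frame(
        test_subject = s, model = model, N = as.integer(N),
        rep = as.integer(rep_i), auc = auc_score(scores, eval_feat$y),
        stringsAsFactors = FALSE)
      donor_sets[[sprintf("%s.%d", s, rep_i)]] <- donors
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, class = c("evaluation_result", "data.frame"),
            leakage_checked = TRUE, donors = donor_sets,
            calibration_blocks = as.integer(calibration_blocks),
            seed = as.integer(seed), shrinkage = shrinkage)
}

#' Per-test-subject mean AUC of an evaluation result
#'
#' Averages over repetitions, giving one AUC per test subject (the unit of
#' the paired comparison).
#'
#' @param result An `evaluation_result`.
#' @return Named numeric vector of mean AUC, ordered by subject id.
#' @export
subject_auc <- function(result) {
  stopifnot(inherits(result, "evaluation_result"))
  out <- tapply(result$auc, result$test_subject, mean)
  out[order(names(out))]
}

#' Paired statistical comparison of two donor-selection models
#'
#' Aggregates each result to one AUC per test subject (mean over
#' repetitions), checks both samples for normality with a Kolmogorov-
#' Smirnov test against a normal with the sample mean and sd, then runs a
#' two-sided paired t-test on the per-subject AUC differences. Zero-
#' variance differences are reported as degenerate (identical samples give
#' `t = 0, p = 1`; a constant nonzero shift gives `p = NA` with
#' `degenerate = TRUE`) rather than a spurious `p = 0`.
#'
#' @param result_a,result_b `evaluation_result`s over the same test
#'   subjects.
#' @return A `paired_comparison`: list with per-sample KS statistics and
#'   p-values, the paired `t`, two-sided `p`, mean difference (a - b),
#'   `n`, and a `degenerate` flag.
#' @export
compare_models <- function(result_a, result_b) {
  a <- subject_auc(result_a)
  b <- subject_auc(result_b)
  if (length(a) != length(b) || !identical(names(a), names(b)))
    stop2("results must cover the same test subjects")
  ks <- function(x) {
    if (stats::sd(x) == 0) return(list(statistic = NA_real_, p.value = NA_real_))
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  }
  ks_a <- ks(a); ks_b <- ks(b)
  d <- a - b
  n <- length(d)
  degenerate <- FALSE
  if (stats::sd(d) == 0) {
    degenerate <- TRUE
    t_stat <- if (mean(d) == 0) 0 else NA_real_
    p <- if (mean(d) == 0) 1 else NA_real_
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(
    model_a = result_a$model[1L], model_b = result_b$model[1L],
    n = n, mean_diff = mean(d),
    ks_a = c(statistic = unname(ks_a$statistic), p = ks_a$p.value),
    ks_b = c(statistic = unname(ks_b$statistic), p = ks_b$p.value),
    t = t_stat, p_value = p, degenerate = degenerate
  ), class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s vs %s over %d test subjects\n",
              x$model_a, x$model_b, x$n))
  cat(sprintf("  mean AUC difference %+0.4f, paired t = %s, p = %s%s\n",
              x$mean_diff, format(x$t), format(x$p_value),
              if (x$degenerate) " (degenerate: zero-variance differences)" else ""))
  invisible(x)
}
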