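# Whole-pipeline driver: simulate -> ERP/similarity -> donor-selection
# evaluation -> ITR, with JSON configuration and provenance-stamped TSV
# outputs.

#' Build a full-pipeline run configuration
#'
#' A single JSON-serializable document holding every knob of the pipeline.
#' Unspecified fields take the package defaults.
#'
#' @param n_subjects,n_clusters Cohort size and latent cluster count.
#' @param paradigm A [paradigm_config()].
#' @param cohort Named list of extra arguments passed to [cohort_spec()]
#'   (dispersions, base ERP parameters, `style`, ...).
#' @param similarity_threshold Cosine match threshold.
#' @param similarity_segment Segment (ms) for ERP vectorization.
#' @param feature A [feature_config()].
#' @param models Donor-selection models to evaluate.
#' @param N_values Donor counts to evaluate.
#' @param reps Random-model repetitions.
#' @param calibration_blocks Calibration blocks for CAR.
#' @param seed Global seed; per-stage sub-seeds are derived from it.
#' @param write_epoch_files Whether [run_experiment()] writes per-subject
#'   epoch containers (they dominate output size).
#' @return A `run_config` object.
#' @export
run_config <- function(n_subjects = 10L, n_clusters = 2L,
                       paradigm = paradigm_config(),
                       cohort = list(),
                       similarity_threshold = 0.5,
                       similarity_segment = c(0, 800),
                       feature = feature_config(),
                       models = c("random", "car"),
                       N_values = c(1L, 3L, 5L),
                       reps = 10L, calibration_blocks = 2L,
                       seed = 1L, write_epoch_files = FALSE) {
  structure(list(
    n_subjects = as.integer(n_subjects), n_clusters = as.integer(n_clusters),
    paradigm = paradigm, cohort = cohort,
    similarity_threshold = similarity_threshold,
    similarity_segment = as.numeric(similarity_segment),
    feature = feature, models = models,
    N_values = as.integer(N_values), reps = as.integer(reps),
    calibration_blocks = as.integer(calibration_blocks),
    seed = as.integer(seed), write_epoch_files = isTRUE(write_epoch_files)
  ), class = "run_config")
}

#' Serialize / deserialize a run configuration as JSON
#'
#' `config_to_json()` and `config_from_json()` round-trip a [run_config()]
#' losslessly through a single JSON document.
#'
#' @param config A `run_config`.
#' @param path Optional file path; if given, the JSON is written/read
#'   there.
#' @return `config_to_json()`: the JSON string (invisibly if written to a
#'   file). `config_from_json()`: a `run_config`.
#' @export
config_to_json <- function(config, path = NULL) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$paradigm <- unclass(x$paradigm)
  x$feature <- unclass(x$feature)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' @rdname config_to_json
#' @param json JSON string (alternative to `path`).
#' @export
config_from_json <- function(path = NULL, json = NULL) {
  if (is.null(json)) json <- paste(readLines(path), collapse = "\n")
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  req <- c("n_subjects", "paradigm", "models", "N_values", "seed")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop2("config is missing field(s): ", paste(miss, collapse = ", "))
  p <- x$paradigm
  paradigm <- paradigm_config(
    n_symbols = p$n_symbols, flash_duration = p$flash_duration,
    off_duration = p$off_duration, rounds_per_trial = p$rounds_per_trial,
    trials_per_block = p$trials_per_block, n_blocks = p$n_blocks,
    acquisition_rate = p$acquisition_rate, symbol_order = p$symbol_order)
  f <- x$feature
  feature <- feature_config(segment = f$segment, bin_width = f$bin_width,
                            channels = f$channels)
  run_config(
    n_subjects = x$n_subjects, n_clusters = x$n_clusters %||% 1L,
    paradigm = paradigm, cohort = as.list(x$cohort),
    similarity_threshold = x$similarity_threshold %||% 0.5,
    similarity_segment = x$similarity_segment %||% c(0, 800),
    feature = feature, models = x$models, N_values = x$N_values,
    reps = x$reps %||% 10L,
    calibration_blocks = x$calibration_blocks %||% 2L,
    seed = x$seed, write_epoch_files = isTRUE(x$write_epoch_files))
}

#' Run the full pipeline and write a result bundle
#'
#' Executes simulate -> coherent averaging -> similarity/match counts ->
#' donor-selection evaluation (each model and donor count N) -> within-
#' subject symbol accuracy and ITR, writing TSV/JSON outputs to `out_dir`.
#' Every table embeds the hash of the configuration that produced it, and
#' the whole run is deterministic given the config (including its seed).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `similarity`, `match`, `evaluation`, `comparisons`, `itr`) and
#'   `config_hash`.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- config_to_json(config)
  cfg_hash <- text_hash(cfg_json)
  stamp <- sprintf("# config_hash: %s", cfg_hash)
  log <- function(stage, ...) message(sprintf("[%s] %s", stage, sprintf(...)))
  fail <- function(stage, e) stop2(sprintf("stage '%s' failed: %s",
                                           stage, conditionMessage(e)))
  writeLines(cfg_json, file.path(out_dir, "config.json"))

  # --- simulate ------------------------------------------------------------
  cohort <- tryCatch({
    log("simulate", "%d subjects, %d clusters, seed %d",
        config$n_subjects, config$n_clusters, config$seed)
    spec <- do.call(cohort_spec, c(list(
      n_subjects = config$n_subjects, n_clusters = config$n_clusters,
      seed = derive_seed(config$seed, "cohort"),
      paradigm = config$paradigm), config$cohort))
    generate_cohort(spec)
  }, error = function(e) fail("simulate", e))
  man <- list(config_hash = cfg_hash, seed = config$seed,
              archetypes = cohort$archetypes)
  writeLines(as.character(jsonlite::toJSON(man, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             file.path(out_dir, "cohort_manifest.json"))
  if (config$write_epoch_files) {
    epdir <- file.path(out_dir, "epochs")
    dir.create(epdir, showWarnings = FALSE)
    for (s in names(cohort$subjects))
      write_epochs(cohort$subjects[[s]], file.path(epdir, paste0(s, ".tsv")))
  }

  # --- ERP + similarity ----------------------------------------------------
  sim <- tryCatch({
    log("similarity", "coherent averages and match counts (threshold %g)",
        config$similarity_threshold)
    erps <- lapply(cohort$subjects, coherent_average)
    mc <- match_counts(erps, threshold = config$similarity_threshold,
                       segment = config$similarity_segment)
    pear <- similarity_matrix(erps, "pearson", config$similarity_segment)
    list(erps = erps, match = mc, pearson = pear)
  }, error = function(e) fail("similarity", e))
  write_similarity(sim$match$similarity, file.path(out_dir, "cosine.tsv"))
  write_similarity(sim$pearson, file.path(out_dir, "pearson.tsv"))
  mc_tab <- data.frame(subject_id = names(sim$match$counts),
                       matches = as.integer(sim$match$counts))
  writeLines(c(stamp, "subject_id\tmatches",
               paste(mc_tab$subject_id, mc_tab$matches, sep = "\t")),
             file.path(out_dir, "match_counts.tsv"))

  # --- evaluation ----------------------------------------------------------
  evals <- list(); comparisons <- list()
  for (N in config$N_values) {
    per_model <- list()
    for (m in config$models) {
      res <- tryCatch({
        log("evaluate", "model %s, N = %d", m, N)
        evaluate_model(cohort, model = m, N = N,
                       calibration_blocks = config$calibration_blocks,
                       reps = config$reps,
                       seed = derive_seed(config$seed, "evaluate", m, N),
                       cfg = config$feature,
                       segment = config$similarity_segment)
      }, error = function(e) fail("evaluate", e))
      per_model[[m]] <- res
      evals[[sprintf("%s.N%d", m, N)]] <- res
    }
    if (all(c("random", "car") %in% names(per_model)))
      comparisons[[sprintf("N%d", N)]] <-
        compare_models(per_model$car, per_model$random)
  }
  ev <- do.call(rbind, c(evals, make.row.names = FALSE))
  ev_lines <- c(stamp, paste(names(ev), collapse = "\t"),
                do.call(paste, c(unname(as.list(ev)), sep = "\t")))
  writeLines(ev_lines, file.path(out_dir, "evaluation.tsv"))
  summ <- stats::aggregate(auc ~ model + N, ev, mean)
  summ_sd <- stats::aggregate(auc ~ model + N, ev, stats::sd)
  summ$sd <- summ_sd$auc
  writeLines(c(stamp, "model\tN\tmean_auc\tsd_auc",
               paste(summ$model, summ$N, num_chr(summ$auc),
                     num_chr(summ$sd), sep = "\t")),
             file.path(out_dir, "auc_vs_N.tsv"))

  # --- within-subject ITR --------------------------------------------------
  itr_tab <- tryCatch({
    log("itr", "within-subject symbol accuracy and ITR")
    T_min <- selection_time(config$paradigm)
    half <- config$paradigm$n_blocks %/% 2L
    rows <- lapply(names(cohort$subjects), function(s) {
      ep <- cohort$subjects[[s]]
      tr <- subset_epochs(ep, ep$block <= max(half, 1L))
      te <- subset_epochs(ep, ep$block > max(half, 1L))
      fe <- extract_features(tr, config$feature)
      clf <- fit_lda(fe$x, fe$y)
      acc <- symbol_accuracy(te, clf, config$feature)
      P <- max(acc$P, 1 / config$paradigm$n_symbols) # chance floor for ITR
      it <- compute_itr(config$paradigm$n_symbols, P, T_min)
      data.frame(subject_id = s, P = acc$P, T_min = T_min,
                 bits_per_selection = it$bits_per_selection, itr = it$itr)
    })
    do.call(rbind, rows)
  }, error = function(e) fail("itr", e))
  writeLines(c(stamp, paste(names(itr_tab), collapse = "\t"),
               do.call(paste, c(unname(as.list(itr_tab)), sep = "\t"))),
             file.path(out_dir, "itr.tsv"))

  prov <- list(config_hash = cfg_hash, seed = config$seed,
               r_version = as.character(getRversion()),
               package_version = as.character(
                 utils::packageVersion("rsvpcar")))
  writeLines(as.character(jsonlite::toJSON(prov, auto_unbox = TRUE,
                                           pretty = TRUE)),
             file.path(out_dir, "provenance.json"))

  invisible(list(cohort = cohort, similarity = sim$pearson,
                 match = sim$match, evaluation = ev,
                 comparisons = comparisons, itr = itr_tab,
                 config_hash = cfg_hash))
}
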