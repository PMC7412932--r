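# Small clustered cohort shared across evaluation tests.
eval_paradigm <- function() paradigm_config(n_symbols = 8L,
                                            rounds_per_trial = 2L,
                                            trials_per_block = 2L,
                                            n_blocks = 4L)

test_that("a degenerate identical noiseless cohort gives AUC 1 everywhere", {
  spec <- cohort_spec(4, 1, seed = 2, paradigm = eval_paradigm(),
                      between_sd_latency = 0, between_sd_amplitude = 0,
                      between_sd_topography = 0, within_sd_latency = 0,
                      within_sd_amplitude = 0, within_sd_topography = 0,
                      base_noise_sd = 0)
  coh <- generate_cohort(spec)
  for (m in c("random", "car")) {
    res <- evaluate_model(coh, m, N = 2, calibration_blocks = 1, reps = 2,
                          seed = 3)
    expect_true(all(res$auc == 1), info = m)
  }
})

test_that("an amplitude-zero cohort stays at chance", {
  spec <- cohort_spec(12, 1, seed = 6, paradigm = eval_paradigm(),
                      base_amplitude = 0, between_sd_amplitude = 0,
                      within_sd_amplitude = 0, base_noise_sd = 8)
  coh <- generate_cohort(spec)
  res <- evaluate_model(coh, "random", N = 3, calibration_blocks = 1,
                        reps = 2, seed = 3)
  expect_gt(mean(subject_auc(res)), 0.45)
  expect_lt(mean(subject_auc(res)), 0.55)
})

test_that("evaluation never trains on or scores excluded epochs", {
  spec <- cohort_spec(5, 2, seed = 8, paradigm = eval_paradigm(),
                      base_noise_sd = 5)
  coh <- generate_cohort(spec)
  for (m in c("random", "car")) {
    res <- evaluate_model(coh, m, N = 2, calibration_blocks = 2, reps = 2,
                          seed = 9)
    expect_true(attr(res, "leakage_checked"))
    donors <- attr(res, "donors")
    for (key in names(donors)) {
      test_subj <- sub("\\.\\d+$", "", key)
      expect_false(test_subj %in% donors[[key]])
      expect_length(donors[[key]], 2L)
    }
    # one row per (test subject, repetition)
    expected_rows <- length(coh$subjects) * (if (m == "car") 1 else 2)
    expect_equal(nrow(res), expected_rows)
    expect_true(all(res$auc >= 0 & res$auc <= 1))
  }
  expect_error(evaluate_model(coh, "random", N = 5, seed = 1), "N")
  expect_error(evaluate_model(coh, "car", N = 2, calibration_blocks = 4,
                              seed = 1), "calibration")
})

test_that("evaluation is deterministic under a fixed seed", {
  spec <- cohort_spec(4, 1, seed = 10, paradigm = eval_paradigm(),
                      base_noise_sd = 6)
  coh <- generate_cohort(spec)
  r1 <- evaluate_model(coh, "random", N = 2, calibration_blocks = 1,
                       reps = 2, seed = 11)
  r2 <- evaluate_model(coh, "random", N = 2, calibration_blocks = 1,
                       reps = 2, seed = 11)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("CAR-selected donors are closer to the test subject's archetype", {
  # parameter recovery: ground-truth (noiseless) ERP similarity of selected
  # donors, CAR vs random, checked over seeds
  for (seed in c(21, 22)) {
    spec <- cohort_spec(10, 2, seed = seed, paradigm = eval_paradigm(),
                        cluster_latencies = c(320, 440), base_noise_sd = 6)
    coh <- generate_cohort(spec)
    arch <- coh$archetypes
    true_erp <- function(s) {
      row <- arch[arch$subject_id == s, ]
      p300_template(row$p300_latency, row$p300_amplitude, row$p300_width)
    }
    sim_to <- function(s, donors)
      mean(vapply(donors, function(d)
        pearson_oracle(true_erp(s), true_erp(d)), numeric(1)))
    r_car <- evaluate_model(coh, "car", N = 4, calibration_blocks = 2,
                            seed = 30)
    r_rnd <- evaluate_model(coh, "random", N = 4, calibration_blocks = 2,
                            reps = 3, seed = 30)
    d_car <- attr(r_car, "donors"); d_rnd <- attr(r_rnd, "donors")
    car_sim <- mean(vapply(names(d_car), function(k)
      sim_to(sub("\\.\\d+$", "", k), d_car[[k]]), numeric(1)))
    rnd_sim <- mean(vapply(names(d_rnd), function(k)
      sim_to(sub("\\.\\d+$", "", k), d_rnd[[k]]), numeric(1)))
    expect_gt(car_sim, rnd_sim)
  }
})

test_that("cross-subject AUC degrades as between-subject dispersion grows", {
  aucs <- vapply(c(0, 40, 120), function(disp) {
    spec <- cohort_spec(6, 6, seed = 40, paradigm = eval_paradigm(),
                        between_sd_latency = disp,
                        within_sd_latency = 0, base_noise_sd = 6)
    coh <- generate_cohort(spec)
    res <- evaluate_model(coh, "random", N = 3, calibration_blocks = 1,
                          reps = 2, seed = 41)
    mean(subject_auc(res))
  }, numeric(1))
  expect_true(all(diff(aucs) <= 0),
              info = paste(round(aucs, 3), collapse = " "))
})

test_that("paired comparison handles normal and degenerate inputs", {
  fake_result <- function(auc, model = "random") {
    structure(data.frame(test_subject = sprintf("S%02d", seq_along(auc)),
                         model = model, N = 2L, rep = 1L, auc = auc),
              class = c("evaluation_result", "data.frame"))
  }
  a <- fake_result(seq(0.5, 0.9, length.out = 10))
  cmp_same <- compare_models(a, a)
  expect_equal(cmp_same$t, 0)
  expect_equal(cmp_same$p_value, 1)
  expect_false(is.na(cmp_same$ks_a[["p"]]))

  b <- fake_result(a$auc + 0.1, "car")
  cmp_shift <- compare_models(b, a)
  expect_true(cmp_shift$degenerate)
  expect_true(is.na(cmp_shift$p_value)) # reported as degenerate, not p = 0

  set.seed(50)
  x <- fake_result(rnorm(30, 0.6, 0.05))
  y <- fake_result(rnorm(30, 0.7, 0.05), "car")
  cmp <- compare_models(y, x)
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$mean_diff, 0)

  expect_error(compare_models(a, fake_result(runif(5))), "same test subjects")
})
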