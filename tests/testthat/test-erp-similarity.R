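test_that("coherent averaging is the element-wise class mean", {
  # two scalar target "epochs" with values 1 and 3 (plus nontargets)
  arr <- array(c(1, 3, 7, 9), c(4, 1, 1))
  ep <- make_epochs(arr, labels = c(1, 1, 0, 0), rate = 1000,
                    window = c(0, 1))
  erp <- coherent_average(ep)
  expect_equal(as.numeric(erp$target_mean), 2)
  expect_equal(as.numeric(erp$nontarget_mean), 8)
  expect_equal(erp$n_target_epochs, 2L)

  # M identical epochs average to that epoch exactly
  one <- matrix(rnorm(2 * 50), 2, 50)
  arr2 <- array(0, c(6, 2, 50))
  for (i in 1:6) arr2[i, , ] <- one
  ep2 <- make_epochs(arr2, labels = c(1, 1, 1, 1, 1, 0), rate = 1000,
                     window = c(0, 50))
  expect_equal(coherent_average(ep2)$target_mean, one,
               ignore_attr = TRUE)

  ep3 <- make_epochs(arr, labels = c(1, 1, 1, 1), rate = 1000,
                     window = c(0, 1))
  expect_error(coherent_average(ep3), "nontarget")
})

test_that("averaging M noisy epochs shrinks residual noise as 1/sqrt(M)", {
  set.seed(42)
  tmpl <- p300_template(350, 5, 70)
  sigma <- 4
  for (M in c(4, 16, 64)) {
    resid <- replicate(50, {
      noisy <- matrix(rnorm(M * length(tmpl), 0, sigma), M) +
        rep(tmpl, each = M)
      sqrt(mean((colMeans(noisy) - tmpl)^2))
    })
    expect_equal(mean(resid), sigma / sqrt(M), tolerance = 0.2)
  }
})

test_that("ERP vectorization concatenates channel blocks over the segment", {
  m <- matrix(seq_len(6 * 200), nrow = 6) # 6 channels x 200 samples
  erp <- fake_erp(m, rate = 200, window = c(-200, 800))
  v <- vectorize_erp(erp, c(0, 800))
  expect_length(v, 6 * 160)
  expect_equal(v[1:160], m[1, 41:200])    # channel 1 block first
  expect_equal(v[161:320], m[2, 41:200])

  # single channel, full window: the row unchanged
  erp1 <- fake_erp(m[1, , drop = FALSE], rate = 200, window = c(-200, 800))
  expect_equal(vectorize_erp(erp1, c(-200, 800)), unname(m[1, ]))

  # permuting channels permutes the blocks
  erp_p <- fake_erp(m[c(2, 1, 3:6), ], rate = 200, window = c(-200, 800))
  vp <- vectorize_erp(erp_p, c(0, 800))
  expect_equal(vp[1:160], v[161:320])
  expect_equal(vp[161:320], v[1:160])

  expect_error(vectorize_erp(erp, c(0, 900)), "segment")
})

test_that("cosine similarity matches hand-computed values and contracts", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(3, 4), c(4, 3)), 24 / 25)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(cosine_similarity(1:3, 1:4), "equal length")
  # scale invariance: cosine(c a, b) = cosine(a, b) for c > 0
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10); cc <- runif(1, 0.1, 100)
    expect_equal(cosine_similarity(cc * a, b), cosine_similarity(a, b))
  }
})

test_that("Pearson correlation matches the (n-1)-denominator formula", {
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(pearson_correlation(1:3, 2 * (1:3) + 3), 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "zero-variance")
  # oracle equality and affine invariance on random vectors
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    expect_equal(pearson_correlation(x, y), pearson_oracle(x, y))
    a <- runif(1, -5, 5); b <- runif(1, -5, 5)
    if (a != 0)
      expect_equal(pearson_correlation(a * x + b, y),
                   sign(a) * pearson_correlation(x, y))
  }
})

test_that("similarity matrices are symmetric with unit diagonal", {
  set.seed(10)
  erps <- lapply(1:5, function(i)
    fake_erp(matrix(rnorm(3 * 100), 3), subject_id = sprintf("S%02d", i),
             rate = 100, window = c(0, 1000)))
  for (metric in c("cosine", "pearson")) {
    sim <- similarity_matrix(erps, metric, segment = c(0, 1000))
    expect_equal(sim$values, t(sim$values))
    expect_equal(unname(diag(sim$values)), rep(1, 5))
    expect_true(all(sim$values >= -1 - 1e-12 & sim$values <= 1 + 1e-12))
  }
})

test_that("match counts equal the brute-force pair count", {
  set.seed(11)
  for (rep_i in 1:5) {
    n <- sample(3:20, 1)
    vecs <- lapply(seq_len(n), function(i) rnorm(30))
    erps <- lapply(seq_len(n), function(i)
      fake_erp(matrix(vecs[[i]], 1), subject_id = sprintf("S%02d", i),
               rate = 30, window = c(0, 1000)))
    thr <- runif(1, -0.3, 0.7)
    mc <- match_counts(erps, threshold = thr, segment = c(0, 1000))
    expect_equal(unname(mc$counts), match_counts_oracle(vecs, thr))
    expect_false(any(diag(mc$binary)))
  }
  # identical ERPs: every subject matches all n-1 others at threshold 0.5
  same <- lapply(1:4, function(i)
    fake_erp(matrix(sin(1:50), 1), subject_id = sprintf("S%02d", i),
             rate = 50, window = c(0, 1000)))
  expect_equal(unname(match_counts(same, 0.5, c(0, 1000))$counts),
               rep(3L, 4))
  # pairwise-orthogonal ERPs: all counts zero
  ortho <- lapply(1:3, function(i) {
    v <- rep(0, 30); v[i] <- 1
    fake_erp(matrix(v, 1), subject_id = sprintf("S%02d", i),
             rate = 30, window = c(0, 1000))
  })
  expect_equal(unname(match_counts(ortho, 0.5, c(0, 1000))$counts),
               rep(0L, 3))
})

test_that("CAR ranking orders donors by descending correlation", {
  set.seed(12)
  base <- matrix(rnorm(2 * 80), 2)
  test <- fake_erp(base, "T01", rate = 80, window = c(0, 1000))
  donors <- list(
    fake_erp(base, "D_copy", rate = 80, window = c(0, 1000)),
    fake_erp(base + matrix(rnorm(160, sd = 0.5), 2), "D_near", rate = 80,
             window = c(0, 1000)),
    fake_erp(-base, "D_neg", rate = 80, window = c(0, 1000)))
  rk <- rank_donors(test, donors, segment = c(0, 1000))
  expect_equal(rk$ranked_donors$subject_id[1], "D_copy")
  expect_equal(rk$ranked_donors$r[1], 1)
  expect_equal(rk$ranked_donors$subject_id[3], "D_neg")
  expect_equal(rk$ranked_donors$r[3], -1)
  expect_true(all(diff(rk$ranked_donors$r) <= 0))
  # ranking is a permutation of the donor ids
  expect_setequal(rk$ranked_donors$subject_id,
                  c("D_copy", "D_near", "D_neg"))
  expect_error(rank_donors(test, list(test)), "test subject")
})

test_that("same-cluster donors rank first on a noiseless two-cluster cohort", {
  spec <- cohort_spec(10, 2, seed = 5,
                      paradigm = paradigm_config(
                        n_symbols = 6L, rounds_per_trial = 1L,
                        trials_per_block = 2L, n_blocks = 2L),
                      cluster_latencies = c(300, 450),
                      within_sd_latency = 5, base_noise_sd = 0)
  coh <- generate_cohort(spec)
  erps <- lapply(coh$subjects, coherent_average)
  cl <- setNames(coh$archetypes$cluster_id, coh$archetypes$subject_id)
  for (s in names(erps)) {
    rk <- rank_donors(erps[[s]], erps[names(erps) != s])
    same <- cl[rk$ranked_donors$subject_id] == cl[s]
    expect_true(all(diff(same) <= 0), # all same-cluster donors first
                info = paste("test subject", s))
    # brute-force check of the ordering itself
    v0 <- vectorize_erp(erps[[s]])
    r_manual <- vapply(rk$ranked_donors$subject_id, function(d)
      pearson_oracle(v0, vectorize_erp(erps[[d]])), numeric(1))
    expect_equal(rk$ranked_donors$r, unname(r_manual))
  }
})
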