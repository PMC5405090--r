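test_that("cross-correlation matches hand-checked anchor cases", {
  a <- c(1, 2, 5, 3, 4)
  expect_equal(cross_correlation(a, a, 0), 1)
  expect_equal(cross_correlation(a, -a + 10, 0), -1)
  # both series constant is undefined
  expect_true(is.nan(cross_correlation(rep(2, 5), rep(3, 5), 1)))
  # out-of-range lag
  expect_error(cross_correlation(a, a, 5), "out of range")
})

test_that("cross-correlation equals the direct-sum oracle on a fixed pair", {
  a <- c(0, 1, 2, 3, 4)
  b <- c(1, 0, 1, 2, 3)
  for (h in -4:4)
    expect_equal(cross_correlation(a, b, h), xcorr_oracle(a, b, h),
                 tolerance = 1e-14, label = paste("lag", h))
  # frozen values computed from the direct-sum oracle
  expect_equal(round(xcorr_oracle(a, b, 0), 10), 0.8320502943)
  expect_equal(round(xcorr_oracle(a, b, -1), 10), 0.6656402355)
  expect_equal(round(xcorr_oracle(a, b, -2), 10), 0.0277350098)
  expect_equal(round(xcorr_oracle(a, b, 1), 10), 0.1664100589)
})

test_that("the regulator series carries the shift", {
  # target reproduces the regulator one interval later: peak at h = -1
  a <- c(0, 1, 0, 0, 0)
  b <- c(0, 0, 1, 0, 0)
  expect_gt(cross_correlation(a, b, -1), 0.9)
  # flipping the convention moves the peak to +1
  expect_equal(cross_correlation(a, b, 1, shift = "target"),
               cross_correlation(a, b, -1))
})

test_that("best_lag recovers implanted shifts and applies the band filter", {
  a <- c(0.3, 2.1, 2.4, 2.2, 2.3)    # step with slight wiggle
  # identical profiles: zero lag, retained
  res0 <- best_lag(a, a)
  expect_equal(res0$h, 0L)
  expect_equal(res0$r, 1)
  expect_true(res0$retained)
  expect_named(res0$r_by_lag, as.character(-3:3))

  # target delayed one index: h = -1, retained
  b <- shift_profile(a, 1)
  res1 <- best_lag(a, b)
  expect_equal(res1$h, -1L)
  expect_true(res1$retained)

  # target LEADS by one index: h = +1, discarded
  res2 <- best_lag(b, a)
  expect_equal(res2$h, 1L)
  expect_false(res2$retained)

  # constant pair is flagged undefined, not an error
  resc <- best_lag(rep(1, 5), rep(2, 5))
  expect_false(resc$defined)
  expect_false(resc$retained)
})

test_that("best_lag agrees with a brute-force oracle on random profiles", {
  set.seed(42)
  for (i in 1:200) {
    a <- rnorm(5); b <- rnorm(5)
    got <- best_lag(a, b)
    want <- best_lag_oracle(a, b)
    expect_equal(got$h, want$h)
    expect_equal(got$r, want$r, tolerance = 1e-12)
  }
})

test_that("lag filter retains exactly the -3..0 band", {
  for (h in -4:4) {
    res <- structure(list(h = as.integer(h), r = 0.5, retained = NA,
                          r_by_lag = numeric(), defined = TRUE),
                     class = "lag_result")
    expect_equal(filter_by_lag(res)$retained, h >= -3 && h <= 0,
                 label = paste("lag", h))
    expect_equal(filter_by_lag(h), h >= -3 && h <= 0)
  }
})

test_that("noise-free index-shifted copies recover h = -k for every k", {
  for (p in 1:4) for (k in 0:3) {
    if (p + k > 4) next
    a <- step_profile(p)
    b <- shift_profile(a, k)
    expect_equal(best_lag(a, b)$h, -k,
                 label = sprintf("step at %d, shift %d", p, k))
  }
})

test_that("lag recovery on noisy unit-amplitude steps stays above 90%", {
  hits <- 0L; total <- 0L
  for (s in 1:200) {
    sim <- simulate_dataset(simulation_spec(
      n_regulators = 5, targets_per_regulator = 2, step_amplitude = 1,
      noise_sd = 0.1, n_null_genes = 60, seed = s))
    fit <- seqreg(sim$counts, sim$pairs)
    rec <- score_recovery(sim$truth, fit$lags, fit$assignments)
    hits <- hits + rec$lag_recovery * rec$n_pairs
    total <- total + rec$n_pairs
  }
  expect_gte(hits / total, 0.9)
})

test_that("best_lag is invariant under affine rescaling of either profile", {
  set.seed(5)
  a <- rnorm(5); b <- rnorm(5)
  base <- best_lag(a, b)
  up <- best_lag(3 * a + 2, b)
  expect_equal(up$h, base$h)
  expect_equal(up$r_by_lag, base$r_by_lag, tolerance = 1e-12)
  neg <- best_lag(a, -2 * b + 1)
  expect_equal(neg$r_by_lag, -base$r_by_lag, tolerance = 1e-12)
})

test_that("|r| stays within 1 plus tolerance across random inputs and lags", {
  set.seed(6)
  for (i in 1:300) {
    a <- rnorm(5); b <- rnorm(5)
    r <- best_lag(a, b)$r_by_lag
    expect_true(all(abs(r[!is.nan(r)]) <= 1 + 1e-9))
  }
})

test_that("lag_table covers all pairs and flags missing or constant genes", {
  sim <- simulate_dataset(simulation_spec(n_regulators = 3,
                                          targets_per_regulator = 2,
                                          n_null_genes = 10, seed = 2))
  expr <- normalize_log(filter_unexpressed(sim$counts))
  pairs <- rbind(sim$pairs,
                 regulatory_pairs("tf001", "absent_gene"))
  class(pairs) <- c("regulatory_pairs", "data.frame")
  lt <- lag_table(expr, pairs)
  expect_equal(nrow(lt), nrow(pairs))
  missing_row <- lt[lt$target == "absent_gene", ]
  expect_false(missing_row$defined)
  expect_false(missing_row$retained)
  expect_true(all(lt$retained[lt$defined] == (lt$h[lt$defined] >= -3 &
                                              lt$h[lt$defined] <= 0)))
})

test_that("correlation_summary reports both statistics consistently", {
  # identical profiles: all means 1, no negatives
  m <- matrix(rep(c(1, 3, 2, 5, 4), 2), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c(3, 4, 5, 6, 8)))
  expr <- structure(m, timepoints = c(3, 4, 5, 6, 8), sample_id = "s",
                    size_factors = rep(1, 5), pseudocount = 1,
                    class = c("log_expr", "matrix", "array"))
  pairs <- regulatory_pairs("a", "b")
  cs <- correlation_summary(expr, pairs)
  expect_equal(cs["pearson", "overall_mean"], 1)
  expect_equal(cs["cross_correlation", "positive_mean"], 1)
  expect_true(is.na(cs["pearson", "negative_mean"]))

  # best-lag |r| can only improve on the zero-lag |r|
  sim <- simulate_dataset(simulation_spec(n_regulators = 5,
                                          targets_per_regulator = 2,
                                          n_null_genes = 20, seed = 9))
  fit <- seqreg(sim$counts, sim$pairs)
  cs2 <- correlation_summary(fit$expr, fit$pairs)
  lt <- fit$lags
  expect_gte(mean(abs(lt$r)), mean(abs(lt$r_lag_0)))

  # mixed-sign arithmetic agrees with a direct recomputation
  zero <- lt$r_lag_0
  expect_equal(cs2["pearson", "overall_mean"], mean(zero))
  expect_equal(cs2["pearson", "negative_mean"], mean(zero[zero < 0]))
  expect_equal(cs2["cross_correlation", "positive_mean"],
               mean(lt$r[lt$r > 0]))
})
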