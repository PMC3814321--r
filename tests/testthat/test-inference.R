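test_that("division estimates invert the cumulative labeling model", {
  est1 <- estimate_divisions(make_counts(rep(0.25, 3)), p = 0.25,
                             n_boot = 200, seed = 1)
  expect_equal(est1$k_hat, 1, tolerance = 1e-12)
  est2 <- estimate_divisions(make_counts(rep(0.4375, 4), n_total = 1600),
                             p = 0.25, n_boot = 200, seed = 1)
  expect_equal(est2$k_hat, 2, tolerance = 1e-12)
  est0 <- estimate_divisions(make_counts(rep(0, 3)), p = 0.1,
                             n_boot = 200, seed = 1)
  expect_equal(est0$k_hat, 0)
  expect_true(est1$ci_low <= est1$k_hat && est1$k_hat <= est1$ci_high)
})

test_that("k_hat is strictly increasing in the pooled labeled fraction", {
  khats <- vapply(c(0.05, 0.2, 0.4, 0.6, 0.8), function(f) {
    estimate_divisions(make_counts(rep(f, 3)), p = 0.1, n_boot = 50,
                       seed = 1)$k_hat
  }, numeric(1))
  expect_true(all(diff(khats) > 0))
})

test_that("saturated labeling is refused rather than extrapolated", {
  expect_error(
    estimate_divisions(make_counts(rep(1, 3)), p = 0.25, seed = 1),
    class = "tlox_model_error"
  )
  expect_error(
    estimate_divisions(make_counts(0.5, n_total = 0), p = 0.25),
    class = "tlox_data_error"
  )
})

test_that("activation probability estimates invert known division counts", {
  est <- estimate_activation_prob(make_counts(rep(0.4375, 3), n_total = 1600),
                                  k = 2, n_boot = 200, seed = 1)
  expect_equal(est$k_hat, 0.25, tolerance = 1e-12)
  est0 <- estimate_activation_prob(make_counts(rep(0, 3)), k = 3,
                                   n_boot = 200, seed = 1)
  expect_equal(est0$k_hat, 0)
  # effective-generation calibration: 24% labeled after 24 h of culture at a
  # 17 h doubling time implies an effective p below the 25% ceiling
  est_cal <- estimate_activation_prob(
    make_counts(rep(0.24, 3), n_total = 2500), k = 24 / 17,
    n_boot = 200, seed = 1
  )
  expect_equal(est_cal$k_hat, 1 - (1 - 0.24)^(17 / 24), tolerance = 1e-12)
  expect_equal(est_cal$k_hat, 0.1767, tolerance = 1e-3)
})

test_that("tidy and glance methods expose estimates as one-row tibbles", {
  est <- estimate_divisions(make_counts(rep(0.3, 3)), p = 0.1,
                            n_boot = 100, seed = 2)
  td <- generics::tidy(est)
  expect_equal(nrow(td), 1L)
  expect_named(td, c("term", "estimate", "conf.low", "conf.high"))
  gl <- generics::glance(est)
  expect_equal(gl$n_mice, 3L)
  expect_equal(gl$assumed, 0.1)
})

test_that("round-trip recovery works across the realistic design grid", {
  withr::local_seed(123)
  for (k in c(1, 3, 6)) {
    for (p in c(0.05, 0.25)) {
      f <- 1 - (1 - p)^k
      counts <- tibble::tibble(
        mouse = paste0("m", 1:3),
        n_labeled = rbinom(3, 10000, f),
        n_total = 10000
      )
      est <- estimate_divisions(counts, p = p, n_boot = 500)
      # deterministic 4-sigma band from the binomial sampling noise
      se_k <- sqrt(f * (1 - f) / 30000) / ((1 - f) * abs(log(1 - p)))
      expect_lt(abs(est$k_hat - k), 4 * se_k)
      expect_gte(est$ci_high, est$ci_low)
    }
  }
})

test_that("single-mouse inputs fall back to cell-level bootstrap", {
  est <- estimate_divisions(
    tibble::tibble(mouse = "m1", n_labeled = 1900, n_total = 10000),
    p = 0.1, n_boot = 500, seed = 3
  )
  expect_equal(est$n_mice, 1L)
  expect_gt(est$ci_high, est$ci_low)
  expect_true(est$ci_low <= est$k_hat && est$k_hat <= est$ci_high)
})

test_that("two-population test is null on duplicated groups", {
  a <- make_counts(c(0.3, 0.32, 0.28), n_total = 2000, prefix = "a")
  res <- two_population_test(a, a, p = 0.1, seed = 1, method = "mouse")
  expect_equal(res$effect, 0)
  expect_equal(res$p_value, 1)
})

test_that("small cohorts trigger the documented cell-level fallback", {
  a <- make_counts(c(0.19, 0.2, 0.18), n_total = 3000, prefix = "a")
  b <- make_counts(c(0.46, 0.48, 0.45), n_total = 3000, prefix = "b")
  expect_warning(
    res <- two_population_test(a, b, p = 0.1, seed = 1),
    class = "tlox_fallback_warning"
  )
  expect_equal(res$method, "cell-proportion")
  expect_lt(res$p_value, 0.05)
  expect_gt(res$effect, 3)
})

test_that("mouse-level permutation runs exactly when cohorts allow it", {
  a <- make_counts(c(0.18, 0.2, 0.19, 0.21), n_total = 3000, prefix = "a")
  b <- make_counts(c(0.45, 0.48, 0.46, 0.47), n_total = 3000, prefix = "b")
  res <- two_population_test(a, b, p = 0.1, seed = 1)
  expect_equal(res$method, "mouse-permutation")
  expect_true(res$exact)
  expect_equal(res$n_perm, choose(8, 4))
  expect_equal(res$p_value, 2 / 70, tolerance = 1e-12)
})

test_that("beta-binomial overdispersion estimates track the generating ICC", {
  withr::local_seed(77)
  rho_true <- 0.05
  f <- 0.3
  shape <- (1 - rho_true) / rho_true
  fm <- rbeta(40, f * shape, (1 - f) * shape)
  counts <- tibble::tibble(
    mouse = paste0("m", 1:40),
    n_labeled = rbinom(40, 2000, fm),
    n_total = 2000
  )
  res <- two_population_test(counts, counts, p = 0.1, n_perm = 50, seed = 1,
                             method = "mouse")
  expect_lt(abs(res$rho[["a"]] - rho_true), 0.03)
})

test_that("time-series fits recover the generating activation probability", {
  # single point at one doubling time inverts exactly
  one <- tibble::tibble(time_h = 17, n_labeled = 2500, n_cells = 10000)
  fit1 <- fit_effective_p_timeseries(one, doubling_time = 17)
  expect_equal(fit1$p_hat, 0.25, tolerance = 1e-3)
  expect_true(fit1$ci_low < 0.25 && 0.25 < fit1$ci_high)

  withr::local_seed(41)
  p_true <- 0.15
  times <- c(12, 24, 36, 48, 60)
  series <- tibble::tibble(
    time_h = times,
    n_labeled = rbinom(5, 1e4, 1 - (1 - p_true)^(times / 17)),
    n_cells = 1e4
  )
  fit <- fit_effective_p_timeseries(series, doubling_time = 17)
  expect_lt(abs(fit$p_hat - p_true), 0.01)
  expect_true(fit$ci_low < p_true && p_true < fit$ci_high)
})

test_that("degenerate time series are rejected with data errors", {
  expect_error(fit_effective_p_timeseries(tibble::tibble(), 17),
               class = "tlox_data_error")
  expect_error(
    fit_effective_p_timeseries(
      tibble::tibble(time_h = 0, n_labeled = 1, n_cells = 10), 17
    ),
    class = "tlox_data_error"
  )
  expect_error(
    fit_effective_p_timeseries(
      tibble::tibble(time_h = 24, n_labeled = 11, n_cells = 10), 17
    ),
    class = "tlox_data_error"
  )
  expect_error(
    fit_effective_p_timeseries(
      tibble::tibble(time_h = 24, n_labeled = 5, n_cells = 10), 0
    ),
    class = "tlox_model_error"
  )
})
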