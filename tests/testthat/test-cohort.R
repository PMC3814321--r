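test_that("cohort generation is exactly reproducible under a seed", {
  cfg <- cohort_config(tibble::tibble(group = "g", k = 2, p = 0.1),
                       n_mice = 3, n_cells = 400)
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_identical(cohort_manifest(a)$mouse_fractions,
                   cohort_manifest(b)$mouse_fractions)
  expect_equal(nrow(a), 3 * 400)
  expect_named(
    a, c("group", "mouse", "gfp_intensity", "tdtomato_intensity",
         "brdu_status", "true_label")
  )
})

test_that("mouse fractions center on the cumulative labeling expectation", {
  k <- 3; p <- 0.1
  cfg <- cohort_config(tibble::tibble(group = "g", k = k, p = p),
                       n_mice = 60, n_cells = 50, rho = 0.02)
  man <- cohort_manifest(generate_cohort(cfg, seed = 8))
  f_true <- 1 - (1 - p)^k
  fr <- man$mouse_fractions$true_fraction
  se <- sqrt(f_true * (1 - f_true) * 0.02 / 60)
  expect_lt(abs(mean(fr) - f_true), 4 * se)
  expect_equal(unique(man$mouse_fractions$expected_fraction), f_true)
})

test_that("zero overdispersion gives exchangeable binomial labels across mice", {
  cfg <- cohort_config(tibble::tibble(group = "g", k = 2, p = 0.2),
                       n_mice = 8, n_cells = 5000, rho = 0)
  ev <- generate_cohort(cfg, seed = 13)
  counts <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ev), mouse),
    n_labeled = sum(true_label), n_total = dplyr::n(), .groups = "drop"
  )
  # all mice share one Bernoulli rate: the ANOVA ICC estimate collapses to ~0
  res <- two_population_test(counts, counts, p = 0.2, n_perm = 10, seed = 1,
                             method = "mouse")
  expect_lt(res$rho[["a"]], 0.005)
  # and the true per-mouse fractions are literally identical
  expect_equal(length(unique(cohort_manifest(ev)$mouse_fractions$true_fraction)), 1L)
})

test_that("BrdU positivity follows the pulse model per group", {
  cfg <- cohort_config(
    tibble::tibble(group = c("hot", "cold"), k = 2, p = 0.1,
                   cycling_fraction = c(0.4, 0.05)),
    n_mice = 3, n_cells = 4000
  )
  ev <- generate_cohort(cfg, seed = 21)
  obs <- tapply(ev$brdu_status, ev$group, mean)
  expected <- vapply(c(hot = 0.4, cold = 0.05), function(cf) {
    brdu_fraction(brdu_params(cf, 24, 8, 4))
  }, numeric(1))
  for (g in names(expected)) {
    se <- sqrt(expected[g] * (1 - expected[g]) / 12000)
    expect_lt(abs(obs[[g]] - expected[[g]]), 4 * se)
  }
})

test_that("invalid cohort configurations are rejected", {
  groups <- tibble::tibble(group = "g", k = 2, p = 0.1)
  expect_error(cohort_config(groups, rho = 1), class = "tlox_config_error")
  expect_error(cohort_config(groups, rho = -0.1), class = "tlox_config_error")
  expect_error(cohort_config(tibble::tibble(group = "g", k = 2, p = 1.2)),
               class = "tlox_config_error")
  expect_error(cohort_config(tibble::tibble(x = 1)),
               class = "tlox_config_error")
  expect_error(generate_cohort(list()), class = "tlox_config_error")
})

test_that("gating with a wide mixture recovers the true labels", {
  cfg <- cohort_config(
    tibble::tibble(group = "g", k = 2, p = 0.25), n_mice = 3, n_cells = 2000,
    intensity = intensity_model(td_meanlog_neg = 0, td_meanlog_pos = 20)
  )
  ev <- generate_cohort(cfg, seed = 31)
  gates <- gate_events(ev)
  truth <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ev), group, mouse),
    n_labeled = sum(true_label), n_total = dplyr::n(), .groups = "drop"
  )
  expect_equal(tibble::as_tibble(gates), truth, ignore_attr = TRUE)
  expect_equal(gate_summary(gates)$error_rate, 0)
})

test_that("midpoint-gate misclassification matches the Gaussian overlap", {
  sep_sd <- 3 # midpoint sits 1.5 sd from each component mean
  cfg <- cohort_config(
    tibble::tibble(group = "g", k = 2, p = 0.25), n_mice = 3, n_cells = 20000,
    intensity = intensity_model(td_meanlog_neg = 2, td_meanlog_pos = 5,
                                td_sdlog = 1)
  )
  ev <- generate_cohort(cfg, seed = 37)
  gates <- gate_events(ev)
  expected_error <- stats::pnorm(-sep_sd / 2) # symmetric for both components
  got <- gate_summary(gates)$error_rate
  expect_lt(abs(got - expected_error), 0.005)
})

test_that("Otsu gating lands between the mixture components", {
  cfg <- cohort_config(tibble::tibble(group = "g", k = 2, p = 0.25),
                       n_mice = 3, n_cells = 5000)
  ev <- generate_cohort(cfg, seed = 41)
  gates <- gate_events(ev, policy = "otsu")
  thr <- gate_summary(gates)$threshold_log
  expect_gt(thr, 2)
  expect_lt(thr, 8)
  expect_lt(gate_summary(gates)$error_rate, 0.01)
})

test_that("poorly separated mixtures raise a separability warning", {
  cfg <- cohort_config(
    tibble::tibble(group = "g", k = 2, p = 0.25), n_mice = 2, n_cells = 500,
    intensity = intensity_model(td_meanlog_neg = 2, td_meanlog_pos = 3.5,
                                td_sdlog = 1)
  )
  ev <- generate_cohort(cfg, seed = 43)
  expect_warning(gate_events(ev), class = "tlox_separability_warning")
})

test_that("gating rejects tables without the needed columns", {
  expect_error(gate_events(tibble::tibble(a = 1)), class = "tlox_data_error")
  expect_error(
    gate_events(tibble::tibble(group = "g", mouse = "m",
                               tdtomato_intensity = -1)),
    class = "tlox_data_error"
  )
})

test_that("generator, gate and estimator close the loop on the shipped scenarios", {
  ev <- generate_cohort(scenario_vg11_liver_node(n_cells = 2000), seed = 51)
  gates <- gate_events(ev)
  for (g in c("liver", "node")) {
    k_true <- if (g == "liver") 6 else 2
    est <- estimate_divisions(gates[gates$group == g, ], p = 0.1,
                              n_boot = 500, seed = 52)
    expect_true(est$ci_low <= k_true && k_true <= est$ci_high)
  }

  # B path: mature-B labeled fraction lands near the configured 43%
  evb <- generate_cohort(scenario_b_path(n_cells = 4000), seed = 53)
  gb <- gate_events(evb)
  f <- sum(gb$n_labeled) / sum(gb$n_total)
  expect_lt(abs(f - 0.43), 0.06)
})

test_that("the neonate/adult contrast reproduces the rate-history discordance", {
  ev <- generate_cohort(scenario_id3_contrast(n_cells = 3000), seed = 61)
  tlox_counts <- gate_events(ev)
  brdu_counts <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ev), group, mouse),
    n_labeled = sum(brdu_status), n_total = dplyr::n(), .groups = "drop"
  )
  rep_out <- history_vs_rate_report(
    brdu_counts, tlox_counts,
    contrasts = tibble::tibble(
      group_a = c("neonate_id3ko", "adult_id3ko"),
      group_b = c("neonate_wt", "adult_wt")
    ),
    n_boot = 1000, seed = 62
  )
  neo <- rep_out[rep_out$group_a == "neonate_id3ko", ]
  adu <- rep_out[rep_out$group_a == "adult_id3ko", ]
  expect_equal(neo$rate_call, "up")
  expect_equal(neo$history_call, "similar")
  expect_equal(adu$rate_call, "down")
  expect_equal(adu$history_call, "up")
  expect_false(any(rep_out$concordant))
})
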