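test_that("recovery ratio matches the closed-form compartment solutions", {
  expect_identical(ratio_recovery(0, 1.87, 4.94e-3), 0)
  expect_equal(ratio_recovery(1e9, 1.87, 4.94e-3), 1.87, tolerance = 1e-12)
  # frozen value computed independently from the compartment solutions
  expect_equal(ratio_recovery(200, 1.87, 4.94e-3, v = 1), 0.691978,
               tolerance = 1e-6)
  t <- c(0, 50, 200, 1000, 5000)
  expect_equal(ratio_recovery(t, 2.4, 3e-3, v = 1.7),
               oracle_ratio(t, 2.4, 3e-3, v = 1.7), tolerance = 1e-12)
  expect_error(ratio_recovery(-1, 1, 1e-3))
  expect_error(ratio_recovery(10, -1, 1e-3))
})

test_that("recovery ratio is monotone increasing and bounded by K_e", {
  withr::with_seed(11, {
    for (i in 1:50) {
      K <- exp(runif(1, log(0.05), log(20)))
      k <- exp(runif(1, log(1e-4), log(0.05)))
      v <- exp(runif(1, log(0.2), log(5)))
      t <- sort(runif(200, 0, 10 / k))
      r <- ratio_recovery(t, K, k, v)
      expect_true(all(diff(r) > 0))
      expect_true(all(r <= K))
    }
  })
})

test_that("export-mode ratio mirrors the import form", {
  t <- seq(0, 3000, by = 60)
  expect_identical(export_ratio_recovery(t, 1.3, 2e-3, 0.8),
                   ratio_recovery(t, 1.3, 2e-3, 0.8))
})

test_that("rate decomposition obeys K_e = k_I/k_E and k = k_I + k_E", {
  expect_equal(rates_from_fit(1, 2), c(k_I = 1, k_E = 1))
  r <- rates_from_fit(1.87, 4.94)
  expect_equal(unname(r["k_I"]), 3.22, tolerance = 5e-3)
  expect_equal(unname(r["k_I"] + r["k_E"]), 4.94)
  expect_equal(unname(r["k_I"] / r["k_E"]), 1.87, tolerance = 1e-12)
  # swapped roles in export mode
  re <- rates_from_fit(1.87, 4.94, mode = "export")
  expect_equal(unname(re["k_E"] / re["k_I"]), 1.87, tolerance = 1e-12)
  # K_e -> Inf pushes everything into the accumulating rate
  expect_equal(unname(rates_from_fit(1e12, 4.94)["k_I"]), 4.94,
               tolerance = 1e-9)
  withr::with_seed(12, for (i in 1:20) {
    K <- exp(runif(1, -3, 3)); k <- runif(1, 0.1, 10)
    r <- rates_from_fit(K, k)
    expect_equal(unname(sum(r)), k, tolerance = 1e-12)
  })
})

test_that("transport_params enforces mass conservation and rate algebra", {
  p <- transport_params(1.87, 4.94e-3, v = 1.6)
  expect_equal(p$k_I + p$k_E, p$k, tolerance = 1e-12)
  expect_equal(p$v * (p$Ne - p$N0), p$C0 - p$Ce, tolerance = 1e-12)
  expect_equal(p$Ne / p$Ce, p$K_e, tolerance = 1e-12)
  expect_error(transport_params(-1, 1e-3))
  expect_error(transport_params(1.87, 0))
  expect_error(transport_params(1.87, 1e-3, v = -2))
})

test_that("split statistic reproduces the printed asymmetries", {
  expect_equal(round(split_percent(3.22, 2.06)), 56)
  expect_equal(split_percent(c(2, 2, 2), c(2, 2, 2)), 0)
  expect_equal(split_percent(2.06, 3.22), -36.02484, tolerance = 1e-5)
  # inverse relation under group exchange
  withr::with_seed(13, for (i in 1:20) {
    a <- runif(5, 0.5, 4); b <- runif(7, 0.5, 4)
    s_ab <- split_percent(a, b)
    s_ba <- split_percent(b, a)
    expect_equal(s_ab, 100 * (1 / (1 + s_ba / 100) - 1), tolerance = 1e-9)
  })
  expect_error(split_percent(numeric(0), 1))
  expect_error(split_percent(1, -1))
})

test_that("group comparison is a calibrated two-sided Mann-Whitney", {
  same <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p.value, 1)
  sep <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_true(sep$U %in% c(0, 9))
  expect_equal(sep$p.value, 0.1)  # exact: 2/20 orderings as extreme
  expect_equal(sep$mean_b, 11)
  expect_error(compare_groups(1, c(1, 2)))
  # null calibration: two samples from one distribution
  rej <- withr::with_seed(14, mean(replicate(2000, {
    compare_groups(rnorm(12), rnorm(12))$p.value < 0.05
  })))
  expect_gt(rej, 0.035)  # 3 sigma around 0.05 at 2000 replicates
  expect_lt(rej, 0.065)
})
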