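test_that("the critical t-value at the published sample size is 2.58", {
  expect_equal(round(critical_t(500, 0.01), 2), 2.58)
})

test_that("t-series implements the printed pooled form exactly", {
  # independent arithmetic evaluation on a 4-trial toy
  x1 <- matrix(c(1.0, 2.0, 0.5, 1.5, 2.0, 3.0, 1.5, 2.5), 4)
  x2 <- matrix(c(0.2, 0.7, 0.1, 0.4, 0.2, 0.7, 0.1, 0.4), 4)
  n <- 4
  hand <- vapply(1:2, function(j) {
    a <- x1[, j]; b <- x2[, j]
    ma <- sum(a) / n; mb <- sum(b) / n
    va <- sum((a - ma)^2) / (n - 1); vb <- sum((b - mb)^2) / (n - 1)
    s2 <- ((n - 1) * va + (n - 1) * vb) / (2 * n - 1)
    (ma - mb) / sqrt(s2 / n)
  }, numeric(1))
  ts <- t_series(x1, x2)
  expect_equal(ts$t, hand, tolerance = 1e-12)
  # identical groups give t == 0; swapping groups negates t
  expect_equal(t_series(x1, x1)$t, c(0, 0))
  expect_equal(t_series(x2, x1)$t, -ts$t)
  # zero pooled variance is flagged, not fabricated
  z <- matrix(1, 4, 1)
  expect_true(is.na(t_series(z, z)$t))
  # the Welch switch changes the scaling as expected
  tw <- t_series(x1, x2, var_form = "welch")
  expect_false(isTRUE(all.equal(tw$t, ts$t)))
})

test_that("cluster extraction matches a brute-force oracle on random series", {
  dt <- 0.001
  withr::with_seed(12, {
    for (i in 1:200) {
      t <- rnorm(300, sd = 1.6)
      got <- extract_clusters(t, critical = 2.58, dt = dt)
      want <- brute_clusters(t, 2.58, dt)
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_equal(got$area_s, want$area_s, tolerance = 1e-12)
        expect_equal(got$length_ms, want$length_ms)
      }
    }
  })
  # constructed constant-height run
  t <- rep(0, 100); t[21:28] <- 3
  cl <- extract_clusters(t, 2.58, dt = 0.002)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$area_s, 8 * 3 * 0.002)
  expect_equal(cl$length_ms, 8 * 2)
  # two runs come out in descending area order
  t[61:75] <- -2.9
  cl2 <- extract_clusters(t, 2.58, dt = 0.002)
  expect_equal(cl2$rank, 1:2)
  expect_equal(cl2$sign, c(-1, 1))
  expect_true(all(diff(cl2$area_s) <= 0))
  expect_equal(nrow(extract_clusters(rep(1, 50), 2.58, 0.001)), 0)
})

test_that("baseline filtering removes sub-baseline clusters only", {
  t <- rep(0, 100); t[11:20] <- 4; t[51:54] <- 3
  cl <- extract_clusters(t, 2.58, 0.001)
  expect_equal(nrow(baseline_filter(cl, 0)), 2)
  kept <- baseline_filter(cl, 0.013)  # above the small cluster's area
  expect_equal(nrow(kept), 1)
  expect_equal(kept$rank, 1L)
  expect_equal(nrow(baseline_filter(cl, 99)), 0)
})

test_that("permutation p-values: separation, determinism, reproducibility", {
  withr::with_seed(13, {
    n <- 12; T_ <- 160
    x2 <- ar1_trials(n, T_, sd = 0.5)
    x1 <- ar1_trials(n, T_, sd = 0.5)
    x1[, 61:90] <- x1[, 61:90] + 6  # huge localized shift
  })
  ct1 <- cluster_test(x1, x2, dt = 0.001, critical = critical_t(n),
                      n_perm_min = 400, seed = 99)
  expect_gte(nrow(ct1$clusters), 1)
  expect_lte(ct1$clusters$p[1], 1 / 400)
  expect_lte(abs(ct1$clusters$start[1] - 61), 3)
  ct2 <- cluster_test(x1, x2, dt = 0.001, critical = critical_t(n),
                      n_perm_min = 400, seed = 99)
  expect_identical(ct1$clusters, ct2$clusters)
  # empty observed clusters short-circuit
  none <- permutation_p(x1, x2, extract_clusters(rep(0, T_), 2.58, 0.001),
                        dt = 0.001)
  expect_equal(nrow(none), 0)
  expect_true(all(c("p", "n_null") %in% names(none)))
  # tidy/glance views
  td <- tidy(ct1); gl <- glance(ct1)
  expect_s3_class(td, "tbl_df")
  expect_equal(gl$n, n)
  expect_gte(gl$n_significant, 1)
})

test_that("first-cluster area grows with the injected effect amplitude", {
  areas <- purrr::map_dbl(c(1.5, 3, 6), function(amp) {
    withr::with_seed(14, {
      n <- 15; T_ <- 200
      x2 <- ar1_trials(n, T_, sd = 0.8)
      x1 <- ar1_trials(n, T_, sd = 0.8)
    })
    x1[, 81:120] <- x1[, 81:120] + amp
    ct <- cluster_test(x1, x2, dt = 0.001, critical = critical_t(15),
                       n_perm_min = 200, seed = 1)
    pm <- propagation_metrics(ct, alpha = 0.05)
    if (pm$found) pm$area_s else 0
  })
  expect_true(all(diff(areas) > 0))
})

test_that("Bonferroni-corrected pointwise test is contained in the suprathreshold set", {
  withr::with_seed(15, {
    n <- 20; T_ <- 150
    x2 <- matrix(rnorm(n * T_), n)
    x1 <- matrix(rnorm(n * T_), n)
  })
  bt0 <- bonferroni_test(x1, x1)
  expect_false(any(bt0$mask))
  x1[, 41:60] <- x1[, 41:60] + 4
  bt <- bonferroni_test(x1, x2, alpha = 0.01)
  expect_true(any(bt$mask[41:60]))
  expect_false(any(bt$mask[-(35:66)]))
  crit <- stats::qt(1 - bt$alpha_corrected / 2, df = 2 * n - 1)
  expect_true(all(abs(bt$tseries$t[bt$mask]) >= crit))
})

test_that("propagation metrics return an explicit none-record without significant clusters", {
  withr::with_seed(16, x2 <- ar1_trials(10, 120))
  ct <- cluster_test(x2, x2, dt = 0.001, critical = critical_t(10),
                     n_perm_min = 200, seed = 3)
  pm <- propagation_metrics(ct, alpha = 0.01)
  expect_false(pm$found)
  expect_true(is.na(pm$area_s) && is.na(pm$length_ms))
})
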