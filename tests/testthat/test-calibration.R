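test_that("Up-state targets are recovered from a constructed bimodal ensemble", {
  withr::with_seed(17, {
    n_tr <- 6; n_t <- 5000
    up <- matrix(runif(n_tr * n_t) < 0.6, n_tr, n_t)
    lfp <- matrix(rnorm(n_tr * n_t, -60, 2), n_tr, n_t)
    lfp[up] <- rnorm(sum(up), 40, 2)
    v_p <- matrix(rnorm(n_tr * n_t, -64, 0.4), n_tr, n_t)
    v_p[up] <- rnorm(sum(up), -54.3, 0.4)
    v_i <- matrix(rnorm(n_tr * n_t, -62, 0.4), n_tr, n_t)
    v_i[up] <- rnorm(sum(up), -52.6, 0.4)
  })
  ens <- synthetic_ensemble(lfp, v_p, v_i)
  tg <- estimate_up_state_targets(ens, c_smooth = 5)
  # constructed Up modes recovered within one 0.5 mV bin
  expect_lt(abs(tg$v_p - -54.3), 0.5)
  expect_lt(abs(tg$v_i - -52.6), 0.5)
  # targets lie above the Down-state peaks by construction
  expect_gt(tg$v_p, -64 + 1)
  expect_gt(tg$v_i, -62 + 1)
  expect_equal(tg$provenance$up_fraction, 0.6, tolerance = 0.02)
})

test_that("target estimation fails explicitly on unimodal input", {
  withr::with_seed(18, {
    lfp <- matrix(rnorm(4 * 4000, 10, 3), 4, 4000)
    v <- matrix(rnorm(4 * 4000, -55, 1), 4, 4000)
  })
  expect_error(estimate_up_state_targets(synthetic_ensemble(lfp, v, v)),
               "bimodality")
})

test_that("calibration is self-consistent at the NREM preset", {
  # solving for the GABA conductances at the NREM fixed point with the
  # NREM AMPA conductance must return the preset values (1, 1)
  net <- network_config(column_params("nrem"))
  tg <- fixed_point_targets(net)
  cal <- calibrate_g_gaba(tg, g_ampa = 1, beta = 0, columns = 1)
  expect_equal(cal$g_gaba_p, 1, tolerance = 1e-6)
  expect_equal(cal$g_gaba_i, 1, tolerance = 1e-6)
  # and the calibrated system's fixed point sits at the targets
  net_back <- network_config(column_params("nrem", g_gaba_p = cal$g_gaba_p,
                                           g_gaba_i = cal$g_gaba_i))
  fp <- find_fixed_point(net_back)
  expect_equal(unname(fp["v_p_1"]), tg$v_p, tolerance = 1e-6)
})

test_that("two-column NREM calibration anchored to the fixed point matches the published preset", {
  tg <- fixed_point_targets(network_config(column_params("nrem")))
  cal <- calibrate_g_gaba(tg, g_ampa = 1, beta = 1, columns = 2)
  expect_equal(cal$g_gaba_p, 1.082, tolerance = 5e-3)
  expect_equal(cal$g_gaba_i, 1.066, tolerance = 5e-3)
})

test_that("calibrated conductances are exactly linear in beta and monotone in the drive", {
  tg <- structure(list(v_p = -54.4, v_i = -52.5), class = "nm_targets")
  cals <- purrr::map_dfr(1:5, function(b)
    calibrate_g_gaba(tg, g_ampa = 2, beta = b, columns = 2))
  incr_p <- diff(cals$g_gaba_p)
  incr_i <- diff(cals$g_gaba_i)
  expect_lt(max(abs(incr_p - incr_p[1])), 1e-10)
  expect_lt(max(abs(incr_i - incr_i[1])), 1e-10)
  expect_true(all(incr_p > 0))
  # monotone in g_ampa at fixed beta
  by_g <- purrr::map_dbl(c(2, 6, 10), function(g)
    calibrate_g_gaba(tg, g_ampa = g, beta = 1, columns = 2)$g_gaba_p)
  expect_true(all(diff(by_g) > 0))
})

test_that("unreachable targets are reported", {
  # so close to E_GABA that the adaptation current cannot be balanced by
  # any positive GABAergic conductance
  bad <- structure(list(v_p = -69.9, v_i = -69.9), class = "nm_targets")
  expect_error(calibrate_g_gaba(bad, g_ampa = 0.01, beta = 0, columns = 1),
               "unreachable|not positive")
})
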