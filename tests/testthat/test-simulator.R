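# Small configurations keep these integration tests fast; the scientific
# regimes themselves are exercised in test-acceptance.R.
tiny_cfg <- function(n_trials = 2, ...)
  integration_config(trial_length = 1, burn_in = 0.5, n_trials = n_trials,
                     ...)

test_that("trials are bit-reproducible from their seed", {
  net <- network_config(column_params("nrem"))
  a <- run_trial(net, tiny_cfg(), seed = 99)
  b <- run_trial(net, tiny_cfg(), seed = 99)
  expect_identical(a$signals, b$signals)
  c <- run_trial(net, tiny_cfg(), seed = 100)
  expect_false(identical(a$signals, c$signals))
})

test_that("ensembles reproduce exactly and reduce to run_trial at n = 1", {
  net <- network_config(column_params("wake"))
  cfg <- tiny_cfg(n_trials = 3)
  e1 <- run_ensemble(net, cfg, master_seed = 5)
  e2 <- run_ensemble(net, cfg, master_seed = 5)
  expect_identical(e1$signals, e2$signals)
  cfg1 <- tiny_cfg(n_trials = 1)
  e3 <- run_ensemble(net, cfg1, master_seed = 5)
  tr <- run_trial(net, cfg1, seed = e3$seeds[1])
  expect_equal(e3$signals[[1]]$v_p[1, ], tr$signals[[1]][, "v_p"])
})

test_that("a zero-amplitude stimulus leaves the trace untouched", {
  p <- column_params("nrem")
  stim0 <- stimulus_spec(onset = 0.2, amplitude = 0)
  a <- run_trial(network_config(p), tiny_cfg(), seed = 7)
  b <- run_trial(network_config(p, stimulus = stim0), tiny_cfg(), seed = 7)
  expect_identical(a$signals, b$signals)
  # and a positive amplitude shifts the pyramidal drive upward
  stim1 <- stimulus_spec(onset = 0.2, duration = 300, amplitude = 5)
  c <- run_trial(network_config(p, stimulus = stim1), tiny_cfg(), seed = 7)
  during <- a$time >= 0.25 & a$time < 0.5
  expect_gt(mean(c$signals[[1]][during, "rate_p"]),
            mean(a$signals[[1]][during, "rate_p"]))
})

test_that("the Heun scheme is second-order on the linear test problem", {
  f <- function(t, y) -y
  solve_to_1 <- function(dt) {
    y <- 1
    for (i in seq_len(round(1 / dt))) y <- heun_step(y, f, 0, dt)
    y
  }
  e1 <- abs(solve_to_1(0.02) - exp(-1))
  e2 <- abs(solve_to_1(0.01) - exp(-1))
  expect_equal(e1 / e2, 4, tolerance = 0.1)
})

test_that("noise-free integration holds a fixed point and converges under dt-halving", {
  net <- network_config(column_params("nrem", noise_sd = 0))
  fp <- find_fixed_point(net)
  cfg <- integration_config(trial_length = 0.1, burn_in = 0, n_trials = 1,
                            record_dt = 0.1)
  tr <- run_trial(net, cfg, seed = 1, init = fp)
  drift <- abs(tr$final_state - fp) / pmax(abs(fp), 1e-3)
  expect_lt(max(drift), 1e-8)
  # dt-halving: trajectories differ by < 0.1% of the dynamic range over 1 s
  y0 <- withr::with_seed(21, random_init(net))
  cfg1 <- integration_config(dt = 0.1, trial_length = 1, burn_in = 0,
                             n_trials = 1, record_dt = 1)
  cfg2 <- integration_config(dt = 0.05, trial_length = 1, burn_in = 0,
                             n_trials = 1, record_dt = 1)
  v1 <- run_trial(net, cfg1, init = y0)$signals[[1]][, "v_p"]
  v2 <- run_trial(net, cfg2, init = y0)$signals[[1]][, "v_p"]
  expect_lt(max(abs(v1 - v2)) / diff(range(v1)), 1e-3)
})

test_that("white-noise scaling reproduces the analytic stationary variance across dt", {
  # linear synapse driven only by noise: Var(s) = gamma * sd^2 / 4
  gam <- 0.07; sd_phi <- 1.8
  sim_var <- function(dt, n_paths = 3000, t_end = 400) {
    n_steps <- round(t_end / dt)
    withr::with_seed(31, {
      s <- matrix(0, n_paths, 2)  # columns: s, sdot
      for (k in seq_len(n_steps)) {
        z <- rnorm(n_paths) * gam^2 * sd_phi * sqrt(dt)
        f0_s <- s[, 2]
        f0_d <- -gam^2 * s[, 1] - 2 * gam * s[, 2]
        p_s <- s[, 1] + dt * f0_s
        p_d <- s[, 2] + dt * f0_d + z
        f1_s <- p_d
        f1_d <- -gam^2 * p_s - 2 * gam * p_d
        s[, 1] <- s[, 1] + dt / 2 * (f0_s + f1_s)
        s[, 2] <- s[, 2] + dt / 2 * (f0_d + f1_d) + z
      }
      var(s[, 1])
    })
  }
  target <- gam * sd_phi^2 / 4
  expect_equal(sim_var(0.1), target, tolerance = 0.1)
  expect_equal(sim_var(0.05), target, tolerance = 0.1)
})

test_that("beta = 0 two-column run decouples into matched one-column runs", {
  p <- column_params("nrem")
  net2 <- network_config(p, columns = 2, coupling = coupling_spec(beta = 0))
  net1 <- network_config(p)
  cfg <- integration_config(trial_length = 0.5, burn_in = 0.2, n_trials = 1,
                            record_dt = 0.5)
  n_steps <- round(0.7 * 1000 / cfg$dt)
  noise <- withr::with_seed(41, matrix(rnorm(4 * n_steps), 4, n_steps))
  y1a <- withr::with_seed(42, random_init(net1))
  y1b <- withr::with_seed(43, random_init(net1))
  y2 <- c(y1a, rep(0, 4), y1b, rep(0, 4))
  tr2 <- run_trial(net2, cfg, init = y2, noise = noise)
  tra <- run_trial(net1, cfg, init = y1a, noise = noise[1:2, ])
  trb <- run_trial(net1, cfg, init = y1b, noise = noise[3:4, ])
  expect_equal(tr2$signals[[1]][, "v_p"], tra$signals[[1]][, "v_p"],
               tolerance = 1e-12)
  expect_equal(tr2$signals[[2]][, "v_p"], trb$signals[[1]][, "v_p"],
               tolerance = 1e-12)
})

test_that("trace and ensemble expose tidy views", {
  fx <- unit_fixtures()
  tb <- tibble::as_tibble(fx$nrem)
  expect_true(all(c("trial", "column", "time", "v_p", "lfp_p") %in% names(tb)))
  expect_equal(nrow(tb), length(fx$nrem$seeds) * length(fx$nrem$time))
  expect_equal(sampling_rate(fx$nrem), 1000)
})
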