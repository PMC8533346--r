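test_that("firing rate sigmoid: half-activation, limits, bounds, monotonicity", {
  p <- column_params("nrem")
  pop_p <- population_of(p, "p")
  # half activation exactly at threshold
  expect_equal(firing_rate(-58.5, pop_p), 0.015)
  # saturation limits
  expect_equal(firing_rate(-1e6, pop_p), 0)
  expect_equal(firing_rate(1e6, pop_p), pop_p$qmax)
  # independent arithmetic evaluation at -50 mV (Table-2 pyramidal values)
  expect_equal(firing_rate(-50, pop_p), 0.027269015, tolerance = 1e-7)
  # bounded in (0, qmax) and strictly increasing for both populations
  v <- seq(-120, 20, by = 0.5)
  for (pop in list(pop_p, population_of(p, "i"))) {
    q <- firing_rate(v, pop)
    expect_true(all(q > 0 & q < pop$qmax))
    expect_true(all(diff(q) > 0))
  }
})

test_that("currents vanish at their reversal potentials and have the right sign", {
  p <- column_params("nrem")
  expect_equal(leak_current(-66, p$e_l_p), 0)
  expect_equal(leak_current(-56, -66), 10)
  v <- seq(-90, -30, by = 7)
  expect_equal(sign(leak_current(v, p$e_l_p)), sign(v - p$e_l_p))
  # AMPA current at E_AMPA = 0 is zero; direct evaluation elsewhere
  st <- c(v_p = 0, v_i = -60, s_pp = 1, s_ip = 1, s_pi = 0, s_ii = 0)
  cur <- synaptic_currents(st, column_params("nrem", g_ampa_p = 2, g_ampa_i = 2))
  expect_equal(unname(cur["i_ampa_p"]), 0)
  expect_equal(unname(cur["i_ampa_i"]), 2 * 1 * (-60))
  # GABA at E_GABA
  st2 <- c(v_p = -70, v_i = -70, s_pp = 0, s_ip = 0, s_pi = 3, s_ii = 3)
  cur2 <- synaptic_currents(st2, p)
  expect_equal(unname(cur2[c("i_gaba_p", "i_gaba_i")]), c(0, 0))
  # KNa at E_K
  expect_equal(kna_current(-100, 10, p), 0)
})

test_that("two-column currents reduce to one-column at beta = 0 and flag stray inter activity", {
  p <- column_params("wake")
  st <- c(v_p = -55, v_i = -53, s_pp = 3, s_ip = 0.8, s_pi = 4, s_ii = 1,
          s_ppx = 0.5, s_ipx = 0.1)
  with_beta0 <- synaptic_currents(st, p, coupling_spec(beta = 0))
  alone <- synaptic_currents(st[1:6], p)
  expect_equal(with_beta0, alone)
  expect_error(synaptic_currents(st, p, coupling = NULL), "inter-column")
})

test_that("KNa current: half-saturation bracket, asymptote, monotonicity, domain", {
  p <- column_params("nrem")
  # at Na = 38.7 the bracket is exactly 1/2
  expect_equal(kna_current(-60, 38.7, p), 0.185 * p$g_kna * (-60 - p$e_k))
  # saturating limit
  expect_equal(kna_current(-60, 1e9, p), 0.37 * p$g_kna * (-60 - p$e_k),
               tolerance = 1e-6)
  na <- seq(1, 60, by = 1)
  expect_true(all(diff(kna_current(-60, na, p)) > 0))
  expect_lt(kna_current(-60, 1e-3, p), 1e-10)
  expect_error(kna_current(-60, 0, p), "positive")
})

test_that("sodium balance: equilibrium at rest, influx sign, root vs simulated steady state", {
  p <- column_params("nrem")
  expect_equal(na_dynamics(9.5, 0, p), 0)
  expect_gt(na_dynamics(9.5, 0.01, p), 0)
  expect_error(na_dynamics(-1, 0, p), "positive")
  # oracle: 1-D root of the balance matches the long-run integration
  q_fix <- 0.012
  na_star <- na_steady_state(q_fix, p)
  na <- 9.5
  f <- function(t, y) na_dynamics(y, q_fix, p)
  for (i in 1:40000) na <- heun_step(na, f, 0, 0.5)
  expect_equal(na, na_star, tolerance = 1e-6)
})

test_that("synaptic kinetics: steady state algebra and alpha-function impulse response", {
  # steady state s* = N*Q + drive for random parameter draws (exact algebra)
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- runif(1, 1, 200); q <- runif(1, 0, 0.05)
      gam <- runif(1, 0.01, 0.2); drv <- runif(1, -0.5, 2)
      d <- synapse_rhs(n * q + drv, 0, q, n, gam, drv)
      expect_equal(unname(d), c(0, 0))
    }
  })
  # zero state with zero input stays put
  expect_equal(unname(synapse_rhs(0, 0, 0, 10, 0.07)), c(0, 0))
  # impulse response equals gamma^2 * t * exp(-gamma * t)
  gam <- 0.07; dt <- 0.01
  y <- c(0, gam^2)  # post-impulse initial condition
  f <- function(t, y) synapse_rhs(y[1], y[2], 0, 1, gam)
  tgrid <- seq(0, 100, by = dt)
  s <- numeric(length(tgrid)); s[1] <- y[1]
  for (k in 2:length(tgrid)) { y <- heun_step(y, f, 0, dt); s[k] <- y[1] }
  expect_equal(s, alpha_response(tgrid, gam), tolerance = 1e-4)
})

test_that("full RHS: compiled and reference implementations agree on random states", {
  withr::with_seed(11, {
    net1 <- network_config(column_params("nrem"))
    net2 <- network_config(column_params("wake", g_ampa_p = 2, g_ampa_i = 2),
                           columns = 2, coupling = coupling_spec(beta = 2))
    for (i in 1:10) {
      y1 <- random_init(net1); y2 <- random_init(net2)
      expect_equal(full_rhs(y1, net1), full_rhs_r(y1, net1), tolerance = 1e-12)
      expect_equal(full_rhs(y2, net2, xi = c(0.7, 0)),
                   full_rhs_r(y2, net2, xi = c(0.7, 0)), tolerance = 1e-12)
    }
  })
  expect_error(full_rhs(rep(NaN, 11), net1), "finite")
})

test_that("full RHS: fixed point, beta = 0 decoupling, and column symmetry", {
  net <- network_config(column_params("nrem"))
  fp <- find_fixed_point(net)
  expect_lt(max(abs(full_rhs(fp, net))), 1e-8)
  # two-column with beta = 0 and no inter activity decouples per column
  net2 <- network_config(column_params("nrem"), columns = 2,
                         coupling = coupling_spec(beta = 0))
  y1 <- withr::with_seed(3, random_init(net))
  y2 <- c(y1, rep(0, 4), y1, rep(0, 4))
  names(y2) <- nmsleep:::state_names(2)
  d2 <- full_rhs(y2, net2)
  d1 <- full_rhs(y1, net)
  expect_equal(unname(d2[1:11]), unname(d1), tolerance = 1e-12)
  expect_equal(unname(d2[16:26]), unname(d1), tolerance = 1e-12)
  # symmetric wiring: identical column states give identical derivatives
  netb <- network_config(column_params("wake"), columns = 2,
                         coupling = coupling_spec(beta = 3))
  yc <- withr::with_seed(4, random_init(netb))
  yc[16:30] <- yc[1:15]
  db <- full_rhs(yc, netb)
  expect_equal(unname(db[16:30]), unname(db[1:15]), tolerance = 1e-12)
})
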