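test_that("LFP synthesis and prestimulus demeaning behave as defined", {
  expect_equal(compute_lfp(0, 0), 0)
  expect_equal(compute_lfp(-3, 2), 5)
  ia <- rnorm(50, -100, 30); ig <- rnorm(50, 60, 20)
  expect_true(all(compute_lfp(ia, ig) >= pmax(abs(ia), abs(ig))))

  tm <- seq(0, 9.999, by = 0.001)
  x <- matrix(rep(7, 2 * length(tm)), 2)
  expect_true(all(demean_prestimulus(x, tm) == 0))
  y <- matrix(rnorm(2 * length(tm)), 2)
  expect_equal(demean_prestimulus(y + 5, tm), demean_prestimulus(y, tm))
  pre <- which(tm >= 0 & tm < 5)
  expect_equal(rowMeans(demean_prestimulus(y, tm)[, pre]), c(0, 0),
               tolerance = 1e-12)
  expect_error(demean_prestimulus(y, tm, window = c(20, 25)), "window")
})

test_that("amplitude distributions normalize and find their mode", {
  withr::with_seed(5, v <- rnorm(5000, -60, 2))
  d <- amplitude_distribution(v, bin = 0.5)
  expect_equal(sum(d$prop), 1)
  expect_lt(abs(distribution_mode(d) - -60), 0.8)
})

test_that("Up/Down threshold sits between well-separated modes and declines unimodal input", {
  withr::with_seed(6, {
    mix <- c(rnorm(4000, -60, 2), rnorm(6000, 20, 2))
    uni <- rnorm(8000, 5, 4)
  })
  th <- updown_threshold(mix, c_smooth = 5)
  expect_true(th$bimodal)
  expect_lt(abs(th$threshold - (-60 + 20) / 2), 1)
  expect_equal(sort(th$peaks), c(-60, 20), tolerance = 1)
  th_u <- updown_threshold(uni, c_smooth = 5)
  expect_false(th_u$bimodal)
  expect_error(label_updown(uni, th_u), "bimodality")
  # the verbatim broad kernel still separates modes hundreds of mV apart
  withr::with_seed(7, wide <- c(rnorm(4000, 30, 10), rnorm(6000, 330, 12)))
  th_w <- updown_threshold(wide, c_smooth = 55)
  expect_true(th_w$bimodal)
  expect_lt(abs(th_w$threshold - 180), 15)
})

test_that("split distributions are normalized by the total event count", {
  withr::with_seed(8, v <- c(rnorm(3000, 0.2, 0.1), rnorm(7000, 12, 1)))
  labels <- rep(c("down", "up"), c(3000, 7000))
  sp <- split_distributions(v, labels, bin = 0.5)
  expect_equal(sum(sp$prop), 1)
  expect_equal(sum(sp$prop[sp$label == "up"]), 0.7, tolerance = 1e-12)
  # all-Up labels: the single distribution carries all mass
  sp_up <- split_distributions(v, rep("up", length(v)))
  expect_equal(sum(sp_up$prop), 1)
  expect_identical(unique(sp_up$label), "up")
})

test_that("spectral estimate localizes a sinusoid and is flat for white noise", {
  fs <- 1000
  tm <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * tm)
  sp <- lfp_spectrum(x, fs)
  expect_equal(sp$freq[which.max(sp$mean_psd)], 10, tolerance = 1e-9)
  # Parseval-ish: total one-sided power close to signal variance
  expect_equal(sum(sp$mean_psd) * fs / round(2 * fs), var(x),
               tolerance = 0.05)
  expect_error(lfp_spectrum(x[1:100], fs), "window")
  # white noise: flat across 4-40 Hz within estimator variance
  withr::with_seed(9, w <- matrix(rnorm(20 * 10000), 20))
  spw <- lfp_spectrum(w, fs)
  b1 <- mean(spw$mean_psd[spw$freq >= 4 & spw$freq < 22])
  b2 <- mean(spw$mean_psd[spw$freq >= 22 & spw$freq < 40])
  expect_equal(b1 / b2, 1, tolerance = 0.05)
  expect_equal(to_db(1), 0)
})

test_that("band ratio is zero for equal powers and invariant to signal scaling", {
  sp <- structure(list(freq = c(1, 2, 3, 35, 40, 45),
                       psd = matrix(c(1, 2, 3, 3, 2, 1), 1),
                       mean_psd = c(1, 2, 3, 3, 2, 1)),
                  class = "nm_spectrum")
  expect_equal(band_ratio(sp)$ratio, 0)
  withr::with_seed(10, x <- matrix(rnorm(4 * 4000), 4))
  r1 <- band_ratio(lfp_spectrum(x, 1000))
  r2 <- band_ratio(lfp_spectrum(10 * x, 1000))
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-10)
})
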