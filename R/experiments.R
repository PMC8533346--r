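#' Simulate a preset ensemble
#'
#' Convenience wrapper: builds the state preset and runs an ensemble.
#'
#' @inheritParams build_state_preset
#' @param n_trials,seed ensemble size and master seed.
#' @param trial_length,burn_in,record_dt forwarded to
#'   [integration_config()].
#' @param ... forwarded to [build_state_preset()].
#' @return An [run_ensemble()] result.
#' @export
simulate_preset <- function(state, columns = 1L, n_trials = 100, seed = 1L,
                            g_ampa = NULL, beta = NULL, stimulus = NULL,
                            trial_length = 10, burn_in = 10, record_dt = 1,
                            ...) {
  net <- build_state_preset(state, columns, g_ampa = g_ampa, beta = beta,
                            stimulus = stimulus, ...)
  cfg <- integration_config(trial_length = trial_length, burn_in = burn_in,
                            n_trials = n_trials, record_dt = record_dt)
  run_ensemble(net, cfg, master_seed = seed)
}

#' Regime dichotomy report
#'
#' Reproduces the spontaneous-activity contrast between brain states in
#' the one-column model: bimodal pooled pyramidal-LFP distribution with a
#' silent Down mode in NREM versus a unimodal distribution in wakefulness,
#' and the spectral crossover (NREM carries more power below 4 Hz, wake
#' more above 30 Hz).
#'
#' @param n_trials trials per state.
#' @param seed master seed (NREM uses `seed`, wake `seed + 1`).
#' @param columns 1 or 2.
#' @param trial_length seconds per trial.
#' @return A list of class `nm_report` with the ensembles' analyses:
#'   thresholds, per-state distributions, spectra, band ratios, and the
#'   headline logical flags.
#' @export
regime_dichotomy <- function(n_trials = 100, seed = 1L, columns = 1L,
                             trial_length = 10) {
  ens <- list(
    nrem = simulate_preset("nrem", columns, n_trials, seed,
                           trial_length = trial_length),
    wake = simulate_preset("wake", columns, n_trials, seed + 1L,
                           trial_length = trial_length)
  )
  fs <- sampling_rate(ens$nrem)
  ana <- purrr::map(ens, function(e) {
    lfp <- demean_prestimulus(ensemble_signal(e, "lfp_p"), e$time,
                              range(e$time) + c(0, 1e-9))
    th <- updown_threshold(as.vector(lfp))
    spec <- lfp_spectrum(lfp, fs)
    res <- list(threshold = th, spectrum = spec,
                band_ratio = band_ratio(spec))
    if (th$bimodal) {
      labels <- label_updown(as.vector(lfp), th)
      rate <- as.vector(ensemble_signal(e, "rate_p")) * 1000  # Hz
      v_p <- as.vector(ensemble_signal(e, "v_p"))
      res$rate_split <- split_distributions(rate, labels, bin = 0.5)
      res$v_split <- split_distributions(v_p, labels, bin = 0.5)
    }
    res
  })
  low <- ana$nrem$spectrum$freq < 4 & ana$nrem$spectrum$freq > 0
  high <- ana$nrem$spectrum$freq > 30
  down_rate <- ana$nrem$rate_split
  down_mode <- if (!is.null(down_rate))
    distribution_mode(dplyr::filter(down_rate, .data$label == "down"))
  else NA_real_
  # band-power ordering: compare mean PSD within each band (slow-wave
  # power dominates NREM, gamma power dominates wake)
  structure(list(
    analyses = ana,
    nrem_bimodal = ana$nrem$threshold$bimodal,
    wake_bimodal = ana$wake$threshold$bimodal,
    down_rate_mode_hz = down_mode,
    nrem_low_gt_wake = mean(ana$nrem$spectrum$mean_psd[low]) >
      mean(ana$wake$spectrum$mean_psd[low]),
    wake_high_gt_nrem = mean(ana$wake$spectrum$mean_psd[high]) >
      mean(ana$nrem$spectrum$mean_psd[high]),
    n_trials = n_trials, seed = seed, columns = columns
  ), class = "nm_report")
}

#' @export
print.nm_report <- function(x, ...) {
  cat("<nm_report> regime dichotomy (", x$n_trials, " trials, ",
      x$columns, " column(s))\n", sep = "")
  cat("  NREM LFP bimodal:     ", x$nrem_bimodal, "\n")
  cat("  wake LFP bimodal:     ", x$wake_bimodal, "\n")
  cat("  Down-state rate mode: ", x$down_rate_mode_hz, "Hz\n")
  cat("  NREM > wake below 4 Hz:", x$nrem_low_gt_wake, "\n")
  cat("  wake > NREM above 30 Hz:", x$wake_high_gt_nrem, "\n")
  invisible(x)
}

#' Evoked-response cluster test for one ensemble
#'
#' Runs a stimulated ensemble and applies the temporal clustering test to
#' one signal, poststimulus (stimulus onset to onset + 5 s) against
#' prestimulus (first 5 s). The LFP is demeaned by its prestimulus mean
#' before testing.
#'
#' @inheritParams simulate_preset
#' @param signal which recorded signal to test.
#' @param perturbed_column which column receives the stimulus.
#' @param test_column which column's signal is tested (set to the
#'   unperturbed column to quantify propagation).
#' @param n_perm_min minimum permutation count.
#' @param ... forwarded to [simulate_preset()].
#' @return A list of class `nm_evoked`: the [cluster_test()] result plus
#'   the ensemble and window metadata.
#' @export
evoked_response <- function(state, columns = 1L, n_trials = 100, seed = 1L,
                            g_ampa = NULL, beta = NULL,
                            signal = "rate_p", perturbed_column = 1L,
                            test_column = 1L, n_perm_min = 1000, ...) {
  stim <- stimulus_spec(onset = 5, column = perturbed_column)
  ens <- simulate_preset(state, columns, n_trials, seed, g_ampa = g_ampa,
                         beta = beta, stimulus = stim, ...)
  test <- evoked_cluster_test(ens, signal = signal,
                              column = test_column,
                              n_perm_min = n_perm_min,
                              seed = seed + 7919L)
  structure(list(test = test, ensemble = ens, signal = signal,
                 test_column = test_column),
            class = "nm_evoked")
}

#' @export
print.nm_evoked <- function(x, ...) {
  cat("<nm_evoked> signal", x$signal, "of column", x$test_column, "\n")
  print(x$test)
  invisible(x)
}

#' Cluster test on an already-simulated stimulated ensemble
#'
#' @param ensemble an [run_ensemble()] result whose network carries a
#'   stimulus.
#' @param signal recorded signal name.
#' @param column column whose signal is tested.
#' @param window_s length of the pre- and poststimulus windows, seconds.
#' @param n_perm_min,critical,var_form,seed forwarded to [cluster_test()].
#' @export
evoked_cluster_test <- function(ensemble, signal = "rate_p", column = 1L,
                                window_s = 5, n_perm_min = 1000,
                                critical = 2.58, var_form = "printed",
                                seed = NULL) {
  stim <- ensemble$network$stimulus
  if (is.null(stim)) stop("ensemble was simulated without a stimulus")
  x <- ensemble_signal(ensemble, signal, column)
  if (grepl("^lfp", signal))
    x <- demean_prestimulus(x, ensemble$time, c(0, stim$onset))
  pre <- x[, window_index(ensemble$time, stim$onset - window_s, stim$onset),
           drop = FALSE]
  post <- x[, window_index(ensemble$time, stim$onset, stim$onset + window_s),
            drop = FALSE]
  k <- min(ncol(pre), ncol(post))
  cluster_test(post[, seq_len(k), drop = FALSE],
               pre[, seq_len(k), drop = FALSE],
               dt = ensemble$cfg$record_dt / 1000, critical = critical,
               n_perm_min = n_perm_min, var_form = var_form, seed = seed)
}

#' Propagation sweep over the conductance grid
#'
#' For each `(g_ampa, beta)` pair, simulates the two-column model with the
#' stimulus on column 1, tests the unperturbed column's pyramidal firing
#' rate post- versus prestimulus, and collects the first significant
#' cluster's area and length.
#'
#' @param g_ampa,beta numeric vectors defining the grid.
#' @param state brain state of the presets.
#' @param n_trials,seed ensemble size and base seed (each grid point uses
#'   a distinct derived seed).
#' @param n_perm_min minimum permutation count.
#' @param alpha significance level on cluster p-values.
#' @param ... forwarded to [simulate_preset()].
#' @return A tibble of class `nm_sweep`: one row per grid point with
#'   `g_ampa`, `beta`, `found`, `area_s`, `length_ms`, `p`.
#' @export
propagation_sweep <- function(g_ampa = c(2, 6, 10), beta = 1:5,
                              state = "wake", n_trials = 100, seed = 1L,
                              n_perm_min = 1000, alpha = 0.01, ...) {
  grid <- tidyr::expand_grid(g_ampa = g_ampa, beta = beta)
  out <- purrr::pmap_dfr(grid, function(g_ampa, beta) {
    i <- which(grid$g_ampa == g_ampa & grid$beta == beta)
    ev <- evoked_response(state, columns = 2L, n_trials = n_trials,
                          seed = seed + 101L * i, g_ampa = g_ampa,
                          beta = beta, signal = "rate_p",
                          perturbed_column = 1L, test_column = 2L,
                          n_perm_min = n_perm_min, ...)
    dplyr::bind_cols(tibble::tibble(g_ampa = g_ampa, beta = beta),
                     propagation_metrics(ev$test, alpha = alpha))
  })
  class(out) <- c("nm_sweep", class(out))
  out
}

#' Deterministic test fixtures
#'
#' Small seeded bundles used by the unit tests and for quick smoke runs:
#' short NREM/wake ensembles, a synthetic bimodal sample with known modes,
#' and a null pair of ensembles from the same preset (no stimulus).
#' Regenerating with the same seed is byte-identical.
#'
#' @param scale `"unit"` (8 trials x 2 s) or `"smoke"` (16 trials x 4 s).
#' @param seed master seed.
#' @return A named list.
#' @export
make_fixtures <- function(scale = c("unit", "smoke"), seed = 42L) {
  scale <- match.arg(scale)
  n <- if (scale == "unit") 8 else 16
  len <- if (scale == "unit") 2 else 4
  burn <- if (scale == "unit") 2 else 5
  bimodal <- with_seed(seed, function()
    c(stats::rnorm(4000, -60, 1.5), stats::rnorm(6000, -20, 1.5)))
  list(
    nrem = simulate_preset("nrem", n_trials = n, seed = seed,
                           trial_length = len, burn_in = burn),
    wake = simulate_preset("wake", n_trials = n, seed = seed + 1L,
                           trial_length = len, burn_in = burn),
    bimodal = bimodal,
    null_pair = list(
      simulate_preset("wake", n_trials = n, seed = seed + 2L,
                      trial_length = len, burn_in = burn),
      simulate_preset("wake", n_trials = n, seed = seed + 3L,
                      trial_length = len, burn_in = burn))
  )
}
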