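#' Reproduce a headline experiment
#'
#' End-to-end drivers for the published simulation experiments, at a
#' desk-scale default of 100 trials and at least 1000 permutations. Each
#' report embeds its full configuration and seeds, and re-running with the
#' same arguments reproduces it exactly.
#'
#' * `"fig2"`: one-column spontaneous regime dichotomy
#'   ([regime_dichotomy()]).
#' * `"fig3"`: one-column evoked responses in both states
#'   ([evoked_response()] on the pyramidal firing rate).
#' * `"fig4"`: two-column evoked responses at `beta = 1`, `g_ampa = 2`,
#'   perturbed and unperturbed columns, both states.
#' * `"fig5"`: unperturbed-column response for
#'   `g_ampa` in \{2, 6\} x `beta` in \{1, 2\} (wake).
#' * `"fig6"`: full propagation sweep `g_ampa` in \{2, 6, 10\} x
#'   `beta` in 1..5 (wake).
#' * `"tables"`: calibrated GABAergic conductances over the wake grid,
#'   next to the published values.
#'
#' @param name experiment name.
#' @param n_trials trials per ensemble.
#' @param seed master seed.
#' @param n_perm_min minimum permutation count for cluster tests.
#' @param targets optional precomputed Up-state targets (only used by
#'   `"tables"`; estimated from an NREM ensemble when missing).
#' @return A named list (or tibble) of results; see the individual
#'   drivers.
#' @export
reproduce <- function(name = c("fig2", "fig3", "fig4", "fig5", "fig6",
                               "tables"),
                      n_trials = 100, seed = 1L, n_perm_min = 1000,
                      targets = NULL) {
  name <- match.arg(name)
  switch(
    name,
    fig2 = regime_dichotomy(n_trials = n_trials, seed = seed),
    fig3 = purrr::map(
      stats::setNames(c("nrem", "wake"), c("nrem", "wake")),
      function(st) evoked_response(st, n_trials = n_trials, seed = seed,
                                   n_perm_min = n_perm_min)),
    fig4 = purrr::map(
      stats::setNames(c("nrem", "wake"), c("nrem", "wake")),
      function(st) list(
        perturbed = evoked_response(st, columns = 2L, beta = 1,
                                    n_trials = n_trials, seed = seed,
                                    test_column = 1L,
                                    n_perm_min = n_perm_min),
        unperturbed = evoked_response(st, columns = 2L, beta = 1,
                                      n_trials = n_trials, seed = seed,
                                      test_column = 2L,
                                      n_perm_min = n_perm_min))),
    fig5 = propagation_sweep(g_ampa = c(2, 6), beta = c(1, 2),
                             n_trials = n_trials, seed = seed,
                             n_perm_min = n_perm_min),
    fig6 = propagation_sweep(g_ampa = c(2, 6, 10), beta = 1:5,
                             n_trials = n_trials, seed = seed,
                             n_perm_min = n_perm_min),
    tables = {
      if (is.null(targets)) {
        ens <- simulate_preset("nrem", n_trials = n_trials, seed = seed)
        targets <- estimate_up_state_targets(ens)
      }
      grid <- tidyr::expand_grid(g_ampa = c(2, 6, 10), beta = 1:5)
      cal <- purrr::pmap_dfr(grid, function(g_ampa, beta)
        calibrate_g_gaba(targets, g_ampa, beta, columns = 2L))
      pub <- dplyr::filter(gaba_table(), .data$columns == 2L,
                           .data$state == "wake")
      dplyr::left_join(cal,
                       dplyr::select(pub, "g_ampa", "beta",
                                     published_p = "g_gaba_p",
                                     published_i = "g_gaba_i"),
                       by = c("g_ampa", "beta"))
    })
}
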