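#' Up-state membrane-potential targets from an NREM ensemble
#'
#' The waking regime is anchored to NREM: the steady-state membrane
#' potentials of the waking model are set to the peak of the Vp and Vi
#' distributions during the NREM Up states. This estimates those targets
#' from a simulated NREM ensemble: the pooled (per-trial demeaned)
#' pyramidal LFP is segmented into Up/Down states via its bimodal
#' distribution, and the mode of the Vp and Vi distributions restricted to
#' Up-state samples (0.5 mV bins) is returned. Up/Down is a column-wide
#' state, so the pyramidal-LFP labels are applied to both populations.
#'
#' @param ensemble an NREM [run_ensemble()] result.
#' @param column column whose signals are used.
#' @param bin amplitude bin width, mV.
#' @param c_smooth Gaussian smoothing width for the LFP distribution, mV.
#' @param window analysis window in seconds, `NULL` for the whole trial.
#' @return An object of class `nm_targets`: `v_p`, `v_i` (mV), and a
#'   `provenance` list (state, trials, threshold, Up fraction).
#' @export
estimate_up_state_targets <- function(ensemble, column = 1L, bin = 0.5,
                                      c_smooth = 55, window = NULL) {
  stopifnot(inherits(ensemble, "nm_ensemble"))
  lfp <- ensemble_signal(ensemble, "lfp_p", column)
  v_p <- ensemble_signal(ensemble, "v_p", column)
  v_i <- ensemble_signal(ensemble, "v_i", column)
  if (!is.null(window)) {
    idx <- window_index(ensemble$time, window[1], window[2])
    lfp <- lfp[, idx, drop = FALSE]
    v_p <- v_p[, idx, drop = FALSE]
    v_i <- v_i[, idx, drop = FALSE]
    tm <- ensemble$time[idx]
  } else tm <- ensemble$time
  lfp <- demean_prestimulus(lfp, tm, range(tm) + c(0, 1e-9))
  th <- updown_threshold(as.vector(lfp), bin = bin, c_smooth = c_smooth)
  if (!th$bimodal)
    stop("no Up/Down bimodality in the LFP distribution; ",
         "cannot estimate Up-state targets")
  labels <- label_updown(as.vector(lfp), th)
  up <- labels == "up"
  if (!any(up)) stop("no Up states detected")
  dist_p <- amplitude_distribution(as.vector(v_p)[up], bin)
  dist_i <- amplitude_distribution(as.vector(v_i)[up], bin)
  structure(list(
    v_p = distribution_mode(dist_p),
    v_i = distribution_mode(dist_i),
    provenance = list(state = ensemble$network$params$state,
                      n_trials = length(ensemble$seeds),
                      master_seed = ensemble$master_seed,
                      threshold = th$threshold,
                      up_fraction = mean(up))
  ), class = "nm_targets")
}

#' Targets from the deterministic fixed point
#'
#' The noise-free steady state of a network as membrane-potential targets.
#' This is the anchor used when coupling columns within NREM: the coupled
#' NREM model is calibrated so its fixed point stays at the one-column
#' NREM fixed point.
#'
#' @param network an [network_config()].
#' @return An `nm_targets` object.
#' @export
fixed_point_targets <- function(network) {
  fp <- find_fixed_point(network)
  structure(list(v_p = unname(fp["v_p_1"]), v_i = unname(fp["v_i_1"]),
                 provenance = list(state = network$params$state,
                                   method = "fixed_point")),
            class = "nm_targets")
}

#' @export
print.nm_targets <- function(x, ...) {
  cat("<nm_targets> Vp* =", x$v_p, "mV, Vi* =", x$v_i, "mV\n")
  invisible(x)
}

#' Calibrate the GABAergic conductances
#'
#' Solves the noise-mean steady state of the (symmetric) network for the
#' two GABAergic conductances such that the membrane potentials sit at the
#' given targets. At a fixed point every synaptic activity equals its mean
#' drive, so the two membrane equations are linear in the two unknown
#' conductances and the solution is closed-form (and therefore exactly
#' linear in `beta` at fixed targets: increasing the inter-/intra ratio
#' adds a constant increment per unit of `beta`).
#'
#' @param targets an `nm_targets` object (or list with `v_p`, `v_i`).
#' @param g_ampa AMPAergic conductance applied to both populations.
#' @param beta inter-/intra-column conductance ratio; 0 for one column.
#' @param columns 1 or 2 (two-column mode adds the `beta`-scaled
#'   inter-column drive).
#' @param params parameter template supplying all other constants.
#' @param phi_mean mean of the noise drive entering the intra-column
#'   AMPAergic synapses.
#' @return A one-row tibble of class `nm_calibration`: `g_ampa`, `beta`,
#'   `g_gaba_p`, `g_gaba_i`, plus the targets as an attribute.
#' @export
calibrate_g_gaba <- function(targets, g_ampa, beta = 0, columns = 1L,
                             params = column_params("nrem"),
                             phi_mean = params$noise_mean) {
  stopifnot(g_ampa > 0, beta >= 0)
  if (columns == 1L) beta <- 0
  p <- params
  v_p <- targets$v_p; v_i <- targets$v_i
  stopifnot(p$e_gaba < v_p, v_p < p$e_ampa, p$e_gaba < v_i, v_i < p$e_ampa)
  q_p <- firing_rate(v_p, population_of(p, "p"), p$c_sigmoid)
  q_i <- firing_rate(v_i, population_of(p, "i"), p$c_sigmoid)
  na <- na_steady_state(q_p, p)
  i_kna <- kna_current(v_p, na, p)
  ampa_p <- g_ampa * (p$n_pp * q_p + phi_mean + beta * p$n_pp_inter * q_p) *
    (v_p - p$e_ampa)
  ampa_i <- g_ampa * (p$n_ip * q_p + phi_mean + beta * p$n_ip_inter * q_p) *
    (v_i - p$e_ampa)
  g_gaba_p <- (-leak_current(v_p, p$e_l_p) - ampa_p -
                 p$tau_p / p$cm * i_kna) /
    (p$n_pi * q_i * (v_p - p$e_gaba))
  g_gaba_i <- (-leak_current(v_i, p$e_l_i) - ampa_i) /
    (p$n_ii * q_i * (v_i - p$e_gaba))
  if (g_gaba_p <= 0 || g_gaba_i <= 0)
    stop("targets unreachable: calibrated conductances not positive (",
         signif(g_gaba_p, 4), ", ", signif(g_gaba_i, 4), ")")
  out <- tibble::tibble(g_ampa = g_ampa, beta = beta,
                        g_gaba_p = g_gaba_p, g_gaba_i = g_gaba_i)
  attr(out, "targets") <- targets
  class(out) <- c("nm_calibration", class(out))
  out
}

#' Build a state preset
#'
#' Returns a ready-to-simulate [network_config()] for a brain state and
#' column count. Combinations published in the conductance tables (see
#' [gaba_table()]) are returned verbatim; any other `(g_ampa, beta)` is
#' calibrated on demand, which requires Up-state `targets`.
#'
#' @param state `"nrem"` or `"wake"`.
#' @param columns 1 or 2.
#' @param g_ampa AMPAergic conductance; defaults to the state's preset
#'   (1 in NREM, 2 in wake).
#' @param beta inter-/intra ratio (two-column mode only), default 1.
#' @param targets optional `nm_targets` for off-table calibration.
#' @param stimulus optional [stimulus_spec()].
#' @param ... overrides forwarded to [column_params()].
#' @return An [network_config()].
#' @export
build_state_preset <- function(state = c("nrem", "wake"), columns = 1L,
                               g_ampa = NULL, beta = NULL, targets = NULL,
                               stimulus = NULL, ...) {
  state <- match.arg(state)
  columns <- as.integer(columns)
  if (is.null(g_ampa)) g_ampa <- if (state == "nrem") 1 else 2
  if (columns == 2L && is.null(beta)) beta <- 1
  tab <- gaba_table()
  hit <- dplyr::filter(tab, .data$state == !!state,
                       .data$columns == !!columns,
                       .data$g_ampa == !!g_ampa,
                       is.na(.data$beta) | .data$beta == !!(beta %||% NA_real_))
  if (nrow(hit) == 1) {
    gg_p <- hit$g_gaba_p; gg_i <- hit$g_gaba_i
  } else {
    if (is.null(targets)) {
      if (state == "nrem") {
        base <- network_config(column_params("nrem"), columns = 1L)
        targets <- fixed_point_targets(base)
      } else {
        stop("no published conductances for this combination; ",
             "supply Up-state targets for calibration")
      }
    }
    cal <- calibrate_g_gaba(targets, g_ampa, beta %||% 0, columns)
    gg_p <- cal$g_gaba_p; gg_i <- cal$g_gaba_i
  }
  params <- column_params(state, g_ampa_p = g_ampa, g_ampa_i = g_ampa,
                          g_gaba_p = gg_p, g_gaba_i = gg_i, ...)
  coupling <- if (columns == 2L) coupling_spec(beta = beta) else NULL
  network_config(params, columns = columns, coupling = coupling,
                 stimulus = stimulus)
}
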