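#' Sigmoid slope constant
#'
#' The constant linking the inverse neural gain to the slope of the tanh
#' firing-rate sigmoid. With `C = pi / (2 * sqrt(3))` the tanh form is
#' identical to a logistic sigmoid with gain `pi / sqrt(3)`, the convention
#' of the neural-mass lineage this model belongs to.
#'
#' @return A single numeric value, approximately 0.9069.
#' @export
sigmoid_constant <- function() pi / (2 * sqrt(3))

# Printed GABAergic conductance grids for the two-column model
# (rows: g_ampa; one column per beta in 1..5).
.gaba_grid <- list(
  "2"  = list(p = c(2.446, 2.599, 2.752, 2.905, 3.058),
              i = c(2.445, 2.576, 2.708, 2.840, 2.971)),
  "6"  = list(p = c(8.869, 9.327, 9.786, 10.245, 10.704),
              i = c(7.972, 8.367, 8.761, 9.156, 9.551)),
  "10" = list(p = c(15.291, 16.055, 16.820, 17.585, 18.349),
              i = c(13.499, 14.157, 14.815, 15.473, 16.131))
)

#' Published GABAergic conductance values
#'
#' The tabulated average GABAergic conductances of the calibrated model:
#' the one-column NREM and wake presets, the two-column NREM and wake
#' presets at `beta = 1`, and the wake grids over
#' `g_ampa` in \{2, 6, 10\} crossed with `beta` in 1..5.
#'
#' @return A tibble with columns `state`, `columns`, `g_ampa`, `beta`,
#'   `g_gaba_p`, `g_gaba_i`.
#' @export
gaba_table <- function() {
  base <- tibble::tribble(
    ~state, ~columns, ~g_ampa, ~beta, ~g_gaba_p, ~g_gaba_i,
    "nrem", 1L, 1, NA_real_, 1,     1,
    "wake", 1L, 2, NA_real_, 2.294, 2.313,
    "nrem", 2L, 1, 1,        1.082, 1.066
  )
  grid <- purrr::map_dfr(names(.gaba_grid), function(g) {
    tibble::tibble(
      state = "wake", columns = 2L, g_ampa = as.numeric(g), beta = 1:5,
      g_gaba_p = .gaba_grid[[g]]$p, g_gaba_i = .gaba_grid[[g]]$i
    )
  })
  dplyr::bind_rows(base, grid)
}

#' Per-column model parameters
#'
#' Builds the full constant set of one cortical column: population sigmoid
#' parameters, synaptic kinetics and connection counts, conductances and
#' reversal potentials, the sodium-dependent potassium adaptation, and the
#' state-dependent noise drive. Defaults are the published NREM and
#' wakefulness presets; any field can be overridden through `...`.
#'
#' The NREM preset has `g_ampa = 1` and unit GABAergic conductances; the
#' wake preset upscales the AMPAergic conductance to 2 and carries the
#' calibrated GABAergic conductances that hold the waking membrane
#' potentials at the NREM Up-state values. The noise drive is stronger in
#' NREM (sd 1.8 ms^-1) than in wake (1 ms^-1).
#'
#' @param state `"nrem"` or `"wake"`.
#' @param ... named overrides of individual fields (e.g. `g_ampa_p = 6`).
#' @return A named list of class `nm_params`.
#' @examples
#' p <- column_params("nrem")
#' p$g_ampa_p
#' @export
column_params <- function(state = c("nrem", "wake"), ...) {
  state <- match.arg(state)
  p <- list(
    state = state,
    # population sigmoids (Qmax ms^-1, theta/sigma mV, tau ms, E_L mV)
    qmax_p = 0.03, qmax_i = 0.06,
    theta_p = -58.5, theta_i = -58.5,
    sigma_p = 6.7, sigma_i = 6,
    tau_p = 30, tau_i = 30,
    e_l_p = -66, e_l_i = -64,
    # synaptic kinetics and wiring
    gamma_p = 70e-3, gamma_i = 58.6e-3,
    n_pp = 160, n_ip = 40, n_pi = 160, n_ii = 40,
    g_ampa_p = 1, g_ampa_i = 1, g_gaba_p = 1, g_gaba_i = 1,
    e_ampa = 0, e_gaba = -70,
    # sodium-dependent potassium adaptation
    g_kna = 1.9, e_k = -100, tau_na = 1.7, alpha_na = 2,
    r_pump = 0.09, na_eq = 9.5, cm = 1,
    # noise drive on intra-column AMPAergic synapses
    noise_mean = 0, noise_sd = 1.8,
    c_sigmoid = sigmoid_constant(),
    # inter-column wiring (used only in two-column mode)
    n_pp_inter = 8, n_ip_inter = 2
  )
  if (state == "wake") {
    p$g_ampa_p <- 2; p$g_ampa_i <- 2
    p$g_gaba_p <- 2.294; p$g_gaba_i <- 2.313
    p$noise_sd <- 1
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  class(p) <- "nm_params"
  validate_params(p)
}

#' @export
print.nm_params <- function(x, ...) {
  cat("<nm_params> state:", x$state,
      " g_ampa:", x$g_ampa_p,
      " g_gaba: (", x$g_gaba_p, ",", x$g_gaba_i, ")",
      " noise sd:", x$noise_sd, "\n")
  invisible(x)
}

validate_params <- function(p) {
  stopifnot(
    p$qmax_p > 0, p$qmax_i > 0, p$sigma_p > 0, p$sigma_i > 0,
    p$tau_p > 0, p$tau_i > 0, p$gamma_p > 0, p$gamma_i > 0,
    p$n_pp >= 0, p$n_ip >= 0, p$n_pi >= 0, p$n_ii >= 0,
    p$n_pp_inter >= 0, p$n_ip_inter >= 0,
    p$g_ampa_p >= 0, p$g_ampa_i >= 0, p$g_gaba_p >= 0, p$g_gaba_i >= 0,
    p$e_ampa > p$e_gaba,
    p$g_kna > 0, p$e_k < 0, p$tau_na > 0, p$alpha_na > 0,
    p$r_pump > 0, p$na_eq > 0, p$cm > 0,
    p$noise_sd >= 0
  )
  p
}

# Population sub-parameter accessor: list(qmax, theta, sigma, tau, e_l).
#' Extract one population's sigmoid parameters
#'
#' @param params an [column_params()] object.
#' @param pop `"p"` (pyramidal) or `"i"` (inhibitory).
#' @return A list with fields `qmax`, `theta`, `sigma`, `tau`, `e_l`.
#' @export
population_of <- function(params, pop = c("p", "i")) {
  pop <- match.arg(pop)
  list(qmax = params[[paste0("qmax_", pop)]],
       theta = params[[paste0("theta_", pop)]],
       sigma = params[[paste0("sigma_", pop)]],
       tau = params[[paste0("tau_", pop)]],
       e_l = params[[paste0("e_l_", pop)]])
}

#' Stimulus specification
#'
#' A transient square increase in the mean of the noise drive to the
#' pyramidal population of one (the perturbed) column.
#'
#' @param onset onset time within the trial, seconds.
#' @param duration pulse duration, ms.
#' @param amplitude pulse amplitude, ms^-1.
#' @param column index of the perturbed column (1 or 2).
#' @return A list of class `nm_stimulus`.
#' @export
stimulus_spec <- function(onset = 5, duration = 100, amplitude = 1, column = 1L) {
  stopifnot(duration > 0, onset >= 0, column %in% c(1L, 2L))
  structure(list(onset = onset, duration = duration,
                 amplitude = amplitude, column = as.integer(column)),
            class = "nm_stimulus")
}

#' Inter-column coupling specification
#'
#' @param beta ratio of the inter- to the intra-column average AMPAergic
#'   conductance (dimensionless).
#' @param n_pp_inter,n_ip_inter mean number of inter-column synaptic
#'   connections from the other column's pyramidal population onto this
#'   column's pyramidal and inhibitory population.
#' @return A list of class `nm_coupling`.
#' @export
coupling_spec <- function(beta = 1, n_pp_inter = 8, n_ip_inter = 2) {
  stopifnot(beta >= 0, n_pp_inter >= 0, n_ip_inter >= 0)
  structure(list(beta = beta, n_pp_inter = n_pp_inter, n_ip_inter = n_ip_inter),
            class = "nm_coupling")
}

#' Network configuration
#'
#' Wires one column, or two identical columns coupled symmetrically through
#' AMPAergic synapses, optionally with a stimulus on one column.
#'
#' @param params per-column parameters from [column_params()].
#' @param columns 1 or 2.
#' @param coupling an [coupling_spec()]; required in two-column mode.
#' @param stimulus an [stimulus_spec()] or `NULL`.
#' @return A list of class `nm_network`.
#' @export
network_config <- function(params, columns = 1L, coupling = NULL, stimulus = NULL) {
  columns <- as.integer(columns)
  stopifnot(inherits(params, "nm_params"), columns %in% c(1L, 2L))
  if (columns == 2L) {
    if (is.null(coupling)) coupling <- coupling_spec(beta = 1)
    params$n_pp_inter <- coupling$n_pp_inter
    params$n_ip_inter <- coupling$n_ip_inter
  } else if (!is.null(coupling)) {
    stop("coupling is only meaningful in two-column mode")
  }
  if (!is.null(stimulus)) stopifnot(inherits(stimulus, "nm_stimulus"))
  structure(list(params = params, columns = columns,
                 coupling = coupling, stimulus = stimulus),
            class = "nm_network")
}

#' @export
print.nm_network <- function(x, ...) {
  cat("<nm_network>", x$columns, "column(s); state:", x$params$state)
  if (!is.null(x$coupling)) cat("; beta:", x$coupling$beta)
  if (!is.null(x$stimulus))
    cat("; stimulus: ", x$stimulus$amplitude, " ms^-1 x ", x$stimulus$duration,
        " ms at ", x$stimulus$onset, " s on column ", x$stimulus$column, sep = "")
  cat("\n")
  invisible(x)
}

#' Integration settings
#'
#' @param dt integration step, ms.
#' @param trial_length recorded trial length, seconds.
#' @param burn_in discarded initial transient, seconds.
#' @param n_trials number of independent trials in an ensemble.
#' @param record_dt sampling interval of the recorded signals, ms; must be
#'   a multiple of `dt`. Signals are band-limited well below the default
#'   500 Hz Nyquist, so 1 ms recording loses nothing relevant.
#' @param record_na also record the sodium concentration.
#' @param noise_mode `"white"` treats the noise drive as continuous-time
#'   white noise (increments scale with `sqrt(dt)`); `"per_step"` holds an
#'   independent draw constant over each step.
#' @return A list of class `nm_integration`.
#' @export
integration_config <- function(dt = 0.1, trial_length = 10, burn_in = 10,
                               n_trials = 500, record_dt = 1,
                               record_na = FALSE,
                               noise_mode = c("white", "per_step")) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(dt > 0, burn_in >= 0, trial_length > 0, n_trials >= 1,
            record_dt >= dt)
  if (abs(record_dt / dt - round(record_dt / dt)) > 1e-9)
    stop("record_dt must be an integer multiple of dt")
  structure(list(dt = dt, trial_length = trial_length, burn_in = burn_in,
                 n_trials = as.integer(n_trials), record_dt = record_dt,
                 record_na = record_na, noise_mode = noise_mode),
            class = "nm_integration")
}

#' Write / read a parameter preset
#'
#' Serializes an [column_params()] object to a human-readable YAML file and
#' reads it back. Round-trips exactly.
#'
#' @param params an `nm_params` object.
#' @param path file path.
#' @return `write_preset()` returns `path` invisibly; `read_preset()`
#'   returns an `nm_params` object.
#' @export
write_preset <- function(params, path) {
  stopifnot(inherits(params, "nm_params"))
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' @rdname write_preset
#' @export
read_preset <- function(path) {
  p <- yaml::read_yaml(path)
  class(p) <- "nm_params"
  validate_params(p)
}
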