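#' One Heun predictor-corrector step
#'
#' Generic stochastic Heun update for `dy = f(t, y) dt + dW`: the additive
#' noise increment is applied in both the predictor and the corrector with
#' the same draw, and the deterministic part is the classical second-order
#' trapezoidal (Heun) scheme.
#'
#' This is the reference scheme the compiled integrator implements for the
#' column model; it is exported so the update rule itself can be exercised
#' on arbitrary systems.
#'
#' @param y state vector.
#' @param f drift function `f(t, y)` returning `dy/dt`.
#' @param t current time.
#' @param dt step size.
#' @param noise_increment additive stochastic increment (already scaled),
#'   same length as `y` or scalar 0.
#' @return The state after one step.
#' @export
heun_step <- function(y, f, t, dt, noise_increment = 0) {
  f0 <- f(t, y)
  y_pred <- y + dt * f0 + noise_increment
  y + dt / 2 * (f0 + f(t + dt, y_pred)) + noise_increment
}

# Run fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Random initial conditions
#'
#' Uniform draws over plausible ranges: membrane potentials in
#' \[-80, -50\] mV, synaptic activities in \[0, 1\] with derivatives in
#' \[-0.01, 0.01\], sodium within 0.5 mM of its resting value. The burn-in
#' absorbs the transient from any point in these ranges.
#'
#' @param network an [network_config()].
#' @return Named state vector.
#' @export
random_init <- function(network) {
  nc <- network$columns
  nv <- if (nc == 2) 15L else 11L
  na_eq <- network$params$na_eq
  one <- function() {
    y <- numeric(nv)
    y[1:2] <- stats::runif(2, -80, -50)
    s_idx <- seq(3, nv - 1, by = 2)
    if (nc == 2) s_idx <- c(seq(3, 9, by = 2), 12, 14)
    d_idx <- s_idx + 1
    y[s_idx] <- stats::runif(length(s_idx), 0, 1)
    y[d_idx] <- stats::runif(length(d_idx), -0.01, 0.01)
    y[11] <- stats::runif(1, na_eq - 0.5, na_eq + 0.5)
    y
  }
  y <- as.vector(vapply(seq_len(nc), function(j) one(), numeric(nv)))
  names(y) <- state_names(nc)
  y
}

#' Simulate one trial
#'
#' Integrates the network with the stochastic Heun method at step `dt`,
#' discards the burn-in, applies the stimulus if the network carries one,
#' and records the six signals (membrane potential, firing rate, LFP for
#' both populations) of every column at `record_dt` resolution. The same
#' seed always reproduces the identical trace.
#'
#' @param network an [network_config()].
#' @param cfg an [integration_config()].
#' @param seed integer seed for this trial (initial conditions and noise).
#' @param init optional fixed initial state (bypasses the random draw).
#' @param noise optional noise matrix, `(2 * columns) x n_steps`, of
#'   standard-normal draws; mainly for targeted tests.
#' @return An object of class `nm_trace`: list with `time` (seconds),
#'   `signals` (per column, a matrix time x signal), `final_state`, and
#'   the configuration metadata.
#' @export
run_trial <- function(network, cfg, seed = 1L, init = NULL, noise = NULL) {
  stopifnot(inherits(network, "nm_network"), inherits(cfg, "nm_integration"))
  stim <- network$stimulus
  if (!is.null(stim) &&
      stim$onset * 1000 + stim$duration > cfg$trial_length * 1000)
    stop("stimulus extends beyond the trial")
  n_burn <- round(cfg$burn_in * 1000 / cfg$dt)
  n_steps <- round(cfg$trial_length * 1000 / cfg$dt)
  rec_every <- round(cfg$record_dt / cfg$dt)
  beta <- if (is.null(network$coupling)) 0 else network$coupling$beta
  body <- function() {
    y0 <- if (is.null(init)) random_init(network) else init
    heun_integrate_cpp(
      as.numeric(y0), unclass(network$params), network$columns, beta,
      cfg$dt, n_burn, n_steps, rec_every,
      network$params$noise_sd, network$params$noise_mean,
      cfg$noise_mode == "white",
      if (is.null(stim)) -1 else stim$onset * 1000,
      if (is.null(stim)) 0 else stim$duration,
      if (is.null(stim)) 0 else stim$amplitude,
      if (is.null(stim)) 0L else stim$column,
      noise, cfg$record_na)
  }
  res <- if (is.null(noise)) with_seed(seed, body) else body()
  n_rec <- n_steps %/% rec_every
  structure(list(
    time = (seq_len(n_rec) - 1) * cfg$record_dt / 1000,
    signals = res[seq_len(network$columns)],
    final_state = stats::setNames(res$final_state,
                                  state_names(network$columns)),
    network = network, cfg = cfg, seed = seed
  ), class = "nm_trace")
}

#' @export
print.nm_trace <- function(x, ...) {
  cat("<nm_trace>", length(x$time), "samples x", x$network$columns,
      "column(s), state", x$network$params$state, ", seed", x$seed, "\n")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.nm_trace <- function(x, ...) {
  purrr::map_dfr(seq_along(x$signals), function(j) {
    m <- x$signals[[j]]
    dplyr::bind_cols(tibble::tibble(time = x$time, column = j),
                     tibble::as_tibble(m))
  })
}

#' Simulate an ensemble of independent trials
#'
#' Derives one seed per trial deterministically from the master seed, runs
#' the trials independently, and stacks each recorded signal into a
#' trials-by-time matrix. Results are invariant to execution order and
#' exactly reproducible from the master seed. Trials whose state diverges
#' are dropped with a warning listing the offending seeds.
#'
#' @inheritParams run_trial
#' @param master_seed integer master seed.
#' @return An object of class `nm_ensemble`: `time` (s), `signals` (per
#'   column, list of trials x time matrices named `v_p`, `v_i`, `rate_p`,
#'   `rate_i`, `lfp_p`, `lfp_i`), `seeds`, and configuration metadata.
#' @export
run_ensemble <- function(network, cfg, master_seed = 1L) {
  seeds <- with_seed(master_seed,
                     function() sample.int(.Machine$integer.max, cfg$n_trials))
  traces <- purrr::map(seeds, function(s) {
    tryCatch(run_trial(network, cfg, seed = s),
             error = function(e) structure(list(seed = s, msg = conditionMessage(e)),
                                           class = "nm_failed_trial"))
  })
  failed <- purrr::keep(traces, inherits, "nm_failed_trial")
  if (length(failed)) {
    warning("dropped ", length(failed), " diverged trial(s) with seed(s): ",
            paste(purrr::map_int(failed, "seed"), collapse = ", "))
    traces <- purrr::discard(traces, inherits, "nm_failed_trial")
    seeds <- purrr::map_int(traces, "seed")
  }
  if (!length(traces)) stop("all trials diverged")
  sig_names <- colnames(traces[[1]]$signals[[1]])
  signals <- purrr::map(seq_len(network$columns), function(j) {
    out <- purrr::map(sig_names, function(s)
      do.call(rbind, purrr::map(traces, function(tr) tr$signals[[j]][, s])))
    stats::setNames(out, sig_names)
  })
  structure(list(time = traces[[1]]$time, signals = signals,
                 seeds = seeds, network = network, cfg = cfg,
                 master_seed = master_seed),
            class = "nm_ensemble")
}

#' @export
print.nm_ensemble <- function(x, ...) {
  cat("<nm_ensemble>", length(x$seeds), "trials x", length(x$time),
      "samples,", x$network$columns, "column(s), state",
      x$network$params$state, "\n")
  invisible(x)
}

#' Extract one signal of an ensemble
#'
#' @param ensemble an [run_ensemble()] result.
#' @param signal one of `"v_p"`, `"v_i"`, `"rate_p"`, `"rate_i"`,
#'   `"lfp_p"`, `"lfp_i"` (and `"na"` if recorded).
#' @param column column index.
#' @return A trials x time numeric matrix.
#' @export
ensemble_signal <- function(ensemble, signal = "lfp_p", column = 1L) {
  stopifnot(inherits(ensemble, "nm_ensemble"))
  m <- ensemble$signals[[column]][[signal]]
  if (is.null(m)) stop("signal ", signal, " not recorded")
  m
}

#' @export
as_tibble.nm_ensemble <- function(x, ...) {
  purrr::map_dfr(seq_along(x$signals), function(j) {
    sigs <- x$signals[[j]]
    purrr::map_dfr(seq_along(x$seeds), function(i) {
      row <- purrr::map(sigs, function(m) m[i, ])
      dplyr::bind_cols(
        tibble::tibble(trial = i, column = j, time = x$time),
        tibble::as_tibble(row))
    })
  })
}

#' Sampling rate of a recorded ensemble or trace
#'
#' @param x an `nm_ensemble` or `nm_trace`.
#' @return Sampling rate, Hz.
#' @export
sampling_rate <- function(x) 1000 / x$cfg$record_dt

# Time-window column indices for a recorded time axis (seconds),
# half-open [from, to).
window_index <- function(time, from, to) which(time >= from & time < to)
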