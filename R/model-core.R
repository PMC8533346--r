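#' Population firing rate
#'
#' Instantaneous sigmoid transfer from average membrane potential to
#' population firing rate,
#' `Q(V) = Qmax * (1 + tanh(C * (V - theta) / sigma)) / 2`.
#'
#' @param v membrane potential, mV (vectorized).
#' @param pop a population parameter list with fields `qmax`, `theta`,
#'   `sigma` (see [population_of()]).
#' @param c_sigmoid slope constant, defaults to [sigmoid_constant()].
#' @return Firing rate in ms^-1, strictly inside `(0, qmax)`.
#' @export
firing_rate <- function(v, pop, c_sigmoid = sigmoid_constant()) {
  stopifnot(pop$qmax > 0, pop$sigma > 0)
  pop$qmax * (1 + tanh(c_sigmoid * (v - pop$theta) / pop$sigma)) / 2
}

#' Leak current
#'
#' `I_L = V - E_L` with implicit unit leak conductance; the membrane time
#' constant carries the leak timescale.
#'
#' @param v membrane potential, mV.
#' @param e_l leak reversal potential, mV.
#' @return Leak current in model units.
#' @export
leak_current <- function(v, e_l) v - e_l

#' Sodium-dependent potassium current
#'
#' `I_KNa = g_KNa * 0.37 / (1 + (38.7 / Na)^3.5) * (V_p - E_K)`:
#' monotone increasing in the sodium concentration, vanishing as `Na -> 0`
#' and saturating at `0.37 * g_KNa * (V_p - E_K)`.
#'
#' @param v_p pyramidal membrane potential, mV.
#' @param na sodium concentration, mM (must be positive).
#' @param adapt adaptation parameters: a list (or `nm_params`) with fields
#'   `g_kna` and `e_k`.
#' @return Current in model units.
#' @export
kna_current <- function(v_p, na, adapt) {
  if (any(na <= 0)) stop("sodium concentration must be positive")
  adapt$g_kna * 0.37 / (1 + (38.7 / na)^3.5) * (v_p - adapt$e_k)
}

#' Sodium pump rate
#'
#' Cubic saturating pump, zeroed at the resting concentration so that the
#' sodium equilibrium at zero firing is exactly `na_eq`:
#' `R_pump * (Na^3 / (Na^3 + 3375) - Na_eq^3 / (Na_eq^3 + 3375))`.
#'
#' @param na sodium concentration, mM.
#' @param adapt list with fields `r_pump`, `na_eq`.
#' @return Extrusion rate, mM.
#' @export
na_pump <- function(na, adapt) {
  adapt$r_pump * (na^3 / (na^3 + 3375) - adapt$na_eq^3 / (adapt$na_eq^3 + 3375))
}

#' Sodium concentration dynamics
#'
#' `tau_Na * dNa/dt = alpha_Na * Q_p - Na_pump(Na)`. At zero firing the
#' unique fixed point is `na_eq`.
#'
#' @param na sodium concentration, mM (positive).
#' @param q_p pyramidal firing rate, ms^-1.
#' @param adapt list with fields `tau_na`, `alpha_na`, `r_pump`, `na_eq`.
#' @return `dNa/dt` in mM/ms.
#' @export
na_dynamics <- function(na, q_p, adapt) {
  if (any(na <= 0)) stop("sodium concentration must be positive")
  (adapt$alpha_na * q_p - na_pump(na, adapt)) / adapt$tau_na
}

#' Sodium steady state for a constant firing rate
#'
#' Root of the sodium balance `alpha_Na * Q_p = Na_pump(Na)`.
#'
#' @inheritParams na_dynamics
#' @return Steady-state concentration, mM.
#' @export
na_steady_state <- function(q_p, adapt) {
  influx <- adapt$alpha_na * q_p
  if (influx >= adapt$r_pump * (1 - adapt$na_eq^3 / (adapt$na_eq^3 + 3375)))
    stop("firing rate exceeds the pump's extrusion capacity; no sodium steady state")
  stats::uniroot(function(na) influx - na_pump(na, adapt),
                 lower = adapt$na_eq * (1 - 1e-9), upper = 1e4,
                 tol = 1e-12)$root
}

#' Second-order synaptic kinetics
#'
#' Critically damped second-order dynamics of one synaptic activity,
#' `s'' = gamma^2 * (N * Q_pre + drive - s) - 2 * gamma * s'`,
#' whose unit impulse response is the alpha function
#' `gamma^2 * t * exp(-gamma * t)`.
#'
#' @param s,sdot synaptic activity and its first derivative.
#' @param q_pre presynaptic firing rate, ms^-1.
#' @param n mean connection count.
#' @param gamma synaptic rate constant, ms^-1.
#' @param drive additive mean drive (noise mean plus stimulus), ms^-1;
#'   zero for GABAergic and inter-column synapses.
#' @return A numeric vector `c(ds, dsdot)`.
#' @export
synapse_rhs <- function(s, sdot, q_pre, n, gamma, drive = 0) {
  stopifnot(gamma > 0)
  c(ds = sdot,
    dsdot = gamma^2 * (n * q_pre + drive - s) - 2 * gamma * sdot)
}

#' Synaptic alpha function
#'
#' Closed-form impulse response of [synapse_rhs()].
#'
#' @param t time since the impulse, ms.
#' @param gamma synaptic rate constant, ms^-1.
#' @export
alpha_response <- function(t, gamma) gamma^2 * t * exp(-gamma * t)

# ---- state vector layout ----------------------------------------------------

state_names <- function(columns) {
  base <- c("v_p", "v_i", "s_pp", "d_pp", "s_ip", "d_ip",
            "s_pi", "d_pi", "s_ii", "d_ii", "na")
  if (columns == 2) base <- c(base, "s_ppx", "d_ppx", "s_ipx", "d_ipx")
  as.vector(vapply(seq_len(columns), function(j) paste0(base, "_", j),
                   character(length(base))))
}

n_state_vars <- function(columns) if (columns == 2) 30L else 11L

#' Synaptic currents of one column
#'
#' AMPAergic and GABAergic currents onto the pyramidal and inhibitory
#' population, including the inter-column AMPAergic term scaled by `beta`
#' in two-column mode.
#'
#' @param state named state vector of one column (`v_p`, `v_i`, `s_pp`,
#'   `s_ip`, `s_pi`, `s_ii`, and `s_ppx`, `s_ipx` in coupled mode).
#' @param params an [column_params()] object.
#' @param coupling an [coupling_spec()] or `NULL` for a single column.
#' @return A named vector `c(i_ampa_p, i_ampa_i, i_gaba_p, i_gaba_i)`.
#' @export
synaptic_currents <- function(state, params, coupling = NULL) {
  has_inter <- all(c("s_ppx", "s_ipx") %in% names(state))
  if (is.null(coupling) && has_inter &&
      any(abs(state[c("s_ppx", "s_ipx")]) > 0))
    stop("inter-column synaptic activities present in one-column mode")
  beta <- if (is.null(coupling)) 0 else coupling$beta
  v_p <- state[["v_p"]]; v_i <- state[["v_i"]]
  i_ampa_p <- params$g_ampa_p * state[["s_pp"]] * (v_p - params$e_ampa)
  i_ampa_i <- params$g_ampa_i * state[["s_ip"]] * (v_i - params$e_ampa)
  if (!is.null(coupling) && has_inter) {
    i_ampa_p <- i_ampa_p +
      beta * params$g_ampa_p * state[["s_ppx"]] * (v_p - params$e_ampa)
    i_ampa_i <- i_ampa_i +
      beta * params$g_ampa_i * state[["s_ipx"]] * (v_i - params$e_ampa)
  }
  c(i_ampa_p = i_ampa_p, i_ampa_i = i_ampa_i,
    i_gaba_p = params$g_gaba_p * state[["s_pi"]] * (v_p - params$e_gaba),
    i_gaba_i = params$g_gaba_i * state[["s_ii"]] * (v_i - params$e_gaba))
}

#' Full deterministic right-hand side
#'
#' Assembles the membrane, synaptic and sodium derivatives of a one- or
#' two-column network. The inhibitory membrane equation carries no
#' adaptation current. Pure function of the state and the mean drives;
#' noise is added by the integrator.
#'
#' @param state named state vector (see [state_names()] via
#'   `nmsleep:::state_names`), or unnamed in the canonical order.
#' @param network an [network_config()].
#' @param xi per-column stimulus drive entering the `s_pp` equation, ms^-1.
#' @param phi_mean mean of the noise drive on intra-column AMPAergic
#'   synapses, ms^-1.
#' @return Named derivative vector, same layout as `state`.
#' @export
full_rhs <- function(state, network, xi = numeric(network$columns),
                     phi_mean = network$params$noise_mean) {
  if (any(!is.finite(state))) stop("non-finite values in state")
  nc <- network$columns
  if (length(state) != n_state_vars(nc))
    stop("state has wrong length for ", nc, " column(s)")
  beta <- if (is.null(network$coupling)) 0 else network$coupling$beta
  dy <- model_rhs_cpp(as.numeric(state), unclass(network$params), nc, beta,
                      as.numeric(xi), phi_mean)
  names(dy) <- state_names(nc)
  dy
}

# Reference R implementation of the drift, independent of the C++ path;
# used in tests to pin the compiled right-hand side.
full_rhs_r <- function(state, network, xi = numeric(network$columns),
                       phi_mean = network$params$noise_mean) {
  p <- network$params
  nc <- network$columns
  nv <- if (nc == 2) 15L else 11L
  y <- as.numeric(state)
  dy <- numeric(length(y))
  pop_p <- population_of(p, "p"); pop_i <- population_of(p, "i")
  beta <- if (is.null(network$coupling)) 0 else network$coupling$beta
  for (j in seq_len(nc)) {
    o <- nv * (j - 1)
    oo <- nv * (nc - j)  # offset of the other column when nc == 2
    v_p <- y[o + 1]; v_i <- y[o + 2]; na <- y[o + 11]
    q_p <- firing_rate(v_p, pop_p, p$c_sigmoid)
    q_i <- firing_rate(v_i, pop_i, p$c_sigmoid)
    st <- c(v_p = v_p, v_i = v_i, s_pp = y[o + 3], s_ip = y[o + 5],
            s_pi = y[o + 7], s_ii = y[o + 9])
    if (nc == 2) st <- c(st, s_ppx = y[o + 12], s_ipx = y[o + 14])
    cur <- synaptic_currents(st, p, network$coupling)
    i_kna <- kna_current(v_p, na, p)
    dy[o + 1] <- (-leak_current(v_p, p$e_l_p) - cur[["i_ampa_p"]] -
                    cur[["i_gaba_p"]]) / p$tau_p - i_kna / p$cm
    dy[o + 2] <- (-leak_current(v_i, p$e_l_i) - cur[["i_ampa_i"]] -
                    cur[["i_gaba_i"]]) / p$tau_i
    dy[o + 3:4] <- synapse_rhs(y[o + 3], y[o + 4], q_p, p$n_pp, p$gamma_p,
                               phi_mean + xi[j])
    dy[o + 5:6] <- synapse_rhs(y[o + 5], y[o + 6], q_p, p$n_ip, p$gamma_p,
                               phi_mean)
    dy[o + 7:8] <- synapse_rhs(y[o + 7], y[o + 8], q_i, p$n_pi, p$gamma_i)
    dy[o + 9:10] <- synapse_rhs(y[o + 9], y[o + 10], q_i, p$n_ii, p$gamma_i)
    dy[o + 11] <- na_dynamics(na, q_p, p)
    if (nc == 2) {
      q_p_other <- firing_rate(y[oo + 1], pop_p, p$c_sigmoid)
      dy[o + 12:13] <- synapse_rhs(y[o + 12], y[o + 13], q_p_other,
                                   p$n_pp_inter, p$gamma_p)
      dy[o + 14:15] <- synapse_rhs(y[o + 14], y[o + 15], q_p_other,
                                   p$n_ip_inter, p$gamma_p)
    }
  }
  names(dy) <- state_names(nc)
  dy
}

#' Deterministic fixed point of the network
#'
#' Solves the noise-mean steady state. Because at a fixed point every
#' synaptic activity equals its drive (`N * Q` plus the mean noise), the
#' problem reduces to the two membrane potentials (identical across
#' columns by symmetry), solved with a damped Newton iteration; the sodium
#' concentration comes from its own 1-D balance.
#'
#' @param network an [network_config()].
#' @param v_start starting guess `c(v_p, v_i)`, mV.
#' @param phi_mean mean noise drive, ms^-1.
#' @param tol residual tolerance on the membrane equations.
#' @return Full named state vector at the fixed point.
#' @export
find_fixed_point <- function(network, v_start = c(-56, -54),
                             phi_mean = network$params$noise_mean,
                             tol = 1e-12) {
  p <- network$params
  beta <- if (is.null(network$coupling)) 0 else network$coupling$beta
  pop_p <- population_of(p, "p"); pop_i <- population_of(p, "i")
  resid <- function(v) {
    q_p <- firing_rate(v[1], pop_p, p$c_sigmoid)
    q_i <- firing_rate(v[2], pop_i, p$c_sigmoid)
    na <- na_steady_state(q_p, p)
    s_pp <- p$n_pp * q_p + phi_mean
    s_ip <- p$n_ip * q_p + phi_mean
    ampa_p <- p$g_ampa_p * (s_pp + beta * p$n_pp_inter * q_p) * (v[1] - p$e_ampa)
    ampa_i <- p$g_ampa_i * (s_ip + beta * p$n_ip_inter * q_p) * (v[2] - p$e_ampa)
    c(-leak_current(v[1], p$e_l_p) - ampa_p -
        p$g_gaba_p * p$n_pi * q_i * (v[1] - p$e_gaba) -
        p$tau_p / p$cm * kna_current(v[1], na, p),
      -leak_current(v[2], p$e_l_i) - ampa_i -
        p$g_gaba_i * p$n_ii * q_i * (v[2] - p$e_gaba))
  }
  v <- v_start
  for (it in 1:200) {
    r <- resid(v)
    if (max(abs(r)) < tol) break
    h <- 1e-6
    jac <- cbind((resid(v + c(h, 0)) - r) / h, (resid(v + c(0, h)) - r) / h)
    step <- solve(jac, -r)
    step <- pmax(pmin(step, 5), -5)  # damp large Newton steps
    v <- v + step
  }
  if (max(abs(resid(v))) > 1e-8)
    stop("fixed-point iteration did not converge (residual ",
         format(max(abs(resid(v)))), ")")
  q_p <- firing_rate(v[1], pop_p, p$c_sigmoid)
  q_i <- firing_rate(v[2], pop_i, p$c_sigmoid)
  na <- na_steady_state(q_p, p)
  one <- c(v[1], v[2],
           p$n_pp * q_p + phi_mean, 0, p$n_ip * q_p + phi_mean, 0,
           p$n_pi * q_i, 0, p$n_ii * q_i, 0, na)
  if (network$columns == 2)
    one <- c(one, p$n_pp_inter * q_p, 0, p$n_ip_inter * q_p, 0)
  y <- rep(one, network$columns)
  names(y) <- state_names(network$columns)
  y
}
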