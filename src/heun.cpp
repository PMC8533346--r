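#include <Rcpp.h>
using namespace Rcpp;

// State layout per column (offset o = 15*j in two-column mode, 11*j otherwise):
//  o+0  v_p    average membrane potential, pyramidal (mV)
//  o+1  v_i    average membrane potential, inhibitory (mV)
//  o+2  s_pp   AMPAergic synaptic activity p->p
//  o+3  d_pp   its first derivative
//  o+4  s_ip   AMPAergic p->i
//  o+5  d_ip
//  o+6  s_pi   GABAergic i->p
//  o+7  d_pi
//  o+8  s_ii   GABAergic i->i
//  o+9  d_ii
//  o+10 na     sodium concentration (mM)
//  o+11 s_ppx  inter-column AMPAergic (other column's p -> this p)  [2-col only]
//  o+12 d_ppx
//  o+13 s_ipx  inter-column AMPAergic (other column's p -> this i)  [2-col only]
//  o+14 d_ipx

struct ModelPars {
  double qmax_p, qmax_i, theta_p, theta_i, sigma_p, sigma_i;
  double tau_p, tau_i, e_l_p, e_l_i;
  double gamma_p, gamma_i, n_pp, n_ip, n_pi, n_ii;
  double g_ampa_p, g_ampa_i, g_gaba_p, g_gaba_i, e_ampa, e_gaba;
  double g_kna, e_k, tau_na, alpha_na, r_pump, na_eq, cm;
  double c_sigmoid;
  double n_pp_inter, n_ip_inter;
};

static ModelPars read_pars(const List& par) {
  ModelPars p;
  p.qmax_p   = as<double>(par["qmax_p"]);
  p.qmax_i   = as<double>(par["qmax_i"]);
  p.theta_p  = as<double>(par["theta_p"]);
  p.theta_i  = as<double>(par["theta_i"]);
  p.sigma_p  = as<double>(par["sigma_p"]);
  p.sigma_i  = as<double>(par["sigma_i"]);
  p.tau_p    = as<double>(par["tau_p"]);
  p.tau_i    = as<double>(par["tau_i"]);
  p.e_l_p    = as<double>(par["e_l_p"]);
  p.e_l_i    = as<double>(par["e_l_i"]);
  p.gamma_p  = as<double>(par["gamma_p"]);
  p.gamma_i  = as<double>(par["gamma_i"]);
  p.n_pp     = as<double>(par["n_pp"]);
  p.n_ip     = as<double>(par["n_ip"]);
  p.n_pi     = as<double>(par["n_pi"]);
  p.n_ii     = as<double>(par["n_ii"]);
  p.g_ampa_p = as<double>(par["g_ampa_p"]);
  p.g_ampa_i = as<double>(par["g_ampa_i"]);
  p.g_gaba_p = as<double>(par["g_gaba_p"]);
  p.g_gaba_i = as<double>(par["g_gaba_i"]);
  p.e_ampa   = as<double>(par["e_ampa"]);
  p.e_gaba   = as<double>(par["e_gaba"]);
  p.g_kna    = as<double>(par["g_kna"]);
  p.e_k      = as<double>(par["e_k"]);
  p.tau_na   = as<double>(par["tau_na"]);
  p.alpha_na = as<double>(par["alpha_na"]);
  p.r_pump   = as<double>(par["r_pump"]);
  p.na_eq    = as<double>(par["na_eq"]);
  p.cm       = as<double>(par["cm"]);
  p.c_sigmoid   = as<double>(par["c_sigmoid"]);
  p.n_pp_inter  = as<double>(par["n_pp_inter"]);
  p.n_ip_inter  = as<double>(par["n_ip_inter"]);
  return p;
}

static inline double firing(double v, double qmax, double theta, double sigma, double c) {
  return 0.5 * qmax * (1.0 + std::tanh(c * (v - theta) / sigma));
}

static inline double na_pump(double na, const ModelPars& p) {
  double na3 = na * na * na;
  double eq3 = p.na_eq * p.na_eq * p.na_eq;
  return p.r_pump * (na3 / (na3 + 3375.0) - eq3 / (eq3 + 3375.0));
}

// Deterministic drift. xi[j] is the stimulus drive (ms^-1) entering the
// s_pp equation of column j; phi_mean is the baseline mean of the noise
// drive on both intra-column AMPAergic synapses.
static void drift(const double* y, double* dy, const ModelPars& p,
                  int ncol, double beta, const double* xi, double phi_mean) {
  int nv = (ncol == 2) ? 15 : 11;
  double g2p = p.gamma_p * p.gamma_p;
  double g2i = p.gamma_i * p.gamma_i;
  for (int j = 0; j < ncol; ++j) {
    int o = nv * j;
    int oo = nv * (1 - j);  // other column (only read when ncol == 2)
    double v_p = y[o + 0], v_i = y[o + 1];
    double na = y[o + 10];
    double q_p = firing(v_p, p.qmax_p, p.theta_p, p.sigma_p, p.c_sigmoid);
    double q_i = firing(v_i, p.qmax_i, p.theta_i, p.sigma_i, p.c_sigmoid);

    double i_ampa_p = p.g_ampa_p * y[o + 2] * (v_p - p.e_ampa);
    double i_ampa_i = p.g_ampa_i * y[o + 4] * (v_i - p.e_ampa);
    if (ncol == 2) {
      i_ampa_p += beta * p.g_ampa_p * y[o + 11] * (v_p - p.e_ampa);
      i_ampa_i += beta * p.g_ampa_i * y[o + 13] * (v_i - p.e_ampa);
    }
    double i_gaba_p = p.g_gaba_p * y[o + 6] * (v_p - p.e_gaba);
    double i_gaba_i = p.g_gaba_i * y[o + 8] * (v_i - p.e_gaba);
    double i_kna = p.g_kna * 0.37 / (1.0 + std::pow(38.7 / na, 3.5)) * (v_p - p.e_k);

    dy[o + 0] = (-(v_p - p.e_l_p) - i_ampa_p - i_gaba_p) / p.tau_p - i_kna / p.cm;
    dy[o + 1] = (-(v_i - p.e_l_i) - i_ampa_i - i_gaba_i) / p.tau_i;

    dy[o + 2] = y[o + 3];
    dy[o + 3] = g2p * (p.n_pp * q_p + phi_mean + xi[j] - y[o + 2]) - 2.0 * p.gamma_p * y[o + 3];
    dy[o + 4] = y[o + 5];
    dy[o + 5] = g2p * (p.n_ip * q_p + phi_mean - y[o + 4]) - 2.0 * p.gamma_p * y[o + 5];
    dy[o + 6] = y[o + 7];
    dy[o + 7] = g2i * (p.n_pi * q_i - y[o + 6]) - 2.0 * p.gamma_i * y[o + 7];
    dy[o + 8] = y[o + 9];
    dy[o + 9] = g2i * (p.n_ii * q_i - y[o + 8]) - 2.0 * p.gamma_i * y[o + 9];

    dy[o + 10] = (p.alpha_na * q_p - na_pump(na, p)) / p.tau_na;

    if (ncol == 2) {
      double v_p_other = y[oo + 0];
      double q_p_other = firing(v_p_other, p.qmax_p, p.theta_p, p.sigma_p, p.c_sigmoid);
      dy[o + 11] = y[o + 12];
      dy[o + 12] = g2p * (p.n_pp_inter * q_p_other - y[o + 11]) - 2.0 * p.gamma_p * y[o + 12];
      dy[o + 13] = y[o + 14];
      dy[o + 14] = g2p * (p.n_ip_inter * q_p_other - y[o + 13]) - 2.0 * p.gamma_p * y[o + 14];
    }
  }
}

// [[Rcpp::export]]
NumericVector model_rhs_cpp(NumericVector state, List par, int n_columns,
                            double beta, NumericVector xi, double phi_mean) {
  ModelPars p = read_pars(par);
  int nv = (n_columns == 2) ? 15 : 11;
  if (state.size() != nv * n_columns)
    stop("state has wrong length for %d column(s)", n_columns);
  NumericVector dy(state.size());
  std::vector<double> xiv(n_columns, 0.0);
  for (int j = 0; j < n_columns && j < xi.size(); ++j) xiv[j] = xi[j];
  drift(REAL(state), REAL(dy), p, n_columns, beta, xiv.data(), phi_mean);
  return dy;
}

// Stochastic Heun integration.
//
// Noise enters the first-derivative equations of the intra-column AMPAergic
// synapses (d_pp, d_ip) of every column as an additive increment
//   gamma_p^2 * sd * sqrt(dt) * z   (white = true; continuous-time convention)
//   gamma_p^2 * sd * dt * z         (white = false; piecewise-constant drive)
// with the same standard-normal draw z used in predictor and corrector.
// Draw order per step: column 0 (s_pp, s_ip), column 1 (s_pp, s_ip).
//
// Recording starts after n_burn_steps; every rec_every-th state is stored,
// n_rec = n_trial_steps / rec_every samples in total.
// [[Rcpp::export]]
List heun_integrate_cpp(NumericVector init, List par, int n_columns, double beta,
                        double dt, int n_burn_steps, int n_trial_steps, int rec_every,
                        double noise_sd, double phi_mean, bool white_noise,
                        double stim_onset_ms, double stim_dur_ms, double stim_amp,
                        int stim_column,
                        Nullable<NumericMatrix> noise, bool record_na) {
  ModelPars p = read_pars(par);
  int nv = (n_columns == 2) ? 15 : 11;
  int n_state = nv * n_columns;
  if (init.size() != n_state)
    stop("init has wrong length for %d column(s)", n_columns);
  int n_total = n_burn_steps + n_trial_steps;
  int n_rec = n_trial_steps / rec_every;

  std::vector<double> y(REAL(init), REAL(init) + n_state);
  std::vector<double> f0(n_state), f1(n_state), ytil(n_state);
  std::vector<double> xi0(n_columns, 0.0), xi1(n_columns, 0.0);
  std::vector<double> z(2 * n_columns);

  bool have_noise = noise.isNotNull();
  NumericMatrix nmat;
  if (have_noise) {
    nmat = NumericMatrix(noise);
    if (nmat.nrow() != 2 * n_columns || nmat.ncol() < n_total)
      stop("noise matrix must be (2*n_columns) x n_steps");
  }
  double namp = p.gamma_p * p.gamma_p * noise_sd *
                (white_noise ? std::sqrt(dt) : dt);

  // output: one matrix per signal per column
  int n_sig = record_na ? 7 : 6;
  std::vector<NumericMatrix> out;
  for (int j = 0; j < n_columns; ++j)
    out.push_back(NumericMatrix(n_rec, n_sig));

  RNGScope scope;
  int i_rec = 0;
  for (int step = 0; step < n_total; ++step) {
    double t_ms = (step - n_burn_steps) * dt;       // trial time of current state
    // stimulus drive at current and next time
    for (int j = 0; j < n_columns; ++j) xi0[j] = xi1[j] = 0.0;
    if (stim_column >= 1 && stim_amp != 0.0) {
      int jc = stim_column - 1;
      if (t_ms >= stim_onset_ms && t_ms < stim_onset_ms + stim_dur_ms) xi0[jc] = stim_amp;
      double t1 = t_ms + dt;
      if (t1 >= stim_onset_ms && t1 < stim_onset_ms + stim_dur_ms) xi1[jc] = stim_amp;
    }

    // record before stepping so that t = 0 is included
    if (step >= n_burn_steps && (step - n_burn_steps) % rec_every == 0 && i_rec < n_rec) {
      for (int j = 0; j < n_columns; ++j) {
        int o = nv * j;
        double v_p = y[o + 0], v_i = y[o + 1];
        double i_ampa_p = p.g_ampa_p * y[o + 2] * (v_p - p.e_ampa);
        double i_ampa_i = p.g_ampa_i * y[o + 4] * (v_i - p.e_ampa);
        if (n_columns == 2) {
          i_ampa_p += beta * p.g_ampa_p * y[o + 11] * (v_p - p.e_ampa);
          i_ampa_i += beta * p.g_ampa_i * y[o + 13] * (v_i - p.e_ampa);
        }
        double i_gaba_p = p.g_gaba_p * y[o + 6] * (v_p - p.e_gaba);
        double i_gaba_i = p.g_gaba_i * y[o + 8] * (v_i - p.e_gaba);
        NumericMatrix& m = out[j];
        m(i_rec, 0) = v_p;
        m(i_rec, 1) = v_i;
        m(i_rec, 2) = firing(v_p, p.qmax_p, p.theta_p, p.sigma_p, p.c_sigmoid);
        m(i_rec, 3) = firing(v_i, p.qmax_i, p.theta_i, p.sigma_i, p.c_sigmoid);
        m(i_rec, 4) = std::fabs(i_ampa_p) + std::fabs(i_gaba_p);
        m(i_rec, 5) = std::fabs(i_ampa_i) + std::fabs(i_gaba_i);
        if (record_na) m(i_rec, 6) = y[o + 10];
      }
      ++i_rec;
    }

    // noise draws (fixed order, one per noisy equation per step)
    for (int j = 0; j < 2 * n_columns; ++j)
      z[j] = have_noise ? nmat(j, step) : norm_rand();

    drift(y.data(), f0.data(), p, n_columns, beta, xi0.data(), phi_mean);
    for (int k = 0; k < n_state; ++k) ytil[k] = y[k] + dt * f0[k];
    for (int j = 0; j < n_columns; ++j) {
      ytil[nv * j + 3] += namp * z[2 * j];
      ytil[nv * j + 5] += namp * z[2 * j + 1];
    }
    drift(ytil.data(), f1.data(), p, n_columns, beta, xi1.data(), phi_mean);
    for (int k = 0; k < n_state; ++k) y[k] += 0.5 * dt * (f0[k] + f1[k]);
    for (int j = 0; j < n_columns; ++j) {
      y[nv * j + 3] += namp * z[2 * j];
      y[nv * j + 5] += namp * z[2 * j + 1];
    }

    if ((step & 1023) == 0) {
      for (int k = 0; k < n_state; ++k)
        if (!std::isfinite(y[k]))
          stop("state diverged (non-finite value) at step %d (t = %g ms)", step, t_ms);
    }
  }
  for (int k = 0; k < n_state; ++k)
    if (!std::isfinite(y[k])) stop("state diverged (non-finite value) at final step");

  List res;
  CharacterVector sig = record_na
    ? CharacterVector::create("v_p", "v_i", "rate_p", "rate_i", "lfp_p", "lfp_i", "na")
    : CharacterVector::create("v_p", "v_i", "rate_p", "rate_i", "lfp_p", "lfp_i");
  for (int j = 0; j < n_columns; ++j) {
    colnames(out[j]) = sig;
    res.push_back(out[j]);
  }
  res.push_back(NumericVector(wrap(std::vector<double>(y.begin(), y.end()))));
  CharacterVector nm(n_columns + 1);
  for (int j = 0; j < n_columns; ++j) nm[j] = "column" + std::to_string(j + 1);
  nm[n_columns] = "final_state";
  res.attr("names") = nm;
  return res;
}
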