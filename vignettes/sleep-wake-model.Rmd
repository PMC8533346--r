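---
title: "A two-column neural-mass model of the sleep-waking cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-column neural-mass model of the sleep-waking cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`nmsleep` simulates one or two cortical columns, each reduced to a
pyramidal (`p`) and an inhibitory (`i`) population. The average membrane
potentials obey a conductance-based mean-field description,

$$\tau_p \dot V_p = -(V_p - E_L^p) - I_{AMPA}^p - I_{GABA}^p
  - \tfrac{\tau_p}{C_m} I_{KNa}, \qquad
  \tau_i \dot V_i = -(V_i - E_L^i) - I_{AMPA}^i - I_{GABA}^i,$$

with a unit leak conductance (the membrane time constant carries the leak
timescale; no separate leak conductance parameter exists). The firing
rate of each population is an instantaneous sigmoid of its potential,
$Q(V) = Q^{max}\,[1 + \tanh(C\,(V-\theta)/\sigma)]/2$ with
$C = \pi/(2\sqrt 3)$, which makes the tanh form identical to the logistic
sigmoid with gain $\pi/\sqrt3$ used throughout this model lineage. `C` is
exposed (`c_sigmoid`) for sensitivity analyses.

Synaptic activity is the presynaptic rate convolved with an alpha
function $\gamma^2 t e^{-\gamma t}$, i.e. critically damped second-order
kinetics

$$\ddot s_{kk'} = \gamma_{k'}^2\,(N_{kk'} Q_{k'} + \phi - s_{kk'})
  - 2\gamma_{k'}\dot s_{kk'},$$

driving currents $I_X^k = \bar g_X^k\, s_{kX}\,(V_k - E_X)$ for
$X \in \{AMPA, GABA\}$. The pyramidal population additionally carries a
sodium-gated potassium current
$I_{KNa} = \bar g_{KNa}\,0.37/(1 + (38.7/\mathrm{Na})^{3.5})\,(V_p - E_K)$
with sodium mass balance
$\tau_{Na}\dot{\mathrm{Na}} = \alpha_{Na} Q_p - \mathrm{Na_{pump}(Na)}$.
The pump is the cubic saturating form
$R_{pump}(\mathrm{Na}^3/(\mathrm{Na}^3+3375) -
\mathrm{Na}_{eq}^3/(\mathrm{Na}_{eq}^3+3375))$, which pins the
zero-firing equilibrium exactly at $\mathrm{Na}_{eq}$. This adaptation
loop (effective timescale a few hundred ms near equilibrium) is what
terminates Up states and produces the slow alternation.

In two-column mode the columns are identical and symmetrically coupled
through AMPAergic synapses only: each column's pyramidal population
projects onto the other column's `p` and `i` populations
($N^{inter}_{pp'} = 8$, $N^{inter}_{ip'} = 2$), through dedicated
second-order synapses that receive neither noise nor stimulus. Their
current is scaled by $\beta$, the ratio of inter- to intra-columnar
AMPAergic conductance:
$I_{AMPA}^k = \bar g_{AMPA}^k s_{kp}(V_k - E_{AMPA}) +
\beta\,\bar g_{AMPA}^k s^{inter}_{kp'}(V_k - E_{AMPA})$.

### The sleep-wake switch

The NREM preset uses $\bar g_{AMPA} = 1$ and unit GABAergic
conductances; its dynamics are a noise-driven alternation between a
depolarized Up state and a quasi-silent Down state. Wakefulness is
reached by *upscaling the excitatory conductance alone*
($\bar g_{AMPA} = 2$), in the spirit of the synaptic homeostasis
hypothesis; the GABAergic conductances are then re-calibrated so that
the waking steady state sits at the NREM Up-state membrane potentials
(see below), and the noise drive weakens from 1.8 to 1 ms$^{-1}$.

## Noise, stimulus, integration

The drive $\phi$ enters only the intra-column AMPAergic equations
(`s_pp`, `s_ip`), one independent process per population; GABAergic and
inter-column synapses are noise-free. We treat $\phi$ as continuous-time
white noise: the Heun update adds
$\gamma_p^2\,\mathrm{sd}\,\sqrt{dt}\,z$, with the same standard-normal
draw $z$ in predictor and corrector. The alternative convention — an
independent draw held constant over each step, increments scaling with
$dt$ — is available (`noise_mode = "per_step"`) but injects roughly
$\sqrt{dt}$-fold less power at `dt = 0.1` ms: under it the NREM preset
produces *no* Up/Down alternation at all, while the white convention
reproduces the full NREM/wake phenomenology and the published
calibration tables, which is why it is the default.

The stimulus is a square 100 ms, 1 ms$^{-1}$ increase in the mean of
$\phi$ on the pyramidal `s_pp` equation of one (the perturbed) column,
at 5 s into a 10 s trial, so the prestimulus window is `[0, 5)` s and the
poststimulus window `[5, 10)` s.

Integration uses the stochastic Heun scheme at `dt = 0.1` ms, discarding
a 10 s burn-in. Initial conditions are uniform draws over plausible
ranges ($V \in [-80, -50]$ mV, synaptic activities in $[0, 1]$ with
small derivatives, Na within 0.5 mM of rest); the burn-in absorbs the
transient from any such start. Signals are recorded at 1 ms resolution
by default — all analyses live far below the resulting 500 Hz Nyquist.
Trials in an ensemble get seeds derived deterministically from one
master seed, so every ensemble is exactly reproducible and
order-independent.

```{r}
library(nmsleep)
net <- build_state_preset("nrem")
cfg <- integration_config(n_trials = 100)
ens <- run_ensemble(net, cfg, master_seed = 1)
```

## Calibration

The waking state is anchored to NREM by matching membrane potentials.
`estimate_up_state_targets()` pools the per-trial demeaned pyramidal LFP
of an NREM ensemble, smooths its 0.5 mV histogram, takes the midpoint of
the two modes as the Up/Down threshold, and returns the mode of the
$V_p$ and $V_i$ distributions over Up-labeled samples (0.5 mV bins).
Up/Down is treated as a column-wide state: the pyramidal-LFP labels are
applied to both populations.

Given targets, `calibrate_g_gaba()` solves the noise-mean steady state
for the two GABAergic conductances. At a fixed point every synaptic
activity equals its mean drive, so the two membrane equations are
*linear* in the two unknown conductances: the solution is closed-form
and exact, rather than an iterative root-find, and is therefore exactly
linear in $\beta$ at fixed targets — which is why the published
conductance grids are equally spaced in $\beta$. The mean-field solve
deliberately ignores the noise variance; the residual mismatch between
the distribution peak of a noisy simulation and the deterministic fixed
point is what the few-percent comparison tolerance absorbs.

Two anchors are used, matching how the conductance tables behave:

* wake presets: targets from the *simulated* NREM Up-state peaks
  (the Up-state mode sits ~2 mV above the deterministic fixed point,
  because conditioning on the Up state skews the noisy excursions);
* two-column NREM: targets from the *deterministic* one-column NREM
  fixed point (`fixed_point_targets()`), which reproduces the published
  two-column NREM conductances to four significant figures.

`build_state_preset()` returns table-exact presets for published
$(\bar g_{AMPA}, \beta)$ combinations and calibrates on demand
otherwise.

## Signal analysis

The LFP proxy of a population is $|I_{AMPA}| + |I_{GABA}|$. Amplitude
distributions use 0.5 mV (or 0.5 Hz) bins normalized by the total event
count. Mode detection smooths the binned counts with a Gaussian kernel
on the amplitude axis — width 55 mV for the pyramidal LFP, 5 mV for the
inhibitory one, applied verbatim and configurable. Two numerical guards
matter here: modes are strict local maxima of the smoothed curve, the
two tallest are kept (ties broken toward wider separation), and a
candidate mode must reach at least 5% of the tallest peak
(`min_peak_frac`) — under so broad a kernel a single outlier bin at the
edge of the support otherwise masquerades as a second mode (observed
relative height ~0.002, against ~0.5 for a genuine Down mode). A
unimodal distribution yields an explicit no-bimodality result, which is
how the waking regime is recognized.

Spectra are Welch-style: 2 s Hann-tapered windows with 90% overlap,
one-sided PSD with taper power correction, averaged over windows within
a trial and then across trials; decibels are `log10(P / 1)`. The
high/low band ratio is the per-trial `log10` of summed power above
30 Hz over summed power below 4 Hz. Because the exact periodogram
normalization of any particular analysis stack is conventional, all
spectral comparisons in the tests are orderings (band power, band-ratio
separation), never absolute dB matches; the wake-over-NREM gamma
ordering is asserted over 30–100 Hz and as band means, since beyond
~200 Hz both spectra sit on the white-noise floor where the NREM drive
(1.8 vs 1 ms$^{-1}$) trivially dominates.

## The cluster permutation test

The evoked-response statistic follows the as-published recipe exactly:

* pointwise $t = (\bar x_1 - \bar x_2)/\sqrt{s^2/n}$ with pooled
  variance $s^2 = ((n-1)s_1^2 + (n-1)s_2^2)/(2n-1)$ — implemented
  verbatim, including the $2n-1$ denominator and the $s^2/n$ scaling
  (note this is $\sqrt2$ larger than the textbook two-sample statistic;
  a `var_form = "welch"` switch exists for sensitivity analyses);
* clusters are maximal runs with $|t| \ge 2.58$ (the two-tailed critical
  value at $p = 0.01$ for the 500-trial scale, `critical_t()`); each
  carries area $\sum |t|\,dt$ (s) and length (ms);
* clusters no larger than the biggest cluster from splitting the
  prestimulus window in half are discarded;
* survivors get permutation p-values: trials are re-assigned between the
  two groups (full relabeling, preserving sizes — the standard
  exchangeability-based scheme), the ranked permuted areas form one null
  distribution per observed rank, permutations continue until the
  deepest rank has at least 1000 null samples, and $p$ is the proportion
  of same-ranked null areas exceeding the observed one. Absolute areas
  are pooled (the two-tailed threshold is already applied).

Propagation between columns is quantified by the *first* (earliest)
poststimulus cluster of the unperturbed pyramidal firing rate: its area
and length grow with $\beta$, and `propagation_metrics()` returns an
explicit none-record when nothing is significant.

One property of this recipe deserves emphasis: the first-cluster
(max-statistic) decision is exactly calibrated — its measured
false-positive rate on null ensembles matches the nominal 0.01 — but
because *every* cluster surviving the baseline filter is tested at 0.01
with its own rank-matched null, the probability that *some* cluster is
declared significant under the null grows with the number of survivors.
All headline decisions in this package (and the propagation
quantification generally) therefore rest on the first cluster, and the
type-I calibration test asserts exactly that decision rule.

## Problem sizes and test design

The package's own study sizes: 100-trial ensembles for the regime
dichotomy and for Up-state target estimation; 250 trials for the
one-column evoked-response check (the poststimulus suppression is a
weak effect — at 100 trials its detection is a coin flip, at 250 it is
reliable while the positive deflection is unambiguous at any scale);
200 trials for the two-grid-point propagation contrast
($\beta = 1$ versus $\beta = 5$ at $\bar g_{AMPA} = 2$); and the full published
scale (500 trials, $\ge$1000 permutations) in `scripts/acceptance.R`,
where the weaker grid points (e.g. $\bar g_{AMPA} = 6$, $\beta = 2$)
genuinely need it. Type-I calibration uses 500 null datasets of AR(1)
trials ($\varphi = 0.95$): the permutation test is exact under
exchangeability for any null process, and autocorrelated noise gives
realistic cluster structure at a tiny fraction of the cost of model
ensembles.

What the synthetic fixtures emulate — and what they do not: the
generator *is* the model, so the tests exercise the actual study
conditions rather than a surrogate; but the model itself idealizes.
Columns are identical and symmetric; there is no thalamus, no
neuromodulation, no REM state, no conduction delay; the LFP is a
synaptic-current proxy without volume conduction; and the noise is
white. Passing tests therefore demonstrate internal reproducibility of
the modeled phenomena, not fidelity to any particular recording.

## Known limitations

* The calibration targets inherit the 0.5 mV bin quantization and the
  simulation's noise convention; calibrated conductances land within a
  few percent of the published grids, not at machine precision.
* The familywise any-cluster error of the cluster recipe exceeds the
  per-cluster level when several clusters survive the baseline filter
  (see above).
* `beta` and the conductances interact: far off the published grid the
  mean-field solve can return targets-unreachable errors (negative
  conductances), which are reported, not clamped.
* Two columns only; no spatial embedding, so "propagation" is strictly
  the two-node effective-connectivity question.
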