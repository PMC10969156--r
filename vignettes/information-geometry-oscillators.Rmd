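---
title: "Information-geometry measures for stochastic coupled oscillator ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-geometry measures for stochastic coupled oscillator ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inforate)
```

## The model

`inforate` studies a phenomenological EEG model: two coupled Duffing-van der
Pol oscillators, the second driven by white noise. In first-order form the
state is $(x_1, x_2, x_3, x_4) = (x_1, x_2, \dot x_1, \dot x_2)$ and

$$
\begin{aligned}
\dot x_1 &= x_3, \qquad \dot x_2 = x_4,\\
\dot x_3 &= -(k_1+k_2)\,x_1 + k_2 x_2 - b_1 x_1^3 - b_2 (x_1-x_2)^3
           + \epsilon_1 x_3 (1-x_1^2),\\
\dot x_4 &= k_2 x_1 - k_2 x_2 + b_2 (x_1-x_2)^3
           + \epsilon_2 x_4 (1-x_2^2) + \mu\, dW .
\end{aligned}
$$

$k_1, k_2$ are linear stiffnesses, $b_1, b_2$ cubic (Duffing) stiffnesses,
$\epsilon_1, \epsilon_2$ amplitude-dependent (van der Pol) damping
coefficients, and $\mu$ the white-noise intensity. Four fitted parameter
sets represent healthy controls (CTL) and Alzheimer's-disease patients (AD)
recorded with eyes closed (EC) or open (EO); `preset_params()` returns them
verbatim. All quantities are in dimensionless model units; one model time
unit is treated as one second wherever frequencies are reported.

The object of study is not a single trajectory but an *ensemble*: the
positions $x_1(t), x_2(t)$ of many independently simulated trajectories
define time-dependent densities $p(x_1,t)$ and $p(x_2,t)$, and every
measure in the package is a functional of those densities.

## Measures

Viewing $p(x,t)$ as a point moving on the statistical manifold with the
Fisher metric, the **information rate**
$$
\Gamma^2(t) = \int \frac{1}{p}\Big(\frac{\partial p}{\partial t}\Big)^2 dx
            = 4\int \Big(\frac{\partial \sqrt p}{\partial t}\Big)^2 dx
$$
is the speed of that motion, and the **information length**
$L(t) = \int_0^t \Gamma\,dt_1$ the distance travelled. The
**causal information rate** $\Gamma_{a\to b} = \Gamma_b^* - \Gamma_b$
compares $b$'s rate with the rate of the joint density in which $a$'s
simultaneous value is known and frozen in time; it vanishes when $a$ and
$b$ are independent at equal times, and the **net causal rate**
$\Gamma_{x_2\to x_1}-\Gamma_{x_1\to x_2}$ summarizes directional dominance
($x_2$ is the noise-driven oscillator). As comparators the package computes
the **differential entropy** $h = -\int p \ln p\,dx$ (nats) and the
**transfer entropy** with one-step histories (bits),
$TE_{a\to b} = H(b'|b) - H(b'|b,a)$ with $b' = x_b(t+\Delta t)$.

## Numerical estimation

**Integration.** `simulate_ensemble()` uses the Euler-Maruyama scheme. The
published step size $dt = 10^{-6}$ compensates the large stiffnesses
($k_1 \approx 7 \times 10^3$); the noise enters only the $x_4$ equation as
$\mu\sqrt{dt}\,\mathcal N(0,1)$ per step. All per-step normals come from an
internal xoshiro256++/ziggurat stream seeded from the run's single integer
seed, so runs are bit-reproducible and, with $\mu = 0$, seed-independent.
A non-finite state aborts the run with the offending recording interval
rather than clipping - clipped tails would silently corrupt exactly the
density tails the measures integrate over. Recording happens at the cadence
$\Delta t = 10^{-4}$ (including $t = 0$) and streams slices to a consumer;
no trajectory history is kept, so memory scales with the ensemble size
only. Only $x_1, x_2$ are recorded by default since no downstream estimator
uses the velocities.

**Densities.** All densities are histograms. The 1-D bin count follows
Rice's rule $\lfloor 2 n^{1/3}\rfloor$ - flooring, not rounding, which is
what reproduces the published counts (542 bins for $2\times10^7$ samples,
58 bins for the 24,999 stationary-window samples). A pair of time slices
being differenced always shares *one* grid built from their pooled samples
(padded by a relative $10^{-9}$), because $\partial_t p$ is only meaningful
on a common support; the pooled range guarantees no sample falls outside.
For $d$-dimensional joints the default policy is
$\lfloor 2 n^{1/(d+2)}\rfloor$ bins per axis - it recovers Rice's rule at
$d = 1$ and keeps per-cell occupancy controlled (for $n = 2\times10^7$:
133 per axis in 2-D, 57 in 3-D). The policy is one swappable function
argument (`bin_policy`), since the exact joint-binning prescription is a
genuinely open design choice. Empty bins contribute zero to every integral
($0\log 0 := 0$).

**Rates.** The time derivative is a forward difference of $\sqrt p$ over
one recording interval: with shared grids the widths cancel and
$\hat\Gamma = (2/\Delta t)\sqrt{\sum_i (\sqrt{m_i'} - \sqrt{m_i})^2}$ - a
scaled Hellinger distance, which also yields the hard bound
$\Gamma \le 2\sqrt 2/\Delta t$ checked in the tests. Differencing $\sqrt p$
rather than $p$ is exactly the simplified estimator form and is stabler in
sparse bins. Inside a causal-rate subtraction the marginal $\Gamma_b$ is
recomputed from the $x_b$-marginal of the *same* joint histogram: because
marginalization contracts Hellinger distance, this guarantees
$\Gamma_b^* \ge \Gamma_b$ on the same data and removes the dominant source
of spurious negative causal rates (mixing bin systems). An explicit
marginal pair can still be supplied for comparison. Transfer entropy takes
all lower-order masses from the same 3-D histogram; a value below
$-10^{-12}$ therefore indicates genuine inconsistency and raises an error
instead of being clamped.

**Stationary window.** Summary statistics select densities with
$t \ge 7.5$ (after the ensembles settle on their attractors) and strictly
before $t_{\rm end}$; rates come from adjacent pairs inside the selection,
so the window $[7.5, 10)$ at cadence $10^{-4}$ holds $25{,}000$ densities
and exactly $24{,}999$ rate samples - matching the published bookkeeping.
Sample SDs use the $n-1$ denominator.

**Spectra.** `power_spectrum()` removes the window mean (the DC term would
otherwise dominate the log-log fit; the choice is inert to the exponent
since fitting starts at 100 Hz) and reports one-sided FFT *amplitudes*, fit
by OLS in log10-log10 over 100-1000 Hz by default. With
$\Delta t = 10^{-4}$ the rate series is a 10 kHz signal (5 kHz Nyquist).

## What the generator emulates - and what it does not

The simulator *is* the study's data generator: four parameter regimes, six
published initial Gaussian ensembles (IC1-IC3 narrow, $\sigma = 0.1$;
IC4-IC6 wide, $\sigma = 0.5$; IC4 is the representative default). Passing
tests on this generator shows the estimators recover information-geometry
quantities from ensemble densities of a nonlinear, non-Gaussian, noise-driven
system. It does *not* show performance on real EEG: experimental recordings
provide one trajectory per channel (requiring sliding-window density
estimation under a local-stationarity assumption), contain measurement
noise and artifacts, and are not generated by this model family. Validation
processes with closed forms (drifting Gaussians, Ornstein-Uhlenbeck
ensembles via `simulate_ou_ensemble()`, independent/coupled Gaussian pairs,
hand-enumerable channels) back every estimator with an analytic oracle.

## Estimator accuracy and known limitations

Histogram plug-in estimators of $\Gamma^*$, causal rates and TE carry a
non-negative finite-sample bias of order $K_{\rm cells}/(2n)$ inside the
squared Hellinger sum (and $K/(2n\ln 2)$ bits for TE). Two consequences
shape the package's testing strategy:

* Independence nulls are assessed against a **permutation null** (shuffling
  the conditioning column), which carries the same bias, rather than
  against literal zero.
* $\Gamma$ curves are validated in regimes where the Hellinger signal
  $(\Gamma\Delta t/2)^2$ dominates the $K/(2n)$ noise floor. The OU
  validation uses $\theta = 1$, initial mean 8 and sd 0.1, equilibrium
  variance 0.01, $\Delta t = 10^{-2}$, $n = 10^6$ trajectories and 100
  recording steps - chosen from that signal-to-floor analysis, and
  recovering the closed-form curve to well under 2%.

The published study runs $2\times10^7$ trajectories for $10^7$ steps -
cluster scale. The test suite and the acceptance script run the same
pipeline at desk scale: $10^4$ trajectories, $t \in [0, 1]$, stationary
window $[0.75, 1)$, the published $dt = 10^{-6}$ and $\Delta t = 10^{-4}$.
At this scale the EC/EO contrast *directions* reproduce robustly (and the
CTL-EC rate magnitudes happen to land near the published ones), but
magnitudes generally depend on the bin count and ensemble size through the
noise floor above, so only directions are asserted. Full-scale magnitude
reproduction is supported by the same code path
(`simulation_config(1e-6, 1e-4, 10)` with `n_traj = 2e7`) given cluster
resources and time.

## A worked desk-scale run

```{r example, eval = FALSE}
cfg <- simulation_config(dt = 1e-6, record_dt = 1e-4, t_end = 1.0)
bundles <- lapply(condition_names(), function(cond)
  run_condition(cond, ic = 4, n_traj = 1e4, config = cfg, seed = 1,
                window_start = 0.75))
report <- compare_conditions(bundles)
report$rate_entropy_table
report$contrasts
```

Each bundle carries the full measure series (`bundle$series`), the
stationary summaries, the empirical measure distributions (Rice bins on the
window count) and the fitted rate spectra. `write_bundle()` serializes
everything as CSV plus JSON sidecars, and the script in `inst/cli/` exposes
the same pipeline from a shell.

## Open design choices made here

* **Noise placement.** The model's $+\mu\,dW$ term sits in the $\dot x_4$
  equation; it is implemented as an additive $\mu\sqrt{dt}$ increment on
  $x_4$ per step, the standard Euler-Maruyama reading of additive white
  noise.
* **Grid range rule.** Published figures plot fixed bin-center axes but no
  range convention is stated; pooling the compared slices is the choice
  here because differencing requires shared support and pooling guarantees
  coverage.
* **Joint bin counts.** The $\lfloor 2 n^{1/(d+2)}\rfloor$ rule is this
  package's policy (swappable), chosen to control per-cell occupancy while
  reducing to Rice's rule in 1-D.
* **Marginal inside the causal subtraction.** Joint-consistent by default
  (see above); the independent-marginal variant remains available through
  the `marginals` argument of `causal_information_rate()`.
* **Window boundary.** The $[7.5, 10)$ window selects densities, not
  rates; this is the convention that yields the published 24,999 count.
* **Units.** Entropy in nats, transfer entropy in bits, rates in inverse
  model-time units; each series records its units in metadata.
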