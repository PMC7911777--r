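---
title: "Methods: linear response for a discrete-time spiking network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear response for a discrete-time spiking network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeLR)
```

## The model and its assumptions

`spikeLR` implements a discrete-time stochastic leaky integrate-and-fire
network. The sub-threshold update is

$$V_k(n+1) = \gamma V_k(n)\,(1-\omega_k(n)) + \sum_j W_{kj}\,\omega_j(n)
  + I_0 + S_k(n) + \sigma_B\,\xi_k(n),$$

with i.i.d. standard Gaussian noise $\xi_k(n)$, and the threshold rule
$\omega_k(n) = 1 \iff V_k(n) \ge \theta$, followed by a reset of $V_k$ to
zero. Two modelling commitments deserve a note:

* **Reset semantics.** The reset value is 0 and there is no refractory
  period. This is forced by the integrated form of the dynamics that the
  whole theory is built on: integrating the update from the last reset
  time $\tau_k(n,\omega)$ gives the conditional-mean voltage as a
  geometric sum of inputs *with no reset-value term*, which only holds if
  the reset is to zero. The reset is applied before integration
  (`V(n+1) = γV(n)(1-ω(n)) + ...`), so the input arriving in the spike
  step itself is retained.
* **Noise variance.** The integrated-noise variance is
  $\sigma_k^2 = \sigma_B^2\,(1-\gamma^{2(n-\tau_k)})/(1-\gamma^2)$,
  *including* the $\sigma_B^2$ factor; a Monte-Carlo variance oracle in
  the test-suite pins this down. $\sigma_k$ equals $\sigma_B$ right after
  a spike and saturates at $\sigma_\infty = \sigma_B/\sqrt{1-\gamma^2}$.

Conditioned on the history, spikes are independent across neurons with
probability $\Pi(X_k)$, $X_k = (\theta - \bar V_k)/\sigma_k$, where
$\bar V_k$ is the noise-free conditional mean (synaptic + constant +
stimulus integration from the last reset) and $\Pi$ is the Gaussian upper
tail. This is exact: the noise enters the threshold crossing only through
$\sigma_k$. The log of the one-step probability is the normalized
potential $\phi(n,\omega)$; summed over a block it gives the block's
conditional log-probability, which makes the process a chain with
(unbounded, geometrically fading) memory.

When no spike has occurred yet, integration starts at the history start;
all analyses discard a burn-in of $10\max(\tau_\gamma, D)$ steps so this
boundary convention never reaches an estimate.

## The two response predictors

A weak stimulus switched on at $t_0$ shifts $X_k$ by
$\delta X_k = -V^{(S)}_k/\sigma_k$, linear in the stimulus. Expanding the
potential to first order yields the susceptibility
$$\zeta_k(r-1,\omega) = \frac{\omega_k(r)\,a^{(1)}(X^{sp}_k) +
  (1-\omega_k(r))\,b^{(1)}(X^{sp}_k)}{\sigma_k(r-1,\omega)},$$
with $a^{(1)} = (\log\Pi)'$ and $b^{(1)} = (\log(1-\Pi))'$. $\zeta_k$ is a
*score variable*: its conditional mean given the history vanishes
identically ($\Pi a^{(1)} + (1-\Pi) b^{(1)} = 0$), which is visible in the
estimated kernels as exact zeros of all same-time cross-neuron entries.

The predicted change of an observable $f$ is the stimulus convolved with a
kernel of spontaneous correlations,
$$\delta\mu_f(n) = -\sum_k \sum_{m=1}^{D+1} \sum_{l=0}^{h_k} \gamma^l\,
 K_{km}\, S_k(n-m-l),$$
where the sum over $l$ implements a mean-field replacement of the random
reset time by the mean inter-spike interval: $h_k = \mathrm{round}(1/\nu_k)$,
clipped to $[1, 10D]$ (the clipping and rounding are our choices; any rule
agreeing with $1/\nu_k$ to one step is equivalent within the mean-field
error, and for $\gamma = 0$ the horizon is irrelevant because only $l=0$
contributes).

* `kernel_order1()`: $K_{km} = C^{(sp)}[f(m,\cdot), \zeta_k(0,\cdot)]$.
* `kernel_hc1()`: $K_{km} = C^{(sp)}[f(m,\cdot), \omega_k(0,\cdot)]$ with
  the scalar prefactor $\gamma^{(1)}/\sigma_\infty$,
  $\gamma^{(1)} = a^{(1)}(\theta_L) - b^{(1)}(\theta_L)$,
  $\theta_L = (\theta - I_0/(1-\gamma))/\sigma_\infty$.

The `hc1` constants follow from substituting the degree-one term of the
monomial expansion of $\zeta_k$ at the mean-field operating point
($X^{sp} \to \theta_L$, $\sigma_k \to \sigma_\infty$): then
$\zeta_k \approx [b^{(1)} + \gamma^{(1)}\omega_k]/\sigma_\infty$, and the
constant term drops because centered correlations annihilate constants.
We derived these constants from the substitution itself rather than
transcribing any printed closed form, and validate the predictor against
`predict_order1` in the regime where $\zeta$ is dominated by its
degree-one monomial (for an uncoupled memoryless neuron the two predictors
coincide exactly, which the test-suite asserts to $10^{-12}$).

Both predictors are exactly linear in the stimulus amplitude and exactly
causal (zero before $t_0$); both properties are asserted as identities,
not statistically.

### Kernel estimation conventions

Kernels are estimated on spontaneous ensembles by pooling trials *and*
anchor times (the spontaneous chain is stationary after burn-in);
stimulus-evoked averages pool trials only, because the evoked process is
non-stationary and time averaging is meaningless there. Standard errors
accompany every estimate and are computed across trials (time samples
within a trial are autocorrelated; trials are independent). The anchor
convention aligns column $m = 1$ with the time step of the
susceptibility's spike variable, so $K_{k,1}$ is the synchronous
correlation.

## The exact oracle and the memory truncation

For $N D \le 12$ bits the package builds the exact Markov chain on spike
blocks of depth $D$: a dense $2^{ND} \times 2^{ND}$ transition matrix with
the voltage integration capped at the block start (a neuron silent within
the block is treated as reset at the block's first step). The invariant
vector comes from power iteration to an $L^1$ residual of $10^{-12}$
(capped at $10^6$ iterations); correlations, the spectral gap, exact
response kernels and exact non-stationary propagation under a stimulus are
all computed on this chain. The truncation error of the capped integration
scales like $\gamma^D$ — and vanishes identically for $\gamma = 0$.

That observation fixes the validation design. The reference two-neuron
fixture (`make_fixture("tiny-net")`) uses $\gamma = 0$ with asymmetric
coupling: the chain then has memory depth one, the depth-2 oracle is
*exact*, and the threshold simulator samples *the same law* — so
simulator-vs-oracle comparisons are pure sampling-error tests with honest
$3\sigma$ bands, and the first-order prediction error against the exact
propagation is a clean quadratic in the amplitude (the test-suite checks
an error ratio in $[3,5]$ under amplitude halving, with oracle-exact
kernels so that estimation noise cannot masquerade as nonlinearity). For
$\gamma > 0$ the simulator offers a truncated-memory mode
(`simulate_trial(..., memory = D)`) that samples exactly the depth-$D$
chain via its conditional Bernoulli law, giving an unbiased oracle
comparison with leak; a dedicated test covers it.

## The lattice study and its calibration

The synthetic-data generator reproduces the study conditions of the
package's headline experiment: $N = 30$ neurons on a chain with
nearest-neighbour excitation $w_+ = 0.2$ and second-neighbour inhibition
of magnitude $w_- = 2$ (the builder takes magnitudes and applies the
inhibitory sign; null boundaries; symmetric, bandwidth-2 matrix),
$\theta = 1$, $\gamma = 0.6$ (decay time $\tau_\gamma \approx 2$ steps),
response depth $D = 10$, lattice spacing $dx = 1$ mm, time bin $b = 10$
ms, and a Gaussian pulse of width $\Delta = 1$ mm travelling left to
right. Parameters that the study design leaves open were fixed once, as
follows:

* **$I_0$ and $\sigma_B$.** The baseline input is calibrated by solving
  $\Pi((\theta - I_0/(1-\gamma))/\sigma_\infty) = \nu_{target}$
  (single-neuron mean field; `calibrate_baseline_input()`). We set
  $\sigma_B = 1$ — noise comparable to threshold — and a target rate of
  0.3/step. The noise scale matters qualitatively: with weak noise the
  $w_- = 2$ inhibition is a multi-$\sigma$ kick that makes joint spikes of
  mutually inhibiting neurons essentially impossible, degenerating the
  delayed-pairwise observable; with $\sigma_B = 1$ the inhibition strongly
  modulates (realized mean rate ≈ 0.11/step, i.e. ~11 Hz at the 10 ms
  bin) without silencing it.
* **Pulse speed and window.** Only $v b / dx$ matters on the grid. At the
  reduced window $T = 200$ steps we use $v = 16$ mm/s so the pulse
  traverses the full 30 mm lattice within the window (2 mm/s would cover
  4 mm); the pulse clock starts at onset with the centre at the left edge
  ($x_{start} = 0$, configurable).
* **Amplitude sweep.** `c(0.5, 1, 1.5, 2)`, linearly spaced. The lower end
  is the smallest amplitude whose prediction error is resolvable above
  the CLT noise floor of the $d^2$ statistic at $M = 2000$ trials; the
  upper end is where the second-order validity diagnostic (the fraction
  of points violating the smallness condition on $\delta X$ at slack 0.1)
  reaches ≈ 15%. Beyond that the empirical response saturates (rates
  cannot exceed 1) and the ranking of two linear predictors stops being
  informative about the first-order theory.
* **Run sizes.** Reduced scale `M = 2000`, `T = 200` by default (the full
  `M = 10000` is a flag). These sizes keep the complete sweep at about
  two minutes on one CPU and are stated here as the package's reference
  problem size.

What the generator does *not* emulate: real recordings have refractory
periods, adaptation, non-Gaussian and correlated noise, unknown and
non-lattice connectivity, and no access to the true potential. Passing
tests therefore demonstrate the internal consistency and correctness of
the estimators and predictors under the model's own law — not that the
first-order theory describes any particular biological preparation.

## Numerical choices

* $\Pi$, $\log\Pi$ and $\log(1-\Pi)$ use `pnorm` in log space, with a
  floor of $10^{-300}$ on probabilities before taking logs, so the
  potential stays finite in saturated corners; the saturation band
  $\Pi \notin [\epsilon, 1-\epsilon]$ is reported by
  `validity_diagnostics()` (default $\epsilon = 0.01$) rather than
  silently enforced.
* $a^{(1)}, b^{(1)}$ (and second derivatives, used by the validity bound)
  are evaluated from the Gaussian hazard and Mills ratio in log space —
  no cancellation-prone $\Pi'$ quotient.
* Monomial indices use the bit layout $(i-1) + N\,\tau$ for neuron $i$ at
  lag $\tau$; the Hammersley–Clifford coefficients come from an in-place
  Möbius transform over the Boolean lattice, exact for $NR \le 24$ bits.
* Per-trial seeds are `master_seed + (0, 1, ..., M-1)`; every public
  entry point that simulates takes an explicit seed, and identical
  configurations reproduce bit-identical rasters and CSVs.
* Silent neurons get the horizon cap and a warning instead of an error:
  a kernel built from a silent ensemble is still well-defined (zero
  columns).
* The trial inner loop is compiled (Rcpp) but draws from R's RNG, so
  seeding semantics are identical to a pure-R implementation.

## Known limitations

* The oracle is dense: $ND \le 12$ bits by default. It is a validation
  instrument, not a production path.
* `predict_hc1`'s mean-field constants ignore the synaptic contribution
  to the operating point; in strongly coupled regimes the `order1` kernel
  is the reference method, and the experiments report both.
* Second- and higher-order response terms are out of scope; the validity
  diagnostics quantify, but do not correct, departures from linearity.
* The continuous-time limit, refractory periods, electric synapses and
  adaptive thresholds are not modelled.
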