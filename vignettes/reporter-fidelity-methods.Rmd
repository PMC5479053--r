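---
title: "Models and methods behind reporterfidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind reporterfidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reporterfidelity)
```

Fluorescent reporter cell lines are the workhorse for observing protein
dynamics in single live cells, but a reporter is only useful if its signal is
representative of the protein it stands in for — in the very cell being
observed. `reporterfidelity` implements a quantitative framework for asking
when that assumption holds and when the genetic intervention that created the
reporter line qualitatively changes the dynamics it was meant to measure. The
motivating system is Nanog in mouse embryonic stem cells, whose reported
heterogeneity has differed conspicuously across reporter architectures.

The package has three mathematical layers and a data layer:

1. stochastic models of two alleles sharing an upstream regulator
   (when can one allele report on the other?);
2. a deterministic positive-feedback circuit whose bistability can be created
   or destroyed by the reporter insertion (when does the reporter perturb the
   system?);
3. the flow-cytometry statistics used to read modality and dependence out of
   per-cell data (how do we measure either effect?);
4. seeded synthetic-data generators that emulate the experimental designs and
   provide ground truth for every statistical claim the package tests.

## Allele coupling under shared regulation

Two alleles transcribed as independent linear birth–death processes with
rates $k_b^{(i)}$, $k_d^{(i)}$ have a stationary joint law that is a product
of Poissons with means $\lambda_i = k_b^{(i)}/k_d^{(i)}$
(`poisson_joint_pmf()`). Making both birth rates proportional to a shared
regulator concentration $x \sim \rho(x)$ couples them: conditional on $x$ the
counts are independent Poisson with means $\lambda_i x$, and the stationary
joint law is the $\rho$-mixture of those conditionals. For a
Gamma$(r,\theta)$ regulator the mixture is the bivariate negative binomial

$$p(m_1, m_2) = \frac{\Gamma(m_1+m_2+r)}{m_1!\,m_2!\,\Gamma(r)}
  (1-p-q)^r\, p^{m_1} q^{m_2}, \qquad
  p = \frac{\lambda_1\theta}{1+\theta(\lambda_1+\lambda_2)},\;
  q = \frac{\lambda_2}{\lambda_1}\,p,$$

implemented in log space via log-gamma (`bnb_joint_pmf()`), with the
truncated support for normalization checks taken at the marginal mean plus
twelve standard deviations. Two moments summarize coupling for *any*
regulator law: $\mathrm{Cov}(m_1,m_2) = \lambda_1\lambda_2\,\mathrm{Var}(x)$
(`joint_covariance()`), and for identical alleles the correlation
$\lambda F/(1+\lambda F)$ with $F$ the regulator Fano factor
(`allelic_correlation()`). Extrinsic noise upstream therefore *synchronizes*
the alleles and improves single-cell reporter accuracy — a counterintuitive
but robust consequence of the model.

Transcriptional bursting pulls the other way. With each allele switching
independently between effective transcription levels $\lambda_+$ and
$\lambda_-$, spending a fraction $w$ of the time active, the slow-switching
covariance is
$\left(w\lambda_+ + (1-w)\lambda_-\right)^2 \mathrm{Var}(x)$
(`bursty_covariance()`), always below the constitutive value at
$\lambda_+$: intrinsic noise decorrelates alleles. The regime is validated by
an exact Gillespie simulation of the two-allele telegraph system
(`simulate_telegraph_ssa()`, compiled in C++). The regulator is drawn once
per replicate ("quenched" extrinsic noise), matching the stationary-mixture
derivation; a piecewise-constant refresh exists but defaults off. The tests
place the switching rates a factor of 100 below the decay rate when checking
the slow-switching formula; that separation is a package choice — the theory
states the regime only qualitatively — and 10% agreement is required there.

## The positive-feedback circuit and reporter-induced rescaling

Total protein $n$ produced from two alleles with basal rate $c_b$,
feedback-activated rate saturating at $c_f$ (Hill coefficient $H$,
half-maximum $K$) and decay $c_d$ obeys, after rescaling concentration by
$2c_f/c_d$ and time by $1/c_d$,

$$\frac{d\bar n}{d\tau} = \alpha + \frac{\bar n^H}{\gamma^H + \bar n^H}
 - \bar n, \qquad \alpha = \frac{c_b}{c_f},\quad
 \gamma_{\mathrm{wt}} = \frac{c_d K}{2 c_f}.$$

$\gamma$ measures decay against maximal feedback; small $\gamma$ means strong
feedback. For $H > 1$ the equation is bistable inside a wedge of the
$(\alpha,\gamma)$ plane bounded by two saddle-node curves.

The central observation is that every common reporter architecture rescales
$\gamma$ while leaving $\alpha$ unchanged, because it alters total functional
production by a design-specific factor (`gamma_factor()`):
knock-in $\to 2$; $m$-insert pre/post with transcription factor
$\epsilon_m \to 2/(1+\epsilon_m)$; fusion with transcription factor
$\epsilon$ and feedback efficacy $\delta \to 2/(1+\epsilon\delta)$;
BAC $\to 1$. Wherever the map $\gamma \mapsto g\gamma$ crosses a fold curve,
the reporter line sits in a different dynamical regime than the wild type —
bimodal where the wild type is unimodal or vice versa. `risk_map()` charts
those regions; dual-allele variants of the pre/post and fusion designs are
exposed (factors $1/\epsilon$ and $1/(\epsilon\delta)$, obtained by the same
production-sum argument) but flagged as extrapolated. How $\epsilon_m$ falls
with insert count is accepted as user input, since no canonical schedule
exists.

### Numerical choices

Equilibria are found by sign-change bracketing on $[0, \alpha+1]$ (the
right-hand side is $\alpha \ge 0$ at the origin and strictly negative beyond
$\alpha + 1$, so the bracket is provably complete) with step $10^{-3}$ and
`uniroot` polishing to $10^{-12}$; a root is stable iff $f' < -10^{-9}$ and
near-zero derivatives raise a degenerate flag rather than a classification.
The fold locus is computed **parametrically**: writing $s = \gamma^H$, the
condition $f = f' = 0$ reduces to a quadratic in $s$ per equilibrium level,
swept over the admissible level range $(0, H/4]$. We deliberately do not
transcribe any closed-form two-branch expression for the curves: the
parametric construction is self-validating (each emitted point satisfies
$f = f' = 0$ to $10^{-8}$, which the tests check) and the cusp follows by
maximizing $\alpha$ along the locus ($\alpha = 1/8$,
$\gamma = 3\sqrt{3}/8$ at $H = 2$, reproduced to $10^{-6}$). Time
integration uses `lsoda` at relative tolerance $10^{-8}$; a steady state is
declared when the derivative norm drops below $10^{-10}$. The reporter obeys
the slaved equation with its own decay rate; matched half-lives give equal
steady states, and a reporter decaying at $c_d/2$ settles at exactly twice
the protein level — both used as integrator checks.

## Flow-cytometry statistics

The pipeline mirrors standard quantitative cytometry practice:

* **MESF calibration** (`mesf_calibrate()`): least-squares fit of
  $\log_{10}$MESF on $\log_{10}$ intensity through the bead populations;
  the fitted line converts arbitrary units into absolute fluorophore
  equivalents. With beads generated as intensity $= g\cdot$MESF, the
  recovered slope is 1 and the intercept $-\log_{10} g$ under this fit
  direction.
* **Alignment** (`align_first_percentile()`): per day and channel, a single
  additive shift in log space matching each day's 1st percentile to the
  reference day's. A shift (not a scale) is used because it preserves
  distribution shape, which is the point of inter-day comparability; the
  operation is idempotent.
* **Mixture modality** (`fit_gmm()`, `select_model_bic()`,
  `bimodality_filter()`): EM fits with one or two Gaussian components on the
  log-transformed, aligned intensities. The log scale is chosen for
  consistency with the MI preprocessing and with cytometry practice; the
  one-component fit is closed-form moment matching. Initialization places
  component means at the 25th/75th percentiles with nine randomly jittered
  restarts, convergence at a log-likelihood gain below $10^{-8}$, and a
  variance floor of $10^{-6}$ times the data variance. BIC uses
  $-2\ell + p\ln n$ with $p = 2$ and $5$; ties go to the simpler model. A
  two-component fit is called robustly bimodal only if both weights exceed
  0.1 and each component's weighted peak exceeds the other component's
  weighted density at that peak. The peak comparison is evaluated at the
  component means — the only canonical evaluation point; note that for equal
  weights and equal variances the criterion cannot reject, so the weight
  rule and BIC carry the burden in that corner of parameter space.
* **Dependence** (`bayesian_blocks()`, `mi_shrinkage()`): each channel is
  discretized separately by Bayesian blocks — dynamic programming over the
  point-measure fitness $N(\log N - \log T)$ with the change-point prior
  calibrated to a false-alarm rate $p_0 = 0.05$ (no canonical $p_0$ exists
  for this application; 0.05 is the standard empirical calibration, and the
  tests verify that homogeneous samples stay unsegmented in $\ge 18/20$
  seeds). Mutual information in nats is then computed from the joint
  contingency table after James–Stein shrinkage of the cell frequencies
  toward the uniform distribution over occupied cells, with the closed-form
  optimal intensity clipped to $[0,1]$. Shrinkage biases the estimate toward
  independence, which is the conservative direction for claiming
  association. Discretization is per-day (margins are re-derived for every
  time point), so cross-day MI comparisons share the method, not the bins.

## Synthetic data and what passing tests do (and do not) show

No public single-cell dataset accompanies the motivating experiments, so the
package generates its own inputs with known ground truth:

* `generate_population()` integrates the feedback circuit and its reporter
  readout as an SDE (Euler–Maruyama, step $10^{-2}$ of the decay time,
  burn-in of 20 decay times, additive noise with a reflecting boundary at
  zero) and maps endpoints to intensities through
  $(\text{gain}\cdot\text{value} + \text{autofluorescence})
  \times e^{\sigma_m Z}$ — multiplicative lognormal measurement noise over
  an additive autofluorescence floor, the minimal model producing
  cytometry-like spreads.
* `generate_mixture_sample()` and `generate_timecourse()` provide direct
  mixture-model control (two channels, within-component correlation,
  exponentially decaying high-state weight over the default day schedule
  0, 1, 2, 3, 5, 7).
* `generate_beads()` provides power-law bead sets for the calibration.

Defaults are artifact choices, stated here rather than inferred from data:
dynamical noise $\sigma = 0.005$ keeps stationary fluctuations well inside
each basin of attraction and away from the reflecting boundary for the
canonical parameter sets (equilibria down to a few hundredths of a
concentration unit), so that population modality reflects the phase portrait
rather than boundary pile-up; measurement noise $\sigma_m = 0.25$ (natural
log) dominates the residual dynamical spread on the log scale, keeping each
state's intensity distribution close to lognormal — without this, the
log-transform of a fluctuating state is detectably skewed and a
two-component fit wins BIC on any unimodal population of $10^4$ cells.
Cells start at the deterministic stable equilibria with equal occupancy
(`init = "equilibria"`), emulating long-run coexistence of subpopulations
without simulating rare barrier crossings; uniform initial conditions are
available as an option. These choices make mono/bistable verdicts
statistically separable, which is exactly what they are for.

What passing tests show: that the *pipeline* distinguishes bistable from
monostable dynamics at realistic sample sizes and noise levels, that the
estimators are calibrated on data satisfying their assumptions, and that the
analytic layers agree with brute-force stochastic and numerical oracles.
What they do not show: anything about instrument-specific artifacts
(spillover, doublets, gating), about measurement models other than
lognormal-over-floor, or about dynamical noise strong enough to mix basins
on the experimental timescale — real data can fail these assumptions in ways
the generators do not emulate.

## Problem sizes

The default study sizes keep every analysis on a laptop scale: $10^5$ draws
for sampler-versus-moment checks, $10^5$ Gillespie replicates for the
slow-switching covariance, a $100 \times 100$ grid for the classification
cross-check, 20 seeds for the MI-ordering property, and 50 replicate
populations of $10^4$ cells for the modality study. These sizes were chosen
so that Monte-Carlo standard errors sit comfortably inside the tolerances
being asserted.

## Known limitations

* The two-allele count model is at mRNA level; protein-level extensions and
  fully doubly-stochastic analytic solutions are out of scope.
* The deterministic classification ignores noise-induced transitions; near
  the fold curves, finite noise blurs the sharp mono/bistable boundary.
* Dual-allele design factors are extrapolated from the production-sum
  argument, not derived independently, and are flagged accordingly.
* FCS binary parsing is intentionally absent: CSV event tables are the
  canonical interchange format here.
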