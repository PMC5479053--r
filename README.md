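# reporterfidelity

Quantitative tools for asking whether a fluorescent reporter faithfully
represents the protein it monitors in single cells — and whether inserting
the reporter construct perturbs the very dynamics it was built to observe.
The motivating case is Nanog in mouse embryonic stem cells, where different
reporter architectures (heterozygous knock-in, 2A/IRES pre/post insertions,
fusions, BAC transgenes) have reported conspicuously different expression
heterogeneity.

The package is aimed at quantitative cell biologists and modelers designing
or interpreting reporter experiments for genes under feedback regulation.

## What it computes

**Allele coupling.** For two alleles driven by a shared upstream regulator
$x$, conditional on $x$ the transcript counts are independent Poisson with
means $\lambda_i x$; for Gamma-distributed $x$ the stationary joint law is a
bivariate negative binomial, and for *any* regulator law

$$\mathrm{Cov}(m_1, m_2) = \lambda_1 \lambda_2 \mathrm{Var}(x), \qquad
\mathrm{Cor}(m_1, m_2) = \frac{\lambda F}{1 + \lambda F}
\;\; (\text{identical alleles},\; F = \mathrm{Var}(x)/\mathbb{E}x).$$

Extrinsic regulator noise synchronizes alleles (improving reporter
accuracy); transcriptional bursting decorrelates them, with slow-switching
covariance $(w\lambda_+ + (1-w)\lambda_-)^2\mathrm{Var}(x)$, validated
against an exact Gillespie simulation.

**Reporter perturbation of feedback.** Total protein from a positive-feedback
circuit reduces to $d\bar n/d\tau = \alpha + \bar n^H/(\gamma^H + \bar n^H) -
\bar n$ with $\alpha = c_b/c_f$, $\gamma_{\rm wt} = c_d K / 2 c_f$. Reporter
designs multiply $\gamma$ by a design factor (knock-in: 2; pre/post:
$2/(1+\epsilon_m)$; fusion: $2/(1+\epsilon\delta)$; BAC: 1). The package
computes equilibria, saddle-node bifurcation curves, and maps of the
$(\alpha,\gamma)$ regions where introducing the reporter flips the system
between monostable and bistable — i.e., where the reporter line's expression
pattern is *not* representative of the wild type.

**Flow statistics.** MESF bead calibration, first-percentile alignment,
Gaussian-mixture fits with BIC selection and robust-bimodality criteria
(weights > 0.1 plus weighted peak dominance), and James–Stein shrinkage
mutual information over Bayesian-blocks discretization.

**Synthetic data.** Seeded generators for SDE-derived cell populations with
known mono/bistability, two-channel mixture samples, differentiation
time-courses (days 0, 1, 2, 3, 5, 7), and calibration beads.

## Worked example

```r
library(reporterfidelity)

# Is this parameter regime at risk under a knock-in reporter?
fp <- feedback_params(c_b = 0.02, c_f = 1, c_d = 1, K = 0.7, H = 2)
nondimensionalize(fp)$gamma
#> [1] 0.35
nondimensionalize(fp, reporter_design("knock_in"))$gamma
#> [1] 0.7
classify_dynamics(dimensionless_params(0.02, 0.35))
#> [1] "bistable"
classify_dynamics(dimensionless_params(0.02, 0.7))
#> [1] "monostable"
```

The wild type is bistable (heterogeneous expression with noise) but the
knock-in line, with $\gamma$ doubled to 0.7 — beyond the fold at this
$\alpha$ — is monostable: the reporter destroys the very heterogeneity it
was meant to measure. Simulating cell populations and running the statistics
pipeline reproduces this at the data level:

```r
pop_wt <- generate_population(population_spec(fp, n_cells = 10000, seed = 1))
pop_ki <- generate_population(population_spec(fp, reporter_design("knock_in"),
                                              n_cells = 10000, seed = 2))
fit2 <- fit_gmm(log10(pop_wt$nanog), k = 2, seed = 1)
fit1 <- fit_gmm(log10(pop_wt$nanog), k = 1, seed = 1)
select_model_bic(fit1, fit2)$k
#> [1] 2
bimodality_filter(fit2)$bimodal
#> [1] TRUE
glance(fit_gmm(log10(pop_ki$nanog), k = 1, seed = 1))$bic <
  glance(fit_gmm(log10(pop_ki$nanog), k = 2, seed = 1))$bic
#> [1] TRUE
```

And the allele-coupling layer, at the sample sizes of a typical figure:

```r
m <- joint_count_model(allele_kinetics(50, 1),
                       regulator("gamma", shape = 2, scale = 0.5))
joint_covariance(m); allelic_correlation(m)
#> [1] 1250
#> [1] 0.9615385
d <- sample_joint_counts(m, 1000, seed = 1)
mi_shrinkage(d$m1, d$m2)$value
#> [1] 0.6840172
```

Study-level runners (`run_risk_scan()`, `run_coexpression_study()`,
`run_timecourse_study()`, `run_flow_analysis()`) wire these layers together
from YAML configurations and write CSV/JSON reports; a thin CLI wrapper
lives at `inst/cli/reporter-pipeline.R`.

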