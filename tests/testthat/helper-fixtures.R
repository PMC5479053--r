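# Independent oracles and shared fixtures.

# Adaptive-quadrature oracle for the Gamma-mixture joint count distribution:
# integrates the conditionally-Poisson integrand against the gamma density,
# independently of the closed-form path under test.
bnb_quadrature <- function(r, theta, lam1, lam2, m1, m2) {
  integrand <- function(x) {
    exp(m1 * log(lam1 * x) - lam1 * x - lgamma(m1 + 1) +
        m2 * log(lam2 * x) - lam2 * x - lgamma(m2 + 1) +
        stats::dgamma(x, shape = r, scale = theta, log = TRUE))
  }
  stats::integrate(integrand, 0, Inf, rel.tol = 1e-12, abs.tol = 0)$value
}

# Dense sign-scan root counter for the dimensionless feedback equation;
# brute-force oracle independent of equilibria()'s bracketing/polishing.
sign_scan_classification <- function(alpha, gamma, H = 2, n_grid = 4001) {
  n <- seq(0, alpha + 1, length.out = n_grid)
  f <- alpha + n^H / (gamma^H + n^H) - n
  sgn <- sign(f)
  crossings <- sum(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- crossings + (abs(f[1]) < 1e-14)
  # alternating stability: outermost roots stable, so >= 3 roots => 2 stable
  if (roots >= 3) "bistable" else "monostable"
}

# Canonical bistable wild-type parameters: alpha = 0.02, gamma_wt = 0.35
# (doubling gamma lands in the monostable region).
canonical_feedback <- function() feedback_params(c_b = 0.02, c_f = 1, c_d = 1, K = 0.7, H = 2)

# Full modality pipeline on one population's channel: log10 transform,
# 1- vs 2-component EM fits, BIC selection, robust-bimodality criteria.
modality_verdict <- function(values, seed = 1L) {
  ln <- log10(values[values > 0])
  f1 <- fit_gmm(ln, 1, seed = seed)
  f2 <- fit_gmm(ln, 2, seed = seed)
  sel <- select_model_bic(f1, f2)
  if (sel$k == 2) bimodality_filter(f2)$bimodal else FALSE
}
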