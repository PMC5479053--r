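#' Kinetic rates for a pair of alleles
#'
#' Bundles the birth (transcription) and decay rates of the two allelic copies
#' of a gene, each modelled as a linear birth-death process. The derived
#' quantity `lambda[i] = birth_rate[i] / decay_rate[i]` is the stationary mean
#' transcript count of allele `i` when the upstream regulator is held at 1.
#'
#' @param birth_rate_1,birth_rate_2 Transcription rates (per unit time) of
#'   alleles 1 and 2. Allele 2 defaults to the same rates as allele 1
#'   (kinetically identical alleles).
#' @param decay_rate_1,decay_rate_2 mRNA decay rates (per unit time).
#'
#' @return An object of class `allele_kinetics` with elements `birth_rate`,
#'   `decay_rate` and `lambda` (each length 2).
#' @examples
#' ak <- allele_kinetics(birth_rate_1 = 50, decay_rate_1 = 1)
#' ak$lambda
#' @export
allele_kinetics <- function(birth_rate_1, decay_rate_1,
                            birth_rate_2 = birth_rate_1,
                            decay_rate_2 = decay_rate_1) {
  rates <- c(birth_rate_1, decay_rate_1, birth_rate_2, decay_rate_2)
  if (!all(is.finite(rates)) || any(rates <= 0)) {
    stop("all allele birth and decay rates must be finite and > 0", call. = FALSE)
  }
  structure(
    list(
      birth_rate = c(birth_rate_1, birth_rate_2),
      decay_rate = c(decay_rate_1, decay_rate_2),
      lambda = c(birth_rate_1 / decay_rate_1, birth_rate_2 / decay_rate_2)
    ),
    class = "allele_kinetics"
  )
}

#' Distribution of the shared upstream regulator
#'
#' Describes the stationary law of the concentration `x` of the regulator that
#' drives transcription from both alleles. Supported families: `constant`
#' (no extrinsic noise), `gamma` (shape--scale parameterization, the usual
#' model for protein concentrations), `gumbel` (location--scale), and
#' `empirical` (resampling from a supplied vector).
#'
#' @param family One of `"constant"`, `"gamma"`, `"gumbel"`, `"empirical"`.
#' @param value Concentration for the constant family.
#' @param shape,scale Shape `r` and scale `theta` of the gamma family
#'   (mean `r*theta`, variance `r*theta^2`); `scale` doubles as the Gumbel
#'   scale parameter.
#' @param location Gumbel location parameter.
#' @param samples Numeric vector for the empirical family.
#'
#' @return An object of class `regulator` with fields `family`, `params`,
#'   `mean` and `var`.
#' @examples
#' regulator("gamma", shape = 2, scale = 0.5)
#' @export
regulator <- function(family = c("constant", "gamma", "gumbel", "empirical"),
                      value = 1, shape = NULL, scale = NULL,
                      location = NULL, samples = NULL) {
  family <- match.arg(family)
  euler_gamma <- 0.57721566490153286
  out <- switch(family,
    constant = {
      if (!is.finite(value) || value < 0) stop("constant regulator needs a finite value >= 0", call. = FALSE)
      list(params = list(value = value), mean = value, var = 0)
    },
    gamma = {
      if (is.null(shape) || is.null(scale) || shape <= 0 || scale <= 0) {
        stop("gamma regulator needs shape > 0 and scale > 0", call. = FALSE)
      }
      list(params = list(shape = shape, scale = scale),
           mean = shape * scale, var = shape * scale^2)
    },
    gumbel = {
      if (is.null(location) || is.null(scale) || scale <= 0) {
        stop("gumbel regulator needs a location and scale > 0", call. = FALSE)
      }
      list(params = list(location = location, scale = scale),
           mean = location + scale * euler_gamma,
           var = pi^2 * scale^2 / 6)
    },
    empirical = {
      if (is.null(samples) || length(samples) == 0 || !all(is.finite(samples))) {
        stop("empirical regulator needs a non-empty vector of finite samples", call. = FALSE)
      }
      list(params = list(samples = as.numeric(samples)),
           mean = mean(samples), var = stats::var(samples))
    }
  )
  if (family != "constant" && out$var <= 0) {
    stop("non-constant regulator families must have positive variance", call. = FALSE)
  }
  structure(c(list(family = family), out), class = "regulator")
}

#' @rdname regulator
#' @param reg A `regulator` object.
#' @param n Number of draws.
#' @export
sample_regulator <- function(reg, n) {
  stopifnot(inherits(reg, "regulator"))
  x <- switch(reg$family,
    constant = rep(reg$params$value, n),
    gamma = stats::rgamma(n, shape = reg$params$shape, scale = reg$params$scale),
    gumbel = reg$params$location - reg$params$scale * log(-log(stats::runif(n))),
    empirical = sample(reg$params$samples, n, replace = TRUE)
  )
  if (any(x < 0)) {
    stop("regulator draws produced negative concentrations; ",
         "use a family/parameterization with nonnegative support", call. = FALSE)
  }
  x
}

#' Two-state (telegraph) transcription kinetics
#'
#' Bursting parameters for an allele that switches between an active state
#' transcribing at effective level `rate_active` and an inactive state at
#' `rate_inactive` (both on the same dimensionless scale as `lambda` in
#' [allele_kinetics()]). The active fraction `w` is the long-run proportion of
#' time spent active; when the switching rates are supplied it equals
#' `switch_on / (switch_on + switch_off)`.
#'
#' @param rate_active,rate_inactive Effective transcription levels
#'   (`rate_active >= rate_inactive >= 0`).
#' @param active_fraction Proportion of time active, in \[0, 1\]. Derived from
#'   the switching rates when those are given.
#' @param switch_on,switch_off Switching rates (per unit time) from inactive to
#'   active and back; required by [simulate_telegraph_ssa()].
#' @return An object of class `burst_kinetics`.
#' @export
burst_kinetics <- function(rate_active, rate_inactive = 0,
                           active_fraction = NULL,
                           switch_on = NULL, switch_off = NULL) {
  if (rate_active < rate_inactive || rate_inactive < 0) {
    stop("need rate_active >= rate_inactive >= 0", call. = FALSE)
  }
  if (!is.null(switch_on) || !is.null(switch_off)) {
    if (is.null(switch_on) || is.null(switch_off) || switch_on < 0 || switch_off < 0 ||
        switch_on + switch_off == 0) {
      stop("switch_on and switch_off must both be supplied and nonnegative", call. = FALSE)
    }
    w <- switch_on / (switch_on + switch_off)
    if (!is.null(active_fraction) && abs(active_fraction - w) > 1e-8) {
      stop("active_fraction is inconsistent with switch_on/(switch_on+switch_off)", call. = FALSE)
    }
    active_fraction <- w
  }
  if (is.null(active_fraction) || active_fraction < 0 || active_fraction > 1) {
    stop("active_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(active_fraction = active_fraction,
         rate_active = rate_active, rate_inactive = rate_inactive,
         switch_on = switch_on, switch_off = switch_off),
    class = "burst_kinetics"
  )
}

#' Joint model for the transcript counts of two coregulated alleles
#'
#' Couples a pair of alleles ([allele_kinetics()]) through a shared upstream
#' regulator ([regulator()]): conditional on the regulator concentration `x`,
#' the counts are independent Poisson with means `lambda[i] * x`. For a
#' gamma-distributed regulator the stationary joint law is the bivariate
#' negative binomial with mixture parameters
#' `p = lambda1*theta / (1 + theta*(lambda1 + lambda2))`, `q = a*p`,
#' `a = lambda2/lambda1`, which are derived here.
#'
#' @param kinetics An [allele_kinetics()] object.
#' @param reg A [regulator()] object.
#' @param bursting Optional [burst_kinetics()]; when present, samplers draw a
#'   transcriptional state per allele (slow-switching stationary regime).
#' @return An object of class `joint_count_model`.
#' @examples
#' m <- joint_count_model(allele_kinetics(50, 1), regulator("gamma", shape = 2, scale = 0.5))
#' m$p
#' @export
joint_count_model <- function(kinetics, reg, bursting = NULL) {
  stopifnot(inherits(kinetics, "allele_kinetics"), inherits(reg, "regulator"))
  if (!is.null(bursting)) stopifnot(inherits(bursting, "burst_kinetics"))
  lam <- kinetics$lambda
  p <- q <- NA_real_
  if (reg$family == "gamma") {
    theta <- reg$params$scale
    p <- lam[1] * theta / (1 + theta * (lam[1] + lam[2]))
    q <- lam[2] * theta / (1 + theta * (lam[1] + lam[2]))
    stopifnot(p >= 0, q >= 0, p + q < 1)
  }
  structure(
    list(kinetics = kinetics, regulator = reg, bursting = bursting,
         p = p, q = q, a = lam[2] / lam[1]),
    class = "joint_count_model"
  )
}

check_counts <- function(m) {
  if (any(!is.finite(m)) || any(m < 0) || any(abs(m - round(m)) > 1e-8)) {
    stop("transcript counts must be nonnegative integers", call. = FALSE)
  }
  round(m)
}

#' Joint PMF of two independent constitutive alleles
#'
#' Stationary joint probability of observing `m1` and `m2` transcripts from
#' two uncoupled alleles (constant regulator absorbed into the rates): the
#' product of two Poisson laws with means `lambda1` and `lambda2`. Computed in
#' log space.
#'
#' @param kinetics An [allele_kinetics()] object.
#' @param m1,m2 Nonnegative integer counts (vectorized, recycled).
#' @return Probabilities, same length as the recycled counts.
#' @examples
#' poisson_joint_pmf(allele_kinetics(1, 1), 0, 0) # exp(-2)
#' @export
poisson_joint_pmf <- function(kinetics, m1, m2) {
  stopifnot(inherits(kinetics, "allele_kinetics"))
  m1 <- check_counts(m1); m2 <- check_counts(m2)
  lam <- kinetics$lambda
  exp(m1 * log(lam[1]) - lam[1] - lgamma(m1 + 1) +
      m2 * log(lam[2]) - lam[2] - lgamma(m2 + 1))
}

#' Bivariate negative binomial joint PMF
#'
#' Stationary joint probability of the transcript counts of two alleles driven
#' by a shared Gamma(`r`, `theta`) regulator:
#' `Gamma(m1+m2+r) / (m1! m2! Gamma(r)) * (1-p-q)^r * p^m1 * q^m2`,
#' evaluated via log-gamma. This is the Gamma mixture of conditionally
#' independent Poisson laws; the marginals are negative binomial.
#'
#' @param model A [joint_count_model()] whose regulator family is `"gamma"`.
#' @param m1,m2 Nonnegative integer counts (vectorized, recycled).
#' @return Probabilities.
#' @export
bnb_joint_pmf <- function(model, m1, m2) {
  stopifnot(inherits(model, "joint_count_model"))
  if (model$regulator$family != "gamma") {
    stop("bnb_joint_pmf requires a gamma-distributed regulator", call. = FALSE)
  }
  m1 <- check_counts(m1); m2 <- check_counts(m2)
  r <- model$regulator$params$shape
  p <- model$p; q <- model$q
  exp(lgamma(m1 + m2 + r) - lgamma(m1 + 1) - lgamma(m2 + 1) - lgamma(r) +
      r * log1p(-p - q) + m1 * log(p) + m2 * log(q))
}

#' Covariance between the outputs of two coregulated alleles
#'
#' Stationary covariance `Cov(m1, m2) = lambda1 * lambda2 * Var(x)`: allele
#' outputs covary in proportion to the variance of the shared upstream
#' regulator, for any regulator distribution. A constant regulator gives 0.
#'
#' @param model A [joint_count_model()].
#' @return The covariance (squared counts).
#' @export
joint_covariance <- function(model) {
  stopifnot(inherits(model, "joint_count_model"))
  prod(model$kinetics$lambda) * model$regulator$var
}

#' Correlation between the outputs of two coregulated alleles
#'
#' Uses `Var(m_i) = lambda_i * E(x) + lambda_i^2 * Var(x)` (Poisson noise plus
#' regulator-driven extrinsic variance). For kinetically identical alleles the
#' correlation reduces to `lambda*F / (1 + lambda*F)` where
#' `F = Var(x)/E(x)` is the regulator's Fano factor, so allelic coordination
#' increases monotonically with upstream dispersion.
#'
#' @param model A [joint_count_model()].
#' @return The correlation, in \[0, 1).
#' @export
allelic_correlation <- function(model) {
  stopifnot(inherits(model, "joint_count_model"))
  lam <- model$kinetics$lambda
  mu <- model$regulator$mean; v <- model$regulator$var
  vm <- lam * mu + lam^2 * v
  if (any(vm <= 0)) stop("correlation undefined: an allele has zero output variance", call. = FALSE)
  prod(lam) * v / sqrt(prod(vm))
}

#' Covariance between bursty alleles sharing a regulator
#'
#' In the slow-switching regime (state switching much slower than mRNA decay),
#' each allele's effective transcription level is `rate_active` with
#' probability `w` and `rate_inactive` otherwise, independently of the other
#' allele, and
#' `Cov(m1, m2) = (w*rate_active + (1-w)*rate_inactive)^2 * Var(x)`.
#' Since the mean level is below `rate_active`, transcriptional bursting can
#' only reduce inter-allele covariance relative to constitutive expression at
#' `rate_active`. The slow-switching regime is a documented contract, not
#' enforced.
#'
#' @param bursting A [burst_kinetics()] object.
#' @param reg A [regulator()] object.
#' @return The covariance.
#' @export
bursty_covariance <- function(bursting, reg) {
  stopifnot(inherits(bursting, "burst_kinetics"), inherits(reg, "regulator"))
  w <- bursting$active_fraction
  (w * bursting$rate_active + (1 - w) * bursting$rate_inactive)^2 * reg$var
}

#' Sample stationary transcript-count pairs
#'
#' Exact stationary sampling by compounding: draw the regulator concentration
#' `x` per cell, then conditionally independent Poisson counts with means
#' `lambda_i * x`. If the model carries [burst_kinetics()], each allele
#' additionally draws an independent transcriptional state (active with
#' probability `w`) and transcribes at the corresponding effective level, the
#' stationary law of the slow-switching regime.
#'
#' @param model A [joint_count_model()].
#' @param n Number of cells (>= 1).
#' @param seed Integer seed; sampling is reproducible and leaves the global
#'   RNG state untouched.
#' @return A tibble with columns `replicate`, `m1`, `m2`, `x`.
#' @examples
#' m <- joint_count_model(allele_kinetics(50, 1), regulator("gamma", shape = 2, scale = 0.5))
#' sample_joint_counts(m, 5, seed = 1)
#' @export
sample_joint_counts <- function(model, n, seed) {
  stopifnot(inherits(model, "joint_count_model"), n >= 1)
  lam <- model$kinetics$lambda
  withr::with_seed(seed, {
    x <- sample_regulator(model$regulator, n)
    if (is.null(model$bursting)) {
      rate1 <- lam[1] * x
      rate2 <- lam[2] * x
    } else {
      b <- model$bursting
      lev <- c(b$rate_inactive, b$rate_active)
      s1 <- stats::rbinom(n, 1, b$active_fraction)
      s2 <- stats::rbinom(n, 1, b$active_fraction)
      rate1 <- lev[s1 + 1] * x
      rate2 <- lev[s2 + 1] * x
    }
    tibble::tibble(
      replicate = seq_len(n),
      m1 = stats::rpois(n, rate1),
      m2 = stats::rpois(n, rate2),
      x = x
    )
  })
}

#' Stochastic simulation of two bursty alleles (telegraph model)
#'
#' Exact Gillespie simulation of two alleles, each switching between an active
#' and an inactive transcriptional state at constant rates, with linear mRNA
#' birth and death. Transcription in state `s` proceeds at rate
#' `level_s * decay_rate_i * x`, so the conditional stationary mean count is
#' `level_s * x`. The regulator concentration `x` is drawn once per replicate
#' (quenched extrinsic noise, matching the stationary-mixture picture);
#' setting `refresh_rate > 0` instead redraws `x` at that rate during the
#' simulation (piecewise-constant extrinsic noise, off by default).
#'
#' Active-state occupancies are time-averaged after discarding the first 10%
#' of each trajectory as burn-in; counts are read out at `t_end`.
#'
#' @param kinetics An [allele_kinetics()] (its decay rates are used; the birth
#'   rates are superseded by the bursting levels).
#' @param bursting A [burst_kinetics()] with switching rates supplied, unless
#'   `active_fraction` is exactly 0 or 1.
#' @param reg A [regulator()] object.
#' @param t_end Simulated time span per replicate.
#' @param n_reps Number of independent replicates.
#' @param seed Integer seed.
#' @param refresh_rate Rate at which `x` is redrawn; 0 keeps it quenched.
#' @return A tibble with columns `replicate`, `m1`, `m2`, `x`, `occ1`, `occ2`
#'   (post-burn-in active fractions).
#' @export
simulate_telegraph_ssa <- function(kinetics, bursting, reg, t_end,
                                   n_reps = 1000, seed = 1L, refresh_rate = 0) {
  stopifnot(inherits(kinetics, "allele_kinetics"),
            inherits(bursting, "burst_kinetics"),
            inherits(reg, "regulator"),
            t_end > 0, n_reps >= 1)
  w <- bursting$active_fraction
  s_on <- bursting$switch_on
  s_off <- bursting$switch_off
  if (is.null(s_on) || is.null(s_off)) {
    if (w > 0 && w < 1) {
      stop("switching rates are required when the active fraction lies strictly in (0, 1)",
           call. = FALSE)
    }
    s_on <- 0; s_off <- 0
  }
  withr::with_seed(seed, {
    x <- sample_regulator(reg, n_reps)
    res <- ssa_telegraph_cpp(
      x, bursting$rate_active, bursting$rate_inactive,
      kinetics$decay_rate[1], kinetics$decay_rate[2],
      s_on, s_off, w, t_end, refresh_rate,
      reg_code(reg), reg_par(reg)
    )
    tibble::tibble(
      replicate = seq_len(n_reps),
      m1 = res$m1, m2 = res$m2, x = res$x,
      occ1 = res$occ1, occ2 = res$occ2
    )
  })
}

reg_code <- function(reg) {
  match(reg$family, c("constant", "gamma", "gumbel", "empirical"))
}

reg_par <- function(reg) {
  switch(reg$family,
    constant = c(reg$params$value, 0),
    gamma = c(reg$params$shape, reg$params$scale),
    gumbel = c(reg$params$location, reg$params$scale),
    empirical = as.numeric(reg$params$samples)
  )
}

#' Truncated support for the joint count PMFs
#'
#' Upper truncation point per allele: at least `mean + 12 standard
#' deviations` of the marginal count distribution, extended for gamma
#' regulators to the exact negative-binomial quantile leaving marginal tail
#' mass below 1e-11, so the excluded joint mass is provably below 1e-10.
#' @param model A [joint_count_model()].
#' @return Integer vector of length 2 (upper count bounds).
#' @keywords internal
count_support_bound <- function(model) {
  lam <- model$kinetics$lambda
  mu <- lam * model$regulator$mean
  v <- lam * model$regulator$mean + lam^2 * model$regulator$var
  bound <- ceiling(mu + 12 * sqrt(v))
  if (model$regulator$family == "gamma") {
    r <- model$regulator$params$shape
    theta <- model$regulator$params$scale
    qb <- stats::qnbinom(1e-11, size = r, prob = 1 / (1 + lam * theta),
                         lower.tail = FALSE)
    bound <- pmax(bound, qb + 1)
  }
  as.integer(bound)
}
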