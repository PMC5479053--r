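test_that("joint PMF of uncoupled alleles matches the closed form and normalizes", {
  ak <- allele_kinetics(1, 1)
  expect_equal(poisson_joint_pmf(ak, 0, 0), exp(-2), tolerance = 1e-12)
  ak2 <- allele_kinetics(2, 1, 3, 1)
  expect_equal(poisson_joint_pmf(ak2, 1, 1), 6 * exp(-5), tolerance = 1e-12)

  ak50 <- allele_kinetics(50, 1)
  total <- sum(outer(0:200, 0:200, function(a, b) poisson_joint_pmf(ak50, a, b)))
  expect_equal(total, 1, tolerance = 1e-10)

  expect_error(poisson_joint_pmf(ak, -1, 0), "nonnegative integers")
  expect_error(poisson_joint_pmf(ak, 1.5, 0), "nonnegative integers")
})

test_that("truncated joint support captures all but < 1e-10 of the BNB mass", {
  m <- joint_count_model(allele_kinetics(50, 1),
                         regulator("gamma", shape = 2, scale = 0.5))
  b <- reporterfidelity:::count_support_bound(m)
  # excluded mass certified by the exact marginal tail
  expect_lt(2 * pnbinom(b[1] - 1, size = 2, prob = 1 / 26, lower.tail = FALSE),
            1e-10)
  total <- sum(vapply(0:b[1], function(m1) sum(bnb_joint_pmf(m, m1, 0:b[2])),
                      numeric(1)))
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("gamma-regulator joint PMF matches its closed form at the origin", {
  m <- joint_count_model(allele_kinetics(50, 1),
                         regulator("gamma", shape = 2, scale = 0.5))
  # p = q = 25/51, so the zero-zero cell is (1 - p - q)^r = (1/51)^2
  expect_equal(m$p, 25 / 51, tolerance = 1e-12)
  expect_equal(bnb_joint_pmf(m, 0, 0), (1 / 51)^2, tolerance = 1e-12)
  expect_error(bnb_joint_pmf(
    joint_count_model(allele_kinetics(50, 1), regulator("constant", value = 1)),
    0, 0), "gamma")
})

test_that("closed-form joint PMF equals adaptive quadrature of the mixture integral", {
  m <- joint_count_model(allele_kinetics(50, 1),
                         regulator("gamma", shape = 2, scale = 0.5))
  expect_equal(bnb_joint_pmf(m, 40, 60), bnb_quadrature(2, 0.5, 50, 50, 40, 60),
               tolerance = 1e-8)
  withr::with_seed(7, {
    for (i in 1:5) {
      r <- runif(1, 0.5, 5); th <- runif(1, 0.05, 1)
      l1 <- runif(1, 5, 80); l2 <- runif(1, 5, 80)
      mm <- joint_count_model(allele_kinetics(l1, 1, l2, 1),
                              regulator("gamma", shape = r, scale = th))
      m1 <- rpois(4, l1 * r * th); m2 <- rpois(4, l2 * r * th)
      for (j in 1:4) {
        expect_equal(bnb_joint_pmf(mm, m1[j], m2[j]),
                     bnb_quadrature(r, th, l1, l2, m1[j], m2[j]),
                     tolerance = 1e-8)
      }
    }
  })
})

test_that("marginals of the joint count law are negative binomial", {
  m <- joint_count_model(allele_kinetics(50, 1),
                         regulator("gamma", shape = 2, scale = 0.5))
  bound <- reporterfidelity:::count_support_bound(m)
  marginal <- vapply(0:10, function(m1) sum(bnb_joint_pmf(m, m1, 0:bound[2])),
                     numeric(1))
  expect_equal(marginal, dnbinom(0:10, size = 2, prob = 1 / (1 + 50 * 0.5)),
               tolerance = 1e-10)
})

test_that("gamma mixture converges to independent Poisson as dispersion vanishes", {
  ak <- allele_kinetics(50, 1)
  tight <- joint_count_model(ak, regulator("gamma", shape = 1e4, scale = 1e-4))
  grid <- 35:65
  expect_lt(max(abs(bnb_joint_pmf(tight, grid, 50) -
                    poisson_joint_pmf(ak, grid, 50))), 1e-3)
})

test_that("inter-allele covariance is lambda1*lambda2*Var(x) for any regulator family", {
  ak <- allele_kinetics(50, 1)
  expect_equal(joint_covariance(joint_count_model(ak, regulator("constant", value = 1))), 0)
  expect_equal(joint_covariance(joint_count_model(
    ak, regulator("gamma", shape = 2, scale = 0.5))), 1250)
  # Gumbel variance is pi^2 * scale^2 / 6
  gum <- joint_count_model(allele_kinetics(20, 1, 30, 1),
                           regulator("gumbel", location = 5, scale = 0.1))
  expect_equal(joint_covariance(gum), 600 * pi^2 * 0.01 / 6, tolerance = 1e-12)
  expect_equal(joint_covariance(gum), 9.8696044, tolerance = 1e-7)

  # family-invariance: same Var(x) => same covariance
  v <- pi^2 * 0.01 / 6
  gam_same_var <- joint_count_model(allele_kinetics(20, 1, 30, 1),
                                    regulator("gamma", shape = 25 / v, scale = v / 5))
  expect_equal(joint_covariance(gam_same_var), joint_covariance(gum), tolerance = 1e-10)
})

test_that("Monte Carlo covariance agrees with the closed form within 3 standard errors", {
  m <- joint_count_model(allele_kinetics(50, 1),
                         regulator("gamma", shape = 2, scale = 0.5))
  s <- sample_joint_counts(m, 1e5, seed = 11)
  d1 <- s$m1 - mean(s$m1); d2 <- s$m2 - mean(s$m2)
  se <- sd(d1 * d2) / sqrt(nrow(s))
  expect_lt(abs(cov(s$m1, s$m2) - 1250), 3 * se)

  gum <- joint_count_model(allele_kinetics(20, 1, 30, 1),
                           regulator("gumbel", location = 5, scale = 0.1))
  sg <- sample_joint_counts(gum, 1e6, seed = 12)
  dg <- (sg$m1 - mean(sg$m1)) * (sg$m2 - mean(sg$m2))
  expect_lt(abs(cov(sg$m1, sg$m2) - joint_covariance(gum)),
            3 * sd(dg) / sqrt(nrow(sg)))
})

test_that("allelic correlation is lambda*F/(1+lambda*F) and monotone in the Fano factor", {
  expect_equal(allelic_correlation(joint_count_model(
    allele_kinetics(50, 1), regulator("constant", value = 1))), 0)
  # F = Var/mean = 0.5 at shape 2, scale 0.5 => 25/26
  expect_equal(allelic_correlation(joint_count_model(
    allele_kinetics(50, 1), regulator("gamma", shape = 2, scale = 0.5))),
    25 / 26, tolerance = 1e-12)
  fano <- c(0.01, 0.05, 0.2, 0.5, 1, 2)
  cors <- vapply(fano, function(f) {
    allelic_correlation(joint_count_model(
      allele_kinetics(50, 1), regulator("gamma", shape = 1 / f, scale = f)))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("bursting covariance reduces to the constitutive law at w = 1 and is always below it", {
  reg <- regulator("gamma", shape = 2, scale = 0.5)
  b1 <- burst_kinetics(100, 1, active_fraction = 1)
  expect_equal(bursty_covariance(b1, reg),
               joint_covariance(joint_count_model(allele_kinetics(100, 1), reg)))
  # rate_active == rate_inactive: independent of w
  expect_equal(bursty_covariance(burst_kinetics(5, 5, active_fraction = 0.2), reg),
               bursty_covariance(burst_kinetics(5, 5, active_fraction = 0.9), reg))
  b <- burst_kinetics(100, 1, active_fraction = 0.3)
  expect_equal(bursty_covariance(b, reg), 30.7^2 * 0.5, tolerance = 1e-12)
  for (w in c(0.1, 0.5, 0.9)) {
    expect_lt(bursty_covariance(burst_kinetics(100, 1, active_fraction = w), reg),
              joint_covariance(joint_count_model(allele_kinetics(100, 1), reg)))
  }
})

test_that("stationary sampler is deterministic in the seed", {
  m <- joint_count_model(allele_kinetics(50, 1),
                         regulator("gamma", shape = 2, scale = 0.5))
  expect_identical(sample_joint_counts(m, 500, seed = 42),
                   sample_joint_counts(m, 500, seed = 42))
  expect_false(identical(sample_joint_counts(m, 500, seed = 42),
                         sample_joint_counts(m, 500, seed = 43)))
})

test_that("telegraph SSA recovers the stationary active fraction", {
  b <- burst_kinetics(100, 1, switch_on = 0.6, switch_off = 1.4)
  ssa <- simulate_telegraph_ssa(allele_kinetics(20, 1), b,
                                regulator("constant", value = 1),
                                t_end = 2000, n_reps = 20, seed = 2)
  expect_equal(mean(c(ssa$occ1, ssa$occ2)), 0.3, tolerance = 0.02)
})

test_that("bursting with a constant regulator overdisperses the counts", {
  b <- burst_kinetics(20, 0, switch_on = 5, switch_off = 5)
  ssa <- simulate_telegraph_ssa(allele_kinetics(20, 1), b,
                                regulator("constant", value = 1),
                                t_end = 30, n_reps = 4000, seed = 3)
  expect_gt(var(ssa$m1) / mean(ssa$m1), 1)
})

test_that("slow-switching SSA covariance approaches the analytic bursty covariance", {
  # switching 100x slower than decay
  b <- burst_kinetics(100, 1, switch_on = 0.003, switch_off = 0.007)
  reg <- regulator("gamma", shape = 2, scale = 0.5)
  ssa <- simulate_telegraph_ssa(allele_kinetics(50, 1), b, reg,
                                t_end = 30, n_reps = 50000, seed = 1)
  expect_equal(cov(ssa$m1, ssa$m2), bursty_covariance(b, reg), tolerance = 0.1)
})

test_that("SSA input contracts are enforced", {
  b_no_rates <- burst_kinetics(100, 1, active_fraction = 0.3)
  expect_error(simulate_telegraph_ssa(allele_kinetics(50, 1), b_no_rates,
                                      regulator("constant", value = 1),
                                      t_end = 10, n_reps = 2, seed = 1),
               "switching rates")
  expect_error(regulator("empirical", samples = numeric(0)), "non-empty")
})

test_that("model constructors enforce their invariants", {
  expect_error(allele_kinetics(-1, 1), "finite and > 0")
  expect_error(regulator("gamma", shape = -2, scale = 0.5), "shape > 0")
  expect_error(burst_kinetics(1, 2), "rate_active >= rate_inactive")
  expect_error(burst_kinetics(2, 1, active_fraction = 0.5,
                              switch_on = 1, switch_off = 9),
               "inconsistent")
})
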