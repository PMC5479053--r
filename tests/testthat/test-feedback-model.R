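test_that("gamma_factor reproduces the design-specific rescalings", {
  expect_equal(gamma_factor(reporter_design("wildtype")), 1)
  expect_equal(gamma_factor(reporter_design("bac")), 1)
  expect_equal(gamma_factor(reporter_design("knock_in")), 2)
  expect_equal(gamma_factor(reporter_design("pre_post", epsilon = 0.5)), 2 / 1.5)
  expect_equal(gamma_factor(reporter_design("fusion", epsilon = 0.8, delta = 0.5)),
               2 / 1.4, tolerance = 1e-12)
  # a perfect, non-perturbing reporter
  expect_equal(gamma_factor(reporter_design("fusion", epsilon = 1, delta = 1)), 1)
  expect_error(reporter_design("pre_post", epsilon = 1.2), "\\[0, 1\\]")
})

test_that("single-allele factors are ordered knock-in >= fusion >= pre/post >= bac", {
  for (eps in c(0.2, 0.5, 0.9)) {
    for (delta in c(0.3, 0.7, 1)) {
      f_ki <- gamma_factor(reporter_design("knock_in"))
      f_fu <- gamma_factor(reporter_design("fusion", epsilon = eps, delta = delta))
      f_pp <- gamma_factor(reporter_design("pre_post", epsilon = eps))
      f_bac <- gamma_factor(reporter_design("bac"))
      expect_true(f_ki >= f_fu && f_fu >= f_pp && f_pp >= f_bac)
      expect_true(f_ki <= 2 && f_bac >= 1)
    }
  }
})

test_that("nondimensionalization yields alpha = c_b/c_f and the rescaled gamma", {
  fp <- feedback_params(c_b = 1, c_f = 2, c_d = 1, K = 4)
  wt <- nondimensionalize(fp)
  expect_equal(wt$alpha, 0.5)
  expect_equal(wt$gamma, 1)
  ki <- nondimensionalize(fp, reporter_design("knock_in"))
  expect_equal(ki$gamma, 2)
  pp <- nondimensionalize(fp, reporter_design("pre_post", epsilon = 0.5))
  expect_equal(pp$gamma, 4 / 3, tolerance = 1e-12)
})

test_that("equilibria solve the fixed-point equation with correct stability", {
  # alpha = 0, H = 2: nonzero roots solve n^2 - n + gamma^2 = 0
  eq <- equilibria(dimensionless_params(0, 0.4, 2))
  expect_equal(eq$level, c(0, 0.2, 0.8), tolerance = 1e-9)
  expect_equal(eq$stable, c(TRUE, FALSE, TRUE))
  expect_equal(attr(eq, "classification"), "bistable")

  eq2 <- equilibria(dimensionless_params(0, 0.6, 2))
  expect_equal(nrow(eq2), 1)
  expect_equal(attr(eq2, "classification"), "monostable")

  eq3 <- equilibria(dimensionless_params(0.3, 1.5, 2))
  expect_equal(nrow(eq3), 1)
  expect_true(eq3$stable)
})

test_that("equilibrium count is odd for generic parameters", {
  withr::with_seed(5, {
    for (i in 1:25) {
      eq <- equilibria(dimensionless_params(runif(1, 0.001, 0.3),
                                            runif(1, 0.05, 1.2), 2))
      if (!attr(eq, "degenerate")) expect_equal(nrow(eq) %% 2, 1)
    }
  })
})

test_that("fold curves carry the analytic cusp and the closed-form boundary points", {
  cusp <- bifurcation_cusp(2)
  expect_equal(unname(cusp["alpha"]), 1 / 8, tolerance = 1e-6)
  expect_equal(unname(cusp["gamma"]), 3 * sqrt(3) / 8, tolerance = 1e-6)

  curves <- bifurcation_curves(2)
  # at alpha = 0 the upper fold sits at gamma = 1/2
  up0 <- curves[curves$branch == "upper", ]
  expect_equal(up0$gamma[which.min(up0$alpha)], 0.5, tolerance = 1e-3)
  # every reported locus point satisfies the defining conditions f = f' = 0
  idx <- seq(1, nrow(curves), length.out = 25)
  for (i in idx) {
    a <- curves$alpha[i]; g <- curves$gamma[i]; n <- curves$level[i]
    expect_equal(a + n^2 / (g^2 + n^2) - n, 0, tolerance = 1e-8)
    expect_equal(2 * g^2 * n / (g^2 + n^2)^2 - 1, 0, tolerance = 1e-6)
  }
})

test_that("no bistability exists for a non-cooperative (H = 1) feedback", {
  curves <- bifurcation_curves(1)
  expect_equal(nrow(curves), 0)
  expect_false(attr(curves, "bistable_possible"))
  withr::with_seed(8, {
    for (i in 1:20) {
      expect_equal(classify_dynamics(dimensionless_params(
        runif(1, 0, 0.3), runif(1, 0.05, 1.5), 1)), "monostable")
    }
  })
})

test_that("root-based classification agrees with the sign-scan oracle and the curve test", {
  cases <- expand.grid(alpha = c(0.01, 0.02, 0.05, 0.1, 0.15),
                       gamma = c(0.1, 0.3, 0.35, 0.5, 0.6, 0.7, 1))
  curves <- bifurcation_curves(2)
  for (i in seq_len(nrow(cases))) {
    a <- cases$alpha[i]; g <- cases$gamma[i]
    cls <- classify_dynamics(dimensionless_params(a, g, 2))
    expect_equal(cls, sign_scan_classification(a, g, 2))
    expect_equal(cls, classify_by_curves(a, g, curves))
  }
})

test_that("risk maps flag exactly the discordant cells", {
  rm_ki <- risk_map(reporter_design("knock_in"), alpha = 0.02, gamma = 0.35)
  expect_true(rm_ki$at_risk)
  expect_equal(rm_ki$direction, "bistable_to_monostable")

  alpha <- seq(0.01, 0.12, length.out = 6)
  gamma <- seq(0.05, 1, length.out = 6)
  rm_bac <- risk_map(reporter_design("bac"), alpha = alpha, gamma = gamma)
  expect_equal(sum(rm_bac$at_risk), 0)

  rm2 <- risk_map(reporter_design("knock_in"), alpha = alpha, gamma = gamma)
  expect_true(all(rm2$at_risk == (rm2$class_wt != rm2$class_design)))
})

test_that("upper-direction risk grows monotonically with the gamma factor", {
  alpha <- seq(0.005, 0.12, length.out = 8)
  gamma <- seq(0.05, 0.8, length.out = 8)
  eps <- c(0.9, 0.5, 0.1) # increasing factor 2/(1+eps)
  risks <- lapply(eps, function(e) {
    rm_ <- risk_map(reporter_design("pre_post", epsilon = e),
                    alpha = alpha, gamma = gamma)
    which(rm_$at_risk & rm_$direction == "bistable_to_monostable")
  })
  expect_true(all(risks[[1]] %in% risks[[2]]))
  expect_true(all(risks[[2]] %in% risks[[3]]))
})

test_that("pre/post risk grows with insert count under a decreasing epsilon schedule", {
  schedule <- c(0.9, 0.6, 0.3)
  alpha <- seq(0.005, 0.12, length.out = 7)
  gamma <- seq(0.05, 0.8, length.out = 7)
  frac <- vapply(1:3, function(m) {
    mean(risk_map(reporter_design("pre_post", epsilon = schedule, insert_count = m),
                  alpha = alpha, gamma = gamma)$at_risk)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[3], frac[1])
})

test_that("ODE steady states respect the slaved reporter algebra", {
  fp <- feedback_params(0.02, 1, 1, 0.7)
  tr <- simulate_ode(fp, reporter_design("knock_in"), n0 = 0.5, t_end = 300)
  ss <- attr(tr, "steady_state")
  expect_true(ss$reached)
  # matched decay: reporter steady state equals the protein steady state
  expect_equal(ss$reporter, ss$nanog, tolerance = 1e-6)
  # half the decay rate: twice the steady level
  tr2 <- simulate_ode(fp, reporter_design("knock_in"), reporter_decay = 0.5,
                      n0 = 0.5, t_end = 300)
  ss2 <- attr(tr2, "steady_state")
  expect_equal(ss2$reporter, 2 * ss2$nanog, tolerance = 1e-6)
})

test_that("ODE endpoints land on stable equilibria of the root finder", {
  fp <- canonical_feedback()
  dp <- nondimensionalize(fp)
  stable <- equilibria(dp)$level[equilibria(dp)$stable]
  scale <- 2 * fp$c_f / fp$c_d
  for (n0 in c(0.05, 0.3, 1.2, 2.5)) {
    ss <- attr(simulate_ode(fp, n0 = n0, t_end = 400), "steady_state")
    expect_true(ss$reached)
    expect_true(min(abs(ss$nanog / scale - stable)) < 1e-6)
    expect_true(ss$stable)
  }
})

test_that("wildtype dynamics equal the aggregated two-allele equation", {
  # the one-equation model for total protein is what simulate_ode integrates;
  # check against an independent integration of the two per-allele equations
  fp <- feedback_params(0.05, 1.3, 0.8, 0.9, 2)
  two_allele <- function(t, y, parms) {
    n <- y[1] + y[2]
    h <- n^fp$H / (fp$K^fp$H + n^fp$H)
    list(c(fp$c_b + fp$c_f * h - fp$c_d * y[1],
           fp$c_b + fp$c_f * h - fp$c_d * y[2]))
  }
  times <- seq(0, 50, length.out = 101)
  ref <- deSolve::ode(c(0.4, 0.1), times, two_allele, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  tr <- simulate_ode(fp, n0 = 0.5, t_end = 50, n_out = 101)
  expect_equal(tr$nanog, ref[, 2] + ref[, 3], tolerance = 1e-6)
})

test_that("dual-allele designs expose the extrapolated factors", {
  f_dual <- gamma_factor(reporter_design("pre_post", epsilon = 0.5, alleles = "dual"))
  expect_equal(as.numeric(f_dual), 2)
  expect_true(attr(f_dual, "extrapolated"))
  expect_gt(as.numeric(gamma_factor(
    reporter_design("fusion", epsilon = 0.5, delta = 0.5, alleles = "dual"))),
    gamma_factor(reporter_design("fusion", epsilon = 0.5, delta = 0.5)))
  expect_error(gamma_factor(reporter_design("pre_post", epsilon = 0, alleles = "dual")),
               "epsilon")
})
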