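#' Kinetic constants of the positive-feedback circuit
#'
#' Parameters of the deterministic model of Nanog-like protein dynamics:
#' each allele produces protein at a basal rate `c_b` plus a
#' feedback-enhanced rate saturating at `c_f` with half-maximum `K` and Hill
#' coefficient `H` in the total protein concentration, and protein decays at
#' rate `c_d`.
#'
#' @param c_b Basal production rate (concentration/time).
#' @param c_f Maximal feedback-enhanced production rate (concentration/time).
#' @param c_d Decay rate (1/time).
#' @param K Half-maximal concentration of the feedback Hill function.
#' @param H Hill coefficient (dimensionless, >= 1).
#' @return An object of class `feedback_params`.
#' @examples
#' feedback_params(c_b = 0.02, c_f = 1, c_d = 1, K = 0.7, H = 2)
#' @export
feedback_params <- function(c_b, c_f, c_d, K, H = 2) {
  vals <- c(c_b, c_f, c_d, K, H)
  if (!all(is.finite(vals)) || any(vals[-5] <= 0) || H < 1) {
    stop("feedback parameters must be finite, positive, with H >= 1", call. = FALSE)
  }
  structure(list(c_b = c_b, c_f = c_f, c_d = c_d, K = K, H = H),
            class = "feedback_params")
}

#' Reporter construct design
#'
#' Describes how a fluorescent reporter is engineered into the locus:
#' \describe{
#'   \item{wildtype}{no reporter; both alleles produce functional protein.}
#'   \item{knock_in}{one allele's coding region replaced by an inert reporter
#'     (heterozygous loss-of-function).}
#'   \item{pre_post}{`insert_count` copies of a self-cleaving (2A/IRES)
#'     reporter appended to one allele; transcription from that allele is
#'     reduced by a factor `epsilon` in \[0, 1\] (supply a nonincreasing
#'     vector to encode a per-insert schedule, indexed by `insert_count`).}
#'   \item{fusion}{the reporter is fused to the protein on one allele;
#'     transcription changes by `epsilon` and feedback efficacy of the fusion
#'     protein by `delta` in \[0, 1\].}
#'   \item{bac}{a BAC transgene carries the reporter under the same promoter,
#'     leaving both endogenous alleles unchanged.}
#' }
#'
#' `alleles = "dual"` applies the pre/post or fusion modification to both
#' alleles. The resulting feedback-strength factors (`1/epsilon`,
#' `1/(epsilon*delta)`) are extrapolated from the same production-sum argument
#' as the single-allele designs and are flagged as such.
#'
#' @param kind Design kind (see above).
#' @param epsilon Transcription-rate factor(s) in \[0, 1\]; vector = per-insert
#'   schedule for `pre_post`.
#' @param delta Feedback-efficacy factor in \[0, 1\] (fusion only).
#' @param insert_count Number of reporter inserts (`pre_post`).
#' @param alleles `"single"` (default) or `"dual"` (extrapolated).
#' @return An object of class `reporter_design`.
#' @examples
#' reporter_design("knock_in")
#' reporter_design("pre_post", epsilon = 0.5)
#' @export
reporter_design <- function(kind = c("wildtype", "knock_in", "pre_post", "fusion", "bac"),
                            epsilon = 1, delta = 1, insert_count = 1L,
                            alleles = c("single", "dual")) {
  kind <- match.arg(kind)
  alleles <- match.arg(alleles)
  if (any(epsilon < 0 | epsilon > 1) || delta < 0 || delta > 1) {
    stop("epsilon and delta must lie in [0, 1]", call. = FALSE)
  }
  if (length(epsilon) > 1 && any(diff(epsilon) > 1e-12)) {
    stop("a per-insert epsilon schedule must be nonincreasing", call. = FALSE)
  }
  if (insert_count < 1 || insert_count != round(insert_count)) {
    stop("insert_count must be a positive integer", call. = FALSE)
  }
  structure(
    list(kind = kind, epsilon = epsilon, delta = delta,
         insert_count = as.integer(insert_count), alleles = alleles),
    class = "reporter_design"
  )
}

design_epsilon <- function(design) {
  eps <- design$epsilon
  eps[min(design$insert_count, length(eps))]
}

#' Design-induced multiplier of the feedback parameter
#'
#' How a reporter design rescales the dimensionless feedback parameter
#' `gamma` relative to the wild type, with identical kinetic constants:
#' wildtype and BAC leave it unchanged (factor 1); a knock-in halves
#' functional production and doubles `gamma`; a pre/post insertion with
#' transcription factor `epsilon` gives `2/(1+epsilon)`; a fusion with
#' efficacy `delta` gives `2/(1+epsilon*delta)`. Single-allele factors lie in
#' \[1, 2\]. Dual-allele variants (extrapolated) give `1/epsilon` and
#' `1/(epsilon*delta)` and require `epsilon > 0` (and `delta > 0`).
#'
#' @param design A [reporter_design()].
#' @return The multiplier, with attribute `extrapolated` for dual-allele
#'   designs.
#' @examples
#' gamma_factor(reporter_design("knock_in")) # 2
#' gamma_factor(reporter_design("fusion", epsilon = 0.8, delta = 0.5))
#' @export
gamma_factor <- function(design) {
  stopifnot(inherits(design, "reporter_design"))
  eps <- design_epsilon(design)
  if (design$alleles == "dual" && design$kind %in% c("pre_post", "fusion")) {
    denom <- if (design$kind == "pre_post") eps else eps * design$delta
    if (denom <= 0) stop("dual-allele designs require epsilon (and delta) > 0", call. = FALSE)
    return(structure(1 / denom, extrapolated = TRUE))
  }
  switch(design$kind,
    wildtype = 1,
    bac = 1,
    knock_in = 2,
    pre_post = 2 / (1 + eps),
    fusion = 2 / (1 + eps * design$delta)
  )
}

#' Nondimensionalize the feedback model
#'
#' Rescaling concentration by `2*c_f/c_d` and time by `1/c_d` reduces the
#' total-protein equation to `dn/dtau = alpha + n^H/(gamma^H + n^H) - n` with
#' `alpha = c_b/c_f` and wild-type `gamma = c_d*K/(2*c_f)`. A reporter design
#' multiplies `gamma` by [gamma_factor()].
#'
#' @param params A [feedback_params()].
#' @param design A [reporter_design()]; defaults to wildtype.
#' @return An object of class `dimensionless_params` with fields `alpha`,
#'   `gamma`, `hill_coeff`.
#' @examples
#' nondimensionalize(feedback_params(1, 2, 1, 4), reporter_design("knock_in"))
#' @export
nondimensionalize <- function(params, design = reporter_design("wildtype")) {
  stopifnot(inherits(params, "feedback_params"))
  dimensionless_params(
    alpha = params$c_b / params$c_f,
    gamma = gamma_factor(design) * params$c_d * params$K / (2 * params$c_f),
    hill_coeff = params$H
  )
}

#' @rdname nondimensionalize
#' @param alpha,gamma,hill_coeff Dimensionless basal rate (>= 0), feedback
#'   parameter (> 0) and Hill coefficient (>= 1).
#' @export
dimensionless_params <- function(alpha, gamma, hill_coeff = 2) {
  if (alpha < 0 || gamma <= 0 || hill_coeff < 1) {
    stop("need alpha >= 0, gamma > 0, hill_coeff >= 1", call. = FALSE)
  }
  structure(list(alpha = alpha, gamma = gamma, hill_coeff = hill_coeff),
            class = "dimensionless_params")
}

feedback_rhs <- function(n, alpha, gamma, H) {
  alpha + n^H / (gamma^H + n^H) - n
}

feedback_rhs_prime <- function(n, alpha, gamma, H) {
  H * gamma^H * n^(H - 1) / (gamma^H + n^H)^2 - 1
}

#' Equilibria of the dimensionless feedback equation
#'
#' Finds all nonnegative roots of `alpha + n^H/(gamma^H + n^H) - n` by
#' sign-change bracketing on `[0, alpha + 1]` (the right-hand side is
#' `alpha >= 0` at 0 and strictly negative beyond `alpha + 1`, so all roots
#' lie inside), followed by root polishing to tolerance 1e-12. A root is
#' stable iff the derivative there is below `-1e-9`; a derivative within
#' `1e-9` of zero marks a fold and sets the `degenerate` attribute instead of
#' contributing to the classification.
#'
#' @param dp A [dimensionless_params()] object.
#' @param step Bracketing step on the search interval.
#' @return A tibble of class `equilibrium_set` with columns `level`, `stable`,
#'   and attributes `classification` (`"monostable"`/`"bistable"`) and
#'   `degenerate`.
#' @examples
#' equilibria(dimensionless_params(alpha = 0, gamma = 0.4))
#' @export
equilibria <- function(dp, step = 1e-3) {
  stopifnot(inherits(dp, "dimensionless_params"))
  alpha <- dp$alpha; gamma <- dp$gamma; H <- dp$hill_coeff
  upper <- alpha + 1
  grid <- seq(0, upper, by = step)
  if (grid[length(grid)] < upper) grid <- c(grid, upper)
  fv <- feedback_rhs(grid, alpha, gamma, H)

  roots <- numeric(0)
  if (abs(fv[1]) < 1e-14) roots <- c(roots, grid[1]) # n = 0 when alpha = 0
  sgn <- sign(fv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flips) {
    rt <- stats::uniroot(feedback_rhs, c(grid[i], grid[i + 1]),
                         alpha = alpha, gamma = gamma, H = H,
                         tol = 1e-12)$root
    roots <- c(roots, rt)
  }
  # grid points that are (numerically) exact roots without a sign flip
  exact <- grid[-1][abs(fv[-1]) < 1e-14]
  roots <- sort(unique(c(roots, exact)))
  if (length(roots) == 0) {
    stop("no equilibrium found on [0, alpha + 1]; numerical failure", call. = FALSE)
  }

  deriv <- ifelse(roots == 0 & H > 1, -1,
                  feedback_rhs_prime(pmax(roots, .Machine$double.eps), alpha, gamma, H))
  degenerate <- any(abs(deriv) <= 1e-9)
  stable <- deriv < -1e-9
  out <- tibble::tibble(level = roots, stable = stable)
  class(out) <- c("equilibrium_set", class(out))
  attr(out, "classification") <- if (sum(stable) >= 2) "bistable" else "monostable"
  attr(out, "degenerate") <- degenerate
  out
}

#' Classify the feedback dynamics as monostable or bistable
#'
#' Wraps [equilibria()]: bistable iff exactly two stable equilibria coexist.
#'
#' @inheritParams equilibria
#' @return `"monostable"` or `"bistable"`.
#' @examples
#' classify_dynamics(dimensionless_params(0.02, 0.35))
#' @export
classify_dynamics <- function(dp, step = 1e-3) {
  attr(equilibria(dp, step = step), "classification")
}

#' Saddle-node bifurcation curves of the feedback model
#'
#' The fold locus, where an equilibrium satisfies both `f = 0` and `f' = 0`,
#' is computed parametrically in the equilibrium level `n`: writing
#' `s = gamma^H`, `f' = 0` reads `s^2 + (2 n^H - H n^(H-1)) s + n^(2H) = 0`,
#' solved in closed form for `s`, after which `alpha = n - n^H/(s + n^H)`.
#' Only the physically meaningful points (`alpha >= 0`, real positive `s`)
#' are returned; they trace the two fold curves in the `(alpha, gamma)` plane,
#' which meet at the cusp (the maximum of `alpha` along the locus). The region
#' enclosed between the curves is bistable. For `H <= 1` the discriminant is
#' never positive at positive levels and no bistability is possible: an empty
#' locus is returned with attribute `bistable_possible = FALSE`.
#'
#' @param H Hill coefficient.
#' @param n_points Number of parameter values along the level sweep.
#' @return A tibble with columns `branch` (`"lower"`/`"upper"`), `level`,
#'   `alpha`, `gamma`; attributes `bistable_possible` and `cusp`
#'   (named vector `alpha`, `gamma`).
#' @examples
#' curves <- bifurcation_curves(H = 2)
#' attr(curves, "cusp")
#' @export
bifurcation_curves <- function(H = 2, n_points = 2000) {
  empty <- tibble::tibble(branch = character(), level = numeric(),
                          alpha = numeric(), gamma = numeric())
  if (H <= 1) {
    attr(empty, "bistable_possible") <- FALSE
    return(empty)
  }
  # fold points exist for levels in (0, H/4]
  n <- seq(1e-6, H / 4, length.out = n_points)
  b <- 2 * n^H - H * n^(H - 1)
  disc <- b^2 - 4 * n^(2 * H)
  ok <- disc >= 0
  n <- n[ok]; b <- b[ok]; disc <- disc[ok]
  s <- (-b + sqrt(disc)) / 2 # the root with alpha >= 0
  alpha <- n - n^H / (s + n^H)
  gamma <- s^(1 / H)
  keep <- alpha >= 0 & s > 0
  n <- n[keep]; alpha <- alpha[keep]; gamma <- gamma[keep]

  cusp <- bifurcation_cusp(H)
  branch <- ifelse(n <= cusp["level"], "lower", "upper")
  out <- tibble::tibble(branch = branch, level = n, alpha = alpha, gamma = gamma)
  attr(out, "bistable_possible") <- TRUE
  attr(out, "cusp") <- cusp[c("alpha", "gamma")]
  out
}

fold_point <- function(n, H) {
  b <- 2 * n^H - H * n^(H - 1)
  disc <- pmax(b^2 - 4 * n^(2 * H), 0)
  s <- (-b + sqrt(disc)) / 2
  c(alpha = n - n^H / (s + n^H), gamma = s^(1 / H))
}

#' Cusp point of the fold locus
#'
#' The cusp, where the two fold curves meet (`f = f' = f'' = 0`), is the
#' maximum of `alpha` along the parametric locus; located by golden-section
#' optimization of `alpha(n)` over the admissible level range.
#'
#' @param H Hill coefficient (> 1).
#' @return Named vector `alpha`, `gamma`, `level`.
#' @export
bifurcation_cusp <- function(H = 2) {
  stopifnot(H > 1)
  opt <- stats::optimize(function(n) fold_point(n, H)["alpha"],
                         interval = c(1e-6, H / 4), maximum = TRUE,
                         tol = 1e-12)
  fp <- fold_point(opt$maximum, H)
  c(alpha = unname(fp["alpha"]), gamma = unname(fp["gamma"]), level = opt$maximum)
}

#' Classify a point by its position relative to the fold curves
#'
#' Side-of-curve test: a point is bistable iff its `alpha` is below the cusp
#' and its `gamma` lies strictly between the interpolated lower and upper fold
#' curves. This is an independent route to the classification in
#' [classify_dynamics()], useful for cross-checks and fast grids.
#'
#' @param alpha,gamma Query coordinates (vectorized).
#' @param curves Output of [bifurcation_curves()].
#' @return Character vector `"monostable"`/`"bistable"`.
#' @export
classify_by_curves <- function(alpha, gamma, curves) {
  if (!isTRUE(attr(curves, "bistable_possible"))) {
    return(rep("monostable", length(alpha)))
  }
  cusp_alpha <- unname(attr(curves, "cusp")["alpha"])
  lo <- curves[curves$branch == "lower", ]
  up <- curves[curves$branch == "upper", ]
  g_lo <- stats::approx(lo$alpha, lo$gamma, xout = alpha, rule = 2)$y
  g_up <- stats::approx(up$alpha, up$gamma, xout = alpha, rule = 2)$y
  unname(ifelse(alpha < cusp_alpha & gamma > g_lo & gamma < g_up,
                "bistable", "monostable"))
}

#' Map of parameter regions at risk of reporter-induced misclassification
#'
#' For each point of an `(alpha, gamma)` grid, compares the stability
#' classification of the wild-type system with that of the reporter system,
#' whose `gamma` is multiplied by [gamma_factor()] while `alpha` is unchanged.
#' Cells where the two classifications differ are "at risk": introducing the
#' reporter qualitatively changes the expression pattern.
#'
#' @param design A [reporter_design()].
#' @param alpha,gamma Numeric vectors of grid coordinates (wild-type `gamma`).
#' @param H Hill coefficient.
#' @return A tibble of class `risk_map` with columns `alpha`, `gamma`,
#'   `class_wt`, `class_design`, `at_risk`, `direction`.
#' @examples
#' rm <- risk_map(reporter_design("knock_in"),
#'                alpha = seq(0.01, 0.12, length.out = 5),
#'                gamma = seq(0.05, 1, length.out = 5))
#' mean(rm$at_risk)
#' @export
risk_map <- function(design, alpha, gamma, H = 2) {
  stopifnot(inherits(design, "reporter_design"), all(alpha >= 0), all(gamma > 0))
  fac <- gamma_factor(design)
  grid <- tidyr::expand_grid(alpha = alpha, gamma = gamma)
  cls <- function(a, g) classify_dynamics(dimensionless_params(a, g, H))
  grid <- dplyr::mutate(
    grid,
    class_wt = purrr::map2_chr(.data$alpha, .data$gamma, cls),
    class_design = if (fac == 1) .data$class_wt else
      purrr::map2_chr(.data$alpha, fac * .data$gamma, cls),
    at_risk = .data$class_wt != .data$class_design,
    direction = dplyr::case_when(
      !.data$at_risk ~ NA_character_,
      .data$class_wt == "bistable" ~ "bistable_to_monostable",
      TRUE ~ "monostable_to_bistable"
    )
  )
  class(grid) <- c("risk_map", class(grid))
  attr(grid, "design") <- design
  attr(grid, "gamma_factor") <- as.numeric(fac)
  grid
}

#' Integrate the feedback circuit and its reporter readout
#'
#' Integrates the dimensional total-protein equation
#' `dn/dt = (2/g) * (c_b + c_f * n^H/(K^H + n^H)) - c_d * n`, where
#' `g = gamma_factor(design)` rescales functional production exactly as the
#' design rescales `gamma`, together with the slaved reporter equation
#' `dr/dt = rho * (c_b + c_f * n^H/(K^H + n^H)) - d_r * r`, with `rho` the
#' reporter allele's transcription factor (0 for wildtype, 1 for knock-in and
#' BAC, `epsilon * insert_count` for pre/post, `epsilon` for fusion). Uses a
#' stiff-capable solver (lsoda, relative tolerance 1e-8). A steady state is
#' declared when the time-derivative norm at the endpoint is below 1e-10.
#'
#' @param params A [feedback_params()].
#' @param design A [reporter_design()].
#' @param reporter_decay Reporter decay rate `d_r`; defaults to `c_d`
#'   (matched half-lives).
#' @param n0,r0 Initial concentrations.
#' @param t_end Integration horizon.
#' @param n_out Number of output time points.
#' @return A tibble with columns `time`, `nanog`, `reporter` and attribute
#'   `steady_state` (list: `reached`, `nanog`, `reporter`, `stable`).
#' @examples
#' tr <- simulate_ode(feedback_params(0.02, 1, 1, 0.7), reporter_design("knock_in"),
#'                    n0 = 0.5, t_end = 50)
#' attr(tr, "steady_state")$reached
#' @export
simulate_ode <- function(params, design = reporter_design("wildtype"),
                         reporter_decay = params$c_d,
                         n0 = 0, r0 = 0, t_end = 100, n_out = 201) {
  stopifnot(inherits(params, "feedback_params"), n0 >= 0, r0 >= 0, t_end > 0)
  g <- as.numeric(gamma_factor(design))
  rho <- switch(design$kind,
    wildtype = 0, knock_in = 1, bac = 1,
    pre_post = design_epsilon(design) * design$insert_count,
    fusion = design_epsilon(design)
  )
  hill <- function(n) n^params$H / (params$K^params$H + n^params$H)
  deriv <- function(t, y, parms) {
    prod_rate <- params$c_b + params$c_f * hill(y[1])
    list(c((2 / g) * prod_rate - params$c_d * y[1],
           rho * prod_rate - reporter_decay * y[2]))
  }
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = c(n = n0, r = r0), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed; solver state ", attr(sol, "istate")[1], call. = FALSE)
  }
  end <- sol[nrow(sol), ]
  d_end <- unlist(deriv(end[1], end[-1], NULL))
  reached <- sqrt(sum(d_end^2)) < 1e-10
  dp <- nondimensionalize(params, design)
  stable <- if (reached) {
    scale <- 2 * params$c_f / (g * params$c_d)
    fp <- feedback_rhs_prime(max(end[2] / scale, .Machine$double.eps),
                             dp$alpha, dp$gamma, dp$hill_coeff)
    fp < -1e-9
  } else NA
  out <- tibble::tibble(time = sol[, 1], nanog = sol[, 2], reporter = sol[, 3])
  attr(out, "steady_state") <- list(reached = reached,
                                    nanog = unname(end[2]),
                                    reporter = unname(end[3]),
                                    stable = stable)
  out
}
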