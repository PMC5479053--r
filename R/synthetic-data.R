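#' Specification of a simulated cell population
#'
#' Bundles everything needed to generate a two-channel fluorescence
#' population from the stochastic feedback dynamics: the circuit parameters,
#' the reporter design, the dynamical noise amplitude, and the measurement
#' model (lognormal multiplicative noise plus an additive autofluorescence
#' floor). The deterministic classification of the chosen parameters is
#' attached as ground truth.
#'
#' @param feedback A [feedback_params()].
#' @param design A [reporter_design()].
#' @param sigma Additive dynamical noise amplitude (concentration/sqrt(time)).
#'   The default keeps stationary fluctuations well inside each basin of
#'   attraction and clear of the reflecting boundary for equilibria down to
#'   a few hundredths of a concentration unit, so that population modality
#'   reflects the deterministic phase portrait rather than boundary pile-up.
#' @param measurement_sdlog Standard deviation of the lognormal measurement
#'   noise (natural-log units).
#' @param autofluorescence Additive intensity floor.
#' @param gain Intensity per unit protein concentration.
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @param init `"equilibria"` starts cells at the deterministic stable
#'   equilibria with equal occupancy; `"uniform"` draws initial levels
#'   uniformly over the admissible range.
#' @param t_end Integration horizon in units of the decay time (the first 20
#'   decay times are burn-in).
#' @param dt Euler-Maruyama step as a fraction of the decay time.
#' @param condition Condition label attached to the events.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(feedback, design = reporter_design("wildtype"),
                            sigma = 0.005, measurement_sdlog = 0.25,
                            autofluorescence = 2, gain = 1000,
                            n_cells = 10000, seed = 1L,
                            init = c("equilibria", "uniform"),
                            t_end = 25, dt = 0.01,
                            condition = NULL) {
  stopifnot(inherits(feedback, "feedback_params"),
            inherits(design, "reporter_design"),
            sigma >= 0, measurement_sdlog >= 0, autofluorescence >= 0,
            gain > 0, n_cells >= 1, t_end > 20, dt > 0)
  init <- match.arg(init)
  dp <- nondimensionalize(feedback, design)
  eq <- equilibria(dp)
  structure(
    list(feedback = feedback, design = design, sigma = sigma,
         measurement_sdlog = measurement_sdlog,
         autofluorescence = autofluorescence, gain = gain,
         n_cells = as.integer(n_cells), seed = as.integer(seed),
         init = init, t_end = t_end, dt = dt,
         condition = condition %||% design$kind,
         classification = attr(eq, "classification"),
         dimensionless = dp, equilibria = eq),
    class = "population_spec"
  )
}

#' Generate a cell population from the stochastic feedback dynamics
#'
#' Euler-Maruyama integration of the total-protein and reporter equations of
#' [simulate_ode()] with additive noise `sigma * dW` and a reflecting
#' boundary at 0, one trajectory per cell. Endpoint concentrations are mapped
#' to fluorescence intensities as
#' `(gain * value + autofluorescence) * exp(measurement_sdlog * Z)`.
#' Deterministic ground truth (the stability classification and equilibria of
#' the chosen parameters) travels with the result. Fully reproducible for a
#' fixed spec.
#'
#' @param spec A [population_spec()].
#' @return An event tibble with columns `cell_id`, `nanog`, `reporter`,
#'   `condition`, `day`, `replicate`, and attribute `ground_truth`. A warning
#'   is raised if more than 1% of integration steps hit the reflecting
#'   boundary.
#' @examples
#' spec <- population_spec(feedback_params(0.02, 1, 1, 0.7),
#'                         n_cells = 200, seed = 7)
#' generate_population(spec)
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  fb <- spec$feedback
  g <- as.numeric(gamma_factor(spec$design))
  rho <- switch(spec$design$kind,
    wildtype = 0, knock_in = 1, bac = 1,
    pre_post = design_epsilon(spec$design) * spec$design$insert_count,
    fusion = design_epsilon(spec$design)
  )
  H <- fb$H; K <- fb$K
  scale <- 2 * fb$c_f / (g * fb$c_d)
  dt <- spec$dt / fb$c_d
  n_steps <- ceiling(spec$t_end / spec$dt)
  sq <- spec$sigma * sqrt(dt)
  n_cells <- spec$n_cells

  withr::with_seed(spec$seed, {
    if (spec$init == "equilibria") {
      stable <- spec$equilibria$level[spec$equilibria$stable] * scale
      n_val <- stable[sample.int(length(stable), n_cells, replace = TRUE)]
    } else {
      n_val <- stats::runif(n_cells, 0, (spec$dimensionless$alpha + 1) * scale)
    }
    prod0 <- fb$c_b + fb$c_f * n_val^H / (K^H + n_val^H)
    r_val <- rho * prod0 / fb$c_d

    reflections <- 0
    KH <- K^H
    track_r <- rho > 0
    for (step in seq_len(n_steps)) {
      nH <- if (H == 2) n_val * n_val else n_val^H
      prod_rate <- fb$c_b + fb$c_f * nH / (KH + nH)
      n_val <- n_val + ((2 / g) * prod_rate - fb$c_d * n_val) * dt
      if (track_r) r_val <- r_val + (rho * prod_rate - fb$c_d * r_val) * dt
      if (spec$sigma > 0) {
        n_val <- n_val + sq * stats::rnorm(n_cells)
        if (track_r) r_val <- abs(r_val + sq * stats::rnorm(n_cells))
        neg <- n_val < 0
        reflections <- reflections + sum(neg)
        n_val <- abs(n_val)
      }
    }
    if (reflections > 0.01 * n_steps * n_cells) {
      warning("more than 1% of integration steps hit the reflecting boundary; ",
              "sigma may be large for these parameters")
    }
    meas <- function(v) {
      (spec$gain * v + spec$autofluorescence) *
        exp(spec$measurement_sdlog * stats::rnorm(n_cells))
    }
    out <- tibble::tibble(
      cell_id = seq_len(n_cells),
      nanog = meas(n_val),
      reporter = if (rho > 0) meas(r_val) else meas(rep(0, n_cells)),
      condition = spec$condition,
      day = 0L,
      replicate = 1L
    )
    attr(out, "ground_truth") <- list(
      classification = spec$classification,
      equilibria_dimensional = spec$equilibria$level * scale,
      stable = spec$equilibria$stable,
      spec = spec
    )
    out
  })
}

#' Generate a two-channel Gaussian-mixture sample
#'
#' Direct ground-truth control for recovery tests: draws cells from a
#' k-component bivariate Gaussian mixture on the log10 scale with a common
#' within-component correlation between the two channels, and returns linear
#' intensities.
#'
#' @param weights Component weights (sum to 1).
#' @param means Matrix (k x 2) of log10 means (columns: nanog, reporter), or
#'   a length-k vector used for both channels.
#' @param sds Matrix (k x 2) of log10 standard deviations, or a scalar /
#'   length-k vector.
#' @param correlation Within-component correlation, in (-1, 1).
#' @param n Number of cells.
#' @param seed Integer seed.
#' @param day,condition,replicate Metadata attached to the events.
#' @return An event tibble with attribute `ground_truth` (the mixture
#'   parameters and each cell's component).
#' @export
generate_mixture_sample <- function(weights, means, sds, correlation = 0,
                                    n, seed, day = 0L,
                                    condition = "synthetic", replicate = 1L) {
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1", call. = FALSE)
  if (abs(correlation) >= 1) stop("correlation must lie in (-1, 1)", call. = FALSE)
  k <- length(weights)
  if (is.vector(means)) means <- cbind(means, means)
  if (length(sds) == 1) sds <- matrix(sds, k, 2)
  if (is.vector(sds)) sds <- cbind(sds, sds)
  stopifnot(nrow(means) == k, nrow(sds) == k, all(sds > 0))
  withr::with_seed(seed, {
    comp <- sample.int(k, n, replace = TRUE, prob = weights)
    z1 <- stats::rnorm(n)
    z2 <- correlation * z1 + sqrt(1 - correlation^2) * stats::rnorm(n)
    log_nanog <- means[comp, 1] + sds[comp, 1] * z1
    log_rep <- means[comp, 2] + sds[comp, 2] * z2
    out <- tibble::tibble(
      cell_id = seq_len(n),
      nanog = 10^log_nanog,
      reporter = 10^log_rep,
      condition = condition,
      day = as.integer(day),
      replicate = as.integer(replicate)
    )
    attr(out, "ground_truth") <- list(weights = weights, means = means,
                                      sds = sds, correlation = correlation,
                                      component = comp)
    out
  })
}

#' Specification of a differentiation time-course
#'
#' Emulates an undirected-differentiation experiment sampled on a fixed day
#' schedule: a high-expressing subpopulation whose weight decays
#' exponentially over days while its mean drifts downward, over a stable
#' low-expressing background.
#'
#' @param days Strictly increasing day schedule.
#' @param n_cells Cells per day.
#' @param seed Integer seed.
#' @param weight_high_day0 Initial weight of the high-expressing component.
#' @param weight_decay_rate Exponential decay rate of that weight per day.
#' @param low_mean,high_mean log10 channel means (length 2: nanog, reporter)
#'   of the two components at day 0.
#' @param mean_drift log10 drift of the high component's means per day
#'   (negative = loss of expression).
#' @param sd log10 standard deviation of each component.
#' @param correlation Within-component channel correlation.
#' @return An object of class `timecourse_spec`.
#' @export
timecourse_spec <- function(days = c(0, 1, 2, 3, 5, 7), n_cells = 5000,
                            seed = 1L, weight_high_day0 = 0.85,
                            weight_decay_rate = 0.3,
                            low_mean = c(1.6, 1.6), high_mean = c(3.2, 3.2),
                            mean_drift = -0.08, sd = 0.25,
                            correlation = 0.6) {
  if (any(diff(days) <= 0)) stop("days must be strictly increasing", call. = FALSE)
  if (weight_high_day0 <= 0 || weight_high_day0 >= 1) {
    stop("weight_high_day0 must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(days = days, n_cells = as.integer(n_cells), seed = as.integer(seed),
         weight_high_day0 = weight_high_day0,
         weight_decay_rate = weight_decay_rate,
         low_mean = low_mean, high_mean = high_mean,
         mean_drift = mean_drift, sd = sd, correlation = correlation),
    class = "timecourse_spec"
  )
}

#' Generate a differentiation time-course
#'
#' One two-channel population per scheduled day, with the high-state weight
#' decaying as `w0 * exp(-rate * day)` (strictly decreasing for positive
#' rate) and the high component's log10 means drifting by
#' `mean_drift * day`. Per-day ground truth is attached.
#'
#' @param spec A [timecourse_spec()].
#' @return An event tibble covering all days, with attribute `ground_truth`
#'   (tibble: `day`, `weight_high`, `high_mean_nanog`, `high_mean_reporter`).
#' @examples
#' tc <- generate_timecourse(timecourse_spec(n_cells = 300, seed = 2))
#' table(tc$day)
#' @export
generate_timecourse <- function(spec) {
  stopifnot(inherits(spec, "timecourse_spec"))
  sub_seeds <- withr::with_seed(spec$seed,
                                sample.int(.Machine$integer.max - 1, length(spec$days)))
  pieces <- vector("list", length(spec$days))
  truth <- vector("list", length(spec$days))
  for (i in seq_along(spec$days)) {
    d <- spec$days[i]
    w_high <- spec$weight_high_day0 * exp(-spec$weight_decay_rate * d)
    hm <- spec$high_mean + spec$mean_drift * d
    pieces[[i]] <- generate_mixture_sample(
      weights = c(1 - w_high, w_high),
      means = rbind(spec$low_mean, hm),
      sds = spec$sd, correlation = spec$correlation,
      n = spec$n_cells, seed = sub_seeds[i], day = d,
      condition = "timecourse"
    )
    truth[[i]] <- tibble::tibble(day = d, weight_high = w_high,
                                 high_mean_nanog = hm[1],
                                 high_mean_reporter = hm[2])
  }
  out <- dplyr::bind_rows(pieces)
  out$cell_id <- seq_len(nrow(out))
  attr(out, "ground_truth") <- dplyr::bind_rows(truth)
  attr(out, "spec") <- spec
  out
}

#' Generate MESF calibration beads
#'
#' Bead populations with certified MESF values and measured intensities
#' `gain * MESF^slope`, optionally blurred by multiplicative lognormal noise.
#'
#' @param mesf_levels Certified MESF values (>= 2 distinct levels).
#' @param gain Intensity per MESF at slope 1.
#' @param slope Power-law exponent of the response.
#' @param noise_sdlog Lognormal measurement noise (natural-log sd).
#' @param seed Integer seed (used only when `noise_sdlog > 0`).
#' @return A [bead_set()].
#' @examples
#' generate_beads(c(1e3, 1e4, 1e5, 1e6), gain = 0.02, seed = 1)
#' @export
generate_beads <- function(mesf_levels, gain = 0.02, slope = 1,
                           noise_sdlog = 0, seed = 1L) {
  if (length(unique(mesf_levels)) < 2) {
    stop("need at least 2 distinct MESF levels", call. = FALSE)
  }
  mesf <- sort(unique(mesf_levels))
  intensity <- withr::with_seed(seed, {
    gain * mesf^slope * exp(noise_sdlog * stats::rnorm(length(mesf)))
  })
  bead_set(tibble::tibble(intensity = intensity, mesf = mesf))
}
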