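#' Validate a calibration-bead table
#'
#' A bead set pairs measured fluorescence intensities with certified MESF
#' (molecules of equivalent soluble fluorophore) values, one row per bead
#' population. At least two distinct levels are required and intensity must
#' increase strictly with MESF.
#'
#' @param beads A data frame with columns `intensity` and `mesf`.
#' @return A tibble of class `bead_set`, sorted by MESF.
#' @export
bead_set <- function(beads) {
  beads <- tibble::as_tibble(beads)
  if (!all(c("intensity", "mesf") %in% names(beads))) {
    stop("bead table needs columns `intensity` and `mesf`", call. = FALSE)
  }
  if (nrow(beads) < 2 || length(unique(beads$mesf)) < 2) {
    stop("calibration requires at least 2 distinct bead levels", call. = FALSE)
  }
  beads <- beads[order(beads$mesf), ]
  if (any(diff(beads$intensity) <= 0) || any(beads$intensity <= 0) || any(beads$mesf <= 0)) {
    stop("bead intensities must be positive and strictly increasing with MESF", call. = FALSE)
  }
  class(beads) <- c("bead_set", class(beads))
  beads
}

#' Calibrate fluorescence intensities to MESF units
#'
#' Fits a least-squares line of `log10(MESF)` on `log10(intensity)` through
#' the bead populations and maps the sample's channel values through the
#' fitted line, converting arbitrary fluorescence units to absolute MESF
#' units.
#'
#' @param sample An event table (tibble) with the channel column.
#' @param beads A [bead_set()] (or data frame coercible to one).
#' @param channel Column to calibrate, `"nanog"` or `"reporter"`.
#' @return The sample with the channel mapped to MESF; the calibration
#'   (class `mesf_calibration`: `intercept`, `slope`, `channel`) is stored in
#'   `attr(, "calibration")[[channel]]`.
#' @examples
#' beads <- generate_beads(c(1e3, 1e4, 1e5), gain = 0.02, seed = 1)
#' events <- tibble::tibble(nanog = c(50, 500))
#' attr(mesf_calibrate(events, beads, "nanog"), "calibration")$nanog
#' @export
mesf_calibrate <- function(sample, beads, channel = c("nanog", "reporter")) {
  channel <- match.arg(channel)
  if (!inherits(beads, "bead_set")) beads <- bead_set(beads)
  sample <- tibble::as_tibble(sample)
  if (!channel %in% names(sample)) {
    stop("sample has no column `", channel, "`", call. = FALSE)
  }
  fit <- stats::lm(log10(mesf) ~ log10(intensity), data = beads)
  coefs <- unname(stats::coef(fit))
  cal <- structure(list(intercept = coefs[1], slope = coefs[2], channel = channel),
                   class = "mesf_calibration")
  v <- sample[[channel]]
  if (any(v <= 0, na.rm = TRUE)) {
    stop("channel `", channel, "` has nonpositive intensities; ",
         "handle background before calibration", call. = FALSE)
  }
  sample[[channel]] <- predict_mesf(cal, v)
  cals <- attr(sample, "calibration") %||% list()
  cals[[channel]] <- cal
  attr(sample, "calibration") <- cals
  attr(sample, "units") <- "MESF"
  sample
}

#' @rdname mesf_calibrate
#' @param cal An `mesf_calibration` object.
#' @param intensity Intensities to convert to MESF.
#' @export
predict_mesf <- function(cal, intensity) {
  10^(cal$intercept + cal$slope * log10(intensity))
}

#' @rdname mesf_calibrate
#' @param mesf MESF values to convert back to raw intensity (inverse map).
#' @export
invert_mesf <- function(cal, mesf) {
  10^((log10(mesf) - cal$intercept) / cal$slope)
}

#' Align samples at the first percentile across days
#'
#' Flow-cytometry distributions measured on different days are made
#' comparable by shifting each day's log-intensities so that its 1st
#' percentile coincides with that of a reference day (a multiplicative
#' rescaling in linear units). The shift preserves distribution shape and is
#' idempotent.
#'
#' @param sample An event table with columns `day` and the channel(s).
#' @param channel Channel column name(s) to align.
#' @param reference_day Day whose percentile anchors the rest; defaults to
#'   the smallest day present.
#' @param prob Quantile used for the anchor (default 0.01).
#' @return The aligned sample; per-day log10 shifts in
#'   `attr(, "shifts")` (tibble `day`, `channel`, `shift`).
#' @export
align_first_percentile <- function(sample, channel = c("nanog", "reporter"),
                                   reference_day = NULL, prob = 0.01) {
  sample <- tibble::as_tibble(sample)
  if (!"day" %in% names(sample)) stop("sample needs a `day` column", call. = FALSE)
  channel <- intersect(channel, names(sample))
  if (length(channel) == 0) stop("no requested channel column present", call. = FALSE)
  days <- sort(unique(sample$day))
  if (is.null(reference_day)) reference_day <- days[1]
  if (!reference_day %in% days) stop("reference_day not present in the data", call. = FALSE)

  shifts <- tidyr::expand_grid(day = days, channel = channel)
  shifts$shift <- NA_real_
  for (ch in channel) {
    qs <- vapply(days, function(d) {
      v <- sample[[ch]][sample$day == d]
      v <- v[is.finite(v) & v > 0]
      if (length(v) < 10) stop("day ", d, " has fewer than 10 usable cells in `",
                               ch, "`", call. = FALSE)
      stats::quantile(log10(v), prob, names = FALSE)
    }, numeric(1))
    ref <- qs[match(reference_day, days)]
    for (i in seq_along(days)) {
      s <- ref - qs[i]
      idx <- sample$day == days[i]
      sample[[ch]][idx] <- sample[[ch]][idx] * 10^s
      shifts$shift[shifts$day == days[i] & shifts$channel == ch] <- s
    }
  }
  attr(sample, "shifts") <- shifts
  sample
}

gmm_loglik <- function(x, w, mu, sd) {
  dens <- vapply(seq_along(w),
                 function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                 numeric(length(x)))
  sum(log(rowSums(matrix(dens, nrow = length(x)))))
}

em_once <- function(x, mu, sd, w, var_floor, tol, max_iter) {
  n <- length(x)
  ll_old <- -Inf
  iter <- 0
  repeat {
    iter <- iter + 1
    dens <- cbind(w[1] * stats::dnorm(x, mu[1], sd[1]),
                  w[2] * stats::dnorm(x, mu[2], sd[2]))
    tot <- rowSums(dens)
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    resp <- dens / tot
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sd <- sqrt(pmax(colSums(resp * (outer(x, mu, "-"))^2) / nk, var_floor))
    ll <- sum(log(tot))
    if (iter >= max_iter || (ll - ll_old) < tol) {
      return(list(w = w, mu = mu, sd = sd, loglik = ll,
                  converged = (ll - ll_old) < tol, iterations = iter))
    }
    ll_old <- ll
  }
}

#' Fit a one- or two-component Gaussian mixture by EM
#'
#' Expectation-maximization on the supplied values (for fluorescence data the
#' convention throughout the package is log-transformed, aligned intensities).
#' The one-component fit is the closed-form maximum likelihood normal fit.
#' The two-component fit uses quantile-based initialization (component means
#' at the 25th/75th percentiles) followed by randomly jittered restarts,
#' convergence when the log-likelihood gain drops below `tol`, and a variance
#' floor of `1e-6` times the data variance. BIC is computed as
#' `-2*loglik + p*log(n)` with `p = 2` (k = 1) or `p = 5` (k = 2).
#'
#' @param values Numeric vector (>= 20 finite values).
#' @param k Number of components, 1 or 2.
#' @param seed Integer seed controlling the restarts.
#' @param n_restarts Number of EM starts for `k = 2` (the first is the
#'   deterministic quantile start).
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @return An object of class `gmm_fit`: list with `k`, `weight`, `mean`,
#'   `sd`, `loglik`, `bic`, `n`, `converged`, `iterations`.
#' @examples
#' x <- c(rnorm(100), rnorm(100, 4))
#' fit_gmm(x, k = 2, seed = 1)
#' @export
fit_gmm <- function(values, k, seed = 1L, n_restarts = 10, tol = 1e-8,
                    max_iter = 500) {
  x <- values[is.finite(values)]
  if (length(x) < 20) stop("fit_gmm needs at least 20 finite values", call. = FALSE)
  if (!k %in% c(1, 2)) stop("k must be 1 or 2", call. = FALSE)
  n <- length(x)
  if (stats::var(x) == 0) stop("degenerate data: all values identical", call. = FALSE)

  if (k == 1) {
    mu <- mean(x)
    sd_mle <- sqrt(mean((x - mu)^2))
    ll <- sum(stats::dnorm(x, mu, sd_mle, log = TRUE))
    fit <- list(w = 1, mu = mu, sd = sd_mle, loglik = ll,
                converged = TRUE, iterations = 0L)
  } else {
    var_floor <- 1e-6 * stats::var(x)
    qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    s0 <- stats::sd(x) / 2
    fit <- withr::with_seed(seed, {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        if (r == 1) {
          mu0 <- qs
        } else {
          mu0 <- stats::quantile(x, sort(stats::runif(2)), names = FALSE)
          if (diff(mu0) == 0) mu0 <- mu0 + c(-s0, s0) / 2
        }
        cand <- em_once(x, mu = mu0, sd = c(s0, s0), w = c(0.5, 0.5),
                        var_floor = var_floor, tol = tol, max_iter = max_iter)
        if (!is.null(cand) && (is.null(best) || cand$loglik > best$loglik)) best <- cand
      }
      best
    })
    if (is.null(fit)) stop("EM failed for every restart", call. = FALSE)
    ord <- order(fit$mu)
    fit$mu <- fit$mu[ord]; fit$sd <- fit$sd[ord]; fit$w <- fit$w[ord]
  }
  p <- if (k == 1) 2 else 5
  structure(
    list(k = k, weight = fit$w, mean = fit$mu, sd = fit$sd,
         loglik = fit$loglik, bic = -2 * fit$loglik + p * log(n),
         n = n, converged = fit$converged, iterations = fit$iterations),
    class = "gmm_fit"
  )
}

#' Select between one- and two-component mixture fits by BIC
#'
#' Lower BIC wins; an exact tie keeps the simpler (one-component) model.
#'
#' @param fit1,fit2 [fit_gmm()] results on the same data with `k = 1` and
#'   `k = 2`.
#' @return The chosen `gmm_fit`.
#' @export
select_model_bic <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "gmm_fit"), inherits(fit2, "gmm_fit"))
  if (fit1$n != fit2$n) stop("fits were computed on different sample sizes", call. = FALSE)
  if (fit1$k > fit2$k) { tmp <- fit1; fit1 <- fit2; fit2 <- tmp }
  if (fit1$bic <= fit2$bic) fit1 else fit2
}

#' Robust-bimodality criteria for a two-component fit
#'
#' A two-component fit is accepted as robustly bimodal iff (a) both
#' component weights exceed 0.1 and (b) each component's weighted peak
#' density exceeds the other component's weighted density at that peak:
#' `w_i * phi_i(mu_i) > w_j * phi_j(mu_i)` for both components. Violations
#' are reported as reason codes `"weight"` and `"peak_dominance"`.
#'
#' @param fit A [fit_gmm()] result with `k = 2`.
#' @param min_weight Weight threshold (default 0.1).
#' @return An object of class `bimodality_verdict`: list with `bimodal`
#'   (logical) and `reasons` (character).
#' @export
bimodality_filter <- function(fit, min_weight = 0.1) {
  stopifnot(inherits(fit, "gmm_fit"))
  if (fit$k != 2) stop("bimodality_filter requires a two-component fit", call. = FALSE)
  reasons <- character()
  if (any(fit$weight <= min_weight)) reasons <- c(reasons, "weight")
  peak_ok <- vapply(1:2, function(i) {
    j <- 3 - i
    fit$weight[i] * stats::dnorm(fit$mean[i], fit$mean[i], fit$sd[i]) >
      fit$weight[j] * stats::dnorm(fit$mean[i], fit$mean[j], fit$sd[j])
  }, logical(1))
  if (!all(peak_ok)) reasons <- c(reasons, "peak_dominance")
  structure(list(bimodal = length(reasons) == 0, reasons = reasons),
            class = "bimodality_verdict")
}

#' Bayesian-blocks segmentation of a univariate sample
#'
#' Optimal piecewise-constant segmentation of the empirical measure by
#' dynamic programming with the event (point-measure) fitness
#' `N * (log N - log T)` per block and a change-point prior calibrated to a
#' false-alarm rate `p0` (the standard empirical calibration
#' `4 - log(73.53 * p0 * n^(-0.478))`). The resulting edges adapt bin widths
#' to the local density and are invariant under affine transformation of the
#' data.
#'
#' @param values Numeric vector with at least 4 distinct values (fewer
#'   triggers a single-bin fallback with a warning).
#' @param p0 False-alarm probability for a spurious change point.
#' @return Strictly increasing numeric vector of bin edges spanning the data.
#' @examples
#' x <- c(rnorm(200), rnorm(200, 8))
#' bayesian_blocks(x)
#' @export
bayesian_blocks <- function(values, p0 = 0.05) {
  x <- values[is.finite(values)]
  ux <- sort(unique(x))
  K <- length(ux)
  if (K < 4) {
    warning("fewer than 4 distinct values; returning a single bin")
    if (K < 2) return(c(ux[1] - 0.5, ux[1] + 0.5))
    return(range(ux))
  }
  n <- length(x)
  wts <- tabulate(match(x, ux))
  edges <- c(ux[1], (ux[-1] + ux[-K]) / 2, ux[K])
  ncp_prior <- 4 - log(73.53 * p0 * n^(-0.478))

  best <- numeric(K)
  last <- integer(K)
  cw <- c(0, cumsum(wts))
  for (r in seq_len(K)) {
    width <- edges[r + 1] - edges[seq_len(r)]
    cnt <- cw[r + 1] - cw[seq_len(r)]
    fitness <- cnt * (log(cnt) - log(width)) - ncp_prior +
      c(0, best[seq_len(r - 1)])
    last[r] <- which.max(fitness)
    best[r] <- max(fitness)
  }
  cps <- integer(0)
  i <- K
  while (i > 0) {
    cps <- c(last[i], cps)
    i <- last[i] - 1L
  }
  unname(edges[c(cps, K + 1L)])
}

#' Shrinkage estimate of mutual information between two channels
#'
#' Discretizes each variable separately with [bayesian_blocks()], forms the
#' joint contingency table, shrinks the cell frequencies toward a uniform
#' target over the occupied cells with the closed-form James-Stein optimal
#' intensity (clipped to \[0, 1\]), and computes the mutual information of
#' the shrunken joint distribution against the product of its margins, in
#' nats. A margin reduced to a single block yields MI = 0 with a warning.
#'
#' @param x,y Paired numeric observations (n >= 20).
#' @param p0 False-alarm rate passed to [bayesian_blocks()].
#' @return An object of class `mi_estimate`: list with `value` (nats),
#'   `edges_x`, `edges_y`, `table`, `lambda` (shrinkage intensity), `n`.
#' @examples
#' s <- sample_joint_counts(
#'   joint_count_model(allele_kinetics(50, 1), regulator("gamma", shape = 2, scale = 0.5)),
#'   1000, seed = 1)
#' mi_shrinkage(s$m1, s$m2)$value
#' @export
mi_shrinkage <- function(x, y, p0 = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 20) stop("mi_shrinkage needs at least 20 paired observations", call. = FALSE)
  ex <- suppressWarnings(bayesian_blocks(x, p0 = p0))
  ey <- suppressWarnings(bayesian_blocks(y, p0 = p0))
  bx <- findInterval(x, ex, rightmost.closed = TRUE, all.inside = TRUE)
  by <- findInterval(y, ey, rightmost.closed = TRUE, all.inside = TRUE)
  tab <- table(factor(bx, levels = seq_len(length(ex) - 1)),
               factor(by, levels = seq_len(length(ey) - 1)))
  out <- list(value = 0, edges_x = ex, edges_y = ey, table = tab,
              lambda = NA_real_, n = n)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warning("a margin collapsed to a single block; MI set to 0")
    return(structure(out, class = "mi_estimate"))
  }
  u <- as.vector(tab) / n
  occ <- u > 0
  target <- ifelse(occ, 1 / sum(occ), 0)
  denom <- (n - 1) * sum((target - u)^2)
  lambda <- if (denom <= 0) 0 else (1 - sum(u^2)) / denom
  lambda <- min(max(lambda, 0), 1)
  p <- lambda * target + (1 - lambda) * u
  pm <- matrix(p, nrow = nrow(tab))
  px <- rowSums(pm); py <- colSums(pm)
  nz <- pm > 0
  mi <- sum(pm[nz] * log(pm[nz] / outer(px, py)[nz]))
  out$value <- max(mi, 0)
  out$lambda <- lambda
  structure(out, class = "mi_estimate")
}
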