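#' Read and validate a study configuration
#'
#' Study configurations are YAML files with a `study` kind
#' (`risk_scan`, `coexpression`, `timecourse` or `flow_analysis`) and
#' kind-specific parameter blocks. Unknown keys are rejected before any
#' computation so that typos fail fast.
#'
#' @param path Path to a YAML file, or a list already in memory.
#' @return The validated configuration (class `study_config`).
#' @export
read_study_config <- function(path) {
  config <- if (is.character(path)) yaml::read_yaml(path) else path
  validate_study_config(config)
}

config_schema <- list(
  risk_scan = c("study", "seed", "hill", "designs", "alpha", "gamma"),
  coexpression = c("study", "seed", "lambda", "n_draws", "regulators"),
  timecourse = c("study", "seed", "days", "n_cells", "weight_high_day0",
                 "weight_decay_rate", "mean_drift"),
  flow_analysis = c("study", "seed", "events", "beads", "reference_day",
                    "channels")
)

#' @rdname read_study_config
#' @param config A configuration list.
#' @export
validate_study_config <- function(config) {
  if (!is.list(config) || is.null(config$study)) {
    stop("configuration must be a list with a `study` kind", call. = FALSE)
  }
  kinds <- names(config_schema)
  if (!config$study %in% kinds) {
    stop("unknown study kind `", config$study, "`; expected one of: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  allowed <- config_schema[[config$study]]
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(config, class = c("study_config", "list"))
}

design_from_config <- function(block) {
  reporter_design(
    kind = block$kind,
    epsilon = block$epsilon %||% 1,
    delta = block$delta %||% 1,
    insert_count = block$insert_count %||% 1L
  )
}

regulator_from_config <- function(block) {
  do.call(regulator, block)
}

provenance <- function(config, seed) {
  list(config_hash = rlang::hash(config),
       seed = seed,
       package = "reporterfidelity",
       version = as.character(utils::packageVersion("reporterfidelity")))
}

write_outputs <- function(tables, report, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Scan reporter designs for bifurcation risk
#'
#' For every design in the configuration, builds a [risk_map()] over the
#' requested `(alpha, gamma)` grid and summarizes the fraction of grid cells
#' whose stability classification changes when the reporter is introduced.
#'
#' @param config A `study_config` of kind `risk_scan` (or a list/path
#'   accepted by [read_study_config()]).
#' @param out_dir Optional output directory; per-design grids are written as
#'   CSV and a JSON report with provenance is produced.
#' @return A list with `maps` (named list of risk maps), `summary` (tibble:
#'   `design`, `gamma_factor`, `n_cells`, `at_risk_fraction`) and
#'   `provenance`.
#' @examples
#' cfg <- list(study = "risk_scan", hill = 2,
#'             designs = list(list(kind = "knock_in"), list(kind = "bac")),
#'             alpha = list(from = 0.01, to = 0.12, n = 4),
#'             gamma = list(from = 0.05, to = 1, n = 4))
#' run_risk_scan(cfg)$summary
#' @export
run_risk_scan <- function(config, out_dir = NULL) {
  config <- read_study_config(config)
  stopifnot(config$study == "risk_scan")
  H <- config$hill %||% 2
  alpha <- with(config$alpha, seq(from, to, length.out = n))
  gamma <- with(config$gamma, seq(from, to, length.out = n))
  maps <- list()
  rows <- list()
  for (block in config$designs) {
    design <- design_from_config(block)
    rm_ <- risk_map(design, alpha = alpha, gamma = gamma, H = H)
    maps[[design$kind]] <- rm_
    rows[[design$kind]] <- tibble::tibble(
      design = design$kind,
      gamma_factor = attr(rm_, "gamma_factor"),
      n_cells = nrow(rm_),
      at_risk_fraction = mean(rm_$at_risk)
    )
  }
  summary <- dplyr::bind_rows(rows)
  prov <- provenance(config, config$seed %||% NA)
  tables <- c(stats::setNames(lapply(maps, tibble::as_tibble),
                              paste0("risk_", names(maps))),
              list(risk_summary = summary))
  write_outputs(tables, list(study = "risk_scan", summary = summary,
                             provenance = prov), out_dir)
  list(maps = maps, summary = summary, provenance = prov)
}

#' Coexpression study across regulator settings
#'
#' For each regulator setting, samples stationary transcript-count pairs from
#' the two-allele model, and tabulates the analytic covariance/correlation
#' against their empirical counterparts together with the estimated mutual
#' information between the allele outputs.
#'
#' @param config A `study_config` of kind `coexpression`: `lambda` (per-allele
#'   mean), `n_draws`, `seed`, and `regulators`, a named list of regulator
#'   blocks passed to [regulator()].
#' @param out_dir Optional output directory (CSV table + JSON report).
#' @return A list with `table` (one row per setting) and `provenance`.
#' @examples
#' cfg <- list(study = "coexpression", seed = 1, lambda = 50, n_draws = 200,
#'             regulators = list(constant = list(family = "constant", value = 1),
#'                               dispersed = list(family = "gamma", shape = 2, scale = 0.5)))
#' run_coexpression_study(cfg)$table
#' @export
run_coexpression_study <- function(config, out_dir = NULL) {
  config <- read_study_config(config)
  stopifnot(config$study == "coexpression")
  lam <- config$lambda %||% 50
  n <- config$n_draws %||% 1000
  seed <- config$seed %||% 1L
  ak <- allele_kinetics(birth_rate_1 = lam, decay_rate_1 = 1)
  rows <- list()
  for (nm in names(config$regulators)) {
    reg <- regulator_from_config(config$regulators[[nm]])
    model <- joint_count_model(ak, reg)
    draws <- sample_joint_counts(model, n, seed = seed)
    mi <- mi_shrinkage(draws$m1, draws$m2)
    rows[[nm]] <- tibble::tibble(
      setting = nm,
      family = reg$family,
      regulator_var = reg$var,
      cov_analytic = joint_covariance(model),
      cov_empirical = stats::cov(draws$m1, draws$m2),
      cor_analytic = allelic_correlation(model),
      cor_empirical = stats::cor(draws$m1, draws$m2),
      mi = mi$value
    )
  }
  table <- dplyr::bind_rows(rows)
  prov <- provenance(config, seed)
  write_outputs(list(coexpression = table),
                list(study = "coexpression", table = table, provenance = prov),
                out_dir)
  list(table = table, provenance = prov)
}

#' Time-course study: generation plus per-day analysis
#'
#' Generates a differentiation time-course with [generate_timecourse()] and
#' runs the flow pipeline on it ([run_flow_analysis()]), returning per-day
#' mixture verdicts and mutual information alongside the generator's ground
#' truth.
#'
#' @param config A `study_config` of kind `timecourse`; keys map onto
#'   [timecourse_spec()] arguments.
#' @param out_dir Optional output directory.
#' @return A list with `events`, `analysis` (see [run_flow_analysis()]),
#'   `truth`, and `provenance`.
#' @export
run_timecourse_study <- function(config, out_dir = NULL) {
  config <- read_study_config(config)
  stopifnot(config$study == "timecourse")
  spec <- timecourse_spec(
    days = config$days %||% c(0, 1, 2, 3, 5, 7),
    n_cells = config$n_cells %||% 5000,
    seed = config$seed %||% 1L,
    weight_high_day0 = config$weight_high_day0 %||% 0.85,
    weight_decay_rate = config$weight_decay_rate %||% 0.3,
    mean_drift = config$mean_drift %||% -0.08
  )
  events <- generate_timecourse(spec)
  analysis <- run_flow_analysis(events, config = list(seed = spec$seed))
  prov <- provenance(config, spec$seed)
  write_outputs(list(timecourse_per_day = analysis$per_group),
                list(study = "timecourse", per_day = analysis$per_group,
                     truth = attr(events, "ground_truth"), provenance = prov),
                out_dir)
  list(events = events, analysis = analysis,
       truth = attr(events, "ground_truth"), provenance = prov)
}

#' End-to-end flow-cytometry analysis
#'
#' The full statistics pipeline on a per-cell event table: optional MESF
#' calibration of both channels, first-percentile alignment across days,
#' log10 transformation (nonpositive intensities are excluded and the
#' excluded fraction reported), per condition-day Gaussian-mixture fits with
#' BIC model selection and the robust-bimodality criteria, and shrinkage
#' mutual information between the two channels.
#'
#' @param events An event tibble or path to a CSV with columns `cell_id`,
#'   `nanog`, `reporter`, `condition`, `day`, `replicate`.
#' @param beads Optional [bead_set()] (or bead CSV path) for MESF
#'   calibration.
#' @param config Optional list: `seed` (GMM restarts), `reference_day`,
#'   `p0` (Bayesian-blocks false-alarm rate), `min_cells` (minimum events per
#'   group, default 20).
#' @param out_dir Optional output directory (per-group CSV + JSON report).
#' @return A list of class `flow_report`: `per_group` (tibble with one row
#'   per condition-day: fits, verdicts, MI), `shifts`, `calibration`,
#'   `excluded_fraction`, `provenance`.
#' @export
run_flow_analysis <- function(events, beads = NULL, config = list(),
                              out_dir = NULL) {
  if (is.character(events)) events <- readr::read_csv(events, show_col_types = FALSE)
  events <- tibble::as_tibble(events)
  required <- c("cell_id", "nanog", "reporter", "condition", "day", "replicate")
  missing <- setdiff(required, names(events))
  if (length(missing) > 0) {
    stop("event table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  seed <- config$seed %||% 1L
  p0 <- config$p0 %||% 0.05
  min_cells <- config$min_cells %||% 20

  calibration <- NULL
  if (!is.null(beads)) {
    if (is.character(beads)) beads <- readr::read_csv(beads, show_col_types = FALSE)
    beads <- bead_set(beads)
    events <- mesf_calibrate(events, beads, "nanog")
    events <- mesf_calibrate(events, beads, "reporter")
    calibration <- attr(events, "calibration")
  }

  shifts <- NULL
  if (length(unique(events$day)) > 1) {
    events <- align_first_percentile(events, channel = c("nanog", "reporter"),
                                     reference_day = config$reference_day)
    shifts <- attr(events, "shifts")
  }

  n_total <- nrow(events)
  usable <- is.finite(events$nanog) & events$nanog > 0
  excluded_fraction <- 1 - mean(usable)
  events <- events[usable, ]

  groups <- dplyr::distinct(events, .data$condition, .data$day)
  rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    sub <- dplyr::filter(events, .data$condition == groups$condition[i],
                         .data$day == groups$day[i])
    ln <- log10(sub$nanog)
    row <- tibble::tibble(condition = groups$condition[i], day = groups$day[i],
                          n_cells = nrow(sub))
    if (nrow(sub) >= min_cells && stats::var(ln) > 0) {
      f1 <- fit_gmm(ln, k = 1, seed = seed)
      f2 <- fit_gmm(ln, k = 2, seed = seed)
      sel <- select_model_bic(f1, f2)
      verdict <- if (sel$k == 2) bimodality_filter(f2) else
        structure(list(bimodal = FALSE, reasons = "bic_single_component"),
                  class = "bimodality_verdict")
      row$k_selected <- sel$k
      row$bic_k1 <- f1$bic
      row$bic_k2 <- f2$bic
      row$bimodal <- verdict$bimodal
      row$reasons <- paste(verdict$reasons, collapse = ";")
      row$weight_high <- if (sel$k == 2) sel$weight[2] else NA_real_
      row$mean_low <- sel$mean[1]
      row$mean_high <- sel$mean[length(sel$mean)]
    } else {
      row$k_selected <- NA_integer_; row$bic_k1 <- NA_real_; row$bic_k2 <- NA_real_
      row$bimodal <- NA; row$reasons <- "too_few_cells"
      row$weight_high <- NA_real_; row$mean_low <- NA_real_; row$mean_high <- NA_real_
    }
    rep_ok <- is.finite(sub$reporter) & sub$reporter > 0
    if (sum(rep_ok) >= min_cells && stats::var(sub$reporter[rep_ok]) > 0) {
      mi <- mi_shrinkage(log10(sub$nanog[rep_ok]), log10(sub$reporter[rep_ok]),
                         p0 = p0)
      row$mi_nats <- mi$value
    } else {
      row$mi_nats <- NA_real_
    }
    rows[[i]] <- row
  }
  per_group <- dplyr::arrange(dplyr::bind_rows(rows), .data$condition, .data$day)
  prov <- provenance(list(config = config, n_events = n_total), seed)
  report <- structure(
    list(per_group = per_group, shifts = shifts, calibration = calibration,
         excluded_fraction = excluded_fraction, provenance = prov),
    class = "flow_report"
  )
  write_outputs(list(flow_per_group = per_group),
                list(study = "flow_analysis", per_group = per_group,
                     excluded_fraction = excluded_fraction, provenance = prov),
                out_dir)
  report
}
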