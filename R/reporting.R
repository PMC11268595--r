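#' Run manifest for reproducibility
#'
#' A small provenance record attached to written reports: a hash of the
#' generating configuration, the master seed, the package version and the
#' per-stage parameters, so every output file can be traced to the run that
#' produced it.
#'
#' @param config The run configuration (any serializable object, e.g. a
#'   [cohort_config()]).
#' @param seed Master seed of the run.
#' @param params Named list of stage parameters (R, K, delta,
#'   grid_resolution, cutoffs, ...).
#' @return A list of class `run_manifest` with a `config_hash` field.
#' @export
run_manifest <- function(config, seed, params = list()) {
  structure(list(
    config_hash = rlang::hash(config),
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("fairmhc")),
    params = params,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' Write a report to JSON and tidy CSV
#'
#' Serializes an [audit_composition()] or [summarize_fairness()] report as
#' a nested JSON file plus a flat CSV (one row per attribute x metric x
#' repeat for fairness reports; per-group counts and rates for audit
#' reports). Undefined values are written as explicit `NA` rows carrying a
#' reason note, never silently dropped. The report is validated before any
#' file is written, so a schema violation leaves no partial output.
#'
#' @param report An `audit_report` or `fairness_report`.
#' @param dir Output directory (created if missing).
#' @param name Base file name (default: the report class).
#' @param manifest Optional [run_manifest()] embedded in the JSON.
#' @return Invisibly, the paths written (`json`, `csv`).
#' @export
write_report <- function(report, dir, name = class(report)[1],
                         manifest = NULL) {
  UseMethod("write_report")
}

#' @export
write_report.fairness_report <- function(report, dir, name = "fairness_report",
                                         manifest = NULL) {
  validate_fairness_report(report)
  write_report_impl(report, dir, name, manifest, csv_part = report$metrics)
}

#' @export
write_report.audit_report <- function(report, dir, name = "audit_report",
                                      manifest = NULL) {
  validate_audit_report(report)
  write_report_impl(report, dir, name, manifest, csv_part = report$composition)
}

write_report_impl <- function(report, dir, name, manifest, csv_part) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  payload <- unclass(report)
  payload$manifest <- if (!is.null(manifest)) unclass(manifest)
  json_path <- file.path(dir, paste0(name, ".json"))
  csv_path <- file.path(dir, paste0(name, ".csv"))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  readr::write_csv(csv_part, csv_path, na = "NA")
  invisible(list(json = json_path, csv = csv_path))
}

validate_fairness_report <- function(report) {
  stopifnot(inherits(report, "fairness_report"))
  need <- c("attribute", "modality", "mitigation", "repeat", "metric",
            "value", "note")
  if (!is.data.frame(report$metrics) || nrow(report$metrics) == 0 ||
      !all(need %in% names(report$metrics))) {
    stop("invalid or empty fairness report; nothing written", call. = FALSE)
  }
  invisible(report)
}

validate_audit_report <- function(report) {
  stopifnot(inherits(report, "audit_report"))
  if (!is.data.frame(report$composition) || nrow(report$composition) == 0) {
    stop("invalid or empty audit report; nothing written", call. = FALSE)
  }
  invisible(report)
}

#' Read a report back from its JSON file
#'
#' Restores the report object written by [write_report()]; a written-then-
#' read report is equal to the original in all data fields.
#'
#' @param path Path to the `.json` file.
#' @return A `fairness_report` or `audit_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tblize <- function(d) if (is.data.frame(d)) tibble::as_tibble(d) else d
  if (!is.null(x$metrics)) {
    x$metrics <- tblize(x$metrics)
    x$metrics$note <- as.character(x$metrics$note)  # all-NA columns lose type
    x$summary <- tblize(x$summary)
    structure(x[c("metrics", "summary", "delta")], class = "fairness_report")
  } else {
    for (f in c("composition", "independence_tests", "covariate_tests",
                "exclusions")) x[[f]] <- tblize(x[[f]])
    structure(x[c("composition", "independence_tests", "covariate_tests",
                  "exclusions", "n_tests", "alpha")], class = "audit_report")
  }
}

#' Boxplot of per-repeat fairness metric distributions
#'
#' Median / IQR boxplots with 1.5-IQR whiskers and outlier marks, one panel
#' per metric, colored by modality and faceted over attributes — the
#' conventional presentation of repeated-CV fairness distributions.
#' Requires ggplot2.
#'
#' @param report A `fairness_report`.
#' @param metrics Metrics to plot (default: the four fairness ratios).
#' @return A ggplot object.
#' @export
plot_fairness <- function(report,
                          metrics = c("dpr_overall", "dpr_privileged",
                                      "eor_overall", "eor_privileged")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_fairness() requires the ggplot2 package", call. = FALSE)
  }
  d <- report$metrics[report$metrics$metric %in% metrics &
                        !is.na(report$metrics$value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$modality, y = .data$value,
                                  fill = .data$mitigation)) +
    ggplot2::geom_boxplot(outlier.shape = 18) +
    ggplot2::facet_grid(metric ~ attribute) +
    ggplot2::labs(x = NULL, y = "ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
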