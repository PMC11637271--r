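# Report writers tying the analyses together: each command writes its
# CSV/JSON outputs plus a JSON run manifest (command, config, seed,
# timestamp, package version, output paths) for provenance.

write_manifest <- function(command, out_dir, outputs, config = NA,
                           seed = NA) {
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("herniaCEA")),
    outputs = outputs)
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

load_config_or_default <- function(config) {
  if (is.null(config)) default_parameters()
  else if (is.character(config)) load_parameters(config)
  else validate_parameters(unclass(config))
}

#' Write the cost-effectiveness report
#'
#' Runs the full base-case and subgroup analysis and writes it as CSV and
#' JSON (mirroring the published table layout: base case plus the
#' moderate and severe pre-operative pain subgroups) with a run manifest.
#'
#' @param config a YAML path, a \code{hernia_params} object, or
#'   \code{NULL} for the defaults.
#' @param out_dir output directory (created if absent).
#' @return The \code{hernia_cea} object, invisibly.
#' @export
write_cea_report <- function(config = NULL, out_dir = ".") {
  params <- load_config_or_default(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cea <- hernia_cea(params)
  df <- as.data.frame(cea)
  csv <- file.path(out_dir, "cea_report.csv")
  json <- file.path(out_dir, "cea_report.json")
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(df, json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  write_manifest("cea", out_dir, c(csv, json),
                 config = if (is.character(config)) config else NA)
  invisible(cea)
}

#' Write the deterministic sensitivity (tornado) report
#'
#' @inheritParams write_cea_report
#' @param comparison pairwise ICER to analyse.
#' @param plot also write a tornado plot (PDF)?
#' @return The \code{hernia_dsa} object, invisibly.
#' @export
write_dsa_report <- function(config = NULL, out_dir = ".",
                             comparison = "ac_vs_none", plot = FALSE) {
  params <- load_config_or_default(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dsa <- one_way_dsa(params, comparison = comparison)
  csv <- file.path(out_dir, "tornado.csv")
  utils::write.csv(as.data.frame(dsa), csv, row.names = FALSE)
  outputs <- csv
  if (plot) {
    pdf <- file.path(out_dir, "tornado.pdf")
    grDevices::pdf(pdf, width = 8, height = 5)
    plot(dsa); grDevices::dev.off()
    outputs <- c(outputs, pdf)
  }
  write_manifest("dsa", out_dir, outputs,
                 config = if (is.character(config)) config else NA)
  invisible(dsa)
}

#' Write the probabilistic sensitivity report
#'
#' Writes the per-draw increments, the acceptability curve, and
#' optionally cost-effectiveness plane / CEAC plots.  Identical config
#' and seed give byte-identical draw files.
#'
#' @inheritParams write_cea_report
#' @param n number of simulations.
#' @param seed RNG seed (recorded in the manifest and output).
#' @param plot also write plots (PDF)?
#' @return The \code{hernia_psa} object, invisibly.
#' @export
write_psa_report <- function(config = NULL, out_dir = ".", n = 1000,
                             seed = 1L, plot = FALSE) {
  params <- load_config_or_default(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(params, n = n, seed = seed)
  draws_csv <- file.path(out_dir, "psa_draws.csv")
  utils::write.csv(cbind(draw = seq_len(psa$n), psa$draws,
                         psa$increments),
                   draws_csv, row.names = FALSE)
  curve <- ceac(psa)
  ceac_csv <- file.path(out_dir, "ceac.csv")
  utils::write.csv(as.data.frame(curve), ceac_csv, row.names = FALSE)
  outputs <- c(draws_csv, ceac_csv)
  if (plot) {
    pdf <- file.path(out_dir, "psa_plots.pdf")
    grDevices::pdf(pdf, width = 7, height = 5)
    for (cm in psa$comparisons) plot(psa, comparison = cm,
                                     wtp = params$thresholds$wtp)
    plot(curve)
    grDevices::dev.off()
    outputs <- c(outputs, pdf)
  }
  write_manifest("psa", out_dir, outputs, seed = seed,
                 config = if (is.character(config)) config else NA)
  invisible(psa)
}

#' Write the budget-impact report
#'
#' Writes the per-year projection for the requested scenario and a JSON
#' scenario summary.
#'
#' @inheritParams write_cea_report
#' @param scenario \code{"baseline"}, \code{"open"} or \code{"capped"}.
#' @param ceiling cumulative budget (USD) for the capped scenario.
#' @return The \code{hernia_bia} object, invisibly.
#' @export
write_bia_report <- function(config = NULL, out_dir = ".",
                             scenario = c("open", "baseline", "capped"),
                             ceiling = 10e6) {
  params <- load_config_or_default(config)
  scenario <- match.arg(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  b <- params$budget_impact
  oc <- weighted_op_cost(params)
  proj <- switch(scenario,
                 baseline = project_backlog(b),
                 open = open_budget_scenario(b, oc),
                 capped = capped_budget_scenario(b, ceiling, oc))
  csv <- file.path(out_dir, paste0("bia_", scenario, ".csv"))
  utils::write.csv(as.data.frame(proj), csv, row.names = FALSE)
  summ <- list(scenario = scenario,
               initial_backlog = attr(proj, "initial_backlog"),
               total_backlog = attr(proj, "total_backlog"),
               total_cost = proj$cumulative_cost[nrow(proj)],
               providers_trained = attr(proj, "providers_trained"),
               facilities_renovated = attr(proj, "facilities_renovated"),
               fraction_addressed = attr(proj, "fraction_addressed"))
  json <- file.path(out_dir, paste0("bia_", scenario, "_summary.json"))
  jsonlite::write_json(summ[!vapply(summ, is.null, logical(1))], json,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(paste0("bia_", scenario), out_dir, c(csv, json),
                 config = if (is.character(config)) config else NA)
  invisible(proj)
}
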