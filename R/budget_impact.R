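#' Share-weighted average cost per repair
#'
#' The expected per-operation cost of the national task-sharing mix
#' (default 68\% MD at USD 163, 32\% AC at USD 149).
#'
#' @param params a \code{hernia_params} object.
#' @return USD per repair.
#' @export
weighted_op_cost <- function(params = default_parameters()) {
  b <- params$budget_impact
  b$share_md * params$strategies$md$cost_per_procedure +
    b$share_ac * params$strategies$ac$cost_per_procedure
}

bia_core <- function(settings) {
  y <- seq_len(settings$horizon_years)
  pop <- settings$population * (1 + settings$population_growth)^y
  list(years = settings$start_year - 1 + y,
       population = pop,
       initial_backlog = settings$prevalence * settings$population,
       incident = settings$incidence_per_100k / 1e5 * pop,
       baseline_repairs = settings$repair_rate_per_100k / 1e5 * pop)
}

bia_projection <- function(core, repairs, annual_extra_cost,
                           avg_op_cost, scenario,
                           providers = NULL, facilities = NULL) {
  n <- length(core$years)
  backlog <- numeric(n)
  clipped <- FALSE
  b <- core$initial_backlog
  for (i in seq_len(n)) {
    b <- b + core$incident[i] - repairs[i]
    if (b < 0) { b <- 0; clipped <- TRUE }
    backlog[i] <- b
  }
  if (clipped)
    message("budget impact: backlog clipped at zero before the horizon end")
  annual_cost <- repairs * avg_op_cost + annual_extra_cost
  out <- data.frame(year = core$years,
                    population = core$population,
                    incident_cases = core$incident,
                    repairs = repairs,
                    backlog = backlog,
                    providers_cum = if (is.null(providers)) NA else providers,
                    facilities_cum = if (is.null(facilities)) NA else facilities,
                    annual_cost = annual_cost,
                    cumulative_cost = cumsum(annual_cost))
  structure(out, scenario = scenario,
            initial_backlog = core$initial_backlog,
            total_backlog = core$initial_backlog + sum(core$incident),
            class = c("hernia_bia", "data.frame"))
}

#' Project the backlog without expanded surgical capacity
#'
#' Status-quo projection: the prevalent pool plus annual incidence, less
#' repairs at the contemporary baseline rate, with geometric population
#' growth.  A negative backlog is clipped at zero (with a message).
#'
#' @param settings the \code{budget_impact} block of a
#'   \code{hernia_params} object.
#' @return A \code{hernia_bia} data frame, one row per year.
#' @export
project_backlog <- function(settings) {
  stopifnot(settings$population > 0)
  core <- bia_core(settings)
  bia_projection(core, repairs = core$baseline_repairs,
                 annual_extra_cost = 0, avg_op_cost = 0,
                 scenario = "baseline")
}

#' Open-budget backlog elimination scenario
#'
#' Schedules repairs (spread evenly over the horizon) so that the entire
#' 10-year backlog — the initial prevalent pool plus accumulated
#' incidence — is cleared by the final year.  Costs comprise operations
#' at the share-weighted AC/MD cost, training of the required providers
#' (sized from repairs per provider-year) and renovation of the required
#' facilities (three providers per facility), charged as the workforce is
#' built up.
#'
#' @param settings the \code{budget_impact} block.
#' @param avg_op_cost USD per operation; defaults to
#'   \code{\link{weighted_op_cost}} of the default strategies.
#' @return A \code{hernia_bia} data frame with attributes
#'   \code{providers_trained}, \code{facilities_renovated},
#'   \code{total_cost}.
#' @export
open_budget_scenario <- function(settings,
                                 avg_op_cost = weighted_op_cost()) {
  core <- bia_core(settings)
  n <- settings$horizon_years
  total <- core$initial_backlog + sum(core$incident)
  repairs <- rep(total / n, n)

  prov_cum <- ceiling(cummax(repairs / settings$repairs_per_provider_year))
  fac_cum <- ceiling(prov_cum / settings$providers_per_facility)
  training <- diff(c(0, prov_cum)) * settings$training_cost
  renovation <- diff(c(0, fac_cum)) * settings$renovation_cost

  out <- bia_projection(core, repairs, training + renovation,
                        avg_op_cost, "open_budget",
                        providers = prov_cum, facilities = fac_cum)
  attr(out, "providers_trained") <- prov_cum[n]
  attr(out, "facilities_renovated") <- fac_cum[n]
  attr(out, "total_cost") <- out$cumulative_cost[n]
  out
}

#' Capped-budget expansion scenario
#'
#' Funds expansion repairs — at the share-weighted operation cost plus a
#' proportional training/renovation overhead per repair — until the
#' cumulative budget ceiling is exhausted, and reports the fraction of
#' the total 10-year backlog addressed.
#'
#' @param settings the \code{budget_impact} block.
#' @param ceiling cumulative budget, USD.
#' @param avg_op_cost USD per operation.
#' @return A \code{hernia_bia} data frame with attributes
#'   \code{funded_repairs}, \code{fraction_addressed},
#'   \code{cost_per_repair}.
#' @export
capped_budget_scenario <- function(settings, ceiling,
                                   avg_op_cost = weighted_op_cost()) {
  stopifnot(ceiling >= 0)
  core <- bia_core(settings)
  n <- settings$horizon_years
  total <- core$initial_backlog + sum(core$incident)

  overhead <- settings$training_cost /
    (settings$repairs_per_provider_year * n) +
    settings$renovation_cost /
      (settings$providers_per_facility *
         settings$repairs_per_provider_year * n)
  cost_per_repair <- avg_op_cost + overhead
  funded <- min(ceiling / cost_per_repair, total)
  repairs <- rep(funded / n, n)

  out <- bia_projection(core, repairs,
                        annual_extra_cost = repairs * overhead,
                        avg_op_cost, "capped_budget")
  attr(out, "ceiling") <- ceiling
  attr(out, "funded_repairs") <- funded
  attr(out, "fraction_addressed") <- funded / total
  attr(out, "cost_per_repair") <- cost_per_repair
  out
}

#' Budget-impact sensitivity analysis
#'
#' Recomputes the open-budget cumulative cost under one-at-a-time input
#' variations: each cost input +/-20\%, providers per facility 2 and 4,
#' provider productivity raised to five repairs per day (1,300 per
#' provider-year over a 5-day, 52-week elective schedule), and removal of
#' the complication-treatment component of the operation cost.
#'
#' @param settings the \code{budget_impact} block.
#' @param avg_op_cost USD per operation (complication component included,
#'   see \code{complication_cost_per_repair} in the settings).
#' @param variations optional data frame (\code{label}, \code{field},
#'   \code{value}) replacing the default set; \code{field = "op_cost"}
#'   varies \code{avg_op_cost} itself.
#' @return Data frame: variation, total cost, absolute and percent change
#'   from the unvaried open-budget total.
#' @export
bia_sensitivity <- function(settings, avg_op_cost = weighted_op_cost(),
                            variations = NULL) {
  if (is.null(variations))
    variations <- rbind(
      data.frame(label = "Operation cost -20%", field = "op_cost",
                 value = avg_op_cost * 0.8),
      data.frame(label = "Operation cost +20%", field = "op_cost",
                 value = avg_op_cost * 1.2),
      data.frame(label = "Training cost -20%", field = "training_cost",
                 value = settings$training_cost * 0.8),
      data.frame(label = "Training cost +20%", field = "training_cost",
                 value = settings$training_cost * 1.2),
      data.frame(label = "Renovation cost -20%", field = "renovation_cost",
                 value = settings$renovation_cost * 0.8),
      data.frame(label = "Renovation cost +20%", field = "renovation_cost",
                 value = settings$renovation_cost * 1.2),
      data.frame(label = "2 providers per facility",
                 field = "providers_per_facility", value = 2),
      data.frame(label = "4 providers per facility",
                 field = "providers_per_facility", value = 4),
      data.frame(label = "Productivity 5 repairs/day",
                 field = "repairs_per_provider_year", value = 1300),
      data.frame(label = "No complication treatment costs",
                 field = "op_cost",
                 value = avg_op_cost - settings$complication_cost_per_repair))
  if (!all(variations$field %in% c("op_cost", names(settings))))
    stop("bia_sensitivity: unknown field in variations")

  base_total <- attr(open_budget_scenario(settings, avg_op_cost),
                     "total_cost")
  rows <- lapply(seq_len(nrow(variations)), function(i) {
    s <- settings; oc <- avg_op_cost
    if (variations$field[i] == "op_cost") oc <- variations$value[i]
    else s[[variations$field[i]]] <- variations$value[i]
    tot <- attr(open_budget_scenario(s, oc), "total_cost")
    data.frame(variation = variations$label[i], total_cost = tot,
               delta = tot - base_total,
               pct_change = 100 * (tot - base_total) / base_total)
  })
  out <- do.call(rbind, rows)
  attr(out, "base_total") <- base_total
  out
}

#' @export
print.hernia_bia <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Budget-impact projection (%s), %d-%d\n",
              attr(x, "scenario"), x$year[1], x$year[n]))
  cat(sprintf("  initial backlog %.0f; 10-year backlog (initial + incidence) %.0f\n",
              attr(x, "initial_backlog"), attr(x, "total_backlog")))
  cat(sprintf("  repairs delivered %.0f; final-year backlog %.0f\n",
              sum(x$repairs), x$backlog[n]))
  if (x$cumulative_cost[n] > 0)
    cat(sprintf("  cumulative cost USD %.1f million\n",
                x$cumulative_cost[n] / 1e6))
  if (!is.null(attr(x, "fraction_addressed")))
    cat(sprintf("  fraction of backlog addressed: %.1f%%\n",
                100 * attr(x, "fraction_addressed")))
  if (!is.null(attr(x, "providers_trained")))
    cat(sprintf("  providers trained %d, facilities renovated %d\n",
                attr(x, "providers_trained"),
                attr(x, "facilities_renovated")))
  invisible(x)
}

#' @export
plot.hernia_bia <- function(x, ...) {
  graphics::plot(x$year, x$backlog / 1e3, type = "b", pch = 16,
                 xlab = "Year", ylab = "Untreated cases (thousands)",
                 main = paste("Backlog projection:", attr(x, "scenario")))
  graphics::abline(h = 0, col = "grey60", lty = 2)
  invisible(x)
}
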