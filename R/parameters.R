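# Pain bands used throughout: IPQ 1 -> none, 2-3 -> mild, 4-5 -> moderate,
# 6-7 -> severe.
PAIN_BANDS <- c("none", "mild", "moderate", "severe")

COMPLICATIONS <- c("excessive_pain", "impaired_wound_healing",
                   "wound_infection", "hematoma_reoperation")

#' Default model parameterization
#'
#' Returns the complete base-case parameter set for the Sierra Leone
#' task-sharing evaluation: strategy costs and risks, disability weights,
#' pre-/post-operative pain mixes, premature-death inputs, a synthetic
#' (Gompertz) life-table stub, willingness-to-pay thresholds, and
#' budget-impact epidemiology.
#'
#' Strategy defaults: associate clinicians (AC) operate at USD 149 per
#' procedure with 0.92\% annual recurrence; non-specialist medical doctors
#' (MD) at USD 163 with 6.86\% recurrence; both face a 0.38\% annual
#' contralateral-hernia risk.  Per-procedure costs are treated as
#' all-inclusive, so complication unit costs default to zero; the
#' complication \emph{rates} observed in the source trial are retained for
#' users supplying their own unit costs.
#'
#' The pre-operative pain mix is a calibrated default (a mild/moderate
#' mixture whose average disability weight makes the untreated cohort
#' accrue 0.75 DALYs over the 10-year base case); see
#' \code{\link{calibrate_pain_mix}} to re-derive or replace it.  The
#' bundled life table is a clearly non-authoritative Gompertz stub scaled
#' to a remaining life expectancy of 28 years at age 40, plausible for
#' Sierra Leonean males; substitute a real country life table via
#' \code{life_table} in the configuration for applied work.
#'
#' @return An object of class \code{hernia_params}: a named list with
#'   components \code{settings}, \code{strategies}, \code{disability_weights},
#'   \code{pain_pre}, \code{pain_post}, \code{premature_death},
#'   \code{life_table}, \code{thresholds} and \code{budget_impact}.
#' @export
#' @examples
#' p <- default_parameters()
#' p$strategies$ac$cost_per_procedure  # 149
default_parameters <- function() {
  params <- list(
    settings = list(
      starting_age = 40L,
      horizon = 10L,
      cycle_length = 1,
      discount_rate = 0.03,
      half_cycle_correction = TRUE,
      # YLL valuation: discounted stream of the full remaining life
      # expectancy at age of death ("full_remaining_LE_discounted"), or
      # life-years capped at the model horizon ("horizon_capped").
      yll_convention = "full_remaining_LE_discounted",
      # State membership for a cycle: occupancy at the cycle start
      # ("cycle_start": a transient hernia cycle counts in full, which is
      # what reconciles the published repaired-arm DALY totals) or the
      # start/end average ("midpoint", the textbook occupancy trapezoid).
      state_membership = "cycle_start",
      discount_timing = "end"
    ),
    strategies = list(
      ac = strategy_params(
        provider = "AC", cost_per_procedure = 149,
        p_recurrence = 0.0092, p_contralateral = 0.0038,
        complication_rates = c(excessive_pain = 0.0522,
                               impaired_wound_healing = 0.0696,
                               wound_infection = 0.0522,
                               hematoma_reoperation = 0.0174)),
      md = strategy_params(
        provider = "MD", cost_per_procedure = 163,
        p_recurrence = 0.0686, p_contralateral = 0.0038,
        complication_rates = c(excessive_pain = 0.0439,
                               impaired_wound_healing = 0.0789,
                               wound_infection = 0.0351,
                               hematoma_reoperation = 0.0088)),
      none = strategy_params(
        provider = "NONE", cost_per_procedure = 0,
        p_recurrence = 0, p_contralateral = 0)
    ),
    disability_weights = c(none = 0, mild = 0.0110,
                           moderate = 0.1140, severe = 0.3240),
    # Calibrated base-case pre-operative mix (see calibrate_pain_mix):
    # a mild/moderate mixture with average DW ~ 0.08.
    pain_pre = c(none = 0, mild = 1 - PAIN_MIX_MODERATE,
                 moderate = PAIN_MIX_MODERATE, severe = 0),
    # Post-operative pain resolves by default (chronic-pain fraction 0).
    pain_post = c(none = 1, mild = 0, moderate = 0, severe = 0),
    premature_death = list(
      p_complication = 0.0056,
      p_mortality_given_complication = 0.20
    ),
    life_table = generate_life_table(e40 = 28),
    thresholds = list(gdp_per_capita = 476, wtp = 3 * 476),
    budget_impact = list(
      population = 2566837,           # adult males; 220,748 / 0.086
      population_growth = 0.021,
      prevalence = 0.086,
      incidence_per_100k = 1250,
      repair_rate_per_100k = 470,
      share_md = 0.68, share_ac = 0.32,
      training_cost = 2000,
      renovation_cost = 12000,
      providers_per_facility = 3,
      repairs_per_provider_year = 27.5,
      complication_cost_per_repair = 3.7,
      start_year = 2024L,
      horizon_years = 10L
    )
  )
  validate_parameters(params)
}

# Moderate fraction of the shipped pre-operative pain mix; value produced
# once by calibrate_pain_mix(target_daly = 0.75) and frozen here.
PAIN_MIX_MODERATE <- 0.5840649

#' Construct a strategy parameter block
#'
#' @param provider one of \code{"AC"}, \code{"MD"}, \code{"NONE"}.
#' @param cost_per_procedure USD (2023) per repair.
#' @param p_recurrence,p_contralateral annual probabilities.
#' @param complication_rates named probabilities for the four
#'   post-operative complication categories.
#' @param complication_unit_costs named USD unit costs (default all zero:
#'   per-procedure costs are treated as all-inclusive).
#' @return A list of class \code{strategy_params}.
#' @export
strategy_params <- function(provider, cost_per_procedure,
                            p_recurrence, p_contralateral,
                            complication_rates = stats::setNames(
                              rep(0, 4), COMPLICATIONS),
                            complication_unit_costs = stats::setNames(
                              rep(0, 4), COMPLICATIONS)) {
  structure(list(provider = provider,
                 cost_per_procedure = cost_per_procedure,
                 p_recurrence = p_recurrence,
                 p_contralateral = p_contralateral,
                 complication_rates = complication_rates,
                 complication_unit_costs = complication_unit_costs),
            class = "strategy_params")
}

#' Annual risk of premature death without surgery
#'
#' The untreated-hernia excess mortality is the product of the annual risk
#' of an acute complication (incarceration/strangulation) and the case
#' fatality of such complications.
#'
#' @param p_complication annual probability of an acute complication
#'   without surgery.
#' @param p_mortality probability of death given the complication.
#' @return The annual premature-death probability.
#' @export
#' @examples
#' premature_death_risk(0.0056, 0.20)  # 0.00112, i.e. ~0.11\% per year
premature_death_risk <- function(p_complication, p_mortality) {
  stopifnot(is.numeric(p_complication), is.numeric(p_mortality))
  if (any(p_complication < 0 | p_complication > 1) ||
      any(p_mortality < 0 | p_mortality > 1))
    stop("premature_death_risk: probabilities must lie in [0, 1]")
  p_complication * p_mortality
}

#' Map an IPQ score to a disability weight
#'
#' Banded lookup: IPQ 1 (no pain) carries zero disability; 2-3 mild;
#' 4-5 moderate; 6-7 severe.
#'
#' @param ipq_score integer score(s) in 1..7.
#' @param dws named disability-weight vector
#'   (\code{none}, \code{mild}, \code{moderate}, \code{severe}).
#' @return Disability weight(s).
#' @export
#' @examples
#' ipq_to_dw(4, default_parameters()$disability_weights)  # 0.114
ipq_to_dw <- function(ipq_score, dws) {
  if (any(ipq_score != round(ipq_score)) ||
      any(ipq_score < 1) || any(ipq_score > 7))
    stop("ipq_to_dw: ipq_score must be an integer in 1..7")
  band <- ipq_band(ipq_score)
  unname(dws[band])
}

ipq_band <- function(ipq_score) {
  PAIN_BANDS[findInterval(ipq_score, c(1, 2, 4, 6))]
}

#' Validate a parameter set
#'
#' Checks every invariant of the model configuration (probability bounds,
#' monotone disability weights, pain mixes summing to one, life-table
#' coverage of the modelled ages, threshold consistency) and returns the
#' parameter set classed as \code{hernia_params}.  Errors name the
#' offending field.
#'
#' @param params a parameter list in the layout of
#'   \code{\link{default_parameters}}.
#' @return The validated \code{hernia_params} object.
#' @export
validate_parameters <- function(params) {
  need <- c("settings", "strategies", "disability_weights", "pain_pre",
            "pain_post", "premature_death", "life_table", "thresholds")
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("parameter set is missing required section(s): ",
         paste(miss, collapse = ", "))

  s <- params$settings
  if (!is.numeric(s$horizon) || s$horizon <= 0)
    stop("settings$horizon must be a positive number of cycles")
  if (!is.numeric(s$discount_rate) || s$discount_rate < 0 ||
      s$discount_rate >= 1)
    stop("settings$discount_rate must lie in [0, 1)")
  if (!is.numeric(s$starting_age) || s$starting_age < 18)
    stop("settings$starting_age must be >= 18")
  if (!s$yll_convention %in%
      c("full_remaining_LE_discounted", "horizon_capped"))
    stop("settings$yll_convention: unknown convention '",
         s$yll_convention, "'")
  if (!s$discount_timing %in% c("start", "mid", "end"))
    stop("settings$discount_timing must be 'start', 'mid' or 'end'")
  if (!s$state_membership %in% c("cycle_start", "midpoint"))
    stop("settings$state_membership must be 'cycle_start' or 'midpoint'")

  for (id in names(params$strategies)) {
    st <- params$strategies[[id]]
    for (f in c("p_recurrence", "p_contralateral")) {
      v <- st[[f]]
      if (!is.numeric(v) || v < 0 || v > 1)
        stop("strategies$", id, "$", f, " must be a probability in [0, 1]")
    }
    if (st$cost_per_procedure < 0)
      stop("strategies$", id, "$cost_per_procedure must be >= 0")
    if (any(st$complication_rates < 0 | st$complication_rates > 1))
      stop("strategies$", id, "$complication_rates must lie in [0, 1]")
    if (any(st$complication_unit_costs < 0))
      stop("strategies$", id, "$complication_unit_costs must be >= 0")
    if (identical(st$provider, "NONE") &&
        (st$cost_per_procedure != 0 || st$p_recurrence != 0))
      stop("strategies$", id,
           ": the no-treatment strategy must have zero cost and recurrence")
  }

  dw <- params$disability_weights
  if (!all(PAIN_BANDS %in% names(dw)))
    stop("disability_weights must name all bands: ",
         paste(PAIN_BANDS, collapse = ", "))
  dw <- dw[PAIN_BANDS]
  if (any(dw < 0) || any(dw > 1) || is.unsorted(dw))
    stop("disability_weights must be non-decreasing over ",
         "none <= mild <= moderate <= severe, within [0, 1]")

  for (f in c("pain_pre", "pain_post")) {
    px <- params[[f]]
    if (!all(PAIN_BANDS %in% names(px)))
      stop(f, " must name all bands: ", paste(PAIN_BANDS, collapse = ", "))
    if (any(px < 0) || any(px > 1))
      stop(f, ": band fractions must lie in [0, 1]")
    if (abs(sum(px) - 1) > 1e-9)
      stop(f, ": band fractions must sum to 1 (got ", sum(px), ")")
  }

  pd <- params$premature_death
  for (f in c("p_complication", "p_mortality_given_complication")) {
    if (!is.numeric(pd[[f]]) || pd[[f]] < 0 || pd[[f]] > 1)
      stop("premature_death$", f, " must be a probability in [0, 1]")
  }

  lt <- params$life_table
  validate_life_table(lt)
  amax <- s$starting_age + s$horizon
  if (min(lt$age) > s$starting_age || max(lt$age) < amax)
    stop("life_table must cover ages ", s$starting_age, "..", amax)

  th <- params$thresholds
  if (!is.null(th$wtp) && !is.null(th$gdp_per_capita) &&
      abs(th$wtp - 3 * th$gdp_per_capita) > 1e-6)
    stop("thresholds: wtp must equal 3 x gdp_per_capita")

  if (!is.null(params$budget_impact)) {
    b <- params$budget_impact
    if (abs(b$share_md + b$share_ac - 1) > 1e-9)
      stop("budget_impact: share_md + share_ac must sum to 1")
    rates <- c(b$population, b$prevalence, b$incidence_per_100k,
               b$repair_rate_per_100k, b$training_cost, b$renovation_cost,
               b$providers_per_facility, b$repairs_per_provider_year)
    if (any(rates < 0)) stop("budget_impact: rates and costs must be >= 0")
    if (b$horizon_years < 1) stop("budget_impact$horizon_years must be >= 1")
  }

  structure(params, class = "hernia_params")
}

#' Load a parameter configuration from YAML
#'
#' Reads a YAML configuration, fills any absent field with the base-case
#' default, and validates.  The life table may be given inline (a mapping
#' with \code{age}, \code{q}, \code{ex} sequences) or as a CSV path
#' (columns \code{age,q,ex}, header required) resolved relative to the
#' configuration file.
#'
#' @param config_path path to a YAML file.
#' @return A validated \code{hernia_params} object.
#' @export
load_parameters <- function(config_path) {
  if (!file.exists(config_path))
    stop("configuration file not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  if (!is.list(cfg)) stop("configuration must be a YAML mapping")

  if (!is.null(cfg$life_table)) {
    if (is.character(cfg$life_table)) {
      path <- cfg$life_table
      if (!file.exists(path))
        path <- file.path(dirname(config_path), cfg$life_table)
      cfg$life_table <- read_life_table(path)
    } else {
      cfg$life_table <- as.data.frame(lapply(cfg$life_table, unlist))
    }
  }
  for (f in c("disability_weights", "pain_pre", "pain_post"))
    if (!is.null(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])
  if (!is.null(cfg$strategies))
    cfg$strategies <- lapply(cfg$strategies, function(st) {
      for (f in c("complication_rates", "complication_unit_costs"))
        if (!is.null(st[[f]])) st[[f]] <- unlist(st[[f]])
      st
    })

  params <- merge_defaults(unclass(default_parameters()), cfg)
  params$strategies <- lapply(params$strategies, function(st)
    do.call(strategy_params, st[c("provider", "cost_per_procedure",
                                  "p_recurrence", "p_contralateral",
                                  "complication_rates",
                                  "complication_unit_costs")]))
  validate_parameters(params)
}

# Recursive default-filling: user values win, absent keys fall back.
merge_defaults <- function(defaults, user) {
  if (!is.list(user) || !is.list(defaults)) return(user)
  out <- defaults
  for (k in names(user)) {
    if (!is.null(out[[k]]) && is.list(out[[k]]) && is.list(user[[k]]) &&
        !is.data.frame(user[[k]]))
      out[[k]] <- merge_defaults(out[[k]], user[[k]])
    else
      out[[k]] <- user[[k]]
  }
  out
}

#' Serialize a parameter set to YAML
#'
#' The written file round-trips through \code{\link{load_parameters}}.
#'
#' @param params a \code{hernia_params} object.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(params, path) {
  p <- unclass(params)
  p$life_table <- as.list(as.data.frame(p$life_table))
  p$strategies <- lapply(p$strategies, function(st) {
    st <- unclass(st)
    st$complication_rates <- as.list(st$complication_rates)
    st$complication_unit_costs <- as.list(st$complication_unit_costs)
    st
  })
  for (f in c("disability_weights", "pain_pre", "pain_post"))
    p[[f]] <- as.list(p[[f]])
  yaml::write_yaml(p, path, precision = 15)
  invisible(path)
}

#' @export
print.hernia_params <- function(x, ...) {
  s <- x$settings
  cat("Hernia CEA parameter set\n")
  cat(sprintf("  cohort: age %d, horizon %d y, discount %.1f%%, HCC %s\n",
              s$starting_age, s$horizon, 100 * s$discount_rate,
              ifelse(s$half_cycle_correction, "on", "off")))
  for (id in names(x$strategies)) {
    st <- x$strategies[[id]]
    cat(sprintf("  %-4s cost/procedure %6.0f USD, recurrence %.2f%%/y, contralateral %.2f%%/y\n",
                st$provider, st$cost_per_procedure,
                100 * st$p_recurrence, 100 * st$p_contralateral))
  }
  dw <- x$disability_weights
  cat(sprintf("  DWs: mild %.4f, moderate %.4f, severe %.4f\n",
              dw["mild"], dw["moderate"], dw["severe"]))
  cat(sprintf("  pre-op pain mix: %s\n",
              paste(sprintf("%s %.1f%%", names(x$pain_pre),
                            100 * x$pain_pre), collapse = ", ")))
  invisible(x)
}
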