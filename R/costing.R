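# Cost accrued per cycle.  The initial procedure (treated strategies) is
# charged at time 0, i.e. undiscounted, in the cycle-1 row; re-repairs of
# recurrent/contralateral hernias are charged at entry into their cycle
# (time t for the cohort entering cycle t+1) and discounted accordingly.
cost_by_cycle <- function(repair_entries, strategy, settings, treated,
                          discount = TRUE) {
  H <- length(repair_entries)
  cost <- numeric(H)
  if (!treated) return(cost)
  r <- if (discount) settings$discount_rate else 0
  unit <- strategy$cost_per_procedure + expected_complication_cost(strategy)
  cost[1] <- unit  # initial repair at time 0
  t <- seq_len(H - 1)
  cost[t + 1] <- repair_entries[t] * unit * (1 + r)^(-t)
  cost
}

#' Bottom-up per-procedure cost from resource line items
#'
#' Consumables (materials, medicines) are costed per procedure as
#' quantity times unit cost; annualized capital, overhead and
#' human-resource items are multiplied by their allocation share to the
#' surgical service and divided by the annual procedure volume.
#'
#' @param items data frame with columns \code{name}, \code{category}
#'   (one of materials, medicines, human_resources, capital, overhead),
#'   \code{quantity}, \code{unit_cost}, \code{allocation_share}.
#' @param annual_volume procedures per year over which shared resources
#'   are spread.
#' @return Cost per procedure, USD.
#' @export
#' @examples
#' items <- data.frame(name = "mesh", category = "materials",
#'                     quantity = 1, unit_cost = 25, allocation_share = 1)
#' bottom_up_cost(items, annual_volume = 500)  # 25
bottom_up_cost <- function(items, annual_volume) {
  if (annual_volume <= 0)
    stop("bottom_up_cost: annual_volume must be positive")
  if (nrow(items) == 0) return(0)
  stopifnot(all(c("category", "quantity", "unit_cost",
                  "allocation_share") %in% names(items)))
  if (any(items$quantity < 0) || any(items$unit_cost < 0) ||
      any(items$allocation_share < 0) || any(items$allocation_share > 1))
    stop("bottom_up_cost: quantities and costs must be >= 0, shares in [0, 1]")
  per_proc <- items$category %in% c("materials", "medicines")
  direct <- sum(items$quantity[per_proc] * items$unit_cost[per_proc] *
                items$allocation_share[per_proc])
  shared <- sum(items$quantity[!per_proc] * items$unit_cost[!per_proc] *
                items$allocation_share[!per_proc]) / annual_volume
  direct + shared
}

#' Read resource line items from CSV
#'
#' Columns: \code{name,category,quantity,unit_cost,allocation_share}.
#'
#' @param path CSV file path.
#' @return A data frame of resource items.
#' @export
read_resource_items <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Expected complication treatment cost per procedure
#'
#' Weighted sum of the four post-operative complication rates (excessive
#' pain, impaired wound healing, wound infection, hematoma/reoperation)
#' and their unit treatment costs.  Zero under the default all-inclusive
#' per-procedure costing.
#'
#' @param strategy a \code{\link{strategy_params}} block.
#' @return Expected cost, USD per procedure.
#' @export
expected_complication_cost <- function(strategy) {
  sum(strategy$complication_rates *
        strategy$complication_unit_costs[names(strategy$complication_rates)])
}

#' Decomposed cohort cost for a strategy run
#'
#' @param trace a \code{cohort_trace} from \code{\link{run_cohort}} under
#'   the same strategy.
#' @param strategy the strategy block (defaults to the trace's).
#' @param settings model settings (defaults to the trace's).
#' @return A list of class \code{cost_result}: \code{initial} (procedure
#'   plus expected complication cost at time 0), \code{complication}
#'   (expected complication component of the initial repair),
#'   \code{re_repair_disc} (discounted re-repair outlays) and
#'   \code{total_disc}.
#' @export
cohort_cost <- function(trace, strategy = attr(trace, "strategy"),
                        settings = attr(trace, "settings")) {
  stopifnot(inherits(trace, "cohort_trace"))
  treated <- !identical(strategy$provider, "NONE")
  compl <- expected_complication_cost(strategy)
  initial <- if (treated) strategy$cost_per_procedure + compl else 0
  entries <- attr(trace, "repair_entries")
  cost <- cost_by_cycle(entries, strategy, settings, treated,
                        discount = TRUE)
  total <- sum(cost)
  structure(list(initial = initial,
                 complication = if (treated) compl else 0,
                 re_repair_disc = total - initial,
                 total_disc = total),
            class = "cost_result")
}

#' @export
print.cost_result <- function(x, ...) {
  cat(sprintf("Cost per patient (discounted): %.2f USD = initial %.2f + re-repairs %.2f\n",
              x$total_disc, x$initial, x$re_repair_disc))
  invisible(x)
}
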