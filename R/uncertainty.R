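# Parameter paths are resolved as $-separated component names into the
# hernia_params list, e.g. "strategies$ac$cost_per_procedure" or
# "disability_weights$moderate".
get_param <- function(params, path) {
  keys <- strsplit(path, "$", fixed = TRUE)[[1]]
  x <- params
  for (k in keys) {
    if (is.null(x[[k]]) && !(is.atomic(x) && k %in% names(x)))
      stop("parameter path does not resolve: ", path)
    x <- x[[k]]
  }
  if (!is.numeric(x) || length(x) != 1)
    stop("parameter path must resolve to a scalar: ", path)
  x
}

set_param <- function(params, path, value) {
  keys <- strsplit(path, "$", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, k) call("[[", acc, k), keys,
                 quote(params))
  eval(call("<-", expr, value))
  params
}

#' Default one-way sensitivity specifications
#'
#' The published deterministic sensitivity grid: discount rate 0-3.5\%,
#' starting age 30-50, procedure costs and disability weights and risks
#' at roughly +/-20\% of base case.
#'
#' @param params the base-case parameters.
#' @return A data frame with columns \code{parameter}, \code{label},
#'   \code{base}, \code{low}, \code{high}.
#' @export
default_dsa_specs <- function(params = default_parameters()) {
  spec <- function(parameter, label, low, high)
    data.frame(parameter = parameter, label = label,
               base = get_param(params, parameter), low = low, high = high)
  out <- rbind(
    spec("settings$discount_rate", "Discount rate", 0, 0.035),
    spec("settings$starting_age", "Starting age", 30, 50),
    spec("strategies$ac$cost_per_procedure", "Cost per procedure (AC)",
         120, 179),
    spec("strategies$md$cost_per_procedure", "Cost per procedure (MD)",
         130, 195),
    spec("disability_weights$mild", "DW mild pain (IPQ 2-3)",
         0.0088, 0.0132),
    spec("disability_weights$moderate", "DW moderate pain (IPQ 4-5)",
         0.0912, 0.1368),
    spec("disability_weights$severe", "DW severe pain (IPQ 6-7)",
         0.2592, 0.3888),
    spec("strategies$ac$p_recurrence", "Risk of recurrent hernia (AC)",
         0.0073, 0.0110),
    spec("strategies$md$p_recurrence", "Risk of recurrent hernia (MD)",
         0.0549, 0.0820),
    spec("strategies$ac$p_contralateral", "Risk of contralateral hernia",
         0.0030, 0.0046),
    spec("premature_death$p_complication",
         "Risk of premature death without surgery", # via its first factor
         0.0056 * 0.09 / 0.11, 0.0056 * 0.13 / 0.11))
  if (any(out$low > out$base + 1e-12) || any(out$high < out$base - 1e-12))
    stop("default_dsa_specs: low <= base <= high violated")
  out
}

icer_for <- function(params, comparison) {
  panel <- cea_panel(params)
  cmp <- panel[[comparison]]
  if (is.na(cmp$icer)) cmp$incremental_cost / cmp$dalys_averted else cmp$icer
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Recomputes the full cost-effectiveness analysis with each parameter
#' set to its low and high value in turn, all else held at base case, and
#' ranks parameters by the span of the resulting ICER.
#'
#' @param params base-case \code{hernia_params}.
#' @param specs specification data frame as from
#'   \code{\link{default_dsa_specs}}; \code{low <= base <= high} required.
#' @param comparison which pairwise ICER to track:
#'   \code{"ac_vs_none"}, \code{"md_vs_none"} or \code{"ac_vs_md"}.
#' @return An object of class \code{hernia_dsa}: a data frame with one
#'   row per parameter (ICER at low and high, span), sorted by
#'   descending span.
#' @export
one_way_dsa <- function(params = default_parameters(),
                        specs = default_dsa_specs(params),
                        comparison = "ac_vs_none") {
  stopifnot(all(c("parameter", "base", "low", "high") %in% names(specs)))
  if (any(specs$low > specs$base + 1e-12) ||
      any(specs$high < specs$base - 1e-12))
    stop("one_way_dsa: specs must satisfy low <= base <= high")
  base_icer <- icer_for(params, comparison)
  note_contra <- grepl("p_contralateral", specs$parameter)

  rows <- lapply(seq_len(nrow(specs)), function(i) {
    at <- function(v) {
      p <- set_param(params, specs$parameter[i], v)
      # contralateral risk is shared by both providers
      if (note_contra[i])
        p <- set_param(p, sub("\\$ac\\$", "$md$", specs$parameter[i]), v)
      icer_for(validate_parameters(unclass(p)), comparison)
    }
    lo <- at(specs$low[i]); hi <- at(specs$high[i])
    data.frame(parameter = specs$parameter[i],
               label = if ("label" %in% names(specs)) specs$label[i]
                       else specs$parameter[i],
               icer_low = lo, icer_high = hi, span = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, base_icer = base_icer, comparison = comparison,
            class = c("hernia_dsa", "data.frame"))
}

#' @export
print.hernia_dsa <- function(x, ...) {
  cat(sprintf("One-way sensitivity of the %s ICER (base %.0f USD/DALY averted)\n",
              attr(x, "comparison"), attr(x, "base_icer")))
  print.data.frame(cbind(x["label"],
                         round(x[c("icer_low", "icer_high", "span")], 1)))
  invisible(x)
}

#' @export
plot.hernia_dsa <- function(x, ...) {
  base <- attr(x, "base_icer")
  n <- nrow(x)
  ord <- rev(seq_len(n))  # widest bar on top
  graphics::par(mar = c(4, 14, 3, 1))
  graphics::plot(NULL, xlim = range(c(x$icer_low, x$icer_high, base)),
                 ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "ICER (USD per DALY averted)", ylab = "",
                 main = paste("Tornado:", attr(x, "comparison")))
  for (i in seq_len(n)) {
    y <- ord[i]
    graphics::rect(min(x$icer_low[i], base), y - 0.35,
                   max(x$icer_low[i], base), y + 0.35, col = "steelblue")
    graphics::rect(min(x$icer_high[i], base), y - 0.35,
                   max(x$icer_high[i], base), y + 0.35,
                   col = "indianred")
  }
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = ord, labels = x$label, las = 1, cex.axis = 0.8)
  invisible(x)
}

#' Default probabilistic sensitivity distributions
#'
#' The published PSA block: disability weights and the recurrence and
#' contralateral risks, each with the stated mean and standard deviation.
#' Procedure costs are not varied probabilistically.
#'
#' @return Data frame with columns \code{parameter}, \code{mean},
#'   \code{sd}, \code{family}.
#' @export
default_psa_dists <- function() {
  data.frame(
    parameter = c("disability_weights$mild", "disability_weights$moderate",
                  "disability_weights$severe",
                  "strategies$ac$p_recurrence", "strategies$md$p_recurrence",
                  "strategies$ac$p_contralateral"),
    mean = c(0.0114, 0.1140, 0.3240, 0.0092, 0.0686, 0.0038),
    sd = c(0.0040, 0.0200, 0.0550, 0.0001, 0.0001, 0.0007),
    family = "beta")
}

#' Draw joint parameter samples for the PSA
#'
#' Probabilities and disability weights are sampled from beta
#' distributions matched to the requested mean and standard deviation by
#' the method of moments.  Means incompatible with a beta of that spread
#' fall back to a normal truncated to [0, 1] with a warning.  A zero
#' standard deviation reproduces the mean exactly.
#'
#' @param dists data frame as from \code{\link{default_psa_dists}}.
#' @param n number of joint draws.
#' @param seed RNG seed (recorded in the result).
#' @return Matrix of \code{n} rows, one column per parameter path.
#' @export
sample_psa <- function(dists, n, seed = 1L) {
  stopifnot(n > 0)
  set.seed(seed)
  draws <- vapply(seq_len(nrow(dists)), function(i) {
    m <- dists$mean[i]; s <- dists$sd[i]
    if (s == 0) return(rep(m, n))
    if (dists$family[i] == "normal") return(stats::rnorm(n, m, s))
    if (dists$family[i] == "gamma") {
      shape <- (m / s)^2
      return(stats::rgamma(n, shape = shape, rate = shape / m))
    }
    v <- s^2
    if (m <= 0 || m >= 1 || v >= m * (1 - m)) {
      warning("sd incompatible with a beta at mean ", m,
              "; using truncated normal for ", dists$parameter[i])
      x <- stats::rnorm(n, m, s)
      return(pmin(pmax(x, 0), 1))
    }
    nu <- m * (1 - m) / v - 1
    stats::rbeta(n, shape1 = m * nu, shape2 = (1 - m) * nu)
  }, numeric(n))
  draws <- matrix(draws, nrow = n,
                  dimnames = list(NULL, dists$parameter))
  attr(draws, "seed") <- seed
  draws
}

#' Probabilistic sensitivity analysis
#'
#' Re-evaluates the full cohort model for each joint parameter draw and
#' records the incremental cost and DALYs averted of every requested
#' pairwise comparison.  The contralateral risk, a single quantity in the
#' model, is applied to both providers.
#'
#' @param params base-case \code{hernia_params}.
#' @param dists sampling distributions (see
#'   \code{\link{default_psa_dists}}).
#' @param n number of simulations (published analysis: 1,000).
#' @param seed RNG seed.
#' @param comparisons character vector of panel comparisons to record.
#' @return An object of class \code{hernia_psa}: per-draw increments per
#'   comparison, the deterministic increments, the draws and the seed.
#' @export
run_psa <- function(params = default_parameters(),
                    dists = default_psa_dists(), n = 1000, seed = 1L,
                    comparisons = c("ac_vs_none", "md_vs_none",
                                    "ac_vs_md")) {
  draws <- sample_psa(dists, n, seed)
  paths <- colnames(draws)
  per_draw <- vector("list", n)
  for (d in seq_len(n)) {
    p <- params
    for (j in seq_along(paths)) {
      p <- set_param(p, paths[j], draws[d, j])
      if (grepl("p_contralateral", paths[j]))
        p <- set_param(p, sub("\\$ac\\$", "$md$", paths[j]), draws[d, j])
    }
    panel <- cea_panel(p)
    per_draw[[d]] <- unlist(lapply(comparisons, function(cm)
      c(panel[[cm]]$incremental_cost, panel[[cm]]$dalys_averted)))
  }
  res <- do.call(rbind, per_draw)
  colnames(res) <- as.vector(t(outer(comparisons,
                                     c("d_cost", "d_daly"),
                                     paste, sep = ".")))
  base_panel <- cea_panel(params)
  deterministic <- sapply(comparisons, function(cm)
    c(d_cost = base_panel[[cm]]$incremental_cost,
      d_daly = base_panel[[cm]]$dalys_averted))
  structure(list(draws = draws, increments = as.data.frame(res),
                 deterministic = deterministic,
                 comparisons = comparisons, n = n, seed = seed),
            class = "hernia_psa")
}

#' @export
print.hernia_psa <- function(x, ...) {
  cat(sprintf("PSA: %d simulations (seed %d)\n", x$n, x$seed))
  for (cm in x$comparisons) {
    dc <- x$increments[[paste0(cm, ".d_cost")]]
    de <- x$increments[[paste0(cm, ".d_daly")]]
    cat(sprintf("  %-11s mean Δcost %8.2f USD, mean DALYs averted %7.4f, ICER %8.1f\n",
                cm, mean(dc), mean(de), mean(dc) / mean(de)))
  }
  invisible(x)
}

#' @export
plot.hernia_psa <- function(x, comparison = x$comparisons[1],
                            wtp = NULL, ...) {
  dc <- x$increments[[paste0(comparison, ".d_cost")]]
  de <- x$increments[[paste0(comparison, ".d_daly")]]
  graphics::plot(de, dc, pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = "Incremental DALYs averted",
                 ylab = "Incremental cost (USD)",
                 main = paste("Cost-effectiveness plane:", comparison))
  graphics::abline(h = 0, v = 0, col = "grey60")
  if (!is.null(wtp)) graphics::abline(0, wtp, lty = 2)
  det <- x$deterministic[, comparison]
  graphics::points(det["d_daly"], det["d_cost"], pch = 4, cex = 1.5,
                   lwd = 2, col = "firebrick")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value the fraction of PSA draws with a
#' non-negative net monetary benefit (threshold x DALYs averted minus
#' incremental cost).
#'
#' @param psa a \code{hernia_psa} object.
#' @param thresholds grid of USD-per-DALY-averted values.
#' @param comparisons subset of the PSA's comparisons.
#' @return Data frame of class \code{hernia_ceac}: \code{threshold} plus
#'   one probability column per comparison.
#' @export
ceac <- function(psa, thresholds = seq(0, 1500, by = 10),
                 comparisons = psa$comparisons) {
  stopifnot(inherits(psa, "hernia_psa"), psa$n > 0)
  out <- data.frame(threshold = thresholds)
  for (cm in comparisons) {
    dc <- psa$increments[[paste0(cm, ".d_cost")]]
    de <- psa$increments[[paste0(cm, ".d_daly")]]
    out[[cm]] <- vapply(thresholds, function(l) mean(l * de - dc >= 0),
                        numeric(1))
  }
  class(out) <- c("hernia_ceac", "data.frame")
  out
}

#' Summary statistics of a CEAC
#'
#' Reports, per comparison, the lowest threshold at which the probability
#' of cost-effectiveness reaches 50\% and the lowest at which it reaches
#' 100\%.
#'
#' @param curve a \code{hernia_ceac} data frame.
#' @return Data frame with one row per comparison.
#' @export
ceac_crossings <- function(curve) {
  cms <- setdiff(names(curve), "threshold")
  do.call(rbind, lapply(cms, function(cm) {
    p <- curve[[cm]]
    data.frame(comparison = cm,
               at_50pct = curve$threshold[match(TRUE, p >= 0.5)],
               at_100pct = curve$threshold[match(TRUE, p >= 1)])
  }))
}

#' @export
plot.hernia_ceac <- function(x, ...) {
  cms <- setdiff(names(x), "threshold")
  cols <- c("steelblue", "firebrick", "forestgreen")[seq_along(cms)]
  graphics::plot(NULL, xlim = range(x$threshold), ylim = c(0, 1),
                 xlab = "Willingness to pay (USD per DALY averted)",
                 ylab = "Probability cost-effective",
                 main = "Cost-effectiveness acceptability")
  for (i in seq_along(cms))
    graphics::lines(x$threshold, x[[cms[i]]], col = cols[i], lwd = 2)
  graphics::legend("bottomright", legend = cms, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
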