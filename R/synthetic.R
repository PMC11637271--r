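# Sampling helpers: draw an IPQ score from a band mix (uniform within
# the band's score range).
BAND_SCORES <- list(none = 1L, mild = 2:3, moderate = 4:5, severe = 6:7)

sample_ipq <- function(n, pain) {
  band <- sample(PAIN_BANDS, n, replace = TRUE, prob = pain[PAIN_BANDS])
  vapply(band, function(b) {
    s <- BAND_SCORES[[b]]
    if (length(s) == 1) s else sample(s, 1)
  }, integer(1))
}

#' Generate a synthetic trial cohort
#'
#' Emulates the source randomized trial at the individual level:
#' patients assigned to an AC or MD surgeon, pre- and post-operative IPQ
#' pain scores drawn from the configured band distributions, one-year
#' recurrence indicators at the provider-specific rates, and independent
#' Bernoulli complication events at the provider-specific rates.
#'
#' @param n cohort size.
#' @param provider_mix fraction operated by ACs.
#' @param rates list with \code{ac} and \code{md}
#'   \code{\link{strategy_params}} blocks.
#' @param pain list with \code{pre} and \code{post} band distributions.
#' @param seed RNG seed (same seed, same cohort).
#' @return Data frame with columns \code{id}, \code{provider},
#'   \code{pre_op_ipq}, \code{post_op_ipq}, \code{recurrence_within_1y}
#'   and one logical column per complication.
#' @export
generate_trial_cohort <- function(n, provider_mix = 0.5,
                                  rates = default_parameters()$strategies,
                                  pain = list(
                                    pre = default_parameters()$pain_pre,
                                    post = default_parameters()$pain_post),
                                  seed = 1L) {
  stopifnot(n > 0, provider_mix >= 0, provider_mix <= 1)
  set.seed(seed)
  provider <- ifelse(stats::runif(n) < provider_mix, "AC", "MD")
  st <- list(AC = rates$ac, MD = rates$md)
  p_rec <- vapply(provider, function(pr) st[[pr]]$p_recurrence, numeric(1))
  out <- data.frame(
    id = seq_len(n),
    provider = provider,
    pre_op_ipq = sample_ipq(n, pain$pre),
    post_op_ipq = sample_ipq(n, pain$post),
    recurrence_within_1y = stats::runif(n) < p_rec)
  for (cm in COMPLICATIONS) {
    p <- vapply(provider, function(pr) st[[pr]]$complication_rates[[cm]],
                numeric(1))
    out[[cm]] <- stats::runif(n) < p
  }
  rownames(out) <- NULL
  out
}

#' Estimate trial parameters from a synthetic cohort
#'
#' Maximum-likelihood proportions per provider (recurrence, each
#' complication) with exact binomial 95\% confidence intervals, plus the
#' pre- and post-operative pain-band distributions.  Closes the
#' generator/estimator round trip used to validate the synthetic-data
#' machinery.
#'
#' @param cohort a data frame from \code{\link{generate_trial_cohort}}.
#' @return A list with per-provider estimates (\code{ac}, \code{md}) and
#'   pooled \code{pain_pre}/\code{pain_post} band fractions.
#' @export
estimate_parameters <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  est_prop <- function(x) {
    bt <- stats::binom.test(sum(x), length(x))
    c(estimate = unname(bt$estimate), lower = bt$conf.int[1],
      upper = bt$conf.int[2])
  }
  one_provider <- function(prov) {
    sub <- cohort[cohort$provider == prov, , drop = FALSE]
    if (nrow(sub) == 0) stop("no patients operated by ", prov)
    compl <- sapply(COMPLICATIONS, function(cm) est_prop(sub[[cm]]))
    list(n = nrow(sub),
         p_recurrence = est_prop(sub$recurrence_within_1y),
         complication_rates = compl)
  }
  band_fractions <- function(scores) {
    f <- table(factor(ipq_band(scores), levels = PAIN_BANDS))
    as.numeric(f) / length(scores)
  }
  list(ac = one_provider("AC"), md = one_provider("MD"),
       pain_pre = stats::setNames(band_fractions(cohort$pre_op_ipq),
                                  PAIN_BANDS),
       pain_post = stats::setNames(band_fractions(cohort$post_op_ipq),
                                   PAIN_BANDS))
}

#' Individual-level microsimulation oracle
#'
#' Simulates \code{n} individual patients through the identical state
#' logic, accrual conventions and discounting of the cohort engine, with
#' per-individual random transitions.  Serves as an independent check of
#' \code{\link{run_cohort}}: the microsimulation means converge to the
#' cohort totals, and agreement within a few Monte-Carlo standard errors
#' validates both implementations.
#'
#' @param params a \code{hernia_params} object.
#' @param strategy strategy id or block.
#' @param n number of simulated individuals.
#' @param seed RNG seed.
#' @return A list with \code{mean_cost}, \code{mean_daly},
#'   \code{mean_yld}, \code{mean_yll}, their standard errors
#'   (\code{se_cost}, \code{se_daly}) and \code{n}.
#' @export
microsim_oracle <- function(params, strategy, n = 10000, seed = 1L) {
  stopifnot(inherits(params, "hernia_params"), n > 0)
  if (is.character(strategy)) strategy <- params$strategies[[strategy]]
  set.seed(seed)

  s <- params$settings
  H <- as.integer(s$horizon)
  r <- s$discount_rate
  lt <- params$life_table
  treated <- !identical(strategy$provider, "NONE")
  p_pd <- premature_death_risk(
    params$premature_death$p_complication,
    params$premature_death$p_mortality_given_complication)
  pr <- strategy$p_recurrence
  pc <- strategy$p_contralateral
  unit_cost <- strategy$cost_per_procedure +
    expected_complication_cost(strategy)
  dw_state <- state_disability_weights(params)

  # per-cycle discount weight for state time (matches state_time_weights)
  df0 <- (1 + r)^(-(0:H))
  w <- if (isTRUE(s$half_cycle_correction))
    0.5 * (df0[1:H] + df0[2:(H + 1)])
  else
    discount_factor(seq_len(H), r, s$discount_timing)
  midpoint <- identical(s$state_membership, "midpoint")

  state <- rep.int(S_NEW, n)
  cost <- rep.int(if (treated) unit_cost else 0, n)  # initial repair, time 0
  yld <- numeric(n)
  yll <- numeric(n)

  for (t in seq_len(H)) {
    age <- s$starting_age + (t - 1)
    q <- lt_q(lt, age)
    alive <- state != S_DEAD
    start_state <- state

    u_bg <- stats::runif(n)
    died_bg <- alive & (u_bg < q)
    surv <- alive & !died_bg
    new_state <- state
    new_state[died_bg] <- S_DEAD

    if (treated) {
      u1 <- stats::runif(n); u2 <- stats::runif(n)
      rec <- surv & (u1 < pr)
      contra <- surv & !rec & (u2 < pc)
      rep_ <- surv & !rec & !contra
      new_state[rec] <- S_REC
      new_state[contra] <- S_NEW
      new_state[rep_] <- S_REP
      if (t < H) {
        entered <- (rec | contra)
        cost[entered] <- cost[entered] + unit_cost * (1 + r)^(-t)
      }
    } else {
      u_pd <- stats::runif(n)
      hern <- surv & (state %in% c(S_NEW, S_REC))
      died_pd <- hern & (u_pd < p_pd)
      new_state[died_pd] <- S_DEAD
      if (any(died_pd)) {
        ex <- lt_ex(lt, s$starting_age + t)
        if (identical(s$yll_convention, "horizon_capped"))
          ex <- min(ex, H - t)
        yll[died_pd] <- yll[died_pd] + annuity(ex, r) * (1 + r)^(-t)
      }
    }

    m <- if (midpoint)
      0.5 * (dw_state[start_state] + dw_state[new_state])
    else
      dw_state[start_state]
    yld <- yld + m * w[t] * s$cycle_length
    state <- new_state
  }

  daly <- yld + yll
  list(mean_cost = mean(cost), mean_yld = mean(yld), mean_yll = mean(yll),
       mean_daly = mean(daly),
       se_cost = stats::sd(cost) / sqrt(n),
       se_daly = stats::sd(daly) / sqrt(n),
       n = n, seed = seed)
}

#' Export a synthetic cohort to CSV
#'
#' @param cohort data frame from \code{\link{generate_trial_cohort}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
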