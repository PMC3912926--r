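#' Costs, life years, QALYs, increments and dominance
#'
#' State rewards follow the evidence table: annual PAD-care cost for the
#' symptomatic/diagnosed PAD state, annual follow-up costs for the post-MI
#' and post-stroke states, one-time event costs charged on entry into the
#' post-amputation/MI/stroke/bleed states (first-year MI and stroke costs
#' replace, not add to, the subsequent-year annual cost in the entry year),
#' annual antiplatelet drug cost while treated (stopping at post-bleed and
#' death), and state utilities, with an age-banded background utility for
#' the no-PAD and asymptomatic states. Membership is counted at cycle end
#' (no half-cycle correction), so cycle 0 accrues nothing.
#'
#' @name economics
NULL

#' Discount factor
#'
#' @param rate annual discount rate (fraction, >= 0).
#' @param cycle cycle index (integer vector, >= 0).
#' @return `(1 + rate)^(-cycle)`.
#' @export
discount_factor <- function(rate, cycle) {
  stopifnot(rate >= 0, all(cycle >= 0))
  (1 + rate)^(-cycle)
}

#' Build the reward schedule for one cohort segment
#'
#' @param params complete named parameter set.
#' @param drug `"aspirin"` or `"clopidogrel"`.
#' @param treated is the segment on antiplatelet treatment? Treated segments
#'   accrue the drug cost in every alive state except post-bleed; untreated
#'   segments accrue it only in the symptomatic (diagnosed, hence treated)
#'   PAD state.
#' @param baseline_utility function `age -> utility` for the no-PAD and
#'   asymptomatic states.
#' @param ages ages at cycles 0..n (used to evaluate the background utility).
#' @return List with `annual_cost` (per-state Euros/year), `event_cost`
#'   (one-time Euros on state entry), and `utility`
#'   (`length(ages) x n_states` matrix).
#' @export
reward_schedule <- function(params, drug = "aspirin", treated = FALSE,
                            baseline_utility = background_utility,
                            ages = 55:110) {
  check_parameter_set(params)
  drug <- match.arg(drug, c("aspirin", "clopidogrel"))
  s <- health_states()
  drug_cost <- params[[paste0("cost_", drug, "_annual")]]

  annual <- stats::setNames(numeric(8), s)
  annual["sym_pad"] <- params[["cost_pad_treatment_annual"]]
  annual["post_mi"] <- params[["cost_mi_subsequent_annual"]]
  annual["post_stroke"] <- params[["cost_stroke_subsequent_annual"]]
  drug_states <- if (treated) {
    c("no_pad", "asym_pad", "sym_pad", "post_amputation", "post_mi",
      "post_stroke")
  } else "sym_pad"
  annual[drug_states] <- annual[drug_states] + drug_cost

  event <- stats::setNames(numeric(8), s)
  event["post_amputation"] <- params[["cost_amputation"]]
  event["post_mi"] <- params[["cost_mi_first_year"]]
  event["post_stroke"] <- params[["cost_stroke_first_year"]]
  event["post_bleed"] <- params[["cost_bleed"]]

  util <- matrix(0, length(ages), 8, dimnames = list(ages, s))
  base <- baseline_utility(ages)
  util[, "no_pad"] <- base
  util[, "asym_pad"] <- base
  util[, "sym_pad"] <- params[["utility_pad"]]
  util[, "post_amputation"] <- params[["utility_post_amputation"]]
  util[, "post_mi"] <- params[["utility_post_mi"]]
  util[, "post_stroke"] <- params[["utility_post_stroke"]]
  util[, "post_bleed"] <- params[["utility_post_bleed"]]
  util[, "dead"] <- 0
  if (any(annual < 0) || any(event < 0)) stop("costs must be >= 0",
                                              call. = FALSE)
  if (any(util < 0) || any(util > 1)) stop("utilities must lie in [0, 1]",
                                           call. = FALSE)
  list(annual_cost = annual, event_cost = event, utility = util)
}

# States whose entry year is charged the one-time event cost instead of the
# state's annual cost.
.event_states <- c("post_amputation", "post_mi", "post_stroke", "post_bleed")

#' Accumulate lifetime costs, life years and QALYs over a trace
#'
#' Life years at cycle t are the alive mass at the end of the cycle; QALYs
#' weight occupancy by state utility; costs sum annual state costs on
#' occupancy, one-time event costs on the mass newly entering an event
#' state (with the entry year of post-MI/stroke charged the first-year cost
#' instead of the subsequent-year annual cost), plus a one-time `entry_cost`
#' at cycle 0. Effects are discounted at `effect_rate`, costs at
#' `cost_rate`.
#'
#' @param cohort a `cohort_trace` from [run_cohort()].
#' @param rewards a schedule from [reward_schedule()] (its utility matrix
#'   must cover every trace cycle).
#' @param cost_rate,effect_rate annual discount rates.
#' @param entry_cost one-time cost at cycle 0 (e.g. screening overhead).
#' @return List of class `strategy_outcome` with numeric vectors
#'   `discounted` and `undiscounted`, each `c(cost, ly, qaly)`.
#' @export
accumulate <- function(cohort, rewards, cost_rate = 0.04,
                       effect_rate = 0.015, entry_cost = 0) {
  trace <- cohort$trace
  inflow <- cohort$inflow
  s <- colnames(trace)
  if (!setequal(s, names(rewards$annual_cost)))
    stop("trace states do not match the reward schedule", call. = FALSE)
  if (nrow(rewards$utility) < nrow(trace))
    stop("utility matrix does not cover every cycle", call. = FALSE)
  n <- nrow(trace) - 1L
  cyc <- seq_len(n)              # rewards accrue at cycles 1..n
  dc <- discount_factor(cost_rate, cyc)
  de <- discount_factor(effect_rate, cyc)

  alive <- 1 - trace[cyc + 1L, "dead"]
  qaly_t <- rowSums(trace[cyc + 1L, s, drop = FALSE] *
                    rewards$utility[cyc + 1L, s, drop = FALSE])
  occ_annual <- trace[cyc + 1L, s, drop = FALSE]
  ev <- intersect(.event_states, s)
  occ_annual[, ev] <- occ_annual[, ev] - inflow[cyc + 1L, ev, drop = FALSE]
  cost_t <- as.numeric(occ_annual %*% rewards$annual_cost[s]) +
    as.numeric(inflow[cyc + 1L, s, drop = FALSE] %*% rewards$event_cost[s])

  out <- list(
    discounted = c(cost = entry_cost + sum(dc * cost_t),
                   ly = sum(de * alive), qaly = sum(de * qaly_t)),
    undiscounted = c(cost = entry_cost + sum(cost_t),
                     ly = sum(alive), qaly = sum(qaly_t)))
  class(out) <- "strategy_outcome"
  out
}

#' Incremental comparison of two strategies
#'
#' @param a,b `strategy_outcome` objects (the intervention `a` is compared
#'   against the comparator `b`) sharing one discounting configuration.
#' @return List of class `incremental_result`: discounted `delta_cost`,
#'   `delta_ly`, `delta_qaly`, undiscounted counterparts, the `icer` when
#'   defined, and a `classification`: `"dominant"` (cheaper and more
#'   effective), `"dominated"` (costlier and less effective),
#'   `"cost-only difference"` (equal QALYs, unequal cost), `"equivalent"`,
#'   or `"icer"`.
#' @export
incremental <- function(a, b) {
  d <- a$discounted - b$discounted
  u <- a$undiscounted - b$undiscounted
  dc <- unname(d["cost"]); dq <- unname(d["qaly"])
  classification <-
    if (dc < 0 && dq > 0) "dominant"
    else if (dc > 0 && dq < 0) "dominated"
    else if (dq == 0 && dc != 0) "cost-only difference"
    else if (dq == 0 && dc == 0) "equivalent"
    else "icer"
  structure(list(
    delta_cost = dc, delta_ly = unname(d["ly"]), delta_qaly = dq,
    delta_cost_undiscounted = unname(u["cost"]),
    delta_ly_undiscounted = unname(u["ly"]),
    delta_qaly_undiscounted = unname(u["qaly"]),
    icer = if (classification == "icer") dc / dq else NA_real_,
    classification = classification), class = "incremental_result")
}

#' Incremental net monetary benefit
#'
#' @param inc an `incremental_result`.
#' @param wtp willingness to pay per QALY (Euros, >= 0), possibly a vector.
#' @return `wtp * delta_qaly - delta_cost`.
#' @export
net_monetary_benefit <- function(inc, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * inc$delta_qaly - inc$delta_cost
}
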