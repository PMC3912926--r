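#' Synthetic parameter tables and analytic toy models
#'
#' Property-testing utilities: [generate_parameter_table()] draws complete,
#' structurally valid random parameter tables with the same row names,
#' roles and distribution families as the packaged evidence table, so the
#' entire pipeline (validation, sampling, decision tree, Markov engine,
#' economics, PSA) runs unmodified on synthetic input;
#' [generate_analytic_toy()] builds a two-state alive/dead model whose life
#' expectancy has a geometric-series closed form, used as an analytic oracle
#' for the cohort engine.
#'
#' @name synthetic_params
NULL

#' Specification for a synthetic parameter table
#'
#' @param seed integer seed (required).
#' @param prob_range,utility_range ranges for event/incidence probabilities
#'   and state utilities.
#' @param cost_range range for one-time/annual costs (Euros).
#' @param rr_range range for treatment relative risks.
#' @param zero_events zero out all event, bleeding and incidence
#'   probabilities (the engine then reduces to background mortality alone).
#' @param force_dominance skew the table so screening is clearly dominant
#'   (high prevalence, strong treatment effect, expensive symptomatic care).
#' @param force_dominated skew the table so screening is clearly dominated
#'   (harmful treatment, free symptomatic care, costly test and bleeds).
#' @return List of class `synthesis_spec`.
#' @export
synthesis_spec <- function(seed, prob_range = c(0.001, 0.05),
                           utility_range = c(0.4, 0.95),
                           cost_range = c(100, 30000),
                           rr_range = c(0.5, 0.95),
                           zero_events = FALSE, force_dominance = FALSE,
                           force_dominated = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  chk <- function(r, lo, hi) length(r) == 2L && r[1] <= r[2] &&
    r[1] >= lo && r[2] <= hi
  if (!chk(prob_range, 0, 1)) stop("infeasible prob_range", call. = FALSE)
  if (!chk(utility_range, 0, 1)) stop("infeasible utility_range",
                                      call. = FALSE)
  if (!chk(cost_range, 0, Inf)) stop("infeasible cost_range", call. = FALSE)
  if (!chk(rr_range, 1e-6, Inf)) stop("infeasible rr_range", call. = FALSE)
  if (force_dominance && force_dominated)
    stop("cannot force dominance and dominatedness at once", call. = FALSE)
  structure(list(seed = as.integer(seed), prob_range = prob_range,
                 utility_range = utility_range, cost_range = cost_range,
                 rr_range = rr_range, zero_events = zero_events,
                 force_dominance = force_dominance,
                 force_dominated = force_dominated),
            class = "synthesis_spec")
}

#' Generate a structurally valid random parameter table
#'
#' Row names, roles and distribution families match the packaged table;
#' values are drawn within each role's domain; per-state event plus death
#' probabilities are kept below 0.9 so every transition row remains valid.
#' Deterministic for a given spec seed.
#'
#' @param spec a [synthesis_spec()].
#' @return A validated `param_table`.
#' @export
generate_parameter_table <- function(spec) {
  stopifnot(inherits(spec, "synthesis_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  template <- default_parameter_table()

  runif1 <- function(r) stats::runif(1, r[1], r[2])
  draw_value <- function(row) {
    v <- switch(row$role,
      probability = runif1(spec$prob_range),
      accuracy = stats::runif(1, 0.6, 1),
      utility = runif1(spec$utility_range),
      cost = runif1(spec$cost_range),
      relative_risk = runif1(spec$rr_range),
      rate = stats::runif(1, 0, 0.06))
    # keep large-stock probabilities on their natural scale
    if (row$name == "pad_prevalence") v <- stats::runif(1, 0.05, 0.35)
    if (row$name == "p_symptomatic_pad") v <- stats::runif(1, 0.1, 0.5)
    if (row$name == "p_death_post_amputation") v <- stats::runif(1, 0.05,
                                                                 0.2)
    if (row$role == "probability" && spec$zero_events &&
        grepl("^(p_(amputation|mi|stroke|bleed)|pad_incidence|p_death)",
              row$name))
      v <- 0
    v
  }

  tab <- template
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    v <- draw_value(row)
    tab$value[i] <- v
    if (row$dist == "beta") {
      if (v <= 0 || v >= 1) {          # degenerate: pin as fixed
        tab$dist[i] <- "fixed"
        tab$moment_a[i] <- NA; tab$moment_b[i] <- NA
      } else {
        ess <- stats::runif(1, 50, 5000)
        tab$moment_a[i] <- v * ess
        tab$moment_b[i] <- (1 - v) * ess
      }
    } else if (row$dist == "gamma") {
      shape <- stats::runif(1, 25, 400)
      tab$moment_a[i] <- shape
      tab$moment_b[i] <- v / shape
    } else if (row$dist == "beta_pert") {
      tab$moment_a[i] <- v * stats::runif(1, 0.6, 0.95)
      tab$moment_b[i] <- v * stats::runif(1, 1.05, 1.4)
      if (row$role == "accuracy") tab$moment_b[i] <- min(tab$moment_b[i], 1)
      if (v == 0) { tab$moment_a[i] <- 0; tab$moment_b[i] <- 0 }
    }
  }

  if (spec$force_dominance) {
    tab <- .set_values(tab, c(pad_prevalence = 0.35, rr_aspirin = 0.4,
                              rr_clopidogrel = 0.4,
                              p_symptomatic_pad = 0.5,
                              cost_pad_treatment_annual = 20000,
                              abi_test_cost = 10, cost_aspirin_annual = 1,
                              cost_clopidogrel_annual = 1,
                              p_bleed_aspirin = 0.001,
                              p_bleed_clopidogrel = 0.001,
                              p_death_pad = 0.05))
  }
  if (spec$force_dominated) {
    tab <- .set_values(tab, c(pad_prevalence = 0.05, rr_aspirin = 1.5,
                              rr_clopidogrel = 1.5,
                              p_symptomatic_pad = 0.01,
                              cost_pad_treatment_annual = 0,
                              abi_test_cost = 5000,
                              cost_aspirin_annual = 500,
                              cost_clopidogrel_annual = 500,
                              p_bleed_aspirin = 0.1,
                              p_bleed_clopidogrel = 0.1,
                              cost_bleed = 20000))
  }

  # guarantee valid transition rows: per-state event + death mass < 0.9
  ev <- c("p_amputation_pad", "p_mi_pad", "p_stroke_pad", "p_death_pad")
  rr_max <- max(tab$value[tab$name %in% c("rr_aspirin", "rr_clopidogrel")],
                1)
  bl_max <- max(tab$value[tab$name %in% c("p_bleed_aspirin",
                                          "p_bleed_clopidogrel")])
  total <- sum(tab$value[tab$name %in% ev]) * rr_max + bl_max
  if (total >= 0.9) {
    scale <- 0.85 / total
    idx <- tab$name %in% c(ev, "p_bleed_aspirin", "p_bleed_clopidogrel")
    tab <- .rescale_rows(tab, idx, scale)
  }
  validate_param_table(tab)
}

.set_values <- function(tab, named) {
  for (nm in names(named)) {
    i <- match(nm, tab$name)
    v <- named[[nm]]
    tab$value[i] <- v
    if (tab$dist[i] == "beta") {
      if (v <= 0 || v >= 1) {
        tab$dist[i] <- "fixed"; tab$moment_a[i] <- NA; tab$moment_b[i] <- NA
      } else {
        tab$moment_a[i] <- v * 200; tab$moment_b[i] <- (1 - v) * 200
      }
    } else if (tab$dist[i] == "gamma") {
      if (v <= 0) {
        tab$dist[i] <- "fixed"; tab$moment_a[i] <- NA; tab$moment_b[i] <- NA
      } else tab$moment_b[i] <- v / tab$moment_a[i]
    } else if (tab$dist[i] == "beta_pert") {
      tab$moment_a[i] <- v * 0.8
      tab$moment_b[i] <- v * 1.2
      if (v == 0) { tab$moment_a[i] <- 0; tab$moment_b[i] <- 0 }
    }
  }
  tab
}

.rescale_rows <- function(tab, idx, scale) {
  for (i in which(idx)) {
    tab$value[i] <- tab$value[i] * scale
    if (tab$dist[i] == "beta") {
      ess <- tab$moment_a[i] + tab$moment_b[i]
      tab$moment_a[i] <- tab$value[i] * ess
      tab$moment_b[i] <- (1 - tab$value[i]) * ess
    } else if (tab$dist[i] == "gamma") {
      tab$moment_b[i] <- tab$value[i] / tab$moment_a[i]
    } else if (tab$dist[i] == "beta_pert") {
      tab$moment_a[i] <- tab$moment_a[i] * scale
      tab$moment_b[i] <- tab$moment_b[i] * scale
    }
  }
  tab
}

#' Two-state analytic toy model
#'
#' Alive/dead chain with constant annual mortality `q`, utility 1 and an
#' annual cost `cost` while alive. With cycle-end state counting, the
#' discounted life expectancy at rate `r` is the geometric series
#' `sum_{t>=1} x^t` with `x = (1 - q) / (1 + r)`: `x / (1 - x)` over an
#' infinite horizon, or `x (1 - x^n) / (1 - x)` truncated at `n` cycles.
#' Undiscounted (`r = 0`, infinite horizon) this reduces to `(1 - q) / q`.
#'
#' @param q constant annual mortality, in (0, 1).
#' @param cost annual cost while alive.
#' @return List with `initial` (named distribution), `matrix` (2 x 2
#'   transition matrix), `le` (function `(r, n)` returning the closed-form
#'   discounted life expectancy over `n` cycles, default infinite), and
#'   `cost`.
#' @export
generate_analytic_toy <- function(q, cost = 0) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("q must lie strictly inside (0, 1)", call. = FALSE)
  m <- matrix(c(1 - q, q, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("alive", "dead"), c("alive", "dead")))
  le <- function(r = 0, n = Inf) {
    x <- (1 - q) / (1 + r)
    if (is.infinite(n)) x / (1 - x) else x * (1 - x^n) / (1 - x)
  }
  list(initial = c(alive = 1, dead = 0), matrix = m, le = le, cost = cost)
}
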