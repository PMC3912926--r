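#' Run configuration
#'
#' Bundles the cohort settings: start age 55, one-year cycles to `max_age`
#' (by which the background life table forces death), discount rates 4% for
#' costs and 1.5% for effects (Dutch guideline values), the antiplatelet
#' drug, the one-time screening cost components, the background life table
#' and background utility, the willingness-to-pay grid for acceptability
#' curves, and PSA size/seed defaults.
#'
#' @param start_age cohort entry age (years).
#' @param max_age horizon: the cohort is followed to this age (death is
#'   certain at the end of the life table).
#' @param cost_rate,effect_rate annual discount rates for costs and effects.
#' @param drug `"aspirin"` or `"clopidogrel"`.
#' @param screening_costs list of one-time screening cost components other
#'   than the ABI test itself (`travel`, `gp_session`, `productivity_loss`),
#'   Euros; the ABI test cost comes from the parameter set.
#' @param life_table background mortality data frame (`age`, `qx`).
#' @param baseline_utility function `age -> utility` for the no-PAD and
#'   asymptomatic states.
#' @param wtp_grid willingness-to-pay grid (Euros/QALY) for CEACs.
#' @param psa_n default number of Monte Carlo iterations.
#' @param seed default master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(start_age = 55, max_age = 110, cost_rate = 0.04,
                       effect_rate = 0.015, drug = "aspirin",
                       screening_costs = list(travel = 0, gp_session = 0,
                                              productivity_loss = 0),
                       life_table = default_life_table(),
                       baseline_utility = background_utility,
                       wtp_grid = seq(0, 80000, by = 1000),
                       psa_n = 1000, seed = 1L) {
  stopifnot(cost_rate >= 0, effect_rate >= 0, max_age > start_age,
            psa_n >= 1)
  drug <- match.arg(drug, c("aspirin", "clopidogrel"))
  if (any(diff(wtp_grid) <= 0)) stop("wtp_grid must be strictly increasing",
                                     call. = FALSE)
  structure(list(start_age = start_age, max_age = max_age,
                 cost_rate = cost_rate, effect_rate = effect_rate,
                 drug = drug, screening_costs = screening_costs,
                 life_table = life_table,
                 baseline_utility = baseline_utility,
                 wtp_grid = wtp_grid, psa_n = psa_n, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Recognised fields mirror the arguments of [run_config()]; scalar fields
#' map directly, `screening_costs` is a mapping, `life_table` may name a CSV
#' path (columns `age`, `qx`). Unknown fields are an error so that typos do
#' not silently fall back to defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("start_age", "max_age", "cost_rate", "effect_rate", "drug",
               "screening_costs", "life_table", "wtp_grid", "psa_n", "seed")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$life_table) && is.character(raw$life_table))
    raw$life_table <- read_life_table(raw$life_table)
  if (!is.null(raw$wtp_grid) && length(raw$wtp_grid) == 3 &&
      !is.null(names(raw$wtp_grid)))
    raw$wtp_grid <- seq(raw$wtp_grid[["from"]], raw$wtp_grid[["to"]],
                        by = raw$wtp_grid[["by"]])
  do.call(run_config, raw)
}

# Initial state distribution of one decision-tree segment.
segment_initial_state <- function(label) {
  s <- health_states()
  init <- stats::setNames(numeric(8), s)
  start <- switch(label,
    true_positive = "asym_pad",      # detected preclinical PAD, on treatment
    false_negative = "asym_pad",     # missed preclinical PAD
    undetected = "asym_pad",
    incidental_treated = "sym_pad",  # clinically manifest, diagnosed PAD
    false_positive = "no_pad",
    true_negative = "no_pad")
  init[start] <- 1
  init
}

#' Evaluate one strategy at one parameter set
#'
#' Runs the decision tree, then propagates every cohort segment through the
#' Markov model to `max_age` and aggregates discounted and undiscounted
#' costs, life years and QALYs, weighting segments by their cohort
#' fractions. Screening charges the one-time overhead (ABI test cost from
#' the parameter set plus any configured travel/GP/productivity components)
#' to every screened person at cycle 0.
#'
#' @param params complete named parameter set (one PSA draw or the point
#'   estimates from [sample_parameters()]).
#' @param screening logical: ABI screening arm (`TRUE`) or no-screening arm.
#' @param config a [run_config()].
#' @return A `strategy_outcome` with `discounted` / `undiscounted`
#'   `c(cost, ly, qaly)` totals and a per-segment breakdown in attribute
#'   `segments`.
#' @export
evaluate_strategy <- function(params, screening, config = run_config()) {
  check_parameter_set(params)
  segs <- if (screening) {
    allocate_screening_arm(params[["pad_prevalence"]],
                           params[["abi_sensitivity"]],
                           params[["abi_specificity"]])
  } else {
    allocate_no_screening_arm(params[["pad_prevalence"]],
                              params[["p_symptomatic_pad"]])
  }
  overhead <- if (screening) {
    screening_overhead(c(list(abi_test = params[["abi_test_cost"]]),
                         config$screening_costs))
  } else 0

  n_cycles <- config$max_age - config$start_age
  ages <- config$start_age + 0:n_cycles

  # Matrix sets shared across segments: (treated, post_bleed_pad) types.
  # Post-bleed occupants carry PAD risks in every segment except false
  # positives, whose bleeds arise without PAD.
  seg_type <- function(treated, label) {
    paste(treated, label == "false_positive", sep = "/")
  }
  types <- unique(mapply(seg_type, segs$on_treatment, segs$label))
  arrays <- lapply(types, function(tp) {
    parts <- strsplit(tp, "/")[[1]]
    transition_array(params, treated = as.logical(parts[1]),
                     drug = config$drug, life_table = config$life_table,
                     start_age = config$start_age, max_age = config$max_age,
                     post_bleed_pad = !as.logical(parts[2]))
  })
  names(arrays) <- types

  disc <- c(cost = 0, ly = 0, qaly = 0)
  undisc <- disc
  seg_rows <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    seg <- segs[i, ]
    if (seg$fraction == 0) next
    rewards <- reward_schedule(params, drug = config$drug,
                               treated = seg$on_treatment,
                               baseline_utility = config$baseline_utility,
                               ages = ages)
    cohort <- run_cohort(segment_initial_state(seg$label),
                         arrays[[seg_type(seg$on_treatment, seg$label)]],
                         n_cycles)
    out <- accumulate(cohort, rewards, cost_rate = config$cost_rate,
                      effect_rate = config$effect_rate,
                      entry_cost = overhead)
    disc <- disc + seg$fraction * out$discounted
    undisc <- undisc + seg$fraction * out$undiscounted
    seg_rows[[i]] <- data.frame(label = seg$label, fraction = seg$fraction,
                                cost = out$discounted["cost"],
                                ly = out$discounted["ly"],
                                qaly = out$discounted["qaly"],
                                row.names = NULL)
  }
  res <- structure(list(discounted = disc, undiscounted = undisc),
                   class = "strategy_outcome")
  attr(res, "segments") <- do.call(rbind, seg_rows)
  attr(res, "screening") <- screening
  attr(res, "drug") <- config$drug
  res
}

#' Deterministic base-case analysis
#'
#' Evaluates both strategies at the parameter point estimates and returns
#' their outcomes and the incremental comparison (screening vs no
#' screening).
#'
#' @param tab a `param_table` (default: the packaged table).
#' @param config a [run_config()].
#' @return List with `screening`, `no_screening` (both `strategy_outcome`)
#'   and `incremental` (an `incremental_result`).
#' @export
run_base_case <- function(tab = default_parameter_table(),
                          config = run_config()) {
  params <- sample_parameters(tab)
  scr <- evaluate_strategy(params, screening = TRUE, config = config)
  nos <- evaluate_strategy(params, screening = FALSE, config = config)
  list(screening = scr, no_screening = nos,
       incremental = incremental(scr, nos))
}

#' Full analysis bundle
#'
#' Convenience driver reproducing the study's headline outputs in one call:
#' the deterministic base case, the paired PSA with its summary in the
#' published table layout, the CE-plane quadrant summary, the CEAC over the
#' configured WTP grid, the one-way tornado table, and the two-way
#' prevalence-by-relative-risk grid. When `out_dir` is given, each result
#' is also written as a CSV.
#'
#' @param tab a `param_table`.
#' @param config a [run_config()].
#' @param out_dir optional output directory for CSV exports.
#' @return List with elements `base_case`, `psa`, `psa_table`, `ce_plane`,
#'   `ceac`, `tornado`, `two_way`.
#' @export
run_full_analysis <- function(tab = default_parameter_table(),
                              config = run_config(), out_dir = NULL) {
  base_case <- run_base_case(tab, config)
  psa <- run_psa(tab, config, n = config$psa_n, seed = config$seed)
  tab2 <- psa_summary_table(psa)
  plane <- ce_plane_summary(psa)
  cc <- ceac(psa, config$wtp_grid)
  tornado <- one_way_sa(tab, config)
  tw <- two_way_sa(tab, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(psa$draws, file.path(out_dir, "psa_draws.csv"),
                     row.names = FALSE)
    utils::write.csv(tab2, file.path(out_dir, "psa_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(cc, file.path(out_dir, "ceac.csv"), row.names = FALSE)
    utils::write.csv(tornado, file.path(out_dir, "tornado.csv"),
                     row.names = FALSE)
    utils::write.csv(tw, file.path(out_dir, "two_way.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(t(plane)),
                     file.path(out_dir, "ce_plane_quadrants.csv"),
                     row.names = FALSE)
  }
  list(base_case = base_case, psa = psa, psa_table = tab2, ce_plane = plane,
       ceac = cc, tornado = tornado, two_way = tw)
}
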