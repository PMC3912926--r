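#' Deterministic sensitivity analyses
#'
#' One-way analysis moves each non-fixed parameter to the 2.5% and 97.5%
#' quantiles of its PSA distribution while all others stay at their point
#' values, recording the incremental outcomes; the tornado ordering is by
#' the absolute range of the incremental QALYs. Two-way analysis sweeps a
#' grid over PAD prevalence and the treatment relative risk.
#'
#' @name sensitivity
NULL

#' One-way (tornado) sensitivity analysis
#'
#' @param tab a `param_table`.
#' @param config a [run_config()].
#' @param outcome which incremental outcome orders the tornado:
#'   `"qaly"` (default) or `"cost"`.
#' @return Data frame, one row per non-fixed parameter, sorted by decreasing
#'   absolute range of the chosen outcome: bounds used, incremental cost and
#'   QALY at each bound, and the ranges.
#' @export
one_way_sa <- function(tab, config = run_config(), outcome = c("qaly",
                                                               "cost")) {
  outcome <- match.arg(outcome)
  validate_param_table(tab)
  base <- sample_parameters(tab)
  vary <- tab[tab$dist != "fixed", ]

  eval_at <- function(params) {
    scr <- evaluate_strategy(params, screening = TRUE, config = config)
    nos <- evaluate_strategy(params, screening = FALSE, config = config)
    incremental(scr, nos)
  }
  rows <- lapply(seq_len(nrow(vary)), function(i) {
    spec <- vary[i, ]
    bounds <- ci95_bounds(spec)
    at <- lapply(bounds, function(v) {
      p <- base
      p[[spec$name]] <- v
      eval_at(p)
    })
    data.frame(name = spec$name, low = bounds[1], high = bounds[2],
               d_cost_low = at[[1]]$delta_cost,
               d_cost_high = at[[2]]$delta_cost,
               d_qaly_low = at[[1]]$delta_qaly,
               d_qaly_high = at[[2]]$delta_qaly,
               cost_range = abs(at[[2]]$delta_cost - at[[1]]$delta_cost),
               qaly_range = abs(at[[2]]$delta_qaly - at[[1]]$delta_qaly),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key <- if (outcome == "qaly") out$qaly_range else out$cost_range
  out <- out[order(-key), ]
  rownames(out) <- NULL
  out
}

#' Two-way sensitivity analysis over prevalence and relative risk
#'
#' @param tab a `param_table`.
#' @param config a [run_config()].
#' @param prevalence_grid PAD prevalence values to test.
#' @param rr_grid treatment relative-risk values to test (for the configured
#'   drug).
#' @return Data frame with one row per grid cell: `prevalence`, `rr`,
#'   incremental cost/LY/QALY and the dominance classification.
#' @export
two_way_sa <- function(tab, config = run_config(),
                       prevalence_grid = seq(0.05, 0.35, by = 0.05),
                       rr_grid = seq(0.6, 1.0, by = 0.1)) {
  validate_param_table(tab)
  if (any(prevalence_grid < 0 | prevalence_grid > 1))
    stop("prevalence grid outside [0, 1]", call. = FALSE)
  if (any(rr_grid <= 0)) stop("relative risks must be > 0", call. = FALSE)
  base <- sample_parameters(tab)
  rr_name <- paste0("rr_", config$drug)
  grid <- expand.grid(prevalence = prevalence_grid, rr = rr_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- base
    p[["pad_prevalence"]] <- grid$prevalence[i]
    p[[rr_name]] <- grid$rr[i]
    scr <- evaluate_strategy(p, screening = TRUE, config = config)
    nos <- evaluate_strategy(p, screening = FALSE, config = config)
    inc <- incremental(scr, nos)
    data.frame(prevalence = grid$prevalence[i], rr = grid$rr[i],
               d_cost = inc$delta_cost, d_ly = inc$delta_ly,
               d_qaly = inc$delta_qaly,
               classification = inc$classification,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
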