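#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of the parameter distributions through the model.
#' Each iteration draws one parameter set and evaluates *both* strategies on
#' it (common random numbers), so incremental results are paired.
#' Per-iteration seeds are derived from the master seed (one `sample.int`
#' stream), making the whole run bit-reproducible.
#'
#' @param tab a `param_table`.
#' @param config a [run_config()].
#' @param n number of Monte Carlo iterations (>= 1).
#' @param seed master seed.
#' @return List of class `psa_result`: `draws` (a data frame with one row
#'   per iteration: discounted and undiscounted cost/ly/qaly per arm and
#'   their increments), `summary` (means of the same columns), `n`, `seed`,
#'   and `n_failed` (iterations whose parameter draw violated model
#'   consistency, reported rather than silently dropped).
#' @export
run_psa <- function(tab, config = run_config(), n = 1000, seed = 1L) {
  stopifnot(n >= 1)
  validate_param_table(tab)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, n)

  rows <- vector("list", n)
  n_failed <- 0L
  failures <- character(0)
  for (i in seq_len(n)) {
    params <- sample_parameters(tab, seed = iter_seeds[i])
    res <- tryCatch({
      scr <- evaluate_strategy(params, screening = TRUE, config = config)
      nos <- evaluate_strategy(params, screening = FALSE, config = config)
      inc <- incremental(scr, nos)
      data.frame(iteration = i, seed = iter_seeds[i],
                 cost_screen = scr$discounted[["cost"]],
                 ly_screen = scr$discounted[["ly"]],
                 qaly_screen = scr$discounted[["qaly"]],
                 cost_noscreen = nos$discounted[["cost"]],
                 ly_noscreen = nos$discounted[["ly"]],
                 qaly_noscreen = nos$discounted[["qaly"]],
                 ucost_screen = scr$undiscounted[["cost"]],
                 uly_screen = scr$undiscounted[["ly"]],
                 uqaly_screen = scr$undiscounted[["qaly"]],
                 ucost_noscreen = nos$undiscounted[["cost"]],
                 uly_noscreen = nos$undiscounted[["ly"]],
                 uqaly_noscreen = nos$undiscounted[["qaly"]],
                 d_cost = inc$delta_cost, d_ly = inc$delta_ly,
                 d_qaly = inc$delta_qaly)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      failures <- c(failures, conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  draws <- do.call(rbind, rows)
  if (is.null(draws) || nrow(draws) == 0L)
    stop("every PSA iteration failed; first error: ", failures[1],
         call. = FALSE)
  if (n_failed > 0L)
    warning(n_failed, " of ", n, " PSA iteration(s) failed a model ",
            "consistency check and were excluded", call. = FALSE)
  structure(list(draws = draws,
                 summary = colMeans(draws[, setdiff(names(draws),
                                                    c("iteration", "seed"))]),
                 n = n, n_failed = n_failed, seed = seed,
                 drug = config$drug),
            class = "psa_result")
}

#' PSA summary in the published table layout
#'
#' Mean costs, life years and QALYs per strategy with the increments of
#' screening over no screening, discounted and undiscounted blocks.
#'
#' @param psa a `psa_result`.
#' @return Data frame with columns `block`, `strategy`, `cost`, `ly`,
#'   `qaly`, `icost`, `ily`, `iqaly`, `classification`.
#' @export
psa_summary_table <- function(psa) {
  s <- psa$summary
  cls_disc <- .dominance_label(s[["d_cost"]], s[["d_qaly"]])
  cls_und <- .dominance_label(s[["ucost_screen"]] - s[["ucost_noscreen"]],
                              s[["uqaly_screen"]] - s[["uqaly_noscreen"]])
  data.frame(
    block = c("discounted", "discounted", "undiscounted", "undiscounted"),
    strategy = rep(c("no_screening", "abi_screening"), 2),
    cost = c(s[["cost_noscreen"]], s[["cost_screen"]],
             s[["ucost_noscreen"]], s[["ucost_screen"]]),
    ly = c(s[["ly_noscreen"]], s[["ly_screen"]],
           s[["uly_noscreen"]], s[["uly_screen"]]),
    qaly = c(s[["qaly_noscreen"]], s[["qaly_screen"]],
             s[["uqaly_noscreen"]], s[["uqaly_screen"]]),
    icost = c(NA, s[["d_cost"]], NA,
              s[["ucost_screen"]] - s[["ucost_noscreen"]]),
    ily = c(NA, s[["d_ly"]], NA, s[["uly_screen"]] - s[["uly_noscreen"]]),
    iqaly = c(NA, s[["d_qaly"]], NA,
              s[["uqaly_screen"]] - s[["uqaly_noscreen"]]),
    classification = c(NA, cls_disc, NA, cls_und),
    stringsAsFactors = FALSE)
}

.dominance_label <- function(d_cost, d_qaly) {
  if (d_cost < 0 && d_qaly > 0) "dominant"
  else if (d_cost > 0 && d_qaly < 0) "dominated"
  else if (d_qaly == 0) "no QALY difference"
  else sprintf("ICER %.0f", d_cost / d_qaly)
}

#' Cost-effectiveness plane quadrant fractions
#'
#' Fractions of PSA iterations falling in each quadrant of the
#' (incremental QALY, incremental cost) plane. Boundary points are assigned
#' to the favourable quadrant: an iteration with `d_qaly >= 0` and
#' `d_cost <= 0` counts as right-lower (more effective, less costly).
#'
#' @param psa a `psa_result`.
#' @return Named numeric vector `c(right_lower, right_upper, left_lower,
#'   left_upper)` summing to 1.
#' @export
ce_plane_summary <- function(psa) {
  dq <- psa$draws$d_qaly
  dc <- psa$draws$d_cost
  rl <- dq >= 0 & dc <= 0
  ru <- dq >= 0 & dc > 0
  ll <- !rl & !ru & dc <= 0
  lu <- !rl & !ru & dc > 0
  c(right_lower = mean(rl), right_upper = mean(ru),
    left_lower = mean(ll), left_upper = mean(lu))
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the fraction of PSA iterations
#' with strictly positive incremental net monetary benefit
#' (`wtp * d_qaly - d_cost > 0`; ties count as not cost-effective).
#'
#' @param psa a `psa_result`.
#' @param wtp_grid strictly increasing WTP grid (Euros/QALY).
#' @return Data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 80000, by = 1000)) {
  if (any(diff(wtp_grid) <= 0) || any(wtp_grid < 0))
    stop("wtp_grid must be non-negative and strictly increasing",
         call. = FALSE)
  dq <- psa$draws$d_qaly
  dc <- psa$draws$d_cost
  prob <- vapply(wtp_grid, function(w) mean(w * dq - dc > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}
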