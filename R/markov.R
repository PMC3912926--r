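#' Markov cohort engine
#'
#' Annual-cycle state-transition model over eight cardiovascular health
#' states: no PAD, asymptomatic PAD, symptomatic (diagnosed) PAD, post
#' amputation, post myocardial infarction, post stroke, post bleed (major
#' bleeding on antiplatelet treatment, after which treatment stops), and the
#' absorbing state death.
#'
#' Structural conventions:
#' * At most one transition per one-year cycle.
#' * Post-amputation/MI/stroke states are terminal apart from death; each has
#'   its own annual mortality.
#' * The symptomatic-PAD state is by definition diagnosed and on treatment:
#'   its event and PAD mortality probabilities carry the treatment relative
#'   risk and it carries the bleeding risk, in every cohort segment.
#' * Asymptomatic PAD and no-PAD rows are treated only in treated segments;
#'   treated no-PAD rows (false positives) incur the bleeding risk but no
#'   relative-risk benefit, which applies to PAD patients only.
#' * Incident PAD (from no PAD) is split at onset into symptomatic (diagnosed,
#'   treated) and asymptomatic by the symptomatic-PAD probability.
#' * Background all-cause mortality q(age) acts as an independent competing
#'   hazard: total death probability is 1 - (1 - p_state_death) (1 - q) and
#'   all other transition mass is scaled by (1 - q).
#'
#' @name markov_engine
NULL

#' The model's health states
#'
#' @return Character vector of the eight state names, death last.
#' @export
health_states <- function() {
  c("no_pad", "asym_pad", "sym_pad", "post_amputation", "post_mi",
    "post_stroke", "post_bleed", "dead")
}

.row_error <- function(state, msg) {
  stop(sprintf("transition row '%s': %s", state, msg), call. = FALSE)
}

# Annual transition matrix before background mortality is applied.
# incidence_param names the age band's PAD incidence row.
transition_core <- function(params, treated, drug, incidence_param,
                            post_bleed_pad = TRUE) {
  check_parameter_set(params)
  drug <- match.arg(drug, c("aspirin", "clopidogrel"))
  rr    <- params[[paste0("rr_", drug)]]
  bleed <- params[[paste0("p_bleed_", drug)]]
  psym  <- params[["p_symptomatic_pad"]]
  s <- health_states()
  m <- matrix(0, 8, 8, dimnames = list(s, s))

  fill_row <- function(state, to) {
    if (any(unlist(to) < 0)) .row_error(state, "negative probability")
    rest <- 1 - sum(unlist(to))
    if (rest < -1e-12)
      .row_error(state, sprintf(
        "event, bleed and death probabilities sum to %.4f > 1",
        sum(unlist(to))))
    m[state, names(to)] <<- unlist(to)
    m[state, state] <<- m[state, state] + max(rest, 0)
  }

  inc <- params[[incidence_param]]
  fill_row("no_pad", list(
    post_amputation = params[["p_amputation_no_pad"]],
    post_mi = params[["p_mi_no_pad"]],
    post_stroke = params[["p_stroke_no_pad"]],
    post_bleed = if (treated) bleed else 0,
    sym_pad = inc * psym,
    asym_pad = inc * (1 - psym)))

  rr_asym <- if (treated) rr else 1
  fill_row("asym_pad", list(
    post_amputation = params[["p_amputation_pad"]] * rr_asym,
    post_mi = params[["p_mi_pad"]] * rr_asym,
    post_stroke = params[["p_stroke_pad"]] * rr_asym,
    post_bleed = if (treated) bleed else 0,
    dead = params[["p_death_pad"]] * rr_asym))

  fill_row("sym_pad", list(
    post_amputation = params[["p_amputation_pad"]] * rr,
    post_mi = params[["p_mi_pad"]] * rr,
    post_stroke = params[["p_stroke_pad"]] * rr,
    post_bleed = bleed,
    dead = params[["p_death_pad"]] * rr))

  fill_row("post_amputation", list(dead = params[["p_death_post_amputation"]]))
  fill_row("post_mi", list(dead = params[["p_death_post_mi"]]))
  fill_row("post_stroke", list(dead = params[["p_death_post_stroke"]]))

  if (post_bleed_pad) {
    fill_row("post_bleed", list(
      post_amputation = params[["p_amputation_pad"]],
      post_mi = params[["p_mi_pad"]],
      post_stroke = params[["p_stroke_pad"]],
      dead = params[["p_death_pad"]]))
  } else {
    fill_row("post_bleed", list(
      post_amputation = params[["p_amputation_no_pad"]],
      post_mi = params[["p_mi_no_pad"]],
      post_stroke = params[["p_stroke_no_pad"]]))
  }

  m["dead", "dead"] <- 1
  m
}

# Overlay background mortality q as an independent competing hazard.
apply_background_mortality <- function(m, q) {
  stopifnot(q >= 0, q <= 1)
  out <- m
  alive <- setdiff(rownames(m), "dead")
  out[alive, ] <- m[alive, ] * (1 - q)
  out[alive, "dead"] <- 1 - (1 - m[alive, "dead"]) * (1 - q)
  out
}

#' Build one annual transition matrix
#'
#' @param params complete named parameter set (see
#'   [required_parameter_names()]).
#' @param treated is this cohort segment on antiplatelet treatment?
#' @param age age at the start of the cycle (years, >= 55); selects the PAD
#'   incidence band and the background mortality.
#' @param drug `"aspirin"` or `"clopidogrel"`.
#' @param life_table background mortality table (`age`, `qx`).
#' @param post_bleed_pad do post-bleed occupants carry PAD event risks
#'   (`TRUE` everywhere except the false-positive segment, whose bleeds are
#'   PAD-free)?
#' @return 8 x 8 row-stochastic matrix over [health_states()].
#' @export
build_transition_matrix <- function(params, treated, age, drug = "aspirin",
                                    life_table = gompertz_life_table(),
                                    post_bleed_pad = TRUE) {
  if (age < 55) stop("age must be >= 55", call. = FALSE)
  core <- transition_core(params, treated, drug,
                          incidence_parameter_for_age(age), post_bleed_pad)
  m <- apply_background_mortality(core,
                                  background_mortality_at(life_table, age))
  check_stochastic(m)
  m
}

check_stochastic <- function(m, tol = 1e-10) {
  if (any(m < -tol) || any(m > 1 + tol))
    stop("transition matrix entries outside [0, 1]", call. = FALSE)
  dev <- abs(rowSums(m) - 1)
  if (any(dev > tol))
    stop(sprintf("transition matrix row '%s' sums to 1 %+.2e",
                 rownames(m)[which.max(dev)], max(dev)), call. = FALSE)
  invisible(m)
}

# All annual matrices for one segment type, ages start_age .. max_age - 1.
# Returns a 3D array [state, state, cycle].
transition_array <- function(params, treated, drug, life_table,
                             start_age = 55, max_age = 110,
                             post_bleed_pad = TRUE) {
  ages <- start_age:(max_age - 1)
  bands <- incidence_parameter_for_age(ages)
  cores <- lapply(unique(bands), function(b)
    transition_core(params, treated, drug, b, post_bleed_pad))
  names(cores) <- unique(bands)
  s <- health_states()
  arr <- array(0, dim = c(8, 8, length(ages)), dimnames = list(s, s, ages))
  for (k in seq_along(ages)) {
    m <- apply_background_mortality(cores[[bands[k]]],
                                    background_mortality_at(life_table,
                                                            ages[k]))
    check_stochastic(m)
    arr[, , k] <- m
  }
  arr
}

#' Run a cohort through a sequence of transition matrices
#'
#' Generic cohort propagation: row t of the trace is row t-1 multiplied by
#' the t-th transition matrix. Works for any state space (the analytic toy
#' models use 2 states), as long as each matrix is row-stochastic over the
#' names of `initial`.
#'
#' @param initial named initial occupancy distribution (sums to 1).
#' @param matrices either a 3D array `[state, state, cycle]` or a function
#'   `cycle index -> matrix`.
#' @param n_cycles number of annual cycles to run.
#' @return List of class `cohort_trace` with elements `trace`
#'   (`(n_cycles + 1) x n_states`, row 1 = cycle 0) and `inflow`
#'   (same shape; new mass entering each state at each cycle from *other*
#'   states, zero at cycle 0).
#' @export
run_cohort <- function(initial, matrices, n_cycles) {
  if (abs(sum(initial) - 1) > 1e-10)
    stop("initial distribution must sum to 1", call. = FALSE)
  states <- names(initial)
  if (is.null(states)) stop("initial distribution must be named",
                            call. = FALSE)
  get_m <- if (is.function(matrices)) {
    matrices
  } else {
    stopifnot(dim(matrices)[3] >= n_cycles)
    function(t) matrices[, , t]
  }
  k <- length(states)
  trace <- matrix(0, n_cycles + 1, k, dimnames = list(0:n_cycles, states))
  inflow <- trace
  trace[1, ] <- initial
  occ <- initial
  for (t in seq_len(n_cycles)) {
    m <- as.matrix(get_m(t))
    if (!all(dim(m) == k)) stop("matrix/state dimension mismatch",
                                call. = FALSE)
    check_stochastic(m)
    nxt <- as.numeric(occ %*% m)
    off <- m
    diag(off) <- 0
    inflow[t + 1, ] <- as.numeric(occ %*% off)
    trace[t + 1, ] <- nxt
    occ <- stats::setNames(nxt, states)
  }
  structure(list(trace = trace, inflow = inflow), class = "cohort_trace")
}
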