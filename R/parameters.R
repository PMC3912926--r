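#' @title Model parameter tables
#'
#' @description
#' The model's evidence base is a flat parameter table: one row per model
#' parameter with a point value, a probability distribution family used in
#' probabilistic sensitivity analysis (PSA), and the two moments of that
#' distribution. Supported families are `fixed` (degenerate), `beta`
#' (moments are the shape parameters alpha, beta), `gamma` (moments are
#' shape and scale, so that shape * scale equals the point value), and
#' `beta_pert` (moments are min and max; the mode is the point value;
#' standard PERT with lambda = 4).
#'
#' @name param_table
NULL

.param_roles <- c("probability", "utility", "cost", "relative_risk", "rate",
                  "accuracy")
.param_dists <- c("fixed", "beta", "gamma", "beta_pert")
.param_cols  <- c("name", "role", "value", "dist", "moment_a", "moment_b",
                  "source")

#' Construct a single parameter specification
#'
#' @param name identifier, unique within a table.
#' @param role one of `"probability"`, `"utility"`, `"cost"`,
#'   `"relative_risk"`, `"rate"`, `"accuracy"`. Determines the admissible
#'   domain of the value (probabilities, utilities and accuracies in
#'   \[0, 1\]; costs and rates non-negative; relative risks positive).
#' @param value point value used in deterministic analyses.
#' @param dist distribution family, one of `"fixed"`, `"beta"`, `"gamma"`,
#'   `"beta_pert"`.
#' @param moment_a,moment_b distribution moments: Beta alpha/beta, Gamma
#'   shape/scale, or PERT min/max. `NA` for fixed parameters.
#' @param source free-text provenance note.
#' @return A one-row `data.frame` with class `param_table`.
#' @export
parameter_spec <- function(name, role, value, dist = "fixed",
                           moment_a = NA_real_, moment_b = NA_real_,
                           source = "") {
  tab <- data.frame(name = as.character(name), role = as.character(role),
                    value = as.numeric(value), dist = as.character(dist),
                    moment_a = as.numeric(moment_a),
                    moment_b = as.numeric(moment_b),
                    source = as.character(source),
                    stringsAsFactors = FALSE)
  validate_param_table(as_param_table(tab))
}

as_param_table <- function(df) {
  class(df) <- c("param_table", "data.frame")
  df
}

#' Validate a parameter table
#'
#' Checks the schema (columns, known roles and distribution families) and the
#' per-role domain invariants, and that distribution moments are admissible
#' (Beta/Gamma moments positive; PERT min <= mode <= max).
#'
#' @param tab a `param_table` data frame.
#' @return `tab`, invisibly classed, if valid; otherwise an error naming the
#'   offending row and field.
#' @export
validate_param_table <- function(tab) {
  missing_cols <- setdiff(.param_cols, names(tab))
  if (length(missing_cols) > 0L) {
    stop("parameter table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    stop("parameter table is empty", call. = FALSE)
  }
  if (anyDuplicated(tab$name)) {
    stop("duplicated parameter name(s): ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad_field <- function(row, field, why) {
    stop(sprintf("parameter '%s': invalid %s (%s)", row$name, field, why),
         call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    if (!row$role %in% .param_roles)
      bad_field(row, "role", paste0("unknown role '", row$role, "'"))
    if (!row$dist %in% .param_dists)
      bad_field(row, "dist", paste0("unknown distribution '", row$dist, "'"))
    if (!is.finite(row$value))
      bad_field(row, "value", "not a finite number")
    ok <- switch(row$role,
      probability = ,
      utility = ,
      accuracy = row$value >= 0 && row$value <= 1,
      cost = ,
      rate = row$value >= 0,
      relative_risk = row$value > 0)
    if (!ok) bad_field(row, "value", paste0("outside the domain of role '",
                                            row$role, "'"))
    if (row$dist %in% c("beta", "gamma")) {
      if (!is.finite(row$moment_a) || row$moment_a <= 0)
        bad_field(row, "moment_a", "must be > 0")
      if (!is.finite(row$moment_b) || row$moment_b <= 0)
        bad_field(row, "moment_b", "must be > 0")
    }
    if (row$dist == "beta_pert") {
      if (!is.finite(row$moment_a) || !is.finite(row$moment_b))
        bad_field(row, "moment_a", "PERT needs finite min and max")
      if (!(row$moment_a <= row$value && row$value <= row$moment_b))
        bad_field(row, "value", "PERT requires min <= mode <= max")
    }
  }
  invisible(as_param_table(tab))
}

#' Load a parameter table from CSV or JSON
#'
#' The CSV schema has header `name,role,value,dist,moment_a,moment_b,source`;
#' the JSON form is an array of objects with the same fields. The packaged
#' default table (`default_parameter_table()`) ships every model parameter:
#' ABI test accuracy, PAD prevalence and age-band incidences, annual event
#' and mortality probabilities, treatment relative risks and bleeding risks,
#' costs in 2012 Euros, and state utilities.
#'
#' @param path path to a `.csv` or `.json` parameter file.
#' @return A validated `param_table` data frame.
#' @export
load_parameter_table <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path,
                               call. = FALSE)
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(tab) > 0) {
    for (col in c("value", "moment_a", "moment_b"))
      if (col %in% names(tab)) tab[[col]] <- as.numeric(tab[[col]])
  }
  validate_param_table(as_param_table(tab))
  as_param_table(tab)
}

#' Write a parameter table to CSV or JSON
#'
#' Inverse of [load_parameter_table()]; a written table reloads to an
#' identical set of specifications.
#'
#' @param tab a `param_table`.
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(tab, path) {
  validate_param_table(tab)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(tab), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(tab), path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' The packaged model parameter table
#'
#' @return The packaged `param_table` with all model parameters (point
#'   values, PSA distribution families and moments).
#' @export
default_parameter_table <- function() {
  load_parameter_table(system.file("extdata", "table1_params.csv",
                                   package = "padscreen", mustWork = TRUE))
}

.pert_shapes <- function(min, mode, max) {
  if (max == min) return(c(a = 1, b = 1))
  c(a = 1 + 4 * (mode - min) / (max - min),
    b = 1 + 4 * (max - mode) / (max - min))
}

#' Analytic mean of a parameter's PSA distribution
#'
#' Beta: alpha / (alpha + beta). Gamma: shape * scale.
#' Beta-PERT: (min + 4 mode + max) / 6. Fixed: the point value.
#'
#' @param tab a `param_table` (one or more rows).
#' @return Named numeric vector of distribution means, one per row.
#' @export
distribution_mean <- function(tab) {
  validate_param_table(tab)
  out <- vapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    switch(row$dist,
      fixed     = row$value,
      beta      = row$moment_a / (row$moment_a + row$moment_b),
      gamma     = row$moment_a * row$moment_b,
      beta_pert = (row$moment_a + 4 * row$value + row$moment_b) / 6)
  }, numeric(1))
  stats::setNames(out, tab$name)
}

#' 95% interval bounds of a parameter's PSA distribution
#'
#' The 2.5% and 97.5% quantiles of the row's distribution, used as the low
#' and high levers of one-way deterministic sensitivity analysis.
#'
#' @param spec a single-row `param_table`.
#' @return Numeric vector `c(lower, upper)`.
#' @export
ci95_bounds <- function(spec) {
  validate_param_table(spec)
  if (nrow(spec) != 1L) stop("ci95_bounds() expects a single row",
                             call. = FALSE)
  p <- c(0.025, 0.975)
  row <- spec[1, ]
  switch(row$dist,
    fixed = stop(sprintf(
      "parameter '%s' is fixed: interval bounds are not applicable",
      row$name), call. = FALSE),
    beta = stats::qbeta(p, row$moment_a, row$moment_b),
    gamma = stats::qgamma(p, shape = row$moment_a, scale = row$moment_b),
    beta_pert = {
      sh <- .pert_shapes(row$moment_a, row$value, row$moment_b)
      row$moment_a + (row$moment_b - row$moment_a) *
        stats::qbeta(p, sh["a"], sh["b"])
    })
}

#' Flag rows whose distribution mean disagrees with the point value
#'
#' A consistency screen on the evidence table: for non-fixed rows it reports
#' those whose analytic distribution mean deviates from the printed point
#' value by more than `tol` in relative terms. A handful of the source
#' table's Beta moments are known to sit outside 5%.
#'
#' @param tab a `param_table`.
#' @param tol relative deviation threshold (default 0.05).
#' @return Data frame of flagged rows with point value, distribution mean
#'   and relative deviation.
#' @export
mean_consistency_flags <- function(tab, tol = 0.05) {
  validate_param_table(tab)
  nonfixed <- tab[tab$dist != "fixed" & tab$value != 0, ]
  m <- distribution_mean(nonfixed)
  rel <- abs(m - nonfixed$value) / abs(nonfixed$value)
  flagged <- rel > tol
  data.frame(name = nonfixed$name[flagged],
             value = nonfixed$value[flagged],
             dist_mean = unname(m[flagged]),
             rel_dev = unname(rel[flagged]),
             stringsAsFactors = FALSE)
}

#' Realize one parameter set
#'
#' Draws one value per table row from its PSA distribution: Beta(alpha, beta),
#' Gamma(shape, scale), PERT(min, mode, max) rescaled to \[min, max\] with
#' shapes alpha = 1 + 4 (mode - min)/(max - min), beta = 1 + 4 (max - mode)/
#' (max - min), or the point value for fixed rows. Draws are reproducible:
#' the same `seed` yields the identical set. The caller's RNG state is left
#' untouched.
#'
#' @param tab a `param_table`.
#' @param seed integer seed for this draw; `NULL` returns the point
#'   estimates (the deterministic parameter set).
#' @return Named numeric vector with attributes `provenance`
#'   (`"point_estimate"` or `"psa_draw"`) and `seed`.
#' @export
sample_parameters <- function(tab, seed = NULL) {
  validate_param_table(tab)
  if (is.null(seed)) {
    out <- stats::setNames(tab$value, tab$name)
    attr(out, "provenance") <- "point_estimate"
    return(out)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  out <- vapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    switch(row$dist,
      fixed = row$value,
      beta = stats::rbeta(1, row$moment_a, row$moment_b),
      gamma = stats::rgamma(1, shape = row$moment_a, scale = row$moment_b),
      beta_pert = {
        sh <- .pert_shapes(row$moment_a, row$value, row$moment_b)
        row$moment_a + (row$moment_b - row$moment_a) *
          stats::rbeta(1, sh["a"], sh["b"])
      })
  }, numeric(1))
  out <- stats::setNames(out, tab$name)
  attr(out, "provenance") <- "psa_draw"
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Draw many values from one parameter's PSA distribution
#'
#' Vectorized counterpart of [sample_parameters()] for a single row; used to
#' check the sampler against closed-form distribution moments.
#'
#' @param spec a single-row `param_table`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return Numeric vector of `n` draws.
#' @export
sample_distribution <- function(spec, n, seed = 1L) {
  validate_param_table(spec)
  if (nrow(spec) != 1L) stop("sample_distribution() expects a single row",
                             call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  row <- spec[1, ]
  switch(row$dist,
    fixed = rep(row$value, n),
    beta = stats::rbeta(n, row$moment_a, row$moment_b),
    gamma = stats::rgamma(n, shape = row$moment_a, scale = row$moment_b),
    beta_pert = {
      sh <- .pert_shapes(row$moment_a, row$value, row$moment_b)
      row$moment_a + (row$moment_b - row$moment_a) *
        stats::rbeta(n, sh["a"], sh["b"])
    })
}

#' Names of parameters the cohort model requires
#'
#' @return Character vector of required parameter names.
#' @export
required_parameter_names <- function() {
  c("abi_test_cost", "cost_pad_treatment_annual", "cost_aspirin_annual",
    "cost_clopidogrel_annual", "cost_amputation", "cost_mi_first_year",
    "cost_mi_subsequent_annual", "cost_stroke_first_year",
    "cost_stroke_subsequent_annual", "cost_bleed",
    "abi_sensitivity", "abi_specificity",
    "pad_prevalence", "pad_incidence_55_64", "pad_incidence_65_74",
    "pad_incidence_75_84", "pad_incidence_85plus",
    "p_amputation_no_pad", "p_mi_no_pad", "p_stroke_no_pad",
    "p_amputation_pad", "p_mi_pad", "p_stroke_pad", "p_symptomatic_pad",
    "rr_aspirin", "p_bleed_aspirin", "rr_clopidogrel", "p_bleed_clopidogrel",
    "p_death_pad", "p_death_post_amputation", "p_death_post_mi",
    "p_death_post_stroke",
    "utility_pad", "utility_post_amputation", "utility_post_mi",
    "utility_post_stroke", "utility_post_bleed")
}

check_parameter_set <- function(params) {
  missing <- setdiff(required_parameter_names(), names(params))
  if (length(missing) > 0L) {
    stop("parameter set is incomplete; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(params)
}
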