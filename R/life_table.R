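#' Background mortality and background utility
#'
#' The cohort model needs an age-indexed annual probability of death from
#' causes outside the model (the modelled PAD, post-event and bleeding
#' mortalities come on top of it as competing hazards), and an age-indexed
#' background utility for people in the no-PAD and undetected-asymptomatic
#' states.
#'
#' @name background_inputs
NULL

#' Gompertz background life table
#'
#' Annual mortality q(age) = a * exp(slope * (age - 55)), capped at 1 and
#' forced to 1 at `max_age`. The level `a` is calibrated by root finding so
#' that the residual life expectancy at age 55 (cycle-end state counting,
#' i.e. sum over t >= 1 of survival to the end of year t) equals `le55`.
#' The default of 27 years matches unisex Dutch residual life expectancy at
#' 55 around 2012.
#'
#' @param le55 target residual life expectancy at age 55, in years.
#' @param slope Gompertz log-mortality slope per year of age.
#' @param max_age age at which death is certain.
#' @return Data frame with columns `age` (55..`max_age`) and `qx` (annual
#'   probability of death during that year of age).
#' @export
gompertz_life_table <- function(le55 = 27, slope = 0.095, max_age = 110) {
  ages <- 55:max_age
  le_for <- function(a) {
    qx <- pmin(1, a * exp(slope * (ages - 55)))
    qx[ages >= max_age] <- 1
    surv <- cumprod(1 - qx)
    sum(surv)
  }
  a <- stats::uniroot(function(a) le_for(a) - le55,
                      lower = 1e-8, upper = 0.2, tol = 1e-12)$root
  qx <- pmin(1, a * exp(slope * (ages - 55)))
  qx[ages >= max_age] <- 1
  data.frame(age = ages, qx = qx)
}

.padscreen_cache <- new.env(parent = emptyenv())

#' Background (other-cause) life table consistent with the cohort model
#'
#' The model adds the tabulated cardiovascular and PAD mortalities on top of
#' background mortality, so the background table must cover *other* causes
#' only: feeding a full all-cause population table to the model would count
#' the modelled cardiovascular deaths twice. This calibration chooses the
#' Gompertz level such that the whole unscreened cohort (point-estimate
#' parameters, modelled mortalities included) attains a total undiscounted
#' life expectancy of `target_le55` — anchored to unisex Dutch residual life
#' expectancy at age 55 of about 27 years around 2012.
#'
#' @param tab parameter table supplying the modelled mortalities.
#' @param target_le55 target all-cause residual life expectancy at 55.
#' @param slope Gompertz log-mortality slope per year of age.
#' @param max_age age at which death is certain.
#' @return Data frame with columns `age`, `qx`.
#' @export
calibrated_life_table <- function(tab = default_parameter_table(),
                                  target_le55 = 27, slope = 0.095,
                                  max_age = 110) {
  params <- sample_parameters(tab)
  ly_for <- function(bg_le) {
    cfg <- structure(list(start_age = 55, max_age = max_age,
                          cost_rate = 0, effect_rate = 0, drug = "aspirin",
                          screening_costs = list(),
                          life_table = gompertz_life_table(bg_le, slope,
                                                           max_age),
                          baseline_utility = background_utility),
                     class = "run_config")
    out <- evaluate_strategy(params, screening = FALSE, config = cfg)
    out$undiscounted[["ly"]]
  }
  bg <- stats::uniroot(function(le) ly_for(le) - target_le55,
                       lower = target_le55, upper = target_le55 + 15,
                       tol = 1e-6)$root
  gompertz_life_table(bg, slope, max_age)
}

#' Default background life table (cached)
#'
#' [calibrated_life_table()] evaluated on the packaged parameter table and
#' memoised for the session.
#'
#' @return Data frame with columns `age`, `qx`.
#' @export
default_life_table <- function() {
  if (is.null(.padscreen_cache$life_table))
    .padscreen_cache$life_table <- calibrated_life_table()
  .padscreen_cache$life_table
}

#' Read a life table from CSV
#'
#' Expected columns: `age`, `qx` (annual mortality probability). Any ages
#' missing at the top of the range are an error; mortality is forced to 1 at
#' the last tabulated age.
#'
#' @param path CSV path.
#' @return Data frame with columns `age`, `qx`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table not found: ", path, call. = FALSE)
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "qx") %in% names(lt)))
    stop("life table needs columns 'age' and 'qx'", call. = FALSE)
  if (any(lt$qx < 0 | lt$qx > 1))
    stop("life table qx outside [0, 1]", call. = FALSE)
  lt <- lt[order(lt$age), c("age", "qx")]
  lt$qx[nrow(lt)] <- 1
  lt
}

background_mortality_at <- function(life_table, age) {
  i <- match(age, life_table$age)
  if (is.na(i)) {
    if (age > max(life_table$age)) return(1)
    stop("no background mortality tabulated for age ", age, call. = FALSE)
  }
  life_table$qx[i]
}

#' Age-banded background utility
#'
#' EQ-5D-style population-norm utilities applied to the no-PAD and
#' undetected-asymptomatic-PAD states (diagnosed/symptomatic states carry
#' their own utilities from the parameter table). Defaults follow US
#' population-catalogue norms: 0.81 (55-64), 0.78 (65-74), 0.74 (75-84),
#' 0.70 (85+).
#'
#' @param age numeric vector of ages.
#' @param values utilities for the four age bands 55-64, 65-74, 75-84, 85+.
#' @return Numeric vector of background utilities.
#' @export
background_utility <- function(age, values = c(0.81, 0.78, 0.74, 0.70)) {
  stopifnot(length(values) == 4L, all(values >= 0 & values <= 1))
  values[findInterval(age, c(-Inf, 65, 75, 85))]
}

#' Age band used for PAD incidence
#'
#' @param age numeric vector of ages.
#' @return Character vector naming the incidence parameter for each age.
#' @export
incidence_parameter_for_age <- function(age) {
  c("pad_incidence_55_64", "pad_incidence_65_74",
    "pad_incidence_75_84", "pad_incidence_85plus")[
      findInterval(age, c(-Inf, 65, 75, 85))]
}
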