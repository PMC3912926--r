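#' Screening decision tree
#'
#' The decision tree splits the age-55 high-risk cohort, before any Markov
#' cycling, into segments defined by PAD status and antiplatelet treatment
#' status. Under screening, allocation follows ABI test accuracy and PAD
#' prevalence; without screening, only the incidentally diagnosed or
#' symptomatic fraction of prevalent PAD is treated.
#'
#' @name decision_tree
NULL

.check_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  x
}

new_segments <- function(label, fraction, has_pad, on_treatment,
                         entry_cost = 0) {
  seg <- data.frame(label = label, fraction = fraction, has_pad = has_pad,
                    on_treatment = on_treatment, entry_cost = entry_cost,
                    stringsAsFactors = FALSE)
  if (any(seg$fraction < -1e-12 | seg$fraction > 1 + 1e-12))
    stop("segment fraction outside [0, 1]", call. = FALSE)
  if (abs(sum(seg$fraction) - 1) > 1e-12)
    stop("segment fractions must sum to 1", call. = FALSE)
  class(seg) <- c("cohort_segments", "data.frame")
  seg
}

#' Allocate the screened cohort
#'
#' One-time ABI testing of everyone: true positives (prevalent PAD, test
#' positive, treated), false negatives (prevalent PAD missed, untreated),
#' false positives (no PAD, treated anyway), true negatives (no PAD,
#' untreated).
#'
#' @param prevalence PAD prevalence in the screened population.
#' @param sensitivity,specificity ABI test accuracy.
#' @return A `cohort_segments` data frame whose fractions sum to 1.
#' @export
allocate_screening_arm <- function(prevalence, sensitivity, specificity) {
  p  <- .check_prob(prevalence, "prevalence")
  se <- .check_prob(sensitivity, "sensitivity")
  sp <- .check_prob(specificity, "specificity")
  new_segments(
    label = c("true_positive", "false_negative", "false_positive",
              "true_negative"),
    fraction = c(p * se, p * (1 - se), (1 - p) * (1 - sp), (1 - p) * sp),
    has_pad = c(TRUE, TRUE, FALSE, FALSE),
    on_treatment = c(TRUE, FALSE, TRUE, FALSE))
}

#' Allocate the unscreened cohort
#'
#' Without screening, prevalent PAD surfaces only when clinically manifest:
#' the symptomatic fraction (`p_symptomatic`) is incidentally diagnosed and
#' treated; the remainder of prevalent PAD goes undetected and untreated;
#' the disease-free remainder is untreated.
#'
#' @param prevalence PAD prevalence.
#' @param p_symptomatic probability that a prevalent PAD case is
#'   symptomatic (and hence diagnosed and treated).
#' @return A `cohort_segments` data frame whose fractions sum to 1.
#' @export
allocate_no_screening_arm <- function(prevalence, p_symptomatic) {
  p  <- .check_prob(prevalence, "prevalence")
  ps <- .check_prob(p_symptomatic, "p_symptomatic")
  new_segments(
    label = c("incidental_treated", "undetected", "true_negative"),
    fraction = c(p * ps, p * (1 - ps), 1 - p),
    has_pad = c(TRUE, TRUE, FALSE),
    on_treatment = c(TRUE, FALSE, FALSE))
}

#' One-time screening overhead per screened person
#'
#' Sum of the ABI test cost, travel to the practice, the GP session, and
#' productivity loss, charged once at cycle 0 to every screened person.
#' Only the ABI test cost is printed in the evidence table; the other three
#' components default to 0 and a warning is raised when all of them are
#' left at 0, since the societal-perspective costing they come from is not
#' publicly tabulated.
#'
#' @param cost_config list with elements `abi_test`, `travel`, `gp_session`,
#'   `productivity_loss` (Euros, all non-negative).
#' @param warn warn when the non-test components are all zero.
#' @return One-time cost in Euros.
#' @export
screening_overhead <- function(cost_config, warn = FALSE) {
  comp <- c(abi_test = 0, travel = 0, gp_session = 0, productivity_loss = 0)
  comp[names(cost_config)] <- unlist(cost_config)
  if (any(comp < 0)) stop("screening cost components must be >= 0",
                          call. = FALSE)
  if (warn && all(comp[c("travel", "gp_session", "productivity_loss")] == 0))
    warning("travel, GP-session and productivity-loss costs are all 0; ",
            "screening overhead covers the ABI test only", call. = FALSE)
  sum(comp)
}
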