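# Shared fixtures: a fast configuration (shorter horizon, flat background
# mortality) for structural tests where the published scale is irrelevant,
# and a life table with zero background mortality for checks of the raw
# transition rows.

flat_life_table <- function(q = 0.02, max_age = 110) {
  lt <- data.frame(age = 55:max_age, qx = q)
  lt$qx[nrow(lt)] <- 1
  lt
}

zero_life_table <- function(max_age = 110) flat_life_table(0, max_age)

fast_config <- function(...) {
  run_config(max_age = 85, life_table = flat_life_table(0.02, 85), ...)
}

point_params <- function(tab = default_parameter_table()) {
  sample_parameters(tab)
}

# Independent quantile oracle: invert the distribution's CDF numerically.
invert_cdf <- function(cdf, p, lower, upper) {
  stats::uniroot(function(x) cdf(x) - p, lower = lower, upper = upper,
                 tol = 1e-10)$root
}
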