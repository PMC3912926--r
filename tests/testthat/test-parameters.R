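test_that("the packaged parameter table loads with every model input", {
  tab <- default_parameter_table()
  expect_s3_class(tab, "param_table")
  expect_true(all(required_parameter_names() %in% tab$name))

  prev <- tab[tab$name == "pad_prevalence", ]
  expect_equal(prev$value, 0.184)
  expect_equal(prev$dist, "beta")
  expect_equal(c(prev$moment_a, prev$moment_b), c(1372, 6082))

  asp <- tab[tab$name == "cost_aspirin_annual", ]
  expect_equal(asp$value, 10)
  expect_equal(asp$dist, "fixed")
})

test_that("schema violations are rejected with the offending row named", {
  empty <- tempfile(fileext = ".csv")
  writeLines("name,role,value,dist,moment_a,moment_b,source", empty)
  expect_error(load_parameter_table(empty), "empty")

  expect_error(load_parameter_table(tempfile()), "not found")

  expect_error(parameter_spec("p", "probability", 1.5), "domain")
  expect_error(parameter_spec("u", "utility", -0.1), "domain")
  expect_error(parameter_spec("c", "cost", -5), "domain")
  expect_error(parameter_spec("r", "oddrole", 0.5), "unknown role")
  expect_error(parameter_spec("d", "cost", 5, dist = "lognormal"),
               "unknown distribution")
  expect_error(parameter_spec("b", "probability", 0.5, "beta", -1, 2),
               "moment_a")
  expect_error(parameter_spec("pp", "cost", 100, "beta_pert", 120, 150),
               "min <= mode <= max")

  tab <- default_parameter_table()
  tab2 <- rbind(as.data.frame(tab), as.data.frame(tab[1, ]))
  expect_error(validate_param_table(tab2), "duplicated")
  expect_error(validate_param_table(tab[, -3]), "missing column")
})

test_that("distribution means match their closed forms", {
  means <- distribution_mean(default_parameter_table())
  expect_equal(unname(means["pad_prevalence"]), 1372 / (1372 + 6082))
  expect_equal(unname(means["pad_prevalence"]), 0.184, tolerance = 1e-3)
  expect_equal(unname(means["cost_pad_treatment_annual"]), 325.09 * 7.29)
  expect_equal(unname(means["cost_pad_treatment_annual"]), 2369,
               tolerance = 5e-4)
  expect_equal(unname(means["rr_aspirin"]), 25.45 / (25.45 + 7.2))
  expect_equal(unname(means["rr_aspirin"]), 0.78, tolerance = 1e-3)
  expect_equal(unname(means["abi_test_cost"]), (55.7 + 4 * 74 + 92.8) / 6)
  expect_equal(unname(means["cost_aspirin_annual"]), 10)

  uniform <- parameter_spec("u", "probability", 0.5, "beta", 1, 1)
  expect_equal(unname(distribution_mean(uniform)), 0.5)
})

test_that("rows whose distribution mean drifts from the point value are flagged", {
  flags <- mean_consistency_flags(default_parameter_table(), tol = 0.05)
  expect_setequal(flags$name, c("p_amputation_no_pad", "p_mi_no_pad",
                                "p_death_post_amputation"))
  # the PAD utility Beta(0.8, 0.4) sits within 5% of its 0.652 point value
  expect_false("utility_pad" %in% flags$name)
  pad_u <- default_parameter_table()
  pad_u <- pad_u[pad_u$name == "utility_pad", ]
  expect_equal(unname(distribution_mean(pad_u)), 2 / 3, tolerance = 1e-12)
})

test_that("parameter tables round-trip through CSV and JSON", {
  tab <- default_parameter_table()
  for (ext in c(".csv", ".json")) {
    path <- tempfile(fileext = ext)
    write_parameter_table(tab, path)
    back <- load_parameter_table(path)
    expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  }
})

test_that("interval bounds equal the numerically inverted CDF", {
  tab <- default_parameter_table()
  prev <- tab[tab$name == "pad_prevalence", ]
  b <- ci95_bounds(prev)
  expect_lt(b[1], 0.184)
  expect_gt(b[2], 0.184)
  expect_equal(b[1], invert_cdf(function(x) pbeta(x, 1372, 6082),
                                0.025, 0, 1), tolerance = 1e-8)
  expect_equal(b[2], invert_cdf(function(x) pbeta(x, 1372, 6082),
                                0.975, 0, 1), tolerance = 1e-8)

  padcost <- tab[tab$name == "cost_pad_treatment_annual", ]
  g <- ci95_bounds(padcost)
  expect_true(g[1] < 2369 && 2369 < g[2])
  expect_equal(g[1], invert_cdf(function(x)
    pgamma(x, shape = 325.09, scale = 7.29), 0.025, 1, 1e5),
    tolerance = 1e-6)

  uniform <- parameter_spec("u", "probability", 0.5, "beta", 1, 1)
  expect_equal(ci95_bounds(uniform), c(0.025, 0.975))

  expect_error(ci95_bounds(tab[tab$name == "cost_aspirin_annual", ]),
               "not applicable")
})

test_that("sampling is seed-deterministic and respects parameter domains", {
  tab <- default_parameter_table()
  a <- sample_parameters(tab, seed = 42)
  b <- sample_parameters(tab, seed = 42)
  expect_identical(a, b)
  c2 <- sample_parameters(tab, seed = 43)
  expect_false(all(a == c2))
  expect_identical(attr(a, "provenance"), "psa_draw")

  point <- sample_parameters(tab)
  expect_equal(unname(point), tab$value, ignore_attr = TRUE)
  expect_identical(attr(point, "provenance"), "point_estimate")

  for (seed in 1:25) {
    draw <- sample_parameters(tab, seed = seed)
    for (i in seq_len(nrow(tab))) {
      v <- draw[[tab$name[i]]]
      switch(tab$role[i],
        probability = , utility = , accuracy =
          expect_true(v >= 0 && v <= 1),
        cost = , rate = expect_gte(v, 0),
        relative_risk = expect_gt(v, 0))
    }
  }
})

test_that("sample means agree with closed-form means to Monte Carlo error", {
  tab <- default_parameter_table()
  n <- 1e5
  cases <- list(
    list(name = "pad_prevalence",
         sd = sqrt(0.184062 * (1 - 0.184062) / (1372 + 6082 + 1))),
    list(name = "abi_test_cost",
         sd = sqrt((74.0833 - 55.7) * (92.8 - 74.0833) / 7)))
  for (cs in cases) {
    spec <- tab[tab$name == cs$name, ]
    mu <- unname(distribution_mean(spec))
    draws <- sample_distribution(spec, n, seed = 99)
    expect_lt(abs(mean(draws) - mu), 3 * cs$sd / sqrt(n))
  }
})
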