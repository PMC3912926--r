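test_that("transition matrices are row-stochastic with death absorbing", {
  params <- point_params()
  lt <- default_life_table()
  for (treated in c(TRUE, FALSE)) {
    for (age in c(55, 64, 65, 74, 75, 84, 85, 100)) {
      m <- build_transition_matrix(params, treated, age, "aspirin", lt)
      expect_true(all(m >= 0 & m <= 1))
      expect_equal(rowSums(m), setNames(rep(1, 8), health_states()),
                   tolerance = 1e-10)
      expect_equal(unname(m["dead", ]), c(rep(0, 7), 1))
    }
  }
})

test_that("untreated PAD rows carry the registry event probabilities", {
  params <- point_params()
  m <- build_transition_matrix(params, treated = FALSE, age = 55,
                               life_table = zero_life_table())
  # no background mortality: residual self-transition is 1 - 0.085 = 0.915
  expect_equal(m["asym_pad", "post_amputation"], 0.016)
  expect_equal(m["asym_pad", "post_mi"], 0.013)
  expect_equal(m["asym_pad", "post_stroke"], 0.019)
  expect_equal(m["asym_pad", "dead"], 0.037)
  expect_equal(m["asym_pad", "post_bleed"], 0)
  expect_equal(m["asym_pad", "asym_pad"], 0.915)
})

test_that("treatment multiplies PAD risks by the relative risk and adds bleeding", {
  params <- point_params()
  m <- build_transition_matrix(params, treated = TRUE, age = 55,
                               life_table = zero_life_table())
  expect_equal(m["asym_pad", "post_amputation"], 0.016 * 0.78)
  expect_equal(m["asym_pad", "post_mi"], 0.013 * 0.78)
  expect_equal(m["asym_pad", "post_stroke"], 0.019 * 0.78)
  expect_equal(m["asym_pad", "dead"], 0.037 * 0.78)
  expect_equal(m["asym_pad", "post_bleed"], 0.026)
  # the symptomatic (diagnosed) state is treated in every segment
  mu <- build_transition_matrix(params, treated = FALSE, age = 55,
                                life_table = zero_life_table())
  expect_equal(mu["sym_pad", ], m["sym_pad", ])
  # false positives: treated no-PAD rows bleed but get no risk reduction
  expect_equal(m["no_pad", "post_mi"], mu["no_pad", "post_mi"])
  expect_equal(m["no_pad", "post_bleed"], 0.026)
  expect_equal(mu["no_pad", "post_bleed"], 0)
})

test_that("background mortality enters as an independent competing hazard", {
  params <- point_params()
  q <- 0.02
  m0 <- build_transition_matrix(params, FALSE, 60,
                                life_table = zero_life_table())
  m <- build_transition_matrix(params, FALSE, 60,
                               life_table = flat_life_table(q))
  alive <- setdiff(health_states(), "dead")
  for (s in alive) {
    expect_equal(m[s, "dead"], 1 - (1 - m0[s, "dead"]) * (1 - q),
                 tolerance = 1e-12)
    others <- setdiff(health_states(), "dead")
    expect_equal(m[s, others], m0[s, others] * (1 - q), tolerance = 1e-12)
  }
})

test_that("incompatible event probabilities fail loudly, naming the row", {
  params <- point_params()
  params[["p_death_pad"]] <- 0.9
  params[["p_amputation_pad"]] <- 0.2
  expect_error(build_transition_matrix(params, FALSE, 55,
                                       life_table = zero_life_table()),
               "asym_pad.*> 1")
})

test_that("cohort propagation matches direct matrix multiplication", {
  params <- sample_parameters(default_parameter_table(), seed = 5)
  lt <- default_life_table()
  n <- 30
  mats <- lapply(seq_len(n), function(t)
    build_transition_matrix(params, TRUE, 54 + t, "aspirin", lt))
  init <- setNames(c(1, rep(0, 7)), health_states())
  res <- run_cohort(init, function(t) mats[[t]], n)

  # independent step-by-step oracle
  occ <- init
  for (t in seq_len(n)) {
    occ <- as.numeric(occ %*% mats[[t]])
    expect_equal(unname(res$trace[t + 1, ]), occ, tolerance = 1e-12)
    occ <- setNames(occ, health_states())
  }
  expect_equal(unname(rowSums(res$trace)), rep(1, n + 1), tolerance = 1e-10)
  expect_true(all(diff(res$trace[, "dead"]) >= -1e-12))

  # inflow = mass arriving from other states
  for (t in 2:(n + 1)) {
    prev <- res$trace[t - 1, ]
    m <- mats[[t - 1]]
    diag(m) <- 0
    expect_equal(unname(res$inflow[t, ]), unname(as.numeric(prev %*% m)),
                 tolerance = 1e-12)
  }
})

test_that("toy chains reproduce geometric decay and fixed points", {
  toy <- generate_analytic_toy(0.5)
  res <- run_cohort(toy$initial, function(t) toy$matrix, 20)
  expect_equal(unname(res$trace[, "alive"]), 0.5^(0:20), tolerance = 1e-12)

  ident <- diag(2)
  dimnames(ident) <- dimnames(toy$matrix)
  same <- run_cohort(c(alive = 0.4, dead = 0.6), function(t) ident, 5)
  expect_true(all(same$trace[, "alive"] == 0.4))
})

test_that("treated cohorts reach each event state no faster than untreated", {
  params <- point_params()
  lt <- default_life_table()
  init <- setNames(c(0, 1, 0, 0, 0, 0, 0, 0), health_states())
  n <- 55
  run_arm <- function(treated) {
    run_cohort(init, function(t)
      build_transition_matrix(params, treated, 54 + t, "aspirin", lt), n)
  }
  tr <- run_arm(TRUE)
  un <- run_arm(FALSE)
  for (s in c("post_amputation", "post_mi", "post_stroke")) {
    expect_true(all(cumsum(tr$inflow[, s]) <=
                    cumsum(un$inflow[, s]) + 1e-12))
  }
})

test_that("degenerate cohort inputs are rejected", {
  toy <- generate_analytic_toy(0.3)
  expect_error(run_cohort(c(alive = 0.5, dead = 0.1),
                          function(t) toy$matrix, 3), "sum to 1")
  expect_error(run_cohort(unname(toy$initial), function(t) toy$matrix, 3),
               "named")
  bad <- toy$matrix
  bad[1, 1] <- 0.9
  expect_error(run_cohort(toy$initial, function(t) bad, 3), "sums to 1")
})
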