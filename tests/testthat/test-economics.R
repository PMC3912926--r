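test_that("discount factors follow the compound-interest closed form", {
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
  expect_equal(discount_factor(0.04, 1), 1 / 1.04)
  expect_equal(discount_factor(0.04, 1), 0.96154, tolerance = 1e-5)
  expect_equal(discount_factor(0.015, 2), 1.015^-2)
  expect_equal(discount_factor(0.015, 2), 0.97066, tolerance = 1e-5)
  expect_error(discount_factor(-0.01, 1))
})

toy_rewards <- function(annual = 100, utility = 1) {
  list(annual_cost = c(alive = annual, dead = 0),
       event_cost = c(alive = 0, dead = 0),
       utility = matrix(c(utility, 0), 61, 2, byrow = TRUE,
                        dimnames = list(0:60, c("alive", "dead"))))
}

test_that("accumulation over toy traces matches geometric closed forms", {
  # everyone dies in the first cycle: only the entry cost remains
  dead_now <- run_cohort(c(alive = 1, dead = 0),
                         function(t) matrix(c(0, 1, 0, 1), 2, 2,
                           byrow = TRUE,
                           dimnames = list(c("alive", "dead"),
                                           c("alive", "dead"))), 10)
  out <- accumulate(dead_now, toy_rewards(), 0, 0, entry_cost = 74)
  expect_equal(unname(out$discounted), c(74, 0, 0))

  # constant mortality, utility 1: LY = QALY = sum over (1-q)^t
  toy <- generate_analytic_toy(0.5, cost = 100)
  res <- run_cohort(toy$initial, function(t) toy$matrix, 60)
  out <- accumulate(res, toy_rewards(100, 1), 0, 0)
  expect_equal(unname(out$undiscounted[["ly"]]), toy$le(0, 60),
               tolerance = 1e-12)
  expect_equal(out$undiscounted[["qaly"]], out$undiscounted[["ly"]])
  expect_equal(out$undiscounted[["cost"]], 100 * toy$le(0, 60),
               tolerance = 1e-9)

  # discounting shrinks towards the discounted geometric series
  outd <- accumulate(res, toy_rewards(100, 1), 0.04, 0.015)
  expect_equal(outd$discounted[["ly"]], toy$le(0.015, 60),
               tolerance = 1e-12)
  expect_equal(outd$discounted[["cost"]], 100 * toy$le(0.04, 60),
               tolerance = 1e-9)
})

test_that("discounted totals never exceed undiscounted ones and fall with the rate", {
  bc <- run_base_case(config = fast_config())
  for (arm in list(bc$screening, bc$no_screening)) {
    expect_true(all(arm$discounted <= arm$undiscounted + 1e-9))
    expect_lte(arm$discounted[["qaly"]], arm$discounted[["ly"]])
  }
  rates <- c(0, 0.015, 0.04, 0.08)
  params <- point_params()
  costs <- sapply(rates, function(r) {
    cfg <- fast_config(cost_rate = r, effect_rate = r)
    evaluate_strategy(params, TRUE, cfg)$discounted[["cost"]]
  })
  expect_true(all(diff(costs) < 0))
})

test_that("first-year event costs replace the annual cost in the entry year", {
  params <- point_params()
  # one cycle from pure symptomatic PAD: MI inflow pays the first-year cost
  cfg <- run_config(max_age = 56, life_table = zero_life_table(56))
  s <- health_states()
  init <- setNames(as.numeric(s == "sym_pad"), s)
  arr <- array(build_transition_matrix(params, TRUE, 55,
                                       life_table = zero_life_table()),
               dim = c(8, 8, 1), dimnames = list(s, s, 55))
  res <- run_cohort(init, arr, 1)
  rew <- reward_schedule(params, treated = TRUE, ages = 55:56)
  out <- accumulate(res, rew, 0, 0)
  stay <- res$trace[2, "sym_pad"]
  mi_in <- res$inflow[2, "post_mi"]
  expected <- stay * (2369 + 10) +
    mi_in * 25328 +
    res$inflow[2, "post_amputation"] * 14343 +
    res$inflow[2, "post_stroke"] * 27964 +
    res$inflow[2, "post_bleed"] * 3457
  expect_equal(out$undiscounted[["cost"]], expected, tolerance = 1e-9)
})

mk_outcome <- function(cost, ly, qaly) {
  structure(list(discounted = c(cost = cost, ly = ly, qaly = qaly),
                 undiscounted = c(cost = cost, ly = ly, qaly = qaly)),
            class = "strategy_outcome")
}

test_that("incremental comparison classifies dominance as published", {
  a <- mk_outcome(26548, 21.79, 15.66)
  b <- mk_outcome(26548 + 1503, 20.69, 15.66 - 0.007)
  inc <- incremental(a, b)
  expect_equal(inc$delta_cost, -1503)
  expect_equal(inc$delta_qaly, 0.007)
  expect_identical(inc$classification, "dominant")
  expect_true(is.na(inc$icer))

  icer <- incremental(mk_outcome(100, 1, 1), mk_outcome(0, 0, 0))
  expect_identical(icer$classification, "icer")
  expect_equal(icer$icer, 100)

  expect_identical(incremental(mk_outcome(5, 1, 1),
                               mk_outcome(5, 1, 1))$classification,
                   "equivalent")
  expect_identical(incremental(mk_outcome(10, 1, 1),
                               mk_outcome(5, 1, 1))$classification,
                   "cost-only difference")
})

test_that("incremental analysis is antisymmetric", {
  set.seed(3)
  for (i in 1:20) {
    a <- mk_outcome(runif(1, 0, 5e4), runif(1, 10, 30), runif(1, 5, 25))
    b <- mk_outcome(runif(1, 0, 5e4), runif(1, 10, 30), runif(1, 5, 25))
    ab <- incremental(a, b)
    ba <- incremental(b, a)
    expect_equal(ab$delta_cost, -ba$delta_cost)
    expect_equal(ab$delta_qaly, -ba$delta_qaly)
    if (ab$classification == "dominant")
      expect_identical(ba$classification, "dominated")
    if (ab$classification == "dominated")
      expect_identical(ba$classification, "dominant")
  }
})

test_that("net monetary benefit is affine in willingness to pay", {
  inc <- incremental(mk_outcome(26548, 21.79, 15.66),
                     mk_outcome(28051, 20.69, 15.653))
  expect_equal(net_monetary_benefit(inc, 40000),
               40000 * inc$delta_qaly - inc$delta_cost)
  expect_equal(net_monetary_benefit(inc, 40000), 1783, tolerance = 1e-3)
  expect_equal(net_monetary_benefit(inc, 0), -inc$delta_cost)
  wtp <- seq(0, 8e4, 1e4)
  nmb <- net_monetary_benefit(inc, wtp)
  slopes <- diff(nmb) / diff(wtp)
  expect_equal(slopes, rep(inc$delta_qaly, length(slopes)))
})
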