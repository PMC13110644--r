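test_that("transition rows implement death-first competing risks", {
  b <- reference_bundle()
  # fix the inputs so the row can be enumerated by hand:
  # p10 chosen so the annual osteoporosis fracture probability is exactly 0.05
  b$epidemiology$p10_fracture_by_state[["osteoporosis"]] <- 1 - (1 - 0.05)^10
  b$epidemiology$background_mortality$prob[] <- 0.01
  P <- build_transition_matrix(50, b)

  # dead row is the identity on dead
  expect_equal(unname(P["dead", ]), c(rep(0, 8), 1))
  # death-first allocation: dead m, fracture (1-m) p, stay the rest
  expect_equal(P["untreated_osteoporosis", "dead"], 0.01)
  expect_equal(P["untreated_osteoporosis", "fracture"], 0.99 * 0.05)
  expect_equal(P["untreated_osteoporosis", "untreated_osteoporosis"], 0.9405)
  # two-event tree oracle: P(survive and no fracture) = (1-m)(1-p)
  expect_equal(P["untreated_osteoporosis", "untreated_osteoporosis"],
               (1 - 0.01) * (1 - 0.05))
  # treated fracture entry is exactly RR times the untreated entry
  rr <- b$epidemiology$rr_bisphosphonate
  expect_equal(P["treated_osteoporosis", "fracture"],
               rr * P["untreated_osteoporosis", "fracture"])
  # non-adherent survivors flow to the matching untreated state
  a <- b$epidemiology$adherence_annual
  rest <- 1 - 0.01 - P["treated_osteoporosis", "fracture"]
  expect_equal(P["treated_osteoporosis", "untreated_osteoporosis"],
               rest * (1 - a))
  # no-fracture state faces mortality only
  expect_equal(unname(P["no_fracture", c("no_fracture", "dead")]), c(0.99, 0.01))
  # fracture is a one-cycle tunnel
  expect_equal(P["fracture", "fracture"], 0)
  expect_equal(P["fracture", "post_fracture"],
               1 - 0.01 * b$epidemiology$fracture_mortality_multiplier)
})

test_that("generated matrices are row-stochastic across random bundles", {
  set.seed(202)
  for (i in 1:20) {
    b <- random_bundle()
    for (age in sample(40:100, 4)) {
      P <- build_transition_matrix(age, b)
      expect_equal(unname(rowSums(P)), rep(1, 9), tolerance = 1e-10)
      expect_true(all(P >= 0 & P <= 1))
    }
  }
})

test_that("impossible probabilities after multipliers are capped with a warning", {
  b <- reference_bundle()
  b$epidemiology$background_mortality$prob[] <- 0.9
  b$epidemiology$fracture_mortality_multiplier <- 1.5
  expect_warning(P <- build_transition_matrix(60, b), "capped")
  expect_equal(unname(rowSums(P)), rep(1, 9), tolerance = 1e-10)
})

test_that("discount factors follow (1+r)^-k with cycle 0 undiscounted", {
  expect_equal(discount_factor(0.035, 0), 1)
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
  expect_equal(discount_factor(0.035, 1), 1 / 1.035)
  expect_equal(discount_factor(0.035, 1), 0.96618, tolerance = 1e-5)
  expect_error(discount_factor(-0.1, 1), "non-negative")
  expect_error(discount_factor(0.035, -1), "non-negative")
})

test_that("zero-risk unit-utility cohort reproduces the annuity closed form", {
  b0 <- degenerate_bundle(discount_rate = 0)
  init <- initial_state_distribution("S1", b0)
  tr <- run_cohort(init$distribution, b0, upfront_cost = 0)
  expect_equal(trace_totals(tr)$mean_qaly, 60)

  b <- degenerate_bundle(discount_rate = 0.035)
  tr <- run_cohort(initial_state_distribution("S1", b)$distribution, b, 0)
  closed_form <- sum(1.035^-(0:59))
  expect_equal(trace_totals(tr)$mean_qaly, closed_form, tolerance = 1e-9)
})

test_that("occupancy is conserved and death is monotone through the horizon", {
  set.seed(303)
  for (i in 1:10) {
    b <- random_bundle()
    tr <- run_cohort(initial_state_distribution("S2", b), b)
    sums <- rowSums(tr$occupancy)
    expect_equal(sums, rep(b$config$cohort_size, length(sums)), tolerance = 1e-9)
    expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-12))
    expect_true(all(tr$cycles$disc_cost <= tr$cycles$cost + 1e-12))
    expect_true(all(tr$cycles$disc_qaly <= tr$cycles$qaly + 1e-12))
  }
})

test_that("undiscounted unit-utility QALYs equal survival-curve life expectancy", {
  b <- reference_bundle()
  b$config$discount_rate <- 0
  b$utilities$baseline_utility_by_age$utility[] <- 1
  b$utilities$fracture_year_multiplier <- 1
  b$utilities$postfracture_multiplier <- 1
  tr <- run_cohort(initial_state_distribution("S2", b), b)
  K <- nrow(tr$cycles)
  alive <- rowSums(tr$occupancy[seq_len(K), setdiff(colnames(tr$occupancy), "dead")])
  expect_equal(sum(tr$cycles$qaly), sum(alive), tolerance = 1e-9)
})

test_that("trace totals scale and degenerate correctly", {
  b <- reference_bundle()
  scr <- initial_state_distribution("S2", b)
  tr <- run_cohort(scr$distribution, b, scr$upfront_cost)
  tot <- trace_totals(tr)

  # doubling the cohort with proportionally scaled occupancy leaves
  # per-person means unchanged
  b2 <- b
  b2$config$cohort_size <- 2000
  scr2 <- initial_state_distribution("S2", b2)
  tot2 <- trace_totals(run_cohort(scr2$distribution, b2, scr2$upfront_cost))
  expect_equal(tot2$mean_cost, tot$mean_cost, tolerance = 1e-9)
  expect_equal(tot2$mean_qaly, tot$mean_qaly, tolerance = 1e-9)

  # all-dead cohort accrues only the upfront cost
  dead <- state_distribution(c(rep(0, 8), 1000))
  tot3 <- trace_totals(run_cohort(dead, b, upfront_cost = 500))
  expect_equal(tot3$mean_cost, 500 / 1000)
  expect_equal(tot3$mean_qaly, 0)
})

test_that("ten-year horizon truncates the model at 10 cycles", {
  b <- reference_bundle()
  b$config$horizon_mode <- "ten_year"
  tr <- run_cohort(initial_state_distribution("S2", b), b)
  expect_equal(nrow(tr$cycles), 10)
  expect_equal(max(tr$cycles$age), 49)
})

test_that("tidy trace export matches the in-memory trace", {
  b <- reference_bundle()
  tr <- run_cohort(initial_state_distribution("S3", b), b)
  df <- trace_to_df(tr)
  expect_equal(nrow(df), nrow(tr$cycles) * 9)
  expect_equal(sum(df$occupancy), sum(tr$occupancy[seq_len(nrow(tr$cycles)), ]))
  expect_equal(unique(df$state), health_states())
})

test_that("microsimulation is exact on deterministic chains and reproducible", {
  b <- degenerate_bundle(discount_rate = 0.035)
  # everyone in no-fracture, no mortality: deterministic trajectory
  init <- state_distribution(c(0, 0, 0, 0, 0, 1000, 0, 0, 0))
  cohort <- trace_totals(run_cohort(init, b, upfront_cost = 1000))
  ms <- microsim_oracle(init, b, upfront_cost = 1000, n_individuals = 50, seed = 9)
  expect_equal(ms$mean_qaly, cohort$mean_qaly, tolerance = 1e-12)
  expect_equal(ms$mean_cost, cohort$mean_cost, tolerance = 1e-12)
  expect_equal(ms$se_qaly, 0)

  ms1 <- microsim_oracle(init, b, 0, n_individuals = 100, seed = 11)
  ms2 <- microsim_oracle(init, b, 0, n_individuals = 100, seed = 11)
  expect_identical(ms1, ms2)
})

test_that("cohort model agrees with the microsimulation oracle", {
  b <- reference_bundle()
  scr <- initial_state_distribution("S2", b)
  cohort <- trace_totals(run_cohort(scr$distribution, b, scr$upfront_cost))
  ms <- microsim_oracle(scr$distribution, b, scr$upfront_cost,
                        n_individuals = 8000, seed = 17)
  expect_lt(abs(ms$mean_cost - cohort$mean_cost), 3 * ms$se_cost)
  expect_lt(abs(ms$mean_qaly - cohort$mean_qaly), 3 * ms$se_qaly)
})

test_that("without fracture risk strategies differ only in costs", {
  b <- reference_bundle()
  b$epidemiology$p10_fracture_by_state[] <- 0
  b$epidemiology$refracture_annual <- 0
  res <- run_cea(b)
  q <- vapply(res$outcomes, `[[`, numeric(1), "mean_qaly")
  expect_equal(unname(q - q[["S1"]]), rep(0, 3), tolerance = 1e-9)
  costs <- vapply(res$outcomes, `[[`, numeric(1), "mean_cost")
  expect_false(isTRUE(all.equal(costs[["S2"]], costs[["S1"]])))
})
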