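test_that("scenarios modify exactly one parameter and leave the input untouched", {
  b <- reference_bundle()
  sc <- scenario_spec("dxa_cost_doubled", c("costs", "cost_dxa"), "multiply", 2)
  b2 <- apply_scenario(b, sc)
  expect_equal(b2$costs$cost_dxa, 2 * b$costs$cost_dxa)
  b2$costs$cost_dxa <- b$costs$cost_dxa
  expect_identical(b2, b)

  b3 <- apply_scenario(b, scenario_spec("full_adherence",
                                        c("epidemiology", "adherence_annual"),
                                        "set_value", 1.0))
  expect_equal(b3$epidemiology$adherence_annual, 1.0)

  ident <- apply_scenario(b, scenario_spec("noop", c("costs", "cost_dxa"),
                                           "multiply", 1))
  expect_identical(ident, b)

  expect_error(apply_scenario(b, scenario_spec("bad", c("costs", "nope"),
                                               "multiply", 2)),
               "unknown parameter path")
  expect_error(apply_scenario(b, scenario_spec("too_big",
                                               c("epidemiology", "adherence_annual"),
                                               "multiply", 2)),
               "outside")
})

test_that("the built-in scenario grid covers the named analyses", {
  b <- reference_bundle()
  sc <- default_scenarios(b)
  labels <- vapply(sc, `[[`, character(1), "label")
  expect_equal(labels[1], "base_case")
  for (need in c("adherence_100pct", "dxa_cost_halved", "dxa_cost_doubled",
                 "fracture_cost_halved", "fracture_cost_doubled",
                 "s1_screened_1pct", "s1_screened_5pct", "ten_year_horizon",
                 "lifetime_fracture_risk", "idfracture_sensitivity_max"))
    expect_true(need %in% labels, label = paste("grid includes", need))
  # IDFracture sensitivity upper bound is 99.9%
  i <- which(labels == "idfracture_sensitivity_max")
  expect_equal(sc[[i]]$operand, 0.999)
  # every scenario yields a valid bundle
  for (s in sc) expect_true(validate_bundle(apply_scenario(b, s)))
})

test_that("DSA identity scenario reproduces the base case exactly", {
  b <- reference_bundle()
  base <- run_cea(b)$comparisons
  tab <- run_dsa(b, list(scenario_spec("base_case", c("config", "cycle_length"),
                                       "multiply", 1)))
  expect_identical(tab$delta_cost, base$delta_cost)
  expect_identical(tab$delta_qaly, base$delta_qaly)
  expect_identical(tab$icer, base$icer)
  expect_error(run_dsa(b, list()), "non-empty")
})

test_that("irrelevant costs leave the comparison unchanged", {
  b <- reference_bundle()
  # an empty post-fracture state at baseline only matters through occupancy;
  # zero fracture risk empties fracture and post-fracture states entirely
  b$epidemiology$p10_fracture_by_state[] <- 0
  b$epidemiology$refracture_annual <- 0
  base <- run_cea(b)$comparisons
  tab <- run_dsa(b, list(scenario_spec("fracture_cost_doubled",
                                       c("costs", "cost_fracture_year1"),
                                       "multiply", 2)))
  expect_equal(tab$icer, base$icer, tolerance = 1e-12)
  expect_equal(tab$delta_cost, base$delta_cost, tolerance = 1e-12)
})

test_that("halving the fracture-year cost shifts costs by the discounted fracture stream", {
  b <- reference_bundle()
  sc1 <- initial_state_distribution("S2", b)
  tr1 <- run_cohort(sc1$distribution, b, sc1$upfront_cost)

  b2 <- apply_scenario(b, scenario_spec("fracture_cost_halved",
                                        c("costs", "cost_fracture_year1"),
                                        "multiply", 0.5))
  tr2 <- run_cohort(initial_state_distribution("S2", b2)$distribution, b2,
                    sc1$upfront_cost)
  # two-run subtraction oracle: occupancy is unchanged, so the cost difference
  # is exactly half the discounted fracture-state cost stream
  K <- nrow(tr1$cycles)
  disc <- discount_factor(b$config$discount_rate, tr1$cycles$cycle)
  frac_stream <- sum(tr1$occupancy[seq_len(K), "fracture"] * disc) *
    b$costs$cost_fracture_year1
  expect_equal(sum(tr1$cycles$disc_cost) - sum(tr2$cycles$disc_cost),
               frac_stream / 2, tolerance = 1e-9)
})

test_that("PSA draws stay in support and collapse as uncertainty vanishes", {
  b <- reference_bundle()
  d <- draw_psa_bundle(b, seed = 21)
  expect_true(validate_bundle(d))
  expect_true(all(d$epidemiology$background_mortality$prob >= 0 &
                    d$epidemiology$background_mortality$prob <= 1))
  expect_true(all(unlist(d$costs) >= 0))
  # boundary parameters (DXA sens/spec = 1) are never perturbed
  expect_equal(d$screening$S3$sensitivity, 1)
  expect_equal(d$screening$S3$specificity, 1)
  # structural settings are frozen
  expect_identical(d$config, b$config)

  b$uncertainty[] <- 1e-4
  d2 <- draw_psa_bundle(b, seed = 22)
  expect_equal(d2$costs$cost_dxa, b$costs$cost_dxa, tolerance = 1e-3)
  expect_equal(d2$epidemiology$adherence_annual, b$epidemiology$adherence_annual,
               tolerance = 1e-3)
})

test_that("sampled parameters are moment-matched around base values", {
  b <- reference_bundle()
  seeds <- seq_len(3000)
  draws <- vapply(seeds, function(s)
    draw_psa_bundle(b, s)$epidemiology$adherence_annual, numeric(1))
  base <- b$epidemiology$adherence_annual
  expect_equal(mean(draws), base, tolerance = 0.01)
  expect_equal(sd(draws), 0.2 * base, tolerance = 0.05)
})

test_that("PSA runs are reproducible and sized as requested", {
  b <- reference_bundle()
  p1 <- run_psa(b, n_draws = 10, seed = 33)
  p2 <- run_psa(b, n_draws = 10, seed = 33)
  expect_identical(p1$points, p2$points)
  expect_equal(nrow(p1$points), 10 * 3)       # three comparisons per draw
  expect_false(identical(p1$points, run_psa(b, n_draws = 10, seed = 34)$points))
  expect_error(run_psa(b, n_draws = 0, seed = 1), "at least 1")
  # default draw count is 1000
  expect_equal(formals(run_psa)$n_draws, 1000)
})

test_that("near-degenerate PSA concentrates on the base case", {
  b <- reference_bundle()
  b$uncertainty[] <- 0.01
  base <- run_cea(b)$comparisons
  psa <- run_psa(b, n_draws = 200, seed = 44)
  pts <- psa$points[psa$points$intervention == "S2" &
                      psa$points$comparator == "S1", ]
  base_s2 <- base[base$intervention == "S2" & base$comparator == "S1", ]
  se_c <- sd(pts$delta_cost) / sqrt(nrow(pts))
  se_q <- sd(pts$delta_qaly) / sqrt(nrow(pts))
  expect_lt(abs(mean(pts$delta_cost) - base_s2$delta_cost), 3 * se_c)
  expect_lt(abs(mean(pts$delta_qaly) - base_s2$delta_qaly), 3 * se_q)
})

test_that("CEAC is the strict-NMB acceptance fraction", {
  pts <- data.frame(intervention = "S2", comparator = "S1",
                    delta_cost = c(-1, 1, 1, 3),
                    delta_qaly = c(0.001, 0.001, -0.001, 0.0001))
  ceac <- compute_ceac(pts, lambdas = 1000)
  # NMB at 1000: {2, 0, -2, -2.9}; the exact zero counts as not cost-effective
  expect_equal(ceac$probability, 0.25)

  all_dom <- data.frame(intervention = "S2", comparator = "S1",
                        delta_cost = -runif(20), delta_qaly = runif(20))
  expect_true(all(compute_ceac(all_dom, c(0, 1e4))$probability == 1))
  all_bad <- data.frame(intervention = "S2", comparator = "S1",
                        delta_cost = runif(20), delta_qaly = -runif(20))
  expect_true(all(compute_ceac(all_bad, c(0, 1e4))$probability == 0))
  expect_error(compute_ceac(pts, numeric(0)), "non-empty")
})

test_that("CEAC and the complementary comparator curve sum to one up to ties", {
  set.seed(55)
  pts <- data.frame(intervention = "S2", comparator = "S1",
                    delta_cost = rnorm(400), delta_qaly = rnorm(400, 0, 0.01))
  flipped <- transform(pts, intervention = "S1", comparator = "S2",
                       delta_cost = -delta_cost, delta_qaly = -delta_qaly)
  lam <- seq(0, 3e4, 5e3)
  p_a <- compute_ceac(pts, lam)$probability
  p_b <- compute_ceac(flipped, lam)$probability
  ties <- vapply(lam, function(l)
    mean(l * pts$delta_qaly - pts$delta_cost == 0), numeric(1))
  expect_equal(p_a + p_b + ties, rep(1, length(lam)))
})

test_that("CE-plane and CEAC plots build without error", {
  b <- reference_bundle()
  psa <- run_psa(b, n_draws = 5, seed = 66)
  expect_s3_class(plot_ce_plane(psa), "ggplot")
  expect_s3_class(plot_ceac(compute_ceac(psa)), "ggplot")
})
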