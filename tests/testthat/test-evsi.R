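test_that("the Markov trace conserves occupancy and matches hand computation", {
  inp <- decision_inputs()
  tr <- markov_trace(inp$control_rate, inp)
  expect_equal(max(abs(rowSums(tr) - 1)), 0, tolerance = 1e-12)
  # exponential control model: failure-free occupancy after 1 year = 0.75
  expect_equal(unname(tr[2, "recurrence_free"]), 0.75, tolerance = 1e-12)
  # dead state is absorbing
  expect_true(all(diff(tr[, "dead"]) >= 0))

  # rate 0 with zero mortality: all mass stays recurrence-free forever
  tr0 <- markov_trace(0, inp, mortality_rate = 0)
  expect_true(all(tr0[, "recurrence_free"] == 1))

  # 2-cycle hand-computed trace
  lam <- 0.4
  mu <- inp$mortality_rate
  pf <- 1 - exp(-lam)
  pd <- 1 - exp(-mu)
  tr2 <- markov_trace(lam, inp, horizon_years = 2)
  expect_equal(tr2[2, ], c(recurrence_free = 1 - pf, recurrence = pf, dead = 0),
               tolerance = 1e-12)
  expect_equal(tr2[3, ],
               c(recurrence_free = (1 - pf)^2,
                 recurrence = pf * (1 - pd) + (1 - pf) * pf,
                 dead = pf * pd),
               tolerance = 1e-12)
  expect_error(markov_trace(0.2, inp, horizon_years = 0.5), "horizon")
})

test_that("expected outcomes accumulate discounted costs and QALYs correctly", {
  inp <- decision_inputs()
  params <- list(c_surv = 5585, c_rec = 17727, u_ff = 0.997, u_rec = 0.96)

  # zero discount, 1 cycle, all recurrence-free
  tr1 <- markov_trace(0, inp, horizon_years = 1, mortality_rate = 0)
  o <- expected_outcomes(tr1, params, inp, "control", discount = 0)
  expect_equal(o[["cost"]], 5585)
  expect_equal(o[["qaly"]], 0.997)
  # treatment arm adds exactly the added-cost stream at equal rates
  ot <- expected_outcomes(tr1, params, inp, "treatment", discount = 0)
  expect_equal(ot[["cost"]] - o[["cost"]], inp$added_cost_trt)
  expect_equal(ot[["qaly"]], o[["qaly"]])

  # brute-force per-cycle oracle on a 5-cycle toy
  lam <- 0.3
  tr5 <- markov_trace(lam, inp, horizon_years = 5)
  o5 <- expected_outcomes(tr5, params, inp, "treatment")
  cost <- 0; qaly <- 0
  for (k in 0:4) {
    d <- 1.03^(-k)
    ff <- unname(tr5[k + 1, 1]); fl <- unname(tr5[k + 1, 2])
    cost <- cost + d * (ff * (5585 + 147.18) + fl * 17727)
    qaly <- qaly + d * (ff * 0.997 + fl * 0.96)
  }
  expect_equal(o5[["cost"]], cost, tolerance = 1e-12)
  expect_equal(o5[["qaly"]], qaly, tolerance = 1e-12)

  # the vectorized engine agrees with the trace-based path
  sy <- rteprior:::disc_state_years(lam, inp)
  full <- expected_outcomes(markov_trace(lam, inp), params, inp, "control")
  expect_equal(full[["cost"]], 5585 * sy$ff + 17727 * sy$fl, tolerance = 1e-9)
  expect_equal(full[["qaly"]], 0.997 * sy$ff + 0.96 * sy$fl, tolerance = 1e-9)
})

test_that("net benefit is linear at the willingness-to-pay threshold", {
  expect_equal(net_benefit(0, 1, 150000), 150000)
  expect_equal(net_benefit(150000, 1, 150000), 0)
  q <- runif(5)
  expect_equal(net_benefit(0, 2 * q, 150000), 2 * net_benefit(0, q, 150000))
})

test_that("PSA draws are moment-matched and seeded", {
  inp <- decision_inputs()
  p1 <- draw_psa_parameters(inp, 10, seed = 3)
  p2 <- draw_psa_parameters(inp, 10, seed = 3)
  expect_identical(p1, p2)

  # se = 0 passes the means through
  inp0 <- decision_inputs(cost_surveillance = c(5585, 0),
                          cost_recurrent = c(17727, 0),
                          utility_ff = c(0.997, 0),
                          utility_recurrent = c(0.96, 0))
  p0 <- draw_psa_parameters(inp0, 3, seed = 1)
  expect_equal(unique(p0$c_surv), 5585)
  expect_equal(unique(p0$u_rec), 0.96)

  big <- draw_psa_parameters(inp, 1e5, seed = 7)
  expect_lt(abs(mean(big$c_surv) - 5585), 3 * 1117 / sqrt(1e5))
  expect_lt(abs(sd(big$c_surv) - 1117), 3 * 1117 / sqrt(1e5))
  expect_lt(abs(mean(big$c_rec) - 17727), 3 * 3545 / sqrt(1e5))
  expect_lt(abs(mean(big$u_ff) - 0.997), 3 * 0.05 / sqrt(1e5))
  expect_lt(abs(mean(big$u_rec) - 0.96), 3 * 0.192 / sqrt(1e5))
  expect_true(all(big$u_ff >= 0 & big$u_ff <= 1))
})

test_that("trial simulation and conjugate updating follow the Poisson-gamma pair", {
  des <- trial_design()
  expect_equal(des$person_years, 616 / 2 * 2.5)
  expect_equal(simulate_trial(0, des, seed = 1)$events, 0L)
  s1 <- simulate_trial(0.3, des, seed = 5)
  expect_identical(s1, simulate_trial(0.3, des, seed = 5))
  set.seed(11)
  evs <- rpois(1e5, 0.3 * des$person_years)
  expect_lt(abs(mean(evs) - 0.3 * des$person_years),
            3 * sqrt(0.3 * des$person_years / 1e5))

  g <- posterior_update(gamma_prior(1, 1), 10, 40)
  expect_equal(g$shape, 11)
  expect_equal(g$rate, 41)
  g0 <- posterior_update(gamma_prior(2, 3), 0, 0)
  expect_equal(c(g0$shape, g0$rate), c(2, 3))
  # posterior mean lies between prior mean and the empirical rate
  gp <- posterior_update(gamma_prior(2, 10), 30, 50)
  expect_gt(gp$shape / gp$rate, 0.2)
  expect_lt(gp$shape / gp$rate, 30 / 50)
})

test_that("population scaling discounts the patient stream", {
  # discount 0, 1 year
  p <- population_scale(10, population_inputs(25900, 1, 0))
  expect_equal(as.numeric(p), 259000)
  # hand-computed 3-year sum
  p3 <- population_scale(1, population_inputs(1000, 3, 0.05))
  expect_equal(as.numeric(p3), 1000 * (1 + 1 / 1.05 + 1 / 1.05^2),
               tolerance = 1e-12)
  # monotone decreasing in the discount rate
  expect_gt(as.numeric(population_scale(1, population_inputs(100, 10, 0.01))),
            as.numeric(population_scale(1, population_inputs(100, 10, 0.06))))
})

test_that("EVSI is seeded, bounded by EVPI, ordered by prior informativeness", {
  inp <- decision_inputs()
  des <- trial_design()
  noninf <- gamma_prior(1, 1)
  empirical <- gamma_prior(17.3, 66.1)

  r1 <- evsi_nested(noninf, inp, des, n_outer = 150, n_inner = 150, seed = 21)
  r1b <- evsi_nested(noninf, inp, des, n_outer = 150, n_inner = 150, seed = 21)
  expect_equal(r1$evsi_per_person, r1b$evsi_per_person)

  # a trial with n = 0 carries no information
  r0 <- evsi_nested(noninf, inp, trial_design(n = 0),
                    n_outer = 150, n_inner = 150, seed = 22)
  expect_lt(abs(r0$evsi_per_person), 6 * r0$mc_se + 2000)

  # 0 <= EVSI <= EVPI at matched seeds (allowing outer MC slack)
  ev_perfect <- evpi(noninf, inp, n_sims = 20000, seed = 21)
  expect_gt(r1$evsi_per_person, -3 * r1$mc_se)
  expect_lt(r1$evsi_per_person, ev_perfect + 3 * r1$mc_se)

  # the tighter empirical prior yields strictly lower EVSI at matched seeds
  r2 <- evsi_nested(empirical, inp, des, n_outer = 150, n_inner = 150,
                    seed = 21)
  expect_lt(r2$evsi_per_person, r1$evsi_per_person)

  # EVSI is nondecreasing in sample size (common random numbers, MC slack)
  sizes <- c(0, 62, 616, 6160)
  ev_n <- vapply(sizes, function(n)
    evsi_nested(noninf, inp, trial_design(n = n),
                n_outer = 120, n_inner = 120, seed = 31)$evsi_per_person, 0)
  slack <- 3 * r1$mc_se
  expect_true(all(diff(ev_n) > -slack))

  # population scaling and JSON provenance
  rp <- evsi_nested(empirical, inp, des, population = population_inputs(),
                    n_outer = 50, n_inner = 50, seed = 41)
  expect_equal(rp$evsi_population,
               rp$evsi_per_person * rp$effective_population,
               tolerance = 1e-9)
  js <- jsonlite::fromJSON(evsi_result_json(rp))
  expect_equal(js$n_outer, 50)
  expect_equal(js$prior$shape, 17.3)
})

test_that("EVPI shrinks with a degenerate prior and respects MC scaling", {
  inp <- decision_inputs()
  # nearly-degenerate prior: almost no decision uncertainty from the rate
  tight <- gamma_prior(1e6, 1e6 / 0.15)
  diffuse <- gamma_prior(1, 1)
  expect_lt(evpi(tight, inp, 2000, 5), evpi(diffuse, inp, 2000, 5))
  expect_gte(evpi(diffuse, inp, 2000, 5), 0)
})
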