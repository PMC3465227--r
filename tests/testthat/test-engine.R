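test_that("two-state toy matches the hand-computed trace and life-years", {
  trace <- two_state_trace(q = 0.5, horizon = 2)
  expect_equal(unname(trace$occupancy[, "A"]), c(1, 0.5, 0.25))
  expect_equal(unname(trace$entrants[, "D"]), c(0, 0.5, 0.25))

  out <- accumulate_outcomes(trace,
                             first_year = c(A = 0, D = 0),
                             prevalence = c(A = 0, D = 0),
                             utilities = c(A = 1, D = 0),
                             discount_rate = 0)
  expect_equal(out$qaly, 1.125)               # (1+0.5)/2 + (0.5+0.25)/2
  expect_equal(out$life_years, 1.125)
})

test_that("trace equals brute-force vector-matrix propagation", {
  withr::with_seed(42, {
    for (rep in 1:50) {
      mats <- lapply(1:12, function(i) random_stochastic_matrix(6))
      init <- runif(6, 0, 100)
      trace <- markov_trace(mats, init)
      oracle <- brute_force_occupancy(mats, init)
      expect_lt(max(abs(unname(trace$occupancy) - oracle)), 1e-12)
    }
  })
})

test_that("entrants are the off-diagonal inflows", {
  M <- matrix(c(0.7, 0.2, 0.1,
                0.0, 0.9, 0.1,
                0.0, 0.0, 1.0), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "D"), c("A", "B", "D")))
  trace <- markov_trace(list(M), c(A = 10, B = 0, D = 0))
  expect_equal(unname(trace$entrants[2, ]), c(0, 2, 1))
  expect_equal(unname(trace$entrants[1, ]), c(10, 0, 0))
  expect_true(all(trace$entrants >= 0))
})

test_that("half-cycle-corrected discounted life-years match the geometric series", {
  for (q in c(0.1, 0.5, 0.9)) {
    for (r in c(0, 0.03, 0.05)) {
      trace <- two_state_trace(q, horizon = 45)
      out <- accumulate_outcomes(trace, c(A = 0, D = 0), c(A = 0, D = 0),
                                 c(A = 1, D = 0), discount_rate = r)
      expect_equal(out$life_years, analytic_hcc_life_years(q, r, 45),
                   tolerance = 1e-10)
    }
  }
})

test_that("occupancy is conserved and death is absorbing on the full model", {
  cfg <- default_config()
  for (p in c(0, 1)) {
    trace <- run_cohort(cfg, scenario_spec(p))
    expect_equal(unname(rowSums(trace$occupancy)), rep(1000, 46),
                 tolerance = 1e-9)
    expect_true(all(diff(trace$occupancy[, "D"]) >= -1e-12))
    expect_true(all(trace$entrants >= -1e-12))
  }
})

test_that("discounting and accrual conventions behave as documented", {
  cfg <- default_config()
  trace <- run_cohort(cfg, scenario_spec(1))
  fy <- first_year_costs(cfg); pv <- prevalence_costs(cfg)
  u <- utility_weights(cfg)

  disc <- accumulate_outcomes(trace, fy, pv, u, discount_rate = 0.03)
  undisc <- accumulate_outcomes(trace, fy, pv, u, discount_rate = 0)
  expect_lt(disc$cost, undisc$cost)
  expect_lt(disc$qaly, undisc$qaly)
  expect_equal(undisc$cost, undisc$cost_undiscounted)
  expect_equal(disc$cost_undiscounted, undisc$cost_undiscounted)
  expect_lte(disc$qaly, disc$life_years)
  expect_lte(undisc$life_years,
             cfg$model$cohort_size * cfg$model$horizon)

  # a single recurring cost accrued wholly in cycle 1 discounts by 1/(1+r)
  M <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "D"), c("A", "D")))
  one <- markov_trace(list(M), c(A = 1, D = 0))
  out <- accumulate_outcomes(one, c(A = 0, D = 0), c(A = 100, D = 0),
                             c(A = 0, D = 0), discount_rate = 0.03)
  expect_equal(out$cost, 100 / 1.03)

  # zero utilities give zero QALYs
  zero <- accumulate_outcomes(trace, fy, pv,
                              c(HD = 0, PD = 0, Tx = 0, LRHD = 0, LRPD = 0,
                                D = 0), discount_rate = 0.03)
  expect_equal(zero$qaly, 0)
})

test_that("annualization divides by cohort-size times horizon and is scale-free", {
  cfg <- default_config()
  out <- run_scenario(cfg, scenario_spec(1))
  expect_equal(out$per_patient_annual_cost, out$cost / (1000 * 45))
  expect_equal(out$per_patient_annual_qaly, out$qaly / (1000 * 45))

  toy <- structure(list(cost = 90000, qaly = 0, cost_undiscounted = 90000,
                        qaly_undiscounted = 0, cohort_size = 1000,
                        horizon = 45, discount_rate = 0),
                   class = "outcome_summary")
  toy <- annualize(toy)
  expect_equal(toy$per_patient_annual_cost, 2)
  expect_equal(toy$per_patient_annual_qaly, 0)
  expect_error(annualize(toy, horizon = 0), "horizon")

  # per-patient figures are invariant to cohort size
  small <- cfg
  small$model$cohort_size <- 1
  a <- run_scenario(cfg, scenario_spec(0))
  b <- run_scenario(small, scenario_spec(0))
  expect_equal(a$per_patient_annual_cost, b$per_patient_annual_cost,
               tolerance = 1e-9)
  expect_equal(a$per_patient_annual_qaly, b$per_patient_annual_qaly,
               tolerance = 1e-9)
})

test_that("identity dynamics freeze the cohort", {
  I6 <- diag(6)
  dimnames(I6) <- list(rrt_states(), rrt_states())
  trace <- markov_trace(rep(list(I6), 45),
                        setNames(c(100, 0, 900, 0, 0, 0), rrt_states()))
  expect_true(all(trace$occupancy[, "Tx"] == 900))
  expect_true(all(trace$entrants[-1, ] == 0))
})

test_that("trace export writes one row per cycle boundary", {
  trace <- run_cohort(default_config(), scenario_spec(1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(trace, path)
  tab <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(tab), 46)
  expect_true(all(rrt_states() %in% names(tab)))
  expect_equal(tab$Tx, unname(trace$occupancy[, "Tx"]), tolerance = 1e-9)
})
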