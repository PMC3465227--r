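test_that("moment matching recovers the analytic mean and sd by formula", {
  b <- make_distribution("beta", 0.5, 0.05)
  expect_equal(b$natural_params$alpha, 49.5)
  expect_equal(b$natural_params$beta, 49.5)

  ln <- make_distribution("lognormal", 1000, 100)
  expect_equal(ln$natural_params$sdlog^2, log(1.01), tolerance = 1e-12)
  expect_equal(ln$natural_params$meanlog, log(1000) - log(1.01) / 2,
               tolerance = 1e-12)

  un <- make_distribution("uniform", 0.03, 0.003)
  expect_equal(un$natural_params$min, 0.03 - 0.003 * sqrt(3))
  expect_equal(un$natural_params$max, 0.03 + 0.003 * sqrt(3))
  expect_equal(un$natural_params$min, 0.0248038, tolerance = 1e-5)
  expect_equal(un$natural_params$max, 0.0351962, tolerance = 1e-5)

  # every family's analytic moments equal the requested ones
  cases <- list(c("beta", 0.0350), c("beta", 0.73), c("normal", 0.69),
                c("lognormal", 31912), c("uniform", 0.03))
  for (cs in cases) {
    m <- as.numeric(cs[2])
    spec <- make_distribution(cs[1], m, 0.10 * m)
    mom <- distribution_moments(spec)
    expect_equal(unname(mom["mean"]), m, tolerance = 1e-12)
    expect_equal(unname(mom["sd"]), 0.10 * m, tolerance = 1e-12)
  }

  expect_error(make_distribution("beta", 0.5, 0.6), "infeasible")
  expect_error(make_distribution("beta", 1.2, 0.1), "\\(0, 1\\)")
  expect_error(make_distribution("lognormal", -5, 1), "mean > 0")
  expect_error(make_distribution("normal", 1, 0), "sd > 0")
})

test_that("sampling recovers the target moments empirically", {
  n <- 1e5
  for (family in c("beta", "normal", "lognormal", "uniform")) {
    m <- if (family == "beta") 0.27 else 2545
    spec <- make_distribution(family, m, 0.10 * m)
    draws <- withr::with_seed(11, draw_distribution(spec, n))
    expect_equal(mean(draws), m, tolerance = 0.02)
    expect_equal(sd(draws), 0.10 * m, tolerance = 0.02)
  }
})

test_that("joint parameter draws are reproducible and respect bounds", {
  cfg <- default_config()
  a <- withr::with_seed(5, sample_parameter_set(cfg))
  b <- withr::with_seed(5, sample_parameter_set(cfg))
  expect_identical(a, b)

  withr::with_seed(21, {
    for (i in 1:20) {
      drawn <- sample_parameter_set(cfg)
      d <- drawn$draws
      probs <- d[grepl("^(trans|mort)_", names(d))]
      expect_true(all(probs >= 0 & probs <= 1))
      utils <- d[grepl("^utility_", names(d))]
      expect_true(all(utils >= 0 & utils <= 1))
      costs <- d[grepl("^cost_", names(d))]
      expect_true(all(costs >= 0))
      # the perturbed config actually carries the draws
      expect_equal(drawn$config$transitions$hd_pd, d[["trans_hd_pd"]])
      expect_equal(drawn$config$costs$prevalence$HD,
                   d[["cost_prevalence_HD"]])
    }
  })

  # near-degenerate dispersion collapses onto the configured means
  tight <- withr::with_seed(5, sample_parameter_set(cfg, relative_sd = 1e-7))
  expect_equal(tight$draws[["cost_first_year_Tx"]], 36772, tolerance = 1e-4)
  expect_equal(tight$draws[["utility_Tx"]], 0.81, tolerance = 1e-4)

  # optional pairing ties late-referral prevalence costs to the HD/PD draws
  paired_cfg <- cfg
  paired_cfg$psa$pair_lr_costs <- TRUE
  paired <- withr::with_seed(5, sample_parameter_set(paired_cfg))
  expect_equal(paired$draws[["cost_prevalence_LRHD"]],
               paired$draws[["cost_prevalence_HD"]])
  expect_equal(paired$draws[["cost_prevalence_LRPD"]],
               paired$draws[["cost_prevalence_PD"]])
})

test_that("probabilistic analysis is seed-deterministic and couples scenarios", {
  cfg <- default_config()
  a <- run_psa(cfg, n = 25, seed = 3)
  b <- run_psa(cfg, n = 25, seed = 3)
  expect_identical(a$samples, b$samples)
  expect_identical(a$summary, b$summary)
  other <- run_psa(cfg, n = 25, seed = 4)
  expect_false(identical(a$samples$delta_cost, other$samples$delta_cost))

  # common random parameters: replaying the first replicate's draw outside
  # run_psa reproduces both scenario outcomes and their deltas
  first <- withr::with_seed(renalcea:::stage_seed(3, "psa"),
                            sample_parameter_set(cfg))
  rate <- first$config$model$discount_rate
  ref <- run_scenario(first$config, scenario_spec(1), discount_rate = rate,
                      renormalize = TRUE)
  cmp <- run_scenario(first$config, scenario_spec(0), discount_rate = rate,
                      renormalize = TRUE)
  expect_equal(a$samples$cost_reference[1], ref$per_patient_annual_cost)
  expect_equal(a$samples$cost_comparator[1], cmp$per_patient_annual_cost)
  expect_equal(a$samples$delta_cost[1],
               cmp$per_patient_annual_cost - ref$per_patient_annual_cost)
  expect_equal(a$samples$delta_qaly,
               a$samples$qaly_comparator - a$samples$qaly_reference)

  expect_equal(nrow(a$samples), 25)
  expect_true(all(a$samples$category %in%
                    c(acceptable_categories(), "dominated",
                      "not_acceptable")))
  expect_equal(sum(a$acceptance), 1)

  # a single replicate's summary is that replicate
  one <- run_psa(cfg, n = 1, seed = 9)
  expect_equal(unname(one$summary["delta_cost", ]),
               rep(one$samples$delta_cost, 3))
})

test_that("degenerate dispersion collapses every replicate to the deterministic result", {
  cfg <- default_config()
  cfg$psa$relative_sd <- 1e-12
  psa <- run_psa(cfg, n = 20, seed = 2)
  det <- deterministic_comparison(cfg)
  expect_lt(max(abs(psa$samples$delta_cost - det$delta_cost)), 1e-6)
  expect_lt(max(abs(psa$samples$delta_qaly - det$delta_qaly)), 1e-6)
})

test_that("percentile intervals follow the documented empirical rule", {
  x <- 1:100
  expect_equal(unname(quantile(x, c(0.025, 0.975))),
               c(3.475, 97.525))
  cfg <- default_config()
  psa <- run_psa(cfg, n = 40, seed = 8)
  expect_equal(psa$summary["delta_cost", "lower"],
               unname(quantile(psa$samples$delta_cost, 0.025)))
  expect_equal(psa$summary["delta_cost", "upper"],
               unname(quantile(psa$samples$delta_cost, 0.975)))
})
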