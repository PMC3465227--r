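make_summary <- function(cost, qaly, name) {
  s <- structure(list(cost = cost * 45000, qaly = qaly * 45000,
                      cost_undiscounted = cost * 45000,
                      qaly_undiscounted = qaly * 45000,
                      cohort_size = 1000, horizon = 45,
                      discount_rate = 0.03, scenario = name),
                 class = "outcome_summary")
  annualize(s)
}

test_that("incremental deltas and ICER follow the ratio contract", {
  ref <- make_summary(cost = 100, qaly = 0.10, "late")
  cmp <- make_summary(cost = 200, qaly = 0.11, "timely")
  inc <- incremental(ref, cmp, wtpt = 45000)
  expect_equal(inc$delta_cost, 100)
  expect_equal(inc$delta_qaly, 0.01)
  expect_equal(inc$icer, 10000)
  expect_equal(inc$category, "efficient_higher_effectiveness")

  # zero effectiveness difference leaves the ICER undefined, not an error
  tie <- incremental(ref, make_summary(200, 0.10, "timely"))
  expect_true(is.na(tie$icer))

  # ICER is invariant to common positive rescaling of both deltas
  scaled <- incremental(make_summary(300, 0.30, "late"),
                        make_summary(600, 0.33, "timely"))
  expect_equal(scaled$icer, inc$icer)

  # the printed deterministic deltas of the study imply this ratio
  expect_equal(425 / 0.0176, 24147.727, tolerance = 1e-6)
})

test_that("classification assigns exactly one category everywhere", {
  expect_equal(classify(-1, 0.1, 45000), "dominant")
  expect_equal(classify(100, 0.01, 45000), "efficient_higher_effectiveness")
  expect_equal(classify(-1000, -0.01, 45000), "efficient_lower_cost")
  expect_equal(classify(100, -0.01, 0), "dominated")
  expect_equal(classify(100, 0.01, 0), "not_acceptable")

  grid <- expand.grid(dc = c(-10, -1, 0, 1, 10),
                      de = c(-0.1, -0.001, 0, 0.001, 0.1),
                      w = c(0, 1000, 45000, 1e6))
  cats <- classify(grid$dc, grid$de, grid$w[1])
  for (w in unique(grid$w)) {
    cats <- classify(grid$dc, grid$de, w)
    expect_true(all(cats %in% c(acceptable_categories(), "dominated",
                                "not_acceptable")))
    expect_equal(length(cats), nrow(grid))
    # boundary conventions: free effectiveness gain dominates, pure cost
    # increase does not
    expect_equal(classify(0, 0.1, w), "dominant")
    expect_equal(classify(-1, 0, w), "dominant")
    expect_equal(classify(0, 0, w), "not_acceptable")
    expect_equal(classify(0, -0.1, w), "dominated")
  }
})

test_that("acceptability curves are complementary and NMB-consistent", {
  grid <- seq(0, 90000, by = 1000)

  dominant <- data.frame(delta_cost = c(-5, -10, -1),
                         delta_qaly = c(0.01, 0.02, 0.005))
  curve <- ceac(dominant, grid)
  comp <- curve[curve$scenario == "timely", ]
  expect_true(all(comp$acceptance == 1))

  mixed <- data.frame(delta_cost = c(10, -10), delta_qaly = c(0.001, -0.001))
  at0 <- ceac(mixed, 0)
  expect_equal(at0$acceptance[at0$scenario == "timely"], 0.5)

  withr::with_seed(99, {
    samples <- data.frame(delta_cost = rnorm(400, 200, 300),
                          delta_qaly = abs(rnorm(400, 0.01, 0.005)))
  })
  curve <- ceac(samples, grid)
  by_wtpt <- tapply(curve$acceptance, curve$wtpt, sum)
  expect_true(all(abs(by_wtpt - 1) < 1e-12))
  # monotone in the threshold when no sample loses effectiveness
  comp <- curve[curve$scenario == "timely", ]
  expect_true(all(diff(comp$acceptance[order(comp$wtpt)]) >= 0))

  # NMB tie counts one half
  tie <- data.frame(delta_cost = 45, delta_qaly = 0.001)
  expect_equal(ceac(tie, 45000)$acceptance, c(0.5, 0.5))

  expect_error(ceac(data.frame(), grid), "delta_cost")
  expect_error(ceac(mixed, numeric(0)), "wtpt_grid")
})

test_that("restricted acceptance renormalizes over no-effectiveness-loss outcomes", {
  samples <- data.frame(
    delta_cost = c(-10, -20, 100, 500, -100),
    delta_qaly = c(0.01, 0.02, 0.01, -0.02, -0.004)
  )
  # at a 20,000 threshold: comparator favourable without loss in rows 1-3,
  # reference in row 4 only (row 5 loses effectiveness either way)
  out <- restricted_acceptance(samples, wtpt = 20000)
  expect_equal(unname(out), c(0.75, 0.25))
  expect_equal(sum(out), 1)

  all_dominant <- data.frame(delta_cost = c(-1, -2), delta_qaly = c(0.1, 0.2))
  expect_equal(unname(restricted_acceptance(all_dominant, 45000)), c(1, 0))

  none <- data.frame(delta_cost = c(100, 200), delta_qaly = c(0.001, 0.002))
  expect_error(restricted_acceptance(none, wtpt = 0), "no replicate")
})

test_that("confidence ellipse uses the chi-square construction", {
  withr::with_seed(7, {
    samples <- data.frame(delta_qaly = rnorm(5000), delta_cost = rnorm(5000))
  })
  ell <- confidence_ellipse(samples)
  expect_equal(ell$chi2_quantile, qchisq(0.95, 2))
  expect_equal(ell$chi2_quantile, 5.9915, tolerance = 1e-4)
  expect_equal(unname(ell$center),
               c(mean(samples$delta_qaly), mean(samples$delta_cost)))

  # boundary points sit exactly on the chi-square contour
  bd <- ellipse_boundary(ell, n_points = 50)
  d2 <- mahalanobis(as.matrix(bd), ell$center, ell$covariance)
  expect_true(all(abs(d2 - ell$chi2_quantile) < 1e-8))

  # membership test agrees with the Mahalanobis rule
  inside <- in_ellipse(ell, samples$delta_qaly, samples$delta_cost)
  d2 <- mahalanobis(cbind(samples$delta_qaly, samples$delta_cost),
                    ell$center, ell$covariance)
  expect_identical(unname(inside), unname(d2 <= ell$chi2_quantile))

  expect_error(confidence_ellipse(samples[1:2, ]), "3 samples")
  flat <- data.frame(delta_qaly = c(1, 2, 3), delta_cost = c(2, 4, 6))
  expect_error(confidence_ellipse(flat), "degenerate|singular")
})
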