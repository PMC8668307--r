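test_that("volatility and sensitivity are observed fractions", {
  expect_equal(estimate_volatility(observation_counts(10, 2)), 0.2)
  expect_equal(estimate_volatility(observation_counts(7, 0)), 0)
  expect_equal(estimate_volatility(observation_counts(10, 10)), 1)
  expect_equal(estimate_sensitivity(observation_counts(1, 1, 1, 1)), 1)
  expect_equal(estimate_sensitivity(observation_counts(5, 4, 4, 0)), 0)
  expect_equal(estimate_sensitivity(observation_counts(5, 4, 4, 3)), 0.75)

  expect_error(estimate_volatility(observation_counts(0, 0)), "n_o = 0")
  expect_error(estimate_sensitivity(observation_counts(3, 0, 0, 0)), "n_ic = 0")
})

test_that("observation tallies are validated and inconsistency is flagged", {
  expect_error(observation_counts(5, 6), "n_oc")
  expect_error(observation_counts(5, 2, 2, 3), "n_ir")
  expect_error(observation_counts(5, -1), "non-negative")
  expect_warning(observation_counts(10, 3, 4, 1), "differs")
  expect_silent(observation_counts(10, 3, 4, 1, linked = FALSE))
})

test_that("rework probability is the volatility-sensitivity product", {
  expect_equal(rework_probability(0.5, 0.4), 0.2)
  expect_equal(rework_probability(1, 1), 1)
  expect_equal(rework_probability(0, 0.9), 0)
  expect_error(rework_probability(1.1, 0.5), "p_i")
  # bounded by each factor, symmetric, monotone
  for (i in 1:50) {
    p <- (i %% 10) / 10; q <- (i %% 7) / 7
    expect_lte(rework_probability(p, q), min(p, q) + 1e-12)
    expect_equal(rework_probability(p, q), rework_probability(q, p))
  }
})

test_that("per-class probabilities combine as at-least-one-triggers", {
  expect_equal(combine_rework_probabilities(0.3), 0.3)
  expect_equal(combine_rework_probabilities(c(0.5, 0.5)), 0.75)
  expect_equal(combine_rework_probabilities(c(0.2, 0, 1)), 1)
  expect_error(combine_rework_probabilities(numeric(0)), "no class")
})

test_that("fit_triangular anchors at the extremes with a clamped mode", {
  expect_equal(fit_triangular(3), triangular_duration(3, 3, 3))
  expect_equal(fit_triangular(c(2, 2)), triangular_duration(2, 2, 2))
  fit <- fit_triangular(c(1, 2, 3))      # n <= 5: median
  expect_equal(c(fit$bcv, fit$mlv, fit$wcv), c(1, 2, 3))
  expect_error(fit_triangular(numeric(0)), "empty")

  # larger samples use the half-sample mode, still bracketing every value
  set.seed(99)
  for (i in 1:20) {
    x <- rlnorm(sample(6:40, 1))
    fit <- fit_triangular(x)
    expect_equal(fit$bcv, min(x))
    expect_equal(fit$wcv, max(x))
    expect_gte(fit$mlv, min(x))
    expect_lte(fit$mlv, max(x))
  }
  # the half-sample mode tracks the dense region, not the tail
  skewed <- c(rep(1, 10) + runif(10, 0, 0.05), 8, 9, 10)
  expect_lt(fit_triangular(skewed)$mlv, 2)
})

test_that("rework impact aggregates as the arithmetic mean of assessments", {
  expect_equal(aggregate_rework_impact(c(0.2, 0.4)), 0.3)
  expect_equal(aggregate_rework_impact(1), 1)
  expect_equal(aggregate_rework_impact(c(0, 0, 0)), 0)
  expect_error(aggregate_rework_impact(numeric(0)), "no rework-impact")
  expect_error(aggregate_rework_impact(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("observation tables estimate one probability per dependency", {
  obs <- data.frame(
    input_id = c("A1", "A1", "A2"),
    consumer_id = c("A2", "A2", "A3"),
    class = c("bleeding", "exposure", "bleeding"),
    n_o = c(10, 10, 8),
    n_oc = c(2, 5, 4),
    n_ic = c(2, 5, 4),
    n_ir = c(1, 2, 1))
  est <- estimate_rework_probabilities(obs)
  expect_equal(nrow(est), 2)
  # classes combine: 1 - (1 - 0.2*0.5)(1 - 0.5*0.4)
  expect_equal(est$p[est$from == "A1"], 1 - (1 - 0.1) * (1 - 0.2))
  expect_equal(est$p[est$from == "A2"], 0.5 * 0.25)
})

test_that("duration tables fit one triangular estimate per activity", {
  samples <- data.frame(activity_id = rep(c("A1", "A2"), c(3, 1)),
                        duration_min = c(1, 2, 3, 5))
  fits <- estimate_durations(samples)
  expect_equal(fits[fits$id == "A1", c("bcv", "mlv", "wcv")],
               data.frame(bcv = 1, mlv = 2, wcv = 3,
                          row.names = which(fits$id == "A1")))
  expect_equal(unlist(fits[fits$id == "A2", c("bcv", "mlv", "wcv")]),
               c(bcv = 5, mlv = 5, wcv = 5))
})
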