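test_that("triangular inverse transform matches the closed-form and a numeric oracle", {
  expect_equal(sample_duration(triangular_duration(0, 1, 2), 0.5), 1)
  expect_equal(sample_duration(triangular_duration(3, 3, 3), 0.2), 3)
  # right-triangle case: invert F(x) = 1 - (1 - x)^2 at u = 0.75
  expect_equal(sample_duration(triangular_duration(0, 0, 1), 0.75), 0.5)
  expect_error(sample_duration(triangular_duration(0, 1, 2), 1.2), "\\[0, 1\\]")

  set.seed(4)
  for (i in 1:25) {
    a <- runif(1, 0, 5); m <- a + runif(1, 0, 3); b <- m + runif(1, 0, 3)
    u <- runif(1)
    d <- triangular_duration(a, m, b)
    expect_equal(sample_duration(d, u), oracle_tri_quantile(u, a, m, b),
                 tolerance = 1e-8)
    expect_gte(sample_duration(d, u), a)
    expect_lte(sample_duration(d, u), b)
  }
})

test_that("triangular sample mean converges to (bcv + mlv + wcv) / 3", {
  set.seed(10)
  d <- triangular_duration(0, 1, 2)
  x <- sample_duration(d, runif(50000))
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 1), 3 * se)
})

test_that("rework iteration counts follow the capped geometric model", {
  set.seed(1)
  expect_identical(sample_rework_count(0, 25), 0L)
  expect_identical(sample_rework_count(1, 7), 7L)

  # closed form equals exhaustive pmf summation
  for (p in c(0.1, 0.5, 0.9)) {
    for (cap in c(1, 5, 25)) {
      expect_equal(expected_rework_count(p, cap),
                   oracle_truncated_geometric_mean(p, cap), tolerance = 1e-12)
    }
  }
  expect_equal(expected_rework_count(0.1, 25), 0.1 * (1 - 0.1^25) / 0.9)
  expect_equal(expected_rework_count(0.1, 25), 1 / 9, tolerance = 1e-9)
  expect_equal(expected_rework_count(1, 9), 9)

  # sampled mean within 3 standard errors of the analytic value
  set.seed(2)
  draws <- replicate(20000, sample_rework_count(0.1, 25))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected_rework_count(0.1, 25)), 3 * se)
  expect_lte(max(draws), 25)

  # literal convention inverts the trigger
  set.seed(3)
  lit <- replicate(5000, sample_rework_count(0.1, 25, "literal"))
  se <- sd(lit) / sqrt(length(lit))
  expect_lt(abs(mean(lit) - expected_rework_count(0.1, 25, "literal")), 4 * se)
  expect_gt(mean(lit), 5)  # 0.1 under the literal reading reworks ~90% of passes
})

test_that("rework duration is the impact-and-learning-scaled original duration", {
  expect_equal(rework_duration(10, 0.3, 1), 3)
  expect_equal(rework_duration(7.3, 1, 1), 7.3)
  expect_equal(rework_duration(10, 0, 0.5), 0)
  expect_error(rework_duration(-1, 0.5, 1), "d0")
  expect_error(rework_duration(1, 1.5, 1), "ri")
  expect_error(rework_duration(1, 0.5, 0), "ic")
})

test_that("simulate_loop walks cyclic dependencies and prices rework", {
  dsm0 <- make_two_activity_loop(p = 0)
  d0 <- c(A = 4, B = 6)
  set.seed(1)
  expect_equal(simulate_loop(c("A", "B"), dsm0, d0)$duration, 0)

  # certain rework, cap 1, full impact: one full repeat of each member
  acts <- data.frame(id = c("A", "B"), bcv = c(4, 6), mlv = c(4, 6),
                     wcv = c(4, 6), rework_impact = 1, improvement_curve = 1)
  dsm1 <- build_dsm(acts, data.frame(from = c("A", "B"), to = c("B", "A"), p = 1))
  set.seed(1)
  out <- simulate_loop(c("A", "B"), dsm1, d0, sim_config(max_reworks_per_edge = 1))
  expect_equal(out$duration, 10)
  expect_identical(unname(out$nr), c(1L, 1L))

  # a loop missing a cyclic edge is a structural error
  one_way <- build_dsm(acts, data.frame(from = "A", to = "B", p = 1))
  expect_error(simulate_loop(c("A", "B"), one_way, d0), "missing cyclic edge.*B->A")
})

test_that("Monte Carlo loop duration matches the truncated-geometric expectation", {
  dsm <- make_two_activity_loop(d = 10, p = 0.5, ri = 0.5)
  cfg <- sim_config(n_runs = 20000, seed = 31, max_reworks_per_edge = 25)
  res <- run_monte_carlo(dsm, cfg)
  loop_dur <- res$loop_durations[, 1]
  analytic <- 2 * 10 * 0.5 * expected_rework_count(0.5, 25)
  se <- sd(loop_dur) / sqrt(length(loop_dur))
  expect_lt(abs(mean(loop_dur) - analytic), 3 * se)
})

test_that("degenerate no-rework runs reduce to the plain duration sum", {
  acts <- data.frame(id = paste0("A", 1:4), bcv = 1:4, mlv = 1:4, wcv = 1:4,
                     rework_impact = 0.5, improvement_curve = 1)
  chain <- data.frame(from = paste0("A", 1:3), to = paste0("A", 2:4), p = 0)
  dsm <- build_dsm(acts, chain)
  set.seed(1)
  rec <- simulate_run(dsm)
  expect_equal(rec$total, 10)
  expect_equal(rec$first_trial_total, 10)

  res <- run_monte_carlo(dsm, sim_config(n_runs = 1, seed = 9))
  expect_equal(res$summary$mean, 10)
  expect_equal(res$summary$min, 10)
  expect_equal(res$summary$max, 10)
})

test_that("the total-duration accounting identity holds exactly on every run", {
  # seed 13 yields two 2-activity loops, exercising the multi-loop path
  for (dsm in list(make_amis_fixture(), make_aplt_fixture(),
                   make_random_dsm(6, density = 0.3, seed = 13))) {
    res <- run_monte_carlo(dsm, sim_config(n_runs = 500, seed = 17))
    reconstructed <- res$first_trial_total +
      (if (ncol(res$loop_durations)) apply(res$loop_durations, 1, sum) else 0) +
      (if (ncol(res$edge_rework)) apply(res$edge_rework, 1, sum) else 0)
    expect_identical(res$totals, reconstructed)
    expect_true(all(res$totals >= 0))
  }
})

test_that("every sampled first-trial duration lies within its triangular support", {
  dsm <- make_amis_fixture()
  part <- partition_dsm(dsm)
  set.seed(5)
  for (i in 1:200) {
    rec <- simulate_run(dsm, part)
    expect_true(all(rec$d0 >= dsm$activities$bcv - 1e-12))
    expect_true(all(rec$d0 <= dsm$activities$wcv + 1e-12))
  }
})

test_that("identical configuration gives bit-identical simulation results", {
  dsm <- make_amis_fixture()
  cfg <- sim_config(n_runs = 400, seed = 123)
  r1 <- run_monte_carlo(dsm, cfg)
  r2 <- run_monte_carlo(dsm, cfg)
  expect_identical(r1$totals, r2$totals)
  expect_identical(r1$rework_counts, r2$rework_counts)
  expect_identical(r1$summary, r2$summary)
  r3 <- run_monte_carlo(dsm, sim_config(n_runs = 400, seed = 124))
  expect_false(identical(r1$totals, r3$totals))
  # the caller's RNG stream is not disturbed
  set.seed(77); before <- runif(5)
  set.seed(77); invisible(run_monte_carlo(dsm, cfg)); after <- runif(5)
  expect_identical(before, after)
})

test_that("raising a single rework probability never decreases any run's total", {
  base <- make_aplt_fixture()
  cfg <- sim_config(n_runs = 300, seed = 42, max_reworks_per_edge = 10)
  totals0 <- run_monte_carlo(base, cfg)$totals
  for (i in c(1, 5, 10)) {
    bumped <- base
    bumped$edges$p[i] <- 0.6
    totals1 <- run_monte_carlo(bumped, cfg)$totals
    expect_true(all(totals1 >= totals0 - 1e-12))
    expect_gt(mean(totals1), mean(totals0))
  }
})

test_that("rework counts never exceed the per-edge cap", {
  dsm <- make_amis_fixture()
  res <- run_monte_carlo(dsm, sim_config(n_runs = 300, seed = 6))
  caps <- ifelse(grepl("^A[67]->A[67]$", colnames(res$rework_counts)), 1, 25)
  expect_true(all(sweep(res$rework_counts, 2, caps, `<=`)))
  # the certain loop edges rework exactly once per pass under the default cap
  expect_true(all(res$rework_counts[, "A6->A7"] == 1L))
  expect_true(all(res$rework_counts[, "A7->A6"] == 1L))
})

test_that("expected_duration is the mlv_only Monte Carlo mean", {
  # single edge, large cap: adds MLV * RI * p/(1-p) = 2 minutes
  acts <- data.frame(id = c("A", "B"), bcv = c(1, 2), mlv = c(1, 2),
                     wcv = c(1, 2), rework_impact = c(0, 1),
                     improvement_curve = 1)
  dsm <- build_dsm(acts, data.frame(from = "A", to = "B", p = 0.5))
  expect_equal(expected_duration(dsm), 3 + 2 * expected_rework_count(0.5, 25))
  expect_equal(expected_duration(dsm), 5, tolerance = 1e-6)

  # all-zero probabilities: plain MLV sum
  dsm0 <- build_dsm(acts, data.frame(from = "A", to = "B", p = 0))
  expect_equal(expected_duration(dsm0), 3)

  # fixture-level self consistency against the engine
  amis <- make_amis_fixture()
  mc <- run_monte_carlo(amis, sim_config(n_runs = 20000, seed = 8,
                                         duration_source = "mlv_only"))
  se <- sd(mc$totals) / sqrt(length(mc$totals))
  expect_lt(abs(mc$summary$mean - expected_duration(amis)), 3 * se)
})

test_that("expected_duration with cap 1 matches a hand-computed walkthrough", {
  # AMIS-structure fixture at total MLV 10: per-activity MLVs
  # (1.2, 1.2, 1.6, 1.2, 0.4, 1.2, 0.4, 0.8, 2.0).  With one iteration
  # allowed per edge the expected count is p, so each relation adds
  # MLV_consumer * RI_consumer * p:
  #   loop edges:  A6->A7: 0.4*1*1 = 0.4;  A7->A6: 1.2*1*1 = 1.2
  #   chain edges (p = 0.1): 0.012 + 0.016 + 0.012 + 0.004 + 0.12 (A5->A6,
  #     RI = 1) + 0.008 + 0.02
  #   extra cleaning edges A4/A5/A6 -> A8: 3 * 0.008 = 0.024
  # total rework 1.816, expected duration 11.816
  amis <- make_amis_fixture(duration_scale = 10)
  expect_equal(expected_duration(amis, max_reworks_per_edge = 1), 11.816,
               tolerance = 1e-12)

  mc <- run_monte_carlo(amis, sim_config(n_runs = 20000, seed = 21,
                                         max_reworks_per_edge = 1,
                                         duration_source = "mlv_only"))
  se <- sd(mc$totals) / sqrt(length(mc$totals))
  expect_lt(abs(mc$summary$mean - 11.816), 3 * se)
})

test_that("simulation configs are validated and file-readable", {
  expect_error(sim_config(n_runs = 0), "n_runs")
  expect_error(sim_config(max_reworks_per_edge = 0), "max_reworks_per_edge")
  td <- withr::local_tempdir()
  writeLines('{"n_runs": 50, "seed": 3, "rework_trigger": "literal"}',
             file.path(td, "cfg.json"))
  cfg <- read_sim_config(file.path(td, "cfg.json"))
  expect_identical(cfg$n_runs, 50L)
  expect_identical(cfg$rework_trigger, "literal")
  writeLines(c("n_runs: 10", "seed: 4", "duration_source: mlv_only"),
             file.path(td, "cfg.yaml"))
  cfg2 <- read_sim_config(file.path(td, "cfg.yaml"))
  expect_identical(cfg2$duration_source, "mlv_only")
  expect_identical(cfg2$max_reworks_per_edge, NULL)
})
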