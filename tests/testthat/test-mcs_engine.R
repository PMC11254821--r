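test_that("percentile implements the type-7 linear interpolation rule", {
  expect_equal(percentile(1:100, 0.5), 50.5)
  expect_equal(percentile(1:100, 0), 1)
  expect_equal(percentile(1:100, 1), 100)
  expect_equal(percentile(rep(4.2, 10), 0.73), 4.2)
  expect_error(percentile(1:10, 1.2), "\\[0, 1\\]")
  expect_error(percentile(numeric(0), 0.5), "empty")
})

test_that("exceedance counts strict threshold crossings", {
  expect_equal(exceedance(c(0.5, 1.5, 2.5, 0.7), 1), 0.5)
  expect_equal(exceedance(c(0.1, 0.2), 1), 0)
  expect_equal(exceedance(c(1, 1, 2), 1), 1 / 3)  # strict >
})

test_that("all-fixed inputs collapse every percentile to the point value", {
  sim <- run_simulation(fixed_config(C = 10, IR = 6.7))
  expect_equal(unique(sim$draws$EDI_Cd), 1.0)
  row <- sim$summary[sim$summary$metric == "EDI_Cd", ]
  for (col in c("Minimum", "P25", "Mean", "P50", "P75", "P90",
                "P95", "P99", "Max"))
    expect_equal(row[[col]], 1.0)
  hi_row <- sim$summary[sim$summary$metric == "HI", ]
  p <- tox_profile("stated")
  manual_hi <- sum(hq(1.0, p$elements$RfD, 10))
  expect_equal(hi_row$Mean, manual_hi)
})

test_that("uniform ingestion rate matches the closed-form mean EDI", {
  conc <- setNames(lapply(risk_elements(), function(e)
    fixed_value(1)), risk_elements())
  cfg <- simulation_config(conc_dists = conc,
                           ef_dist = fixed_value(100),
                           ir_dist = uniform_dist(5, 10, "IR"),
                           sex = "male", n_iter = 1e5, seed = 3)
  sim <- run_simulation(cfg)
  closed <- edi(EF = 100, Ed = 20, IR = 7.5, C = 1, BA = 1,
                AT = 365 * 70, W = 67)
  expect_lt(abs(mean(sim$draws$EDI_Cd) - closed) / closed, 0.005)
})

test_that("identical seeds give bit-identical results", {
  spec <- generator_spec(seed = 5L)
  samples <- generate_samples(spec)
  b <- bioaccessible_content(samples)
  conc <- lapply(risk_elements(), function(el)
    fit_dist(b$bioaccessible_conc[b$element == el], "lognormal"))
  names(conc) <- risk_elements()
  ef <- fit_dist(c(5, 10, 20, 40, 120), "empirical", "EF")
  run <- function() run_simulation(simulation_config(
    conc_dists = conc, ef_dist = ef, sex = "female",
    n_iter = 500, seed = 99))
  expect_identical(run()$summary, run()$summary)
  expect_identical(run()$draws, run()$draws)
})

test_that("summary invariants hold on a stochastic run", {
  spec <- generator_spec(seed = 2L)
  b <- bioaccessible_content(generate_samples(spec))
  conc <- lapply(risk_elements(), function(el)
    fit_dist(b$bioaccessible_conc[b$element == el], "lognormal"))
  names(conc) <- risk_elements()
  ef <- fit_dist(
    generate_questionnaire(spec)$exposure_frequency[1:500],
    "empirical", "EF")
  sim <- run_simulation(simulation_config(
    conc_dists = conc, ef_dist = ef, sex = "male", n_iter = 4000,
    seed = 17))

  s <- sim$summary
  cols <- c("Minimum", "P25", "P50", "P75", "P90", "P95", "P99",
            "Max")
  for (i in seq_len(nrow(s))) {
    vals <- as.numeric(s[i, cols])
    expect_true(all(diff(vals) >= 0))
    expect_gte(s$Mean[i], s$Minimum[i])
    expect_lte(s$Mean[i], s$Max[i])
  }
  # additivity dominance, per draw
  expect_true(all(sim$draws$HI >= sim$draws$HQ_As))
  expect_true(all(sim$draws$TCR >= sim$draws$CR_As))
  # shared EF/IR draws induce positive HQ correlation across elements
  expect_gt(cor(sim$draws$HQ_As, sim$draws$HQ_Cd), 0)
  # exceedance bookkeeping
  expect_equal(
    sim$exceedance$probability[sim$exceedance$metric == "HI"],
    mean(sim$draws$HI > 1))
  expect_true(all(sim$exceedance$probability >= 0 &
                    sim$exceedance$probability <= 1))
})

test_that("doubling the iteration count moves the mean by < 3 SE", {
  spec <- generator_spec(seed = 8L)
  b <- bioaccessible_content(generate_samples(spec))
  conc <- lapply(risk_elements(), function(el)
    fit_dist(b$bioaccessible_conc[b$element == el], "lognormal"))
  names(conc) <- risk_elements()
  ef <- fit_dist(c(5, 10, 20, 40, 120, 200), "empirical", "EF")
  mk <- function(n, seed) run_simulation(simulation_config(
    conc_dists = conc, ef_dist = ef, sex = "male", n_iter = n,
    seed = seed))
  a <- mk(4000, 21)
  bg <- mk(8000, 22)
  se <- sd(bg$draws$HI) / sqrt(4000)
  expect_lt(abs(mean(a$draws$HI) - mean(bg$draws$HI)), 3 * se)
})

test_that("distributions violating kernel preconditions abort by name", {
  conc <- setNames(lapply(risk_elements(), function(e)
    fixed_value(1)), risk_elements())
  neg <- fit_dist(rnorm(100, 0, 5), "normal", "C_Cd")
  conc$Cd <- neg
  cfg <- simulation_config(conc_dists = conc,
                           ef_dist = fixed_value(100),
                           n_iter = 2000, seed = 1)
  expect_error(run_simulation(cfg), "C_Cd")
})

test_that("simulation_config validates completeness", {
  conc <- setNames(lapply(risk_elements(), function(e)
    fixed_value(1)), risk_elements())
  expect_error(simulation_config(conc_dists = conc[1:3],
                                 ef_dist = fixed_value(10)),
               "Cu")
  expect_error(simulation_config(conc_dists = conc,
                                 ef_dist = fixed_value(10),
                                 n_iter = 0))
})
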