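uniform01 <- function(k) lapply(seq_len(k), function(i)
  uniform_dist(0, 1))

test_that("Saltelli design has the expected geometry and determinism", {
  des <- saltelli_design(6, 1024, seed = 1)
  expect_equal(dim(des$A), c(1024, 6))
  expect_equal(dim(des$B), c(1024, 6))
  expect_length(des$AB, 6)
  # (k + 2) * n_base model-input rows in total
  total_rows <- nrow(des$A) + nrow(des$B) +
    sum(vapply(des$AB, nrow, 1L))
  expect_equal(total_rows, (6 + 2) * 1024)
  # AB_i is A with column i replaced by B's
  expect_equal(des$AB[[3]][, 3], des$B[, 3])
  expect_equal(des$AB[[3]][, -3], des$A[, -3])

  des2 <- saltelli_design(6, 1024, seed = 1)
  expect_identical(des, des2)
  des3 <- saltelli_design(6, 1024, seed = 2)
  expect_false(identical(des$A, des3$A))
})

test_that("mapped designs stay inside each variable's support", {
  dists <- list(uniform_dist(5, 10),
                fit_dist(rlnorm(100), "lognormal"),
                fit_dist(c(2, 3, 9), "empirical"))
  des <- map_design(saltelli_design(3, 128, seed = 4), dists)
  expect_true(all(des$A[, 1] >= 5 & des$A[, 1] <= 10))
  expect_true(all(des$A[, 2] > 0))
  expect_true(all(des$A[, 3] %in% c(2, 3, 9)))
})

test_that("additive equal-variance model splits indices 50/50", {
  des <- map_design(saltelli_design(2, 1024, seed = 11), uniform01(2))
  f <- function(M) M[, 1] + M[, 2]
  idx <- sobol_indices(f(des$A), f(des$B), sapply(des$AB, f),
                       c("X1", "X2"), n_boot = 100)
  expect_equal(idx$main_effect, c(0.5, 0.5), tolerance = 0.05)
  # additive: total effect equals main effect within the bootstrap CI
  expect_true(all(abs(idx$total_effect - idx$main_effect) <=
                    idx$ST_ci + idx$S1_ci))
  expect_lt(abs(sum(idx$main_effect) - 1), 0.1)
})

test_that("an inert input gets zero main and total effect", {
  des <- map_design(saltelli_design(2, 1024, seed = 5), uniform01(2))
  f <- function(M) 3 * M[, 1]
  idx <- sobol_indices(f(des$A), f(des$B), sapply(des$AB, f),
                       n_boot = 0)
  expect_equal(idx$main_effect[1], 1, tolerance = 0.05)
  expect_lt(abs(idx$main_effect[2]), 0.05)
  expect_lt(idx$total_effect[2], 0.05)
})

test_that("indices are invariant to affine rescaling of the output", {
  des <- map_design(saltelli_design(2, 256, seed = 9), uniform01(2))
  f <- function(M) M[, 1] + 2 * M[, 2]
  y <- list(A = f(des$A), B = f(des$B), AB = sapply(des$AB, f))
  i1 <- sobol_indices(y$A, y$B, y$AB, n_boot = 0)
  i2 <- sobol_indices(10 * y$A - 4, 10 * y$B - 4, 10 * y$AB - 4,
                      n_boot = 0)
  expect_equal(i1$main_effect, i2$main_effect, tolerance = 1e-10)
  expect_equal(i1$total_effect, i2$total_effect, tolerance = 1e-10)
})

test_that("zero output variance is an explicit error", {
  des <- saltelli_design(2, 64, seed = 2)
  y <- rep(1, 64)
  expect_error(sobol_indices(y, y, cbind(y, y), n_boot = 0),
               "variance")
})

test_that("rank_drivers sorts by total effect with main-effect ties", {
  idx <- data.frame(variable = c("EF", "C_As", "IR"),
                    main_effect = c(0.5, 0.3, 0.1),
                    total_effect = c(0.5, 0.3, 0.1))
  expect_equal(rank_drivers(idx)$variable, c("EF", "C_As", "IR"))

  tie <- data.frame(variable = c("a", "b"),
                    main_effect = c(0.1, 0.3),
                    total_effect = c(0.4, 0.4))
  expect_equal(rank_drivers(tie)$variable, c("b", "a"))
})

test_that("sobol_risk ranks inputs of the synthetic scenario", {
  spec <- generator_spec()  # the packaged default fixture
  b <- bioaccessible_content(generate_samples(spec))
  conc <- lapply(risk_elements(), function(el)
    select_best(b$bioaccessible_conc[b$element == el],
                c("lognormal", "gamma", "weibull", "normal"),
                variable_name = paste0("C_", el)))
  names(conc) <- risk_elements()
  ef <- fit_dist(
    generate_questionnaire(spec)$exposure_frequency[1:2000],
    "empirical", "EF")
  cfg <- simulation_config(conc_dists = conc, ef_dist = ef,
                           sex = "male", n_iter = 10, seed = 31)
  idx <- sobol_risk(cfg, n_base = 512, n_boot = 0)
  expect_setequal(idx$variable,
                  c("EF", "IR", "C_Cd", "C_As", "C_Hg", "C_Cu"))
  ranked <- rank_drivers(idx)
  expect_equal(ranked$variable[1], "EF")
  expect_equal(ranked$variable[2], "C_As")
})

test_that("the tornado diagnostic agrees on the dominant input", {
  spec <- generator_spec()
  b <- bioaccessible_content(generate_samples(spec))
  conc <- lapply(risk_elements(), function(el)
    select_best(b$bioaccessible_conc[b$element == el],
                c("lognormal", "gamma", "weibull", "normal"),
                variable_name = paste0("C_", el)))
  names(conc) <- risk_elements()
  ef <- fit_dist(
    generate_questionnaire(spec)$exposure_frequency[1:2000],
    "empirical", "EF")
  cfg <- simulation_config(conc_dists = conc, ef_dist = ef,
                           sex = "male", n_iter = 10, seed = 31)
  tor <- tornado_risk(cfg)
  expect_equal(tor$variable[1], "EF")
  expect_true(all(tor$swing[tor$variable %in%
                              c("EF", "IR", "C_As")] > 0))
})
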