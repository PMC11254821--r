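test_that("bioaccessible content and percent follow the defining ratio", {
  s <- data.frame(sample_id = "s1", origin = "A", element = "Cd",
                  total_conc = 2.0, gastric_conc = 0.50,
                  intestinal_conc = 0.36)
  b <- bioaccessible_content(s)
  expect_equal(b$bioaccessible_conc, 0.86)
  expect_equal(b$bioaccessibility_pct, 43.0)
  expect_false(b$flag_over_100)
})

test_that("gastric + intestinal equal to total gives exactly 100%", {
  s <- data.frame(sample_id = "s1", origin = "A", element = "As",
                  total_conc = 1.5, gastric_conc = 0.9,
                  intestinal_conc = 0.6)
  expect_equal(bioaccessible_content(s)$bioaccessibility_pct, 100)
})

test_that("zero total is an undefined ratio, >100% is flagged not cut", {
  s0 <- data.frame(sample_id = "s1", origin = "A", element = "Cd",
                   total_conc = 0, gastric_conc = 0.1,
                   intestinal_conc = 0.1)
  expect_error(bioaccessible_content(s0), "undefined")

  s2 <- data.frame(sample_id = "s1", origin = "A", element = "Cd",
                   total_conc = 1, gastric_conc = 0.8,
                   intestinal_conc = 0.4)
  b <- suppressMessages(bioaccessible_content(s2))
  expect_true(b$flag_over_100)
  expect_equal(b$bioaccessibility_pct, 120)
  capped <- suppressMessages(bioaccessible_content(s2,
                                                   cap_at_100 = TRUE))
  expect_equal(capped$bioaccessibility_pct, 100)
  expect_true(capped$flag_over_100)
})

test_that("origin summary reports mean and sample SD, mean only for n = 1", {
  res <- data.frame(
    sample_id = paste0("s", 1:4),
    origin = c("X", "X", "X", "Y"),
    element = "Cd",
    bioaccessible_conc = c(0.62, 0.98, 1.34, 1.73),
    bioaccessibility_pct = 50, flag_over_100 = FALSE)
  s <- summarize_by_origin(res)
  x <- s[s$origin == "X", ]
  expect_equal(x$n_batches, 3L)
  expect_equal(x$mean_conc, 0.98)
  expect_equal(x$sd_conc, 0.36)
  y <- s[s$origin == "Y", ]
  expect_equal(y$mean_conc, 1.73)
  expect_true(is.na(y$sd_conc))
})

test_that("equal values give SD zero; missing records are excluded with a note", {
  res <- data.frame(sample_id = paste0("s", 1:3), origin = "X",
                    element = "Hg",
                    bioaccessible_conc = c(1, 1, 1),
                    bioaccessibility_pct = 40, flag_over_100 = FALSE)
  expect_equal(summarize_by_origin(res)$sd_conc, 0)

  res$bioaccessible_conc[3] <- NA
  expect_message(s <- summarize_by_origin(res), "excluded")
  expect_equal(s$n_batches, 2L)
})

test_that("mean bioaccessibility averages per-sample percents", {
  res <- data.frame(sample_id = c("a", "b"), origin = "X",
                    element = "Cd",
                    bioaccessible_conc = c(0.4, 0.92),
                    bioaccessibility_pct = c(40, 46),
                    flag_over_100 = FALSE)
  m <- mean_bioaccessibility(res)
  expect_equal(m$mean_pct, 43.0)

  one <- res[1, ]
  expect_equal(mean_bioaccessibility(one)$mean_pct, 40)
})

test_that("synthetic cohort recovers the generator's bioaccessibility targets", {
  spec <- generator_spec(seed = 11L)
  b <- bioaccessible_content(generate_samples(spec))
  m <- mean_bioaccessibility(b)
  for (el in risk_elements()) {
    got <- m$mean_pct[m$element == el]
    expect_lt(abs(got - spec$bioaccessibility_target[[el]]), 3)
  }
})

test_that("origin table export is wide with Mean +/- SD cells", {
  spec <- generator_spec(seed = 3L)
  s <- summarize_by_origin(bioaccessible_content(
    generate_samples(spec)))
  path <- tempfile(fileext = ".csv")
  write_origin_table(s, path)
  wide <- read.csv(path, check.names = FALSE)
  expect_true(all(c("origin", "batches", risk_elements()) %in%
                    names(wide)))
  expect_equal(nrow(wide), length(unique(s$origin)))
  expect_match(wide$Cd[wide$origin == "Shanghai"], "\\+/-")
  expect_no_match(wide$Cd[wide$origin == "Anhui"], "\\+/-")
})
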