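test_that("continuous exposure reduces EDI to IR * C / W", {
  expect_equal(edi(EF = 365, Ed = 70, IR = 6.7, C = 10, BA = 1,
                   AT = 365 * 70, W = 67), 1.0)
})

test_that("EDI is linear in each factor and halves with BA = 0.5", {
  base <- edi(EF = 33.7, Ed = 20, IR = 7.5, C = 6.0, BA = 1,
              AT = 25550, W = 67)
  expect_equal(base, 1.77e-2, tolerance = 0.01)
  expect_equal(edi(33.7, 20, 7.5, 6.0, BA = 0.5, AT = 25550, W = 67),
               base / 2)
  for (mult in c(0.5, 2, 3)) {
    expect_equal(edi(33.7, 20, 7.5 * mult, 6.0, 1, 25550, 67),
                 base * mult)
    expect_equal(edi(33.7, 20, 7.5, 6.0 * mult, 1, 25550, 67),
                 base * mult)
  }
})

test_that("EDI rejects nonpositive AT/W and out-of-range EF/BA", {
  expect_error(edi(10, 20, 7.5, 1, 1, AT = 0, W = 67), "AT")
  expect_error(edi(10, 20, 7.5, 1, 1, AT = 100, W = 0), "W")
  expect_error(edi(400, 20, 7.5, 1, 1, 100, 67), "EF")
  expect_error(edi(10, 20, 7.5, 1, BA = 1.2, AT = 100, W = 67), "BA")
})

test_that("female/male EDI contrast is exactly the body-weight ratio", {
  args <- list(EF = 50, Ed = 20, IR = 7, C = 3, BA = 1, AT = 25550)
  m <- do.call(edi, c(args, W = exposure_defaults("male")$W))
  f <- do.call(edi, c(args, W = exposure_defaults("female")$W))
  expect_equal(f / m, 67.0 / 56.7)
})

test_that("hazard quotient follows EDI * SF * 0.001 / RfD", {
  expect_equal(hq(1.77e-2, RfD = 0.0003, SF = 10), 0.59)
  expect_equal(hq(4.13e-3, RfD = 0.001, SF = 10), 4.13e-2)
  expect_equal(hq(0, RfD = 0.001), 0)
  expect_error(hq(1, RfD = 0), "RfD")
})

test_that("hazard index sums the four elements and rejects omissions", {
  hqs <- c(Cd = 4.13e-2, As = 0.59, Hg = 1.31e-2, Cu = 4.97e-3)
  expect_equal(round(hi(hqs), 2), 0.65)
  expect_equal(hi(c(Cd = 0, As = 0, Hg = 0, Cu = 0)), 0)
  expect_equal(hi(c(Cd = 0, As = 0.3, Hg = 0, Cu = 0)), 0.3)
  expect_gte(hi(hqs), max(hqs))
  expect_error(hi(hqs[c("Cd", "As")]), "Hg")
})

test_that("cancer risk follows EDI * CSF * 0.001 and TCR sums Cd + As", {
  expect_printed(cr(1.77e-2, CSF = 1.5), 2.66e-5)
  expect_printed(cr(4.13e-3, CSF = 6.1), 2.52e-5)
  expect_equal(cr(0, CSF = 1.5), 0)
  expect_error(cr(1, CSF = -1), "CSF")

  crs <- c(Cd = 2.52e-5, As = 2.66e-5)
  expect_equal(tcr(crs), 5.18e-5)
  expect_gte(tcr(crs), max(crs))
  expect_equal(tcr(c(Cd = 0, As = 1e-6)), 1e-6)
  expect_error(tcr(c(As = 1e-6)), "Cd")
})

test_that("shipped tox profiles differ only in Hg/Cu reference doses", {
  stated <- tox_profile("stated")
  tc <- tox_profile("table_consistent")
  for (el in c("Cd", "As")) {
    expect_equal(stated$elements$RfD[stated$elements$element == el],
                 tc$elements$RfD[tc$elements$element == el])
  }
  expect_equal(stated$elements$RfD[stated$elements$element == "Hg"],
               1e-4)
  expect_equal(tc$elements$RfD[tc$elements$element == "Hg"], 5e-4)
  expect_equal(stated$safety_factor, 10)
  expect_equal(stated$elements$carcinogen,
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("tox profiles round-trip through YAML", {
  p <- tox_profile("table_consistent")
  path <- tempfile(fileext = ".yaml")
  write_tox_profile(p, path)
  back <- read_tox_profile(path)
  expect_equal(back$elements, p$elements)
  expect_equal(back$safety_factor, 10)
  # the generic constructor dispatches on a .yaml path too
  expect_equal(tox_profile(path)$elements, p$elements)
})

test_that("risk_point assembles EDI/HQ/CR per element", {
  p <- tox_profile("stated")
  r <- risk_point("As", EF = 365, Ed = 70, IR = 6.7, C = 10, BA = 1,
                  AT = 365 * 70, W = 67, profile = p)
  expect_equal(r$EDI, 1)
  expect_equal(r$HQ, 10 * 0.001 / 0.0003)
  expect_equal(r$CR, 1.5e-3)
  r2 <- risk_point("Cu", EF = 365, Ed = 70, IR = 6.7, C = 10, BA = 1,
                   AT = 365 * 70, W = 67, profile = p)
  expect_true(is.na(r2$CR))
})
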