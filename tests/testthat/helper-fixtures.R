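# Shared fixtures and expectation helpers.

# Agreement with a value printed at finite precision: |x - printed|
# must not exceed `ulp` units in the printed value's last significant
# digit (e.g. printed 0.54 with ulp = 1 allows diffs up to 0.01).
# The last-digit unit is detected from the printed value itself.
printed_unit <- function(x) {
  for (d in 1:7) {
    u <- 10^(floor(log10(abs(x))) - d + 1)
    if (abs(x / u - round(x / u)) < 1e-8) return(u)
  }
  u
}

expect_printed <- function(computed, printed, ulp = 1) {
  unit <- printed_unit(printed)
  expect_lt(abs(computed - printed), ulp * unit * 1.02)
}

# A tiny valid sample table.
tiny_samples <- function() {
  data.frame(
    sample_id = c("s1", "s2"),
    origin = c("A", "A"),
    element = c("Cd", "Cd"),
    total_conc = c(1.0, 2.0),
    gastric_conc = c(0.2, 0.5),
    intestinal_conc = c(0.2, 0.36),
    stringsAsFactors = FALSE)
}

write_tiny_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

# All-fixed simulation config whose deterministic EDI is
# IR * C / W (continuous exposure), handy for exactness checks.
fixed_config <- function(C = 1, EF = 365, Ed = 70, IR = 1, W = 67,
                         n_iter = 100, seed = 1,
                         profile = tox_profile("stated")) {
  conc <- setNames(lapply(risk_elements(), function(e)
    fixed_value(C, paste0("C_", e))), risk_elements())
  simulation_config(conc_dists = conc,
                    ef_dist = fixed_value(EF, "EF"),
                    ir_dist = fixed_value(IR, "IR"),
                    sex = "male", n_iter = n_iter, seed = seed,
                    profile = profile, Ed = Ed, AT = 365 * 70, W = W)
}
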