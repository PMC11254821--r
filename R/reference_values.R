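## Published probabilistic summary values for the dried-earthworm
## exposure scenario this package's defaults emulate.  The mean and
## 90th-percentile EDIs act as *inputs* to regression checks of the
## deterministic kernel (HQ/HI/CR/TCR must map them onto the published
## risk numbers); they are reference data, not computed output.

#' Published exposure and risk summary for the default scenario
#'
#' Mean and 90th-percentile estimated daily intakes (ug/kg/day) per
#' element and sex from the published probabilistic assessment of
#' potentially toxic elements in dried earthworms, together with the
#' hazard quotients and cancer risks printed alongside them.  Used as a
#' fixed reference to verify that the hazard-quotient, hazard-index and
#' cancer-risk kernels reproduce the published deterministic relations.
#'
#' @return Data frame with columns `element`, `sex`, `edi_mean`,
#'   `edi_p90`, `hq_mean`, `hq_p90`, `cr_mean` (`NA` for the
#'   non-carcinogens Hg and Cu).
#' @export
reference_risk_table <- function() {
  data.frame(
    element = rep(c("Cd", "As", "Hg", "Cu"), each = 2),
    sex = rep(c("male", "female"), times = 4),
    edi_mean = c(4.13e-3, 3.76e-3, 1.77e-2, 1.63e-2,
                 6.65e-4, 5.97e-4, 1.99e-2, 1.83e-2),
    edi_p90 = c(1.19e-2, 1.04e-2, 5.34e-2, 4.71e-2,
                1.45e-3, 1.32e-3, 5.81e-2, 5.16e-2),
    hq_mean = c(4.13e-2, 3.76e-2, 0.59, 0.54,
                1.31e-2, 1.19e-2, 4.97e-3, 4.58e-3),
    hq_p90 = c(0.12, 0.10, 1.78, 1.57,
               2.89e-2, 2.64e-2, 1.45e-2, 1.29e-2),
    cr_mean = c(2.52e-5, 2.30e-5, 2.66e-5, 2.44e-5,
                NA_real_, NA_real_, NA_real_, NA_real_),
    stringsAsFactors = FALSE)
}

#' Published aggregate risk reference values
#'
#' Mean hazard index per sex and the male total cancer risk from the
#' published assessment.  (The published female TCR disagrees with the
#' sum of the published female cancer-risk means in its last digit and
#' is therefore not included as a reference.)
#'
#' @return Named list `hi_mean` (male/female), `tcr_mean_male`.
#' @export
reference_aggregates <- function() {
  list(hi_mean = c(male = 0.65, female = 0.59),
       tcr_mean_male = 5.18e-5)
}
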