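#' The neuropsychological test battery and composite membership
#'
#' Returns one row per test with its score orientation, theoretical domain,
#' and composite membership. The five composites are: immediate learning,
#' delayed recall, executive function, a three-test preclinical Alzheimer
#' cognitive composite (PACC3 = AVLT Total + Logical Memory II + Digit
#' Symbol), and a four-test computerized (CogState-style) global composite
#' (CPAL + GML-MPS + GML-CT + OCL). The MMSE and Clock Draw carry raw
#' clinical cut-offs but contribute to no composite.
#'
#' Timed or error-count scores (Trail Making B, CPAL errors, GML completion
#' time) are `lower_better`; they are sign-flipped before norming so that
#' higher z is always better performance.
#'
#' @return A data frame with columns `test`, `orientation`
#'   (`"higher_better"`/`"lower_better"`), `domain` (one of `immediate`,
#'   `delayed`, `executive`, `cogstate`, `global`), and logical membership
#'   columns `immediate`, `delayed`, `executive`, `pacc3`, `cogstate_global`.
#' @export
#' @examples
#' specs <- default_test_specs()
#' specs$test[specs$pacc3]
default_test_specs <- function() {
  s <- function(test, orientation, domain, imm = FALSE, del = FALSE,
                exe = FALSE, pacc = FALSE, cog = FALSE) {
    data.frame(test = test, orientation = orientation, domain = domain,
               immediate = imm, delayed = del, executive = exe,
               pacc3 = pacc, cogstate_global = cog)
  }
  rbind(
    s("avlt_total",    "higher_better", "immediate", imm = TRUE, pacc = TRUE),
    s("avlt_delayed",  "higher_better", "delayed",   del = TRUE),
    s("lm_i",          "higher_better", "immediate", imm = TRUE),
    s("lm_ii",         "higher_better", "delayed",   del = TRUE, pacc = TRUE),
    s("bvmt_total",    "higher_better", "immediate", imm = TRUE),
    s("bvmt_delayed",  "higher_better", "delayed",   del = TRUE),
    s("stroop_cw",     "higher_better", "executive", exe = TRUE),
    s("tmt_b",         "lower_better",  "executive", exe = TRUE),
    s("digit_symbol",  "higher_better", "executive", exe = TRUE, pacc = TRUE),
    s("mmse",          "higher_better", "global"),
    s("clock_draw",    "higher_better", "global"),
    s("cpal",          "lower_better",  "cogstate",  cog = TRUE),
    s("gml_mps",       "higher_better", "cogstate",  cog = TRUE),
    s("gml_ct",        "lower_better",  "cogstate",  cog = TRUE),
    s("ocl",           "higher_better", "cogstate",  cog = TRUE)
  )
}

COMPOSITE_NAMES <- c("immediate", "delayed", "executive", "pacc3",
                     "cogstate_global")

# Composites used as "domains" by the flagging algorithm and the actuarial
# multi-test MCI rule (the computerized battery is deliberately excluded:
# it is held out of status determination to avoid circularity).
STAGING_DOMAINS <- c("immediate", "delayed", "executive")

#' True score-generating model of the synthetic battery
#'
#' Per-test linear models on the oriented raw-score scale used by the
#' cohort generator: expected oriented score =
#' `level + age_slope * (age - 60) + sex_offset * sex +
#'  literacy_slope * (literacy - 100)`, with residual scale `sd`.
#' Values are chosen to mimic plausible raw-score ranges for each
#' instrument in a late-middle-aged cohort; clinical cut-off tests (MMSE,
#' Clock Draw, AVLT Delayed, Logical Memory II) sit roughly 3 residual SD
#' above their cut-offs for an unimpaired 65-year-old.
#'
#' @return Data frame keyed by `test` with columns `level`, `age_slope`,
#'   `sex_offset`, `literacy_slope`, `sd` (oriented scale).
#' @keywords internal
default_test_params <- function() {
  p <- function(test, level, age_slope, sex_offset, literacy_slope, sd) {
    data.frame(test = test, level = level, age_slope = age_slope,
               sex_offset = sex_offset, literacy_slope = literacy_slope,
               sd = sd)
  }
  rbind(
    p("avlt_total",   50.0, -0.35, 3.0, 0.15, 7.0),
    p("avlt_delayed", 11.0, -0.06, 0.7, 0.03, 1.9),
    p("lm_i",         28.0, -0.12, 1.5, 0.12, 5.5),
    p("lm_ii",        30.0, -0.10, 1.5, 0.12, 4.5),
    p("bvmt_total",   26.0, -0.20, 1.0, 0.06, 4.5),
    p("bvmt_delayed", 10.0, -0.07, 0.4, 0.02, 1.6),
    p("stroop_cw",    50.0, -0.35, 0.0, 0.10, 8.0),
    p("tmt_b",       -65.0, -0.90, 0.0, 0.25, 18.0),   # oriented = -seconds
    p("digit_symbol", 55.0, -0.40, 2.0, 0.12, 9.0),
    p("mmse",         28.9, -0.02, 0.1, 0.02, 0.7),
    p("clock_draw",    9.3, -0.01, 0.0, 0.01, 0.5),
    p("cpal",        -40.0, -0.50, 0.0, 0.10, 12.0),   # oriented = -errors
    p("gml_mps",       1.2, -0.008, 0.0, 0.002, 0.25),
    p("gml_ct",     -120.0, -1.00, 0.0, 0.20, 25.0),   # oriented = -seconds
    p("ocl",           1.0, -0.004, 0.02, 0.001, 0.12)
  )
}
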