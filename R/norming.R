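#' Fit robust internal regression norms
#'
#' Fits, per test, an ordinary-least-squares model of the oriented raw
#' score on age, sex and literacy (reading standard score) over a robust
#' subsample of visits — visits from participants believed cognitively
#' stable — so that impaired performance does not distort the normative
#' expectation. `lower_better` tests are sign-flipped before fitting, so
#' predictions and z-scores are always on a higher-is-better scale.
#'
#' @param visits Visit data frame (see [generate_cohort()] /
#'   [read_visits()]).
#' @param robust_mask Logical vector, one entry per visit row, selecting
#'   the robust fitting subsample.
#' @param specs Test specification table, default [default_test_specs()].
#' @param min_n Minimum robust fitting visits per test (default 50).
#' @return A `norm_model`: data frame with one row per test (`test`,
#'   `intercept`, `age_slope`, `sex_offset`, `literacy_slope`,
#'   `residual_sd`, `robust_n`) carrying the spec table as an attribute.
#' @export
fit_robust_norms <- function(visits, robust_mask,
                             specs = default_test_specs(), min_n = 50) {
  stopifnot(is.logical(robust_mask), length(robust_mask) == nrow(visits))
  sub <- visits[robust_mask, , drop = FALSE]
  for (p in c("age", "sex", "wrat3_std")) {
    v <- sub[[p]][!is.na(sub[[p]])]
    if (length(unique(v)) < 2)
      stop(sprintf("degenerate design: predictor '%s' is constant in the robust subsample", p),
           call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(specs)), function(j) {
    test <- specs$test[j]
    if (is.null(sub[[test]]))
      stop(sprintf("visits table has no column for test '%s'", test),
           call. = FALSE)
    y <- oriented_score(sub[[test]], specs$orientation[j])
    ok <- complete.cases(y, sub$age, sub$sex, sub$wrat3_std)
    if (sum(ok) < min_n)
      stop(sprintf("too few robust visits for test '%s' (%d < %d)",
                   test, sum(ok), min_n), call. = FALSE)
    fit <- lm(y ~ age + sex + wrat3_std, data = sub, subset = ok)
    rsd <- sqrt(sum(resid(fit)^2) / fit$df.residual)
    if (rsd < 1e-8)
      stop(sprintf("degenerate fit for test '%s': residual SD ~ 0", test),
           call. = FALSE)
    data.frame(test = test, intercept = coef(fit)[["(Intercept)"]],
               age_slope = coef(fit)[["age"]],
               sex_offset = coef(fit)[["sex"]],
               literacy_slope = coef(fit)[["wrat3_std"]],
               residual_sd = rsd, robust_n = sum(ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, specs = specs, class = c("norm_model", "data.frame"))
}

oriented_score <- function(x, orientation) {
  if (orientation == "lower_better") -x else x
}

#' Demographically adjusted z-scores
#'
#' Computes, for every visit row and every normed test,
#' `z = (oriented score - predicted score) / residual_sd`. Orientation is
#' applied before prediction, so a faster Trail Making B time yields a
#' higher z. Visits missing a demographic predictor get `NA` z-scores for
#' every test (no imputation); a missing raw score gives `NA` for that
#' test only.
#'
#' @param visits Visit data frame.
#' @param model A `norm_model` from [fit_robust_norms()].
#' @return Numeric matrix, rows matching `visits`, one column per test.
#' @export
zscore <- function(visits, model) {
  specs <- attr(model, "specs")
  z <- matrix(NA_real_, nrow(visits), nrow(model),
              dimnames = list(NULL, model$test))
  demo_ok <- complete.cases(visits$age, visits$sex, visits$wrat3_std)
  for (j in seq_len(nrow(model))) {
    test <- model$test[j]
    orient <- specs$orientation[specs$test == test]
    y <- oriented_score(visits[[test]], orient)
    pred <- model$intercept[j] + model$age_slope[j] * visits$age +
      model$sex_offset[j] * visits$sex +
      model$literacy_slope[j] * visits$wrat3_std
    zj <- (y - pred) / model$residual_sd[j]
    zj[!demo_ok] <- NA_real_
    z[, j] <- zj
  }
  z
}

#' Mean z-score per composite
#'
#' Averages the z-scores of the tests contributing to each composite.
#' A composite is `NA` when fewer than its required number of tests are
#' present: all listed tests for the pencil-and-paper composites, at least
#' 3 of 4 for the computerized global composite.
#'
#' @param z z-score matrix from [zscore()] (or a single named vector).
#' @param specs Test specification table.
#' @return Matrix with one column per composite (`immediate`, `delayed`,
#'   `executive`, `pacc3`, `cogstate_global`) plus attribute `"n_tests"`
#'   giving contributing-test counts.
#' @export
composite_zscores <- function(z, specs = default_test_specs()) {
  if (is.null(dim(z))) z <- matrix(z, 1, dimnames = list(NULL, names(z)))
  unknown <- setdiff(specs$test, colnames(z))
  if (length(unknown))
    stop("z matrix lacks tests named in specs: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- matrix(NA_real_, nrow(z), length(COMPOSITE_NAMES),
                dimnames = list(NULL, COMPOSITE_NAMES))
  counts <- out
  for (comp in COMPOSITE_NAMES) {
    members <- specs$test[specs[[comp]]]
    need <- if (comp == "cogstate_global") 3L else length(members)
    zi <- z[, members, drop = FALSE]
    k <- rowSums(!is.na(zi))
    m <- rowMeans(zi, na.rm = TRUE)
    m[k < need] <- NA_real_
    out[, comp] <- m
    counts[, comp] <- k
  }
  attr(out, "n_tests") <- counts
  out
}

#' Standard-score composites (mean 100, SD 15)
#'
#' Converts composite mean z-scores to the standard-score metric:
#' `100 + 15 * mean_z / scale`. With the default `scale = 1` this is the
#' plain affine conversion (all contributing z at -1 gives 85). The
#' norming pipeline ([robust_norms()]) instead supplies per-composite
#' scales fitted as the SD of the mean z over the robust subsample, so
#' that reported composites genuinely have SD 15 there.
#'
#' @param z z-score matrix (or single named vector) from [zscore()].
#' @param specs Test specification table.
#' @param scale Named per-composite divisors, recycled if length 1.
#' @return Matrix of composite standard scores.
#' @export
#' @examples
#' z <- setNames(rep(-1, 15), default_test_specs()$test)
#' composites(z)  # every composite at 85
composites <- function(z, specs = default_test_specs(), scale = 1) {
  cz <- composite_zscores(z, specs)
  if (length(scale) == 1) scale <- setNames(rep(scale, ncol(cz)),
                                            colnames(cz))
  if (any(scale[colnames(cz)] <= 0, na.rm = TRUE))
    stop("composite scale divisors must be positive", call. = FALSE)
  out <- 100 + 15 * sweep(cz, 2, scale[colnames(cz)], "/")
  attr(out, "n_tests") <- attr(cz, "n_tests")
  out
}

#' Two-pass robust norming pipeline
#'
#' Constructs the robust subsample and fits the final internal norms in a
#' fixed two-pass scheme: (1) flag visits on raw clinical cut-offs and
#' informant criteria alone (no norms needed) and fit preliminary norms on
#' participants never flagged; (2) stage every visit with the preliminary
#' norms and refit on participants never assigned CU-D, MCI or dementia.
#' Per-composite standard-score scales (SD of the composite mean z over
#' the final robust subsample) are fitted alongside and stored as the
#' `"composite_scale"` attribute.
#'
#' @param visits Visit data frame.
#' @param specs,thresholds,min_n Battery specification, flagging
#'   thresholds and minimum robust sample size.
#' @return A `norm_model` (as [fit_robust_norms()]) with attributes
#'   `"composite_scale"` and `"robust_mask"`.
#' @export
robust_norms <- function(visits, specs = default_test_specs(),
                         thresholds = flag_thresholds(), min_n = 50) {
  ## pass 1: raw + informant criteria only
  pre <- flag_visits(visits, z = NULL, thresholds = thresholds,
                     specs = specs)
  bad1 <- unique(visits$participant_id[pre$flagged])
  mask1 <- !(visits$participant_id %in% bad1)
  norms1 <- fit_robust_norms(visits, mask1, specs, min_n)
  ## pass 2: stage with preliminary norms, drop ever-impaired participants
  staged <- stage_visits(visits, norms1, thresholds)
  bad2 <- unique(staged$participant_id[staged$label != "CU_S"])
  mask2 <- !(visits$participant_id %in% bad2)
  norms2 <- fit_robust_norms(visits, mask2, specs, min_n)
  cz <- composite_zscores(zscore(visits[mask2, , drop = FALSE], norms2),
                          specs)
  scales <- apply(cz, 2, sd, na.rm = TRUE)
  attr(norms2, "composite_scale") <- scales
  attr(norms2, "robust_mask") <- mask2
  norms2
}

#' @export
print.norm_model <- function(x, ...) {
  cat(sprintf("<norm_model> %d tests, robust n %d-%d\n", nrow(x),
              min(x$robust_n), max(x$robust_n)))
  print.data.frame(cbind(x[1:4] , round(x[5:7], 3)), ...)
  invisible(x)
}
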