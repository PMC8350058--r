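#' Settings for Logan graphical analysis
#'
#' @param k2_prime Reference-region efflux constant in 1/min (default
#'   0.149, the cerebellum gray-matter convention for PiB).
#' @param t_star Start of the linear fitting window in minutes (default
#'   35).
#' @return A `logan_settings` list.
#' @export
logan_settings <- function(k2_prime = 0.149, t_star = 35) {
  if (k2_prime <= 0) stop("k2_prime must be positive", call. = FALSE)
  structure(list(k2_prime = k2_prime, t_star = t_star),
            class = "logan_settings")
}

#' Logan graphical distribution volume ratio
#'
#' Reference-region Logan analysis: for each frame T with mid-time at or
#' after `t_star`, the ordinate is `int_0^T C_t dt / C_t(T)` and the
#' abscissa `[int_0^T C_ref dt + C_ref(T)/k2'] / C_t(T)`; the DVR is the
#' ordinary-least-squares slope over those frames. Integrals use the
#' trapezoid rule from time 0 (a zero-activity point at t = 0 is
#' prepended).
#'
#' @param tac A `tac_pair` (see [generate_tac_pair()]) or any list with
#'   `times`, `target_activity`, `reference_activity`.
#' @param settings A [logan_settings()] object.
#' @return The fitted DVR (slope), with the linear-window frame count as
#'   attribute `"n_frames"`.
#' @export
logan_dvr <- function(tac, settings = logan_settings()) {
  t <- tac$times; ct <- tac$target_activity; cr <- tac$reference_activity
  if (length(t) != length(ct) || length(t) != length(cr) ||
      any(diff(t) <= 0) || any(ct < 0) || any(cr < 0))
    stop("invalid TAC pair: need equal-length curves on increasing times",
         call. = FALSE)
  if (settings$t_star > max(t))
    stop("t_star lies beyond the scan duration", call. = FALSE)
  int_t <- cumtrapz0(t, ct)
  int_r <- cumtrapz0(t, cr)
  use <- t >= settings$t_star
  if (sum(use) < 3)
    stop("fewer than 3 frames at or after t_star", call. = FALSE)
  if (any(ct[use] <= 0))
    stop("zero target activity within the Logan window", call. = FALSE)
  y <- int_t[use] / ct[use]
  x <- (int_r[use] + cr[use] / settings$k2_prime) / ct[use]
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  structure(slope, n_frames = sum(use))
}

# cumulative trapezoid integral from time zero (prepending a zero sample)
cumtrapz0 <- function(t, y) {
  tt <- c(0, t); yy <- c(0, y)
  cumsum(c(0, diff(tt) * (head(yy, -1) + yy[-1]) / 2))[-1]
}

#' Population amyloid trajectory model
#'
#' A rising sigmoid mapping age to expected global PiB DVR for an
#' amyloid accumulator:
#' `DVR(age) = floor + (ceiling - floor) * plogis(rate * (age - midpoint))`.
#' Used to convert an observed DVR into an estimated age of reaching the
#' positivity threshold by shifting the midpoint so the curve passes
#' through the observation.
#'
#' @param floor,ceiling DVR asymptotes (floor < threshold < ceiling).
#' @param rate Slope parameter in 1/years (default 0.15).
#' @param pib_threshold Positivity threshold (default 1.2).
#' @return A `trajectory_model` list.
#' @export
trajectory_model <- function(floor = 1.0, ceiling = 2.2, rate = 0.15,
                             pib_threshold = 1.2) {
  if (!(floor < pib_threshold && pib_threshold < ceiling) || rate <= 0)
    stop("need floor < pib_threshold < ceiling and rate > 0", call. = FALSE)
  structure(list(floor = floor, ceiling = ceiling, rate = rate,
                 pib_threshold = pib_threshold),
            class = "trajectory_model")
}

#' Estimate the age of reaching amyloid positivity
#'
#' Anchors the trajectory sigmoid through the observation
#' `(scan_age, observed_dvr)` by shifting its midpoint, then solves
#' `DVR(age*) = pib_threshold` for the onset age by monotone root
#' bracketing (tolerance 1e-6 years). An observation exactly at the
#' threshold returns `scan_age`; observations at or outside the sigmoid
#' range are an estimation error.
#'
#' @param observed_dvr Observed global PiB DVR, strictly inside
#'   `(floor, ceiling)`.
#' @param scan_age Age at the PET scan, years.
#' @param model A [trajectory_model()].
#' @return Estimated onset age in years.
#' @export
estimate_onset_age <- function(observed_dvr, scan_age,
                               model = trajectory_model()) {
  if (observed_dvr <= model$floor || observed_dvr >= model$ceiling)
    stop("observed_dvr outside the trajectory range; onset unknown",
         call. = FALSE)
  frac_obs <- (observed_dvr - model$floor) / (model$ceiling - model$floor)
  mid <- scan_age - qlogis(frac_obs) / model$rate
  f <- function(age) model$floor + (model$ceiling - model$floor) *
    plogis(model$rate * (age - mid)) - model$pib_threshold
  lo <- mid - 60 / model$rate * 1  # generous monotone bracket
  hi <- mid + 60 / model$rate * 1
  uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' PiB positivity and chronicity
#'
#' Sets the positivity flag (`global_pib_dvr >= threshold`) and the
#' chronicity — years since crossing the positivity threshold, computed
#' as assessment age minus estimated onset age. Negative chronicity means
#' estimated time until positivity. With `onset_age = NULL` the onset is
#' estimated from the observed DVR via [estimate_onset_age()]; records
#' whose DVR lies outside the trajectory range get `NA` chronicity.
#'
#' @param pet PET data frame with `global_pib_dvr` (and `scan_age` when
#'   onsets are estimated).
#' @param assessment_age Age at the cognitive assessment (vector or
#'   scalar); defaults to `scan_age`.
#' @param onset_age Known onset ages, or `NULL` to estimate.
#' @param model A [trajectory_model()]; its threshold defines positivity.
#' @return `pet` with columns `pib_positive` and `chronicity` added.
#' @export
pib_status_and_chronicity <- function(pet, assessment_age = NULL,
                                      onset_age = NULL,
                                      model = trajectory_model()) {
  if (is.null(pet$global_pib_dvr))
    stop("pet must contain global_pib_dvr", call. = FALSE)
  if (is.null(assessment_age)) assessment_age <- pet$scan_age
  pet$pib_positive <- !is.na(pet$global_pib_dvr) &
    pet$global_pib_dvr >= model$pib_threshold
  if (is.null(onset_age)) {
    onset_age <- vapply(seq_len(nrow(pet)), function(i) {
      dvr <- pet$global_pib_dvr[i]
      if (is.na(dvr) || dvr <= model$floor || dvr >= model$ceiling)
        return(NA_real_)
      estimate_onset_age(dvr, pet$scan_age[i], model)
    }, numeric(1))
  }
  pet$chronicity <- assessment_age - onset_age
  pet
}

#' Data-derived tau SUVR positivity thresholds
#'
#' Threshold per region = mean + 2 sample standard deviations of the
#' SUVRs in the PiB-negative subset; positivity is then strict
#' (`SUVR > threshold`).
#'
#' @param pet PET data frame with `pib_positive` and `suvr_*` columns.
#' @param regions Region names (default entorhinal, hippocampus).
#' @param min_negative Minimum PiB-negative scans per region (default
#'   10); fewer leaves that region's threshold `NA`.
#' @return Named numeric vector of thresholds.
#' @export
tau_thresholds <- function(pet, regions = c("entorhinal", "hippocampus"),
                           min_negative = 10) {
  if (is.null(pet$pib_positive))
    stop("pet must contain pib_positive (run pib_status_and_chronicity)",
         call. = FALSE)
  vapply(regions, function(r) {
    v <- pet[[paste0("suvr_", r)]][!pet$pib_positive]
    v <- v[!is.na(v)]
    if (length(v) < min_negative) return(NA_real_)
    mean(v) + 2 * sd(v)
  }, numeric(1))
}

#' Compare PET biomarkers across cognitive status groups
#'
#' For each continuous quantity (global PiB DVR, chronicity, regional tau
#' SUVR): Kruskal-Wallis omnibus with pairwise Wilcoxon follow-ups and
#' Cliff's delta per pair. For each positivity flag (PiB, per-region
#' tau): Fisher's exact omnibus with pairwise follow-ups. Groups without
#' PET data are dropped with a warning.
#'
#' @param pet PET data frame (after [pib_status_and_chronicity()]).
#' @param status Cognitive status at the assessment nearest each scan,
#'   aligned with `pet` rows.
#' @param regions Tau regions to analyse.
#' @param alpha Omnibus gate for follow-ups.
#' @return Tidy data frame: `analysis`, `groups`, `estimate`, `p`,
#'   `effect_size`, `magnitude`.
#' @export
biomarker_group_comparison <- function(pet, status,
                                       regions = c("entorhinal",
                                                   "hippocampus"),
                                       alpha = 0.05) {
  status <- as.factor(status)
  empty <- levels(status)[table(status) == 0]
  if (length(empty))
    warning("dropping empty status group(s): ",
            paste(empty, collapse = ", "))
  status <- droplevels(status)
  thr <- tau_thresholds(pet, regions)
  cont <- c(global_pib_dvr = "global_pib_dvr", chronicity = "chronicity",
            setNames(paste0("suvr_", regions), paste0("suvr_", regions)))
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- data.frame(...)
  for (qn in names(cont)) {
    v <- pet[[cont[[qn]]]]
    if (is.null(v)) next
    gc <- group_compare(v, status, "kruskal_wallis", alpha)
    add(analysis = qn, groups = "omnibus", estimate = NA_real_,
        p = gc$omnibus_p, effect_size = NA_real_, magnitude = "")
    if (!is.null(gc$pairwise)) {
      for (i in seq_len(nrow(gc$pairwise))) {
        g1 <- gc$pairwise$group1[i]; g2 <- gc$pairwise$group2[i]
        d <- cliffs_delta(v[status == g1], v[status == g2])
        add(analysis = qn, groups = paste(g1, "vs", g2),
            estimate = d$estimate, p = gc$pairwise$p[i],
            effect_size = d$estimate, magnitude = d$magnitude_label)
      }
    }
  }
  flags <- c(pib_positive = "pib_positive",
             setNames(paste0("tau_positive_", regions),
                      paste0("tau_positive_", regions)))
  pet2 <- pet
  for (r in regions)
    pet2[[paste0("tau_positive_", r)]] <-
      if (is.na(thr[[r]])) NA else pet[[paste0("suvr_", r)]] > thr[[r]]
  for (qn in names(flags)) {
    f <- pet2[[flags[[qn]]]]
    if (is.null(f) || all(is.na(f))) next
    tab <- table(status[!is.na(f)], f[!is.na(f)])
    if (ncol(tab) < 2 || nrow(tab) < 2) next
    gc <- group_compare(tab, family = "fisher_exact", alpha = alpha)
    add(analysis = qn, groups = "omnibus", estimate = NA_real_,
        p = gc$omnibus_p, effect_size = NA_real_, magnitude = "")
    if (!is.null(gc$pairwise))
      for (i in seq_len(nrow(gc$pairwise)))
        add(analysis = qn,
            groups = paste(gc$pairwise$group1[i], "vs",
                           gc$pairwise$group2[i]),
            estimate = NA_real_, p = gc$pairwise$p[i],
            effect_size = NA_real_, magnitude = "")
  }
  out <- do.call(rbind, rows)
  attr(out, "tau_thresholds") <- thr
  out
}
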