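#' Configuration of the synthetic longitudinal cohort
#'
#' Builds the full parameterization of the synthetic-cohort generator:
#' demographics, visit schedule, latent cognitive-state dynamics, the
#' state-dependent score model, informant-report model, and the amyloid/tau
#' biomarker model. All defaults together constitute the calibrated study
#' conditions: a late-middle-aged, risk-enriched cohort enrolled around age
#' 54 with follow-up visits at roughly 2-year intervals, whose assigned
#' statuses reproduce the observed progression (about 2.9% from a CU-S
#' baseline, about 13.5% from a CU-D baseline) and per-visit CU-D reversion
#' (about 48%).
#'
#' @param n_participants Number of participants (default 1229).
#' @param baseline_age_mean,baseline_age_sd Baseline age distribution in
#'   years (default 54, 6.6).
#' @param female_fraction Proportion coded `sex = 1` (default 0.70).
#' @param literacy_mean,literacy_sd Reading-recognition standard score
#'   distribution (default 106, 9).
#' @param visit_interval_mean,visit_interval_sd,visit_interval_min Visit
#'   interval distribution in years, truncated below (default 2.3, 0.3, 1).
#' @param n_visits_max Maximum visits per participant (default 6; minimum 2).
#' @param visit_count_weights Sampling weights for total visit counts
#'   `2:n_visits_max` (default mirrors the observed most-recent-visit
#'   distribution 131/183/325/481/234).
#' @param baseline_state_probs Baseline latent-state distribution over
#'   `CU_S, CU_D, MCI, DEMENTIA` (default 1110/1229, 119/1229, 0, 0:
#'   clinically impaired participants are excluded at enrollment).
#' @param transition_matrix Per-interval latent transition probabilities
#'   (rows `CU_S, CU_D, MCI, DEMENTIA`; each row sums to 1).
#' @param state_score_shift 4 x 5 matrix of per-domain mean z shifts by
#'   latent state (domains `immediate, delayed, executive, cogstate,
#'   global`).
#' @param cu_d_profile Focal-deficit profile for the CU_D state, or `NULL`
#'   to use the uniform `state_score_shift["CU_D", ]` row. See Details.
#' @param trait_persistence Share of per-test z variance that is a stable
#'   participant-test trait rather than visit noise (default 0.78,
#'   a 2-year test-retest correlation typical of adjusted scores).
#' @param informant_model Per-state informant/self-report model; see
#'   Details.
#' @param amyloid_model Accumulator fractions, onset-age distributions and
#'   the population DVR-vs-age sigmoid; see Details.
#' @param tau_model Per-state, per-region tau SUVR means/SDs.
#' @param tac Kinetic constants for synthetic time-activity curves.
#' @param pet_fraction Fraction of participants with PET (default 0.21).
#' @param test_specs,test_params Battery definition and true generating
#'   models; defaults [default_test_specs()], [default_test_params()].
#' @param seed Integer seed; every random draw flows from it.
#'
#' @details
#' The CU_D state is generated with a focal-deficit profile rather than a
#' uniform shift: each CU_D participant has one affected memory domain and
#' within it one focal test carrying a deep deficit (`focal_shift`, default
#' -3.6 z), with mild shifts elsewhere. This mirrors the subclinical
#' phenotype of an isolated, reproducible low score, and it is what lets a
#' composite-based flag detect CU_D without the multi-test MCI rule firing.
#'
#' `informant_model` holds per-state probabilities of an abnormal CDR/QDRS
#' rating, binomial deficit rates for the 16-point IADL, Poisson excess for
#' the IQCODE above its no-change score of 48, self-report distributions,
#' and a `persistence` weight: informant propensities are participant-level
#' latents, so abnormal ratings recur across visits.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_participants = 1229,
                       baseline_age_mean = 54,
                       baseline_age_sd = 6.6,
                       female_fraction = 0.70,
                       literacy_mean = 106,
                       literacy_sd = 9,
                       visit_interval_mean = 2.3,
                       visit_interval_sd = 0.3,
                       visit_interval_min = 1,
                       n_visits_max = 6,
                       visit_count_weights = c(131, 183, 325, 481, 234),
                       baseline_state_probs = c(CU_S = 1110 / 1229,
                                                CU_D = 119 / 1229,
                                                MCI = 0, DEMENTIA = 0),
                       transition_matrix = default_transition_matrix(),
                       state_score_shift = default_state_score_shift(),
                       cu_d_profile = default_cu_d_profile(),
                       trait_persistence = 0.78,
                       informant_model = default_informant_model(),
                       amyloid_model = default_amyloid_model(),
                       tau_model = default_tau_model(),
                       tac = default_tac_settings(),
                       pet_fraction = 0.21,
                       test_specs = default_test_specs(),
                       test_params = default_test_params(),
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_transition_matrix <- function() {
  m <- rbind(CU_S     = c(0.979, 0.020, 0.001, 0.000),
             CU_D     = c(0.160, 0.740, 0.100, 0.000),
             MCI      = c(0.209, 0.302, 0.389, 0.100),
             DEMENTIA = c(0.000, 0.000, 0.050, 0.950))
  colnames(m) <- STATUS_LEVELS
  m
}

#' @rdname sim_config
#' @export
default_state_score_shift <- function() {
  m <- rbind(CU_S     = c(0, 0, 0, 0, 0),
             CU_D     = c(-0.35, -0.35, -0.35, -0.40, -0.30),
             MCI      = c(-2.0, -2.1, -0.9, -0.55, -1.5),
             DEMENTIA = c(-3.0, -3.2, -1.8, -1.00, -3.0))
  colnames(m) <- c("immediate", "delayed", "executive", "cogstate", "global")
  m
}

#' @rdname sim_config
#' @export
default_cu_d_profile <- function() {
  list(
    focal_shift = -3.6,          # z shift of the focal test
    within_domain_shift = -0.15, # other tests of the affected domain
    # candidate focal tests per affected memory domain; only tests without a
    # raw clinical cut-off, so an isolated subclinical deficit does not
    # trip a clinical-threshold criterion by construction
    focal_tests = list(
      immediate = c("avlt_total", "lm_i", "bvmt_total"),
      delayed = "bvmt_delayed"
    )
  )
}

#' @rdname sim_config
#' @export
default_informant_model <- function() {
  list(
    cdr_abnormal_prob = c(CU_S = 0.031, CU_D = 0.124, MCI = 0.42,
                          DEMENTIA = 0.90),
    dementia_cdr1_prob = 0.85,   # abnormal dementia ratings reach CDR >= 1
    iadl_deficit_prob = c(CU_S = 0.015, CU_D = 0.03, MCI = 0.06,
                          DEMENTIA = 0.25),
    iqcode_lambda = c(CU_S = 0.3, CU_D = 1.0, MCI = 3.0, DEMENTIA = 8.0),
    persistence = 0.90,
    self_memory_probs = rbind(   # yes / dont_know / no
      CU_S = c(0.239, 0.188, 0.573),
      CU_D = c(0.269, 0.227, 0.504),
      MCI = c(0.333, 0.286, 0.381),
      DEMENTIA = c(0.45, 0.25, 0.30)),
    likert_mean = c(CU_S = 5.3, CU_D = 5.0, MCI = 4.3, DEMENTIA = 3.5),
    likert_sd = 1.1
  )
}

#' @rdname sim_config
#' @export
default_amyloid_model <- function() {
  list(
    # accumulator probability and onset-age distribution by last latent state
    accumulator_prob = c(CU_S = 0.35, CU_D = 0.55, MCI = 0.80,
                         DEMENTIA = 0.90),
    onset_age_mean = c(CU_S = 68, CU_D = 66, MCI = 60, DEMENTIA = 56),
    onset_age_sd = c(CU_S = 9, CU_D = 9, MCI = 8, DEMENTIA = 8),
    floor = 1.0, ceiling = 2.2, rate = 0.15,  # population DVR-age sigmoid
    nonaccumulator_dvr_mean = 1.05,
    nonaccumulator_dvr_sd = 0.045,
    dvr_noise_sd = 0.02,
    pib_threshold = 1.2,
    scan_age_jitter_sd = 1.0
  )
}

#' @rdname sim_config
#' @export
default_tau_model <- function() {
  list(
    entorhinal = list(mean = c(CU_S = 1.02, CU_D = 1.05, MCI = 1.65,
                               DEMENTIA = 1.90),
                      sd = c(CU_S = 0.10, CU_D = 0.11, MCI = 0.40,
                             DEMENTIA = 0.45)),
    hippocampus = list(mean = c(CU_S = 0.90, CU_D = 0.93, MCI = 1.22,
                                DEMENTIA = 1.45),
                       sd = c(CU_S = 0.08, CU_D = 0.09, MCI = 0.22,
                              DEMENTIA = 0.30))
  )
}

#' @rdname sim_config
#' @export
default_tac_settings <- function() {
  list(
    frame_durations = c(rep(2, 5), rep(5, 12)),  # minutes; 0-70 min dynamic
    k1_ref = 0.50,    # reference-region influx, mL/min/g
    k2_ref = 0.149,   # reference efflux; equals the Logan k2' convention
    k2_target = 0.12, # target-region efflux, per minute
    input_tau = 2.0   # plasma input C_p(t) = t * exp(-t / input_tau)
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$n_participants) || cfg$n_participants <= 0)
    stop("n_participants must be a positive count", call. = FALSE)
  if (cfg$baseline_age_sd <= 0 || cfg$visit_interval_sd <= 0)
    stop("baseline_age_sd and visit_interval_sd must be > 0", call. = FALSE)
  if (cfg$n_visits_max < 2)
    stop("n_visits_max must be at least 2", call. = FALSE)
  tm <- cfg$transition_matrix
  if (!is.matrix(tm) || nrow(tm) != 4 || ncol(tm) != 4)
    stop("transition_matrix must be 4 x 4 over CU_S, CU_D, MCI, DEMENTIA",
         call. = FALSE)
  if (any(tm < 0) || any(tm > 1))
    stop("transition_matrix entries must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(tm) - 1) > 1e-12))
    stop("every transition_matrix row must sum to 1 (tolerance 1e-12)",
         call. = FALSE)
  if (length(cfg$visit_count_weights) != cfg$n_visits_max - 1)
    stop("visit_count_weights must have length n_visits_max - 1",
         call. = FALSE)
  if (abs(sum(cfg$baseline_state_probs) - 1) > 1e-8)
    stop("baseline_state_probs must sum to 1", call. = FALSE)
  if (cfg$trait_persistence < 0 || cfg$trait_persistence >= 1)
    stop("trait_persistence must lie in [0, 1)", call. = FALSE)
  if (cfg$pet_fraction < 0 || cfg$pet_fraction > 1)
    stop("pet_fraction must lie in [0, 1]", call. = FALSE)
  am <- cfg$amyloid_model
  if (!(am$floor < am$pib_threshold && am$pib_threshold < am$ceiling))
    stop("amyloid model requires floor < pib_threshold < ceiling",
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  participants: %d, visits <= %d, seed %d\n",
              x$n_participants, x$n_visits_max, x$seed))
  cat(sprintf("  baseline age %.1f (SD %.1f), interval %.1f y, %.0f%% female\n",
              x$baseline_age_mean, x$baseline_age_sd,
              x$visit_interval_mean, 100 * x$female_fraction))
  cat("  transition matrix (per interval):\n")
  print(round(x$transition_matrix, 3))
  invisible(x)
}
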