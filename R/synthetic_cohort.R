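#' Generate a synthetic longitudinal cohort
#'
#' Simulates participants through latent cognitive states
#' (`CU_S, CU_D, MCI, DEMENTIA`) evolving as a first-order Markov chain per
#' visit interval, and draws everything downstream of the latent state:
#' raw neuropsychological scores from the same demographic model the
#' norming module fits (prediction + state shift + noise, with a stable
#' participant-test trait component), informant and self-report ratings
#' from per-state persistent propensities, and per-participant amyloid/tau
#' PET records. The latent state is carried in the output as generator
#' ground truth and is never used by the staging pipeline.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `synthetic_cohort`: a list with
#'   \describe{
#'     \item{visits}{long-format data frame, one row per participant-visit,
#'       with demographics, one column per raw test, informant/self
#'       ratings, and `latent_state`.}
#'     \item{pet}{one row per scanned participant: `participant_id`,
#'       `scan_age`, `global_pib_dvr`, `suvr_entorhinal`,
#'       `suvr_hippocampus`, plus generator truth columns
#'       `is_accumulator`, `true_onset_age`, `last_latent_state`.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 50, seed = 7)
#' coh <- generate_cohort(cfg)
#' head(coh$visits[, 1:6])
generate_cohort <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_participants)
  specs <- config$test_specs
  params <- config$test_params[match(config$test_specs$test,
                                     config$test_params$test), ]
  if (anyNA(params$test))
    stop("test_params must cover every test in test_specs", call. = FALSE)

  ## ---- participant-level draws (fixed order for reproducibility) ----
  id <- sprintf("P%05d", seq_len(n))
  age0 <- rnorm(n, config$baseline_age_mean, config$baseline_age_sd)
  sex <- as.integer(runif(n) < config$female_fraction)
  lit <- round(rnorm(n, config$literacy_mean, config$literacy_sd), 1)
  kmax <- config$n_visits_max
  nvis <- if (kmax == 2) rep(2L, n) else
    sample(2:kmax, n, replace = TRUE, prob = config$visit_count_weights)
  base_state <- sample(STATUS_LEVELS, n, replace = TRUE,
                       prob = config$baseline_state_probs)
  traits <- matrix(rnorm(n * nrow(specs)), n) *
    sqrt(config$trait_persistence)
  inf_latent <- matrix(rnorm(n * 3), n)  # cdr, iadl, iqcode propensities
  prof <- config$cu_d_profile
  if (!is.null(prof)) {
    focal_domain <- sample(names(prof$focal_tests), n, replace = TRUE)
    focal_test <- vapply(focal_domain, function(d) {
      cand <- prof$focal_tests[[d]]
      if (length(cand) == 1) cand else sample(cand, 1)
    }, character(1))
  }

  ## ---- latent chain and visit ages ----
  state <- matrix(NA_character_, n, kmax)
  state[, 1] <- base_state
  cum_tm <- t(apply(config$transition_matrix, 1, cumsum))
  for (v in 2:kmax) {
    u <- runif(n)
    cur <- status_rank(state[, v - 1])
    state[, v] <- STATUS_LEVELS[rowSums(u > cum_tm[cur, , drop = FALSE]) + 1]
  }
  intervals <- matrix(pmax(config$visit_interval_min,
                           rnorm(n * (kmax - 1), config$visit_interval_mean,
                                 config$visit_interval_sd)), n)
  if (kmax > 2)
    for (v in 2:(kmax - 1)) intervals[, v] <- intervals[, v - 1] +
      intervals[, v]
  ages <- cbind(age0, age0 + intervals)

  ## ---- expand to visit rows ----
  row_p <- rep(seq_len(n), nvis)            # participant index per visit row
  row_v <- unlist(lapply(nvis, seq_len), use.names = FALSE)
  N <- length(row_p)
  idx <- cbind(row_p, row_v)
  v_state <- state[idx]
  v_rank <- status_rank(v_state)
  v_age <- round(ages[idx], 2)
  v_sex <- sex[row_p]
  v_lit <- lit[row_p]

  ## ---- per-test z and raw scores ----
  sqrt_p <- sqrt(config$trait_persistence)
  sqrt_e <- sqrt(1 - config$trait_persistence)
  shift_tab <- config$state_score_shift
  scores <- matrix(NA_real_, N, nrow(specs),
                   dimnames = list(NULL, specs$test))
  for (j in seq_len(nrow(specs))) {
    test <- specs$test[j]
    dom <- specs$domain[j]
    sh <- shift_tab[v_rank, dom]
    if (!is.null(prof)) {
      is_cud <- v_state == "CU_D"
      in_focal_dom <- is_cud & focal_domain[row_p] == dom
      sh[in_focal_dom] <- prof$within_domain_shift
      sh[in_focal_dom & focal_test[row_p] == test] <- prof$focal_shift
    }
    z <- sh + sqrt_p * traits[row_p, j] + sqrt_e * rnorm(N)
    pred <- params$level[j] + params$age_slope[j] * (v_age - 60) +
      params$sex_offset[j] * v_sex +
      params$literacy_slope[j] * (v_lit - 100)
    oriented <- pred + z * params$sd[j]
    scores[, j] <- round(
      if (specs$orientation[j] == "lower_better") -oriented else oriented, 3)
  }

  ## ---- informant and self reports ----
  im <- config$informant_model
  wi <- im$persistence
  we <- sqrt(1 - wi^2)
  uu <- pnorm(wi * inf_latent[row_p, ] + we * matrix(rnorm(N * 3), N))
  cdr_ab <- uu[, 1] > 1 - im$cdr_abnormal_prob[v_rank]
  cdr1 <- runif(N) < im$dementia_cdr1_prob
  cdr <- ifelse(cdr_ab, ifelse(v_state == "DEMENTIA" & cdr1, 1, 0.5), 0)
  qdrs <- cdr  # global ratings are reported jointly
  iadl <- 16L - qbinom(uu[, 2], 16, im$iadl_deficit_prob[v_rank])
  iqcode <- pmin(80L, 48L + qpois(uu[, 3], im$iqcode_lambda[v_rank]))
  smp_u <- runif(N)
  smp_cum <- t(apply(im$self_memory_probs, 1, cumsum))
  smp <- c("yes", "dont_know", "no")[
    rowSums(smp_u > smp_cum[v_rank, , drop = FALSE]) + 1]
  likert <- pmin(7L, pmax(1L, as.integer(round(
    im$likert_mean[v_rank] + im$likert_sd * rnorm(N)))))

  visits <- data.frame(participant_id = id[row_p], visit_index = row_v,
                       age = v_age, sex = v_sex, wrat3_std = v_lit,
                       scores, cdr_global = cdr, qdrs_global = qdrs,
                       iadl = iadl, iqcode = iqcode,
                       self_memory_problem = smp,
                       self_memory_likert = likert,
                       latent_state = v_state)
  rownames(visits) <- NULL

  ## ---- PET records ----
  has_pet <- runif(n) < config$pet_fraction
  am <- config$amyloid_model
  last_state <- state[cbind(seq_len(n), nvis)]
  last_rank <- status_rank(last_state)
  acc <- runif(n) < am$accumulator_prob[last_rank]
  onset <- rnorm(n, am$onset_age_mean[last_rank], am$onset_age_sd[last_rank])
  scan_age <- round(ages[cbind(seq_len(n), nvis)] +
                      rnorm(n, 0, am$scan_age_jitter_sd), 2)
  dvr_true <- ifelse(acc, amyloid_dvr_at_age(scan_age, onset, am),
                     pmax(0.9, rnorm(n, am$nonaccumulator_dvr_mean,
                                     am$nonaccumulator_dvr_sd)))
  dvr <- round(pmax(0.85, dvr_true + rnorm(n, 0, am$dvr_noise_sd)), 4)
  tau <- config$tau_model
  suvr_ent <- round(pmax(0.5, rnorm(n, tau$entorhinal$mean[last_rank],
                                    tau$entorhinal$sd[last_rank])), 4)
  suvr_hip <- round(pmax(0.5, rnorm(n, tau$hippocampus$mean[last_rank],
                                    tau$hippocampus$sd[last_rank])), 4)
  pet <- data.frame(participant_id = id, scan_age = scan_age,
                    global_pib_dvr = dvr, suvr_entorhinal = suvr_ent,
                    suvr_hippocampus = suvr_hip, is_accumulator = acc,
                    true_onset_age = round(onset, 3),
                    last_latent_state = last_state)[has_pet, ]
  rownames(pet) <- NULL

  structure(list(visits = visits, pet = pet, config = config),
            class = "synthetic_cohort")
}

# Population amyloid trajectory: a rising sigmoid of age anchored so that
# the curve crosses the positivity threshold exactly at the onset age.
amyloid_dvr_at_age <- function(age, onset_age, model) {
  frac <- (model$pib_threshold - model$floor) / (model$ceiling - model$floor)
  mid <- onset_age - qlogis(frac) / model$rate
  model$floor + (model$ceiling - model$floor) *
    plogis(model$rate * (age - mid))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants, %d visits, %d PET\n",
              length(unique(x$visits$participant_id)), nrow(x$visits),
              nrow(x$pet)))
  print(table(latent = x$visits$latent_state))
  invisible(x)
}

#' Generate a synthetic target/reference time-activity curve pair
#'
#' Builds a dynamic PET fixture for the Logan graphical method. The plasma
#' input is a gamma-variate bolus `C_p(t) = t exp(-t/tau)`; the reference
#' region follows a one-tissue compartment model with efflux `k2_ref`, and
#' the target region a one-tissue model whose equilibrium
#' distribution-volume ratio relative to the reference equals `true_dvr`
#' (influx scaled as `K1 = true_dvr * (K1_ref / k2_ref) * k2_target`).
#' In `"proportional"` mode the target is simply `true_dvr` times the
#' reference curve, for which the Logan slope is exactly `true_dvr`.
#'
#' @param true_dvr Target-to-reference distribution volume ratio (> 0).
#' @param config A [sim_config()] or the `tac` settings list from one.
#' @param mode `"kinetic"` (one-tissue simulation, default) or
#'   `"proportional"`.
#' @return A `tac_pair`: list with `times` (mid-frame minutes),
#'   `target_activity`, `reference_activity`.
#' @export
#' @examples
#' tac <- generate_tac_pair(1.5)
#' logan_dvr(tac, logan_settings())
generate_tac_pair <- function(true_dvr, config = sim_config(),
                              mode = c("kinetic", "proportional")) {
  mode <- match.arg(mode)
  if (!is.numeric(true_dvr) || length(true_dvr) != 1 || true_dvr <= 0)
    stop("true_dvr must be a single positive number", call. = FALSE)
  s <- if (inherits(config, "sim_config")) config$tac else config
  ends <- cumsum(s$frame_durations)
  times <- ends - s$frame_durations / 2
  ref <- s$k1_ref * ott_response(times, s$k2_ref, s$input_tau)
  tgt <- if (mode == "proportional") true_dvr * ref else {
    k1 <- true_dvr * (s$k1_ref / s$k2_ref) * s$k2_target
    k1 * ott_response(times, s$k2_target, s$input_tau)
  }
  structure(list(times = times, target_activity = tgt,
                 reference_activity = ref), class = "tac_pair")
}

# Tissue response of a one-tissue compartment with unit influx to the
# bolus input t*exp(-t/tau):  integral_0^t s e^(-s/tau) e^(-k (t-s)) ds.
ott_response <- function(t, k, tau) {
  b <- 1 / tau - k
  if (abs(b) < 1e-9) exp(-k * t) * t^2 / 2
  else exp(-k * t) * (1 - exp(-b * t) * (1 + b * t)) / b^2
}
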