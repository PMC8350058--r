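test_that("Logan DVR is invariant to rescaling and unit changes", {
  tac <- generate_tac_pair(1.4)
  base <- as.numeric(logan_dvr(tac))
  scaled <- list(times = tac$times,
                 target_activity = 37 * tac$target_activity,
                 reference_activity = 37 * tac$reference_activity)
  expect_equal(as.numeric(logan_dvr(scaled)), base, tolerance = 1e-12)
  # minutes -> seconds with k2' and t* converted consistently
  sec <- list(times = tac$times * 60,
              target_activity = tac$target_activity,
              reference_activity = tac$reference_activity)
  s2 <- logan_settings(k2_prime = 0.149 / 60, t_star = 35 * 60)
  expect_equal(as.numeric(logan_dvr(sec, s2)), base, tolerance = 1e-9)
})

test_that("Logan DVR validates its window and inputs", {
  tac <- generate_tac_pair(1.4)
  expect_error(logan_dvr(tac, logan_settings(t_star = 60)),
               "fewer than 3 frames")
  expect_error(logan_dvr(tac, logan_settings(t_star = 100)),
               "beyond the scan")
  bad <- tac; bad$target_activity <- bad$target_activity[-1]
  expect_error(logan_dvr(bad), "equal-length")
  expect_error(logan_settings(k2_prime = 0), "positive")
  zt <- tac; zt$target_activity[10:17] <- 0
  expect_error(logan_dvr(zt), "zero target activity")
})

test_that("PiB positivity respects the threshold and chronicity subtracts", {
  pet <- data.frame(participant_id = c("a", "b"), scan_age = c(70, 60),
                    global_pib_dvr = c(1.19, 1.30))
  out <- pib_status_and_chronicity(pet, assessment_age = c(70, 60),
                                   onset_age = c(65, 68))
  expect_false(out$pib_positive[1])   # 1.19 is below the 1.2 threshold
  expect_true(out$pib_positive[2])
  expect_equal(out$chronicity, c(5, -8))
  # antisymmetry of the subtraction
  expect_equal((70 - 65) + (65 - 70), 0)
})

test_that("onset-age estimation inverts the trajectory", {
  mod <- trajectory_model()
  # at the threshold the onset is the scan age itself
  expect_equal(estimate_onset_age(1.2, 70, mod), 70, tolerance = 1e-5)
  # noise-free accumulators across onset ages are recovered within 0.5 y
  am <- default_amyloid_model()
  for (onset in seq(55, 80, by = 2.5)) {
    scan <- onset + 4
    dvr <- cogstage:::amyloid_dvr_at_age(scan, onset, am)
    expect_lt(abs(estimate_onset_age(dvr, scan, mod) - onset), 0.5)
  }
  expect_error(estimate_onset_age(1.0, 70, mod), "outside")
  expect_error(estimate_onset_age(2.2, 70, mod), "outside")
})

test_that("estimated chronicity recovers generator onsets for accumulators", {
  pet <- cached_cohort()$pet
  out <- pib_status_and_chronicity(pet)
  acc <- out$is_accumulator & !is.na(out$chronicity) &
    out$global_pib_dvr > 1.05 & out$global_pib_dvr < 2.1
  est_onset <- out$scan_age[acc] - out$chronicity[acc]
  err <- est_onset - out$true_onset_age[acc]
  # DVR measurement noise (SD 0.02) propagates through the inversion
  expect_lt(median(abs(err)), 1.5)
})

test_that("tau thresholds are mean + 2 SD of the PiB-negative subset", {
  set.seed(11)
  suvr <- rnorm(40, 1, 0.06)
  pet <- data.frame(participant_id = sprintf("p%02d", 1:40),
                    scan_age = 65, global_pib_dvr = 1.05,
                    suvr_hippocampus = suvr, suvr_entorhinal = suvr + 0.1,
                    pib_positive = FALSE)
  thr <- tau_thresholds(pet)
  expect_equal(unname(thr["hippocampus"]), mean(suvr) + 2 * sd(suvr))
  # shifting every PiB(-) SUVR by c shifts the threshold by exactly c
  pet2 <- pet
  pet2$suvr_hippocampus <- pet2$suvr_hippocampus + 0.25
  expect_equal(unname(tau_thresholds(pet2)["hippocampus"]),
               unname(thr["hippocampus"]) + 0.25, tolerance = 1e-12)
  # identical values: threshold equals the value, strict > flags no one
  pet3 <- pet
  pet3$suvr_hippocampus <- 1.1
  thr3 <- tau_thresholds(pet3)["hippocampus"]
  expect_equal(unname(thr3), 1.1)
  expect_false(any(pet3$suvr_hippocampus > thr3))
  # too few negatives leaves the threshold unavailable
  expect_true(is.na(tau_thresholds(pet[1:5, ])["hippocampus"]))
})

test_that("biomarker group comparison separates generator status groups", {
  coh <- cached_cohort(2000, seed = 8)
  pet <- pib_status_and_chronicity(coh$pet)
  status <- pet$last_latent_state
  status[status == "DEMENTIA"] <- "MCI"
  res <- biomarker_group_comparison(pet, status)
  thr <- attr(res, "tau_thresholds")
  expect_true(all(is.finite(thr)))
  # MCI has a higher tau-positive fraction than CU_S by construction
  frac_pos <- function(st, region)
    mean(pet[[paste0("suvr_", region)]][status == st] > thr[[region]])
  expect_gt(frac_pos("MCI", "entorhinal"), frac_pos("CU_S", "entorhinal"))
  expect_gt(frac_pos("MCI", "hippocampus"), frac_pos("CU_S", "hippocampus"))
  # an injected DVR separation yields a large Cliff's delta
  d <- cliffs_delta(pet$global_pib_dvr[status == "MCI"],
                    pet$global_pib_dvr[status == "CU_S"])
  expect_gt(d$estimate, 0.3)
  omnibus <- res[res$groups == "omnibus", ]
  expect_lt(omnibus$p[omnibus$analysis == "suvr_entorhinal"], 0.01)
})

test_that("empty status groups are dropped with a warning", {
  coh <- cached_cohort()
  pet <- pib_status_and_chronicity(coh$pet)
  status <- factor(rep("CU_S", nrow(pet)),
                   levels = c("CU_S", "CU_D", "GHOST"))
  status[seq_len(floor(nrow(pet) / 2))] <- "CU_D"
  expect_warning(biomarker_group_comparison(pet, status), "GHOST")
})
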