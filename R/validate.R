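#' Run the full validity-analysis pipeline
#'
#' Orchestrates the four validity hypotheses on a (typically synthetic)
#' cohort: (1) concurrent separation of composite scores and subjective
#' reports across assigned status groups; (2) within-person change from a
#' CU-S first assessment by status at follow-up (change-score ANCOVA);
#' (3) progression risk (proportions with exact intervals, adjusted
#' logistic model) and next-visit reversion; (4) amyloid/tau PET
#' comparisons at the status nearest each scan. Every table is written as
#' tidy CSV next to a plain-text report; the run log records the seed and
#' a configuration hash so runs can be reproduced exactly.
#'
#' @param cohort A `synthetic_cohort` (or list with `visits`, `pet`), or
#'   `NULL` to generate one from `config`.
#' @param config [sim_config()] used when `cohort` is `NULL` (and for its
#'   seed/hash in the log).
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param thresholds [flag_thresholds()] for staging.
#' @param analyses Subset of `c("concurrent", "change", "progression",
#'   "biomarkers")`.
#' @param alpha,fdr_q Significance level and FDR rate.
#' @return Invisibly, a list of result tables (`concurrent`, `change`,
#'   `progression`, `logistic`, `reversion`, `biomarkers`), the fitted
#'   `norms`, the `staged` labels, and the `log` lines.
#' @export
run_validate <- function(cohort = NULL, config = sim_config(),
                         out_dir = NULL,
                         thresholds = flag_thresholds(),
                         analyses = c("concurrent", "change",
                                      "progression", "biomarkers"),
                         alpha = 0.05, fdr_q = 0.05) {
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    message(line)
  }
  if (is.null(cohort)) {
    say("generating synthetic cohort (n = %d, seed = %d)",
        config$n_participants, config$seed)
    cohort <- generate_cohort(config)
  }
  visits <- cohort$visits
  say("config hash %s; %d participants, %d visits",
      config_hash(config), length(unique(visits$participant_id)),
      nrow(visits))

  norms <- robust_norms(visits, thresholds = thresholds)
  say("robust norms fitted on %d visits", norms$robust_n[1])
  scales <- attr(norms, "composite_scale")
  z <- zscore(visits, norms)
  comp <- composites(z, attr(norms, "specs"), scale = scales)
  staged <- stage_visits(visits, norms, thresholds)
  say("status distribution: %s",
      paste(names(table(staged$label)), table(staged$label),
            sep = "=", collapse = ", "))

  res <- list(norms = norms, staged = staged)
  grp3 <- function(lab) factor(ifelse(lab %in% c("MCI", "DEMENTIA"),
                                      "MCI_DEM", lab),
                               levels = c("CU_S", "CU_D", "MCI_DEM"))

  ## ---- hypothesis 1: concurrent separation at the last visit ----
  if ("concurrent" %in% analyses) {
    last <- !duplicated(visits$participant_id, fromLast = TRUE)
    g <- grp3(staged$label[last])
    rows <- list()
    for (cn in colnames(comp)) {
      v <- comp[last, cn]
      gc <- group_compare(v, g, "anova", alpha)
      rows[[length(rows) + 1]] <- data.frame(
        analysis = cn, groups = "omnibus", estimate = NA_real_,
        p = gc$omnibus_p, effect_size = NA_real_, magnitude = "")
      if (!is.null(gc$pairwise)) for (i in seq_len(nrow(gc$pairwise))) {
        g1 <- gc$pairwise$group1[i]; g2 <- gc$pairwise$group2[i]
        d <- cliffs_delta(v[g == g1], v[g == g2])
        rows[[length(rows) + 1]] <- data.frame(
          analysis = cn, groups = paste(g1, "vs", g2),
          estimate = mean(v[g == g1], na.rm = TRUE) -
            mean(v[g == g2], na.rm = TRUE),
          p = gc$pairwise$p[i], effect_size = d$estimate,
          magnitude = d$magnitude_label)
      }
    }
    res$concurrent <- do.call(rbind, rows)
    say("concurrent: %d comparisons", nrow(res$concurrent))
  } else say("concurrent: skipped")

  ## ---- hypothesis 2: within-person change from CU-S at visit 1 ----
  if ("change" %in% analyses) {
    first <- visits$visit_index == 1
    second <- visits$visit_index == 2
    p1 <- visits$participant_id[first]
    p2 <- visits$participant_id[second]
    both <- intersect(p1[staged$label[first] == "CU_S"], p2)
    i1 <- which(first)[match(both, p1)]
    i2 <- which(second)[match(both, p2)]
    g <- grp3(staged$label[i2])
    interval <- visits$age[i2] - visits$age[i1]
    rows <- list()
    for (cn in colnames(comp)) {
      ch <- comp[i2, cn] - comp[i1, cn]
      an <- change_ancova(ch, g, comp[i1, cn], interval)
      rows[[length(rows) + 1]] <- data.frame(
        analysis = cn, groups = "omnibus",
        estimate = NA_real_, p = an$kruskal_p,
        effect_size = NA_real_, magnitude = "adjusted_means:" %+%
          paste(sprintf("%s=%.1f", names(an$adjusted_means),
                        an$adjusted_means), collapse = ","))
      for (i in seq_len(nrow(an$contrasts)))
        rows[[length(rows) + 1]] <- data.frame(
          analysis = cn,
          groups = paste(an$contrasts$group1[i], "vs",
                         an$contrasts$group2[i]),
          estimate = an$contrasts$estimate[i], p = an$contrasts$p[i],
          effect_size = NA_real_, magnitude = "")
    }
    res$change <- do.call(rbind, rows)
    say("change: %d CU-S-at-first participants with follow-up",
        length(both))
  } else say("change: skipped")

  ## ---- hypothesis 3: progression and reversion ----
  if ("progression" %in% analyses) {
    tl <- status_timelines(staged)
    tl <- tl[tl$baseline_label %in% c("CU_S", "CU_D"), ]
    base_info <- visits[visits$visit_index == 1, ]
    m <- match(tl$participant_id, base_info$participant_id)
    last_age <- tapply(visits$age, visits$participant_id, max)
    fup <- as.numeric(last_age[tl$participant_id]) - base_info$age[m]
    rows <- list()
    for (bl in c("CU_S", "CU_D")) {
      sub <- tl$baseline_label == bl
      k <- sum(tl$primary_progression[sub]); nn <- sum(sub)
      ci <- exact_binomial_ci(k, nn)
      wald <- exact_binomial_ci(k, nn, method = "wald")
      rows[[length(rows) + 1]] <- data.frame(
        analysis = "primary_progression", groups = bl,
        estimate = k / nn, ci_lower = ci$lower, ci_upper = ci$upper,
        wald_lower = wald$lower, wald_upper = wald$upper,
        n = nn, events = k)
    }
    res$progression <- do.call(rbind, rows)
    res$logistic <- logistic_progression(
      tl$primary_progression, tl$baseline_label == "CU_D",
      covariates = data.frame(sex = base_info$sex[m],
                              baseline_age = base_info$age[m],
                              literacy = base_info$wrat3_std[m],
                              followup_years = fup))
    res$reversion <- reversion_summary(staged)
    say("progression: CU_S %.1f%%, CU_D %.1f%%; CU_D reversion %.1f%%",
        100 * res$progression$estimate[1],
        100 * res$progression$estimate[2],
        100 * res$reversion$proportion[res$reversion$to == "any_less" &
                                         res$reversion$from == "CU_D"])
  } else say("progression: skipped")

  ## ---- hypothesis 4: PET biomarkers ----
  if ("biomarkers" %in% analyses && !is.null(cohort$pet) &&
      nrow(cohort$pet) > 0) {
    pet <- pib_status_and_chronicity(cohort$pet)
    st <- status_nearest_scan(visits, staged, pet)
    res$biomarkers <- biomarker_group_comparison(pet, grp3(st))
    say("biomarkers: %d scans, tau thresholds %s", nrow(pet),
        paste(sprintf("%.3f",
                      attr(res$biomarkers, "tau_thresholds")),
              collapse = "/"))
  } else say("biomarkers: skipped")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- sprintf("seed %d hash %s", config$seed, config_hash(config))
    for (nm in intersect(names(res), c("concurrent", "change",
                                       "progression", "logistic",
                                       "reversion", "biomarkers"))) {
      tab <- res[[nm]]
      tab$run <- stamp
      write.csv(tab, file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
    write_norm_model(norms, file.path(out_dir, "norms.csv"))
    write.csv(staged, file.path(out_dir, "statuses.csv"),
              row.names = FALSE)
    writeLines(c(paste("run:", stamp), log),
               file.path(out_dir, "report.txt"))
    say("wrote outputs to %s", out_dir)
  }
  res$log <- log
  invisible(res)
}

`%+%` <- function(a, b) paste0(a, b)

# assigned status at the assessment nearest each PET scan (nearest-prior
# visit on an exact tie)
status_nearest_scan <- function(visits, staged, pet) {
  vapply(seq_len(nrow(pet)), function(i) {
    idx <- which(visits$participant_id == pet$participant_id[i])
    if (!length(idx)) return(NA_character_)
    gap <- abs(visits$age[idx] - pet$scan_age[i])
    cand <- idx[gap == min(gap)]
    staged$label[cand[1]]  # earlier visit wins ties
  }, character(1))
}
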