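#' Flagging and status-assignment thresholds
#'
#' All cut-offs of the two-tier staging algorithm, with the published
#' defaults: raw clinical cut-offs (Clock Draw <= 7, MMSE <= 26, AVLT
#' Delayed Recall <= 5, Logical Memory II <= 16), informant cut-offs
#' (CDR >= 0.5, QDRS >= 0.5, Lawton IADL < 14, IQCODE > 52), the domain
#' composite flag (mean domain z <= -1.5), and the actuarial MCI rule
#' (>= 2 tests within one domain at z <= -1.5). Ties follow the printed
#' inequality directions exactly, with no tolerance band.
#'
#' @param clock_draw_max_pass,mmse_max_pass,avlt_delay_max_pass,lm2_delay_max_pass
#'   Raw-score cut-offs; a score less than or equal to the value fires.
#' @param cdr_flag_min,qdrs_flag_min Global rating cut-offs (fire at >=).
#' @param iadl_flag_below IADL criterion (fires at <, default 14).
#' @param iqcode_flag_above IQCODE criterion (fires at >, default 52).
#' @param domain_z_flag Domain composite z flag threshold (<=, default
#'   -1.5).
#' @param mci_z_cut,mci_min_tests_per_domain Actuarial MCI rule: at least
#'   `mci_min_tests_per_domain` tests within one staging domain at
#'   `z <= mci_z_cut`.
#' @return A `flag_thresholds` list.
#' @export
flag_thresholds <- function(clock_draw_max_pass = 7, mmse_max_pass = 26,
                            avlt_delay_max_pass = 5, lm2_delay_max_pass = 16,
                            cdr_flag_min = 0.5, qdrs_flag_min = 0.5,
                            iadl_flag_below = 14, iqcode_flag_above = 52,
                            domain_z_flag = -1.5, mci_z_cut = -1.5,
                            mci_min_tests_per_domain = 2) {
  th <- as.list(environment())
  stopifnot(vapply(th, is.finite, logical(1)))
  if (th$domain_z_flag >= 0)
    stop("domain_z_flag must be negative", call. = FALSE)
  structure(th, class = "flag_thresholds")
}

# criterion id -> does this criterion count as a clinical raw-score cut-off
RAW_CRITERIA <- c("clock_draw", "mmse", "avlt_delayed", "lm_ii")
INFORMANT_CRITERIA <- c("cdr", "qdrs", "iadl", "iqcode")

#' Apply the flagging algorithm to visits
#'
#' First tier of the staging process: a visit is flagged when ANY
#' criterion fires — a raw clinical cut-off, an informant cut-off, or a
#' staging-domain composite z at or below the flag threshold. Missing
#' inputs never fire a criterion. With `z = NULL` only the norm-free
#' criteria (raw + informant) are evaluated, which is how the first
#' robust-norming pass screens visits.
#'
#' @param visits Visit data frame.
#' @param z z-score matrix from [zscore()], or `NULL`.
#' @param thresholds A [flag_thresholds()] list.
#' @param specs Test specification table.
#' @return List with `flagged` (logical) and `fired` (list of character
#'   criterion ids, empty when unflagged).
#' @export
flag_visits <- function(visits, z = NULL, thresholds = flag_thresholds(),
                        specs = default_test_specs()) {
  n <- nrow(visits)
  th <- thresholds
  fire <- function(x, op, cut) !is.na(x) & op(x, cut)
  crit <- list(
    clock_draw = fire(visits$clock_draw, `<=`, th$clock_draw_max_pass),
    mmse = fire(visits$mmse, `<=`, th$mmse_max_pass),
    avlt_delayed = fire(visits$avlt_delayed, `<=`, th$avlt_delay_max_pass),
    lm_ii = fire(visits$lm_ii, `<=`, th$lm2_delay_max_pass),
    cdr = fire(visits$cdr_global, `>=`, th$cdr_flag_min),
    qdrs = fire(visits$qdrs_global, `>=`, th$qdrs_flag_min),
    iadl = fire(visits$iadl, `<`, th$iadl_flag_below),
    iqcode = fire(visits$iqcode, `>`, th$iqcode_flag_above)
  )
  if (!is.null(z)) {
    cz <- composite_zscores(z, specs)
    for (dom in STAGING_DOMAINS)
      crit[[paste0("domain_", dom)]] <- fire(cz[, dom], `<=`,
                                             th$domain_z_flag)
  }
  mat <- do.call(cbind, crit)
  flagged <- rowSums(mat) > 0
  fired <- lapply(seq_len(n), function(i) names(crit)[mat[i, ]])
  list(flagged = flagged, fired = fired)
}

#' Actuarial status assignment for flagged visits
#'
#' Second tier: unflagged visits are CU-S by definition. For flagged
#' visits a deterministic actuarial rule set stands in for the consensus
#' conference: the cognitive MCI criterion holds when at least
#' `mci_min_tests_per_domain` tests within one staging domain fall at or
#' below `mci_z_cut`, or when any clinical raw cut-off fired. A flagged
#' visit is labelled MCI when the cognitive criterion holds and
#' instrumental functioning is largely preserved (IADL >= 14), DEMENTIA
#' when the cognitive criterion holds with functional loss (IADL < 14)
#' and CDR >= 1, and CU-D otherwise.
#'
#' @param flags Result of [flag_visits()] (with z supplied).
#' @param z z-score matrix for the same visits.
#' @param visits Visit data frame (for IADL and CDR).
#' @param thresholds A [flag_thresholds()] list.
#' @param specs Test specification table.
#' @return Character vector of labels (`CU_S`, `CU_D`, `MCI`,
#'   `DEMENTIA`).
#' @export
assign_status <- function(flags, z, visits,
                          thresholds = flag_thresholds(),
                          specs = default_test_specs()) {
  th <- thresholds
  n <- nrow(visits)
  low_per_domain <- vapply(STAGING_DOMAINS, function(dom) {
    tests <- specs$test[specs$domain == dom]
    zi <- z[, tests, drop = FALSE]
    rowSums(!is.na(zi) & zi <= th$mci_z_cut)
  }, numeric(n))
  if (is.null(dim(low_per_domain)))
    low_per_domain <- matrix(low_per_domain, nrow = 1)
  pair_rule <- apply(low_per_domain, 1, max) >= th$mci_min_tests_per_domain
  raw_fired <- vapply(flags$fired, function(f)
    any(f %in% RAW_CRITERIA), logical(1))
  cognitive <- pair_rule | raw_fired
  iadl_ok <- is.na(visits$iadl) | visits$iadl >= th$iadl_flag_below
  cdr_dementia <- !is.na(visits$cdr_global) & visits$cdr_global >= 1
  label <- rep("CU_S", n)
  fl <- flags$flagged
  label[fl] <- "CU_D"
  label[fl & cognitive & iadl_ok] <- "MCI"
  label[fl & cognitive & !iadl_ok & cdr_dementia] <- "DEMENTIA"
  label
}

#' Stage every visit of a cohort
#'
#' Runs the full two-tier process — z-scoring against the supplied norms,
#' flagging, and actuarial assignment — and returns one labelled row per
#' visit.
#'
#' @param visits Visit data frame.
#' @param norms A `norm_model` (typically from [robust_norms()]).
#' @param thresholds A [flag_thresholds()] list.
#' @return Data frame `participant_id`, `visit_index`, `label`,
#'   `fired_criteria` (semicolon-separated, empty for CU-S).
#' @export
stage_visits <- function(visits, norms, thresholds = flag_thresholds()) {
  specs <- attr(norms, "specs")
  z <- zscore(visits, norms)
  flags <- flag_visits(visits, z, thresholds, specs)
  label <- assign_status(flags, z, visits, thresholds, specs)
  data.frame(participant_id = visits$participant_id,
             visit_index = visits$visit_index, label = label,
             fired_criteria = vapply(flags$fired, paste,
                                     character(1), collapse = ";"))
}

#' Progression outcomes for one status timeline
#'
#' @param labels Ordered per-visit status labels for one participant.
#' @return List with `primary_progression` (MCI/dementia at some visit
#'   >= 2 AND at the most recent visit), `anyvisit_progression`
#'   (MCI/dementia at some visit >= 2, even with later reversion) and
#'   `nextvisit_events` (data frame of consecutive-visit `from`/`to`
#'   pairs).
#' @export
progression_outcomes <- function(labels) {
  if (length(labels) < 2)
    stop("progression outcomes are undefined for single-visit timelines",
         call. = FALSE)
  clinical <- labels %in% c("MCI", "DEMENTIA")
  k <- length(labels)
  list(primary_progression = any(clinical[-1]) && clinical[k],
       anyvisit_progression = any(clinical[-1]),
       nextvisit_events = data.frame(from = labels[-k], to = labels[-1]))
}

#' Per-participant status timelines and progression outcomes
#'
#' @param staged Staged visits from [stage_visits()] (single-visit
#'   participants are dropped with a message).
#' @return Data frame, one row per participant: `participant_id`,
#'   `n_visits`, `baseline_label`, `last_label`, `primary_progression`,
#'   `anyvisit_progression`.
#' @export
status_timelines <- function(staged) {
  sp <- split(staged[order(staged$participant_id, staged$visit_index), ],
              factor(staged$participant_id,
                     levels = unique(staged$participant_id)))
  short <- vapply(sp, nrow, integer(1)) < 2
  if (any(short)) {
    message(sum(short), " single-visit participant(s) dropped from outcomes")
    sp <- sp[!short]
  }
  rows <- lapply(sp, function(d) {
    out <- progression_outcomes(d$label)
    data.frame(participant_id = d$participant_id[1], n_visits = nrow(d),
               baseline_label = d$label[1], last_label = d$label[nrow(d)],
               primary_progression = out$primary_progression,
               anyvisit_progression = out$anyvisit_progression)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Next-visit reversion summary
#'
#' Counts next-visit moves to a strictly less impaired status (ordering
#' CU_S < CU_D < MCI < DEMENTIA) from CU-D and from MCI status-visits.
#' Denominators are status-visits with a follow-up visit, allowing
#' repeated statuses within person across visits. Exact Clopper-Pearson
#' intervals accompany each proportion; a zero denominator leaves the
#' proportion and interval undefined.
#'
#' @param staged Staged visits from [stage_visits()].
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `from`, `to` (`any_less` or a specific
#'   status), `reverted`, `pairs`, `proportion`, `ci_lower`, `ci_upper`.
#' @export
reversion_summary <- function(staged, level = 0.95) {
  sp <- split(staged[order(staged$participant_id, staged$visit_index), ],
              staged$participant_id)
  from <- character(0); to <- character(0)
  for (d in sp) {
    k <- nrow(d)
    if (k >= 2) {
      from <- c(from, d$label[-k])
      to <- c(to, d$label[-1])
    }
  }
  count_row <- function(f, t) {
    pairs <- sum(from == f)
    reverted <- if (t == "any_less")
      sum(from == f & status_rank(to) < status_rank(f))
    else sum(from == f & to == t)
    if (pairs == 0)
      return(data.frame(from = f, to = t, reverted = 0L, pairs = 0L,
                        proportion = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_))
    ci <- exact_binomial_ci(reverted, pairs, level)
    data.frame(from = f, to = t, reverted = reverted, pairs = pairs,
               proportion = reverted / pairs, ci_lower = ci$lower,
               ci_upper = ci$upper)
  }
  out <- rbind(count_row("CU_D", "any_less"), count_row("CU_D", "CU_S"),
               count_row("MCI", "any_less"), count_row("MCI", "CU_D"),
               count_row("MCI", "CU_S"))
  rownames(out) <- NULL
  out
}
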