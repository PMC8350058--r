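stage_one <- function(v, thresholds = flag_thresholds()) {
  norms <- truth_norms()
  z <- zscore(v, norms)
  flags <- flag_visits(v, z, thresholds)
  list(flags = flags,
       label = assign_status(flags, z, v, thresholds))
}

test_that("an MMSE exactly at the cut-off flags with only that criterion", {
  v <- make_visit(raw = list(mmse = 26))
  s <- stage_one(v)
  expect_true(s$flags$flagged)
  expect_equal(s$flags$fired[[1]], "mmse")
})

test_that("a fully normal visit does not flag and is CU_S", {
  v <- make_visit()
  s <- stage_one(v)
  expect_false(s$flags$flagged)
  expect_length(s$flags$fired[[1]], 0)
  expect_equal(s$label, "CU_S")
})

test_that("IQCODE of 53 flags on the informant criterion alone", {
  v <- make_visit(iqcode = 53)
  s <- stage_one(v)
  expect_true(s$flags$flagged)
  expect_equal(s$flags$fired[[1]], "iqcode")
})

test_that("missing inputs never fire a criterion", {
  v <- make_visit()
  v$mmse <- NA; v$iadl <- NA; v$cdr_global <- NA
  s <- stage_one(v)
  expect_false(s$flags$flagged)
  expect_equal(s$label, "CU_S")
})

test_that("ties follow printed inequality directions exactly", {
  # IADL exactly 14 passes (< 14 fires); CDR exactly 0.5 fires (>= 0.5)
  expect_false(stage_one(make_visit(iadl = 14))$flags$flagged)
  expect_true(stage_one(make_visit(iadl = 13))$flags$flagged)
  expect_true(stage_one(make_visit(cdr = 0.5))$flags$flagged)
  expect_false(stage_one(make_visit(iqcode = 52))$flags$flagged)
})

test_that("a single deep test drives the composite flag but assigns CU_D", {
  # one delayed-memory test far below expectation: domain composite fires,
  # but only one test is below the multi-test cut, so not MCI
  v <- make_visit(z_offset = list(bvmt_delayed = -4.8))
  s <- stage_one(v)
  expect_true(s$flags$flagged)
  expect_equal(s$flags$fired[[1]], "domain_delayed")
  expect_equal(s$label, "CU_D")
})

test_that("two impaired memory tests with functional loss and CDR 1 are DEMENTIA", {
  v <- make_visit(z_offset = list(avlt_delayed = -2, lm_ii = -2),
                  iadl = 12, cdr = 1)
  s <- stage_one(v)
  expect_equal(s$label, "DEMENTIA")
  # deep two-test memory impairment with preserved functioning is MCI
  # (z -2.6 each also pushes the delayed composite past the -1.5 flag)
  v2 <- make_visit(z_offset = list(avlt_delayed = -2.6, lm_ii = -2.6))
  expect_equal(stage_one(v2)$label, "MCI")
  # functional loss without CDR >= 1 stays CU_D (remaining flagged)
  v3 <- make_visit(z_offset = list(avlt_delayed = -2, lm_ii = -2),
                   iadl = 12, cdr = 0.5)
  expect_equal(stage_one(v3)$label, "CU_D")
})

test_that("a raw clinical cut-off alone satisfies the MCI cognitive criterion", {
  v <- make_visit(raw = list(mmse = 25))
  s <- stage_one(v)
  expect_equal(s$label, "MCI")
})

test_that("flagging and assignment are monotone under score worsening", {
  set.seed(31)
  specs <- default_test_specs()
  imp_rank <- function(l) match(l, cogstage:::STATUS_LEVELS)
  for (i in 1:40) {
    zoff <- as.list(setNames(round(rnorm(15, -0.6, 1.2), 2), specs$test))
    v <- make_visit(z_offset = zoff,
                    iadl = sample(c(12, 14, 16), 1),
                    cdr = sample(c(0, 0.5, 1), 1))
    s0 <- stage_one(v)
    test <- sample(specs$test, 1)
    worse <- v
    sgn <- if (specs$orientation[specs$test == test] == "lower_better")
      1 else -1
    worse[[test]] <- worse[[test]] + sgn * runif(1, 0.5, 4) *
      truth_norms()$residual_sd[truth_norms()$test == test]
    s1 <- stage_one(worse)
    if (s0$flags$flagged) expect_true(s1$flags$flagged)
    expect_gte(imp_rank(s1$label), imp_rank(s0$label))
  }
})

test_that("CU_S is equivalent to an empty fired set", {
  coh <- cached_cohort()
  norms <- cached_norms()
  z <- zscore(coh$visits, norms)
  flags <- flag_visits(coh$visits, z, specs = attr(norms, "specs"))
  label <- assign_status(flags, z, coh$visits, specs = attr(norms, "specs"))
  fired_empty <- lengths(flags$fired) == 0
  expect_identical(label == "CU_S", fired_empty)
  expect_identical(flags$flagged, !fired_empty)
})

test_that("progression outcomes follow their definitions", {
  o <- progression_outcomes(c("CU_S", "CU_D", "MCI", "MCI"))
  expect_true(o$primary_progression)
  expect_true(o$anyvisit_progression)
  o2 <- progression_outcomes(c("CU_S", "MCI", "CU_S"))
  expect_false(o2$primary_progression)
  expect_true(o2$anyvisit_progression)
  o3 <- progression_outcomes(c("CU_S", "CU_S"))
  expect_false(o3$primary_progression)
  expect_false(o3$anyvisit_progression)
  expect_equal(o$nextvisit_events$from, c("CU_S", "CU_D", "MCI"))
  expect_equal(o$nextvisit_events$to, c("CU_D", "MCI", "MCI"))
  expect_error(progression_outcomes("CU_S"), "single-visit")
})

test_that("primary progression implies any-visit progression on real timelines", {
  staged <- stage_visits(cached_cohort()$visits, cached_norms())
  tl <- status_timelines(staged)
  expect_true(all(!tl$primary_progression | tl$anyvisit_progression))
})

test_that("reversion summary counts next-visit moves with exact intervals", {
  staged <- data.frame(
    participant_id = rep(c("A", "B", "C"), each = 3),
    visit_index = rep(1:3, 3),
    label = c("CU_D", "CU_S", "CU_D",   # A: one reversion of one CU_D pair
              "MCI", "CU_D", "MCI",     # B: MCI->CU_D, CU_D->MCI
              "CU_S", "CU_S", "CU_S"),
    fired_criteria = "")
  rs <- reversion_summary(staged)
  # CU_D pairs with follow-up: A visit 1 (reverts) and B visit 2 (worsens)
  cud <- rs[rs$from == "CU_D" & rs$to == "any_less", ]
  expect_equal(cud$pairs, 2)
  expect_equal(cud$reverted, 1)
  expect_equal(cud$proportion, 0.5)
  # MCI pairs: B visit 1 only, reverting to CU_D
  mci <- rs[rs$from == "MCI" & rs$to == "CU_D", ]
  expect_equal(mci$reverted, 1)
  expect_equal(mci$pairs, 1)
  ci <- exact_binomial_ci(mci$reverted, mci$pairs)
  expect_equal(mci$ci_lower, ci$lower)
  expect_equal(mci$ci_upper, ci$upper)
})

test_that("zero reversions give a zero lower confidence bound", {
  staged <- data.frame(participant_id = rep("A", 3), visit_index = 1:3,
                       label = c("CU_D", "CU_D", "MCI"),
                       fired_criteria = "")
  rs <- reversion_summary(staged)
  cud <- rs[rs$from == "CU_D" & rs$to == "any_less", ]
  expect_equal(cud$proportion, 0)
  expect_equal(cud$ci_lower, 0)
  mci <- rs[rs$from == "MCI" & rs$to == "any_less", ]
  expect_equal(mci$pairs, 0)
  expect_true(is.na(mci$proportion) && is.na(mci$ci_lower))
})
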