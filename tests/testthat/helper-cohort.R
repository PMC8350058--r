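# Shared fixtures, generated once per test run.

.fixtures <- new.env(parent = emptyenv())

cached_cohort <- function(n = 500, seed = 42) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_cohort(sim_config(n_participants = n,
                                                   seed = seed))
  .fixtures[[key]]
}

cached_norms <- function(n = 500, seed = 42) {
  key <- sprintf("norms_%d_%d", n, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- robust_norms(cached_cohort(n, seed)$visits)
  .fixtures[[key]]
}

# Norm model equal to the generator's true score model, so a visit "at its
# norm prediction" has z exactly 0.
truth_norms <- function() {
  pars <- cogstage:::default_test_params()
  m <- data.frame(test = pars$test,
                  intercept = pars$level - 60 * pars$age_slope -
                    100 * pars$literacy_slope,
                  age_slope = pars$age_slope,
                  sex_offset = pars$sex_offset,
                  literacy_slope = pars$literacy_slope,
                  residual_sd = pars$sd, robust_n = 1000L)
  structure(m, specs = default_test_specs(),
            class = c("norm_model", "data.frame"))
}

# One visit row with every test at its normative prediction (z = 0) and
# normal informant ratings; override raw scores or z offsets by test name.
make_visit <- function(age = 65, sex = 1, lit = 106, raw = list(),
                       z_offset = list(), cdr = 0, qdrs = 0, iadl = 16,
                       iqcode = 48) {
  norms <- truth_norms()
  specs <- attr(norms, "specs")
  row <- data.frame(participant_id = "T0001", visit_index = 1L, age = age,
                    sex = sex, wrat3_std = lit)
  for (j in seq_len(nrow(norms))) {
    test <- norms$test[j]
    pred <- norms$intercept[j] + norms$age_slope[j] * age +
      norms$sex_offset[j] * sex + norms$literacy_slope[j] * lit
    if (!is.null(z_offset[[test]]))
      pred <- pred + z_offset[[test]] * norms$residual_sd[j]
    val <- if (specs$orientation[specs$test == test] == "lower_better")
      -pred else pred
    if (!is.null(raw[[test]])) val <- raw[[test]]
    row[[test]] <- val
  }
  row$cdr_global <- cdr; row$qdrs_global <- qdrs
  row$iadl <- iadl; row$iqcode <- iqcode
  row$self_memory_problem <- "no"; row$self_memory_likert <- 6L
  row$latent_state <- "CU_S"
  row
}

# Brute-force Cliff's delta by full pairwise enumeration.
brute_cliffs <- function(x, y) {
  d <- outer(x, y, function(a, b) sign(a - b))
  mean(d)
}

# Brute-force BH step-up by direct evaluation of the definition.
brute_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(k)) rej[p <= ps[max(k)]] <- TRUE
  rej
}
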