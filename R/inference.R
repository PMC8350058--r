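#' Cliff's delta effect size
#'
#' Rank-based effect size for two samples:
#' `delta = (#(x_i > y_j) - #(x_i < y_j)) / (|x| * |y|)`, the probability
#' that a random observation from `x` exceeds one from `y` minus the
#' reverse. Ties contribute zero. Computed from midranks, so large
#' samples do not require the full pairwise enumeration. Magnitude labels
#' follow the conventional bands: |d| < 0.147 negligible, < 0.33 small,
#' < 0.474 medium, otherwise large.
#'
#' @param x,y Numeric samples (non-empty; NAs dropped).
#' @return List `kind`, `estimate`, `magnitude_label`.
#' @export
#' @examples
#' cliffs_delta(c(2, 4), c(1, 3))$estimate  # 0.5
cliffs_delta <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("cliffs_delta requires two non-empty samples", call. = FALSE)
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  # W = #(x>y) + 0.5 #(x==y), from the rank-sum statistic
  w <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  est <- (2 * w - m * n) / (m * n)
  list(kind = "cliffs_delta", estimate = est,
       magnitude_label = delta_magnitude(est))
}

delta_magnitude <- function(d) {
  a <- abs(d)
  if (a < 0.147) "negligible" else if (a < 0.33) "small"
  else if (a < 0.474) "medium" else "large"
}

#' Cramer's V association measure
#'
#' `V = sqrt(chi^2 / (N * min(r - 1, c - 1)))` with the Pearson chi-square
#' statistic (no continuity correction). Magnitude labels use the same
#' conventional bands as [cliffs_delta()].
#'
#' @param table An r x c contingency table of counts (r, c >= 2).
#' @return List `kind`, `estimate`, `magnitude_label`.
#' @export
cramers_v <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2 || any(table < 0) ||
      sum(table) == 0)
    stop("cramers_v needs an r x c table of non-negative counts, r,c >= 2",
         call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("cramers_v is undefined with an empty row or column margin",
         call. = FALSE)
  chi2 <- suppressWarnings(chisq.test(table, correct = FALSE)$statistic)
  v <- sqrt(as.numeric(chi2) /
              (sum(table) * (min(dim(table)) - 1)))
  list(kind = "cramers_v", estimate = v,
       magnitude_label = delta_magnitude(v))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile bounds: the lower limit is 0 when `successes = 0` and
#' the upper limit is 1 when `successes = trials`. A `method = "wald"`
#' normal-approximation interval is also available for large-n
#' proportions.
#'
#' @param successes,trials Counts with `0 <= successes <= trials`,
#'   `trials > 0`.
#' @param level Confidence level (default 0.95).
#' @param method `"clopper_pearson"` (default), `"wilson_cc"` (the score
#'   interval with continuity correction, as printed by many clinical
#'   reports), or `"wald"`.
#' @return List `successes`, `trials`, `level`, `lower`, `upper`,
#'   `method`.
#' @export
#' @examples
#' exact_binomial_ci(13, 43)                       # (0.172, 0.461)
#' exact_binomial_ci(13, 43, method = "wilson_cc") # (0.177, 0.463)
exact_binomial_ci <- function(successes, trials, level = 0.95,
                              method = c("clopper_pearson", "wilson_cc",
                                         "wald")) {
  method <- match.arg(method)
  if (trials <= 0 || successes < 0 || successes > trials ||
      successes != round(successes) || trials != round(trials))
    stop("need integer counts with 0 <= successes <= trials, trials > 0",
         call. = FALSE)
  p <- successes / trials
  a <- 1 - level
  if (method == "clopper_pearson") {
    lower <- if (successes == 0) 0 else
      qbeta(a / 2, successes, trials - successes + 1)
    upper <- if (successes == trials) 1 else
      qbeta(1 - a / 2, successes + 1, trials - successes)
  } else if (method == "wilson_cc") {
    zq <- qnorm(1 - a / 2)
    n <- trials
    lower <- if (successes == 0) 0 else
      (2 * n * p + zq^2 - 1 -
         zq * sqrt(zq^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
      (2 * (n + zq^2))
    upper <- if (successes == trials) 1 else
      (2 * n * p + zq^2 + 1 +
         zq * sqrt(zq^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
      (2 * (n + zq^2))
    lower <- max(0, lower); upper <- min(1, upper)
  } else {
    zq <- qnorm(1 - a / 2)
    half <- zq * sqrt(p * (1 - p) / trials)
    lower <- max(0, p - half); upper <- min(1, p + half)
  }
  list(successes = successes, trials = trials, level = level,
       lower = lower, upper = upper, method = method)
}

#' Benjamini-Hochberg step-up rejections
#'
#' Rejects all hypotheses with `p <= p_(k*)` where
#' `k* = max{k : p_(k) <= k q / m}`; no hypothesis is rejected when no k
#' qualifies.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param q Target false-discovery rate (default 0.05).
#' @return Logical rejection flags, aligned with `pvalues`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH") <= q
}

#' Power of the two-sided two-proportion z-test
#'
#' Normal approximation without continuity correction: the null standard
#' error pools the proportions, the alternative uses the unpooled
#' variances.
#'
#' @param p1,p2 True group proportions in (0, 1).
#' @param n1,n2 Group sizes.
#' @param alpha Two-tailed level (default 0.05).
#' @return Power as a probability.
#' @export
#' @examples
#' two_proportion_power(0.025, 0.101, 1110, 119)  # about 0.93
two_proportion_power <- function(p1, p2, n1, n2, alpha = 0.05) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) >= 1) || n1 <= 0 || n2 <= 0)
    stop("proportions must lie strictly in (0, 1) and sizes be positive",
         call. = FALSE)
  pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  zq <- qnorm(1 - alpha / 2)
  d <- p1 - p2
  pnorm((-zq * se0 - d) / se1) + 1 - pnorm((zq * se0 - d) / se1)
}

#' Change-score ANCOVA across follow-up status groups
#'
#' Ordinary-least-squares fit of the within-person change on group
#' indicators, the baseline score on the same measure (adjusting for
#' regression to the mean) and the assessment interval in years. Returns
#' covariate-adjusted group means (evaluated at the covariate means) with
#' pairwise contrasts, and a companion nonparametric check: a
#' Kruskal-Wallis test of the group effect on the residuals from the
#' covariates-only fit.
#'
#' @param change Per-person score difference (follow-up minus baseline).
#' @param group Factor-like status at follow-up (>= 2 levels, each with
#'   >= 2 members).
#' @param baseline Score at the first assessment.
#' @param interval Years between assessments.
#' @return List with `fit`, `adjusted_means` (named vector), `contrasts`
#'   (data frame `group1`, `group2`, `estimate`, `se`, `p`), and
#'   `kruskal_p`.
#' @export
change_ancova <- function(change, group, baseline, interval) {
  group <- droplevels(as.factor(group))
  ok <- complete.cases(change, group, baseline, interval)
  change <- change[ok]; group <- droplevels(group[ok])
  baseline <- baseline[ok]; interval <- interval[ok]
  if (nlevels(group) < 2 || any(table(group) < 2))
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  dat <- data.frame(change, group, baseline, interval)
  fit <- lm(change ~ group + baseline + interval, data = dat)
  if (any(is.na(coef(fit))))
    stop("singular ANCOVA design", call. = FALSE)
  lv <- levels(group)
  newd <- data.frame(group = factor(lv, levels = lv),
                     baseline = mean(baseline), interval = mean(interval))
  adj <- setNames(predict(fit, newd), lv)
  # pairwise contrasts on the group coefficients
  cn <- names(coef(fit))
  lmat <- sapply(lv, function(g) as.numeric(cn == paste0("group", g)))
  vc <- vcov(fit)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  contrasts <- do.call(rbind, lapply(pairs, function(pr) {
    l <- lmat[, pr[1]] - lmat[, pr[2]]
    est <- sum(l * coef(fit))
    se <- sqrt(drop(t(l) %*% vc %*% l))
    data.frame(group1 = pr[1], group2 = pr[2], estimate = est, se = se,
               p = 2 * pt(abs(est / se), fit$df.residual,
                          lower.tail = FALSE))
  }))
  resid0 <- resid(lm(change ~ baseline + interval, data = dat))
  kw <- kruskal.test(resid0, dat$group)
  list(fit = fit, adjusted_means = adj, contrasts = contrasts,
       kruskal_p = kw$p.value)
}

#' Adjusted logistic model for progression risk
#'
#' Maximum-likelihood logistic regression of the progression outcome on a
#' baseline CU-D indicator, adjusting for sex, baseline age, literacy and
#' follow-up years (any subset of covariates may be supplied as columns
#' of `covariates`). Returns odds ratios with Wald confidence intervals.
#' Complete separation raises an explicit error instead of returning
#' silently diverged estimates.
#'
#' @param outcome Logical or 0/1 progression outcome.
#' @param status0 Baseline CU-D indicator (logical or 0/1).
#' @param covariates Optional data frame of adjustment covariates.
#' @param level Confidence level for the Wald intervals.
#' @return Data frame, one row per model term: `term`, `estimate`
#'   (log-odds), `se`, `or`, `ci_lower`, `ci_upper`, `p`.
#' @export
logistic_progression <- function(outcome, status0, covariates = NULL,
                                 level = 0.95) {
  outcome <- as.integer(outcome)
  if (length(unique(outcome[!is.na(outcome)])) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  dat <- data.frame(outcome = outcome, status0 = as.numeric(status0))
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- suppressWarnings(glm(outcome ~ ., data = dat, family = binomial()))
  co <- summary(fit)$coefficients
  if (!fit$converged || any(abs(co[, "Estimate"]) > 15) ||
      any(co[, "Std. Error"] > 100))
    stop("logistic model did not converge (possible complete separation)",
         call. = FALSE)
  zq <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                    se = co[, "Std. Error"],
                    or = exp(co[, "Estimate"]),
                    ci_lower = exp(co[, "Estimate"] - zq * co[, "Std. Error"]),
                    ci_upper = exp(co[, "Estimate"] + zq * co[, "Std. Error"]),
                    p = co[, "Pr(>|z|)"])
  rownames(out) <- NULL
  out
}

#' Omnibus group comparison with pairwise follow-ups
#'
#' Runs the named standard omnibus test — one-way ANOVA, Kruskal-Wallis,
#' or Fisher's exact on a contingency table — and, only when the omnibus
#' p-value is below `alpha`, pairwise follow-ups (Welch t after ANOVA,
#' Wilcoxon rank-sum after Kruskal-Wallis, pairwise Fisher after Fisher),
#' optionally corrected by the Benjamini-Hochberg rule.
#'
#' @param values Numeric outcome (for `anova`/`kruskal_wallis`) or a
#'   groups x categories count table (for `fisher_exact`).
#' @param group Group labels aligned with `values` (ignored for tables).
#' @param family `"anova"`, `"kruskal_wallis"` or `"fisher_exact"`.
#' @param alpha Omnibus significance gate for follow-ups (default 0.05).
#' @param fdr_q If non-`NULL`, BH-correct the pairwise family at this
#'   rate and report rejection flags.
#' @return List `family`, `omnibus_p`, `pairwise` (data frame or `NULL`).
#' @export
group_compare <- function(values, group = NULL,
                          family = c("anova", "kruskal_wallis",
                                     "fisher_exact"),
                          alpha = 0.05, fdr_q = NULL) {
  family <- match.arg(family)
  if (family == "fisher_exact") {
    tab <- as.matrix(values)
    if (!is.null(group))
      stop("for fisher_exact supply a contingency table, not raw values",
           call. = FALSE)
    omni <- fisher.test(tab)$p.value
    groups <- rownames(tab) %||% paste0("g", seq_len(nrow(tab)))
    pair_fun <- function(i, j)
      fisher.test(tab[c(i, j), , drop = FALSE])$p.value
    npair_src <- seq_len(nrow(tab))
  } else {
    if (!is.numeric(values))
      stop(sprintf("family '%s' needs a numeric outcome", family),
           call. = FALSE)
    group <- droplevels(as.factor(group))
    ok <- complete.cases(values, group)
    values <- values[ok]; group <- droplevels(group[ok])
    if (nlevels(group) < 2) stop("need >= 2 groups", call. = FALSE)
    omni <- if (family == "anova")
      summary(aov(values ~ group))[[1]][["Pr(>F)"]][1]
    else kruskal.test(values, group)$p.value
    groups <- levels(group)
    pair_fun <- function(i, j) {
      xi <- values[group == groups[i]]; xj <- values[group == groups[j]]
      if (family == "anova") t.test(xi, xj)$p.value
      else suppressWarnings(wilcox.test(xi, xj)$p.value)
    }
    npair_src <- seq_along(groups)
  }
  pairwise <- NULL
  if (!is.na(omni) && omni < alpha) {
    prs <- utils::combn(npair_src, 2, simplify = FALSE)
    pairwise <- do.call(rbind, lapply(prs, function(pr)
      data.frame(group1 = groups[pr[1]], group2 = groups[pr[2]],
                 p = pair_fun(pr[1], pr[2]))))
    if (!is.null(fdr_q)) pairwise$reject_fdr <- bh_fdr(pairwise$p, fdr_q)
  }
  list(family = family, omnibus_p = omni, pairwise = pairwise)
}
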