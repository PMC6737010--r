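# Age-group binning, repeated-measures ANCOVA-style tests with a scrubbing
# covariate, Bonferroni post hocs, and Pearson correlations with age and
# cognition.
#
# The original analyses were SPSS-style MANCOVAs; here within-subject
# factors are handled by a univariate general-linear-model F test with the
# subject as error stratum (stats::aov + Error()). Multivariate statistics
# (Wilks/Pillai) are deliberately not reproduced.

.AGE_BREAKS <- c(20, 34, 49, 64, 80)
.AGE_GROUPS <- c("YA", "yMA", "oMA", "OA")

#' Age group labels
#' @return Character vector `c("YA", "yMA", "oMA", "OA")` (young adults
#'   20-34, younger middle-aged 35-49, older middle-aged 50-64, older
#'   adults 65-80).
#' @export
age_groups <- function() .AGE_GROUPS

#' Assign an age to its analysis age group
#'
#' Bins: YA 20-34, yMA 35-49, oMA 50-64, OA 65-80 (inclusive bounds).
#'
#' @param age Numeric vector of ages in years, each in [20, 80].
#' @return Factor with levels `YA, yMA, oMA, OA`.
#' @export
#' @examples
#' assign_age_group(c(34, 35, 80))
assign_age_group <- function(age) {
  if (any(!is.finite(age)) || any(age < 20 | age > 80))
    stop("age outside supported range [20, 80]")
  cut(age, breaks = c(19, 34, 49, 64, 80), labels = .AGE_GROUPS,
      right = TRUE)
}

#' Repeated-measures ANCOVA-style effect tests
#'
#' Fits a general linear model of a long-format dependent variable on
#' between-subject factors (age group, optionally scan length), a
#' between-subject covariate (scrubbing percentage) and within-subject
#' factors (network, direction, threshold), with the subject as error
#' stratum for within-subject effects. Reports an F, df pair and p value
#' per requested effect (all main effects and interactions of the supplied
#' factors).
#'
#' @param data Data frame in long format; one row per subject x
#'   within-factor cell.
#' @param dv Name of the dependent-variable column.
#' @param between Character vector of between-subject factor columns
#'   (e.g. `"age_group"`, optionally plus `"scan_length"`).
#' @param within Character vector of within-subject factor columns
#'   (subset of e.g. `c("network", "direction", "threshold")`); may be
#'   empty.
#' @param covariate Name of a numeric between-subject covariate column, or
#'   `NULL` for none. A constant covariate is dropped with a warning.
#' @param subject Name of the subject-id column (default `"subject_id"`).
#' @return Data frame with columns `effect`, `df1`, `df2`, `F`, `p`.
#' @export
ancova_effects <- function(data, dv, between = "age_group",
                           within = character(), covariate = "scrub_percent",
                           subject = "subject_id") {
  data <- as.data.frame(data)
  need <- c(dv, between, within, covariate, subject)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "))
  data[[subject]] <- factor(data[[subject]])
  for (f in c(between, within)) data[[f]] <- factor(data[[f]])
  if (!is.null(covariate)) {
    if (stats::var(data[[covariate]]) == 0) {
      warning("covariate '", covariate, "' is constant; dropped")
      covariate <- NULL
    }
  }
  if (length(within) > 0L) {
    counts <- table(data[[subject]])
    expected <- prod(vapply(within, function(f) nlevels(data[[f]]), integer(1)))
    bad <- names(counts)[counts != expected]
    if (length(bad) > 0L)
      stop("unbalanced within-subject cells for subject(s): ",
           paste(bad, collapse = ", "))
  }
  rhs_terms <- paste(c(covariate,
                       paste(c(between, within), collapse = " * ")),
                     collapse = " + ")
  if (length(within) > 0L) {
    err <- sprintf("Error(%s/(%s))", subject, paste(within, collapse = " * "))
    fml <- stats::as.formula(paste(dv, "~", rhs_terms, "+", err))
  } else {
    fml <- stats::as.formula(paste(dv, "~", rhs_terms))
  }
  fit <- stats::aov(fml, data = data)
  .extract_aov_effects(fit)
}

# flatten summary.aov / summary.aovlist into effect/F/df/p rows
.extract_aov_effects <- function(fit) {
  sm <- summary(fit)
  tabs <- if (inherits(fit, "aovlist")) lapply(sm, function(s) s[[1L]])
          else sm
  rows <- list()
  for (tab in tabs) {
    tab <- as.data.frame(tab)
    nm <- trimws(rownames(tab))
    resid_row <- nm == "Residuals"
    df2 <- if (any(resid_row)) tab$Df[resid_row] else NA_real_
    for (r in which(!resid_row)) {
      if (is.na(tab[r, "F value"])) next
      rows[[length(rows) + 1L]] <- data.frame(
        effect = nm[r], df1 = tab$Df[r], df2 = df2,
        F = tab[r, "F value"], p = tab[r, "Pr(>F)"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted group means
#'
#' Group means of a per-subject dependent variable adjusted to the grand
#' mean of the covariate (classic ANCOVA adjusted means).
#'
#' @param dv Numeric vector, one value per subject.
#' @param groups Factor of group labels.
#' @param covariate Numeric covariate, or `NULL` for raw means.
#' @return Named numeric vector of (adjusted) group means.
#' @export
adjusted_group_means <- function(dv, groups, covariate = NULL) {
  groups <- factor(groups)
  if (is.null(covariate)) {
    return(tapply(dv, groups, mean))
  }
  fit <- stats::lm(dv ~ covariate + groups)
  grid <- data.frame(covariate = mean(covariate), groups = levels(groups))
  stats::setNames(stats::predict(fit, grid), levels(groups))
}

#' Bonferroni-corrected pairwise group comparisons
#'
#' All unordered group pairs are compared with pooled-variance two-sample
#' t tests; p values are multiplied by the number of pairs (6 for four
#' groups) and capped at 1.
#'
#' @param dv Numeric vector, one value per subject.
#' @param groups Factor (or coercible) of group labels; every group needs
#'   n >= 2.
#' @return Data frame with columns `group1`, `group2`, `mean_diff`
#'   (group1 - group2), `t`, `df`, `p_raw`, `p_bonferroni`.
#' @export
bonferroni_pairwise <- function(dv, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  if (length(lev) < 2L) stop("need at least 2 groups")
  ns <- table(groups)
  if (any(ns < 2L))
    stop("group(s) with n < 2: ", paste(names(ns)[ns < 2], collapse = ", "))
  combs <- utils::combn(lev, 2L)
  m <- ncol(combs)
  rows <- lapply(seq_len(m), function(j) {
    g1 <- combs[1, j]; g2 <- combs[2, j]
    x <- dv[groups == g1]; y <- dv[groups == g2]
    if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
      # identical-within groups with equal means: no evidence of difference
      tt <- list(statistic = c(t = 0),
                 parameter = c(df = length(x) + length(y) - 2), p.value = 1)
      if (mean(x) != mean(y))
        tt <- list(statistic = c(t = Inf),
                   parameter = c(df = length(x) + length(y) - 2), p.value = 0)
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
    }
    data.frame(group1 = g1, group2 = g2, mean_diff = mean(x) - mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_bonferroni = min(1, m * tt$p.value))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between age and a connectivity metric
#'
#' @param ages Numeric vector of ages.
#' @param values Numeric metric values, same length.
#' @return List with `r`, `p` (two-sided, from the t transform), `n`.
#' @export
age_metric_correlation <- function(ages, values) {
  if (length(ages) != length(values)) stop("length mismatch")
  if (length(ages) < 3L) stop("need n >= 3")
  if (stats::var(ages) == 0 || stats::var(values) == 0)
    stop("zero variance input")
  ct <- stats::cor.test(ages, values, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ages))
}

#' Z-score raw task scores and average into cognitive domains
#'
#' Each task is z-scored against the reference sample's mean and standard
#' deviation; domain scores are the unweighted mean of task z-scores within
#' each domain (VOCAB, SPEED, FLUID, MEM in the standard battery).
#'
#' @param scores Data frame / matrix of raw task scores (rows = subjects,
#'   columns = tasks).
#' @param domains Named list mapping domain name -> character vector of
#'   task columns.
#' @param reference Optional data frame of the same tasks supplying the
#'   reference means/sds (default: `scores` itself, i.e. the whole sample).
#' @return Data frame of domain z-scores, one column per domain.
#' @export
zscore_cognition <- function(scores, domains, reference = scores) {
  scores <- as.data.frame(scores)
  reference <- as.data.frame(reference)
  tasks <- unique(unlist(domains))
  miss <- setdiff(tasks, names(scores))
  if (length(miss) > 0L) stop("missing task column(s): ",
                              paste(miss, collapse = ", "))
  zs <- lapply(tasks, function(tk) {
    mu <- mean(reference[[tk]]); sdv <- stats::sd(reference[[tk]])
    if (sdv == 0) stop("zero-variance task: ", tk)
    (scores[[tk]] - mu) / sdv
  })
  names(zs) <- tasks
  out <- lapply(domains, function(tk) rowMeans(as.data.frame(zs[tk])))
  as.data.frame(out)
}

#' Correlations between cognition domain scores and connectivity metrics
#'
#' Pearson r between each cognitive domain z-score and each metric column,
#' uncorrected for multiple comparisons (the analyses are exploratory by
#' design).
#'
#' @param cognition Data frame of domain z-scores (columns = domains).
#' @param metrics Data frame of per-subject metric values (columns =
#'   metrics), same row order as `cognition`.
#' @return Long data frame: `domain`, `metric`, `r`, `p`, `n`.
#' @export
cognition_metric_correlations <- function(cognition, metrics) {
  cognition <- as.data.frame(cognition)
  metrics <- as.data.frame(metrics)
  if (nrow(cognition) != nrow(metrics)) stop("row count mismatch")
  rows <- list()
  for (d in names(cognition)) for (m in names(metrics)) {
    res <- age_metric_correlation(cognition[[d]], metrics[[m]])
    rows[[length(rows) + 1L]] <- data.frame(domain = d, metric = m,
                                            r = res$r, p = res$p, n = res$n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
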