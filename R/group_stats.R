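#' Welch's unequal-variance two-sample t-test
#'
#' Statistic `t = (xbar1 - xbar2) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' t distribution. Preferred over the pooled-variance test when group
#' variances cannot be assumed equal, as is typical for neuroimaging
#' features.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @return list with `t`, `nu` (degrees of freedom), `p`.
#' @export
welch_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop_fmt("each sample needs n >= 2")
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (v1 == 0 && v2 == 0) stop_fmt("both samples have zero variance")
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  nu <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = tstat, nu = nu, p = 2 * stats::pt(-abs(tstat), df = nu))
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' `d = (xbar1 - xbar2) / s_pooled` with the classic
#' `(n1 - 1, n2 - 1)`-weighted pooled standard deviation and no
#' small-sample correction. Conventional benchmarks: |d| ~ 0.2 small,
#' ~ 0.5 medium, >= 0.8 large.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @return scalar effect size, sign following `mean(a) - mean(b)`.
#' @export
cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop_fmt("each sample needs n >= 2")
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) stop_fmt("pooled SD is zero")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values (monotone, capped at 1), in input order.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop_fmt("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' @keywords internal
#' @noRd
contrast_one <- function(a, b, groups = c("A", "B")) {
  w <- welch_t(a, b)
  data.frame(group1 = groups[1L], group2 = groups[2L],
             n1 = length(a), n2 = length(b),
             mean1 = mean(a), mean2 = mean(b),
             sd1 = stats::sd(a), sd2 = stats::sd(b),
             t = w$t, nu = w$nu, p = w$p, d = cohens_d(a, b),
             stringsAsFactors = FALSE)
}

#' Familial group contrasts over the network feature table
#'
#' For every condition x contrast x feature, runs Welch's t-test and
#' Cohen's d, then applies Benjamini-Hochberg FDR within each declared
#' family. The default family is one BH correction per condition x
#' contrast x feature class (e.g. the 21 inter-network tests of one
#' condition form one family).
#'
#' @param features feature data.frame from [build_feature_table()] (needs
#'   `subject_id`, `group`, `condition` plus feature columns).
#' @param contrasts list of 2-vectors `c(groupA, groupB)`; defaults to the
#'   four familial contrasts (illness: SCZ vs CON; state: SCZ vs SCZ-SIB;
#'   liability: SCZ-SIB vs CON-SIB; environment: CON vs CON-SIB).
#' @param conditions task conditions to analyse.
#' @param family `"condition_contrast_class"` (default),
#'   `"condition_contrast"` or `"global"` BH family rule.
#' @return data.frame of class `contrast_result`: condition, contrast,
#'   feature, group summaries, t, nu, p, q, d.
#' @export
run_contrasts <- function(features,
                          contrasts = list(c("SCZ", "CON"),
                                           c("SCZ", "SCZ-SIB"),
                                           c("SCZ-SIB", "CON-SIB"),
                                           c("CON", "CON-SIB")),
                          conditions = intersect(TASK_CONDITIONS,
                                                 unique(features$condition)),
                          family = c("condition_contrast_class",
                                     "condition_contrast", "global")) {
  family <- match.arg(family)
  feat_cols <- setdiff(names(features),
                       c("subject_id", "group", "condition"))
  rows <- list()
  for (cond in conditions) {
    sub <- features[features$condition == cond, , drop = FALSE]
    for (ct in contrasts) {
      for (g in ct) if (sum(sub$group == g) < 2L)
        stop_fmt("group '%s' missing or n < 2 in condition %s", g, cond)
      a_rows <- sub[sub$group == ct[1L], , drop = FALSE]
      b_rows <- sub[sub$group == ct[2L], , drop = FALSE]
      for (f in feat_cols) {
        r <- contrast_one(a_rows[[f]], b_rows[[f]], ct)
        r <- cbind(data.frame(condition = cond,
                              contrast = paste(ct, collapse = ":"),
                              feature = f, stringsAsFactors = FALSE), r)
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  res <- do.call(rbind, rows)
  fam_key <- switch(family,
    condition_contrast_class = paste(res$condition, res$contrast,
                                     feature_class(res$feature)),
    condition_contrast = paste(res$condition, res$contrast),
    global = rep("all", nrow(res)))
  res$q <- NA_real_
  for (k in unique(fam_key)) {
    idx <- fam_key == k
    res$q[idx] <- bh_fdr(res$p[idx])
  }
  rownames(res) <- NULL
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Per-ROI contrasts on the nodal metric table
#'
#' Welch t / Cohen's d / BH-FDR per ROI for one nodal metric, with one BH
#' family per condition x contrast (all R ROIs).
#'
#' @param nodal long nodal table from [build_feature_table()].
#' @param metric `"strength"` or `"clustering"`.
#' @inheritParams run_contrasts
#' @return `contrast_result` data.frame with `feature` = ROI label and an
#'   extra `network` column.
#' @export
nodal_contrasts <- function(nodal, metric = c("strength", "clustering"),
                            contrasts = list(c("SCZ", "CON")),
                            conditions = intersect(TASK_CONDITIONS,
                                                   unique(nodal$condition))) {
  metric <- match.arg(metric)
  rows <- list()
  for (cond in conditions) {
    sub <- nodal[nodal$condition == cond, , drop = FALSE]
    for (ct in contrasts) {
      for (roi in unique(sub$roi)) {
        rs <- sub[sub$roi == roi, , drop = FALSE]
        a <- rs[[metric]][rs$group == ct[1L]]
        b <- rs[[metric]][rs$group == ct[2L]]
        if (length(a) < 2L || length(b) < 2L)
          stop_fmt("group '%s' missing or n < 2 for ROI %s",
                   ct[which(c(length(a), length(b)) < 2L)][1L], roi)
        r <- contrast_one(a, b, ct)
        r <- cbind(data.frame(condition = cond,
                              contrast = paste(ct, collapse = ":"),
                              feature = roi, network = rs$network[1L],
                              stringsAsFactors = FALSE), r)
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  res <- do.call(rbind, rows)
  fam_key <- paste(res$condition, res$contrast)
  res$q <- NA_real_
  for (k in unique(fam_key)) {
    idx <- fam_key == k
    res$q[idx] <- bh_fdr(res$p[idx])
  }
  rownames(res) <- NULL
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' One-way ANOVA with partial eta squared, from group summaries
#'
#' Operates on summary statistics (mean, SD, n per group) so that printed
#' demographic tables can be re-analysed without subject-level data.
#' `F = (SSB/df1) / (SSW/df2)` and `eta_p^2 = SSB / (SSB + SSW)`.
#'
#' @param means,sds,ns numeric vectors, one entry per group (>= 3 groups,
#'   each n >= 2).
#' @return list with `F`, `df1`, `df2`, `eta_p_squared`.
#' @export
anova_eta <- function(means, sds, ns) {
  k <- length(means)
  stopifnot(length(sds) == k, length(ns) == k)
  if (k < 2L) stop_fmt("need at least 2 groups")
  if (any(ns < 2L)) stop_fmt("each group needs n >= 2")
  if (all(sds == 0) && length(unique(means)) == 1L)
    stop_fmt("no variance anywhere: ANOVA undefined")
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1L
  df2 <- N - k
  list(F = (ssb / df1) / (ssw / df2), df1 = df1, df2 = df2,
       eta_p_squared = ssb / (ssb + ssw))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Standard convention: the two-sided p-value sums the hypergeometric
#' probabilities of all tables (at fixed margins) no more probable than
#' the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L))
  if (any(tab < 0) || any(tab != round(tab)))
    stop_fmt("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_fmt("zero margin: Fisher's exact test undefined")
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}
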