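#' Fit the effect-size-weighted composite model
#'
#' Selects the inter-network features with FDR q below threshold in the
#' given contrast x condition and uses their absolute Cohen's d values as
#' weights, so metrics with larger group differences contribute more to
#' the composite.
#'
#' @param contrasts a `contrast_result` table from [run_contrasts()].
#' @param condition task condition to build the model for.
#' @param contrast contrast label (e.g. `"SCZ:CON"`).
#' @param q_threshold FDR significance threshold.
#' @param classes feature classes eligible for selection (default: the
#'   inter-network metrics only).
#' @return list of class `composite_model`: `features`, `weights`,
#'   `condition`, `contrast`.
#' @export
fit_composite <- function(contrasts, condition = "1-back",
                          contrast = "SCZ:CON", q_threshold = 0.05,
                          classes = "inter") {
  sel <- contrasts[contrasts$condition == condition &
                   contrasts$contrast == contrast &
                   feature_class(contrasts$feature) %in% classes &
                   contrasts$q < q_threshold, , drop = FALSE]
  if (!nrow(sel))
    stop_fmt("no feature significant at q < %g for %s / %s: no composite model",
             q_threshold, contrast, condition)
  structure(list(features = sel$feature,
                 weights = stats::setNames(abs(sel$d), sel$feature),
                 condition = condition, contrast = contrast),
            class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("composite_model (%s, %s): %d feature(s)\n",
              x$contrast, x$condition, length(x$features)))
  print(round(x$weights, 4))
  invisible(x)
}

#' Composite discriminant score per subject
#'
#' `score_i = sum_j x_ij * |d_j|` over the model's selected features,
#' applied to the raw feature values.
#'
#' @param model a `composite_model` (or a named weight vector).
#' @param features feature data.frame containing the model's columns.
#' @return numeric vector of per-row scores.
#' @export
composite_score <- function(model, features) {
  w <- if (inherits(model, "composite_model")) model$weights else model
  miss <- setdiff(names(w), names(features))
  if (length(miss))
    stop_fmt("feature(s) missing from table: %s", paste(miss, collapse = ", "))
  as.numeric(as.matrix(features[, names(w), drop = FALSE]) %*% w)
}

#' ROC analysis of a score against binary labels
#'
#' AUC by the Mann-Whitney rank estimator with midrank tie handling; the
#' empirical curve by a sweep over all observed thresholds; a stratified
#' percentile bootstrap confidence interval. If the raw AUC is below 0.5
#' the score is negated first (`flipped` records this), so the reported
#' AUC is always >= 0.5.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1, logical, or a 2-level factor; the
#'   second level / 1 is the positive class).
#' @param ci_B bootstrap replicates for the 95% CI (0 skips the CI).
#' @param seed seed for the bootstrap.
#' @return list of class `roc_result`: `auc`, `auc_ci`, `curve`
#'   (data.frame threshold/sensitivity/specificity), `flipped`, `youden`
#'   (threshold, sensitivity, specificity at the Youden optimum).
#' @export
roc <- function(scores, labels, ci_B = 2000, seed = 1L) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) != 2L) stop_fmt("both classes must be present")
  flipped <- FALSE
  a <- auc_rank(scores, y)
  if (a < 0.5) {
    flipped <- TRUE
    scores <- -scores
    a <- auc_rank(scores, y)
  }
  curve <- roc_curve(scores, y)
  ci <- c(NA_real_, NA_real_)
  if (ci_B > 0) {
    pos <- which(y == 1L); neg <- which(y == 0L)
    boot <- withr::with_seed(seed, vapply(seq_len(ci_B), function(b) {
      i <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
      auc_rank(scores[i], y[i])
    }, numeric(1)))
    ci <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  }
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))
  # ties broken toward higher specificity
  best <- best[which.max(curve$specificity[best])]
  structure(list(auc = a, auc_ci = ci, curve = curve, flipped = flipped,
                 youden = list(threshold = curve$threshold[best],
                               sensitivity = curve$sensitivity[best],
                               specificity = curve$specificity[best])),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f (95%% CI %.3f-%.3f)%s\n",
              x$auc, x$auc_ci[1], x$auc_ci[2],
              if (x$flipped) " [score orientation flipped]" else ""))
  cat(sprintf("  Youden: threshold %.4f, sensitivity %.2f, specificity %.2f\n",
              x$youden$threshold, x$youden$sensitivity, x$youden$specificity))
  invisible(x)
}

#' Rank (Mann-Whitney) AUC estimator with midrank ties
#' @param scores numeric scores.
#' @param y 0/1 labels, 1 = positive.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop_fmt("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @keywords internal
#' @noRd
roc_curve <- function(scores, y) {
  # decision rule: positive iff score >= threshold; thresholds midway
  # between consecutive distinct scores, plus sentinels
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2, Inf)
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(pos >= t), numeric(1)),
    specificity = vapply(thr, function(t) mean(neg < t), numeric(1)))
}

#' Youden-optimal operating point
#'
#' The threshold maximizing `sensitivity + specificity - 1`; ties are
#' broken toward higher specificity.
#'
#' @param x a `roc_result`.
#' @return list with `threshold`, `sensitivity`, `specificity`.
#' @export
youden <- function(x) {
  stopifnot(inherits(x, "roc_result"))
  x$youden
}

#' Trapezoidal area under the empirical ROC curve
#'
#' Independent of the rank estimator; used as a cross-check
#' (the two agree to numerical precision).
#'
#' @param x a `roc_result`.
#' @return area under the (1 - specificity, sensitivity) polyline.
#' @export
auc_trapezoid <- function(x) {
  stopifnot(inherits(x, "roc_result"))
  fpr <- 1 - x$curve$specificity
  tpr <- x$curve$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Profile misclassified cases at the Youden operating point
#'
#' Classifies each subject by the fitted ROC's Youden threshold (taking a
#' flipped orientation into account), cross-tabulates misclassification
#' against a binary case attribute (e.g. membership of one clinical
#' subtype) among positive-class subjects, tests the table with Fisher's
#' exact test, and reports group means of any named metadata columns for
#' misclassified vs correctly classified cases.
#'
#' @param scores numeric scores (as passed to [roc()]).
#' @param labels binary labels (positive class = cases).
#' @param roc_fit a `roc_result` for these scores/labels.
#' @param case_attribute logical vector over subjects (the attribute being
#'   tested for enrichment among misclassified cases).
#' @param metadata optional data.frame of numeric columns to summarize.
#' @return list with `crosstab` (2x2: misclassified x attribute),
#'   `fisher_p` (NA with `note` when a margin is degenerate), and
#'   `metadata_means`.
#' @export
misclassification_profile <- function(scores, labels, roc_fit,
                                      case_attribute, metadata = NULL) {
  stopifnot(inherits(roc_fit, "roc_result"))
  y <- as.integer(as.factor(labels)) - 1L
  s <- if (roc_fit$flipped) -scores else scores
  pred <- as.integer(s >= roc_fit$youden$threshold)
  cases <- which(y == 1L)
  mis <- pred[cases] != 1L
  att <- as.logical(case_attribute)[cases]
  tab <- table(factor(mis, levels = c(TRUE, FALSE),
                      labels = c("misclassified", "correct")),
               factor(att, levels = c(TRUE, FALSE),
                      labels = c("attribute", "other")))
  out <- list(crosstab = tab, fisher_p = NA_real_, note = NULL,
              metadata_means = NULL)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    out$note <- "not applicable: degenerate margin"
  else
    out$fisher_p <- fisher_exact_2x2(tab)
  if (!is.null(metadata)) {
    md <- metadata[cases, , drop = FALSE]
    out$metadata_means <- rbind(
      misclassified = colMeans(md[mis, , drop = FALSE]),
      correct = colMeans(md[!mis, , drop = FALSE]))
  }
  out
}
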