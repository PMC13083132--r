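#' Effect-size recovery simulation
#'
#' Repeatedly generates feature-mode synthetic cohorts with the planted
#' effect map, runs the contrast stage, and averages the estimated Cohen's
#' d for one feature. Used to verify that the generator-plus-contrast
#' pipeline recovers planted standardized effects.
#'
#' @param group1,group2 contrast groups.
#' @param condition task condition.
#' @param feature feature name (see [inter_feature_name()]).
#' @param n_per_group subjects per group in each replicate.
#' @param replicates number of replicate cohorts.
#' @param effect_map planted effects (default [paper_effect_map()]).
#' @param rho between-feature correlation.
#' @param seed master seed; each replicate derives its own.
#' @return list with `mean_d` (mean estimated Cohen's d), `d_values`,
#'   `planted` (the planted value, NA if the map has none).
#' @export
effect_recovery <- function(group1, group2, condition, feature,
                            n_per_group = 1000, replicates = 200,
                            effect_map = paper_effect_map(), rho = 0.25,
                            seed = 1L) {
  sizes <- stats::setNames(c(n_per_group, n_per_group), c(group1, group2))
  ds <- vapply(seq_len(replicates), function(r) {
    cfg <- cohort_config(group_sizes = sizes, conditions = condition,
                         effect_map = effect_map, rho = rho,
                         seed = derive_seed(seed, paste0("rep", r)))
    ft <- generate_feature_tables(cfg)
    ct <- run_contrasts(ft, contrasts = list(c(group1, group2)),
                        conditions = condition)
    ct$d[ct$feature == feature]
  }, numeric(1))
  hit <- effect_map$group1 == group1 & effect_map$group2 == group2 &
    effect_map$condition == condition & effect_map$feature == feature
  list(mean_d = mean(ds), d_values = ds,
       planted = if (any(hit)) effect_map$d[hit][1] else NA_real_)
}

#' Composite-score discrimination simulation
#'
#' Simulates replicate two-group cohorts whose feature vectors are
#' multivariate normal with unit variances, equicorrelation `rho`, and
#' planted standardized group differences; scores every subject with the
#' planted-|d|-weighted composite and reports the mean rank-estimator AUC.
#' With weights w equal to the planted shifts, the expected AUC has the
#' closed form `pnorm(w'delta / (sqrt(2) sqrt(w' Sigma w)))`.
#'
#' @param n_case,n_control group sizes per replicate.
#' @param delta planted |d| per feature (cases are shifted by `-delta`,
#'   i.e. a deficit).
#' @param rho between-feature correlation.
#' @param replicates number of replicate cohorts.
#' @param seed master seed.
#' @return list with `mean_auc`, `auc_values`, and `closed_form`.
#' @export
composite_auc_simulation <- function(n_case = 23, n_control = 20,
                                     delta = c(1.547, 1.155), rho = 0.25,
                                     replicates = 2000, seed = 1L) {
  p <- length(delta)
  Sigma <- matrix(rho, p, p); diag(Sigma) <- 1
  w <- stats::setNames(abs(delta), sprintf("f%d", seq_len(p)))
  aucs <- withr::with_seed(derive_seed(seed, "composite-auc"), {
    vapply(seq_len(replicates), function(r) {
      cases <- MASS::mvrnorm(n_case, -delta, Sigma)
      controls <- MASS::mvrnorm(n_control, rep(0, p), Sigma)
      X <- as.data.frame(rbind(cases, controls))
      names(X) <- names(w)
      sc <- composite_score(w, X)
      # deficit model: controls score higher; AUC for separating the groups
      auc_rank(sc, rep(c(0, 1), c(n_case, n_control)))
    }, numeric(1))
  })
  closed <- stats::pnorm(sum(abs(delta) * delta) /
                           (sqrt(2) * sqrt(drop(t(abs(delta)) %*% Sigma %*%
                                                  abs(delta)))))
  list(mean_auc = mean(aucs), auc_values = aucs, closed_form = closed)
}

#' Subtype recovery simulation
#'
#' Generates replicate synthetic clinical cohorts from the default
#' three-subtype preset, runs normalization and consensus-clustering model
#' selection, and reports the chosen k and the adjusted Rand index between
#' recovered and planted subtypes for each replicate.
#'
#' @param n_subjects cohort size per replicate.
#' @param n_seeds number of replicate cohorts.
#' @param preset a [subtype_preset()].
#' @param k_range candidate cluster numbers.
#' @param iterations consensus iterations.
#' @param seed master seed.
#' @return data.frame with one row per replicate: seed, chosen_k, ari.
#' @export
subtype_recovery <- function(n_subjects = 98, n_seeds = 50,
                             preset = subtype_preset(), k_range = 2:6,
                             iterations = 100, seed = 1L) {
  unit <- stats::setNames(rep(list(c(0, 1)), length(COGNITIVE_COLUMNS)),
                          COGNITIVE_COLUMNS)
  rows <- lapply(seq_len(n_seeds), function(i) {
    si <- derive_seed(seed, paste0("subtype", i))
    clin <- generate_clinical_table(preset, n = n_subjects, seed = si)
    norm <- minmax_normalize(clin, bounds = unit)
    sel <- select_k(norm$data, k_range = k_range, iterations = iterations,
                    seed = si)
    truth <- clin$true_subtype[clin$subject_id %in% rownames(norm$data)]
    sol <- sel$solutions[[as.character(sel$k)]]
    data.frame(seed = si, chosen_k = sel$k,
               ari = pair_concordance(sol$labels, truth)$ari)
  })
  do.call(rbind, rows)
}
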