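#' Cohort simulation configuration
#'
#' Bundles everything the synthetic-cohort generators need. Defaults
#' reproduce the study design being emulated: four groups (23 patients, 34
#' patient siblings, 20 controls, 21 control siblings), three N-back load
#' conditions, 165 ROIs in six networks, 137 volumes per run, and planted
#' group x condition inter-network effects that are largest for the
#' cerebellar-sensorimotor pair under moderate (1-back) load.
#'
#' @param group_sizes named integer vector of subjects per group.
#' @param conditions task conditions to simulate.
#' @param atlas an [atlas_map()]; defaults to the synthetic 165-ROI atlas.
#' @param n_volumes volumes per run (T).
#' @param within_network_corr baseline within-block correlation.
#' @param between_network_corr baseline between-block correlation.
#' @param block_effects data.frame overriding block correlations per group x
#'   condition x network pair (columns: group, condition, net1, net2, value);
#'   defaults to [default_block_effects()].
#' @param noise_sd observation noise SD added on the diagonal of the target
#'   covariance.
#' @param subject_block_sd SD of per-subject Gaussian variation around the
#'   group-level block correlations. Real cohorts vary in their true
#'   connectivity; without this term, between-subject variance would be
#'   estimation noise only and standardized group effects would come out
#'   implausibly large.
#' @param high_motion_frac fraction of subjects simulated with high head
#'   motion (their FD traces mostly exceed the 0.5 mm threshold).
#' @param fd_meanlog,fd_sdlog log-normal parameters of ordinary FD traces
#'   (mm); high-motion subjects use `fd_meanlog_high`.
#' @param fd_meanlog_high log-mean for high-motion subjects.
#' @param rho between-feature correlation used by the direct feature-mode
#'   generator.
#' @param effect_map planted standardized effects for feature mode; defaults
#'   to [paper_effect_map()].
#' @param seed integer seed driving all generators.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c("SCZ" = 23, "SCZ-SIB" = 34,
                                          "CON" = 20, "CON-SIB" = 21),
                          conditions = TASK_CONDITIONS,
                          atlas = default_atlas(),
                          n_volumes = 137,
                          within_network_corr = 0.30,
                          between_network_corr = 0.10,
                          block_effects = default_block_effects(),
                          noise_sd = 0.5,
                          subject_block_sd = 0.10,
                          high_motion_frac = 0.10,
                          fd_meanlog = log(0.12), fd_sdlog = 0.45,
                          fd_meanlog_high = log(0.55),
                          rho = 0.25,
                          effect_map = paper_effect_map(),
                          seed = 20260101) {
  if (any(group_sizes < 2L)) stop_fmt("all group sizes must be >= 2")
  if (abs(within_network_corr) >= 1 || abs(between_network_corr) >= 1)
    stop_fmt("block correlations must lie in (-1, 1)")
  structure(list(group_sizes = group_sizes, conditions = conditions,
                 atlas = atlas, n_volumes = n_volumes,
                 within_network_corr = within_network_corr,
                 between_network_corr = between_network_corr,
                 block_effects = block_effects, noise_sd = noise_sd,
                 subject_block_sd = subject_block_sd,
                 high_motion_frac = high_motion_frac,
                 fd_meanlog = fd_meanlog, fd_sdlog = fd_sdlog,
                 fd_meanlog_high = fd_meanlog_high,
                 rho = rho, effect_map = effect_map, seed = seed),
            class = "cohort_config")
}

#' Planted block-correlation modulations
#'
#' Default group x condition overrides of the between-network block
#' correlations on the covariance scale. Healthy groups (CON, CON-SIB,
#' SCZ-SIB) engage cerebellar-sensorimotor and cerebellar-cingulo-opercular
#' coupling with load, peaking at 1-back; the patient group fails to
#' recruit these couplings, with the largest deficit at 1-back, plus a
#' mild cerebellar-default-mode elevation at 0-back.
#'
#' @return data.frame with columns group, condition, net1, net2, value.
#' @export
default_block_effects <- function() {
  healthy <- c("CON", "CON-SIB", "SCZ-SIB")
  rows <- list()
  add <- function(groups, condition, net1, net2, value)
    for (g in groups) rows[[length(rows) + 1L]] <<-
      data.frame(group = g, condition = condition, net1 = net1, net2 = net2,
                 value = value, stringsAsFactors = FALSE)
  # load-dependent cerebellar engagement in non-patient groups
  add(healthy, "0-back", "CER", "SM", 0.25); add(healthy, "0-back", "CER", "CO", 0.20)
  add(healthy, "1-back", "CER", "SM", 0.32); add(healthy, "1-back", "CER", "CO", 0.28)
  add(healthy, "2-back", "CER", "SM", 0.28); add(healthy, "2-back", "CER", "CO", 0.24)
  # patient group: blunted recruitment, worst at moderate load
  add("SCZ", "0-back", "CER", "SM", 0.17); add("SCZ", "0-back", "CER", "CO", 0.16)
  add("SCZ", "1-back", "CER", "SM", 0.12); add("SCZ", "1-back", "CER", "CO", 0.14)
  add("SCZ", "2-back", "CER", "SM", 0.17); add("SCZ", "2-back", "CER", "CO", 0.18)
  # mild default-mode coupling elevation at rest-like load
  add("SCZ", "0-back", "CER", "DMN", 0.16)
  do.call(rbind, rows)
}

#' Planted standardized effect sizes (feature mode)
#'
#' The planted Cohen's d values used by the direct feature-mode generator:
#' cerebellar-sensorimotor and cerebellar-cingulo-opercular deficits in
#' patients, maximal at 1-back, plus the clinical-state contrast against
#' patient siblings.
#'
#' @return data.frame with columns group1, group2, condition, feature, d.
#' @export
paper_effect_map <- function() {
  nm <- function(k, m) inter_feature_name(k, m)
  data.frame(
    group1 = c("SCZ", "SCZ", "SCZ", "SCZ", "SCZ", "SCZ"),
    group2 = c("CON", "CON", "CON", "CON", "CON", "SCZ-SIB"),
    condition = c("0-back", "0-back", "1-back", "1-back", "2-back", "1-back"),
    feature = c(nm("CER", "SM"), nm("CER", "DMN"), nm("CER", "SM"),
                nm("CER", "CO"), nm("CER", "SM"), nm("CER", "SM")),
    d = c(-1.078, 0.726, -1.547, -1.155, -0.914, -1.086),
    stringsAsFactors = FALSE)
}

#' Build the target ROI-level correlation matrix from a network-block design
#'
#' Fills an R x R correlation matrix with `within_network_corr` inside each
#' network block and `block_corr[k, m]` between blocks, unit diagonal. If
#' the result is not positive definite it is repaired by eigenvalue
#' clipping at 1e-6 followed by re-normalization to unit diagonal.
#'
#' @param block_corr symmetric 6x6 (or n x n) matrix of between-network
#'   correlations, dimnames = network names.
#' @param atlas an [atlas_map()].
#' @param within_network_corr within-block off-diagonal correlation in (0, 1).
#' @return R x R correlation matrix with attribute `projected` (logical).
#' @export
build_target_covariance <- function(block_corr, atlas, within_network_corr) {
  nets <- atlas$networks
  block_corr <- as.matrix(block_corr)
  if (!isTRUE(all.equal(block_corr, t(block_corr))))
    stop_fmt("block_corr must be symmetric")
  if (any(abs(block_corr[row(block_corr) != col(block_corr)]) >= 1))
    stop_fmt("block correlations must lie in (-1, 1)")
  if (within_network_corr <= 0 || within_network_corr >= 1)
    stop_fmt("within_network_corr must lie in (0, 1)")
  if (is.null(dimnames(block_corr)))
    dimnames(block_corr) <- list(nets, nets)
  R <- length(atlas$roi_labels)
  net_idx <- match(atlas$network_of, nets)
  S <- block_corr[net_idx, net_idx]
  same <- outer(net_idx, net_idx, "==")
  S[same] <- within_network_corr
  diag(S) <- 1
  dimnames(S) <- list(atlas$roi_labels, atlas$roi_labels)
  ev <- eigen(S, symmetric = TRUE)
  projected <- FALSE
  if (min(ev$values) < 1e-6) {
    projected <- TRUE
    vals <- pmax(ev$values, 1e-6)
    S <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    dsc <- 1 / sqrt(diag(S))
    S <- S * tcrossprod(dsc)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    dimnames(S) <- list(atlas$roi_labels, atlas$roi_labels)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
      stop_fmt("block structure infeasible: remains non-PD after projection")
  }
  attr(S, "projected") <- projected
  S
}

#' @keywords internal
#' @noRd
group_block_corr <- function(config, group, condition) {
  nets <- config$atlas$networks
  n <- length(nets)
  B <- matrix(config$between_network_corr, n, n, dimnames = list(nets, nets))
  eff <- config$block_effects
  if (!is.null(eff)) {
    sel <- eff[eff$group == group & eff$condition == condition, , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      B[sel$net1[i], sel$net2[i]] <- sel$value[i]
      B[sel$net2[i], sel$net1[i]] <- sel$value[i]
    }
  }
  diag(B) <- 1
  B
}

#' Simulate ROI time series and FD traces for a full cohort
#'
#' Each subject x condition series is drawn from a zero-mean multivariate
#' normal whose correlation structure follows the group x condition network
#' blocks (plus `noise_sd^2` diagonal observation noise). FD traces are
#' log-normal; a configurable fraction of subjects is simulated as
#' high-motion so that the QC exclusion rule has work to do. Fully
#' deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `timeseries` (list of [roi_timeseries()]), `fd` (list
#'   of [fd_trace()]) and `subjects` (data.frame: subject_id, group,
#'   high_motion).
#' @export
generate_roi_timeseries <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  atlas <- config$atlas
  R <- length(atlas$roi_labels)
  if (config$n_volumes < R)
    warning(sprintf(
      "T = %d < R = %d: sample covariance is rank-deficient (allowed; thresholding still applies)",
      config$n_volumes, R), call. = FALSE)
  withr::with_seed(config$seed, {
    groups <- rep(names(config$group_sizes), config$group_sizes)
    ids <- sprintf("%03d", seq_along(groups))
    high <- stats::runif(length(ids)) < config$high_motion_frac
    nnet <- length(atlas$networks)
    ts_list <- list()
    for (s in seq_along(ids)) {
      for (cond in config$conditions) {
        B <- group_block_corr(config, groups[s], cond)
        if (config$subject_block_sd > 0) {
          # per-subject true-connectivity variation, symmetric over the
          # unique network pairs (within-network values included)
          jit <- matrix(0, nnet, nnet)
          jit[upper.tri(jit, diag = TRUE)] <-
            stats::rnorm(nnet * (nnet + 1) / 2, 0, config$subject_block_sd)
          jit <- jit + t(jit) - diag(diag(jit))
          within_s <- min(max(config$within_network_corr + diag(jit)[1], 0.02),
                          0.95)
          diag(jit) <- 0
          B <- B + jit
          B[B > 0.95] <- 0.95; B[B < -0.95] <- -0.95
          diag(B) <- 1
        } else within_s <- config$within_network_corr
        S <- build_target_covariance(B, atlas, within_s)
        diag(S) <- diag(S) + config$noise_sd^2
        draw <- MASS::mvrnorm(config$n_volumes, mu = rep(0, R), Sigma = S)
        mat <- t(draw)
        rownames(mat) <- atlas$roi_labels
        ts_list[[length(ts_list) + 1L]] <-
          roi_timeseries(ids[s], groups[s], cond, mat)
      }
    }
    fd_list <- lapply(seq_along(ids), function(s) {
      ml <- if (high[s]) config$fd_meanlog_high else config$fd_meanlog
      fd_trace(ids[s], stats::rlnorm(config$n_volumes, ml, config$fd_sdlog))
    })
    list(timeseries = ts_list, fd = fd_list,
         subjects = data.frame(subject_id = ids, group = groups,
                               high_motion = high, stringsAsFactors = FALSE))
  })
}

#' @keywords internal
#' @noRd
resolve_group_means <- function(effect_map, groups, conditions, features) {
  mu <- array(0, dim = c(length(groups), length(conditions), length(features)),
              dimnames = list(groups, conditions, features))
  fixed <- array(FALSE, dim = dim(mu), dimnames = dimnames(mu))
  for (i in seq_len(nrow(effect_map))) {
    e <- effect_map[i, ]
    if (!e$feature %in% features)
      stop_fmt("unknown feature in effect map: '%s'", e$feature)
    if (!e$condition %in% conditions) next
    if (!all(c(e$group1, e$group2) %in% groups)) next
    a <- e$group1; b <- e$group2; cc <- e$condition; f <- e$feature
    if (fixed[a, cc, f] && fixed[b, cc, f]) {
      if (abs((mu[a, cc, f] - mu[b, cc, f]) - e$d) > 1e-9)
        warning(sprintf("inconsistent planted effects for %s/%s on %s",
                        a, b, f), call. = FALSE)
    } else if (fixed[a, cc, f]) {
      mu[b, cc, f] <- mu[a, cc, f] - e$d
    } else {
      mu[a, cc, f] <- mu[b, cc, f] + e$d
    }
    fixed[a, cc, f] <- fixed[b, cc, f] <- TRUE
  }
  mu
}

#' Simulate network-feature tables directly (feature mode)
#'
#' Bypasses the time-series and graph stages: draws the 33-feature vector
#' per subject x condition from a multivariate normal with unit variances,
#' equicorrelation `rho`, and group means offset by the planted
#' standardized differences of `config$effect_map`. Because feature
#' variances are 1, planted mean differences are Cohen's d values exactly,
#' which makes this mode the reference for effect-size recovery.
#'
#' @param config a [cohort_config()].
#' @return feature data.frame (subject_id, group, condition, 33 features).
#' @export
generate_feature_tables <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  feats <- feature_names(config$atlas$networks)
  groups <- names(config$group_sizes)
  mu <- resolve_group_means(config$effect_map, groups, config$conditions, feats)
  p <- length(feats)
  Sigma <- matrix(config$rho, p, p); diag(Sigma) <- 1
  withr::with_seed(config$seed, {
    rows <- list()
    for (g in groups) {
      n <- config$group_sizes[[g]]
      ids <- sprintf("%s-%03d", g, seq_len(n))
      for (cond in config$conditions) {
        X <- MASS::mvrnorm(n, mu = mu[g, cond, ], Sigma = Sigma)
        if (n == 1L) X <- matrix(X, nrow = 1L)
        colnames(X) <- feats
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(subject_id = ids, group = g, condition = cond,
                     stringsAsFactors = FALSE),
          as.data.frame(X))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Clinical-cognitive subtype preset
#'
#' Defines the planted three-subtype structure of the synthetic clinical
#' table: per-subtype centroids on the normalized \[0, 1\] scale, subtype
#' mixing proportions, within-subtype noise, and per-subtype diagnostic
#' composition. Defaults encode one near-asymptomatic, cognitively strong
#' subtype of controls and control siblings; one patient-enriched subtype
#' with marked fluid-cognitive impairment and elevated negative symptoms;
#' and one mixed subtype of intermediate performance with relative working
#' memory sparing.
#'
#' @param k number of subtypes.
#' @param centroids k x 20 matrix (columns = [clinical_feature_columns()])
#'   of mean normalized scores in \[0, 1\].
#' @param within_subtype_sd Gaussian noise SD around the centroid.
#' @param mixing subtype proportions (sums to 1).
#' @param group_composition k x 4 matrix of diagnostic-group probabilities
#'   per subtype (rows sum to 1; columns = SCZ, SCZ-SIB, CON, CON-SIB).
#' @return list of class `subtype_preset`.
#' @export
subtype_preset <- function(k = 3,
                           centroids = default_subtype_centroids(),
                           within_subtype_sd = 0.07,
                           mixing = c(36, 29, 33) / 98,
                           group_composition = default_group_composition()) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != k) stop_fmt("centroids must have k = %d rows", k)
  if (any(centroids < 0 | centroids > 1))
    stop_fmt("centroids must lie in [0, 1]")
  if (abs(sum(mixing) - 1) > 1e-8) stop_fmt("mixing must sum to 1")
  if (length(mixing) != k) stop_fmt("mixing must have k entries")
  group_composition <- as.matrix(group_composition)
  if (any(abs(rowSums(group_composition) - 1) > 1e-8))
    stop_fmt("group_composition rows must sum to 1")
  structure(list(k = k, centroids = centroids,
                 within_subtype_sd = within_subtype_sd, mixing = mixing,
                 group_composition = group_composition),
            class = "subtype_preset")
}

#' @rdname subtype_preset
#' @export
default_subtype_centroids <- function() {
  cols <- clinical_feature_columns()
  ctr <- matrix(NA_real_, 3, length(cols), dimnames = list(NULL, cols))
  # subtype 1: minimal symptom burden, strong verbal/visual memory
  ctr[1, SYMPTOM_COLUMNS] <- 0.05
  ctr[1, COGNITIVE_COLUMNS] <- 0.625
  # subtype 2: fluid-cognitive impairment with elevated negative symptoms
  ctr[2, ] <- c(0.35, 0.55,              # global SAPS, SANS
                0.45, 0.35, 0.25, 0.35,  # hallucinations, delusions, bizarre, FTD
                0.65, 0.50, 0.55, 0.45, 0.50,  # SANS domains
                0.45, 0.475, 0.45, 0.475, 0.45, 0.425, 0.45, 0.375, 0.45)
  # subtype 3: intermediate, working memory relatively spared
  ctr[3, SYMPTOM_COLUMNS] <- 0.20
  ctr[3, COGNITIVE_COLUMNS] <- 0.45
  ctr[3, c("digit_span", "spatial_span", "lns")] <- 0.525
  ctr
}

#' @rdname subtype_preset
#' @export
default_group_composition <- function() {
  m <- rbind(c(0.00, 0.00, 0.56, 0.44),
             c(0.79, 0.21, 0.00, 0.00),
             c(0.29, 0.29, 0.21, 0.21))
  dimnames(m) <- list(NULL, STUDY_GROUPS)
  m
}

#' Simulate a clinical-cognitive table with planted subtypes
#'
#' Each subject's subtype is drawn from the preset mixing; features are
#' the subtype centroid plus Gaussian noise truncated to \[0, 1\]; the
#' diagnostic group label is drawn from the subtype's composition. Symptom
#' columns are emitted on the 0-5 item-mean scale (5 x normalized value);
#' cognitive columns are emitted already unit-normalized. The planted
#' subtype is kept in a `true_subtype` column for evaluation only.
#'
#' @param preset a [subtype_preset()].
#' @param n number of subjects.
#' @param seed integer seed.
#' @return clinical data.frame with `subject_id`, `group`, the 20 feature
#'   columns and `true_subtype`.
#' @export
generate_clinical_table <- function(preset, n = 98, seed = 20260101) {
  stopifnot(inherits(preset, "subtype_preset"))
  if (n < preset$k) stop_fmt("n = %d < k = %d subtypes", n, preset$k)
  cols <- clinical_feature_columns()
  withr::with_seed(seed, {
    subtype <- sample.int(preset$k, n, replace = TRUE, prob = preset$mixing)
    X <- preset$centroids[subtype, , drop = FALSE] +
      matrix(stats::rnorm(n * length(cols), 0, preset$within_subtype_sd),
             n, length(cols))
    X <- pmin(pmax(X, 0), 1)
    colnames(X) <- cols
    grp <- vapply(subtype, function(s)
      sample(STUDY_GROUPS, 1L, prob = preset$group_composition[s, ]), "")
    df <- data.frame(subject_id = sprintf("%03d", seq_len(n)), group = grp,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(X))
    for (col in SYMPTOM_COLUMNS) df[[col]] <- 5 * df[[col]]
    df$true_subtype <- subtype
    df
  })
}
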