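#' Default pipeline configuration
#'
#' Nested list understood by [run_all()]. `cohort` entries override
#' [cohort_config()] arguments; `clinical` controls the subtype stream;
#' `connect`, `contrast`, `roc` and `cluster` control the corresponding
#' stages.
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @return a named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 20260101) {
  structure(list(
    seed = seed,
    cohort = list(),                       # overrides for cohort_config()
    clinical = list(n = 98),               # subtype stream
    connect = list(percentile = 85, fd_threshold = 0.5, max_fraction = 0.20,
                   signed = TRUE),
    contrast = list(family = "condition_contrast_class"),
    roc = list(condition = "1-back", contrast = "SCZ:CON",
               q_threshold = 0.05, ci_B = 2000),
    cluster = list(k_range = 2:6, iterations = 100, subsample = 0.8)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- utils::modifyList(unclass(default_pipeline_config()),
                           yaml::read_yaml(path))
  validate_pipeline_config(structure(cfg, class = "pipeline_config"))
}

#' @keywords internal
#' @noRd
validate_pipeline_config <- function(config) {
  need <- c("seed", "cohort", "clinical", "connect", "contrast", "roc",
            "cluster")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop_fmt("pipeline config missing section(s): %s",
             paste(miss, collapse = ", "))
  stopifnot(is.numeric(config$seed),
            config$connect$percentile > 0, config$connect$percentile < 100,
            config$roc$q_threshold > 0, config$roc$q_threshold < 1)
  config
}

#' @keywords internal
#' @noRd
stage_stamp <- function(out_dir, stage, hash, seed) {
  jsonlite::write_json(list(stage = stage, config_hash = hash, seed = seed),
                       file.path(out_dir, paste0(stage, ".stamp.json")),
                       auto_unbox = TRUE)
}

#' @keywords internal
#' @noRd
stage_cached <- function(out_dir, stage, hash, files) {
  stamp <- file.path(out_dir, paste0(stage, ".stamp.json"))
  if (!file.exists(stamp) || !all(file.exists(file.path(out_dir, files))))
    return(FALSE)
  s <- jsonlite::read_json(stamp)
  identical(s$config_hash, hash)
}

#' Run the full pipeline end to end
#'
#' Simulate cohort, apply motion QC, build connectomes, extract the
#' network feature table, run the familial contrasts, fit and evaluate the
#' composite ROC, run the clinical subtype stream, and assemble the
#' report. Every artifact is stamped with the config hash and master seed;
#' stages whose outputs already carry the current hash are reloaded
#' instead of recomputed.
#'
#' @param config a `pipeline_config` (see [default_pipeline_config()]).
#' @param out_dir output directory.
#' @return list of stage outputs (invisibly): `qc`, `features`, `nodal`,
#'   `contrasts`, `roc`, `clustering`, `report`.
#' @export
run_all <- function(config = default_pipeline_config(), out_dir) {
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- hash_config(unclass(config))
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- simulate + connect + metrics -------------------------------------
  feat_files <- c("features.csv", "nodal.csv", "qc_report.csv")
  if (stage_cached(out_dir, "metrics", hash, feat_files)) {
    features <- utils::read.csv(file.path(out_dir, "features.csv"),
                                stringsAsFactors = FALSE)
    nodal <- utils::read.csv(file.path(out_dir, "nodal.csv"),
                             stringsAsFactors = FALSE)
    qc <- utils::read.csv(file.path(out_dir, "qc_report.csv"),
                          stringsAsFactors = FALSE)
  } else {
    cohort_cfg <- stage("simulate",
      do.call(cohort_config,
              utils::modifyList(list(seed = derive_seed(seed, "simulate")),
                                config$cohort)))
    cohort <- stage("simulate",
                    suppressWarnings(generate_roi_timeseries(cohort_cfg)))
    qc <- stage("qc", {
      dec <- lapply(cohort$fd, qc_exclude,
                    fd_threshold = config$connect$fd_threshold,
                    max_fraction = config$connect$max_fraction)
      data.frame(subject_id = vapply(cohort$fd, `[[`, "", "subject_id"),
                 proportion_high_fd = vapply(dec, `[[`, 0, "proportion"),
                 decision = ifelse(vapply(dec, `[[`, TRUE, "exclude"),
                                   "exclude", "keep"),
                 stringsAsFactors = FALSE)
    })
    tab <- stage("metrics", {
      keep_ids <- qc$subject_id[qc$decision == "keep"]
      graphs <- lapply(
        Filter(function(ts) ts$subject_id %in% keep_ids, cohort$timeseries),
        build_connectome, percentile = config$connect$percentile,
        signed = config$connect$signed)
      build_feature_table(graphs, cohort_cfg$atlas)
    })
    features <- tab$features; nodal <- tab$nodal
    utils::write.csv(qc, file.path(out_dir, "qc_report.csv"), row.names = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(nodal, file.path(out_dir, "nodal.csv"), row.names = FALSE)
    stage_stamp(out_dir, "metrics", hash, seed)
  }

  # --- contrasts ---------------------------------------------------------
  contrasts <- stage("contrast",
    run_contrasts(features, family = config$contrast$family))
  utils::write.csv(contrasts, file.path(out_dir, "contrasts.csv"),
                   row.names = FALSE)
  stage_stamp(out_dir, "contrast", hash, seed)

  # --- composite ROC -----------------------------------------------------
  roc_out <- stage("roc", {
    model <- tryCatch(
      fit_composite(contrasts, condition = config$roc$condition,
                    contrast = config$roc$contrast,
                    q_threshold = config$roc$q_threshold),
      error = function(e) NULL)
    if (is.null(model)) NULL else {
      grp <- strsplit(config$roc$contrast, ":", fixed = TRUE)[[1L]]
      sub <- features[features$condition == config$roc$condition &
                      features$group %in% grp, , drop = FALSE]
      sc <- composite_score(model, sub)
      fit <- roc(sc, as.integer(sub$group == grp[1L]),
                 ci_B = config$roc$ci_B, seed = derive_seed(seed, "roc"))
      list(model = model, roc = fit, subjects = sub$subject_id, scores = sc)
    }
  })
  if (!is.null(roc_out)) {
    jsonlite::write_json(
      list(condition = config$roc$condition, contrast = config$roc$contrast,
           weights = as.list(roc_out$model$weights),
           subjects = roc_out$subjects, scores = roc_out$scores,
           auc = roc_out$roc$auc, auc_ci = roc_out$roc$auc_ci,
           youden = roc_out$roc$youden,
           curve = roc_out$roc$curve, config_hash = hash),
      file.path(out_dir, "roc.json"), auto_unbox = TRUE, digits = NA)
  }
  stage_stamp(out_dir, "roc", hash, seed)

  # --- clinical subtype stream ------------------------------------------
  clustering <- stage("cluster", {
    clin <- generate_clinical_table(subtype_preset(),
                                    n = config$clinical$n,
                                    seed = derive_seed(seed, "clinical"))
    norm <- minmax_normalize(
      clin, bounds = stats::setNames(rep(list(c(0, 1)), length(COGNITIVE_COLUMNS)),
                                     COGNITIVE_COLUMNS))
    sel <- select_k(norm$data, k_range = config$cluster$k_range,
                    iterations = config$cluster$iterations,
                    subsample = config$cluster$subsample,
                    seed = derive_seed(seed, "cluster"))
    sol <- sel$solutions[[as.character(sel$k)]]
    prof <- profile_subtypes(sol, norm)
    list(selection = sel, solution = sol, profiles = prof,
         normalized = norm, clinical = clin)
  })
  utils::write.csv(
    data.frame(subject_id = rownames(clustering$normalized$data),
               subtype = clustering$solution$labels),
    file.path(out_dir, "labels.csv"), row.names = FALSE)
  utils::write.table(round(clustering$solution$consensus, 6),
                     file.path(out_dir, "consensus.tsv"), sep = "\t",
                     quote = FALSE, col.names = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(list(k = clustering$selection$k, stable = clustering$selection$stable,
           config_hash = hash),
      clustering$solution$metrics),
    file.path(out_dir, "cluster_metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(clustering$profiles$profiles),
                   file.path(out_dir, "profiles.csv"))
  stage_stamp(out_dir, "cluster", hash, seed)

  # --- report ------------------------------------------------------------
  report <- make_report(out_dir)
  invisible(list(qc = qc, features = features, nodal = nodal,
                 contrasts = contrasts, roc = roc_out,
                 clustering = clustering, report = report))
}

#' Assemble the summary report from stage outputs
#'
#' Reads the stage artifacts in `out_dir` and writes `report.json`
#' (machine-readable) and `report.md` (human-readable): significant
#' features per contrast x condition, the composite AUC block, and the
#' cluster stability metrics. Missing stage outputs are listed as not run.
#'
#' @param out_dir directory populated by [run_all()].
#' @param q_threshold significance threshold applied when listing features.
#' @return the report list, invisibly.
#' @export
make_report <- function(out_dir, q_threshold = 0.05) {
  rep <- list(significant_features = "not run", roc = "not run",
              clustering = "not run")
  f_contr <- file.path(out_dir, "contrasts.csv")
  if (file.exists(f_contr)) {
    ct <- utils::read.csv(f_contr, stringsAsFactors = FALSE)
    sig <- ct[ct$q < q_threshold,
              c("condition", "contrast", "feature", "t", "q", "d")]
    rownames(sig) <- NULL
    rep$significant_features <- sig
  }
  f_roc <- file.path(out_dir, "roc.json")
  if (file.exists(f_roc)) {
    rj <- jsonlite::read_json(f_roc, simplifyVector = TRUE)
    rep$roc <- rj[c("condition", "contrast", "weights", "auc", "auc_ci",
                    "youden")]
  }
  f_cl <- file.path(out_dir, "cluster_metrics.json")
  if (file.exists(f_cl))
    rep$clustering <- jsonlite::read_json(f_cl, simplifyVector = TRUE)
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  md <- c("# Pipeline report", "", "## Significant features (q < 0.05)", "")
  if (is.data.frame(rep$significant_features) &&
      nrow(rep$significant_features)) {
    sf <- rep$significant_features
    md <- c(md, paste0("- ", sf$condition, " ", sf$contrast, " ", sf$feature,
                       ": d = ", round(sf$d, 3), ", q = ",
                       signif(sf$q, 3)))
  } else md <- c(md, "(none)")
  md <- c(md, "", "## Composite ROC", "")
  md <- c(md, if (is.list(rep$roc))
    sprintf("AUC = %.3f (95%% CI %.3f-%.3f), sensitivity %.2f, specificity %.2f",
            rep$roc$auc, rep$roc$auc_ci[1], rep$roc$auc_ci[2],
            rep$roc$youden$sensitivity, rep$roc$youden$specificity)
    else "(not run)")
  md <- c(md, "", "## Clinical subtypes", "")
  md <- c(md, if (is.list(rep$clustering))
    sprintf("k = %d (stable: %s), PAC = %.3f, silhouette = %.3f",
            rep$clustering$k, rep$clustering$stable, rep$clustering$pac,
            rep$clustering$silhouette)
    else "(not run)")
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(rep)
}
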