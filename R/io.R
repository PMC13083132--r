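STUDY_GROUPS <- c("SCZ", "SCZ-SIB", "CON", "CON-SIB")
TASK_CONDITIONS <- c("0-back", "1-back", "2-back")

# columns of the clinical-cognitive table, in fixed order
SYMPTOM_COLUMNS <- c(
  "saps_global", "sans_global",
  "saps_hallucinations", "saps_delusions", "saps_bizarre_behavior",
  "saps_formal_thought_disorder",
  "sans_affective_flattening", "sans_alogia", "sans_avolition_apathy",
  "sans_anhedonia_asociality", "sans_attention")
COGNITIVE_COLUMNS <- c(
  "iq", "digit_span", "spatial_span", "lns", "family_pictures",
  "logical_memory", "matrix_reasoning", "vocabulary", "symbol_search")

#' Clinical feature column names
#'
#' The 20 clinical-cognitive features used for subtyping: 2 global symptom
#' scores, 4 positive-symptom (SAPS) domains, 5 negative-symptom (SANS)
#' domains, and 9 neuropsychological scores.
#'
#' @return character vector of length 20.
#' @export
clinical_feature_columns <- function() c(SYMPTOM_COLUMNS, COGNITIVE_COLUMNS)

#' Construct a ROI time-series object
#'
#' One subject x task-condition matrix of mean BOLD signals, rows ordered
#' as the atlas.
#'
#' @param subject_id subject identifier.
#' @param group one of `SCZ`, `SCZ-SIB`, `CON`, `CON-SIB`.
#' @param condition one of `0-back`, `1-back`, `2-back`.
#' @param data numeric R x T matrix, rownames = ROI labels.
#' @param sampling_interval repetition time in seconds.
#' @return an object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(subject_id, group, condition, data,
                           sampling_interval = 2.5) {
  group <- match.arg(group, STUDY_GROUPS)
  condition <- match.arg(condition, TASK_CONDITIONS)
  data <- as.matrix(data)
  if (ncol(data) < 3L) stop_fmt("need at least 3 time points, got %d", ncol(data))
  if (!all(is.finite(data))) stop_fmt("non-finite values in time series")
  if (is.null(rownames(data))) stop_fmt("data must carry ROI labels as rownames")
  structure(list(subject_id = as.character(subject_id), group = group,
                 condition = condition, data = data,
                 sampling_interval = sampling_interval),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("roi_timeseries: %s [%s, %s] %d ROIs x %d volumes (TR %.2fs)\n",
              x$subject_id, x$group, x$condition,
              nrow(x$data), ncol(x$data), x$sampling_interval))
  invisible(x)
}

#' @keywords internal
#' @noRd
timeseries_filename <- function(ts) {
  sprintf("sub-%s_group-%s_task-%s.tsv", ts$subject_id, ts$group, ts$condition)
}

#' @keywords internal
#' @noRd
parse_timeseries_filename <- function(path) {
  base <- basename(path)
  grp <- paste(STUDY_GROUPS, collapse = "|")
  cond <- paste(TASK_CONDITIONS, collapse = "|")
  pat <- sprintf("^sub-(.+)_group-(%s)_task-(%s)\\.tsv$", grp, cond)
  if (!grepl(pat, base)) return(NULL)
  list(subject_id = sub(pat, "\\1", base),
       group = sub(pat, "\\2", base),
       condition = sub(pat, "\\3", base))
}

#' Write a ROI time series to TSV
#'
#' Writes a tab-separated table with a `roi_id` column followed by time
#' points `t0001`, `t0002`, ... A JSON sidecar with subject metadata is
#' written alongside (same basename, `.json`).
#'
#' @param ts a [roi_timeseries()].
#' @param dir output directory (created if needed). The filename follows
#'   the convention `sub-<id>_group-<g>_task-<c>.tsv`.
#' @return the TSV path, invisibly.
#' @export
write_timeseries <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, timeseries_filename(ts))
  # %.17g keeps doubles bit-exact across the round trip
  num <- apply(ts$data, 2L, function(col) sprintf("%.17g", col))
  df <- data.frame(roi_id = rownames(ts$data), num, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("roi_id", sprintf("t%04d", seq_len(ncol(ts$data))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(list(subject_id = ts$subject_id, group = ts$group,
                            condition = ts$condition,
                            sampling_interval = ts$sampling_interval),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ROI time series from TSV
#'
#' Rows are re-ordered to atlas order; subject metadata is taken from the
#' JSON sidecar when present, else parsed from the filename convention
#' `sub-<id>_group-<g>_task-<c>.tsv`.
#'
#' @param path TSV file path.
#' @param atlas an [atlas_map()] fixing ROI order.
#' @return a [roi_timeseries()].
#' @export
read_timeseries <- function(path, atlas) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (names(df)[1L] != "roi_id") stop_fmt("%s: first column must be roi_id", path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop_fmt("%s: non-numeric cell in time series", path)
  dimnames(mat) <- list(df$roi_id, NULL)
  missing <- setdiff(atlas$roi_labels, df$roi_id)
  if (length(missing))
    stop_fmt("%s: missing ROI(s) relative to atlas: %s", path,
             paste(utils::head(missing, 5L), collapse = ", "))
  mat <- mat[atlas$roi_labels, , drop = FALSE]
  side <- sub("\\.tsv$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else parse_timeseries_filename(path)
  if (is.null(meta))
    stop_fmt("%s: no sidecar and filename does not follow sub-/group-/task- convention",
             path)
  roi_timeseries(meta$subject_id, meta$group, meta$condition, mat,
                 sampling_interval = meta$sampling_interval %||% 2.5)
}

#' Construct a framewise-displacement trace
#'
#' @param subject_id subject identifier.
#' @param fd numeric vector of per-volume framewise displacement (mm).
#' @return an object of class `fd_trace`.
#' @export
fd_trace <- function(subject_id, fd) {
  fd <- as.numeric(fd)
  if (!length(fd)) stop_fmt("empty FD trace")
  if (any(!is.finite(fd)) || any(fd < 0))
    stop_fmt("FD values must be finite and non-negative")
  structure(list(subject_id = as.character(subject_id), fd = fd),
            class = "fd_trace")
}

#' Write / read an FD trace (TSV columns volume, fd_mm)
#' @param trace an [fd_trace()].
#' @param dir output directory.
#' @return the file path, invisibly.
#' @export
write_fd_trace <- function(trace, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, sprintf("sub-%s_fd.tsv", trace$subject_id))
  utils::write.table(
    data.frame(volume = seq_along(trace$fd),
               fd_mm = sprintf("%.17g", trace$fd)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fd_trace
#' @param path TSV file path (`sub-<id>_fd.tsv`).
#' @export
read_fd_trace <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  if (!all(c("volume", "fd_mm") %in% names(df)))
    stop_fmt("%s: FD trace needs columns volume, fd_mm", path)
  id <- sub("^sub-(.+)_fd\\.tsv$", "\\1", basename(path))
  fd_trace(id, df$fd_mm[order(df$volume)])
}

#' @keywords internal
#' @noRd
validate_clinical <- function(df, path = "<clinical>") {
  need <- c("subject_id", "group", clinical_feature_columns())
  if (anyDuplicated(names(df))) stop_fmt("%s: duplicate column names", path)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  bad_grp <- setdiff(unique(df$group), STUDY_GROUPS)
  if (length(bad_grp))
    stop_fmt("%s: unknown group label(s): %s", path, paste(bad_grp, collapse = ", "))
  for (col in SYMPTOM_COLUMNS) {
    v <- df[[col]]
    out <- which(!is.na(v) & (v < 0 | v > 5))
    if (length(out))
      stop_fmt("%s: %s out of 0-5 range at row(s) %s", path, col,
               paste(utils::head(out, 5L), collapse = ", "))
  }
  df
}

#' Read / write the clinical-cognitive table (CSV)
#'
#' Columns: `subject_id`, `group`, the 11 symptom scores (0-5 item-mean
#' scale) and 9 cognitive scores (see [clinical_feature_columns()]).
#' Empty cells are missing values; symptom scores outside 0-5 raise a
#' validation error naming the offending rows.
#'
#' @param path CSV file path.
#' @return a `data.frame` with attribute `missing_mask` (logical matrix over
#'   the feature columns).
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  df <- validate_clinical(df, path)
  feat <- clinical_feature_columns()
  attr(df, "missing_mask") <- is.na(as.matrix(df[, feat]))
  df
}

#' @rdname read_clinical_table
#' @param df a validated clinical table.
#' @export
write_clinical_table <- function(df, path) {
  validate_clinical(df)
  keep <- intersect(c("subject_id", "group", clinical_feature_columns(),
                      "true_subtype"), names(df))
  utils::write.csv(df[, keep], path, row.names = FALSE, na = "")
  invisible(path)
}
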