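# Cohort file exchange: CSV or Parquet, two tables (baseline + hourly panel).

BASELINE_REQUIRED <- c("subject_id", "age", "female", "cci", "sepsis",
                       "mech_vent", "vasopressor", "ckd", "full_code",
                       "hospital_pre_hours", "icu_discharge_hour",
                       "rrt_init_hour", "death_hour")

read_table_any <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop_ccw("reading Parquet requires the 'arrow' package")
    as.data.frame(arrow::read_parquet(path))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
}

write_table_any <- function(df, path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop_ccw("writing Parquet requires the 'arrow' package")
    arrow::write_parquet(df, path)
  } else {
    write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a cohort from baseline and panel files
#'
#' Reads the two-table long format (CSV or Parquet, chosen by extension),
#' validates the schema, and reassembles the internal cohort object.
#' Validation failures name the offending column or (subject, hour) pair.
#'
#' @param baseline_path file with one row per subject.
#' @param panel_path file with one row per subject-hour.
#' @return a `ccw_cohort`.
#' @export
read_cohort <- function(baseline_path, panel_path) {
  bl <- read_table_any(baseline_path)
  pn <- read_table_any(panel_path)
  assert_cols(bl, BASELINE_REQUIRED, "baseline table")
  assert_cols(pn, c("subject_id", "hour", PANEL_VARS), "panel table")
  if (any(pn$hour < 0)) stop_ccw("panel contains negative hours")
  key <- paste(pn$subject_id, pn$hour)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop_ccw("duplicate (subject_id, hour) pair in panel: (",
             sub(" ", ", ", d), ")")
  }
  unknown <- setdiff(unique(pn$subject_id), bl$subject_id)
  if (length(unknown))
    stop_ccw("panel has subjects absent from baseline: ",
             paste(head(unknown, 3), collapse = ", "))
  pn <- pn[order(pn$subject_id, pn$hour), , drop = FALSE]
  # hours must start at 0 and step by 1 within subject until truncation
  first <- !duplicated(pn$subject_id)
  if (any(pn$hour[first] != 0))
    stop_ccw("panel hours must start at 0 for every subject (subject ",
             pn$subject_id[first][pn$hour[first] != 0][1L], ")")
  step <- diff(pn$hour)
  bad <- which(step != 1 & !first[-1L]) + 1L
  if (length(bad))
    stop_ccw("non-contiguous panel hours for subject ", pn$subject_id[bad[1L]],
             " at hour ", pn$hour[bad[1L]])

  n <- nrow(bl)
  H1 <- max(pn$hour) + 1L
  idx <- cbind(match(pn$subject_id, bl$subject_id), pn$hour + 1L)
  panel <- lapply(setNames(PANEL_VARS, PANEL_VARS), function(v) {
    m <- matrix(NA_real_, n, H1)
    m[idx] <- pn[[v]]
    m
  })
  kdigo <- NULL
  if (!anyNA(panel$creatinine[, 1L])) {
    kdigo <- kdigo_stage_matrix(panel$creatinine, panel$creatinine[, 1L])
  }
  for (col in c("rrt_init_hour", "death_hour"))
    bl[[col]] <- as.numeric(bl[[col]])
  structure(list(baseline = bl, panel = panel, kdigo = kdigo,
                 hours = 0:(H1 - 1L),
                 config = NULL), class = "ccw_cohort")
}

#' Write a cohort (and optional ground truth) to files
#'
#' Emits `baseline.<ext>` and `panel.<ext>` into `dir` (CSV by default,
#' Parquet with `format = "parquet"`), and `ground_truth.json` when a
#' [simulate_counterfactual_truth()] result is supplied.
#'
#' @param cohort a `ccw_cohort`.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"parquet"`.
#' @param ground_truth optional `ground_truth` object.
#' @return the output paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "parquet"),
                         ground_truth = NULL) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- cohort_tables(cohort)
  ext <- if (format == "csv") ".csv" else ".parquet"
  paths <- c(
    baseline = file.path(dir, paste0("baseline", ext)),
    panel = file.path(dir, paste0("panel", ext))
  )
  write_table_any(tabs$baseline, paths[["baseline"]])
  write_table_any(tabs$panel, paths[["panel"]])
  if (!is.null(ground_truth)) {
    gt_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(unclass(ground_truth), gt_path,
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, ground_truth = gt_path)
  }
  invisible(paths)
}
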