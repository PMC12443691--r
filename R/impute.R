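#' Last-observation-carried-forward imputation of the hourly panel
#'
#' Replaces each missing time-varying value with the subject's most recent
#' observed value. A leading gap (missing at hour 0) has no preceding hour
#' and is filled from the subject's baseline value of the variable, taken as
#' the first observed value of the series; a series with no observed value at
#' all stays missing.
#'
#' @param x a `ccw_cohort` or a long panel data frame (columns `subject_id`,
#'   `hour`, one column per variable, sorted by subject then hour).
#' @param ... unused.
#' @return object of the same class with the panel filled.
#' @export
locf_impute <- function(x, ...) UseMethod("locf_impute")

first_observed <- function(m) {
  lead <- m[, 1L]
  nas <- which(is.na(lead))
  for (i in nas) {
    obs <- which(!is.na(m[i, ]))
    if (length(obs)) lead[i] <- m[i, obs[1L]]
  }
  lead
}

#' @export
locf_impute.ccw_cohort <- function(x, ...) {
  for (v in names(x$panel)) {
    m <- x$panel[[v]]
    if (anyNA(m)) x$panel[[v]] <- locf_matrix(m, lead = first_observed(m))
  }
  if (!is.null(x$panel$creatinine))
    x$kdigo <- kdigo_stage_matrix(x$panel$creatinine, x$panel$creatinine[, 1L])
  x
}

#' @export
locf_impute.data.frame <- function(x, ...) {
  assert_cols(x, c("subject_id", "hour"), "panel")
  x <- x[order(x$subject_id, x$hour), , drop = FALSE]
  vars <- setdiff(names(x), c("subject_id", "hour"))
  new_subj <- c(TRUE, x$subject_id[-1L] != x$subject_id[-nrow(x)])
  nr <- nrow(x)
  for (v in vars) {
    col <- x[[v]]
    if (!anyNA(col)) next
    # forward fill within subject
    for (i in seq_len(nr)[-1L]) {
      if (is.na(col[i]) && !new_subj[i]) col[i] <- col[i - 1L]
    }
    # remaining NAs are leading gaps: seed from the first observed value
    for (i in rev(seq_len(max(nr - 1L, 0L)))) {
      if (is.na(col[i]) && !new_subj[i + 1L] && !is.na(col[i + 1L]))
        col[i] <- col[i + 1L]
    }
    x[[v]] <- col
  }
  x
}

#' Predictive mean matching imputation of the baseline table
#'
#' Chained-equations multiple imputation with predictive mean matching
#' (PMM) for incomplete numeric baseline variables. Records missing the sex
#' indicator are removed outright. Each incomplete variable is regressed on
#' the other numeric covariates over the observed rows; every missing entry
#' is replaced by the observed value of one of the `k` donors whose
#' predicted means are nearest to the missing entry's prediction, so imputed
#' values always lie in the observed support. The chain sweeps all
#' incomplete variables `sweeps` times per imputation.
#'
#' @param baseline baseline data frame (one row per subject).
#' @param m number of completed tables (default 1; the analysis pipeline
#'   uses the first, additional tables serve sensitivity diagnostics).
#' @param k donor pool size (default 5).
#' @param sweeps chained-equation sweeps (default 10).
#' @param seed RNG seed.
#' @param exclude columns never used as model variables (identifiers and
#'   outcome/timing fields).
#' @return list of `m` completed data frames; attribute `"dropped_missing_sex"`
#'   counts removed records.
#' @export
pmm_impute <- function(baseline, m = 1L, k = 5L, sweeps = 10L, seed = 1L,
                       exclude = c("subject_id", "rrt_init_hour", "death_hour",
                                   "icu_discharge_hour")) {
  stopifnot(is.data.frame(baseline))
  dropped <- 0L
  if ("female" %in% names(baseline) && anyNA(baseline$female)) {
    dropped <- sum(is.na(baseline$female))
    baseline <- baseline[!is.na(baseline$female), , drop = FALSE]
  }
  num_vars <- names(baseline)[vapply(baseline, is.numeric, logical(1))]
  num_vars <- setdiff(num_vars, exclude)
  incomplete <- num_vars[vapply(num_vars, function(v) anyNA(baseline[[v]]), logical(1))]
  for (v in incomplete) {
    if (sum(!is.na(baseline[[v]])) < max(k, 2L))
      stop_ccw("variable '", v, "' has too few complete donors for PMM")
  }
  set.seed(seed)
  out <- vector("list", m)
  for (imp in seq_len(m)) {
    df <- baseline
    # initialize holes by sampling observed values
    for (v in incomplete) {
      nas <- is.na(df[[v]])
      df[[v]][nas] <- sample(df[[v]][!nas], sum(nas), replace = TRUE)
    }
    if (length(incomplete)) {
      for (sw in seq_len(sweeps)) {
        for (v in incomplete) {
          nas <- is.na(baseline[[v]])
          preds <- setdiff(num_vars, v)
          fml <- if (length(preds))
            as.formula(paste(v, "~", paste(preds, collapse = "+")))
          else as.formula(paste(v, "~ 1"))
          fit <- lm(fml, data = df[!nas, , drop = FALSE])
          yhat_all <- predict(fit, newdata = df)
          yhat_obs <- yhat_all[!nas]
          y_obs <- baseline[[v]][!nas]
          yhat_mis <- yhat_all[nas]
          kk <- min(k, length(y_obs))
          imp_vals <- vapply(yhat_mis, function(p) {
            d <- abs(yhat_obs - p)
            donors <- y_obs[order(d)[seq_len(kk)]]
            donors[sample.int(kk, 1L)]
          }, numeric(1))
          df[[v]][nas] <- imp_vals
        }
      }
    }
    out[[imp]] <- df
  }
  attr(out, "dropped_missing_sex") <- dropped
  out
}
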