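#' Eligibility criteria for an emulated RRT timing trial
#'
#' @param min_icu_hours required ICU stay, hours (stay must *exceed* this;
#'   default 72).
#' @param min_resp_rate respiratory rate threshold, breaths/min; the rate at
#'   the candidate eligibility hour must exceed it (default 10).
#' @param require_no_ckd exclude subjects with pre-existing chronic kidney
#'   disease (default `TRUE`).
#' @param require_full_code require full code status (default `TRUE`).
#' @param min_pre_randomization_hours required hours of hospitalization
#'   before time zero (default 12); in-hospital hours before ICU admission
#'   count toward it.
#' @param min_aki_stage minimum KDIGO stage at time zero: 1 for the broad
#'   trial, 3 for the severe-AKI trial.
#' @param eligibility_window_hours window (hours from ICU admission) within
#'   which the criteria must first be met (default 72).
#' @return object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(min_icu_hours = 72,
                                 min_resp_rate = 10,
                                 require_no_ckd = TRUE,
                                 require_full_code = TRUE,
                                 min_pre_randomization_hours = 12,
                                 min_aki_stage = 1L,
                                 eligibility_window_hours = 72) {
  if (!min_aki_stage %in% 1:3) stop_ccw("min_aki_stage must be 1, 2 or 3")
  if (min_icu_hours < 0 || min_resp_rate < 0 || min_pre_randomization_hours < 0 ||
      eligibility_window_hours < 0)
    stop_ccw("eligibility thresholds must be non-negative")
  structure(list(
    min_icu_hours = min_icu_hours,
    min_resp_rate = min_resp_rate,
    require_no_ckd = isTRUE(require_no_ckd),
    require_full_code = isTRUE(require_full_code),
    min_pre_randomization_hours = min_pre_randomization_hours,
    min_aki_stage = as.integer(min_aki_stage),
    eligibility_window_hours = eligibility_window_hours
  ), class = "eligibility_criteria")
}

#' Screen a cohort for trial eligibility
#'
#' Evaluates the eligibility criteria on the hourly grid and assigns each
#' qualifying subject a time zero at the *first* hour all criteria hold
#' within the eligibility window. Hour-level criteria are the KDIGO stage
#' (creatinine-based, staged against the first recorded creatinine), the
#' respiratory-rate threshold, being alive, RRT-naive, and having accrued
#' the required pre-randomization hospital hours; subject-level criteria are
#' the ICU-stay duration, CKD history and code status. Missing hour-level
#' values fail the hour; missing subject-level fields are a hard error
#' (impute first).
#'
#' @param cohort a `ccw_cohort` (simulated or read from files, after
#'   imputation if the data have holes).
#' @param criteria an [eligibility_criteria()].
#' @return data frame of eligible subjects (one row each) with
#'   `time_zero_hour`, `aki_stage_t0`, the baseline covariates, the panel
#'   covariates snapshotted at time zero, and follow-up fields relative to
#'   time zero (`rrt_init_rel_hour`, `death_rel_hour`). Attribute
#'   `"exclusions"` tallies excluded subjects per criterion (sequential
#'   attribution, CONSORT style); the tally sums to `n - n_eligible`.
#' @export
apply_eligibility <- function(cohort, criteria = eligibility_criteria()) {
  stopifnot(inherits(cohort, "ccw_cohort"), inherits(criteria, "eligibility_criteria"))
  bl <- cohort$baseline
  n <- nrow(bl)
  W1 <- as.integer(criteria$eligibility_window_hours) + 1L
  if (W1 > length(cohort$hours))
    stop_ccw("panel does not cover the eligibility window")
  for (f in c("icu_discharge_hour", "ckd", "full_code", "hospital_pre_hours")) {
    if (any(is.na(bl[[f]])))
      stop_ccw("baseline field '", f, "' has missing values; impute before screening")
  }
  empty <- eligible_skeleton(cohort)
  if (n == 0L) {
    attr(empty, "exclusions") <- c(icu_stay = 0L, ckd = 0L, full_code = 0L,
                                   no_qualifying_hour = 0L)
    return(empty)
  }

  kdigo <- cohort$kdigo
  if (is.null(kdigo)) {
    base_creat <- cohort$panel$creatinine[, 1L]
    kdigo <- kdigo_stage_matrix(cohort$panel$creatinine, base_creat)
  }

  ok_icu <- bl$icu_discharge_hour > criteria$min_icu_hours
  ok_ckd <- if (criteria$require_no_ckd) bl$ckd == 0L else rep(TRUE, n)
  ok_code <- if (criteria$require_full_code) bl$full_code == 1L else rep(TRUE, n)

  hours <- 0:(W1 - 1L)
  rr <- cohort$panel$resp_rate[, seq_len(W1), drop = FALSE]
  ok_rr <- !is.na(rr) & rr > criteria$min_resp_rate
  st <- kdigo[, seq_len(W1), drop = FALSE]
  ok_stage <- !is.na(st) & st >= criteria$min_aki_stage
  death <- ifelse(is.na(bl$death_hour), Inf, bl$death_hour)
  ok_alive <- outer(death, hours, ">")
  init <- ifelse(is.na(bl$rrt_init_hour), Inf, bl$rrt_init_hour)
  ok_naive <- outer(init, hours, ">=")
  ok_pre <- outer(bl$hospital_pre_hours, hours, "+") >=
    criteria$min_pre_randomization_hours

  E <- ok_rr & ok_stage & ok_alive & ok_naive & ok_pre &
    ok_icu & ok_ckd & ok_code
  t0 <- first_true_col(E) - 1L
  keep <- which(!is.na(t0))

  excl <- c(
    icu_stay = sum(!ok_icu),
    ckd = sum(ok_icu & !ok_ckd),
    full_code = sum(ok_icu & ok_ckd & !ok_code),
    no_qualifying_hour = sum(ok_icu & ok_ckd & ok_code & is.na(t0))
  )

  if (!length(keep)) {
    attr(empty, "exclusions") <- excl
    return(empty)
  }
  t0k <- t0[keep]
  snap_idx <- cbind(keep, t0k + 1L)
  out <- data.frame(
    subject_id = bl$subject_id[keep],
    time_zero_hour = t0k,
    aki_stage_t0 = kdigo[snap_idx],
    age = bl$age[keep], female = bl$female[keep], race = bl$race[keep],
    cci = bl$cci[keep], sepsis = bl$sepsis[keep],
    mech_vent = bl$mech_vent[keep], vasopressor = bl$vasopressor[keep],
    stringsAsFactors = FALSE
  )
  for (v in PANEL_VARS) out[[v]] <- cohort$panel[[v]][snap_idx]
  ih <- bl$rrt_init_hour[keep]
  out$rrt_init_rel_hour <- ifelse(is.na(ih), NA_real_, ih - t0k)
  dh <- bl$death_hour[keep]
  out$death_rel_hour <- ifelse(is.na(dh), NA_real_, dh - t0k)
  attr(out, "exclusions") <- excl
  out
}

eligible_skeleton <- function(cohort) {
  out <- data.frame(subject_id = integer(), time_zero_hour = integer(),
                    aki_stage_t0 = integer(), age = numeric(),
                    female = integer(), race = character(), cci = numeric(),
                    sepsis = integer(), mech_vent = integer(),
                    vasopressor = integer(), stringsAsFactors = FALSE)
  for (v in PANEL_VARS) out[[v]] <- numeric()
  out$rrt_init_rel_hour <- numeric()
  out$death_rel_hour <- numeric()
  out
}
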