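#' Configuration for the synthetic ICU cohort generator
#'
#' Builds the configuration object consumed by [simulate_cohort()] and
#' [simulate_counterfactual_truth()]. The generator emulates the structure of
#' an hourly ICU EHR extract: baseline demographics and comorbidity,
#' hourly vitals/labs evolving as bounded random walks and AR(1) processes,
#' KDIGO-stageable creatinine trajectories, a confounded discrete-time
#' logistic hazard of RRT initiation (sicker patients initiate sooner), and a
#' discrete-time logistic death hazard with a front-loaded time trend. Death
#' is simulated hourly while the covariate panel runs and daily thereafter up
#' to the follow-up horizon.
#'
#' @param n_subjects number of subjects (>= 0).
#' @param seed integer seed; identical configs (including the seed) reproduce
#'   byte-identical cohorts.
#' @param grace_hours grace period (hours) used by the counterfactual "early"
#'   strategy, which follows the natural initiation hazard and forces
#'   initiation at the end of the grace window. Default 72.
#' @param horizon_days follow-up horizon in days (default 90).
#' @param panel_hours hours of hourly covariate panel simulated per subject
#'   (default 168 = 7 days, covering a 72 h eligibility window plus a 72 h
#'   grace period with margin). RRT initiation can occur at any panel hour.
#' @param scenario one of `"null"` (no treatment effect on death),
#'   `"protective"` (log-HR -0.35 once treated), `"stage_split"` (harmful in
#'   KDIGO stages 1-2, protective in stage 3). Sets `treatment_log_hr` unless
#'   that is supplied directly.
#' @param treatment_log_hr either a single log hazard ratio applied to the
#'   death hazard from the initiation hour on, or a named vector
#'   `c(stage1 =, stage2 =, stage3 =)` resolved at the KDIGO stage on the
#'   initiation hour (stage 0 uses `stage1`).
#' @param baseline_coefs named numeric vector for the hourly initiation
#'   hazard on the logit scale. Recognized names: `intercept`, `sofa`,
#'   `sepsis`, `vasopressor`, `age10` (per decade above 65), `hour`
#'   (per absolute hour). All drivers are covariates of the default
#'   weight-model specification, so the analysis weight model is congenial.
#' @param outcome_coefs named numeric vector for the hourly death hazard:
#'   `intercept`, `sofa`, `lactate`, `creatinine`, `sepsis`, `cci`, `age10`,
#'   `log_days` (coefficient on log(1 + t/24); negative values front-load
#'   mortality into the acute phase, as seen in ICU cohorts).
#' @param missing_rates named list/vector of probabilities used by
#'   [inject_missingness()]; names refer to baseline or panel columns.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects,
                       seed = 1L,
                       grace_hours = 72L,
                       horizon_days = 90L,
                       panel_hours = 168L,
                       scenario = c("null", "protective", "stage_split"),
                       treatment_log_hr = NULL,
                       baseline_coefs = NULL,
                       outcome_coefs = NULL,
                       missing_rates = NULL) {
  scenario <- match.arg(scenario)
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 0)
    stop_ccw("n_subjects must be a single non-negative count")
  if (grace_hours < 1) stop_ccw("grace_hours must be >= 1")
  if (horizon_days < 1) stop_ccw("horizon_days must be >= 1")
  if (panel_hours < grace_hours + 72)
    stop_ccw("panel_hours must cover the eligibility window plus the grace period")
  if (is.null(treatment_log_hr)) {
    treatment_log_hr <- switch(scenario,
      null = 0,
      protective = -0.35,
      stage_split = c(stage1 = 0.35, stage2 = 0.35, stage3 = -0.45))
  }
  bc <- c(intercept = -6.35, sofa = 0.15, sepsis = 0.35, vasopressor = 0.5,
          age10 = 0.05, hour = -0.018)
  if (!is.null(baseline_coefs)) bc[names(baseline_coefs)] <- baseline_coefs
  oc <- c(intercept = -7.75, sofa = 0.13, lactate = 0.18, creatinine = 0.06,
          sepsis = 0.25, cci = 0.07, age10 = 0.25, log_days = -1.3)
  if (!is.null(outcome_coefs)) oc[names(outcome_coefs)] <- outcome_coefs
  if (!is.null(missing_rates)) {
    mr <- unlist(missing_rates)
    assert_prob(mr, "missing_rates")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    seed = as.integer(seed),
    grace_hours = as.integer(grace_hours),
    horizon_days = as.integer(horizon_days),
    panel_hours = as.integer(panel_hours),
    scenario = scenario,
    treatment_log_hr = treatment_log_hr,
    baseline_coefs = bc,
    outcome_coefs = oc,
    missing_rates = missing_rates
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic ICU cohort configuration\n")
  cat(sprintf("  subjects: %d   seed: %d   scenario: %s\n",
              x$n_subjects, x$seed, x$scenario))
  cat(sprintf("  grace: %d h   horizon: %d d   panel: %d h\n",
              x$grace_hours, x$horizon_days, x$panel_hours))
  if (length(x$treatment_log_hr) > 1L)
    cat("  treatment log-HR by stage:",
        paste(sprintf("%s=%.2f", names(x$treatment_log_hr), x$treatment_log_hr),
              collapse = " "), "\n")
  else
    cat(sprintf("  treatment log-HR: %.2f\n", x$treatment_log_hr))
  invisible(x)
}
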