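# End-to-end pipeline: eligibility -> clone -> censor -> weight -> estimate,
# for one or both emulated trials, plus the naive comparator that exhibits
# immortal time bias.

#' Emulate the RRT timing target trial(s) on a cohort
#'
#' Runs the complete clone-censor-weight analysis for each configured trial:
#' hour-level eligibility screening, cloning into the two strategy arms with
#' protocol-deviation censoring over the grace period, pooled logistic
#' treatment-hazard models and stabilized inverse-probability weights,
#' IPW Cox and Weibull AFT outcome models at each horizon, doubly robust
#' (AIPW) per-strategy risks and risk differences, and balance/collinearity
#' diagnostics. Hourly panels with missing values are LOCF-imputed first and
#' incomplete baseline fields are PMM-imputed.
#'
#' @param cohort a `ccw_cohort` (simulated or read from files).
#' @param trials named list of [eligibility_criteria()], one per emulated
#'   trial. Default: the broad trial (stage >= 1) and the severe trial
#'   (stage 3).
#' @param grace_hours grace period in hours (default 72).
#' @param horizons outcome horizons in days (default `c(30, 90)`).
#' @param weight_spec a [weight_model_spec()].
#' @param estimators subset of `c("cox", "aft", "aipw")`.
#' @param outcome_covariates adjustment covariates for the outcome models.
#' @param seed seed used by the (stochastic) PMM imputation step.
#' @return object of class `ccw_emulation`; see [summary.ccw_emulation()],
#'   [coef.ccw_emulation()].
#' @export
ccw_emulate <- function(cohort,
                        trials = list(trial1 = eligibility_criteria(min_aki_stage = 1),
                                      trial2 = eligibility_criteria(min_aki_stage = 3)),
                        grace_hours = 72,
                        horizons = c(30, 90),
                        weight_spec = weight_model_spec(),
                        estimators = c("cox", "aft", "aipw"),
                        outcome_covariates = OUTCOME_COVARS,
                        seed = 1L) {
  stopifnot(inherits(cohort, "ccw_cohort"))
  if (!length(estimators)) stop_ccw("enable at least one estimator")
  estimators <- match.arg(estimators, several.ok = TRUE)
  if (any(horizons <= 0)) stop_ccw("horizons must be positive")

  if (any(vapply(cohort$panel, anyNA, logical(1))))
    cohort <- locf_impute(cohort)
  base_model_vars <- c("age", "cci", "hospital_pre_hours")
  if (anyNA(cohort$baseline[base_model_vars])) {
    cohort$baseline <- pmm_impute(cohort$baseline, m = 1L, seed = seed)[[1L]]
  }

  res <- lapply(trials, function(cr) {
    ccw_trial(cohort, cr, grace_hours, horizons, weight_spec,
              estimators, outcome_covariates)
  })
  structure(list(trials = res, grace_hours = grace_hours,
                 horizons = horizons, estimators = estimators,
                 n_subjects = nrow(cohort$baseline)),
            class = "ccw_emulation")
}

# One trial: screening through estimation.
ccw_trial <- function(cohort, criteria, grace_hours, horizons, weight_spec,
                      estimators, outcome_covariates) {
  elig <- apply_eligibility(cohort, criteria)
  if (nrow(elig) < 10L)
    stop_ccw("fewer than 10 eligible subjects; cannot emulate the trial")
  hmax <- max(horizons)

  rs <- initiation_risk_set(cohort, elig, grace_hours)
  den <- fit_treatment_hazard_model(rs, weight_spec, "denominator")
  num <- fit_treatment_hazard_model(rs, weight_spec, "numerator")

  clones <- apply_protocol_censoring(
    clone_subjects(elig, grace_hours, horizon_days = hmax))
  pt <- person_time_expand(clones)
  pt <- compute_stabilized_ipw(pt, den, num, weight_spec$truncation)
  wdiag <- attr(pt, "weight_diagnostics")

  # clone-level resolved (truncated) weight = weight on the clone's last row
  last <- !duplicated(pt$clone_row, fromLast = TRUE)
  clones$sw <- NA_real_
  clones$sw[pt$clone_row[last]] <- pt$sw_trunc[last]

  ti <- ifelse(is.na(elig$rrt_init_rel_hour), Inf, elig$rrt_init_rel_hour)
  elig$init_within_grace <- as.integer(ti < grace_hours)

  rw_max <- resolved_clone_weights(elig, den, num, grace_hours, hmax)
  bal_tab <- adherent_clone_table(elig, rw_max, weighting = "regime")
  balance <- smd_balance(bal_tab, weight_spec$denominator, bal_tab$sw)

  vif_vars <- unique(c(weight_spec$denominator, outcome_covariates))
  vif_vars <- drop_constant(elig, intersect(vif_vars, names(elig)))
  vif <- vif_table(elig[vif_vars])

  t1_vars <- c("age", "female", "race", "cci", "sepsis", "mech_vent",
               "vasopressor", PANEL_VARS)
  td <- ifelse(is.na(elig$death_rel_hour), Inf, elig$death_rel_hour)
  t1df <- elig
  t1df$death_90d <- as.integer(td <= 90 * 24)
  t1df$death_30d <- as.integer(td <= 30 * 24)
  t1df$group <- ifelse(elig$init_within_grace == 1L, "rrt_within_grace", "no_rrt")
  table1 <- baseline_table(t1df, "group",
                           c(t1_vars, "death_90d", "death_30d"))

  by_horizon <- lapply(horizons, function(h) {
    out <- list(horizon = h)
    if ("cox" %in% estimators) {
      out$cox <- fit_weighted_cox(pt, outcome_covariates, h)
      out$ph_test <- tryCatch(test_proportional_hazards(out$cox),
                              error = function(e) NULL)
    }
    if ("aft" %in% estimators)
      out$aft <- fit_weibull_aft(clones, outcome_covariates, h)
    if ("aipw" %in% estimators) {
      rw <- resolved_clone_weights(elig, den, num, grace_hours, h)
      act <- adherent_clone_table(elig, rw)
      om_covs <- unique(c(weight_spec$denominator, outcome_covariates))
      om <- fit_outcome_model(act, h, intersect(om_covs, names(act)))
      out$risk_early <- aipw_risk(elig, rw, om, "early", h)
      out$risk_never <- aipw_risk(elig, rw, om, "never", h)
      out$rd <- aipw_risk_difference(out$risk_early, out$risk_never)
    }
    out
  })
  names(by_horizon) <- paste0("d", horizons)

  curves <- if ("cox" %in% estimators)
    survival_curves(clones, outcome_covariates, weight_col = "sw",
                    horizon_days = hmax) else NULL

  list(criteria = criteria,
       n_eligible = nrow(elig),
       n_initiated_within_grace = sum(elig$init_within_grace),
       exclusions = attr(elig, "exclusions"),
       eligible = elig,
       treatment_model = den,
       numerator_model = num,
       weight_diagnostics = wdiag,
       balance = balance,
       vif = vif,
       table1 = table1,
       estimates = by_horizon,
       curves = curves)
}

#' Naive ever-versus-never-treated Cox model
#'
#' The biased comparator the clone-censor-weight design exists to avoid:
#' subjects are classified by whether they *ever* initiated RRT during
#' follow-up and that label is treated as fixed from time zero, so the
#' person-time a starter had to survive to reach initiation is
#' misclassified as treated (immortal time bias).
#'
#' @param eligible output of [apply_eligibility()].
#' @param covariates adjustment covariates (default physiology set).
#' @param horizon_days horizon in days.
#' @return object of class `ccw_cox` (HR of ever- vs never-treated).
#' @export
naive_ever_never_cox <- function(eligible, covariates = OUTCOME_COVARS,
                                 horizon_days = 90) {
  hh <- horizon_days * 24
  td <- ifelse(is.na(eligible$death_rel_hour), Inf, eligible$death_rel_hour)
  ti <- ifelse(is.na(eligible$rrt_init_rel_hour), Inf, eligible$rrt_init_rel_hour)
  df <- eligible
  df$time <- pmin(td, hh) / 24
  df$event <- as.integer(td <= hh)
  df$ever <- as.integer(ti < pmin(td, hh))
  df <- df[df$time > 0, , drop = FALSE]
  covariates <- drop_constant(df, intersect(covariates, names(df)))
  fml <- as.formula(paste("Surv(time, event) ~ ever +",
                          paste(covariates, collapse = " + ")))
  fit <- coxph(fml, data = df, ties = "efron")
  b <- coef(fit)[["ever"]]
  se <- sqrt(diag(fit$var))[[1L]]
  structure(list(hr = exp(b), ci_low = exp(b - qnorm(0.975) * se),
                 ci_high = exp(b + qnorm(0.975) * se),
                 p_value = 2 * pnorm(-abs(b / se)), robust_se = se,
                 horizon = horizon_days,
                 events = tapply(df$event, df$ever, sum),
                 n_subjects = nrow(df), covariates = covariates, fit = fit),
            class = "ccw_cox")
}

#' Run the full emulation from a single configuration
#'
#' Pipeline driver: builds or reads the cohort, runs [ccw_emulate()] for the
#' configured trials, and (optionally) writes the results bundle to disk
#' (JSON estimates, CSV diagnostics, Markdown Table 1). Deterministic given
#' the seed.
#'
#' @param config a list with either `simulate` (arguments to [sim_config()])
#'   or `baseline_path`/`panel_path`; optional `trials`, `grace_hours`,
#'   `horizons`, `estimators`, `seed`, `output_dir`.
#' @return the `ccw_emulation` object, with the stage-count log as
#'   attribute `"log"`.
#' @export
run_emulation <- function(config) {
  seed <- config$seed %||% 1L
  if (!is.null(config$simulate)) {
    sc <- do.call(sim_config, utils::modifyList(config$simulate,
                                                list(seed = seed)))
    cohort <- simulate_cohort(sc)
  } else if (!is.null(config$baseline_path)) {
    cohort <- read_cohort(config$baseline_path, config$panel_path)
  } else {
    stop_ccw("config needs either $simulate or $baseline_path/$panel_path")
  }
  log <- list(n_subjects = nrow(cohort$baseline))
  emu <- ccw_emulate(
    cohort,
    trials = config$trials %||% list(trial1 = eligibility_criteria(min_aki_stage = 1),
                                     trial2 = eligibility_criteria(min_aki_stage = 3)),
    grace_hours = config$grace_hours %||% 72,
    horizons = config$horizons %||% c(30, 90),
    estimators = config$estimators %||% c("cox", "aft", "aipw"),
    seed = seed)
  for (tn in names(emu$trials)) {
    tr <- emu$trials[[tn]]
    log[[tn]] <- list(n_eligible = tr$n_eligible,
                      n_clones = 2L * tr$n_eligible,
                      exclusions = tr$exclusions)
  }
  attr(emu, "log") <- log
  if (!is.null(config$output_dir)) write_results(emu, config$output_dir)
  emu
}

#' Write a results bundle to a directory
#'
#' @param emu a `ccw_emulation`.
#' @param dir output directory.
#' @return output paths, invisibly.
#' @export
write_results <- function(emu, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  est <- coef(emu)
  jsonlite::write_json(est, file.path(dir, "estimates.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  for (tn in names(emu$trials)) {
    tr <- emu$trials[[tn]]
    write.csv(tr$balance, file.path(dir, paste0(tn, "_balance.csv")),
              row.names = FALSE)
    write.csv(tr$vif, file.path(dir, paste0(tn, "_vif.csv")), row.names = FALSE)
    write.csv(as.data.frame(tr$table1), file.path(dir, paste0(tn, "_table1.csv")),
              row.names = FALSE)
    write_table1_md(tr$table1, file.path(dir, paste0(tn, "_table1.md")))
    excl <- data.frame(criterion = names(tr$exclusions),
                       n_excluded = as.integer(tr$exclusions))
    write.csv(excl, file.path(dir, paste0(tn, "_exclusions.csv")),
              row.names = FALSE)
    if (!is.null(tr$curves))
      write.csv(as.data.frame(tr$curves),
                file.path(dir, paste0(tn, "_curves.csv")), row.names = FALSE)
  }
  invisible(dir)
}
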