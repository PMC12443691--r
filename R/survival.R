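# Outcome models on the weighted clone data: IPW Cox, proportional-hazards
# diagnostics, Weibull AFT sensitivity model, and survival curves.

OUTCOME_COVARS <- c("sbp", "mbp", "temperature", "ph", "bicarbonate",
                    "lactate", "hemoglobin", "urea_nitrogen", "creatinine")

drop_constant <- function(df, covs) {
  keep <- vapply(covs, function(v) {
    x <- df[[v]]
    if (!is.numeric(x)) return(FALSE)
    r <- range(x, na.rm = TRUE)
    is.finite(r[1L]) && r[1L] != r[2L]
  }, logical(1))
  covs[keep]
}

censor_at_horizon <- function(time, event, horizon_hours) {
  over <- time > horizon_hours
  event[over] <- 0L
  time[over] <- horizon_hours
  list(time = time, event = event)
}

# Merge consecutive person-time rows of a clone that share the same weight:
# the counting-process partial likelihood is invariant to splitting an
# interval with constant weight and covariates, and never-arm clones carry
# ~70 hourly rows of slowly drifting weights that this reduces to one row
# per change.
collapse_person_time <- function(pt, weight_col) {
  if (!"clone_row" %in% names(pt)) return(pt)
  w <- pt[[weight_col]]
  new_clone <- c(TRUE, diff(pt$clone_row) != 0)
  change <- new_clone | c(TRUE, diff(w) != 0)
  grp <- cumsum(change)
  first <- !duplicated(grp)
  last <- !duplicated(grp, fromLast = TRUE)
  out <- pt[last, , drop = FALSE]
  out$tstart <- pt$tstart[first]
  out
}

#' Weighted Cox model for the strategy effect on mortality
#'
#' Fits an IPW Cox proportional hazards model of death on the strategy arm,
#' adjusted for the time-zero physiology covariates, on the expanded
#' person-time rows. The partial likelihood incorporates the truncated
#' stabilized weights, ties are handled with the Efron approximation, and
#' standard errors are robust (sandwich) clustered on the subject — clones
#' of one subject are copies of the same person and must not count twice.
#'
#' @param person_time weighted person-time from [compute_stabilized_ipw()]
#'   (needs `tstart`, `tstop`, `event`, `arm`, the weight column, the
#'   cluster column, and the covariates).
#' @param covariates adjustment covariate names (default: the time-zero
#'   physiology set). Constant columns are dropped.
#' @param horizon_days if given, follow-up is administratively censored at
#'   this horizon before fitting (30-day estimates are exactly the 90-day
#'   machinery run on data censored at day 30).
#' @param weight_col,cluster_col column names for weights and the robust
#'   cluster.
#' @return object of class `ccw_cox`: `hr`, `ci_low`, `ci_high`, `p_value`,
#'   `robust_se` (log scale), `horizon`, per-arm event counts, and the
#'   underlying `coxph` fit.
#' @export
fit_weighted_cox <- function(person_time, covariates = OUTCOME_COVARS,
                             horizon_days = NULL, weight_col = "sw_trunc",
                             cluster_col = "subject_id") {
  assert_cols(person_time, c("tstart", "tstop", "event", "arm",
                             weight_col, cluster_col), "person-time table")
  df <- person_time
  if (!is.null(horizon_days)) {
    hh <- horizon_days * 24
    df <- df[df$tstart < hh, , drop = FALSE]
    ce <- censor_at_horizon(df$tstop, df$event, hh)
    df$tstop <- ce$time; df$event <- ce$event
  }
  df <- collapse_person_time(df, weight_col)
  w <- df[[weight_col]]
  if (any(!is.finite(w) | w <= 0)) stop_ccw("weights must be positive and finite")
  ev <- tapply(df$event, df$arm, sum)
  if (length(ev) < 2L || any(ev == 0))
    stop_ccw("each arm needs at least one event")
  df$.arm <- factor(df$arm, levels = c("never", "early"))
  df$.w <- w
  df$.cl <- df[[cluster_col]]
  covariates <- drop_constant(df, intersect(covariates, names(df)))
  rhs <- paste(c(".arm", covariates, "cluster(.cl)"), collapse = " + ")
  fit <- coxph(as.formula(paste("Surv(tstart, tstop, event) ~", rhs)),
               data = df, weights = .w, ties = "efron")
  b <- coef(fit)[".armearly"]
  se <- sqrt(diag(fit$var))[which(names(coef(fit)) == ".armearly")]
  structure(list(
    hr = exp(unname(b)),
    ci_low = exp(unname(b - qnorm(0.975) * se)),
    ci_high = exp(unname(b + qnorm(0.975) * se)),
    p_value = 2 * pnorm(-abs(unname(b) / se)),
    robust_se = unname(se),
    horizon = horizon_days %||% attr(person_time, "horizon_days"),
    events = ev,
    n_subjects = length(unique(df$.cl)),
    covariates = covariates,
    fit = fit
  ), class = "ccw_cox")
}

#' @export
print.ccw_cox <- function(x, ...) {
  cat(sprintf("IPW Cox model, %s-day mortality\n", format(x$horizon)))
  cat(sprintf("  HR (early vs never) %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$hr, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  events: early %d / never %d; robust SE (log HR) %.3f, clustered on subject\n",
              x$events[["early"]], x$events[["never"]], x$robust_se))
  invisible(x)
}

#' Schoenfeld-residual test of proportional hazards
#'
#' Correlates the scaled Schoenfeld residuals of a fitted Cox model with
#' Kaplan-Meier-transformed time (the common default, configurable) and
#' returns the per-covariate and global tests.
#'
#' @param cox_fit a `ccw_cox` object or a `coxph` fit.
#' @param transform time transform passed to [survival::cox.zph()]
#'   (default `"km"`).
#' @return object of class `ccw_phtest`: `global_p`, `table` (rows per
#'   covariate plus GLOBAL), and the `cox.zph` object.
#' @export
test_proportional_hazards <- function(cox_fit, transform = "km") {
  fit <- if (inherits(cox_fit, "ccw_cox")) cox_fit$fit else cox_fit
  if (is.null(fit$nevent) || fit$nevent == 0) stop_ccw("no events in the Cox fit")
  z <- cox.zph(fit, transform = transform)
  tab <- as.data.frame(z$table)
  structure(list(global_p = tab["GLOBAL", "p"],
                 table = tab, zph = z), class = "ccw_phtest")
}

#' @export
print.ccw_phtest <- function(x, ...) {
  cat(sprintf("Schoenfeld global PH test: p = %.4g\n", x$global_p))
  print(round(x$table, 4))
  invisible(x)
}

#' Weibull accelerated failure time model
#'
#' Sensitivity model that does not rely on proportional hazards: a Weibull
#' AFT regression of follow-up time on the strategy arm and the time-zero
#' physiology covariates, on one record per clone with its resolved
#' stabilized weight. The exponentiated arm coefficient is the acceleration
#' factor (AF) multiplying survival time under early initiation; robust
#' (sandwich) standard errors are clustered on the subject. Clones censored
#' at time zero carry no information and are dropped.
#'
#' @param clones clone-level data frame with `time` (hours since time zero),
#'   `event`, `arm`, `subject_id`, the covariates and the weight column.
#' @param covariates adjustment covariates (default the physiology set).
#' @param horizon_days optional administrative censoring before fitting.
#' @param weight_col clone-level weight column (default `"sw"`).
#' @return object of class `ccw_aft`: `acceleration_factor`, `ci_low`,
#'   `ci_high`, `p_value`, `percent_change`, `label` (the reporting
#'   convention: "x% reduction in survival time" for AF < 1, "x times
#'   longer" for AF > 1), Weibull `shape`/`scale`, and the `survreg` fit.
#' @export
fit_weibull_aft <- function(clones, covariates = OUTCOME_COVARS,
                            horizon_days = NULL, weight_col = "sw") {
  assert_cols(clones, c("time", "event", "arm", "subject_id", weight_col),
              "clone table")
  df <- clones
  if (!is.null(horizon_days)) {
    ce <- censor_at_horizon(df$time, df$event, horizon_days * 24)
    df$time <- ce$time; df$event <- ce$event
  }
  df <- df[df$time > 0, , drop = FALSE]
  df$.time_d <- df$time / 24
  df$.arm <- factor(df$arm, levels = c("never", "early"))
  df$.w <- df[[weight_col]]
  covariates <- drop_constant(df, intersect(covariates, names(df)))
  rhs <- paste(c(".arm", covariates, "cluster(subject_id)"), collapse = " + ")
  fit <- tryCatch(
    survreg(as.formula(paste("Surv(.time_d, event) ~", rhs)), data = df,
            weights = .w, dist = "weibull", robust = TRUE),
    error = function(e) stop_ccw("Weibull AFT did not converge: ", conditionMessage(e)))
  b <- coef(fit)[".armearly"]
  i <- which(names(coef(fit)) == ".armearly")
  se <- sqrt(diag(fit$var))[i]
  af <- exp(unname(b))
  ci <- exp(unname(b) + c(-1, 1) * qnorm(0.975) * se)
  structure(list(
    acceleration_factor = af,
    ci_low = ci[1], ci_high = ci[2],
    p_value = 2 * pnorm(-abs(unname(b) / se)),
    robust_se = unname(se),
    percent_change = if (af < 1) (1 - af) * 100 else (af - 1) * 100,
    label = aft_label(af, ci),
    shape = 1 / fit$scale,
    scale_param = fit$scale,
    horizon = horizon_days %||% attr(clones, "horizon_days"),
    fit = fit
  ), class = "ccw_aft")
}

# Reporting convention for acceleration factors: below 1 as a percent
# reduction in survival time, above 1 as a multiplicative lengthening.
aft_label <- function(af, ci) {
  if (af < 1) {
    sprintf("%.1f%% (95%% CI: %.1f-%.1f%%) reduction in survival time",
            (1 - af) * 100, (1 - ci[2]) * 100, (1 - ci[1]) * 100)
  } else {
    sprintf("%.2f (95%% CI: %.2f-%.2f) times longer survival", af, ci[1], ci[2])
  }
}

#' @export
print.ccw_aft <- function(x, ...) {
  cat(sprintf("Weibull AFT model, %s-day horizon (shape k = %.2f)\n",
              format(x$horizon), x$shape))
  cat(sprintf("  AF (early vs never) %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$acceleration_factor, x$ci_low, x$ci_high, x$p_value))
  cat("  ", x$label, "\n", sep = "")
  invisible(x)
}

#' Survival curves per strategy arm
#'
#' Two complementary sets of curves: the weighted product-limit
#' (Kaplan-Meier) estimate per arm using the resolved clone weights, and
#' covariate-adjusted curves from a Cox model stratified on the arm,
#' evaluated at the covariate means. With unit weights the first reduces to
#' the classical Kaplan-Meier estimate.
#'
#' @param clones clone-level data frame (`time` in hours, `event`, `arm`,
#'   weight column, covariates).
#' @param covariates covariates for the adjusted (stratified Cox) curves;
#'   `NULL` skips them.
#' @param weight_col clone weight column.
#' @param horizon_days optional administrative censoring.
#' @return data frame of class `ccw_curves`: `type` (`"weighted_km"` or
#'   `"cox_adjusted"`), `arm`, `time` (days), `surv`, `n_risk`.
#' @export
survival_curves <- function(clones, covariates = NULL, weight_col = "sw",
                            horizon_days = NULL) {
  df <- clones
  if (!is.null(horizon_days)) {
    ce <- censor_at_horizon(df$time, df$event, horizon_days * 24)
    df$time <- ce$time; df$event <- ce$event
  }
  df <- df[df$time > 0, , drop = FALSE]
  df$.time_d <- df$time / 24
  df$.w <- df[[weight_col]]
  km <- survfit(Surv(.time_d, event) ~ arm, data = df, weights = .w)
  arm_lab <- sub("^arm=", "", rep(names(km$strata), km$strata))
  out <- data.frame(type = "weighted_km", arm = arm_lab, time = km$time,
                    surv = km$surv, n_risk = km$n.risk,
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- drop_constant(df, intersect(covariates, names(df)))
    fml <- as.formula(paste("Surv(.time_d, event) ~",
                            paste(c(covariates, "strata(arm)"), collapse = " + ")))
    cfit <- coxph(fml, data = df, weights = .w, ties = "efron")
    nd <- as.data.frame(lapply(df[covariates], mean))
    sf <- survfit(cfit, newdata = nd)
    arm2 <- sub("^arm=", "", rep(names(sf$strata), sf$strata))
    out <- rbind(out, data.frame(type = "cox_adjusted", arm = arm2,
                                 time = sf$time, surv = as.numeric(sf$surv),
                                 n_risk = sf$n.risk, stringsAsFactors = FALSE))
  }
  class(out) <- c("ccw_curves", "data.frame")
  out
}

#' @export
plot.ccw_curves <- function(x, type = "weighted_km", ...) {
  d <- x[x$type == type, , drop = FALSE]
  plot(NA, xlim = range(0, d$time), ylim = c(0, 1),
       xlab = "Days since time zero", ylab = "Survival probability",
       main = sprintf("Survival by strategy (%s)", type), ...)
  cols <- c(early = "#2166ac", never = "#b2182b")
  for (a in unique(d$arm)) {
    da <- d[d$arm == a, ]
    lines(stats::stepfun(da$time, c(1, da$surv)), do.points = FALSE,
          col = cols[[a]] %||% "black", lwd = 2)
  }
  graphics::legend("bottomleft", legend = names(cols), col = cols, lwd = 2, bty = "n")
  invisible(x)
}
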