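# S3 methods for the fitted emulation object.

#' @export
print.ccw_emulation <- function(x, ...) {
  cat("Clone-censor-weight target trial emulation\n")
  cat(sprintf("  cohort: %d subjects; grace period %g h; horizons %s days\n",
              x$n_subjects, x$grace_hours,
              paste(x$horizons, collapse = "/")))
  for (tn in names(x$trials)) {
    tr <- x$trials[[tn]]
    cat(sprintf("  %s (stage >= %d): %d eligible, %d initiated within grace\n",
                tn, tr$criteria$min_aki_stage, tr$n_eligible,
                tr$n_initiated_within_grace))
  }
  cat("Use summary() for estimates, coef() for the estimate table.\n")
  invisible(x)
}

#' Summarize an emulation fit
#'
#' @param object a `ccw_emulation`.
#' @param ... unused.
#' @export
summary.ccw_emulation <- function(object, ...) {
  for (tn in names(object$trials)) {
    tr <- object$trials[[tn]]
    cat(sprintf("== %s: KDIGO stage >= %d, %d eligible (%d initiated within %g h) ==\n",
                tn, tr$criteria$min_aki_stage, tr$n_eligible,
                tr$n_initiated_within_grace, object$grace_hours))
    cat(sprintf("  mean stabilized weight %.3f; max |SMD| after weighting %.3f; max VIF %.2f\n",
                tr$weight_diagnostics$mean_sw,
                max(abs(tr$balance$smd_weighted), na.rm = TRUE),
                max(tr$vif$vif[is.finite(tr$vif$vif)])))
    for (h in names(tr$estimates)) {
      e <- tr$estimates[[h]]
      cat(sprintf("  -- %s-day mortality --\n", sub("^d", "", h)))
      if (!is.null(e$cox))
        cat(sprintf("   Cox HR %.3f (%.3f-%.3f), p=%.3g%s\n", e$cox$hr,
                    e$cox$ci_low, e$cox$ci_high, e$cox$p_value,
                    if (!is.null(e$ph_test))
                      sprintf("; PH global p=%.3g", e$ph_test$global_p) else ""))
      if (!is.null(e$aft))
        cat(sprintf("   AFT AF %.3f (%.3f-%.3f): %s\n",
                    e$aft$acceleration_factor, e$aft$ci_low, e$aft$ci_high,
                    e$aft$label))
      if (!is.null(e$rd))
        cat(sprintf("   AIPW risk early %.1f%% never %.1f%%; rd %.1f pp (%.1f to %.1f)\n",
                    100 * e$risk_early$risk, 100 * e$risk_never$risk,
                    e$rd$rd, e$rd$ci_low, e$rd$ci_high))
    }
  }
  invisible(object)
}

#' Estimate table of an emulation fit
#'
#' @param object a `ccw_emulation`.
#' @param ... unused.
#' @return data frame with one row per trial x horizon x estimator:
#'   `estimate` is the HR (Cox), acceleration factor (AFT), risk (AIPW
#'   risks, proportion) or risk difference (percentage points).
#' @export
coef.ccw_emulation <- function(object, ...) {
  rows <- list()
  add <- function(trial, horizon, estimator, est, lo, hi, p = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      trial = trial, horizon_days = horizon, estimator = estimator,
      estimate = est, ci_low = lo, ci_high = hi, p_value = p,
      stringsAsFactors = FALSE)
  }
  for (tn in names(object$trials)) {
    tr <- object$trials[[tn]]
    for (h in names(tr$estimates)) {
      e <- tr$estimates[[h]]
      hd <- as.numeric(sub("^d", "", h))
      if (!is.null(e$cox))
        add(tn, hd, "cox_hr", e$cox$hr, e$cox$ci_low, e$cox$ci_high, e$cox$p_value)
      if (!is.null(e$aft))
        add(tn, hd, "aft_af", e$aft$acceleration_factor, e$aft$ci_low,
            e$aft$ci_high, e$aft$p_value)
      if (!is.null(e$rd)) {
        add(tn, hd, "aipw_risk_early", e$risk_early$risk,
            e$risk_early$ci_low, e$risk_early$ci_high)
        add(tn, hd, "aipw_risk_never", e$risk_never$risk,
            e$risk_never$ci_low, e$risk_never$ci_high)
        add(tn, hd, "aipw_rd_pp", e$rd$rd, e$rd$ci_low, e$rd$ci_high)
      }
    }
  }
  do.call(rbind, rows)
}

#' Plot survival curves of an emulation fit
#'
#' @param x a `ccw_emulation`.
#' @param trial trial name (default first).
#' @param type `"weighted_km"` or `"cox_adjusted"`.
#' @param ... passed to [plot.ccw_curves()].
#' @export
plot.ccw_emulation <- function(x, trial = names(x$trials)[1L],
                               type = "weighted_km", ...) {
  cur <- x$trials[[trial]]$curves
  if (is.null(cur)) stop_ccw("no curves stored (Cox estimator disabled)")
  plot(cur, type = type, ...)
}
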