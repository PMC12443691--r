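# Doubly robust (augmented IPW) estimation of fixed-horizon mortality risks
# per strategy and their difference.

#' Outcome model for death by a fixed horizon
#'
#' Weighted logistic regression of death-by-horizon on the strategy arm and
#' the time-zero covariates, fitted among the clones adherent to their
#' strategy through the grace period (each weighted by its resolved
#' stabilized weight). Supplies the outcome predictions m_a(X) used by the
#' AIPW estimator.
#'
#' @param adherent_clones data frame with one row per adherent clone:
#'   `arm`, `Y` (0/1 death by horizon), covariates, and a weight column.
#' @param horizon_days outcome horizon (bookkeeping; `Y` must already match).
#' @param covariates covariate names.
#' @param weight_col weight column (use unit weights for an unweighted fit).
#' @return object of class `ccw_outcome_fit`; `predict()` with `arm =`
#'   returns per-subject predicted risks under that strategy.
#' @export
fit_outcome_model <- function(adherent_clones, horizon_days, covariates,
                              weight_col = "sw") {
  assert_cols(adherent_clones, c("arm", "Y", weight_col, covariates),
              "adherent clone table")
  df <- adherent_clones
  df$.arm <- factor(df$arm, levels = c("never", "early"))
  df$.w <- df[[weight_col]]
  covariates <- drop_constant(df, covariates)
  fml <- as.formula(paste("Y ~ .arm +",
                          paste(c("1", covariates), collapse = " + ")))
  fit <- suppressWarnings(  # non-integer weighted binomial likelihood
    glm(fml, data = df, family = binomial(), weights = .w, model = FALSE))
  if (!fit$converged) stop_ccw("outcome model did not converge")
  bad <- separated_covariates(fit, df, covariates)
  if (length(bad))
    stop_ccw("possible separation in the outcome model; check covariate(s): ",
             paste(bad, collapse = ", "))
  X <- model.matrix(stats::delete.response(stats::terms(fml)), df)
  structure(list(fit = fit, covariates = covariates,
                 horizon = horizon_days,
                 X = X, Y = df$Y, sw = df$.w,
                 fitted = as.numeric(fit$fitted.values),
                 subject_id = df$subject_id,
                 vc = suppressWarnings(vcov(fit))),
            class = "ccw_outcome_fit")
}

#' @export
predict.ccw_outcome_fit <- function(object, newdata, arm, ...) {
  nd <- newdata
  nd$.arm <- factor(arm, levels = c("never", "early"))
  as.numeric(predict(object$fit, newdata = nd, type = "response"))
}

#' AIPW risk of death under one strategy
#'
#' Augmented inverse-probability-weighted estimate of the horizon mortality
#' risk had everyone followed the given strategy:
#' \deqn{\hat\psi_a = \frac{1}{n}\sum_i \hat m_a(X_i) +
#'   \frac{\sum_i D_i(a)\,sw_i\,(Y_i - \hat m_a(X_i))}{\sum_i D_i(a)\,sw_i}}
#' where \eqn{D_i(a)} indicates adherence to strategy a through the grace
#' period (grace-period deaths are adherent to both) and \eqn{sw_i} is the
#' resolved stabilized weight. The augmentation term is normalized by the
#' realized weight mass (Hajek form), which keeps the estimator doubly
#' robust under the grace-period design. Confidence intervals come from the
#' influence-function standard error.
#'
#' @param eligible eligible-subject table (one row per subject, time-zero
#'   covariates).
#' @param adherence_weights output of [resolved_clone_weights()] with `Y`
#'   computed at this horizon.
#' @param outcome_fit a [fit_outcome_model()] at the same horizon.
#' @param strategy `"early"` or `"never"`.
#' @param horizon_days horizon in days.
#' @return object of class `ccw_risk`: `strategy`, `horizon`, `risk`,
#'   `ci_low`, `ci_high`, `se`, `n`, and the per-subject influence
#'   contributions (`phi`) used for covariance-aware differences.
#' @export
aipw_risk <- function(eligible, adherence_weights, outcome_fit,
                      strategy = c("early", "never"), horizon_days) {
  strategy <- match.arg(strategy)
  aw <- adherence_weights
  if (!identical(aw$subject_id, eligible$subject_id))
    stop_ccw("adherence weights and eligible table must align by subject")
  D <- if (strategy == "early") aw$D_early else aw$D_never
  sw <- if (strategy == "early") {
    if (!is.null(aw$sw_early_reg)) aw$sw_early_reg else aw$sw_early
  } else aw$sw_never
  if (sum(D) == 0) stop_ccw("no subjects adherent to strategy '", strategy, "'")
  m <- predict(outcome_fit, eligible, arm = strategy)
  n <- nrow(eligible)
  Dsw <- D * sw
  wbar <- mean(Dsw)
  Tn <- sum(Dsw * (aw$Y - m)) / sum(Dsw)
  psi <- mean(m) + Tn
  # influence contributions of the Hajek-normalized augmentation: the
  # normalizing mass is itself estimated, hence the -Tn term
  phi <- m + Dsw * (aw$Y - m - Tn) / wbar
  # the nuisance models are estimated on the same subjects; propagate their
  # sampling variability into the influence function where the fit objects
  # are available
  phi <- phi + aipw_nuisance_terms(eligible, aw, outcome_fit, strategy, D, m)
  se <- sd(phi) / sqrt(n)
  structure(list(
    strategy = strategy, horizon = horizon_days,
    risk = psi,
    ci_low = max(0, psi - qnorm(0.975) * se),
    ci_high = min(1, psi + qnorm(0.975) * se),
    se = se, n = n, phi = phi
  ), class = "ccw_risk")
}

#' @export
print.ccw_risk <- function(x, ...) {
  cat(sprintf("AIPW %d-day mortality risk, strategy '%s': %.1f%% (95%% CI %.1f-%.1f%%), n = %d\n",
              x$horizon, x$strategy, 100 * x$risk, 100 * x$ci_low,
              100 * x$ci_high, x$n))
  invisible(x)
}

#' AIPW risk difference between strategies
#'
#' Difference in AIPW risks (early minus never) in percentage points, with a
#' covariance-aware influence-function standard error (the two risks are
#' estimated on the same subjects).
#'
#' @param risk_early,risk_never `ccw_risk` objects at the same horizon.
#' @return object of class `ccw_rd`: `rd` (percentage points), `ci_low`,
#'   `ci_high`, `se`, `horizon`.
#' @export
aipw_risk_difference <- function(risk_early, risk_never) {
  if (!identical(risk_early$horizon, risk_never$horizon))
    stop_ccw("risk estimates are at different horizons")
  if (risk_early$n != risk_never$n)
    stop_ccw("risk estimates cover different subjects")
  d <- risk_early$phi - risk_never$phi
  rd <- (risk_early$risk - risk_never$risk) * 100
  se <- sd(d) / sqrt(length(d)) * 100
  structure(list(
    rd = rd,
    ci_low = rd - qnorm(0.975) * se,
    ci_high = rd + qnorm(0.975) * se,
    se = se, horizon = risk_early$horizon
  ), class = "ccw_rd")
}

#' @export
print.ccw_rd <- function(x, ...) {
  cat(sprintf("AIPW %d-day risk difference (early - never): %.1f pp (95%% CI %.1f to %.1f)\n",
              x$horizon, x$rd, x$ci_low, x$ci_high))
  invisible(x)
}

# Chain-rule influence terms for the estimated nuisance parameters: the
# AIPW functional depends on the initiation-hazard coefficients (through
# the weights) and on the outcome-model coefficients (through m and the
# residual term). For each block, d(psi)/d(beta) is obtained numerically
# (weights) or analytically (outcome model) and combined with the per
# subject maximum-likelihood influence of beta-hat. Returns a per-subject
# vector aligned with `eligible` (zeros when the ingredients are absent,
# e.g. hand-built or cross-fitted probability objects).
aipw_nuisance_terms <- function(eligible, aw, outcome_fit, strategy, D, m) {
  out <- numeric(nrow(eligible))
  fits <- attr(aw, "fits")
  Y <- aw$Y
  Dsw0 <- D * (if (strategy == "early") {
    if (!is.null(aw$sw_early_reg)) aw$sw_early_reg else aw$sw_early
  } else aw$sw_never)
  sumDsw0 <- sum(Dsw0)
  psi_of_sw <- function(sw_a) {
    Dsw <- D * sw_a
    mean(m) + sum(Dsw * (Y - m)) / sum(Dsw)
  }
  ## weight-model blocks (numeric directional derivatives)
  if (!is.null(fits) && !is.null(fits$den$X) && all(is.finite(fits$den$vc)) &&
      !is.null(fits$num$X) && all(is.finite(fits$num$vc))) {
    den <- fits$den; num <- fits$num
    g <- fits$grace_hours
    keys <- den$keys; n_rows <- den$n_rows; yrs <- den$fit$y
    ti <- ifelse(is.na(eligible$rrt_init_rel_hour), Inf, eligible$rrt_init_rel_hour)
    td <- ifelse(is.na(eligible$death_rel_hour), Inf, eligible$death_rel_hour)
    init <- ti < g
    sw_from <- function(p, p0) {
      wc <- weight_components_core(p, p0, keys, n_rows, yrs, g)
      pos <- match(eligible$subject_id, wc$subject_id)
      F0g <- wc$F0_grace
      F0tau <- wc$F0_res[pos]
      if (strategy == "early")
        ifelse(init, wc$se[pos] / F0g,
               wc$cn_res[pos] * pmax(F0g - F0tau, 0) / (F0g * (1 - F0tau)))
      else wc$cn_res[pos]
    }
    lp <- qlogis(den$p); lp0 <- qlogis(num$p)
    psi0 <- psi_of_sw(sw_from(den$p, num$p))
    h <- 1e-4
    block <- function(fit, perturb) {
      grad <- vapply(seq_len(ncol(fit$X)), function(k) {
        (perturb(fit$X[, k]) - psi0) / h
      }, numeric(1))
      v <- drop(fit$vc %*% grad)
      contrib <- drop(fit$X %*% v) * (yrs - fit$p)
      agg <- rowsum(contrib, keys$subject_id)
      drop(agg)[match(eligible$subject_id, rownames(agg))]
    }
    out <- out + block(den, function(xk) psi_of_sw(sw_from(plogis(lp + h * xk), num$p)))
    out <- out + block(num, function(xk) psi_of_sw(sw_from(den$p, plogis(lp0 + h * xk))))
  }
  ## outcome-model block (analytic)
  om <- outcome_fit
  if (!is.null(om$X) && all(is.finite(om$vc))) {
    nd <- eligible
    nd$.arm <- factor(strategy, levels = c("never", "early"))
    fml_terms <- stats::delete.response(stats::terms(om$fit))
    Xp <- model.matrix(fml_terms, nd)
    mp <- m * (1 - m)
    grad_m <- colMeans(Xp * mp) - colSums(Xp * (Dsw0 * mp)) / sumDsw0
    v_m <- drop(om$vc %*% grad_m)
    contrib <- om$sw * (om$Y - om$fitted) * drop(om$X %*% v_m)
    agg <- rowsum(contrib, om$subject_id)
    add <- drop(agg)[match(eligible$subject_id, rownames(agg))]
    add[is.na(add)] <- 0
    out <- out + add
  }
  out[is.na(out)] <- 0
  out
}

#' Subject-level bootstrap for the AIPW risk difference
#'
#' Nonparametric bootstrap alternative to the influence-function intervals:
#' subjects are resampled with replacement (both clones of a subject move
#' together), and the treatment-hazard models, resolved weights, outcome
#' model and AIPW risks are re-estimated on every resample.
#'
#' @param cohort the `ccw_cohort`.
#' @param eligible output of [apply_eligibility()] on that cohort.
#' @param grace_hours,horizon_days design constants.
#' @param weight_spec a [weight_model_spec()].
#' @param outcome_covariates covariates of the outcome model.
#' @param B bootstrap replicates (default 500).
#' @param seed RNG seed for the resampling.
#' @return list with the point estimates (`rd`, `risk_early`, `risk_never`,
#'   percentage/probability scales as in [aipw_risk_difference()]) and
#'   percentile CIs (`rd_ci`, `risk_early_ci`, `risk_never_ci`).
#' @export
aipw_bootstrap <- function(cohort, eligible, grace_hours = 72,
                           horizon_days = 90,
                           weight_spec = weight_model_spec(),
                           outcome_covariates = NULL,
                           B = 500L, seed = 1L) {
  if (is.null(outcome_covariates))
    outcome_covariates <- unique(c(weight_spec$denominator, OUTCOME_COVARS))
  fit_once <- function(el) {
    rs <- initiation_risk_set(cohort, el, grace_hours)
    den <- fit_treatment_hazard_model(rs, weight_spec)
    num <- fit_treatment_hazard_model(rs, weight_spec, type = "numerator")
    rw <- resolved_clone_weights(el, den, num, grace_hours, horizon_days)
    act <- adherent_clone_table(el, rw)
    om <- fit_outcome_model(act, horizon_days,
                            intersect(outcome_covariates, names(act)))
    re <- aipw_risk(el, rw, om, "early", horizon_days)
    rn <- aipw_risk(el, rw, om, "never", horizon_days)
    c(re$risk, rn$risk, aipw_risk_difference(re, rn)$rd)
  }
  point <- fit_once(eligible)
  set.seed(seed)
  n <- nrow(eligible)
  draws <- matrix(NA_real_, B, 3L)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    el_b <- eligible[idx, , drop = FALSE]
    # repeated draws of one subject must count as distinct individuals in
    # the weight machinery; the original id is kept for the panel lookup
    # and a resample index is used as the analysis key
    el_b$.boot_id <- seq_len(n)
    draws[b, ] <- tryCatch(fit_once_boot(el_b, cohort, grace_hours,
                                         horizon_days, weight_spec,
                                         outcome_covariates),
                           error = function(e) rep(NA_real_, 3L))
  }
  ci <- function(j) unname(quantile(draws[, j], c(0.025, 0.975), na.rm = TRUE))
  list(risk_early = point[1], risk_never = point[2], rd = point[3],
       risk_early_ci = ci(1), risk_never_ci = ci(2), rd_ci = ci(3),
       B_effective = sum(!is.na(draws[, 3])))
}

# one bootstrap replicate: like fit_once but keyed on the resample index so
# duplicated subjects count as distinct
fit_once_boot <- function(el_b, cohort, grace_hours, horizon_days,
                          weight_spec, outcome_covariates) {
  rs <- initiation_risk_set(cohort, el_b, grace_hours)
  # re-key person-hours by resample position, not original id
  reps <- attr(rs, "n_rows")
  rs$subject_id <- rep(el_b$.boot_id, reps)
  den <- fit_treatment_hazard_model(rs, weight_spec)
  num <- fit_treatment_hazard_model(rs, weight_spec, type = "numerator")
  el2 <- el_b
  el2$subject_id <- el_b$.boot_id
  rw <- resolved_clone_weights(el2, den, num, grace_hours, horizon_days)
  act <- adherent_clone_table(el2, rw)
  om <- fit_outcome_model(act, horizon_days,
                          intersect(outcome_covariates, names(act)))
  re <- aipw_risk(el2, rw, om, "early", horizon_days)
  rn <- aipw_risk(el2, rw, om, "never", horizon_days)
  c(re$risk, rn$risk, aipw_risk_difference(re, rn)$rd)
}

#' Long table of adherent clones
#'
#' One row per clone adherent to its strategy through the grace period,
#' carrying the time-zero covariates, the horizon outcome `Y` and the
#' resolved weight `sw`. This is the input of [fit_outcome_model()]
#' (`weighting = "regime"`) and of the balance diagnostics
#' (`weighting = "classic"`).
#'
#' @param eligible output of [apply_eligibility()].
#' @param adherence_weights output of [resolved_clone_weights()].
#' @param weighting which early-arm weight column populates `sw`.
#' @return data frame with the eligible columns plus `arm`, `Y`, `sw`.
#' @export
adherent_clone_table <- function(eligible, adherence_weights,
                                 weighting = c("regime", "classic")) {
  weighting <- match.arg(weighting)
  aw <- adherence_weights
  rows_e <- which(aw$D_early == 1L)
  rows_n <- which(aw$D_never == 1L)
  sw_e <- if (weighting == "regime" && !is.null(aw$sw_early_reg))
    aw$sw_early_reg else aw$sw_early
  one_arm <- function(rows, arm, sw) {
    if (!length(rows)) return(NULL)
    cbind(eligible[rows, , drop = FALSE], arm = arm, Y = aw$Y[rows],
          sw = sw[rows])
  }
  tab <- rbind(one_arm(rows_e, "early", sw_e),
               one_arm(rows_n, "never", aw$sw_never))
  rownames(tab) <- NULL
  tab
}
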