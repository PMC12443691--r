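# Treatment-hazard models and stabilized inverse-probability-of-censoring
# weights for the clone-censor-weight design.

#' Specification of the weight models
#'
#' Covariate sets for the pooled discrete-time logistic models of RRT
#' initiation. The denominator model conditions on baseline and current
#' (time-varying) covariates; the numerator model is the stabilizing
#' marginal model and by default contains only the intercept and the
#' flexible time term, so the weights also remove baseline confounding
#' between the arms. Time since eligibility enters both models as a natural
#' cubic spline.
#'
#' @param denominator covariate names for the denominator model. Time-varying
#'   variables (`sofa`, `heart_rate`, `resp_rate`, `dbp`, `spo2`, and any
#'   other panel variable) are evaluated at the current hour; the rest at
#'   time zero. `time_zero_hour` (hours from ICU admission to eligibility)
#'   is included so that, together with the spline in hours since
#'   eligibility, initiation-hazard trends on the absolute ICU clock are
#'   representable.
#' @param numerator covariate names for the numerator model; must be a
#'   subset of the denominator set. Default: none (intercept + time spline).
#' @param truncation lower/upper percentiles for weight truncation
#'   (default 1st/99th).
#' @param time_df degrees of freedom of the natural spline on hours since
#'   eligibility (default 4, i.e. 3 internal knots).
#' @return object of class `weight_model_spec`.
#' @export
weight_model_spec <- function(denominator = c("age", "female", "cci", "sepsis",
                                              "vasopressor", "sofa", "heart_rate",
                                              "resp_rate", "dbp", "spo2",
                                              "time_zero_hour"),
                              numerator = character(0),
                              truncation = c(0.01, 0.99),
                              time_df = 4L) {
  if (!all(numerator %in% denominator))
    stop_ccw("numerator covariates must be a subset of the denominator covariates")
  assert_prob(truncation, "truncation percentiles")
  if (length(truncation) != 2L || truncation[1] > truncation[2])
    stop_ccw("truncation must be c(lower, upper) percentiles")
  structure(list(denominator = denominator, numerator = numerator,
                 truncation = truncation, time_df = as.integer(time_df)),
            class = "weight_model_spec")
}

#' Person-hour risk set for the initiation hazard
#'
#' One row per subject-hour in which RRT initiation is still possible:
#' from time zero while the subject is alive and untreated, through the
#' whole window in which initiation can be observed (the hourly panel).
#' The never-initiate clone can deviate at *any* hour, not only within the
#' grace period, so the censoring weights need the initiation hazard over
#' the full opportunity window; grace-period resolution is handled
#' downstream. `y = 1` marks the initiation hour. Time-varying covariates
#' are taken at the corresponding absolute panel hour.
#'
#' @param cohort the `ccw_cohort` the subjects came from.
#' @param eligible output of [apply_eligibility()] on that cohort.
#' @param grace_hours grace period (hours), stored for downstream use.
#' @param max_hours cap on hours since eligibility (default: the panel).
#' @return data frame with `subject_id`, `hours_since_elig`, `y`, baseline
#'   covariates and current-hour panel covariates, ordered by subject and
#'   hour.
#' @export
initiation_risk_set <- function(cohort, eligible, grace_hours = 72,
                                max_hours = NULL) {
  g <- grace_hours
  ti <- ifelse(is.na(eligible$rrt_init_rel_hour), Inf, eligible$rrt_init_rel_hour)
  td <- ifelse(is.na(eligible$death_rel_hour), Inf, eligible$death_rel_hour)
  cap <- max(cohort$hours) - eligible$time_zero_hour
  if (!is.null(max_hours)) cap <- pmin(cap, max_hours)
  # at risk entering hour s: s <= ti, s < td, s < cap
  n_rows <- pmin(ti + 1, td, cap)
  n_rows <- as.integer(n_rows)
  if (any(n_rows < 1L)) stop_ccw("subject with empty initiation risk set")
  row_i <- rep(seq_len(nrow(eligible)), n_rows)
  s <- sequence(n_rows) - 1L
  out <- data.frame(
    subject_id = eligible$subject_id[row_i],
    hours_since_elig = s,
    time_zero_hour = eligible$time_zero_hour[row_i],
    y = as.integer(s == ti[row_i]),
    age = eligible$age[row_i], female = eligible$female[row_i],
    cci = eligible$cci[row_i], sepsis = eligible$sepsis[row_i],
    vasopressor = eligible$vasopressor[row_i],
    mech_vent = eligible$mech_vent[row_i],
    stringsAsFactors = FALSE
  )
  subj_idx <- match(eligible$subject_id, cohort$baseline$subject_id)
  abs_col <- cbind(subj_idx[row_i], eligible$time_zero_hour[row_i] + s + 1L)
  for (v in PANEL_VARS) out[[v]] <- cohort$panel[[v]][abs_col]
  attr(out, "n_rows") <- n_rows
  attr(out, "grace_hours") <- g
  out
}

#' Pooled logistic model of the hourly initiation hazard
#'
#' Fits P(initiate RRT at hour t | covariates, still untreated) by pooled
#' logistic regression over the person-hour risk set, with hours since
#' eligibility as a natural cubic spline.
#'
#' @param risk_set output of [initiation_risk_set()] (or any data frame with
#'   `y`, `hours_since_elig` and the covariates).
#' @param spec a [weight_model_spec()].
#' @param type `"denominator"` (full covariate set) or `"numerator"`
#'   (stabilizing subset).
#' @return object of class `ccw_hazard_fit`: the glm fit, a coefficient
#'   table, and per-row predicted probabilities aligned with `risk_set`.
#' @export
fit_treatment_hazard_model <- function(risk_set, spec = weight_model_spec(),
                                       type = c("denominator", "numerator")) {
  type <- match.arg(type)
  if (nrow(risk_set) == 0L) stop_ccw("empty risk set")
  covs <- if (type == "denominator") spec$denominator else spec$numerator
  assert_cols(risk_set, c("y", "hours_since_elig", covs), "risk set")
  X <- hazard_model_matrix(risk_set, covs, spec$time_df)
  fit <- suppressWarnings(glm.fit(X, risk_set$y, family = binomial()))
  cf <- setNames(fit$coefficients, colnames(X))
  bad <- separated_covariates(list(coefficients = cf), risk_set, covs)
  if (length(bad))
    stop_ccw("possible complete separation in the initiation model; ",
             "check covariate(s): ", paste(bad, collapse = ", "))
  if (!fit$converged) stop_ccw("initiation-hazard model did not converge")
  vc <- tryCatch(chol2inv(chol(crossprod(X * sqrt(fit$weights)))),
                 error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(diag(vc))
  ctab <- cbind(Estimate = cf, `Std. Error` = se, `z value` = cf / se,
                `Pr(>|z|)` = 2 * pnorm(-abs(cf / se)))
  structure(list(
    fit = fit,
    type = type,
    coefficients = ctab,
    p = as.numeric(fit$fitted.values),
    keys = risk_set[c("subject_id", "hours_since_elig")],
    n_rows = attr(risk_set, "n_rows"),
    X = X,
    vc = vc,
    spec = spec
  ), class = "ccw_hazard_fit")
}

#' @export
print.ccw_hazard_fit <- function(x, ...) {
  cat(sprintf("Pooled logistic initiation-hazard model (%s), %d person-hours, %d initiations\n",
              x$type, length(x$p), sum(x$fit$y)))
  print(round(x$coefficients, 4))
  invisible(x)
}

# Model matrix of the pooled logistic initiation model: intercept, natural
# spline in hours since eligibility, covariates. Built by hand because the
# risk set has one row per person-hour and the formula machinery would
# dominate runtime.
hazard_model_matrix <- function(risk_set, covs, time_df, knots = NULL) {
  df_t <- min(time_df, length(unique(risk_set$hours_since_elig)) - 1L)
  if (df_t >= 1L) {
    basis <- if (is.null(knots))
      splines::ns(risk_set$hours_since_elig, df = df_t)
    else
      splines::ns(risk_set$hours_since_elig,
                  knots = attr(knots, "knots"),
                  Boundary.knots = attr(knots, "Boundary.knots"))
    colnames(basis) <- paste0("time_ns", seq_len(ncol(basis)))
    X <- cbind(`(Intercept)` = 1, basis)
    attr(X, "basis") <- basis
  } else {
    X <- cbind(`(Intercept)` = rep(1, nrow(risk_set)))
  }
  if (length(covs)) {
    cm <- vapply(covs, function(v) as.numeric(risk_set[[v]]),
                 numeric(nrow(risk_set)))
    if (is.null(dim(cm))) cm <- matrix(cm, nrow = 1L, dimnames = list(NULL, covs))
    X <- cbind(X, cm)
  }
  X
}

#' Cross-fitted initiation-hazard probabilities
#'
#' Fits the denominator and numerator pooled logistic models with K-fold
#' cross-fitting by subject: each subject's person-hour probabilities are
#' predicted from models estimated on the other folds, removing the
#' own-observation overfitting that otherwise couples the weights to the
#' data they re-weight.
#'
#' @param risk_set output of [initiation_risk_set()].
#' @param spec a [weight_model_spec()].
#' @param k number of folds (default 2).
#' @param seed seed for the fold assignment.
#' @return list with elements `den` and `num`, `ccw_hazard_fit`-shaped
#'   objects whose `p` holds out-of-fold probabilities; usable wherever the
#'   in-sample fits are.
#' @export
fit_treatment_hazard_crossfit <- function(risk_set, spec = weight_model_spec(),
                                          k = 2L, seed = 1L) {
  ids <- unique(risk_set$subject_id)
  set.seed(seed)
  fold_of <- setNames(sample(rep(seq_len(k), length.out = length(ids))), ids)
  fold <- fold_of[as.character(risk_set$subject_id)]
  out <- list()
  for (type in c("denominator", "numerator")) {
    covs <- if (type == "denominator") spec$denominator else spec$numerator
    p <- numeric(nrow(risk_set))
    for (f in seq_len(k)) {
      train <- risk_set[fold != f, , drop = FALSE]
      Xtr <- hazard_model_matrix(train, covs, spec$time_df)
      fit <- suppressWarnings(glm.fit(Xtr, train$y, family = binomial()))
      test <- risk_set[fold == f, , drop = FALSE]
      Xte <- hazard_model_matrix(test, covs, spec$time_df,
                                 knots = attr(Xtr, "basis"))
      p[fold == f] <- plogis(drop(Xte %*% fit$coefficients))
    }
    out[[substr(type, 1, 3)]] <- structure(list(
      fit = list(y = risk_set$y, converged = TRUE),
      type = type, p = p,
      keys = risk_set[c("subject_id", "hours_since_elig")],
      n_rows = attr(risk_set, "n_rows"), spec = spec,
      cross_fitted = TRUE
    ), class = "ccw_hazard_fit")
  }
  out
}

# Per-subject weight ingredients shared by the person-time weights, the
# clone-resolved weights (AFT/AIPW) and the balance diagnostics. When
# grace_hours is given, the cumulative quantities are also evaluated at the
# grace boundary (strategy-resolution time), even though the risk set runs
# over the whole initiation-opportunity window.
weight_components <- function(den_fit, num_fit, grace_hours = NULL) {
  if (!identical(den_fit$keys, num_fit$keys))
    stop_ccw("denominator and numerator fits were not estimated on the same risk set")
  n_rows <- den_fit$n_rows
  if (is.null(n_rows)) n_rows <- as.integer(table(factor(den_fit$keys$subject_id,
                                                  levels = unique(den_fit$keys$subject_id))))
  weight_components_core(den_fit$p, num_fit$p, den_fit$keys, n_rows,
                         den_fit$fit$y, grace_hours)
}

# Same computation from raw probability vectors (used when re-evaluating the
# weights under nuisance-coefficient perturbations).
weight_components_core <- function(p, p0, keys, n_rows, y, grace_hours = NULL) {
  if (any(p <= 0 | p >= 1 | p0 <= 0 | p0 >= 1))
    stop_ccw("fitted adherence probability of 0 or 1 encountered; ",
             "truncate or respecify the weight models")
  starts <- cumsum(c(1L, n_rows[-length(n_rows)]))
  # cumulative product of (1 - p0)/(1 - p) within subject
  lr <- log1p(-p0) - log1p(-p)
  cs <- cumsum(lr)
  offset <- cs[starts] - lr[starts]
  grp <- rep(seq_along(n_rows), n_rows)
  cn <- exp(cs - offset[grp])
  init_row <- which(y == 1L)
  # full timing likelihood ratio for initiators: the non-initiation hours
  # contribute (1-p0)/(1-p) and the initiation hour contributes p0/p
  cn_before <- cn / exp(lr)
  se <- rep(NA_real_, length(n_rows))
  se[grp[init_row]] <- cn_before[init_row] * p0[init_row] / p[init_row]
  # rows capped at the grace boundary (strategy resolution)
  g_rows <- if (is.null(grace_hours)) n_rows else pmin(n_rows, grace_hours)
  # cumulative numerator-model initiation probability: per subject over its
  # own risk hours up to resolution (F0_res), and over the grace window
  # using the marginal fitted hazard per hour (F0_grace)
  ln0 <- cumsum(log1p(-p0))
  off0 <- ln0[starts] - log1p(-p0[starts])
  F0_res <- 1 - exp(ln0[starts + g_rows - 1L] - off0)
  hrs <- keys$hours_since_elig
  p0_grid <- tapply(p0, hrs, mean)
  if (!is.null(grace_hours))
    p0_grid <- p0_grid[as.numeric(names(p0_grid)) < grace_hours]
  F0_grace <- 1 - prod(1 - p0_grid)
  list(subject_id = keys$subject_id[starts],
       starts = starts, n_rows = n_rows, grp = grp,
       p = p, p0 = p0, cn = cn,
       cn_res = cn[starts + g_rows - 1L],
       se = se, F0_res = F0_res, F0_grace = F0_grace)
}

#' Stabilized inverse-probability weights on the person-time table
#'
#' Attaches per-hour adherence probabilities and cumulative stabilized
#' weights to the expanded clone table. For the never-initiate clone the
#' weight at hour t is the cumulative product over hourly checkpoints s <= t
#' of (1 - p0(s)) / (1 - p(s)); for the early clone it is 1 until
#' initiation and p0(t*) / p(t*) from the initiation hour on. Weights are
#' frozen once a clone's adherence is fully resolved (after initiation, and
#' after the grace period closes), and truncated at the configured
#' percentiles of the weight distribution over person-time rows.
#'
#' @param person_time output of [person_time_expand()].
#' @param den_fit,num_fit denominator and numerator [fit_treatment_hazard_model()]
#'   fits on the same risk set.
#' @param truncation percentiles, default from the denominator fit's spec.
#' @return `person_time` with columns `p_denominator`, `p_numerator`, `sw`,
#'   `sw_trunc`; attribute `"weight_diagnostics"` holds the mean, quantiles
#'   and truncation bounds of the untruncated weights.
#' @export
compute_stabilized_ipw <- function(person_time, den_fit, num_fit,
                                   truncation = den_fit$spec$truncation) {
  if (is.null(person_time$rrt_init_rel_hour))
    stop_ccw("person_time must carry rrt_init_rel_hour (expand with covariates = TRUE)")
  wc <- weight_components(den_fit, num_fit)
  pos <- match(person_time$subject_id, wc$subject_id)
  if (anyNA(pos)) stop_ccw("person-time rows without fitted probabilities")
  last_s <- wc$n_rows[pos] - 1L
  s_eff <- pmin(person_time$tstart, last_s)
  row_idx <- wc$starts[pos] + s_eff

  ti <- ifelse(is.na(person_time$rrt_init_rel_hour), Inf,
               person_time$rrt_init_rel_hour)

  early <- person_time$arm == "early"
  # both arms share the cumulative (1-p0)/(1-p) ratio while untreated; the
  # early clone switches to the frozen timing likelihood ratio at initiation
  sw <- wc$cn[row_idx]
  post_init <- early & person_time$tstart >= ti
  sw[post_init] <- wc$se[pos[post_init]]
  if (anyNA(sw)) stop_ccw("unresolved weight for an early-arm clone; ",
                          "initiation outside the fitted risk set")

  in_set <- person_time$tstart <= last_s & person_time$tstart == s_eff &
    person_time$tstop - person_time$tstart <= 1
  person_time$p_denominator <- ifelse(in_set, wc$p[row_idx], NA_real_)
  person_time$p_numerator <- ifelse(in_set, wc$p0[row_idx], NA_real_)
  person_time$sw <- sw
  bounds <- quantile(sw, truncation, names = FALSE)
  person_time$sw_trunc <- pmin(pmax(sw, bounds[1]), bounds[2])
  attr(person_time, "weight_diagnostics") <- list(
    mean_sw = mean(sw),
    quantiles = quantile(sw, c(0, 0.01, 0.25, 0.5, 0.75, 0.99, 1)),
    truncation = truncation,
    bounds = bounds
  )
  person_time
}

#' Clone-level resolved weights and adherence indicators
#'
#' Reduces the weighting process to one record per subject: adherence of
#' each (hypothetical) clone to its strategy through the grace period, the
#' stabilized weight at resolution, and the death-by-horizon outcome.
#' Subjects dying within the grace period before initiating are adherent to
#' both strategies.
#'
#' Two early-arm weight columns are returned. `sw_early` is the classic
#' stabilized weight (the early clone's weight at resolution, matching the
#' person-time weights). `sw_early_reg` additionally calibrates the
#' adherent mass to the *truncated natural-timing regime* ("initiate at the
#' naturally paced hour, conditioned to fall inside the grace window"):
#' initiator weights are divided by `F0` (the marginal within-grace
#' initiation probability under the numerator model) and grace-period-death
#' weights are multiplied by the remaining-timing-mass ratio
#' `(F0 - F0(tau)) / (1 - F0(tau)) / F0`. Without this calibration the
#' (rare, always-adherent) grace-period deaths carry several times their
#' regime share of the normalized weight mass and fixed-horizon risk
#' estimates are biased upward even under a null effect; the AIPW estimator
#' therefore uses `sw_early_reg`.
#'
#' @param eligible output of [apply_eligibility()].
#' @param den_fit,num_fit initiation-hazard fits.
#' @param grace_hours grace period (hours).
#' @param horizon_days outcome horizon (days).
#' @param truncation optional percentiles at which each resolved-weight
#'   column is truncated within its component group (initiators,
#'   grace-period deaths, never-adherent). Default `NULL` (untruncated):
#'   the resolved weights feed mean-type estimators whose small-sample
#'   behaviour is degraded, not helped, by clipping the informative tails.
#' @return data frame: `subject_id`, `D_early`, `D_never`, `sw_early`,
#'   `sw_early_reg`, `sw_never`, `Y` (death by horizon); attribute
#'   `"F0_grace"`.
#' @export
resolved_clone_weights <- function(eligible, den_fit, num_fit,
                                   grace_hours = 72, horizon_days = 90,
                                   truncation = NULL) {
  wc <- weight_components(den_fit, num_fit, grace_hours = grace_hours)
  pos <- match(eligible$subject_id, wc$subject_id)
  g <- grace_hours
  ti <- ifelse(is.na(eligible$rrt_init_rel_hour), Inf, eligible$rrt_init_rel_hour)
  td <- ifelse(is.na(eligible$death_rel_hour), Inf, eligible$death_rel_hour)
  init <- ti < g
  F0g <- wc$F0_grace
  F0tau <- wc$F0_res[pos]
  out <- data.frame(
    subject_id = eligible$subject_id,
    D_early = as.integer(init | (td <= g & td <= ti)),
    D_never = as.integer(!(ti < pmin(g, td))),
    sw_early = ifelse(init, wc$se[pos], wc$cn_res[pos]),
    sw_early_reg = ifelse(init, wc$se[pos] / F0g,
                          wc$cn_res[pos] *
                            pmax(F0g - F0tau, 0) / (F0g * (1 - F0tau))),
    sw_never = wc$cn_res[pos],
    Y = as.integer(td <= horizon_days * 24)
  )
  # truncate each resolved-weight column at its percentiles, mirroring the
  # person-time weight truncation; initiators and grace-period deaths sit on
  # different weight scales (timing ratio vs remaining-mass calibration) and
  # are truncated within their own groups
  if (!is.null(truncation)) {
    trunc_grp <- function(w, grp) {
      for (v in unique(grp[!is.na(grp)])) {
        i <- which(grp == v)
        if (length(i) >= 2L) {
          q <- quantile(w[i], truncation, names = FALSE, na.rm = TRUE)
          w[i] <- pmin(pmax(w[i], q[1]), q[2])
        }
      }
      w
    }
    grp_e <- ifelse(out$D_early == 1L, ifelse(init, "init", "death"), NA)
    out$sw_early <- trunc_grp(out$sw_early, grp_e)
    out$sw_early_reg <- trunc_grp(out$sw_early_reg, grp_e)
    out$sw_never <- trunc_grp(out$sw_never,
                              ifelse(out$D_never == 1L, "adh", NA))
  }
  attr(out, "F0_grace") <- F0g
  attr(out, "fits") <- list(den = den_fit, num = num_fit,
                            grace_hours = grace_hours)
  out
}

#' Standardized mean differences before and after weighting
#'
#' SMD = (weighted mean in arm 1 - weighted mean in arm 0) divided by the
#' unweighted pooled standard deviation sqrt((s1^2 + s0^2)/2). Reported both
#' unweighted ("before") and with the supplied weights ("after"). A zero
#' pooled SD yields SMD 0 when the means agree and `NA` (flagged) otherwise.
#'
#' @param table data frame with one row per clone (or unit).
#' @param covariates covariate column names (numeric or 0/1).
#' @param weights balancing weights, one per row.
#' @param arm_col name of the two-level arm column (default `"arm"`).
#' @return data frame: `covariate`, `smd_unweighted`, `smd_weighted`,
#'   `balanced` (|weighted SMD| < 0.1).
#' @export
smd_balance <- function(table, covariates, weights = rep(1, nrow(table)),
                        arm_col = "arm") {
  assert_cols(table, c(arm_col, covariates), "balance table")
  arms <- sort(unique(as.character(table[[arm_col]])))
  if (length(arms) != 2L) stop_ccw("balance requires exactly two non-empty arms")
  ref <- if ("early" %in% arms) "early" else arms[2L]
  g1 <- table[[arm_col]] == ref
  smd_one <- function(x, w) {
    m1 <- wmean(x[g1], w[g1]); m0 <- wmean(x[!g1], w[!g1])
    s <- sqrt((sd(x[g1])^2 + sd(x[!g1])^2) / 2)
    if (s == 0 || !is.finite(s)) return(if (isTRUE(all.equal(m1, m0))) 0 else NA_real_)
    (m1 - m0) / s
  }
  before <- vapply(covariates, function(v) smd_one(as.numeric(table[[v]]),
                                                   rep(1, nrow(table))), numeric(1))
  after <- vapply(covariates, function(v) smd_one(as.numeric(table[[v]]),
                                                  weights), numeric(1))
  data.frame(covariate = covariates,
             smd_unweighted = unname(before),
             smd_weighted = unname(after),
             balanced = abs(unname(after)) < 0.1,
             row.names = NULL)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing covariate j on the remaining
#' covariates (with intercept). Values above 5 conventionally flag
#' concerning multicollinearity; a perfectly collinear covariate is reported
#' as `Inf` with a warning naming it.
#'
#' @param x numeric matrix or data frame of covariates (>= 2 columns, more
#'   rows than columns).
#' @return data frame: `covariate`, `vif`.
#' @export
vif_table <- function(x) {
  x <- as.matrix(as.data.frame(x))
  if (ncol(x) < 2L) stop_ccw("VIF needs at least two covariates")
  if (nrow(x) <= ncol(x)) stop_ccw("VIF needs more rows than covariates")
  vifs <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(is.infinite(vifs)))
    warning("perfectly collinear covariate(s): ",
            paste(colnames(x)[is.infinite(vifs)], collapse = ", "))
  data.frame(covariate = colnames(x), vif = vifs, row.names = NULL)
}
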