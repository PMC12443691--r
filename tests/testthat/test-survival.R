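test_that("unit weights reproduce the unweighted Cox fit exactly", {
  df <- sim_two_arm_surv(400, hr = 1.5, seed = 5)
  fit <- fit_weighted_cox(df, covariates = character(0), weight_col = "sw_trunc")
  ref <- survival::coxph(survival::Surv(tstop, event) ~ arm, data = df,
                         ties = "efron")
  expect_equal(log(fit$hr), -unname(coef(ref)), tolerance = 1e-8)
})

test_that("the weighted Cox recovers a known hazard ratio", {
  df <- sim_two_arm_surv(2500, hr = 2, seed = 7)
  fit <- fit_weighted_cox(df, covariates = character(0))
  expect_equal(fit$hr, 2, tolerance = 0.075)
  expect_true(fit$ci_low < fit$hr && fit$hr < fit$ci_high)
})

test_that("null arm labels give nominal confidence-interval coverage", {
  cover <- vapply(1:200, function(i) {
    df <- sim_two_arm_surv(120, hr = 1, rate0 = 0.02, seed = 1000 + i)
    df$arm <- sample(df$arm)
    fit <- fit_weighted_cox(df, covariates = character(0))
    fit$ci_low <= 1 && 1 <= fit$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("errors surface for empty arms and bad weights", {
  df <- sim_two_arm_surv(50, seed = 2)
  df$event[df$arm == "early"] <- 0L
  expect_error(fit_weighted_cox(df, covariates = character(0)), "event")
  df2 <- sim_two_arm_surv(50, seed = 2)
  df2$sw_trunc <- -1
  expect_error(fit_weighted_cox(df2, covariates = character(0)), "positive")
})

test_that("row collapsing leaves the weighted Cox estimate unchanged", {
  coh <- simulate_cohort(sim_config(500, seed = 24))
  el <- apply_eligibility(coh, eligibility_criteria())
  rs <- initiation_risk_set(coh, el, 72)
  den <- fit_treatment_hazard_model(rs)
  num <- fit_treatment_hazard_model(rs, type = "numerator")
  pt <- compute_stabilized_ipw(
    person_time_expand(apply_protocol_censoring(clone_subjects(el, 72, 90))),
    den, num)
  fit_fast <- fit_weighted_cox(pt, horizon_days = 90)
  pt_nocollapse <- pt
  pt_nocollapse$clone_row <- NULL
  fit_full <- fit_weighted_cox(pt_nocollapse, horizon_days = 90,
                               cluster_col = "subject_id")
  expect_equal(fit_fast$hr, fit_full$hr, tolerance = 1e-8)
  expect_equal(fit_fast$robust_se, fit_full$robust_se, tolerance = 1e-6)
})

test_that("Schoenfeld test: single-covariate global p equals the covariate's p", {
  df <- sim_two_arm_surv(300, hr = 1.6, seed = 9)
  fit <- fit_weighted_cox(df, covariates = character(0))
  ph <- test_proportional_hazards(fit)
  expect_equal(ph$global_p, ph$table[".arm", "p"], tolerance = 1e-10)
  expect_true(ph$global_p >= 0 && ph$global_p <= 1)
})

test_that("Schoenfeld test detects a reversing effect and keeps size under PH", {
  # size under proportional hazards
  p_ph <- vapply(1:100, function(i) {
    df <- sim_two_arm_surv(150, hr = 1.5, rate0 = 0.02, seed = 3000 + i)
    test_proportional_hazards(fit_weighted_cox(df, character(0)))$global_p
  }, numeric(1))
  expect_lt(mean(p_ph < 0.05), 0.15)
  # power: effect that reverses over time
  set.seed(77)
  n <- 2000
  arm <- rep(c("never", "early"), each = n)
  # piecewise hazard: early arm protected before day 20, harmed after
  t1 <- rexp(2 * n, ifelse(arm == "early", 0.01, 0.03))
  t2 <- 20 + rexp(2 * n, ifelse(arm == "early", 0.05, 0.015))
  time <- ifelse(t1 < 20, t1, t2)
  df <- data.frame(subject_id = seq_len(2 * n), arm = arm,
                   tstart = 0, tstop = pmin(time, 90),
                   event = as.integer(time <= 90), sw_trunc = 1)
  ph <- test_proportional_hazards(fit_weighted_cox(df, character(0)))
  expect_lt(ph$global_p, 0.001)
})

test_that("Weibull AFT recovers a null and formats the reporting conventions", {
  df <- sim_two_arm_surv(800, hr = 1, seed = 11)
  aft <- fit_weibull_aft(df, covariates = character(0), weight_col = "sw")
  expect_equal(aft$acceleration_factor, 1, tolerance = 0.15)
  expect_equal(rrtccw:::aft_label(0.852, c(0.846, 0.858)),
               "14.8% (95% CI: 14.2-15.4%) reduction in survival time")
  expect_equal(rrtccw:::aft_label(3.08, c(3.04, 3.13)),
               "3.08 (95% CI: 3.04-3.13) times longer survival")
})

test_that("percent change is zero at AF = 1", {
  df <- sim_two_arm_surv(500, hr = 1, seed = 12)
  aft <- fit_weibull_aft(df, covariates = character(0), weight_col = "sw")
  expect_lt(abs(aft$percent_change), 15)
  expect_true(aft$ci_low < 1 && 1 < aft$ci_high)
})

test_that("survival curves: no events give S = 1; unit weights give the product-limit estimate", {
  df <- sim_two_arm_surv(100, seed = 13)
  df0 <- df; df0$event <- 0L
  cur0 <- survival_curves(df0, weight_col = "sw")
  expect_true(all(cur0$surv == 1))
  cur <- survival_curves(df, weight_col = "sw")
  km <- survival::survfit(survival::Surv(time / 24, event) ~ arm, data = df)
  expect_equal(cur$surv[cur$arm == "early"],
               km$surv[seq_len(km$strata[1])], tolerance = 1e-10)
})

test_that("exponential data reproduce the closed-form survival at 90 days", {
  df <- sim_two_arm_surv(20000, hr = 1, rate0 = 0.01, seed = 14)
  cur <- survival_curves(df, weight_col = "sw")
  s90 <- cur[cur$arm == "never" & cur$time <= 90, ]
  expect_equal(tail(s90$surv, 1), exp(-0.9), tolerance = 0.02)
})

test_that("30-day estimates equal the 90-day machinery on data censored at day 30", {
  coh <- simulate_cohort(sim_config(600, seed = 25, scenario = "protective"))
  el <- apply_eligibility(coh, eligibility_criteria())
  rs <- initiation_risk_set(coh, el, 72)
  den <- fit_treatment_hazard_model(rs)
  num <- fit_treatment_hazard_model(rs, type = "numerator")
  pt <- compute_stabilized_ipw(
    person_time_expand(apply_protocol_censoring(clone_subjects(el, 72, 90))),
    den, num)
  f30 <- fit_weighted_cox(pt, horizon_days = 30)
  pt_c <- pt[pt$tstart < 720, ]
  ce <- rrtccw:::censor_at_horizon(pt_c$tstop, pt_c$event, 720)
  pt_c$tstop <- ce$time; pt_c$event <- ce$event
  f30b <- fit_weighted_cox(pt_c, horizon_days = NULL)
  expect_equal(f30$hr, f30b$hr, tolerance = 1e-10)
})
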