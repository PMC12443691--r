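# Helper: run the weighting pipeline on a simulated cohort and return the
# ingredients the AIPW estimator needs.
aipw_ingredients <- function(n, seed, scenario = "null", horizon = 90) {
  coh <- simulate_cohort(sim_config(n, seed = seed, scenario = scenario))
  el <- apply_eligibility(coh, eligibility_criteria())
  rs <- initiation_risk_set(coh, el, 72)
  den <- fit_treatment_hazard_model(rs)
  num <- fit_treatment_hazard_model(rs, type = "numerator")
  rw <- resolved_clone_weights(el, den, num, 72, horizon)
  list(el = el, rw = rw)
}

test_that("arm-saturated outcome model reproduces the arm proportions", {
  act <- data.frame(arm = rep(c("early", "never"), c(10, 20)),
                    Y = c(rep(1, 3), rep(0, 7), rep(1, 5), rep(0, 15)),
                    sw = 1)
  om <- fit_outcome_model(act, 90, character(0))
  nd <- data.frame(dummy = 1:5)
  expect_equal(predict(om, nd, arm = "early"), rep(0.3, 5), tolerance = 1e-8)
  expect_equal(predict(om, nd, arm = "never"), rep(0.25, 5), tolerance = 1e-8)
})

test_that("with constant propensity and an intercept-only outcome model, AIPW equals the Hajek IPW mean", {
  ing <- aipw_ingredients(500, seed = 26)
  rw <- ing$rw
  rw$sw_early_reg <- 1; rw$sw_never <- 1  # as under randomized treatment
  act <- adherent_clone_table(ing$el, rw)
  om <- fit_outcome_model(act, 90, character(0))
  r <- aipw_risk(ing$el, rw, om, "early", 90)
  ipw <- weighted.mean(rw$Y, rw$D_early)
  expect_equal(r$risk, ipw, tolerance = 1e-10)
})

test_that("identical arms give a risk difference of exactly zero", {
  ing <- aipw_ingredients(400, seed = 27)
  rw <- ing$rw
  rw$D_never <- rw$D_early
  rw$sw_never <- rw$sw_early_reg
  act <- adherent_clone_table(ing$el, rw)
  om <- fit_outcome_model(act, 90, character(0))
  re <- aipw_risk(ing$el, rw, om, "early", 90)
  rn <- aipw_risk(ing$el, rw, om, "never", 90)
  rd <- aipw_risk_difference(re, rn)
  expect_equal(rd$rd, 0, tolerance = 1e-9)
  expect_true(rd$ci_low <= 0 && 0 <= rd$ci_high)
})

test_that("AIPW equals the g-formula plug-in under unit weights", {
  ing <- aipw_ingredients(500, seed = 28)
  rw <- ing$rw
  rw$sw_early_reg <- 1; rw$sw_never <- 1
  act <- adherent_clone_table(ing$el, rw)
  om <- fit_outcome_model(act, 90, c("age", "sofa"))
  re <- aipw_risk(ing$el, rw, om, "early", 90)
  # canonical-link MLE residuals average to zero in-sample per arm, so the
  # augmentation vanishes and AIPW reduces to the outcome-model mean
  gf <- mean(predict(om, ing$el, arm = "early"))
  expect_equal(re$risk, gf, tolerance = 1e-6)
})

test_that("risk difference arithmetic and guards", {
  r1 <- structure(list(strategy = "early", horizon = 90, risk = 0.245,
                       ci_low = 0.24, ci_high = 0.25, se = 0.002, n = 100,
                       phi = rep(0.245, 100)), class = "ccw_risk")
  r2 <- structure(list(strategy = "never", horizon = 90, risk = 0.219,
                       ci_low = 0.215, ci_high = 0.223, se = 0.002, n = 100,
                       phi = rep(0.219, 100)), class = "ccw_risk")
  rd <- aipw_risk_difference(r1, r2)
  expect_equal(rd$rd, 2.6)
  r3 <- r2; r3$horizon <- 30
  expect_error(aipw_risk_difference(r1, r3), "horizon")
})

test_that("the 30-day risk difference equals the 90-day machinery run at horizon 30", {
  coh <- simulate_cohort(sim_config(700, seed = 29, scenario = "protective"))
  el <- apply_eligibility(coh, eligibility_criteria())
  rs <- initiation_risk_set(coh, el, 72)
  den <- fit_treatment_hazard_model(rs)
  num <- fit_treatment_hazard_model(rs, type = "numerator")
  rw30 <- resolved_clone_weights(el, den, num, 72, 30)
  act30 <- adherent_clone_table(el, rw30)
  om30 <- fit_outcome_model(act30, 30, c("age", "sofa", "lactate"))
  re <- aipw_risk(el, rw30, om30, "early", 30)
  rn <- aipw_risk(el, rw30, om30, "never", 30)
  td <- ifelse(is.na(el$death_rel_hour), Inf, el$death_rel_hour)
  expect_identical(rw30$Y, as.integer(td <= 720))
  rd30 <- aipw_risk_difference(re, rn)
  expect_equal(rd30$horizon, 30)
})

test_that("the subject-level bootstrap returns coherent percentile intervals", {
  coh <- simulate_cohort(sim_config(600, seed = 98))
  el <- apply_eligibility(coh, eligibility_criteria())
  bs <- aipw_bootstrap(coh, el, B = 12, seed = 4)
  expect_equal(bs$B_effective, 12L)
  expect_lt(bs$rd_ci[1], bs$rd_ci[2])
  expect_true(all(bs$risk_never_ci >= 0 & bs$risk_never_ci <= 1))
  # deterministic given the seed
  bs2 <- aipw_bootstrap(coh, el, B = 12, seed = 4)
  expect_identical(bs$rd_ci, bs2$rd_ci)
})

test_that("zero adherent subjects is an error", {
  ing <- aipw_ingredients(200, seed = 30)
  rw <- ing$rw
  act <- adherent_clone_table(ing$el, rw)
  om <- fit_outcome_model(act, 90, character(0))
  rw$D_early <- 0L
  expect_error(aipw_risk(ing$el, rw, om, "early", 90), "adherent")
})
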