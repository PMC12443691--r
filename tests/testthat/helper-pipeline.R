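# Lean single-replicate pipeline used by the calibration and recovery
# studies: simulate -> screen -> weight -> estimate, computing only the
# pieces a given study needs.
run_ccw_rep <- function(n, seed, scenario = "null", horizon = 90,
                        pieces = c("cox"),
                        wspec = weight_model_spec(),
                        outcome_covariates = NULL,
                        truth = FALSE) {
  if (is.null(outcome_covariates))
    outcome_covariates <- unique(c(wspec$denominator, rrtccw:::OUTCOME_COVARS))
  cfg <- sim_config(n, seed = seed, scenario = scenario)
  coh <- rrtccw:::sim_engine(cfg, keep_internals = truth)
  el <- apply_eligibility(coh, eligibility_criteria())
  rs <- initiation_risk_set(coh, el, 72)
  den <- fit_treatment_hazard_model(rs, wspec)
  num <- fit_treatment_hazard_model(rs, wspec, type = "numerator")
  out <- list(el = el, den = den, num = num)
  if ("cox" %in% pieces) {
    cl <- apply_protocol_censoring(clone_subjects(el, 72, horizon))
    pt <- compute_stabilized_ipw(person_time_expand(cl), den, num,
                                 wspec$truncation)
    out$pt <- pt
    out$cox <- fit_weighted_cox(pt, horizon_days = horizon)
  }
  if ("aipw" %in% pieces) {
    rw <- resolved_clone_weights(el, den, num, 72, horizon)
    act <- adherent_clone_table(el, rw)
    om <- fit_outcome_model(act, horizon,
                            intersect(outcome_covariates, names(act)))
    re <- aipw_risk(el, rw, om, "early", horizon)
    rn <- aipw_risk(el, rw, om, "never", horizon)
    out$rw <- rw
    out$rd <- aipw_risk_difference(re, rn)
  }
  if ("naive" %in% pieces) {
    out$naive <- naive_ever_never_cox(el, horizon_days = horizon)
  }
  if (truth) out$gt <- simulate_counterfactual_truth(cfg, engine = coh)
  out
}
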