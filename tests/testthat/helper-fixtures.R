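# Shared fixtures and independent oracles for the test suite.

# A small eligible-subject table built by hand: only the columns the
# clone/censor machinery needs, plus one covariate.
make_eligible <- function(subject_id, init_rel, death_rel, x = 0) {
  data.frame(subject_id = subject_id,
             time_zero_hour = 0L,
             rrt_init_rel_hour = init_rel,
             death_rel_hour = death_rel,
             x = x,
             stringsAsFactors = FALSE)
}

# Independent re-derivation of the clone/censor rules, written as an explicit
# per-subject case analysis (deliberately different from the vectorized
# implementation).
brute_force_clone <- function(init_rel, death_rel, g, horizon_hours) {
  ti <- if (is.na(init_rel)) Inf else init_rel
  td <- if (is.na(death_rel)) Inf else death_rel
  early <- if (ti < g) {
    if (td <= horizon_hours) list(time = td, event = 1L, acens = 0L)
    else list(time = horizon_hours, event = 0L, acens = 0L)
  } else {
    if (td <= min(g, horizon_hours)) list(time = td, event = 1L, acens = 0L)
    else if (g <= horizon_hours) list(time = g, event = 0L, acens = 1L)
    else list(time = horizon_hours, event = 0L, acens = 0L)
  }
  never <- if (td <= min(ti, horizon_hours)) {
    list(time = td, event = 1L, acens = 0L)
  } else if (ti < min(td, horizon_hours)) {
    list(time = ti, event = 0L, acens = 1L)
  } else {
    list(time = horizon_hours, event = 0L, acens = 0L)
  }
  list(early = early, never = never)
}

# Fake initiation-hazard fits with hand-set probabilities, for exercising
# the weight arithmetic without fitting a model. `rows` is a data frame with
# subject_id, hours_since_elig, y, p (denominator) and p0 (numerator).
fake_hazard_fits <- function(rows) {
  n_rows <- as.integer(table(factor(rows$subject_id,
                                    levels = unique(rows$subject_id))))
  keys <- rows[c("subject_id", "hours_since_elig")]
  mk <- function(p) {
    structure(list(fit = list(y = rows$y), p = p, keys = keys,
                   n_rows = n_rows,
                   spec = weight_model_spec()),
              class = "ccw_hazard_fit")
  }
  list(den = mk(rows$p), num = mk(rows$p0))
}

# Deterministic two-arm survival data with exponential times (days),
# optional Weibull shape, used by the outcome-model tests.
sim_two_arm_surv <- function(n, hr = 1, rate0 = 0.01, shape = 1,
                             horizon_days = 90, seed = 1) {
  set.seed(seed)
  arm <- rep(c("never", "early"), each = n)
  rate <- ifelse(arm == "early", rate0 * hr, rate0)
  # Weibull PH: S(t) = exp(-rate * t^shape)
  u <- runif(2 * n)
  t_event <- (-log(u) / rate)^(1 / shape)
  time <- pmin(t_event, horizon_days)
  data.frame(subject_id = seq_len(2 * n), arm = arm,
             tstart = 0, tstop = time, time = time * 24,
             event = as.integer(t_event <= horizon_days),
             sw = 1, sw_trunc = 1, stringsAsFactors = FALSE)
}
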