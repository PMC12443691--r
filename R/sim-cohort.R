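# Synthetic ICU cohort generator.
#
# Covariate paths are simulated for every hour of the panel regardless of
# death (death truncates the *exported* panel), which is what lets the
# counterfactual machinery re-run the death process under both treatment
# strategies on shared random numbers.

# AR(1) parameters for the vitals/labs panel: population mean,
# between-subject SD, within-subject (stationary) SD. phi is the hourly
# autocorrelation. Magnitudes follow typical ICU AKI cohorts.
PANEL_AR1 <- list(
  heart_rate    = c(87,   8,    4),
  resp_rate     = c(20,   2.6,  1.2),
  sbp           = c(113, 12,    5),
  dbp           = c(60,   7.5,  3),
  temperature   = c(36.9, 0.25, 0.08),
  spo2          = c(97.2, 1.4,  0.6),
  ph            = c(7.37, 0.05, 0.015),
  bicarbonate   = c(22.4, 2.9,  0.5),
  hemoglobin    = c(9.0,  1.0,  0.15),
  urea_nitrogen = c(40,  15,    1.0)
)
AR1_PHI <- 0.95

PANEL_VARS <- c("sofa", names(PANEL_AR1), "mbp", "lactate", "creatinine")

sim_ar1 <- function(n, H1, mu_pop, sd_between, sd_within, phi = AR1_PHI) {
  mu <- rnorm(n, mu_pop, sd_between)
  inn <- sd_within * sqrt(1 - phi^2)
  x <- matrix(0, n, H1)
  x[, 1L] <- rnorm(n, 0, sd_within)
  e <- matrix(rnorm(n * (H1 - 1L), 0, inn), n, H1 - 1L)
  for (j in seq_len(H1 - 1L))
    x[, j + 1L] <- phi * x[, j] + e[, j]
  mu + x
}

# Full generative engine. Returns the factual cohort plus, when
# keep_internals = TRUE, the hazard linear predictors and uniform draws
# needed to replay the death process under counterfactual strategies.
sim_engine <- function(config, keep_internals = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  H <- config$panel_hours          # hourly death/initiation steps 0..H-1
  H1 <- H + 1L                     # panel columns, hours 0..H
  n_daily <- config$horizon_days   # daily death steps after the panel

  set.seed(config$seed)
  if (n == 0L) return(empty_cohort(config))

  ## ---- baseline covariates -------------------------------------------------
  age <- pmin(pmax(rnorm(n, 65, 15), 18), 95)
  female <- rbinom(n, 1L, 0.40)
  race <- sample(c("white", "black", "asian", "hispanic", "other"), n,
                 replace = TRUE, prob = c(0.63, 0.15, 0.035, 0.045, 0.14))
  cci <- pmin(pmax(round(rnorm(n, 7, 3)), 0), 16)
  sepsis <- rbinom(n, 1L, 0.62)
  mech_vent <- rbinom(n, 1L, 0.40)
  vasopressor <- rbinom(n, 1L, 0.06)
  ckd <- rbinom(n, 1L, 0.12)
  full_code <- rbinom(n, 1L, 0.92)
  hospital_pre_hours <- round(rgamma(n, shape = 2, scale = 18))
  icu_los_hours <- round(24 * rlnorm(n, log(6), 0.7))

  ## ---- hourly covariate panel ---------------------------------------------
  panel <- list()
  # SOFA: random walk clipped to the 0-24 score range. Hourly steps have
  # SD 0.25: organ failure scores evolve on a scale of days, and per-hour
  # unit-SD jumps would both be clinically implausible and make the
  # time-varying initiation hazard so volatile that inverse-probability
  # weights have unusable tails.
  sofa <- matrix(0, n, H1)
  sofa[, 1L] <- pmin(pmax(rnorm(n, 8, 3.5), 0), 24)
  sofa_steps <- matrix(rnorm(n * H, 0, 0.25), n, H)
  for (j in seq_len(H)) {
    sofa[, j + 1L] <- pmin(pmax(sofa[, j] + sofa_steps[, j], 0), 24)
  }
  panel$sofa <- sofa
  for (v in names(PANEL_AR1)) {
    p <- PANEL_AR1[[v]]
    panel[[v]] <- sim_ar1(n, H1, p[1], p[2], p[3])
  }
  panel$spo2 <- pmin(panel$spo2, 100)
  panel$resp_rate <- pmax(panel$resp_rate, 4)
  # MBP tracks (SBP + 2 DBP)/3 with an independent measurement/site
  # deviation so the three pressures are correlated but not collinear
  panel$mbp <- (panel$sbp + 2 * panel$dbp) / 3 + matrix(rnorm(n * H1, 0, 5), n, H1)
  # lactate: AR(1) on the log scale (right-skewed, multiplicative noise)
  panel$lactate <- exp(sim_ar1(n, H1, log(2.0), 0.40, 0.06))
  # creatinine: geometric random walk with subject-specific drift, so a
  # subset of subjects progresses through the KDIGO stages
  drift <- rnorm(n, 0.010, 0.007)
  lcre0 <- rnorm(n, log(1.1), 0.25)
  steps <- matrix(rnorm(n * H, 0, 0.02), n, H)
  lcre <- matrix(0, n, H1)
  lcre[, 1L] <- lcre0
  for (j in seq_len(H)) lcre[, j + 1L] <- lcre[, j] + drift + steps[, j]
  panel$creatinine <- pmin(pmax(exp(lcre), 0.3), 15)

  base_creat <- panel$creatinine[, 1L]
  kdigo <- kdigo_stage_matrix(panel$creatinine, base_creat)

  ## ---- hazards -------------------------------------------------------------
  bc <- config$baseline_coefs
  oc <- config$outcome_coefs
  hours_hourly <- 0:(H - 1L)
  # initiation hazard at hour s uses covariates at hour s
  lp_trt <- bc[["intercept"]] +
    bc[["sofa"]] * panel$sofa[, 1:H, drop = FALSE] +
    bc[["sepsis"]] * sepsis +
    bc[["vasopressor"]] * vasopressor +
    bc[["age10"]] * (age - 65) / 10 +
    matrix(bc[["hour"]] * hours_hourly, n, H, byrow = TRUE)
  # death hazard for interval (s, s+1] uses covariates at hour s
  lp_death_cov <- oc[["sofa"]] * panel$sofa[, 1:H, drop = FALSE] +
    oc[["lactate"]] * panel$lactate[, 1:H, drop = FALSE] +
    oc[["creatinine"]] * panel$creatinine[, 1:H, drop = FALSE]
  lp_death_base <- oc[["intercept"]] +
    oc[["sepsis"]] * sepsis + oc[["cci"]] * cci +
    oc[["age10"]] * (age - 65) / 10
  lp_death <- lp_death_base + lp_death_cov +
    matrix(oc[["log_days"]] * log1p(hours_hourly / 24), n, H, byrow = TRUE)
  # frozen covariates for the daily phase
  lp_death_frozen <- lp_death_base +
    oc[["sofa"]] * panel$sofa[, H1] +
    oc[["lactate"]] * panel$lactate[, H1] +
    oc[["creatinine"]] * panel$creatinine[, H1]

  u_trt <- matrix(runif(n * H), n, H)
  u_death <- matrix(runif(n * (H + n_daily)), n, H + n_daily)

  ## ---- factual treatment + death process ----------------------------------
  resolve_effect <- function(idx, init_s) {
    tl <- config$treatment_log_hr
    if (length(tl) == 1L) return(rep(unname(tl), length(idx)))
    st <- kdigo[cbind(idx, init_s + 1L)]
    unname(tl[pmax(st, 1L)])
  }
  alive <- rep(TRUE, n)
  treated_eff <- rep(0, n)
  treated <- rep(FALSE, n)
  init_hour <- rep(NA_integer_, n)
  death_hour <- rep(NA_real_, n)
  p_trt_mat <- plogis(lp_trt)
  # RRT is only ever started during an AKI episode: once KDIGO stage >= 1
  # has been reached the initiation decision stays on the table even if the
  # instantaneous stage dips back (episode-based gating)
  aki_seen <- kdigo[, 1:H, drop = FALSE] >= 1L
  if (H > 1L) for (j in 2:H) aki_seen[, j] <- aki_seen[, j] | aki_seen[, j - 1L]
  p_trt_mat[!aki_seen] <- 0
  p_death_mat <- plogis(lp_death)
  for (s in 0:(H - 1L)) {
    can_init <- alive & !treated
    if (any(can_init)) {
      new <- which(can_init & u_trt[, s + 1L] < p_trt_mat[, s + 1L])
      if (length(new)) {
        treated[new] <- TRUE
        init_hour[new] <- s
        treated_eff[new] <- resolve_effect(new, s)
      }
    }
    pd <- p_death_mat[, s + 1L]
    tr <- which(treated & treated_eff != 0)
    if (length(tr)) pd[tr] <- plogis(lp_death[tr, s + 1L] + treated_eff[tr])
    dies <- which(alive & u_death[, s + 1L] < pd)
    if (length(dies)) {
      alive[dies] <- FALSE
      death_hour[dies] <- s + 1L
    }
  }
  for (k in seq_len(n_daily)) {
    t_start <- H + 24L * (k - 1L)
    lp <- lp_death_frozen + oc[["log_days"]] * log1p(t_start / 24) +
      treated_eff * treated
    p_day <- 1 - (1 - plogis(lp))^24
    dies <- which(alive & u_death[, H + k] < p_day)
    if (length(dies)) {
      alive[dies] <- FALSE
      death_hour[dies] <- t_start + 24L
    }
  }

  icu_discharge_hour <- pmin(icu_los_hours,
                             ifelse(is.na(death_hour), Inf, death_hour))

  baseline <- data.frame(
    subject_id = seq_len(n),
    age = age, female = female, race = race, cci = cci,
    sepsis = sepsis, mech_vent = mech_vent, vasopressor = vasopressor,
    ckd = ckd, full_code = full_code,
    hospital_pre_hours = hospital_pre_hours,
    icu_discharge_hour = icu_discharge_hour,
    rrt_init_hour = init_hour,
    death_hour = death_hour,
    stringsAsFactors = FALSE
  )

  cohort <- structure(list(
    baseline = baseline,
    panel = panel,
    kdigo = kdigo,
    hours = 0:H,
    config = config
  ), class = "ccw_cohort")
  if (keep_internals) {
    cohort$internals <- list(
      lp_trt = lp_trt, lp_death = lp_death, lp_death_frozen = lp_death_frozen,
      u_trt = u_trt, u_death = u_death, kdigo = kdigo,
      n_daily = n_daily, H = H, resolve_effect = resolve_effect
    )
  }
  cohort
}

empty_cohort <- function(config) {
  baseline <- data.frame(
    subject_id = integer(), age = numeric(), female = integer(),
    race = character(), cci = numeric(), sepsis = integer(),
    mech_vent = integer(), vasopressor = integer(), ckd = integer(),
    full_code = integer(), hospital_pre_hours = numeric(),
    icu_discharge_hour = numeric(), rrt_init_hour = integer(),
    death_hour = numeric(), stringsAsFactors = FALSE
  )
  H1 <- config$panel_hours + 1L
  panel <- lapply(setNames(PANEL_VARS, PANEL_VARS),
                  function(v) matrix(numeric(), 0L, H1))
  structure(list(baseline = baseline, panel = panel,
                 kdigo = matrix(integer(), 0L, H1),
                 hours = 0:config$panel_hours, config = config),
            class = "ccw_cohort")
}

#' Simulate a synthetic ICU cohort with confounded RRT initiation
#'
#' Generates `n_subjects` subject histories: baseline covariates, an hourly
#' vitals/labs panel with KDIGO-stageable creatinine, a confounded
#' discrete-time hazard of RRT initiation, and death simulated hourly while
#' the panel runs and daily thereafter to the horizon. Identical
#' configurations (including the seed) give identical cohorts.
#'
#' @param config a [sim_config()] object.
#' @return a `ccw_cohort` object: `$baseline` (one row per subject, including
#'   `rrt_init_hour`, `death_hour` and `icu_discharge_hour`), `$panel` (a
#'   named list of subject-by-hour matrices), `$kdigo` (staged creatinine)
#'   and `$hours`. Use [cohort_tables()] for the long-format view or
#'   [write_cohort()] to export CSV/Parquet.
#' @examples
#' coh <- simulate_cohort(sim_config(50, seed = 7))
#' nrow(coh$baseline)
#' @export
simulate_cohort <- function(config) {
  sim_engine(config, keep_internals = FALSE)
}

#' @export
print.ccw_cohort <- function(x, ...) {
  n <- nrow(x$baseline)
  cat(sprintf("Synthetic ICU cohort: %d subjects, hourly panel 0-%d h\n",
              n, max(x$hours)))
  if (n) {
    cat(sprintf("  RRT initiated: %d (%.1f%%)   deaths: %d (%.1f%%)\n",
                sum(!is.na(x$baseline$rrt_init_hour)),
                100 * mean(!is.na(x$baseline$rrt_init_hour)),
                sum(!is.na(x$baseline$death_hour)),
                100 * mean(!is.na(x$baseline$death_hour))))
  }
  invisible(x)
}

#' Long-format tables for a cohort
#'
#' Converts a `ccw_cohort` into the two-table long format used for file
#' exchange: a baseline table (one row per subject) and an hourly panel table
#' (one row per subject-hour, truncated at death so no panel record follows
#' `death_hour`).
#'
#' @param cohort a `ccw_cohort`.
#' @return list with elements `baseline` and `panel` (data frames).
#' @export
cohort_tables <- function(cohort) {
  stopifnot(inherits(cohort, "ccw_cohort"))
  n <- nrow(cohort$baseline)
  H1 <- length(cohort$hours)
  if (n == 0L) {
    panel <- data.frame(subject_id = integer(), hour = integer())
    for (v in PANEL_VARS) panel[[v]] <- numeric()
    panel$kdigo_stage <- integer()
    return(list(baseline = cohort$baseline, panel = panel))
  }
  death <- cohort$baseline$death_hour
  last_hour <- pmin(ifelse(is.na(death), Inf, death), max(cohort$hours))
  n_rows <- pmin(last_hour, max(cohort$hours)) + 1L
  idx <- rep(seq_len(n), n_rows)
  hour <- sequence(n_rows) - 1L
  keep <- cbind(idx, hour + 1L)
  panel <- data.frame(subject_id = cohort$baseline$subject_id[idx], hour = hour)
  for (v in PANEL_VARS) panel[[v]] <- cohort$panel[[v]][keep]
  panel$kdigo_stage <- cohort$kdigo[keep]
  list(baseline = cohort$baseline, panel = panel)
}

#' Inject missingness into a cohort
#'
#' Sets baseline and/or panel fields missing completely at random at the
#' configured per-variable rates (for exercising the imputation machinery).
#'
#' @param cohort a `ccw_cohort`.
#' @param missing_rates named list/vector of probabilities; names are
#'   baseline columns (e.g. `age`, `cci`) or panel variables (e.g. `sofa`).
#' @param seed integer seed for the hole pattern.
#' @return the cohort with holes; attribute `"n_missing"` tallies the number
#'   of values removed per variable.
#' @export
inject_missingness <- function(cohort, missing_rates, seed = 1L) {
  stopifnot(inherits(cohort, "ccw_cohort"))
  mr <- unlist(missing_rates)
  assert_prob(mr, "missing_rates")
  set.seed(seed)
  counts <- integer(0)
  for (v in names(mr)) {
    if (v %in% names(cohort$panel)) {
      m <- cohort$panel[[v]]
      holes <- matrix(runif(length(m)) < mr[[v]], nrow(m), ncol(m))
      holes[is.na(m)] <- FALSE
      m[holes] <- NA_real_
      cohort$panel[[v]] <- m
      counts[v] <- sum(holes)
    } else if (v %in% names(cohort$baseline)) {
      x <- cohort$baseline[[v]]
      holes <- runif(length(x)) < mr[[v]] & !is.na(x)
      x[holes] <- NA
      cohort$baseline[[v]] <- x
      counts[v] <- sum(holes)
    } else {
      stop_ccw("unknown variable in missing_rates: ", v)
    }
  }
  attr(cohort, "n_missing") <- counts
  cohort
}
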