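# Clone-censor machinery: every eligible subject is duplicated into the two
# strategy arms at time zero, then artificially censored at the hour its data
# deviate from the assigned strategy.

#' Clone eligible subjects into the two strategy arms
#'
#' Creates two identical replicates of every eligible subject, one assigned
#' to "initiate RRT within the grace period" (`arm = "early"`) and one to
#' "never initiate" (`arm = "never"`), both starting follow-up at time zero
#' with the same covariate snapshot. Deaths within the grace period belong to
#' both clones; protocol-deviation censoring is applied afterwards by
#' [apply_protocol_censoring()].
#'
#' @param eligible output of [apply_eligibility()].
#' @param grace_hours grace period in hours (default 72).
#' @param horizon_days administrative follow-up horizon in days (default 90).
#'   Hospital or ICU discharge does not end mortality follow-up.
#' @return clone-level data frame (two rows per subject): arm, follow-up
#'   time in hours since time zero (`time`, before protocol censoring this is
#'   death or the horizon), `event`, and the covariate snapshot.
#' @export
clone_subjects <- function(eligible, grace_hours = 72, horizon_days = 90) {
  n <- nrow(eligible)
  hh <- horizon_days * 24
  one <- function(arm) {
    df <- eligible
    df$arm <- arm
    td <- ifelse(is.na(df$death_rel_hour), Inf, df$death_rel_hour)
    df$time <- pmin(td, hh)
    df$event <- as.integer(td <= hh)
    df$artificial_censor <- 0L
    df$admin_censor <- as.integer(td > hh)
    df
  }
  out <- rbind(one("early"), one("never"))
  out <- out[order(out$subject_id, out$arm), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grace_hours") <- grace_hours
  attr(out, "horizon_days") <- horizon_days
  out
}

#' Censor clones at protocol deviation
#'
#' Applies the deviation rules hour by hour: the never-initiate clone is
#' censored at the hour RRT factually begins (at any hour), and the
#' early-initiation clone is censored at the end of the grace period if RRT
#' has not begun by then. Initiation strictly before `grace_hours` counts as
#' within the grace period. Death at the same hour as a would-be censoring
#' takes precedence (the event is kept), which preserves the rule that
#' grace-period deaths are assigned to both clones.
#'
#' @param clones output of [clone_subjects()].
#' @param grace_hours grace period in hours; may be `Inf`, in which case the
#'   early arm reduces to "ever initiate" with no artificial censoring.
#' @return the clone table with `time`, `event`, `artificial_censor`,
#'   `admin_censor` finalized.
#' @export
apply_protocol_censoring <- function(clones, grace_hours = attr(clones, "grace_hours")) {
  assert_cols(clones, c("arm", "time", "event", "rrt_init_rel_hour",
                        "death_rel_hour"), "clone table")
  g <- grace_hours
  hh <- (attr(clones, "horizon_days") %||% 90) * 24
  ti <- ifelse(is.na(clones$rrt_init_rel_hour), Inf, clones$rrt_init_rel_hour)
  if (any(ti < 0)) stop_ccw("RRT initiation precedes time zero")
  td <- ifelse(is.na(clones$death_rel_hour), Inf, clones$death_rel_hour)

  early <- clones$arm == "early"
  time <- clones$time
  event <- clones$event
  acens <- integer(nrow(clones))

  # early arm: deviation = still untreated when the grace period closes
  nonadh <- early & ti >= g
  ev_e <- nonadh & td <= pmin(g, hh)
  cs_e <- nonadh & !ev_e & g <= pmin(td, hh)
  time[ev_e] <- td[ev_e]
  event[ev_e] <- 1L
  time[cs_e] <- g
  event[cs_e] <- 0L
  acens[cs_e] <- 1L

  # never arm: deviation = any factual initiation (death at the same hour wins)
  never <- !early
  dev <- never & ti < pmin(td, hh)
  ev_n <- never & td <= pmin(ti, hh)
  time[dev & !ev_n] <- ti[dev & !ev_n]
  event[dev & !ev_n] <- 0L
  acens[dev & !ev_n] <- 1L

  clones$time <- time
  clones$event <- as.integer(event)
  clones$artificial_censor <- acens
  clones$admin_censor <- as.integer(!event & !acens)
  attr(clones, "grace_hours") <- grace_hours
  attr(clones, "horizon_days") <- hh / 24
  clones
}

#' Expand censored clones into person-time rows
#'
#' Discrete-time representation for the pooled models: one row per
#' clone-hour through the grace period (where the stabilized weights change)
#' and one row per clone-day thereafter. Rows carry counting-process
#' intervals `(tstart, tstop]` in hours since time zero; `event` and the
#' censoring flags sit on each clone's final row.
#'
#' @param clones censored clone table from [apply_protocol_censoring()].
#' @param grace_hours hourly-resolution window (default: the table's grace
#'   attribute).
#' @param covariates logical: carry the time-zero covariate snapshot on every
#'   row (default `TRUE`).
#' @return person-time data frame with columns `subject_id`, `arm`, `hour`
#'   (= `tstop`), `tstart`, `tstop`, `at_risk`, `event`,
#'   `artificial_censor`, `admin_censor`, `treated` and `clone_row` (row
#'   index into `clones`).
#' @export
person_time_expand <- function(clones, grace_hours = attr(clones, "grace_hours"),
                               covariates = TRUE) {
  g <- grace_hours
  time <- clones$time
  ti <- ifelse(is.na(clones$rrt_init_rel_hour), Inf, clones$rrt_init_rel_hour)
  nh <- pmin(time, g)                       # hourly rows
  nh_int <- as.integer(ceiling(nh))
  nd <- as.integer(pmax(ceiling((time - g) / 24), 0))  # daily rows

  idx_h <- rep(seq_along(time), nh_int)
  start_h <- sequence(nh_int) - 1
  stop_h <- pmin(start_h + 1, time[idx_h])

  idx_d <- rep(seq_along(time), nd)
  j_d <- sequence(nd)
  start_d <- g + 24 * (j_d - 1)
  stop_d <- pmin(start_d + 24, time[idx_d])

  idx <- c(idx_h, idx_d)
  tstart <- c(start_h, start_d)
  tstop <- c(stop_h, stop_d)
  ord <- order(idx, tstart)
  idx <- idx[ord]; tstart <- tstart[ord]; tstop <- tstop[ord]

  last <- tstop >= time[idx]
  pt <- data.frame(
    subject_id = clones$subject_id[idx],
    arm = clones$arm[idx],
    hour = tstop,
    tstart = tstart,
    tstop = tstop,
    at_risk = 1L,
    event = as.integer(last & clones$event[idx] == 1L),
    artificial_censor = as.integer(last & clones$artificial_censor[idx] == 1L),
    admin_censor = as.integer(last & clones$admin_censor[idx] == 1L),
    treated = as.integer(clones$arm[idx] == "early" & ti[idx] <= tstart),
    clone_row = idx,
    stringsAsFactors = FALSE
  )
  if (covariates) {
    snap <- setdiff(names(clones), c(names(pt), "time", "event",
                                     "artificial_censor", "admin_censor", "arm"))
    for (v in snap) pt[[v]] <- clones[[v]][idx]
  }
  attr(pt, "grace_hours") <- g
  attr(pt, "horizon_days") <- attr(clones, "horizon_days")
  pt
}
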