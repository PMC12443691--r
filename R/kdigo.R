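#' KDIGO creatinine staging of acute kidney injury
#'
#' Stages an hourly serum creatinine series against a baseline value using the
#' KDIGO creatinine criteria: stage 1 for creatinine >= 1.5x baseline or an
#' absolute rise >= 0.3 mg/dL within 48 h, stage 2 for >= 2.0x baseline, and
#' stage 3 for >= 3.0x baseline or an absolute creatinine >= 4.0 mg/dL.
#' Urine-output criteria are not used, and staging never looks at RRT receipt,
#' so downstream treatment models cannot leak treatment into the exposure
#' definition.
#'
#' @param creatinine numeric vector of hourly creatinine values (mg/dL),
#'   ordered in time. `NA` values yield `NA` stages.
#' @param baseline_creatinine single positive baseline creatinine (mg/dL);
#'   conventionally the first recorded value.
#' @param window_hours width of the rolling window (hours) for the
#'   0.3 mg/dL absolute-rise rule (default 48, the KDIGO definition).
#' @return integer vector of stages 0-3, same length as `creatinine`.
#' @examples
#' kdigo_stage(c(1.0, 1.2, 3.2), 1.0)
#' @export
kdigo_stage <- function(creatinine, baseline_creatinine, window_hours = 48) {
  if (!is.numeric(baseline_creatinine) || length(baseline_creatinine) != 1L ||
      is.na(baseline_creatinine) || baseline_creatinine <= 0)
    stop_ccw("baseline_creatinine must be a single positive value")
  if (any(creatinine <= 0, na.rm = TRUE))
    stop_ccw("creatinine values must be positive")
  m <- matrix(creatinine, nrow = 1L)
  drop(kdigo_stage_matrix(m, baseline_creatinine, window_hours))
}

# Matrix version: creat is n x H (hour 0 .. H-1 columns), base a length-n
# vector. Rolling 48 h minimum is built from lagged pmin's so the whole
# cohort stages in a few dozen vectorized passes.
kdigo_stage_matrix <- function(creat, base, window_hours = 48) {
  H <- ncol(creat)
  # sparse-table rolling minimum over the trailing window: repeatedly halve
  # the window with lagged pmin's (O(log window) passes over the matrix)
  W <- as.integer(min(window_hours + 1L, H))  # window includes current hour
  rmin <- creat
  if (W > 1L) {
    stages <- list(`1` = creat)
    k <- 1L
    while (2L * k <= W) {
      prev <- stages[[as.character(k)]]
      cur <- prev
      cols <- (k + 1L):H
      cur[, cols] <- pmin(prev[, cols], prev[, cols - k])
      k <- 2L * k
      stages[[as.character(k)]] <- cur
    }
    # combine the largest power-of-two block with a (possibly overlapping)
    # equally sized block anchored at the window start
    blk <- stages[[as.character(k)]]
    rmin <- blk
    off <- W - k
    if (off > 0L) {
      cols <- (off + 1L):H
      rmin[, cols] <- pmin(blk[, cols], blk[, cols - off])
    }
  }
  ratio <- creat / base
  rise <- creat - rmin
  # highest criterion met wins; the absolute >= 4.0 mg/dL rule reaches stage 3
  # regardless of the ratio criteria
  stage <- pmax((ratio >= 1.5 | rise >= 0.3) * 1L,
                (ratio >= 2.0) * 2L,
                (ratio >= 3.0 | creat >= 4.0) * 3L)
  mode(stage) <- "integer"
  stage
}
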