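# Internal helpers shared across modules.

# Round half away from zero at `digits` decimals (printed-table convention;
# base round() uses banker's rounding).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ccw <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, what) {
  if (any(!is.finite(x) | x < 0 | x > 1))
    stop_ccw(what, " must lie in [0, 1]")
  invisible(x)
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_ccw(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

# Weighted mean / variance with NA protection.
wmean <- function(x, w) sum(x * w) / sum(w)

# Row-wise last-observation-carried-forward on an n x H matrix, optionally
# seeding leading NAs from `lead` (length-n vector). Column loop keeps this
# vectorized over subjects.
locf_matrix <- function(m, lead = NULL) {
  if (!is.matrix(m)) stop_ccw("locf_matrix expects a matrix")
  if (!is.null(lead)) {
    isna <- is.na(m[, 1L])
    m[isna, 1L] <- lead[isna]
  }
  if (ncol(m) > 1L) {
    for (j in 2:ncol(m)) {
      isna <- is.na(m[, j])
      if (any(isna)) m[isna, j] <- m[isna, j - 1L]
    }
  }
  m
}

# First TRUE index per row of a logical matrix (NA treated as FALSE);
# returns NA_integer_ for rows with no TRUE.
first_true_col <- function(m) {
  m[is.na(m)] <- FALSE
  hit <- rowSums(m) > 0
  out <- rep(NA_integer_, nrow(m))
  if (any(hit)) out[hit] <- max.col(m[hit, , drop = FALSE], ties.method = "first")
  out
}

# Flag covariates whose coefficients look separated: non-finite, or an
# SD-standardized logit coefficient beyond exp(10) per SD.
separated_covariates <- function(fit, data, covariates) {
  cf <- coef(fit)
  bad <- character(0)
  for (v in covariates) {
    if (!v %in% names(cf)) next
    b <- cf[[v]]
    s <- sd(data[[v]], na.rm = TRUE)
    if (!is.finite(b) || (is.finite(s) && s > 0 && abs(b) * s > 10))
      bad <- c(bad, v)
  }
  if (any(!is.finite(cf))) bad <- unique(c(bad, names(cf)[!is.finite(cf)]))
  bad
}

# Format "x (y)" summaries for tables.
fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA",
         formatC(round_half_up(x, digits), format = "f", digits = digits))
}
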