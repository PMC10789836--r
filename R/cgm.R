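#' Flash/continuous glucose monitoring trace
#'
#' @param timestamps POSIXct vector, or ISO-8601 strings, strictly
#'   increasing.
#' @param glucose interstitial glucose, mmol/l, strictly positive.
#' @param interval_min nominal sensor sampling interval in minutes; inferred
#'   from the median time step when `NULL`.
#' @return an object of class `cgm_trace`.
#' @export
cgm_trace <- function(timestamps, glucose, interval_min = NULL) {
  if (is.character(timestamps)) {
    timestamps <- as.POSIXct(timestamps, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                            "%Y-%m-%d %H:%M:%S"))
  }
  stopifnot(inherits(timestamps, "POSIXct"),
            length(timestamps) == length(glucose))
  if (anyNA(timestamps)) stop("unparseable timestamps")
  dt <- diff(as.numeric(timestamps)) / 60
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  check_positive(glucose, "glucose")
  if (is.null(interval_min)) interval_min <- median(dt)
  structure(list(timestamps = timestamps, glucose = as.numeric(glucose),
                 interval_min = interval_min),
            class = "cgm_trace")
}

#' @export
print.cgm_trace <- function(x, ...) {
  cat(sprintf("CGM trace: %d samples, %s to %s (nominal %g min)\n",
              length(x$glucose), format(min(x$timestamps)),
              format(max(x$timestamps)), x$interval_min))
  invisible(x)
}

# per-sample wear-time weights in minutes: each sample covers the interval to
# the next one, capped so that gaps beyond max_gap_factor * nominal interval
# contribute no wear time; the last sample covers one nominal interval.
cgm_weights <- function(trace, max_gap_factor = 2) {
  dt <- diff(as.numeric(trace$timestamps)) / 60
  w <- c(dt, trace$interval_min)
  w[w > max_gap_factor * trace$interval_min] <- 0
  w
}

#' Summarize a glucose monitoring trace
#'
#' Wear-time-weighted mean and coefficient of variation, and the
#' time-in-ranges family as percentages of valid wear time: below 3.9 mmol/l
#' (TBR), within the closed interval 3.9-10 mmol/l (TIR), above 10 mmol/l
#' (TAR), and above the 7.8 and 6.7 mmol/l thresholds ("below"/"above" are
#' strict).  Samples separated from their successor by more than
#' `max_gap_factor` times the nominal interval contribute no wear time, so
#' sensor gaps shrink the denominator rather than biasing the percentages.
#' CV uses the population (n-denominator) standard deviation.
#'
#' @param trace a [cgm_trace()].
#' @param max_gap_factor gap tolerance as a multiple of the nominal
#'   interval.
#' @param exclude_leading_hours hours of data dropped from the start of the
#'   trace (e.g. a sensor warm-up period); default 0.
#' @return an object of class `cgm_summary`: a list with `mean`, `cv`,
#'   `tbr_3_9`, `tir_3_9_10`, `tar_10`, `t_above_7_8`, `t_above_6_7`,
#'   `wear_hours`.
#' @export
cgm_summary <- function(trace, max_gap_factor = 2,
                        exclude_leading_hours = 0) {
  stopifnot(inherits(trace, "cgm_trace"))
  if (exclude_leading_hours > 0) {
    cut <- min(trace$timestamps) + exclude_leading_hours * 3600
    keep <- trace$timestamps >= cut
    trace <- cgm_trace(trace$timestamps[keep], trace$glucose[keep],
                       trace$interval_min)
  }
  w <- cgm_weights(trace, max_gap_factor)
  g <- trace$glucose
  wear_min <- sum(w)
  if (wear_min < 24 * 60) {
    stop(sprintf(
      "insufficient valid wear time: %.1f h of gap-free data (need >= 24 h)",
      wear_min / 60))
  }
  mu <- sum(w * g) / wear_min
  sigma <- sqrt(sum(w * (g - mu)^2) / wear_min)
  pct <- function(mask) sum(w[mask]) / wear_min * 100
  out <- list(
    mean = mu,
    cv = sigma / mu * 100,
    tbr_3_9 = pct(g < 3.9),
    tir_3_9_10 = pct(g >= 3.9 & g <= 10),
    tar_10 = pct(g > 10),
    t_above_7_8 = pct(g > 7.8),
    t_above_6_7 = pct(g > 6.7),
    wear_hours = wear_min / 60
  )
  class(out) <- "cgm_summary"
  out
}

#' @export
print.cgm_summary <- function(x, ...) {
  cat("CGM summary\n")
  cat(sprintf("  mean %.2f mmol/l, CV %.1f%% (%.1f h wear)\n",
              x$mean, x$cv, x$wear_hours))
  cat(sprintf("  TBR<3.9: %.1f%%  TIR 3.9-10: %.1f%%  TAR>10: %.1f%%\n",
              x$tbr_3_9, x$tir_3_9_10, x$tar_10))
  cat(sprintf("  >7.8: %.1f%%  >6.7: %.1f%%\n",
              x$t_above_7_8, x$t_above_6_7))
  invisible(x)
}

#' Ambulatory daily glucose profile
#'
#' Pools all monitored days by clock time and returns the median and the
#' 10th/90th percentiles per time-of-day bin, the standard presentation of
#' flash-monitoring reports.
#'
#' @param trace a [cgm_trace()] spanning at least 3 days.
#' @param bin_minutes bin width in minutes; must divide 24 h.
#' @return a data.frame with `tod_min` (bin start, minutes after midnight),
#'   `median`, `p10`, `p90`, `n`.
#' @export
cgm_daily_profile <- function(trace, bin_minutes = 60) {
  stopifnot(inherits(trace, "cgm_trace"))
  if ((24 * 60) %% bin_minutes != 0) {
    stop("'bin_minutes' must divide 24 hours")
  }
  span_days <- diff(range(as.numeric(trace$timestamps))) / 86400
  if (span_days < 3) stop("need at least 3 days of data")
  lt <- as.POSIXlt(trace$timestamps, tz = "UTC")
  tod <- lt$hour * 60 + lt$min + lt$sec / 60
  bin <- floor(tod / bin_minutes) * bin_minutes
  sp <- split(trace$glucose, bin)
  data.frame(
    tod_min = as.numeric(names(sp)),
    median = vapply(sp, median, numeric(1)),
    p10 = vapply(sp, quantile, numeric(1), probs = 0.1, names = FALSE),
    p90 = vapply(sp, quantile, numeric(1), probs = 0.9, names = FALSE),
    n = lengths(sp),
    row.names = NULL
  )
}

#' Count postprandial peaks in the average daily profile
#'
#' Averages the trace by clock time, smooths the 24-h mean profile with a
#' circular moving average, and counts local maxima exceeding a prominence
#' threshold over the surrounding +/- 3 h.  Reproduces the visual reading of
#' flash-monitoring reports: two postprandial peaks under breakfast+lunch
#' carbohydrate timing, three under a three-meal distribution.
#'
#' @param trace a [cgm_trace()].
#' @param bin_minutes time-of-day averaging bin, minutes.
#' @param window_minutes width of the circular smoothing window, minutes.
#' @param prominence minimum height above the neighbouring minima, mmol/l.
#' @return integer peak count.
#' @export
count_postprandial_peaks <- function(trace, bin_minutes = 15,
                                     window_minutes = 120,
                                     prominence = 0.5) {
  stopifnot(inherits(trace, "cgm_trace"))
  lt <- as.POSIXlt(trace$timestamps, tz = "UTC")
  tod <- floor((lt$hour * 60 + lt$min) / bin_minutes) * bin_minutes
  prof <- tapply(trace$glucose, tod, mean)
  k <- max(1, round(window_minutes / bin_minutes))
  sm <- as.numeric(stats::filter(as.numeric(prof), rep(1 / k, k),
                                 circular = TRUE))
  n <- length(sm)
  half <- round(180 / bin_minutes)
  peaks <- 0L
  for (i in seq_len(n)) {
    l <- sm[(i - 2) %% n + 1]
    r <- sm[i %% n + 1]
    if (sm[i] > l && sm[i] >= r) {
      nb <- sm[((i - 1) + (-half:half)) %% n + 1]
      if (sm[i] - min(nb) > prominence) peaks <- peaks + 1L
    }
  }
  peaks
}
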