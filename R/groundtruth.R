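# MET ground truth from indirect calorimetry: resting VO2, steady-state
# bout VO2, MET conversion and four-level intensity labels.

#' Ground-truth configuration
#'
#' @param rest_window minutes into the rest period over which resting VO2
#'   is averaged (default minutes 6 to 9).
#' @param steady_min_duration minimum steady-state duration, s.
#' @param trend_slope_tol maximum absolute least-squares VO2 slope for a
#'   window to count as steady, (ml/kg/min) per min. The quantitative
#'   threshold operationalizes the visual "no clear trend" criterion; the
#'   default 0.3 is strict enough to reject the first-order VO2 onset ramp
#'   even when a long flat tail would otherwise dilute its slope.
#' @param steady_avg_max_s the steady value is the mean over at most this
#'   many final seconds of the qualifying suffix, so late-plateau samples
#'   dominate and residual onset-lag bias is negligible.
#' @param met_cutoffs upper boundaries (exclusive) of the sedentary, light
#'   and moderate classes, METs. Boundary values belong to the upper class.
#' @return a `wearsite_gt_config` list.
#' @export
gt_config <- function(rest_window = c(6, 9),
                      steady_min_duration = 180,
                      trend_slope_tol = 0.3,
                      steady_avg_max_s = 180,
                      met_cutoffs = c(sedentary_lt = 1.5, light_lt = 3.0,
                                      moderate_lt = 6.0)) {
  stopifnot(length(met_cutoffs) == 3L,
            met_cutoffs[1] > 0, all(diff(met_cutoffs) > 0))
  structure(list(rest_window = rest_window,
                 steady_min_duration = steady_min_duration,
                 trend_slope_tol = trend_slope_tol,
                 steady_avg_max_s = steady_avg_max_s,
                 met_cutoffs = met_cutoffs),
            class = "wearsite_gt_config")
}

#' Resting VO2 from the seated rest period
#'
#' Arithmetic mean of the VO2 bins between minutes `rest_window[1]` and
#' `rest_window[2]` of the rest period (left-closed, right-open in time).
#'
#' @param series calorimetry series: list with `t` (s), `vo2` (ml/kg/min)
#'   and `rest_start` (s).
#' @param config see [gt_config()].
#' @return resting VO2, ml/kg/min.
#' @export
resting_vo2 <- function(series, config = gt_config()) {
  lo <- series$rest_start + config$rest_window[1] * 60
  hi <- series$rest_start + config$rest_window[2] * 60
  w <- series$t >= lo & series$t < hi
  if (!any(w)) {
    stop("no calorimetry samples in the resting window [", lo, ", ", hi, ") s")
  }
  mean(series$vo2[w])
}

#' Steady-state VO2 of one activity bout
#'
#' Scans suffix windows of the bout (every window ending at the bout end)
#' and locates the longest suffix of duration at least
#' `steady_min_duration` whose least-squares slope magnitude is within
#' `trend_slope_tol`; the returned value is the mean over (at most) the
#' final `steady_avg_max_s` seconds of that suffix. Returns an exclusion
#' when no qualifying window exists (including bouts shorter than the
#' minimum duration).
#'
#' @param series calorimetry series (see [resting_vo2()]).
#' @param bout one annotation row with `start_s` and `end_s`.
#' @param config see [gt_config()].
#' @return list with `value` (ml/kg/min or `NA`), `excluded` (logical),
#'   `reason` (string or `NA`), and `window_start_s` of the steady window.
#' @export
steady_state_vo2 <- function(series, bout, config = gt_config()) {
  w <- series$t >= bout$start_s & series$t < bout$end_s
  tt <- series$t[w]
  vv <- series$vo2[w]
  n <- length(tt)
  dt <- series$interval
  if (is.null(dt)) dt <- if (n > 1) stats::median(diff(tt)) else 0
  excl <- function(reason) list(value = NA_real_, excluded = TRUE,
                                reason = reason, window_start_s = NA_real_)
  if (n == 0L) return(excl("no calorimetry samples in bout"))
  if (n * dt < config$steady_min_duration) {
    return(excl("bout shorter than minimum steady-state duration"))
  }
  # suffix least-squares slopes in O(n) via reverse cumulative sums
  x <- tt / 60  # minutes
  rs <- function(v) rev(cumsum(rev(v)))
  Sx <- rs(x); Sy <- rs(vv); Sxx <- rs(x^2); Sxy <- rs(x * vv)
  m <- n - seq_len(n) + 1L
  denom <- m * Sxx - Sx^2
  slope <- ifelse(denom > 0, (m * Sxy - Sx * Sy) / denom, 0)
  ok <- (m * dt >= config$steady_min_duration) &
    abs(slope) <= config$trend_slope_tol
  if (!any(ok)) return(excl("no steady-state window"))
  i <- which(ok)[1L]  # longest qualifying suffix
  j <- max(i, n - as.integer(ceiling(config$steady_avg_max_s / dt)) + 1L)
  list(value = mean(vv[j:n]), excluded = FALSE, reason = NA_character_,
       window_start_s = tt[i])
}

#' Convert a bout's VO2 to metabolic equivalents
#'
#' METs are the ratio of the bout's oxygen consumption to the participant's
#' resting consumption; the rest period itself is 1 MET by definition.
#'
#' @param bout_vo2 steady-state bout VO2, ml/kg/min (vectorized).
#' @param resting resting VO2, ml/kg/min (> 0).
#' @return METs.
#' @export
compute_mets <- function(bout_vo2, resting) {
  if (length(resting) != 1L || is.na(resting) || resting <= 0) {
    stop("`resting` must be a single positive VO2 value")
  }
  bout_vo2 / resting
}

#' Classify METs into four intensity levels
#'
#' Half-open interval lookup on the configured cut-offs; boundary values
#' belong to the upper class (1.5 is light, 3.0 moderate, 6.0 vigorous).
#'
#' @param mets numeric METs (non-negative, vectorized).
#' @param config see [gt_config()].
#' @return ordered factor with levels sedentary < light < moderate <
#'   vigorous (`NA` propagates).
#' @export
classify_intensity <- function(mets, config = gt_config()) {
  if (any(is.nan(mets)) || any(mets < 0, na.rm = TRUE)) {
    stop("`mets` must be non-negative and not NaN")
  }
  idx <- findInterval(mets, config$met_cutoffs) + 1L
  intensity_factor(.INTENSITIES[idx])
}

#' Ground-truth results for a whole session
#'
#' Runs the full criterion pipeline on one simulated (or ingested) session:
#' resting VO2 from the rest window, steady-state VO2 per bout, MET
#' conversion and intensity labels. The rest segment's steady-state VO2 is
#' by convention the resting VO2 itself, so the rest period is always
#' exactly 1.0 MET.
#'
#' @param session a `wearsite_session`, or any list with `calorimetry` and
#'   `annotations`.
#' @param config see [gt_config()].
#' @return list with `resting_vo2`, `rest_mets` (identically 1), and
#'   `bouts`: data.frame (`bout_index`, `steady_vo2`, `mets`, `intensity`,
#'   `excluded`, `exclusion_reason`).
#' @export
session_ground_truth <- function(session, config = gt_config()) {
  series <- session$calorimetry
  resting <- resting_vo2(series, config)
  ann <- session$annotations
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    ss <- steady_state_vo2(series, ann[i, ], config)
    mets <- if (ss$excluded) NA_real_ else compute_mets(ss$value, resting)
    data.frame(bout_index = ann$bout_index[i],
               steady_vo2 = ss$value, mets = mets,
               intensity = if (is.na(mets)) NA_character_ else
                 as.character(classify_intensity(mets, config)),
               excluded = ss$excluded,
               exclusion_reason = ss$reason)
  })
  bouts <- do.call(rbind, rows)
  bouts$intensity <- intensity_factor(bouts$intensity)
  list(resting_vo2 = resting,
       rest_mets = compute_mets(resting, resting),
       bouts = bouts)
}
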