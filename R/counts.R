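# ActiGraph-style activity-count emulation and classical hip cut-point
# intensity classification, including deliberate wear-site misspecification.

#' Count-emulation configuration
#'
#' Stage constants of the frequency-band count emulation: resample to 30 Hz,
#' DC removal, Butterworth band-pass in the human-movement band, rectify,
#' dead-band, saturate, quantize, sum per second, aggregate to epochs.
#' Exact device-firmware parity is not claimed; every constant is exposed.
#'
#' @param resample_hz working rate for the filter stage, Hz.
#' @param band pass band, Hz.
#' @param order Butterworth order.
#' @param deadband_g rectified samples below this are zeroed, g.
#' @param saturation_g rectified samples are clipped here, g.
#' @param resolution_g quantization step, g per count.
#' @param sum_decimate per-second sums are divided by this before
#'   quantization (equivalent to summing every `sum_decimate`-th sample).
#' @return a list of stage constants.
#' @export
counts_config <- function(resample_hz = 30, band = c(0.29, 1.63), order = 3,
                          deadband_g = 0.068, saturation_g = 2.13,
                          resolution_g = 0.0164, sum_decimate = 10) {
  list(resample_hz = resample_hz, band = band, order = order,
       deadband_g = deadband_g, saturation_g = saturation_g,
       resolution_g = resolution_g, sum_decimate = sum_decimate)
}

#' Convert a raw recording to per-epoch activity counts
#'
#' @param recording a `wearsite_recording` (sample rate >= 30 Hz).
#' @param epoch_s epoch length, s (default 60).
#' @param config see [counts_config()].
#' @return a `wearsite_counts`: list with `epoch_s`, `epoch_start_s`,
#'   `axis_counts` (epochs x 3 integer matrix, columns x/y/z) and
#'   `vm_counts` (per-epoch vector magnitude).
#' @export
raw_to_counts <- function(recording, epoch_s = 60,
                          config = counts_config()) {
  fs <- recording$sample_rate
  if (fs < 30) stop("sample rate must be >= 30 Hz for count emulation")
  dur <- length(recording$t) / fs
  n_sec <- floor(dur)
  if (n_sec < epoch_s) stop("recording shorter than one epoch (", epoch_s,
                            " s)")
  hz <- config$resample_hz
  grid <- seq(0, n_sec - 1 / hz, by = 1 / hz)
  bf <- signal::butter(config$order, config$band / (hz / 2), type = "pass")
  t0 <- recording$t - recording$t[1]
  counts_sec <- sapply(c("x", "y", "z"), function(a) {
    v <- approx(t0, recording[[a]], xout = grid, rule = 2)$y
    v <- v - mean(v)  # DC removal ahead of the band-pass
    f <- as.numeric(signal::filter(bf, v))
    r <- pmin(abs(f), config$saturation_g)
    r[r < config$deadband_g] <- 0
    per_sec <- colSums(matrix(r, nrow = hz))
    floor(per_sec / config$sum_decimate / config$resolution_g)
  })
  n_ep <- n_sec %/% epoch_s
  keep <- seq_len(n_ep * epoch_s)
  axis_counts <- apply(counts_sec[keep, , drop = FALSE], 2, function(v) {
    colSums(matrix(v, nrow = epoch_s))
  })
  axis_counts <- matrix(axis_counts, nrow = n_ep, ncol = 3L,
                        dimnames = list(NULL, c("x", "y", "z")))
  structure(list(epoch_s = epoch_s,
                 epoch_start_s = (seq_len(n_ep) - 1L) * epoch_s +
                   recording$t[1],
                 axis_counts = axis_counts,
                 vm_counts = round(sqrt(rowSums(axis_counts^2)))),
            class = "wearsite_counts")
}

#' Cut-point sets
#'
#' `adult_cutpoints()` are the classical hip vertical-axis counts-per-minute
#' boundaries (sedentary < 100, light < 1952, moderate < 5725, vigorous
#' above); `child_cutpoints()` are the children's hip protocol rescaled from
#' its native 15-s epoch to counts per minute (100 / 2296 / 4012).
#'
#' @param epoch_s epoch the thresholds refer to, s. Thresholds scale
#'   proportionally when classifying counts at other epochs (see
#'   [cutpoint_classify()]).
#' @return a `wearsite_cutpoints` list: `name`, `group`, `epoch_s`,
#'   `thresholds` (3 strictly increasing boundaries), `axis`.
#' @export
adult_cutpoints <- function(epoch_s = 60) {
  cutpoint_set("adult_hip", "adult", epoch_s,
               thresholds = c(100, 1952, 5725) * epoch_s / 60,
               axis = "vertical")
}

#' @rdname adult_cutpoints
#' @export
child_cutpoints <- function(epoch_s = 60) {
  cutpoint_set("child_hip", "child", epoch_s,
               thresholds = c(100, 2296, 4012) * epoch_s / 60,
               axis = "vertical")
}

#' @rdname adult_cutpoints
#' @param name label for the set.
#' @param group `"adult"` or `"child"`.
#' @param thresholds three strictly increasing count boundaries mapping to
#'   the four intensity classes.
#' @param axis `"vertical"` (a single axis column) or `"vector_magnitude"`.
#' @export
cutpoint_set <- function(name, group, epoch_s, thresholds,
                         axis = c("vertical", "vector_magnitude")) {
  axis <- match.arg(axis)
  stopifnot(length(thresholds) == 3L, all(diff(thresholds) > 0))
  structure(list(name = name, group = group, epoch_s = epoch_s,
                 thresholds = thresholds, axis = axis),
            class = "wearsite_cutpoints")
}

#' Classify per-epoch counts with a cut-point set
#'
#' @param counts a `wearsite_counts`.
#' @param cutpoints a `wearsite_cutpoints`.
#' @param vertical_axis column used when `axis = "vertical"`; the hip
#'   protocol's vertical is the y column (2).
#' @param rescale_epochs allow proportional threshold rescaling when the
#'   counts epoch differs from the cut-point epoch; if `FALSE`, mismatched
#'   epochs are a configuration error.
#' @return ordered factor of per-epoch intensity labels.
#' @export
cutpoint_classify <- function(counts, cutpoints, vertical_axis = 2L,
                              rescale_epochs = TRUE) {
  thr <- cutpoints$thresholds
  if (counts$epoch_s != cutpoints$epoch_s) {
    if (!rescale_epochs) {
      stop("counts epoch (", counts$epoch_s, " s) does not match cut-point ",
           "epoch (", cutpoints$epoch_s, " s) and rescaling is disabled")
    }
    thr <- thr * counts$epoch_s / cutpoints$epoch_s
  }
  v <- if (cutpoints$axis == "vertical") {
    counts$axis_counts[, vertical_axis]
  } else {
    counts$vm_counts
  }
  intensity_factor(.INTENSITIES[findInterval(v, thr) + 1L])
}

# under/correct/over tabulation against ordinal truth, by group
tabulate_ucr <- function(truth, pred, group) {
  stopifnot(length(truth) == length(pred), length(truth) == length(group))
  ti <- as.integer(intensity_factor(truth))
  pi <- as.integer(intensity_factor(pred))
  out <- expand.grid(group = unique(as.character(group)),
                     intensity = .INTENSITIES, stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(out)), function(r) {
    w <- group == out$group[r] & ti == match(out$intensity[r], .INTENSITIES)
    n <- sum(w)
    if (n == 0L) {
      c(under = NA_real_, correct = NA_real_, over = NA_real_, n = 0)
    } else {
      c(under = 100 * sum(pi[w] < ti[w]) / n,
        correct = 100 * sum(pi[w] == ti[w]) / n,
        over = 100 * sum(pi[w] > ti[w]) / n, n = n)
    }
  })
  cbind(out, do.call(rbind, cells))
}

#' Misspecification report for the counts baseline
#'
#' Applies hip-calibrated cut-points (adult and child protocols for the
#' respective groups) to counts computed from the recordings of
#' `applied_site`, compares the per-epoch predictions with the bout-level
#' MET ground truth, and tabulates the fraction of epochs classified below
#' ("under"), at ("correct") and above ("over") the true intensity, per
#' group and true intensity, plus combined rows. Epochs must lie entirely
#' within a bout after trimming the first and final minute; epochs of
#' excluded bouts contribute nothing.
#'
#' @param sessions list of `wearsite_session` objects with recordings.
#' @param ground_truths list of [session_ground_truth()] results, parallel
#'   to `sessions`.
#' @param applied_site which wear-site's recordings the hip protocol is
#'   applied to (`"hip"` reproduces the correctly-specified baseline).
#' @param epoch_s epoch length, s.
#' @param trim_s seconds trimmed from each end of every bout.
#' @param cutpoints named list of cut-point sets per group.
#' @param counts_cfg see [counts_config()].
#' @return list with `table` (under/correct/over percentages by group x
#'   intensity plus combined rows), `overall_accuracy`, and the pooled
#'   per-epoch `truth`/`pred` vectors.
#' @export
misspecification_report <- function(sessions, ground_truths,
                                    applied_site = "hip", epoch_s = 60,
                                    trim_s = 60,
                                    cutpoints = list(
                                      adult = adult_cutpoints(),
                                      child = child_cutpoints()),
                                    counts_cfg = counts_config()) {
  truth <- character(0); pred <- character(0); grp <- character(0)
  for (k in seq_along(sessions)) {
    ses <- sessions[[k]]
    gt <- ground_truths[[k]]
    rec <- ses$recordings[[applied_site]]
    if (is.null(rec)) stop("session ", k, " has no ", applied_site,
                           " recording")
    cts <- raw_to_counts(rec, epoch_s = epoch_s, config = counts_cfg)
    cp <- cutpoints[[ses$profile$group]]
    lab <- as.character(cutpoint_classify(cts, cp))
    ann <- ses$annotations
    ep_lo <- cts$epoch_start_s
    ep_hi <- ep_lo + epoch_s
    for (i in seq_len(nrow(ann))) {
      b <- gt$bouts[gt$bouts$bout_index == ann$bout_index[i], ]
      if (nrow(b) == 0L || b$excluded || is.na(b$intensity)) next
      inside <- ep_lo >= ann$start_s[i] + trim_s &
        ep_hi <= ann$end_s[i] - trim_s
      if (!any(inside)) next
      truth <- c(truth, rep(as.character(b$intensity), sum(inside)))
      pred <- c(pred, lab[inside])
      grp <- c(grp, rep(ses$profile$group, sum(inside)))
    }
  }
  tab <- tabulate_ucr(truth, pred, grp)
  combined <- tabulate_ucr(truth, pred, rep("combined", length(truth)))
  comb_rows <- do.call(rbind, lapply(unique(grp), function(g) {
    w <- grp == g
    ti <- as.integer(intensity_factor(truth[w]))
    pi <- as.integer(intensity_factor(pred[w]))
    data.frame(group = g, intensity = "combined",
               under = 100 * mean(pi < ti), correct = 100 * mean(pi == ti),
               over = 100 * mean(pi > ti), n = sum(w))
  }))
  ti <- as.integer(intensity_factor(truth))
  pi <- as.integer(intensity_factor(pred))
  all_row <- data.frame(group = "combined", intensity = "combined",
                        under = 100 * mean(pi < ti),
                        correct = 100 * mean(pi == ti),
                        over = 100 * mean(pi > ti), n = length(ti))
  list(table = rbind(tab, comb_rows, all_row),
       overall_accuracy = mean(pi == ti),
       truth = intensity_factor(truth), pred = intensity_factor(pred),
       group = grp, applied_site = applied_site)
}
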