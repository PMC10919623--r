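# Fixed-length window segmentation, labeling, covariates and splits.

new_window_set <- function(x, site, intensity, participant_id, group,
                           covariates, window_len, stride) {
  structure(list(x = x, site = site_factor(site),
                 intensity = intensity_factor(intensity),
                 participant_id = participant_id, group = group,
                 covariates = covariates, window_len = window_len,
                 stride = stride),
            class = "wearsite_windows")
}

#' Number of windows in a window set
#' @param set a `wearsite_windows`.
#' @return integer count.
#' @export
n_windows <- function(set) dim(set$x)[1]

#' @export
print.wearsite_windows <- function(x, ...) {
  cat(sprintf(paste0("<wearsite_windows> %d windows of %d samples x 3 axes",
                     " (%d participants)%s\n"),
              n_windows(x), x$window_len,
              length(unique(x$participant_id)),
              if (is.null(x$covariates)) "" else ", covariates attached"))
  invisible(x)
}

#' Subset a window set by index
#' @param set a `wearsite_windows`.
#' @param idx integer or logical index over windows.
#' @return the subset `wearsite_windows`.
#' @export
subset_windows <- function(set, idx) {
  new_window_set(set$x[idx, , , drop = FALSE], set$site[idx],
                 set$intensity[idx], set$participant_id[idx],
                 set$group[idx],
                 if (is.null(set$covariates)) NULL else
                   set$covariates[idx, , drop = FALSE],
                 set$window_len, set$stride)
}

#' Combine window sets
#' @param sets list of `wearsite_windows` with equal window length.
#' @return one concatenated `wearsite_windows`.
#' @export
combine_window_sets <- function(sets) {
  sets <- Filter(function(s) n_windows(s) > 0L, sets)
  if (length(sets) == 0L) stop("no non-empty window sets to combine")
  L <- sets[[1]]$window_len
  stopifnot(all(vapply(sets, function(s) s$window_len, 0) == L))
  n <- sum(vapply(sets, n_windows, 0L))
  x <- array(0, c(n, L, 3L))
  at <- 0L
  for (s in sets) {
    k <- n_windows(s)
    x[at + seq_len(k), , ] <- s$x
    at <- at + k
  }
  has_cov <- !vapply(sets, function(s) is.null(s$covariates), TRUE)
  cov <- if (all(has_cov)) do.call(rbind, lapply(sets, `[[`, "covariates"))
  else NULL
  new_window_set(
    x,
    unlist(lapply(sets, function(s) as.character(s$site))),
    unlist(lapply(sets, function(s) as.character(s$intensity))),
    unlist(lapply(sets, `[[`, "participant_id")),
    unlist(lapply(sets, `[[`, "group")),
    cov, L, sets[[1]]$stride)
}

#' Segment a recording into labeled fixed-length windows
#'
#' Windows tile each annotated bout at the given stride after trimming
#' `trim_s` seconds from both ends (the non-steady entry/exit phases).
#' Excluded bouts contribute no windows; no window crosses a bout boundary.
#' Each window inherits the bout's intensity label and the recording's
#' wear-site.
#'
#' @param recording a `wearsite_recording`.
#' @param bout_results the `bouts` data.frame of [session_ground_truth()]
#'   (columns `bout_index`, `intensity`, `excluded`), or `NULL` to keep all
#'   annotated bouts with `NA` intensity.
#' @param window_len window length, samples (100 samples = 1 s at 100 Hz).
#' @param stride hop between window starts, samples (default non-overlap).
#' @param trim_s seconds removed from each end of every bout.
#' @param participant_id,group labels stored per window.
#' @return a `wearsite_windows`; zero windows when every trimmed bout is
#'   shorter than one window.
#' @export
segment_windows <- function(recording, bout_results = NULL,
                            window_len = 100L, stride = 100L, trim_s = 60,
                            participant_id = NA_character_,
                            group = NA_character_) {
  stopifnot(window_len >= 1L, stride >= 1L)
  fs <- recording$sample_rate
  ann <- recording$bout_annotations
  starts <- integer(0)
  labels <- character(0)
  for (i in seq_len(nrow(ann))) {
    lab <- NA_character_
    if (!is.null(bout_results)) {
      b <- bout_results[bout_results$bout_index == ann$bout_index[i], ]
      if (nrow(b) == 0L || isTRUE(b$excluded) || is.na(b$intensity)) next
      lab <- as.character(b$intensity)
    }
    i0 <- round((ann$start_s[i] + trim_s - recording$t[1]) * fs) + 1L
    i1 <- round((ann$end_s[i] - trim_s - recording$t[1]) * fs)
    i1 <- min(i1, length(recording$t))
    if (i1 - i0 + 1L < window_len) next  # over-trimmed: zero windows
    st <- seq.int(i0, i1 - window_len + 1L, by = stride)
    starts <- c(starts, st)
    labels <- c(labels, rep(lab, length(st)))
  }
  n <- length(starts)
  x <- array(0, c(n, window_len, 3L))
  if (n > 0L) {
    idx <- outer(starts, 0:(window_len - 1L), `+`)
    x[, , 1] <- recording$x[idx]
    x[, , 2] <- recording$y[idx]
    x[, , 3] <- recording$z[idx]
  }
  new_window_set(x, rep(recording$site, n), labels,
                 rep(participant_id, n), rep(group, n), NULL,
                 window_len, stride)
}

#' Build a labeled window set from simulated sessions
#'
#' Runs [session_ground_truth()] per session (unless supplied), segments
#' every requested wear-site recording, and concatenates windows across
#' participants with participant id, group and raw anthropometric
#' covariates (age, height, weight) attached.
#'
#' @param sessions list of `wearsite_session`.
#' @param sites wear-sites to include.
#' @param ground_truths optional list of precomputed ground truths.
#' @param gt_cfg see [gt_config()].
#' @inheritParams segment_windows
#' @return a `wearsite_windows` with covariates.
#' @export
build_window_set <- function(sessions, sites = c("hip", "wrist", "chest"),
                             ground_truths = NULL, gt_cfg = gt_config(),
                             window_len = 100L, stride = 100L, trim_s = 60) {
  sets <- list()
  for (k in seq_along(sessions)) {
    ses <- sessions[[k]]
    gt <- if (is.null(ground_truths)) session_ground_truth(ses, gt_cfg)
    else ground_truths[[k]]
    for (s in intersect(sites, names(ses$recordings))) {
      ws <- segment_windows(ses$recordings[[s]], gt$bouts,
                            window_len = window_len, stride = stride,
                            trim_s = trim_s,
                            participant_id = ses$profile$id,
                            group = ses$profile$group)
      if (n_windows(ws) > 0L) {
        ws$covariates <- matrix(
          rep(c(ses$profile$age, ses$profile$height, ses$profile$weight),
              each = n_windows(ws)),
          ncol = 3L, dimnames = list(NULL, c("age", "height", "weight")))
        sets[[length(sets) + 1L]] <- ws
      }
    }
  }
  combine_window_sets(sets)
}

#' Train/validation split of a window set
#'
#' `window_random` partitions individual windows uniformly at random (the
#' historical scheme for this pipeline; note it leaks participant identity
#' across the split). `by_participant` partitions whole participants and is
#' the leakage-safe alternative recommended for generalization claims.
#'
#' @param set a `wearsite_windows`.
#' @param train_fraction fraction of windows (or participants) assigned to
#'   training, in (0, 1).
#' @param seed integer seed; the partition is deterministic given the seed.
#' @param scheme `"window_random"` or `"by_participant"`.
#' @return list with `train` and `validation` window sets.
#' @export
split_windows <- function(set, train_fraction = 0.9, seed,
                          scheme = c("window_random", "by_participant")) {
  scheme <- match.arg(scheme)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)")
  }
  n <- n_windows(set)
  withr::with_seed(seed, {
    if (scheme == "window_random") {
      k <- round(n * train_fraction)
      tr <- sample.int(n, k)
    } else {
      ids <- unique(set$participant_id)
      kp <- max(1L, round(length(ids) * train_fraction))
      trid <- sample(ids, kp)
      tr <- which(set$participant_id %in% trid)
    }
  })
  if (length(tr) == 0L || length(tr) == n) {
    stop("split left one side empty; adjust `train_fraction`")
  }
  list(train = subset_windows(set, tr),
       validation = subset_windows(set, setdiff(seq_len(n), tr)))
}

#' Subsample a window set
#'
#' Draws a uniform random subset of windows (without replacement), e.g. to
#' fix the problem size of a training run.
#'
#' @param set a `wearsite_windows`.
#' @param n number of windows to keep (capped at the available count).
#' @param seed integer seed.
#' @return the subsampled `wearsite_windows`.
#' @export
subsample_windows <- function(set, n, seed) {
  n <- min(n, n_windows(set))
  idx <- withr::with_seed(seed, sample.int(n_windows(set), n))
  subset_windows(set, sort(idx))
}

#' Attach anthropometric covariates to a window set
#'
#' Joins age, height and weight from participant profiles by participant
#' id. With `standardize = TRUE` the covariates are z-scored; supply
#' `stats` (means and SDs from a training split) to standardize a
#' validation set with training statistics.
#'
#' @param set a `wearsite_windows`.
#' @param profiles participant profile data.frame.
#' @param standardize z-score the covariates.
#' @param stats optional list with `mean` and `sd` vectors of length 3.
#' @return the window set with a `covariates` matrix (and, when
#'   standardized, the statistics used in attribute `"cov_stats"`).
#' @export
attach_covariates <- function(set, profiles, standardize = FALSE,
                              stats = NULL) {
  m <- match(set$participant_id, profiles$id)
  if (anyNA(m)) {
    stop("missing profile for participant(s): ",
         paste(unique(set$participant_id[is.na(m)]), collapse = ", "))
  }
  cov <- cbind(age = profiles$age[m], height = profiles$height[m],
               weight = profiles$weight[m])
  if (standardize) {
    if (is.null(stats)) {
      stats <- list(mean = colMeans(cov),
                    sd = pmax(apply(cov, 2, sd), 1e-8))
    }
    cov <- sweep(sweep(cov, 2, stats$mean), 2, stats$sd, `/`)
    attr(cov, "cov_stats") <- stats
  }
  set$covariates <- cov
  set
}
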