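# Synthetic cohort, protocol, signal and calorimetry generator.
#
# The generator encodes three discriminative signals the downstream
# classifiers rely on: static gravity orientation (-> wear-site), movement
# amplitude and step frequency scaling with metabolic intensity
# (-> intensity), and an anthropometric modulation of the amplitude-to-MET
# mapping (-> covariates carry information).

#' Generator configuration
#'
#' All free constants of the synthetic-data model in one list. Movement
#' amplitude is calibrated so that hip vertical-axis emulated counts line up
#' approximately with the classical counts-per-minute to MET regression used
#' by hip cut-point protocols (about 1952 cpm near 3 METs and 5725 cpm near
#' 6 METs).
#'
#' @param sample_rate accelerometer sampling rate, Hz.
#' @param rest_duration_s seated rest block at the start of a session, s.
#' @param rest_between_s rest gap between activity bouts, s.
#' @param bout_duration_range_s range of realized bout durations, s.
#' @param cal_interval_s calorimetry averaging bin, s.
#' @param cal_noise_cv multiplicative noise CV of observed VO2 bins.
#' @param vo2_tau_s first-order time constant of the VO2 on/off kinetics, s.
#' @param steady_fail_frac fraction of bouts simulated as never reaching a
#'   metabolic steady state (VO2 keeps ramping for the whole bout).
#' @param met_floor lower truncation of per-bout MET draws.
#' @param amp_per_met movement amplitude scale, g per MET above rest.
#' @param white_noise_sd sensor white-noise SD, g.
#' @param drift_sd slow orientation-drift amplitude, g.
#' @param sedentary_ceiling_g movement-band RMS ceiling expected at rest, g.
#' @return a named list of generator constants, including per-site gravity
#'   orientations, movement loadings and gains, gait-waveform mixing
#'   weights, anthropometric coupling exponents, and the per-group,
#'   per-category VO2/MET distribution table.
#' @export
generator_config <- function(sample_rate = 100,
                             rest_duration_s = 600,
                             rest_between_s = 180,
                             bout_duration_range_s = c(300, 480),
                             cal_interval_s = 5,
                             cal_noise_cv = 0.03,
                             vo2_tau_s = 30,
                             steady_fail_frac = 0.05,
                             met_floor = 0.1,
                             amp_per_met = 0.22,
                             white_noise_sd = 0.015,
                             drift_sd = 0.02,
                             sedentary_ceiling_g = 0.05) {
  list(
    sample_rate = sample_rate,
    rest_duration_s = rest_duration_s,
    rest_between_s = rest_between_s,
    bout_duration_range_s = bout_duration_range_s,
    cal_interval_s = cal_interval_s,
    cal_noise_cv = cal_noise_cv,
    vo2_tau_s = vo2_tau_s,
    steady_fail_frac = steady_fail_frac,
    met_floor = met_floor,
    amp_per_met = amp_per_met,
    white_noise_sd = white_noise_sd,
    drift_sd = drift_sd,
    sedentary_ceiling_g = sedentary_ceiling_g,
    # unit gravity orientation per site (device-local axes)
    orientation = list(hip   = c(0.08, -0.99, 0.12),
                       wrist = c(-0.67, -0.21, 0.71),
                       chest = c(0.05, -0.93, 0.36)),
    # how the scalar movement process projects onto the device axes;
    # the hip protocol's "vertical" is the y column (loading 1 at the hip)
    loading = list(hip   = c(0.30, 1.00, 0.35),
                   wrist = c(1.00, 0.80, 0.60),
                   chest = c(0.20, 1.00, 0.50)),
    # site gains: desk-type (irregular) tasks move the wrist a lot at near-
    # rest METs; locomotion is hip/chest dominant with arm-swing at the wrist
    gain_irregular = c(hip = 0.9, wrist = 2.5, chest = 0.45),
    gain_locomotor = c(hip = 1.0, wrist = 1.7, chest = 0.9),
    # gait waveform: stride sway (f/2), step fundamental (f), harmonic (2f),
    # broadband impact noise; amplitudes before unit-RMS normalization
    gait_mix = c(stride = 0.70, step = 0.75, harmonic = 0.30, noise = 0.35),
    step_freq_base = 1.2,
    step_freq_per_met = 0.18,
    lanyard_freq = 0.25,
    lanyard_amp = 0.05,
    cov_ref = c(weight = 60, age = 25),
    cov_exp = c(weight = -0.4, age = -0.2),
    amp_mod_sd = 0.05,
    # per-group, per-category VO2/MET distributions (ml/kg/min and METs)
    met_table = data.frame(
      group    = rep(c("adult", "child"), each = 4L),
      category = rep(1:4, 2L),
      met_mean = c(1.7, 1.7, 5.8, 8.2, 1.8, 1.8, 4.8, 7.7),
      met_sd   = c(0.9, 0.9, 1.9, 2.3, 1.0, 1.0, 1.5, 2.1)
    ),
    resting_vo2 = data.frame(
      group = c("adult", "child"),
      mean  = c(4.09, 5.71),
      sd    = c(0.98, 1.91)
    )
  )
}

# truncated-normal draws by inverse CDF (deterministic under set.seed)
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Default activity catalog
#'
#' The 17-activity laboratory catalog spanning four intensity categories:
#' (1) sedentary or light daily-living activities, (2) light physical
#' activities, (3) moderate physical activities, (4) vigorous physical
#' activities. Each activity carries the MET distribution of its category
#' for the requested group (the available aggregate statistics are
#' category-level) and a flag marking gait-periodic (locomotor) movement.
#'
#' @param group `"adult"` or `"child"`; selects the MET distribution column.
#' @param config generator configuration, see [generator_config()].
#' @return data.frame with columns `name`, `category`, `met_mean`, `met_sd`,
#'   `locomotor`.
#' @export
default_catalog <- function(group = c("adult", "child"),
                            config = generator_config()) {
  group <- match.arg(group)
  acts <- data.frame(
    name = c("sitting_writing", "reading", "card_game", "sewing",
             "light_sweeping", "folding_clothes", "tablet_seated",
             "walk_2.0kph", "walk_3.2kph", "stretching",
             "walk_4.0kph", "walk_4.8kph", "walk_4.8kph_incline",
             "video_workout",
             "run_6.4kph", "run_7.2kph", "stair_climbing"),
    category = c(rep(1L, 7L), rep(2L, 3L), rep(3L, 4L), rep(4L, 3L)),
    locomotor = c(rep(FALSE, 7L), TRUE, TRUE, FALSE,
                  TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
  mt <- config$met_table[config$met_table$group == group, ]
  acts$met_mean <- mt$met_mean[match(acts$category, mt$category)]
  acts$met_sd <- mt$met_sd[match(acts$category, mt$category)]
  acts[, c("name", "category", "met_mean", "met_sd", "locomotor")]
}

#' Sample synthetic participant profiles
#'
#' Draws adult and child profiles whose age, BMI and resting VO2
#' distributions match the configured cohort statistics. Adult ages use a
#' shifted gamma (minimum 18 y) whose mean and SD equal the configured
#' values; a normal truncated at 18 would inflate the realized mean. Child
#' ages, BMI and resting VO2 use truncated normals with wide bounds.
#'
#' @param n_adult,n_child number of profiles per group (non-negative).
#' @param seed integer seed; output is fully reproducible.
#' @param config generator configuration.
#' @return data.frame with columns `id`, `group`, `sex`, `age` (years),
#'   `height` (cm), `weight` (kg), `resting_vo2` (ml/kg/min).
#' @export
sample_participants <- function(n_adult, n_child, seed,
                                config = generator_config()) {
  if (length(n_adult) != 1L || length(n_child) != 1L ||
      is.na(n_adult) || is.na(n_child) || n_adult < 0 || n_child < 0) {
    stop("`n_adult` and `n_child` must be single non-negative counts")
  }
  n_adult <- as.integer(n_adult)
  n_child <- as.integer(n_child)
  withr::with_seed(seed, {
    res <- list()
    if (n_adult > 0L) {
      # 18 + Gamma with mean 8.9 and sd 8.7
      k <- (8.9 / 8.7)^2
      age <- 18 + rgamma(n_adult, shape = k, scale = 8.7^2 / 8.9)
      height <- rtnorm(n_adult, 168, 8, 145, 200)
      bmi <- rtnorm(n_adult, 21.8, 2.0, 14, 35)
      rv <- config$resting_vo2
      resting <- rtnorm(n_adult, rv$mean[rv$group == "adult"],
                        rv$sd[rv$group == "adult"], 1.5, Inf)
      sex <- ifelse(runif(n_adult) < 11 / 26, "female", "male")
      res$adult <- data.frame(
        id = sprintf("A%03d", seq_len(n_adult)), group = "adult", sex = sex,
        age = age, height = height, weight = bmi * (height / 100)^2,
        resting_vo2 = resting)
    }
    if (n_child > 0L) {
      age <- rtnorm(n_child, 12.1, 2.3, 6, 17.9)
      height <- pmin(pmax(80 + 5.5 * age + rnorm(n_child, 0, 6), 100), 190)
      bmi <- rtnorm(n_child, 18.3, 2.5, 12, 35)
      rv <- config$resting_vo2
      resting <- rtnorm(n_child, rv$mean[rv$group == "child"],
                        rv$sd[rv$group == "child"], 1.5, Inf)
      sex <- ifelse(runif(n_child) < 19 / 28, "female", "male")
      res$child <- data.frame(
        id = sprintf("C%03d", seq_len(n_child)), group = "child", sex = sex,
        age = age, height = height, weight = bmi * (height / 100)^2,
        resting_vo2 = resting)
    }
    out <- do.call(rbind, res)
    if (is.null(out)) {
      out <- data.frame(id = character(), group = character(),
                        sex = character(), age = numeric(),
                        height = numeric(), weight = numeric(),
                        resting_vo2 = numeric())
    }
    rownames(out) <- NULL
    out
  })
}

#' Draw a per-participant activity protocol
#'
#' Shuffles the catalog and draws, without replacement, three activities
#' from category 1, three from categories 2 or 3, and one from category 4
#' (seven bouts), in randomized order, with realized bout durations uniform
#' on the configured range and a fixed rest gap after each bout.
#'
#' @param profile one-row participant profile (see [sample_participants()]).
#' @param catalog activity catalog; defaults to the profile's group catalog.
#' @param seed integer seed.
#' @param config generator configuration.
#' @return a `wearsite_protocol`: list with `participant_id` and a `bouts`
#'   data.frame (`name`, `category`, `met_mean`, `met_sd`, `locomotor`,
#'   `planned_duration`, `rest_after`).
#' @export
draw_protocol <- function(profile, catalog = NULL, seed,
                          config = generator_config()) {
  if (is.null(catalog)) catalog <- default_catalog(profile$group, config)
  n1 <- sum(catalog$category == 1L)
  n23 <- sum(catalog$category %in% c(2L, 3L))
  n4 <- sum(catalog$category == 4L)
  if (n1 < 3L || n23 < 3L || n4 < 1L) {
    stop("catalog must contain >= 3 category-1, >= 3 category-2/3 and >= 1 ",
         "category-4 activities")
  }
  withr::with_seed(seed, {
    pick <- function(rows, k) rows[sample.int(length(rows), k)]
    idx <- c(pick(which(catalog$category == 1L), 3L),
             pick(which(catalog$category %in% c(2L, 3L)), 3L),
             pick(which(catalog$category == 4L), 1L))
    idx <- idx[sample.int(7L)]
    bouts <- catalog[idx, ]
    bouts$planned_duration <- round(runif(
      7L, config$bout_duration_range_s[1], config$bout_duration_range_s[2]))
    bouts$rest_after <- config$rest_between_s
    rownames(bouts) <- NULL
    structure(list(participant_id = profile$id, bouts = bouts),
              class = "wearsite_protocol")
  })
}

# anthropometric modulation of the amplitude-to-MET mapping
cov_factor <- function(profile, config) {
  unname((profile$weight / config$cov_ref[["weight"]])^config$cov_exp[["weight"]] *
         (profile$age / config$cov_ref[["age"]])^config$cov_exp[["age"]])
}

# AR(1) noise with unit stationary RMS; `fc` is the -3 dB corner in Hz
ar1_noise <- function(n, fc, fs) {
  a <- exp(-2 * pi * fc / fs)
  x <- stats::filter(rnorm(n), a, method = "recursive")
  as.numeric(x) * sqrt(1 - a^2)
}

# scalar unit-RMS movement waveform for one bout
movement_waveform <- function(n, fs, met, locomotor, height, config) {
  if (locomotor) {
    f <- (config$step_freq_base + config$step_freq_per_met * met) *
      sqrt(170 / height)
    tt <- seq_len(n) / fs
    m <- config$gait_mix
    w <- m[["stride"]] * sin(pi * f * tt + runif(1, 0, 2 * pi)) +
      m[["step"]] * sin(2 * pi * f * tt + runif(1, 0, 2 * pi)) +
      m[["harmonic"]] * sin(4 * pi * f * tt + runif(1, 0, 2 * pi)) +
      m[["noise"]] * ar1_noise(n, 3, fs)
    w / sqrt(m[["stride"]]^2 / 2 + m[["step"]]^2 / 2 +
               m[["harmonic"]]^2 / 2 + m[["noise"]]^2)
  } else {
    ar1_noise(n, 1.5, fs)
  }
}

# n x 3 acceleration matrix for one bout (or rest when met = 1)
bout_acceleration <- function(n, profile, site, met, locomotor, config) {
  fs <- config$sample_rate
  gain <- if (locomotor) config$gain_locomotor[[site]] else
    config$gain_irregular[[site]]
  amp <- config$amp_per_met / sqrt(2) * max(met - 1, 0) * gain *
    cov_factor(profile, config)
  acc <- matrix(rnorm(n * 3L, 0, config$white_noise_sd), n, 3L)
  grav <- config$orientation[[site]]
  for (k in 1:3) {
    acc[, k] <- acc[, k] + grav[k] +
      config$drift_sd * ar1_noise(n, 0.05, fs)
  }
  if (amp > 0) {
    w <- movement_waveform(n, fs, met, locomotor, profile$height, config)
    # slow multiplicative amplitude modulation
    w <- w * (1 + config$amp_mod_sd * ar1_noise(n, 0.1, fs))
    load <- config$loading[[site]]
    for (k in 1:3) acc[, k] <- acc[, k] + amp * load[k] * w
  }
  if (site == "chest") {
    tt <- seq_len(n) / fs
    sway <- config$lanyard_amp * (1 + 0.5 * max(met - 1, 0)) *
      sin(2 * pi * config$lanyard_freq * tt + runif(1, 0, 2 * pi))
    acc[, 1] <- acc[, 1] + sway
    acc[, 3] <- acc[, 3] + 0.7 * sway
  }
  acc
}

new_recording <- function(site, sample_rate, t, xyz, annotations) {
  structure(list(site = site, sample_rate = sample_rate, t = t,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 bout_annotations = annotations),
            class = "wearsite_recording")
}

#' @export
print.wearsite_recording <- function(x, ...) {
  cat(sprintf("<wearsite_recording> site=%s, %.1f s at %g Hz, %d bouts\n",
              x$site, length(x$t) / x$sample_rate, x$sample_rate,
              nrow(x$bout_annotations)))
  invisible(x)
}

#' Simulate a single-bout triaxial recording
#'
#' Generates one wear-site recording of one activity bout: static gravity
#' orientation with slow drift, a movement component whose RMS amplitude
#' scales with the bout MET level (site gain and anthropometric
#' modulation applied), gait harmonics for locomotor activities, a
#' low-frequency lanyard sway at the chest, and sensor white noise.
#'
#' @param profile one-row participant profile.
#' @param activity one-row activity spec (a catalog row); its `met_mean` is
#'   used as the realized MET level (set `met` to override).
#' @param site `"hip"`, `"wrist"` or `"chest"`.
#' @param duration bout duration, s.
#' @param seed integer seed.
#' @param config generator configuration.
#' @param met optional realized MET level overriding `activity$met_mean`.
#' @return a `wearsite_recording` annotated with the single bout.
#' @export
simulate_bout_signal <- function(profile, activity, site, duration, seed,
                                 config = generator_config(), met = NULL) {
  if (!site %in% .SITES) {
    stop("unknown wear-site: ", site, " (expected hip, wrist or chest)")
  }
  if (duration <= 0) stop("`duration` must be positive")
  if (is.null(met)) met <- activity$met_mean
  fs <- config$sample_rate
  n <- round(duration * fs)
  withr::with_seed(seed, {
    xyz <- bout_acceleration(n, profile, site, met, activity$locomotor,
                             config)
    new_recording(site, fs, seq_len(n) / fs - 1 / fs, xyz,
                  data.frame(bout_index = 1L, start_s = 0,
                             end_s = duration))
  })
}

#' Simulate a full laboratory session
#'
#' A session is a 10-minute seated rest followed by the protocol's seven
#' bouts separated by rest gaps. For each bout a latent MET level is drawn
#' from the activity's truncated-normal MET distribution; observed VO2
#' follows first-order on/off kinetics toward the plateau
#' `met * resting_vo2` (5-s bins, multiplicative noise). A configurable
#' fraction of bouts never settles (the VO2 ramps for the whole bout),
#' emulating steady-state failures. All requested wear-site recordings share
#' one timeline and identical bout annotations. Latent draws are returned so
#' pipeline-level parameter-recovery checks are non-circular.
#'
#' @param profile one-row participant profile.
#' @param protocol a `wearsite_protocol` (see [draw_protocol()]).
#' @param sites character vector of wear-sites to record.
#' @param seed integer seed.
#' @param config generator configuration.
#' @param signals set `FALSE` to skip accelerometer synthesis and return
#'   calorimetry (and latents) only, e.g. for large ground-truth-only runs.
#' @return a `wearsite_session`: list with `profile`, `protocol`,
#'   `recordings` (named by site), `calorimetry` (list with `interval`, `t`,
#'   `vo2`, `rest_start`, `rest_end`), `annotations`, and `latent`
#'   (per-bout `met_draw`, `steady_fail`).
#' @export
simulate_session <- function(profile, protocol, sites = .SITES, seed,
                             config = generator_config(), signals = TRUE) {
  if (length(sites) == 0L) stop("`sites` must be non-empty")
  if (!all(sites %in% .SITES)) {
    stop("unknown wear-site: ", paste(setdiff(sites, .SITES), collapse = ", "))
  }
  bouts <- protocol$bouts
  nb <- nrow(bouts)
  withr::with_seed(seed, {
    met_draw <- rtnorm(nb, bouts$met_mean, bouts$met_sd, config$met_floor)
    steady_fail <- runif(nb) < config$steady_fail_frac
    # timeline
    start <- numeric(nb)
    t0 <- config$rest_duration_s
    for (i in seq_len(nb)) {
      start[i] <- t0
      t0 <- t0 + bouts$planned_duration[i] + bouts$rest_after[i]
    }
    total <- t0
    ann <- data.frame(bout_index = seq_len(nb), start_s = start,
                      end_s = start + bouts$planned_duration)

    # ---- calorimetry at cal_interval_s bins over the whole session ----
    dt <- config$cal_interval_s
    tb <- seq(0, total - dt, by = dt)
    resting <- profile$resting_vo2
    plateau <- met_draw * resting
    lag <- exp(-dt / config$vo2_tau_s)
    v <- numeric(length(tb))
    state <- resting
    for (k in seq_along(tb)) {
      tk <- tb[k]
      i <- which(tk >= ann$start_s & tk < ann$end_s)
      if (length(i) == 1L) {
        if (steady_fail[i]) {
          # never settles: target ramps linearly across the bout
          frac <- (tk - ann$start_s[i]) / bouts$planned_duration[i]
          target <- resting + (plateau[i] - resting) * frac
        } else {
          target <- plateau[i]
        }
      } else {
        target <- resting
      }
      state <- target + (state - target) * lag
      v[k] <- state
    }
    vo2 <- pmax(v * (1 + rnorm(length(v), 0, config$cal_noise_cv)), 0)
    calorimetry <- list(interval = dt, t = tb, vo2 = vo2, rest_start = 0,
                        rest_end = config$rest_duration_s)

    # ---- accelerometry, one stream per site, shared timeline ----
    recordings <- list()
    if (isTRUE(signals)) {
      fs <- config$sample_rate
      n_total <- round(total * fs)
      tt <- seq_len(n_total) / fs - 1 / fs
      for (s in sites) {
        xyz <- bout_acceleration(n_total, profile, s, 1, FALSE, config)
        for (i in seq_len(nb)) {
          i0 <- round(ann$start_s[i] * fs) + 1L
          i1 <- round(ann$end_s[i] * fs)
          seg <- bout_acceleration(i1 - i0 + 1L, profile, s, met_draw[i],
                                   bouts$locomotor[i], config)
          xyz[i0:i1, ] <- seg
        }
        recordings[[s]] <- new_recording(s, fs, tt, xyz, ann)
      }
    }
    structure(list(profile = profile, protocol = protocol,
                   recordings = recordings, calorimetry = calorimetry,
                   annotations = ann,
                   latent = data.frame(bout_index = seq_len(nb),
                                       activity = bouts$name,
                                       category = bouts$category,
                                       met_draw = met_draw,
                                       steady_fail = steady_fail)),
              class = "wearsite_session")
  })
}

#' @export
print.wearsite_session <- function(x, ...) {
  cat(sprintf("<wearsite_session> %s (%s), %d bouts, sites: %s\n",
              x$profile$id, x$profile$group, nrow(x$annotations),
              if (length(x$recordings)) paste(names(x$recordings),
                                              collapse = ", ") else "none"))
  invisible(x)
}

#' Simulate a cohort of sessions
#'
#' Convenience wrapper: samples profiles, draws one protocol per participant
#' and simulates each session with per-participant sub-seeds derived from
#' `seed`.
#'
#' @inheritParams sample_participants
#' @param sites wear-sites to record.
#' @param signals synthesize accelerometry (`TRUE`) or calorimetry only.
#' @param config generator configuration.
#' @return list with `profiles` (data.frame) and `sessions` (list of
#'   `wearsite_session`, named by participant id).
#' @export
simulate_cohort <- function(n_adult, n_child, seed, sites = .SITES,
                            signals = TRUE, config = generator_config()) {
  profiles <- sample_participants(n_adult, n_child, seed, config)
  sessions <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    sub <- (seed + 7919L * i) %% .Machine$integer.max
    prot <- draw_protocol(p, seed = sub, config = config)
    sessions[[i]] <- simulate_session(p, prot, sites = sites,
                                      seed = sub + 1L, config = config,
                                      signals = signals)
  }
  names(sessions) <- profiles$id
  list(profiles = profiles, sessions = sessions)
}

#' Movement-band RMS of a recording segment
#'
#' High-passes each axis above 0.25 Hz (removing gravity and slow drift) and
#' returns the RMS of the residual vector magnitude; the generator's measure
#' of movement intensity.
#'
#' @param recording a `wearsite_recording`.
#' @return movement-band RMS in g.
#' @export
movement_rms <- function(recording) {
  fs <- recording$sample_rate
  bf <- signal::butter(2, 0.25 / (fs / 2), type = "high")
  res <- vapply(c("x", "y", "z"), function(a) {
    v <- signal::filtfilt(bf, recording[[a]] - mean(recording[[a]]))
    mean(v^2)
  }, numeric(1))
  sqrt(sum(res))
}
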