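# Shared fixtures, built in code at test time.

fixture_profile <- function(group = "adult") {
  data.frame(id = if (group == "adult") "A001" else "C001", group = group,
             sex = "female", age = if (group == "adult") 30 else 11,
             height = if (group == "adult") 170 else 145,
             weight = if (group == "adult") 63 else 38,
             resting_vo2 = if (group == "adult") 4.09 else 5.71)
}

fixture_activity <- function(category = 3L, locomotor = TRUE,
                             met_mean = 5.8, met_sd = 1.9,
                             name = "walk_4.8kph") {
  data.frame(name = name, category = category, met_mean = met_mean,
             met_sd = met_sd, locomotor = locomotor)
}

# calorimetry series built directly from a vo2 function of time
fixture_calorimetry <- function(vo2_fun, total_s = 1200, interval = 5,
                                rest_end = 600) {
  t <- seq(0, total_s - interval, by = interval)
  list(interval = interval, t = t, vo2 = vo2_fun(t), rest_start = 0,
       rest_end = rest_end)
}

# recording fabricated from raw axis vectors (100 Hz by default)
fixture_recording <- function(x, y = x, z = x, fs = 100, site = "hip",
                              annotations = NULL) {
  n <- length(x)
  if (is.null(annotations)) {
    annotations <- data.frame(bout_index = 1L, start_s = 0, end_s = n / fs)
  }
  structure(list(site = site, sample_rate = fs, t = seq_len(n) / fs - 1 / fs,
                 x = x, y = y, z = z, bout_annotations = annotations),
            class = "wearsite_recording")
}

# label-only window set over pure-noise windows, for model unit tests
fixture_toy_windows <- function(n, window_len = 30, seed = 5,
                                shift = 0.5, n_classes = 2) {
  withr::with_seed(seed, {
    cls <- c("hip", "wrist", "chest")[seq_len(n_classes)]
    y <- rep(cls, length.out = n)
    x <- array(rnorm(n * window_len * 3), c(n, window_len, 3))
    x[, , 1] <- x[, , 1] + shift * (match(y, cls) - (n_classes + 1) / 2)
    ws <- wearsite:::new_window_set(
      x, rep("hip", n), rep(NA_character_, n), sprintf("P%02d", seq_len(n)),
      rep("adult", n), NULL, window_len, window_len)
    ws$site <- factor(y, levels = c("hip", "wrist", "chest"))
    ws
  })
}

one_bout_results <- function(intensity = "moderate", excluded = FALSE,
                             bout_index = 1L) {
  data.frame(bout_index = bout_index,
             steady_vo2 = 20, mets = 5,
             intensity = intensity, excluded = excluded,
             exclusion_reason = NA_character_)
}
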