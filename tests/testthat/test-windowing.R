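# Window segmentation, bookkeeping, splits and covariates.

make_bout_recording <- function(duration_s, fs = 100) {
  n <- duration_s * fs
  fixture_recording(rnorm(n, 0, 0.1),
                    annotations = data.frame(bout_index = 1L, start_s = 0,
                                             end_s = duration_s))
}

test_that("window counts follow the tiling formula", {
  withr::with_seed(1, {
    rec <- make_bout_recording(300)
    # 5-min bout, 60-s trims, stride 100 -> (300 - 120) one-second windows
    ws <- segment_windows(rec, one_bout_results(), stride = 100L)
    expect_equal(n_windows(ws), 180L)
    # stride 50 -> floor((18000 - 100) / 50) + 1
    ws <- segment_windows(rec, one_bout_results(), stride = 50L)
    expect_equal(n_windows(ws), 359L)
    # over-trimmed bout contributes zero windows
    ws <- segment_windows(make_bout_recording(90), one_bout_results())
    expect_equal(n_windows(ws), 0L)
    # excluded bout contributes zero windows
    ws <- segment_windows(rec, one_bout_results(excluded = TRUE))
    expect_equal(n_windows(ws), 0L)
  })
})

test_that("window bookkeeping matches the formula across random geometries", {
  withr::with_seed(42, {
    for (i in 1:5) {
      dur <- sample(150:500, 1)
      stride <- sample(c(25, 50, 100, 150), 1)
      trim <- sample(c(10, 30, 60), 1)
      rec <- make_bout_recording(dur)
      ws <- segment_windows(rec, one_bout_results(), stride = stride,
                            trim_s = trim)
      samples <- (dur - 2 * trim) * 100
      expected <- if (samples < 100) 0L else
        floor((samples - 100) / stride) + 1
      expect_equal(n_windows(ws), expected)
    }
  })
})

test_that("windows never cross bout boundaries and inherit bout labels", {
  fs <- 100
  n <- 30 * fs
  ann <- data.frame(bout_index = 1:2, start_s = c(0, 15), end_s = c(10, 30))
  # bout 1 constant 1, bout 2 constant 2, gap constant 0
  x <- numeric(n)
  x[1:(10 * fs)] <- 1
  x[(15 * fs + 1):(30 * fs)] <- 2
  rec <- fixture_recording(x, annotations = ann)
  br <- rbind(one_bout_results("light", bout_index = 1L),
              one_bout_results("vigorous", bout_index = 2L))
  ws <- segment_windows(rec, br, trim_s = 1)
  expect_equal(n_windows(ws), 8L + 13L)
  vals <- apply(ws$x[, , 1], 1, unique)
  expect_true(all(vals %in% c(1, 2)))  # no window mixes bouts
  expect_equal(as.character(ws$intensity[vals == 1]),
               rep("light", 8))
  expect_equal(as.character(ws$intensity[vals == 2]),
               rep("vigorous", 13))
})

test_that("splits are exact, deterministic and participant-safe", {
  ws <- fixture_toy_windows(1000)
  sp <- split_windows(ws, 0.9, seed = 5)
  expect_equal(n_windows(sp$train), 900L)
  expect_equal(n_windows(sp$validation), 100L)
  sp2 <- split_windows(ws, 0.9, seed = 5)
  expect_identical(sp$train$participant_id, sp2$train$participant_id)
  expect_identical(sp$train$x, sp2$train$x)

  wsp <- ws
  wsp$participant_id <- rep(sprintf("P%02d", 1:10), each = 100)
  bp <- split_windows(wsp, 0.8, seed = 6, scheme = "by_participant")
  expect_length(intersect(unique(bp$train$participant_id),
                          unique(bp$validation$participant_id)), 0L)
  expect_error(split_windows(ws, 1.0, seed = 1), "train_fraction")
})

test_that("covariates join per participant and standardize with training stats", {
  ws <- fixture_toy_windows(20)
  ws$participant_id <- rep(c("A001", "C001"), each = 10)
  profiles <- rbind(fixture_profile("adult"), fixture_profile("child"))
  out <- attach_covariates(ws, profiles)
  expect_equal(unique(out$covariates[1:10, "age"]), 30)
  expect_equal(unique(out$covariates[11:20, "height"]), 145)
  expect_error(attach_covariates(
    ws, profiles[profiles$id == "A001", ]), "missing profile")

  # single participant: one shared covariate triple
  ws1 <- fixture_toy_windows(6)
  ws1$participant_id <- rep("A001", 6)
  out1 <- attach_covariates(ws1, profiles)
  expect_equal(nrow(unique(out1$covariates)), 1L)

  # z-scoring: training means zero; validation uses training statistics
  tr <- attach_covariates(ws, profiles, standardize = TRUE)
  expect_equal(unname(colMeans(tr$covariates)), rep(0, 3))
  stats <- attr(tr$covariates, "cov_stats")
  va <- fixture_toy_windows(4)
  va$participant_id <- rep("A001", 4)
  va <- attach_covariates(va, profiles, standardize = TRUE, stats = stats)
  manual <- (30 - stats$mean[["age"]]) / stats$sd[["age"]]
  expect_equal(unname(va$covariates[1, "age"]), manual)
  expect_false(isTRUE(all.equal(unname(colMeans(va$covariates)),
                                rep(0, 3))))
})

test_that("session window sets carry site, group and covariates", {
  prof <- fixture_profile()
  prot <- draw_protocol(prof, seed = 71)
  ses <- simulate_session(prof, prot, sites = c("hip", "wrist"), seed = 72)
  ws <- build_window_set(list(ses), sites = c("hip", "wrist"))
  expect_gt(n_windows(ws), 0)
  expect_setequal(as.character(unique(ws$site)), c("hip", "wrist"))
  expect_equal(unique(ws$participant_id), "A001")
  expect_equal(unique(ws$covariates[, "weight"]), prof$weight)
  # per-site window counts match: identical annotations, identical tiling
  expect_equal(sum(ws$site == "hip"), sum(ws$site == "wrist"))

  sub <- subsample_windows(ws, 50, seed = 3)
  expect_equal(n_windows(sub), 50L)
  expect_identical(subsample_windows(ws, 50, seed = 3)$x, sub$x)
})
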