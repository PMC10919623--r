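# Synthetic cohort, protocol and signal generator.

test_that("participant sampling respects counts, invariants and the seed", {
  expect_equal(nrow(sample_participants(0, 0, seed = 1)), 0L)
  expect_error(sample_participants(-1, 0, seed = 1), "non-negative")

  p <- sample_participants(40, 30, seed = 9)
  expect_equal(sum(p$group == "adult"), 40L)
  expect_equal(sum(p$group == "child"), 30L)
  expect_true(all(p$age > 0 & p$height > 0 & p$weight > 0 &
                    p$resting_vo2 > 0))
  expect_true(all(p$age[p$group == "adult"] >= 18))
  expect_true(all(p$age[p$group == "child"] < 18))

  expect_identical(p, sample_participants(40, 30, seed = 9))
  p2 <- sample_participants(40, 30, seed = 10)
  expect_false(identical(p, p2))
})

test_that("cohort statistics recover the configured distributions", {
  p <- sample_participants(500, 500, seed = 7)
  ad <- p[p$group == "adult", ]
  ch <- p[p$group == "child", ]
  # adult age: mean 26.9, sd 8.7 (shifted-gamma parameterization)
  expect_lt(abs(mean(ad$age) - 26.9), 1.0)
  # BMI within 2 SE of configured means
  expect_lt(abs(mean(ad$weight / (ad$height / 100)^2) - 21.8),
            2 * 2.0 / sqrt(500))
  expect_lt(abs(mean(ch$weight / (ch$height / 100)^2) - 18.3),
            2 * 2.5 / sqrt(500))
  expect_lt(abs(mean(ch$age) - 12.1), 2 * 2.3 / sqrt(500))
})

test_that("protocol drawing enforces the 3/3/1 category composition", {
  prof <- fixture_profile()
  prot <- draw_protocol(prof, seed = 3)
  b <- prot$bouts
  expect_equal(nrow(b), 7L)
  expect_equal(sum(b$category == 1), 3L)
  expect_equal(sum(b$category %in% 2:3), 3L)
  expect_equal(sum(b$category == 4), 1L)
  expect_equal(anyDuplicated(b$name), 0L)  # without replacement
  expect_true(all(b$planned_duration >= 300 & b$planned_duration <= 480))
  expect_identical(draw_protocol(prof, seed = 3), prot)

  # forced composition when the catalog is exactly 3+3+1
  cat17 <- default_catalog("adult")
  small <- cat17[c(which(cat17$category == 1)[1:3],
                   which(cat17$category %in% 2:3)[1:3],
                   which(cat17$category == 4)[1]), ]
  prot2 <- draw_protocol(prof, catalog = small, seed = 4)
  expect_setequal(prot2$bouts$name, small$name)

  expect_error(draw_protocol(prof, catalog = cat17[cat17$category != 4, ],
                             seed = 1),
               "category-4")
})

test_that("default catalog has 17 activities with category MET parameters", {
  for (g in c("adult", "child")) {
    cat17 <- default_catalog(g)
    expect_equal(nrow(cat17), 17L)
    expect_true(all(cat17$met_mean > 0 & cat17$met_sd >= 0))
  }
  # moderate/vigorous rows differ between groups
  expect_false(isTRUE(all.equal(default_catalog("adult")$met_mean,
                                default_catalog("child")$met_mean)))
})

test_that("resting signal is gravity-dominated and below the sedentary ceiling", {
  prof <- fixture_profile()
  act <- fixture_activity(1L, FALSE, met_mean = 1.0, name = "reading")
  cfg <- generator_config()
  for (s in c("hip", "wrist", "chest")) {
    rec <- simulate_bout_signal(prof, act, s, duration = 60, seed = 5)
    vm <- sqrt(rec$x^2 + rec$y^2 + rec$z^2)
    expect_lt(abs(mean(vm) - 1), 0.1)
    expect_lt(movement_rms(rec), cfg$sedentary_ceiling_g)
  }
  expect_error(simulate_bout_signal(prof, act, "ankle", 60, seed = 1),
               "unknown wear-site")
  expect_error(simulate_bout_signal(prof, act, "hip", -5, seed = 1),
               "positive")
})

test_that("mean orientation separates wear-sites", {
  prof <- fixture_profile()
  act <- fixture_activity(2L, TRUE, met_mean = 2.0, name = "walk_3.2kph")
  gvec <- function(site) {
    r <- simulate_bout_signal(prof, act, site, 60, seed = 8)
    v <- c(mean(r$x), mean(r$y), mean(r$z))
    v / sqrt(sum(v^2))
  }
  ang <- function(a, b) acos(sum(a * b)) * 180 / pi
  expect_gt(ang(gvec("hip"), gvec("wrist")), 20)
  expect_gt(ang(gvec("hip"), gvec("chest")), 10)
  expect_gt(ang(gvec("wrist"), gvec("chest")), 20)
})

test_that("movement-band RMS increases strictly with MET at a fixed site", {
  prof <- fixture_profile()
  for (site in c("hip", "wrist")) {
    for (loco in c(TRUE, FALSE)) {
      act <- fixture_activity(3L, loco)
      rms <- vapply(c(1.2, 2.5, 4, 6, 8.5), function(m) {
        movement_rms(simulate_bout_signal(prof, act, site, 30, seed = 12,
                                          met = m))
      }, numeric(1))
      expect_true(all(diff(rms) > 0))
    }
  }
})

test_that("sessions align sites, embed latents and match resting VO2", {
  prof <- fixture_profile()
  prot <- draw_protocol(prof, seed = 31)
  ses <- simulate_session(prof, prot, sites = c("hip", "wrist", "chest"),
                          seed = 32)
  expect_length(ses$recordings, 3L)
  for (r in ses$recordings) {
    expect_identical(r$bout_annotations, ses$annotations)
  }
  # rest-segment calorimetry reproduces the profile's resting VO2
  rest <- ses$calorimetry$vo2[ses$calorimetry$t < 600]
  expect_lt(abs(mean(rest) - prof$resting_vo2) / prof$resting_vo2, 0.05)
  expect_equal(nrow(ses$latent), 7L)
  expect_true(all(ses$latent$met_draw > 0))
  expect_error(simulate_session(prof, prot, sites = character(0), seed = 1),
               "non-empty")

  # determinism of the full session
  ses2 <- simulate_session(prof, prot, sites = c("hip", "wrist", "chest"),
                           seed = 32)
  expect_identical(ses$recordings$hip$x, ses2$recordings$hip$x)
  expect_identical(ses$calorimetry$vo2, ses2$calorimetry$vo2)
})

test_that("ground-truth pipeline recovers the latent MET draw within 2%", {
  prof <- fixture_profile()
  prot <- draw_protocol(prof, seed = 61)
  ses <- simulate_session(prof, prot, sites = "hip", seed = 62,
                          signals = FALSE)
  gt <- session_ground_truth(ses)
  cmp <- merge(gt$bouts, ses$latent, by = "bout_index")
  kept <- cmp[!cmp$excluded & !cmp$steady_fail & cmp$category >= 3, ]
  expect_gt(nrow(kept), 0L)
  expect_true(all(abs(kept$mets - kept$met_draw) / kept$met_draw < 0.02))
})
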