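# Accuracy, confusion, under/correct/over collapse and table rendering.

test_that("accuracy counts agreements", {
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(accuracy(c("a", "b"), c("b", "a")), 0.0)
  expect_equal(accuracy(c("a", "b", "b", "b"), c("a", "a", "b", "b")),
               0.75)
  expect_error(accuracy("a", c("a", "b")), "equal length")
})

test_that("confusion matrices conserve counts with rows as truth", {
  cls <- c("sedentary", "light", "moderate", "vigorous")
  cf <- confusion(pred = cls, truth = cls, classes = cls)
  expect_equal(unname(diag(cf)), rep(1L, 4))
  expect_equal(sum(cf), 4)

  cf <- confusion(pred = "vigorous", truth = "moderate", classes = cls)
  expect_equal(unname(cf["moderate", "vigorous"]), 1)
  expect_equal(sum(cf), 1)

  expect_error(confusion("thigh", "hip", c("hip", "wrist")), "unknown")
})

test_that("under/correct/over collapse matches hand percentages", {
  cls <- c("sedentary", "light", "moderate", "vigorous")
  cf <- matrix(0, 4, 4, dimnames = list(cls, cls))
  diag(cf) <- c(5, 2, 3, 4)
  out <- collapse_under_over(cf)
  expect_equal(out$correct, rep(100, 4))

  # light row predicted (sed 1, light 2, mod 1) -> 25 / 50 / 25
  cf["light", ] <- c(1, 2, 1, 0)
  out <- collapse_under_over(cf)
  lt <- out[out$intensity == "light", ]
  expect_equal(c(lt$under, lt$correct, lt$over), c(25, 50, 25))
  # boundary rows have structurally absent cells
  expect_true(is.na(out$under[out$intensity == "sedentary"]))
  expect_true(is.na(out$over[out$intensity == "vigorous"]))
  # mass conservation before rounding
  present <- out[out$n > 0, ]
  sums <- rowSums(cbind(present$under, present$correct, present$over),
                  na.rm = TRUE)
  expect_equal(unname(sums), rep(100, nrow(present)))
})

test_that("evaluation reports tie accuracy to the confusion diagonal", {
  withr::with_seed(31, {
    cls <- c("sedentary", "light", "moderate", "vigorous")
    truth <- sample(cls, 200, replace = TRUE)
    pred <- ifelse(runif(200) < 0.7, truth, sample(cls, 200,
                                                   replace = TRUE))
    rep <- evaluation_report(pred, truth, cls)
    expect_equal(rep$overall_accuracy,
                 sum(diag(rep$confusion)) / sum(rep$confusion))
    expect_equal(rep$overall_accuracy, accuracy(pred, truth))
    expect_true(all(rep$per_class$sensitivity >= 0 &
                      rep$per_class$sensitivity <= 1))
  })
})

test_that("rendered tables round-trip through CSV", {
  withr::with_seed(33, {
    truth <- sample(c("sedentary", "light", "moderate", "vigorous"), 300,
                    replace = TRUE)
    pred <- ifelse(runif(300) < 0.8, truth,
                   sample(c("sedentary", "light", "moderate", "vigorous"),
                          300, replace = TRUE))
    grp <- sample(c("adult", "child"), 300, replace = TRUE)
  })
  rep1 <- list(table = wearsite:::tabulate_ucr(truth, pred, grp))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t2")
  wide <- render_table2(list(hip = rep1), path = p)
  expect_true(file.exists(paste0(p, ".csv")))
  expect_true(file.exists(paste0(p, ".txt")))
  back <- utils::read.csv(paste0(p, ".csv"))
  expect_equal(back$hip_correct,
               ifelse(is.na(rep1$table$correct), NA, rep1$table$correct))
  # a perfect cell prints 100% in the correct column
  perf <- list(table = wearsite:::tabulate_ucr(
    rep("light", 4), rep("light", 4), rep("adult", 4)))
  w <- render_table2(list(hip = perf))
  expect_equal(w$hip_correct[w$intensity == "light" & w$group == "adult"],
               "100%")

  grid <- expand.grid(purpose = c("site", "intensity", "intensity_cov"),
                      group = c("adult", "child", "combined"),
                      site_scope = c("two", "three"),
                      architecture = c("lstm", "bilstm"),
                      stringsAsFactors = FALSE)
  grid$accuracy <- withr::with_seed(34, runif(nrow(grid), 0.85, 0.97))
  p3 <- file.path(dir, "t3")
  wide3 <- render_table3(grid, path = p3)
  expect_equal(nrow(wide3), 9L)  # 3 purposes x 3 groups
  expect_equal(ncol(wide3), 2L + 4L)  # 2 scopes x 2 architectures
  back3 <- utils::read.csv(paste0(p3, ".csv"))
  expect_equal(back3$two_site_lstm[1],
               100 * grid$accuracy[grid$purpose == "site" &
                                     grid$group == "adult" &
                                     grid$site_scope == "two" &
                                     grid$architecture == "lstm"])
})
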