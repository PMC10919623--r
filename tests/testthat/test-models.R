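# Sequence-classifier architectures, training contracts and prediction.

test_that("layer specifications match the two architectures", {
  lstm <- nn_layer_spec(model_config("lstm", "intensity4"))
  expect_equal(sum(lstm$learnable), 3L)
  expect_equal(lstm$layer, c("lstm", "dense_relu", "output_softmax"))

  bi <- nn_layer_spec(model_config("bilstm", "site3"))
  expect_equal(bi$layer, c("conv1d_relu", "maxpool", "bilstm", "lstm",
                           "lstm", "dense_relu", "output_softmax"))
  expect_equal(bi$output_dim[nrow(bi)], 3L)

  # covariate concatenation widens the dense input by exactly 3
  H <- 32
  with_cov <- nn_layer_spec(model_config("lstm", "intensity4",
                                         use_covariates = TRUE,
                                         recurrent_units = H))
  expect_equal(with_cov$input_dim[2], H + 3L)

  expect_error(model_config("lstm", "site2", n_classes = 4), "n_classes")
  expect_error(model_config("lstm", "site2", dropout_rate = 1),
               "dropout_rate")
  expect_error(model_config("lstm", "site2", epochs = 0), "epochs")
})

test_that("training separates a linearly separable toy set like the oracle", {
  ws <- fixture_toy_windows(500, shift = 2.0)
  # independent oracle: threshold on the channel-1 mean is perfect here
  ch1 <- apply(ws$x[, , 1], 1, mean)
  oracle <- ifelse(ch1 > 0, "wrist", "hip")
  expect_equal(accuracy(oracle, ws$site), 1.0)

  sp <- split_windows(ws, 0.9, seed = 3)
  cfg <- model_config("lstm", "site2", recurrent_units = 16,
                      dense_units = 16, epochs = 10, batch_size = 32,
                      window_len = 30, seed = 11)
  fit <- train_model(cfg, sp$train, sp$validation)
  expect_equal(nrow(fit$history), 10L)
  expect_gte(fit$history$val_acc[10], 0.95)
})

test_that("training is bitwise-deterministic given the seed", {
  ws <- fixture_toy_windows(200)
  sp <- split_windows(ws, 0.9, seed = 2)
  cfg <- model_config("bilstm", "site2", recurrent_units = 8,
                      dense_units = 8, conv_filters = 8, epochs = 3,
                      batch_size = 32, window_len = 30, seed = 21)
  f1 <- train_model(cfg, sp$train, sp$validation)
  f2 <- train_model(cfg, sp$train, sp$validation)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})

test_that("label-shuffled training yields chance-level validation accuracy", {
  # unstructured inputs: with clustered inputs a network aligns clusters to
  # classes from finite-sample label correlations even after shuffling
  ws <- fixture_toy_windows(1000, shift = 0)
  sp <- split_windows(ws, 0.9, seed = 7)
  shuf <- sp$train
  shuf$site <- withr::with_seed(8, sample(shuf$site))
  cfg <- model_config("lstm", "site2", recurrent_units = 16,
                      dense_units = 16, epochs = 5, batch_size = 32,
                      window_len = 30, seed = 9)
  fit <- train_model(cfg, shuf, sp$validation)
  expect_lt(abs(fit$history$val_acc[5] - 0.5), 0.1)
})

test_that("training contract errors are raised", {
  ws <- fixture_toy_windows(40)
  empty <- subset_windows(ws, integer(0))
  cfg <- model_config("lstm", "site2", window_len = 30, epochs = 1)
  expect_error(train_model(cfg, empty, ws), "empty")
  mono <- subset_windows(ws, which(ws$site == "hip"))
  expect_error(train_model(cfg, mono, ws), "single class")
  cfgc <- model_config("lstm", "site2", window_len = 30, epochs = 1,
                       use_covariates = TRUE)
  expect_error(train_model(cfgc, ws, ws), "covariates")
})

test_that("predictions are proper probabilities with deterministic tie-breaks", {
  ws <- fixture_toy_windows(120)
  sp <- split_windows(ws, 0.8, seed = 4)
  cfg <- model_config("lstm", "site2", recurrent_units = 8,
                      dense_units = 8, epochs = 2, batch_size = 32,
                      window_len = 30, seed = 5)
  fit <- train_model(cfg, sp$train, sp$validation)
  pr <- predict_model(fit, sp$validation)
  expect_equal(max(abs(rowSums(pr$prob) - 1)), 0, tolerance = 1e-5)
  expect_true(all(pr$prob >= 0))

  # duplicated window: identical probability rows
  x2 <- sp$validation$x[c(1, 1), , , drop = FALSE]
  pr2 <- predict_model(fit, x2)
  expect_identical(pr2$prob[1, ], pr2$prob[2, ])

  # ties break toward the lowest class index
  expect_equal(wearsite:::argmax_first(rbind(c(0.5, 0.5))), 1L)
  expect_equal(wearsite:::argmax_first(rbind(c(0.2, 0.4, 0.4))), 2L)

  bad <- sp$validation$x[, 1:10, , drop = FALSE]
  expect_error(predict_model(fit, bad), "shape")
})

test_that("experiment grid filters tasks, groups and sites", {
  ws <- fixture_toy_windows(300, n_classes = 3)
  ws$group <- rep(c("adult", "child"), length.out = 300)
  ws$intensity <- intensity_factor(
    rep(c("sedentary", "light", "moderate", "vigorous"), length.out = 300))
  ws$covariates <- matrix(rnorm(900), 300, 3,
                          dimnames = list(NULL, c("age", "height",
                                                  "weight")))
  grid <- run_experiment_grid(
    ws, purposes = c("site", "intensity_cov"), groups = c("adult",
                                                          "combined"),
    site_scopes = "two", architectures = "lstm", seed = 2, epochs = 1,
    recurrent_units = 4, dense_units = 4, window_len = 30)
  expect_equal(nrow(grid), 4L)
  expect_true(all(!is.na(grid$accuracy)))
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 1))
  # two-site scope drops chest windows; group cells drop the other group
  two_site_n <- sum(as.character(ws$site) %in% c("hip", "wrist"))
  adult_n <- sum(as.character(ws$site) %in% c("hip", "wrist") &
                   ws$group == "adult")
  comb <- grid[grid$group == "combined", ]
  expect_equal(unique(comb$n_train + comb$n_val), two_site_n)
  ad <- grid[grid$group == "adult", ]
  expect_equal(unique(ad$n_train + ad$n_val), adult_n)
})
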