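# Sequence classifiers for wear-site detection and intensity
# classification over raw 1-second acceleration windows.

task_classes <- function(task) {
  switch(task,
         site2 = c("hip", "wrist"),
         site3 = c("hip", "wrist", "chest"),
         intensity4 = .INTENSITIES,
         stop("unknown task: ", task))
}

#' Model configuration
#'
#' Two fixed architectures are available. `"lstm"`: one fully connected
#' LSTM layer, one dense layer with ReLU activation and dropout, and one
#' dense output layer with softmax activation. `"bilstm"` (stacked): one
#' convolution layer, one pooling layer, one bidirectional LSTM layer, two
#' LSTM layers, one dense layer with ReLU activation and dropout, and one
#' dense output layer with softmax. When `use_covariates` is set, the three
#' standardized anthropometric covariates (age, height, weight) are
#' concatenated to the final recurrent state ahead of the dense layer.
#'
#' @param architecture `"lstm"` or `"bilstm"`.
#' @param task `"site2"` (hip/wrist), `"site3"` (hip/wrist/chest) or
#'   `"intensity4"` (sedentary/light/moderate/vigorous).
#' @param n_classes optional; must equal the task's class count.
#' @param recurrent_units,dense_units hidden widths.
#' @param dropout_rate dropout probability on the dense layer, in [0, 1).
#' @param conv_filters,conv_kernel,pool_size convolution/pooling stage of
#'   the stacked model.
#' @param use_covariates concatenate age/height/weight covariates.
#' @param epochs training epochs (default 20).
#' @param batch_size,learning_rate,clip_norm optimizer settings
#'   (adaptive-moment optimizer).
#' @param lr_schedule `"cosine"` (decay to 5% of the base rate across the
#'   epochs; the default) or `"constant"`.
#' @param head_pooling how the recurrent output sequence is summarized
#'   before the dense head: `"last"` (final hidden state, the default) or
#'   `"mean"` (temporal mean of the top recurrent layer's outputs).
#' @param weight_decay decoupled weight-decay coefficient (0 disables).
#' @param label_smoothing label-smoothing mass spread uniformly over the
#'   classes (0 disables); useful when class labels are intrinsically
#'   noisy near decision boundaries.
#' @param window_len,n_channels input window shape.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout; training is deterministic given the seed.
#' @return a `wearsite_model_config` list.
#' @export
model_config <- function(architecture = c("lstm", "bilstm"),
                         task = c("site2", "site3", "intensity4"),
                         n_classes = NULL, recurrent_units = 64L,
                         dense_units = 64L, dropout_rate = 0.2,
                         conv_filters = 64L, conv_kernel = 9L,
                         pool_size = 3L, use_covariates = FALSE,
                         epochs = 20L, batch_size = 32L,
                         learning_rate = 1.5e-3,
                         lr_schedule = c("cosine", "constant"),
                         head_pooling = c("last", "mean"),
                         weight_decay = 0, label_smoothing = 0.1,
                         clip_norm = 5,
                         window_len = 100L, n_channels = 3L, seed = 1L) {
  architecture <- match.arg(architecture)
  task <- match.arg(task)
  lr_schedule <- match.arg(lr_schedule)
  head_pooling <- match.arg(head_pooling)
  k <- length(task_classes(task))
  if (!is.null(n_classes) && n_classes != k) {
    stop("task `", task, "` requires n_classes = ", k, ", got ", n_classes)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must be in [0, 1)")
  }
  if (epochs < 1L) stop("`epochs` must be >= 1")
  structure(list(architecture = architecture, task = task, n_classes = k,
                 recurrent_units = as.integer(recurrent_units),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 pool_size = as.integer(pool_size),
                 use_covariates = isTRUE(use_covariates),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 lr_schedule = lr_schedule, head_pooling = head_pooling,
                 weight_decay = weight_decay,
                 label_smoothing = label_smoothing,
                 clip_norm = clip_norm,
                 window_len = as.integer(window_len),
                 n_channels = as.integer(n_channels),
                 seed = as.integer(seed)),
            class = "wearsite_model_config")
}

#' Layer specification of a model configuration
#'
#' @param config a `wearsite_model_config`.
#' @return data.frame with one row per layer: `layer`, `type`,
#'   `output_dim`, `input_dim`, `learnable`. The dense layer's `input_dim`
#'   is the recurrent output width plus 3 when covariates are used.
#' @export
nn_layer_spec <- function(config) {
  H <- config$recurrent_units
  D <- config$dense_units
  nc <- if (config$use_covariates) 3L else 0L
  if (config$architecture == "lstm") {
    data.frame(
      layer = c("lstm", "dense_relu", "output_softmax"),
      type = c("recurrent", "dense", "dense"),
      input_dim = c(config$n_channels, H + nc, D),
      output_dim = c(H, D, config$n_classes),
      learnable = c(TRUE, TRUE, TRUE))
  } else {
    t_conv <- config$window_len - config$conv_kernel + 1L
    t_pool <- t_conv %/% config$pool_size
    data.frame(
      layer = c("conv1d_relu", "maxpool", "bilstm", "lstm", "lstm",
                "dense_relu", "output_softmax"),
      type = c("conv", "pool", "recurrent", "recurrent", "recurrent",
               "dense", "dense"),
      input_dim = c(config$n_channels, config$conv_filters,
                    config$conv_filters, 2L * H, H, H + nc, D),
      output_dim = c(config$conv_filters, config$conv_filters, 2L * H, H,
                     H, D, config$n_classes),
      learnable = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
      seq_len = c(t_conv, t_pool, t_pool, t_pool, t_pool, NA, NA))
  }
}

#' Build an untrained model
#'
#' @param config a `wearsite_model_config`.
#' @return a `wearsite_model` holding the configuration and layer spec.
#' @export
build_model <- function(config) {
  structure(list(config = config, layers = nn_layer_spec(config)),
            class = "wearsite_model")
}

#' @export
print.wearsite_model <- function(x, ...) {
  cat(sprintf("<wearsite_model> %s for task %s (%d classes)%s\n",
              x$config$architecture, x$config$task, x$config$n_classes,
              if (x$config$use_covariates) " + covariates" else ""))
  print(x$layers)
  invisible(x)
}

window_labels <- function(set, task) {
  cls <- task_classes(task)
  lab <- if (startsWith(task, "site")) as.character(set$site)
  else as.character(set$intensity)
  if (any(!lab %in% cls)) {
    stop("window set contains labels outside task `", task, "`: ",
         paste(setdiff(unique(lab), cls), collapse = ", "))
  }
  factor(lab, levels = cls)
}

cpp_cfg <- function(config) {
  list(arch = if (config$architecture == "lstm") 0L else 1L,
       window_len = config$window_len, n_channels = config$n_channels,
       n_classes = config$n_classes,
       recurrent_units = config$recurrent_units,
       dense_units = config$dense_units,
       conv_filters = config$conv_filters,
       conv_kernel = config$conv_kernel, pool_size = config$pool_size,
       n_covariates = if (config$use_covariates) 3L else 0L,
       dropout_rate = config$dropout_rate, epochs = config$epochs,
       batch_size = config$batch_size,
       learning_rate = config$learning_rate,
       lr_schedule = config$lr_schedule,
       head_pooling = config$head_pooling,
       weight_decay = config$weight_decay,
       label_smoothing = config$label_smoothing,
       clip_norm = config$clip_norm, seed = config$seed)
}

#' Train a model on labeled windows
#'
#' Minimizes multi-class cross-entropy with an adaptive-moment optimizer
#' for the configured number of epochs. Validation data are only ever
#' evaluated, never trained on. When covariates are used they are z-scored
#' with training-split statistics (stored on the returned model and
#' re-applied at prediction time). Training is deterministic given the
#' configuration seed.
#'
#' @param model a `wearsite_model` (see [build_model()]), or a
#'   `wearsite_model_config`.
#' @param train_set,val_set `wearsite_windows` with the task's labels
#'   present; the sets must be disjoint.
#' @return a `wearsite_trained`: `config`, `weights`, `history` (per-epoch
#'   train/validation loss and accuracy), `classes`, `cov_stats`.
#' @export
train_model <- function(model, train_set, val_set = NULL) {
  config <- if (inherits(model, "wearsite_model_config")) model
  else model$config
  if (n_windows(train_set) == 0L) stop("empty training set")
  if (dim(train_set$x)[2] != config$window_len) {
    stop("window length ", dim(train_set$x)[2],
         " does not match config window_len ", config$window_len)
  }
  y <- window_labels(train_set, config$task)
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class; at least two are required")
  }
  cov_stats <- NULL
  ctr <- matrix(0, 0, 0)
  cva <- matrix(0, 0, 0)
  if (config$use_covariates) {
    if (is.null(train_set$covariates)) {
      stop("`use_covariates = TRUE` but the training set has no covariates")
    }
    cov_stats <- list(mean = colMeans(train_set$covariates),
                      sd = pmax(apply(train_set$covariates, 2, sd), 1e-8))
    std <- function(m) sweep(sweep(m, 2, cov_stats$mean), 2, cov_stats$sd,
                             `/`)
    ctr <- std(train_set$covariates)
  }
  has_val <- !is.null(val_set) && n_windows(val_set) > 0L
  xv <- array(0, c(0L, config$window_len, config$n_channels))
  yv <- integer(0)
  if (has_val) {
    xv <- val_set$x
    yv <- as.integer(window_labels(val_set, config$task)) - 1L
    if (config$use_covariates) {
      if (is.null(val_set$covariates)) {
        stop("validation set has no covariates")
      }
      cva <- sweep(sweep(val_set$covariates, 2, cov_stats$mean), 2,
                   cov_stats$sd, `/`)
    }
  }
  fit <- cpp_fit(train_set$x, ctr, as.integer(y) - 1L, xv, cva, yv,
                 cpp_cfg(config))
  history <- data.frame(epoch = seq_len(config$epochs),
                        train_loss = fit$history$train_loss,
                        train_acc = fit$history$train_acc,
                        val_loss = fit$history$val_loss,
                        val_acc = fit$history$val_acc)
  structure(list(config = config, weights = fit$weights,
                 history = history, classes = task_classes(config$task),
                 cov_stats = cov_stats),
            class = "wearsite_trained")
}

#' @export
print.wearsite_trained <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(paste0("<wearsite_trained> %s/%s, %d epochs; final train acc",
                     " %.3f, val acc %.3f\n"),
              x$config$architecture, x$config$task, x$config$epochs,
              last$train_acc, last$val_acc))
  invisible(x)
}

#' Predict class probabilities and labels for windows
#'
#' @param model a `wearsite_trained`.
#' @param windows a `wearsite_windows` or an n x window_len x 3 array.
#' @param covariates optional covariate matrix when `windows` is a bare
#'   array; ignored otherwise (the set's covariates are used). Required iff
#'   the model was trained with covariates.
#' @return list with `prob` (rows sum to 1, columns named by class) and
#'   `labels` (factor; argmax, ties broken toward the lowest class index).
#' @export
predict_model <- function(model, windows, covariates = NULL) {
  config <- model$config
  if (inherits(windows, "wearsite_windows")) {
    covariates <- windows$covariates
    x <- windows$x
  } else {
    x <- windows
  }
  if (length(dim(x)) != 3L || dim(x)[2] != config$window_len ||
      dim(x)[3] != config$n_channels) {
    stop("window array shape does not match the model input (n x ",
         config$window_len, " x ", config$n_channels, ")")
  }
  cv <- matrix(0, 0, 0)
  if (config$use_covariates) {
    if (is.null(covariates)) stop("model requires covariates")
    cv <- sweep(sweep(covariates, 2, model$cov_stats$mean), 2,
                model$cov_stats$sd, `/`)
  }
  p <- cpp_predict(x, cv, model$weights, cpp_cfg(config))
  colnames(p) <- model$classes
  labels <- factor(model$classes[argmax_first(p)], levels = model$classes)
  list(prob = p, labels = labels)
}

#' Run the full experiment grid
#'
#' Trains and evaluates one model per grid cell: purpose (wear-site
#' detection, intensity classification, intensity with covariates) x group
#' (adult, children, combined) x wear-site scope (hip+wrist, or all three)
#' x architecture. For wear-site tasks the scope sets the class count (2 or
#' 3); for intensity tasks the scope restricts which sites' windows enter.
#' Each cell gets its own train/validation split of the filtered windows.
#'
#' @param window_set a `wearsite_windows` with covariates, both groups and
#'   all requested sites.
#' @param purposes subset of `c("site", "intensity", "intensity_cov")`.
#' @param groups subset of `c("adult", "child", "combined")`.
#' @param site_scopes subset of `c("two", "three")`.
#' @param architectures subset of `c("lstm", "bilstm")`.
#' @param train_fraction,split_scheme split settings (see
#'   [split_windows()]).
#' @param seed integer seed for splits and training.
#' @param epochs,... forwarded to [model_config()].
#' @return data.frame with one row per cell: grid coordinates, validation
#'   `accuracy` (fraction), and window counts; cells with no data carry
#'   `NA`.
#' @export
run_experiment_grid <- function(window_set,
                                purposes = c("site", "intensity",
                                             "intensity_cov"),
                                groups = c("adult", "child", "combined"),
                                site_scopes = c("two", "three"),
                                architectures = c("lstm", "bilstm"),
                                train_fraction = 0.9,
                                split_scheme = "window_random",
                                seed = 1L, epochs = 20L, ...) {
  grid <- expand.grid(purpose = purposes, group = groups,
                      site_scope = site_scopes,
                      architecture = architectures,
                      stringsAsFactors = FALSE)
  grid$accuracy <- NA_real_
  grid$n_train <- NA_integer_
  grid$n_val <- NA_integer_
  for (r in seq_len(nrow(grid))) {
    sites <- if (grid$site_scope[r] == "two") c("hip", "wrist") else .SITES
    keep <- as.character(window_set$site) %in% sites
    if (grid$group[r] != "combined") {
      keep <- keep & window_set$group == grid$group[r]
    }
    if (!any(keep)) next
    sub <- subset_windows(window_set, which(keep))
    task <- if (grid$purpose[r] == "site") {
      if (grid$site_scope[r] == "two") "site2" else "site3"
    } else "intensity4"
    sp <- split_windows(sub, train_fraction, seed = seed,
                        scheme = split_scheme)
    cfg <- model_config(architecture = grid$architecture[r], task = task,
                        use_covariates = grid$purpose[r] == "intensity_cov",
                        epochs = epochs, seed = seed, ...)
    fit <- train_model(cfg, sp$train, sp$validation)
    grid$accuracy[r] <- fit$history$val_acc[cfg$epochs]
    grid$n_train[r] <- n_windows(sp$train)
    grid$n_val[r] <- n_windows(sp$validation)
  }
  grid
}
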