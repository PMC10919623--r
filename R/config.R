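# Pipeline configuration: nested defaults, validation, YAML round-trip,
# and a content hash stamped on every artifact.

#' Default pipeline configuration
#'
#' Nested list covering every stage: seeds, generator constants,
#' ground-truth settings, cut-points, windowing and the model grid. Any
#' subset of keys can be overridden from a YAML file; unknown keys are
#' rejected.
#'
#' @return a nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = "wearsite_out",
    log_level = "info",
    cohort = list(n_adult = 2L, n_child = 2L,
                  sites = c("hip", "wrist", "chest")),
    generator = generator_config(),
    groundtruth = unclass(gt_config()),
    counts = list(epoch_s = 60L, trim_s = 60,
                  emulation = counts_config()),
    windowing = list(window_len = 100L, stride = 100L, trim_s = 60,
                     train_fraction = 0.9, scheme = "window_random",
                     max_windows = NA_integer_),
    models = list(purposes = c("site", "intensity", "intensity_cov"),
                  groups = c("adult", "child", "combined"),
                  site_scopes = c("two", "three"),
                  architectures = c("lstm", "bilstm"),
                  epochs = 20L, recurrent_units = 64L, dense_units = 64L,
                  batch_size = 32L, learning_rate = 1.5e-3,
                  dropout_rate = 0.2)
  )
}

# recursively overlay user values onto defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
                         !is.data.frame(defaults[[k]])) {
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' @param path YAML file with overrides, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
load_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname load_pipeline_config
#' @param config configuration list to validate.
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(is.numeric(config$seed),
            config$windowing$train_fraction > 0,
            config$windowing$train_fraction < 1,
            config$models$epochs >= 1)
  cuts <- config$groundtruth$met_cutoffs
  if (!(cuts[1] > 0 && all(diff(cuts) > 0))) {
    stop("groundtruth$met_cutoffs must be positive and strictly increasing")
  }
  invisible(config)
}

#' Content hash of a configuration
#'
#' MD5 of the canonical JSON serialization; stamped into manifests and
#' report filenames so every artifact names the configuration that
#' produced it.
#'
#' @param config configuration list.
#' @return 32-character hash string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = 10,
                       dataframe = "columns", force = TRUE)
  unname(tools::md5sum(tf))
}
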