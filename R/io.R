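# CSV/JSON artifact input and output.

#' Write / read a triaxial recording as CSV
#'
#' Recordings are stored as plain CSV with header `t,x,y,z` (seconds and
#' g). Reading validates the column layout and strictly increasing
#' timestamps and reports the first offending line on failure.
#'
#' @param recording a `wearsite_recording`.
#' @param path file path.
#' @param digits numeric precision retained on write.
#' @return `write_recording()`: the path, invisibly. `read_recording()`:
#'   a `wearsite_recording` (bout annotations are carried separately in
#'   the session manifest).
#' @export
write_recording <- function(recording, path, digits = 6) {
  dt <- data.table::data.table(
    t = round(recording$t, digits), x = round(recording$x, digits),
    y = round(recording$y, digits), z = round(recording$z, digits))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_recording
#' @param site wear-site label to attach on read.
#' @param sample_rate sampling rate of the stored stream, Hz.
#' @export
read_recording <- function(path, site = "hip", sample_rate = 100) {
  dt <- data.table::fread(path)
  if (!identical(names(dt), c("t", "x", "y", "z"))) {
    stop("expected CSV header `t,x,y,z` in ", path, ", got: ",
         paste(names(dt), collapse = ","))
  }
  if (nrow(dt) == 0L) {
    warning("recording file ", path, " contains a header only")
  } else {
    bad <- which(!vapply(dt, is.numeric, TRUE))
    if (length(bad)) {
      stop("non-numeric values in column(s) ",
           paste(names(dt)[bad], collapse = ", "), " of ", path)
    }
    dd <- diff(dt$t)
    if (any(dd <= 0)) {
      stop("timestamps not strictly increasing in ", path, " at line ",
           which(dd <= 0)[1] + 2L)  # +1 header, +1 next row
    }
  }
  new_recording(site, sample_rate, dt$t, as.matrix(dt[, c("x", "y", "z")]),
                data.frame(bout_index = integer(), start_s = numeric(),
                           end_s = numeric()))
}

#' Write / read a calorimetry series as CSV (`t,vo2`)
#'
#' @param series calorimetry list (`t`, `vo2`, `interval`, `rest_start`,
#'   `rest_end`).
#' @param path file path.
#' @export
write_calorimetry <- function(series, path) {
  data.table::fwrite(data.table::data.table(t = series$t,
                                            vo2 = series$vo2), path)
  invisible(path)
}

#' @rdname write_calorimetry
#' @param interval,rest_start,rest_end metadata not stored in the CSV.
#' @export
read_calorimetry <- function(path, interval = NULL, rest_start = 0,
                             rest_end = 600) {
  dt <- data.table::fread(path)
  if (!identical(names(dt), c("t", "vo2"))) {
    stop("expected CSV header `t,vo2` in ", path)
  }
  if (any(dt$vo2 < 0, na.rm = TRUE)) stop("negative VO2 values in ", path)
  if (is.null(interval)) {
    interval <- if (nrow(dt) > 1) stats::median(diff(dt$t)) else NA_real_
  }
  list(interval = interval, t = dt$t, vo2 = dt$vo2,
       rest_start = rest_start, rest_end = rest_end)
}

#' Write / read participant profiles as CSV
#' @param profiles profile data.frame (see [sample_participants()]).
#' @param path file path.
#' @export
write_profiles <- function(profiles, path) {
  data.table::fwrite(profiles, path)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  need <- c("id", "group", "sex", "age", "height", "weight", "resting_vo2")
  dt <- as.data.frame(data.table::fread(path))
  missing <- setdiff(need, names(dt))
  if (length(missing)) {
    stop("profile file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(dt$age <= 0 | dt$height <= 0 | dt$weight <= 0 |
          dt$resting_vo2 <= 0)) {
    stop("non-positive anthropometrics in ", path)
  }
  dt
}

#' Write a simulated session to disk
#'
#' One CSV per wear-site recording, one calorimetry CSV, and a JSON
#' manifest linking the files with bout annotations, latent draws, the
#' seed and the config hash.
#'
#' @param session a `wearsite_session`.
#' @param dir output directory.
#' @param config_hash hash string recorded in the manifest.
#' @param seed seed recorded in the manifest.
#' @return path of the manifest, invisibly.
#' @export
write_session <- function(session, dir, config_hash = NA_character_,
                          seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- session$profile$id
  files <- list()
  for (s in names(session$recordings)) {
    f <- file.path(dir, sprintf("%s_%s.csv", id, s))
    write_recording(session$recordings[[s]], f)
    files[[s]] <- basename(f)
  }
  calf <- file.path(dir, sprintf("%s_calorimetry.csv", id))
  write_calorimetry(session$calorimetry, calf)
  manifest <- list(participant = id, group = session$profile$group,
                   recordings = files, calorimetry = basename(calf),
                   annotations = session$annotations,
                   latent = session$latent, seed = seed,
                   config_hash = config_hash)
  mf <- file.path(dir, sprintf("%s_manifest.json", id))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(mf)
}

#' Read a session back from its manifest
#'
#' @param manifest_path path to a `*_manifest.json` written by
#'   [write_session()].
#' @param profiles profile data.frame containing the participant.
#' @param sample_rate sampling rate of the stored recordings, Hz.
#' @return a `wearsite_session` (latent draws restored from the manifest).
#' @export
read_session <- function(manifest_path, profiles, sample_rate = 100) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  ann <- as.data.frame(man$annotations)
  profile <- profiles[profiles$id == man$participant, ]
  if (nrow(profile) != 1L) {
    stop("profile for participant ", man$participant, " not found")
  }
  recordings <- list()
  for (s in names(man$recordings)) {
    rec <- read_recording(file.path(dir, man$recordings[[s]]), site = s,
                          sample_rate = sample_rate)
    rec$bout_annotations <- ann
    recordings[[s]] <- rec
  }
  cal <- read_calorimetry(file.path(dir, man$calorimetry),
                          rest_start = 0,
                          rest_end = min(ann$start_s))
  structure(list(profile = profile, protocol = NULL,
                 recordings = recordings, calorimetry = cal,
                 annotations = ann,
                 latent = as.data.frame(man$latent)),
            class = "wearsite_session")
}
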