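#' Thermal condition vocabulary
#'
#' Three constant floor temperatures plus eight ramp conditions
#' (cool/warm x fast/slow x down/up).
#'
#' @return character vector of the 11 valid condition labels.
#' @export
thermal_conditions <- function() {
  c("15C", "25C", "35C",
    "CFD", "CFU", "CSD", "CSU",
    "WFU", "WFD", "WSU", "WSD")
}

#' Construct and validate an acquisition
#'
#' One imaging session: an N x T matrix of ROI cerebral-blood-volume signals
#' with metadata, and an optional tissue-motion reference trace used for
#' artifact scrubbing.
#'
#' @param signals numeric N x T matrix, rows in `roi$names` order.
#' @param acquisition_id,animal_id character identifiers.
#' @param condition one of [thermal_conditions()].
#' @param fs sampling rate in Hz (> 0).
#' @param roi an `roi_set`.
#' @param motion_ref optional nonnegative numeric vector of length T.
#' @return object of class `acquisition`.
#' @export
acquisition <- function(signals, acquisition_id, animal_id, condition, fs,
                        roi = default_roi_set(), motion_ref = NULL) {
  if (!is.matrix(signals) || nrow(signals) != n_roi(roi)) {
    stop("`signals` must be an N x T matrix with N = ", n_roi(roi))
  }
  if (ncol(signals) < 1) stop("acquisition must contain at least one frame")
  if (anyNA(signals)) stop("`signals` contains missing values")
  if (!condition %in% thermal_conditions()) {
    stop("unknown condition label '", condition, "'")
  }
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be a positive sampling rate")
  if (!is.null(motion_ref)) {
    if (length(motion_ref) != ncol(signals)) {
      stop("`motion_ref` length must equal the number of frames")
    }
    if (anyNA(motion_ref) || any(motion_ref < 0)) {
      stop("`motion_ref` must be nonnegative with no missing values")
    }
  }
  rownames(signals) <- roi$names
  structure(list(signals = signals, acquisition_id = acquisition_id,
                 animal_id = animal_id, condition = condition, fs = fs,
                 roi = roi, motion_ref = motion_ref),
            class = "acquisition")
}

#' @export
#' @method print acquisition
print.acquisition <- function(x, ...) {
  cat("<acquisition> ", x$acquisition_id, ": animal ", x$animal_id,
      ", condition ", x$condition, ", ", nrow(x$signals), " ROIs x ",
      ncol(x$signals), " frames @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

manifest_columns <- c("acquisition_id", "animal_id", "condition",
                      "fs_hz", "path")

#' Read a cohort manifest
#'
#' Delimited text with columns `acquisition_id`, `animal_id`, `condition`,
#' `fs_hz`, `path` (one row per acquisition). Condition labels are validated
#' against [thermal_conditions()] and acquisition ids must be unique.
#'
#' @param path manifest file.
#' @return data.frame of acquisition descriptors.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_columns, names(m))
  if (length(missing)) {
    stop("manifest is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!m$condition %in% thermal_conditions())
  if (length(bad)) {
    stop("unknown condition label '", m$condition[bad[1]],
         "' in manifest row ", bad[1])
  }
  dup <- m$acquisition_id[duplicated(m$acquisition_id)]
  if (length(dup)) {
    stop("duplicate acquisition_id in manifest: ",
         paste(unique(dup), collapse = ", "))
  }
  m
}

#' Write a cohort manifest
#' @param manifest data.frame with the manifest columns.
#' @param path destination file.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, manifest_columns, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one acquisition from a delimited signal file
#'
#' One row per frame, one column per ROI (order-insensitive; reordered to
#' `roi$names`), optional `motion_ref` column, header mandatory.
#'
#' @param path signal file (comma-separated).
#' @param acquisition_id,animal_id,condition,fs session metadata (typically
#'   from the manifest row).
#' @param roi an `roi_set`.
#' @return an `acquisition`.
#' @export
read_acquisition <- function(path, acquisition_id, animal_id, condition, fs,
                             roi = default_roi_set()) {
  if (!file.exists(path)) stop("acquisition file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("acquisition file is empty: ", path)
  missing <- setdiff(roi$names, names(d))
  if (length(missing)) {
    stop("acquisition file ", path, " is missing ROI columns: ",
         paste(missing, collapse = ", "))
  }
  sig <- t(as.matrix(d[, roi$names, drop = FALSE]))
  if (anyNA(sig)) stop("acquisition file ", path, " contains NaN/NA cells")
  mref <- if ("motion_ref" %in% names(d)) d$motion_ref else NULL
  acquisition(sig, acquisition_id, animal_id, condition, fs,
              roi = roi, motion_ref = mref)
}

#' Write an acquisition's signals to a delimited file
#' @param acq an `acquisition`.
#' @param path destination (comma-separated; frames as rows).
#' @export
write_acquisition <- function(acq, path) {
  d <- as.data.frame(t(acq$signals))
  if (!is.null(acq$motion_ref)) d$motion_ref <- acq$motion_ref
  write_table(d, path)
}

#' Write a numeric table or matrix losslessly
#'
#' Values are formatted with 17 significant digits so that a write-then-read
#' round trip reproduces finite doubles to better than 1e-12 relative error.
#'
#' @param x data.frame or matrix.
#' @param path destination file.
#' @param rownames write row names as a leading column?
#' @export
write_table <- function(x, path, rownames = FALSE) {
  d <- as.data.frame(x)
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(v) sprintf("%.17g", v))
  utils::write.csv(d, path, row.names = rownames, quote = FALSE)
  invisible(path)
}

#' Write a ROI-labeled square matrix
#' @param m matrix with ROI row/col names.
#' @param path destination file.
#' @export
write_matrix <- function(m, path) {
  write_table(as.data.frame(m), path, rownames = TRUE)
}

#' Read back a ROI-labeled square matrix written by [write_matrix()]
#' @param path file produced by [write_matrix()].
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

#' Write a JSON provenance sidecar next to an output file
#'
#' @param path the data file the sidecar describes; the sidecar is written
#'   to `paste0(path, ".json")`.
#' @param meta named list (seed, configuration hash, package version, ...).
#' @export
write_sidecar <- function(path, meta) {
  meta$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  meta$package_version <- as.character(utils::packageVersion("thermofc"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paste0(path, ".json"))
}

#' Stable hash of a configuration object
#' @param x any serializable R object.
#' @return md5 hex string.
#' @export
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Write / read a cleaned series
#'
#' The signal matrix goes to `<path>` (frames as rows, ROI columns) and the
#' bookkeeping (epochs, status, source id, sampling rate) to a JSON sidecar
#' `<path>.meta.json`, so a scrubbed cohort can be persisted and reloaded
#' without recomputation.
#'
#' @param clean a `clean_series`.
#' @param path destination file (CSV).
#' @export
write_clean_series <- function(clean, path) {
  meta <- list(source_id = clean$source_id, fs = clean$fs,
               status = clean$status, n_raw = clean$n_raw,
               n_kept = clean$n_kept,
               epoch_start = clean$epochs$start,
               epoch_length = clean$epochs$length)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (clean$status == "ok") {
    write_table(as.data.frame(t(clean$signals)), path)
  }
  invisible(path)
}

#' @rdname write_clean_series
#' @param roi an `roi_set` (column order of the stored file).
#' @return `read_clean_series`: a `clean_series`.
#' @export
read_clean_series <- function(path, roi = default_roi_set()) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  epochs <- data.frame(start = as.integer(meta$epoch_start %||% integer(0)),
                       length = as.integer(meta$epoch_length %||%
                                             integer(0)))
  sig <- NULL
  if (identical(meta$status, "ok")) {
    d <- utils::read.csv(path)
    sig <- t(as.matrix(d[, roi$names, drop = FALSE]))
    rownames(sig) <- roi$names
  }
  structure(list(signals = sig, epochs = epochs,
                 source_id = meta$source_id, fs = meta$fs,
                 status = meta$status, n_raw = meta$n_raw,
                 n_kept = meta$n_kept),
            class = "clean_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
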