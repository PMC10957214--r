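#' Scrubbing / signal-conditioning configuration
#'
#' Parameters of the cleaning chain applied to each acquisition: artifact
#' thresholds (robust z-scores on the tissue-motion reference and on the mean
#' absolute ROI deviation), minimum epoch length, low-pass filter, polynomial
#' detrending order, optional moving-average smoothing, normalization and
#' global-component removal.
#'
#' @param motion_z_threshold robust z cutoff on `motion_ref` (default 3).
#' @param doppler_z_threshold robust z cutoff on mean absolute ROI deviation
#'   (default 3).
#' @param min_epoch_len minimum run of artifact-free frames kept (default 50).
#' @param lowpass_cutoff_hz low-pass cutoff in Hz (default 0.1).
#' @param filter_order Butterworth order (default 4; applied forward-backward
#'   so the effective attenuation is doubled).
#' @param detrend_order polynomial detrending order (default 3).
#' @param smoothing_window centered moving-average window in frames; 0
#'   disables (default 0).
#' @param normalize `"zscore"` (per-ROI, default) or `"none"`.
#' @param remove_global subtract the leading SVD component? (default TRUE).
#' @param filter_per_epoch filter each epoch separately instead of the
#'   concatenated series (default FALSE: filtering follows concatenation).
#' @return object of class `scrub_config`.
#' @export
scrub_config <- function(motion_z_threshold = 3, doppler_z_threshold = 3,
                         min_epoch_len = 50, lowpass_cutoff_hz = 0.1,
                         filter_order = 4, detrend_order = 3,
                         smoothing_window = 0,
                         normalize = c("zscore", "none"),
                         remove_global = TRUE, filter_per_epoch = FALSE) {
  normalize <- match.arg(normalize)
  stopifnot(motion_z_threshold > 0, doppler_z_threshold > 0,
            min_epoch_len >= 1, lowpass_cutoff_hz > 0, filter_order >= 1,
            detrend_order >= 0, smoothing_window >= 0)
  structure(list(motion_z_threshold = motion_z_threshold,
                 doppler_z_threshold = doppler_z_threshold,
                 min_epoch_len = min_epoch_len,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 filter_order = filter_order, detrend_order = detrend_order,
                 smoothing_window = smoothing_window, normalize = normalize,
                 remove_global = remove_global,
                 filter_per_epoch = filter_per_epoch),
            class = "scrub_config")
}

robust_z <- function(x) {
  med <- stats::median(x)
  s <- stats::mad(x)  # 1.4826 * MAD, consistent for the normal
  if (s == 0) return(rep(0, length(x)))
  (x - med) / s
}

#' Flag motion-artifact frames
#'
#' A frame is discarded when the robust z-score (median/MAD) of the
#' tissue-motion reference exceeds `motion_z_threshold`, or when the robust
#' z-score of the mean absolute ROI deviation from the per-ROI median exceeds
#' `doppler_z_threshold`. With no `motion_ref` only the Doppler criterion
#' applies.
#'
#' @param acq an `acquisition`.
#' @param cfg a `scrub_config`.
#' @return logical keep-mask of length T (TRUE = frame retained).
#' @export
detect_artifact_frames <- function(acq, cfg = scrub_config()) {
  sig <- acq$signals
  tt <- ncol(sig)
  dev <- colMeans(abs(sig - apply(sig, 1, stats::median)))
  if (all(dev == 0)) {
    warning("constant signals in acquisition ", acq$acquisition_id,
            "; all frames kept")
    return(rep(TRUE, tt))
  }
  bad <- robust_z(dev) > cfg$doppler_z_threshold
  if (!is.null(acq$motion_ref)) {
    bad <- bad | robust_z(acq$motion_ref) > cfg$motion_z_threshold
  }
  !bad
}

#' Extract maximal kept epochs of at least a minimum length
#'
#' Runs of consecutive `TRUE` frames shorter than `min_epoch_len` are dropped
#' entirely; survivors are returned in temporal order as 0-based half-open
#' intervals.
#'
#' @param keep_mask logical vector.
#' @param min_epoch_len minimum run length.
#' @return data.frame with columns `start` (0-based) and `length`.
#' @export
extract_epochs <- function(keep_mask, min_epoch_len = 50) {
  stopifnot(length(keep_mask) >= 1)
  r <- rle(as.logical(keep_mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  keep <- r$values & r$lengths >= min_epoch_len
  data.frame(start = starts[keep], length = r$lengths[keep])
}

# Zero-phase Butterworth low-pass with endpoint-anchored baseline removal
# and odd-reflection edge padding: a constant passes through exactly and the
# startup transient of the narrow-band filter is pushed outside the data.
filtfilt_reflect <- function(v, bf, w_norm) {
  n <- length(v)
  base <- v[1] + (v[n] - v[1]) * (seq_len(n) - 1) / max(n - 1, 1)
  r <- v - base
  pad <- min(n - 1L, as.integer(ceiling(3 / w_norm)) + 6L * length(bf$b))
  pre <- 2 * r[1] - r[seq(pad + 1L, 2L)]
  post <- 2 * r[n] - r[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(pre, r, post))
  y[(pad + 1L):(pad + n)] + base
}

#' Zero-phase low-pass filter of an ROI signal matrix
#'
#' Butterworth design applied forward-backward (zero phase, unit DC gain).
#'
#' @param signals N x T matrix.
#' @param fs sampling rate in Hz.
#' @param cutoff_hz low-pass cutoff (< fs/2).
#' @param order filter order (default 4).
#' @return filtered N x T matrix.
#' @export
lowpass_filter <- function(signals, fs, cutoff_hz = 0.1, order = 4) {
  if (cutoff_hz >= fs / 2) {
    stop("cutoff ", cutoff_hz, " Hz must be below the Nyquist frequency ",
         fs / 2, " Hz")
  }
  if (ncol(signals) <= 3 * order) {
    stop("need more than ", 3 * order, " frames to filter")
  }
  w <- cutoff_hz / (fs / 2)
  bf <- signal::butter(order, w, type = "low")
  out <- t(apply(signals, 1, filtfilt_reflect, bf = bf, w_norm = w))
  dimnames(out) <- dimnames(signals)
  out
}

#' Remove a per-ROI polynomial trend
#'
#' Least-squares fit of a degree-`order` polynomial in time to each row,
#' subtracted; residuals are orthogonal to the polynomial basis.
#'
#' @param signals N x T matrix.
#' @param order polynomial order (default 3).
#' @return detrended N x T matrix.
#' @export
detrend_polynomial <- function(signals, order = 3) {
  tt <- ncol(signals)
  stopifnot(tt >= order + 2)
  u <- seq(-1, 1, length.out = tt)
  basis <- stats::poly(u, degree = order, raw = FALSE)
  basis <- cbind(1, basis)
  fit <- stats::lm.fit(basis, t(signals))
  out <- t(fit$residuals)
  dimnames(out) <- dimnames(signals)
  out
}

#' Remove the shared global component
#'
#' Subtracts the best rank-1 approximation (leading singular triplet) of the
#' row-centered N x T matrix; this suppresses brain-wide covariation before
#' connectivity analysis.
#'
#' @param signals N x T matrix (T >= N).
#' @return N x T matrix, row-centered with the leading component removed.
#' @export
remove_global_component <- function(signals) {
  stopifnot(ncol(signals) >= nrow(signals))
  xc <- signals - rowMeans(signals)
  sv <- svd(xc, nu = 1, nv = 1)
  out <- xc - sv$d[1] * sv$u %*% t(sv$v)
  dimnames(out) <- dimnames(signals)
  out
}

moving_average <- function(v, window) {
  if (window <= 1) return(v)
  half <- (window - 1) / 2
  lo <- pmax(seq_along(v) - floor(half), 1L)
  hi <- pmin(seq_along(v) + ceiling(half), length(v))
  cs <- cumsum(c(0, v))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

zscore_rows <- function(x) {
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  if (any(sd == 0)) {
    stop("zero-variance ROI: ",
         paste(rownames(x)[sd == 0], collapse = ", "))
  }
  (x - mu) / sd
}

#' Run the full cleaning chain on one acquisition
#'
#' Artifact detection, epoch extraction and concatenation, zero-phase
#' low-pass filtering, polynomial detrending, optional smoothing, per-ROI
#' normalization and global-component removal, in that order. Acquisitions
#' whose concatenated retained length falls below `min_epoch_len` are marked
#' `status = "discarded"` rather than silently dropped.
#'
#' @param acq an `acquisition`.
#' @param cfg a `scrub_config`.
#' @return object of class `clean_series`: `signals` (N x T or NULL),
#'   `epochs` (0-based half-open, original frame indexing), `source_id`,
#'   `fs`, `status` ("ok"/"discarded"), `n_raw`, `n_kept`.
#' @export
clean_acquisition <- function(acq, cfg = scrub_config()) {
  keep <- detect_artifact_frames(acq, cfg)
  epochs <- extract_epochs(keep, cfg$min_epoch_len)
  n_kept <- sum(epochs$length)
  if (n_kept < cfg$min_epoch_len) {
    return(structure(list(signals = NULL, epochs = epochs,
                          source_id = acq$acquisition_id, fs = acq$fs,
                          status = "discarded", n_raw = ncol(acq$signals),
                          n_kept = n_kept),
                     class = "clean_series"))
  }
  idx <- unlist(lapply(seq_len(nrow(epochs)), function(k) {
    epochs$start[k] + seq_len(epochs$length[k])  # 1-based into signals
  }))
  sig <- acq$signals[, idx, drop = FALSE]

  filt <- function(x) lowpass_filter(x, acq$fs, cfg$lowpass_cutoff_hz,
                                     cfg$filter_order)
  if (cfg$filter_per_epoch) {
    off <- 0L
    for (k in seq_len(nrow(epochs))) {
      cols <- off + seq_len(epochs$length[k])
      sig[, cols] <- filt(sig[, cols, drop = FALSE])
      off <- off + epochs$length[k]
    }
  } else {
    sig <- filt(sig)
  }
  if (cfg$detrend_order > 0) sig <- detrend_polynomial(sig, cfg$detrend_order)
  if (cfg$smoothing_window > 1) {
    sig <- t(apply(sig, 1, moving_average, window = cfg$smoothing_window))
    rownames(sig) <- acq$roi$names
  }
  if (cfg$normalize == "zscore") sig <- zscore_rows(sig)
  if (cfg$remove_global) sig <- remove_global_component(sig)
  structure(list(signals = sig, epochs = epochs,
                 source_id = acq$acquisition_id, fs = acq$fs, status = "ok",
                 n_raw = ncol(acq$signals), n_kept = n_kept),
            class = "clean_series")
}

#' @export
#' @method print clean_series
print.clean_series <- function(x, ...) {
  cat("<clean_series> ", x$source_id, ": status ", x$status, ", ",
      x$n_kept, "/", x$n_raw, " frames in ", nrow(x$epochs),
      " epoch(s)\n", sep = "")
  invisible(x)
}

#' Scrub an entire cohort
#'
#' @param acqs list of `acquisition` objects.
#' @param cfg a `scrub_config`.
#' @return list with `clean` (list of `clean_series`) and `report`
#'   (data.frame: per-acquisition frames kept/discarded and status).
#' @export
preprocess_cohort <- function(acqs, cfg = scrub_config()) {
  clean <- lapply(acqs, clean_acquisition, cfg = cfg)
  report <- do.call(rbind, lapply(clean, function(cs) {
    data.frame(acquisition_id = cs$source_id, n_raw = cs$n_raw,
               n_kept = cs$n_kept, n_epochs = nrow(cs$epochs),
               status = cs$status)
  }))
  list(clean = clean, report = report)
}
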