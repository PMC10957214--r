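#' ROI set: ordered region labels with network group membership
#'
#' An `roi_set` fixes the storage order of regions of interest and assigns
#' each region to one of three functional groups (somatomotor, cingulate,
#' hypothalamus). All matrices and vectorized edge/cofluctuation layouts in
#' the package use this order.
#'
#' @param names character vector of unique ROI labels, in canonical order.
#' @param groups named character vector mapping every ROI name to one of
#'   `"somatomotor"`, `"cingulate"`, `"hypothalamus"`.
#' @return An object of class `roi_set` with elements `names` and `groups`.
#' @export
roi_set <- function(names, groups) {
  if (anyDuplicated(names)) stop("ROI names must be unique")
  if (!setequal(base::names(groups), names)) {
    stop("`groups` must name every ROI exactly once")
  }
  ok <- c("somatomotor", "cingulate", "hypothalamus")
  if (!all(groups %in% ok)) {
    stop("ROI groups must be one of: ", paste(ok, collapse = ", "))
  }
  structure(list(names = names, groups = groups[names]), class = "roi_set")
}

#' Default 10-ROI imaging-plane layout
#'
#' Hindlimb primary somatosensory, primary/secondary motor, cingulate and
#' hypothalamic regions of the bregma -0.34 mm coronal plane, left then right
#' hemisphere, in the canonical numbering 1-10 used throughout.
#'
#' @return An `roi_set` of size 10.
#' @export
default_roi_set <- function() {
  nm <- c("S1HLL", "M1L", "M2L", "CgL", "CgR", "M2R", "M1R", "S1HLR",
          "HyThL", "HyThR")
  gr <- c(S1HLL = "somatomotor", M1L = "somatomotor", M2L = "somatomotor",
          CgL = "cingulate", CgR = "cingulate",
          M2R = "somatomotor", M1R = "somatomotor", S1HLR = "somatomotor",
          HyThL = "hypothalamus", HyThR = "hypothalamus")
  roi_set(nm, gr)
}

#' @export
#' @method print roi_set
print.roi_set <- function(x, ...) {
  cat("<roi_set> ", length(x$names), " ROIs: ",
      paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

n_roi <- function(roi) length(roi$names)

#' Indices of ROIs in a given group
#' @param roi an `roi_set`.
#' @param group one of `"somatomotor"`, `"cingulate"`, `"hypothalamus"`.
#' @return integer indices into `roi$names`.
#' @export
roi_group_idx <- function(roi, group) {
  which(roi$groups == group)
}
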