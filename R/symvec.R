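#' Length of the vectorized form of an n x n symmetric matrix
#'
#' @param n matrix dimension.
#' @param with_diagonal include the diagonal? `n(n+1)/2` if `TRUE`,
#'   `n(n-1)/2` if `FALSE`.
#' @return integer length.
#' @export
sym_vector_length <- function(n, with_diagonal = TRUE) {
  if (with_diagonal) n * (n + 1L) / 2L else n * (n - 1L) / 2L
}

#' Index pairs (i, j) of the vectorized upper triangle
#'
#' Row-major upper-triangle ordering, fixed package-wide: (1,1),(1,2),...,
#' (1,n),(2,2),... with the diagonal, or (1,2),...,(1,n),(2,3),... without.
#'
#' @param n matrix dimension.
#' @param with_diagonal include diagonal pairs?
#' @return two-column integer matrix with columns `i`, `j` (i <= j).
#' @export
sym_pairs <- function(n, with_diagonal = TRUE) {
  j <- rep(seq_len(n), each = n)
  i <- rep(seq_len(n), times = n)
  keep <- if (with_diagonal) i <= j else i < j
  m <- cbind(i = i[keep], j = j[keep])
  # order by i then j (row-major upper triangle)
  m[order(m[, "i"], m[, "j"]), , drop = FALSE]
}

#' Vectorize a symmetric matrix
#'
#' Fixed row-major upper-triangle ordering; inverse of
#' [devectorize_symmetric()].
#'
#' @param m symmetric numeric matrix (asymmetry beyond `tol` is an error).
#' @param with_diagonal include the diagonal entries?
#' @param tol symmetry tolerance.
#' @return a `sym_vector`: list with `values`, `n`, `with_diagonal`.
#' @export
vectorize_symmetric <- function(m, with_diagonal = TRUE, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("`m` must be a square matrix")
  if (max(abs(m - t(m))) > tol) {
    stop("matrix is not symmetric within tolerance ", format(tol))
  }
  n <- nrow(m)
  p <- sym_pairs(n, with_diagonal)
  v <- m[cbind(p[, "i"], p[, "j"])]
  if (!is.null(rownames(m))) {
    names(v) <- paste(rownames(m)[p[, "i"]], rownames(m)[p[, "j"]], sep = "~")
  }
  structure(list(values = v, n = n, with_diagonal = with_diagonal),
            class = "sym_vector")
}

#' Rebuild a symmetric matrix from its vectorized form
#'
#' @param v a `sym_vector`, or a bare numeric vector (then `n` and
#'   `with_diagonal` must be given).
#' @param n matrix dimension (ignored for `sym_vector` input).
#' @param with_diagonal whether `v` includes the diagonal; entries of an
#'   absent diagonal are set to `diag_value`.
#' @param diag_value diagonal fill when `with_diagonal = FALSE` (default 1,
#'   the correlation-matrix convention).
#' @return symmetric `n` x `n` matrix.
#' @export
devectorize_symmetric <- function(v, n = NULL, with_diagonal = TRUE,
                                  diag_value = 1) {
  if (inherits(v, "sym_vector")) {
    n <- v$n
    with_diagonal <- v$with_diagonal
    v <- v$values
  }
  if (is.null(n)) stop("`n` required for bare numeric input")
  if (length(v) != sym_vector_length(n, with_diagonal)) {
    stop("vector length ", length(v), " inconsistent with n = ", n)
  }
  m <- matrix(0, n, n)
  p <- sym_pairs(n, with_diagonal)
  m[cbind(p[, "i"], p[, "j"])] <- v
  m[cbind(p[, "j"], p[, "i"])] <- v
  if (!with_diagonal) diag(m) <- diag_value
  m
}

#' Edge labels for the vectorized layout
#' @param roi an `roi_set`.
#' @param with_diagonal include self-pairs?
#' @return character vector like `"S1HLL~M1L"`, in vectorization order.
#' @export
sym_pair_labels <- function(roi, with_diagonal = TRUE) {
  p <- sym_pairs(n_roi(roi), with_diagonal)
  paste(roi$names[p[, "i"]], roi$names[p[, "j"]], sep = "~")
}
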