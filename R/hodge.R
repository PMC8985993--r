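# Oriented boundary matrices, combinatorial (Hodge) Laplacians, spectra and
# Betti numbers.  Orientation is induced by ascending vertex index within
# each simplex; spectra are orientation-invariant, so this choice is purely
# internal.

#' Relative tolerance below which an eigenvalue counts as zero
#'
#' An eigenvalue lambda is treated as zero when
#' `lambda < tol * max(1, lambda_max)`.  Double-precision symmetric
#' eigensolvers on these small integer matrices are accurate to far better
#' than 1e-8.
#' @export
ZERO_EIGENVALUE_TOL <- 1e-8

.zero_threshold <- function(values, tol = ZERO_EIGENVALUE_TOL) {
  m <- if (length(values)) max(abs(values)) else 0
  tol * max(1, m)
}

#' Signed boundary matrix of a Dowker complex
#'
#' Entry (i, j) is the incidence of the i-th (k-1)-simplex in the j-th
#' k-simplex: `(-1)^(m-1)` when the face is obtained by deleting the m-th
#' vertex (ascending-index orientation), 0 otherwise.  Each column has
#' exactly k+1 nonzeros with alternating signs, and `B_k %*% B_{k+1} = 0`.
#'
#' @param K a `dowker_complex`.
#' @param k dimension, `1 <= k <= max_dim`.
#' @return numeric matrix, (# (k-1)-simplices) x (# k-simplices).
#' @export
boundary_matrix <- function(K, k) {
  stopifnot(inherits(K, "dowker_complex"))
  if (k < 1L || k > K$max_dim) {
    stop("k must be between 1 and max_dim = ", K$max_dim)
  }
  faces <- K$simplices[[k]]
  simp <- K$simplices[[k + 1L]]
  B <- matrix(0, nrow(faces), nrow(simp))
  if (nrow(simp) == 0L || nrow(faces) == 0L) return(B)
  face_key <- apply(faces, 1L, paste, collapse = ",")
  face_index <- stats::setNames(seq_along(face_key), face_key)
  for (j in seq_len(nrow(simp))) {
    v <- simp[j, ]
    for (m in seq_len(k + 1L)) {
      key <- paste(v[-m], collapse = ",")
      i <- unname(face_index[key])
      if (is.na(i)) {
        stop("complex not face-closed: missing face {", key,
             "} of simplex {", paste(v, collapse = ","), "}")
      }
      B[i, j] <- (-1)^(m - 1L)
    }
  }
  B
}

#' Combinatorial (Hodge) Laplacian of a Dowker complex
#'
#' `L_k = t(B_k) %*% B_k + B_{k+1} %*% t(B_{k+1})`; for k = 0 only the
#' upper term exists, so `L_0 = B_1 %*% t(B_1)` is the graph Laplacian of
#' the 1-skeleton over the present vertex set (diagonal = vertex degree,
#' off-diagonal -1 iff two vertices are upper-adjacent).  For k > 0 the
#' diagonal is the upper degree plus k + 1 for lower adjacency, with
#' off-diagonal entries of modulus 1 cancelling for upper-adjacent pairs.
#' An empty dimension yields a 0 x 0 matrix.
#'
#' @param K a `dowker_complex`.
#' @param k dimension, `0 <= k <= max_dim`.  When `k == max_dim` the
#'   unenumerated `B_{k+1}` term is taken as zero.
#' @return square symmetric numeric matrix.
#' @export
hodge_laplacian <- function(K, k) {
  stopifnot(inherits(K, "dowker_complex"))
  if (k < 0L || k > K$max_dim) {
    stop("k must be between 0 and max_dim = ", K$max_dim)
  }
  nk <- n_simplices(K, k)
  if (nk == 0L) return(matrix(0, 0L, 0L))
  L <- matrix(0, nk, nk)
  if (k >= 1L) {
    Bk <- boundary_matrix(K, k)
    L <- L + crossprod(Bk)
  }
  if (k < K$max_dim && n_simplices(K, k + 1L) > 0L) {
    Bk1 <- boundary_matrix(K, k + 1L)
    L <- L + tcrossprod(Bk1)
  }
  L
}

#' Eigenvalue spectrum of a Hodge Laplacian
#'
#' Dense symmetric eigendecomposition; eigenvalues returned in ascending
#' order.  The input must be symmetric and positive semi-definite up to the
#' zero tolerance.
#'
#' @param L square symmetric matrix.
#' @param tol relative zero tolerance (see [ZERO_EIGENVALUE_TOL]).
#' @return ascending numeric vector of eigenvalues (empty for a 0 x 0
#'   matrix).
#' @export
laplacian_spectrum <- function(L, tol = ZERO_EIGENVALUE_TOL) {
  stopifnot(is.matrix(L), nrow(L) == ncol(L))
  if (nrow(L) == 0L) return(numeric(0))
  if (!isSymmetric(unname(L), tol = 1e-10)) {
    stop("Laplacian must be symmetric")
  }
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  thr <- .zero_threshold(ev, tol)
  if (ev[1L] < -thr) {
    stop("matrix is not positive semi-definite (min eigenvalue ",
         format(ev[1L]), ")")
  }
  ev
}

#' Betti number from the Laplacian kernel
#'
#' The k-th Betti number equals the multiplicity of (numerically) zero
#' eigenvalues of `L_k`.  Requires `k < max_dim` so that the
#' `B_{k+1}` term of the Laplacian is meaningful, unless the complex is
#' known to have no (k+1)-simplices.
#'
#' @param K a `dowker_complex`.
#' @param k dimension.
#' @param tol relative zero tolerance.
#' @return non-negative integer.
#' @export
betti_number <- function(K, k, tol = ZERO_EIGENVALUE_TOL) {
  ev <- laplacian_spectrum(hodge_laplacian(K, k), tol)
  if (length(ev) == 0L) return(0L)
  sum(ev < .zero_threshold(ev, tol))
}
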