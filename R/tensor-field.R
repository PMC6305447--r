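#' @importFrom stats coef cor.test lm rnorm runif sd t.test
#' @importFrom utils write.csv
NULL

# Symmetric 3x3 tensors are stored as 6-vectors in the fixed component order
#   xx, xy, xz, yy, yz, zz
# A tensor *field* is a numeric matrix with one row per voxel/cell and 6
# columns, optionally carrying a "dim"/"mask" attribute when it covers a grid.

SYM6_NAMES <- c("xx", "xy", "xz", "yy", "yz", "zz")

# index of component (a,b) of the 3x3 matrix inside the 6-vector
SYM6_INDEX <- matrix(c(1, 2, 3,
                       2, 4, 5,
                       3, 5, 6), 3, 3, byrow = TRUE)

#' Convert a 6-component tensor vector to a symmetric 3x3 matrix
#'
#' Components are ordered `xx, xy, xz, yy, yz, zz`.
#'
#' @param v numeric vector of length 6.
#' @return a symmetric 3x3 matrix.
#' @export
sym6_to_mat <- function(v) {
  stopifnot(length(v) == 6)
  matrix(v[SYM6_INDEX], 3, 3)
}

#' Convert a symmetric 3x3 matrix to its 6-component vector
#'
#' @param m symmetric 3x3 matrix (symmetrized by averaging if needed).
#' @return numeric vector `c(xx, xy, xz, yy, yz, zz)`.
#' @export
mat_to_sym6 <- function(m) {
  stopifnot(all(dim(m) == c(3, 3)))
  m <- (m + t(m)) / 2
  c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
}

# quadratic-form row for a direction g: q %*% sym6 == g' T g
sym6_quadform_row <- function(g) {
  c(g[1]^2, 2 * g[1] * g[2], 2 * g[1] * g[3], g[2]^2, 2 * g[2] * g[3], g[3]^2)
}

# coerce input (vector, 3x3 matrix, or n x 6 matrix) to an n x 6 matrix
as_sym6_matrix <- function(x) {
  if (is.matrix(x) && all(dim(x) == c(3, 3)) && isTRUE(all.equal(x, t(x))))
    return(matrix(mat_to_sym6(x), 1, 6, dimnames = list(NULL, SYM6_NAMES)))
  if (is.null(dim(x)) && length(x) == 6)
    return(matrix(x, 1, 6, dimnames = list(NULL, SYM6_NAMES)))
  if (is.matrix(x) && ncol(x) == 6) return(x)
  stop("cannot interpret input as a symmetric tensor (field); expected length-6 vector, 3x3 matrix or n x 6 matrix")
}

# Eigen-decompose every row of an n x 6 tensor field.
# Returns list(values = n x 3 (descending), vectors = list-free 3x3xn array).
field_eigen <- function(tf) {
  tf <- as_sym6_matrix(tf)
  n <- nrow(tf)
  vals <- matrix(0, n, 3)
  vecs <- array(0, c(3, 3, n))
  for (i in seq_len(n)) {
    e <- eigen(sym6_to_mat(tf[i, ]), symmetric = TRUE)
    vals[i, ] <- e$values
    vecs[, , i] <- e$vectors
  }
  list(values = vals, vectors = vecs)
}

# Rebuild an n x 6 field from eigenvalues/eigenvectors.
field_from_eigen <- function(values, vectors) {
  n <- nrow(values)
  out <- matrix(0, n, 6, dimnames = list(NULL, SYM6_NAMES))
  for (i in seq_len(n)) {
    m <- vectors[, , i] %*% diag(values[i, ], 3) %*% t(vectors[, , i])
    out[i, ] <- mat_to_sym6(m)
  }
  out
}

#' Repair a tensor field to be symmetric positive semi-definite
#'
#' Negative eigenvalues (which can arise from noisy fits) are clamped to a
#' small positive fraction of the voxel mean diffusivity so that downstream
#' eigen-normalization and the transport solver always see SPD tensors.
#'
#' @param tf tensor field (n x 6 matrix, 6-vector, or 3x3 matrix).
#' @param floor_frac eigenvalue floor as a fraction of the voxel mean
#'   eigenvalue (default `1e-12`).
#' @return repaired n x 6 tensor field; attribute `"repaired"` counts voxels
#'   that were modified.
#' @export
spd_repair <- function(tf, floor_frac = 1e-12) {
  tf <- as_sym6_matrix(tf)
  md <- (tf[, 1] + tf[, 4] + tf[, 6]) / 3
  bad <- integer(0)
  for (i in seq_len(nrow(tf))) {
    e <- eigen(sym6_to_mat(tf[i, ]), symmetric = TRUE)
    floorv <- max(abs(md[i]), .Machine$double.eps) * floor_frac
    if (any(e$values < floorv)) {
      v <- pmax(e$values, floorv)
      tf[i, ] <- mat_to_sym6(e$vectors %*% diag(v, 3) %*% t(e$vectors))
      bad <- c(bad, i)
    }
  }
  attr(tf, "repaired") <- length(bad)
  tf
}

# symmetric principal square root of a 3x3 SPSD matrix
mat_sqrt_spd <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), 3) %*% t(e$vectors)
}

# 3D rotation applied to an n x 6 field: T -> Q T Q'
rotate_sym6 <- function(tf, Q) {
  tf <- as_sym6_matrix(tf)
  out <- tf
  for (i in seq_len(nrow(tf)))
    out[i, ] <- mat_to_sym6(Q %*% sym6_to_mat(tf[i, ]) %*% t(Q))
  out
}

# trace of every row
sym6_trace <- function(tf) {
  tf <- as_sym6_matrix(tf)
  unname(tf[, 1] + tf[, 4] + tf[, 6])
}
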