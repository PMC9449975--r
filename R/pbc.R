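#' Minimum-image distance under periodic boundary conditions
#'
#' Computes the shortest distance between two points given a (possibly
#' triclinic) periodic box. With `box = NULL` the plain Euclidean distance
#' is returned. Orthorhombic boxes use the closed-form wrap; triclinic
#' boxes search the 27 neighbouring images of the lattice-reduced
#' displacement, which is exact for the compact boxes MD engines produce.
#'
#' @param a,b numeric 3-vectors (nm).
#' @param box 3x3 box matrix (rows are lattice vectors, nm) or `NULL`.
#' @return distance in nm.
#' @examples
#' box <- diag(3) * 10
#' min_image_distance(c(0, 0, 0), c(0, 0, 9.5), box)  # 0.5
#' @export
min_image_distance <- function(a, b, box = NULL) {
  d <- as.numeric(b) - as.numeric(a)
  if (is.null(box)) return(sqrt(sum(d^2)))
  sqrt(min_image_sq(matrix(d, 1L, 3L), box))
}

#' Squared minimum-image lengths of displacement rows
#' @param d n x 3 matrix of displacement vectors.
#' @param box 3x3 box matrix or NULL.
#' @return numeric vector of squared lengths.
#' @keywords internal
min_image_sq <- function(d, box = NULL) {
  if (is.null(box)) return(rowSums(d^2))
  box <- as.matrix(box)
  off_diag <- box; diag(off_diag) <- 0
  if (all(abs(off_diag) < 1e-12)) {
    # orthorhombic fast path
    L <- diag(box)
    for (k in 1:3) d[, k] <- d[, k] - L[k] * round(d[, k] / L[k])
    return(rowSums(d^2))
  }
  # triclinic: reduce to the central cell in fractional coordinates, then
  # scan the 27 surrounding images
  inv <- solve(box)
  frac <- d %*% inv
  frac <- frac - round(frac)
  d0 <- frac %*% box
  best <- rep(Inf, nrow(d0))
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    shift <- i * box[1, ] + j * box[2, ] + k * box[3, ]
    cand <- sweep(d0, 2L, -shift)
    best <- pmin(best, rowSums(cand^2))
  }
  best
}

#' Minimum-image distances from each row of `x` to each row of `y`
#' @return matrix nrow(x) x nrow(y) of distances (nm).
#' @keywords internal
pbc_dist_matrix <- function(x, y, box = NULL) {
  nx <- nrow(x); ny <- nrow(y)
  d <- matrix(0, nx, ny)
  for (j in seq_len(ny)) {
    disp <- sweep(x, 2L, y[j, ])
    d[, j] <- sqrt(min_image_sq(disp, box))
  }
  d
}

#' Minimum distance between two atom sets in one frame
#' @keywords internal
pbc_min_dist <- function(x, y, box = NULL) {
  best <- Inf
  # loop over the smaller set to keep the temporary matrices modest
  if (nrow(x) > nrow(y)) { tmp <- x; x <- y; y <- tmp }
  for (i in seq_len(nrow(x))) {
    disp <- sweep(y, 2L, x[i, ])
    best <- min(best, min(min_image_sq(disp, box)))
  }
  sqrt(best)
}
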