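# Periodic-boundary geometry.  The synthetic membrane is quasi-2D: the two
# membrane-plane axes (x, y) are periodic by default, z is not.

#' Minimum-image displacement between points in a periodic box
#'
#' Computes `a - b` under the minimum-image convention: every periodic
#' component of the result is wrapped into `[-L/2, L/2)`; non-periodic
#' components are plain differences.
#'
#' @param a,b Numeric 3-vectors, or n x 3 matrices of positions (nm). If both
#'   are matrices they must have the same number of rows; a vector is recycled
#'   against a matrix.
#' @param box Orthorhombic box edge lengths, numeric 3-vector (nm).
#' @param periodic Logical 3-vector marking which axes are periodic.
#'   Default `c(TRUE, TRUE, FALSE)` (membrane-plane periodicity).
#' @return Displacement with the same shape as the wider of `a`, `b`.
#' @export
#' @examples
#' min_image_displacement(c(9.7, 0, 0), c(0.2, 0, 0), box = c(10, 10, 10))
min_image_displacement <- function(a, b, box, periodic = c(TRUE, TRUE, FALSE)) {
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop("invalid geometry: box edge lengths must be three finite positive numbers")
  }
  if (is.null(dim(a)) && is.null(dim(b))) {
    d <- as.numeric(a) - as.numeric(b)
    w <- periodic
    d[w] <- d[w] - box[w] * floor(d[w] / box[w] + 0.5)
    return(d)
  }
  a <- if (is.null(dim(a))) matrix(a, nrow = NROW(b), ncol = 3, byrow = TRUE) else as.matrix(a)
  b <- if (is.null(dim(b))) matrix(b, nrow = NROW(a), ncol = 3, byrow = TRUE) else as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  d <- a - b
  for (ax in which(periodic)) {
    d[, ax] <- d[, ax] - box[ax] * floor(d[, ax] / box[ax] + 0.5)
  }
  d
}

#' Minimum-image distance
#'
#' @inheritParams min_image_displacement
#' @param plane If `TRUE`, only the in-plane (x, y) components enter the
#'   distance, the convention used for membrane-plane reaction coordinates.
#' @return Distance(s) in nm; a scalar for vector input, a vector for matrices.
#' @export
min_image_distance <- function(a, b, box, periodic = c(TRUE, TRUE, FALSE),
                               plane = FALSE) {
  d <- min_image_displacement(a, b, box, periodic)
  if (is.null(dim(d))) {
    if (plane) d <- d[1:2]
    sqrt(sum(d^2))
  } else {
    if (plane) d <- d[, 1:2, drop = FALSE]
    sqrt(rowSums(d^2))
  }
}

#' Wrap positions into the primary box image
#'
#' Periodic components are wrapped into `[0, L)`; non-periodic components are
#' untouched.
#'
#' @param x n x 3 matrix of positions (nm).
#' @inheritParams min_image_displacement
#' @return Matrix of wrapped positions.
#' @export
wrap_positions <- function(x, box, periodic = c(TRUE, TRUE, FALSE)) {
  x <- as.matrix(x)
  for (ax in which(periodic)) {
    x[, ax] <- x[, ax] - box[ax] * floor(x[, ax] / box[ax])
  }
  x
}
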