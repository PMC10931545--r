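#' Rigid (rotation + translation) transform
#'
#' @param rotation 3 x 3 rotation matrix; must be orthonormal with
#'   determinant +1 within 1e-8.
#' @param translation length-3 numeric, mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be proper (determinant +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rotation angle %.4f deg, translation (%.3f, %.3f, %.3f) mm\n",
              rotation_angle_deg(x$rotation),
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues formula.
#'
#' @param axis length-3 direction (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- as.numeric(axis)
  n <- sqrt(sum(a^2))
  if (n == 0) stop("rotation axis has zero length")
  a <- a / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rotation matrix, in degrees
#'
#' @param R 3 x 3 rotation matrix.
#' @return angle in [0, 180] degrees.
#' @export
rotation_angle_deg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Compose two rigid transforms
#'
#' `compose_rigid(a, b)` applies `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return the composed [rigid_transform()].
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param x a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_rigid <- function(x) {
  Rt <- t(x$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% x$translation))
}

#' Apply a rigid transform to points
#'
#' @param points n x 3 matrix or length-3 vector.
#' @param transform a [rigid_transform()].
#' @return transformed points, same shape as input.
#' @export
apply_rigid <- function(points, transform) {
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1L, 3L) else as.matrix(points)
  out <- sweep(p %*% t(transform$rotation), 2L, transform$translation, `+`)
  if (single) as.numeric(out) else out
}

# Least-squares rigid alignment (Kabsch/Umeyama without scale): finds the
# rigid transform mapping P onto Q minimizing sum ||R p + t - q||^2.
kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2L, cp), sweep(Q, 2L, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, cq - as.numeric(R %*% cp))
}
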