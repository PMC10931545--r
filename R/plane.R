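#' Cutting plane with an in-plane 2D basis
#'
#' A plane is an origin, a unit normal, and a deterministic right-handed
#' in-plane basis (u, v) with u x v = normal. The basis fixes the 2D frame
#' used for cut contours and projected axes.
#'
#' The u axis is the component of a fixed reference direction orthogonal to
#' the normal: +z by default, falling back to +y when the normal is within
#' ~25 degrees of +z (|normal . z| > 0.9). v completes the right-handed
#' triad. Identical inputs always produce bitwise-identical bases.
#'
#' @param origin length-3 point on the plane (mm).
#' @param normal length-3 normal; normalized internally, must be nonzero.
#' @return an object of class `cut_plane` with fields `origin`, `normal`,
#'   `u_axis`, `v_axis`.
#' @export
make_plane <- function(origin, normal) {
  origin <- as.numeric(origin)
  normal <- as.numeric(normal)
  stopifnot(length(origin) == 3L, length(normal) == 3L)
  len <- sqrt(sum(normal^2))
  if (len == 0) stop("plane normal has zero length")
  n <- normal / len
  ref <- if (abs(n[3]) > 0.9) c(0, 1, 0) else c(0, 0, 1)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],   # v = n x u so that u x v = n
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  structure(list(origin = origin, normal = n, u_axis = u, v_axis = v),
            class = "cut_plane")
}

#' @export
print.cut_plane <- function(x, ...) {
  cat(sprintf("cut_plane: origin (%.2f, %.2f, %.2f), normal (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Project 3D points into plane coordinates
#'
#' Returns (dot(p - origin, u), dot(p - origin, v)). The projection is an
#' isometry for in-plane points and never increases distances.
#'
#' @param points length-3 vector or n x 3 matrix (mm).
#' @param plane a [make_plane()] object.
#' @return length-2 vector or n x 2 matrix of plane coordinates (mm).
#' @export
project_to_plane <- function(points, plane) {
  stopifnot(inherits(plane, "cut_plane"))
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1L, 3L) else as.matrix(points)
  d <- sweep(p, 2L, plane$origin)
  out <- cbind(d %*% plane$u_axis, d %*% plane$v_axis)
  colnames(out) <- c("u", "v")
  if (single) c(u = out[1, 1], v = out[1, 2]) else out
}

#' Signed distance of points from a plane
#'
#' Positive on the side the normal points to.
#'
#' @param points length-3 vector or n x 3 matrix (mm).
#' @param plane a [make_plane()] object.
#' @return numeric vector of signed distances (mm).
#' @export
plane_signed_distance <- function(points, plane) {
  p <- if (is.null(dim(points))) matrix(points, 1L, 3L) else as.matrix(points)
  as.numeric(sweep(p, 2L, plane$origin) %*% plane$normal)
}

# planes are "the same frame" when origin and basis agree to tolerance
same_plane_frame <- function(a, b, tol = 1e-9) {
  inherits(a, "cut_plane") && inherits(b, "cut_plane") &&
    max(abs(a$origin - b$origin), abs(a$normal - b$normal),
        abs(a$u_axis - b$u_axis), abs(a$v_axis - b$v_axis)) <= tol
}
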