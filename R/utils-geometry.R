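# Small 3-D vector/rotation helpers shared across modules.

#' Cross product of two 3-vectors
#' @param a,b numeric length-3 vectors.
#' @return numeric length-3 vector a x b.
#' @keywords internal
cross3 <- function(a, b) {
  unname(c(a[2] * b[3] - a[3] * b[2],
           a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1]))
}

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (!is.finite(n) || n < .Machine$double.eps)
    stop("cannot normalize a zero (or non-finite) vector")
  unname(v / n)
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation by `angle_deg`
#' degrees about `axis` (need not be unit length).
#'
#' @param axis numeric length-3 rotation axis.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- unit_vec(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotation taking unit vector v onto unit vector w (identity if parallel,
# 180 deg about any perpendicular if antiparallel).
rotation_between <- function(v, w) {
  v <- unit_vec(v); w <- unit_vec(w)
  d <- sum(v * w)
  ax <- cross3(v, w)
  if (vec_norm(ax) < 1e-12) {
    if (d > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any axis perpendicular to v
    p <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- cross3(v, p)
    return(rotation_about_axis(ax, 180))
  }
  ang <- atan2(vec_norm(ax), d) * 180 / pi
  rotation_about_axis(ax, ang)
}

# Apply a rigid transform X -> (X - center) R^T + center + shift to an
# n x 3 coordinate matrix.
transform_coords <- function(X, R = diag(3), center = c(0, 0, 0),
                             shift = c(0, 0, 0)) {
  sweep(sweep(X, 2, center) %*% t(R), 2, center + shift, "+")
}
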