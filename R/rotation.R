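#' Angle-axis rotation matrix
#'
#' Rodrigues rotation matrix for an angle-axis vector `p` (direction = axis,
#' magnitude = rotation angle in radians), with optional analytic derivatives
#' `dR/dp_k`. The `p -> 0` limit is handled by series expansion.
#'
#' @param p numeric length-3 angle-axis vector
#' @param derivatives also return the three derivative matrices
#' @return the 3x3 rotation matrix, or (with `derivatives = TRUE`) a list
#'   with elements `R` and `dR` (list of three 3x3 matrices)
#' @export
rotation_matrix <- function(p, derivatives = FALSE) {
  stopifnot(length(p) == 3, all(is.finite(p)))
  out <- .cpp_rotation_matrix(as.numeric(p), derivatives)
  if (derivatives) out else out$R
}

#' Canonical angle-axis form
#'
#' Reduces an angle-axis vector to the representative with `|p| <= pi`
#' describing the same rotation (the angle is wrapped into `(-pi, pi]` along
#' the same axis).
#'
#' @param p numeric length-3 angle-axis vector
#' @return an equivalent angle-axis vector with norm at most pi
#' @export
canonicalize_aa <- function(p) {
  stopifnot(length(p) == 3, all(is.finite(p)))
  th <- sqrt(sum(p^2))
  if (th <= pi) return(p)
  # wrap angle into (-pi, pi]
  th_new <- th %% (2 * pi)
  if (th_new > pi) th_new <- th_new - 2 * pi
  p * (th_new / th)
}

# compose two rotations given as angle-axis vectors: returns aa of R(p1) R(p2)
aa_compose <- function(p1, p2) {
  aa_from_matrix(rotation_matrix(p1) %*% rotation_matrix(p2))
}

# angle-axis vector from a rotation matrix (canonical, |p| <= pi), through
# a largest-pivot quaternion extraction, which is uniformly accurate over
# SO(3) including half-turns
aa_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  vals <- c(tr, R[1, 1], R[2, 2], R[3, 3])
  k <- which.max(vals)
  if (k == 1) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (k == 2) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (k == 3) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  vn <- sqrt(sum(q[2:4]^2))
  if (vn < 1e-300) return(c(0, 0, 0))
  th <- 2 * atan2(vn, q[1])
  q[2:4] / vn * th
}

# uniform random rotation as an angle-axis vector (via uniform unit
# quaternion, equivalent to a uniform axis with angle density prop. to
# sin^2(theta/2))
random_rotation_aa <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  th <- 2 * acos(max(-1, min(1, q[1])))
  s <- sqrt(max(0, 1 - q[1]^2))
  axis <- if (s < 1e-12) c(1, 0, 0) else q[2:4] / s
  canonicalize_aa(axis * th)
}
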