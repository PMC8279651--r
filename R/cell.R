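#' Triclinic unit cell
#'
#' Constructs a unit cell from the six lattice parameters. Lengths are in
#' Angstrom; angles are taken in degrees at this (and every other) I/O
#' boundary and stored internally in radians. The constructor rejects
#' degenerate cells, i.e. cells whose angular volume factor
#' \eqn{P = \sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma +
#' 2\cos\alpha\cos\beta\cos\gamma}} is not real and positive (a guard against
#' malformed input; during optimization the WCA penalty keeps cells away from
#' this region).
#'
#' @param a,b,c cell edge lengths (Angstrom), positive
#' @param alpha,beta,gamma cell angles, in degrees unless `degrees = FALSE`
#' @param degrees interpret the angles as degrees (default) or radians
#' @return an object of class `unit_cell`
#' @examples
#' cell <- unit_cell(6.868, 9.477, 7.285, 90, 90, 90)
#' cell_volume(cell)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      degrees = TRUE) {
  lengths <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (degrees) ang <- ang * pi / 180
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("cell lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= pi))
    stop("cell angles must lie strictly between 0 and 180 degrees")
  cell <- structure(list(par = unname(c(lengths, ang))), class = "unit_cell")
  P <- .cpp_p_factor(cell$par)
  if (is.na(P) || P < 1e-6)
    stop("degenerate cell: angular volume factor P is not real and positive")
  cell
}

# internal: unit_cell from the length-6 parameter vector (radians)
new_cell_from_par <- function(par) {
  unit_cell(par[1], par[2], par[3], par[4], par[5], par[6], degrees = FALSE)
}

#' @export
print.unit_cell <- function(x, ...) {
  p <- cell_parameters(x)
  cat(sprintf(
    "unit cell: a = %.4f  b = %.4f  c = %.4f A | alpha = %.3f  beta = %.3f  gamma = %.3f deg\n",
    p[1], p[2], p[3], p[4], p[5], p[6]))
  v <- cell_volume(x)
  cat(sprintf("volume %.3f A^3, angular factor P = %.5f\n", v$V, v$P))
  invisible(x)
}

#' Cell parameters in I/O units
#'
#' @param cell a [unit_cell()]
#' @return named numeric vector `(a, b, c, alpha, beta, gamma)` with lengths
#'   in Angstrom and angles in degrees
#' @export
cell_parameters <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  p <- cell$par
  c(a = p[1], b = p[2], c = p[3],
    alpha = p[4] * 180 / pi, beta = p[5] * 180 / pi, gamma = p[6] * 180 / pi)
}

#' Cell matrix H
#'
#' Returns the 3x3 matrix whose columns are the cell vectors, in the fixed
#' orientation convention: **a** along +x and **b** in the xy-plane with a
#' positive y-component. `H` maps fractional to absolute coordinates.
#'
#' @param cell a [unit_cell()]
#' @return 3x3 numeric matrix (Angstrom)
#' @export
cell_matrix <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  .cpp_cell_matrix(cell$par)
}

#' Cell volume and angular volume factor
#'
#' `V = a b c P` with
#' `P = sqrt(1 - cos^2(alpha) - cos^2(beta) - cos^2(gamma)
#'           + 2 cos(alpha) cos(beta) cos(gamma))`.
#'
#' @param cell a [unit_cell()]
#' @return list with elements `V` (Angstrom^3) and `P` (dimensionless)
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  P <- .cpp_p_factor(cell$par)
  if (is.na(P)) stop("degenerate cell: P^2 <= 0")
  list(V = prod(cell$par[1:3]) * P, P = P)
}

#' Reciprocal lattice vector lengths
#'
#' `a* = |b x c| / V` and cyclic permutations; equal to the row norms of
#' `solve(cell_matrix(cell))`.
#'
#' @param cell a [unit_cell()]
#' @return named numeric vector `(a_star, b_star, c_star)` in 1/Angstrom
#' @export
reciprocal_lengths <- function(cell) {
  H <- cell_matrix(cell)
  V <- abs(det(H))
  av <- H[, 1]; bv <- H[, 2]; cv <- H[, 3]
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  c(a_star = sqrt(sum(cr(bv, cv)^2)) / V,
    b_star = sqrt(sum(cr(cv, av)^2)) / V,
    c_star = sqrt(sum(cr(av, bv)^2)) / V)
}

#' Fractional/absolute coordinate transforms
#'
#' `frac_to_abs` computes the product of H with the fractional coordinates;
#' `abs_to_frac` inverts it.
#' Coordinates may be a length-3 vector or a 3-row matrix.
#'
#' @param H 3x3 cell matrix (see [cell_matrix()])
#' @param rbar,r coordinates, fractional resp. absolute (Angstrom)
#' @return coordinates of the same shape
#' @export
frac_to_abs <- function(H, rbar) {
  if (is.matrix(rbar)) H %*% rbar else drop(H %*% rbar)
}

#' @rdname frac_to_abs
#' @export
abs_to_frac <- function(H, r) {
  if (abs(det(H)) < 1e-12) stop("singular cell matrix")
  if (is.matrix(r)) solve(H, r) else drop(solve(H, r))
}

#' Derivatives of the cell matrix
#'
#' Analytic derivatives of [cell_matrix()] with respect to each of the six
#' cell parameters (angle derivatives per radian).
#'
#' @param cell a [unit_cell()]
#' @return named list of six 3x3 matrices, `a, b, c, alpha, beta, gamma`
#' @export
cell_matrix_derivatives <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  .cpp_cell_matrix_derivs(cell$par)
}

#' WCA penalty on the angular volume factor
#'
#' A repulsive, cut-and-shifted penalty on the angular volume factor P that
#' prevents the optimizer from reaching degenerate cell-angle combinations:
#' \deqn{U_P = \epsilon_P (\sigma_P / P^6 - 1)^2 \quad (P^6 < \sigma_P),
#'       \qquad U_P = 0 \quad (P^6 \ge \sigma_P).}
#' It switches on exactly at `P = sigma_P^(1/6)` (0.818 for the default
#' `sigma_P = 0.3`), where both the value and the first derivative vanish,
#' and diverges as P approaches 0.
#'
#' @param cell a [unit_cell()]
#' @param eps_P penalty strength in kJ/mol (default 0.001 hartree)
#' @param sigma_P dimensionless penalty range
#' @return list with `energy` (kJ/mol) and `grad_angles`, the derivative with
#'   respect to (alpha, beta, gamma) in kJ/mol per radian
#' @export
wca_cell_penalty <- function(cell, eps_P = 0.001 * 2625.4996394799,
                             sigma_P = 0.3) {
  stopifnot(inherits(cell, "unit_cell"))
  ang <- cell$par[4:6]
  ca <- cos(ang[1]); cb <- cos(ang[2]); cg <- cos(ang[3])
  P2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (P2 <= 0) stop("degenerate cell: P^2 <= 0")
  P <- sqrt(P2)
  P6 <- P2^3
  g <- c(alpha = 0, beta = 0, gamma = 0)
  if (P6 >= sigma_P) return(list(energy = 0, grad_angles = g))
  x <- sigma_P / P6 - 1
  dUdP <- 2 * eps_P * x * (-6 * sigma_P / (P6 * P))
  dPdc <- c(cb * cg - ca, ca * cg - cb, ca * cb - cg) / P
  g[] <- dUdP * dPdc * (-sin(ang))
  list(energy = eps_P * x^2, grad_angles = g)
}

#' Periodic image limits
#'
#' Number of neighboring cells that must be searched in each lattice
#' direction so that the full interaction sphere of radius `r_c` around every
#' molecule is covered: `M = floor(2 * r_c * a_star) + 1` (and likewise for
#' b, c).
#'
#' @param cell a [unit_cell()]
#' @param r_c interaction cutoff (Angstrom), positive
#' @return named integer vector `(M_a, M_b, M_c)`
#' @export
image_limits <- function(cell, r_c) {
  stopifnot(r_c > 0)
  rl <- reciprocal_lengths(cell)
  # the small epsilon keeps exact-integer boundary cases (e.g. 2 r_c a* = 3)
  # from rounding down through floating-point noise
  setNames(as.integer(floor(2 * r_c * rl + 1e-9) + 1), c("M_a", "M_b", "M_c"))
}
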