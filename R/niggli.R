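#' Niggli-reduced cell
#'
#' Canonical reduced form of a lattice (Krivy-Gruber algorithm on the metric
#' tensor, with tolerance stabilization). Cells describing the same lattice
#' in different bases -- axis permutations, sign flips, or any unimodular
#' re-basing -- reduce to the same parameters, which makes the reduced cell
#' the comparison form used for archive deduplication and polymorph
#' matching. Idempotent: reducing a reduced cell returns it unchanged.
#'
#' @param cell a [unit_cell()]
#' @return a [unit_cell()] in Niggli-reduced form (a <= b <= c)
#' @export
reduce_cell <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  p <- cell$par
  a2 <- p[1]^2; b2 <- p[2]^2; c2 <- p[3]^2
  xi <- 2 * p[2] * p[3] * cos(p[4])
  eta <- 2 * p[1] * p[3] * cos(p[5])
  zeta <- 2 * p[1] * p[2] * cos(p[6])
  eps <- 1e-8 * (a2 * b2 * c2)^(1 / 3)

  sgn <- function(x) if (x > eps) 1 else if (x < -eps) -1 else 0
  for (iter in 1:200) {
    # A1: order A <= B
    if (a2 > b2 + eps || (abs(a2 - b2) <= eps && abs(xi) > abs(eta) + eps)) {
      tmp <- a2; a2 <- b2; b2 <- tmp
      tmp <- xi; xi <- eta; eta <- tmp
      next
    }
    # A2: order B <= C
    if (b2 > c2 + eps || (abs(b2 - c2) <= eps && abs(eta) > abs(zeta) + eps)) {
      tmp <- b2; b2 <- c2; c2 <- tmp
      tmp <- eta; eta <- zeta; zeta <- tmp
      next
    }
    # A3/A4: sign normalization
    l <- sgn(xi); m <- sgn(eta); n <- sgn(zeta)
    if (l * m * n == 1) {
      xi <- abs(xi); eta <- abs(eta); zeta <- abs(zeta)
    } else {
      xi <- -abs(xi); eta <- -abs(eta); zeta <- -abs(zeta)
    }
    # A5
    if (abs(xi) > b2 + eps ||
        (abs(xi - b2) <= eps && 2 * eta < zeta - eps) ||
        (abs(xi + b2) <= eps && zeta < -eps)) {
      s <- if (xi > 0) 1 else -1
      c2 <- b2 + c2 - s * xi
      eta <- eta - s * zeta
      xi <- xi - 2 * s * b2
      next
    }
    # A6
    if (abs(eta) > a2 + eps ||
        (abs(eta - a2) <= eps && 2 * xi < zeta - eps) ||
        (abs(eta + a2) <= eps && zeta < -eps)) {
      s <- if (eta > 0) 1 else -1
      c2 <- a2 + c2 - s * eta
      xi <- xi - s * zeta
      eta <- eta - 2 * s * a2
      next
    }
    # A7
    if (abs(zeta) > a2 + eps ||
        (abs(zeta - a2) <= eps && 2 * xi < eta - eps) ||
        (abs(zeta + a2) <= eps && eta < -eps)) {
      s <- if (zeta > 0) 1 else -1
      b2 <- a2 + b2 - s * zeta
      xi <- xi - s * eta
      zeta <- zeta - 2 * s * a2
      next
    }
    # A8
    if (xi + eta + zeta + a2 + b2 < -eps ||
        (abs(xi + eta + zeta + a2 + b2) <= eps &&
         2 * (a2 + eta) + zeta > eps)) {
      c2 <- a2 + b2 + c2 + xi + eta + zeta
      xi <- 2 * b2 + xi + zeta
      eta <- 2 * a2 + eta + zeta
      next
    }
    break
  }
  a <- sqrt(a2); b <- sqrt(b2); cc <- sqrt(c2)
  unit_cell(a, b, cc,
            acos(pmin(1, pmax(-1, xi / (2 * b * cc)))),
            acos(pmin(1, pmax(-1, eta / (2 * a * cc)))),
            acos(pmin(1, pmax(-1, zeta / (2 * a * b)))),
            degrees = FALSE)
}
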