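test_that("cell matrix follows the fixed orientation convention", {
  expect_equal(cell_matrix(unit_cell(1, 1, 1, 90, 90, 90)), diag(3))
  expect_equal(cell_matrix(unit_cell(2, 3, 4, 90, 90, 90)), diag(c(2, 3, 4)))
  # beta = 120 tilts only the c vector: |c| = 2, a.c = 2*2*cos(120)
  H <- cell_matrix(unit_cell(2, 2, 2, 90, 120, 90))
  expect_equal(H[, 3], c(-1, 0, sqrt(3)), tolerance = 1e-12)

  set.seed(41)
  for (k in 1:50) {
    cell <- random_cell()
    H <- cell_matrix(cell)
    p <- cell$par
    expect_equal(sqrt(colSums(H^2)), p[1:3], tolerance = 1e-12)
    expect_equal(sum(H[, 2] * H[, 3]) / (p[2] * p[3]), cos(p[4]),
                 tolerance = 1e-12)
    expect_equal(sum(H[, 1] * H[, 3]) / (p[1] * p[3]), cos(p[5]),
                 tolerance = 1e-12)
    expect_equal(sum(H[, 1] * H[, 2]) / (p[1] * p[2]), cos(p[6]),
                 tolerance = 1e-12)
    expect_true(all(H[lower.tri(H)] == 0))  # a || x, b in the xy-plane
  }
})

test_that("cell volume equals a b c P and the cell-matrix determinant", {
  expect_equal(cell_volume(unit_cell(1, 1, 1, 90, 90, 90)),
               list(V = 1, P = 1))
  expect_equal(cell_volume(unit_cell(2, 3, 4, 90, 90, 90))$V, 24)
  # rhombohedral 60/60/60: triple product of explicitly built vectors
  av <- c(1, 0, 0)
  bv <- c(cos(pi / 3), sin(pi / 3), 0)
  cv_x <- cos(pi / 3)
  cv_y <- (cos(pi / 3) - cos(pi / 3) * cos(pi / 3)) / sin(pi / 3)
  cv <- c(cv_x, cv_y, sqrt(1 - cv_x^2 - cv_y^2))
  oracle_V <- abs(det(cbind(av, bv, cv)))
  v <- cell_volume(unit_cell(1, 1, 1, 60, 60, 60))
  expect_equal(v$P, sqrt(0.5), tolerance = 1e-12)
  expect_equal(v$V, oracle_V, tolerance = 1e-12)

  set.seed(42)
  for (k in 1:200) {
    cell <- random_cell()
    expect_equal(det(cell_matrix(cell)), cell_volume(cell)$V,
                 tolerance = 1e-12)
  }
})

test_that("degenerate cells are rejected at construction", {
  expect_error(unit_cell(1, 1, 1, 5, 5, 170), "degenerate")
  expect_error(unit_cell(-1, 1, 1, 90, 90, 90), "positive")
  expect_error(unit_cell(1, 1, 1, 190, 90, 90), "between")
})

test_that("reciprocal lengths match the inverse cell matrix", {
  expect_equal(unname(reciprocal_lengths(unit_cell(10, 10, 10, 90, 90, 90))),
               rep(0.1, 3))
  expect_equal(unname(reciprocal_lengths(unit_cell(2, 3, 4, 90, 90, 90))),
               c(0.5, 1 / 3, 0.25))
  set.seed(43)
  for (k in 1:20) {
    cell <- random_cell()
    H <- cell_matrix(cell)
    rl <- reciprocal_lengths(cell)
    expect_equal(unname(rl), unname(sqrt(rowSums(solve(H)^2))),
                 tolerance = 1e-12)
    # a* V = |b x c| exactly as constructed
    bxc <- c(H[2, 2] * H[3, 3] - H[3, 2] * H[2, 3],
             H[3, 2] * H[1, 3] - H[1, 2] * H[3, 3],
             H[1, 2] * H[2, 3] - H[2, 2] * H[1, 3])
    expect_equal(rl[["a_star"]] * cell_volume(cell)$V, sqrt(sum(bxc^2)),
                 tolerance = 1e-12)
    # a a* >= 1, equality iff a is orthogonal to span(b, c)
    expect_gte(cell$par[1] * rl[["a_star"]], 1 - 1e-12)
  }
  expect_equal(unit_cell(7, 3, 4, 90, 90, 90)$par[1] *
                 reciprocal_lengths(unit_cell(7, 3, 4, 90, 90, 90))[["a_star"]],
               1, tolerance = 1e-12)
})

test_that("fractional/absolute transforms invert each other", {
  expect_equal(frac_to_abs(diag(3), c(0.3, 0.4, 0.5)), c(0.3, 0.4, 0.5))
  expect_equal(frac_to_abs(diag(c(2, 3, 4)), c(0.5, 0.5, 0.5)), c(1, 1.5, 2))
  set.seed(44)
  H <- cell_matrix(random_cell())
  pts <- matrix(runif(300), 3)
  expect_lt(max(abs(abs_to_frac(H, frac_to_abs(H, pts)) - pts)), 1e-12)
  expect_error(abs_to_frac(matrix(0, 3, 3), c(1, 1, 1)), "singular")
})

test_that("cell-matrix derivatives match central finite differences", {
  dHa <- cell_matrix_derivatives(unit_cell(2, 3, 4, 90, 90, 90))$a
  expect_equal(dHa, rbind(c(1, 0, 0), 0, 0))
  # at right angles the volume is stationary in every angle
  cell0 <- unit_cell(3, 3, 3, 90, 90, 90)
  dH0 <- cell_matrix_derivatives(cell0)
  H0 <- cell_matrix(cell0)
  dV_dalpha <- sum(diag(solve(H0) %*% dH0$alpha)) * det(H0)  # Jacobi formula
  expect_equal(dV_dalpha, 0, tolerance = 1e-12)

  set.seed(45)
  h <- 1e-6
  for (k in 1:10) {
    cell <- random_cell()
    dH <- cell_matrix_derivatives(cell)
    for (t in 1:6) {
      pp <- cell$par; pp[t] <- pp[t] + h
      pm <- cell$par; pm[t] <- pm[t] - h
      fd <- (cell_matrix(crystalhop:::new_cell_from_par(pp)) -
             cell_matrix(crystalhop:::new_cell_from_par(pm))) / (2 * h)
      scale <- max(1, max(abs(dH[[t]])))
      expect_lt(max(abs(fd - dH[[t]])) / scale, 1e-6)
    }
  }
})

test_that("WCA cell penalty activates exactly at P = sigma_P^(1/6)", {
  # orthogonal cell: P = 1, no penalty
  expect_equal(wca_cell_penalty(unit_cell(5, 6, 7, 90, 90, 90))$energy, 0)
  # with beta = gamma = 90 the angular factor is P = sin(alpha), so alpha
  # parameterizes P directly
  cell_with_P <- function(P) unit_cell(5, 5, 5, asin(P), pi / 2, pi / 2,
                                       degrees = FALSE)
  thr <- 0.3^(1 / 6)
  expect_equal(round(thr, 3), 0.818)
  expect_equal(wca_cell_penalty(cell_with_P(thr + 1e-9))$energy, 0)
  expect_gt(wca_cell_penalty(cell_with_P(thr - 1e-4))$energy, 0)
  # strictly decreasing in P below the threshold
  grid <- seq(0.3, thr - 1e-6, length.out = 40)
  u <- vapply(grid, function(P) wca_cell_penalty(cell_with_P(P))$energy,
              numeric(1))
  expect_true(all(diff(u) < 0))
  expect_gt(wca_cell_penalty(cell_with_P(0.4))$energy,
            wca_cell_penalty(cell_with_P(0.6))$energy)
  expect_gt(wca_cell_penalty(cell_with_P(0.6))$energy, 0)
  # C1 at the threshold: one-sided secant derivatives agree (the penalty is
  # quadratic in (sigma_P/P^6 - 1), so the left secant is O(h))
  h <- 1e-11
  uL <- wca_cell_penalty(cell_with_P(thr - h))$energy
  uR <- wca_cell_penalty(cell_with_P(thr + h))$energy
  expect_lt(abs(uL / h - uR / h), 1e-8)
  # analytic angle gradient matches finite differences
  cellp <- cell_with_P(0.55)
  g <- wca_cell_penalty(cellp)$grad_angles
  h <- 1e-6
  for (t in 1:3) {
    pp <- cellp$par; pp[3 + t] <- pp[3 + t] + h
    pm <- cellp$par; pm[3 + t] <- pm[3 + t] - h
    fd <- (wca_cell_penalty(crystalhop:::new_cell_from_par(pp))$energy -
           wca_cell_penalty(crystalhop:::new_cell_from_par(pm))$energy) / (2 * h)
    expect_equal(unname(g[t]), fd, tolerance = 1e-5)
  }
})

test_that("image limits reproduce floor(2 r_c a*) + 1", {
  expect_equal(unname(image_limits(unit_cell(10, 10, 10, 90, 90, 90), 15)),
               c(4L, 4L, 4L))
  expect_equal(unname(image_limits(unit_cell(10, 10, 10, 90, 90, 90), 4)),
               c(1L, 1L, 1L))
  # tilting shrinks the interplanar spacing (raises a*); M never decreases
  tri <- unit_cell(10, 10, 10, 90, 90, 60)
  ortho <- unit_cell(10, 10, 10, 90, 90, 90)
  expect_true(all(image_limits(tri, 12) >= image_limits(ortho, 12)))
})
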