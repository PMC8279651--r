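test_that("angle-axis rotation matrices are proper and differentiable", {
  expect_equal(rotation_matrix(c(0, 0, 0)), diag(3))
  expect_equal(drop(rotation_matrix(c(0, 0, pi / 2)) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  set.seed(51)
  h <- 1e-6
  for (k in 1:8) {
    p <- rnorm(3) * sample(c(0.3, 1, 2.2), 1)
    rd <- rotation_matrix(p, derivatives = TRUE)
    expect_equal(t(rd$R) %*% rd$R, diag(3), tolerance = 1e-12)
    expect_equal(det(rd$R), 1, tolerance = 1e-12)
    for (t in 1:3) {
      pp <- p; pp[t] <- pp[t] + h
      pm <- p; pm[t] <- pm[t] - h
      fd <- (rotation_matrix(pp) - rotation_matrix(pm)) / (2 * h)
      expect_lt(max(abs(fd - rd$dR[[t]])), 1e-6)
    }
  }
  # group homomorphism on collinear angle-axis vectors
  ax <- c(1, 2, -1) / sqrt(6)
  expect_equal(rotation_matrix(0.7 * ax) %*% rotation_matrix(0.5 * ax),
               rotation_matrix(1.2 * ax), tolerance = 1e-12)
})

test_that("canonicalize_aa wraps to |p| <= pi without changing the rotation", {
  p <- canonicalize_aa(c(0, 0, 3 * pi / 2))
  expect_equal(p, c(0, 0, -pi / 2), tolerance = 1e-12)
  expect_equal(rotation_matrix(p), rotation_matrix(c(0, 0, 3 * pi / 2)),
               tolerance = 1e-12)
  expect_equal(canonicalize_aa(c(0, 0, 0)), c(0, 0, 0))
  set.seed(52)
  for (k in 1:25) {
    p <- rnorm(3) * runif(1, 0, 12)
    pc <- canonicalize_aa(p)
    expect_lte(sqrt(sum(pc^2)), pi + 1e-12)
    expect_equal(rotation_matrix(pc), rotation_matrix(p), tolerance = 1e-9)
  }
})

test_that("expand_sites applies x = H X + R x0", {
  cfg <- crystal_config(matrix(0, 3, 1), matrix(0, 3, 1),
                        unit_cell(1, 1, 1, 90, 90, 90))
  expect_equal(unname(expand_sites(cfg, ref_benzene))[, ],
               unname(ref_benzene$sites), ignore_attr = TRUE)

  set.seed(50)
  cell <- random_cell()
  H <- cell_matrix(cell)
  com <- matrix(runif(3), 3, 1)
  p <- matrix(rnorm(3), 3, 1)
  a1 <- expand_sites(crystal_config(com, p, cell), ref_benzene)
  # shifting the fractional COM by a lattice vector shifts every site by
  # the cell vector a; the constructor wraps COMs, so the stored
  # configuration (and hence the expansion) is unchanged
  a2 <- expand_sites(crystal_config(com + c(1, 0, 0), p, cell), ref_benzene)
  expect_equal(a1, a2, tolerance = 1e-12)
  manual <- drop(H %*% (com[, 1] + c(1, 0, 0))) +
    rotation_matrix(p[, 1]) %*% ref_benzene$sites
  expect_equal(unname(manual - a1), matrix(H[, 1], 3, 12), tolerance = 1e-10,
               ignore_attr = TRUE)

  # a half-turn about the ring normal maps the carbon set onto itself
  cfg0 <- crystal_config(matrix(0.5, 3, 1), matrix(c(0, 0, pi), 3, 1),
                         unit_cell(20, 20, 20, 90, 90, 90))
  cfg1 <- crystal_config(matrix(0.5, 3, 1), matrix(0, 3, 1),
                         unit_cell(20, 20, 20, 90, 90, 90))
  c_rot <- expand_sites(cfg0, ref_benzene)[, 1:6]
  c_ref <- expand_sites(cfg1, ref_benzene)[, 1:6]
  match_dist <- apply(c_rot, 2, function(x)
    min(sqrt(colSums((c_ref - x)^2))))
  expect_lt(max(match_dist), 1e-10)
})

test_that("COM gradients transform with the transpose of H", {
  g <- matrix(rnorm(6), 3, 2)
  expect_equal(com_gradient_to_fractional(g, diag(3)), g)
  expect_equal(com_gradient_to_fractional(c(1, 1, 1), diag(c(2, 3, 4))),
               c(2, 3, 4))
})

test_that("aa_gradient assembles dU/dp from site gradients", {
  # orientation-independent energy of an isolated molecule: zero gradient
  zero_g <- aa_gradient(matrix(0, 3, 12), rnorm(3), ref_benzene$sites)
  expect_equal(zero_g, c(0, 0, 0))
  # consistency with the kernel's analytic dU/dp for a benzene pair
  cell <- unit_cell(30, 30, 30, 90, 90, 90)
  set.seed(53)
  cfg <- crystal_config(cbind(c(.5, .5, .5), c(.5 + 5 / 30, .5, .5)),
                        cbind(rnorm(3, 0, .5), rnorm(3, 0, .5)), cell)
  eg <- total_energy(cfg, ref_benzene, params_benzene, settings_fast)
  h <- 1e-5
  for (i in 1:6) {
    idx <- 6 + i  # angle-axis block of the packed vector (N = 2)
    fd <- fd_energy_component(cfg, idx, h, ref_benzene, params_benzene,
                              settings_fast)
    an <- packed_gradient(eg)[idx]
    expect_equal(an, fd, tolerance = 1e-5 * max(1, abs(fd)))
  }
  # rotations offset by a full turn along the same axis give equal energy
  p1 <- cfg$p[, 1]
  p2 <- p1 * (1 + 2 * pi / sqrt(sum(p1^2)))
  cfg2 <- cfg
  cfg2$p[, 1] <- p2
  e1 <- total_energy(cfg, ref_benzene, params_benzene, settings_fast,
                     gradients = FALSE)$energy
  e2 <- total_energy(cfg2, ref_benzene, params_benzene, settings_fast,
                     gradients = FALSE)$energy
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("random starts are seeded, well-formed and overlap-free", {
  c1 <- random_start(4, seed = 7, ref = ref_benzene)
  c2 <- random_start(4, seed = 7, ref = ref_benzene)
  expect_identical(c1, c2)
  expect_equal(dim(c1$com), c(3L, 4L))
  expect_equal(dim(c1$p), c(3L, 4L))
  expect_true(all(c1$com >= 0 & c1$com < 1))

  # independent brute-force distance check across images
  brute_min_dist <- function(cfg) {
    H <- cell_matrix(cfg$cell)
    xs <- expand_sites(cfg, ref_benzene)
    mol <- attr(xs, "molecule")
    best <- Inf
    for (s1 in -1:1) for (s2 in -1:1) for (s3 in -1:1) {
      off <- drop(H %*% c(s1, s2, s3))
      home <- s1 == 0 && s2 == 0 && s3 == 0
      for (i in seq_len(ncol(xs))) {
        d2 <- colSums((xs + off - xs[, i])^2)
        keep <- if (home) mol != mol[i] else rep(TRUE, ncol(xs))
        if (any(keep)) best <- min(best, sqrt(min(d2[keep])))
      }
    }
    best
  }
  for (s in 1:12)
    expect_gte(brute_min_dist(random_start(4, seed = s, ref = ref_benzene)),
               1.5)
})
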