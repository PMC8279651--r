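test_that("an isolated molecule with all images beyond the cutoff has zero energy", {
  cfg <- crystal_config(matrix(0.5, 3, 1), matrix(rnorm(3), 3, 1),
                        unit_cell(40, 40, 40, 90, 90, 90))
  e <- short_range_sum(cfg, ref_benzene, params_benzene,
                       energy_settings(r_c = 8))
  expect_identical(e$energy, 0)
})

test_that("short-range sum agrees with a brute-force enlarged-limit oracle", {
  set.seed(71)
  cfg <- random_start(2, seed = 5, ref = ref_benzene,
                      length_range = c(6.5, 8), vm_range = c(110, 220))
  st <- energy_settings(r_c = 6)
  got <- short_range_sum(cfg, ref_benzene, params_benzene, st,
                         gradients = FALSE)$energy

  # direct R sum over an image block 3 cells beyond the M-limit rule
  H <- cell_matrix(cfg$cell)
  M <- image_limits(cfg$cell, 6) + 3L
  xs <- expand_sites(cfg, ref_benzene)
  mol <- attr(xs, "molecule")
  types <- rep(ref_benzene$types, cfg$n_mol)
  zs <- lapply(1:2, function(m) rotation_matrix(cfg$p[, m])[, 3])
  A <- params_benzene$A; B <- params_benzene$B; C6 <- params_benzene$C6
  d1 <- params_benzene$d1
  ns <- ncol(xs)
  zmat <- vapply(mol, function(m) zs[[m]], numeric(3))  # molecule normal per site
  total <- 0
  for (n1 in -M[1]:M[1]) for (n2 in -M[2]:M[2]) for (n3 in -M[3]:M[3]) {
    off <- drop(H %*% c(n1, n2, n3))
    home <- n1 == 0 && n2 == 0 && n3 == 0
    for (i in seq_len(ns)) {
      d <- xs + off - xs[, i]
      r <- sqrt(colSums(d^2))
      keep <- r <= 6 & r > 1e-9 & !(home & mol == mol[i])
      if (!any(keep)) next
      rj <- r[keep]
      rhat <- sweep(d[, keep, drop = FALSE], 2, rj, "/")
      ci <- colSums(rhat * zs[[mol[i]]])
      cj <- colSums(rhat * zmat[, keep, drop = FALSE])
      ti <- types[i]; tj <- types[keep]
      rho <- d1[ti] * ci^2 + d1[tj] * cj^2
      Aij <- A[ti, tj]; Bij <- B[ti, tj]; Cij <- C6[ti, tj]
      disp <- crystalhop::exp6_pair_energy(rj, 0, Bij, Cij, damp = TRUE)$energy
      shift <- crystalhop::exp6_pair_energy(6, Aij, Bij, Cij,
                                            damp = TRUE)$energy
      total <- total + sum(Aij * exp(-Bij * (rj - rho)) + disp - shift)
    }
  }
  expect_equal(got, total / 2, tolerance = 1e-12)
})

test_that("energy per molecule is identical for a doubled supercell", {
  set.seed(72)
  for (s in c(3, 9)) {
    cfg4 <- random_start(4, seed = s, ref = ref_benzene)
    p4 <- cfg4$cell$par
    cell8 <- crystalhop:::new_cell_from_par(c(2 * p4[1], p4[2:6]))
    com8 <- cbind(cfg4$com / c(2, 1, 1), cfg4$com / c(2, 1, 1) + c(.5, 0, 0))
    cfg8 <- crystal_config(com8, cbind(cfg4$p, cfg4$p), cell8)
    e4 <- total_energy(cfg4, ref_benzene, params_benzene, settings_fast)
    e8 <- total_energy(cfg8, ref_benzene, params_benzene, settings_fast)
    expect_equal(e8$energy_per_molecule, e4$energy_per_molecule,
                 tolerance = 1e-8)
    # per-molecule gradients replicate too
    expect_equal(e8$grad_p[, 1:4], e4$grad_p, tolerance = 1e-6)
  }
})

test_that("Ewald matches a brute-force damped direct sum on rock-salt", {
  rs <- rocksalt_fixture()
  got <- ewald_sum(rs$config, rs$ref, rs$params, energy_settings(r_c = 12),
                   gradients = FALSE)$energy
  oracle <- direct_coulomb_sum(rs$config, rs$ref, mu = 0.1, n_images = 10)
  expect_equal(got, oracle, tolerance = 1e-4 / abs(oracle))
  # the same number from the literature Madelung constant, corrected for
  # the excluded intramolecular Na-Cl interaction of each rigid pair
  ke <- 1389.35457644382
  madelung <- 4 * (-1.74756459463 * ke / (rs$a / 2)) - 4 * (-ke / (rs$a / 2))
  expect_equal(got, madelung, tolerance = 1e-7)
})

test_that("Ewald total is invariant to the splitting parameter", {
  rs <- rocksalt_fixture()
  e1 <- ewald_sum(rs$config, rs$ref, rs$params,
                  energy_settings(r_c = 12), gradients = FALSE)$energy
  e2 <- ewald_sum(rs$config, rs$ref, rs$params,
                  energy_settings(r_c = 12, alpha = 2 * 5.6 / 12,
                                  k_eps = 1e-14), gradients = FALSE)$energy
  expect_equal(e2, e1, tolerance = 1e-6)

  set.seed(73)
  cfgb <- random_start(2, seed = 2, ref = ref_benzene)
  b1 <- ewald_sum(cfgb, ref_benzene, params_benzene,
                  energy_settings(r_c = 8), gradients = FALSE)$energy
  b2 <- ewald_sum(cfgb, ref_benzene, params_benzene,
                  energy_settings(r_c = 8, alpha = 1.1, k_eps = 1e-14),
                  gradients = FALSE)$energy
  expect_equal(b2, b1, tolerance = 1e-6 * max(1, abs(b1)))
})

test_that("two opposite charges in a large cell approach the Coulomb limit", {
  one_site <- reference_geometry(matrix(0, 3, 1), "Q", 0, NULL)
  qp <- pair_params("Q", matrix(1e-10, 1, 1), matrix(1, 1, 1),
                    matrix(0, 1, 1), damp = FALSE)
  L <- 100; r0 <- 2.5
  cfg <- crystal_config(cbind(c(.5, .5, .5), c(.5 + r0 / L, .5, .5)),
                        matrix(0, 3, 2), unit_cell(L, L, L, 90, 90, 90))
  e <- ewald_sum(cfg, one_site, qp, energy_settings(r_c = 20),
                 gradients = FALSE,
                 charges = matrix(c(1, -1), 1, 2))$energy
  ke <- 1389.35457644382
  expect_equal(e, -ke / r0, tolerance = 1e-4)
})

test_that("Ewald requires a charge-neutral cell", {
  one_site <- reference_geometry(matrix(0, 3, 1), "Q", 0, NULL)
  qp <- pair_params("Q", matrix(1e-10, 1, 1), matrix(1, 1, 1),
                    matrix(0, 1, 1), damp = FALSE)
  cfg <- crystal_config(cbind(c(.5, .5, .5), c(.8, .5, .5)),
                        matrix(0, 3, 2), unit_cell(20, 20, 20, 90, 90, 90))
  expect_error(ewald_sum(cfg, one_site, qp, charges = matrix(c(1, 1), 1, 2)),
               "neutral")
})

test_that("total energy assembles components and full analytic gradients", {
  set.seed(74)
  cfg <- random_start(4, seed = 21, ref = ref_benzene)
  eg <- total_energy(cfg, ref_benzene, params_benzene, settings_fast)
  expect_equal(sum(eg$components), eg$energy, tolerance = 1e-10)

  # zeroed charges: total reduces to short-range + penalty
  ref0 <- benzene_geometry(q_h = 0)
  e0 <- total_energy(cfg, ref0, params_benzene, settings_fast)
  es <- short_range_sum(cfg, ref0, params_benzene, settings_fast)
  wp <- wca_cell_penalty(cfg$cell, settings_fast$eps_P, settings_fast$sigma_P)
  expect_equal(e0$energy, es$energy + wp$energy, tolerance = 1e-10)

  # lattice translation invariance
  shift <- runif(3)
  cfg_t <- crystal_config(cfg$com + shift, cfg$p, cfg$cell)
  et <- total_energy(cfg_t, ref_benzene, params_benzene, settings_fast,
                     gradients = FALSE)
  expect_equal(et$energy, eg$energy, tolerance = 1e-10 * abs(eg$energy))

  # all 6N+6 gradient components vs central finite differences
  g_an <- packed_gradient(eg)
  for (i in seq_along(g_an)) {
    fd <- fd_energy_component(cfg, i, 1e-5, ref_benzene, params_benzene,
                              settings_fast)
    expect_equal(g_an[i], fd, tolerance = 1e-5 * max(1e-2, abs(fd)))
  }

  # Newton's third law at fixed cell: absolute COM forces sum to zero
  # (reciprocal-space part included via the fractional relation)
  H <- cell_matrix(cfg$cell)
  gabs <- solve(t(H), eg$grad_com)
  expect_lt(max(abs(rowSums(gabs))), 1e-9)
})
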