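test_that("Niggli reduction is canonical, idempotent and basis-independent", {
  cub <- unit_cell(5, 5, 5, 90, 90, 90)
  expect_equal(cell_parameters(reduce_cell(cub)), cell_parameters(cub))

  # axis permutation reduces to the same parameters
  p1 <- cell_parameters(reduce_cell(unit_cell(7, 5, 6, 90, 90, 90)))
  p2 <- cell_parameters(reduce_cell(unit_cell(5, 6, 7, 90, 90, 90)))
  expect_equal(unname(p1), unname(p2), tolerance = 1e-10)

  set.seed(101)
  for (k in 1:12) {
    cell <- random_cell()
    ref_red <- cell_parameters(reduce_cell(cell))
    H <- cell_matrix(cell)
    for (j in 1:4) {
      U <- random_unimodular()
      H2 <- H %*% U  # same lattice, re-based
      len <- sqrt(colSums(H2^2))
      ang <- c(acos(sum(H2[, 2] * H2[, 3]) / (len[2] * len[3])),
               acos(sum(H2[, 1] * H2[, 3]) / (len[1] * len[3])),
               acos(sum(H2[, 1] * H2[, 2]) / (len[1] * len[2])))
      cell2 <- unit_cell(len[1], len[2], len[3], ang[1], ang[2], ang[3],
                         degrees = FALSE)
      expect_equal(unname(cell_parameters(reduce_cell(cell2))),
                   unname(ref_red), tolerance = 1e-6)
    }
    # idempotent
    expect_equal(cell_parameters(reduce_cell(reduce_cell(cell))),
                 ref_red, tolerance = 1e-10)
    # reduced convention: a <= b <= c
    expect_true(all(diff(ref_red[1:3]) >= -1e-9))
  }
})

make_record <- function(energy_pm, cell, com = NULL, p = NULL, n = 4) {
  if (is.null(com)) com <- matrix(seq(0.05, 0.95, length.out = 3 * n), 3)
  if (is.null(p)) p <- matrix(0.1 * seq_len(3 * n), 3)
  res <- list(energy = energy_pm * n, energy_per_molecule = energy_pm,
              config = crystal_config(com, p, cell), rms_grad = 1e-7,
              converged = TRUE)
  crystalhop:::new_minimum_record(res, step = 1L)
}

test_that("same_minimum is reflexive, symmetric and origin/order independent", {
  cell <- unit_cell(7, 8, 9, 90, 95, 90)
  r1 <- make_record(-41.587, cell)
  expect_true(same_minimum(r1, r1))

  # same structure, common fractional shift and molecule reordering
  cfg <- r1$config
  perm <- c(3, 1, 4, 2)
  cfg2 <- crystal_config(cfg$com[, perm] + c(0.21, -0.4, 0.13),
                         cfg$p[, perm], cfg$cell)
  r2 <- crystalhop:::new_minimum_record(
    list(energy = r1$energy, energy_per_molecule = r1$energy_per_molecule,
         config = cfg2, rms_grad = 1e-7, converged = TRUE), 5L)
  expect_true(same_minimum(r1, r2))
  expect_true(same_minimum(r2, r1))

  # literature benzene I vs III: the energy gap alone separates them
  rI <- make_record(-41.587, unit_cell(6.868, 9.477, 7.285, 90, 90, 90))
  rIII <- make_record(-41.121, unit_cell(5.686, 11.155, 7.912, 90, 112.655, 90))
  expect_false(same_minimum(rI, rIII))
})

test_that("archive deduplication is idempotent and keeps first encounters", {
  cell <- unit_cell(7, 8, 9, 90, 95, 90)
  a <- minima_archive()
  res <- list(energy = -100, energy_per_molecule = -25,
              config = crystal_config(matrix(runif(12), 3), matrix(0, 3, 4),
                                      cell),
              rms_grad = 1e-7, converged = TRUE)
  a <- archive_add(a, res, step = 7)
  a <- archive_add(a, res, step = 12)     # same minimum again, later
  expect_equal(length(a), 1L)
  expect_equal(a$records[[1]]$first_step, 7L)
  expect_equal(a$records[[1]]$encounters, 2L)
  res2 <- res
  res2$energy_per_molecule <- -20; res2$energy <- -80
  a <- archive_add(a, res2, step = 3)
  expect_equal(length(a), 2L)

  merged <- archive_merge(a, a)
  expect_equal(length(merged), length(a))
})

test_that("molecular volume and energy windows behave as documented", {
  expect_equal(molecular_volume(unit_cell(10, 10, 10, 90, 90, 90), 4), 250)
  # arithmetic on the reported orthorhombic N = 4 global-minimum cell
  expect_equal(molecular_volume(unit_cell(6.868, 9.477, 7.285, 90, 90, 90), 4),
               6.868 * 9.477 * 7.285 / 4, tolerance = 1e-12)
  expect_equal(molecular_volume(unit_cell(6.868, 9.477, 7.285, 90, 90, 90), 4),
               118.5, tolerance = 1e-3)
  expect_equal(molecular_volume(unit_cell(2 * 6.868, 9.477, 7.285, 90, 90, 90), 8),
               molecular_volume(unit_cell(6.868, 9.477, 7.285, 90, 90, 90), 4))

  refs <- benzene_reference_polymorphs()
  a <- minima_archive()
  for (i in seq_len(nrow(refs)))
    a <- archive_add(a, list(
      energy = refs$energy_per_molecule[i] * 4,
      energy_per_molecule = refs$energy_per_molecule[i],
      config = crystal_config(matrix(runif(12), 3), matrix(rnorm(12) * i, 3),
                              unit_cell(refs$a[i], refs$b[i], refs$c[i],
                                        refs$alpha[i], refs$beta[i],
                                        refs$gamma[i])),
      rms_grad = 1e-7, converged = TRUE), step = i)
  expect_equal(length(a), 5L)

  w0 <- lowest_within(a, 0)
  expect_equal(nrow(w0), 1L)
  expect_equal(w0$energy_per_molecule, -41.587)
  # all five literature polymorphs lie within 5 kJ/mol of the global minimum
  expect_equal(nrow(lowest_within(a, 5)), 5L)
  expect_true(all(diff(lowest_within(a, 5)$energy_per_molecule) >= 0))
  sizes <- vapply(c(0, 0.3, 0.5, 1.3, 1.5, 5),
                  function(w) nrow(lowest_within(a, w)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(lowest_within(minima_archive(), 5), "empty")
})

test_that("the five reference polymorph labels are mutually exclusive", {
  refs <- benzene_reference_polymorphs()
  for (i in seq_len(nrow(refs))) {
    rec <- make_record(refs$energy_per_molecule[i],
                       unit_cell(refs$a[i], refs$b[i], refs$c[i],
                                 refs$alpha[i], refs$beta[i], refs$gamma[i]))
    for (j in seq_len(nrow(refs))) {
      if (i == j) next
      expect_false(crystalhop:::matches_label(rec, refs[j, ]))
    }
    expect_true(crystalhop:::matches_label(rec, refs[i, ]))
  }
})

test_that("orientation angle sets support the Z determination", {
  cell <- unit_cell(8, 8, 8, 90, 90, 90)
  # all molecules parallel: every pairwise angle is zero
  par_cfg <- crystal_config(matrix(runif(12), 3),
                            matrix(c(.3, .1, .2), 3, 4), cell)
  expect_lt(max(orientation_angle_set(par_cfg)), 1e-4)
  expect_equal(distinct_orientations(par_cfg), 1L)

  # four distinct tilts: six nonzero pairwise angles, Z-consistent count
  tilts <- cbind(c(.5, .5, 0), c(-.5, .5, 0), c(.5, -.5, 0), c(-.5, -.5, 0))
  cfg4 <- crystal_config(matrix(runif(12), 3), tilts, cell)
  angs <- orientation_angle_set(cfg4)
  expect_length(angs, 6L)
  expect_true(all(angs[angs > 1] > 10))
  expect_equal(distinct_orientations(cfg4), 4L)

  # invariant under a global rotation of all molecules
  g <- rotation_matrix(c(0.3, -1.1, 0.7))
  p_rot <- vapply(1:4, function(m) aa_of(g %*% rotation_matrix(tilts[, m])),
                  numeric(3))
  cfg_rot <- crystal_config(cfg4$com, p_rot, cell)
  expect_equal(orientation_angle_set(cfg_rot), angs, tolerance = 1e-9)
})

test_that("MFET averages first encounters and reports censoring", {
  cell <- unit_cell(7, 8, 9, 90, 95, 90)
  rec <- make_record(-41.587, cell)
  fake_run <- function(first_step) {
    r <- rec; r$first_step <- first_step
    structure(list(archive = structure(list(records = list(r)),
                                       class = "minima_archive")),
              class = "bh_run")
  }
  lbl <- rec
  m1 <- mfet(list(fake_run(9)), lbl)
  expect_equal(m1$mean, 9)
  m2 <- mfet(list(fake_run(10), fake_run(20)), lbl)
  expect_equal(m2$mean, 15)
  expect_equal(m2$n_censored, 0)

  other <- make_record(-20, unit_cell(11, 12, 13, 90, 90, 90))
  m3 <- mfet(list(fake_run(10)), other)
  expect_true(is.na(m3$mean))
  expect_equal(m3$n_censored, 1)
})
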