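# Shared fixtures and independent oracles. Everything is generated in code;
# the heavier shared objects are built once per test run.

ref_benzene <- benzene_geometry()
params_benzene <- benzene_params_synthetic()
settings_fast <- energy_settings(r_c = 8)

# small-cell settings for brute-force comparisons
settings_tiny <- energy_settings(r_c = 6)

# a random triclinic cell that is comfortably non-degenerate
random_cell <- function() {
  repeat {
    len <- runif(3, 5, 12)
    ang <- runif(3, 60, 120)
    cell <- tryCatch(unit_cell(len[1], len[2], len[3], ang[1], ang[2], ang[3]),
                     error = function(e) NULL)
    if (!is.null(cell) && cell_volume(cell)$P > 0.35) return(cell)
  }
}

# central finite difference of the total energy along one packed coordinate
fd_energy_component <- function(config, i, h, ref, params, settings) {
  x <- pack_config(config)
  n <- config$n_mol
  e_at <- function(xv) total_energy(unpack_config(xv, n), ref, params,
                                    settings, gradients = FALSE)$energy
  xp <- x; xp[i] <- xp[i] + h
  xm <- x; xm[i] <- xm[i] - h
  (e_at(xp) - e_at(xm)) / (2 * h)
}

packed_gradient <- function(eg) {
  c(as.numeric(eg$grad_com), as.numeric(eg$grad_p), eg$grad_cell)
}

# rock-salt toy lattice: 4 rigid Na-Cl pairs per cubic cell, so the system
# is charge-neutral molecule by molecule. The intramolecular Na-Cl
# interaction is excluded by the rigid-body convention.
rocksalt_fixture <- function(a = 5.64) {
  ion_pair <- reference_geometry(
    sites = cbind(c(-a / 4, 0, 0), c(a / 4, 0, 0)),
    elements = c("Na", "Cl"), charges = c(1, -1), bonds = cbind(1, 2))
  toy_params <- pair_params(c("Na", "Cl"), A = matrix(1e-10, 2, 2),
                            B = matrix(1, 2, 2), C6 = matrix(0, 2, 2),
                            damp = FALSE)
  na_frac <- cbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5))
  config <- crystal_config(na_frac + c(0.25, 0, 0), matrix(0, 3, 4),
                           unit_cell(a, a, a, 90, 90, 90))
  list(ref = ion_pair, params = toy_params, config = config, a = a)
}

# brute-force damped direct Coulomb sum over an explicit image block,
# excluding intramolecular same-image pairs. At finite damping mu the
# erfc-damped pair sum must carry its analytic self and intramolecular
# correction terms (an exact identity for any mu); mu is chosen small
# enough that the reciprocal-space remainder is below 1e-12, so no
# reciprocal sum appears anywhere in this oracle.
direct_coulomb_sum <- function(config, ref, mu = 0.1, n_images = 10) {
  ke <- 1389.35457644382
  H <- cell_matrix(config$cell)
  xs <- expand_sites(config, ref)
  mol <- attr(xs, "molecule")
  q <- rep(ref$charges, config$n_mol)
  shifts <- as.matrix(expand.grid(-n_images:n_images, -n_images:n_images,
                                  -n_images:n_images))
  total <- 0
  for (k in seq_len(nrow(shifts))) {
    off <- drop(H %*% shifts[k, ])
    home <- all(shifts[k, ] == 0)
    for (i in seq_len(ncol(xs))) {
      d2 <- colSums((xs + off - xs[, i])^2)
      qq <- q[i] * q
      skip <- if (home) mol == mol[i] else rep(FALSE, ncol(xs))
      ok <- !skip & d2 > 1e-12
      r <- sqrt(d2[ok])
      total <- total + sum(ke * qq[ok] * erfc_r(mu * r) / r)
    }
  }
  total <- total / 2
  # finite-damping corrections (see note above)
  total <- total - ke * mu / sqrt(pi) * sum(q^2)
  S <- ncol(ref$sites)
  for (m in seq_len(config$n_mol))
    for (i in seq_len(S - 1))
      for (j in (i + 1):S) {
        r0 <- sqrt(sum((ref$sites[, j] - ref$sites[, i])^2))
        total <- total - ke * ref$charges[i] * ref$charges[j] *
          (1 - erfc_r(mu * r0)) / r0
      }
  total
}

erfc_r <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)

random_rotation_matrix_test <- function() {
  rotation_matrix(rnorm(3) / sqrt(3) * runif(1, 0.2, 2.8))
}

aa_of <- function(R) crystalhop:::aa_from_matrix(R)

# random unimodular (det +1) integer matrix built from shear generators
random_unimodular <- function(n_ops = 6) {
  U <- diag(3)
  for (k in seq_len(n_ops)) {
    i <- sample(3, 1); j <- sample(setdiff(1:3, i), 1)
    S <- diag(3)
    S[i, j] <- sample(c(-2, -1, 1, 2), 1)
    U <- U %*% S
  }
  U
}

# benzene-I-like orthorhombic herringbone start: four molecules on the
# face-centered positions of the experimental Pbca cell with paired tilted
# orientations. A synthetic stand-in start (not an experimental structure);
# minimization relaxes it to the nearest minimum of the model in use.
benzene_I_like_start <- function() {
  cell <- unit_cell(6.92, 9.55, 7.44, 90, 90, 90)
  com <- cbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5))
  tilt <- 0.55
  p <- cbind(c(tilt, tilt, 0), c(-tilt, tilt, 0),
             c(tilt, -tilt, 0), c(-tilt, -tilt, 0))
  crystal_config(com, p, cell)
}

# cached minimized benzene-I-like record shared by the acceptance tests
minimized_benzene_I_like <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- minimize_crystal(benzene_I_like_start(), ref_benzene,
                                 params_benzene, settings_fast)
    cache
  }
})
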