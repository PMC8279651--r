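#' Lattice-energy summation settings
#'
#' @param r_c site-site cutoff for the short-range model and the real-space
#'   Ewald sum (Angstrom). The cutoff is sharp (no switching function); the
#'   image limits `M = floor(2 r_c a*) + 1` guarantee that all pairs within
#'   `r_c` are found.
#' @param alpha Ewald splitting parameter (1/Angstrom); `NULL` selects
#'   `5.6 / r_c`, which makes the real-space tail negligible at the cutoff
#' @param k_cutoff reciprocal-space cutoff (1/Angstrom); `NULL` derives it
#'   from `k_eps`
#' @param k_eps target truncation factor `exp(-k^2/(4 alpha^2))` at the
#'   reciprocal cutoff
#' @param eps_P,sigma_P WCA cell-penalty constants (kJ/mol, dimensionless);
#'   defaults 0.001 hartree and 0.3
#' @param shift_cutoff subtract each pair's energy at `r_c` inside the
#'   lattice sum, making the truncated energy continuous when pairs cross
#'   the cutoff (default). Without the shift the sum is discontinuous by
#'   the pair energy at `r_c` (about C6/r_c^6), which blocks tight
#'   gradient convergence whenever a minimum presses a pair against the
#'   cutoff boundary.
#' @return a list of class `energy_settings`
#' @export
energy_settings <- function(r_c = 15, alpha = NULL, k_cutoff = NULL,
                            k_eps = 1e-12, eps_P = 0.001 * 2625.4996394799,
                            sigma_P = 0.3, shift_cutoff = TRUE) {
  structure(list(r_c = r_c,
                 alpha = if (is.null(alpha)) -1 else alpha,
                 k_cutoff = if (is.null(k_cutoff)) -1 else k_cutoff,
                 k_eps = k_eps, eps_P = eps_P, sigma_P = sigma_P,
                 shift_cutoff = isTRUE(shift_cutoff)),
            class = "energy_settings")
}

# internal: call the C++ kernel
kernel_energy <- function(config, ref, params, settings, want_grad,
                          do_short = TRUE, do_elec = TRUE, do_penalty = TRUE,
                          charges = NULL) {
  st <- unclass(settings)
  st$do_short <- do_short; st$do_elec <- do_elec; st$do_penalty <- do_penalty
  if (is.null(charges))
    charges <- matrix(ref$charges, ncol(ref$sites), config$n_mol)
  if (do_elec && abs(sum(charges)) > 1e-9)
    stop("Ewald summation requires a charge-neutral cell (net charge ",
         signif(sum(charges), 3), " e)")
  kp <- params_for_kernel(params, ref)
  out <- .cpp_energy(config$com, config$p, config$cell$par, ref$sites,
                     charges, ref$types, kp, st, want_grad)
  out$energy_per_molecule <- out$energy / config$n_mol
  out$n_mol <- config$n_mol
  class(out) <- "energy_gradient"
  out
}

#' @export
print.energy_gradient <- function(x, ...) {
  cat(sprintf("lattice energy: %.6f kJ/mol (%.6f kJ/mol per molecule)\n",
              x$energy, x$energy_per_molecule))
  comp <- x$components
  for (nm in names(comp))
    if (comp[[nm]] != 0) cat(sprintf("  %-12s %14.6f\n", nm, comp[[nm]]))
  invisible(x)
}

#' Total lattice energy and gradients
#'
#' Assembles the full lattice energy of a configuration: short-range
#' site-site model summed over periodic images within the cutoff, Ewald
#' electrostatics (real, reciprocal, self and rigid intramolecular exclusion
#' terms), and the WCA cell penalty. Gradients are analytic with respect to
#' the fractional COMs, the angle-axis vectors, and the six cell parameters
#' (angle derivatives per radian); component energies sum to the total.
#'
#' @param config a [crystal_config()]
#' @param ref a [reference_geometry()]
#' @param params a [pair_params()] table
#' @param settings an [energy_settings()] list
#' @param gradients compute gradients (default) or energy only
#' @return an `energy_gradient` object: `energy`, `energy_per_molecule`,
#'   named `components` vector, `grad_com` (3 x N), `grad_p` (3 x N),
#'   `grad_cell` (length 6)
#' @export
total_energy <- function(config, ref, params, settings = energy_settings(),
                         gradients = TRUE) {
  kernel_energy(config, ref, params, settings, gradients)
}

#' Short-range lattice sum (model term only)
#'
#' The non-electrostatic site-site model summed over periodic images with
#' the image-limit rule; excludes intramolecular same-image pairs, includes
#' each molecule's interaction with its own periodic images.
#'
#' @inheritParams total_energy
#' @return an `energy_gradient` object
#' @export
short_range_sum <- function(config, ref, params, settings = energy_settings(),
                            gradients = TRUE) {
  kernel_energy(config, ref, params, settings, gradients,
                do_elec = FALSE, do_penalty = FALSE)
}

#' Ewald electrostatic lattice sum
#'
#' Point-charge electrostatics of the periodic system by Ewald summation:
#' real-space (erfc-damped, cut at `r_c`), reciprocal-space, self, and
#' rigid-body intramolecular exclusion terms. Requires a charge-neutral
#' cell. The total is independent of the splitting parameter `alpha` over a
#' wide range (a standard consistency check).
#'
#' @inheritParams total_energy
#' @param charges optional S x N matrix of per-molecule site charges,
#'   overriding the reference geometry charges (used for charged toy
#'   lattices)
#' @return an `energy_gradient` object
#' @export
ewald_sum <- function(config, ref, params, settings = energy_settings(),
                      gradients = TRUE, charges = NULL) {
  kernel_energy(config, ref, params, settings, gradients,
                do_short = FALSE, do_penalty = FALSE, charges = charges)
}

#' Transform an absolute COM gradient to fractional coordinates
#'
#' Chain rule through `X = H Xbar`: `dU/dXbar = t(H) %*% dU/dX`.
#'
#' @param grad_abs 3-vector or 3 x N matrix of absolute COM gradients
#' @param H cell matrix
#' @return gradient with respect to fractional COMs, same shape
#' @export
com_gradient_to_fractional <- function(grad_abs, H) {
  if (is.matrix(grad_abs)) t(H) %*% grad_abs else drop(t(H) %*% grad_abs)
}

#' Angle-axis gradient from site gradients
#'
#' `dU/dp_k = sum_i dU/dx_i . (dR/dp_k x_i^0)` for one rigid body.
#'
#' @param site_grads 3 x S matrix of dU/dx for the sites of one molecule
#' @param p angle-axis vector of the molecule
#' @param ref_sites 3 x S body-frame site positions
#' @return length-3 gradient dU/dp
#' @export
aa_gradient <- function(site_grads, p, ref_sites) {
  rd <- rotation_matrix(p, derivatives = TRUE)
  vapply(1:3, function(k) sum(site_grads * (rd$dR[[k]] %*% ref_sites)),
         numeric(1))
}

#' Single site-site model interaction
#'
#' Evaluates one orientation-dependent site-site term of the short-range
#' model together with its derivatives; mainly useful for inspecting the
#' potential and for testing. Electrostatics are not included.
#'
#' @param r_ij separation vector from site i to site j (Angstrom)
#' @param z_i,z_j unit plane normals of the two parent molecules
#' @param params a [pair_params()] table
#' @param pair character length-2, the element pair, e.g. `c("C", "H")`
#' @return list with `energy` (kJ/mol), `dUdd` (derivative w.r.t. `r_ij`),
#'   `dUdzi`, `dUdzj` (derivatives w.r.t. the normals)
#' @export
site_pair_energy <- function(r_ij, z_i, z_j, params, pair) {
  i <- match(pair[1], params$types); j <- match(pair[2], params$types)
  if (is.na(i) || is.na(j))
    stop("no parameters for element pair ", paste(pair, collapse = "-"))
  .cpp_pair_eval(as.numeric(r_ij), as.numeric(z_i), as.numeric(z_j),
                 params$A[i, j], params$B[i, j], params$C6[i, j],
                 params$d1[i], params$d1[j], params$damp)
}

#' Isotropic exp-6 pair interaction
#'
#' The orientation-independent limit of the site-site model (all `d1 = 0`):
#' `U = A exp(-B r) - f6(B r) C6 / r^6`. Serves as a simple fallback model
#' with the same contract; its orientation derivatives are identically zero.
#'
#' @param r separation (Angstrom), scalar or vector
#' @param A,B,C6 exp-6 parameters
#' @param damp apply Tang-Toennies order-6 damping
#' @return list with `energy` and `dUdr`
#' @export
exp6_pair_energy <- function(r, A, B, C6, damp = TRUE) {
  f6 <- rep(1, length(r)); df6 <- rep(0, length(r))
  if (damp) {
    x <- B * r
    s <- rep(0, length(r)); term <- rep(1, length(r))
    for (k in 0:6) {
      if (k > 0) term <- term * x / k
      s <- s + term
    }
    f6 <- 1 - exp(-x) * s
    df6 <- exp(-x) * term  # x^6/720
  }
  U <- A * exp(-B * r) - f6 * C6 / r^6
  dU <- -B * A * exp(-B * r) - df6 * B * C6 / r^6 + 6 * f6 * C6 / r^7
  list(energy = U, dUdr = dU)
}
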