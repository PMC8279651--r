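#' Local minimization control parameters
#'
#' @param memory LBFGS history length
#' @param maxit iteration cap; hitting it yields an unconverged result
#' @param rms_tol convergence threshold on the root-mean-square of the raw
#'   6N+6 gradient vector, in kJ/mol/Angstrom (the fractional, angular and
#'   cell components are mixed into one scalar criterion as printed)
#' @param max_step cap on the norm of a single LBFGS step in the mixed
#'   variable vector
#' @param noise_tol bounded energy rise (kJ/mol) the optimizer may accept
#'   as a last resort when a descent direction points straight across a
#'   residual discontinuity of the truncated lattice sum (for example the
#'   small force kink at the shifted cutoff); ordinary steps use a strict
#'   energy-decrease test. The best-visited point is returned, so the
#'   final energy never exceeds the starting energy.
#' @return list of class `minimize_control`
#' @export
minimize_control <- function(memory = 10, maxit = 5000, rms_tol = 1.8897e-6,
                             max_step = 0.5, noise_tol = 1e-4) {
  structure(list(memory = as.integer(memory), maxit = as.integer(maxit),
                 rms_tol = rms_tol, max_step = max_step,
                 noise_tol = noise_tol),
            class = "minimize_control")
}

#' LBFGS minimization of the lattice energy
#'
#' Minimizes the total lattice energy over the joint variable vector
#' (fractional COMs, angle-axis vectors, six cell parameters) with
#' limited-memory BFGS and analytic gradients, converging when the RMS of
#' the raw gradient vector drops to `rms_tol` (default 1.8897e-6
#' kJ/mol/Angstrom). On exit COMs are wrapped into `[0, 1)` and angle-axis
#' vectors canonicalized, which leaves the energy unchanged.
#'
#' @param config starting [crystal_config()]
#' @param ref a [reference_geometry()]
#' @param params a [pair_params()] table
#' @param settings an [energy_settings()] list
#' @param control a [minimize_control()] list
#' @return an object of class `minimization_result`: `config`, `energy`,
#'   `energy_per_molecule`, `rms_grad`, `iterations`, `n_eval`, `converged`
#' @export
minimize_crystal <- function(config, ref, params,
                             settings = energy_settings(),
                             control = minimize_control()) {
  stopifnot(inherits(config, "crystal_config"))
  st <- unclass(settings)
  st$do_short <- TRUE; st$do_elec <- TRUE; st$do_penalty <- TRUE
  charges <- matrix(ref$charges, ncol(ref$sites), config$n_mol)
  if (abs(sum(charges)) > 1e-9)
    stop("minimization requires a charge-neutral cell")
  kp <- params_for_kernel(params, ref)
  out <- .cpp_minimize_crystal(config$com, config$p, config$cell$par,
                               ref$sites, charges, ref$types, kp, st,
                               control$memory, control$maxit,
                               control$rms_tol, control$max_step,
                               control$noise_tol)
  cfg <- canonicalize_config(
    crystal_config(out$com, out$p, new_cell_from_par(out$cellpar)))
  structure(list(config = cfg, energy = out$energy,
                 energy_per_molecule = out$energy / config$n_mol,
                 rms_grad = out$rms_grad, iterations = out$iterations,
                 n_eval = out$n_eval, converged = out$converged),
            class = "minimization_result")
}

#' @export
print.minimization_result <- function(x, ...) {
  cat(sprintf(
    "%s after %d LBFGS iterations (%d evaluations)\n",
    if (x$converged) "converged" else "NOT converged", x$iterations, x$n_eval))
  cat(sprintf("energy %.6f kJ/mol (%.6f per molecule), RMS gradient %.3e\n",
              x$energy, x$energy_per_molecule, x$rms_grad))
  invisible(x)
}

#' Generic LBFGS driver
#'
#' The same optimizer used for the crystal landscape, applied to an
#' arbitrary objective; used to validate the optimizer against functions
#' with known stationary points.
#'
#' @param fgr function of `x` returning `list(f = , g = )`
#' @param x0 numeric start vector
#' @param control a [minimize_control()]
#' @return list with `x`, `f`, `rms_grad`, `iterations`, `n_eval`,
#'   `converged`
#' @export
lbfgs_minimize <- function(fgr, x0, control = minimize_control()) {
  .cpp_lbfgs_generic(fgr, as.numeric(x0), control$memory, control$maxit,
                     control$rms_tol, control$max_step, control$noise_tol)
}
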