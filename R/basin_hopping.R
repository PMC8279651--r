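#' Basin-hopping run parameters
#'
#' Step sizes follow the molecular-crystal protocol: every molecule is
#' translated by up to 0.159 Angstrom (in absolute space, converted to
#' fractional through the current cell) and rotated by up to 0.3 radians
#' about a random axis at every step; with every third step the cell lengths
#' and angles additionally change by up to 0.159 Angstrom and 0.1 radians.
#' The fictitious Metropolis temperature adapts to hold the acceptance ratio
#' near `target_acceptance`.
#'
#' @param steps number of basin-hopping steps
#' @param max_translation maximum molecular displacement per step (Angstrom)
#' @param max_rotation maximum rotation angle per step (radians)
#' @param cell_period perturb the cell every `cell_period`-th step
#' @param max_cell_length_step,max_cell_angle_step cell perturbation bounds
#'   (Angstrom, radians)
#' @param target_acceptance acceptance ratio the temperature adaptation
#'   steers toward
#' @param temperature initial fictitious temperature (kJ/mol)
#' @param adapt_interval adapt the temperature every this many steps
#' @param adapt_factor multiplicative temperature update factor
#' @return list of class `bh_config`
#' @export
bh_config <- function(steps = 100, max_translation = 0.159,
                      max_rotation = 0.3, cell_period = 3,
                      max_cell_length_step = 0.159,
                      max_cell_angle_step = 0.1, target_acceptance = 0.5,
                      temperature = 1.0, adapt_interval = 50,
                      adapt_factor = 1.05) {
  stopifnot(steps >= 1, max_translation >= 0, max_rotation >= 0,
            cell_period >= 1, temperature > 0, adapt_factor > 1)
  structure(as.list(environment()), class = "bh_config")
}

#' Random structural perturbation
#'
#' Applies one basin-hopping move to a configuration: every molecule gets an
#' independent random translation (uniform in the ball of radius
#' `max_translation` in absolute space, converted to fractional) and an
#' independent random rotation (uniform axis, angle uniform up to
#' `max_rotation`). When `step_index` is a multiple of `cell_period` the six
#' cell parameters are additionally perturbed, each length by up to
#' `max_cell_length_step` and each angle by up to `max_cell_angle_step`;
#' degenerate proposals are resampled.
#'
#' Uses R's global RNG stream, so runs seeded with `set.seed()` are
#' reproducible.
#'
#' @param config a [crystal_config()]
#' @param step_index current basin-hopping step (1-based)
#' @param bh a [bh_config()]
#' @return the proposed [crystal_config()]
#' @export
perturb_config <- function(config, step_index, bh = bh_config()) {
  H <- cell_matrix(config$cell)
  Hinv <- solve(H)
  com <- config$com
  p <- config$p
  n <- config$n_mol
  for (m in seq_len(n)) {
    # uniform in the ball: direction uniform, radius ~ R * U^(1/3)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    dr <- u * bh$max_translation * runif(1)^(1 / 3)
    com[, m] <- com[, m] + drop(Hinv %*% dr)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0, bh$max_rotation)
    p[, m] <- aa_compose(ax * ang, p[, m])
  }
  cell <- config$cell
  if (step_index %% bh$cell_period == 0) {
    for (try in 1:100) {
      par <- config$cell$par +
        c(runif(3, -1, 1) * bh$max_cell_length_step,
          runif(3, -1, 1) * bh$max_cell_angle_step)
      cand <- tryCatch(new_cell_from_par(par), error = function(e) NULL)
      if (!is.null(cand)) { cell <- cand; break }
    }
  }
  crystal_config(com, p, cell)
}

#' Metropolis acceptance on minimized energies
#'
#' Accepts downhill moves always and uphill moves with probability
#' `exp(-(e_new - e_prev) / temperature)`.
#'
#' @param e_new,e_prev minimized energies of the proposed and current
#'   structures (kJ/mol)
#' @param temperature fictitious temperature (kJ/mol), positive
#' @return logical
#' @export
metropolis_accept <- function(e_new, e_prev, temperature) {
  stopifnot(temperature > 0)
  if (e_new <= e_prev) return(TRUE)
  runif(1) < exp(-(e_new - e_prev) / temperature)
}

#' Adaptive temperature update
#'
#' Multiplicative update steering the acceptance ratio toward the target:
#' the temperature is divided by `factor` when the recent acceptance ratio
#' exceeds the target and multiplied by `factor` when it falls below.
#'
#' @param ratio recent acceptance ratio in `[0, 1]`
#' @param temperature current temperature
#' @param target target acceptance ratio
#' @param factor multiplicative update (> 1)
#' @return updated temperature
#' @export
adapt_temperature <- function(ratio, temperature, target = 0.5,
                              factor = 1.05) {
  stopifnot(ratio >= 0, ratio <= 1, factor > 1)
  if (ratio > target) temperature / factor
  else if (ratio < target) temperature * factor
  else temperature
}

#' Basin-hopping global optimization
#'
#' Runs the basin-hopping loop: perturb, LBFGS-minimize, Metropolis-accept
#' on the minimized energies. Accepted minima become the reference for the
#' next step; every distinct converged minimum is archived together with
#' the step at which it was first encountered. Unconverged minimizations
#' are logged and count as rejections; they never enter the archive. For a
#' fixed seed the trace and archive are reproducible.
#'
#' @param start starting [crystal_config()] (e.g. from [random_start()]);
#'   it is minimized before the loop starts
#' @param ref a [reference_geometry()]
#' @param params a [pair_params()] table
#' @param settings an [energy_settings()] list
#' @param bh a [bh_config()]
#' @param seed integer seed for the perturbation/acceptance stream
#' @param control a [minimize_control()]
#' @param match_tol tolerances for archive deduplication, see
#'   [match_tolerances()]
#' @param verbose print a one-line record per step
#' @return an object of class `bh_run`: `trace` (one row per step: proposed
#'   minimized energy, acceptance, temperature, archived minimum id),
#'   `archive` (a [minima_archive()]), `start_energy`, `seed`, `bh`
#' @export
run_basin_hopping <- function(start, ref, params,
                              settings = energy_settings(),
                              bh = bh_config(), seed = 1,
                              control = minimize_control(),
                              match_tol = match_tolerances(),
                              verbose = FALSE) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  cur <- minimize_crystal(start, ref, params, settings, control)
  if (!cur$converged)
    warning("starting configuration did not converge; continuing from it anyway")
  archive <- minima_archive()
  if (cur$converged) archive <- archive_add(archive, cur, step = 0, tol = match_tol)
  temperature <- bh$temperature
  accept_window <- logical(0)
  trace <- data.frame(step = integer(bh$steps), energy = numeric(bh$steps),
                      energy_per_molecule = numeric(bh$steps),
                      accepted = logical(bh$steps),
                      converged = logical(bh$steps),
                      temperature = numeric(bh$steps),
                      minimum_id = integer(bh$steps))
  for (k in seq_len(bh$steps)) {
    prop <- perturb_config(cur$config, k, bh)
    res <- minimize_crystal(prop, ref, params, settings, control)
    accepted <- FALSE
    min_id <- NA_integer_
    if (res$converged) {
      archive <- archive_add(archive, res, step = k, tol = match_tol)
      min_id <- attr(archive, "last_id")
      accepted <- metropolis_accept(res$energy, cur$energy, temperature)
    }
    if (accepted) cur <- res
    accept_window <- c(accept_window, accepted)
    if (length(accept_window) >= bh$adapt_interval) {
      temperature <- adapt_temperature(mean(accept_window), temperature,
                                       bh$target_acceptance, bh$adapt_factor)
      accept_window <- logical(0)
    }
    trace[k, ] <- list(k, res$energy, res$energy_per_molecule, accepted,
                       res$converged, temperature, min_id)
    if (verbose)
      cat(sprintf("step %4d  E/mol %12.6f  %s  T %.4f  min %s\n", k,
                  res$energy_per_molecule,
                  if (accepted) "acc" else "rej", temperature,
                  ifelse(is.na(min_id), "-", min_id)))
  }
  structure(list(trace = trace, archive = archive,
                 start_energy = cur$energy, seed = seed, bh = bh),
            class = "bh_run")
}

#' @export
print.bh_run <- function(x, ...) {
  n_acc <- sum(x$trace$accepted)
  cat(sprintf("basin-hopping run: %d steps, %d accepted (ratio %.2f), seed %d\n",
              nrow(x$trace), n_acc, n_acc / nrow(x$trace), x$seed))
  print(x$archive)
  invisible(x)
}
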