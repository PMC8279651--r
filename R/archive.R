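#' Minima archive
#'
#' Container for deduplicated local minima found during basin-hopping (or by
#' direct minimization). Each record stores the energy per molecule, the
#' configuration, its Niggli-reduced cell, a sorted intermolecular
#' COM-distance fingerprint, the step at which the minimum was first
#' encountered, and an encounter count.
#'
#' @return an empty archive of class `minima_archive`
#' @export
minima_archive <- function() {
  structure(list(records = list()), class = "minima_archive")
}

#' @export
print.minima_archive <- function(x, ...) {
  cat(sprintf("minima archive: %d distinct minima\n", length(x$records)))
  if (length(x$records)) {
    idx <- archive_index(x)
    print(idx[order(idx$energy_per_molecule), ], row.names = FALSE, digits = 6)
  }
  invisible(x)
}

#' @export
length.minima_archive <- function(x) length(x$records)

#' Matching tolerances for minima comparison
#'
#' Two minima are considered the same when all three criteria hold: energy
#' per molecule within `energy` kJ/mol, Niggli-reduced cell parameters
#' within `length` Angstrom and `angle` degrees, and RMS difference of the
#' sorted minimum-image COM-distance fingerprints below `fingerprint`
#' Angstrom.
#'
#' @param energy energy window, kJ/mol per molecule
#' @param length reduced-cell length tolerance, Angstrom
#' @param angle reduced-cell angle tolerance, degrees
#' @param fingerprint COM-distance fingerprint RMS tolerance, Angstrom
#' @return list of class `match_tolerances`
#' @export
match_tolerances <- function(energy = 0.01, length = 0.1, angle = 1,
                             fingerprint = 0.1) {
  structure(list(energy = energy, length = length, angle = angle,
                 fingerprint = fingerprint), class = "match_tolerances")
}

# sorted minimum-image intermolecular COM distances (includes, for each
# pair, the nearest periodic image only); molecule-order and origin
# independent
com_fingerprint <- function(config) {
  n <- config$n_mol
  if (n < 2) return(numeric(0))
  H <- cell_matrix(config$cell)
  shifts <- t(as.matrix(expand.grid(-1:1, -1:1, -1:1)))
  out <- numeric(0)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      df <- config$com[, j] - config$com[, i]
      df <- df - round(df)
      d <- H %*% (df + shifts)
      out <- c(out, sqrt(min(colSums(d^2))))
    }
  sort(out)
}

# build an archive record from a minimization result
new_minimum_record <- function(res, step) {
  structure(list(energy = res$energy,
                 energy_per_molecule = res$energy_per_molecule,
                 config = res$config,
                 reduced_cell = reduce_cell(res$config$cell),
                 fingerprint = com_fingerprint(res$config),
                 rms_grad = res$rms_grad,
                 first_step = step, encounters = 1L),
            class = "minimum_record")
}

#' Compare two minima
#'
#' Reflexive and symmetric structure comparison using the criteria of
#' [match_tolerances()]. Structures re-expressed with shifted origins,
#' re-based lattice vectors or permuted molecules compare equal.
#'
#' @param m1,m2 `minimum_record` objects (from an archive)
#' @param tol a [match_tolerances()] list
#' @return logical
#' @export
same_minimum <- function(m1, m2, tol = match_tolerances()) {
  if (abs(m1$energy_per_molecule - m2$energy_per_molecule) > tol$energy)
    return(FALSE)
  p1 <- cell_parameters(m1$reduced_cell)
  p2 <- cell_parameters(m2$reduced_cell)
  if (any(abs(p1[1:3] - p2[1:3]) > tol$length)) return(FALSE)
  if (any(abs(p1[4:6] - p2[4:6]) > tol$angle)) return(FALSE)
  f1 <- m1$fingerprint; f2 <- m2$fingerprint
  if (length(f1) != length(f2)) return(FALSE)
  if (length(f1) && sqrt(mean((f1 - f2)^2)) > tol$fingerprint) return(FALSE)
  TRUE
}

#' Add a minimization result to an archive
#'
#' Matches the result against the stored records; on a match the encounter
#' count is incremented (the earliest first-encounter step and the
#' lowest-energy representative are kept), otherwise a new record is
#' appended. The id of the matched/added record is returned in the
#' attribute `last_id`.
#'
#' @param archive a [minima_archive()]
#' @param res a converged `minimization_result`
#' @param step basin-hopping step at which the minimum was produced
#' @param tol a [match_tolerances()] list
#' @return the updated archive
#' @export
archive_add <- function(archive, res, step = NA_integer_,
                        tol = match_tolerances()) {
  if (!isTRUE(res$converged))
    stop("only converged minimization results may enter the archive")
  rec <- new_minimum_record(res, step)
  for (i in seq_along(archive$records)) {
    if (same_minimum(archive$records[[i]], rec, tol)) {
      old <- archive$records[[i]]
      old$encounters <- old$encounters + 1L
      if (!is.na(step) && (is.na(old$first_step) || step < old$first_step))
        old$first_step <- step
      if (rec$energy_per_molecule < old$energy_per_molecule) {
        keep <- old[c("first_step", "encounters")]
        rec[names(keep)] <- keep
        old <- rec
      }
      archive$records[[i]] <- old
      attr(archive, "last_id") <- i
      return(archive)
    }
  }
  archive$records[[length(archive$records) + 1]] <- rec
  attr(archive, "last_id") <- length(archive$records)
  archive
}

#' Merge archives
#'
#' Deduplicating union; idempotent (`archive_merge(a, a)` has the same
#' records as `a`).
#'
#' @param a,b archives
#' @param tol a [match_tolerances()] list
#' @return merged archive
#' @export
archive_merge <- function(a, b, tol = match_tolerances()) {
  for (rec in b$records) {
    fake <- list(energy = rec$energy,
                 energy_per_molecule = rec$energy_per_molecule,
                 config = rec$config, rms_grad = rec$rms_grad,
                 converged = TRUE)
    a <- archive_add(a, fake, step = rec$first_step, tol = tol)
  }
  a
}

#' Tabular archive index
#'
#' @param archive a [minima_archive()]
#' @return data.frame with one row per distinct minimum: id, energy per
#'   molecule, Niggli-reduced cell parameters, molecular volume, first
#'   encounter step and encounter count
#' @export
archive_index <- function(archive) {
  recs <- archive$records
  if (!length(recs))
    return(data.frame(id = integer(0), energy_per_molecule = numeric(0)))
  do.call(rbind, lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    p <- cell_parameters(r$reduced_cell)
    data.frame(id = i, energy_per_molecule = r$energy_per_molecule,
               a = p[1], b = p[2], c = p[3],
               alpha = p[4], beta = p[5], gamma = p[6],
               V_m = molecular_volume(r$config$cell, r$config$n_mol),
               first_step = r$first_step, encounters = r$encounters,
               row.names = NULL)
  }))
}

#' Molecular volume
#'
#' Cell volume divided by the number of molecules in the simulation cell.
#'
#' @param cell a [unit_cell()]
#' @param n_mol number of molecules
#' @return molecular volume in Angstrom^3
#' @export
molecular_volume <- function(cell, n_mol) {
  cell_volume(cell)$V / n_mol
}

#' Minima within an energy window of the global minimum
#'
#' @param archive a non-empty [minima_archive()]
#' @param window energy window above the global minimum, kJ/mol per molecule
#' @return [archive_index()] rows sorted by energy, restricted to the window
#'   (always includes the global minimum)
#' @export
lowest_within <- function(archive, window) {
  if (!length(archive$records)) stop("archive is empty")
  idx <- archive_index(archive)
  idx <- idx[order(idx$energy_per_molecule), ]
  idx[idx$energy_per_molecule <= idx$energy_per_molecule[1] + window, ]
}

#' Intermolecular orientation angles
#'
#' Pairwise angles between the molecular plane normals of all molecules in
#' the cell, folded into `[0, 90]` degrees (the normal is a two-fold
#' ambiguous axis for a planar molecule). The number of distinct values
#' supports the determination of the number of symmetry-independent
#' orientations, hence of Z.
#'
#' @param config a [crystal_config()]
#' @return sorted numeric vector of `choose(N, 2)` angles in degrees
#' @export
orientation_angle_set <- function(config) {
  n <- config$n_mol
  stopifnot(n >= 2)
  normals <- vapply(seq_len(n),
                    function(m) rotation_matrix(config$p[, m])[, 3],
                    numeric(3))
  out <- numeric(0)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      out <- c(out, acos(pmin(1, abs(sum(normals[, i] * normals[, j])))) * 180 / pi)
  sort(out)
}

#' Count distinct molecular orientations
#'
#' @param config a [crystal_config()]
#' @param tol_deg two orientations closer than this angle (normals compared
#'   up to sign) count as equal
#' @return number of distinct orientations among the N molecules
#' @export
distinct_orientations <- function(config, tol_deg = 2) {
  n <- config$n_mol
  normals <- vapply(seq_len(n),
                    function(m) rotation_matrix(config$p[, m])[, 3],
                    numeric(3))
  groups <- integer(0)
  reps <- list()
  for (m in seq_len(n)) {
    hit <- FALSE
    for (g in seq_along(reps)) {
      ang <- acos(pmin(1, abs(sum(reps[[g]] * normals[, m])))) * 180 / pi
      if (ang < tol_deg) { hit <- TRUE; break }
    }
    if (!hit) reps[[length(reps) + 1]] <- normals[, m]
  }
  length(reps)
}

#' Reference benzene polymorphs located by basin-hopping
#'
#' The five low-energy benzene polymorphs reported from N = 4 basin-hopping
#' with the published anisotropic benzene pair potential: energies per
#' molecule (kJ/mol), simulation-cell parameters (Angstrom/degrees; for the
#' Z = 2 monoclinic forms these describe a two-unit-cell supercell), space
#' groups, and mean first-encounter times in basin-hopping steps. These are
#' literature reference values for labeling archives; the synthetic
#' parameter set shipped with this package produces its own, different,
#' landscape.
#'
#' @return data.frame with one row per polymorph
#' @export
benzene_reference_polymorphs <- function() {
  data.frame(
    name = c("I", "III", "III'", "V", "II'"),
    Z = c(4L, 2L, 2L, 4L, 4L),
    space_group = c("Pbca", "P2_1/c", "P2_1/c", "Pbcn", "C2/c"),
    a = c(6.868, 5.686, 6.235, 5.367, 11.085),
    b = c(9.477, 11.155, 11.382, 10.241, 5.738),
    c = c(7.285, 7.912, 7.002, 8.741, 7.601),
    alpha = c(90, 90, 90, 90, 90),
    beta = c(90, 112.655, 107.922, 90, 105.001),
    gamma = c(90, 90, 90, 90, 90),
    energy_per_molecule = c(-41.587, -41.121, -41.389, -40.178, -40.337),
    mfet_steps = c(64, 14, 8, 70, 90),
    stringsAsFactors = FALSE)
}

# label: either a minimum_record or a one-row data.frame with cell
# parameters and energy_per_molecule (e.g. a row of
# benzene_reference_polymorphs)
matches_label <- function(record, label, tol = match_tolerances()) {
  if (inherits(label, "minimum_record"))
    return(same_minimum(record, label, tol))
  if (abs(record$energy_per_molecule - label$energy_per_molecule) > tol$energy)
    return(FALSE)
  ref_cell <- reduce_cell(unit_cell(label$a, label$b, label$c,
                                    label$alpha, label$beta, label$gamma))
  p1 <- cell_parameters(record$reduced_cell)
  p2 <- cell_parameters(ref_cell)
  all(abs(p1[1:3] - p2[1:3]) <= tol$length) &&
    all(abs(p1[4:6] - p2[4:6]) <= tol$angle)
}

#' Mean first-encounter time of a labeled minimum
#'
#' Over a set of independent basin-hopping runs, the mean of the step at
#' which a minimum matching `label` was first archived. Runs that never
#' encounter the label are reported as censored and excluded from the mean,
#' never silently averaged.
#'
#' @param runs list of `bh_run` objects (from [run_basin_hopping()])
#' @param label a `minimum_record`, or a one-row data.frame with cell
#'   parameters and `energy_per_molecule` (e.g. a row of
#'   [benzene_reference_polymorphs()])
#' @param tol a [match_tolerances()] list
#' @return list with `mean` (NA if never encountered), `first_steps`
#'   (per-run first-encounter step, NA when censored), `n_censored`
#' @export
mfet <- function(runs, label, tol = match_tolerances()) {
  stopifnot(length(runs) >= 1)
  first_steps <- vapply(runs, function(run) {
    hits <- vapply(run$archive$records,
                   function(r) matches_label(r, label, tol), logical(1))
    if (!any(hits)) return(NA_real_)
    min(vapply(run$archive$records[hits], function(r) as.numeric(r$first_step),
               numeric(1)))
  }, numeric(1))
  found <- !is.na(first_steps)
  list(mean = if (any(found)) mean(first_steps[found]) else NA_real_,
       first_steps = first_steps,
       n_censored = sum(!found))
}
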