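#' Run manifest
#'
#' Collects everything needed to reproduce a run bit-for-bit on the same
#' build: seed, parameter file hash, summation settings, basin-hopping
#' configuration and package version.
#'
#' @param seed integer seed of the run
#' @param params a [pair_params()] (its `md5` attribute, when present, is
#'   recorded)
#' @param settings an [energy_settings()] list
#' @param bh a [bh_config()] list, or NULL for plain minimizations
#' @param extra optional named list of additional fields
#' @return list of class `run_manifest`
#' @export
run_manifest <- function(seed, params, settings, bh = NULL, extra = NULL) {
  m <- list(package = "crystalhop",
            version = as.character(packageVersion("crystalhop")),
            r_version = R.version.string,
            seed = seed,
            params_md5 = if (!is.null(attr(params, "md5")))
              attr(params, "md5") else NA_character_,
            params_types = params$types,
            settings = unclass(settings),
            bh = if (!is.null(bh)) unclass(bh) else NULL,
            extra = extra)
  class(m) <- "run_manifest"
  m
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`
#' @param path JSON file path
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(m) <- "run_manifest"
  m
}

#' Persist a basin-hopping run
#'
#' Writes a portable plain-text container: `trace.csv` (the per-step
#' record), `archive/index.csv` plus one P1 CIF per distinct minimum, and
#' `manifest.json`.
#'
#' @param run a `bh_run` from [run_basin_hopping()]
#' @param dir output directory (created if needed)
#' @param ref the [reference_geometry()] used in the run
#' @param manifest optional [run_manifest()]
#' @return `dir`, invisibly
#' @export
save_bh_run <- function(run, dir, ref, manifest = NULL) {
  dir.create(file.path(dir, "archive"), recursive = TRUE, showWarnings = FALSE)
  write.table(run$trace, file.path(dir, "trace.csv"), sep = ",",
              row.names = FALSE, qmethod = "double")
  idx <- archive_index(run$archive)
  write.table(idx, file.path(dir, "archive", "index.csv"), sep = ",",
              row.names = FALSE, qmethod = "double")
  for (i in seq_along(run$archive$records)) {
    r <- run$archive$records[[i]]
    write_cif(r$config, ref,
              file.path(dir, "archive", sprintf("min_%03d.cif", i)),
              title = sprintf("minimum_%03d", i), energy = r$energy)
  }
  if (!is.null(manifest)) write_manifest(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Load a persisted basin-hopping run
#'
#' Rebuilds a `bh_run`-shaped object (trace plus archive) from a directory
#' written by [save_bh_run()]. Energies are re-evaluated from the stored
#' structures when `params` is supplied, otherwise taken from the index.
#'
#' @param dir directory written by [save_bh_run()]
#' @param ref the [reference_geometry()] of the run
#' @return list with `trace` and `archive`
#' @export
load_bh_run <- function(dir, ref) {
  trace <- read.table(file.path(dir, "trace.csv"), sep = ",", header = TRUE)
  idx <- read.table(file.path(dir, "archive", "index.csv"), sep = ",",
                    header = TRUE)
  archive <- minima_archive()
  for (k in seq_len(nrow(idx))) {
    cfg <- read_cif(file.path(dir, "archive", sprintf("min_%03d.cif", idx$id[k])),
                    ref)
    res <- list(energy = idx$energy_per_molecule[k] * cfg$n_mol,
                energy_per_molecule = idx$energy_per_molecule[k],
                config = cfg, rms_grad = NA_real_, converged = TRUE)
    archive <- archive_add(archive, res, step = idx$first_step[k])
    archive$records[[length(archive$records)]]$encounters <-
      as.integer(idx$encounters[k])
  }
  structure(list(trace = trace, archive = archive), class = "bh_run")
}

#' Export the seeded fixtures used by the test suite
#'
#' Writes the deterministic inputs that the examples and tests construct in
#' code: seeded random benzene starts (as P1 CIFs), the synthetic parameter
#' table, and the reference polymorph table.
#'
#' @param dir output directory
#' @param seeds seeds for the random starts
#' @param n_mol molecules per start
#' @param d_min minimum intersite distance for the exported starts; the
#'   default keeps intermolecular contacts clearly longer than bonds so the
#'   files re-import cleanly
#' @return `dir`, invisibly
#' @export
export_fixtures <- function(dir, seeds = 1:3, n_mol = 4, d_min = 2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- benzene_geometry()
  for (s in seeds) {
    cfg <- random_start(n_mol, seed = s, ref = ref, d_min = d_min,
                        vm_range = c(150, 300))
    write_cif(cfg, ref, file.path(dir, sprintf("random_start_seed%d.cif", s)),
              title = sprintf("random_start_seed%d", s))
  }
  file.copy(system.file("extdata", "benzene_params_synthetic.txt",
                        package = "crystalhop", mustWork = TRUE),
            file.path(dir, "benzene_params_synthetic.txt"), overwrite = TRUE)
  write.table(benzene_reference_polymorphs(),
              file.path(dir, "benzene_reference_polymorphs.csv"), sep = ",",
              row.names = FALSE, qmethod = "double")
  invisible(dir)
}
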