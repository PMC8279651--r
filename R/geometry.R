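#' Rigid reference geometry
#'
#' Defines a rigid molecular body: site positions in the body frame (Angstrom,
#' 3 x S matrix), elements, point charges (e) and explicit bonds. The body
#' frame origin is the rotation center used by [expand_sites()]; the
#' constructor requires the site centroid to sit at the origin.
#'
#' Connectivity is declared, not inferred: the site-site model excludes all
#' intramolecular pairs (constant for a rigid body) and the CIF reader uses
#' the bond graph to identify molecules. [infer_bonds()] exists as a helper
#' for imported coordinates but its output must be passed explicitly.
#'
#' @param sites 3 x S numeric matrix of body-frame site positions (Angstrom)
#' @param elements character vector of element symbols, length S
#' @param charges numeric point charges in units of e, length S
#' @param bonds two-column integer matrix of bonded site index pairs
#' @param allow_net_charge permit a non-neutral body (used for charged toy
#'   lattices; the Ewald sum still requires overall cell neutrality)
#' @return an object of class `reference_geometry`
#' @seealso [benzene_geometry()]
#' @export
reference_geometry <- function(sites, elements, charges, bonds,
                               allow_net_charge = FALSE) {
  sites <- as.matrix(sites)
  if (nrow(sites) != 3) stop("sites must be a 3 x S matrix")
  S <- ncol(sites)
  stopifnot(length(elements) == S, length(charges) == S)
  if (max(abs(rowMeans(sites))) > 1e-8)
    stop("reference geometry must be centered at the origin")
  if (!allow_net_charge && abs(sum(charges)) > 1e-10)
    stop("total charge of the reference geometry must be zero")
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && (min(bonds) < 1 || max(bonds) > S))
    stop("bond indices out of range")
  types <- match(elements, unique(elements))
  structure(list(sites = sites, elements = as.character(elements),
                 charges = as.numeric(charges), bonds = bonds,
                 types = types, type_labels = unique(elements)),
            class = "reference_geometry")
}

#' @export
print.reference_geometry <- function(x, ...) {
  cat(sprintf("rigid reference geometry: %d sites (%s), %d bonds, net charge %.3f e\n",
              ncol(x$sites), paste(x$type_labels, collapse = "/"),
              nrow(x$bonds), sum(x$charges)))
  invisible(x)
}

#' Rigid benzene reference geometry
#'
#' D6h benzene centered at the origin and lying in the xy-plane of the body
#' frame. Bond lengths default to r(C-C) = 1.39 Angstrom and r(C-H) = 1.08
#' Angstrom. Point charges of +q on hydrogen and -q on carbon reproduce the
#' molecular quadrupole; the default q = 0.145 e matches the experimental
#' gas-phase quadrupole moment of about -1.8 e A^2 for this geometry.
#'
#' @param r_cc,r_ch bond lengths in Angstrom
#' @param q_h hydrogen point charge in e (carbon carries -q_h)
#' @return a [reference_geometry()] with sites ordered C1..C6, H1..H6
#'   (H `i` bonded to C `i`)
#' @export
benzene_geometry <- function(r_cc = 1.39, r_ch = 1.08, q_h = 0.145) {
  ang <- (0:5) * pi / 3
  r_c <- r_cc  # hexagon circumradius equals the C-C bond length
  cpos <- rbind(r_c * cos(ang), r_c * sin(ang), rep(0, 6))
  hpos <- rbind((r_c + r_ch) * cos(ang), (r_c + r_ch) * sin(ang), rep(0, 6))
  bonds <- rbind(cbind(1:6, c(2:6, 1)),   # ring
                 cbind(1:6, 7:12))        # C-H
  reference_geometry(cbind(cpos, hpos),
                     c(rep("C", 6), rep("H", 6)),
                     c(rep(-q_h, 6), rep(q_h, 6)),
                     bonds)
}

#' Infer bonds from distances
#'
#' Returns pairs of sites closer than `cutoff` (default 1.8 Angstrom). A
#' convenience for imported XYZ-style coordinates; the result must be
#' reviewed and passed to [reference_geometry()] explicitly.
#'
#' @param sites 3 x S matrix of positions (Angstrom)
#' @param cutoff bond distance cutoff (Angstrom)
#' @return two-column integer matrix of site index pairs
#' @export
infer_bonds <- function(sites, cutoff = 1.8) {
  S <- ncol(sites)
  out <- NULL
  for (i in seq_len(S - 1))
    for (j in (i + 1):S)
      if (sqrt(sum((sites[, i] - sites[, j])^2)) < cutoff)
        out <- rbind(out, c(i, j))
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

#' Export a set of site coordinates in XYZ format
#'
#' @param sites 3 x S matrix (Angstrom)
#' @param elements element symbols
#' @param path output file
#' @param comment second-line comment
#' @return the path, invisibly
#' @export
write_xyz <- function(sites, elements, path, comment = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(ncol(sites)), comment), con)
  for (i in seq_len(ncol(sites)))
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", elements[i],
                       sites[1, i], sites[2, i], sites[3, i]), con)
  invisible(path)
}
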