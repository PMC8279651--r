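#' Write a configuration as a P1 CIF
#'
#' Exports the expanded crystal (all N molecules, all sites) as a standard
#' P1 crystallographic information file: cell in Angstrom/degrees,
#' fractional atomic coordinates wrapped into `[0, 1)`. Energy and
#' provenance go into CIF comments.
#'
#' @param config a [crystal_config()]
#' @param ref a [reference_geometry()]
#' @param path output file
#' @param title data block name
#' @param energy optional energy (kJ/mol) recorded in a comment
#' @return the path, invisibly
#' @export
write_cif <- function(config, ref, path, title = "crystalhop",
                      energy = NULL) {
  H <- cell_matrix(config$cell)
  xs <- expand_sites(config, ref)
  fr <- solve(H, xs)
  fr <- fr - floor(fr)
  p <- cell_parameters(config$cell)
  S <- ncol(ref$sites)
  lab <- paste0(ref$elements[rep(seq_len(S), config$n_mol)],
                rep(seq_len(S), config$n_mol), "_",
                rep(seq_len(config$n_mol), each = S))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# generated by crystalhop %s", as.character(packageVersion("crystalhop"))),
    if (!is.null(energy))
      sprintf("# energy_kj_per_mol %.8f (%.8f per molecule)", energy,
              energy / config$n_mol),
    sprintf("data_%s", gsub("[^A-Za-z0-9_-]", "_", title)),
    "_symmetry_space_group_name_H-M   'P 1'",
    "_symmetry_Int_Tables_number      1",
    sprintf("_cell_length_a    %12.6f", p[1]),
    sprintf("_cell_length_b    %12.6f", p[2]),
    sprintf("_cell_length_c    %12.6f", p[3]),
    sprintf("_cell_angle_alpha %12.6f", p[4]),
    sprintf("_cell_angle_beta  %12.6f", p[5]),
    sprintf("_cell_angle_gamma %12.6f", p[6]),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z"), con)
  el <- ref$elements[rep(seq_len(S), config$n_mol)]
  for (i in seq_len(ncol(fr)))
    writeLines(sprintf("%-10s %-2s %12.8f %12.8f %12.8f", lab[i], el[i],
                       fr[1, i], fr[2, i], fr[3, i]), con)
  invisible(path)
}

# strip standard uncertainty suffixes like 1.234(5)
cif_num <- function(x) as.numeric(sub("\\(.*\\)", "", x))

#' Read a P1 (or symmetry-expanded) CIF as a rigid-body configuration
#'
#' Parses the cell and fractional coordinates, groups sites into molecules
#' by bond connectivity (minimum-image distances below `bond_cutoff`,
#' unwrapping molecules split across the cell boundary), checks every
#' fragment against the reference geometry, and replaces each molecule by
#' the rigid reference at its fitted COM and orientation (best-fit rotation
#' over the bond-graph-compatible correspondences). Fragments that do not
#' match the reference composition, or fit worse than `fit_tol`, are
#' rejected with an error.
#'
#' @param path CIF file
#' @param ref a [reference_geometry()] (defaults to rigid benzene)
#' @param bond_cutoff bond detection distance (Angstrom): either a single
#'   number for all element pairs, or `NULL` (default) for an element-aware
#'   cutoff of 1.2 times the sum of covalent radii, which keeps short
#'   intermolecular contacts from fusing molecules
#' @param fit_tol maximum RMSD (Angstrom) between a fragment and the fitted
#'   rigid reference
#' @return a [crystal_config()] with attribute `fit_rmsd` (per-molecule
#'   fit RMSD in Angstrom)
#' @export
read_cif <- function(path, ref = benzene_geometry(), bond_cutoff = NULL,
                     fit_tol = 0.5) {
  if (!file.exists(path)) stop("CIF not found: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!grepl("^\\s*#", ln)]
  get_scalar <- function(tag) {
    hit <- grep(paste0("^\\s*", tag, "\\b"), ln, value = TRUE)
    if (!length(hit)) stop("CIF lacks tag ", tag)
    cif_num(strsplit(trimws(hit[1]), "\\s+")[[1]][2])
  }
  cell <- unit_cell(get_scalar("_cell_length_a"), get_scalar("_cell_length_b"),
                    get_scalar("_cell_length_c"), get_scalar("_cell_angle_alpha"),
                    get_scalar("_cell_angle_beta"), get_scalar("_cell_angle_gamma"))
  # find the atom_site loop
  loops <- grep("^\\s*loop_\\s*$", ln)
  frac <- NULL; elements <- NULL
  for (L in loops) {
    tags <- character(0)
    i <- L + 1
    while (i <= length(ln) && grepl("^\\s*_", ln[i])) {
      tags <- c(tags, trimws(ln[i])); i <- i + 1
    }
    if (!any(grepl("^_atom_site_fract_x", tags))) next
    rows <- list()
    while (i <= length(ln)) {
      l <- trimws(ln[i])
      if (!nzchar(l) || grepl("^(_|loop_|data_)", l)) break
      rows[[length(rows) + 1]] <- strsplit(l, "\\s+")[[1]]
      i <- i + 1
    }
    tab <- do.call(rbind, rows)
    cx <- match("_atom_site_fract_x", tags)
    cy <- match("_atom_site_fract_y", tags)
    cz <- match("_atom_site_fract_z", tags)
    frac <- rbind(cif_num(tab[, cx]), cif_num(tab[, cy]), cif_num(tab[, cz]))
    ct <- match("_atom_site_type_symbol", tags)
    if (is.na(ct)) {
      cl <- match("_atom_site_label", tags)
      elements <- sub("[0-9_].*$", "", tab[, cl])
    } else elements <- sub("[0-9+-].*$", "", tab[, ct])
    break
  }
  if (is.null(frac)) stop("CIF has no atom_site loop with fractional coordinates")
  n_sites <- ncol(frac)
  S <- ncol(ref$sites)
  if (n_sites %% S != 0)
    stop("CIF contains ", n_sites, " sites, not a multiple of the ", S,
         "-site reference molecule")
  H <- cell_matrix(cell)
  # connectivity by minimum image, with element-aware bond cutoffs
  cut_fun <- if (is.null(bond_cutoff)) {
    radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, S = 1.05,
               Cl = 1.02, Br = 1.2, Na = 1.66, P = 1.07)
    function(ei, ej) {
      ri <- radii[ei]; rj <- radii[ej]
      if (is.na(ri) || is.na(rj)) 1.8 else 1.2 * (ri + rj)
    }
  } else function(ei, ej) bond_cutoff
  min_image_vec <- function(df) {
    df <- df - round(df)
    drop(H %*% df)
  }
  adj <- vector("list", n_sites)
  for (i in seq_len(n_sites))
    for (j in seq_len(n_sites))
      if (i != j) {
        v <- min_image_vec(frac[, j] - frac[, i])
        if (sqrt(sum(v^2)) < cut_fun(elements[i], elements[j]))
          adj[[i]] <- c(adj[[i]], j)
      }
  # fragments by BFS, unwrapping across the boundary
  assigned <- rep(NA_integer_, n_sites)
  pos <- matrix(NA_real_, 3, n_sites)  # unwrapped absolute positions
  n_frag <- 0
  for (s in seq_len(n_sites)) {
    if (!is.na(assigned[s])) next
    n_frag <- n_frag + 1
    assigned[s] <- n_frag
    pos[, s] <- drop(H %*% frac[, s])
    queue <- s
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (j in adj[[i]]) {
        if (!is.na(assigned[j])) next
        assigned[j] <- n_frag
        pos[, j] <- pos[, i] + min_image_vec(frac[, j] - frac[, i])
        queue <- c(queue, j)
      }
    }
  }
  coms <- matrix(0, 3, n_frag)
  ps <- matrix(0, 3, n_frag)
  rmsds <- numeric(n_frag)
  for (f in seq_len(n_frag)) {
    idx <- which(assigned == f)
    if (length(idx) != S ||
        !identical(sort(elements[idx]), sort(ref$elements)))
      stop("CIF fragment ", f, " (", length(idx), " sites: ",
           paste(sort(unique(elements[idx])), collapse = ","),
           ") does not match the reference molecule")
    fit <- fit_rigid_reference(pos[, idx, drop = FALSE], elements[idx], ref)
    if (fit$rmsd > fit_tol)
      stop(sprintf("CIF fragment %d fits the rigid reference poorly (RMSD %.3f A)",
                   f, fit$rmsd))
    coms[, f] <- solve(H, fit$com)
    ps[, f] <- fit$p
    rmsds[f] <- fit$rmsd
  }
  out <- crystal_config(coms, ps, cell)
  attr(out, "fit_rmsd") <- rmsds
  out
}

# Kabsch best-fit rotation mapping ref sites onto a fragment, searching the
# bond-graph-compatible correspondences (ring cycle rotations/reflections
# for a single-ring reference; identity order otherwise).
fit_rigid_reference <- function(frag, frag_elements, ref) {
  S <- ncol(ref$sites)
  com <- rowMeans(frag)
  fc <- frag - com
  ring <- ring_order(ref)
  candidates <- list()
  if (!is.null(ring)) {
    frag_ring <- ring_order_fragment(frag, frag_elements)
    if (is.null(frag_ring)) stop("fragment carbon ring could not be traced")
    nr <- length(ring$c_order)
    for (shift in 0:(nr - 1)) for (dir in c(1, -1)) {
      ord <- if (dir == 1) c(seq_len(nr), seq_len(nr))[(shift + 1):(shift + nr)]
      else rev(c(seq_len(nr), seq_len(nr))[(shift + 1):(shift + nr)])
      perm <- integer(S)
      perm[ring$c_order] <- frag_ring$c_order[ord]
      perm[ring$h_of_c[ring$c_order]] <- frag_ring$h_of_c[frag_ring$c_order[ord]]
      candidates[[length(candidates) + 1]] <- perm
    }
  } else {
    candidates[[1]] <- seq_len(S)
  }
  best <- NULL
  for (perm in candidates) {
    if (anyNA(perm)) next
    X <- ref$sites            # 3 x S, body frame (centered)
    Y <- fc[, perm]           # fragment sites matched to reference order
    C <- Y %*% t(X)
    sv <- svd(C)
    dd <- sign(det(sv$u %*% t(sv$v)))
    R <- sv$u %*% diag(c(1, 1, dd)) %*% t(sv$v)
    rmsd <- sqrt(mean(colSums((Y - R %*% X)^2)))
    if (is.null(best) || rmsd < best$rmsd)
      best <- list(rmsd = rmsd, R = R)
  }
  list(com = com, p = aa_from_matrix(best$R), rmsd = best$rmsd)
}

# ring traversal of the reference: returns carbon cycle order and the
# hydrogen attached to each carbon, or NULL if the reference is not a
# single C-ring with pendant atoms
ring_order <- function(ref) {
  cid <- which(ref$elements == "C")
  if (length(cid) < 3) return(NULL)
  bl <- ref$bonds
  nbr <- function(i) unique(c(bl[bl[, 1] == i, 2], bl[bl[, 2] == i, 1]))
  cc_nbr <- lapply(cid, function(i) intersect(nbr(i), cid))
  if (any(lengths(cc_nbr) != 2)) return(NULL)
  ord <- cid[1]
  prev <- NA
  while (length(ord) < length(cid)) {
    nb <- setdiff(cc_nbr[[match(ord[length(ord)], cid)]], prev)
    prev <- ord[length(ord)]
    ord <- c(ord, nb[1])
  }
  h_of_c <- rep(NA_integer_, ncol(ref$sites))
  for (i in cid) {
    h <- setdiff(nbr(i), cid)
    if (length(h) == 1) h_of_c[i] <- h
  }
  list(c_order = ord, h_of_c = h_of_c)
}

# same for an imported fragment, using distances
ring_order_fragment <- function(frag, elements, cc_cut = 1.75, ch_cut = 1.3) {
  cid <- which(elements == "C")
  d <- as.matrix(dist(t(frag)))
  cc_nbr <- lapply(cid, function(i) cid[d[i, cid] > 0 & d[i, cid] < cc_cut])
  if (any(lengths(cc_nbr) != 2)) return(NULL)
  ord <- cid[1]
  prev <- NA
  while (length(ord) < length(cid)) {
    nb <- setdiff(cc_nbr[[match(ord[length(ord)], cid)]], prev)
    prev <- ord[length(ord)]
    ord <- c(ord, nb[1])
  }
  hid <- which(elements == "H")
  h_of_c <- rep(NA_integer_, ncol(frag))
  for (i in cid) h_of_c[i] <- hid[which.min(d[i, hid])]
  list(c_order = ord, h_of_c = h_of_c)
}
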