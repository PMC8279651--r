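#' Crystal configuration
#'
#' The full state of a periodic rigid-molecule crystal: N fractional
#' center-of-mass vectors (wrapped into `[0, 1)`), N absolute angle-axis
#' orientation vectors, and a [unit_cell()].
#'
#' @param com 3 x N matrix of fractional COM coordinates
#' @param p 3 x N matrix of angle-axis vectors
#' @param cell a [unit_cell()]
#' @return an object of class `crystal_config`
#' @export
crystal_config <- function(com, p, cell) {
  com <- as.matrix(com); p <- as.matrix(p)
  if (nrow(com) != 3 || nrow(p) != 3 || ncol(com) != ncol(p))
    stop("com and p must be 3 x N matrices with matching N")
  stopifnot(inherits(cell, "unit_cell"))
  com <- com - floor(com)
  com[com >= 1] <- 0  # tiny negatives can round up to exactly 1
  structure(list(com = com, p = p, cell = cell,
                 n_mol = ncol(com)),
            class = "crystal_config")
}

#' @export
print.crystal_config <- function(x, ...) {
  cat(sprintf("crystal configuration: %d rigid molecules\n", x$n_mol))
  print(x$cell)
  invisible(x)
}

#' Expand rigid bodies to absolute site coordinates
#'
#' Applies `x_i^m = H X^m + R(p^m) x_i^0` for every molecule m and site i.
#'
#' @param config a [crystal_config()]
#' @param ref a [reference_geometry()]
#' @return 3 x (N*S) matrix of absolute coordinates with attribute
#'   `molecule` giving the molecule index of each column
#' @export
expand_sites <- function(config, ref) {
  H <- cell_matrix(config$cell)
  S <- ncol(ref$sites)
  out <- matrix(0, 3, config$n_mol * S)
  for (m in seq_len(config$n_mol)) {
    R <- rotation_matrix(config$p[, m])
    out[, (m - 1) * S + seq_len(S)] <-
      drop(H %*% config$com[, m]) + R %*% ref$sites
  }
  attr(out, "molecule") <- rep(seq_len(config$n_mol), each = S)
  out
}

#' Pack and unpack the optimization variable vector
#'
#' The joint variable vector has the fixed layout
#' `[X1..XN | p1..pN | a b c alpha beta gamma]` of length `6N + 6`, with
#' fractional COMs, angle-axis components, lengths in Angstrom and angles in
#' radians.
#'
#' @param config a [crystal_config()]
#' @return `pack_config`: numeric vector of length `6N + 6`
#' @export
pack_config <- function(config) {
  c(as.numeric(config$com), as.numeric(config$p), config$cell$par)
}

#' @rdname pack_config
#' @param x numeric vector of length `6N + 6`
#' @param n_mol number of molecules N
#' @export
unpack_config <- function(x, n_mol) {
  if (length(x) != 6 * n_mol + 6)
    stop("variable vector has length ", length(x), ", expected ", 6 * n_mol + 6)
  crystal_config(matrix(x[1:(3 * n_mol)], 3),
                 matrix(x[3 * n_mol + 1:(3 * n_mol)], 3),
                 new_cell_from_par(x[6 * n_mol + 1:6]))
}

# wrap COMs into [0,1) and canonicalize angle-axis vectors
canonicalize_config <- function(config) {
  p <- config$p
  for (m in seq_len(ncol(p))) p[, m] <- canonicalize_aa(p[, m])
  crystal_config(config$com - floor(config$com), p, config$cell)
}

#' Seeded random high-energy starting configuration
#'
#' Draws a random starting point of the kind used to initialize independent
#' basin-hopping runs: cell lengths uniform in `length_range` and angles
#' uniform in `angle_range` (accepted only if the angular volume factor
#' P > 0.5 and the molecular volume V/N falls in `vm_range`), COMs uniform
#' in the cell, and orientations uniform over rotations. Configurations in
#' which any intersite distance (across periodic images) falls below `d_min`
#' are redrawn, which avoids pathological overlaps that stall the first
#' minimization.
#'
#' @param n_mol number of molecules
#' @param seed integer seed; the result is a deterministic function of it
#' @param ref a [reference_geometry()] (for the overlap check)
#' @param length_range,angle_range cell parameter ranges (Angstrom, degrees)
#' @param vm_range admissible molecular volume V/N (Angstrom^3)
#' @param d_min minimum intersite distance (Angstrom)
#' @param max_tries redraw budget before giving up
#' @return a [crystal_config()]
#' @export
random_start <- function(n_mol, seed, ref = benzene_geometry(),
                         length_range = c(6.5, 11), angle_range = c(70, 110),
                         vm_range = c(100, 260), d_min = 1.5,
                         max_tries = 2000) {
  stopifnot(n_mol >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    len <- runif(3, length_range[1], length_range[2])
    ang <- runif(3, angle_range[1], angle_range[2])
    cell <- tryCatch(unit_cell(len[1], len[2], len[3], ang[1], ang[2], ang[3]),
                     error = function(e) NULL)
    if (is.null(cell)) next
    v <- cell_volume(cell)
    if (v$P < 0.5 || v$V / n_mol < vm_range[1] || v$V / n_mol > vm_range[2]) next
    com <- matrix(runif(3 * n_mol), 3)
    p <- vapply(seq_len(n_mol), function(i) random_rotation_aa(), numeric(3))
    config <- crystal_config(com, p, cell)
    if (min_intersite_distance(config, ref) >= d_min) return(config)
  }
  stop("random_start: could not satisfy the minimum-distance constraint in ",
       max_tries, " tries")
}

# minimum distance between sites of different molecules (and between a
# molecule and its own periodic images), scanning images -1..1
min_intersite_distance <- function(config, ref) {
  H <- cell_matrix(config$cell)
  xs <- expand_sites(config, ref)
  mol <- attr(xs, "molecule")
  dmin <- Inf
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (k in seq_len(nrow(shifts))) {
    off <- drop(H %*% shifts[k, ])
    same_cell <- all(shifts[k, ] == 0)
    for (i in seq_len(ncol(xs))) {
      d2 <- colSums((xs + off - xs[, i])^2)
      excl <- if (same_cell) mol == mol[i] else rep(FALSE, ncol(xs))
      d2 <- d2[!excl]
      if (length(d2)) dmin <- min(dmin, sqrt(min(d2)))
    }
  }
  dmin
}
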