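#' Site-site pair parameters
#'
#' Container for the per-element-pair parameters of the short-range model:
#' Born-Mayer repulsion prefactor `A` (kJ/mol) and hardness `B` (1/Angstrom),
#' dispersion coefficient `C6` (kJ mol^-1 Angstrom^6), a per-element
#' anisotropic range shift `d1` (Angstrom) that modulates the repulsive
#' contact as a function of the molecular orientations, and a flag selecting
#' Tang-Toennies order-6 dispersion damping. All matrices are symmetric in
#' the element pair; `C6` must be non-negative.
#'
#' The interaction of two sites i, j belonging to molecules with unit plane
#' normals `z_i`, `z_j`, separated by `r` along unit vector `rhat`, is
#' \deqn{U = A e^{-B (r - \rho)} - f_6(Br) C_6 / r^6, \qquad
#'       \rho = d_{1,i} (z_i \cdot \hat r)^2 + d_{1,j} (z_j \cdot \hat r)^2,}
#' so a negative `d1` pulls the repulsive wall inward for approaches along
#' the molecular normal. Setting all `d1 = 0` recovers a plain isotropic
#' exp-6 model. Point-charge electrostatics are handled separately by the
#' Ewald sum and are not part of this term.
#'
#' @param types character vector of element labels
#' @param A,B,C6 symmetric `length(types)`-square matrices
#' @param d1 per-element range shifts (Angstrom)
#' @param damp logical, apply Tang-Toennies damping to the dispersion
#' @return an object of class `pair_params`
#' @export
pair_params <- function(types, A, B, C6, d1 = rep(0, length(types)),
                        damp = TRUE) {
  nt <- length(types)
  A <- as.matrix(A); B <- as.matrix(B); C6 <- as.matrix(C6)
  for (nm in c("A", "B", "C6")) {
    M <- get(nm)
    if (!all(dim(M) == c(nt, nt))) stop(nm, " must be ", nt, " x ", nt)
    if (max(abs(M - t(M))) > 1e-12) stop(nm, " must be symmetric in the element pair")
  }
  if (any(C6 < 0)) stop("dispersion coefficients C6 must be non-negative")
  if (any(A < 0) || any(B <= 0)) stop("repulsion parameters must be positive")
  stopifnot(length(d1) == nt)
  dimnames(A) <- dimnames(B) <- dimnames(C6) <- list(types, types)
  structure(list(types = as.character(types), A = A, B = B, C6 = C6,
                 d1 = setNames(as.numeric(d1), types), damp = isTRUE(damp)),
            class = "pair_params")
}

#' @export
print.pair_params <- function(x, ...) {
  cat("site-site pair parameters for elements:", paste(x$types, collapse = ", "),
      if (x$damp) "(damped dispersion)" else "(undamped dispersion)", "\n")
  pairs <- which(upper.tri(x$A, diag = TRUE), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    cat(sprintf("  %s-%s: A = %10.1f kJ/mol  B = %5.3f 1/A  C6 = %8.2f kJ A^6/mol\n",
                x$types[i], x$types[j], x$A[i, j], x$B[i, j], x$C6[i, j]))
  }
  cat("  d1:", paste(sprintf("%s = %+.3f A", x$types, x$d1), collapse = ", "), "\n")
  invisible(x)
}

#' Read a pair-parameter table
#'
#' Plain-text key-value format, one record per line:
#' `types <labels...>`, `damp <TRUE/FALSE>`, `A <el> <el> <value>` (likewise
#' `B`, `C6`), `d1 <el> <value>`. Every unordered element pair must be given
#' exactly once for each of A, B and C6; missing entries are reported by
#' name. Lines starting with `#` are comments.
#'
#' @param path file to read
#' @return a [pair_params()] object, with attribute `md5` recording the file
#'   hash for run manifests
#' @export
load_pair_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ln <- readLines(path)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  tok <- strsplit(ln, "[[:space:]]+")
  key <- vapply(tok, `[`, "", 1)
  types <- NULL
  damp <- TRUE
  for (t in tok[key == "types"]) types <- t[-1]
  if (is.null(types)) stop("parameter file has no 'types' record")
  nt <- length(types)
  for (t in tok[key == "damp"]) damp <- as.logical(t[2])
  mats <- list(A = matrix(NA_real_, nt, nt), B = matrix(NA_real_, nt, nt),
               C6 = matrix(NA_real_, nt, nt))
  d1 <- setNames(rep(NA_real_, nt), types)
  for (t in tok[key %in% c("A", "B", "C6")]) {
    i <- match(t[2], types); j <- match(t[3], types)
    if (is.na(i) || is.na(j)) stop("unknown element in record: ", paste(t, collapse = " "))
    v <- as.numeric(t[4])
    mats[[t[1]]][i, j] <- v
    mats[[t[1]]][j, i] <- v
  }
  for (t in tok[key == "d1"]) {
    i <- match(t[2], types)
    if (is.na(i)) stop("unknown element in d1 record: ", t[2])
    d1[i] <- as.numeric(t[3])
  }
  d1[is.na(d1)] <- 0
  for (nm in names(mats)) {
    miss <- which(is.na(mats[[nm]]) & upper.tri(mats[[nm]], diag = TRUE), arr.ind = TRUE)
    if (nrow(miss))
      stop("parameter table incomplete: missing ", nm, " for pair(s) ",
           paste(sprintf("%s-%s", types[miss[, 1]], types[miss[, 2]]), collapse = ", "))
  }
  out <- pair_params(types, mats$A, mats$B, mats$C6, d1, damp)
  attr(out, "md5") <- unname(tools::md5sum(path))
  out
}

#' Write a pair-parameter table
#'
#' Inverse of [load_pair_params()]; a round trip preserves all values.
#'
#' @param params a [pair_params()] object
#' @param path output file
#' @param header optional comment lines written at the top
#' @return the path, invisibly
#' @export
write_pair_params <- function(params, path, header = NULL) {
  stopifnot(inherits(params, "pair_params"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  writeLines(paste("types", paste(params$types, collapse = " ")), con)
  writeLines(paste("damp", params$damp), con)
  for (nm in c("A", "B", "C6")) {
    M <- params[[nm]]
    idx <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
    for (k in seq_len(nrow(idx)))
      writeLines(sprintf("%s %s %s %.10g", nm, params$types[idx[k, 1]],
                         params$types[idx[k, 2]], M[idx[k, 1], idx[k, 2]]), con)
  }
  for (i in seq_along(params$types))
    writeLines(sprintf("d1 %s %.10g", params$types[i], params$d1[i]), con)
  invisible(path)
}

#' Synthetic benzene parameter set
#'
#' Loads the parameter table shipped with the package
#' (`extdata/benzene_params_synthetic.txt`). This is a *synthetic* stand-in
#' model, not a published benzene potential: exp-6 magnitudes of the
#' classic Williams type for aromatic C/H, Tang-Toennies damping, and a
#' small negative carbon `d1` that shortens the repulsive contact along the
#' ring normal. It produces a physically sensible benzene crystal landscape
#' for demonstrating and testing the basin-hopping machinery; its minima do
#' not reproduce any published potential's energies.
#'
#' @return a [pair_params()] object
#' @export
benzene_params_synthetic <- function() {
  load_pair_params(system.file("extdata", "benzene_params_synthetic.txt",
                               package = "crystalhop", mustWork = TRUE))
}

# internal: convert pair_params + reference_geometry to the list the C++
# kernel expects
params_for_kernel <- function(params, ref) {
  it <- match(ref$type_labels, params$types)
  if (anyNA(it))
    stop("parameter table lacks element(s): ",
         paste(ref$type_labels[is.na(it)], collapse = ", "))
  list(A = params$A[it, it, drop = FALSE],
       B = params$B[it, it, drop = FALSE],
       C6 = params$C6[it, it, drop = FALSE],
       d1 = as.numeric(params$d1[it]),
       damp = params$damp)
}
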