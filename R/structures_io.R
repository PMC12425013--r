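#' Protein structures, residue frames and conformational ensembles
#'
#' A `gd_structure` holds one chain of a protein at Calpha (plus backbone N
#' and C) resolution; a `gd_frames` holds the per-residue rigid frames
#' `T_i = (R_i, t_i)` built from the backbone; a `gd_ensemble` holds `T`
#' conformations as a `T x N x 3` coordinate array.  All coordinates are in
#' Angstrom.  Residue indexing is 0-based internally only inside matrix
#' algebra; everything user-facing is 1-based.
#'
#' @name structures
NULL

#' Construct a protein structure object
#'
#' @param sequence one-letter amino-acid string (or character vector) of
#'   length N.
#' @param ca N x 3 matrix of Calpha coordinates (Angstrom).
#' @param n_coords,c_coords optional N x 3 matrices of backbone N and C
#'   coordinates; required for frame construction.
#' @param chain_id chain identifier.
#' @param resno integer residue numbers (default `1:N`).
#' @return an object of class `gd_structure`.
#' @export
gd_structure <- function(sequence, ca, n_coords = NULL, c_coords = NULL,
                         chain_id = "A", resno = NULL) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 2L) stop("a structure needs at least 2 residues")
  if (ncol(ca) != 3L || !all(is.finite(ca))) stop("`ca` must be a finite N x 3 matrix")
  if (length(sequence) != n) stop("sequence length must equal coordinate row count")
  for (nm in c("n_coords", "c_coords")) {
    m <- get(nm)
    if (!is.null(m)) {
      m <- as.matrix(m)
      if (!all(dim(m) == c(n, 3L)) || !all(is.finite(m)))
        stop("`", nm, "` must be a finite N x 3 matrix")
      assign(nm, m)
    }
  }
  if (is.null(resno)) resno <- seq_len(n)
  structure(list(sequence = toupper(sequence), ca = ca,
                 n_coords = n_coords, c_coords = c_coords,
                 chain_id = chain_id, resno = as.integer(resno)),
            class = "gd_structure")
}

#' @export
print.gd_structure <- function(x, ...) {
  cat(sprintf("<gd_structure> chain %s, %d residues%s\n", x$chain_id,
              nrow(x$ca),
              if (is.null(x$n_coords)) " (Calpha only)" else " (N/CA/C backbone)"))
  cat(" sequence:", paste(x$sequence, collapse = ""), "\n")
  invisible(x)
}

#' Number of residues of a structure/ensemble/frame set
#' @param x a `gd_structure`, `gd_ensemble` or `gd_frames` object.
#' @return integer residue count.
#' @export
n_residues <- function(x) {
  if (inherits(x, "gd_structure")) nrow(x$ca)
  else if (inherits(x, "gd_ensemble")) dim(x$coords)[2]
  else if (inherits(x, "gd_frames")) dim(x$rotations)[1]
  else stop("unsupported type")
}

#' Construct a conformational ensemble
#'
#' @param coords `T x N x 3` array of Calpha coordinates (Angstrom), or an
#'   `N x 3` matrix for a single conformation.
#' @param aligned logical; have the frames been superposed onto a common
#'   reference?
#' @return an object of class `gd_ensemble`.
#' @export
gd_ensemble <- function(coords, aligned = FALSE) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L, dim(coords)[1] >= 1L)
  if (!all(is.finite(coords))) stop("ensemble coordinates must be finite")
  structure(list(coords = coords, aligned = isTRUE(aligned)), class = "gd_ensemble")
}

#' @export
print.gd_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<gd_ensemble> %d conformations x %d residues%s\n",
              d[1], d[2], if (x$aligned) ", aligned" else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# PDB reading (single structures and multi-model ensembles) via bio3d

.pick_altloc <- function(atoms) {
  # within one (resno, insert, elety) group keep highest occupancy, ties -> 'A'
  if (nrow(atoms) == 1L) return(atoms)
  o <- atoms$o
  o[is.na(o)] <- 1
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  ord <- order(-o, alt)
  atoms[ord[1L], , drop = FALSE]
}

.atoms_to_structure <- function(atom, chain, path) {
  chains <- sort(unique(atom$chain[!is.na(atom$chain)]))
  if (length(chains) == 0L) chains <- ""
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stop("file has multiple chains (", paste(chains, collapse = ", "),
           "); pass `chain` explicitly")
    chain <- chains[1L]
  }
  if (!chain %in% chains)
    stop("chain '", chain, "' not found in ", path,
         "; available chains: ", paste(chains, collapse = ", "))
  a <- atom[(atom$chain %in% chain | (is.na(atom$chain) & chain == "")) &
              atom$elety %in% c("CA", "N", "C"), , drop = FALSE]
  a$insert[is.na(a$insert)] <- ""
  key <- paste(a$resno, a$insert, sep = "_")
  # residue order: by residue number, insertion codes preserved in file order
  res_keys <- unique(key[order(a$resno, match(key, key))])
  pick <- function(k, ety) {
    sel <- a[key == k & a$elety == ety, , drop = FALSE]
    if (nrow(sel) == 0L) return(NULL)
    .pick_altloc(sel)
  }
  n <- length(res_keys)
  ca <- matrix(NA_real_, n, 3); nn <- matrix(NA_real_, n, 3); cc <- matrix(NA_real_, n, 3)
  seq1 <- character(n); resno <- integer(n)
  for (i in seq_len(n)) {
    rca <- pick(res_keys[i], "CA")
    if (is.null(rca))
      stop("residue ", res_keys[i], " of chain '", chain, "' has no CA atom")
    ca[i, ] <- c(rca$x, rca$y, rca$z)
    seq1[i] <- bio3d::aa321(rca$resid)
    resno[i] <- rca$resno
    rn <- pick(res_keys[i], "N"); rc <- pick(res_keys[i], "C")
    if (!is.null(rn)) nn[i, ] <- c(rn$x, rn$y, rn$z)
    if (!is.null(rc)) cc[i, ] <- c(rc$x, rc$y, rc$z)
  }
  seq1[is.na(seq1) | seq1 == ""] <- "X"
  has_bb <- all(is.finite(nn)) && all(is.finite(cc))
  gd_structure(seq1, ca,
               n_coords = if (has_bb) nn else NULL,
               c_coords = if (has_bb) cc else NULL,
               chain_id = chain, resno = resno)
}

#' Read a single-chain protein structure from a PDB file
#'
#' Reads Calpha and backbone N/C atoms of one chain.  Alternate locations are
#' resolved to the highest occupancy (ties go to altloc 'A'); residues are
#' ordered by residue number with insertion codes preserved.  For multi-model
#' files the first model is used.
#'
#' @param path PDB file path.
#' @param chain chain identifier; may be omitted for single-chain files.
#' @return a [gd_structure()].
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("could not parse PDB file ", path,
                                           ": ", conditionMessage(e)))
  .atoms_to_structure(pdb$atom, chain, path)
}

#' Read a multi-model PDB file as a conformational ensemble
#'
#' Calpha coordinates of every MODEL are collected into a `T x N x 3` array.
#'
#' @inheritParams read_structure
#' @param aligned mark the ensemble as already superposed (default `FALSE`).
#' @return a [gd_ensemble()].
#' @export
read_ensemble <- function(path, chain = NULL, aligned = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  ref <- .atoms_to_structure(pdb$atom, chain, path)
  sel <- bio3d::atom.select(pdb, elety = "CA",
                            chain = if (nzchar(ref$chain_id)) ref$chain_id else NULL,
                            verbose = FALSE)
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  nT <- nrow(xyz); n <- ncol(xyz) / 3L
  coords <- array(NA_real_, c(nT, n, 3L))
  for (t in seq_len(nT)) coords[t, , ] <- matrix(xyz[t, ], ncol = 3L, byrow = TRUE)
  gd_ensemble(coords, aligned = aligned)
}

#' Write an ensemble as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` record pair per conformation, Calpha atoms only,
#' using the template's sequence, chain and residue numbering.  A per-residue
#' scalar (e.g. RMSF) may be written into the B-factor column.
#'
#' @param ensemble a [gd_ensemble()].
#' @param template a [gd_structure()] with matching residue count.
#' @param path output file path.
#' @param bfactor optional numeric vector of length N written as B-factors.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, template, path, bfactor = NULL) {
  nT <- dim(ensemble$coords)[1]; n <- dim(ensemble$coords)[2]
  if (n != n_residues(template))
    stop("ensemble has ", n, " residues but template has ", n_residues(template))
  if (is.null(bfactor)) bfactor <- rep(0, n)
  if (length(bfactor) != n) stop("bfactor must have one value per residue")
  xyz <- matrix(NA_real_, nT, 3L * n)
  for (t in seq_len(nT)) xyz[t, ] <- as.vector(t(ensemble$coords[t, , ]))
  resid3 <- bio3d::aa123(template$sequence)
  resid3[is.na(resid3)] <- "UNK"
  bio3d::write.pdb(file = path, xyz = xyz, resno = template$resno,
                   resid = resid3, eleno = seq_len(n),
                   elety = rep("CA", n),
                   chain = rep(if (nzchar(template$chain_id)) template$chain_id else "A", n),
                   b = round(bfactor, 2))
  invisible(path)
}

#' Write a single structure (Calpha trace) as a PDB file
#' @inheritParams write_ensemble
#' @param structure a [gd_structure()].
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, bfactor = NULL) {
  st <- structure
  n <- n_residues(st)
  has_bb <- !is.null(st$n_coords) && !is.null(st$c_coords)
  if (!has_bb)
    return(write_ensemble(gd_ensemble(st$ca), st, path, bfactor = bfactor))
  # interleave N, CA, C per residue so frames survive a round trip
  xyz <- matrix(NA_real_, 3L * n, 3L)
  xyz[seq(1, 3 * n, 3), ] <- st$n_coords
  xyz[seq(2, 3 * n, 3), ] <- st$ca
  xyz[seq(3, 3 * n, 3), ] <- st$c_coords
  resid3 <- rep(bio3d::aa123(st$sequence), each = 3L)
  resid3[is.na(resid3)] <- "UNK"
  b <- if (is.null(bfactor)) rep(0, n) else bfactor
  bio3d::write.pdb(file = path, xyz = as.vector(t(xyz)),
                   resno = rep(st$resno, each = 3L), resid = resid3,
                   eleno = seq_len(3L * n),
                   elety = rep(c("N", "CA", "C"), n),
                   chain = rep(if (nzchar(st$chain_id)) st$chain_id else "A", 3L * n),
                   b = round(rep(b, each = 3L), 2))
  invisible(path)
}

# ---------------------------------------------------------------------------
# residue frames

#' Build per-residue rigid frames from backbone atoms
#'
#' Gram-Schmidt construction in the AlphaFold2 structure-module convention:
#' the first axis points along `C - CA`, the second is the component of
#' `N - CA` orthogonal to it, the third completes a right-handed triad.
#' `t_i` is the Calpha coordinate.
#'
#' If the structure is Calpha-only, frames fall back to identity rotations
#' with a warning; covariance predictions made in such frames are no longer
#' rotation-equivariant.
#'
#' @param structure a [gd_structure()].
#' @param tol collinearity tolerance on the Gram-Schmidt residual norm.
#' @return an object of class `gd_frames` with `rotations` (`N x 3 x 3`,
#'   each `R_i` orthogonal with `det = +1`) and `translations` (`N x 3`).
#' @export
frames_from_backbone <- function(structure, tol = 1e-6) {
  n <- n_residues(structure)
  R <- array(0, c(n, 3, 3))
  if (is.null(structure$n_coords) || is.null(structure$c_coords)) {
    warning("structure has no backbone N/C atoms; using identity rotations ",
            "(predictions lose rotation equivariance)")
    for (i in seq_len(n)) R[i, , ] <- diag(3)
  } else {
    for (i in seq_len(n)) {
      v1 <- structure$c_coords[i, ] - structure$ca[i, ]
      u <- structure$n_coords[i, ] - structure$ca[i, ]
      n1 <- sqrt(sum(v1^2))
      if (n1 < tol) stop("degenerate backbone at residue ", structure$resno[i])
      e1 <- v1 / n1
      v2 <- u - sum(u * e1) * e1
      n2 <- sqrt(sum(v2^2))
      if (n2 < tol)
        stop("collinear N, CA, C at residue ", structure$resno[i])
      e2 <- v2 / n2
      e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      R[i, , ] <- cbind(e1, e2, e3)
    }
  }
  structure(list(rotations = R, translations = structure$ca),
            class = "gd_frames")
}

#' @export
print.gd_frames <- function(x, ...) {
  cat(sprintf("<gd_frames> %d residue frames\n", dim(x$rotations)[1]))
  invisible(x)
}
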