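#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation U and translation t minimising
#' \eqn{\sum_k ||U x_k + t - y_k||^2} over paired atoms (x = mobile,
#' y = reference). Reflections are excluded by the usual determinant
#' correction of the SVD solution.
#'
#' @param reference_atoms n x 3 matrix of reference coordinates (Angstrom).
#' @param mobile_atoms n x 3 matrix of mobile coordinates, paired row-wise.
#' @return object of class \code{rigid_transform}: \code{rotation} (3 x 3,
#'   det +1), \code{translation} (length 3), \code{rmsd} (Angstrom over the
#'   pairing, after the fit), \code{n_atoms}.
#' @export
kabsch_fit <- function(reference_atoms, mobile_atoms) {
  y <- matrix(as.numeric(reference_atoms), ncol = 3)
  x <- matrix(as.numeric(mobile_atoms), ncol = 3)
  if (nrow(x) != nrow(y)) stop("paired coordinate sets must have equal size")
  if (nrow(x) < 3) stop("need at least 3 paired atoms")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  sv_chk <- svd(xc)$d
  if (sv_chk[2] < 1e-8 * max(sv_chk[1], 1e-12))
    stop("paired atoms are collinear; rotation is underdetermined")
  h <- t(xc) %*% yc
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  u <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cy - as.numeric(u %*% cx)
  fitted <- xc %*% t(u)
  rmsd <- sqrt(mean(rowSums((fitted - yc)^2)))
  structure(list(rotation = u, translation = tr, rmsd = rmsd,
                 n_atoms = nrow(x)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix (or length-3n xyz vector).
#' @param transform a \code{rigid_transform}.
#' @return coordinates in the same shape as the input.
#' @export
apply_transform <- function(coords, transform) {
  vec <- is.null(dim(coords))
  m <- matrix(as.numeric(coords), ncol = 3, byrow = vec)
  out <- sweep(m %*% t(transform$rotation), 2, -transform$translation)
  if (vec) as.numeric(t(out)) else out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: %d paired atoms, fit RMSD %.4f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

# internal: coerce path / bio3d pdb into list(atom, xyz-vector)
.as_structure <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    x <- bio3d::read.pdb(x, verbose = FALSE)
  if (inherits(x, "pdb")) {
    xyz <- if (is.matrix(x$xyz)) x$xyz[1, ] else x$xyz
    return(list(atom = x$atom, xyz = as.numeric(xyz)))
  }
  if (is.list(x) && !is.null(x$atom) && !is.null(x$xyz))
    return(list(atom = x$atom, xyz = as.numeric(x$xyz)))
  if (inherits(x, "scored_ensemble"))
    return(list(atom = x$atoms, xyz = as.numeric(x$xyz[1, ])))
  stop("cannot interpret structure input")
}

.atom_coords <- function(st, rows) {
  matrix(st$xyz[bio3d::atom2xyz(rows)], ncol = 3, byrow = TRUE)
}

.is_hydrogen <- function(atom) {
  el <- atom$elesy
  byname <- grepl("^[0-9]*H", trimws(atom$elety))
  ifelse(!is.na(el) & el != "", trimws(el) == "H", byname)
}

#' Transfer nonprotein components from a reference complex onto a model
#'
#' Superposes the reference complex onto the target model using shared
#' backbone atoms (paired by residue number), then applies the fitted rigid
#' transform to the selected nonprotein records (ligands, cofactors, ions)
#' and appends them to the target. Steric clashes between transferred and
#' target heavy atoms closer than \code{clash_cutoff} are reported, not
#' repaired (relaxation is the MD engine's job).
#'
#' @param reference_complex reference structure holding the components
#'   (path, bio3d \code{pdb}, or list with \code{atom}/\code{xyz}).
#' @param target_model target protein structure (same forms accepted).
#' @param selection character vector of component residue names to transfer
#'   (e.g. \code{c("RTL")}, \code{c("FMN")}, \code{c("GDP", "MG")}).
#' @param fit_atoms atom names used for the superposition (default CA only;
#'   use \code{c("N","CA","C")} for a full-backbone fit).
#' @param clash_cutoff heavy-atom clash distance in Angstrom (default 2.0).
#' @return list with \code{atom} and \code{xyz} of the merged structure,
#'   \code{transform} (the \code{rigid_transform} used), \code{clashes}
#'   (data.frame of sub-cutoff pairs) and \code{n_transferred}.
#' @export
transfer_components <- function(reference_complex, target_model, selection,
                                fit_atoms = "CA", clash_cutoff = 2.0) {
  ref <- .as_structure(reference_complex)
  tgt <- .as_structure(target_model)
  sel_rows <- which(ref$atom$resid %in% selection)
  if (length(sel_rows) == 0)
    stop(sprintf("selection matches nothing in the reference: %s",
                 paste(selection, collapse = ", ")))
  pair_rows <- function(st) which(st$atom$type == "ATOM" &
                                    st$atom$elety %in% fit_atoms)
  rr <- pair_rows(ref); tr <- pair_rows(tgt)
  rkey <- paste(ref$atom$resno[rr], ref$atom$elety[rr])
  tkey <- paste(tgt$atom$resno[tr], tgt$atom$elety[tr])
  shared <- intersect(rkey, tkey)
  if (length(shared) < 3)
    stop("no mappable backbone atoms between reference and target")
  rr <- rr[match(shared, rkey)]
  tr <- tr[match(shared, tkey)]
  tf <- kabsch_fit(.atom_coords(tgt, tr), .atom_coords(ref, rr))
  moved <- apply_transform(.atom_coords(ref, sel_rows), tf)
  # merged structure: target atoms + transferred component records
  comp_atom <- ref$atom[sel_rows, , drop = FALSE]
  comp_atom$type <- "HETATM"
  merged_atom <- rbind(tgt$atom, comp_atom)
  merged_atom$eleno <- seq_len(nrow(merged_atom))
  rownames(merged_atom) <- NULL
  merged_xyz <- c(tgt$xyz, as.numeric(t(moved)))
  # clash report: transferred vs target heavy atoms < cutoff
  t_heavy <- which(!.is_hydrogen(tgt$atom))
  c_heavy <- which(!.is_hydrogen(comp_atom))
  clashes <- data.frame()
  if (length(t_heavy) > 0 && length(c_heavy) > 0) {
    dm <- .cross_dist(moved[c_heavy, , drop = FALSE],
                      .atom_coords(tgt, t_heavy))
    hit <- which(dm < clash_cutoff, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      clashes <- data.frame(
        component_atom = paste(comp_atom$resid[c_heavy[hit[, 1]]],
                               comp_atom$elety[c_heavy[hit[, 1]]]),
        protein_atom = paste(tgt$atom$resid[t_heavy[hit[, 2]]],
                             tgt$atom$resno[t_heavy[hit[, 2]]],
                             tgt$atom$elety[t_heavy[hit[, 2]]]),
        distance = dm[hit])
      clashes <- clashes[order(clashes$distance), ]
      rownames(clashes) <- NULL
    }
  }
  list(atom = merged_atom, xyz = merged_xyz, transform = tf,
       clashes = clashes, n_transferred = length(sel_rows))
}

#' Write a structure (atom table + xyz) as PDB
#'
#' Thin wrapper over \code{bio3d::write.pdb}.
#'
#' @param structure list with \code{atom} and \code{xyz} (as returned by
#'   \code{\link{transfer_components}}), or a bio3d \code{pdb}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  st <- .as_structure(structure)
  bio3d::write.pdb(xyz = st$xyz, type = st$atom$type, resno = st$atom$resno,
                   resid = st$atom$resid, eleno = st$atom$eleno,
                   elety = st$atom$elety, chain = st$atom$chain,
                   elesy = st$atom$elesy, file = path)
  invisible(path)
}
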