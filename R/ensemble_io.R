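#' Scored conformational ensembles
#'
#' A \code{scored_ensemble} bundles the all-atom coordinates of every model
#' of a conformational ensemble with one scalar score per model (Rosetta
#' convention: lower is better). All models share a single atom table; the
#' coordinates live in an \code{n_models x 3*n_atoms} matrix in bio3d's xyz
#' layout.
#'
#' @param atoms data.frame with at least \code{elety}, \code{resid},
#'   \code{chain}, \code{resno}, \code{elesy} (element symbol, may be NA).
#' @param xyz numeric matrix, one row per model, \code{3 * nrow(atoms)}
#'   columns.
#' @param scores numeric vector, one per model.
#' @param model_ids character vector of stable model identifiers.
#' @return an object of class \code{scored_ensemble} with fields
#'   \code{atoms}, \code{xyz}, \code{scores}, \code{model_ids},
#'   \code{sequence} (one-letter codes along the chain).
#' @export
scored_ensemble <- function(atoms, xyz, scores = NULL, model_ids = NULL) {
  xyz <- matrix(xyz, ncol = 3 * nrow(atoms))
  n <- nrow(xyz)
  if (n < 1) stop("ensemble must contain at least one model")
  if (is.null(scores)) scores <- rep(0, n)
  if (is.null(model_ids)) model_ids <- sprintf("model_%d", seq_len(n))
  if (length(scores) != n || length(model_ids) != n)
    stop("models, scores and model_ids must have equal length")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (!all(is.finite(scores))) stop("scores must be finite")
  ca <- atoms$elety == "CA"
  seq1 <- tryCatch(bio3d::aa321(atoms$resid[ca]), warning = function(w)
    suppressWarnings(bio3d::aa321(atoms$resid[ca])))
  structure(list(atoms = atoms, xyz = xyz, scores = as.numeric(scores),
                 model_ids = as.character(model_ids), sequence = seq1),
            class = "scored_ensemble")
}

#' @export
print.scored_ensemble <- function(x, ...) {
  cat(sprintf("scored_ensemble: %d models, %d atoms, %d residues\n",
              nrow(x$xyz), nrow(x$atoms), length(x$sequence)))
  cat(sprintf("  score range: [%.3f, %.3f]\n",
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' @export
length.scored_ensemble <- function(x) nrow(x$xyz)

# internal: per-MODEL-block atom keys for the consistency pre-scan.
# Returns a list of character vectors ("<elety>/<resno>"), one per block.
.scan_model_blocks <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    return(list(keys = list(.atom_keys(lines[is_atom])), serial = 1L))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) < length(model_starts))
    model_ends <- c(model_ends, length(lines))
  keys <- vector("list", length(model_starts))
  for (k in seq_along(model_starts)) {
    block <- lines[model_starts[k]:model_ends[k]]
    keys[[k]] <- .atom_keys(block[grepl("^(ATOM  |HETATM)", block)])
  }
  serial <- suppressWarnings(as.integer(substr(lines[model_starts], 11, 14)))
  if (anyNA(serial)) serial <- seq_along(model_starts)
  list(keys = keys, serial = serial)
}

.atom_keys <- function(atom_lines) {
  if (length(atom_lines) == 0) return(character(0))
  paste0(trimws(substr(atom_lines, 13, 16)), "/",
         trimws(substr(atom_lines, 22, 22)),
         trimws(substr(atom_lines, 23, 26)))
}

.check_model_consistency <- function(keys, labels) {
  ref <- keys[[1]]
  for (k in seq_along(keys)[-1]) {
    cur <- keys[[k]]
    if (identical(cur, ref)) next
    m <- min(length(ref), length(cur))
    diff1 <- which(ref[seq_len(m)] != cur[seq_len(m)])
    if (length(diff1) > 0) {
      stop(sprintf(
        "inconsistent atom sets: %s has atom '%s' where '%s' was expected (position %d)",
        labels[k], cur[diff1[1]], ref[diff1[1]], diff1[1]))
    }
    if (length(cur) < length(ref)) {
      stop(sprintf("inconsistent atom sets: %s lacks atom '%s' present in %s",
                   labels[k], ref[length(cur) + 1], labels[1]))
    }
    stop(sprintf("inconsistent atom sets: %s has extra atom '%s'",
                 labels[k], cur[length(ref) + 1]))
  }
  invisible(TRUE)
}

# internal: altloc filter on a bio3d atom table -- keep, per
# (chain, resno, insert, elety) group, the highest-occupancy location,
# ties broken in favour of altloc "A". Returns kept row indices.
.altloc_keep <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
  keep <- rep(TRUE, nrow(atom))
  for (g in split(seq_len(nrow(atom)), key)) {
    if (length(g) == 1) next
    best <- g[occ[g] == max(occ[g])]
    if (length(best) > 1) {
      a <- best[alt[best] == "A"]
      best <- if (length(a) > 0) a[1] else best[1]
    } else best <- best[1]
    keep[setdiff(g, best)] <- FALSE
  }
  keep
}

#' Read a multi-model coordinate file (or several single-model files)
#'
#' Parses PDB input into a \code{\link{scored_ensemble}}. One model is taken
#' per MODEL/ENDMDL block (or per file when \code{source} lists several
#' files). Scores are initialised to 0; attach real scores with
#' \code{\link{attach_scores}}. Only ATOM records of the selected chain are
#' retained; alternate locations are resolved to the highest-occupancy copy
#' (ties prefer altloc A).
#'
#' @param source path to a (multi-model) PDB file, or a character vector of
#'   single-model PDB paths with consistent atoms.
#' @param chain chain identifier to extract; default: the first chain
#'   containing CA atoms.
#' @return a \code{\link{scored_ensemble}}.
#' @export
read_model_ensemble <- function(source, chain = NULL) {
  if (length(source) == 0) stop("no input files given")
  if (length(source) == 1) {
    lines <- readLines(source, warn = FALSE)
    scan <- .scan_model_blocks(lines)
    if (length(scan$keys[[1]]) == 0) stop("zero models: no ATOM records found")
    .check_model_consistency(scan$keys,
                             sprintf("model %s", scan$serial))
    pdb <- bio3d::read.pdb(source, multi = TRUE, rm.alt = FALSE,
                           verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    ids <- sprintf("model_%d", scan$serial)
    ens <- list(atom = pdb$atom, xyz = xyz, ids = ids)
  } else {
    pdbs <- lapply(source, bio3d::read.pdb, rm.alt = FALSE, verbose = FALSE)
    keys <- lapply(pdbs, function(p)
      paste0(p$atom$elety, "/", p$atom$chain, p$atom$resno))
    .check_model_consistency(keys, basename(source))
    xyz <- do.call(rbind, lapply(pdbs, function(p) as.numeric(p$xyz)))
    ids <- sub("\\.[^.]*$", "", basename(source))
    ens <- list(atom = pdbs[[1]]$atom, xyz = xyz, ids = ids)
  }
  atom <- ens$atom
  keep <- .altloc_keep(atom) & atom$type == "ATOM"
  if (is.null(chain)) {
    ca_chains <- unique(atom$chain[keep & atom$elety == "CA"])
    if (length(ca_chains) == 0) stop("no protein chain (CA atoms) found")
    chain <- ca_chains[1]
  }
  keep <- keep & (atom$chain %in% chain | is.na(atom$chain))
  if (!any(keep)) stop(sprintf("chain '%s' selects no atoms", chain))
  idx <- which(keep)
  atoms <- atom[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  xyz <- ens$xyz[, bio3d::atom2xyz(idx), drop = FALSE]
  scored_ensemble(atoms, xyz, model_ids = ens$ids)
}

#' Attach per-model scores from a score table
#'
#' Reads a whitespace-delimited score table in the Rosetta scorefile
#' convention (optional leading \code{SCORE:} tokens, a header row naming the
#' columns) and replaces the ensemble's scores, matching rows to models by
#' identifier. Model order is preserved.
#'
#' @param ensemble a \code{\link{scored_ensemble}}.
#' @param table path to the score table, or its lines as a character vector.
#' @param score_col,id_col header names of the score and model-id columns.
#' @return the ensemble with \code{scores} replaced.
#' @export
attach_scores <- function(ensemble, table, score_col = "score",
                          id_col = "description") {
  stopifnot(inherits(ensemble, "scored_ensemble"))
  lines <- if (length(table) == 1 && file.exists(table))
    readLines(table, warn = FALSE) else as.character(table)
  lines_raw <- lines
  lines <- sub("^SCORE:\\s*", "", lines)
  keep <- which(trimws(lines) != "" & !grepl("^#", lines))
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  hdr_at <- which(vapply(toks, function(t) score_col %in% t && id_col %in% t,
                         logical(1)))
  if (length(hdr_at) == 0)
    stop(sprintf("score table has no header with columns '%s' and '%s'",
                 score_col, id_col))
  hdr <- toks[[hdr_at[1]]]
  si <- match(score_col, hdr); ii <- match(id_col, hdr)
  rows <- toks[seq_along(toks) > hdr_at[1]]
  row_lines <- keep[seq_along(toks) > hdr_at[1]]
  ids <- character(0); vals <- numeric(0)
  for (r in seq_along(rows)) {
    t <- rows[[r]]
    if (length(t) < max(si, ii)) next
    v <- suppressWarnings(as.numeric(t[si]))
    if (is.na(v))
      stop(sprintf("non-numeric score '%s' on line %d of score table",
                   t[si], row_lines[r]))
    ids <- c(ids, t[ii]); vals <- c(vals, v)
  }
  if (anyDuplicated(ids)) {
    for (d in unique(ids[duplicated(ids)])) {
      if (length(unique(vals[ids == d])) > 1)
        stop(sprintf("model id '%s' appears with differing scores", d))
    }
    first <- !duplicated(ids)
    ids <- ids[first]; vals <- vals[first]
  }
  m <- match(ensemble$model_ids, ids)
  if (anyNA(m))
    stop(sprintf("score table is missing model id(s): %s",
                 paste(ensemble$model_ids[is.na(m)], collapse = ", ")))
  ensemble$scores <- vals[m]
  ensemble
}

# internal: vectorised dihedral over all models of an xyz matrix.
# i1..i4 are atom (row) indices into the atom table.
.dihedral_models <- function(xyz, i1, i2, i3, i4) {
  p <- function(i) xyz[, bio3d::atom2xyz(i), drop = FALSE]
  a <- p(i1); b <- p(i2); cc <- p(i3); d <- p(i4)
  b1 <- b - a; b2 <- cc - b; b3 <- d - cc
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross(b2n, n1)
  wrap_angle(atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi)
}

#' One torsion observed across an ensemble
#'
#' @param residue_index 1-based chain position.
#' @param kind \code{"phi"} or \code{"psi"}.
#' @param angles degrees, one per model; wrapped to \code{[-180, 180)}.
#' @param weights nonnegative model weights; normalised to sum 1.
#' @return object of class \code{torsion_sample}.
#' @export
torsion_sample <- function(residue_index, kind = c("phi", "psi"), angles,
                           weights = NULL) {
  kind <- match.arg(kind)
  if (length(angles) < 1) stop("empty torsion sample")
  if (is.null(weights)) weights <- rep(1 / length(angles), length(angles))
  if (length(weights) != length(angles))
    stop("weights must match angle count")
  if (any(weights < 0) || !all(is.finite(weights)))
    stop("weights must be finite and nonnegative")
  weights <- weights / sum(weights)
  structure(list(residue_index = as.integer(residue_index), kind = kind,
                 angles = wrap_angle(as.numeric(angles)), weights = weights),
            class = "torsion_sample")
}

#' Extract backbone phi/psi torsions from an ensemble
#'
#' For a chain of L residues emits 2L-2 \code{\link{torsion_sample}}s:
#' phi (C(i-1)-N(i)-CA(i)-C(i)) for residues 2..L and
#' psi (N(i)-CA(i)-C(i)-N(i+1)) for residues 1..L-1. Weights start uniform;
#' reweight with \code{\link{score_weights}}.
#'
#' @param ensemble a \code{\link{scored_ensemble}} whose every residue has
#'   backbone N, CA and C atoms.
#' @return list of \code{torsion_sample} objects (phi block first, then psi),
#'   each carrying \code{residue_index} along the chain (1-based).
#' @export
extract_backbone_torsions <- function(ensemble) {
  stopifnot(inherits(ensemble, "scored_ensemble"))
  at <- ensemble$atoms
  resnos <- unique(at$resno)
  L <- length(resnos)
  if (L < 2) stop("need at least 2 residues for backbone torsions")
  bb <- matrix(NA_integer_, nrow = L, ncol = 3,
               dimnames = list(NULL, c("N", "CA", "C")))
  for (i in seq_len(L)) {
    rows <- which(at$resno == resnos[i])
    for (nm in c("N", "CA", "C")) {
      hit <- rows[at$elety[rows] == nm]
      if (length(hit) == 0)
        stop(sprintf("residue %s is missing backbone atom %s",
                     resnos[i], nm))
      bb[i, nm] <- hit[1]
    }
  }
  out <- vector("list", 2L * (L - 1L))
  k <- 0
  for (i in 2:L) {
    ang <- .dihedral_models(ensemble$xyz, bb[i - 1, "C"], bb[i, "N"],
                            bb[i, "CA"], bb[i, "C"])
    k <- k + 1
    out[[k]] <- torsion_sample(i, "phi", ang)
  }
  for (i in 1:(L - 1)) {
    ang <- .dihedral_models(ensemble$xyz, bb[i, "N"], bb[i, "CA"],
                            bb[i, "C"], bb[i + 1, "N"])
    k <- k + 1
    out[[k]] <- torsion_sample(i, "psi", ang)
  }
  out
}

#' Atom index quadruples for each backbone torsion
#'
#' Maps every phi/psi torsion of the ensemble's chain to the 1-based indices
#' of its four defining atoms in the ensemble atom table (the order atoms
#' appear in the PDB, which is also the 1-based numbering a matching
#' topology would use).
#'
#' @param ensemble a \code{\link{scored_ensemble}}.
#' @return data.frame with columns \code{residue_index}, \code{kind},
#'   \code{ai}, \code{aj}, \code{ak}, \code{al}.
#' @export
torsion_atom_indices <- function(ensemble) {
  at <- ensemble$atoms
  resnos <- unique(at$resno)
  L <- length(resnos)
  idx <- function(i, nm) {
    rows <- which(at$resno == resnos[i] & at$elety == nm)
    if (length(rows) == 0)
      stop(sprintf("residue %s is missing backbone atom %s", resnos[i], nm))
    rows[1]
  }
  recs <- list()
  for (i in 2:L)
    recs[[length(recs) + 1]] <- data.frame(
      residue_index = i, kind = "phi", ai = idx(i - 1, "C"),
      aj = idx(i, "N"), ak = idx(i, "CA"), al = idx(i, "C"))
  for (i in 1:(L - 1))
    recs[[length(recs) + 1]] <- data.frame(
      residue_index = i, kind = "psi", ai = idx(i, "N"),
      aj = idx(i, "CA"), ak = idx(i, "C"), al = idx(i + 1, "N"))
  do.call(rbind, recs)
}
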