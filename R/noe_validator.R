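#' Parse CYANA-style upper-limit distance restraints
#'
#' Reads lines of the form
#' \code{res_i name_i atom_i  res_j name_j atom_j  bound} (Angstrom), with
#' \code{#} comments. Wildcard and pseudoatom selectors are expanded against
#' the standard amino-acid proton nomenclature; duplicate records are
#' collapsed; malformed or unknown-residue lines are skipped with a warning
#' and collected in the report.
#'
#' @param text path to a .upl file, or its lines as a character vector.
#' @return object of class \code{noe_restraint_set}: \code{records}
#'   (data.frame with residue numbers/names, selectors, expanded proton
#'   lists, upper bound), \code{pairs} (unordered inter-residue pair index,
#'   columns \code{i}, \code{j} with \code{i < j}) and \code{report} (list
#'   of skipped lines).
#' @export
parse_upl <- function(text) {
  lines <- if (length(text) == 1 && file.exists(text))
    readLines(text, warn = FALSE) else as.character(text)
  body <- sub("#.*$", "", lines)
  skipped <- character(0)
  recs <- list()
  for (ln in seq_along(body)) {
    l <- trimws(body[ln])
    if (l == "") next
    tk <- strsplit(l, "\\s+")[[1]]
    if (length(tk) < 7) {
      skipped <- c(skipped, sprintf("line %d: expected 7 fields, got %d",
                                    ln, length(tk)))
      next
    }
    ri <- suppressWarnings(as.integer(tk[1]))
    rj <- suppressWarnings(as.integer(tk[4]))
    bound <- suppressWarnings(as.numeric(tk[7]))
    if (is.na(ri) || is.na(rj) || is.na(bound)) {
      skipped <- c(skipped, sprintf("line %d: non-numeric field", ln))
      next
    }
    pi_ <- expand_proton_selector(tk[2], tk[3])
    pj <- expand_proton_selector(tk[5], tk[6])
    if (is.null(pi_) || is.null(pj)) {
      bad <- if (is.null(pi_)) tk[2] else tk[5]
      warning(sprintf("line %d: unknown residue name '%s'; skipped", ln, bad))
      skipped <- c(skipped, sprintf("line %d: unknown residue '%s'", ln, bad))
      next
    }
    if (length(pi_) == 0 || length(pj) == 0) {
      skipped <- c(skipped,
                   sprintf("line %d: selector matches no proton", ln))
      next
    }
    recs[[length(recs) + 1]] <- data.frame(
      resno_i = ri, resid_i = toupper(tk[2]), selector_i = tk[3],
      resno_j = rj, resid_j = toupper(tk[5]), selector_j = tk[6],
      bound = bound,
      protons_i = paste(sort(pi_), collapse = ","),
      protons_j = paste(sort(pj), collapse = ","),
      stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) unique(do.call(rbind, recs)) else data.frame()
  if (nrow(records) == 0) stop("no valid restraints parsed (empty set)")
  rownames(records) <- NULL
  inter <- records[records$resno_i != records$resno_j, , drop = FALSE]
  pairs <- unique(data.frame(i = pmin(inter$resno_i, inter$resno_j),
                             j = pmax(inter$resno_i, inter$resno_j)))
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(records = records, pairs = pairs,
                 report = list(skipped = skipped)),
            class = "noe_restraint_set")
}

#' @export
print.noe_restraint_set <- function(x, ...) {
  cat(sprintf("noe_restraint_set: %d records, %d inter-residue pairs (%d lines skipped)\n",
              nrow(x$records), nrow(x$pairs), length(x$report$skipped)))
  invisible(x)
}

# internal: restraint pairs from flexible input
.as_pairs <- function(restraints) {
  if (inherits(restraints, "noe_restraint_set")) return(restraints$pairs)
  p <- as.data.frame(restraints)
  if (!all(c("i", "j") %in% names(p))) names(p)[1:2] <- c("i", "j")
  data.frame(i = pmin(p$i, p$j), j = pmax(p$i, p$j))
}

# internal: per-residue atom rows for the distance statistic.
# mode "proton": hydrogens; mode "heavy": non-hydrogens (proxy for missing
# protons; pair with a +1 A cutoff relaxation at the comparison site).
.residue_atom_rows <- function(atoms, resno, mode) {
  rows <- which(atoms$resno == resno)
  if (length(rows) == 0) stop(sprintf("residue %s missing from structure",
                                      resno))
  hyd <- .is_hydrogen(atoms[rows, , drop = FALSE])
  sel <- if (mode == "proton") rows[hyd] else rows[!hyd]
  if (length(sel) == 0) {
    if (mode == "proton")
      stop(sprintf("residue %s has no hydrogens; use mode = \"heavy\" (proxy) or add protons",
                   resno))
    stop(sprintf("residue %s has no heavy atoms", resno))
  }
  sel
}

#' Ensemble-averaged minimum interproton distance of a residue pair
#'
#' For each model, the minimum proton-proton distance between the two
#' residues is found; the values are averaged over models (plain mean; an
#' r^-6 ensemble average is available via \code{average = "r6"} for users who
#' want NOE-intensity-weighted averaging).
#'
#' @param ensemble a \code{\link{scored_ensemble}} (or anything
#'   \code{\link{transfer_components}} accepts for a single model).
#' @param i,j residue numbers.
#' @param mode \code{"proton"} (default) or \code{"heavy"} (proxy when the
#'   structure has no hydrogens).
#' @param average \code{"mean"} (default) or \code{"r6"}
#'   (\eqn{(\langle d^{-6}\rangle)^{-1/6}}).
#' @return distance in Angstrom.
#' @export
ensemble_min_distance <- function(ensemble, i, j,
                                  mode = c("proton", "heavy"),
                                  average = c("mean", "r6")) {
  mode <- match.arg(mode); average <- match.arg(average)
  ens <- if (inherits(ensemble, "scored_ensemble")) ensemble else {
    st <- .as_structure(ensemble)
    scored_ensemble(st$atom, matrix(st$xyz, nrow = 1))
  }
  ri <- .residue_atom_rows(ens$atoms, i, mode)
  rj <- .residue_atom_rows(ens$atoms, j, mode)
  per_model <- vapply(seq_len(nrow(ens$xyz)), function(m) {
    a <- matrix(ens$xyz[m, bio3d::atom2xyz(ri)], ncol = 3, byrow = TRUE)
    b <- matrix(ens$xyz[m, bio3d::atom2xyz(rj)], ncol = 3, byrow = TRUE)
    min(.cross_dist(a, b))
  }, numeric(1))
  if (average == "mean") mean(per_model)
  else mean(per_model^-6)^(-1 / 6)
}

#' Predict restrained residue pairs from a single structure
#'
#' Approximates a "measured" NOE pair set from one structure: every residue
#' pair (sequence separation > \code{exclude}) whose minimum interproton
#' distance is at most \code{cutoff} would be expected to give an NOE signal.
#' Useful when original restraint data are unavailable and a single
#' NOE-based reference structure must stand in for them.
#'
#' @param structure single-model structure (path, bio3d pdb, or
#'   \code{scored_ensemble} whose first model is used).
#' @param cutoff distance cutoff in Angstrom (default 6).
#' @param exclude sequence-neighbour exclusion window (default 1:
#'   \code{|i-j| <= 1} skipped).
#' @param mode \code{"proton"} or \code{"heavy"} proxy (adds 1 A to the
#'   cutoff to compensate for the missing proton extension).
#' @return data.frame of pairs (\code{i < j}).
#' @export
predict_restrained_pairs <- function(structure, cutoff = 6, exclude = 1,
                                     mode = c("proton", "heavy")) {
  mode <- match.arg(mode)
  st <- .as_structure(structure)
  ens <- scored_ensemble(st$atom, matrix(st$xyz, nrow = 1))
  resnos <- sort(unique(ens$atoms$resno))
  eff <- if (mode == "heavy") cutoff + 1.0 else cutoff
  out <- list()
  for (a in seq_along(resnos)) for (b in seq_along(resnos)) {
    if (b <= a) next
    if (abs(resnos[b] - resnos[a]) <= exclude) next
    d <- ensemble_min_distance(ens, resnos[a], resnos[b], mode = mode)
    if (d <= eff)
      out[[length(out) + 1]] <- data.frame(i = resnos[a], j = resnos[b])
  }
  if (length(out) == 0) return(data.frame(i = integer(0), j = integer(0)))
  do.call(rbind, out)
}

#' Residue-pair contact/restraint state matrix
#'
#' Classifies every residue pair (sequence separation > \code{exclude}) of
#' one ensemble: \code{"black"} if the ensemble-averaged minimum interproton
#' distance is within \code{cutoff} (close enough to produce an NOE signal),
#' \code{"red"} if it is not but a measured restraint links the pair
#' (violated restraint), \code{"white"} otherwise. Two matrices from
#' different ensembles can be combined into the asymmetric display form with
#' \code{\link{combine_contact_matrices}}.
#'
#' @param ensemble a \code{\link{scored_ensemble}}.
#' @param restraints a \code{noe_restraint_set} or a pair data.frame.
#' @param cutoff Angstrom (default 6).
#' @param exclude neighbour exclusion window (default 1).
#' @param mode \code{"proton"} or \code{"heavy"} proxy (cutoff relaxed 1 A).
#' @return object of class \code{contact_matrix}: \code{states} (L x L
#'   character matrix, NA on the excluded band), \code{distances},
#'   \code{resnos}, \code{cutoff}.
#' @export
contact_matrix <- function(ensemble, restraints, cutoff = 6, exclude = 1,
                           mode = c("proton", "heavy")) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stop("cutoff must be positive")
  pairs <- .as_pairs(restraints)
  pkey <- paste(pairs$i, pairs$j)
  resnos <- sort(unique(ensemble$atoms$resno))
  L <- length(resnos)
  eff <- if (mode == "heavy") cutoff + 1.0 else cutoff
  states <- matrix(NA_character_, L, L, dimnames = list(resnos, resnos))
  dists <- matrix(NA_real_, L, L, dimnames = list(resnos, resnos))
  for (a in seq_len(L)) for (b in seq_len(L)) {
    if (b <= a || abs(resnos[b] - resnos[a]) <= exclude) next
    d <- ensemble_min_distance(ensemble, resnos[a], resnos[b], mode = mode)
    st <- if (d <= eff) "black"
    else if (paste(resnos[a], resnos[b]) %in% pkey) "red"
    else "white"
    states[a, b] <- states[b, a] <- st
    dists[a, b] <- dists[b, a] <- d
  }
  structure(list(states = states, distances = dists, resnos = resnos,
                 cutoff = cutoff, exclude = exclude, mode = mode),
            class = "contact_matrix")
}

#' Combine two contact matrices into the asymmetric display form
#'
#' Lower triangle from \code{lower}, upper triangle from \code{upper}
#' (e.g. unrefined ensemble below the diagonal, refined ensemble above).
#'
#' @param lower,upper \code{contact_matrix} objects over the same residues.
#' @return a \code{contact_matrix} whose \code{states} mixes the triangles;
#'   \code{provenance} records which ensemble fills which triangle.
#' @export
combine_contact_matrices <- function(lower, upper) {
  stopifnot(identical(lower$resnos, upper$resnos))
  s <- lower$states
  s[upper.tri(s)] <- upper$states[upper.tri(s)]
  out <- lower
  out$states <- s
  out$distances[upper.tri(s)] <- upper$distances[upper.tri(s)]
  out$provenance <- c(lower = "lower", upper = "upper")
  out
}

#' Write a contact matrix as a TSV state table
#'
#' @param cm a \code{contact_matrix}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_contact_tsv <- function(cm, path) {
  utils::write.table(cm$states, path, sep = "\t", quote = FALSE,
                     na = ".", col.names = NA)
  invisible(path)
}

#' NOE fulfillment ratio of an ensemble
#'
#' Percentage of restrained residue pairs whose ensemble-averaged minimum
#' interproton distance is within the cutoff. The statistic is residue-level
#' (are the residues close enough to give an NOE signal), not proton-level.
#'
#' @inheritParams contact_matrix
#' @return percentage in [0, 100].
#' @export
fulfillment_ratio <- function(ensemble, restraints, cutoff = 6, exclude = 1,
                              mode = c("proton", "heavy")) {
  mode <- match.arg(mode)
  pairs <- .as_pairs(restraints)
  pairs <- pairs[abs(pairs$j - pairs$i) > exclude, , drop = FALSE]
  if (nrow(pairs) == 0) stop("empty restraint set after neighbour exclusion")
  eff <- if (mode == "heavy") cutoff + 1.0 else cutoff
  ok <- vapply(seq_len(nrow(pairs)), function(k)
    ensemble_min_distance(ensemble, pairs$i[k], pairs$j[k],
                          mode = mode) <= eff, logical(1))
  100 * mean(ok)
}

#' Per-model backbone RMSD against a reference
#'
#' Superposes each model onto the reference on the selected backbone atoms
#' (paired by residue number and atom name) and reports the fitted RMSD.
#'
#' @param models a \code{\link{scored_ensemble}} (or a bio3d multi-model
#'   pdb / path).
#' @param reference single-model reference structure.
#' @param fit_atoms atom names used for fitting and RMSD (default N, CA, C).
#' @return list with \code{rmsd} (one value per model, Angstrom),
#'   \code{mean}, \code{sd}.
#' @export
backbone_rmsd_series <- function(models, reference,
                                 fit_atoms = c("N", "CA", "C")) {
  ens <- if (inherits(models, "scored_ensemble")) models else
    read_model_ensemble(models)
  ref <- .as_structure(reference)
  er <- which(ens$atoms$elety %in% fit_atoms)
  rr <- which(ref$atom$elety %in% fit_atoms & ref$atom$type == "ATOM")
  ekey <- paste(ens$atoms$resno[er], ens$atoms$elety[er])
  rkey <- paste(ref$atom$resno[rr], ref$atom$elety[rr])
  shared <- intersect(ekey, rkey)
  if (length(shared) < 3) stop("no mappable backbone atoms")
  er <- er[match(shared, ekey)]
  rr <- rr[match(shared, rkey)]
  refxyz <- matrix(ref$xyz[bio3d::atom2xyz(rr)], ncol = 3, byrow = TRUE)
  vals <- vapply(seq_len(nrow(ens$xyz)), function(m) {
    mob <- matrix(ens$xyz[m, bio3d::atom2xyz(er)], ncol = 3, byrow = TRUE)
    kabsch_fit(refxyz, mob)$rmsd
  }, numeric(1))
  list(rmsd = vals, mean = mean(vals), sd = stats::sd(vals))
}
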