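#' Write one tabulated dihedral potential file
#'
#' Serialises a \code{\link{potential_table}} as XVG-style whitespace text:
#' three columns -- angle (degrees), PEF (kJ/mol), -dPEF (kJ/mol/degree) --
#' one row per grid point (-180..+180 inclusive). Comment lines record the
#' torsion identity, temperature and kernel bandwidth. Units are kJ/mol and
#' degrees throughout; consumers with radian-based table conventions must
#' rescale the force column.
#'
#' @param table a \code{potential_table} with its force column filled (it is
#'   filled on the fly if absent).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_dihedral_table <- function(table, path) {
  stopifnot(inherits(table, "potential_table"))
  if (is.null(table$force)) table <- potential_force(table)
  if (anyNA(table$pef) || anyNA(table$force) ||
      !all(is.finite(c(table$pef, table$force))))
    stop("NaN/Inf in potential table; refusing to write")
  bw <- if (!is.null(table$density)) table$density$bandwidth else NA
  hdr <- c(
    sprintf("# tabulated dihedral potential: %s residue %s",
            table$torsion_id["kind"], table$torsion_id["residue_index"]),
    sprintf("# temperature_K %g", table$temperature),
    sprintf("# bandwidth_deg %g", bw),
    "# columns: angle_deg pef_kJ_per_mol force_kJ_per_mol_per_deg",
    "@ xaxis label \"angle (degrees)\"")
  rows <- sprintf("%10.4f %.10e %.10e", table$grid, table$pef, table$force)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read back a tabulated dihedral potential file
#'
#' @param path file written by \code{\link{write_dihedral_table}} (or any
#'   three-column angle/energy/force text with #/@ comments).
#' @return a \code{potential_table} (no kernel density attached).
#' @export
read_dihedral_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[grepl("^[#@]", lines)]
  data <- lines[!grepl("^[#@]", lines) & trimws(lines) != ""]
  m <- do.call(rbind, lapply(strsplit(trimws(data), "\\s+"), as.numeric))
  if (ncol(m) < 3) stop("expected three columns: angle, pef, force")
  temp <- sub(".*temperature_K ", "", grep("temperature_K", meta, value = TRUE))
  temp <- if (length(temp)) as.numeric(temp[1]) else NA_real_
  kind <- NA_character_; resi <- NA_integer_
  id_line <- grep("tabulated dihedral potential:", meta, value = TRUE)
  if (length(id_line)) {
    tk <- strsplit(id_line[1], "\\s+")[[1]]
    kind <- tk[which(tk == "potential:") + 1]
    resi <- as.integer(tk[which(tk == "residue") + 1])
  }
  structure(list(grid = m[, 1], pef = m[, 2], force = m[, 3],
                 pef_offset = NA_real_, temperature = temp,
                 rt = GAS_CONSTANT_KJ * temp,
                 torsion_id = c(residue_index = resi, kind = kind),
                 density = NULL, grid_step = m[2, 1] - m[1, 1]),
            class = "potential_table")
}

#' Write a full set of dihedral tables with a manifest
#'
#' One table file per torsion, named \code{table_d<index>.xvg} with unique,
#' contiguous table indices starting at \code{start_index} (configurable so
#' indices do not collide with engine-reserved tables). A JSON manifest maps
#' each torsion to its file and index.
#'
#' @param tables list of \code{potential_table}s.
#' @param dir output directory (created if needed).
#' @param start_index first table index.
#' @return the manifest as a data.frame (\code{residue_index}, \code{kind},
#'   \code{table_index}, \code{file}); also written to
#'   \code{dir/manifest.json}.
#' @export
export_table_set <- function(tables, dir, start_index = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(tables)
  manifest <- data.frame(
    residue_index = vapply(tables, function(t)
      as.integer(t$torsion_id["residue_index"]), integer(1)),
    kind = vapply(tables, function(t) t$torsion_id[["kind"]], character(1)),
    table_index = start_index + seq_len(n) - 1L,
    file = sprintf("table_d%d.xvg", start_index + seq_len(n) - 1L),
    stringsAsFactors = FALSE)
  for (i in seq_len(n))
    write_dihedral_table(tables[[i]], file.path(dir, manifest$file[i]))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest
}

# internal: split GROMACS-dialect topology into lines with per-line section
# labels ([ defaults ], [ atoms ], [ dihedrals ], ...)
.top_sections <- function(lines) {
  sec <- character(length(lines))
  cur <- ""
  for (i in seq_along(lines)) {
    l <- sub(";.*$", "", lines[i])
    m <- regmatches(l, regexec("^\\s*\\[\\s*([A-Za-z0-9_]+)\\s*\\]", l))[[1]]
    if (length(m) == 2) cur <- m[2]
    sec[i] <- cur
  }
  sec
}

#' Patch a topology to use tabulated backbone dihedrals
#'
#' For every torsion in the manifest, locates the matching atom quadruple in
#' the topology's \code{[ dihedrals ]} section(s), comments out its native
#' proper-dihedral line(s) (function types 1/2/3/4/5/9; kept, not deleted,
#' for auditability) and inserts one tabulated-dihedral line
#' (function type 8, the torsion's table index, force constant 1.0).
#' All other lines are preserved byte for byte. Patching a topology that
#' already has a tabulated line for one of the quadruples is refused.
#'
#' @param topology topology text as a character vector of lines, or a file
#'   path.
#' @param manifest the data.frame returned by \code{\link{export_table_set}}.
#' @param atom_map data.frame mapping torsions to 1-based atom indices
#'   (columns \code{residue_index}, \code{kind}, \code{ai}, \code{aj},
#'   \code{ak}, \code{al}), e.g. from \code{\link{torsion_atom_indices}}.
#' @return object of class \code{topology_patch}: \code{original} and
#'   \code{patched} line vectors plus a \code{replacements} data.frame
#'   (quadruple, table index, number of native lines commented).
#' @export
patch_topology <- function(topology, manifest, atom_map) {
  lines <- if (length(topology) == 1 && file.exists(topology))
    readLines(topology, warn = FALSE) else as.character(topology)
  original <- lines
  if (nrow(manifest) == 0) {
    return(structure(list(original = original, patched = lines,
                          replacements = data.frame()),
                     class = "topology_patch"))
  }
  key <- c("residue_index", "kind")
  map <- merge(manifest, atom_map, by = key, sort = FALSE)
  if (nrow(map) < nrow(manifest))
    stop("atom_map does not cover all torsions in the manifest")
  sec <- .top_sections(lines)
  in_dih <- sec == "dihedrals"
  parse_dih <- function(l) {
    body <- sub(";.*$", "", l)
    if (trimws(body) == "" || grepl("^\\s*\\[", body)) return(NULL)
    tk <- strsplit(trimws(body), "\\s+")[[1]]
    if (length(tk) < 5) return(NULL)
    suppressWarnings(as.numeric(tk[1:5]))
  }
  parsed <- lapply(seq_along(lines), function(i)
    if (in_dih[i]) parse_dih(lines[i]) else NULL)
  quad_of <- function(p) paste(p[1:4], collapse = "-")
  rev_quad <- function(p) paste(rev(p[1:4]), collapse = "-")
  repl <- list()
  insertions <- list()  # line index -> new lines to add after
  for (r in seq_len(nrow(map))) {
    q <- c(map$ai[r], map$aj[r], map$ak[r], map$al[r])
    qf <- paste(q, collapse = "-")
    hit <- which(vapply(parsed, function(p)
      !is.null(p) && !anyNA(p[1:4]) &&
        (quad_of(p) == qf || rev_quad(p) == qf), logical(1)))
    if (length(hit) == 0)
      stop(sprintf("topology has no dihedral line for %s residue %d (atoms %s)",
                   map$kind[r], map$residue_index[r], qf))
    functs <- vapply(hit, function(i) parsed[[i]][5], numeric(1))
    if (any(functs == 8))
      stop(sprintf(
        "topology already contains a tabulated dihedral for atoms %s; refusing to re-patch",
        qf))
    bad <- !(functs %in% c(1, 2, 3, 4, 5, 9))
    if (any(bad))
      stop(sprintf("unrecognized dihedral function type %s for atoms %s",
                   functs[bad][1], qf))
    for (i in hit)
      lines[i] <- paste0("; replaced by tabulated dihedral: ", lines[i])
    new_line <- sprintf("%5d %5d %5d %5d     8 %5d     1.0  ; %s residue %d",
                        q[1], q[2], q[3], q[4], map$table_index[r],
                        map$kind[r], map$residue_index[r])
    last <- max(hit)
    insertions[[as.character(last)]] <-
      c(insertions[[as.character(last)]], new_line)
    repl[[r]] <- data.frame(residue_index = map$residue_index[r],
                            kind = map$kind[r],
                            ai = q[1], aj = q[2], ak = q[3], al = q[4],
                            table_index = map$table_index[r],
                            native_lines = length(hit))
  }
  if (length(insertions) > 0) {
    at <- sort(as.integer(names(insertions)), decreasing = TRUE)
    for (i in at) {
      add <- insertions[[as.character(i)]]
      lines <- append(lines, add, after = i)
    }
  }
  structure(list(original = original, patched = lines,
                 replacements = do.call(rbind, repl)),
            class = "topology_patch")
}

#' Recover table indices from a patched topology
#'
#' Parses function-type-8 dihedral lines out of a patched topology; used to
#' verify manifest/topology consistency.
#'
#' @param patched character vector of topology lines (or file path).
#' @return data.frame with \code{ai..al} and \code{table_index}.
#' @export
read_tabulated_dihedrals <- function(patched) {
  lines <- if (length(patched) == 1 && file.exists(patched))
    readLines(patched, warn = FALSE) else as.character(patched)
  sec <- .top_sections(lines)
  out <- list()
  for (i in which(sec == "dihedrals")) {
    body <- sub(";.*$", "", lines[i])
    if (trimws(body) == "" || grepl("^\\s*\\[", body)) next
    tk <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
    if (length(tk) >= 6 && !anyNA(tk[1:6]) && tk[5] == 8)
      out[[length(out) + 1]] <- data.frame(ai = tk[1], aj = tk[2],
                                           ak = tk[3], al = tk[4],
                                           table_index = tk[6])
  }
  if (length(out) == 0) return(data.frame())
  do.call(rbind, out)
}
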