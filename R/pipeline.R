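#' Pipeline run configuration
#'
#' Collects every tunable of the ensemble-to-potentials pipeline with its
#' default: simulation temperature 310 K, score-softening scale tau (NULL =
#' sd of scores), kernel bandwidth law (base 5 degrees at a 10,000-model
#' reference ensemble, clamped to [2, 30] degrees), 1-degree grid, 1e-6
#' uniform density floor, 6 Angstrom NOE cutoff, and the first tabulated
#' table index.
#'
#' @param temperature kelvin (> 0).
#' @param tau score-softening scale (NULL = sd of scores; Inf = unweighted).
#' @param base_bandwidth,n_ref,h_min,h_max bandwidth law parameters
#'   (degrees / model counts), see \code{\link{kde_bandwidth}}.
#' @param grid_step degrees.
#' @param density_floor uniform mixing fraction for regularization.
#' @param cutoff NOE distance cutoff, Angstrom.
#' @param table_start first tabulated-dihedral table index.
#' @param chain chain selector for input PDBs (NULL = first protein chain).
#' @param seed integer seed for any stochastic step.
#' @return object of class \code{run_config} (a validated list).
#' @export
run_config <- function(temperature = 310, tau = NULL, base_bandwidth = 5,
                       n_ref = 10000, h_min = 2, h_max = 30, grid_step = 1,
                       density_floor = 1e-6, cutoff = 6, table_start = 1,
                       chain = NULL, seed = 1) {
  pos <- c(temperature = temperature, base_bandwidth = base_bandwidth,
           n_ref = n_ref, h_min = h_min, h_max = h_max,
           grid_step = grid_step, density_floor = density_floor,
           cutoff = cutoff)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    stop(sprintf("config parameters must be strictly positive: %s",
                 paste(bad, collapse = ", ")))
  if (!is.null(tau) && (is.na(tau) || tau <= 0))
    stop("tau must be positive (or Inf, or NULL for the sd default)")
  structure(list(temperature = temperature, tau = tau,
                 base_bandwidth = base_bandwidth, n_ref = n_ref,
                 h_min = h_min, h_max = h_max, grid_step = grid_step,
                 density_floor = density_floor, cutoff = cutoff,
                 table_start = as.integer(table_start), chain = chain,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file path.
#' @return \code{read_run_config}: a \code{run_config};
#'   \code{write_run_config}: the path, invisibly.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(vals$tau) && is.character(vals$tau) && vals$tau == "Inf")
    vals$tau <- Inf
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config a \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  if (!is.null(out$tau) && is.infinite(out$tau)) out$tau <- "Inf"
  out <- out[!vapply(out, is.null, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the ensemble-to-tabulated-potentials pipeline
#'
#' Extracts backbone torsions from the scored ensemble, converts scores to
#' model weights, estimates each torsion's score-weighted circular density
#' with an ensemble-size-adapted bandwidth, Boltzmann-inverts at the
#' configured temperature, differentiates analytically, writes one tabulated
#' dihedral file per torsion plus a JSON manifest and run report, and (when
#' a topology is given) patches it so every backbone phi/psi uses its table.
#'
#' @param ensemble a \code{\link{scored_ensemble}} (scores attached).
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory.
#' @param topology optional topology lines or file path to patch.
#' @return list with \code{tables} (potential_table list), \code{manifest},
#'   \code{patch} (\code{topology_patch} or NULL), \code{report} (also
#'   written to \code{out_dir/report.json}; patched topology to
#'   \code{out_dir/NEW.TOP}).
#' @export
run_pipeline <- function(ensemble, config = run_config(), out_dir,
                         topology = NULL) {
  stopifnot(inherits(ensemble, "scored_ensemble"),
            inherits(config, "run_config"))
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  on_fail <- function(e) {
    if (created) unlink(out_dir, recursive = TRUE)
    stop(e)
  }
  tryCatch({
    samples <- extract_backbone_torsions(ensemble)
    w <- score_weights(ensemble$scores, tau = config$tau)
    n <- length(ensemble)
    h <- kde_bandwidth(n, config$base_bandwidth, config$n_ref,
                       config$h_min, config$h_max)
    tables <- lapply(samples, function(s) {
      s$weights <- w
      d <- weighted_circular_density(s, bandwidth = h,
                                     grid_step = config$grid_step,
                                     floor_mix = config$density_floor)
      potential_force(boltzmann_invert(d, config$temperature))
    })
    manifest <- export_table_set(tables, file.path(out_dir, "tables"),
                                 start_index = config$table_start)
    patch <- NULL
    if (!is.null(topology)) {
      amap <- torsion_atom_indices(ensemble)
      patch <- patch_topology(topology, manifest, amap)
      writeLines(patch$patched, file.path(out_dir, "NEW.TOP"))
    }
    report <- list(
      n_models = n, n_torsions = length(tables),
      temperature_K = config$temperature, bandwidth_deg = h,
      config = unclass(config)[!vapply(unclass(config), is.null,
                                       logical(1))],
      torsions = data.frame(
        residue_index = manifest$residue_index, kind = manifest$kind,
        table_index = manifest$table_index,
        bandwidth_deg = h,
        mode_deg = vapply(tables, function(t)
          t$grid[which.min(t$pef)], numeric(1)),
        barrier_kJ_mol = vapply(tables, function(t) max(t$pef),
                                numeric(1))))
    if (!is.null(report$config$tau) && is.infinite(report$config$tau))
      report$config$tau <- "Inf"
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    list(tables = tables, manifest = manifest, patch = patch,
         report = report)
  }, error = on_fail)
}

#' Index of the best-scoring model
#'
#' Lowest score wins (Rosetta convention); ties resolved by model order.
#'
#' @param ensemble a \code{\link{scored_ensemble}}.
#' @return integer model index.
#' @export
best_model <- function(ensemble) which.min(ensemble$scores)
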