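# Independent oracles, deliberately implemented on different routes than the
# package code they check.

# dihedral via acos of plane normals + triple-product sign (package uses the
# atan2 formulation)
oracle_dihedral <- function(a, b, c, d) {
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b - a, c - b)
  n2 <- cross(c - b, d - c)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosphi <- min(max(cosphi, -1), 1)
  s <- sign(sum(cross(n1, n2) * (c - b)))
  if (s == 0) s <- 1
  wrap_angle(s * acos(cosphi) * 180 / pi)
}

# brute-force wrapped-Gaussian KDE: explicit sum over 5 periodic images,
# same floor-mixing and grid renormalisation contract as the package
oracle_wrapped_density <- function(angles, weights, h, grid_step = 1,
                                   floor_mix = 1e-6) {
  grid <- seq(-180, 180, by = grid_step)
  raw <- vapply(grid, function(g) {
    tot <- 0
    for (m in seq_along(angles)) {
      for (k in -2:2) {
        x <- g - angles[m] + 360 * k
        tot <- tot + weights[m] * exp(-0.5 * (x / h)^2) / (h * sqrt(2 * pi))
      }
    }
    tot
  }, numeric(1))
  mixed <- (1 - floor_mix) * raw + floor_mix / 360
  mixed / (sum(mixed[-length(mixed)]) * grid_step)
}

# exhaustive interproton scan over an ensemble structure (list atom/xyz or
# scored_ensemble), returning the min proton-proton distance of a residue
# pair in one model
oracle_min_proton_dist <- function(atoms, xyz_model, i, j) {
  hyd <- function(r) {
    rows <- which(atoms$resno == r)
    rows[grepl("^H", trimws(atoms$elety[rows]))]
  }
  ai <- hyd(i); aj <- hyd(j)
  best <- Inf
  for (p in ai) for (q in aj) {
    cp <- xyz_model[(3 * p - 2):(3 * p)]
    cq <- xyz_model[(3 * q - 2):(3 * q)]
    best <- min(best, sqrt(sum((cp - cq)^2)))
  }
  best
}

# ML von Mises concentration from the mean resultant length (Fisher's
# piecewise approximation)
oracle_kappa_ml <- function(angles_deg) {
  th <- angles_deg * pi / 180
  r <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

circ_mean_deg <- function(angles_deg) {
  th <- angles_deg * pi / 180
  wrap_angle(atan2(mean(sin(th)), mean(cos(th))) * 180 / pi)
}

# absolute circular difference in degrees
circ_diff <- function(a, b) abs(wrap_angle(a - b))

# small helix-like scored ensemble written to disk and read back through the
# real readers
make_disk_ensemble <- function(n_residues = 4, n_models = 3, seed = 7,
                               dir = withr::local_tempdir(.local_envir =
                                 parent.frame())) {
  spec <- make_torsion_spec(n_residues)
  ens <- build_ensemble_structures(spec, n_models, seed = seed)
  pdb <- file.path(dir, "ens.pdb")
  sc <- file.path(dir, "scores.sc")
  write_ensemble_pdb(ens, pdb)
  write_score_table(ens, sc)
  list(ens = ens, pdb = pdb, scores = sc, dir = dir)
}
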