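# Synthetic ensembles with known ground truth: von Mises torsion mixtures,
# idealized backbones grown from those torsions, toy complexes and the file
# writers (multi-model PDB, score table, .upl) that let integration tests
# exercise the real readers.

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. \code{kappa = 0} gives the uniform
#' circular distribution.
#'
#' @param n sample size.
#' @param mu mean direction in degrees.
#' @param kappa concentration (>= 0).
#' @return angles in degrees, wrapped to \code{[-180, 180)}.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-10) return(stats::runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1
      out[i] <- sign(stats::runif(1) - 0.5) * acos(pmin(pmax(f, -1), 1))
    }
  }
  wrap_angle(out * 180 / pi + mu)
}

#' von Mises (mixture) log-density per degree
#'
#' @param x angles in degrees.
#' @param mu,kappa,w component means (degrees), concentrations, weights.
#' @return log-density values (probability per degree).
#' @export
dvonmises_mix <- function(x, mu, kappa, w = rep(1 / length(mu), length(mu))) {
  w <- w / sum(w)
  dens <- 0
  for (k in seq_along(mu)) {
    d <- (x - mu[k]) * pi / 180
    # scaled Bessel; switch to the asymptotic expansion where besselI
    # underflows (I0(k)e^-k ~ 1/sqrt(2 pi k) for large k)
    i0s <- besselI(kappa[k], 0, expon.scaled = TRUE)
    log_i0s <- if (is.finite(i0s) && i0s > 0) log(i0s) else
      -0.5 * log(2 * pi * kappa[k]) + log1p(1 / (8 * kappa[k]))
    logd <- kappa[k] * (cos(d) - 1) - log(2 * pi) - log_i0s
    dens <- dens + w[k] * exp(logd)
  }
  log(dens * pi / 180)
}

#' Per-torsion von Mises mixture specification
#'
#' Describes the ground-truth torsion distributions of a synthetic ensemble:
#' one mixture (means, concentrations, weights) per residue and torsion
#' kind. The default is a uniform helix-like spec (phi -60, psi -45,
#' kappa 8) for every residue.
#'
#' @param n_residues chain length (>= 2).
#' @param phi,psi lists with elements \code{mu}, \code{kappa} and optional
#'   \code{w} (vectors over mixture components), applied to every residue;
#'   alternatively a list of such lists, one per residue that carries the
#'   torsion (phi: residues 2..L, psi: residues 1..L-1).
#' @return object of class \code{torsion_spec}.
#' @export
make_torsion_spec <- function(n_residues,
                              phi = list(mu = -60, kappa = 8),
                              psi = list(mu = -45, kappa = 8)) {
  if (n_residues < 2) stop("need at least 2 residues")
  norm1 <- function(comp) {
    if (is.null(comp$w)) comp$w <- rep(1 / length(comp$mu), length(comp$mu))
    if (length(comp$mu) != length(comp$kappa) ||
        length(comp$mu) != length(comp$w))
      stop("mu, kappa and w must have equal length")
    if (any(comp$kappa < 0)) stop("kappa must be >= 0")
    if (any(comp$w < 0)) stop("mixture weights must be >= 0")
    comp$w <- comp$w / sum(comp$w)
    comp
  }
  expand <- function(x, m) {
    if (!is.null(x$mu)) x <- rep(list(x), m)
    if (length(x) != m) stop("per-residue spec list has wrong length")
    lapply(x, norm1)
  }
  structure(list(n_residues = as.integer(n_residues),
                 phi = expand(phi, n_residues - 1),   # residues 2..L
                 psi = expand(psi, n_residues - 1)),  # residues 1..L-1
            class = "torsion_spec")
}

#' Sample a scored torsion ensemble from a spec
#'
#' Draws per-model phi/psi angles from the spec's mixtures and assigns each
#' model a Rosetta-convention score: the negative log-likelihood of its
#' angles under the spec plus Gaussian noise (lower score = more probable
#' model), so scores are anti-correlated with sample likelihood.
#'
#' @param spec a \code{\link{make_torsion_spec}} result.
#' @param n_models number of models (>= 1).
#' @param seed integer seed (all randomness is derived from it).
#' @param score_noise_frac noise sd as a fraction of the score range
#'   (default 0.1).
#' @return list with \code{samples} (list of \code{\link{torsion_sample}}s,
#'   phi block for residues 2..L then psi for 1..L-1), \code{scores},
#'   \code{angles} (matrix, models x torsions) and \code{loglik}.
#' @export
sample_torsion_ensemble <- function(spec, n_models, seed = 1,
                                    score_noise_frac = 0.1) {
  stopifnot(inherits(spec, "torsion_spec"))
  if (n_models < 1) stop("n_models must be >= 1")
  set.seed(seed)
  L <- spec$n_residues
  draw_mix <- function(comp, n) {
    ki <- sample.int(length(comp$mu), n, replace = TRUE, prob = comp$w)
    ang <- numeric(n)
    for (k in unique(ki))
      ang[ki == k] <- rvonmises(sum(ki == k), comp$mu[k], comp$kappa[k])
    ang
  }
  samples <- list()
  angmat <- NULL
  loglik <- rep(0, n_models)
  for (i in seq_len(L - 1)) {      # phi of residue i+1
    comp <- spec$phi[[i]]
    ang <- draw_mix(comp, n_models)
    loglik <- loglik + dvonmises_mix(ang, comp$mu, comp$kappa, comp$w)
    samples[[length(samples) + 1]] <- torsion_sample(i + 1, "phi", ang)
    angmat <- cbind(angmat, ang)
  }
  for (i in seq_len(L - 1)) {      # psi of residue i
    comp <- spec$psi[[i]]
    ang <- draw_mix(comp, n_models)
    loglik <- loglik + dvonmises_mix(ang, comp$mu, comp$kappa, comp$w)
    samples[[length(samples) + 1]] <- torsion_sample(i, "psi", ang)
    angmat <- cbind(angmat, ang)
  }
  score <- -loglik
  rng <- diff(range(score))
  if (rng > 0 && score_noise_frac > 0)
    score <- score + stats::rnorm(n_models, 0, score_noise_frac * rng)
  colnames(angmat) <- vapply(samples, function(s)
    paste0(s$kind, s$residue_index), character(1))
  list(samples = samples, scores = score, angles = angmat, loglik = loglik)
}

# internal: NeRF-style atom placement from three frame atoms.
# Returns the point at distance `bond` from c, with angle(b,c,new) =
# angle_deg and dihedral(a,b,c,new) = torsion_deg.
.place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# ideal backbone geometry (Engh-Huber-like averages)
.BB <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
            b_n_h = 1.010, b_ca_ha = 1.090,
            a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
            a_ca_c_o = 120.5)

#' Grow an idealized backbone from phi/psi torsions
#'
#' Builds an all-trans (omega = 180) polypeptide backbone with fixed ideal
#' bond lengths and angles, placing N, CA, C, O plus pseudo-protons H
#' (amide) and HA per residue. Sufficient for torsion-extraction and
#' NOE-proximity tests; not a physically relaxed model.
#'
#' @param phi phi angles for residues 2..L (degrees).
#' @param psi psi angles for residues 1..L-1 (degrees).
#' @param sequence three-letter residue codes (length L, default all ALA).
#' @return list with a bio3d-style \code{atom} data.frame and an \code{xyz}
#'   coordinate vector.
#' @export
build_backbone <- function(phi, psi, sequence = NULL) {
  L <- length(phi) + 1
  if (length(psi) != L - 1) stop("need L-1 phi and L-1 psi angles")
  if (is.null(sequence)) sequence <- rep("ALA", L)
  if (length(sequence) != L) stop("sequence length must match torsions")
  g <- .BB
  N <- matrix(NA_real_, L, 3); CA <- N; C <- N; O <- N; H <- N; HA <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(L - 1)) {
    N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n,
                              g$a_ca_c_n, psi[i])
    CA[i + 1, ] <- .place_atom(CA[i, ], C[i, ], N[i + 1, ], g$b_n_ca,
                               g$a_c_n_ca, 180)  # trans peptide bond
    C[i + 1, ] <- .place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c,
                              g$a_n_ca_c, phi[i])
  }
  for (i in seq_len(L)) {
    tor_o <- if (i < L) psi[i] + 180 else 180
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o,
                          tor_o)
    H[i, ] <- if (i == 1)
      .place_atom(C[1, ], CA[1, ], N[1, ], g$b_n_h, 114, 180)
    else
      .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], g$b_n_h, 119, 180)
    HA[i, ] <- .place_atom(N[i, ], C[i, ], CA[i, ], g$b_ca_ha, 109, 120)
  }
  names_per_res <- c("N", "CA", "C", "O", "H", "HA")
  coords <- list(N, CA, C, O, H, HA)
  atom <- do.call(rbind, lapply(seq_len(L), function(i) {
    data.frame(type = "ATOM", eleno = 0L, elety = names_per_res,
               alt = NA_character_, resid = sequence[i],
               chain = "A", resno = i, insert = NA_character_,
               o = 1, b = 0,
               elesy = substr(names_per_res, 1, 1),
               stringsAsFactors = FALSE)
  }))
  atom$eleno <- seq_len(nrow(atom))
  xyz <- unlist(lapply(seq_len(L), function(i)
    as.numeric(t(do.call(rbind, lapply(coords, function(m) m[i, ]))))))
  list(atom = atom, xyz = xyz)
}

#' Build a scored ensemble of idealized structures from a torsion spec
#'
#' Samples torsions with \code{\link{sample_torsion_ensemble}} and grows one
#' idealized backbone per model, yielding a \code{\link{scored_ensemble}}
#' whose extracted torsions equal the sampled ones (up to geometry round-off)
#' and whose scores follow the Rosetta convention.
#'
#' @inheritParams sample_torsion_ensemble
#' @param sequence optional three-letter residue codes.
#' @return a \code{\link{scored_ensemble}} with attribute
#'   \code{"torsions"} holding the sampled \code{torsion_sample}s.
#' @export
build_ensemble_structures <- function(spec, n_models, seed = 1,
                                      sequence = NULL,
                                      score_noise_frac = 0.1) {
  ts <- sample_torsion_ensemble(spec, n_models, seed = seed,
                                score_noise_frac = score_noise_frac)
  L <- spec$n_residues
  phi_idx <- seq_len(L - 1)
  psi_idx <- (L - 1) + seq_len(L - 1)
  first <- NULL
  xyz <- matrix(NA_real_, n_models, 0)
  rows <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    st <- build_backbone(phi = ts$angles[m, phi_idx],
                         psi = ts$angles[m, psi_idx],
                         sequence = sequence)
    if (is.null(first)) {
      first <- st
      xyz <- matrix(NA_real_, n_models, length(st$xyz))
    }
    xyz[m, ] <- st$xyz
  }
  ens <- scored_ensemble(first$atom, xyz, scores = ts$scores)
  attr(ens, "torsions") <- ts$samples
  ens
}

#' Write a scored ensemble as a multi-model PDB file
#'
#' Each model is serialised with \code{bio3d::write.pdb} and wrapped in
#' MODEL/ENDMDL records.
#'
#' @param ensemble a \code{\link{scored_ensemble}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  at <- ensemble$atoms
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  out <- character(0)
  for (m in seq_len(nrow(ensemble$xyz))) {
    bio3d::write.pdb(xyz = ensemble$xyz[m, ], type = at$type,
                     resno = at$resno, resid = at$resid, eleno = at$eleno,
                     elety = at$elety, chain = at$chain, elesy = at$elesy,
                     file = tmp)
    lines <- readLines(tmp, warn = FALSE)
    lines <- lines[!grepl("^END", lines)]
    out <- c(out, sprintf("MODEL     %4d", m), lines, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Write a Rosetta-style score table for an ensemble
#'
#' @param ensemble a \code{\link{scored_ensemble}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_score_table <- function(ensemble, path) {
  lines <- c("SCORE: score description",
             sprintf("SCORE: %.4f %s", ensemble$scores, ensemble$model_ids))
  writeLines(lines, path)
  invisible(path)
}

#' Write residue-pair restraints as a CYANA-style .upl file
#'
#' @param records data.frame with columns \code{resno_i}, \code{resid_i},
#'   \code{atom_i}, \code{resno_j}, \code{resid_j}, \code{atom_j},
#'   \code{bound}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_upl <- function(records, path) {
  lines <- sprintf("%4d %-4s %-5s %4d %-4s %-5s %6.2f",
                   records$resno_i, records$resid_i, records$atom_i,
                   records$resno_j, records$resid_j, records$atom_j,
                   records$bound)
  writeLines(lines, path)
  invisible(path)
}

# internal: random proper rotation (QR of a Gaussian matrix, det-corrected)
.random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Build a toy protein-ligand complex plus perturbed targets
#'
#' Constructs an idealized helical protein with pseudo-protons, adds a rigid
#' dummy "ligand" (HETATM records, residue name LIG) in a surface pocket
#' near the chain midpoint, and produces perturbed protein-only copies via
#' known rigid transforms plus optional per-atom Gaussian noise.
#'
#' @param n_residues chain length (>= 4).
#' @param ligand_atoms number of dummy ligand atoms.
#' @param seed integer seed.
#' @param n_targets number of perturbed copies.
#' @param sigma per-atom Gaussian noise sd in Angstrom (default 0).
#' @return list with \code{reference} (protein + ligand), \code{protein}
#'   (protein only), \code{targets} (list of perturbed copies),
#'   \code{transforms} (the rigid transforms applied, as
#'   rotation/translation lists).
#' @export
build_toy_complex <- function(n_residues = 8, ligand_atoms = 5, seed = 1,
                              n_targets = 3, sigma = 0) {
  if (n_residues < 4) stop("need at least 4 residues")
  set.seed(seed)
  phi <- rep(-60, n_residues - 1)
  psi <- rep(-45, n_residues - 1)
  prot <- build_backbone(phi, psi)
  ca <- which(prot$atom$elety == "CA")
  mid <- matrix(prot$xyz[bio3d::atom2xyz(ca)], ncol = 3, byrow = TRUE)
  center <- colMeans(mid)
  pocket <- mid[ceiling(length(ca) / 2), ]
  dir_out <- pocket - center
  dir_out <- dir_out / max(sqrt(sum(dir_out^2)), 1e-9)
  lig_xyz <- t(vapply(seq_len(ligand_atoms), function(k)
    pocket + 4 * dir_out + stats::rnorm(3, 0, 1.2), numeric(3)))
  # keep the pocket clash-free: push the ligand outward until every atom is
  # at least 2.5 A from the protein
  prot_mat <- matrix(prot$xyz, ncol = 3, byrow = TRUE)
  for (it in 1:20) {
    if (min(.cross_dist(lig_xyz, prot_mat)) >= 2.5) break
    lig_xyz <- sweep(lig_xyz, 2, dir_out, "+")
  }
  lig_atom <- data.frame(type = "HETATM",
                         eleno = nrow(prot$atom) + seq_len(ligand_atoms),
                         elety = sprintf("C%d", seq_len(ligand_atoms)),
                         alt = NA_character_, resid = "LIG", chain = "A",
                         resno = n_residues + 10L, insert = NA_character_,
                         o = 1, b = 0, elesy = "C", stringsAsFactors = FALSE)
  reference <- list(atom = rbind(prot$atom, lig_atom),
                    xyz = c(prot$xyz, as.numeric(t(lig_xyz))))
  targets <- list(); transforms <- list()
  for (k in seq_len(n_targets)) {
    rot <- .random_rotation()
    tr <- stats::rnorm(3, 0, 5)
    m <- matrix(prot$xyz, ncol = 3, byrow = TRUE)
    moved <- sweep(m %*% t(rot), 2, -tr)
    if (sigma > 0) moved <- moved + matrix(stats::rnorm(length(moved), 0,
                                                        sigma), ncol = 3)
    targets[[k]] <- list(atom = prot$atom, xyz = as.numeric(t(moved)))
    transforms[[k]] <- list(rotation = rot, translation = tr)
  }
  list(reference = reference, protein = prot, targets = targets,
       transforms = transforms)
}

#' Write a toy GROMACS-dialect topology for an ensemble's chain
#'
#' Emits a minimal topology with \code{[ moleculetype ]}, \code{[ atoms ]}
#' and \code{[ dihedrals ]} sections. The dihedrals section lists one
#' proper-dihedral line (function type 9) per backbone phi/psi quadruple
#' plus untouchable non-backbone lines (the O-improper-like quadruples), so
#' topology patching can be exercised on a realistic layout.
#'
#' @param ensemble a \code{\link{scored_ensemble}}.
#' @return character vector of topology lines.
#' @export
make_toy_topology <- function(ensemble) {
  at <- ensemble$atoms
  amap <- torsion_atom_indices(ensemble)
  lines <- c("; toy topology", "[ moleculetype ]",
             "; name  nrexcl", "Protein   3", "", "[ atoms ]",
             ";   nr  type  resnr  resid  atom  cgnr  charge")
  lines <- c(lines, sprintf("%6d %5s %6d %6s %5s %5d %8.3f",
                            seq_len(nrow(at)), at$elesy, at$resno,
                            at$resid, at$elety, seq_len(nrow(at)), 0))
  lines <- c(lines, "", "[ dihedrals ]",
             ";  ai    aj    ak    al  funct  params")
  for (r in seq_len(nrow(amap)))
    lines <- c(lines, sprintf("%5d %5d %5d %5d     9   180.0  4.6  2",
                              amap$ai[r], amap$aj[r], amap$ak[r],
                              amap$al[r]))
  # non-backbone-torsion lines (carbonyl O quadruples); must stay untouched
  resnos <- unique(at$resno)
  for (i in seq_along(resnos)) {
    rows <- which(at$resno == resnos[i])
    o <- rows[at$elety[rows] == "O"]
    n <- rows[at$elety[rows] == "N"]
    ca <- rows[at$elety[rows] == "CA"]
    cc <- rows[at$elety[rows] == "C"]
    if (length(o) && length(n) && length(ca) && length(cc))
      lines <- c(lines, sprintf("%5d %5d %5d %5d     4   180.0 43.9  2",
                                ca[1], n[1], o[1], cc[1]))
  }
  lines
}
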