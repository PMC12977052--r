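# tiny hand-built ensemble: residues with single protons at controlled
# positions, so every distance is known exactly
place_h_ensemble <- function(coords_by_model) {
  # coords_by_model: list of matrices (residues x 3)
  nres <- nrow(coords_by_model[[1]])
  atom <- do.call(rbind, lapply(seq_len(nres), function(i)
    data.frame(type = "ATOM", eleno = 0L, elety = c("CA", "HA"),
               alt = NA, resid = "ALA", chain = "A", resno = i,
               insert = NA, o = 1, b = 0, elesy = c("C", "H"),
               stringsAsFactors = FALSE)))
  atom$eleno <- seq_len(nrow(atom))
  xyz <- do.call(rbind, lapply(coords_by_model, function(m) {
    # CA at the stated point, HA 0.5 A above it in z
    out <- numeric(0)
    for (i in seq_len(nres))
      out <- c(out, m[i, ], m[i, ] + c(0, 0, 0.5))
    out
  }))
  scored_ensemble(atom, xyz)
}

line_coords <- function(gaps) {
  # residues along x with the stated consecutive gaps
  x <- cumsum(c(0, gaps))
  cbind(x, 0, 0)
}

test_that("upl parsing expands wildcards and pseudoatoms, deduplicates", {
  r <- parse_upl("12 ALA HA 47 LEU HB* 5.5")
  expect_equal(nrow(r$records), 1)
  expect_equal(r$records$protons_j, "HB2,HB3")
  expect_equal(r$pairs, data.frame(i = 12L, j = 47L))

  dup <- parse_upl(c("12 ALA HA 47 LEU HB* 5.5",
                     "12 ALA HA 47 LEU HB* 5.5",
                     "# a comment",
                     "3 VAL QQG 9 PHE QR 6.0"))
  expect_equal(nrow(dup$records), 2)
  qr <- dup$records[dup$records$resno_i == 3, ]
  expect_equal(qr$protons_i, "HG11,HG12,HG13,HG21,HG22,HG23")
  expect_equal(qr$protons_j, "HD1,HD2,HE1,HE2,HZ")

  expect_error(parse_upl(c("# only", "# comments")), "empty")
  expect_warning(r2 <- parse_upl(c("1 ALA HA 5 XXX HB2 4.0",
                                   "1 ALA HA 6 GLY QA 4.0")),
                 "unknown residue")
  expect_equal(nrow(r2$records), 1)
  expect_length(r2$report$skipped, 1)
})

test_that("ensemble minimum distances match brute force and average rules", {
  m1 <- line_coords(c(4, 4))   # residues 1,2,3: pair (1,3) at 8 A (CA)
  m2 <- line_coords(c(2, 2))   # pair (1,3) at 4 A
  ens <- place_h_ensemble(list(m1, m2))
  # single model: that model's minimum
  e1 <- place_h_ensemble(list(m1))
  expect_equal(ensemble_min_distance(e1, 1, 3), 8)
  # two models, minima 8 and 4 -> mean 6
  expect_equal(ensemble_min_distance(ens, 1, 3), 6)
  expect_error(ensemble_min_distance(ens, 1, 9), "residue 9")

  # brute-force oracle over a 10-model synthetic ensemble
  toy <- build_toy_complex(n_residues = 6, seed = 5)$protein
  set.seed(6)
  xyz <- do.call(rbind, lapply(1:10, function(m)
    toy$xyz + rnorm(length(toy$xyz), 0, 0.4)))
  tens <- scored_ensemble(toy$atom, xyz)
  d_pkg <- ensemble_min_distance(tens, 2, 5)
  d_oracle <- mean(vapply(1:10, function(m)
    oracle_min_proton_dist(toy$atom, xyz[m, ], 2, 5), numeric(1)))
  expect_equal(d_pkg, d_oracle, tolerance = 1e-9)
})

test_that("predicted restrained pairs equal an exhaustive proton scan", {
  toy <- build_toy_complex(n_residues = 7, seed = 8)$protein
  got <- predict_restrained_pairs(toy, cutoff = 6)
  # oracle: all-pair scan
  want <- list()
  for (i in 1:7) for (j in 1:7) {
    if (j <= i + 1) next
    d <- oracle_min_proton_dist(toy$atom, toy$xyz, i, j)
    if (d <= 6) want[[length(want) + 1]] <- c(i, j)
  }
  want <- do.call(rbind, want)
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$i, got$j), paste(want[, 1], want[, 2]))

  # threshold inclusivity: closest protons at 5.9 in, 6.1 out
  e59 <- place_h_ensemble(list(line_coords(c(2.95, 2.95))))
  e61 <- place_h_ensemble(list(line_coords(c(3.05, 3.05))))
  expect_true("1 3" %in% with(predict_restrained_pairs(e59, 6),
                              paste(i, j)))
  expect_false("1 3" %in% with(predict_restrained_pairs(e61, 6),
                               paste(i, j)))
})

test_that("contact matrix classifies black/red/white by the 6 A rule", {
  # residues on a line: pair (1,3) at 5 A, (1,4) at 7 A, (2,4) at 7 A
  ens <- place_h_ensemble(list(line_coords(c(2.5, 2.5, 4.5))))
  restraints <- data.frame(i = c(1, 1), j = c(3, 4))
  cm <- contact_matrix(ens, restraints, cutoff = 6)
  expect_equal(cm$states["1", "3"], "black")  # restrained and close
  expect_equal(cm$states["1", "4"], "red")    # restrained but 7 A
  expect_equal(cm$states["2", "4"], "white")  # unrestrained and 7 A
  expect_true(is.na(cm$states["1", "2"]))     # neighbour band excluded
  expect_true(is.na(cm$states["2", "2"]))
  # symmetric per ensemble; states partition counted pairs
  expect_equal(cm$states["3", "1"], "black")
  counted <- cm$states[!is.na(cm$states)]
  expect_true(all(counted %in% c("black", "red", "white")))

  # asymmetric combination holds each triangle's provenance
  ens2 <- place_h_ensemble(list(line_coords(c(2.0, 2.0, 2.0))))
  cm2 <- contact_matrix(ens2, restraints, cutoff = 6)
  both <- combine_contact_matrices(cm, cm2)
  expect_equal(both$states["4", "1"], cm$states["4", "1"])   # lower
  expect_equal(both$states["1", "4"], cm2$states["1", "4"])  # upper

  tsv <- tempfile(fileext = ".tsv")
  write_contact_tsv(both, tsv)
  back <- utils::read.table(tsv, sep = "\t", header = TRUE, row.names = 1,
                            na.strings = ".", check.names = FALSE)
  expect_equal(unname(as.matrix(back)["1", "4"]), both$states["1", "4"])
})

test_that("fulfillment ratio counts restrained pairs within cutoff", {
  # 4 restrained pairs at 5, 5, 5 and 7 A -> 75%
  ens <- place_h_ensemble(list(line_coords(c(2.5, 2.5, 2.0, 3.0))))
  # pairs: (1,3)=5, (2,4)=4.5, (3,5)=5, (1,4)=7
  restraints <- data.frame(i = c(1, 2, 3, 1), j = c(3, 4, 5, 4))
  expect_equal(fulfillment_ratio(ens, restraints, cutoff = 6), 75)
  expect_equal(fulfillment_ratio(ens, restraints[1:3, ], cutoff = 6), 100)
  expect_error(fulfillment_ratio(ens, restraints[0, ], cutoff = 6), "empty")

  # monotone non-decreasing in the cutoff
  ratios <- vapply(c(4, 5, 6, 8, 12), function(cu)
    fulfillment_ratio(ens, restraints, cutoff = cu), numeric(1))
  expect_true(all(diff(ratios) >= 0))

  # ratio equals 100 * black_restrained / (black_restrained + red)
  cm <- contact_matrix(ens, restraints, cutoff = 6)
  key <- paste(restraints$i, restraints$j)
  st <- vapply(seq_len(nrow(restraints)), function(k)
    cm$states[as.character(restraints$i[k]),
              as.character(restraints$j[k])], character(1))
  expect_equal(fulfillment_ratio(ens, restraints, 6),
               100 * sum(st == "black") / (sum(st == "black") +
                                             sum(st == "red")))
})

test_that("restraints predicted from a structure are 100% fulfilled by it", {
  toy <- build_toy_complex(n_residues = 8, seed = 13)$protein
  ens1 <- scored_ensemble(toy$atom, matrix(toy$xyz, nrow = 1))
  pairs <- predict_restrained_pairs(ens1, cutoff = 6)
  expect_gt(nrow(pairs), 0)
  expect_equal(fulfillment_ratio(ens1, pairs, cutoff = 6), 100)
})

test_that("statistics ignore model order and degrade with noise", {
  toy <- build_toy_complex(n_residues = 8, seed = 17)$protein
  pairs <- predict_restrained_pairs(
    scored_ensemble(toy$atom, matrix(toy$xyz, nrow = 1)), cutoff = 6)
  noisy <- function(sigma, seed) {
    set.seed(seed)
    xyz <- do.call(rbind, lapply(1:6, function(m)
      toy$xyz + rnorm(length(toy$xyz), 0, sigma)))
    scored_ensemble(toy$atom, xyz)
  }
  ens <- noisy(1.0, 23)
  perm <- ens
  perm$xyz <- ens$xyz[6:1, , drop = FALSE]
  expect_equal(fulfillment_ratio(ens, pairs, 6),
               fulfillment_ratio(perm, pairs, 6))
  # fulfillment non-increasing with noise amplitude (averaged over seeds)
  f_at <- function(sigma) mean(vapply(1:3, function(s)
    fulfillment_ratio(noisy(sigma, s), pairs, 6), numeric(1)))
  f0 <- f_at(0); f2 <- f_at(2); f5 <- f_at(5)
  expect_equal(f0, 100)
  expect_true(f2 >= f5)
  expect_true(f0 >= f2)
})

test_that("backbone RMSD series is zero for rigid copies, matches bio3d", {
  toy <- build_toy_complex(n_residues = 8, seed = 19, n_targets = 2,
                           sigma = 0)
  ref <- toy$protein
  ens <- scored_ensemble(ref$atom,
                         rbind(ref$xyz, toy$targets[[1]]$xyz,
                               toy$targets[[2]]$xyz))
  rs <- backbone_rmsd_series(ens, ref)
  expect_equal(rs$rmsd, rep(0, 3), tolerance = 1e-9)
  expect_equal(rs$mean, 0, tolerance = 1e-9)

  # displaced copy: compare against bio3d's fit as independent oracle
  disp <- ref$xyz
  ca1 <- which(ref$atom$elety == "CA")[1]
  disp[3 * ca1 - 2] <- disp[3 * ca1 - 2] + 1.0
  ens2 <- scored_ensemble(ref$atom, matrix(disp, nrow = 1))
  rs2 <- backbone_rmsd_series(ens2, ref)
  bb <- which(ref$atom$elety %in% c("N", "CA", "C"))
  inds <- bio3d::atom2xyz(bb)
  fitted <- bio3d::fit.xyz(fixed = ref$xyz, mobile = disp,
                           fixed.inds = inds, mobile.inds = inds)
  oracle_rmsd <- sqrt(sum((ref$xyz[inds] - fitted[inds])^2) / length(bb))
  expect_equal(rs2$rmsd, oracle_rmsd, tolerance = 1e-6)
  # closed-form bound: refit can only reduce sqrt(d^2/N)
  expect_lte(rs2$rmsd, sqrt(1 / length(bb)) + 1e-9)
  expect_gt(rs2$rmsd, 0.5 * sqrt(1 / length(bb)))
})
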