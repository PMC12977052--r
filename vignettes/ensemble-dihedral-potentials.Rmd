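---
title: "From scored ensembles to tabulated dihedral potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From scored ensembles to tabulated dihedral potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsionpef)
```

## The problem

Chemical-shift-guided structure prediction (CS-Rosetta and relatives)
produces large ensembles of candidate models, each with an empirical score
(lower = better). The information those ensembles carry most directly is the
distribution of the backbone torsion angles φ (C~i−1~–N~i~–Cα~i~–C~i~) and
ψ (N~i~–Cα~i~–C~i~–N~i+1~). `torsionpef` turns those distributions into
smooth, differentiable restraining potentials that an MD engine can use in
place of its native backbone torsion terms, so that a refinement simulation
explores conformations consistent with the experimental ensemble without
recomputing chemical shifts at every step.

## The model

For each torsion $\alpha$ the package estimates a score-weighted periodic
density and Boltzmann-inverts it at the simulation temperature:

$$\mathrm{PEF}(\alpha) = -RT \,\ln P(\alpha),$$

with $R = 8.31446\times10^{-3}$ kJ mol^−1^ K^−1^. Introducing the physical
temperature here (rather than rescaling each potential to the native force
field's torsional fluctuations) makes the restraint magnitudes consistent
across torsions and trivially transferable to another simulation
temperature: the potentials are exactly linear in $T$ at fixed density, so a
run at 350 K simply scales every PEF by 350/310.

The steps, each an exported function:

1. **Weights** (`score_weights`): $w_m \propto e^{-(s_m - \min s)/\tau}$.
   The softening scale τ defaults to the standard deviation of the scores —
   scale-free after the min shift, monotone in the score, and degrading to
   uniform weights when scores are uninformative (τ = ∞ reproduces the
   unweighted estimate).
2. **Density** (`weighted_circular_density`): a wrapped-Gaussian kernel
   density on a 1° grid from −180° to +180° (duplicated periodic endpoint,
   the tabulated-file convention). The wrapped kernel is summed over ±2
   periodic images, which is exact to well below 10^−9^ for bandwidths up to
   60°. A wrapped Gaussian was chosen over a von Mises kernel because its
   derivative is equally cheap and analytic, which the force column uses.
3. **Bandwidth** (`kde_bandwidth`): $h(n) = h_0 (n_\mathrm{ref}/n)^{1/5}$
   with $h_0 = 5°$ at $n_\mathrm{ref} = 10{,}000$ models, clamped to
   [2°, 30°]. The 1/5 exponent is the Silverman rate, so smaller ensembles
   (e.g. 100 models from a restraint-assisted protocol instead of 10,000)
   get proportionally wider kernels.
4. **Regularization**: the density is mixed with a uniform floor
   (ε = 10^−6^ of the mass) and renormalised before the logarithm. Without
   it, never-visited regions would invert to infinite barriers; with it,
   barrier heights are capped at roughly $RT\ln(P_\mathrm{max}\cdot 360 /
   \varepsilon)$ and the potential stays finite and differentiable
   everywhere.
5. **Inversion and force** (`boltzmann_invert`, `potential_force`): the PEF
   is gauge-shifted so its minimum is 0 (the shift is retained in
   `pef_offset` and does not affect forces). The restraining force
   $-d\mathrm{PEF}/d\alpha$ is computed analytically through the kernel
   chain rule ($RT\,P'/P$); a periodic central-difference path exists for
   tables without an attached density and agrees to second order in the
   grid step.

Each torsion is treated independently; no φ/ψ coupling terms are built.
Iterative (self-consistent) Boltzmann inversion is deliberately out of
scope: the potentials are a one-shot conversion of the ensemble statistics.

## Export

`export_table_set` writes one XVG-style three-column table per torsion
(angle in degrees, energy in kJ/mol, force in kJ/mol/degree — consumers
whose table convention is per-radian must rescale the third column) with
unique contiguous table indices from a configurable start, plus a JSON
manifest. `patch_topology` rewrites a GROMACS-dialect topology: every
backbone φ/ψ quadruple's native proper-dihedral lines (function types
1/2/3/4/5/9) are commented out — kept, not deleted, for auditability — and
one tabulated-dihedral line (function type 8, force constant 1.0) is
inserted per torsion. Re-patching an already patched topology is refused.
All other lines survive byte for byte.

## Ligand reinsertion

Ensemble predictors ignore nonprotein components, so `transfer_components`
superposes a reference complex onto the chosen model (Kabsch fit on shared
Cα atoms paired by residue number; `fit_atoms = c("N","CA","C")` for a
full-backbone fit) and carries the selected HETATM records across. Cα-only
fitting was chosen as the default because it is robust to side-chain
divergence between the crystal reference and the predicted model. Steric
clashes (heavy-atom pairs under 2.0 Å) are reported, never repaired —
relaxation is the MD engine's job. No docking fallback is provided; a
reference pose is required.

## NOE validation

`parse_upl` reads CYANA-style upper-limit restraints, expanding wildcard
(`HB*`) and pseudoatom (`QB`, `QQD`, `QR`, …) selectors against a standard
amino-acid proton nomenclature table. The validation statistic is
residue-level: a pair "forms an NOE signal" when the mean over models of
the per-model minimum interproton distance is within 6 Å (the conventional
NOE observability limit; configurable). `contact_matrix` classifies every
pair with sequence separation > 1 as black (close), red (restrained but
far — a violated restraint), or white, and two ensembles can share one
asymmetric matrix for display. `fulfillment_ratio` is the percentage of
restrained pairs that are black.

Design choices a user should know:

* The distance statistic is a plain mean of per-model minima, matching the
  proximity rule above; $\langle r^{-6}\rangle^{-1/6}$ averaging is
  available (`average = "r6"`) but not the default.
* Sequence neighbours ($|i-j| \le 1$) are excluded from matrices and
  ratios as trivially close.
* For structures without hydrogens a heavy-atom proxy mode relaxes the
  cutoff by 1.0 Å (roughly one C–H bond); it is off by default.
* When no measured restraints exist, `predict_restrained_pairs` derives a
  pseudo-restraint set from a single reference structure: every pair whose
  protons come within the cutoff. A single rigid structure cannot average
  out flexible regions, so this overpredicts restraints relative to real
  NOESY data — fulfillment ratios computed against such sets are
  conservative.

## The synthetic generator and what tests show

`make_torsion_spec` / `sample_torsion_ensemble` define ground truth as
per-torsion von Mises mixtures and draw model ensembles whose scores are
the negative log-likelihood of the model's angles plus Gaussian noise
(10 % of the score range by default), reproducing the essential coupling of
real ensembles: better-scoring models sit in better-populated regions.
`build_ensemble_structures` grows an idealized all-trans backbone
(fixed Engh–Huber-like bond geometry, NeRF chain construction) per model so
the PDB readers, torsion extraction and topology mapping are exercised on
real files; `build_toy_complex` adds a rigid dummy ligand and rigidly
perturbed copies with known transforms.

What the generator does **not** emulate: realistic side chains (only amide
H and Hα pseudo-protons are placed), correlated φ/ψ moves, score functions
with systematic biases, or heterogeneous per-residue model quality. Passing
tests therefore demonstrate the estimator/exporter machinery is correct
under the stated statistical model, not that refined real-protein ensembles
will improve — that claim requires running the MD refinement itself, which
is out of scope here.

Default study conditions used in the tests: ensembles of 1000–2000 angle
samples for distribution-level properties (mode recovery within 3°,
curvature $\approx RT\kappa$, two-state energy gaps), 40–50 model
structural ensembles of 4–8 residues for file-level and pipeline
properties. These sizes resolve the statistics being tested while keeping
the suite fast.

## Numerical choices

* Grid: 1° spacing, 361 points with duplicated endpoint; densities are
  renormalised on the grid so the discrete integral is 1 to 10^−6^.
* Curvature measurement (`pef_curvature`): the second derivative at a KDE
  minimum from a 3-point difference is noisy; the exported helper fits a
  quadratic over a ±20° window (±30° ≈ 1.5 circular sd is appropriate for
  κ ≈ 8 distributions).
* Two-state checks construct mixtures at exact composition: with binomial
  component assignment the realized mass ratio itself fluctuates by more
  than the tolerance being verified.
* Kabsch: reflections excluded by the determinant correction; collinear
  point sets are rejected (the rotation about the line is undetermined).
* Ties in best-model selection resolve to the earliest model.
* Altloc records resolve to the highest occupancy, ties preferring
  altloc A; multi-chain files operate on one chain (default: the first
  chain with Cα atoms).
* No score-outlier filtering is applied to ensembles by default; τ already
  downweights poor models smoothly.

## Limitations

* The exact weighting and bandwidth rules of other implementations of this
  approach are not published; the forms here are documented choices, not
  claims of equivalence.
* The topology patcher understands the GROMACS text dialect only, and only
  proper-dihedral replacement; engines with different tabulated-potential
  conventions need an adapter.
* Residue-pair NOE validation intentionally ignores which protons carry a
  restraint; it is a coarse ensemble-quality readout, not a violation
  analysis.
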