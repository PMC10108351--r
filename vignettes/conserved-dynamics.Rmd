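---
title: "Comparative conformational dynamics of homologous enzymes with FlexDyn"
author: "FlexDyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative conformational dynamics of homologous enzymes with FlexDyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FlexDyn)
```

## The scientific problem

Homologous enzymes such as the catalytic human cyclophilins (peptidyl-prolyl
isomerases) share nearly identical folds yet differ measurably in their
intrinsic backbone dynamics. Comparing per-residue flexibility across isoforms
and across functional states of the catalytic cycle — substrate-free,
*cis*-bound, transition-state-bound (the peptide ω torsion restrained near
90°), and *trans*-bound — identifies *key dynamic residues*: positions whose
flexibility is both high and conserved across the family, such as the
gatekeeper loops flanking the isomerase active site. A companion energetic
analysis asks whether a variant actually catalyzes isomerization: by
transition-state theory, the enzyme lowers the reaction barrier iff it binds
the ω = 90° transition state more strongly (more negative binding free energy
ΔG) than both ground states.

FlexDyn implements this comparative pipeline for desk-scale ensembles:
multi-model PDB in, flexibility profiles, PCA summaries, conservation
statistics and catalysis verdicts out. Because the original microsecond MD
trajectories are not redistributable, the package ships a fully seeded
synthetic-ensemble generator whose planted structure (collective modes,
flexibility hotspots, cross-isoform conservation, autocorrelated energy
series) provides a recoverable ground truth for every stage.

## Mixed ensembles and flexibility metrics

Two per-residue metrics are computed, each over a *mixed ensemble* — the plain
concatenation of the frames of two functional states (free + *cis* =
"binding"; *cis* + ts = "catalysis"), with no reweighting. Concatenation is
deliberate: a mean shift between states contributes to the mixed-ensemble
variance (law of total variance), which is exactly the binding- or
catalysis-coupled flexibility being measured. An optional flag subsamples the
longer member to equal length when unequal sampling is a concern.

**RMSF.** Frames are iteratively superposed: all frames are least-squares
rigid-fit (Kabsch, over all backbone atoms) onto the current mean, the mean is
recomputed, and the cycle repeats until the mean moves < 1e-6 Å (RMS) or 10
iterations. Fluctuations are measured about the converged mean — not the first
frame or a crystal structure — and the per-residue RMSF is the arithmetic
average over the four backbone heavy atoms N, Cα, C, O.

**Angular variance.** Backbone φ, ψ and side-chain χ1 torsions are circularly
*shifted* before any linear statistic: the sample values are sorted on the
circle, the largest gap between circularly consecutive values is located, and
the circle is cut at that gap's midpoint so all values unwrap into one
contiguous interval (the dPCA+ idea of moving the periodic boundary into the
least-populated region). Ties between equal gaps are resolved toward the gap
whose midpoint lies closest to +180°, then toward the smallest midpoint, so
results are deterministic. The per-residue angular variance is the **maximum**
of the per-torsion sample variances (deg²) over the residue's available
angles; glycine, which has no χ1, simply competes φ against ψ. Shifting is
applied to the concatenated (mixed) series, not per state — shifting per state
would re-center each state separately and destroy cross-state comparability.

Sample (n−1) variances are used throughout; at the frame counts involved the
choice is immaterial, but fixing it makes tests exact.

## PCA, residue contributions, RMSIP

Cartesian PCA diagonalizes the covariance of the flattened, superposed
backbone coordinates; dihedral PCA does the same for the shifted φ/ψ series
(χ1 participates in angular variance but not in dPCA). Rank deficiency —
frames fewer than coordinates — is handled by symmetric eigendecomposition
with eigenvalues clamped at ≥ 0; eigenvector signs are fixed by making the
largest-magnitude loading positive. The contribution of a residue to a PC is
the sum of squared loadings of its coordinates, normalized to sum to one;
squared loadings (rather than displacement amplitudes) keep contributions
comparable across isoforms and sum exactly to the identity. Subspace overlap
between two models is the root mean square inner product over the top
n = 10 PCs,

$$\mathrm{RMSIP} = \sqrt{\tfrac1n \sum_{i\le n}\sum_{j\le n} (v_i^a \cdot v_j^b)^2},$$

which is 1 for identical and 0 for orthogonal subspaces; independent random
10-dimensional subspaces of a 300-dimensional space average
√(10/300) ≈ 0.183. Multi-system comparisons concatenate the ensembles —
restricted to the backbone atoms of universal alignment columns and
superposed to the joint mean — before a single PCA, and report per-frame
projections labeled by source so state overlaps can be compared in the
PC1/PC2 plane (convex-hull areas of the projection clouds quantify sampled
space).

## Residue equivalence across isoforms

Cross-isoform comparison uses a user-supplied FASTA multiple sequence
alignment. Each isoform's 1-based residue numbering maps to 1-based alignment
columns; only *universal* columns — occupied in every isoform — enter
flexibility and conservation analyses, so positions not aligned across the
whole family are excluded. Reports are in alignment-column numbering, with an
option to echo a reference isoform's residue numbering. For branched residues
the χ1 gamma atom follows IUPAC priority (OG/OG1 > SG > CG/CG1/CG2); this is a
convention, flagged here because structures with unusual atom naming may need
renaming upstream.

## Conservation and key dynamic residues

Dynamical conservation between two isoforms is the Pearson correlation of
their flexibility profiles over shared universal columns
(pairwise-complete when positions are missing); the family summary is the
mean off-diagonal correlation over all isoform pairs. Zero-variance profiles
yield undefined entries, which are excluded from the mean with a logged
count. Key dynamic residues are operationalized with a transparent rule
replacing by-inspection reading of profile plots: within each isoform, flag
positions exceeding mean + z·SD of that isoform's profile (default z = 2); a
position's consensus score is the fraction of isoforms flagging it; positions
reaching a strict majority (configurable) are selected and merged into
maximal contiguous intervals.

## Catalysis from binding-energy series

Per-frame binding free energies (e.g. MM-PBSA output, which FlexDyn consumes
but never computes) are summarized by their mean and a *blocked* standard
error: non-overlapping blocks of 10 samples (the last partial block dropped),
SD of block means over √(number of blocks) — honest under the weak
frame-to-frame autocorrelation of energies sampled every ~100 frames.
With margin δ_g = max(z·√(SEM_ts² + SEM_g²), δ_min) against ground state g,
the verdict is:

* **catalytic** — mean ΔG(ts) is below both ground-state means by more than
  the margin (transition-state stabilization: barrier lowered from both the
  *cis* and the *trans* side);
* **non-catalytic** — mean ΔG(ts) is below *neither* ground-state mean by
  more than the margin. This deliberately covers both "similar" energies
  (unaltered barrier) and transition-state binding *weaker* than a ground
  state (a raised barrier) — in either case the enzyme does not accelerate
  isomerization;
* **indeterminate** — stabilized relative to exactly one ground state.

The floor δ_min defaults to 0.6 kcal/mol, about RT at 300 K: with very long
series the statistical margin shrinks toward zero and sub-thermal mean
differences would otherwise flip verdicts, although differences below thermal
noise are not mechanistically meaningful. Setting `deltaMin = 0` recovers the
purely statistical rule; the boundary behavior at exactly z·SEM is exercised
in the test suite by sweeping the transition-state mean across the margin.
Only energy *differences* enter, so all verdicts are invariant under a common
offset. Barrier-change estimates Δ_cis = mean(cis) − mean(ts) and
Δ_trans = mean(trans) − mean(ts) are reported with propagated uncertainties.

## The synthetic-data generator

The generator emulates the statistical structure of per-state backbone
ensembles without any physics:

* **Reference chain.** A fixed internal-coordinate build (ideal bond lengths
  and angles, ω frozen at 180°, φ = −120°, ψ = 130°). Only relative dihedral
  changes matter downstream, so one published ideal geometry set suffices.
* **Collective modes.** Each mode assigns a unit-norm per-residue weight
  vector and a random (seeded) 3D direction per residue, applied equally to
  the residue's four backbone atoms; frame t displaces the reference by
  a_k(t)·σ_k along the flattened unit mode with a_k(t) standard normal. Modes
  are *internal*: their rigid-body component (translations and infinitesimal
  rotations at the reference) is projected out, because ensemble
  superposition removes rigid motion and only the internal part is
  recoverable by PCA. A mode whose weights are zero outside a residue block
  is kept exactly block-supported by alternating projections between the
  support constraint and the rigid-free constraint (the intersection is
  nonempty for any block of three or more residues), so localized planted
  modes remain localized ground truths.
* **Noise.** Independent isotropic per-atom Gaussian noise with per-residue,
  per-state σ; the expected RMSF of a pure-noise residue is σ√3.
* **Families.** Per-isoform amplitude profiles are
  √ρ·common + √(1−ρ)·isoform-specific on the log scale and then
  exponentiated — positivity without the truncation that would distort the
  planted correlation ρ. With the default log-scale SD of 0.25 the Pearson
  correlation between exponentiated profiles is within ~0.01 of ρ across
  ρ ∈ [0, 1], so ρ is directly recoverable as the mean off-diagonal profile
  correlation. An optional hotspot interval multiplies all isoforms'
  amplitudes by a common factor (default 3), planting a consensus key
  region.
* **Energy series.** Stationary AR(1) with state-specific mean and SD and
  innovation variance σ²(1−φ²); defaults sd = 2 kcal/mol, φ = 0.3, 1000
  samples — weakly correlated but not iid, matching the intent of blocked
  error analysis.
* **Seeding.** One master seed expands into independent streams via a fixed
  integer mixing rule (stream id documented per generator), so every artifact
  is bit-reproducible and different isoforms/states get independent draws.

What the generator does **not** emulate: anharmonicity and multi-well free
energy surfaces, correlated (non-isotropic) noise, side-chain packing,
sequence-dependent geometry, or any solvent/force-field physics. Passing
recovery tests therefore demonstrates the correctness of the estimators on
ensembles with known planted structure — not the physical accuracy of any MD
protocol.

## Study scales used in the tests

Problem sizes were chosen as the package's own desk-scale study conditions:
160-residue chains (cyclophilin-domain scale) and five isoforms; 5000 frames
for closed-form moment checks (Monte-Carlo error ≪ the asserted tolerances);
120–150 frames per ensemble and 60–100 seed replicates for recovery-rate
studies; 2000 frames per state for the end-to-end pipeline run; 1000-sample
energy series for verdict stability. The verdict study replicates the four
enzyme systems' printed mean binding energies with sd 2 kcal/mol.

## Numerical choices and degenerate inputs

* Angle convention (−180, 180] everywhere; values exactly at −180 are mapped
  to +180.
* Dihedrals with collinear defining atoms are flagged missing (NA) for that
  frame; residues whose every torsion series is degenerate are reported NA in
  angular-variance profiles.
* `shiftAngles` requires two finite values; an all-identical series is
  returned unchanged.
* Superposition rejects collinear (rank < 2) structures; PCA rejects
  unsuperposed or single-frame input; dihedral PCA tolerates constant columns
  but rejects an all-constant matrix.
* Eigenvalue clamping at ≥ 0 guards rank-deficient covariances; the trace
  identity (eigenvalue sum = total coordinate variance) holds to 1e-6
  relative.
* The multi-model PDB reader is strict: consistent atom records across
  models, complete N/CA/C/O per residue, no altlocs or insertion codes —
  violations are rejected with the offending model or residue named.

## Known limitations

* Binding-energy input is consumed, never computed: no Poisson–Boltzmann
  solver, entropy estimate, or force field is included.
* Sequence alignment is an input (compute it upstream, e.g. with MUSCLE or
  MAFFT); no alignment or phylogenetic inference is performed.
* The trajectory format is multi-model PDB only; binary trajectory readers
  can be plugged in by constructing `BackboneEnsemble` objects directly.
* Density contouring of PC projections is left to plotting tools; FlexDyn
  exports projection tables and hull areas.
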