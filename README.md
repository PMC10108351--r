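# FlexDyn

Comparative conformational-dynamics analysis of homologous protein
ensembles, built for the kind of question asked of the catalytic human
cyclophilins (peptidyl-prolyl isomerases, CypA–E): which residues carry
the dominant, *conserved* backbone dynamics across a family of isoforms,
how does flexibility change between functional states of the catalytic
cycle (substrate-free, *cis*-bound, transition-state-bound with the
peptide ω torsion near 90°, *trans*-bound), and does a given variant
actually stabilize the transition state enough to catalyze
isomerization?

It is aimed at structural bioinformaticians who have per-state backbone
ensembles (from MD or any other source) as multi-model PDB files, a
multiple sequence alignment relating the isoforms, and per-frame
binding-energy series (e.g. MM-PBSA output) — and who want the
comparative analysis layer, not the simulation layer.

## What it computes

* **Mixed-ensemble flexibility profiles.** Frames of two states are
  concatenated (free+*cis* = "binding", *cis*+ts = "catalysis") so
  between-state shifts count as flexibility. Per residue:
  - RMSF (Å): fluctuation about the iteratively converged mean structure
    after least-squares superposition, averaged over the backbone heavy
    atoms N, Cα, C, O;
  - angular variance (deg²): the maximum over φ, ψ, χ1 of the sample
    variance of each torsion after *maximal-gap circular shifting* (the
    periodic boundary is cut in the least-populated gap, as in dPCA+).
* **PCA.** Cartesian PCA of superposed backbone coordinates and
  dihedral PCA of shifted φ/ψ series; per-residue PC contributions
  (normalized squared loadings); joint PCA over concatenated systems
  with per-state projections; subspace overlap via
  RMSIP = √((1/n) Σᵢ Σⱼ (vᵢᵃ·vⱼᵇ)²) over the top n = 10 PCs.
* **Conservation.** Pearson correlation of flexibility profiles between
  isoform pairs over universally aligned columns, the family mean
  off-diagonal correlation, and consensus *key dynamic residues*
  (per-isoform z-score flags, majority consensus, maximal contiguous
  intervals).
* **Catalysis.** Per-state mean binding free energy with blocked SEM,
  barrier-change estimates Δ_cis = mean(cis) − mean(ts) and
  Δ_trans = mean(trans) − mean(ts), and a transition-state-stabilization
  verdict: *catalytic* iff the ts mean undercuts both ground states by
  more than δ = max(z·pooled SEM, 0.6 kcal/mol).
* **Synthetic ground truth.** A seeded generator plants collective
  modes, per-residue amplitudes, flexibility hotspots, families with a
  tunable conservation level ρ, and AR(1) energy series, so every
  estimator above can be validated by recovery.

## Worked example

```r
library(FlexDyn)

## a three-isoform synthetic family with a planted hotspot at 28-31
spec <- familySpec(nIsoforms = 3, nResidues = 60,
                   states = c("free", "cis"), nFrames = 300,
                   hotspot = c(28, 31), hotspotFactor = 3, rho = 0.6,
                   seed = 42)
fam <- generateIsoformFamily(spec)

## binding-process RMSF profile per isoform
profiles <- lapply(names(fam$ensembles), function(id) {
  binding <- mixEnsembles(fam$ensembles[[id]]$free,
                          fam$ensembles[[id]]$cis)
  backboneRMSF(superposeEnsemble(binding))
})

profileCorrelationMatrix(profiles)
#> ConservationMatrix (rmsf, binding): 3 isoforms, mean off-diagonal r = 0.913

identifyKeyRegions(profiles)
#> KeyRegionReport: z = 2.00, consensus >= 0.67
#>   regions: [28, 31]

## catalysis verdict from binding-energy series around the CypE
## wild-type means
es <- energySpec(means = c(cis = -17.98, ts = -23.33, trans = -14.59),
                 sds = 2, phi = 0.3, nSamples = 1000, seed = 42)
assessCatalysis(generateEnergySeries(es, "cis",  "CypE_WT"),
                generateEnergySeries(es, "ts",   "CypE_WT"),
                generateEnergySeries(es, "trans", "CypE_WT"))
#> CatalysisReport: CypE_WT -> catalytic
#>   mean dG (kcal/mol): cis -17.94, ts -23.37, trans -14.55
#>   barrier changes: delta_cis 5.43 +/- 0.11, delta_trans 8.83 +/- 0.12
```

Reading the output: the family's binding-state dynamics are highly
conserved (mean pairwise r = 0.91), the consensus key-region rule
recovers the planted hotspot interval exactly, and the energy replica is
judged catalytic because the transition state binds 5.4 kcal/mol more
strongly than the *cis* ground state and 8.8 kcal/mol more strongly than
*trans*, far beyond the noise margin.

Real data enter through `readMultiModelPDB()` (strict multi-model PDB),
`buildEquivalenceMap()` (aligned FASTA; only columns occupied in every
isoform are compared) and `readEnergyTable()` (two-column TSV). A thin
command-line wrapper with subcommands `simulate`, `dihedrals`, `rmsf`,
`angvar`, `pca`, `rmsip`, `conserve` and `energetics` is installed at
`system.file("cli", "flexdyn.R", package = "FlexDyn")`.

The methods vignette (`vignettes/conserved-dynamics.Rmd`) documents the
model and estimator choices: shifting and tie-breaking rules, the
superposition scheme, the verdict margins, the generator's planted
structure, and its limitations.

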