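---
title: "Seed-and-grow construction of protein-peptide complex structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-and-grow construction of protein-peptide complex structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Linear peptide ligands such as the N-terminal tail of histone H3
(`ARTKQTARKSTGGKA...`) bind reader proteins through shallow surface
pockets. Docking a full 10-15-residue peptide with ~50 rotatable bonds is
beyond reliable exhaustive search, and scoring functions that reward
total contact area are misled by the long disordered C-terminal part that
in reality dangles into solvent: in experimentally determined
histone-reader complexes, mostly the first five residues carry the
interaction.

`seedgrow` implements a fragment-seeded strategy that turns this binding
pattern into an advantage:

1. **Fragment**: cut the peptide into capped dipeptides (a sliding
   two-residue window; the cut amide bonds are blocked with acetyl and
   N-methyl-amide groups, except that window 1 keeps its genuine free
   N-terminus).
2. **Seed dock**: dock the anchoring dipeptide rigidly into a search box
   around the binding region and cluster the placements into ranked
   binding modes.
3. **Grow**: from every ranked seed pose, rebuild the full peptide in
   situ, residue by residue, with the seed's coordinates frozen.
4. **Score and select**: score every grown model with the intermolecular
   interaction energy, rank by the energy of the first five residues, and
   report the model closest to the mean coordinates of the top 1%.
5. **Evaluate**: when a reference pose exists, superpose targets (Kabsch
   on C-alpha atoms) and measure heavy-atom RMSD for the full ligand and
   the first five residues (`RMSD_top` for the selected model, `RMSD_best`
   for the best model in the pool).

## The interaction energy

All scoring uses one physics-based quantity, the intermolecular energy

$$E_\mathrm{inter} = \sum_{i}^{N_L}\sum_{j}^{N_T}
  \left[\varepsilon_{ij}\left(\frac{R_{ij}}{r_{ij}}\right)^{12}
  - 2\varepsilon_{ij}\left(\frac{R_{ij}}{r_{ij}}\right)^{6}\right]
  + \frac{C\, q_i q_j}{\varepsilon_r(r_{ij})\, r_{ij}}$$

with $R_{ij} = R_i + R_j$, $\varepsilon_{ij} =
\sqrt{\varepsilon_i\varepsilon_j}$, and $C = 332.0637$ kcal Å mol$^{-1}$
e$^{-2}$ so that charges in elementary units and distances in Å give
kcal/mol. The sum runs over *all* ligand x target atom pairs — there are
no exclusions, no intramolecular terms, no solvation term and no explicit
waters. Pair terms are attributed to the ligand atom's residue, giving the
per-residue decomposition used for seed selection and for the
first-five-residue ranking score.

Electrostatic screening uses the sigmoidal distance-dependent dielectric

$$\varepsilon_r(r) = A + \frac{B}{1 + k\,e^{-\lambda B r}},\qquad
  B = \varepsilon_0 - A,$$

rising from $A + B/(1+k) \approx 1.35$ at contact to the bulk-water value
$\varepsilon_0 = 78.4$ at long range. The constants ($A = -8.5525$,
$\lambda = 0.003627$ Å$^{-1}$, $k = 7.7839$) are the classic
Mehler-Solmajer values; they are exposed in `dielectric_params()` rather
than hard-wired.

Van der Waals parameters come from a shipped united-atom table keyed by
element (C 2.00 Å / 0.150, N 1.75 / 0.160, O 1.60 / 0.200, S 2.00 /
0.200, polar H 1.00 / 0.020 kcal/mol). The structure model is
polar-hydrogen-only: hydrogens are built only on N/O/S donors, and carbon
radii are united-atom-compatible, which is why a single element-keyed row
suffices per element.

Partial charges use a fixed per-residue template keyed by (residue, atom
name). A template was chosen over an iterative partial-equalisation
calculation because it is deterministic, testable, and exactly
charge-conserving: every residue sums to its formal charge (+1 for
Lys/Arg and trimethyl-lysine, -1 for Asp/Glu, 0 otherwise), and the
N-terminal amine block sums to the same value as the backbone N-H pair it
replaces. Charges present in an input mol2 file always take precedence.
The absolute energies therefore differ from what any particular
charge-assignment tool would give; all ranking decisions in the protocol
are comparisons under one consistent scheme, which is what matters for
selection.

## Structure preparation

`prepare_target()` reproduces standard rigid-receptor preparation: keep
the first protein chain (first chain in file order containing a standard
amino acid), drop heteroatoms and waters, keep blank/'A' alternate
locations, strip any input hydrogens, add polar hydrogens at ideal
geometry, and assign parameters. Preparation is idempotent. Missing
side-chain atoms in the input are tolerated (their charges are simply
absent); modelling missing residues is out of scope.

## Fragment geometry

Fragments and peptides are built from ideal internal coordinates (bond
1.329 Å amide, 1.458/1.525 Å backbone, tetrahedral/trigonal angles from
standard tables) with NeRF placement. The default build is extended
($\phi = -120^\circ, \psi = 120^\circ, \omega = 180^\circ$, anti side
chains). No force-field minimisation is applied: the docking stage
samples fragment torsions and the growing stage re-samples everything
beyond the seed, so small deviations from minimised geometry do not
propagate. Trimethyl-lysine (`M3K`) is supported as a modified residue
(three methyls on NZ, +1 spread over the methyl carbons, parameters
approximate); no other modifications and no D-amino acids.

The free N-terminus of window 1 is built neutral (NH2). Whether a
protonated amine would be more appropriate depends on the system's pH
and is configurable at the charge-template level; the neutral choice
keeps the fragment's net charge equal to the sum of its side-chain
formal charges.

## Seed docking

The external genetic-algorithm docker the protocol is usually paired with
is deliberately out of scope; its role is filled by two interchangeable
routes with the same contract:

* `import_poses()` ingests externally docked poses (PDB/mol2), verifies
  atom correspondence against the fragment template and re-scores them
  with $E_\mathrm{inter}$, so external and internal poses rank on one
  scale.
* `dock_seed()` is a built-in systematic rigid-body search: fragment
  conformers (the input conformation plus torsion-perturbed copies) x
  random orientations x a translational grid restricted to the search
  box and to a 2.5-7 Å band around the target surface, scored with
  $E_\mathrm{inter}$ and refined by rigid-body coordinate descent.

The search box follows the conventional grid vocabulary: 60 x 60 x 60
points at 0.375 Å spacing, centred on the reference ligand centroid when
a reference is available. Blind binding-site detection is not attempted —
without a reference the user must supply a centre.

Two numerical choices matter. First, the coarse translational scan clamps
pair distances at $0.75\,R_{ij}$ (a soft core): with a 2.25 Å scan
stride, a placement one grid step away from a good pose almost always
overlaps the receptor slightly, and without the clamp the $r^{-12}$ wall
would discard exactly the placements worth refining. Refinement uses the
true potential. Second, orientations are drawn uniformly (Shoemake
quaternions) from a seeded RNG, so runs are reproducible; ten independent
replicates of 58 orientations each give 580 orientations in total, a
desk-scale stand-in for stochastic global search.

Poses are clustered by greedy leader clustering in the shared target
frame (no superposition): visiting poses by increasing score, a pose
joins the first cluster whose leader is within 2.0 Å heavy-atom RMSD,
else founds a new cluster. 2.0 Å is the conventional pose-clustering
tolerance. The representative of each rank is its best-scoring member.

A note on invariance: docking results shift exactly with a joint
*translation* of target and box (the grid is anchored to the box centre).
Joint *rotations* are not representable because the box is axis-aligned
and the orientation set is drawn in the world frame; rotating a system
relative to the grid axes can change results within the search's
stochastic scatter.

## Growing

`grow_peptide()` replaces the homology-modelling builder that the
protocol treats as a black box with an explicit, testable sampler:

* The seed's residues are copied unchanged (the anchoring contract is
  exact, not approximate). Caps are removed; the cap heavy atoms fix the
  junction torsions — the N-methyl-amide nitrogen is exactly where the
  next residue's backbone N must attach, so the first added residue on
  each side reuses that torsion instead of resampling it. Resampling
  would occasionally place the new N on top of the seed's carbonyl O.
* Extension is N-ward first (when the seed is internal), then C-ward.
  Each added residue draws $(\phi,\psi)$ from weighted Ramachandran
  basins — $\alpha$ (-100..-40, -60..-10) x 0.35, $\beta$ (-160..-90,
  100..170) x 0.45, PPII (-90..-55, 120..170) x 0.20 — and side-chain
  $\chi$ angles from the anti/gauche rotamer states (0.45/0.35/0.20, with
  8 degrees of Gaussian jitter).
* A candidate residue is rejected if any heavy atom comes closer than
  $0.7\,(R_i+R_j)$ to the target or to a non-adjacent ligand residue.
  Among up to 8 clash-free candidates per residue, the one with the best
  incremental $E_\mathrm{inter}$ against the target is kept — growth is
  greedy and energy-guided, which is what steers the chain along the
  receptor surface rather than into solvent.
* A model that dead-ends is regrown from the seed (up to 50 restarts);
  100 models are grown per seed rank by default, matching the protocol's
  per-step model count. Terminal residues are completed with a neutral
  carboxylic acid / neutral amine.

There is no loop closure to a C-terminal anchor, no receptor flexibility,
and no restraint language: the seed anchor plus clash rejection plus
energy guidance are the entire model.

## Selection

`score_pool()` computes full-ligand and first-five-residue energies for
every model; the ranking key is the first-five energy (most negative
first). `select_representative()` takes the best `ceil(0.01 n)` models
(top 1%, floor of one), averages their heavy-atom coordinates atom-wise
in the common target frame, and returns the member closest to that mean —
never the synthetic average itself. Ties break to the lowest model id.
Heavy atoms only are averaged, consistent with the heavy-atom RMSD
convention. The rationale for a representative rather than the single
top-scoring model is robustness: the top 1% usually contains the best
model, but the single best energy often does not belong to it.
`ranking_ablation()` re-ranks the same pool under the Lennard-Jones-only
or Coulomb-only component for comparison studies; the combined energy is
the default because either component alone ranks worse.

## The synthetic fixture

`make_planted_complex()` generates the test bed: a 5-15-residue prefix of
the histone H3 tail in an ideal extended conformation, cradled by a toy
receptor built from standard-residue pseudo-atoms (alanine C-beta
carbons; serine O-gamma oxygens supply negative charge opposite the
peptide's cationic nitrogens), so the shipped parameter table applies
unchanged. The receptor is a one-sided concave shell: a dense contact
layer at 3.6-4.6 Å around residues 1-2 (the C-C pair minimum is 4.0 Å),
an outer bulk layer behind it, a thinner wall along residue 3 and a
sparse floor under residues 3-5, all restricted to one hemisphere so the
pocket is enterable. This emulates the empirical pattern that the first
residues anchor the peptide while the C-terminus stays exposed; the
per-residue energy minimum lands on residue 1 or 2 by construction, and
the planted pose is clash-free at factor 0.7.

What the fixture does *not* emulate: real side-chain packing, backbone
flexibility of the receptor, water-mediated contacts, and realistic
charge anisotropy. Passing the planted-recovery tests therefore
demonstrates that the machinery (search, growth, scoring, selection)
works as specified — not that the energy function would rank real
histone-reader poses as well as it ranks toy poses.

Default problem sizes were chosen to keep a full pipeline run on one
desk-scale core in the one-to-two-minute range: a 6-residue peptide,
~60-90 receptor pseudo-atoms, 580 orientations, 5 grown ranks x 100
models. All are configuration knobs.

## Reproducibility

Every stochastic stage takes an explicit integer seed; stage seeds derive
deterministically from the pipeline's master seed (`rng_seed`), and rank
r of the growing stage uses `rng_seed + 1000 r`. Re-running a pipeline
with the same configuration reproduces the ranking table byte for byte.
Growing is robust at the distribution level: pools grown under different
seeds have median energies within a few percent on the fixture.

## Known limitations

* Greedy residue-by-residue growth cannot revise earlier choices; a
  mis-grown residue 3 biases residues 4+. The model pool across ranks and
  restarts, not backtracking, is the mitigation.
* The energy function has no desolvation or entropy terms, so highly
  charged interfaces are over-rewarded relative to hydrophobic ones.
* The built-in docker is a systematic sampler, not a global optimiser; on
  rugged landscapes it relies on orientation density and the soft-core
  scan to find the native basin.
* Apo/holo residue-numbering mismatches between model and reference
  targets are not reconciled automatically; superposition matches C-alpha
  atoms by residue number.
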