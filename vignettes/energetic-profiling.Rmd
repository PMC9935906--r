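---
title: "Energetic profiling of amyloid fibril polymorphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energetic profiling of amyloid fibril polymorphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Amyloid fibrils are stacks of identically folded monomer layers: each
layer is a flat, beta-strand-rich fold, and layers repeat along the
fibril axis with a rise of about 4.75 Å and a small helical twist
(the cross-β architecture). A single protein sequence — tau is the
canonical example — can adopt many distinct folds (polymorphs), each
associated with a different disease. Which residues hold a given fold
together, and which residues distinguish one fold from another?

`fibrilscan` answers both questions with an in silico alanine scan.
Every scannable position is truncated to alanine in **every** layer of
an N-layer protofilament stack, the assembly is re-scored, and the
energy change

\[
\Delta REU^{assembly}_{mut-wt} = bound_{mut} - bound_{wt}
\]

is averaged over an ensemble of replicates. A companion interface
metric separates the central three layers rigidly from the rest of the
stack and rescores without re-optimisation:

\[
\Delta\Delta G^{interface} = [bound - unbound]_{mut} - [bound - unbound]_{wt}.
\]

Per-residue profiles are min–max normalised to a 0–100 scale,
smoothed over 5-residue windows, and thresholded into hotspots
(normalised value > 40) and minimally important positions (< 10).
Profiles from many structures feed a Ward clustering of polymorphs and
an interpretable random-forest classifier whose predictions are
decomposed exactly into per-residue-cluster contributions.

# The scan protocol

`run_alanine_scan()` follows a restrained ensemble protocol:

1. **Input minimisation.** The whole input structure is relaxed by
   greedy coordinate descent on side-chain χ1 angles under harmonic
   atom-pair restraints to the input coordinates, until the objective
   improves by less than one energy unit per sweep.
2. **Replicate perturbation.** For each replicate (35 by default), the
   χ1 angles of all residues whose CB lies within 8 Å of the mutation
   site are jittered (Gaussian, `perturb_sigma_chi = 10` degrees) and
   relaxed. This supplies an ensemble with the same statistical role as
   a backbone-sampling Monte Carlo scheme — a per-position mean with a
   spread — at desk scale. The original protocol's sampler settings
   are recorded in `scan_config()$sampler_note` for provenance but are
   not used by the built-in backend.
3. **Branching.** The perturbed model is branched into a mutant
   (truncate the position to CB in every layer, repack the
   neighbourhood, relax) and a wild-type (repack, relax) model. Both
   branches re-seed the random stream identically, so an
   alanine-to-alanine "mutation" produces exactly zero energy change at
   every replicate — a built-in control.
4. **Scoring.** Both bound states are scored; with at least five
   layers the unbound state (central trimer translated 500 Å, beyond
   every interaction cutoff, with no re-optimisation) gives the
   interface ΔΔG.

Glycine positions are excluded by default: their backbone torsions
frequently occupy regions not permissible for alanine, and forcing a
CB there produces clashes rather than interpretable energetics. An
`override_glycine` flag exists for clash analyses, and the
`geometry` module ships φ/ψ permissibility grids to make the argument
quantitative (see below).

## The CrossBetaPotential backend

The published protocol runs on an external molecular-modelling engine.
That engine is deliberately **not** reimplemented here; the backend is
a contract, and external per-residue score tables can be ingested with
`ingest_external_scores()` (schema: `structure_id, residue, replicate,
bound_mut, bound_wt`). The built-in surrogate preserves the
*interpreted term structure* of a full-atom energy function —
attractive, repulsive, solvation, electrostatic — and aims to preserve
orderings, never absolute magnitudes:

* **attractive** — a plateaued Lennard-Jones branch: −ε inside the
  contact distance, the full 12-6 form beyond it, switched smoothly to
  zero between 5.5 and 6 Å;
* **repulsive** — the positive LJ excess inside the contact distance,
  clamped below 0.6 of the contact distance so clashes are penalised
  but finite;
* **solvation** — per-atom accessible area (Shrake–Rupley, 92 points
  in the scoring path) times an atomic solvation parameter;
* **electrostatic** — screened Coulomb between charged-group
  centroids (Lys/Arg +1, Asp/Glu −1), cutoff 8 Å.

Parameter choices worth stating explicitly, because they are design
decisions rather than fits: well depths are 0.14 (C), 0.10 (N, O) and
0.18 (S). Hydrogen bonding is not modelled, so polar atoms carry *no
extra* dispersion — otherwise polar contacts would dominate orderings
that in full-atom scans are dominated by nonpolar burial. The
dielectric (80) and the small solvation parameters keep those terms
secondary, again matching the observed term hierarchy in which the
attractive term dominates hotspot energetics. The restraint weight
defaults to 0.02 per pair: with roughly fifty restraint pairs per atom
inside the 9 Å cutoff, a unit weight would freeze the descent
entirely against this potential's scale; the published unit weight
belongs to the original engine's energy scale.

Cross terms are split half/half between partner residues, which makes
the per-residue attribution sum *exactly* to the total and the
edge/internal layer decomposition exact:
`delta_edge + delta_internal == delta_assembly` to machine precision
for every position and replicate (`layer_decomposition()`).

The relax/repack inner objective is the pairwise part of the backend
(attractive + repulsive) plus the restraints. Solvation and the
screened Coulomb term are evaluated at scoring time only: both vary
slowly with χ1 and recomputing accessible areas inside the descent
loop would dominate runtime without changing which rotamer wins. The
descent contract (the objective never increases) is stated and tested
on this inner objective.

# Stack construction and geometry

`build_stack()` extends a deposited assembly by superposing a
duplicate's top two layers onto the current bottom two layers
(backbone atoms N, CA, C, O), deleting the overlapping pair and
appending the rest, until the target layer count is reached; the
central window is kept and chains are relettered A… from the top. An
overlap RMSD above 0.5 Å aborts the extension as geometrically
incompatible. For exactly helical input the output's consecutive-layer
transform is constant to 1e−6.

Layer order is recovered from coordinates by projecting each chain's
CA centroid onto the principal axis of the chain centroids. (The
centroids of a protofilament lie on the helical axis; the principal
axis of *all* atoms can fall in the layer plane for wide flat folds,
which is why centroids are used.) The axis sign is anchored to the
file's chain order so that read/write round trips preserve layer
order.

`estimate_layer_transform()` reports the helical rise (projection of
the inter-layer translation onto the rotation axis, oriented along the
stacking direction) and the signed twist. A caveat documented and
respected by the tests: the screw axis of a noisy near-identity
rotation is poorly conditioned, so oracle comparisons on jittered
stacks use a larger twist than the 1-degree cross-β default.

Torsions follow the IUPAC convention (degrees in (−180, 180]);
terminal residues and chain breaks (peptide C–N > 2.5 Å) are flagged
`NA`, never zero-filled. Permissibility of a (φ, ψ) pair is evaluated
against shipped 5°×5° density grids at a configurable
highest-density-region contour (default 99.5% of mass). The shipped
grids are **synthetic stand-ins** — smooth Gaussian-mixture densities
emulating the torsion statistics of alanine-like and glycine residues
in high-resolution globular structures — because the original
reference set (X-ray structures between 1.5 and 2.5 Å) cannot be
redistributed here. The grid files
(`inst/extdata/synthetic_rama_*.tsv`) are data, not code, and any grid
in the same plain-text format can be swapped in.

# SASA and folding burial

`residue_sasa()` implements Shrake–Rupley with a deterministic
golden-section spiral lattice (default 960 points; results are
bit-stable across runs). Hydrogens are excluded throughout — the
readers drop them — and the per-element radius table is shipped as
data. `delta_sasa_folding()` computes per-residue areas in three
states: a fully extended monomer (idealised φ = −120, ψ = +120
backbone with extended side chains), the central layer extracted
alone, and the central layer inside the central trimer, giving

* `dsasa_single_layer = extended − monomer` (burial on folding), and
* `dsasa_fibril = extended − in_fibril` (burial in the fibril).

Because additional layers can only occlude, `dsasa_fibril ≥
dsasa_single_layer` residue by residue; this monotone-burial contract
is tested. The extended state's torsions are a conventional
β-extended reference; the original protocol's extended-state geometry
is undocumented, and small negative `dsasa_single_layer` values can
occur where the extended chain shadows a side chain more than the
sparse synthetic layer does.

`nonpolar_burial()` reduces the two-state comparison to the buried
area of carbon and sulfur atoms — the surrogate's measure of
nonpolar burial, which the scan energetics rank-correlate with
(Spearman ≥ 0.8 on the synthetic fibrils; tested).

# The synthetic generator

The generator (`fibril_spec()`, `generate_fibril()`) is first-class,
tested code, and its defaults define the study conditions: rise
4.75 Å (inside the canonical 4.7–4.8 Å cross-β spacing), twist −1°,
nine layers. It threads a sequence onto a 2-D fold path (CA positions
3.8 Å apart), builds a pleated backbone (amide N and carbonyl C dip
alternately along the fibril axis; carbonyl O points along the axis as
in cross-β hydrogen bonding), points side chains alternately at the
two sheet faces, and stacks layers with the rigid helical transform.

Side chains use idealised internal-coordinate templates with realistic
heavy-atom counts; χ1 is the single free dihedral and later dihedrals
are held at idealised rotamer values (rings are built flat, in the
layer plane — a perpendicular ring would clash with its own stacking
image at the 4.75 Å rise). This simplified geometry is the
generator's *only* mode: the tests need solvent-burial and packing
orderings, not atomic realism, and a rotamer library would add nothing
the tests could see. Full-atom structures read from PDB/mmCIF files
keep their deposited side chains.

Three fold presets mirror the coarse topology classes of tau
protofilaments:

* `two_sided` — a three-strand serpentine whose central strand is held
  on both faces. Ile313, Phe314 and Leu315 are planted as buried
  large-nonpolar hotspots against a short-polar (Ser/Thr/Lys/Gly)
  background; the sheet gaps (9.2 and 8.0 Å) were sized to the
  planted side chains' reach so they make van der Waals contact
  without clashing, and the construction was verified by SASA: the
  planted positions are the top buried-nonpolar residues of the fold.
* `one_sided` — a two-strand hairpin (C-shaped folds).
* `straight` — a single-strand control.

What the generator deliberately does **not** emulate: backbone
heterogeneity between layers, bound cofactors or unresolved densities,
protofilament pairing interfaces, and hydrogen-bond geometry. Tests
passing on these fixtures therefore demonstrate the *machinery* —
construction, scoring identities, ranking, clustering, classification
— not predictive accuracy on deposited structures, for which external
engine scores can be ingested.

`generate_profiles()` emulates the scan's replicate structure directly
(class mean plus clipped Gaussian noise in the external-score schema),
and `planted_class_profiles()` builds a classifier study: seven parent
classes named after the tauopathy fold families, two structures per
class, 35 replicates, and four class-distinctive residues per class
raised by three noise standard deviations over a shared base profile
of 48 residues. Four distinctive residues (rather than one or two)
make the 3σ effect the dominant source of class information after
per-replicate normalisation; that choice is part of the fixture's
design, made before the benchmark was frozen.

# Profiles, clustering and classification

Normalisation is min–max to [0, 100] per structure (matching the 0–100
hotspot thresholds); a degenerate profile (min = max) maps to all
zeros, and excluded positions stay `NA` through every transform.
Windowed averages skip `NA` and renormalise by the count actually
used, keeping motif-level maps contiguous across excluded glycines;
windows truncate at the termini.

For classification the order of operations is: normalise each
replicate profile, intersect residues across structures (residues
absent or excluded anywhere are dropped for all), then — for the
structure dendrogram — average replicates and take Euclidean
distances. Ward linkage uses the `ward.D2` convention: merge heights
equal the square root of twice the increase in within-cluster sum of
squares, which the tests verify against an exhaustive
recompute-from-scratch oracle.

Residue columns are agglomerated to 20 composite features
(Ward/Euclidean on the column vectors; each feature is the mean of its
members). Cluster identities are canonicalised by each cluster's
smallest residue number, so the reduced matrix is invariant to input
column permutations.

The forest protocol: per restart, each structure's replicates are
split at random into 9 training and 26 held-out rows; a 100-tree
forest is fit on the training rows, labelled by parent class
(subtypes map to parents through a shipped, editable table with a
suffix-stripping fallback); the best-accuracy restart wins, ties going
to the lower restart index. The published protocol text is internally
inconsistent about the split (26 of 35 as test vs "nine of the 30" as
train); this package adopts 9 train / 26 test of 35 — the stated
25% / 75% split — and exposes both numbers as options. The default
restart count is 50 in the tests (scaled from the full 2500, which the
acceptance script uses).

Class probabilities are *soft votes*: each tree predicts the class
distribution of the training rows at its leaf, and the forest averages
over trees. That definition is what makes the decision-path
decomposition exact: walking a tree's path and attributing each
split's change in node distribution to the splitting feature
telescopes to `bias + Σ contributions = prediction` identically, per
tree and therefore per forest. Conventional majority-vote
probabilities would not satisfy the identity, which is why the report
exposes `predict_prob()` alongside the fitted `randomForest` object.

The exact Mann–Whitney test (`mann_whitney_exact()`) enumerates all
label assignments when there are no ties and `choose(n1+n2, n1) ≤
2e6`, reporting twice the smaller tail (capped at 1); otherwise it
falls back to a midrank normal approximation with tie and continuity
corrections, and records which path was taken.

# Numerical choices and degenerate inputs

* Superposition is Kabsch with a determinant correction; mirror
  solutions are forbidden. Collinear point sets are an error, not a
  silent answer.
* Alternate locations keep altloc A (occupancy-weighted averaging was
  rejected for determinism); waters, heteroatoms and hydrogens are
  dropped on read; missing CB atoms of non-glycine residues are
  rebuilt from ideal backbone geometry and logged.
* Author residue numbering is preserved everywhere and never
  renumbered, so hotspots map directly onto motifs such as 306–311.
* All randomness flows through a single integer seed expanded per
  stage/position/replicate by a small documented multiplicative hash
  (`derive_seed()`), keeping derived seeds below 2^31.
* The unbound-state separation is 500 Å; any distance beyond all
  cutoffs is equivalent.
* Replicate summaries report the plain mean (not the median), matching
  the published protocol; no outlier trimming is applied.

# Problem sizes used by the test suite

The suite exercises the full protocol shapes at reduced replicate
counts, chosen as the package's own desk-scale defaults for testing:
scans on the nine-layer two-sided preset run 1–3 replicates per
position (the planted-hotspot margin is roughly thirty standard
deviations of the replicate noise, so replicate count does not change
the ranking); the 20-seed hotspot-recovery and burial-coupling studies
use 2 replicates; the classifier benchmark runs the full 7 × 2 × 35
replicate design with 50 restarts in the tests and 2500 in the
acceptance script.

# Known limitations

* The surrogate backend preserves orderings, not magnitudes; absolute
  energies are not comparable to any published force field, and
  backbone degrees of freedom are frozen after the pleated
  construction (the published backbone RMSD analysis shows near-native
  backbones, 0.3–0.6 Å, which motivates the fixed-backbone design).
* Only χ1 is sampled; branched and aromatic side chains relax as rigid
  groups.
* Paired-protofilament interfaces are handled by selection only: the
  partner filament is discarded, and any stabilisation it contributed
  is ignored.
* The permissibility grids are synthetic stand-ins, suitable for
  contour-style classification but not for population statistics.
* `ΔSASA` folding metrics inherit the extended-reference convention;
  per-residue values can be slightly negative where the reference
  shadows a side chain.
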