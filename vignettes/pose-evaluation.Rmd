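---
title: "SAR-guided evaluation of docking pose ensembles: methods and design"
author: "sarpose"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarpose)
```

# The procedure

`sarpose` implements a pose-evaluation protocol for docking a congeneric
ligand series into a low-confidence receptor model (the motivating case:
propafenone-type inhibitors docked into P-glycoprotein homology models).
The protocol deliberately avoids scoring functions. Its logic:

1. pool the poses of *all* ligands of the series;
2. cluster them by the RMSD of their shared scaffold;
3. keep clusters that accommodate (nearly) the whole series;
4. among those, keep clusters consistent with the series'
   structure–activity relationship (SAR);
5. rank the survivors by explicit, auditable geometric criteria.

The assumptions this rests on: the series binds in a common mode (so a
credible pose cluster must host most ligands); the activity difference
that ligand-efficiency metrics isolate (here: a hydroxyl group) is
caused by a protein contact (so clusters where that contact is
geometrically impossible are rejected); and poses from the same docking
run share one receptor frame (so in-place RMSD is meaningful).

# Scaffold mapping

The scaffold is supplied as configuration, not discovered: a
heavy-atom molecular graph (`scaffold_spec()`), with
`default_scaffold()` encoding an arylketone core — a benzene ring
bearing a phenyl ketone and, ortho to it, an aryl ether with a
two-carbon linker to an amine nitrogen (18 heavy atoms). Matching a
pose's ligand onto the scaffold is non-induced labelled subgraph
isomorphism (igraph's LAD solver, element labels plus degree bounds as
vertex domains); bond orders are ignored, hydrogens excluded. Matching
is purely topological, so it is computed once per ligand and shared by
all of its poses.

All symmetry-equivalent matches are enumerated. The pendant
monosubstituted phenyl contributes a twofold ring-flip automorphism;
without minimising the RMSD over these mappings, two physically
identical placements could differ by an artefactual ~2.5 Å. Whether the
original protocol did this is not documented anywhere we know of; it is
the only defensible choice, and it never increases the distance. More
than 64 matches per ligand is treated as a configuration error.

# Clustering

`scaffold_rmsd()` is in-place: no Kabsch superposition. Superposing
before the RMSD would erase exactly the information the clustering is
supposed to resolve — *where* in the cavity a pose sits. Cross-ligand
distances are well-defined because only the shared scaffold atoms
enter, in canonical order.

The pooled matrix is clustered by complete linkage
(`stats::hclust`) and cut at `cut_height` (default 3 Å). Numerical
choices:

* **Inclusive boundary.** A merge at exactly the cut height joins its
  clusters. The implementation counts merges with height ≤ cut + 1e-9
  and cuts the tree by cluster count, which pins the behaviour down
  regardless of floating-point representation of the heights.
* **Complete-linkage contract.** Every cluster's diameter
  (`formation_height` = max intra-cluster pairwise RMSD) is ≤ the cut,
  and merging any two output clusters would exceed it. Both properties
  are asserted in the test suite.
* **Deterministic labels.** Cluster ids are assigned by descending
  size, ties by smallest member index; kept clusters are labelled
  CSC I, CSC II, ... in reports. The Roman numerals echo the field's
  naming convention and imply nothing beyond ordering.

The CSC filter (`filter_csc()`) keeps clusters whose poses span at
least `min_ligands` distinct ligands (default 4 of a 5-ligand series).

# Interaction fingerprints

Per-residue, aggregated over a pose set (`plif()`), with frequencies =
count / number of poses:

* **Contacts**: any residue heavy atom within 4.5 Å (inclusive) of any
  ligand heavy atom. 4.5 Å is the conventional fingerprint radius for
  "residue lines the site".
* **Hydrogen bonds** (`detect_hbonds()`): donor–acceptor heavy-atom
  distance ≤ 3.5 Å. The D–H···A angle test (≥ 120°) applies only when
  the donor carries explicit hydrogens — docking poses and
  low-resolution models usually do not, and inventing hydrogen
  positions would manufacture precision. Donor/acceptor typing: protein
  side by residue/atom-name tables plus backbone N (donor) and O
  (acceptor); ligand side from topology (hydroxyl O = donor+acceptor,
  carbonyl/ether O = acceptor, amine N by protonation state, which is
  an input tag and never computed). Each bond carries a score
  `min(1, exp(-(d - 2.6)))` — 1 at an ideal 2.6 Å, decaying with
  distance. The score supports *relative* statements only ("this
  cluster's bond is weaker"); it is not an energy.
* **Aromatic interactions**: ligand all-carbon six-rings (found as
  C6-cycle subgraph matches) and residue rings (PHE/TYR/TRP/HIS) with
  centroid distance ≤ 5.0 Å count as π/π; an ionised ligand amine near
  a residue ring counts as π/cation. Ring-plane angles are not tested —
  with toy geometry and low-confidence receptor models an angle
  criterion would be precision theatre.
* **Clashes** (`clash_count()`): ligand–protein heavy-atom pairs closer
  than the sum of Bondi van der Waals radii minus a 0.4 Å tolerance,
  the usual allowance for soft contacts.
* A residue's `direct` flag records a typed interaction (H-bond or
  aromatic) in at least one pose, as opposed to mere 4.5 Å proximity;
  the two notions are reported separately.

`compare_fingerprints()` thresholds each state's fingerprint at a
contact frequency (default 0.1) and reports every Venn region — the
binding-site comparison across receptor states.

# Rotamer scan

`rotamer_scan()` asks whether rotating one residue's side chain can
create a hydrogen bond that the input conformation lacks — the
induced-fit argument for the scaffold carbonyl. It enumerates a
χ1 × χ2 grid (default step 30°, which must divide 360°), rotating
rigidly about the CA–CB and CB–CG axes. Angles are reported as *deltas*
relative to the input conformation, not absolute IUPAC dihedrals: the
receptor model carries no bond table, and ground truth for a planted
rotamer is naturally the applied delta. A rotamer is reported only if
the moved side chain is clash-free against both the rest of the
receptor and the pose, and creates ≥ 1 new H-bond. The identity rotamer
reproduces the input coordinates exactly (rotation by 0°), so it can
never appear in the results.

# SAR metrics and prioritisation

`LLE = pIC50 − logP` and `LE = pIC50 / HAC` reproduce the published
table for the packaged series exactly under half-up rounding to two
decimals (half-up, not banker's rounding — display convention; full
precision is kept internally, and the rounding guard adds 1e-9 before
truncation to absorb binary representation artefacts).

Fit quality is `FQ = 1.37·pIC50/HAC / LE_scale(HAC)`; the 1.37 converts
log-units to kcal/mol because the published reference scales were fit
on kcal-scaled LE, while the LE *column* convention is the plain
pIC50/HAC. Two reference scales are provided (a cubic polynomial in
1/HAC and an exponential), plus an `identity` scale for inspection.
Note that FQ under `identity` is proportional to LE and therefore
favours the smallest ligand of a series; only the size-normalised
scales single out GPV062 as most efficient. The published FQ column for
this series is not exactly reproduced by any combination of the
published scales and LE conventions, so FQ is treated as
variant-dependent and only its ordering is asserted.

`filter_hydroxyl_csc()` keeps CSCs in which the designated ligand's
designated hydroxyl oxygen (resolved from topology: the unique oxygen
with one single-bonded heavy neighbour, or an explicit atom index)
hydrogen-bonds any protein residue in at least `min_poses_with_hbond`
poses (default 1 — the weakest reading of "is able to form"; the
threshold is exposed because a cluster-majority reading is equally
defensible). `rank_hypotheses()` orders survivors lexicographically:
distinct H-bond partner count, then carbonyl rotamer reachability, then
mean H-bond score. A lexicographic order rather than a weighted score
keeps every decision auditable; disabling all criteria preserves input
order. Photoaffinity-labelling overlap is an optional annotation
(user-supplied residue list), never a ranking criterion.

# The synthetic scene generator

`make_scene()` replaces the external docking runs. What it emulates:

* a groove-shaped receptor of three pseudo-α-helices (1.5 Å rise, 100°
  twist), chain A, with tyrosines at 307/310, phenylalanines at
  336/343 and an asparagine at 754 pointing into the groove — stand-ins
  for the transmembrane 5/8 interface residues. Side chains are
  idealised templates tilted 40° off the CA–CB axis (the real
  CA–CB–CG bend; without it a χ1 rotation would not move the tyrosine
  hydroxyl at all). Residue layouts that fold onto themselves
  (inter-residue atoms < 1.2 Å) are rejected.
* five toy ligands sharing the packaged scaffold, with distinct
  substituents; only GPV062 carries a hydroxyl (on a piperidine-like
  ring, its "4-OH"). These are minimal chemically plausible graphs, not
  the real structures — mapping, clustering and interaction geometry do
  not require real chemistry.
* pose ensembles: per (ligand, cluster), the rigid template at the
  cluster centre under a per-cluster base orientation, plus isotropic
  Gaussian jitter (σ, default 0.3 Å) and an orientation wobble with
  angle s.d. 10·σ degrees — tying the wobble to σ makes σ = 0 fully
  degenerate (identical same-ligand poses), which the tests exploit.
  Under these defaults the mean intra-cluster scaffold RMSD stays below
  3σ and inter-cluster RMSD above the centre separation minus 6σ.
* planted geometry: clusters named in `planted_hbond_specs` are
  anchored so one representative pose (no jitter, reference
  orientation) puts the designated atom exactly 2.8 Å from the named
  receptor atom; planted clashes use 2.0 Å (well below carbon–carbon
  van der Waals contact). Unanchored centres are placed first-fit along
  the groove axis under the separation constraint and — when H-bonds
  are planted anywhere — a 5.5 Å clearance between the designated
  atom's position and every receptor polar atom, so unplanted clusters
  cannot acquire accidental hydrogen bonds. If a base orientation
  leaves no feasible position it is redrawn (bounded rejection
  sampling); genuinely infeasible configurations error.
* determinism: one RNG stream seeded once per scene, consumed in
  documented order (cluster orientations, then poses in ligand/pose
  order); a fixed seed reproduces the written scene byte-identically.

What it does **not** emulate: docking energetics, scoring, receptor
flexibility beyond the single-residue rotamer scan, solvent, realistic
secondary-structure geometry, or the pose diversity of a genetic
algorithm. Passing tests on these scenes therefore demonstrate that the
*protocol* — distance computation, clustering, filtering, detection,
ranking — is implemented correctly, not that it would select the true
binding mode for real docking output. In the same spirit, the cluster
counts of the original study (hundreds of clusters from docking into
homology models) depend on the external docking software and are out of
scope; the packaged scenes are labelled synthetic throughout.

Dedicated scenes exercise the detectors: `make_hbond_scene()` plants
three textbook hydrogen bonds and two decoys (one beyond the distance
cutoff, one distance-compliant but with an explicit hydrogen pointing
55° away, against an acceptor-only partner so that the angle test is
the only thing that can reject it); `make_rotamer_scene()` places a
ligand so its carbonyl is reachable exactly at a planted on-grid χ1 of
Tyr307, with `blocked` and `far` variants.

# Problem sizes

The default scene is 5 ligands × 100 poses (one docking run's worth);
the validation suite uses 20 poses per ligand and K = 4 planted
clusters — a 100×100 RMSD matrix per scene, which makes the 20-seed
recovery study and the 50-scene oracle-equivalence checks run in
seconds while leaving the planted separation/jitter ratio (12 Å vs
σ = 0.3 Å) untouched. Oracle checks compare against plain double-loop
reimplementations that share no code with the vectorised paths.

# Known limitations

* MOL2 input is not supported; pose ensembles are exchanged as tagged
  SDF (tags `ligand_id`, `pose_id`, `protonation`), receptors as PDB
  (ATOM records, no insertion codes, altloc A kept).
* H-bond criteria are geometric and hydrogen-agnostic by default;
  interaction strengths are distance-decay scores, not energies, and
  will not match any particular commercial tool's values.
* The scaffold must be supplied; there is no automatic
  maximum-common-substructure search.
* `fit_quality()` magnitudes are variant-dependent (see above); only
  within-series orderings should be interpreted.
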