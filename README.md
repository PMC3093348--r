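# sarpose

Structure–activity-guided evaluation of multi-ligand docking pose
ensembles, built around the P-glycoprotein (P-gp/ABCB1) inhibitor
use case.

## The problem

P-gp is an ATP-driven efflux pump whose overexpression causes multidrug
resistance. Its binding cavity is large, hydrophobic and polyspecific, no
high-resolution human structure exists, and docking into homology models
produces hundreds of poses whose scoring-function ranks are unreliable.
A practical way out is to avoid scoring functions and instead exploit
what a congeneric inhibitor series already tells us:

1. **Common-scaffold clustering.** All ligands of a series (here the
   propafenone-type inhibitors GPV005/019/062/186/366) share one
   scaffold. Poses of *all* ligands are pooled and compared by the RMSD
   of their scaffold heavy atoms, computed **in place** (no
   superposition — all poses share the receptor frame, and the point is
   to distinguish binding locations):

   `RMSD(a, b) = min over symmetry mappings of sqrt( (1/N) * sum_i ||a_i - b_i||^2 )`

   The pooled matrix is clustered by complete linkage and cut at 3 Å.
2. **Common-scaffold clusters (CSCs).** Only clusters containing poses
   of at least 4 of the 5 ligands are kept — a common binding mode must
   accommodate the whole series.
3. **SAR filter.** Ligand-efficiency metrics single out one ligand whose
   potency is not explained by lipophilicity or size:

   - lipophilic ligand efficiency `LLE = pIC50 − logP`
   - ligand efficiency `LE = pIC50 / HAC` (HAC = heavy-atom count)
   - fit quality `FQ = 1.37·pIC50/HAC / LE_scale(HAC)` with a published
     size-dependent reference scale

   For this series that ligand is GPV062, and its distinguishing feature
   is a hydroxyl group — so only CSCs in which GPV062's hydroxyl
   hydrogen-bonds the protein are credible binding hypotheses.
4. **Interaction fingerprints and rotamer scans.** Per-residue
   protein–ligand interaction fingerprints (contacts ≤ 4.5 Å, geometric
   H-bonds, aromatic interactions) characterise each CSC; side-chain
   rotamer scans test whether a nearby tyrosine can rotate into a new,
   clash-free H-bond with the scaffold carbonyl; steric-clash counts and
   photoaffinity-labelling overlap annotate the final lexicographic
   ranking.

Because the original docking runs are not reproducible without the
external software, the package ships a deterministic synthetic scene
generator (`make_scene()`): a toy helical groove receptor with tyrosines
in the roles of Y307/Y310, plus pose ensembles with planted cluster
structure, planted hydrogen bonds and planted clashes — ground truth for
every stage of the pipeline.

## Worked example

```r
library(sarpose)

# ligand-efficiency metrics from the packaged activity table
act <- read_activity_table(system.file("extdata",
        "propafenone_activities.csv", package = "sarpose"))
efficiency_table(act)
#>   ligand_id pIC50 HAC logP  LLE   LE   FQ          fq_variant
#> 1    GPV005  6.22  27 4.38 1.84 0.23 0.86 reynolds_polynomial
#> 2    GPV019  6.21  33 5.15 1.06 0.19 0.82 reynolds_polynomial
#> 3    GPV062  7.24  34 4.15 3.09 0.21 0.95 reynolds_polynomial
#> 4    GPV186  6.19  26 5.54 0.65 0.24 0.86 reynolds_polynomial
#> 5    GPV366  5.78  33 4.94 0.84 0.18 0.77 reynolds_polynomial
```

GPV062 has by far the highest LLE (3.09) and the highest fit quality —
the SAR signal the pose filter is built on.

```r
# a synthetic scene: 5 ligands x 20 poses, 4 planted clusters, with the
# GPV062 hydroxyl H-bond planted in clusters 1 (to Tyr307-OH) and 3 (to
# Asn754-OD1)
scene <- make_scene(scene_config(
  seed = 7, poses_per_ligand = 20, n_centers = 4,
  center_min_separation = 10,
  planted_hbond_specs = list(
    list(cluster = 1, ligand_id = "GPV062", atom = "hydroxyl",
         chain = "A", resnum = 307, atom_name = "OH"),
    list(cluster = 3, ligand_id = "GPV062", atom = "hydroxyl",
         chain = "A", resnum = 754, atom_name = "OD1"))))

res <- run_pipeline("demo_out", scene = scene)
#> [sarpose] 100 poses, 5 ligands
#> [sarpose] 4 clusters at 3 Angstrom cut
#> [sarpose] 4 common-scaffold clusters (100 poses)
#> [sarpose] 2 CSCs pass the hydroxyl H-bond filter
#> [sarpose] wrote 12 files to demo_out

res$ranking[, c("rank", "csc_label", "n_members", "n_ligands",
                "hydroxyl_partners", "carbonyl_rotamer")]
#>   rank csc_label n_members n_ligands hydroxyl_partners carbonyl_rotamer
#> 1    1   CSC III        25         5     ASN754;ASN754            FALSE
#> 2    2     CSC I        25         5            TYR307            FALSE
```

All four planted clusters are recovered at the 3 Å cut and survive the
4-of-5 CSC filter; the hydroxyl filter then retains exactly the two
clusters with the planted H-bond, annotated with their partner residues.
`demo_out/` contains the cluster statistics table, per-residue PLIF
tables, per-CSC SDF files, the prioritisation report, the efficiency
metrics and a manifest.

Each stage is also available on its own (`build_scaffold_maps()`,
`rmsd_matrix()`, `cluster_poses()`, `filter_csc()`, `plif()`,
`detect_hbonds()`, `clash_count()`, `rotamer_scan()`,
`filter_hydroxyl_csc()`, `rank_hypotheses()`), so pose ensembles from
any docking program can be substituted for the synthetic scenes via
tagged SDF files (`read_pose_ensemble()`). A command-line wrapper lives
in `inst/scripts/run_pipeline.R`.

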