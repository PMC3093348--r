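demo_pipeline_objects <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    s <- make_scene(demo_scene_config())
    maps <- build_scaffold_maps(s$ensemble)
    clusters <- cluster_poses(rmsd_matrix(s$ensemble, maps))
    cscs <- filter_csc(clusters)
    cache <<- list(scene = s, cscs = cscs)
    cache
  }
})

test_that("the hydroxyl filter retains exactly the planted clusters", {
  obj <- demo_pipeline_objects()
  kept <- filter_hydroxyl_csc(obj$cscs, obj$scene$ensemble, obj$scene$receptor)
  expect_equal(csc_truth_clusters(kept, obj$scene), c(1, 3))
  # partner annotation distinguishes the tyrosine from the asparagine cluster
  partners <- lapply(kept, function(cl) unique(cl$hydroxyl_partners$resnum))
  expect_setequal(unlist(partners), c(307, 754))
  expect_true(all(vapply(kept, function(cl) cl$n_poses_with_hbond >= 1, TRUE)))
})

test_that("a zero pose threshold disables the hydroxyl filter", {
  obj <- demo_pipeline_objects()
  kept <- filter_hydroxyl_csc(obj$cscs, obj$scene$ensemble, obj$scene$receptor,
                              sar_filter_spec(min_poses_with_hbond = 0))
  expect_equal(length(kept), length(obj$cscs))
})

test_that("a missing designated ligand yields a warning and empty result", {
  s <- make_scene(scene_config(
    seed = 9, poses_per_ligand = 8, n_centers = 2, n_ligands = 5,
    cluster_ligands = rep(list(c("GPV005", "GPV019", "GPV186", "GPV366")), 2)))
  maps <- build_scaffold_maps(s$ensemble)
  cscs <- filter_csc(cluster_poses(rmsd_matrix(s$ensemble, maps)))
  expect_gt(length(cscs), 0)
  expect_warning(kept <- filter_hydroxyl_csc(cscs, s$ensemble, s$receptor),
                 "absent")
  expect_equal(length(kept), 0)
})

test_that("the hydroxyl filter commutes with cluster subsetting", {
  obj <- demo_pipeline_objects()
  full <- filter_hydroxyl_csc(obj$cscs, obj$scene$ensemble, obj$scene$receptor)
  sub <- obj$cscs[c(1, 3)]
  kept_sub <- filter_hydroxyl_csc(sub, obj$scene$ensemble, obj$scene$receptor)
  ids_full <- vapply(full, function(cl) cl$cluster_id, 1L)
  ids_sub <- vapply(kept_sub, function(cl) cl$cluster_id, 1L)
  sub_ids <- vapply(sub, function(cl) cl$cluster_id, 1L)
  expect_setequal(ids_sub, intersect(ids_full, sub_ids))
})

test_that("the atom selector resolves to exactly one oxygen", {
  s <- make_scene(scene_config(seed = 9, poses_per_ligand = 1, n_centers = 1))
  p062 <- ligand_poses(s$ensemble, "GPV062")[[1]]
  idx <- sarpose:::resolve_sar_atom(p062, "hydroxyl")
  expect_equal(p062$atoms$element[idx], "O")
  expect_equal(idx, 24L)  # the planted 4-OH oxygen of the template
  p005 <- ligand_poses(s$ensemble, "GPV005")[[1]]
  expect_error(sarpose:::resolve_sar_atom(p005, "hydroxyl"), "0 hydroxyl")
  expect_error(sarpose:::resolve_sar_atom(p062, 1), "oxygen")
  expect_error(sarpose:::resolve_sar_atom(p062, 999), "out of range")
})

test_that("ranking prefers the cluster whose carbonyl is rotamer-reachable", {
  rs <- make_rotamer_scene(chi_target = 120)
  far <- make_rotamer_scene(far = TRUE)
  p1 <- rs$pose
  p2 <- pose("GPV062", 2L, far$pose$atoms, far$pose$bonds)
  ens <- pose_ensemble(list(p1, p2))
  mk_csc <- function(id, label, idx) {
    structure(list(cluster_id = id, csc_label = label,
                   members = data.frame(ligand_id = "GPV062", pose_id = idx,
                                        index = idx),
                   ligand_set = "GPV062", formation_height = 0,
                   hydroxyl_partners = data.frame(chain = "A", resnum = 307,
                                                  resname = "TYR",
                                                  protein_atom = "OH"),
                   n_poses_with_hbond = 1L, mean_hbond_score = 0.5),
              class = "pose_cluster")
  }
  kept <- list(mk_csc(1, "CSC A", 2L), mk_csc(2, "CSC B", 1L))  # B is reachable
  rep <- rank_hypotheses(kept, ens, rs$receptor)
  expect_equal(rep$csc_label[rep$rank == 1], "CSC B")
  expect_true(rep$carbonyl_rotamer[rep$rank == 1])
  expect_false(rep$carbonyl_rotamer[rep$rank == 2])
})

test_that("ranking is stable when no criterion separates the clusters", {
  far <- make_rotamer_scene(far = TRUE)
  p1 <- far$pose
  p2 <- pose("GPV062", 2L, far$pose$atoms, far$pose$bonds)
  ens <- pose_ensemble(list(p1, p2))
  mk_csc <- function(id, label, idx) {
    structure(list(cluster_id = id, csc_label = label,
                   members = data.frame(ligand_id = "GPV062", pose_id = idx,
                                        index = idx),
                   ligand_set = "GPV062", formation_height = 0,
                   hydroxyl_partners = data.frame(chain = "A", resnum = 307,
                                                  resname = "TYR",
                                                  protein_atom = "OH"),
                   n_poses_with_hbond = 1L, mean_hbond_score = 0.5),
              class = "pose_cluster")
  }
  rep <- rank_hypotheses(list(mk_csc(1, "first", 1L), mk_csc(2, "second", 2L)),
                         ens, far$receptor)
  expect_equal(rep$csc_label, c("first", "second"))
  expect_error(rank_hypotheses(list(), ens, far$receptor), "no clusters")
})

test_that("a single retained CSC gets rank 1 and PAL overlap is annotated", {
  obj <- demo_pipeline_objects()
  kept <- filter_hydroxyl_csc(obj$cscs, obj$scene$ensemble, obj$scene$receptor)
  pal <- data.frame(chain = "A", resnum = c(304, 307, 310))
  rep <- rank_hypotheses(kept[1], obj$scene$ensemble, obj$scene$receptor,
                         pal_residues = pal)
  expect_equal(rep$rank, 1)
  expect_true(is.finite(rep$pal_overlap))
})
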