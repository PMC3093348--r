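translated_pose <- function(p, t) {
  a <- p$atoms
  a$x <- a$x + t[1]; a$y <- a$y + t[2]; a$z <- a$z + t[3]
  pose(p$ligand_id, p$pose_id + 1000L, a, p$bonds, p$protonation)
}

test_that("in-place scaffold RMSD satisfies identity, translation and symmetry", {
  pr <- random_scaffold_pair(101)
  ens <- pose_ensemble(list(pr$a, pr$b))
  maps <- build_scaffold_maps(ens)
  mp <- maps$GPV005
  expect_equal(scaffold_rmsd(pr$a, pr$a, mp, mp), 0)
  # a rigid translation by (3, 0, 0) shifts every atom equally: RMSD = 3
  pb <- translated_pose(pr$a, c(3, 0, 0))
  expect_equal(scaffold_rmsd(pr$a, pb, mp, mp), 3, tolerance = 1e-12)
  expect_equal(scaffold_rmsd(pr$a, pr$b, mp, mp),
               scaffold_rmsd(pr$b, pr$a, mp, mp))
})

test_that("scaffold RMSD equals the brute-force minimum over mapping pairs", {
  for (seed in c(1, 7, 23, 99)) {
    pr <- random_scaffold_pair(seed)
    ens <- pose_ensemble(list(pr$a, pr$b))
    mp <- build_scaffold_maps(ens)$GPV005
    expect_equal(scaffold_rmsd(pr$a, pr$b, mp, mp),
                 bf_scaffold_rmsd(pr$a, pr$b, mp, mp), tolerance = 1e-9)
  }
})

test_that("scaffold RMSD behaves as a metric on seeded random triples", {
  for (seed in 1:10) {
    set.seed(seed)
    tpl <- sarpose:::build_ligand_templates()$GPV366
    mk <- function(id) {
      R <- sarpose:::rotation_matrix(rnorm(3), runif(1, 0, pi))
      xyz <- t(R %*% t(tpl$xyz)) + matrix(rnorm(3, 0, 6), nrow(tpl$xyz), 3,
                                          byrow = TRUE)
      pose("GPV366", id, data.frame(element = tpl$elem, x = xyz[, 1],
                                    y = xyz[, 2], z = xyz[, 3]),
           data.frame(from = tpl$bonds[, 1], to = tpl$bonds[, 2],
                      order = tpl$bonds[, 3]))
    }
    ps <- list(mk(1), mk(2), mk(3))
    mp <- build_scaffold_maps(pose_ensemble(ps))$GPV366
    d12 <- scaffold_rmsd(ps[[1]], ps[[2]], mp, mp)
    d13 <- scaffold_rmsd(ps[[1]], ps[[3]], mp, mp)
    d23 <- scaffold_rmsd(ps[[2]], ps[[3]], mp, mp)
    expect_gte(d12 + d23, d13 - 1e-9)
    expect_gte(d12 + d13, d23 - 1e-9)
    expect_gte(d13 + d23, d12 - 1e-9)
  }
})

test_that("the RMSD matrix pools all ligands and matches pairwise calls", {
  s <- make_scene(scene_config(seed = 13, poses_per_ligand = 2, n_centers = 2))
  maps <- build_scaffold_maps(s$ensemble)
  m <- rmsd_matrix(s$ensemble, maps)
  n <- length(s$ensemble$poses)
  expect_equal(dim(m$values), c(n, n))
  expect_equal(diag(m$values), rep(0, n))
  expect_equal(m$values, t(m$values))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      pi <- s$ensemble$poses[[i]]; pj <- s$ensemble$poses[[j]]
      expect_equal(m$values[i, j],
                   scaffold_rmsd(pi, pj, maps[[pi$ligand_id]], maps[[pj$ligand_id]]),
                   tolerance = 1e-9)
    }
  }
  # one pose: 1 x 1 zero matrix
  one <- pose_ensemble(s$ensemble$poses[1])
  m1 <- rmsd_matrix(one, maps)
  expect_equal(m1$values, matrix(0, 1, 1))
})

test_that("complete linkage at the cut separates well-separated groups", {
  # two planted groups: intra <= 1, inter >= 10
  pr <- random_scaffold_pair(55)
  base <- pr$a
  mk <- function(id, t) translated_pose(pose(base$ligand_id, id, base$atoms,
                                             base$bonds), t)
  ps <- list(mk(1L, c(0, 0, 0)), mk(2L, c(0.5, 0, 0)), mk(3L, c(0, 0.5, 0)),
             mk(10L, c(15, 0, 0)), mk(11L, c(15.5, 0, 0)))
  ens <- pose_ensemble(ps)
  maps <- build_scaffold_maps(ens)
  cl <- cluster_poses(rmsd_matrix(ens, maps), clustering_config(cut_height = 3))
  expect_equal(length(cl), 2)
  expect_setequal(cl[[1]]$members$index, 1:3)  # largest first
  expect_setequal(cl[[2]]$members$index, 4:5)
})

test_that("all-singleton input stays singletons and poses are conserved", {
  pr <- random_scaffold_pair(56)
  base <- pr$a
  ps <- lapply(1:5, function(i)
    translated_pose(pose(base$ligand_id, i, base$atoms, base$bonds),
                    c(10 * i, 0, 0)))
  ens <- pose_ensemble(ps)
  maps <- build_scaffold_maps(ens)
  m <- rmsd_matrix(ens, maps)
  cl <- cluster_poses(m)
  expect_equal(length(cl), 5)
  expect_equal(sum(vapply(cl, function(c) nrow(c$members), 1L)), nrow(m$values))
})

test_that("the cut is inclusive at exactly the cut height", {
  pr <- random_scaffold_pair(57)
  base <- pr$a
  ps <- list(pose(base$ligand_id, 1L, base$atoms, base$bonds),
             translated_pose(pose(base$ligand_id, 2L, base$atoms, base$bonds),
                             c(3, 0, 0)))
  ens <- pose_ensemble(ps)
  maps <- build_scaffold_maps(ens)
  cl <- cluster_poses(rmsd_matrix(ens, maps), clustering_config(cut_height = 3))
  expect_equal(length(cl), 1)
  expect_equal(cl[[1]]$formation_height, 3, tolerance = 1e-9)
})

test_that("complete-linkage contract holds on a generated scene", {
  s <- make_scene(scene_config(seed = 21, poses_per_ligand = 10, n_centers = 3))
  maps <- build_scaffold_maps(s$ensemble)
  m <- rmsd_matrix(s$ensemble, maps)
  cfg <- clustering_config()
  cl <- cluster_poses(m, cfg)
  for (c1 in cl) {
    g <- c1$members$index
    expect_equal(c1$formation_height,
                 if (length(g) > 1) max(m$values[g, g]) else 0)
    expect_lte(c1$formation_height, cfg$cut_height)
  }
  # merging any two output clusters would exceed the cut
  if (length(cl) > 1) {
    for (i in 1:(length(cl) - 1)) {
      for (j in (i + 1):length(cl)) {
        gi <- cl[[i]]$members$index; gj <- cl[[j]]$members$index
        expect_gt(max(m$values[gi, gj]), cfg$cut_height)
      }
    }
  }
  expect_equal(sum(vapply(cl, function(c) nrow(c$members), 1L)), nrow(m$values))
})

test_that("planted clusters are recovered exactly on the reference scene", {
  s <- make_scene(scene_config(seed = 42, poses_per_ligand = 20, n_centers = 4,
                               center_min_separation = 12, jitter_sigma = 0.3))
  maps <- build_scaffold_maps(s$ensemble)
  m <- rmsd_matrix(s$ensemble, maps)
  cl <- cluster_poses(m)
  expect_equal(scene_ari(s, cl, m), 1)
})

test_that("the CSC filter equals a brute-force distinct-ligand recount", {
  set.seed(77)
  for (rep in 1:25) {
    nlig <- sample(4:5, 1)
    ligs <- paste0("L", seq_len(nlig))
    clusters <- lapply(1:6, function(ci) {
      n <- sample(1:8, 1)
      members <- data.frame(ligand_id = sample(ligs, n, replace = TRUE),
                            pose_id = seq_len(n), index = seq_len(n))
      structure(list(cluster_id = ci, members = members,
                     ligand_set = sort(unique(members$ligand_id)),
                     formation_height = 1),
                class = "pose_cluster")
    })
    cfg <- clustering_config(min_ligands = 4, total_ligands = nlig)
    kept <- filter_csc(clusters, cfg)
    bf <- Filter(function(cl) length(unique(cl$members$ligand_id)) >= 4, clusters)
    expect_equal(length(kept), length(bf))
    expect_setequal(vapply(kept, function(cl) cl$cluster_id, 1L),
                    vapply(bf, function(cl) cl$cluster_id, 1L))
  }
})

test_that("CSC labels are Roman numerals by descending size and 4-of-5 is enforced", {
  s <- make_scene(scene_config(
    seed = 31, poses_per_ligand = 10, n_centers = 3,
    cluster_ligands = list(c("GPV005", "GPV019", "GPV062", "GPV186"),
                           c("GPV005", "GPV019", "GPV366"),
                           c("GPV005", "GPV019", "GPV062", "GPV186", "GPV366"))))
  maps <- build_scaffold_maps(s$ensemble)
  m <- rmsd_matrix(s$ensemble, maps)
  cl <- cluster_poses(m)
  expect_equal(length(cl), 3)
  cscs <- filter_csc(cl)
  expect_equal(length(cscs), 2)  # the 3-ligand cluster is dropped
  expect_equal(vapply(cscs, function(c) c$csc_label, ""), c("CSC I", "CSC II"))
  expect_gte(nrow(cscs[[1]]$members), nrow(cscs[[2]]$members))
  expect_equal(attr(cscs, "n_dropped"), 1)
})

test_that("single-ligand clusters never qualify as CSCs", {
  s <- make_scene(scene_config(
    seed = 32, poses_per_ligand = 6, n_centers = 2, n_ligands = 2,
    cluster_ligands = list("GPV005", "GPV019")))
  maps <- build_scaffold_maps(s$ensemble)
  cl <- cluster_poses(rmsd_matrix(s$ensemble, maps))
  expect_equal(length(filter_csc(cl)), 0)
})
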