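probe_at <- function(xyz, element = "C") {
  pose("PROBE", 1L, data.frame(element = element, x = xyz[1], y = xyz[2],
                               z = xyz[3]),
       data.frame(from = integer(0), to = integer(0), order = integer(0)))
}

test_that("the contact cutoff is inclusive at exactly 4.5 Angstrom", {
  rec <- fixture_receptor()
  cb <- sarpose:::receptor_atom_xyz(rec, "A", 307, "CB")
  dir <- sarpose:::unit(c(0, 0, cb[3]) - cb)
  hit <- contact_residues(probe_at(cb + 4.5 * dir), rec)
  expect_true(307 %in% hit$resnum)
  # nudge just beyond the cutoff relative to the nearest 307 atom
  far <- contact_residues(probe_at(cb + 30 * dir + c(0, 0, 50)), rec)
  expect_equal(nrow(far), 0)
})

test_that("contact residues equal the brute-force double loop on random scenes", {
  rec <- fixture_receptor()
  for (seed in c(2, 9, 17)) {
    p <- random_probe_pose(seed, center = c(0, 0, 10 + 3 * seed %% 20))
    got <- contact_residues(p, rec)
    expect_identical(sort(paste(got$chain, got$resnum)),
                     bf_contact_residues(p, rec))
  }
})

test_that("planted hydrogen bonds are detected and decoys rejected", {
  sc <- make_hbond_scene()
  hb <- detect_hbonds(sc$pose, sc$receptor)
  got <- sort(paste(hb$ligand_index, hb$resnum, hb$protein_atom))
  want <- sort(paste(sc$planted$ligand_index, sc$planted$resnum,
                     sc$planted$atom_name))
  expect_identical(got, want)
  expect_false(any(hb$ligand_index %in% sc$decoys$ligand_index))
  expect_true(all(hb$distance <= 3.5))
  expect_true(all(hb$score > 0 & hb$score <= 1))
})

test_that("hydrogen-bond scores decay with distance and saturate at ideal geometry", {
  rec <- fixture_receptor()
  oh <- sarpose:::receptor_atom_xyz(rec, "A", 307, "OH")
  dir <- sarpose:::unit(c(0, 0, oh[3]) - oh)
  mk <- function(d) {
    at <- data.frame(element = c("O", "C"),
                     x = c(oh[1] + d * dir[1], oh[1] + (d + 1.4) * dir[1]),
                     y = c(oh[2] + d * dir[2], oh[2] + (d + 1.4) * dir[2]),
                     z = c(oh[3] + d * dir[3], oh[3] + (d + 1.4) * dir[3]))
    pose("P", 1L, at, data.frame(from = 1L, to = 2L, order = 1L))
  }
  sub <- data.frame(chain = "A", resnum = 307)
  s26 <- detect_hbonds(mk(2.6), rec, residue_subset = sub)
  s30 <- detect_hbonds(mk(3.0), rec, residue_subset = sub)
  s34 <- detect_hbonds(mk(3.4), rec, residue_subset = sub)
  expect_equal(s26$score[1], 1)
  expect_gt(s30$score[1], s34$score[1])
  expect_equal(nrow(detect_hbonds(mk(5.0), rec, residue_subset = sub)), 0)
})

test_that("hydrogen bonds imply contacts when the H-bond cutoff is tighter", {
  s <- make_scene(demo_scene_config(seed = 19, poses_per_ligand = 6))
  cfg <- interaction_config()
  for (p in ligand_poses(s$ensemble, "GPV062")[1:6]) {
    hb <- detect_hbonds(p, s$receptor, cfg)
    if (!nrow(hb)) next
    ct <- contact_residues(p, s$receptor, cfg)
    expect_true(all(paste(hb$chain, hb$resnum) %in% paste(ct$chain, ct$resnum)))
  }
})

test_that("PLIF frequencies aggregate per-pose interactions exactly", {
  s <- make_scene(scene_config(seed = 23, poses_per_ligand = 6, n_centers = 2))
  set <- s$ensemble$poses[1:12]
  fp <- plif(set, s$receptor, pose_set_id = "check")
  expect_equal(fp$n_poses, 12)
  expect_true(all(fp$table$contact_freq >= 0 & fp$table$contact_freq <= 1))
  # recompute one residue's contact count independently
  for (r in seq_len(min(5, nrow(fp$table)))) {
    key <- paste(fp$table$chain[r], fp$table$resnum[r])
    n <- sum(vapply(set, function(p) {
      ct <- contact_residues(p, s$receptor)
      key %in% paste(ct$chain, ct$resnum)
    }, TRUE))
    expect_equal(fp$table$contact[r], n)
  }
  expect_true(all(fp$table$contact[fp$table$direct] >= 1))
})

test_that("PLIF is invariant under pose order and additive over disjoint sets", {
  s <- make_scene(scene_config(seed = 23, poses_per_ligand = 4, n_centers = 2))
  set <- s$ensemble$poses[1:8]
  f1 <- plif(set, s$receptor)
  f2 <- plif(rev(set), s$receptor)
  expect_equal(f1$table[order(f1$table$resnum), ],
               f2$table[order(f2$table$resnum), ], ignore_attr = TRUE)
  fa <- plif(set[1:4], s$receptor)$table
  fb <- plif(set[5:8], s$receptor)$table
  key <- function(t) paste(t$chain, t$resnum)
  for (k in intersect(key(fa), key(fb))) {
    expect_equal(fa$contact[key(fa) == k] + fb$contact[key(fb) == k],
                 f1$table$contact[key(f1$table) == k])
  }
})

test_that("a single pose yields only 0/1 frequencies and empty sets error", {
  s <- make_scene(scene_config(seed = 23, poses_per_ligand = 1, n_centers = 1))
  fp <- plif(s$ensemble$poses[1], s$receptor)
  expect_true(all(fp$table$contact_freq %in% c(0, 1)))
  expect_error(plif(list(), s$receptor), "empty pose set")
})

test_that("fingerprint comparison performs exact set algebra", {
  mk_fp <- function(resnums, freq = 1) {
    structure(list(pose_set_id = "x", n_poses = 1,
                   table = data.frame(chain = "A", resnum = resnums,
                                      resname = "ALA", contact = 1, hbond = 0,
                                      aromatic = 0, contact_freq = freq,
                                      hbond_freq = 0, aromatic_freq = 0,
                                      direct = FALSE)),
              class = "interaction_fp")
  }
  cmp <- compare_fingerprints(list(A = mk_fp(c(307, 310, 343)),
                                   B = mk_fp(c(310, 343, 724))))
  expect_setequal(cmp$regions[["A&B"]], c("A 310", "A 343"))
  expect_setequal(cmp$regions[["A_only"]], "A 307")
  expect_setequal(cmp$regions[["B_only"]], "A 724")

  same <- compare_fingerprints(list(A = mk_fp(1:3), B = mk_fp(1:3)))
  expect_equal(length(same$regions[["A_only"]]), 0)
  expect_equal(length(same$regions[["B_only"]]), 0)

  # three fingerprints: the 7 Venn regions partition the residue universe
  cmp3 <- compare_fingerprints(list(A = mk_fp(c(1, 2, 3, 4)),
                                    B = mk_fp(c(3, 4, 5)),
                                    C = mk_fp(c(4, 5, 6))))
  allres <- unique(c(cmp3$residues$A, cmp3$residues$B, cmp3$residues$C))
  pooled <- unlist(cmp3$regions)
  expect_setequal(pooled, allres)
  expect_equal(length(pooled), length(allres))  # disjoint
  # brute-force membership check for every residue
  for (r in allres) {
    inA <- r %in% cmp3$residues$A; inB <- r %in% cmp3$residues$B
    inC <- r %in% cmp3$residues$C
    key <- if (inA && inB && inC) "A&B&C"
      else if (inA && inB) "A&B" else if (inA && inC) "A&C"
      else if (inB && inC) "B&C"
      else if (inA) "A_only" else if (inB) "B_only" else "C_only"
    expect_true(r %in% cmp3$regions[[key]])
  }
  expect_error(compare_fingerprints(list(A = mk_fp(1))), "at least two")
})

test_that("the frequency threshold controls binding-site membership", {
  t1 <- data.frame(chain = "A", resnum = c(1, 2), resname = "ALA",
                   contact = c(9, 1), hbond = 0, aromatic = 0,
                   contact_freq = c(0.9, 0.1), hbond_freq = 0,
                   aromatic_freq = 0, direct = FALSE)
  fp1 <- structure(list(pose_set_id = "x", n_poses = 10, table = t1),
                   class = "interaction_fp")
  cmp <- compare_fingerprints(list(A = fp1, B = fp1), min_freq = 0.5)
  expect_setequal(cmp$residues$A, "A 1")
})

test_that("clash counting matches brute force and flags deep overlap", {
  rec <- fixture_receptor()
  cb <- sarpose:::receptor_atom_xyz(rec, "A", 304, "CB")
  expect_gte(clash_count(probe_at(cb + c(0, 0, 2.0)), rec), 1)
  expect_equal(clash_count(probe_at(c(0, 0, 200)), rec), 0)
  cfg <- interaction_config()
  for (seed in c(4, 12, 31)) {
    p <- random_probe_pose(seed, center = c(0, 0, 5 + seed %% 30), n = 20)
    expect_equal(clash_count(p, rec, cfg),
                 bf_clash_count(p, rec, cfg$vdw_radii, cfg$clash_tolerance))
  }
  bad <- probe_at(cb, element = "C")
  bad$atoms$element <- "C"
  cfg2 <- interaction_config(vdw_radii = c(N = 1.55, O = 1.52, H = 1.2))
  expect_error(clash_count(bad, rec, cfg2), "van der Waals")
})

test_that("hydrogen-bond pair sets match the brute-force enumeration", {
  rec <- fixture_receptor()
  for (seed in c(3, 14, 28)) {
    p <- random_probe_pose(seed, center = c(0, 0, 12 + seed %% 25), n = 30)
    hb <- detect_hbonds(p, rec)
    got <- sort(unique(paste(hb$ligand_index, hb$chain, hb$resnum, hb$protein_atom)))
    expect_identical(got, bf_hbond_pairs(p, rec))
  }
})

test_that("aromatic ring detection finds ligand phenyls and nearby residue rings", {
  rec <- fixture_receptor()
  # place a GPV062 template phenyl centroid near the F343 ring centroid
  rc <- sarpose:::receptor_ring_centroids(rec)
  f343 <- rc[rc$resnum == 343, ]
  tpl <- sarpose:::build_ligand_templates()$GPV005
  cent <- as.numeric(f343[, c("x", "y", "z")])
  dirv <- sarpose:::unit(c(0, 0, cent[3]) - cent)
  ringB_cent <- colMeans(tpl$xyz[9:14, ])
  xyz <- sweep(tpl$xyz, 2, ringB_cent) +
    matrix(cent + 4.0 * dirv, nrow(tpl$xyz), 3, byrow = TRUE)
  p <- pose("GPV005", 1L, data.frame(element = tpl$elem, x = xyz[, 1],
                                     y = xyz[, 2], z = xyz[, 3]),
            data.frame(from = tpl$bonds[, 1], to = tpl$bonds[, 2],
                       order = tpl$bonds[, 3]))
  ar <- sarpose:::aromatic_interactions(p, rec)
  expect_true(!is.null(ar) && any(ar$resnum == 343 & ar$type == "pi_pi"))
  # the ionized amine close to a ring registers as pi/cation
  p2 <- p; p2$protonation <- "ionized"
  p2 <- pose("GPV005", 1L, p2$atoms, p2$bonds, protonation = "ionized")
  ar2 <- sarpose:::aromatic_interactions(p2, rec)
  expect_true(is.null(ar2) || all(c(ar2$type) %in% c("pi_pi", "pi_cation")))
})
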