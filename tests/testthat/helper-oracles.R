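# Independent brute-force oracles. These deliberately use plain double
# loops and share no code with the implementation paths they check.

bf_scaffold_rmsd <- function(poseA, poseB, mapsA, mapsB) {
  mA <- if (inherits(mapsA, "scaffold_map")) mapsA$mappings else mapsA
  mB <- if (inherits(mapsB, "scaffold_map")) mapsB$mappings else mapsB
  best <- Inf
  for (a in mA) {
    for (b in mB) {
      ss <- 0
      for (i in seq_along(a)) {
        pa <- as.numeric(poseA$atoms[a[i], c("x", "y", "z")])
        pb <- as.numeric(poseB$atoms[b[i], c("x", "y", "z")])
        ss <- ss + sum((pa - pb)^2)
      }
      best <- min(best, sqrt(ss / length(a)))
    }
  }
  best
}

bf_contact_residues <- function(p, rec, cutoff = 4.5) {
  la <- p$atoms[p$atoms$is_heavy, ]
  ra <- rec$atoms[rec$atoms$is_heavy, ]
  hits <- character(0)
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(la))) {
      d <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                  (ra$z[i] - la$z[j])^2)
      if (d <= cutoff) {
        hits <- c(hits, paste(ra$chain[i], ra$resnum[i]))
        break
      }
    }
  }
  sort(unique(hits))
}

bf_clash_count <- function(p, rec, radii, tol = 0.4) {
  la <- p$atoms[p$atoms$is_heavy, ]
  ra <- rec$atoms[rec$atoms$is_heavy, ]
  n <- 0L
  for (i in seq_len(nrow(la))) {
    for (j in seq_len(nrow(ra))) {
      d <- sqrt((la$x[i] - ra$x[j])^2 + (la$y[i] - ra$y[j])^2 +
                  (la$z[i] - ra$z[j])^2)
      if (d < radii[la$element[i]] + radii[ra$element[j]] - tol) n <- n + 1L
    }
  }
  n
}

# Brute-force H-bond pair enumeration on pre-typed polar atom tables
# (typing itself is a design rule, not a computation under test).
bf_hbond_pairs <- function(p, rec, da_max = 3.5, dha_min = 120) {
  lp <- sarpose:::ligand_polar_atoms(p)
  rp <- sarpose:::receptor_polar_atoms(rec)
  out <- character(0)
  for (i in seq_len(nrow(lp))) {
    for (j in seq_len(nrow(rp))) {
      d <- sqrt((lp$x[i] - rp$x[j])^2 + (lp$y[i] - rp$y[j])^2 +
                  (lp$z[i] - rp$z[j])^2)
      if (d > da_max) next
      ok <- FALSE
      if (lp$donor[i] && rp$acceptor[j]) {
        hxyz <- sarpose:::ligand_h_neighbours(p, lp$index[i])
        if (is.null(hxyz)) {
          ok <- TRUE
        } else {
          for (hr in seq_len(nrow(hxyz))) {
            ang <- sarpose:::angle_deg(c(lp$x[i], lp$y[i], lp$z[i]), hxyz[hr, ],
                                       c(rp$x[j], rp$y[j], rp$z[j]))
            if (ang >= dha_min) ok <- TRUE
          }
        }
      }
      if (!ok && lp$acceptor[i] && rp$donor[j]) ok <- TRUE
      if (ok) out <- c(out, paste(lp$index[i], rp$chain[j], rp$resnum[j], rp$name[j]))
    }
  }
  sort(unique(out))
}

# Small deterministic random pose used by oracle-equivalence checks:
# a loose chain of heavy atoms scattered near a given centre.
random_probe_pose <- function(seed, center = c(0, 0, 20), n = 25) {
  set.seed(seed)
  elem <- sample(c("C", "N", "O"), n, replace = TRUE, prob = c(0.7, 0.15, 0.15))
  xyz <- matrix(stats::rnorm(n * 3, 0, 4), n, 3)
  xyz <- sweep(xyz, 2, center, `+`)
  bonds <- data.frame(from = seq_len(n - 1), to = 2:n, order = 1)
  pose("PROBE", seed, data.frame(element = elem, x = xyz[, 1], y = xyz[, 2],
                                 z = xyz[, 3]), bonds)
}

# Random rigid scaffold pair with both ring-flip mappings, for RMSD checks.
random_scaffold_pair <- function(seed) {
  set.seed(seed)
  tpl <- sarpose:::build_ligand_templates()$GPV005
  mk <- function(id) {
    R <- sarpose:::rotation_matrix(stats::rnorm(3), stats::runif(1, 0, pi))
    xyz <- t(R %*% t(tpl$xyz)) + matrix(stats::rnorm(3, 0, 5), nrow(tpl$xyz),
                                        3, byrow = TRUE)
    pose("GPV005", id, data.frame(element = tpl$elem, x = xyz[, 1],
                                  y = xyz[, 2], z = xyz[, 3]),
         data.frame(from = tpl$bonds[, 1], to = tpl$bonds[, 2],
                    order = tpl$bonds[, 3]))
  }
  list(a = mk(1), b = mk(2))
}

# Shared fixtures, built once per test run.
fixture_receptor <- local({
  rec <- NULL
  function() {
    if (is.null(rec)) rec <<- make_receptor()
    rec
  }
})

# The demo scene with hydrogen bonds planted in clusters 1 and 3.
demo_scene_config <- function(seed = 7, poses_per_ligand = 20) {
  scene_config(seed = seed, poses_per_ligand = poses_per_ligand,
               n_centers = 4, center_min_separation = 10,
               planted_hbond_specs = list(
                 list(cluster = 1, ligand_id = "GPV062", atom = "hydroxyl",
                      chain = "A", resnum = 307, atom_name = "OH"),
                 list(cluster = 3, ligand_id = "GPV062", atom = "hydroxyl",
                      chain = "A", resnum = 754, atom_name = "OD1")))
}

# Map implementation cluster labels back to planted labels and compute ARI.
scene_ari <- function(scene, clusters, mat) {
  lab <- integer(nrow(mat$pose_index))
  for (ci in seq_along(clusters)) lab[clusters[[ci]]$members$index] <- ci
  key <- paste(mat$pose_index$ligand_id, mat$pose_index$pose_id)
  tl <- scene$truth$labels
  planted <- tl$cluster[match(key, paste(tl$ligand_id, tl$pose_id))]
  mclust::adjustedRandIndex(lab, planted)
}

# Truth clusters represented in a CSC (via member overlap).
csc_truth_clusters <- function(cscs, scene) {
  tl <- scene$truth$labels
  sort(unique(unlist(lapply(cscs, function(cl) {
    key <- paste(cl$members$ligand_id, cl$members$pose_id)
    unique(tl$cluster[match(key, paste(tl$ligand_id, tl$pose_id))])
  }))))
}
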