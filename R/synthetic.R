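# Deterministic synthetic scenes: a toy groove-shaped receptor and
# multi-ligand pose ensembles with planted cluster structure, planted
# hydrogen bonds and planted clashes, plus ground-truth labels. The
# generator stands in for external docking runs so that every pipeline
# stage is testable; it emulates the geometry of the problem (a ligand
# series sharing a scaffold, posed inside a helical groove), not the
# chemistry or energetics of real docking.

#' Scene configuration
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @param n_ligands number of ligands (max 5; the packaged series).
#' @param poses_per_ligand poses generated per ligand (default 100,
#'   mirroring one genetic-algorithm docking run per molecule).
#' @param n_centers number of planted pose clusters K (default 4).
#' @param center_min_separation minimum distance between planted cluster
#'   centres, Angstrom (default 12).
#' @param jitter_sigma isotropic Gaussian positional jitter per pose,
#'   Angstrom (default 0.3). Pose orientations additionally wobble by a
#'   rotation with angle s.d. `10 * jitter_sigma` degrees, so
#'   `jitter_sigma = 0` gives exactly superposed same-ligand poses.
#' @param cluster_ligands optional list (length `n_centers`) of ligand-id
#'   vectors restricting which ligands populate each cluster; default all
#'   ligands in every cluster.
#' @param planted_hbond_specs list of planted hydrogen bonds, each a list
#'   `(cluster, ligand_id, atom, chain, resnum, atom_name)`; `atom` is
#'   `"hydroxyl"` or an atom index. The cluster is anchored so that the
#'   designated ligand atom of one representative pose sits exactly 2.8
#'   Angstrom from the named receptor atom.
#' @param planted_clash_specs list of planted clashes, each a list
#'   `(cluster, ligand_id, atom_index, chain, resnum, atom_name)`; the
#'   representative pose's atom is placed 2.0 Angstrom from the named
#'   receptor atom (well below van der Waals contact for heavy atoms).
#' @return a `scene_config` list.
#' @export
scene_config <- function(seed = 1, n_ligands = 5, poses_per_ligand = 100,
                         n_centers = 4, center_min_separation = 12,
                         jitter_sigma = 0.3, cluster_ligands = NULL,
                         planted_hbond_specs = list(),
                         planted_clash_specs = list()) {
  stopifnot(is_count(seed), n_ligands >= 1, n_ligands <= 5,
            poses_per_ligand >= 1, n_centers >= 1,
            center_min_separation > 0, jitter_sigma >= 0)
  structure(list(seed = as.integer(seed), n_ligands = n_ligands,
                 poses_per_ligand = poses_per_ligand, n_centers = n_centers,
                 center_min_separation = center_min_separation,
                 jitter_sigma = jitter_sigma,
                 cluster_ligands = cluster_ligands,
                 planted_hbond_specs = planted_hbond_specs,
                 planted_clash_specs = planted_clash_specs),
            class = "scene_config")
}

# ------------------------------------------------------------- receptor

# Side-chain templates: local coordinates with CB at the origin, the
# chain extending mostly along +x (the CA->CB direction), tilted 40
# degrees off that axis — real side chains bend at CB (CA-CB-CG about
# 114 degrees), and without the bend a chi1 rotation would leave the
# distal atoms (e.g. the tyrosine OH) sitting on the rotation axis.
# Idealised bond lengths, close enough for interaction geometry.
sidechain_tilt <- function(xyz, ang = 40) {
  a <- ang * pi / 180
  R <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  xyz %*% R
}
SIDECHAIN_TEMPLATES <- list(
  ALA = list(names = character(0), xyz = matrix(0, 0, 3)),
  LEU = list(names = c("CG", "CD1", "CD2"),
             xyz = sidechain_tilt(rbind(c(1.53, 0, 0), c(2.15, 1.10, 0.45),
                                        c(2.15, -1.10, 0.45)))),
  ASN = list(names = c("CG", "OD1", "ND2"),
             xyz = sidechain_tilt(rbind(c(1.52, 0, 0), c(2.13, 1.06, 0),
                                        c(2.13, -1.06, 0)))),
  PHE = list(names = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             xyz = sidechain_tilt(rbind(c(1.51, 0, 0), c(2.21, 1.20, 0),
                                        c(2.21, -1.20, 0), c(3.60, 1.20, 0),
                                        c(3.60, -1.20, 0), c(4.29, 0, 0)))),
  TYR = list(names = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
             xyz = sidechain_tilt(rbind(c(1.51, 0, 0), c(2.21, 1.20, 0),
                                        c(2.21, -1.20, 0), c(3.60, 1.20, 0),
                                        c(3.60, -1.20, 0), c(4.29, 0, 0),
                                        c(5.66, 0, 0))))
)

# The three pseudo-helices lining the groove. Phases are chosen so the
# hydrogen-bond-capable marker residues (tyrosines playing the Y307/Y310
# roles, an asparagine on the third helix) face the groove axis.
HELIX_LAYOUT <- list(
  list(range = 291:320, azimuth = 90, phase = 20,
       special = c(`304` = "LEU", `307` = "TYR", `310` = "TYR")),
  list(range = 331:360, azimuth = 210, phase = 40,
       special = c(`336` = "PHE", `343` = "PHE")),
  list(range = 746:775, azimuth = 330, phase = 120,
       special = c(`754` = "ASN", `769` = "LEU"))
)

#' Build the synthetic toy receptor
#'
#' A deterministic arrangement of three pseudo-alpha-helices (chain A)
#' around a groove along the z axis, loosely mimicking the transmembrane
#' 5/8 interface of an efflux transporter: tyrosines at positions 307 and
#' 310, phenylalanines at 336/343 and an asparagine at 754 point their
#' side chains into the groove; all other residues are alanine. Backbone
#' N/CA/C/O atoms are placed on an ideal helical trace (rise 1.5
#' Angstrom/residue, 100 degrees twist). No randomness.
#'
#' @param cfg a [scene_config()] (only layout-independent fields used).
#' @param helix_radius distance of each helix axis from the groove axis
#'   (default 12).
#' @return a [receptor] with `model_id = "synthetic_groove"`.
#' @export
make_receptor <- function(cfg = scene_config(), helix_radius = 12) {
  rows <- list()
  for (hx in HELIX_LAYOUT) {
    phi <- hx$azimuth * pi / 180
    u <- c(cos(phi), sin(phi), 0)   # radial: groove axis -> helix axis
    w <- c(-sin(phi), cos(phi), 0)
    resnums <- hx$range
    nres <- length(resnums)
    th <- (hx$phase + 100 * (seq_len(nres) - 1)) * pi / 180
    axis_pts <- t(vapply(seq_len(nres), function(i)
      helix_radius * u + c(0, 0, 1.5 * (i - 1)), numeric(3)))
    ca <- axis_pts + 2.3 * (outer(cos(th), u) + outer(sin(th), w))
    for (i in seq_len(nres)) {
      rn <- resnums[i]
      resname <- unname(hx$special[as.character(rn)])
      if (is.na(resname) || is.null(resname)) resname <- "ALA"
      prev <- if (i > 1) ca[i - 1, ] else 2 * ca[i, ] - ca[i + 1, ]
      nxt <- if (i < nres) ca[i + 1, ] else 2 * ca[i, ] - ca[i - 1, ]
      n_at <- ca[i, ] + 1.1 * unit(prev - ca[i, ])
      c_at <- ca[i, ] + 1.1 * unit(nxt - ca[i, ])
      side_dir <- unit(ca[i, ] - axis_pts[i, ])
      o_at <- c_at + 1.23 * unit(pracma_cross(unit(nxt - prev), side_dir))
      atoms <- rbind(n_at, ca[i, ], c_at, o_at)
      names_ <- c("N", "CA", "C", "O")
      elems <- c("N", "C", "C", "O")
      tpl <- SIDECHAIN_TEMPLATES[[resname]]
      cb <- ca[i, ] + 1.53 * side_dir
      atoms <- rbind(atoms, cb)
      names_ <- c(names_, "CB"); elems <- c(elems, "C")
      if (nrow(tpl$xyz) > 0) {
        # local frame: x = side_dir, z = groove axis projected, y = cross
        ex <- side_dir
        ez <- unit(c(0, 0, 1) - sum(c(0, 0, 1) * ex) * ex)
        ey <- pracma_cross(ez, ex)
        sc <- sweep(tpl$xyz %*% rbind(ex, ey, ez), 2, cb, `+`)
        atoms <- rbind(atoms, sc)
        names_ <- c(names_, tpl$names)
        elems <- c(elems, substr(tpl$names, 1, 1))
      }
      dimnames(atoms) <- NULL
      rows[[length(rows) + 1]] <- data.frame(
        chain = "A", resnum = rn, resname = resname, name = names_,
        element = elems, x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
        stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, rows)
  rec <- receptor(at, model_id = "synthetic_groove", state_label = "apo")
  check_layout_overlaps(rec)
  rec
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Atoms of residues at least two apart in sequence (or different chains)
# must not overlap; a toy layout that folds onto itself is a user error.
check_layout_overlaps <- function(rec, tol = 1.2) {
  a <- rec$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- cross_dist(xyz, xyz)
  sep <- abs(outer(a$resnum, a$resnum, `-`))
  same_chain <- outer(a$chain, a$chain, `==`)
  bad <- d < tol & (sep >= 2 | !same_chain)
  diag(bad) <- FALSE
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("receptor layout produces overlapping atoms: %s%d:%s and %s%d:%s",
                 a$chain[ij[1]], a$resnum[ij[1]], a$name[ij[1]],
                 a$chain[ij[2]], a$resnum[ij[2]], a$name[ij[2]]))
  }
  invisible(rec)
}

# -------------------------------------------------------------- ligands

# Hexagonal ring helper: six atoms, the first at `attach`, ring extending
# along `dir`, ring plane spanned by dir and `perp`.
ring6 <- function(attach, dir, perp) {
  dir <- unit(dir)
  perp <- unit(perp - sum(perp * dir) * dir)
  center <- attach + 1.39 * dir
  ang <- (0:5) * pi / 3
  t(vapply(ang, function(a)
    center + 1.39 * (cos(a) * (-dir) + sin(a) * perp), numeric(3)))
}

# Template coordinates and bonds for the five toy ligands. Atoms 1..18
# are the common scaffold in canonical order (see default_scaffold());
# substituents differ per ligand. GPV062 carries the series' only
# hydroxyl oxygen (the "4-OH"), attached to the para position of a
# piperidine-like ring around the amine nitrogen.
build_ligand_templates <- function() {
  sc_b <- default_scaffold()$bonds
  ringA <- ring6(c(1.39, 0, 0), c(-1, 0, 0), c(0, 1, 0))
  # place ring A canonically: atoms at 60-degree spacing, radius 1.39
  ringA <- t(vapply((0:5) * pi / 3, function(a)
    1.39 * c(cos(a), sin(a), 0), numeric(3)))
  c7 <- c(2.87, 0, 0)
  o8 <- c7 + c(0.605, 1.048, 0)
  b1 <- c7 + 1.48 * c(0.5, -0.866, 0)
  ringB <- ring6(b1, c(0.5, -0.866, 0), c(0, 0, 1))
  o15 <- ringA[2, ] + 1.36 * c(0.5, 0.866, 0)
  c16 <- o15 + 1.43 * unit(c(0.2, 0.75, 0.63))
  c17 <- c16 + 1.52 * unit(c(0.63, 0.2, 0.75))
  n18 <- c17 + 1.47 * unit(c(0.2, 0.63, 0.75))
  scaffold_xyz <- rbind(ringA, c7, o8, ringB, o15, c16, c17, n18)
  scaffold_elem <- c(rep("C", 6), "C", "O", rep("C", 6), "O", "C", "C", "N")
  scaffold_bonds <- cbind(sc_b, order = c(rep(1, 6), 1, 2, rep(1, 7), 1, 1, 1, 1))
  scaffold_bonds[8, "order"] <- 2  # C7=O8

  grow_chain <- function(from, dirs, len = 1.52) {
    out <- matrix(0, length(dirs), 3)
    pos <- from
    for (i in seq_along(dirs)) {
      pos <- pos + len * unit(dirs[[i]])
      out[i, ] <- pos
    }
    out
  }
  d1 <- c(0.63, 0.75, 0.2); d2 <- c(0.2, 0.75, 0.63); d3 <- c(0.63, 0.2, 0.75)

  lig <- list()
  # GPV005: N-propyl
  xyz <- rbind(scaffold_xyz, grow_chain(n18, list(d1, d2, d3)))
  bonds <- rbind(scaffold_bonds, cbind(rbind(c(18, 19), c(19, 20), c(20, 21)), order = 1))
  lig$GPV005 <- list(xyz = xyz, elem = c(scaffold_elem, rep("C", 3)), bonds = bonds)
  # GPV019: N-phenylethyl
  ch <- grow_chain(n18, list(d1, d2))
  ph <- ring6(ch[2, ] + 1.5 * unit(d3), d3, c(0.75, -0.63, 0.2))
  xyz <- rbind(scaffold_xyz, ch, ph)
  bonds <- rbind(scaffold_bonds,
                 cbind(rbind(c(18, 19), c(19, 20), c(20, 21),
                             c(21, 22), c(22, 23), c(23, 24), c(24, 25),
                             c(25, 26), c(26, 21)), order = 1))
  lig$GPV019 <- list(xyz = xyz, elem = c(scaffold_elem, rep("C", 8)), bonds = bonds)
  # GPV062: 4-hydroxy-4-phenyl piperidine-like ring around N18
  pip <- ring6(n18, d3, c(0.75, -0.63, 0.2))  # row 1 == n18 position
  c19_23 <- pip[2:6, ]                        # ring carbons
  c21 <- pip[4, ]                             # para position
  o24 <- c21 + 1.42 * unit(d3)
  ph <- ring6(c21 + 1.5 * unit(c(-0.2, 0.9, 0.38)), c(-0.2, 0.9, 0.38),
              c(0.9, 0.2, -0.38))
  xyz <- rbind(scaffold_xyz, c19_23, o24, ph)
  bonds <- rbind(scaffold_bonds,
                 cbind(rbind(c(18, 19), c(19, 20), c(20, 21), c(21, 22),
                             c(22, 23), c(23, 18),        # piperidine ring
                             c(21, 24),                   # hydroxyl
                             c(21, 25), c(25, 26), c(26, 27), c(27, 28),
                             c(28, 29), c(29, 30), c(30, 25)), order = 1))
  lig$GPV062 <- list(xyz = xyz, elem = c(scaffold_elem, rep("C", 5), "O", rep("C", 6)),
                     bonds = bonds)
  # GPV186: N-methyl-N-phenyl
  me <- n18 + 1.47 * unit(c(0.9, -0.1, -0.42))
  ph <- ring6(n18 + 1.42 * unit(d2), d2, c(0.75, 0.2, -0.63))
  xyz <- rbind(scaffold_xyz, me, ph)
  bonds <- rbind(scaffold_bonds,
                 cbind(rbind(c(18, 19), c(18, 20), c(20, 21), c(21, 22),
                             c(22, 23), c(23, 24), c(24, 25), c(25, 20)),
                       order = 1))
  lig$GPV186 <- list(xyz = xyz, elem = c(scaffold_elem, rep("C", 7)), bonds = bonds)
  # GPV366: N-pentyl
  xyz <- rbind(scaffold_xyz, grow_chain(n18, list(d1, d2, d3, d1, d2)))
  bonds <- rbind(scaffold_bonds,
                 cbind(rbind(c(18, 19), c(19, 20), c(20, 21), c(21, 22), c(22, 23)),
                       order = 1))
  lig$GPV366 <- list(xyz = xyz, elem = c(scaffold_elem, rep("C", 5)), bonds = bonds)
  lig
}

# ------------------------------------------------------------ ensembles

receptor_atom_xyz <- function(rec, chain, resnum, atom_name) {
  sel <- rec$atoms$chain == chain & rec$atoms$resnum == resnum &
    rec$atoms$name == atom_name
  if (!any(sel)) {
    stop(sprintf("receptor atom (%s, %s, %s) not found", chain, resnum, atom_name))
  }
  as.numeric(rec$atoms[which(sel)[1], c("x", "y", "z")])
}

random_rotation <- function(sd_deg) {
  ax <- stats::rnorm(3)
  ang <- stats::rnorm(1, 0, sd_deg) * pi / 180
  rotation_matrix(ax, ang)
}

# Designated atom index within a ligand template (the planted-spec
# resolver; mirrors the "hydroxyl" convention of the SAR filter but works
# on the template directly).
template_atom_index <- function(tpl, atom) {
  if (is.numeric(atom)) return(as.integer(atom))
  if (identical(atom, "hydroxyl")) {
    deg <- table(factor(c(tpl$bonds[, 1], tpl$bonds[, 2]),
                        levels = seq_along(tpl$elem)))
    idx <- which(tpl$elem == "O" & as.integer(deg) == 1 &
                   !seq_along(tpl$elem) %in% tpl$bonds[tpl$bonds[, 3] >= 2, 1:2])
    if (length(idx) != 1) stop("template has no unique hydroxyl oxygen")
    return(idx)
  }
  stop("unknown atom selector in planted spec: ", atom)
}

#' Generate a pose ensemble with planted structure
#'
#' Each ligand is a rigid template sharing the packaged scaffold. Poses
#' are sampled per (ligand, cluster) by placing the template at the
#' cluster centre under a per-cluster base orientation, then adding
#' isotropic Gaussian jitter and a small random orientation wobble.
#' Clusters named in `planted_hbond_specs` / `planted_clash_specs` are
#' anchored so that one representative pose (no jitter) realises the
#' planted geometry exactly (donor-acceptor 2.8 Angstrom; clash contact
#' 2.0 Angstrom). Remaining cluster centres are placed on the groove
#' axis, kept at least `center_min_separation` apart and at least 8
#' Angstrom away from any receptor polar atom (so no accidental hydrogen
#' bonds arise for unanchored clusters).
#'
#' Consumes the current RNG stream; use [make_scene()] for seeded,
#' byte-reproducible scenes.
#'
#' @param rec receptor from [make_receptor()].
#' @param cfg a [scene_config()].
#' @return list with `$ensemble` (a [pose_ensemble]) and `$truth`
#'   (labels data.frame, planted H-bond/clash tables, per-cluster ligand
#'   sets, cluster centres).
#' @export
make_pose_ensemble <- function(rec, cfg = scene_config()) {
  templates <- build_ligand_templates()[seq_len(cfg$n_ligands)]
  lig_ids <- names(templates)
  K <- cfg$n_centers
  cluster_ligs <- cfg$cluster_ligands %||% rep(list(lig_ids), K)
  if (length(cluster_ligs) != K) stop("cluster_ligands must have n_centers entries")

  # base orientation per cluster (RNG draw 1..K, in cluster order).
  # Anchored clusters keep the template's reference orientation so the
  # planted geometry — and hence scene feasibility — does not depend on
  # the seed.
  rots <- lapply(seq_len(K), function(k) random_rotation(45))
  anchored_k <- c(vapply(cfg$planted_hbond_specs, function(s) s$cluster, 1),
                  vapply(cfg$planted_clash_specs, function(s) s$cluster, 1))
  for (k in anchored_k) rots[[k]] <- diag(3)

  # scaffold centroids per ligand
  centroids <- lapply(templates, function(t) colMeans(t$xyz[1:18, , drop = FALSE]))

  # --- anchored centres
  centers <- vector("list", K)
  anchors <- list()
  for (spec in cfg$planted_hbond_specs) {
    k <- spec$cluster
    partner <- receptor_atom_xyz(rec, spec$chain, spec$resnum, spec$atom_name)
    target <- partner + 2.8 * unit(c(0, 0, partner[3]) - partner)
    tpl <- templates[[spec$ligand_id]]
    if (is.null(tpl)) stop("planted H-bond names unknown ligand ", spec$ligand_id)
    ai <- template_atom_index(tpl, spec$atom %||% "hydroxyl")
    local <- tpl$xyz[ai, ] - centroids[[spec$ligand_id]]
    centers[[k]] <- target - as.numeric(rots[[k]] %*% local)
    anchors[[length(anchors) + 1]] <- list(cluster = k, ligand_id = spec$ligand_id,
                                           atom_index = ai, target = target,
                                           kind = "hbond", spec = spec)
  }
  for (spec in cfg$planted_clash_specs) {
    k <- spec$cluster
    if (!is.null(centers[[k]])) stop("cluster ", k, " anchored twice")
    partner <- receptor_atom_xyz(rec, spec$chain, spec$resnum, spec$atom_name)
    target <- partner + 2.0 * unit(c(0, 0, partner[3]) - partner)
    tpl <- templates[[spec$ligand_id]]
    ai <- as.integer(spec$atom_index %||% 1)
    local <- tpl$xyz[ai, ] - centroids[[spec$ligand_id]]
    centers[[k]] <- target - as.numeric(rots[[k]] %*% local)
    anchors[[length(anchors) + 1]] <- list(cluster = k, ligand_id = spec$ligand_id,
                                           atom_index = ai, target = target,
                                           kind = "clash", spec = spec)
  }

  # --- unanchored centres: first fit along the groove axis. When
  # hydrogen bonds are planted somewhere in the scene, unanchored
  # clusters must not create accidental ones: the designated ligand
  # atom's position (centre + rotated template offset) is kept at least
  # 5.5 Angstrom (cutoff 3.5 + jitter slack) from every receptor polar
  # atom.
  polar <- receptor_polar_atoms(rec)
  polar_xyz <- as.matrix(polar[, c("x", "y", "z")])
  crit_offsets <- lapply(cfg$planted_hbond_specs, function(spec) {
    tpl <- templates[[spec$ligand_id]]
    ai <- template_atom_index(tpl, spec$atom %||% "hydroxyl")
    tpl$xyz[ai, ] - centroids[[spec$ligand_id]]
  })
  zmax <- max(rec$atoms$z)
  cand_z <- seq(2, zmax - 2, by = 0.25)
  for (k in seq_len(K)) {
    if (!is.null(centers[[k]])) next
    placed <- do.call(rbind, centers[!vapply(centers, is.null, TRUE)])
    # the clearance depends on the cluster's base orientation; if an
    # orientation leaves no feasible axis position, redraw it (bounded
    # rejection sampling, deterministic under the scene seed)
    for (attempt in seq_len(20)) {
      ok <- vapply(cand_z, function(z) {
        pt <- c(0, 0, z)
        for (off in crit_offsets) {
          crit <- pt + as.numeric(rots[[k]] %*% off)
          if (min(cross_dist(matrix(crit, 1), polar_xyz)) < 5.5) return(FALSE)
        }
        if (is.null(placed)) return(TRUE)
        min(cross_dist(matrix(pt, 1), placed)) >= cfg$center_min_separation
      }, TRUE)
      if (any(ok)) break
      rots[[k]] <- random_rotation(45)
    }
    if (!any(ok)) {
      stop("cannot place cluster centre ", k, ": no axis position satisfies ",
           "the separation and polar-clearance constraints")
    }
    centers[[k]] <- c(0, 0, cand_z[which(ok)[1]])
  }
  cm <- do.call(rbind, centers)
  if (K > 1) {
    dd <- cross_dist(cm, cm); diag(dd) <- Inf
    if (min(dd) < cfg$center_min_separation - 1e-9) {
      stop(sprintf("planted cluster centres are only %.2f Angstrom apart ",
                   min(dd)), "(< center_min_separation); planted geometry infeasible")
    }
  }

  # --- poses (RNG draws in ligand order, then pose order)
  poses <- list()
  labels <- list()
  planted_hb <- list(); planted_cl <- list()
  rot_sd <- 10 * cfg$jitter_sigma
  for (L in lig_ids) {
    tpl <- templates[[L]]
    X0 <- sweep(tpl$xyz, 2, centroids[[L]])
    allowed <- which(vapply(cluster_ligs, function(s) L %in% s, TRUE))
    if (!length(allowed)) next
    assign_k <- allowed[((seq_len(cfg$poses_per_ligand) - 1) %% length(allowed)) + 1]
    first_in_cluster <- !duplicated(assign_k)
    for (j in seq_len(cfg$poses_per_ligand)) {
      k <- assign_k[j]
      is_rep <- first_in_cluster[j] &&
        any(vapply(anchors, function(a) a$cluster == k && a$ligand_id == L, TRUE))
      if (is_rep) {
        Rj <- diag(3); tj <- c(0, 0, 0)
      } else {
        Rj <- random_rotation(rot_sd)
        tj <- stats::rnorm(3, 0, cfg$jitter_sigma)
      }
      xyz <- t(rots[[k]] %*% Rj %*% t(X0)) +
        matrix(centers[[k]] + tj, nrow(X0), 3, byrow = TRUE)
      poses[[length(poses) + 1]] <- pose(
        L, j, data.frame(element = tpl$elem, x = xyz[, 1], y = xyz[, 2],
                         z = xyz[, 3]),
        data.frame(from = tpl$bonds[, 1], to = tpl$bonds[, 2],
                   order = tpl$bonds[, 3]))
      labels[[length(labels) + 1]] <- data.frame(ligand_id = L, pose_id = j,
                                                 cluster = k)
      if (is_rep) {
        for (a in anchors) {
          if (a$cluster != k || a$ligand_id != L) next
          rec_df <- data.frame(ligand_id = L, pose_id = j, cluster = k,
                               ligand_index = a$atom_index,
                               chain = a$spec$chain, resnum = a$spec$resnum,
                               atom_name = a$spec$atom_name)
          if (a$kind == "hbond") planted_hb[[length(planted_hb) + 1]] <- rec_df
          else planted_cl[[length(planted_cl) + 1]] <- rec_df
        }
      }
    }
  }
  truth <- list(
    labels = do.call(rbind, labels),
    planted_hbonds = if (length(planted_hb)) do.call(rbind, planted_hb) else NULL,
    planted_clashes = if (length(planted_cl)) do.call(rbind, planted_cl) else NULL,
    cluster_ligand_sets = cluster_ligs,
    centers = cm)
  list(ensemble = pose_ensemble(poses, receptor_ref = rec$model_id),
       truth = truth)
}

#' Generate a complete synthetic scene
#'
#' Seeds the RNG once (receptor layout is deterministic; cluster base
#' orientations are drawn first, then per-pose jitter in ligand/pose
#' order), so a fixed seed reproduces the scene byte-identically.
#'
#' @param cfg a [scene_config()].
#' @return list with `$receptor`, `$ensemble`, `$truth`, `$config`.
#' @export
make_scene <- function(cfg = scene_config()) {
  rec <- make_receptor(cfg)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(cfg$seed)
  pe <- make_pose_ensemble(rec, cfg)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(receptor = rec, ensemble = pe$ensemble, truth = pe$truth, config = cfg)
}

#' Write a scene to disk
#'
#' Writes `receptor.pdb`, `poses.sdf`, `ground_truth.json` and
#' `scene.yaml` into a directory.
#'
#' @param scene output of [make_scene()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_receptor(scene$receptor, file.path(dir, "receptor.pdb"))
  write_pose_ensemble(scene$ensemble, file.path(dir, "poses.sdf"))
  truth <- scene$truth
  truth$centers <- as.data.frame(truth$centers)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", null = "null", digits = NA)
  cfg <- scene$config
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)], file.path(dir, "scene.yaml"))
  invisible(dir)
}

# ----------------------------------------------- special-purpose scenes

#' Scene with planted and decoy hydrogen-bond geometries
#'
#' One pose whose polar atoms realise three textbook hydrogen bonds to
#' groove-facing receptor atoms (2.8-3.2 Angstrom) and two decoys: one
#' beyond the distance cutoff (5.0 Angstrom) and one distance-compliant
#' but with an explicit hydrogen pointing away from the acceptor
#' (D-H...A about 55 degrees), which the angle test must reject.
#'
#' @return list with `$receptor`, `$pose`, `$planted` (data.frame of the
#'   three real bonds) and `$decoys`.
#' @export
make_hbond_scene <- function() {
  rec <- make_receptor()
  site <- function(chain, resnum, atom) receptor_atom_xyz(rec, chain, resnum, atom)
  toward_axis <- function(p) unit(c(0, 0, p[3]) - p)
  y307 <- site("A", 307, "OH"); y310 <- site("A", 310, "OH")
  n754 <- site("A", 754, "OD1")
  # planted: ligand hydroxyl oxygens in textbook geometry near three
  # polar receptor atoms
  p1 <- y307 + 2.8 * toward_axis(y307)
  # approach the asparagine carbonyl head-on (along CG->OD1), keeping the
  # probe well clear of the adjacent ND2
  cg754 <- site("A", 754, "CG")
  p2 <- n754 + 2.9 * unit(n754 - cg754)
  p3 <- y310 + 3.2 * toward_axis(y310)
  # decoys: a distance violation (5.0 Angstrom, off-axis so it stays far
  # from every other polar atom) and an angle violation against an
  # acceptor-only partner (a backbone carbonyl O), so the explicit
  # hydrogen's bad geometry is the only thing that can reject it
  d1 <- y307 + 5.0 * unit(toward_axis(y307) + c(0, 0, 0.8))
  o343 <- site("A", 343, "O")
  d2 <- o343 + 3.0 * toward_axis(o343)
  atoms <- data.frame(element = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0))
  bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
  add <- function(el, xyz) {
    atoms <<- rbind(atoms, data.frame(element = el, x = xyz[1], y = xyz[2],
                                      z = xyz[3]))
    nrow(atoms)
  }
  link <- function(i, j, o = 1) {
    bonds <<- rbind(bonds, data.frame(from = i, to = j, order = o))
  }
  # each O gets a single carbon neighbour pulled toward the groove axis
  for (p in list(p1, p2, p3, d1)) {
    o <- add("O", p); c <- add("C", p + 1.43 * toward_axis(p)); link(o, c)
  }
  # angle decoy: O with explicit H pointing away from the acceptor
  o <- add("O", d2)
  c <- add("C", d2 + 1.43 * toward_axis(d2)); link(o, c)
  h <- add("H", d2 + 0.97 * unit(pracma_cross(toward_axis(d2), c(1, 0, 0)) +
                                   0.8 * toward_axis(d2)))
  link(o, h)
  # chain the carbons so the molecule is connected
  cidx <- which(atoms$element == "C")
  for (i in seq_len(length(cidx) - 1)) link(cidx[i], cidx[i + 1])
  p <- pose("HBPROBE", 1, atoms, bonds)
  planted <- data.frame(ligand_index = c(1, 3, 5),
                        chain = "A", resnum = c(307, 754, 310),
                        atom_name = c("OH", "OD1", "OH"))
  decoys <- data.frame(ligand_index = c(7, 9), reason = c("distance", "angle"),
                       resnum = c(307, 343))
  list(receptor = rec, pose = p, planted = planted, decoys = decoys)
}

#' Scene for the rotamer-scan experiment
#'
#' Places a GPV062-like ligand so that its scaffold carbonyl oxygen sits
#' 2.8 Angstrom from where the tyrosine-307 hydroxyl lands after a chi1
#' rotation of `chi_target` degrees — the planted induced-fit geometry.
#' At the input conformation no hydrogen bond exists. Variants: `blocked`
#' inserts a blocker residue that clashes with the rotated ring (the
#' planted rotamer must then be rejected); `far` moves the ligand out of
#' reach (the scan must come back empty).
#'
#' @param chi_target planted chi1 delta in degrees (default 120; keep it
#'   on the scan grid).
#' @param blocked,far scene variants (default FALSE).
#' @return list with `$receptor`, `$pose`, `$chi_target`,
#'   `$carbonyl_index`.
#' @export
make_rotamer_scene <- function(chi_target = 120, blocked = FALSE, far = FALSE) {
  rec <- make_receptor()
  res <- residue_atoms(rec, "A", 307)
  ca <- as.numeric(res[res$name == "CA", c("x", "y", "z")])
  cb <- as.numeric(res[res$name == "CB", c("x", "y", "z")])
  ring_names <- SIDECHAIN_TOPO$TYR$beyond_cb
  ring <- as.matrix(res[match(ring_names, res$name), c("x", "y", "z")])
  ring_rot <- rotate_about_axis(ring, ca, cb - ca, chi_target)
  oh_rot <- ring_rot[ring_names == "OH", ]
  cz_rot <- ring_rot[ring_names == "CZ", ]
  out_dir <- unit(oh_rot - cz_rot)
  target <- oh_rot + 2.8 * out_dir

  tpl <- build_ligand_templates()$GPV062
  # orient the ligand so the C7->O8 axis points back toward the tyrosine,
  # i.e. the molecule extends away from the rotated ring
  a <- unit(tpl$xyz[8, ] - tpl$xyz[7, ])
  b <- -out_dir
  v <- pracma_cross(a, b); s <- vnorm(v); cth <- sum(a * b)
  R <- if (s < 1e-9) diag(3) * sign(cth) else {
    Vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    diag(3) + Vx + Vx %*% Vx * ((1 - cth) / s^2)
  }
  xyz <- t(R %*% t(tpl$xyz))
  xyz <- sweep(xyz, 2, xyz[8, ] - target, `-`)
  if (far) xyz <- sweep(xyz, 2, c(0, 0, 60), `+`)
  p <- pose("GPV062", 1, data.frame(element = tpl$elem, x = xyz[, 1],
                                    y = xyz[, 2], z = xyz[, 3]),
            data.frame(from = tpl$bonds[, 1], to = tpl$bonds[, 2],
                       order = tpl$bonds[, 3]))
  if (blocked) {
    # a pseudo-residue whose CB sits on the rotated ring centroid: clashes
    # with the planted rotamer, not with the input conformation
    blk <- colMeans(ring_rot[3:6, ])
    extra <- data.frame(chain = "B", resnum = 1, resname = "ALA",
                        name = c("N", "CA", "C", "O", "CB"), element = c("N", "C", "C", "O", "C"),
                        x = blk[1] + c(0, 1.5, 3.0, 3.6, 1.9),
                        y = blk[2] + c(0, 0.4, 0.8, 1.9, -1.0),
                        z = blk[3] + c(6, 6.2, 6.4, 6.6, 0.0))
    extra$x[5] <- blk[1]; extra$y[5] <- blk[2]; extra$z[5] <- blk[3]
    rec <- receptor(rbind(rec$atoms[, names(extra)], extra),
                    model_id = rec$model_id, state_label = rec$state_label)
  }
  list(receptor = rec, pose = p, chi_target = chi_target, carbonyl_index = 8L)
}
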