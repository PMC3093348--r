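# Protein-ligand interaction geometry: residue contacts, geometric
# hydrogen bonds, aromatic interactions, steric clashes, and per-residue
# interaction fingerprints aggregated over pose sets (PLIF).

# Bondi van der Waals radii, Angstrom.
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                 F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

#' Interaction geometry configuration
#'
#' @param contact_cutoff residue contact cutoff, Angstrom (default 4.5,
#'   inclusive at the boundary): a residue is "in contact" when any of its
#'   heavy atoms lies within this distance of any ligand heavy atom.
#' @param hbond_da_max maximum donor-acceptor heavy-atom distance for a
#'   hydrogen bond (default 3.5).
#' @param hbond_dha_min minimum D-H...A angle in degrees (default 120),
#'   applied only when an explicit hydrogen is present on the donor —
#'   docking poses and low-resolution models usually lack hydrogens.
#' @param aromatic_centroid_max maximum ring-centroid distance for
#'   aromatic (pi/pi, pi/cation) interactions (default 5.0).
#' @param clash_tolerance allowed van der Waals overlap before a pair
#'   counts as a steric clash (default 0.4).
#' @param vdw_radii named element -> radius table (default Bondi).
#' @return an `interaction_config` list.
#' @export
interaction_config <- function(contact_cutoff = 4.5, hbond_da_max = 3.5,
                               hbond_dha_min = 120, aromatic_centroid_max = 5.0,
                               clash_tolerance = 0.4, vdw_radii = BONDI_RADII) {
  stopifnot(contact_cutoff > 0, hbond_da_max > 0, aromatic_centroid_max > 0,
            clash_tolerance > 0)
  structure(list(contact_cutoff = contact_cutoff, hbond_da_max = hbond_da_max,
                 hbond_dha_min = hbond_dha_min,
                 aromatic_centroid_max = aromatic_centroid_max,
                 clash_tolerance = clash_tolerance, vdw_radii = vdw_radii),
            class = "interaction_config")
}

#' Residues in contact with a pose
#'
#' @param p a [pose].
#' @param rec a [receptor] in the same frame.
#' @param cfg an [interaction_config()].
#' @return data.frame (`chain`, `resnum`, `resname`, `min_dist`) of
#'   residues with any heavy atom within `contact_cutoff` (inclusive) of
#'   any ligand heavy atom.
#' @export
contact_residues <- function(p, rec, cfg = interaction_config()) {
  lig <- pose_coords(p, heavy_only = TRUE)
  ra <- rec$atoms[rec$atoms$is_heavy, ]
  d <- cross_dist(as.matrix(ra[, c("x", "y", "z")]), lig)
  mind <- apply(d, 1, min)
  key <- paste(ra$chain, ra$resnum)
  res_min <- tapply(mind, key, min)
  hit <- names(res_min)[res_min <= cfg$contact_cutoff]
  first <- ra[!duplicated(key), ]
  first_key <- paste(first$chain, first$resnum)
  sel <- first[first_key %in% hit, c("chain", "resnum", "resname")]
  sel$min_dist <- as.numeric(res_min[paste(sel$chain, sel$resnum)])
  sel <- sel[order(sel$chain, sel$resnum), ]
  rownames(sel) <- NULL
  sel
}

# --- donor / acceptor typing ------------------------------------------

# Side-chain donor/acceptor atoms by residue type; backbone N (donor,
# except proline) and O (acceptor) are handled generically.
RECEPTOR_POLAR <- list(
  TYR = list(donor = "OH", acceptor = "OH"),
  SER = list(donor = "OG", acceptor = "OG"),
  THR = list(donor = "OG1", acceptor = "OG1"),
  ASN = list(donor = "ND2", acceptor = "OD1"),
  GLN = list(donor = "NE2", acceptor = "OE1"),
  HIS = list(donor = c("ND1", "NE2"), acceptor = c("ND1", "NE2")),
  TRP = list(donor = "NE1", acceptor = character(0)),
  LYS = list(donor = "NZ", acceptor = character(0)),
  ARG = list(donor = c("NE", "NH1", "NH2"), acceptor = character(0)),
  ASP = list(donor = character(0), acceptor = c("OD1", "OD2")),
  GLU = list(donor = character(0), acceptor = c("OE1", "OE2"))
)

# Polar atoms of a receptor: data.frame with role flags.
receptor_polar_atoms <- function(rec) {
  a <- rec$atoms
  donor <- (a$name == "N" & a$resname != "PRO")
  acceptor <- (a$name == "O")
  for (rn in names(RECEPTOR_POLAR)) {
    sel <- a$resname == rn
    donor <- donor | (sel & a$name %in% RECEPTOR_POLAR[[rn]]$donor)
    acceptor <- acceptor | (sel & a$name %in% RECEPTOR_POLAR[[rn]]$acceptor)
  }
  out <- a[donor | acceptor, ]
  out$donor <- donor[donor | acceptor]
  out$acceptor <- acceptor[donor | acceptor]
  rownames(out) <- NULL
  out
}

# Ligand donor/acceptor typing from topology. Heavy-atom rules:
#   O, one heavy neighbour via a single bond  -> hydroxyl: donor+acceptor
#   O, double bond                            -> carbonyl: acceptor
#   O, two heavy neighbours                   -> ether: acceptor (weak)
#   N with explicit H, or degree <= 2         -> donor (+acceptor if neutral)
#   N, degree 3                               -> acceptor if neutral,
#                                                donor if ionized (N-H+)
ligand_polar_atoms <- function(p) {
  a <- p$atoms
  nb_count <- integer(nrow(a)); has_double <- logical(nrow(a))
  has_h <- logical(nrow(a))
  if (nrow(p$bonds)) {
    for (k in seq_len(nrow(p$bonds))) {
      i <- p$bonds$from[k]; j <- p$bonds$to[k]
      if (a$is_heavy[i] && a$is_heavy[j]) {
        nb_count[i] <- nb_count[i] + 1L; nb_count[j] <- nb_count[j] + 1L
        if (p$bonds$order[k] >= 2) { has_double[i] <- TRUE; has_double[j] <- TRUE }
      } else {
        if (a$element[i] == "H") has_h[j] <- TRUE
        if (a$element[j] == "H") has_h[i] <- TRUE
      }
    }
  }
  donor <- acceptor <- logical(nrow(a))
  isO <- a$element == "O"; isN <- a$element == "N"
  hydroxyl <- isO & nb_count == 1 & !has_double
  donor[hydroxyl] <- TRUE; acceptor[isO] <- TRUE
  ionized <- p$protonation == "ionized"
  donor[isN & (has_h | nb_count <= 2 | ionized)] <- TRUE
  acceptor[isN & !ionized] <- TRUE
  idx <- which((donor | acceptor) & a$is_heavy)
  data.frame(index = idx, name = a$name[idx], element = a$element[idx],
             x = a$x[idx], y = a$y[idx], z = a$z[idx],
             donor = donor[idx], acceptor = acceptor[idx],
             hydroxyl = hydroxyl[idx])
}

# Explicit hydrogens bonded to ligand atom i (coordinates), if any.
ligand_h_neighbours <- function(p, i) {
  if (!nrow(p$bonds)) return(NULL)
  hs <- c(p$bonds$to[p$bonds$from == i], p$bonds$from[p$bonds$to == i])
  hs <- hs[p$atoms$element[hs] == "H"]
  if (!length(hs)) return(NULL)
  as.matrix(p$atoms[hs, c("x", "y", "z")])
}

#' Detect protein-ligand hydrogen bonds
#'
#' Geometric criterion on heavy atoms: donor-acceptor distance at most
#' `hbond_da_max`, with the D-H...A angle test (>= `hbond_dha_min`)
#' applied only when the donor carries explicit hydrogens. Each bond gets
#' a distance-decay score, 1 at an ideal 2.6 Angstrom and decaying
#' exponentially beyond — it supports relative-strength comparisons only.
#'
#' @param p a [pose].
#' @param rec a [receptor].
#' @param cfg an [interaction_config()].
#' @param residue_subset optional data.frame (`chain`, `resnum`) limiting
#'   the receptor side (used by the rotamer scan).
#' @return data.frame, one row per hydrogen bond: ligand atom
#'   (`ligand_atom`, `ligand_index`), residue (`chain`, `resnum`,
#'   `resname`, `protein_atom`), `donor_side` ("ligand" or "protein"),
#'   `distance`, `angle` (NA without explicit H) and `score`.
#' @export
detect_hbonds <- function(p, rec, cfg = interaction_config(),
                          residue_subset = NULL) {
  lp <- ligand_polar_atoms(p)
  rp <- receptor_polar_atoms(rec)
  if (!is.null(residue_subset)) {
    keep <- paste(rp$chain, rp$resnum) %in%
      paste(residue_subset$chain, residue_subset$resnum)
    rp <- rp[keep, ]
  }
  out <- list()
  if (nrow(lp) == 0 || nrow(rp) == 0) return(empty_hbonds())
  d <- cross_dist(as.matrix(lp[, c("x", "y", "z")]),
                  as.matrix(rp[, c("x", "y", "z")]))
  cand <- which(d <= cfg$hbond_da_max, arr.ind = TRUE)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    dist <- d[i, j]
    lig_xyz <- c(lp$x[i], lp$y[i], lp$z[i])
    rec_xyz <- c(rp$x[j], rp$y[j], rp$z[j])
    pairings <- character(0)
    if (lp$donor[i] && rp$acceptor[j]) pairings <- c(pairings, "ligand")
    if (lp$acceptor[i] && rp$donor[j]) pairings <- c(pairings, "protein")
    for (side in pairings) {
      ang <- NA_real_
      if (side == "ligand") {
        hxyz <- ligand_h_neighbours(p, lp$index[i])
        if (!is.null(hxyz)) {
          ang <- max(apply(hxyz, 1, function(h) angle_deg(lig_xyz, h, rec_xyz)))
          if (ang < cfg$hbond_dha_min) next
        }
      }
      # receptor models carry no hydrogens; protein-donor angle untested
      out[[length(out) + 1]] <- data.frame(
        ligand_atom = lp$name[i], ligand_index = lp$index[i],
        chain = rp$chain[j], resnum = rp$resnum[j], resname = rp$resname[j],
        protein_atom = rp$name[j], donor_side = side,
        distance = dist, angle = ang,
        score = min(1, exp(-(dist - 2.6))))
      break  # one record per atom pair even if both directions possible
    }
  }
  if (!length(out)) return(empty_hbonds())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_hbonds <- function() {
  data.frame(ligand_atom = character(), ligand_index = integer(),
             chain = character(), resnum = integer(), resname = character(),
             protein_atom = character(), donor_side = character(),
             distance = numeric(), angle = numeric(), score = numeric())
}

# --- aromatic interactions --------------------------------------------

AROMATIC_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

# Centroids of aromatic residue rings.
receptor_ring_centroids <- function(rec) {
  a <- rec$atoms
  out <- list()
  res <- receptor_residues(rec)
  for (r in seq_len(nrow(res))) {
    rn <- res$resname[r]
    if (!rn %in% names(AROMATIC_RING_ATOMS)) next
    sel <- a$chain == res$chain[r] & a$resnum == res$resnum[r] &
      a$name %in% AROMATIC_RING_ATOMS[[rn]]
    if (sum(sel) < 5) next
    xyz <- colMeans(as.matrix(a[sel, c("x", "y", "z")]))
    out[[length(out) + 1]] <- data.frame(chain = res$chain[r],
                                         resnum = res$resnum[r], resname = rn,
                                         x = xyz[1], y = xyz[2], z = xyz[3])
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Centroids of all-carbon six-membered rings of a ligand (phenyl rings),
# found as C6-cycle subgraph matches de-duplicated by vertex set.
ligand_ring_centroids <- function(p) {
  heavy <- which(p$atoms$is_heavy)
  hidx <- match(seq_len(nrow(p$atoms)), heavy)
  b <- as.matrix(p$bonds[, c("from", "to"), drop = FALSE])
  b <- b[p$atoms$is_heavy[b[, 1]] & p$atoms$is_heavy[b[, 2]], , drop = FALSE]
  if (nrow(b) == 0) return(NULL)
  b <- cbind(hidx[b[, 1]], hidx[b[, 2]])
  hex <- cbind(1:6, c(2:6, 1))
  m <- match_subgraph(rep("C", 6), hex, p$atoms$element[heavy], b)
  if (!length(m)) return(NULL)
  sets <- unique(lapply(m, function(v) sort(heavy[v])))
  # keep genuine cycles only (each vertex exactly two in-set neighbours is
  # guaranteed by the cycle pattern)
  t(vapply(sets, function(s) colMeans(as.matrix(p$atoms[s, c("x", "y", "z")])),
           numeric(3)))
}

# Cationic centres of a pose: ionizable amine nitrogens, counted only in
# the ionized protonation state.
ligand_cation_sites <- function(p) {
  if (p$protonation != "ionized") return(NULL)
  lp <- ligand_polar_atoms(p)
  lp <- lp[lp$element == "N", ]
  if (!nrow(lp)) return(NULL)
  as.matrix(lp[, c("x", "y", "z")])
}

# Aromatic interactions of one pose: pi/pi (ligand ring centroid vs
# residue ring centroid) and pi/cation (ligand N+ vs residue ring).
aromatic_interactions <- function(p, rec, cfg = interaction_config()) {
  rc <- receptor_ring_centroids(rec)
  if (is.null(rc)) return(NULL)
  rxyz <- as.matrix(rc[, c("x", "y", "z")])
  hits <- list()
  lrc <- ligand_ring_centroids(p)
  if (!is.null(lrc)) {
    d <- cross_dist(lrc, rxyz)
    idx <- which(apply(d, 2, min) <= cfg$aromatic_centroid_max)
    for (j in idx) {
      hits[[length(hits) + 1]] <- data.frame(chain = rc$chain[j],
                                             resnum = rc$resnum[j],
                                             resname = rc$resname[j],
                                             type = "pi_pi",
                                             distance = min(d[, j]))
    }
  }
  cat_xyz <- ligand_cation_sites(p)
  if (!is.null(cat_xyz)) {
    d <- cross_dist(cat_xyz, rxyz)
    idx <- which(apply(d, 2, min) <= cfg$aromatic_centroid_max)
    for (j in idx) {
      hits[[length(hits) + 1]] <- data.frame(chain = rc$chain[j],
                                             resnum = rc$resnum[j],
                                             resname = rc$resname[j],
                                             type = "pi_cation",
                                             distance = min(d[, j]))
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

#' Count steric clashes between a pose and the receptor
#'
#' A clash is a ligand-heavy/protein-heavy atom pair closer than the sum
#' of their van der Waals radii minus `clash_tolerance`.
#'
#' @param p a [pose].
#' @param rec a [receptor].
#' @param cfg an [interaction_config()].
#' @return integer clash count.
#' @export
clash_count <- function(p, rec, cfg = interaction_config()) {
  la <- p$atoms[p$atoms$is_heavy, ]
  ra <- rec$atoms[rec$atoms$is_heavy, ]
  clash_count_atoms(la, ra, cfg)
}

# Core clash counter on two atom tables (element + coords).
clash_count_atoms <- function(la, ra, cfg) {
  elems <- unique(c(la$element, ra$element))
  unknown <- setdiff(elems, names(cfg$vdw_radii))
  if (length(unknown)) {
    stop("no van der Waals radius for element(s): ", paste(unknown, collapse = ", "))
  }
  if (nrow(la) == 0 || nrow(ra) == 0) return(0L)
  d <- cross_dist(as.matrix(la[, c("x", "y", "z")]),
                  as.matrix(ra[, c("x", "y", "z")]))
  lim <- outer(cfg$vdw_radii[la$element], cfg$vdw_radii[ra$element], `+`) -
    cfg$clash_tolerance
  sum(d < lim)
}

# --- fingerprints ------------------------------------------------------

#' Protein-ligand interaction fingerprint of a pose set
#'
#' Per-residue counts of contacts (any heavy atom within the contact
#' cutoff), hydrogen bonds and aromatic interactions, aggregated over the
#' poses of a set (typically a cluster or a whole run), plus frequencies
#' (count / number of poses). A residue's `direct` flag marks a typed
#' interaction (H-bond or aromatic) observed in at least one pose, as
#' opposed to mere proximity.
#'
#' @param pose_set list of [pose] objects (non-empty).
#' @param rec a [receptor].
#' @param cfg an [interaction_config()].
#' @param pose_set_id label stored on the result.
#' @return an `interaction_fp`: list with `$pose_set_id`, `$n_poses` and
#'   `$table` (chain, resnum, resname, contact, hbond, aromatic counts,
#'   `*_freq` columns, `direct`).
#' @export
plif <- function(pose_set, rec, cfg = interaction_config(),
                 pose_set_id = "pose_set") {
  if (length(pose_set) == 0) stop("empty pose set")
  acc <- new.env(parent = emptyenv())
  bump <- function(key, resname, what) {
    rec0 <- acc[[key]] %||% list(resname = resname, contact = 0L,
                                 hbond = 0L, aromatic = 0L)
    rec0[[what]] <- rec0[[what]] + 1L
    acc[[key]] <- rec0
  }
  for (p in pose_set) {
    cr <- contact_residues(p, rec, cfg)
    for (r in seq_len(nrow(cr))) {
      bump(paste(cr$chain[r], cr$resnum[r]), cr$resname[r], "contact")
    }
    hb <- detect_hbonds(p, rec, cfg)
    if (nrow(hb)) {
      for (key in unique(paste(hb$chain, hb$resnum))) {
        rn <- hb$resname[paste(hb$chain, hb$resnum) == key][1]
        bump(key, rn, "hbond")
      }
    }
    ar <- aromatic_interactions(p, rec, cfg)
    if (!is.null(ar)) {
      for (key in unique(paste(ar$chain, ar$resnum))) {
        rn <- ar$resname[paste(ar$chain, ar$resnum) == key][1]
        bump(key, rn, "aromatic")
      }
    }
  }
  keys <- ls(acc)
  n <- length(pose_set)
  if (!length(keys)) {
    tab <- data.frame(chain = character(), resnum = integer(),
                      resname = character(), contact = integer(),
                      hbond = integer(), aromatic = integer(),
                      contact_freq = numeric(), hbond_freq = numeric(),
                      aromatic_freq = numeric(), direct = logical())
  } else {
    parts <- strsplit(keys, " ")
    tab <- data.frame(
      chain = vapply(parts, `[`, "", 1),
      resnum = as.integer(vapply(parts, `[`, "", 2)),
      resname = vapply(keys, function(k) acc[[k]]$resname, ""),
      contact = vapply(keys, function(k) acc[[k]]$contact, 1L),
      hbond = vapply(keys, function(k) acc[[k]]$hbond, 1L),
      aromatic = vapply(keys, function(k) acc[[k]]$aromatic, 1L))
    tab$contact_freq <- tab$contact / n
    tab$hbond_freq <- tab$hbond / n
    tab$aromatic_freq <- tab$aromatic / n
    tab$direct <- tab$hbond + tab$aromatic > 0
    tab <- tab[order(tab$chain, tab$resnum), ]
    rownames(tab) <- NULL
  }
  structure(list(pose_set_id = pose_set_id, n_poses = n, table = tab),
            class = "interaction_fp")
}

#' @export
print.interaction_fp <- function(x, ...) {
  cat(sprintf("<interaction_fp '%s': %d poses, %d residues>\n",
              x$pose_set_id, x$n_poses, nrow(x$table)))
  invisible(x)
}

#' Compare interaction fingerprints across states
#'
#' Residues above a frequency threshold per fingerprint, plus every Venn
#' region of the resulting sets — the cross-state binding-site comparison
#' (e.g. binding-competent vs nucleotide-bound models).
#'
#' @param fps named list of `interaction_fp` objects (>= 2).
#' @param min_freq minimum contact frequency for a residue to count as
#'   part of a state's binding site (default 0.1).
#' @return list with `$residues` (named list of residue keys per state)
#'   and `$regions` (named list: Venn region -> residue keys; region names
#'   like `"A&B"`, `"A_only"`).
#' @export
compare_fingerprints <- function(fps, min_freq = 0.1) {
  if (length(fps) < 2) stop("need at least two fingerprints")
  if (is.null(names(fps)) || any(names(fps) == "")) {
    names(fps) <- paste0("state", seq_along(fps))
  }
  sets <- lapply(fps, function(fp) {
    t <- fp$table
    paste(t$chain[t$contact_freq >= min_freq], t$resnum[t$contact_freq >= min_freq])
  })
  nm <- names(sets)
  all_res <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_res %in% s,
                       logical(length(all_res)))
  if (length(all_res) == 1) membership <- matrix(membership, nrow = 1,
                                                 dimnames = list(NULL, nm))
  regions <- list()
  for (mask in seq_len(2^length(nm) - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_along(nm) - 1)))
    key <- paste(nm[inset], collapse = "&")
    if (sum(inset) == 1) key <- paste0(nm[inset], "_only")
    sel <- apply(membership, 1, function(row) all(row == inset))
    regions[[key]] <- all_res[sel]
  }
  list(residues = sets, regions = regions)
}
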