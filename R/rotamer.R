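# Side-chain rotamer exploration: can rotating one residue's side chain
# create a new, clash-free hydrogen bond to the ligand (the tyrosine ->
# carbonyl experiment)?

# Side-chain topology by residue type: atoms moved by a chi1 rotation
# (about CA->CB) and by a chi2 rotation (about CB->CG). NULL chi2 = chi1
# only. GLY/ALA have no rotatable side chain.
SIDECHAIN_TOPO <- list(
  TYR = list(beyond_cb = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
             beyond_cg = c("CD1", "CD2", "CE1", "CE2", "CZ", "OH")),
  PHE = list(beyond_cb = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             beyond_cg = c("CD1", "CD2", "CE1", "CE2", "CZ")),
  ASN = list(beyond_cb = c("CG", "OD1", "ND2"), beyond_cg = c("OD1", "ND2")),
  GLN = list(beyond_cb = c("CG", "CD", "OE1", "NE2"),
             beyond_cg = c("CD", "OE1", "NE2")),
  LEU = list(beyond_cb = c("CG", "CD1", "CD2"), beyond_cg = c("CD1", "CD2")),
  SER = list(beyond_cb = "OG", beyond_cg = NULL),
  THR = list(beyond_cb = c("OG1", "CG2"), beyond_cg = NULL)
)

#' Scan side-chain rotamers of one residue against a pose
#'
#' Enumerates a chi1 x chi2 grid of side-chain rotations (rigid rotation
#' about the CA-CB and CB-CG axes, applied as deltas to the input
#' conformation). For each rotamer the moved side-chain atoms are checked
#' for steric clashes against the rest of the receptor and the pose, and
#' for hydrogen bonds to the ligand. Returned are the clash-free rotamers
#' that create at least one hydrogen bond not present in the input
#' conformation — candidate induced-fit interactions.
#'
#' @param rec a [receptor].
#' @param chain,resnum the residue to rotate (e.g. `"A"`, `307`).
#' @param p the [pose] to test against.
#' @param chi_step grid step in degrees; must divide 360 (default 30).
#' @param cfg an [interaction_config()].
#' @return list of rotamer results, each with `chi` (c(chi1, chi2) delta
#'   in degrees), `new_hbonds` (data.frame as in [detect_hbonds()]) and
#'   `clash_count` (always 0 for returned rotamers).
#' @export
rotamer_scan <- function(rec, chain, resnum, p, chi_step = 30,
                         cfg = interaction_config()) {
  if (360 %% chi_step != 0) stop("chi_step must divide 360")
  res <- residue_atoms(rec, chain, resnum)
  topo <- SIDECHAIN_TOPO[[res$resname[1]]]
  if (is.null(topo)) {
    stop("residue ", res$resname[1], " has no rotatable side chain")
  }
  need <- c("CA", "CB")
  if (!all(need %in% res$name)) stop("residue lacks CA/CB atoms")
  ca <- as.numeric(res[res$name == "CA", c("x", "y", "z")])
  cb <- as.numeric(res[res$name == "CB", c("x", "y", "z")])
  has_chi2 <- !is.null(topo$beyond_cg)
  grid <- seq(0, 360 - chi_step, by = chi_step)
  grid2 <- if (has_chi2) grid else 0

  # receptor without this residue, for the clash check
  other <- rec$atoms[!(rec$atoms$chain == chain & rec$atoms$resnum == resnum), ]
  other <- other[other$is_heavy, ]
  lig_heavy <- p$atoms[p$atoms$is_heavy, ]

  # H-bond pairs present at the input conformation
  sub <- data.frame(chain = chain, resnum = resnum)
  hb0 <- detect_hbonds(p, rec, cfg, residue_subset = sub)
  key0 <- paste(hb0$ligand_index, hb0$protein_atom)

  mk_rotated <- function(a1, a2) {
    r <- res
    xyz <- as.matrix(r[, c("x", "y", "z")])
    mv1 <- r$name %in% topo$beyond_cb
    if (a1 != 0 && any(mv1)) {
      xyz[mv1, ] <- rotate_about_axis(xyz[mv1, , drop = FALSE], ca, cb - ca, a1)
    }
    if (has_chi2 && a2 != 0) {
      cg <- xyz[r$name == "CG", ]
      mv2 <- r$name %in% topo$beyond_cg
      xyz[mv2, ] <- rotate_about_axis(xyz[mv2, , drop = FALSE], cb, cg - cb, a2)
    }
    r$x <- xyz[, 1]; r$y <- xyz[, 2]; r$z <- xyz[, 3]
    r
  }

  results <- list()
  for (a1 in grid) {
    for (a2 in grid2) {
      rres <- mk_rotated(a1, a2)
      moved <- rres[rres$name %in% topo$beyond_cb, ]
      # clash of the moved side chain against receptor-minus-residue and pose
      ncl <- clash_count_atoms(moved, other, cfg) +
        clash_count_atoms(moved, lig_heavy, cfg)
      if (ncl > 0) next
      # rebuild a receptor view with the rotated residue, restricted lookup
      rec2 <- rec
      sel <- rec2$atoms$chain == chain & rec2$atoms$resnum == resnum
      rec2$atoms[sel, c("x", "y", "z")] <- rres[, c("x", "y", "z")]
      hb <- detect_hbonds(p, rec2, cfg, residue_subset = sub)
      if (!nrow(hb)) next
      hb <- hb[hb$protein_atom %in% topo$beyond_cb, , drop = FALSE]
      newb <- hb[!(paste(hb$ligand_index, hb$protein_atom) %in% key0), ,
                 drop = FALSE]
      if (!nrow(newb)) next
      results[[length(results) + 1]] <-
        list(chain = chain, resnum = resnum, chi = c(chi1 = a1, chi2 = a2),
             new_hbonds = newb, clash_count = 0L)
    }
  }
  results
}
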