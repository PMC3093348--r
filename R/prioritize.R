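# SAR-guided prioritisation of common-scaffold clusters.
#
# The structure-activity argument: the series' most efficient ligand owes
# its potency to a hydroxyl group, so only clusters in which that hydroxyl
# can hydrogen-bond to the protein are credible binding hypotheses.

#' SAR filter specification
#'
#' @param ligand_id the ligand whose hydroxyl drives the SAR (default
#'   `"GPV062"`, the 4-hydroxy-4-phenylpiperidine of the packaged series).
#' @param atom_selector either `"hydroxyl"` (resolve the ligand's unique
#'   hydroxyl oxygen from topology: an oxygen with exactly one heavy
#'   neighbour via a single bond) or an explicit 1-based atom index.
#' @param min_poses_with_hbond minimum number of the ligand's poses in a
#'   cluster that must show the hydroxyl-protein hydrogen bond for the
#'   cluster to be kept (default 1; 0 disables the filter).
#' @return a `sar_filter_spec` list.
#' @export
sar_filter_spec <- function(ligand_id = "GPV062", atom_selector = "hydroxyl",
                            min_poses_with_hbond = 1) {
  stopifnot(min_poses_with_hbond >= 0)
  structure(list(ligand_id = ligand_id, atom_selector = atom_selector,
                 min_poses_with_hbond = min_poses_with_hbond),
            class = "sar_filter_spec")
}

# Resolve the designated oxygen of a pose. Errors unless exactly one atom
# qualifies.
resolve_sar_atom <- function(p, selector) {
  if (is.numeric(selector)) {
    idx <- as.integer(selector)
    if (idx < 1 || idx > nrow(p$atoms)) stop("atom_selector index out of range")
    if (p$atoms$element[idx] != "O") stop("atom_selector must name an oxygen")
    return(idx)
  }
  if (!identical(selector, "hydroxyl")) stop("unknown atom_selector: ", selector)
  lp <- ligand_polar_atoms(p)
  idx <- lp$index[lp$hydroxyl]
  if (length(idx) != 1) {
    stop("ligand ", p$ligand_id, " has ", length(idx),
         " hydroxyl oxygens; selector must resolve to exactly one")
  }
  idx
}

#' Keep CSCs where the designated hydroxyl hydrogen-bonds to the protein
#'
#' For each common-scaffold cluster, the designated ligand's poses are
#' checked for a hydrogen bond (as donor or acceptor) between the selected
#' hydroxyl oxygen and any protein residue. Clusters with at least
#' `spec$min_poses_with_hbond` such poses are retained and annotated with
#' the partner residues.
#'
#' @param cscs list of CSCs from [filter_csc()].
#' @param ens the [pose_ensemble].
#' @param rec the [receptor].
#' @param spec a [sar_filter_spec()].
#' @param cfg an [interaction_config()].
#' @return the retained CSCs, each with added fields `hydroxyl_partners`
#'   (data.frame of partner residues/atoms), `n_poses_with_hbond` and
#'   `mean_hbond_score`.
#' @export
filter_hydroxyl_csc <- function(cscs, ens, rec, spec = sar_filter_spec(),
                                cfg = interaction_config()) {
  if (spec$min_poses_with_hbond == 0) return(cscs)
  present <- any(vapply(cscs, function(cl) spec$ligand_id %in% cl$ligand_set, TRUE))
  if (!present) {
    warning("ligand ", spec$ligand_id, " absent from every cluster")
    return(list())
  }
  kept <- list()
  for (cl in cscs) {
    rows <- cl$members$index[cl$members$ligand_id == spec$ligand_id]
    partners <- list(); n_ok <- 0L; scores <- numeric(0)
    for (i in rows) {
      p <- ens$poses[[i]]
      oidx <- resolve_sar_atom(p, spec$atom_selector)
      hb <- detect_hbonds(p, rec, cfg)
      hb <- hb[hb$ligand_index == oidx, , drop = FALSE]
      if (nrow(hb)) {
        n_ok <- n_ok + 1L
        scores <- c(scores, hb$score)
        partners[[length(partners) + 1]] <-
          hb[, c("chain", "resnum", "resname", "protein_atom")]
      }
    }
    if (n_ok >= spec$min_poses_with_hbond) {
      pu <- unique(do.call(rbind, partners))
      rownames(pu) <- NULL
      cl$hydroxyl_partners <- pu
      cl$n_poses_with_hbond <- n_ok
      cl$mean_hbond_score <- mean(scores)
      kept[[length(kept) + 1]] <- cl
    }
  }
  kept
}

#' Rank retained CSCs into an ordered binding-hypothesis report
#'
#' Lexicographic ranking (not a weighted score, so the decision stays
#' auditable): (1) number of distinct protein residues hydrogen-bonding
#' the designated hydroxyl, descending; (2) whether a clash-free rotamer
#' of a nearby tyrosine-like residue can create a new hydrogen bond to the
#' ligand's carbonyl oxygen ([rotamer_scan()]); (3) mean hydroxyl H-bond
#' score, descending. Ties keep input order.
#'
#' @param kept CSCs from [filter_hydroxyl_csc()] (non-empty).
#' @param ens the [pose_ensemble].
#' @param rec the [receptor].
#' @param spec a [sar_filter_spec()].
#' @param cfg an [interaction_config()].
#' @param chi_step rotamer grid step in degrees (default 30).
#' @param rotamer_radius search radius for candidate rotatable residues
#'   around the carbonyl, Angstrom (default 8).
#' @param pal_residues optional data.frame (`chain`, `resnum`) of
#'   photoaffinity-labelled residues; adds an overlap count annotation.
#' @return data.frame report, one row per CSC in rank order.
#' @export
rank_hypotheses <- function(kept, ens, rec, spec = sar_filter_spec(),
                            cfg = interaction_config(), chi_step = 30,
                            rotamer_radius = 8, pal_residues = NULL) {
  if (!length(kept)) stop("no clusters to rank")
  rows <- lapply(kept, function(cl) {
    n_partners <- if (is.null(cl$hydroxyl_partners)) 0L else
      nrow(unique(cl$hydroxyl_partners[, c("chain", "resnum")]))
    carbonyl_ok <- csc_carbonyl_rotamer(cl, ens, rec, spec, cfg, chi_step,
                                        rotamer_radius)
    pal <- NA_integer_
    if (!is.null(pal_residues)) {
      fp <- plif(cluster_member_poses(cl, ens), rec, cfg,
                 pose_set_id = cl$csc_label %||% as.character(cl$cluster_id))
      pal <- sum(paste(fp$table$chain, fp$table$resnum) %in%
                   paste(pal_residues$chain, pal_residues$resnum))
    }
    data.frame(
      csc_label = cl$csc_label %||% paste("cluster", cl$cluster_id),
      n_members = nrow(cl$members),
      n_ligands = length(cl$ligand_set),
      n_hydroxyl_partners = n_partners,
      hydroxyl_partners = paste(
        if (is.null(cl$hydroxyl_partners)) character(0) else
          paste0(cl$hydroxyl_partners$resname, cl$hydroxyl_partners$resnum),
        collapse = ";"),
      carbonyl_rotamer = carbonyl_ok,
      mean_hbond_score = cl$mean_hbond_score %||% NA_real_,
      pal_overlap = pal)
  })
  report <- do.call(rbind, rows)
  ord <- order(-report$n_hydroxyl_partners, -report$carbonyl_rotamer,
               -ifelse(is.na(report$mean_hbond_score), -Inf,
                       report$mean_hbond_score))
  report <- report[ord, ]
  report$rank <- seq_len(nrow(report))
  rownames(report) <- NULL
  report[, c("rank", setdiff(names(report), "rank"))]
}

# Does some rotatable residue near the designated ligand's carbonyl admit a
# clash-free rotamer forming a new H-bond that involves the carbonyl O?
csc_carbonyl_rotamer <- function(cl, ens, rec, spec, cfg, chi_step,
                                 rotamer_radius) {
  rows <- cl$members$index[cl$members$ligand_id == spec$ligand_id]
  if (!length(rows)) return(FALSE)
  p <- ens$poses[[rows[1]]]
  co <- ligand_carbonyl_oxygens(p)
  if (!length(co)) return(FALSE)
  cxyz <- as.matrix(p$atoms[co, c("x", "y", "z"), drop = FALSE])
  res <- receptor_residues(rec)
  res <- res[res$resname %in% names(SIDECHAIN_TOPO), , drop = FALSE]
  for (r in seq_len(nrow(res))) {
    ra <- residue_atoms(rec, res$chain[r], res$resnum[r])
    if (min(cross_dist(as.matrix(ra[, c("x", "y", "z")]), cxyz)) > rotamer_radius) next
    hits <- rotamer_scan(rec, res$chain[r], res$resnum[r], p,
                         chi_step = chi_step, cfg = cfg)
    for (h in hits) {
      if (any(h$new_hbonds$ligand_index %in% co)) return(TRUE)
    }
  }
  FALSE
}

# Indices of carbonyl oxygens of a pose (O double-bonded to C).
ligand_carbonyl_oxygens <- function(p) {
  a <- p$atoms
  if (!nrow(p$bonds)) return(integer(0))
  dbl <- p$bonds[p$bonds$order >= 2, , drop = FALSE]
  idx <- unique(c(dbl$from[a$element[dbl$to] == "O"] * 0 + dbl$to[a$element[dbl$to] == "O"],
                  dbl$from[a$element[dbl$from] == "O"]))
  idx[a$element[idx] == "O"]
}
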