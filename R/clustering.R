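# Common-scaffold RMSD clustering.
#
# All poses of all ligands share the receptor coordinate frame, so RMSD is
# computed in place (no superposition): superposing would erase the
# difference between binding locations, which is exactly what the
# clustering must resolve. Cross-ligand distances are well-defined because
# they are computed on the shared scaffold atoms only.

#' Clustering configuration
#'
#' @param cut_height dendrogram cut, Angstrom (default 3.0; inclusive at
#'   the boundary).
#' @param linkage agglomeration method (only `"complete"` supported; the
#'   complete-linkage criterion guarantees every cluster's diameter is at
#'   most the cut height).
#' @param min_ligands minimum number of distinct ligands for a cluster to
#'   count as a common-scaffold cluster (default 4).
#' @param total_ligands expected series size (default 5); informational.
#' @return a `clustering_config` list.
#' @export
clustering_config <- function(cut_height = 3.0, linkage = "complete",
                              min_ligands = 4, total_ligands = 5) {
  stopifnot(cut_height > 0, min_ligands >= 1, min_ligands <= total_ligands)
  linkage <- match.arg(linkage, "complete")
  structure(list(cut_height = cut_height, linkage = linkage,
                 min_ligands = min_ligands, total_ligands = total_ligands),
            class = "clustering_config")
}

#' In-place scaffold RMSD between two poses
#'
#' sqrt(mean of squared distances) over the N scaffold atoms in canonical
#' order, minimised over all symmetry-equivalent scaffold mappings of both
#' poses (otherwise e.g. a phenyl ring flip would inflate the RMSD of two
#' physically identical placements).
#'
#' @param poseA,poseB [pose] objects in the same receptor frame.
#' @param mapsA,mapsB `scaffold_map` objects (or lists of mappings) for the
#'   respective ligands.
#' @return RMSD in Angstrom.
#' @export
scaffold_rmsd <- function(poseA, poseB, mapsA, mapsB) {
  mA <- if (inherits(mapsA, "scaffold_map")) mapsA$mappings else mapsA
  mB <- if (inherits(mapsB, "scaffold_map")) mapsB$mappings else mapsB
  n <- length(mA[[1]])
  if (any(lengths(mA) != n) || any(lengths(mB) != n)) {
    stop("scaffold mapping length mismatch")
  }
  best <- Inf
  for (a in mA) {
    ca <- scaffold_coords(poseA, a)
    for (b in mB) {
      cb <- scaffold_coords(poseB, b)
      r <- sqrt(sum((ca - cb)^2) / n)
      if (r < best) best <- r
    }
  }
  best
}

#' Pairwise scaffold-RMSD matrix of an ensemble
#'
#' All pose pairs are pooled across ligands — the cross-ligand entries are
#' the point of common-scaffold clustering.
#'
#' @param ens a [pose_ensemble].
#' @param maps output of [build_scaffold_maps()].
#' @return an `rmsd_matrix`: list with `$pose_index` (data.frame
#'   ligand_id/pose_id) and `$values` (symmetric matrix, Angstrom).
#' @export
rmsd_matrix <- function(ens, maps) {
  poses <- ens$poses
  np <- length(poses)
  n <- length(maps[[1]]$mappings[[1]])
  # one flattened coordinate row per (pose, mapping)
  rows <- list(); owner <- integer(0)
  for (i in seq_len(np)) {
    p <- poses[[i]]
    mp <- maps[[p$ligand_id]]
    if (is.null(mp)) stop("no scaffold map for ligand ", p$ligand_id)
    for (m in mp$mappings) {
      rows[[length(rows) + 1]] <- as.numeric(scaffold_coords(p, m))
      owner <- c(owner, i)
    }
  }
  X <- do.call(rbind, rows)
  rs <- rowSums(X^2)
  D2 <- outer(rs, rs, `+`) - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  vals <- matrix(0, np, np)
  blocks <- split(seq_along(owner), owner)
  for (i in seq_len(np)) {
    bi <- blocks[[i]]
    for (j in seq_len(i - 1)) {
      d <- sqrt(min(D2[bi, blocks[[j]], drop = FALSE]) / n)
      vals[i, j] <- d; vals[j, i] <- d
    }
  }
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite RMSD between poses %d and %d", bad[1], bad[2]))
  }
  idx <- data.frame(ligand_id = vapply(poses, function(p) p$ligand_id, ""),
                    pose_id = vapply(poses, function(p) p$pose_id, 1L))
  structure(list(pose_index = idx, values = vals), class = "rmsd_matrix")
}

#' Cluster poses by complete linkage at a fixed height
#'
#' Agglomerative complete-linkage clustering of the pooled scaffold-RMSD
#' matrix, cut at `cfg$cut_height` (inclusive: a merge at exactly the cut
#' height is kept). Cluster ids are assigned by descending size, ties by
#' smallest member index.
#'
#' @param mat an [rmsd_matrix()].
#' @param cfg a [clustering_config()].
#' @return list of `pose_cluster` objects, each with `cluster_id`,
#'   `members` (data.frame ligand_id/pose_id/index), `ligand_set` and
#'   `formation_height` (max intra-cluster pairwise RMSD).
#' @export
cluster_poses <- function(mat, cfg = clustering_config()) {
  v <- mat$values
  np <- nrow(v)
  if (any(v < 0) || any(abs(diag(v)) > 1e-12) || any(abs(v - t(v)) > 1e-9)) {
    stop("invalid RMSD matrix")
  }
  if (np == 1) {
    labels <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(v), method = cfg$linkage)
    k <- np - sum(hc$height <= cfg$cut_height + 1e-9)
    labels <- if (k >= np) seq_len(np) else stats::cutree(hc, k = k)
  }
  groups <- split(seq_len(np), labels)
  # order: descending size, then smallest member index
  ord <- order(-lengths(groups), vapply(groups, min, 1L))
  groups <- groups[ord]
  lapply(seq_along(groups), function(ci) {
    g <- groups[[ci]]
    members <- cbind(mat$pose_index[g, , drop = FALSE], index = g)
    rownames(members) <- NULL
    fh <- if (length(g) > 1) max(v[g, g]) else 0
    structure(list(cluster_id = ci, members = members,
                   ligand_set = sort(unique(members$ligand_id)),
                   formation_height = fh),
              class = "pose_cluster")
  })
}

#' Filter clusters to common-scaffold clusters (CSCs)
#'
#' Keeps clusters whose poses span at least `cfg$min_ligands` distinct
#' ligands of the series (default: 4 of 5) — the common-binding-mode
#' filter. Kept clusters are labelled with Roman numerals by descending
#' size ("CSC I", "CSC II", ...).
#'
#' @param clusters output of [cluster_poses()].
#' @param cfg a [clustering_config()].
#' @return list of CSCs (clusters with an added `csc_label`), with
#'   kept/dropped counts in attributes `n_dropped` and `poses_retained`.
#' @export
filter_csc <- function(clusters, cfg = clustering_config()) {
  keep <- vapply(clusters, function(cl) length(cl$ligand_set) >= cfg$min_ligands, TRUE)
  kept <- clusters[keep]
  kept <- kept[order(-vapply(kept, function(cl) nrow(cl$members), 1L),
                     vapply(kept, function(cl) min(cl$members$index), 1L))]
  kept <- lapply(seq_along(kept), function(i) {
    cl <- kept[[i]]
    cl$csc_label <- paste("CSC", as.character(utils::as.roman(i)))
    cl
  })
  attr(kept, "n_dropped") <- sum(!keep)
  attr(kept, "poses_retained") <- sum(vapply(kept, function(cl) nrow(cl$members), 1L))
  kept
}

#' Poses belonging to a cluster
#'
#' @param cl a `pose_cluster` (or CSC).
#' @param ens the [pose_ensemble] the cluster was computed from.
#' @return list of [pose] objects.
#' @export
cluster_member_poses <- function(cl, ens) {
  ens$poses[cl$members$index]
}
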