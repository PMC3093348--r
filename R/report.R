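# Report writers: cluster statistics, per-residue PLIF tables, per-cluster
# SDF files.

#' Write pipeline reports
#'
#' Writes (a) `cluster_stats.csv` — run-level statistics (total poses,
#' clusters at the cut, CSCs with retained pose count, SAR-filtered
#' CSCs); (b) `cluster_table.csv` — one row per cluster/CSC; (c)
#' per-residue PLIF tables (`plif_<id>.csv`); (d) per-CSC pose sets as
#' multi-record SDF files; (e) `prioritization.csv` if a ranking report
#' is given.
#'
#' @param out_dir output directory (created if missing).
#' @param ens the [pose_ensemble].
#' @param clusters all clusters from [cluster_poses()].
#' @param cscs CSCs from [filter_csc()].
#' @param fps optional named list of `interaction_fp` objects.
#' @param sar_kept optional CSCs retained by [filter_hydroxyl_csc()].
#' @param ranking optional report from [rank_hypotheses()].
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(out_dir, ens, clusters, cscs, fps = NULL,
                         sar_kept = NULL, ranking = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stats <- data.frame(
    statistic = c("total_poses", "clusters_at_cut", "common_scaffold_clusters",
                  "poses_in_cscs", "sar_filtered_cscs"),
    value = c(length(ens$poses), length(clusters), length(cscs),
              attr(cscs, "poses_retained") %||%
                sum(vapply(cscs, function(cl) nrow(cl$members), 1L)),
              if (is.null(sar_kept)) NA_integer_ else length(sar_kept)))
  f <- file.path(out_dir, "cluster_stats.csv")
  utils::write.csv(stats, f, row.names = FALSE)
  files <- c(files, f)

  rows <- lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id,
               csc_label = cl$csc_label %||% "",
               n_members = nrow(cl$members),
               n_ligands = length(cl$ligand_set),
               ligands = paste(cl$ligand_set, collapse = ";"),
               formation_height = cl$formation_height)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), csc_label = character(),
               n_members = integer(), n_ligands = integer(),
               ligands = character(), formation_height = numeric())
  # carry CSC labels onto the full table
  for (csc in cscs) tab$csc_label[tab$cluster_id == csc$cluster_id] <- csc$csc_label
  f <- file.path(out_dir, "cluster_table.csv")
  utils::write.csv(tab, f, row.names = FALSE)
  files <- c(files, f)

  for (nm in names(fps %||% list())) {
    f <- file.path(out_dir, paste0("plif_", gsub("[^A-Za-z0-9_-]", "_", nm), ".csv"))
    utils::write.csv(fps[[nm]]$table, f, row.names = FALSE)
    files <- c(files, f)
  }

  for (csc in cscs) {
    slug <- gsub("[^A-Za-z0-9_-]", "_", csc$csc_label)
    f <- file.path(out_dir, paste0("poses_", slug, ".sdf"))
    write_pose_ensemble(pose_ensemble(cluster_member_poses(csc, ens),
                                      receptor_ref = ens$receptor_ref), f)
    files <- c(files, f)
  }

  if (!is.null(ranking)) {
    f <- file.path(out_dir, "prioritization.csv")
    utils::write.csv(ranking, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
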