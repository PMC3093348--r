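# End-to-end orchestration: generate or load inputs, cluster, filter,
# fingerprint, prioritise, report.

#' Run the full pose-evaluation pipeline
#'
#' Stages: (1) input — either a packaged synthetic scene (`scene` given)
#' or files (`receptor_path` + `poses_path`); (2) scaffold mapping;
#' (3) pooled scaffold-RMSD matrix and complete-linkage clustering at the
#' cut height; (4) CSC filter (>= `min_ligands` distinct ligands);
#' (5) PLIF of all poses and of the CSC poses; (6) efficiency metrics
#' from the activity table; (7) SAR hydroxyl filter and ranking;
#' (8) reports + manifest. Identical config and inputs give identical
#' outputs.
#'
#' @param out_dir output directory.
#' @param scene a scene from [make_scene()], or NULL to read files.
#' @param receptor_path,poses_path input files (used when `scene` is
#'   NULL).
#' @param activity_path activity CSV; default the packaged propafenone
#'   table.
#' @param scaffold a [scaffold_spec()] (default [default_scaffold()]).
#' @param clustering a [clustering_config()].
#' @param interaction an [interaction_config()].
#' @param sar a [sar_filter_spec()].
#' @param pal_residues optional data.frame (`chain`, `resnum`) of
#'   photoaffinity-labelled residues for the ranking annotation.
#' @param verbose log stage progress via `message()` (default TRUE).
#' @return invisible list with all stage outputs (`ensemble`, `clusters`,
#'   `cscs`, `fps`, `metrics`, `sar_kept`, `ranking`, `files`).
#' @export
run_pipeline <- function(out_dir, scene = NULL, receptor_path = NULL,
                         poses_path = NULL,
                         activity_path = system.file("extdata",
                                                     "propafenone_activities.csv",
                                                     package = "sarpose"),
                         scaffold = default_scaffold(),
                         clustering = clustering_config(),
                         interaction = interaction_config(),
                         sar = sar_filter_spec(),
                         pal_residues = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message("[sarpose] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.null(scene)) {
    if (is.null(receptor_path) || is.null(poses_path)) {
      stop("either a scene or receptor_path + poses_path must be given")
    }
    say("reading receptor from ", receptor_path)
    rec <- stage("input", read_receptor(receptor_path))
    say("reading pose ensemble from ", poses_path)
    ens <- stage("input", read_pose_ensemble(poses_path))
  } else {
    rec <- scene$receptor
    ens <- scene$ensemble
    say("using generated scene (seed ", scene$config$seed, ")")
  }
  say(length(ens$poses), " poses, ", length(ensemble_ligands(ens)), " ligands")

  maps <- stage("scaffold", build_scaffold_maps(ens, scaffold))
  mat <- stage("rmsd", rmsd_matrix(ens, maps))
  clusters <- stage("cluster", cluster_poses(mat, clustering))
  say(length(clusters), " clusters at ", clustering$cut_height, " Angstrom cut")
  cscs <- stage("csc", filter_csc(clusters, clustering))
  say(length(cscs), " common-scaffold clusters (",
      attr(cscs, "poses_retained"), " poses)")

  fps <- list(all = plif(ens$poses, rec, interaction, pose_set_id = "all"))
  if (length(cscs)) {
    csc_poses <- unlist(lapply(cscs, cluster_member_poses, ens = ens),
                        recursive = FALSE)
    fps$csc <- stage("plif", plif(csc_poses, rec, interaction, pose_set_id = "csc"))
  }

  metrics <- NULL
  if (!is.null(activity_path) && nzchar(activity_path) && file.exists(activity_path)) {
    metrics <- stage("sar_metrics", efficiency_table(read_activity_table(activity_path)))
  }

  sar_kept <- NULL; ranking <- NULL
  if (length(cscs)) {
    sar_kept <- stage("sar_filter",
                      filter_hydroxyl_csc(cscs, ens, rec, sar, interaction))
    say(length(sar_kept), " CSCs pass the hydroxyl H-bond filter")
    if (length(sar_kept)) {
      ranking <- stage("rank", rank_hypotheses(sar_kept, ens, rec, sar,
                                               interaction,
                                               pal_residues = pal_residues))
      fps$sar <- plif(unlist(lapply(sar_kept, cluster_member_poses, ens = ens),
                             recursive = FALSE),
                      rec, interaction, pose_set_id = "sar")
    }
  }

  files <- stage("report", write_report(out_dir, ens, clusters, cscs, fps,
                                        sar_kept, ranking))
  if (!is.null(metrics)) {
    f <- file.path(out_dir, "efficiency_metrics.csv")
    utils::write.csv(metrics, f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("sarpose")),
    n_poses = length(ens$poses),
    n_ligands = length(ensemble_ligands(ens)),
    n_clusters = length(clusters),
    n_cscs = length(cscs),
    n_sar_kept = if (is.null(sar_kept)) NA else length(sar_kept),
    clustering = unclass(clustering),
    interaction = unclass(interaction)[c("contact_cutoff", "hbond_da_max",
                                         "hbond_dha_min",
                                         "aromatic_centroid_max",
                                         "clash_tolerance")],
    config_hash = config_hash(list(clustering = unclass(clustering),
                                   sar = unclass(sar))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("wrote ", length(files) + 1, " files to ", out_dir)
  invisible(list(receptor = rec, ensemble = ens, clusters = clusters,
                 cscs = cscs, fps = fps, metrics = metrics,
                 sar_kept = sar_kept, ranking = ranking,
                 files = c(files, file.path(out_dir, "manifest.json"))))
}

# md5 of a canonical JSON rendering of the configuration.
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}
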