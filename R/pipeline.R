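# End-to-end orchestration: sampling -> core selection -> modularization ->
# local/global Bayesian networks -> essentiality, with every intermediate
# artifact written to a run directory and a machine-readable manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline. The defaults are the framework's
#' reference settings: 1000 samples per condition, significance threshold
#' 1e-2, activity threshold 0.95, 300 adjoined pattern matrices, clustering
#' cutoff 1.0, 4 discretization intervals.
#'
#' @param model_path path to a model TSV (or SBML, by extension).
#' @param constraints_path path to a constraints CSV.
#' @param out_dir run directory.
#' @param knockouts character vector of knocked-out reaction ids.
#' @param n_per_condition samples per condition.
#' @param p_thresh,activity_thresh core-selection thresholds.
#' @param n_perms adjoined flux-pattern matrices.
#' @param cutoff clustering cut threshold.
#' @param cut_criterion `"inconsistent"` or `"distance"`.
#' @param bins discretization intervals.
#' @param tabu_restarts,tabu_len,max_parents,max_iter tabu-search settings.
#' @param seed master seed for every random draw of the run.
#' @return a `fmb_config` list.
#' @export
fmb_config <- function(model_path, constraints_path, out_dir,
                       knockouts = character(), n_per_condition = 1000,
                       p_thresh = 1e-2, activity_thresh = 0.95,
                       n_perms = 300, cutoff = 1.0,
                       cut_criterion = "inconsistent", bins = 4,
                       tabu_restarts = 3, tabu_len = 10, max_parents = 4,
                       max_iter = 200, seed = 1) {
  stopifnot(p_thresh > 0, p_thresh <= 1, activity_thresh >= 0, activity_thresh < 1,
            n_perms >= 1, bins >= 2, n_per_condition >= 2)
  structure(as.list(environment()), class = "fmb_config")
}

read_any_model <- function(path) {
  if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) read_sbml(path)
  else read_model_tsv(path)
}

#' Run the full pipeline
#'
#' Executes flux sampling, core selection, modularization, local network
#' learning with representative selection, global network learning, and
#' essentiality scoring, writing `flux.tsv`, `core/`, `clusters.tsv`,
#' `linkage.tsv`, `local_bns/`, `tmi_table.tsv`, `global_bn.graphml`,
#' `global_bn.dot`, `essentiality.tsv`, `manifest.json` and `report.txt`
#' into the run directory. Identical configurations (including the seed)
#' produce identical artifacts.
#'
#' @param config an [fmb_config()].
#' @return the run directory, invisibly; the manifest is also returned as
#'   attribute `"manifest"`.
#' @export
run_fmb <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "core"), showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "local_bns"), showWarnings = FALSE)

  model <- read_any_model(cfg$model_path)
  constraints <- load_constraints(cfg$constraints_path)
  perturbation <- fmb_perturbation(cfg$knockouts)

  message("stage sample: ", 2 * cfg$n_per_condition, " LAD flux samples")
  fm <- sample_flux_matrix(model, constraints, perturbation,
                           cfg$n_per_condition, cfg$seed)
  write_flux_tsv(fm, file.path(cfg$out_dir, "flux.tsv"))

  message("stage core: significance/activity/duplicate filters")
  core <- select_core(fm, cfg$p_thresh, cfg$activity_thresh)
  write_core_table(core, file.path(cfg$out_dir, "core", "core_table.tsv"))
  write_flux_tsv(core$reduced, file.path(cfg$out_dir, "core", "reduced_flux.tsv"))

  message("stage cluster: ", cfg$n_perms, " adjoined flux-pattern matrices")
  d <- pattern_dist(core$reduced$values, cfg$n_perms, derive_seed(cfg$seed, "perms"))
  clusters <- hierarchical_cluster(d, cfg$cutoff, cfg$cut_criterion,
                                   labels = rownames(core$reduced$values))
  clusters <- reinsert_duplicates(clusters, core$duplicate_groups)
  write_cluster_table(clusters, core$duplicate_groups,
                      file.path(cfg$out_dir, "clusters.tsv"))
  if (!is.null(clusters$hclust)) {
    hc <- clusters$hclust
    utils::write.table(
      data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                 height = hc$height, inconsistency = clusters$inconsistency),
      file.path(cfg$out_dir, "linkage.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  message("stage bn: local networks, representatives, global network")
  flux_all <- fm$values[names(clusters$assignment), , drop = FALSE]
  local <- learn_local_bns(clusters, flux_all, k = cfg$bins,
                           max_iter = cfg$max_iter, tabu_len = cfg$tabu_len,
                           restarts = cfg$tabu_restarts,
                           max_parents = cfg$max_parents,
                           seed = derive_seed(cfg$seed, "local"))
  utils::write.table(local$tmi_table, file.path(cfg$out_dir, "tmi_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cid in names(local$bns))
    write_bn(local$bns[[cid]],
             file.path(cfg$out_dir, "local_bns", sprintf("cluster_%s.graphml", cid)))
  global <- learn_global_bn(local$representatives, local$bins,
                            max_iter = cfg$max_iter, tabu_len = cfg$tabu_len,
                            restarts = cfg$tabu_restarts,
                            max_parents = cfg$max_parents,
                            seed = derive_seed(cfg$seed, "global"))
  write_bn(global, file.path(cfg$out_dir, "global_bn.graphml"), "graphml")
  write_bn(global, file.path(cfg$out_dir, "global_bn.dot"), "dot")

  message("stage essentiality: single-deletion FBA")
  ess <- essentiality_table(model, constraints, perturbation, clusters)
  utils::write.table(ess$table, file.path(cfg$out_dir, "essentiality.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  manifest <- list(
    package = "fmbr",
    version = as.character(utils::packageVersion("fmbr")),
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    counts = c(as.list(core$counts),
               list(clusters = clusters$n_clusters,
                    clustered_reactions = length(clusters$assignment),
                    representatives = length(local$representatives),
                    global_arcs = sum(global$adj))),
    global_mdl_bits = global$mdl,
    mean_essentiality = as.list(ess$overall_means),
    files = file_md5s(cfg$out_dir))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_reports(cfg$out_dir)
  out <- cfg$out_dir
  attr(out, "manifest") <- manifest
  invisible(out)
}

file_md5s <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  files <- files[!basename(files) %in% c("manifest.json", "report.txt")]
  md5 <- tools::md5sum(files)
  names(md5) <- sub(paste0("^", dir, "/?"), "", files)
  as.list(md5)
}

#' Write the human-readable run summary
#'
#' Produces `report.txt` from a completed run directory: each cluster's
#' roster ordered by TMI with its representative flagged, cluster
#' essentiality averages, and the influence list (children) of every node of
#' the global network.
#'
#' @param run_dir a directory produced by [run_fmb()].
#' @return path of the report, invisibly.
#' @export
write_reports <- function(run_dir) {
  need <- c("tmi_table.tsv", "essentiality.tsv", "global_bn.graphml", "clusters.tsv")
  for (f in need) if (!file.exists(file.path(run_dir, f)))
    stop_fmb("missing artifact '%s'; rerun the corresponding stage", f)
  tmi_tab <- utils::read.delim(file.path(run_dir, "tmi_table.tsv"))
  ess <- utils::read.delim(file.path(run_dir, "essentiality.tsv"))
  g <- igraph::read_graph(file.path(run_dir, "global_bn.graphml"), format = "graphml")

  lines <- c("FMB run summary", "===============", "")
  reps <- tmi_tab$reaction_id[tmi_tab$is_representative]
  names(reps) <- tmi_tab$cluster_id[tmi_tab$is_representative]
  for (cid in sort(unique(tmi_tab$cluster_id))) {
    sub <- tmi_tab[tmi_tab$cluster_id == cid, ]
    sub <- sub[order(-sub$tmi_bits, sub$reaction_id), ]
    em <- ess[!is.na(ess$cluster_id) & ess$cluster_id == cid, ]
    avg <- tapply(em$essentiality, em$condition, mean)
    lines <- c(lines, sprintf("cluster %d (essentiality %s):", cid,
                              paste(sprintf("%s %.3f", names(avg), avg), collapse = ", ")))
    lines <- c(lines, sprintf("  %s%s  TMI %.3f bits",
                              ifelse(sub$is_representative, "* ", "  "),
                              sub$reaction_id, sub$tmi_bits))
  }
  lines <- c(lines, "", "global network influences (node -> children):")
  vnames <- igraph::V(g)$name %||% igraph::V(g)$id
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  for (i in seq_along(vnames)) {
    kids <- vnames[adj[i, ] > 0]
    lines <- c(lines, sprintf("  %s -> %s (%d)", vnames[i],
                              if (length(kids)) paste(kids, collapse = ", ") else "-",
                              length(kids)))
  }
  path <- file.path(run_dir, "report.txt")
  writeLines(lines, path)
  invisible(path)
}
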