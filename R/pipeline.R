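#' Run the full analysis pipeline on a simulated scenario
#'
#' Executes the stages in order — simulate, downsample, purify, cluster,
#' pseudotime, windowed differential expression, TF network, deconvolution —
#' writing every artifact under `out_dir` together with a manifest and a run
#' log echoing the resolved configuration, derived stage seeds and per-stage
#' record counts.  Identical configuration and seed give byte-identical
#' numeric outputs.
#'
#' Purification is applied to the populations that arrive through the sorted
#' c-kit+ route (the cluster-resident populations plus contaminants,
#' `config$purify_pool`); the separately sorted endothelial/EHT/yolk-sac
#' populations enter the analysis by sort identity, as in the study design
#' being emulated.
#'
#' @param config An `iahc_config` from [run_config()].
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return The manifest: a named list of per-stage artifact paths (also
#'   written as `manifest.json`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = config$out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("iahctools pipeline run",
                 utils::capture.output(print(config)))
  manifest <- list()
  path <- function(...) file.path(out_dir, paste0(...))

  # -- simulate ----------------------------------------------------------
  seed_sim <- derive_seed(config$seed, "simulate")
  scen <- switch(config$scenario, e11 = scenario_e11, e10 = scenario_e10)
  sim <- simulate_cells(scen(contaminants = config$contaminants),
                        n_genes = config$n_genes,
                        mean_depth = config$mean_depth,
                        dispersion = config$dispersion, seed = seed_sim)
  bulks <- simulate_wiahcs(sim, n_wiahcs = config$n_wiahcs,
                           size_range = config$wiahc_size_range,
                           seed = derive_seed(config$seed, "wiahcs"))
  write_count_matrix(sim$counts, path("counts.mtx"))
  write_annotation(sim$annotation, path("annotation.tsv"))
  truth_json <- path("truth.json")
  jsonlite::write_json(list(cell_time = as.list(sim$truth$cell_time),
                            cell_population = as.list(sim$truth$cell_population),
                            wiahc_members = bulks$truth$wiahc_members,
                            wiahc_side = as.list(bulks$truth$wiahc_side)),
                       truth_json, auto_unbox = TRUE, digits = NA)
  utils::write.table(data.frame(gene = rownames(bulks$counts), bulks$counts,
                                check.names = FALSE),
                     path("bulks.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_annotation(bulks$meta, path("bulk_meta.tsv"))
  manifest$simulate <- c(path("counts.mtx"), path("counts.genes.tsv"),
                         path("counts.cells.tsv"), path("annotation.tsv"),
                         truth_json, path("bulks.tsv"), path("bulk_meta.tsv"))
  log_lines <- c(log_lines,
                 sprintf("simulate: seed %d, %d cells, %d genes, %d bulks",
                         seed_sim, ncol(sim$counts), nrow(sim$counts),
                         ncol(bulks$counts)))

  # -- downsample --------------------------------------------------------
  seed_ds <- derive_seed(config$seed, "downsample")
  ds <- downsample_cells(sim$counts, depth = config$downsample_depth,
                         seed = seed_ds)
  write_count_matrix(ds$counts, path("downsampled.mtx"))
  writeLines(ds$discarded, path("discarded_cells.txt"))
  manifest$downsample <- c(path("downsampled.mtx"),
                           path("downsampled.genes.tsv"),
                           path("downsampled.cells.tsv"),
                           path("discarded_cells.txt"))
  log_lines <- c(log_lines,
                 sprintf("downsample: seed %d, depth %d, %d retained, %d discarded",
                         seed_ds, config$downsample_depth, ncol(ds$counts),
                         length(ds$discarded)))

  # -- purify ------------------------------------------------------------
  pops <- stats::setNames(sim$annotation$population, sim$annotation$cell)
  pool <- names(pops)[pops %in% config$purify_pool]
  pur <- purify(sim$counts[, pool, drop = FALSE])
  analysis_cells <- intersect(colnames(ds$counts),
                              c(setdiff(colnames(sim$counts), pool),
                                pur$selected))
  acounts <- ds$counts[, analysis_cells, drop = FALSE]
  utils::write.table(data.frame(cell = pur$selected), path("purified_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pur$rejected, path("purify_rejections.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$purify <- c(path("purified_cells.tsv"), path("purify_rejections.tsv"))
  log_lines <- c(log_lines,
                 sprintf("purify: %d of %d pool cells kept; %d analysis cells",
                         length(pur$selected), length(pool),
                         length(analysis_cells)))

  # -- cluster -----------------------------------------------------------
  k <- if (config$n_clusters > 0) config$n_clusters else NULL
  cl <- cluster_cells(acounts, k = k,
                      seed = derive_seed(config$seed, "cluster"))
  utils::write.table(data.frame(cell = names(cl$cluster),
                                cluster = as.integer(cl$cluster)),
                     path("clusters.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$cluster <- path("clusters.tsv")
  log_lines <- c(log_lines, sprintf("cluster: k = %d", cl$k))

  # -- pseudotime --------------------------------------------------------
  genes_use <- filter_genes_min_expression(acounts)
  pt <- order_cells(acounts, gene_subset = genes_use,
                    seed = derive_seed(config$seed, "pseudotime"))
  utils::write.table(data.frame(cell = names(pt$pt), pseudotime = pt$pt),
                     path("pseudotime.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$pseudotime <- path("pseudotime.tsv")
  log_lines <- c(log_lines,
                 sprintf("pseudotime: %d cells, %d embedding genes",
                         length(pt$pt), length(genes_use)))

  # -- windowed DE -------------------------------------------------------
  wde <- windowed_de(acounts, pt,
                     window_spec(width = config$window_width,
                                 half = config$window_half,
                                 step = config$window_step,
                                 alpha = config$de_alpha))
  utils::write.table(wde, path("windowed_de.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$de <- path("windowed_de.tsv")
  log_lines <- c(log_lines, sprintf("windowed_de: %d windows", nrow(wde)))

  # -- TF network --------------------------------------------------------
  panels <- marker_panels()
  tf_list <- c(panels$tf_I, panels$tf_II, panels$tf_III)
  sm <- smooth_profiles(acounts, pt)
  tfs <- select_tfs(sm, tf_list)
  tf_labels <- cluster_tf_profiles(sm[tfs, , drop = FALSE], pt)
  net <- build_network(sm[tfs, , drop = FALSE],
                       threshold = config$network_threshold,
                       labels = tf_labels)
  utils::write.table(tf_labels, path("tf_clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(net$edges, path("tf_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_graphml(net, path("tf_network.graphml"))
  manifest$tfnet <- c(path("tf_clusters.tsv"), path("tf_edges.tsv"),
                      path("tf_network.graphml"))
  log_lines <- c(log_lines,
                 sprintf("tfnet: %d TFs selected, %d edges at |r| >= %g",
                         length(tfs), nrow(net$edges),
                         config$network_threshold))

  # -- deconvolution -----------------------------------------------------
  member_pops <- c("EHT", "preHSC-I", "preHSC-II", "progenitor")
  ref_cells <- analysis_cells[pops[analysis_cells] %in% member_pops]
  reference <- ds$counts[, ref_cells, drop = FALSE]
  decon_out <- vector("list", ncol(bulks$counts))
  names(decon_out) <- colnames(bulks$counts)
  contrib_rows <- list()
  prob_rows <- list()
  dens_rows <- list()
  for (i in seq_len(ncol(bulks$counts))) {
    id <- colnames(bulks$counts)[i]
    dc <- deconvolve(bulks$counts[, i], reference, bulks$meta$n[i],
                     decon_config(n_swaps = config$decon_swaps,
                                  n_restarts = config$decon_restarts,
                                  seed = derive_seed(config$seed,
                                                     paste0("decon_", id))))
    pr <- contribution_probability(dc)
    cc <- cluster_contribution(dc, cl)
    dn <- pseudotime_density(pr, pt)
    decon_out[[id]] <- list(n = dc$n,
                            correlation = dc$correlation,
                            accepted = dc$accepted,
                            members = dc$members)
    contrib_rows[[id]] <- data.frame(wiahc = id, side = bulks$meta$side[i],
                                     cluster = names(cc$mean),
                                     fraction = as.numeric(cc$mean))
    prob_rows[[id]] <- data.frame(wiahc = id, cell = names(pr),
                                  probability = as.numeric(pr))
    dens_rows[[id]] <- data.frame(wiahc = id, dn)
  }
  jsonlite::write_json(decon_out, path("decon.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(do.call(rbind, contrib_rows), path("decon_contributions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, prob_rows), path("decon_probabilities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, dens_rows), path("decon_densities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sim_mat <- wiahc_similarity(bulks)
  utils::write.table(data.frame(wiahc = rownames(sim_mat$distance),
                                sim_mat$distance, check.names = FALSE),
                     path("wiahc_similarity.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$decon <- c(path("decon.json"), path("decon_contributions.tsv"),
                      path("decon_probabilities.tsv"),
                      path("decon_densities.tsv"),
                      path("wiahc_similarity.tsv"))
  log_lines <- c(log_lines,
                 sprintf("decon: %d bulks vs %d reference cells (%d swaps x %d restarts)",
                         ncol(bulks$counts), ncol(reference),
                         config$decon_swaps, config$decon_restarts))

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = FALSE)
  writeLines(log_lines, path("run_log.txt"))
  manifest$log <- path("run_log.txt")
  manifest$manifest <- path("manifest.json")
  invisible(manifest)
}
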