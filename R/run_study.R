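#' Run the full co-segregation inflation study on simulated data
#'
#' Chains the whole pipeline: simulate a DH population, curate it with
#' the segregation filter, group markers into linkage groups, build the
#' full and skeleton map of every LG, run the Phase II proportion-level
#' resampling experiment, summarize inflation factors per level, and
#' fit the prediction panel under both partition designs. All
#' randomness derives from `master_seed`. When `out_dir` is given, the
#' genotypes, truth table, maps, cluster reports, records, summaries,
#' prediction results and the resolved configuration (YAML) are written
#' there.
#'
#' @param config a [sim_config()]; its `seed` is overridden by
#'   `master_seed`.
#' @param design an [experiment_design()].
#' @param fn mapping function.
#' @param p_cutoff,max_dist_cM linkage-grouping cutoffs.
#' @param alpha,max_missing segregation-filter settings.
#' @param min_informative minimum informative lines per marker pair.
#' @param master_seed master seed of the study.
#' @param predict_designs partition designs to score.
#' @param correct_dr apply one pass of double-recombinant correction to
#'   each LG after the full map is built, before cluster detection.
#' @param window_cM correction window.
#' @param clusters_from `"detected"` (zero-recombination clusters
#'   estimated from the corrected calls) or `"truth"` (the simulator's
#'   known cluster membership; see [clusters_from_truth()]).
#' @param out_dir optional output directory.
#' @return a list: sim (simulation output), filtered genotypes, groups,
#'   per-LG full maps, clusters and skeletons, records, summary,
#'   predictions.
#' @export
run_study <- function(config = sim_config(),
                      design = experiment_design(),
                      fn = c("kosambi", "haldane"),
                      p_cutoff = 1e-10, max_dist_cM = 15.0,
                      alpha = 0.05, max_missing = 0.10,
                      min_informative = 20, master_seed = 1L,
                      predict_designs = c("holdout_80_20", "cv10x5"),
                      correct_dr = TRUE, window_cM = 10,
                      clusters_from = c("detected", "truth"),
                      out_dir = NULL) {
  fn <- match.arg(fn)
  clusters_from <- match.arg(clusters_from)
  config$seed <- derive_seed(master_seed, "simulate")
  sim <- simulate_dh_population(config)
  filtered <- segregation_filter(sim$geno, alpha, max_missing)
  groups <- group_markers(filtered, p_cutoff, max_dist_cM, fn,
                          min_informative)
  lg_results <- list()
  records <- list()
  for (g in seq_along(groups$groups)) {
    lg_id <- sprintf("LG%02d", g)
    markers <- groups$groups[[g]]
    sub <- filtered[, markers, drop = FALSE]
    pw <- pairwise_linkage(sub, min_informative)
    full_order <- order_markers(sub, markers, min_informative, pw = pw)
    full_map <- build_map(sub, full_order, fn, lg_id, min_informative,
                          pw = pw)
    if (correct_dr) {
      sub <- correct_double_recombinants(sub, full_map, window_cM)
      pw <- pairwise_linkage(sub, min_informative)
      full_order <- order_markers(sub, markers, min_informative, pw = pw)
      full_map <- build_map(sub, full_order, fn, lg_id, min_informative,
                            pw = pw)
    }
    clusters <- if (clusters_from == "truth")
      clusters_from_truth(sim$truth[sim$truth$marker %in% markers, ], sub)
    else find_clusters(sub, markers, min_informative, pw = pw)
    clusters <- select_delegates(clusters,
                                 derive_seed(master_seed, lg_id,
                                             "delegates"))
    skeleton <- build_skeleton(sub, clusters, fn, lg_id, min_informative,
                               pw = pw)
    records[[g]] <- phase2_sampled(sub, clusters, design, fn, lg_id,
                                   master_seed, min_informative, pw = pw)
    lg_results[[lg_id]] <- list(markers = markers, full_map = full_map,
                                clusters = clusters, skeleton = skeleton)
  }
  records <- do.call(rbind, records)
  if (is.null(records) || nrow(records) == 0)
    stop("no sequential-map records produced; no linkage group supports ",
         "the experiment design")
  summary <- summarize_inflation(records)
  dataset <- make_if_dataset(records)
  predictions <- do.call(rbind, lapply(predict_designs, function(d)
    fit_if_models(dataset, d, seed = derive_seed(master_seed, "predict"))))
  result <- list(sim = sim, filtered = filtered, groups = groups,
                 lgs = lg_results, records = records, summary = summary,
                 predictions = predictions)
  if (!is.null(out_dir)) write_study_outputs(result, config, design, fn,
                                             master_seed, out_dir)
  result
}

# Serialize every study artifact plus the resolved configuration so a
# run can be audited and reproduced from its output directory alone.
write_study_outputs <- function(result, config, design, fn, master_seed,
                                out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes_mstmap(result$sim$geno,
                         file.path(out_dir, "genotypes.mstmap.txt"),
                         distance_function = fn)
  write_truth_table(result$sim$truth, file.path(out_dir, "truth.tsv"))
  maps <- do.call(rbind, lapply(result$lgs, `[[`, "full_map"))
  skeletons <- do.call(rbind, lapply(result$lgs, `[[`, "skeleton"))
  write_map(maps, file.path(out_dir, "full_map.tsv"))
  write_map(skeletons, file.path(out_dir, "skeleton_map.tsv"))
  for (lg_id in names(result$lgs))
    write_cluster_report(result$lgs[[lg_id]]$clusters,
                         file.path(out_dir,
                                   paste0("clusters_", lg_id, ".tsv")),
                         lg_id)
  write.table(result$records, file.path(out_dir, "records.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$summary, file.path(out_dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$predictions, file.path(out_dir, "predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- list(master_seed = master_seed, mapping_function = fn,
              n_lines = config$n_lines, n_lg = config$n_lg,
              lg_length_cM = config$lg_length_cM,
              n_unique_loci = config$n_unique_loci,
              coseg_proportion = config$coseg_proportion,
              miscall_rate = config$miscall_rate,
              missing_rate = config$missing_rate,
              levels = design$levels, replicates = design$replicates,
              fallback_levels = design$fallback_levels,
              fallback_replicates = design$fallback_replicates)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
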