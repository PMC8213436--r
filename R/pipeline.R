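# End-to-end pipeline: annotate -> DEG -> counter-regulation -> network ->
# hubs -> filter/select -> enrich, with every threshold carried in one
# config whose defaults are the study parameterization, so a bare run on
# synthetic inputs reproduces the analysis design.

#' Pipeline configuration with the study default thresholds
#'
#' All screening thresholds live here: mass tolerance 5 mDa / 10 ppm,
#' fold-change 2 (|log2FC| >= 1) with p < 0.05, similarity 0.80, QED 0.49,
#' hub-rule median multipliers (2, 1, 1), enrichment top-30 export.
#'
#' @param seed Seed forwarded to the generators when `use_generator` is TRUE.
#' @param full_scale Generator preset at full study sizes.
#' @param use_generator Generate inputs instead of reading them (default
#'   TRUE; set FALSE and fill `paths` to run on files).
#' @param paths Named list of input paths (`library`, `features`, `counts`,
#'   `groups`, `ppi`, `gmt`, `disease_genes`, `predictions`) used when
#'   `use_generator` is FALSE.
#' @param out_dir Output directory for intermediate tables and the report
#'   (NULL: nothing written).
#' @param ... Threshold overrides (`tol_mda`, `tol_ppm`, `lfc_cutoff`,
#'   `p_cutoff`, `min_similarity`, `min_qed`, `degree_mult`,
#'   `betweenness_mult`, `closeness_mult`, `top_sets`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, full_scale = FALSE,
                            use_generator = TRUE, paths = list(),
                            out_dir = NULL, ...) {
  cfg <- list(
    seed = as.integer(seed), full_scale = full_scale,
    use_generator = use_generator, paths = paths, out_dir = out_dir,
    tol_mda = 5, tol_ppm = 10,
    lfc_cutoff = 1, p_cutoff = 0.05,
    min_similarity = 0.80, min_qed = 0.49,
    degree_mult = 2, betweenness_mult = 1, closeness_mult = 1,
    top_sets = 30L
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  num <- c("tol_mda", "tol_ppm", "lfc_cutoff", "p_cutoff", "min_similarity",
           "min_qed", "degree_mult", "betweenness_mult", "closeness_mult")
  stopifnot(all(vapply(cfg[num], function(x)
    is.numeric(x) && length(x) == 1L && x > 0, logical(1))))
  if (!use_generator) {
    need <- c("library", "features", "counts", "groups", "ppi", "gmt",
              "disease_genes", "predictions")
    miss <- setdiff(need, names(paths))
    if (length(miss) > 0L) {
      stop("config missing input path(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    absent <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(absent) > 0L) {
      stop("input file(s) not found: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.pipeline_inputs <- function(cfg) {
  if (cfg$use_generator) {
    gcfg <- generator_config(seed = cfg$seed, full_scale = cfg$full_scale)
    gen_all(gcfg)
  } else {
    p <- cfg$paths
    groups_tbl <- readr::read_csv(p$groups, show_col_types = FALSE)
    list(
      library = read_compound_library(p$library),
      features = read_features(p$features),
      counts = read_counts(p$counts),
      groups = groups_tbl$group,
      ppi = read_edge_list(p$ppi),
      target_map = .read_csv_strict(p$predictions,
                                    c("constituent", "gene", "similarity", "qed"),
                                    c("similarity", "qed")),
      disease_genes = readLines(p$disease_genes),
      anti_genes = NULL,
      collection = read_gmt(p$gmt),
      universe = NULL,
      ground_truth = NULL
    )
  }
}

#' Run the full integrative-pharmacology pipeline
#'
#' Executes, in order: MS feature annotation against the compound library;
#' differential-expression calling for the disease (TNF vs Con) and
#' treatment (TNF_WBT vs TNF) contrasts; counter-regulation screening; the
#' compound-target-disease network build; two-stage median-threshold hub
#' extraction; similarity/QED filtering with dual-median key-constituent
#' selection (content = per-compound MS response); and hypergeometric
#' pathway enrichment of the hub genes. Intermediate tables and a JSON +
#' text report are written to `cfg$out_dir` when set.
#'
#' @param cfg A [pipeline_config()].
#' @return A `run_report` list: per-stage counts, the stage results
#'   themselves (`results`), the config echo and wall time.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  inp <- .pipeline_inputs(cfg)

  ann <- match_features(inp$features, inp$library,
                        tol_mda = cfg$tol_mda, tol_ppm = cfg$tol_ppm)

  deg1 <- call_degs(inp$counts, inp$groups, "Con", "TNF",
                    lfc_cutoff = cfg$lfc_cutoff, p_cutoff = cfg$p_cutoff)
  deg2 <- call_degs(inp$counts, inp$groups, "TNF", "TNF_WBT",
                    lfc_cutoff = cfg$lfc_cutoff, p_cutoff = cfg$p_cutoff)
  counter <- counter_regulated(deg1, deg2)

  anti <- if (length(counter) > 0L) counter else inp$anti_genes
  net <- build_network(anti, inp$target_map, inp$disease_genes, inp$ppi)
  hubs <- extract_hubs(net, ppi = inp$ppi, degree_mult = cfg$degree_mult,
                       betweenness_mult = cfg$betweenness_mult,
                       closeness_mult = cfg$closeness_mult)

  filtered <- filter_predictions(inp$target_map,
                                 min_similarity = cfg$min_similarity,
                                 min_qed = cfg$min_qed)
  info <- inp$library |>
    dplyr::select(constituent = "compound", content = "response", "herb") |>
    dplyr::filter(.data$constituent %in% inp$target_map$constituent)
  scores <- hub_target_frequency(filtered, hubs$hubs, info)
  selection <- select_key_constituents(scores)

  enr <- enrich(hubs$hubs, inp$collection, universe = inp$universe,
                top = cfg$top_sets)

  report <- list(
    counts = list(
      n_features = nrow(inp$features),
      n_annotated_features = length(unique(ann$feature_id)),
      n_annotations = nrow(ann),
      deg_contrast1 = as.list(glance.deg_table(deg1)[, c("n_flagged", "n_up", "n_down")]),
      deg_contrast2 = as.list(glance.deg_table(deg2)[, c("n_flagged", "n_up", "n_down")]),
      n_counter_regulated = length(counter),
      n_network_nodes = igraph::vcount(net),
      n_network_edges = igraph::ecount(net),
      density_stage1 = hubs$stages$density[1],
      n_core = length(hubs$core),
      density_stage2 = if (hubs$stage2_skipped) NA else hubs$stages$density[2],
      n_hubs = length(hubs$hubs),
      n_key_constituents = sum(selection$selected),
      n_enriched_sets = sum(enr$q_value < 0.05)
    ),
    thresholds = cfg[c("tol_mda", "tol_ppm", "lfc_cutoff", "p_cutoff",
                       "min_similarity", "min_qed", "degree_mult",
                       "betweenness_mult", "closeness_mult", "top_sets")],
    seed = cfg$seed,
    version = as.character(utils::packageVersion("herbnet")),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    results = list(annotation = ann, deg1 = deg1, deg2 = deg2,
                   counter = counter, network = net, hubs = hubs,
                   selection = selection, enrichment = enr,
                   ground_truth = inp$ground_truth)
  )
  class(report) <- "run_report"

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(cfg$out_dir, f)
    readr::write_csv(ann, o("annotations.csv"))
    readr::write_csv(tidy.deg_table(deg1), o("deg_TNF_vs_Con.csv"))
    readr::write_csv(tidy.deg_table(deg2), o("deg_TNFWBT_vs_TNF.csv"))
    writeLines(counter, o("counter_regulated_genes.txt"))
    write_graphml(net, o("network.graphml"), hubs$centralities$stage1)
    readr::write_csv(tidy.hub_result(hubs), o("hub_centralities.csv"))
    readr::write_csv(tidy.constituent_selection(selection),
                     o("key_constituents.csv"))
    readr::write_csv(tidy.enrichment_table(enr), o("enrichment.csv"))
    write_json_report(report$counts, o("report.json"))
    utils::capture.output(print(report), file = o("report.txt"))
  }
  report
}

#' @method print run_report
#' @export
print.run_report <- function(x, ...) {
  cnt <- x$counts
  cat("Integrative pharmacology pipeline report\n")
  cat(sprintf("  features annotated: %d / %d (%d candidate annotations)\n",
              cnt$n_annotated_features, cnt$n_features, cnt$n_annotations))
  cat(sprintf("  DEGs TNF vs Con: %d (%d up, %d down)\n",
              cnt$deg_contrast1$n_flagged, cnt$deg_contrast1$n_up,
              cnt$deg_contrast1$n_down))
  cat(sprintf("  DEGs TNF_WBT vs TNF: %d (%d up, %d down)\n",
              cnt$deg_contrast2$n_flagged, cnt$deg_contrast2$n_up,
              cnt$deg_contrast2$n_down))
  cat(sprintf("  counter-regulated genes: %d\n", cnt$n_counter_regulated))
  cat(sprintf("  network: %d nodes, %d edges, density %.3f\n",
              cnt$n_network_nodes, cnt$n_network_edges, cnt$density_stage1))
  cat(sprintf("  core nodes: %d; hub nodes: %d (stage-2 density %.3f)\n",
              cnt$n_core, cnt$n_hubs,
              ifelse(is.na(cnt$density_stage2), NA, cnt$density_stage2)))
  cat(sprintf("  key constituents: %d; enriched sets (q < 0.05): %d\n",
              cnt$n_key_constituents, cnt$n_enriched_sets))
  cat(sprintf("  seed %d, %.1f s\n", x$seed, x$wall_time_s))
  invisible(x)
}
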