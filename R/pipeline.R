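#' Default pipeline configuration
#'
#' One hierarchical list holding every stage's parameters, including each
#' default that fills a gap the upstream protocol leaves open (k-means k and
#' centroid threshold, stage gate, SOM geometry, correlation series, role
#' thresholds), so a run is fully auditable from its config.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    synthetic = list(enabled = TRUE),
    fold_change = list(pseudocount = 1, extreme_tau = 3),
    selection = list(k = 12, centroid_tau = 2.0, min_coverage = 0.6),
    ordination = list(stage_tau = 1, mode = "stage_gated", dims = 2,
                      add_origin = FALSE),
    som = list(shape = c(10, 10), epochs = 100),
    network = list(r_threshold = -0.9, include_baseline = TRUE,
                   z_threshold = 2.5, p_threshold = 0.62)
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package required to read YAML configs")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  utils::modifyList(default_config(), config)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> logFC -> correlate -> select -> ordinate -> som
#' -> network -> recovery and aggregates a machine-readable report. Either
#' supply miRNA/cytokine abundance tables plus references via `data`, or
#' leave `data = NULL` to analyse a synthetic dataset generated under the
#' config's seed (the default), in which case recovery scores against the
#' planted ground truth are included.
#'
#' @param config a config list (see [default_config()]) or a path to a
#'   YAML/JSON config file; partial lists are completed with the defaults.
#' @param data optional list with elements `mirna`, `cytokine`,
#'   `mirna_reference`, `cytokine_reference` (and optionally `truth`).
#' @param out_dir optional directory; when given, intermediate tables (TSV)
#'   and the report (JSON) are written there.
#' @return report list with per-space correlation summaries, the two-factor
#'   ANOVA, selection sizes and Venn counts, ordination coordinates,
#'   per-lineage network results, and recovery scores when ground truth is
#'   available.
#' @export
run_pipeline <- function(config = default_config(), data = NULL, out_dir = NULL) {
  cf <- read_config(if (is.list(config)) config else config)
  if (is.null(data)) {
    sim <- generate_dataset(synthetic_config(seed = cf$seed))
    data <- sim
  }
  truth <- data$truth

  # displacement spaces
  mirna_lfc <- suppressWarnings(compute_logfc(data$mirna, data$mirna_reference))
  cyt_lfc <- log2_concentration(data$cytokine, cf$fold_change$pseudocount)

  # correlation structure of the two spaces
  corr <- lapply(list(miRNA = mirna_lfc, cytokine = cyt_lfc),
                 sample_correlation_matrix)
  summaries <- lapply(corr, within_between_summary)
  anova_cells <- do.call(rbind, lapply(names(summaries), function(sp)
    data.frame(value = c(summaries[[sp]]$within, summaries[[sp]]$between),
               within = rep(c("yes", "no"),
                            c(length(summaries[[sp]]$within),
                              length(summaries[[sp]]$between))),
               space = sp, stringsAsFactors = FALSE)))
  anova_tab <- two_factor_anova(anova_cells$value, anova_cells$within,
                                anova_cells$space,
                                names_ab = c("within/between lineages",
                                             "miRNA/cytokine spaces"))

  # signature selection and overlap
  selection <- kmeans_select(mirna_lfc, k = cf$selection$k,
                             centroid_tau = cf$selection$centroid_tau,
                             min_coverage = cf$selection$min_coverage,
                             seed = cf$seed + 10L)
  venn <- venn_counts(selection)

  # Jaccard ordination of conditions
  pm <- build_presence_matrix(selection, mirna_lfc,
                              stage_tau = cf$ordination$stage_tau,
                              mode = cf$ordination$mode)
  ord <- ordinate_conditions(pm, dims = cf$ordination$dims,
                             add_origin = cf$ordination$add_origin)

  # SOM mosaic of miRNA dynamics
  som <- train_som(mirna_lfc, shape = cf$som$shape, epochs = cf$som$epochs,
                   seed = cf$seed + 20L)

  # per-lineage bipartite networks
  networks <- list()
  for (L in LINEAGES) {
    g <- build_network(mirna_lfc, cyt_lfc, selection$selected[[L]], L,
                       r_threshold = cf$network$r_threshold,
                       cytokine_reference = data$cytokine_reference,
                       pseudocount = cf$fold_change$pseudocount,
                       include_baseline = cf$network$include_baseline)
    part <- girvan_newman(g)
    roles <- node_roles(g, part, cf$network$z_threshold, cf$network$p_threshold)
    networks[[L]] <- list(
      graph = g, partition = part, roles = roles,
      descriptors = descriptors(g),
      betweenness_ranking = node_betweenness_ranking(g),
      central_cytokines = central_cytokines(g, part),
      modularity = part$q
    )
  }

  report <- list(
    seed = cf$seed,
    correlation = lapply(summaries, function(s)
      list(within = as.list(s$within), between = as.list(s$between),
           within_mean = s$within_mean, between_mean = s$between_mean,
           ratio = s$ratio)),
    anova = anova_tab,
    selection = list(sizes = lengths(selection$selected),
                     k = selection$k, venn = as.list(venn)),
    ordination = list(coords = ord$coords,
                      gof = ord$gof,
                      eigenvalues = ord$eigenvalues),
    som = list(shape = som$shape, qe = som$qe),
    networks = lapply(networks, function(x)
      list(modularity = x$modularity,
           n_communities = length(unique(x$partition$membership)),
           descriptors = x$descriptors,
           top_betweenness = head(x$betweenness_ranking, 10),
           high_p = x$roles$node[x$roles$p >= cf$network$p_threshold],
           high_z = x$roles$node[x$roles$z >= cf$network$z_threshold]))
  )

  if (!is.null(truth)) {
    edges_all <- do.call(rbind, lapply(LINEAGES, function(L) {
      g <- networks[[L]]$graph
      if (igraph::ecount(g) == 0) return(NULL)
      e <- igraph::ends(g, igraph::E(g))
      type <- setNames(igraph::V(g)$type, igraph::V(g)$name)
      data.frame(mirna = ifelse(type[e[, 1]] == "miRNA", e[, 1], e[, 2]),
                 cytokine = ifelse(type[e[, 1]] == "miRNA", e[, 2], e[, 1]),
                 lineage = L, stringsAsFactors = FALSE)
    }))
    # module recovery judged on one lineage's network communities
    part_e <- networks$E$partition$membership
    report$recovery <- recovery_report(
      truth,
      signatures = selection$selected,
      edges = edges_all,
      partition = part_e)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(mirna_lfc, file.path(out_dir, "mirna_logfc.tsv"))
    write_table(cyt_lfc, file.path(out_dir, "cytokine_log2.tsv"))
    utils::write.table(pm, file.path(out_dir, "presence_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    jsonlite::write_json(report_for_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  c(report, list(objects = list(
    mirna_logfc = mirna_lfc, cytokine_log2 = cyt_lfc,
    correlations = corr, selection = selection,
    presence = pm, ordination = ord, som = som, networks = networks)))
}

# strip non-serializable pieces for JSON output
report_for_json <- function(report) {
  report$ordination$coords <- as.data.frame(report$ordination$coords)
  report$objects <- NULL
  report
}
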