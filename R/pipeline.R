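#' Assemble and validate a pipeline configuration
#'
#' Defaults mirror the analysis settings of the study design this pipeline
#' models: 10,000 bootstrap iterations, 10,000 ANOVA permutations, K-means
#' K selected over 2-12 by silhouette, 0.05 significance thresholds, 3-state
#' discretization, and a Bayesian network with at most 5 parents per node.
#' Either \code{synthetic} (a [synthetic_config()]) or the input paths
#' (\code{alignments}, \code{catalog}, \code{design}, \code{annotations},
#' \code{phenotype}) must be supplied.
#'
#' @param ... configuration overrides (see Details in [run_pipeline()]).
#' @param yaml optional path to a YAML file whose keys seed the
#'   configuration before \code{...} overrides are applied.
#' @return a validated configuration list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(..., yaml = NULL) {
  cfg <- list(
    synthetic = NULL,
    alignments = NULL, catalog = NULL, design = NULL,
    annotations = NULL, phenotype = NULL,
    host_organism = "host",
    iterations = 10000L, pseudocount = 1,
    alpha_expressed = 0.05, rpkm_threshold = 2, expressed_filter = TRUE,
    n_perm = 10000L, alpha_sde = 0.05, sde_use_fdr = TRUE,
    k_min = 2L, k_max = 12L, n_restarts = 25L,
    alpha_enrich = 0.05,
    n_bins = 2L, max_parents = 5L, bn_restarts = 20L, bn_edge_penalty = 1,
    up_threshold = 0.5,
    sensor_terms = "GO:0048544",
    out_dir = NULL, seed = 1L
  )
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    cfg[names(y)] <- y
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  for (a in c("alpha_expressed", "alpha_sde", "alpha_enrich"))
    if (cfg[[a]] <= 0 || cfg[[a]] >= 1) stopf("%s must be in (0, 1)", a)
  if (is.null(cfg$synthetic)) {
    paths <- unlist(cfg[c("alignments", "catalog", "design",
                          "annotations", "phenotype")])
    if (length(paths) < 5)
      stopf("configuration error: need a synthetic config or all five input paths")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stopf("configuration error: missing input file(s): %s",
            paste(missing, collapse = ", "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full tripartite-community circuit pipeline
#'
#' Executes quantification (bootstrap RPKM, expression significance, quantile
#' normalization), per-organism read attribution and fold enrichment,
#' two-factor permutation ANOVA with FDR control, silhouette-selected K-means
#' clustering with condition profiles and phenotype correlation,
#' hypergeometric annotation enrichment, constrained Bayesian-network
#' learning with transitive pruning, Boolean gate fitting, and the
#' sensor-candidate screen. Every stochastic stage derives its seed from the
#' configuration seed, so a rerun with the same configuration reproduces
#' identical outputs.
#'
#' @param config a [pipeline_config()] (or a list/YAML path accepted by it).
#' @return object of class \code{mhb_pipeline} bundling all stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- pipeline_config(yaml = config)
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)

  inp <- run_stage("input", {
    if (!is.null(config$synthetic)) {
      exp <- generate_experiment(config$synthetic)
      list(alignments = exp$alignments, catalog = exp$catalog,
           design = check_design(exp$design), annotations = exp$annotations,
           phenotype = exp$phenotype, truth = exp$truth)
    } else {
      list(alignments = read_alignment_tsv(config$alignments),
           catalog = read_gene_catalog(config$catalog),
           design = check_design(utils::read.csv(config$design)),
           annotations = read_annotations(config$annotations),
           phenotype = utils::read.csv(config$phenotype),
           truth = NULL)
    }
  })

  expr <- run_stage("quantification", {
    e <- bootstrap_rpkm(inp$alignments, inp$catalog,
                        iterations = config$iterations,
                        seed = derive_seed(config$seed, 1))
    expression_significance(e, alpha = config$alpha_expressed,
                            rpkm_threshold = config$rpkm_threshold)
  })
  normalized <- run_stage("normalization",
                          normalize_matrix(expr, config$pseudocount))

  community <- run_stage("community_stats", {
    fr <- organism_read_fractions(inp$alignments, inp$catalog)
    folds <- list(
      fungus = fold_enrichment_test(fr, inp$design, "fungus",
                                    c("fungus", "both"),
                                    c("baseline", "bacterium")),
      bacterium = fold_enrichment_test(fr, inp$design, "bacterium",
                                       c("bacterium", "both"),
                                       c("baseline", "fungus")),
      bacterium_tripartite = fold_enrichment_test(fr, inp$design, "bacterium",
                                                  "both", "bacterium"))
    root_biomass <- setNames(
      inp$phenotype$root_biomass[match(inp$design$condition,
                                       inp$phenotype$condition)],
      inp$design$sample_id)
    list(fractions = fr, folds = folds,
         bacterium_root_biomass_pcc =
           phenotype_read_correlation(fr, root_biomass, "bacterium"))
  })

  de <- run_stage("differential_expression", {
    host_genes <- inp$catalog$gene_id[inp$catalog$organism == config$host_organism]
    mat <- normalized[rownames(normalized) %in% host_genes, , drop = FALSE]
    if (config$expressed_filter) {
      keep <- tapply(expr$expressed_flag, expr$gene_id, any)
      mat <- mat[keep[rownames(mat)] %in% TRUE, , drop = FALSE]
    }
    res <- permutation_anova2(mat, inp$design, n_perm = config$n_perm,
                              seed = derive_seed(config$seed, 2))
    part <- sde_partition(res, alpha = config$alpha_sde,
                          use_fdr = config$sde_use_fdr)
    list(matrix = mat, anova = res, partition = part)
  })

  clust <- run_stage("clustering", {
    sde_genes <- de$partition$membership$gene_id[de$partition$membership$sde_flag]
    if (length(sde_genes) < config$k_min + 1)
      stopf("only %d SDE genes; too few to cluster", length(sde_genes))
    m <- de$matrix[sde_genes, , drop = FALSE]
    model <- select_k_silhouette(condition_means(m, inp$design),
                                 config$k_min, config$k_max,
                                 seed = derive_seed(config$seed, 3),
                                 n_restarts = config$n_restarts)
    prof <- cluster_profiles(model, m, inp$design)
    pheno <- inp$phenotype$pct_mycorrhization[
      match(colnames(prof), inp$phenotype$condition)]
    r_all <- apply(prof, 1, function(x)
      if (stats::sd(x) == 0) NA_real_ else stats::cor(x, pheno))
    target <- which.max(r_all)
    corr <- if (model$K >= 3)
      profile_phenotype_correlation(prof, pheno, target) else NULL
    list(model = model, profiles = prof, matrix = m,
         mycorrhization_cluster = unname(target), phenotype_correlation = corr)
  })

  enr <- run_stage("enrichment", {
    host_ann <- inp$annotations[
      inp$annotations$gene_id %in%
        inp$catalog$gene_id[inp$catalog$organism == config$host_organism], ]
    enrich_clusters(clust$model, host_ann,
                    background = unique(host_ann$gene_id),
                    alpha = config$alpha_enrich)
  })

  net <- run_stage("network_circuit", {
    tab <- build_node_table(clust$model, clust$matrix, inp$design)
    tab <- discretize_nodes(tab, config$n_bins)
    bn <- learn_structure(tab, max_parents = config$max_parents,
                          n_restarts = config$bn_restarts,
                          edge_penalty = config$bn_edge_penalty,
                          seed = derive_seed(config$seed, 4))
    pruned <- transitive_prune(bn)
    circuit <- fit_gates(pruned, tab, inp$design,
                         up_threshold = config$up_threshold,
                         target_cluster = paste0("cluster_",
                                                 clust$mycorrhization_cluster))
    candidates <- screen_sensor_candidates(circuit, enr, clust$model,
                                           inp$annotations,
                                           sensor_terms = config$sensor_terms)
    list(node_table = tab, bn = bn, pruned = pruned, circuit = circuit,
         candidates = candidates)
  })

  out <- structure(list(
    config = config, input = inp, expression = expr, normalized = normalized,
    community = community, de = de, clustering = clust, enrichment = enr,
    network = net
  ), class = "mhb_pipeline")
  if (!is.null(config$out_dir)) run_stage("write_outputs",
                                          write_pipeline_outputs(out))
  out
}

write_pipeline_outputs <- function(x) {
  dir <- x$config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_tsv(x$expression, x$normalized, file.path(dir, "expression"))
  utils::write.table(x$de$anova, file.path(dir, "anova.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(venn = as.list(x$de$partition$venn),
                            n_sde = x$de$partition$n_sde),
                       file.path(dir, "venn.json"), auto_unbox = TRUE)
  write_cluster_tsv(x$clustering$model, x$clustering$profiles, dir)
  utils::write.table(as.data.frame(x$enrichment),
                     file.path(dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(nodes = x$network$bn$nodes,
                            edges = x$network$pruned$edges,
                            score = x$network$bn$score),
                       file.path(dir, "network.json"), auto_unbox = TRUE,
                       digits = NA)
  write_circuit_dot(x$network$circuit, file.path(dir, "circuit.dot"))
  utils::write.table(x$network$candidates,
                     file.path(dir, "sensor_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$community$fractions,
                     file.path(dir, "read_fractions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.mhb_pipeline <- function(x, ...) {
  cat("Tripartite-community regulatory-circuit pipeline\n")
  cat(sprintf("  samples: %d   catalog genes: %d\n",
              nrow(x$input$design), nrow(x$input$catalog)))
  cat(sprintf("  SDE genes: %d   clusters (K): %d\n",
              x$de$partition$n_sde, x$clustering$model$K))
  if (!is.null(x$clustering$phenotype_correlation)) {
    pc <- x$clustering$phenotype_correlation
    cat(sprintf("  mycorrhization cluster: %d (PCC %.2f, z %.2f, p %.4f)\n",
                pc$target_cluster, pc$r[pc$target_cluster], pc$z, pc$p))
  }
  g <- x$network$circuit$gates[[paste0("cluster_",
                                       x$clustering$mycorrhization_cluster)]]
  xor_gates <- vapply(x$network$circuit$gates,
                      function(g) identical(g$gate, "XOR"), logical(1))
  if (any(xor_gates))
    cat("  XOR-gated cluster node(s):",
        paste(names(xor_gates)[xor_gates], collapse = ", "), "\n")
  cat(sprintf("  sensor candidates: %d gene(s)\n", nrow(x$network$candidates)))
  invisible(x)
}

#' @export
summary.mhb_pipeline <- function(object, ...) {
  x <- object
  print(x)
  cat("\nVenn partition of SDE genes (F=fungus, B=bacterium, I=interaction):\n")
  print(x$de$partition$venn)
  cat("\nCluster profiles (mean log2 FC vs baseline):\n")
  print(round(x$clustering$profiles, 2))
  cat("\nRead-attribution folds:\n")
  f <- x$community$folds
  cat(sprintf("  fungus present/absent: %.2f (p %.3f)\n", f$fungus$fold,
              f$fungus$p))
  cat(sprintf("  bacterium present/absent: %.2f (p %.3f)\n", f$bacterium$fold,
              f$bacterium$p))
  cat(sprintf("  bacterium tripartite/alone: %.2f (p %.3f)\n",
              f$bacterium_tripartite$fold, f$bacterium_tripartite$p))
  cat("\n")
  print(x$network$circuit)
  invisible(x)
}

#' @export
plot.mhb_pipeline <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  prof <- x$clustering$profiles
  graphics::barplot(t(prof), beside = TRUE, las = 2,
                    legend.text = colnames(prof),
                    args.legend = list(x = "topright", cex = 0.7, bty = "n"),
                    ylab = "mean log2 FC vs baseline",
                    main = "Cluster condition profiles")
  sil <- x$clustering$model$silhouette_by_k
  graphics::plot(as.integer(names(sil)), sil, type = "b", pch = 19,
                 xlab = "K", ylab = "mean silhouette",
                 main = "Silhouette model selection")
  graphics::abline(v = x$clustering$model$K, lty = 2)
  invisible(x)
}
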