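#' Preset condition-response pattern matrices
#'
#' Returns a matrix of planted log2 fold-changes (relative to the host-only
#' baseline) with one row per planted co-regulation cluster and one column per
#' community condition, in the canonical order \code{baseline, fungus,
#' bacterium, both}. The \code{"fig3-like"} preset mimics the six cluster
#' shapes observed in tripartite aspen-root communities: a cluster repressed in
#' every co-culture (most strongly by the fungus alone), a
#' mycorrhization-tracking cluster, two bacterium-tracking clusters (one down,
#' one up), an antifungal-defense-like cluster induced by the fungus alone, and
#' one cluster induced when exactly one symbiont is present (the XOR pattern).
#'
#' @param preset_name one of \code{"fig3-like"}, \code{"xor-only"},
#'   \code{"null"}.
#' @param effect log2 fold-change magnitude used by \code{"xor-only"}.
#' @return numeric matrix, clusters x conditions, with a baseline column of
#'   zeros and an \code{"xor_cluster"} attribute giving the row index of the
#'   XOR-patterned cluster (or \code{NA} if none).
#' @export
expression_pattern_matrix <- function(preset_name, effect = 2) {
  cn <- condition_levels()
  m <- switch(preset_name,
    "fig3-like" = {
      p <- rbind(
        c(0, -2.5, -0.8, -1.2),  # repressed in all co-cultures
        c(0,  0.6, -1.2,  2.4),  # tracks mycorrhization
        c(0,  0.0, -2.0, -2.0),  # down whenever bacterium present
        c(0,  2.2, -0.2, -1.8),  # antifungal-defense-like: fungus alone, attenuated by the helper
        c(0,  2.0,  2.0,  0.0),  # XOR: up iff exactly one symbiont
        c(0, -1.2,  1.8,  1.8)   # up with bacterium, down with fungus alone
      )
      attr(p, "xor_cluster") <- 5L
      p
    },
    "xor-only" = {
      p <- matrix(c(0, effect, effect, 0), nrow = 1)
      attr(p, "xor_cluster") <- 1L
      p
    },
    "null" = {
      p <- matrix(0, nrow = 1, ncol = 4)
      attr(p, "xor_cluster") <- NA_integer_
      p
    },
    stopf("unknown pattern preset '%s'", preset_name)
  )
  dimnames(m) <- list(paste0("cluster_", seq_len(nrow(m))), cn)
  m
}

#' Configuration for a synthetic tripartite-community experiment
#'
#' Bundles and validates every knob of the generator. Defaults emulate the
#' study conditions of a 2x2 (fungus x bacterium presence) factorial design
#' with 3 replicate root transcriptomes per condition, a heavily host-dominated
#' read pool, and six planted co-regulation clusters including one XOR-gated
#' cluster carrying a uniquely enriched sensor annotation.
#'
#' @param n_genes named integer vector: genes per organism
#'   (\code{host}, \code{fungus}, \code{bacterium}).
#' @param gene_length_range gene length interval in bp.
#' @param n_replicates replicates per condition.
#' @param pattern planted log2 fold-change matrix (clusters x 4 conditions,
#'   baseline column all zero), e.g. from [expression_pattern_matrix()]. Its
#'   \code{"xor_cluster"} attribute flags at most one XOR-patterned row.
#' @param genes_per_cluster host genes planted per cluster.
#' @param multimap_fraction fraction of reads receiving 1-3 decoy alignments.
#' @param cross_organism_decoy_prob per-decoy probability that the decoy gene
#'   is drawn from a different organism than the read's true origin
#'   (emulating the rare cross-organism ambiguity of 50-bp reads).
#' @param noise_sd log-scale SD of the lognormal replicate noise on expected
#'   counts.
#' @param library_size reads per sample.
#' @param fungus_share,bacterium_share_alone,bacterium_share_both fraction of
#'   a sample's reads truly originating from the symbiont when it is present
#'   (bacterial load is higher in the tripartite condition); the host
#'   contributes the remainder, so host attribution stays above 98\%.
#' @param enrichment_plan data.frame (\code{cluster}, \code{term},
#'   \code{fraction}): per planted cluster, the GO term planted on that
#'   fraction of its genes. \code{NULL} gives one term per cluster at 0.4.
#' @param sensor_term,sensor_genes annotation planted on exactly
#'   \code{sensor_genes} genes of the XOR cluster (skipped if no XOR row).
#' @param n_background_terms,background_rate size of the background GO
#'   vocabulary and the per-gene Poisson mean of background annotations.
#' @param phenotype_plan data.frame (\code{condition},
#'   \code{pct_mycorrhization}, \code{shoot_biomass}, \code{root_biomass});
#'   \code{NULL} gives the default: mycorrhization 0 without the fungus and
#'   1.7x higher with helper bacteria present, flat biomass.
#' @param poisson_counts draw read counts Poisson around expectations
#'   (\code{TRUE}) or round them deterministically (\code{FALSE}).
#' @param seed RNG seed.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_genes = c(host = 2000L, fungus = 300L, bacterium = 150L),
                             gene_length_range = c(300L, 3000L),
                             n_replicates = 3L,
                             pattern = expression_pattern_matrix("fig3-like"),
                             genes_per_cluster = 60L,
                             multimap_fraction = 0.05,
                             cross_organism_decoy_prob = 0.015,
                             noise_sd = 0.25,
                             library_size = 1e5,
                             fungus_share = 0.0135,
                             bacterium_share_alone = 5e-4,
                             bacterium_share_both = 1.75e-3,
                             enrichment_plan = NULL,
                             sensor_term = "GO:0048544",
                             sensor_genes = 8L,
                             n_background_terms = 60L,
                             background_rate = 1.2,
                             phenotype_plan = NULL,
                             poisson_counts = TRUE,
                             seed = 1L) {
  if (!all(c("host", "fungus", "bacterium") %in% names(n_genes)))
    stopf("n_genes must be named host/fungus/bacterium")
  if (library_size <= 0) stopf("library_size must be positive")
  if (multimap_fraction < 0 || multimap_fraction > 1)
    stopf("multimap_fraction must be in [0, 1]")
  if (!is.matrix(pattern) || ncol(pattern) != 4)
    stopf("pattern must be a clusters x 4-condition matrix")
  if (any(pattern[, 1] != 0))
    stopf("pattern baseline column must be identically zero")
  xc <- attr(pattern, "xor_cluster") %||% NA_integer_
  if (length(xc) > 1) stopf("at most one planted cluster may be flagged XOR")
  n_clusters <- nrow(pattern)
  if (n_clusters * genes_per_cluster > n_genes[["host"]])
    stopf("planted clusters exceed the host gene count")
  if (is.null(enrichment_plan)) {
    enrichment_plan <- data.frame(
      cluster = seq_len(n_clusters),
      term = sprintf("GO:%07d", 7100000L + seq_len(n_clusters)),
      fraction = 0.4,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(phenotype_plan)) {
    phenotype_plan <- data.frame(
      condition = condition_levels(),
      pct_mycorrhization = c(0, 25, 0, 42.5),
      shoot_biomass = c(1.21, 1.18, 1.25, 1.22),
      root_biomass = c(0.82, 0.80, 0.85, 0.78),
      stringsAsFactors = FALSE
    )
  }
  if (any(phenotype_plan$pct_mycorrhization[phenotype_plan$condition %in%
                                            c("baseline", "bacterium")] != 0))
    stopf("percent mycorrhization must be 0 in fungus-absent conditions")
  structure(list(
    n_genes = n_genes, gene_length_range = gene_length_range,
    n_replicates = as.integer(n_replicates), pattern = pattern,
    genes_per_cluster = as.integer(genes_per_cluster),
    multimap_fraction = multimap_fraction,
    cross_organism_decoy_prob = cross_organism_decoy_prob,
    noise_sd = noise_sd, library_size = library_size,
    fungus_share = fungus_share,
    bacterium_share_alone = bacterium_share_alone,
    bacterium_share_both = bacterium_share_both,
    enrichment_plan = enrichment_plan,
    sensor_term = sensor_term, sensor_genes = as.integer(sensor_genes),
    n_background_terms = as.integer(n_background_terms),
    background_rate = background_rate,
    phenotype_plan = phenotype_plan,
    poisson_counts = isTRUE(poisson_counts), seed = seed
  ), class = "synthetic_config")
}

#' Generate a complete synthetic tripartite-community experiment
#'
#' Simulates per-sample read-to-gene alignment tables for a 2x2 factorial
#' community design with known ground truth. Expected read counts per gene are
#' proportional to gene length x a log-uniform baseline abundance x
#' 2^(planted log2 fold-change) x lognormal replicate noise, scaled within each
#' organism to that organism's read share in the sample's condition (absent
#' organisms contribute no true reads; their residual attribution arises only
#' from cross-organism decoy alignments). A configurable fraction of reads
#' receives 1-3 decoy alignments, emulating multi-mapping of short reads.
#'
#' @param config a [synthetic_config()].
#' @return list of class \code{mhb_experiment} with elements
#'   \code{alignments} (data.frame: \code{read_id}, \code{gene_id},
#'   \code{sample_id}; one row per alignment), \code{catalog} (gene_id,
#'   organism, length_bp), \code{design}, \code{annotations} (gene_id, term),
#'   \code{phenotype}, and \code{truth} (planted cluster labels, pattern,
#'   XOR cluster id, enrichment plan, per-read true origin).
#' @export
generate_experiment <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stopf("config must be built with synthetic_config()")
  with_seed(config$seed, generate_experiment_impl(config))
}

generate_experiment_impl <- function(cfg) {
  orgs <- c("host", "fungus", "bacterium")
  n <- vapply(orgs, function(o) as.integer(cfg$n_genes[[o]]), integer(1))
  ids <- list(
    host = sprintf("ASP_%05d", seq_len(n[["host"]])),
    fungus = sprintf("LAC_%05d", seq_len(n[["fungus"]])),
    bacterium = sprintf("PSE_%05d", seq_len(n[["bacterium"]]))
  )
  catalog <- data.frame(
    gene_id = unlist(ids, use.names = FALSE),
    organism = rep(orgs, n),
    length_bp = sample(cfg$gene_length_range[1]:cfg$gene_length_range[2],
                       sum(n), replace = TRUE),
    stringsAsFactors = FALSE
  )

  abund <- lapply(orgs, function(o) 10^stats::runif(n[[o]], 0, 3))
  names(abund) <- orgs

  # planted clusters over host genes; label 0 marks unregulated (null) genes.
  # Regulated genes are drawn from above the 30th abundance percentile so the
  # planted truth sits above the sampling-noise detection floor and recovery
  # metrics measure the pipeline rather than sequencing depth.
  n_clusters <- nrow(cfg$pattern)
  eligible <- ids$host[abund$host > stats::quantile(abund$host, 0.3)]
  planted <- sample(eligible, n_clusters * cfg$genes_per_cluster)
  gene_cluster <- setNames(rep(0L, n[["host"]]), ids$host)
  gene_cluster[planted] <- rep(seq_len(n_clusters), each = cfg$genes_per_cluster)

  design <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        condition = condition_levels(),
                        stringsAsFactors = FALSE)
  design$fungus <- as.integer(design$condition %in% c("fungus", "both"))
  design$bacterium <- as.integer(design$condition %in% c("bacterium", "both"))
  design$sample_id <- sprintf("%s_r%d", design$condition, design$replicate)
  design <- design[, c("sample_id", "fungus", "bacterium", "replicate", "condition")]

  len_by_org <- split(catalog$length_bp, factor(catalog$organism, levels = orgs))

  org_share <- function(cond) {
    f <- if (cond %in% c("fungus", "both")) cfg$fungus_share else 0
    b <- if (cond == "both") cfg$bacterium_share_both
         else if (cond == "bacterium") cfg$bacterium_share_alone else 0
    if (n[["fungus"]] == 0) f <- 0      # organisms without catalog genes
    if (n[["bacterium"]] == 0) b <- 0   # cannot absorb read share
    c(host = 1 - f - b, fungus = f, bacterium = b)
  }

  aln <- vector("list", nrow(design))
  origin <- vector("list", nrow(design))
  gene_pool_idx <- split(seq_len(nrow(catalog)),
                         factor(catalog$organism, levels = orgs))
  host_cluster_idx <- gene_cluster  # aligned with ids$host

  for (s in seq_len(nrow(design))) {
    cond <- design$condition[s]
    shares <- org_share(cond)
    counts <- integer(nrow(catalog))
    off <- 0L
    for (o in orgs) {
      w <- abund[[o]] * len_by_org[[o]]
      if (o == "host") {
        fc <- rep(0, n[["host"]])
        reg <- host_cluster_idx > 0
        fc[reg] <- cfg$pattern[host_cluster_idx[reg], cond]
        w <- w * 2^fc
      }
      if (cfg$noise_sd > 0 && length(w))
        w <- w * stats::rlnorm(length(w), 0, cfg$noise_sd)
      mu <- if (shares[[o]] > 0 && sum(w) > 0)
        cfg$library_size * shares[[o]] * w / sum(w) else rep(0, length(w))
      cnt <- if (cfg$poisson_counts) stats::rpois(length(mu), mu) else round(mu)
      counts[off + seq_along(cnt)] <- as.integer(cnt)
      off <- off + length(cnt)
    }
    n_reads <- sum(counts)
    true_gene <- rep.int(seq_len(nrow(catalog)), counts)
    read_id <- sprintf("%s_R%06d", design$sample_id[s], seq_len(n_reads))

    pairs_r <- seq_len(n_reads)
    pairs_g <- true_gene
    if (cfg$multimap_fraction > 0 && n_reads > 0) {
      n_mm <- floor(cfg$multimap_fraction * n_reads)
      mm <- sample.int(n_reads, n_mm)
      nd <- sample(1:3, n_mm, replace = TRUE)
      dr <- rep.int(mm, nd)                       # read index per decoy
      d_true_org <- catalog$organism[true_gene[dr]]
      cross <- stats::runif(length(dr)) < cfg$cross_organism_decoy_prob
      d_org <- d_true_org
      if (any(cross)) {
        pick_other <- function(o) {
          others <- setdiff(orgs, o)
          others[sample.int(length(others), 1L)]
        }
        d_org[cross] <- vapply(d_true_org[cross], pick_other, character(1))
      }
      d_gene <- integer(length(dr))
      for (o in orgs) {
        sel <- d_org == o
        if (any(sel)) {
          pool <- gene_pool_idx[[o]]
          d_gene[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
        }
      }
      keep <- d_gene != true_gene[dr]
      pairs_r <- c(pairs_r, dr[keep])
      pairs_g <- c(pairs_g, d_gene[keep])
      dup <- duplicated(cbind(pairs_r, pairs_g))
      pairs_r <- pairs_r[!dup]; pairs_g <- pairs_g[!dup]
    }
    ord <- order(pairs_r, pairs_g)
    aln[[s]] <- data.frame(read_id = read_id[pairs_r[ord]],
                           gene_id = catalog$gene_id[pairs_g[ord]],
                           sample_id = design$sample_id[s],
                           stringsAsFactors = FALSE)
    origin[[s]] <- data.frame(read_id = read_id, sample_id = design$sample_id[s],
                              gene_id = catalog$gene_id[true_gene],
                              stringsAsFactors = FALSE)
  }

  annotations <- synth_annotations(cfg, ids$host, gene_cluster)

  truth <- list(
    gene_cluster = gene_cluster,
    pattern = cfg$pattern,
    xor_cluster = attr(cfg$pattern, "xor_cluster") %||% NA_integer_,
    enrichment_plan = cfg$enrichment_plan,
    sensor_term = cfg$sensor_term,
    sensor_genes = attr(annotations, "sensor_genes"),
    phenotype = cfg$phenotype_plan,
    read_origin = do.call(rbind, origin)
  )

  structure(list(
    alignments = do.call(rbind, aln),
    catalog = catalog,
    design = design,
    annotations = annotations,
    phenotype = cfg$phenotype_plan,
    truth = truth,
    config = cfg
  ), class = "mhb_experiment")
}

# Background vocabulary + planted per-cluster enrichments + the sensor term.
synth_annotations <- function(cfg, host_ids, gene_cluster) {
  vocab <- sprintf("GO:%07d", 7000000L + seq_len(cfg$n_background_terms))
  n_bg <- stats::rpois(length(host_ids), cfg$background_rate)
  gene <- rep(host_ids, n_bg)
  term <- vocab[sample.int(length(vocab), sum(n_bg), replace = TRUE)]

  for (i in seq_len(nrow(cfg$enrichment_plan))) {
    cl <- cfg$enrichment_plan$cluster[i]
    tm <- cfg$enrichment_plan$term[i]
    members <- names(gene_cluster)[gene_cluster == cl]
    n_in <- max(1L, round(cfg$enrichment_plan$fraction[i] * length(members)))
    hit <- sample(members, n_in)
    # sprinkle the term into the background so K_bg > k
    out <- names(gene_cluster)[gene_cluster != cl]
    hit_bg <- sample(out, max(1L, round(0.01 * length(out))))
    gene <- c(gene, hit, hit_bg)
    term <- c(term, rep(tm, length(hit) + length(hit_bg)))
  }

  sensor_genes <- character(0)
  xc <- attr(cfg$pattern, "xor_cluster") %||% NA_integer_
  if (!is.na(xc) && cfg$sensor_genes > 0) {
    members <- names(gene_cluster)[gene_cluster == xc]
    sensor_genes <- sample(members, min(cfg$sensor_genes, length(members)))
    out <- names(gene_cluster)[gene_cluster != xc]
    bg_hit <- sample(out, max(1L, round(0.003 * length(out))))
    gene <- c(gene, sensor_genes, bg_hit)
    term <- c(term, rep(cfg$sensor_term, length(sensor_genes) + length(bg_hit)))
  }

  ann <- unique(data.frame(gene_id = gene, term = term, stringsAsFactors = FALSE))
  ann <- ann[order(ann$gene_id, ann$term), ]
  rownames(ann) <- NULL
  attr(ann, "sensor_genes") <- sort(sensor_genes)
  ann
}

#' Write a synthetic experiment to plain-text fixture files
#'
#' Writes the alignment TSV dialect (\code{read_id, gene_id, sample_id}),
#' gene catalog TSV, design CSV, annotation TSV, phenotype CSV, and the
#' ground truth as JSON into \code{dir}.
#'
#' @param experiment an [generate_experiment()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of paths written.
#' @export
write_experiment <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- file.path(dir, c("alignments.tsv", "catalog.tsv", "design.csv",
                        "annotations.tsv", "phenotype.csv", "truth.json"))
  utils::write.table(experiment$alignments, p[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(experiment$catalog, p[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(experiment$design, p[3], row.names = FALSE, quote = FALSE)
  utils::write.table(experiment$annotations, p[4], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(experiment$phenotype, p[5], row.names = FALSE, quote = FALSE)
  tr <- experiment$truth
  jsonlite::write_json(list(
    gene_cluster = as.list(tr$gene_cluster),
    pattern = tr$pattern, xor_cluster = tr$xor_cluster,
    sensor_term = tr$sensor_term, sensor_genes = tr$sensor_genes
  ), p[6], auto_unbox = TRUE, digits = NA)
  invisible(p)
}
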