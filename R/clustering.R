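#' K-means clustering of co-regulated genes
#'
#' Clusters gene row-vectors (samples as dimensions) with K-means on
#' Euclidean distances, K-means++ seeding, and the best of \code{n_restarts}
#' runs by within-cluster sum of squares. Rows are mean-centered by default
#' so distance reflects the shape of the condition response rather than
#' absolute expression; full z-scoring is available via \code{scale_rows}.
#' A restart whose converged solution would leave a cluster empty is
#' re-seeded from fresh K-means++ centers.
#'
#' @param matrix genes x samples matrix restricted to the genes of interest.
#' @param K number of clusters (>= 2, <= number of genes).
#' @param seed RNG seed.
#' @param n_restarts random restarts (default 25).
#' @param center_rows,scale_rows feature-space preprocessing flags.
#' @return list with \code{assignment} (named integer vector),
#'   \code{centroids} (K x samples), \code{wcss}, \code{K}, and the
#'   preprocessed \code{features} matrix.
#' @export
kmeans_fit <- function(matrix, K, seed = 1L, n_restarts = 25L,
                       center_rows = TRUE, scale_rows = FALSE) {
  if (K < 2) stopf("K must be >= 2")
  if (nrow(matrix) < K) stopf("need at least K genes to form K clusters")
  X <- prep_features(matrix, center_rows, scale_rows)
  if (nrow(X) == K) {   # every gene its own cluster
    return(list(assignment = setNames(seq_len(K), rownames(X)),
                centroids = unname(X), wcss = 0, K = K, features = X))
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- NULL
      for (try in 1:5) {
        centers <- X[kmeanspp_seed(X, K), , drop = FALSE]
        fit <- tryCatch(
          stats::kmeans(X, centers = centers, iter.max = 100L),
          error = function(e) NULL)
        if (!is.null(fit) && length(unique(fit$cluster)) == K) break
        fit <- NULL
      }
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stopf("K-means failed to produce %d non-empty clusters", K)
    list(assignment = setNames(best$cluster, rownames(X)),
         centroids = best$centers, wcss = best$tot.withinss, K = K,
         features = X)
  })
}

prep_features <- function(matrix, center_rows, scale_rows) {
  X <- as.matrix(matrix)
  if (center_rows || scale_rows) X <- X - rowMeans(X)
  if (scale_rows) {
    s <- sqrt(rowSums(X^2) / max(1, ncol(X) - 1))
    X <- X / ifelse(s > 0, s, 1)
  }
  X
}

# K-means++ seeding: spread initial centers by squared-distance weighting.
kmeanspp_seed <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums((X - X[rep(idx[1], n), , drop = FALSE])^2)
  for (k in seq_len(K - 1L)) {
    if (all(d2 == 0)) idx[k + 1L] <- sample.int(n, 1L)
    else idx[k + 1L] <- sample.int(n, 1L, prob = d2)
    d2 <- pmin(d2, rowSums((X - X[rep(idx[k + 1L], n), , drop = FALSE])^2))
  }
  idx
}

#' Per-condition replicate-mean expression matrix
#'
#' Averages each gene's expression over the replicates of every condition.
#' Replicate averaging cancels per-sample measurement noise, which otherwise
#' dominates gene-gene distances and blurs co-regulation structure.
#'
#' @param matrix genes x samples matrix.
#' @param design study design data.frame.
#' @return genes x conditions matrix (canonical condition order).
#' @export
condition_means <- function(matrix, design) {
  design <- check_design(design)
  out <- vapply(condition_levels(), function(cn) {
    rowMeans(matrix[, design$sample_id[design$condition == cn], drop = FALSE])
  }, numeric(nrow(matrix)))
  rownames(out) <- rownames(matrix)
  out
}

#' Silhouette-based selection of the number of clusters
#'
#' Fits K-means for each K in \code{[k_min, k_max]}, computes the mean
#' silhouette coefficient over genes (Euclidean distances), and returns the
#' model at the silhouette maximum, breaking ties toward smaller K.
#'
#' @inheritParams kmeans_fit
#' @param k_min,k_max candidate range (default 2 to 12; truncated with a
#'   warning when \code{k_max} reaches the number of genes).
#' @return object of class \code{cluster_model}: the selected fit plus
#'   \code{silhouette_by_k}.
#' @export
select_k_silhouette <- function(matrix, k_min = 2L, k_max = 12L, seed = 1L,
                                n_restarts = 25L, center_rows = TRUE,
                                scale_rows = FALSE) {
  if (k_min < 2) stopf("k_min must be >= 2")
  if (k_max < k_min) stopf("k_max must be >= k_min")
  if (k_max >= nrow(matrix)) {
    warning("k_max reaches the number of genes; truncating")
    k_max <- nrow(matrix) - 1L
  }
  X <- prep_features(matrix, center_rows, scale_rows)
  D <- stats::dist(X)
  ks <- k_min:k_max
  fits <- vector("list", length(ks))
  sil <- setNames(numeric(length(ks)), ks)
  for (i in seq_along(ks)) {
    fits[[i]] <- kmeans_fit(matrix, ks[i], seed = derive_seed(seed, ks[i]),
                            n_restarts = n_restarts,
                            center_rows = center_rows, scale_rows = scale_rows)
    sw <- cluster::silhouette(fits[[i]]$assignment, D)
    sil[i] <- mean(sw[, "sil_width"])
  }
  best <- which(sil == max(sil))[1]  # ties toward smaller K
  model <- fits[[best]]
  model$silhouette_by_k <- sil
  class(model) <- "cluster_model"
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("K-means co-regulation model\n")
  cat(sprintf("  genes: %d   K: %d   mean silhouette: %.3f\n",
              length(x$assignment), x$K,
              x$silhouette_by_k[as.character(x$K)]))
  cat("  cluster sizes:", paste(table(x$assignment), collapse = ", "), "\n")
  invisible(x)
}

#' Per-condition cluster expression profiles
#'
#' For every cluster and condition, the mean over member genes and replicates
#' of the gene's log2 expression minus its mean log2 expression in the
#' baseline (host-only) condition. The baseline column is identically zero.
#'
#' @param model a [select_k_silhouette()] or [kmeans_fit()] result.
#' @param matrix the normalized log2 expression matrix the model was fit on.
#' @param design study design data.frame.
#' @param baseline baseline condition name (default \code{"baseline"}).
#' @return clusters x conditions numeric matrix of mean log2 fold-changes.
#' @export
cluster_profiles <- function(model, matrix, design, baseline = "baseline") {
  design <- check_design(design)
  genes <- names(model$assignment)
  Y <- matrix[genes, design$sample_id, drop = FALSE]
  base_mean <- rowMeans(Y[, design$condition == baseline, drop = FALSE])
  dev <- Y - base_mean
  conds <- condition_levels()
  prof <- matrix(0, model$K, length(conds),
                 dimnames = list(paste0("cluster_", seq_len(model$K)), conds))
  for (k in seq_len(model$K)) {
    members <- model$assignment == k
    for (cn in conds)
      prof[k, cn] <- mean(dev[members, design$condition == cn])
  }
  prof
}

#' Correlation of cluster profiles with a condition-level phenotype
#'
#' Pearson correlation between each cluster's per-condition profile and the
#' phenotype vector; the target cluster's correlation is standardized against
#' the other clusters' correlations, \eqn{z = (r_t - \bar r_{others}) /
#' sd(r_{others})}, with a one-tailed upper normal p-value. Zero-variance
#' profiles or phenotypes give an undefined (NA) correlation and are excluded
#' from the reference set.
#'
#' @param profiles clusters x conditions matrix from [cluster_profiles()].
#' @param phenotype numeric vector over the same conditions (e.g. percent
#'   mycorrhization).
#' @param target_cluster row index of the cluster under test.
#' @return list with \code{r} (per-cluster correlations), \code{z}, \code{p},
#'   \code{target_cluster}.
#' @export
profile_phenotype_correlation <- function(profiles, phenotype, target_cluster) {
  if (nrow(profiles) < 3)
    stopf("need >= 3 clusters to form a reference distribution")
  if (length(phenotype) != ncol(profiles))
    stopf("phenotype must cover the same conditions as the profiles")
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  r <- apply(profiles, 1, safe_cor, b = phenotype)
  others <- r[-target_cluster]
  sig <- correlation_significance(r[[target_cluster]], others)
  c(list(r = r), sig, list(target_cluster = target_cluster))
}

#' Normal-distribution significance of a correlation against a reference set
#'
#' Standardizes a target correlation against the mean and SD of a reference
#' set of correlations, \eqn{z = (r_t - \bar r)/sd(r)}, and returns the
#' one-tailed upper normal probability.
#'
#' @param r_target the target correlation.
#' @param reference_r correlations of the reference set (NAs dropped).
#' @return list with \code{z} and \code{p}.
#' @export
correlation_significance <- function(r_target, reference_r) {
  reference_r <- reference_r[!is.na(reference_r)]
  if (length(reference_r) < 2)
    stopf("need >= 2 reference correlations")
  z <- (r_target - mean(reference_r)) / stats::sd(reference_r)
  list(z = unname(z), p = unname(stats::pnorm(z, lower.tail = FALSE)))
}

#' Write clustering outputs as plain-text tables
#'
#' @param model a \code{cluster_model}.
#' @param profiles matching [cluster_profiles()] matrix.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_cluster_tsv <- function(model, profiles, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- file.path(dir, c("cluster_assignment.tsv", "cluster_profiles.tsv",
                        "silhouette_by_k.tsv"))
  utils::write.table(data.frame(gene_id = names(model$assignment),
                                cluster = unname(model$assignment)),
                     p[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cluster = rownames(profiles), profiles),
                     p[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(K = names(model$silhouette_by_k),
                                mean_silhouette = unname(model$silhouette_by_k)),
                     p[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(p)
}
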