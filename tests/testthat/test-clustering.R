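test_that("K-means recovers separated structure and degenerate K", {
  set.seed(1)
  X <- rbind(matrix(stats::rnorm(20 * 4, mean = 0), 20, 4),
             matrix(stats::rnorm(20 * 4, mean = 8), 20, 4))
  rownames(X) <- sprintf("g%02d", 1:40)
  f <- kmeans_fit(X, 2, seed = 1, n_restarts = 5, center_rows = FALSE)
  expect_equal(length(unique(f$assignment[1:20])), 1)
  expect_equal(length(unique(f$assignment[21:40])), 1)
  expect_false(f$assignment[1] == f$assignment[21])

  fK <- kmeans_fit(X[1:8, ], 8, seed = 1, n_restarts = 3, center_rows = FALSE)
  expect_equal(fK$wcss, 0)
  expect_equal(as.vector(table(fK$assignment)), rep(1L, 8))

  expect_error(kmeans_fit(X, 1), "K must be")
  expect_error(kmeans_fit(X[1:3, ], 5), "at least K genes")
})

test_that("planted six-pattern clusters are recovered with high ARI across seeds", {
  pattern <- expression_pattern_matrix("fig3-like")
  for (s in 1:10) {
    d <- pattern_matrix_data(pattern, genes_per_cluster = 30,
                             noise_sd = 0.25, seed = s)
    cm <- condition_means(d$matrix, d$design)
    f <- kmeans_fit(cm, 6, seed = s, n_restarts = 10)
    expect_gte(ari(f$assignment, d$truth), 0.95)
  }
})

test_that("silhouette selection finds the planted K and breaks ties downward", {
  set.seed(2)
  X <- rbind(matrix(stats::rnorm(15 * 4), 15, 4),
             matrix(stats::rnorm(15 * 4, mean = 10), 15, 4))
  rownames(X) <- sprintf("g%02d", 1:30)
  m <- select_k_silhouette(X, 2, 8, seed = 1, n_restarts = 5,
                           center_rows = FALSE)
  expect_equal(m$K, 2)
  expect_equal(names(which.max(m$silhouette_by_k)), "2")

  pattern <- expression_pattern_matrix("fig3-like") * 2  # high separation
  d <- pattern_matrix_data(pattern, genes_per_cluster = 30,
                           noise_sd = 0.2, seed = 3)
  m6 <- select_k_silhouette(condition_means(d$matrix, d$design), 2, 12,
                            seed = 1, n_restarts = 10)
  expect_equal(m6$K, 6)
  expect_gte(ari(m6$assignment, d$truth), 0.95)

  expect_warning(select_k_silhouette(X[1:10, ], 2, 12, seed = 1,
                                     n_restarts = 2, center_rows = FALSE),
                 "truncat")
})

test_that("silhouette of the true partition beats merged alternatives", {
  pattern <- expression_pattern_matrix("fig3-like")
  d <- pattern_matrix_data(pattern, genes_per_cluster = 25,
                           noise_sd = 0.15, seed = 9)
  X <- condition_means(d$matrix, d$design)
  X <- X - rowMeans(X)
  D <- stats::dist(X)
  sil <- function(lab) mean(cluster::silhouette(lab, D)[, "sil_width"])
  merged <- d$truth
  merged[merged == 6] <- 5   # merge two planted clusters
  expect_gt(sil(d$truth), sil(merged))
})

test_that("cluster profiles compute log2 deviations from the baseline condition", {
  design <- make_design(3)
  genes <- c("flat1", "flat2", "up_both")
  m <- matrix(5, 3, 12, dimnames = list(genes, design$sample_id))
  cond_both <- design$fungus == 1 & design$bacterium == 1
  m["up_both", cond_both] <- 7
  model <- list(assignment = setNames(c(1L, 1L, 2L), genes), K = 2L)
  prof <- cluster_profiles(model, m, design)
  expect_equal(unname(prof[1, ]), c(0, 0, 0, 0))
  expect_equal(unname(prof[2, ]), c(0, 0, 0, 2))
  expect_true(all(prof[, "baseline"] == 0))

  # invariant to gene and sample order
  perm <- sample(ncol(m))
  prof2 <- cluster_profiles(model, m[c(3, 1, 2), perm], design[perm, ])
  expect_equal(prof2, prof)
})

test_that("profile-phenotype correlation standardizes against the other clusters", {
  prof <- rbind(c(0, 1, 0, 2), c(0, -1, 1, -2), c(0, 2, -1, 0), c(0, 0.5, 0.2, 1))
  rownames(prof) <- paste0("cluster_", 1:4)
  colnames(prof) <- c("baseline", "fungus", "bacterium", "both")
  pheno <- c(0, 25, 0, 42.5)
  out <- profile_phenotype_correlation(prof, pheno, target_cluster = 1)
  expect_equal(unname(out$r[1]), stats::cor(prof[1, ], pheno))
  ref <- out$r[-1]
  z_oracle <- (out$r[[1]] - mean(ref)) / stats::sd(ref)
  expect_equal(out$z, z_oracle)
  expect_equal(out$p, pracma::erfc(z_oracle / sqrt(2)) / 2, tolerance = 1e-12)

  # perfect and orthogonal profiles
  prof[1, ] <- pheno
  expect_equal(unname(profile_phenotype_correlation(prof, pheno, 1)$r[1]), 1)
  prof[2, ] <- c(-1, 1, 1, -1) * stats::sd(pheno)  # zero covariance with pheno
  prof[2, ] <- prof[2, ] - mean(prof[2, ])
  r2 <- profile_phenotype_correlation(prof, pheno, 1)$r[[2]]
  expect_lt(abs(r2 - stats::cor(prof[2, ], pheno)), 1e-12)

  # zero-variance profile excluded as missing
  prof[3, ] <- 0
  out3 <- profile_phenotype_correlation(prof, pheno, 1)
  expect_true(is.na(out3$r[[3]]))
  expect_false(is.na(out3$z))
  expect_error(profile_phenotype_correlation(prof[1:2, ], pheno, 1), ">= 3")
})

test_that("planted antagonistic clusters are the most anticorrelated profile pair", {
  pattern <- expression_pattern_matrix("fig3-like")
  pc <- stats::cor(t(pattern))
  expected_pair <- sort(which(pc == min(pc), arr.ind = TRUE)[1, ])
  d <- pattern_matrix_data(pattern, genes_per_cluster = 30,
                           noise_sd = 0.2, seed = 13)
  model <- kmeans_fit(condition_means(d$matrix, d$design), 6, seed = 2,
                      n_restarts = 10)
  prof <- cluster_profiles(model, d$matrix, d$design)
  cc <- stats::cor(t(prof))
  expect_equal(unname(cc), t(unname(cc)))
  expect_equal(unname(diag(cc)), rep(1, 6))
  got_pair <- sort(which(cc == min(cc), arr.ind = TRUE)[1, ])
  # map learned clusters back to planted ids via majority vote
  maj <- function(k) as.integer(names(which.max(table(
    d$truth[model$assignment == k]))))
  expect_setequal(unname(vapply(got_pair, maj, integer(1))),
                  unname(expected_pair))
})
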