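# Shared fixtures and independent oracles, all built in code at test time.

# Small synthetic experiment for fast tests; ... overrides any default.
tiny_config <- function(seed = 1L, ...) {
  args <- list(n_genes = c(host = 400L, fungus = 60L, bacterium = 40L),
               genes_per_cluster = 20L, library_size = 2e4, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

# Scaled study conditions used for end-to-end recovery runs.
recovery_config <- function(seed) {
  synthetic_config(n_genes = c(host = 1000L, fungus = 150L, bacterium = 80L),
                   genes_per_cluster = 40L, library_size = 5e4, seed = seed)
}

recovery_pipeline_config <- function(seed, ...) {
  pipeline_config(synthetic = recovery_config(seed), iterations = 100L,
                  n_perm = 1999L, k_max = 8L, n_restarts = 10L,
                  bn_restarts = 15L, seed = seed, ...)
}

# Did the run assign an XOR(fungus, bacterium) gate to the learned cluster
# holding the majority of the planted XOR genes?
xor_recovered <- function(res) {
  truth <- res$input$truth
  xg <- names(truth$gene_cluster)[truth$gene_cluster == truth$xor_cluster]
  asn <- res$clustering$model$assignment
  tab <- table(asn[names(asn) %in% xg])
  if (!length(tab)) return(FALSE)
  g <- res$network$circuit$gates[[paste0("cluster_", names(tab)[which.max(tab)])]]
  identical(g$gate, "XOR") && setequal(g$dependent, c("fungus", "bacterium"))
}

# Adjusted Rand index (direct contingency-table formula).
ari <- function(a, b) {
  t <- table(a, b); n <- sum(t)
  sc <- function(x) sum(choose(x, 2))
  exp_ <- sc(rowSums(t)) * sc(colSums(t)) / choose(n, 2)
  (sc(t) - exp_) / (0.5 * (sc(rowSums(t)) + sc(colSums(t))) - exp_)
}

# Balanced 2x2 design with r replicates.
make_design <- function(r = 3L) {
  d <- expand.grid(replicate = seq_len(r),
                   fungus = 0:1, bacterium = 0:1)
  d$sample_id <- sprintf("s%02d", seq_len(nrow(d)))
  d[, c("sample_id", "fungus", "bacterium", "replicate")]
}

# Expression matrix with planted condition patterns (genes x 4r samples).
pattern_matrix_data <- function(pattern, genes_per_cluster, noise_sd, seed,
                                r = 3L) {
  set.seed(seed)
  design <- make_design(r)
  cond <- ifelse(design$fungus & design$bacterium, "both",
                 ifelse(design$fungus == 1, "fungus",
                        ifelse(design$bacterium == 1, "bacterium", "baseline")))
  K <- nrow(pattern)
  n <- K * genes_per_cluster
  truth <- rep(seq_len(K), each = genes_per_cluster)
  m <- matrix(stats::rnorm(n * nrow(design), sd = noise_sd), n, nrow(design))
  for (g in seq_len(n)) m[g, ] <- m[g, ] + pattern[truth[g], cond]
  rownames(m) <- sprintf("g%04d", seq_len(n))
  colnames(m) <- design$sample_id
  list(matrix = m, design = design, truth = truth, condition = cond)
}

# --- independent oracles -----------------------------------------------------

# Hypergeometric upper tail by direct combinatorial enumeration.
hyper_tail_enum <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Transitive reduction by delete-one-edge reachability (recursive DFS).
transitive_reduction_oracle <- function(adj) {
  n <- nrow(adj)
  reach_dfs <- function(a, from, to) {
    seen <- rep(FALSE, n)
    rec <- function(v) {
      if (v == to) return(TRUE)
      if (seen[v]) return(FALSE)
      seen[v] <<- TRUE
      for (w in which(a[v, ] > 0)) if (rec(w)) return(TRUE)
      FALSE
    }
    rec(from)
  }
  out <- adj
  for (i in seq_len(n)) for (j in which(adj[i, ] > 0)) {
    a2 <- adj; a2[i, j] <- 0
    if (reach_dfs(a2, i, j)) out[i, j] <- 0
  }
  out
}

# Independent BDeu + sparsity-prior scorer, written with plain loops.
bdeu_oracle <- function(states, j, parents, card, ess = 1, edge_penalty = 1) {
  n <- nrow(states)
  r <- card[j]
  q <- 1
  for (p in parents) q <- q * card[p]
  cfg_of <- function(row) {
    idx <- 0; mult <- 1
    for (p in parents) { idx <- idx + states[row, p] * mult; mult <- mult * card[p] }
    idx
  }
  cfgs <- vapply(seq_len(n), cfg_of, numeric(1))
  total <- 0
  for (cf in unique(cfgs)) {
    rows <- which(cfgs == cf)
    total <- total + lgamma(ess / q) - lgamma(ess / q + length(rows))
    for (s in 0:(r - 1)) {
      njk <- sum(states[rows, j] == s)
      total <- total + lgamma(ess / (r * q) + njk) - lgamma(ess / (r * q))
    }
  }
  unname(total - edge_penalty * length(parents))
}

# All DAG adjacency matrices over n nodes (n <= 4).
all_dags <- function(n) {
  cells <- which(diag(n) == 0)
  out <- list()
  for (code in 0:(2^length(cells) - 1)) {
    adj <- matrix(0L, n, n)
    adj[cells] <- as.integer(intToBits(code))[seq_along(cells)]
    # acyclic check via repeated leaf stripping
    a <- adj; ok <- TRUE
    while (nrow(a) > 0) {
      leaf <- which(colSums(a) == 0)
      if (!length(leaf)) { ok <- FALSE; break }
      a <- a[-leaf[1], -leaf[1], drop = FALSE]
    }
    if (ok) out[[length(out) + 1]] <- adj
  }
  out
}

# CPDAG fingerprint: skeleton plus v-structures (Markov equivalence class).
cpdag_key <- function(adj) {
  n <- nrow(adj)
  skel <- (adj + t(adj)) > 0
  vs <- character(0)
  for (j in seq_len(n)) {
    pa <- which(adj[, j] > 0)
    if (length(pa) >= 2)
      for (a in pa) for (b in pa) if (a < b && !skel[a, b])
        vs <- c(vs, paste(a, b, j))
  }
  paste(paste(which(skel[upper.tri(skel)]), collapse = ","),
        paste(sort(vs), collapse = ";"), sep = "|")
}
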