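# small helper: manual node table over the 2x2 design
manual_table <- function(cluster_values, design = make_design(3)) {
  vals <- cbind(fungus = design$fungus, bacterium = design$bacterium,
                cluster_values)
  rownames(vals) <- design$sample_id
  kind <- setNames(c("presence", "presence",
                     rep("cluster", ncol(cluster_values))), colnames(vals))
  node_table(vals, kind, design)
}

test_that("node tables carry per-sample cluster means and presence indicators", {
  design <- make_design(3)
  m <- matrix(stats::rnorm(36), 3, 12,
              dimnames = list(c("a", "b", "c"), design$sample_id))
  model <- list(assignment = setNames(c(1L, 2L, 2L), c("a", "b", "c")), K = 2L)
  tab <- build_node_table(model, m, design)
  expect_equal(unname(tab$values[, "cluster_1"]), unname(m["a", ]))
  expect_equal(unname(tab$values[, "cluster_2"]),
               unname(colMeans(m[c("b", "c"), ])))
  expect_equal(unname(tab$values[, "fungus"]), design$fungus)
  expect_equal(tab$kind[["fungus"]], "presence")

  # permuting sample order permutes rows identically
  perm <- sample(12)
  tab2 <- build_node_table(model, m[, perm], design[perm, ])
  expect_equal(tab2$values[rownames(tab$values), ], tab$values)

  expect_error(node_table(matrix(2, 2, 2, dimnames = list(NULL, c("f", "x"))),
                          c(f = "presence", x = "cluster")),
               "only 0/1")
})

test_that("quantile discretization uses ranks and passes presence through", {
  design <- make_design(3)
  cv <- matrix(c(1:6, 6:1), 12, 1, dimnames = list(NULL, "cluster_1"))
  tab <- manual_table(cv[1:12, , drop = FALSE], design)
  # canonical 6-value example on a plain node table
  tab6 <- node_table(matrix(1:6, 6, 1, dimnames = list(NULL, "cluster_1")),
                     c(cluster_1 = "cluster"))
  d6 <- discretize_nodes(tab6, n_bins = 3)
  expect_equal(unname(d6$states[, 1]), c(0L, 0L, 1L, 1L, 2L, 2L))
  # monotone transformation leaves states unchanged
  tab6b <- node_table(matrix((1:6)^3, 6, 1, dimnames = list(NULL, "cluster_1")),
                      c(cluster_1 = "cluster"))
  expect_equal(discretize_nodes(tab6b, 3)$states, d6$states)

  d <- discretize_nodes(tab, n_bins = 3)
  expect_equal(unname(d$states[, "fungus"]), design$fungus)
  expect_equal(d$cardinality[["fungus"]], 2L)

  const <- manual_table(matrix(5, 12, 1, dimnames = list(NULL, "cluster_1")))
  dc <- discretize_nodes(const, 2)
  expect_equal(attr(dc$states, "constant_nodes"), "cluster_1")
  expect_true(all(dc$states[, "cluster_1"] == 0L))
  expect_error(discretize_nodes(tab, 1), "n_bins")
})

test_that("independent nodes yield (near-)empty learned structures", {
  empty_enough <- 0
  for (s in 1:50) {
    set.seed(s)
    vals <- matrix(stats::runif(30 * 4), 30, 4,
                   dimnames = list(NULL, paste0("cluster_", 1:4)))
    tab <- node_table(vals, setNames(rep("cluster", 4), colnames(vals)))
    tab <- discretize_nodes(tab, 2)
    bn <- learn_structure(tab, max_parents = 3, n_restarts = 3, seed = s)
    if (nrow(bn$edges) <= 1) empty_enough <- empty_enough + 1
  }
  expect_gte(empty_enough, 45)   # >= 90% of 50 seeds
})

test_that("greedy search matches exhaustive search on a strong 4-node chain", {
  set.seed(21)
  n <- 200
  a <- stats::rbinom(n, 1, 0.5)
  flip <- function(x, p = 0.1) ifelse(stats::runif(n) < p, 1 - x, x)
  b <- flip(a); c_ <- flip(b); d <- flip(c_)
  vals <- cbind(cluster_1 = a, cluster_2 = b, cluster_3 = c_, cluster_4 = d)
  tab <- node_table(vals, setNames(rep("cluster", 4), colnames(vals)))
  tab <- discretize_nodes(tab, 2)
  bn <- learn_structure(tab, max_parents = 3, n_restarts = 5, seed = 2)

  # exhaustive oracle over all 543 DAGs with an independently written scorer
  best_score <- -Inf; best_adj <- NULL
  for (adj in all_dags(4)) {
    sc <- 0
    for (j in 1:4)
      sc <- sc + bdeu_oracle(tab$states, j, which(adj[, j] > 0),
                             tab$cardinality)
    if (sc > best_score) { best_score <- sc; best_adj <- adj }
  }
  dimnames(best_adj) <- dimnames(bn$adj)
  expect_equal(unname(bn$score), best_score, tolerance = 1e-9)
  expect_equal(cpdag_key(bn$adj), cpdag_key(best_adj))
  # hill-climbing end point scores at least as high as the empty graph
  empty_sc <- sum(vapply(1:4, function(j)
    bdeu_oracle(tab$states, j, integer(0), tab$cardinality), numeric(1)))
  expect_gte(bn$score, empty_sc)
})

test_that("presence nodes are never the child of any edge", {
  d <- pattern_matrix_data(expression_pattern_matrix("fig3-like"), 10, 0.2, 31)
  model <- kmeans_fit(condition_means(d$matrix, d$design), 6, seed = 1,
                      n_restarts = 5)
  tab <- discretize_nodes(build_node_table(model, d$matrix, d$design))
  bn <- learn_structure(tab, n_restarts = 10, seed = 3)
  expect_false(any(bn$edges$to %in% c("fungus", "bacterium")))
})

test_that("transitive pruning equals brute-force transitive reduction", {
  adj <- matrix(0L, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  adj["A", "B"] <- adj["B", "C"] <- adj["A", "C"] <- 1L
  pruned <- transitive_prune(adj)
  expect_equal(sum(pruned), 2)
  expect_equal(pruned["A", "C"], 0L)
  expect_equal(pruned["A", "B"], 1L)

  chain <- adj; chain["A", "C"] <- 0L
  expect_equal(transitive_prune(chain), chain)

  set.seed(8)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < 0.4)
    perm <- sample(n)   # hide the topological order
    a <- a[perm, perm]
    pr <- transitive_prune(a)
    expect_equal(pr, transitive_reduction_oracle(a))
    expect_equal(transitive_prune(pr), pr)   # idempotent
    # reachability unchanged
    closure <- function(x) { r <- x > 0
      repeat { nx <- r | (r %*% r > 0); if (identical(nx, r)) break; r <- nx }; r }
    expect_equal(closure(pr), closure(a))
  }
  cyc <- matrix(0L, 2, 2); cyc[1, 2] <- cyc[2, 1] <- 1L
  expect_error(transitive_prune(cyc), "cyclic")
})

test_that("gate fitting reproduces every two-input truth table exactly", {
  parent_states <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  for (f in 0:15) {
    tt <- as.integer(intToBits(f))[1:4]
    child <- tt[parent_states %*% c(1, 2) + 1]
    fit <- mhbcircuit:::fit_boolean_function(parent_states, child)
    expect_equal(fit$mismatch, 0)
    expect_equal(fit$tt[parent_states %*% c(1, 2) + 1], child)
  }
  # canonical labels and parent-order invariance
  lab <- function(tt4, dep = c(TRUE, TRUE)) mhbcircuit:::gate_label(tt4, dep)
  expect_equal(lab(c(0L, 0L, 0L, 1L)), "AND")
  expect_equal(lab(c(0L, 1L, 1L, 0L)), "XOR")
  expect_equal(lab(c(1L, 0L, 0L, 1L)), "XNOR")
  expect_equal(lab(c(1L, 0L, 0L, 0L)), "NOR")
  swap2 <- function(tt) tt[c(1, 3, 2, 4)]   # permute the two inputs
  for (f in 0:15) {
    tt <- as.integer(intToBits(f))[1:4]
    dep <- vapply(1:2, function(m) mhbcircuit:::tt_depends(tt, 2, m), logical(1))
    expect_equal(lab(swap2(tt), rev(dep)), lab(tt, dep))
  }
  # constants have no dependent inputs
  expect_equal(lab(rep(0L, 4), c(FALSE, FALSE)), "CONST0")
  expect_equal(lab(rep(1L, 4), c(FALSE, FALSE)), "CONST1")
  fitc <- mhbcircuit:::fit_boolean_function(parent_states, rep(1, 4))
  expect_equal(sum(fitc$dependent), 0)
})

test_that("an XOR-regulated cluster node gets the XOR gate on the circuit", {
  design <- make_design(3)
  cond_value <- c(baseline = 0, fungus = 2, bacterium = 2, both = 0)
  cond <- ifelse(design$fungus & design$bacterium, "both",
                 ifelse(design$fungus == 1, "fungus",
                        ifelse(design$bacterium == 1, "bacterium", "baseline")))
  cv <- matrix(cond_value[cond], 12, 1, dimnames = list(NULL, "cluster_1"))
  tab <- manual_table(cv, design)
  adj <- matrix(0L, 3, 3, dimnames = list(colnames(tab$values),
                                          colnames(tab$values)))
  adj["fungus", "cluster_1"] <- adj["bacterium", "cluster_1"] <- 1L
  net <- structure(list(adj = adj, nodes = colnames(tab$values),
                        kind = tab$kind,
                        edges = data.frame(from = c("fungus", "bacterium"),
                                           to = "cluster_1")),
                   class = "bayes_net")
  circ <- fit_gates(net, tab, design, up_threshold = 0.5,
                    target_cluster = "cluster_1")
  g <- circ$gates[["cluster_1"]]
  expect_equal(g$gate, "XOR")
  expect_equal(g$mismatches, 0)
  expect_setequal(g$dependent, c("fungus", "bacterium"))
  expect_equal(unname(circ$condition_states[, "cluster_1"]), c(0L, 1L, 1L, 0L))
  expect_equal(unname(circ$mhb_activity), c(0L, 1L, 1L, 0L))

  dot <- withr::local_tempfile(fileext = ".dot")
  write_circuit_dot(circ, dot)
  txt <- readLines(dot)
  expect_true(any(grepl("fungus.*->.*cluster_1", txt)))
  expect_true(any(grepl("XOR", txt)))
})

test_that("the sensor screen applies all three criteria", {
  model <- list(assignment = setNames(rep(1:2, each = 10),
                                      sprintf("g%02d", 1:20)), K = 2L)
  ann <- data.frame(gene_id = c(sprintf("g%02d", 1:8), "g15"),
                    term = "GO:0048544")
  enr <- data.frame(cluster = c(1L, 2L), term = "GO:0048544",
                    k = c(8L, 1L), n = 10L, K_bg = 9L, N_bg = 100L,
                    p = c(1e-9, 0.5), enriched_flag = c(TRUE, FALSE),
                    unique_flag = c(TRUE, FALSE))
  gates <- list(cluster_1 = list(node = "cluster_1",
                                 parents = c("fungus", "bacterium"),
                                 dependent = c("fungus", "bacterium"),
                                 gate = "XOR", mismatches = 0L),
                cluster_2 = list(node = "cluster_2", parents = "fungus",
                                 dependent = "fungus", gate = "ID",
                                 mismatches = 0L))
  net <- list(kind = c(fungus = "presence", bacterium = "presence",
                       cluster_1 = "cluster", cluster_2 = "cluster"))
  circ <- structure(list(gates = gates, net = net), class = "boolean_circuit")
  hits <- screen_sensor_candidates(circ, enr, model, ann)
  expect_setequal(hits$gene_id, sprintf("g%02d", 1:8))
  expect_true(all(hits$cluster == 1))

  # no gate integrating both presence inputs -> empty result, not an error
  gates$cluster_1$dependent <- "fungus"
  circ2 <- structure(list(gates = gates, net = net), class = "boolean_circuit")
  expect_equal(nrow(screen_sensor_candidates(circ2, enr, model, ann)), 0)
  # enriched but not uniquely -> empty
  enr$unique_flag <- FALSE
  expect_equal(nrow(screen_sensor_candidates(circ, enr, model, ann)), 0)
})
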