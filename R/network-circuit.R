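#' Construct a node table for network inference
#'
#' @param values samples x nodes numeric matrix (sample ids as rownames).
#' @param kind named character vector over nodes, \code{"presence"} or
#'   \code{"cluster"}; presence nodes must hold only 0/1 values.
#' @param design optional study design to carry along.
#' @return object of class \code{node_table}.
#' @export
node_table <- function(values, kind, design = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stopf("values must have node names as columns")
  kind <- kind[colnames(values)]
  if (anyNA(kind) || !all(kind %in% c("presence", "cluster")))
    stopf("kind must label every node as presence or cluster")
  for (nd in names(kind)[kind == "presence"])
    if (!all(values[, nd] %in% c(0, 1)))
      stopf("presence node '%s' must take only 0/1 values", nd)
  structure(list(values = values, kind = kind, design = design),
            class = "node_table")
}

#' Build the cluster/presence node table from a fitted cluster model
#'
#' One cluster node per cluster, holding the per-sample mean expression of
#' its member genes, plus the two presence indicator nodes from the design.
#'
#' @param model a \code{cluster_model}.
#' @param matrix normalized log2 expression matrix the model was fit on.
#' @param design study design data.frame.
#' @return a [node_table()].
#' @export
build_node_table <- function(model, matrix, design) {
  design <- check_design(design)
  genes <- names(model$assignment)
  Y <- matrix[genes, design$sample_id, drop = FALSE]
  vals <- cbind(fungus = design$fungus, bacterium = design$bacterium)
  for (k in sort(unique(model$assignment))) {
    members <- model$assignment == k
    if (!any(members)) {
      warning(sprintf("cluster %d is empty and excluded", k))
      next
    }
    vals <- cbind(vals, colMeans(Y[members, , drop = FALSE]))
    colnames(vals)[ncol(vals)] <- paste0("cluster_", k)
  }
  rownames(vals) <- design$sample_id
  kind <- setNames(c("presence", "presence",
                     rep("cluster", ncol(vals) - 2)), colnames(vals))
  node_table(vals, kind, design)
}

#' Discretize node values into quantile bins
#'
#' Cluster nodes are binned by rank into \code{n_bins} equal-frequency
#' states (0-indexed); rank-based binning makes the states invariant under
#' any monotone transformation of a node's values. Presence nodes pass
#' through as binary states. A constant node collapses to a single state and
#' is flagged. The default is a binary (median) split: with a handful of
#' samples per condition, conditional distributions over more than two
#' states are not identifiable, and binary states keep the network's
#' semantics aligned with the Boolean gate layer built on top of it.
#'
#' @param table a [node_table()].
#' @param n_bins number of states for cluster nodes (default 2).
#' @return the table with \code{states} (integer matrix) and
#'   \code{cardinality} added; constant nodes listed in
#'   \code{attr(states, "constant_nodes")}.
#' @export
discretize_nodes <- function(table, n_bins = 2L) {
  if (n_bins < 2) stopf("n_bins must be >= 2")
  v <- table$values
  states <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  card <- setNames(integer(ncol(v)), colnames(v))
  constant <- character(0)
  for (nd in colnames(v)) {
    if (table$kind[nd] == "presence") {
      states[, nd] <- as.integer(v[, nd])
      card[nd] <- 2L
    } else {
      x <- v[, nd]
      if (length(unique(x)) == 1L) {
        states[, nd] <- 0L
        card[nd] <- 1L
        constant <- c(constant, nd)
        next
      }
      b <- ceiling(n_bins * rank(x, ties.method = "average") / length(x)) - 1L
      # relabel to consecutive 0-based states
      states[, nd] <- match(b, sort(unique(b))) - 1L
      card[nd] <- n_bins
    }
  }
  attr(states, "constant_nodes") <- constant
  table$states <- states
  table$cardinality <- card
  table$n_bins <- n_bins
  table
}

# BDeu (Bayesian-Dirichlet equivalent uniform) local score, ESS = 1.
bdeu_node_score <- function(states, j, parents, card, ess = 1) {
  N <- nrow(states)
  r <- card[j]
  q <- if (length(parents)) prod(card[parents]) else 1
  cfg <- if (length(parents)) {
    f <- 0
    mult <- 1
    for (p in parents) {
      f <- f + states[, p] * mult
      mult <- mult * card[p]
    }
    f
  } else rep(0, N)
  a_j <- ess / q
  a_jk <- ess / (r * q)
  tab <- table(cfg, states[, j])
  nj <- rowSums(tab)
  sum(lgamma(a_j) - lgamma(a_j + nj)) +
    sum(lgamma(a_jk + tab) - lgamma(a_jk))
}

#' Learn a constrained Bayesian-network structure by greedy hill climbing
#'
#' Maximizes the decomposable BDeu score (equivalent sample size 1) over DAGs
#' by greedy hill climbing with all local moves (add, delete, reverse),
#' subject to acyclicity, a cap on parents per node, and the constraint that
#' presence nodes are never the child of any edge. The best network over
#' \code{n_restarts} initializations is returned; the first restart starts
#' from the empty graph, the others from random presence-rooted DAGs (random
#' initializations are what allow jointly-informative parent pairs, such as
#' the two presence inputs of an XOR-regulated cluster, to enter together
#' even when neither input is marginally informative).
#'
#' The maximized objective is the BDeu log marginal likelihood plus a
#' sparsity structure prior of \code{-edge_penalty} per parent: on
#' near-deterministic small-sample data the raw BDeu score increases with
#' every added parent, and the prior is what makes parent sets minimal.
#'
#' @param table a discretized [node_table()] (see [discretize_nodes()]).
#' @param max_parents parent cap per node (default 5).
#' @param n_restarts search restarts (default 20).
#' @param seed RNG seed.
#' @param ess BDeu equivalent sample size (default 1).
#' @param edge_penalty log-prior cost (nats) per parent (default 1).
#' @return object of class \code{bayes_net}: adjacency matrix \code{adj}
#'   (\code{adj[i, j] = 1} for an edge i -> j), \code{edges} data.frame,
#'   \code{score}, node metadata and search settings.
#' @export
learn_structure <- function(table, max_parents = 5L, n_restarts = 20L,
                            seed = 1L, ess = 1, edge_penalty = 1) {
  if (is.null(table$states)) stopf("discretize the node table first")
  if (max_parents < 1) stopf("max_parents must be >= 1")
  states <- table$states
  if (nrow(states) < 2) stopf("need at least 2 samples to score a network")
  card <- table$cardinality
  kind <- table$kind
  nodes <- colnames(states)
  nn <- length(nodes)

  cache <- new.env(parent = emptyenv())
  sc <- function(j, parents) {
    key <- paste(j, paste(sort(parents), collapse = ","), sep = "|")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- bdeu_node_score(states, j, sort(parents), card, ess) -
        edge_penalty * length(parents)
      cache[[key]] <- v
    }
    v
  }
  reachable <- function(adj, from, to) {
    seen <- rep(FALSE, nn); stack <- from
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v == to) return(TRUE)
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, which(adj[v, ] > 0))
    }
    FALSE
  }

  climb <- function(adj) {
    node_sc <- vapply(seq_len(nn), function(j)
      sc(j, which(adj[, j] > 0)), numeric(1))
    repeat {
      best <- NULL; best_delta <- 1e-9
      for (i in seq_len(nn)) for (j in seq_len(nn)) {
        if (i == j) next
        if (adj[i, j] > 0) {
          pj <- which(adj[, j] > 0)
          d <- sc(j, setdiff(pj, i)) - node_sc[j]
          if (d > best_delta) { best_delta <- d; best <- list("del", i, j, d) }
          if (kind[i] != "presence" && sum(adj[, i]) < max_parents) {
            adj[i, j] <- 0
            ok <- !reachable(adj, i, j)
            adj[i, j] <- 1
            if (ok) {
              d <- (sc(j, setdiff(pj, i)) - node_sc[j]) +
                   (sc(i, c(which(adj[, i] > 0), j)) - node_sc[i])
              if (d > best_delta) { best_delta <- d; best <- list("rev", i, j, d) }
            }
          }
        } else if (kind[j] != "presence" && sum(adj[, j]) < max_parents &&
                   !reachable(adj, j, i)) {
          d <- sc(j, c(which(adj[, j] > 0), i)) - node_sc[j]
          if (d > best_delta) { best_delta <- d; best <- list("add", i, j, d) }
        }
      }
      # paired addition of the two presence roots: an XOR-type dependence on
      # both community members is invisible to single-edge moves, because
      # neither presence input is marginally informative on its own.
      roots <- which(kind == "presence")
      if (length(roots) == 2 && max_parents >= 2) {
        for (j in which(kind != "presence")) {
          cur <- which(adj[, j] > 0)
          # augment with both roots
          miss <- roots[adj[roots, j] == 0]
          if (length(miss) == 2 && length(cur) + 2 <= max_parents) {
            d <- sc(j, c(cur, miss)) - node_sc[j]
            if (d > best_delta) { best_delta <- d; best <- list("pair", miss, j, d) }
          }
          # or replace the whole parent set by the two roots
          if (!setequal(cur, roots)) {
            d <- sc(j, roots) - node_sc[j]
            if (d > best_delta) { best_delta <- d; best <- list("setpair", roots, j, d) }
          }
        }
      }
      if (is.null(best)) break
      i <- best[[2]]; j <- best[[3]]
      if (best[[1]] == "add") adj[i, j] <- 1
      else if (best[[1]] == "del") adj[i, j] <- 0
      else if (best[[1]] == "pair") adj[i, j] <- 1
      else if (best[[1]] == "setpair") { adj[, j] <- 0L; adj[i, j] <- 1L }
      else { adj[i, j] <- 0; adj[j, i] <- 1 }
      node_sc[j] <- sc(j, which(adj[, j] > 0))
      if (best[[1]] == "rev") node_sc[i] <- sc(i, which(adj[, i] > 0))
    }
    list(adj = adj, score = sum(node_sc))
  }

  random_init <- function() {
    adj <- matrix(0L, nn, nn, dimnames = list(nodes, nodes))
    ord <- c(which(kind == "presence"), sample(which(kind != "presence")))
    for (a in seq_len(nn - 1)) for (b in (a + 1):nn) {
      i <- ord[a]; j <- ord[b]
      if (kind[j] == "presence") next
      p_edge <- if (kind[i] == "presence") 0.5 else 0.2
      if (stats::runif(1) < p_edge && sum(adj[, j]) < max_parents)
        adj[i, j] <- 1L
    }
    adj
  }

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      adj0 <- if (r == 1)
        matrix(0L, nn, nn, dimnames = list(nodes, nodes)) else random_init()
      fit <- climb(adj0)
      if (is.null(best) || fit$score > best$score) best <- fit
    }
    edges <- which(best$adj > 0, arr.ind = TRUE)
    structure(list(
      adj = best$adj,
      edges = data.frame(from = nodes[edges[, 1]], to = nodes[edges[, 2]],
                         stringsAsFactors = FALSE),
      score = best$score, nodes = nodes, kind = kind,
      max_parents = max_parents, n_restarts = n_restarts, seed = seed,
      ess = ess, edge_penalty = edge_penalty
    ), class = "bayes_net")
  })
}

#' @export
print.bayes_net <- function(x, ...) {
  cat(sprintf("Bayesian network: %d nodes, %d edges, BDeu score %.3f\n",
              length(x$nodes), nrow(x$edges), x$score))
  if (nrow(x$edges))
    cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n")
  invisible(x)
}

#' Remove redundant transitive edges from a DAG
#'
#' Every edge A -> C for which another directed path A to C exists is
#' removed (the transitive reduction, which is unique for a DAG and leaves
#' reachability unchanged).
#'
#' @param net a \code{bayes_net} or a 0/1 adjacency matrix.
#' @return the same type with redundant edges removed.
#' @export
transitive_prune <- function(net) {
  adj <- if (inherits(net, "bayes_net")) net$adj else as.matrix(net)
  storage.mode(adj) <- "integer"
  n <- nrow(adj)
  reach <- adj > 0
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  if (any(diag(reach))) stopf("input graph is cyclic")
  pruned <- adj
  for (a in seq_len(n)) for (cc in which(adj[a, ] > 0)) {
    via <- adj[a, ] > 0 & reach[, cc]
    via[cc] <- FALSE
    if (any(via)) pruned[a, cc] <- 0L
  }
  if (inherits(net, "bayes_net")) {
    net$adj <- pruned
    e <- which(pruned > 0, arr.ind = TRUE)
    net$edges <- data.frame(from = net$nodes[e[, 1]], to = net$nodes[e[, 2]],
                            stringsAsFactors = FALSE)
    net
  } else pruned
}

# Best boolean function of the given parent condition-states for one child.
# Enumerates all 2^(2^k) functions for k <= 3; ties broken by fewer
# dependent inputs, then by canonical (ascending truth-table) order.
fit_boolean_function <- function(parent_states, child) {
  k <- ncol(parent_states)
  cfg <- as.integer(parent_states %*% 2^(seq_len(k) - 1)) + 1L
  best <- NULL
  for (f in 0:(2^(2^k) - 1)) {
    tt <- as.integer(intToBits(f))[seq_len(2^k)]
    mism <- sum(tt[cfg] != child)
    dep <- vapply(seq_len(k), function(m) tt_depends(tt, k, m), logical(1))
    cand <- list(tt = tt, mismatch = mism, dependent = dep, f = f)
    if (is.null(best) ||
        mism < best$mismatch ||
        (mism == best$mismatch && sum(dep) < sum(best$dependent)))
      best <- cand
  }
  best
}

# Does truth table tt (over k inputs, input m as bit m-1) depend on input m?
tt_depends <- function(tt, k, m) {
  idx <- seq_len(2^k) - 1L
  bit <- bitwAnd(idx %/% 2^(m - 1), 1L)
  any(tt[idx[bit == 0] + 1L] != tt[bitwXor(idx[bit == 0], as.integer(2^(m - 1))) + 1L])
}

# Reduce a truth table to its dependent inputs and name the canonical gate.
gate_label <- function(tt, dependent) {
  k <- length(dependent)
  keep <- which(dependent)
  kd <- length(keep)
  if (kd == 0) return(if (tt[1] == 0) "CONST0" else "CONST1")
  idx <- seq_len(2^k) - 1L
  sub <- vapply(seq_len(2^kd) - 1L, function(s) {
    full <- sum(bitwAnd(s %/% 2^(seq_len(kd) - 1), 1L) * 2^(keep - 1))
    tt[full + 1L]
  }, integer(1))
  key <- paste(sub, collapse = "")
  if (kd == 1) return(switch(key, "01" = "ID", "10" = "NOT", "GENERIC-1"))
  if (kd == 2) return(switch(key,
    "0001" = "AND", "0111" = "OR", "1110" = "NAND", "1000" = "NOR",
    "0110" = "XOR", "1001" = "XNOR", "GENERIC-2"))
  paste0("GENERIC-", kd)
}

#' Fit Boolean logic gates on a pruned network scaffold
#'
#' Each node is binarized per condition: a cluster node is ON in a condition
#' iff its mean log2 fold-change versus the baseline condition exceeds
#' \code{up_threshold} (the dead zone means down- or un-regulated states are
#' OFF); presence nodes follow the design. For every cluster node with
#' parents, the Boolean function of its parents minimizing mismatches over
#' the four conditions is selected by exhaustive enumeration (up to 3
#' effective inputs; larger parent sets are reduced by greedy input
#' selection), and labeled with its canonical gate name.
#'
#' @param net a (typically [transitive_prune()]d) \code{bayes_net}.
#' @param table the [node_table()] used to learn it.
#' @param design study design data.frame (4 conditions).
#' @param up_threshold log2 fold-change above which a cluster node is ON
#'   (default 0.5).
#' @param target_cluster optional cluster node name whose binary state is
#'   exposed as the derived \code{mhb_activity} output of the circuit.
#' @return object of class \code{boolean_circuit}.
#' @export
fit_gates <- function(net, table, design, up_threshold = 0.5,
                      target_cluster = NULL) {
  design <- check_design(design)
  conds <- condition_levels()
  v <- table$values[design$sample_id, , drop = FALSE]
  cond_states <- matrix(0L, length(conds), ncol(v),
                        dimnames = list(conds, colnames(v)))
  for (nd in colnames(v)) {
    cm <- tapply(v[, nd], factor(design$condition, levels = conds), mean)
    if (table$kind[nd] == "presence") {
      cond_states[, nd] <- as.integer(round(cm))
    } else {
      fc <- cm - cm["baseline"]
      cond_states[, nd] <- as.integer(fc > up_threshold)
    }
  }

  gates <- list()
  for (nd in colnames(v)[table$kind == "cluster"]) {
    parents <- net$nodes[net$adj[, nd] > 0]
    parents <- parents[order(match(parents, colnames(v)))]  # canonical order
    if (!length(parents)) {
      gates[[nd]] <- list(node = nd, parents = character(0),
                          dependent = character(0), truth_table = NULL,
                          gate = NA_character_, mismatches = NA_integer_)
      next
    }
    use <- parents
    if (length(parents) > 3) {
      use <- character(0)
      child <- cond_states[, nd]
      cur_mism <- Inf
      repeat {
        cand <- setdiff(parents, use)
        if (!length(cand) || length(use) >= 3) break
        trial <- vapply(cand, function(p) {
          fit_boolean_function(cond_states[, c(use, p), drop = FALSE],
                               child)$mismatch
        }, numeric(1))
        if (min(trial) < cur_mism) {
          use <- c(use, cand[which.min(trial)])
          cur_mism <- min(trial)
        } else break
      }
      use <- use[order(match(use, colnames(v)))]
    }
    fit <- fit_boolean_function(cond_states[, use, drop = FALSE],
                                cond_states[, nd])
    gates[[nd]] <- list(
      node = nd, parents = parents,
      dependent = use[fit$dependent],
      truth_table = fit$tt, mismatches = fit$mismatch,
      gate = gate_label(fit$tt, fit$dependent))
  }

  mhb <- if (!is.null(target_cluster) && target_cluster %in% colnames(v))
    cond_states[, target_cluster] else NULL
  structure(list(gates = gates, condition_states = cond_states,
                 up_threshold = up_threshold, net = net,
                 target_cluster = target_cluster, mhb_activity = mhb),
            class = "boolean_circuit")
}

#' @export
print.boolean_circuit <- function(x, ...) {
  cat("Boolean circuit over", length(x$gates), "cluster nodes\n")
  for (g in x$gates) {
    if (is.na(g$gate))
      cat(sprintf("  %s: no parents\n", g$node))
    else
      cat(sprintf("  %s = %s(%s)   [mismatches: %d]\n", g$node, g$gate,
                  paste(g$dependent, collapse = ", "), g$mismatches))
  }
  if (!is.null(x$mhb_activity))
    cat("  mhb_activity <-", x$target_cluster, ": states",
        paste(x$mhb_activity, collapse = ""), "\n")
  invisible(x)
}

#' Screen for sensor-candidate genes behind MHB integration
#'
#' Applies the three-criteria screen: (i) clusters whose fitted gate depends
#' on both presence inputs (e.g. an XOR of fungus and bacterium presence);
#' (ii) sensor annotation terms enriched in such a cluster; (iii) those terms
#' additionally uniquely enriched there. Returns the member genes of
#' qualifying clusters that carry qualifying terms.
#'
#' @param circuit a [fit_gates()] result.
#' @param enrichment an [enrich_clusters()] result.
#' @param model the \code{cluster_model} behind both.
#' @param annotations data.frame (\code{gene_id}, \code{term}).
#' @param sensor_terms candidate sensor terms (default \code{GO:0048544},
#'   recognition of pollen).
#' @return data.frame (\code{gene_id}, \code{cluster}, \code{term}) of
#'   candidates with per-criterion logical attributes \code{criteria}
#'   (clusters passing (i), terms passing (ii) and (iii)).
#' @export
screen_sensor_candidates <- function(circuit, enrichment, model, annotations,
                                     sensor_terms = "GO:0048544") {
  presence <- names(circuit$net$kind)[circuit$net$kind == "presence"]
  qual_clusters <- integer(0)
  for (g in circuit$gates) {
    if (!is.na(g$gate) && all(presence %in% g$dependent))
      qual_clusters <- c(qual_clusters,
                         as.integer(sub("cluster_", "", g$node)))
  }
  crit <- list(clusters_i = qual_clusters, terms_ii = character(0),
               terms_iii = character(0))
  empty <- data.frame(gene_id = character(0), cluster = integer(0),
                      term = character(0), stringsAsFactors = FALSE)
  if (!length(qual_clusters)) {
    attr(empty, "criteria") <- crit
    return(empty)
  }
  e <- enrichment[enrichment$cluster %in% qual_clusters &
                  enrichment$term %in% sensor_terms, , drop = FALSE]
  crit$terms_ii <- unique(e$term[e$enriched_flag])
  e <- e[e$enriched_flag & e$unique_flag, , drop = FALSE]
  crit$terms_iii <- unique(e$term)
  if (!nrow(e)) {
    attr(empty, "criteria") <- crit
    return(empty)
  }
  out <- list()
  for (i in seq_len(nrow(e))) {
    members <- names(model$assignment)[model$assignment == e$cluster[i]]
    hits <- annotations$gene_id[annotations$term == e$term[i] &
                                annotations$gene_id %in% members]
    if (length(hits))
      out[[length(out) + 1]] <- data.frame(
        gene_id = sort(unique(hits)), cluster = e$cluster[i],
        term = e$term[i], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  attr(res, "criteria") <- crit
  res
}

#' Export the circuit as Graphviz DOT
#'
#' Presence nodes are drawn as circles, cluster nodes as boxes; edges whose
#' parent and child condition states associate negatively are drawn with
#' blunt (tee) arrowheads as inhibitory.
#'
#' @param circuit a [fit_gates()] result.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_circuit_dot <- function(circuit, path) {
  st <- circuit$condition_states
  lines <- c("digraph mhb_circuit {", "  rankdir=LR;")
  for (nd in colnames(st)) {
    shape <- if (circuit$net$kind[nd] == "presence") "circle" else "box"
    lines <- c(lines, sprintf('  "%s" [shape=%s];', nd, shape))
  }
  for (g in circuit$gates) {
    for (p in g$parents) {
      a <- st[, p]; b <- st[, g$node]
      inhib <- stats::sd(a) > 0 && stats::sd(b) > 0 && stats::cor(a, b) < 0
      style <- if (inhib) ' [arrowhead=tee]' else ''
      lab <- if (!is.na(g$gate) && length(g$dependent) > 1)
        sprintf(' [label="%s"]', g$gate) else ''
      attrs <- if (nzchar(style)) style else lab
      lines <- c(lines, sprintf('  "%s" -> "%s"%s;', p, g$node, attrs))
    }
  }
  if (!is.null(circuit$mhb_activity)) {
    lines <- c(lines, '  "mhb_activity" [shape=doublecircle];',
               sprintf('  "%s" -> "mhb_activity";', circuit$target_cluster))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
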