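#' Upper-tail cumulative hypergeometric probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(\code{N_bg} background
#' genes, \code{K_bg} of them annotated, \code{n} drawn), computed exactly.
#'
#' @param k annotated genes observed in the cluster.
#' @param n cluster size.
#' @param K_bg annotated genes in the background.
#' @param N_bg background size.
#' @return probability in (0, 1].
#' @export
hypergeometric_tail <- function(k, n, K_bg, N_bg) {
  if (any(k < 0) || any(n > N_bg) || any(K_bg > N_bg) || any(k > n) ||
      any(k > K_bg))
    stopf("inconsistent hypergeometric arguments (need k <= n <= N, k <= K <= N)")
  stats::phyper(k - 1, K_bg, N_bg - K_bg, n, lower.tail = FALSE)
}

#' Per-cluster annotation enrichment against the genome background
#'
#' Tests every (cluster, term) pair with at least one annotated member gene
#' by the cumulative hypergeometric upper tail, relative to the distribution
#' of annotations over the background gene set (by convention, all annotated
#' genes of the host genome). No multiple-testing correction is applied by
#' default; a raw threshold flags enrichment.
#'
#' @param model a \code{cluster_model} (or any list with a named
#'   \code{assignment} vector).
#' @param annotations data.frame (\code{gene_id}, \code{term}).
#' @param background character vector of background gene ids; cluster genes
#'   must be a subset.
#' @param alpha raw significance threshold (default 0.05).
#' @param adjust apply BH across all tests and threshold the adjusted values
#'   instead (off by default).
#' @return data.frame of class \code{enrichment_table}: per (cluster, term)
#'   \code{k}, \code{n}, \code{K_bg}, \code{N_bg}, \code{p},
#'   \code{enriched_flag}, \code{unique_flag}.
#' @export
enrich_clusters <- function(model, annotations, background, alpha = 0.05,
                            adjust = FALSE) {
  background <- unique(background)
  if (!length(background)) stopf("background gene set is empty")
  assignment <- model$assignment
  extra <- setdiff(names(assignment), background)
  if (length(extra))
    warning(sprintf("%d clustered gene(s) outside the background are ignored",
                    length(extra)))
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term")])
  N_bg <- length(background)
  K_by_term <- table(ann$term)

  rows <- list()
  for (cl in sort(unique(assignment))) {
    members <- intersect(names(assignment)[assignment == cl], background)
    n <- length(members)
    in_cl <- ann[ann$gene_id %in% members, , drop = FALSE]
    if (!nrow(in_cl)) next
    k_by_term <- table(in_cl$term)
    terms <- names(k_by_term)
    rows[[length(rows) + 1]] <- data.frame(
      cluster = cl, term = terms,
      k = as.integer(k_by_term),
      n = n,
      K_bg = as.integer(K_by_term[terms]),
      N_bg = N_bg,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(cluster = integer(0), term = character(0),
                      k = integer(0), n = integer(0), K_bg = integer(0),
                      N_bg = integer(0), p = numeric(0),
                      enriched_flag = logical(0), unique_flag = logical(0))
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p <- hypergeometric_tail(out$k, out$n, out$K_bg, out$N_bg)
  crit <- if (adjust) bh_fdr(out$p) else out$p
  out$enriched_flag <- crit < alpha
  out <- unique_enrichment(out)
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Flag terms enriched in exactly one cluster
#'
#' @param table an [enrich_clusters()] result (or any data.frame with
#'   \code{term} and \code{enriched_flag}).
#' @return the table with \code{unique_flag} set: true iff the term's
#'   \code{enriched_flag} is true in exactly one cluster.
#' @export
unique_enrichment <- function(table) {
  n_enr <- tapply(table$enriched_flag, table$term, sum)
  table$unique_flag <- table$enriched_flag & n_enr[table$term] == 1
  table$unique_flag <- unname(table$unique_flag)
  table
}

#' Read a gene-to-term annotation map
#'
#' Accepts the 2-column TSV dialect (\code{gene_id}, \code{term}) or GAF 2.x
#' (columns 2 and 5; rows filtered to aspect \code{P} via column 9 when
#' present).
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"gaf"} (guessed from the extension).
#' @return data.frame (\code{gene_id}, \code{term}).
#' @export
read_annotations <- function(path, format = c("auto", "tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gaf(\\.gz)?$", path, ignore.case = TRUE)) "gaf" else "tsv"
  if (format == "tsv") {
    a <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "term") %in% names(a)))
      stopf("annotation TSV must have gene_id and term columns")
    return(unique(a[, c("gene_id", "term")]))
  }
  g <- utils::read.delim(path, header = FALSE, comment.char = "!",
                         stringsAsFactors = FALSE)
  if (ncol(g) >= 9) g <- g[g[[9]] == "P", , drop = FALSE]
  unique(data.frame(gene_id = g[[2]], term = g[[5]], stringsAsFactors = FALSE))
}
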