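#' Bootstrapped RPKM quantification of multi-mapped alignments
#'
#' Converts per-sample read-to-gene alignment tables into bootstrap
#' expression estimates. In each iteration every multi-aligned read is
#' assigned uniformly at random to exactly one of its candidate genes
#' (uniquely aligned reads always count for their single gene), per-gene
#' RPKM is computed as
#' \deqn{RPKM_g = \frac{n_g}{(L_g/1000)\,(N/10^6)}}
#' with \eqn{L_g} the gene length in bp and \eqn{N} the number of distinct
#' aligned reads in the sample (each read counted once regardless of its
#' number of alignments), and the mean and SD are taken across iterations.
#'
#' @param alignments data.frame with columns \code{read_id}, \code{gene_id}
#'   and \code{sample_id} (one row per alignment; several samples allowed).
#' @param catalog data.frame with \code{gene_id}, \code{organism},
#'   \code{length_bp}.
#' @param iterations bootstrap iterations (default 10000).
#' @param seed RNG seed.
#' @return data.frame of class \code{bootstrap_expression}: one row per
#'   gene x sample with \code{unique_rpkm} (uniquely aligned reads only),
#'   \code{mean_rpkm}, \code{sd_rpkm}. All catalog genes are reported for
#'   every sample (zero for genes without reads).
#' @export
bootstrap_rpkm <- function(alignments, catalog, iterations = 10000L, seed = 1L) {
  if (iterations < 1) stopf("iterations must be >= 1")
  if (nrow(alignments) == 0) stopf("alignments are empty")
  miss <- setdiff(unique(alignments$gene_id), catalog$gene_id)
  if (length(miss))
    stopf("alignments reference %d gene(s) missing from the catalog (e.g. %s)",
          length(miss), miss[1])
  if (anyDuplicated(catalog$gene_id)) stopf("catalog gene_ids must be unique")
  samples <- unique(alignments$sample_id)
  out <- with_seed(seed, {
    res <- lapply(samples, function(s) {
      one <- alignments[alignments$sample_id == s, , drop = FALSE]
      bootstrap_rpkm_sample(one, catalog, iterations, s)
    })
    do.call(rbind, res)
  })
  rownames(out) <- NULL
  class(out) <- c("bootstrap_expression", "data.frame")
  out
}

bootstrap_rpkm_sample <- function(aln, catalog, iterations, sample_id) {
  ng <- nrow(catalog)
  gidx <- match(aln$gene_id, catalog$gene_id)
  rid <- factor(aln$read_id)
  n_reads <- nlevels(rid)
  hits_per_read <- tabulate(as.integer(rid), nbins = n_reads)

  ord <- order(as.integer(rid))
  g_ord <- gidx[ord]
  r_ord <- as.integer(rid)[ord]
  is_unique_read <- hits_per_read == 1L
  uniq_rows <- is_unique_read[r_ord]
  base <- tabulate(g_ord[uniq_rows], nbins = ng)

  multi_g <- g_ord[!uniq_rows]
  multi_len <- hits_per_read[!is_unique_read]
  n_multi <- length(multi_len)
  scale <- 1e9 / (catalog$length_bp * n_reads)

  if (n_multi == 0L) {
    mean_cnt <- base
    sd_cnt <- rep(0, ng)
  } else {
    start <- c(0L, cumsum(multi_len)[-n_multi])
    s1 <- numeric(ng); s2 <- numeric(ng)
    for (it in seq_len(iterations)) {
      pick <- start + floor(stats::runif(n_multi) * multi_len) + 1L
      cnt <- base + tabulate(multi_g[pick], nbins = ng)
      s1 <- s1 + cnt
      s2 <- s2 + cnt * cnt
    }
    mean_cnt <- s1 / iterations
    v <- if (iterations > 1) pmax(0, (s2 - s1^2 / iterations) / (iterations - 1))
         else rep(0, ng)
    sd_cnt <- sqrt(v)
  }
  data.frame(gene_id = catalog$gene_id, sample_id = sample_id,
             unique_rpkm = base * scale,
             mean_rpkm = mean_cnt * scale,
             sd_rpkm = sd_cnt * scale,
             stringsAsFactors = FALSE)
}

#' Expression-significance calls from bootstrap estimates
#'
#' Computes, per gene and sample, the cumulative-normal probability that
#' expression is at or below zero given the bootstrap mean and SD,
#' \eqn{p = \Phi((0 - \mu)/\sigma)}, adjusts it by Benjamini-Hochberg within
#' each sample, and flags a gene as significantly expressed when the adjusted
#' probability is below \code{alpha} and the bootstrap mean RPKM exceeds
#' \code{rpkm_threshold}. A zero bootstrap SD yields \eqn{p = 0} for positive
#' means and \eqn{p = 1} otherwise.
#'
#' @param expr a [bootstrap_rpkm()] result.
#' @param alpha significance level on the adjusted probability (default 0.05).
#' @param rpkm_threshold minimum bootstrap mean RPKM (default 2).
#' @return \code{expr} with columns \code{p_expressed}, \code{q_expressed}
#'   and \code{expressed_flag} added.
#' @export
expression_significance <- function(expr, alpha = 0.05, rpkm_threshold = 2) {
  p <- ifelse(expr$sd_rpkm > 0,
              stats::pnorm(0, mean = expr$mean_rpkm, sd = expr$sd_rpkm),
              ifelse(expr$mean_rpkm > 0, 0, 1))
  expr$p_expressed <- p
  expr$q_expressed <- stats::ave(p, expr$sample_id, FUN = bh_fdr)
  expr$expressed_flag <- expr$q_expressed < alpha & expr$mean_rpkm > rpkm_threshold
  expr
}

#' Log2 quantile-normalized expression matrix
#'
#' Builds the genes x samples matrix of \code{log2(mean_rpkm + pseudocount)}
#' and quantile-normalizes it so every sample shares the same distribution of
#' order statistics (ties replaced by the average of the tied quantiles).
#'
#' @param expr a [bootstrap_rpkm()] result covering all samples over the same
#'   gene set.
#' @param pseudocount RPKM added before log2 (default 1).
#' @return numeric matrix (genes x samples) with dimnames.
#' @export
normalize_matrix <- function(expr, pseudocount = 1) {
  genes <- unique(expr$gene_id)
  samples <- unique(expr$sample_id)
  per_sample <- split(expr$gene_id, expr$sample_id)
  same <- vapply(per_sample, function(g) identical(sort(g), sort(genes)),
                 logical(1))
  if (!all(same)) stopf("samples were not quantified over the same gene set")
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(expr$gene_id, genes), match(expr$sample_id, samples))] <-
    log2(expr$mean_rpkm + pseudocount)
  limma::normalizeQuantiles(m, ties = TRUE)
}

#' Read the simple alignment TSV dialect
#'
#' One row per alignment with columns \code{read_id}, \code{gene_id},
#' \code{sample_id} (a missing \code{sample_id} column is filled with
#' \code{sample}).
#'
#' @param path TSV file.
#' @param sample sample id used when the file has no \code{sample_id} column.
#' @return alignment data.frame.
#' @export
read_alignment_tsv <- function(path, sample = NULL) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("read_id", "gene_id") %in% names(a)))
    stopf("alignment TSV must have read_id and gene_id columns")
  if (is.null(a$sample_id)) {
    if (is.null(sample)) stopf("no sample_id column and no sample given")
    a$sample_id <- sample
  }
  a[, c("read_id", "gene_id", "sample_id")]
}

#' Read alignments from SAM/BAM
#'
#' Collapses all mapped records per read into its candidate gene set
#' (reference names are the gene ids, as for alignments against gene models).
#' Unmapped records are dropped and mapping quality is ignored, as
#' appropriate for all-alignments short-read output.
#'
#' @param path SAM or BAM file.
#' @param sample sample id to attach.
#' @return alignment data.frame (\code{read_id}, \code{gene_id},
#'   \code{sample_id}).
#' @export
read_alignments_sam <- function(path, sample) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stopf("Rsamtools is required to read SAM/BAM input")
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  b <- Rsamtools::scanBam(path,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "rname"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
  a <- unique(data.frame(read_id = b$qname, gene_id = as.character(b$rname),
                         sample_id = sample, stringsAsFactors = FALSE))
  a[order(a$read_id, a$gene_id), , drop = FALSE]
}

#' Read a gene catalog from TSV or GFF3
#'
#' TSV input needs columns \code{gene_id}, \code{organism}, \code{length_bp}.
#' GFF3 input uses \code{gene} features; length is end - start + 1 (1-based
#' inclusive), the gene id is taken from the \code{ID} attribute and the
#' organism from \code{organism}, falling back to the seqid.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"gff3"} (guessed from the extension).
#' @return catalog data.frame.
#' @export
read_gene_catalog <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "tsv") {
    ct <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "organism", "length_bp") %in% names(ct)))
      stopf("catalog TSV must have gene_id, organism, length_bp columns")
    return(ct[, c("gene_id", "organism", "length_bp")])
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("rtracklayer is required to read GFF3 catalogs")
  g <- rtracklayer::import(path, format = "gff3")
  g <- g[g$type == "gene"]
  org <- if (!is.null(g$organism)) as.character(g$organism)
         else as.character(GenomicRanges::seqnames(g))
  data.frame(gene_id = as.character(g$ID), organism = org,
             length_bp = BiocGenerics::width(g), stringsAsFactors = FALSE)
}

#' Write per-sample expression tables
#'
#' One TSV per sample with the column roles Unique RPKM, Ave RPKM, SD RPKM,
#' Log2Norm RPKM and pVal.
#'
#' @param expr a significance-annotated [bootstrap_rpkm()] result.
#' @param normalized the matching [normalize_matrix()] output.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_expression_tsv <- function(expr, normalized, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (s in colnames(normalized)) {
    one <- expr[expr$sample_id == s, , drop = FALSE]
    one$log2norm_rpkm <- normalized[match(one$gene_id, rownames(normalized)), s]
    cols <- c("gene_id", "unique_rpkm", "mean_rpkm", "sd_rpkm",
              "log2norm_rpkm", "p_expressed", "q_expressed", "expressed_flag")
    p <- file.path(dir, sprintf("expression_%s.tsv", s))
    utils::write.table(one[, intersect(cols, names(one))], p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
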