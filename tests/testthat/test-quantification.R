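catalog2 <- data.frame(gene_id = c("gA", "gB"), organism = "host",
                       length_bp = c(1000L, 1000L), stringsAsFactors = FALSE)

test_that("bootstrap RPKM matches the closed form without ambiguity", {
  aln <- data.frame(read_id = sprintf("r%02d", 1:10), gene_id = "gA",
                    sample_id = "s1", stringsAsFactors = FALSE)
  e <- bootstrap_rpkm(aln, catalog2[1, ], iterations = 50, seed = 1)
  expect_equal(e$mean_rpkm, 1e6)   # 10 / (1 kb * 10 reads / 1e6)
  expect_equal(e$sd_rpkm, 0)
  expect_equal(e$unique_rpkm, 1e6)
})

test_that("genes without reads report zero expression", {
  aln <- data.frame(read_id = "r1", gene_id = "gA", sample_id = "s1")
  e <- bootstrap_rpkm(aln, catalog2, iterations = 10, seed = 1)
  gB <- e[e$gene_id == "gB", ]
  expect_equal(gB$mean_rpkm, 0)
  expect_equal(gB$sd_rpkm, 0)
})

test_that("an ambiguous read splits evenly across candidates (binomial oracle)", {
  aln <- rbind(
    data.frame(read_id = "amb", gene_id = c("gA", "gB"), sample_id = "s1"),
    data.frame(read_id = sprintf("u%d", 1:9), gene_id = "gA", sample_id = "s1"))
  it <- 10000L
  e <- bootstrap_rpkm(aln, catalog2, iterations = it, seed = 42)
  # mean assigned count of the ambiguous read per gene ~ Binomial(it, 1/2)/it
  se3 <- 3 * sqrt(0.25 / it)
  scale <- 1e9 / (1000 * 10)
  countB <- e$mean_rpkm[e$gene_id == "gB"] / scale
  expect_lt(abs(countB - 0.5), se3)
  # bootstrap SD of a fair coin count is ~0.5 per iteration
  expect_lt(abs(e$sd_rpkm[e$gene_id == "gB"] / scale - 0.5), 0.05)
})

test_that("assigned reads are conserved and unambiguous input has zero SD", {
  exp <- generate_experiment(tiny_config(seed = 6, multimap_fraction = 0.2))
  s <- "both_r1"
  aln <- exp$alignments[exp$alignments$sample_id == s, ]
  e <- bootstrap_rpkm(aln, exp$catalog, iterations = 25, seed = 9)
  n_reads <- length(unique(aln$read_id))
  counts <- e$mean_rpkm * exp$catalog$length_bp[match(e$gene_id, exp$catalog$gene_id)] *
    n_reads / 1e9
  expect_equal(sum(counts), n_reads, tolerance = 1e-8)

  exp0 <- generate_experiment(tiny_config(seed = 6, multimap_fraction = 0))
  aln0 <- exp0$alignments[exp0$alignments$sample_id == s, ]
  e0 <- bootstrap_rpkm(aln0, exp0$catalog, iterations = 5, seed = 9)
  expect_true(all(e0$sd_rpkm == 0))
  expect_equal(e0$mean_rpkm, e0$unique_rpkm)
})

test_that("alignments to unknown genes are an integrity error", {
  aln <- data.frame(read_id = "r1", gene_id = "nope", sample_id = "s1")
  expect_error(bootstrap_rpkm(aln, catalog2, 10, 1), "missing from the catalog")
  expect_error(bootstrap_rpkm(aln[0, ], catalog2, 10, 1), "empty")
})

test_that("expression significance follows the cumulative-normal model", {
  expr <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"), sample_id = "s1",
    unique_rpkm = 0,
    mean_rpkm = c(0, 2, 2.5, 1.9),
    sd_rpkm = c(1, 1, 0.01, 0.01))
  out <- expression_significance(expr)
  expect_equal(out$p_expressed[1], 0.5)
  # independent CDF oracle for Phi(-2)
  oracle <- pracma::erfc(2 / sqrt(2)) / 2
  expect_equal(out$p_expressed[2], oracle, tolerance = 1e-12)
  # called expressed only above both thresholds
  expect_true(out$expressed_flag[3])    # q < 0.05, mean 2.5 > 2
  expect_false(out$expressed_flag[4])   # mean 1.9 <= 2
  # zero-SD handling
  z <- expression_significance(data.frame(
    gene_id = c("a", "b"), sample_id = "s1", unique_rpkm = 0,
    mean_rpkm = c(3, 0), sd_rpkm = 0))
  expect_equal(z$p_expressed, c(0, 1))
})

test_that("quantile normalization equalizes column distributions", {
  # hand-computed two-column case: post-log columns (1,3) and (2,4)
  expr <- data.frame(
    gene_id = rep(c("g1", "g2"), 2),
    sample_id = rep(c("s1", "s2"), each = 2),
    unique_rpkm = 0,
    mean_rpkm = c(2^1 - 1, 2^3 - 1, 2^2 - 1, 2^4 - 1),
    sd_rpkm = 0)
  m <- normalize_matrix(expr, pseudocount = 1)
  expect_equal(unname(m[, "s1"]), c(1.5, 3.5))
  expect_equal(unname(m[, "s2"]), c(1.5, 3.5))

  # identical columns are a fixed point
  expr2 <- expr
  expr2$mean_rpkm <- c(1, 7, 1, 7)
  m2 <- normalize_matrix(expr2, pseudocount = 1)
  expect_equal(unname(m2[, 1]), log2(c(1, 7) + 1))
  expect_equal(m2[, 1], m2[, 2], ignore_attr = TRUE)

  # defining property on a tie-free random matrix, and idempotency
  set.seed(8)
  genes <- sprintf("g%03d", 1:60)
  expr3 <- expand.grid(gene_id = genes, sample_id = c("s1", "s2", "s3"),
                       stringsAsFactors = FALSE)
  expr3$unique_rpkm <- 0
  expr3$mean_rpkm <- stats::runif(nrow(expr3), 0, 500)
  expr3$sd_rpkm <- 0
  m3 <- normalize_matrix(expr3)
  sorted <- apply(m3, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  expr4 <- expr3
  expr4$mean_rpkm <- 2^m3[cbind(match(expr3$gene_id, rownames(m3)),
                                match(expr3$sample_id, colnames(m3)))] - 1
  expect_equal(normalize_matrix(expr4), m3, tolerance = 1e-12)

  # inconsistent gene sets are an integrity error
  expect_error(normalize_matrix(expr3[-1, ]), "same gene set")
})

test_that("SAM and GFF3 readers recover candidate sets and gene lengths", {
  sam <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:gA\tLN:1000",
    "@SQ\tSN:gB\tLN:1000",
    "r1\t0\tgA\t1\t0\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r1\t256\tgB\t1\t0\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r2\t0\tgB\t5\t0\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\t*")
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, f)
  a <- read_alignments_sam(f, sample = "s1")
  expect_equal(a$read_id, c("r1", "r1", "r2"))   # unmapped r3 dropped
  expect_equal(a$gene_id, c("gA", "gB", "gB"))

  gff <- c("##gff-version 3",
           "chr1\ttest\tgene\t101\t400\t.\t+\t.\tID=gX;organism=host",
           "chr1\ttest\tmRNA\t101\t400\t.\t+\t.\tID=tX;Parent=gX",
           "chr2\ttest\tgene\t1\t250\t.\t-\t.\tID=gY;organism=fungus")
  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, g)
  ct <- read_gene_catalog(g)
  expect_equal(ct$gene_id, c("gX", "gY"))
  expect_equal(ct$length_bp, c(300L, 250L))  # end - start + 1
  expect_equal(ct$organism, c("host", "fungus"))
})
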