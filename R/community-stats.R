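#' Per-organism read attribution per sample
#'
#' A read counts toward an organism if at least one of its candidate genes
#' belongs to it, so a multi-aligned read can count toward several organisms
#' and the per-sample percentages may sum to more than 100.
#'
#' @param alignments alignment data.frame (\code{read_id}, \code{gene_id},
#'   \code{sample_id}).
#' @param catalog gene catalog covering all aligned genes.
#' @return data.frame of class \code{read_fraction_table}: one row per
#'   sample x organism with \code{reads} and \code{pct} (percent of the
#'   sample's aligned reads), plus \code{total_reads}.
#' @export
organism_read_fractions <- function(alignments, catalog) {
  miss <- setdiff(unique(alignments$gene_id), catalog$gene_id)
  if (length(miss)) stopf("catalog does not cover %d aligned gene(s)", length(miss))
  orgs <- unique(catalog$organism)
  org_of <- setNames(catalog$organism, catalog$gene_id)
  rows <- list()
  for (s in unique(alignments$sample_id)) {
    one <- alignments[alignments$sample_id == s, , drop = FALSE]
    total <- length(unique(one$read_id))
    hit <- unique(data.frame(read_id = one$read_id,
                             organism = org_of[one$gene_id],
                             stringsAsFactors = FALSE))
    cnt <- table(factor(hit$organism, levels = orgs))
    rows[[s]] <- data.frame(sample_id = s, organism = orgs,
                            total_reads = total,
                            reads = as.integer(cnt),
                            pct = 100 * as.integer(cnt) / total,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("read_fraction_table", "data.frame")
  out
}

#' Fold enrichment of an organism's reads between condition groups
#'
#' Fold = mean per-sample percent attribution in the present-condition group
#' over the absent-condition group, with a one-tailed (greater) two-sample
#' Welch t-test on the per-sample percentages.
#'
#' @param fractions an [organism_read_fractions()] result.
#' @param design study design data.frame.
#' @param organism organism label to test.
#' @param present_conditions,absent_conditions condition name sets (each
#'   must cover >= 2 samples).
#' @return list with \code{fold}, \code{p}, and the two group means.
#' @export
fold_enrichment_test <- function(fractions, design, organism,
                                 present_conditions, absent_conditions) {
  design <- check_design(design)
  pick <- function(conds) {
    ids <- design$sample_id[design$condition %in% conds]
    x <- fractions$pct[fractions$organism == organism &
                       fractions$sample_id %in% ids]
    if (length(x) < 2) stopf("need >= 2 samples per group")
    x
  }
  pres <- pick(present_conditions)
  abs_ <- pick(absent_conditions)
  if (mean(abs_) == 0) {
    warning("absent-group mean is zero; fold is infinite")
    return(list(fold = Inf, p = NA_real_, mean_present = mean(pres),
                mean_absent = 0))
  }
  tt <- stats::t.test(pres, abs_, alternative = "greater", var.equal = FALSE)
  list(fold = mean(pres) / mean(abs_), p = unname(tt$p.value),
       mean_present = mean(pres), mean_absent = mean(abs_))
}

#' Correlation between read attribution and a per-sample phenotype
#'
#' @param fractions an [organism_read_fractions()] result.
#' @param phenotype_values numeric vector named by sample id (or in the order
#'   of the fraction table's samples for the chosen organism).
#' @param organism organism label.
#' @return Pearson correlation coefficient (NA when either side has zero
#'   variance).
#' @export
phenotype_read_correlation <- function(fractions, phenotype_values, organism) {
  f <- fractions[fractions$organism == organism, , drop = FALSE]
  y <- if (!is.null(names(phenotype_values)))
    phenotype_values[f$sample_id] else phenotype_values
  if (length(y) != nrow(f)) stopf("phenotype values must pair with samples")
  if (stats::sd(f$pct) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(f$pct, y)
}
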