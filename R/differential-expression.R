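#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, delegated to
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p_values vector of probabilities.
#' @return adjusted probabilities (empty input gives empty output).
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Two-factor permutation ANOVA over the 2x2 community design
#'
#' Per gene, a fixed-effects two-way ANOVA decomposition (Type II sums of
#' squares, so unbalanced designs are handled) yields F statistics for the
#' fungus and bacterium main effects and their interaction. Permutation
#' p-values use \eqn{p = (1 + \#\{F^* \ge F_{obs}\})/(1 + n_{perm})}, with one
#' shared schedule of whole-column label permutations applied to every gene
#' and all three tests.
#'
#' @param matrix genes x samples matrix (e.g. from [normalize_matrix()]).
#' @param design study design data.frame (\code{sample_id}, \code{fungus},
#'   \code{bacterium}, \code{replicate}); every condition needs >= 2
#'   replicates.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for the permutation schedule.
#' @return data.frame of class \code{anova_perm2}: per gene
#'   \code{F_fungus}, \code{F_bacterium}, \code{F_interaction}, permutation
#'   \code{p_*} and BH-adjusted \code{q_*} (adjusted per factor across genes).
#' @export
permutation_anova2 <- function(matrix, design, n_perm = 10000L, seed = 1L) {
  design <- check_design(design)
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (is.null(colnames(matrix)))
    stopf("matrix must carry sample ids as column names")
  idx <- match(design$sample_id, colnames(matrix))
  if (anyNA(idx)) stopf("matrix columns do not match the design samples")
  Y <- matrix[, idx, drop = FALSE]
  if (min(table(design$condition)) < 2)
    stopf("every condition needs at least 2 replicates for ANOVA")

  A <- factor(design$fungus)
  B <- factor(design$bacterium)
  n <- ncol(Y)
  res_maker <- function(X) {
    q <- qr(X)
    diag(n) - tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
  }
  R_A <- res_maker(stats::model.matrix(~A))
  R_B <- res_maker(stats::model.matrix(~B))
  R_AB <- res_maker(stats::model.matrix(~A + B))
  R_full <- res_maker(stats::model.matrix(~A * B))
  df_e <- n - qr(stats::model.matrix(~A * B))$rank

  # total SS is invariant under column permutation; it sets the numerical
  # floor below which effect SS is treated as exactly zero (constant genes)
  tot <- rowSums((Y - rowMeans(Y))^2)
  tol <- 1e-10 * pmax(tot, .Machine$double.eps)
  f_stats <- function(Yp) {
    rss <- function(R) rowSums((Yp %*% R) * Yp)
    r_full <- rss(R_full)
    mse <- r_full / df_e
    ss <- cbind(fungus = rss(R_B) - rss(R_AB),
                bacterium = rss(R_A) - rss(R_AB),
                interaction = rss(R_AB) - r_full)
    ss[ss < tol] <- 0
    f <- ss / mse
    f[is.nan(f) | f < 0] <- 0
    f
  }

  f_obs <- f_stats(Y)
  count <- matrix(0, nrow(Y), 3)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      count <- count + (f_stats(Y[, perm, drop = FALSE]) >= f_obs - 1e-12)
    }
  })
  p <- (1 + count) / (1 + n_perm)
  out <- data.frame(gene_id = rownames(Y),
                    F_fungus = f_obs[, 1], F_bacterium = f_obs[, 2],
                    F_interaction = f_obs[, 3],
                    p_fungus = p[, 1], p_bacterium = p[, 2],
                    p_interaction = p[, 3],
                    stringsAsFactors = FALSE)
  out$q_fungus <- bh_fdr(out$p_fungus)
  out$q_bacterium <- bh_fdr(out$p_bacterium)
  out$q_interaction <- bh_fdr(out$p_interaction)
  rownames(out) <- NULL
  class(out) <- c("anova_perm2", "data.frame")
  out
}

#' Partition significantly differentially expressed genes by factor
#'
#' Flags a gene as significant for a factor when its (by default BH-adjusted)
#' permutation probability is below \code{alpha}, and returns the per-factor
#' gene sets together with the seven-region Venn partition of the SDE union.
#'
#' @param result an [permutation_anova2()] result.
#' @param alpha significance threshold (default 0.05).
#' @param use_fdr use the adjusted \code{q_*} columns (default) or the raw
#'   permutation \code{p_*} columns.
#' @return list with \code{membership} (data.frame of per-gene logical flags
#'   and \code{sde_flag}), \code{sets} (per-factor gene id vectors),
#'   \code{venn} (named counts of the 7 exclusive regions) and \code{n_sde}.
#' @export
sde_partition <- function(result, alpha = 0.05, use_fdr = TRUE) {
  pref <- if (use_fdr) "q_" else "p_"
  fa <- result[[paste0(pref, "fungus")]] < alpha
  ba <- result[[paste0(pref, "bacterium")]] < alpha
  ia <- result[[paste0(pref, "interaction")]] < alpha
  membership <- data.frame(gene_id = result$gene_id,
                           fungus = fa, bacterium = ba, interaction = ia,
                           sde_flag = fa | ba | ia, stringsAsFactors = FALSE)
  key <- paste0(ifelse(fa, "F", ""), ifelse(ba, "B", ""), ifelse(ia, "I", ""))
  regions <- c("F", "B", "I", "FB", "FI", "BI", "FBI")
  venn <- vapply(regions, function(r) sum(key == r), integer(1))
  list(membership = membership,
       sets = list(fungus = result$gene_id[fa],
                   bacterium = result$gene_id[ba],
                   interaction = result$gene_id[ia]),
       venn = venn,
       n_sde = sum(membership$sde_flag))
}
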