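## Expression filtering, simplified fold-change estimation, the
## translation-efficiency T statistic with FDR control, and Fisher
## odds-ratio overlap of methylation targets with differentially expressed
## genes.

#' Filter genes by mean counts per million
#'
#' Genes with mean CPM across samples below the threshold are considered
#' non-expressed.
#'
#' @param count_matrix genes x samples raw counts (rownames = gene ids).
#' @param cpm_threshold minimum mean CPM to keep a gene.
#' @return named logical vector over genes (TRUE = expressed).
#' @export
filter_expressed <- function(count_matrix, cpm_threshold = 1) {
  lib <- colSums(count_matrix)
  if (any(lib <= 0)) stop("zero library size")
  cpm <- sweep(count_matrix, 2L, lib, "/") * 1e6
  keep <- rowMeans(cpm) >= cpm_threshold
  stats::setNames(as.vector(keep), rownames(count_matrix))
}

#' Estimate per-gene log2 fold changes with delta-method standard errors
#'
#' A documented simplified estimator standing in for GLM machinery:
#' library-size-normalized group means with a pseudocount give the log2
#' fold change; the SE comes from the delta method under a
#' negative-binomial model with a single common dispersion estimated by
#' trimmed method-of-moments across genes:
#' `SE^2 = ((1/mu1 + phi)/n1 + (1/mu2 + phi)/n2) / ln(2)^2`.
#'
#' Total-count library normalization removes any global abundance shift, so
#' a fold change applied to every gene is by construction invisible
#' (the usual compositionality of count data); set `normalize = FALSE` when
#' libraries are known to be depth-matched.
#'
#' @param counts genes x samples raw count matrix.
#' @param group_labels factor/character of length ncol(counts) with two
#'   levels; the fold change is level 2 over level 1.
#' @param pseudocount added to normalized group means.
#' @param assay label stored in the result (`"RNA"` or `"Ribo"`).
#' @param normalize divide columns by relative library size first.
#' @return data.frame(gene_id, log2fc, se, assay) and attributes
#'   `dispersion`.
#' @export
estimate_fc <- function(counts, group_labels, pseudocount = 0.5,
                        assay = "RNA", normalize = TRUE) {
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) < 2L)) stop("need >= 2 replicates per group")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size")
  norm <- if (normalize) sweep(counts, 2L, lib / mean(lib), "/") else counts
  i1 <- which(g == levels(g)[1L]); i2 <- which(g == levels(g)[2L])
  if (sum(counts[, i1]) == 0 || sum(counts[, i2]) == 0) {
    stop("a group has zero total counts")
  }
  mu1 <- rowMeans(norm[, i1, drop = FALSE])
  mu2 <- rowMeans(norm[, i2, drop = FALSE])
  # common dispersion by a pooled moment ratio across genes and groups:
  # var = mu + phi * mu^2  =>  phi = sum(v - mu) / sum(mu^2)
  v1 <- apply(norm[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(norm[, i2, drop = FALSE], 1L, stats::var)
  phi <- max(0, (sum(v1 - mu1) + sum(v2 - mu2)) /
                (sum(mu1^2) + sum(mu2^2)))
  n1 <- length(i1); n2 <- length(i2)
  m1 <- mu1 + pseudocount; m2 <- mu2 + pseudocount
  log2fc <- log2(m2 / m1)
  se <- sqrt((1 / m1 + phi) / n1 + (1 / m2 + phi) / n2) / log(2)
  out <- data.frame(gene_id = rownames(counts), log2fc = log2fc, se = se,
                    assay = assay, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "dispersion") <- phi
  out
}

#' Translation-efficiency differential test
#'
#' The differential translation efficiency of a gene is the difference
#' between its Ribo-seq and RNA-seq log2 fold changes; assuming the log2FCs
#' are normal, the statistic is
#' `T = |log2FC_Ribo - log2FC_RNA| / sqrt(SE_Ribo^2 + SE_RNA^2)`,
#' the two-tailed p-value is the standard-normal tail probability, and q is
#' the Benjamini-Hochberg adjustment over tested genes. Genes whose SE sum
#' is not positive are reported NA and excluded from the correction.
#'
#' @param fc_ribo,fc_rna data.frames with gene_id, log2fc, se (shared
#'   genes are intersected).
#' @return data.frame(gene_id, log2fc_ribo, log2fc_rna, delta, t, p, q).
#' @export
translation_efficiency_test <- function(fc_ribo, fc_rna) {
  m <- merge(fc_ribo[, c("gene_id", "log2fc", "se")],
             fc_rna[, c("gene_id", "log2fc", "se")],
             by = "gene_id", suffixes = c("_ribo", "_rna"))
  delta <- m$log2fc_ribo - m$log2fc_rna
  denom <- sqrt(m$se_ribo^2 + m$se_rna^2)
  testable <- is.finite(denom) & denom > 0
  t <- ifelse(testable, abs(delta) / denom, NA_real_)
  p <- ifelse(testable, 2 * pnorm(-t), NA_real_)
  q <- rep(NA_real_, length(p))
  q[testable] <- p.adjust(p[testable], method = "BH")
  data.frame(gene_id = m$gene_id, log2fc_ribo = m$log2fc_ribo,
             log2fc_rna = m$log2fc_rna, delta = delta, t = t, p = p, q = q,
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher's exact test and odds ratio for a 2x2 table
#'
#' The p-value is the sum of hypergeometric probabilities of tables at
#' least as extreme as the observed one (the standard two-sided
#' convention); the sample odds ratio is `(a d)/(b c)` with a Haldane 0.5
#' correction applied to the OR and its Wald CI only when any cell is zero.
#'
#' @param a,b,c,d the 2x2 cell counts (`a` = target & DE, `b` = target &
#'   not DE, `c` = non-target & DE, `d` = neither).
#' @param conf_level Wald confidence level for the OR.
#' @return list(or, ci_lo, ci_hi, p).
#' @export
odds_ratio_test <- function(a, b, c, d, conf_level = 0.95) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- zq * sqrt(sum(1 / cells))
  list(or = or, ci_lo = exp(log(or) - half), ci_hi = exp(log(or) + half),
       p = p)
}

#' Odds-ratio overlap of methylation targets with differential expression
#'
#' For each RPM threshold, the target set is the genes whose site RPM is
#' strictly greater than the threshold; for each direction, a 2x2 table of
#' target membership against differential expression over the universe is
#' tested with Fisher's exact test.
#'
#' @param gene_rpm data.frame(gene_id, rpm): the best site RPM per gene
#'   (genes absent are non-targets).
#' @param up_genes,down_genes character vectors of differentially expressed
#'   genes (both must be subsets of `universe`).
#' @param universe character vector of expressed genes.
#' @param rpm_thresholds numeric thresholds to sweep.
#' @return data.frame(threshold, direction, a, b, c, d, or, ci_lo, ci_hi, p).
#' @export
overlap_odds_ratio <- function(gene_rpm, up_genes, down_genes, universe,
                               rpm_thresholds = c(0, 0.5, 1, 3, 5, 10, 50)) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  sets <- list(up = intersect(up_genes, universe),
               down = intersect(down_genes, universe))
  rows <- list()
  for (thr in rpm_thresholds) {
    target <- intersect(gene_rpm$gene_id[gene_rpm$rpm > thr], universe)
    for (dir in names(sets)) {
      de <- sets[[dir]]
      a <- length(intersect(target, de))
      b <- length(target) - a
      c <- length(de) - a
      d <- length(universe) - a - b - c
      res <- odds_ratio_test(a, b, c, d)
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = thr, direction = dir, a = a, b = b, c = c, d = d,
        or = res$or, ci_lo = res$ci_lo, ci_hi = res$ci_hi, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
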