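## Allele-specific poly(A) tail length, 3'-end position and abundance.
##
## All three features share the gene-level coverage filters (more than 20
## reads per allele -- or either allele for abundance -- and per-allele
## counts at least twice the undetermined count) and BH correction per
## feature across genes.

#' Gene-level coverage filter for allelic feature comparisons
#'
#' @param n_hap1,n_hap2 reads assigned to each allele.
#' @param n_undetermined reads whose allele could not be determined.
#' @param min_reads threshold, default 20 (strict `>`).
#' @param mode `"each"` (both alleles must exceed `min_reads`; poly(A) and
#'   3'-end comparisons) or `"either"` (one allele suffices; abundance).
#' @return logical: the count condition holds and each allele has at least
#'   twice the undetermined count.
#' @export
passes_gene_filters <- function(n_hap1, n_hap2, n_undetermined,
                                min_reads = 20L, mode = c("each", "either")) {
  mode <- match.arg(mode)
  count_ok <- if (mode == "each") n_hap1 > min_reads && n_hap2 > min_reads
  else n_hap1 > min_reads || n_hap2 > min_reads
  count_ok && n_hap1 >= 2 * n_undetermined && n_hap2 >= 2 * n_undetermined
}

## two-sided rank-sum comparison; exact for small tie-free samples,
## normal approximation with continuity and tie correction otherwise
rank_sum_p <- function(x, y) {
  exact <- length(x) <= 25L && length(y) <= 25L &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))$p.value
}

#' Compare poly(A) tail lengths between alleles for one gene
#'
#' Two-sided Wilcoxon rank-sum test on the per-read tail lengths of the two
#' alleles; exact for tie-free samples of at most 25 per side, normal
#' approximation with continuity and tie correction otherwise.
#'
#' @param tails_hap1,tails_hap2 numeric vectors of per-read tail lengths
#'   (nt).
#' @return list `p`, `n_hap1`, `n_hap2`, `median_hap1`, `median_hap2`,
#'   `effect` (median hap1 - median hap2, nt).
#' @export
compare_polya <- function(tails_hap1, tails_hap2) {
  list(p = rank_sum_p(tails_hap1, tails_hap2),
       n_hap1 = length(tails_hap1), n_hap2 = length(tails_hap2),
       median_hap1 = stats::median(tails_hap1),
       median_hap2 = stats::median(tails_hap2),
       effect = stats::median(tails_hap1) - stats::median(tails_hap2))
}

#' Compare 3'-end positions between alleles for one gene
#'
#' Two-sided rank-sum test on the strand-resolved genomic 3'-end positions,
#' with the additional requirement (applied by [ends_table()] after FDR
#' correction) that the mean positions differ by at least `min_shift` nt for
#' an APA call.
#'
#' @param ends_hap1,ends_hap2 numeric vectors of 3'-end genomic positions.
#' @return list `p`, `n_hap1`, `n_hap2`, `mean_hap1`, `mean_hap2`,
#'   `mean_shift` (absolute difference of means, nt).
#' @export
compare_three_prime_ends <- function(ends_hap1, ends_hap2) {
  list(p = rank_sum_p(ends_hap1, ends_hap2),
       n_hap1 = length(ends_hap1), n_hap2 = length(ends_hap2),
       mean_hap1 = mean(ends_hap1), mean_hap2 = mean(ends_hap2),
       mean_shift = abs(mean(ends_hap1) - mean(ends_hap2)))
}

#' Allelic ratio and abundance skew for one gene
#'
#' The allelic ratio is the number of reads assigned to haplotype 1 divided
#' by the number assigned to haplotype 1 or 2. Skew is tested with an exact
#' two-sided binomial test against p = 0.5.
#'
#' @param n_hap1,n_hap2 allele-assigned read counts.
#' @return list `ratio`, `p`, `n_hap1`, `n_hap2`.
#' @export
allelic_ratio_and_skew <- function(n_hap1, n_hap2) {
  tot <- n_hap1 + n_hap2
  list(ratio = if (tot > 0) n_hap1 / tot else NA_real_,
       p = if (tot > 0) stats::binom.test(n_hap1, tot, 0.5)$p.value
       else NA_real_,
       n_hap1 = n_hap1, n_hap2 = n_hap2)
}

## shared scaffolding for the per-gene feature tables
feature_by_gene <- function(reads, value_col, compare_fun, min_reads = 20L) {
  rows <- lapply(split(reads, reads$gene_id), function(g) {
    n1 <- sum(g$allele == "hap1"); n2 <- sum(g$allele == "hap2")
    nu <- sum(g$allele == "undetermined")
    if (!passes_gene_filters(n1, n2, nu, min_reads, mode = "each"))
      return(NULL)
    x <- g[[value_col]][g$allele == "hap1"]
    y <- g[[value_col]][g$allele == "hap2"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0L || length(y) == 0L) return(NULL)
    cbind(data.frame(gene_id = g$gene_id[1], stringsAsFactors = FALSE),
          as.data.frame(compare_fun(x, y)))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}

#' Allele-specific poly(A) tail length across genes
#'
#' Applies the gene filters, runs [compare_polya()] per gene, adjusts with
#' Benjamini-Hochberg across genes, and calls genes with FDR < `fdr_max`.
#'
#' @param reads data.frame with columns `read_id`, `gene_id`, `allele`
#'   (`hap1`/`hap2`/`undetermined`), `polya`.
#' @param min_reads per-allele coverage threshold (strict `>`); default 20.
#' @param fdr_max FDR cutoff; default 0.05.
#' @return data.frame with one row per tested gene and columns from
#'   [compare_polya()] plus `fdr` and `call`; `NULL` when no gene passes.
#' @export
polya_table <- function(reads, min_reads = 20L, fdr_max = 0.05) {
  out <- feature_by_gene(reads, "polya", compare_polya, min_reads)
  if (is.null(out)) return(NULL)
  out$fdr <- bh_adjust(out$p)
  out$call <- !is.na(out$fdr) & out$fdr < fdr_max
  out
}

#' Allele-specific poly(A) tail length stratified by splice state
#'
#' Repeats the poly(A) comparison within read classes: all reads, fully
#' spliced reads only (`all_spliced`), and partially spliced reads only,
#' with the same filters applied per class.
#'
#' @param reads as in [polya_table()], plus a `splice_state` column.
#' @inheritParams polya_table
#' @return data.frame with an extra `read_class` column
#'   (`all`/`all_spliced`/`partially_spliced`); BH correction is applied
#'   within each class.
#' @export
polya_by_splice_state <- function(reads, min_reads = 20L, fdr_max = 0.05) {
  classes <- list(all = reads,
                  all_spliced = reads[reads$splice_state %in% "all_spliced", ],
                  partially_spliced =
                    reads[reads$splice_state %in% "partially_spliced", ])
  out <- lapply(names(classes), function(cl) {
    t <- polya_table(classes[[cl]], min_reads, fdr_max)
    if (is.null(t)) return(NULL)
    cbind(read_class = cl, t, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(out)) rownames(out) <- NULL
  out
}

#' Allele-specific 3'-end position (APA) across genes
#'
#' As [polya_table()] but on strand-resolved 3'-end positions; the call
#' additionally requires at least `min_shift` nt between the allele mean
#' 3'-end positions.
#'
#' @param reads data.frame with columns `gene_id`, `allele`, `end_pos`.
#' @param min_shift minimum mean 3'-end shift in nt; default 10
#'   (inclusive).
#' @inheritParams polya_table
#' @return data.frame per tested gene with columns from
#'   [compare_three_prime_ends()] plus `fdr` and `call`.
#' @export
ends_table <- function(reads, min_reads = 20L, fdr_max = 0.05,
                       min_shift = 10) {
  out <- feature_by_gene(reads, "end_pos", compare_three_prime_ends,
                         min_reads)
  if (is.null(out)) return(NULL)
  out$fdr <- bh_adjust(out$p)
  out$call <- !is.na(out$fdr) & out$fdr < fdr_max &
    out$mean_shift >= min_shift
  out
}

#' Allele-specific transcript abundance across genes
#'
#' Binomial skew test per gene with BH correction; a gene is skewed when
#' FDR < `fdr_max` and the allelic ratio is below `ratio_bounds[1]` or
#' above `ratio_bounds[2]`. An optional secondary annotation flags genes
#' with p < 0.01 and ratio outside (0.45, 0.55).
#'
#' @param reads data.frame with columns `gene_id`, `allele`.
#' @param min_reads coverage threshold (strict `>`, either allele);
#'   default 20.
#' @param fdr_max FDR cutoff; default 0.05.
#' @param ratio_bounds skew bounds on the allelic ratio; default
#'   `c(0.4, 0.6)` (strict).
#' @return data.frame per tested gene: `gene_id`, `n_hap1`, `n_hap2`,
#'   `n_undetermined`, `ratio`, `p`, `fdr`, `call`, `weak_skew`.
#' @export
abundance_table <- function(reads, min_reads = 20L, fdr_max = 0.05,
                            ratio_bounds = c(0.4, 0.6)) {
  rows <- lapply(split(reads, reads$gene_id), function(g) {
    n1 <- sum(g$allele == "hap1"); n2 <- sum(g$allele == "hap2")
    nu <- sum(g$allele == "undetermined")
    if (!passes_gene_filters(n1, n2, nu, min_reads, mode = "either"))
      return(NULL)
    rs <- allelic_ratio_and_skew(n1, n2)
    data.frame(gene_id = g$gene_id[1], n_hap1 = n1, n_hap2 = n2,
               n_undetermined = nu, ratio = rs$ratio, p = rs$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$fdr <- bh_adjust(out$p)
  out$call <- !is.na(out$fdr) & out$fdr < fdr_max &
    (out$ratio < ratio_bounds[1] | out$ratio > ratio_bounds[2])
  out$weak_skew <- !is.na(out$p) & out$p < 0.01 &
    (out$ratio < 0.45 | out$ratio > 0.55)
  rownames(out) <- NULL
  out
}

#' Enrichment of allele-specific poly(A) genes among abundance-skewed genes
#'
#' Two-sided Fisher's exact test on the 2x2 classification of genes by
#' allele-specific poly(A) tail length and skewed allelic abundance.
#'
#' @param has_polya,skewed logical vectors over the same genes.
#' @return list `odds_ratio` (sample odds ratio of the 2x2 table), `p`,
#'   `table`; `NULL` components when a margin is empty (not testable).
#' @export
polya_skew_enrichment <- function(has_polya, skewed) {
  tab <- table(factor(has_polya, levels = c(TRUE, FALSE)),
               factor(skewed, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p = NA_real_, table = tab))
  ft <- stats::fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p = ft$p.value, table = tab)
}

#' Correlation of allelic ratios between subcellular compartments
#'
#' Pearson correlation of per-gene allelic ratios measured in two
#' compartments (e.g. chromatin vs cytoplasm), over genes with a ratio in
#' both.
#'
#' @param ratios_a,ratios_b numeric vectors of allelic ratios, paired by
#'   gene.
#' @return Pearson R.
#' @export
compartment_ratio_correlation <- function(ratios_a, ratios_b) {
  stopifnot(length(ratios_a) == length(ratios_b))
  stats::cor(ratios_a, ratios_b, use = "complete.obs")
}
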