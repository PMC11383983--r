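## Association between splicing order and genotype across allele-samples.
##
## Each allele of each individual is treated as one sample, with genotype 0
## for the reference allele and 2 for the alternative allele. SNPs within a
## gene (plus 500 nt of flank) that share the same genotype vector form a
## haplotype block. The association test here is a pooled chi-square
## contingency test between the genotype-0 and genotype-2 groups; this is a
## declared simplification of a Dirichlet-multinomial transcript-usage fit
## and output columns name it (`p_chisq_pooled`).

#' Group SNPs into haplotype blocks by shared genotype vectors
#'
#' @param gm genotype matrix: rows = SNPs (rownames = SNP ids), columns =
#'   allele-samples, entries 0 (reference) or 2 (alternative).
#' @return data.frame `block_id`, `snp_id`, `genotype_key`; blocks are
#'   numbered by the order of their first SNP in genomic/row order, and the
#'   partition is invariant to permuting the input rows.
#' @export
group_haplotype_blocks <- function(gm) {
  gm <- as.matrix(gm)
  if (nrow(gm) < 1L) stop("need at least one SNP")
  if (!all(gm %in% c(0, 2))) stop("genotype entries must be 0 or 2")
  key <- apply(gm, 1L, paste, collapse = ",")
  first <- tapply(seq_along(key), key, min)
  lev <- names(sort(first))
  block <- match(key, lev)
  out <- data.frame(block_id = sprintf("block%d", block),
                    snp_id = rownames(gm), genotype_key = key,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$block_id, out$snp_id), ]
}

#' Coverage and allele-frequency filter for genotype association
#'
#' A (group, block) pair is tested only if at least `min_samples`
#' allele-samples have at least `min_reads` reads at the splicing level
#' considered, and the minor genotype among those samples is carried by at
#' least `min_minor` allele-samples.
#'
#' @param sample_reads named numeric vector of read counts per
#'   allele-sample.
#' @param genotypes named vector (same names) of genotypes 0/2.
#' @param min_samples minimum qualifying allele-samples; default 10.
#' @param min_reads minimum reads per allele-sample; default 10.
#' @param min_minor minimum minor-genotype allele count; default 2.
#' @return list `pass` (logical), `qualifying` (character vector of
#'   allele-sample names used).
#' @export
filter_for_association <- function(sample_reads, genotypes,
                                   min_samples = 10L, min_reads = 10L,
                                   min_minor = 2L) {
  qual <- names(sample_reads)[sample_reads >= min_reads]
  g <- genotypes[qual]
  maf <- min(sum(g == 0), sum(g == 2))
  list(pass = length(qual) >= min_samples && maf >= min_minor,
       qualifying = qual)
}

#' Test a haplotype block for association with splicing order
#'
#' Pools intermediate-isoform counts at one splicing level across the
#' allele-samples of each genotype group and compares the two pooled
#' distributions with a chi-square contingency test (no continuity
#' correction; pattern columns empty in both groups dropped).
#'
#' @param counts matrix of intermediate-isoform counts: rows =
#'   allele-samples, columns = patterns at one splicing level.
#' @param genotypes named vector of genotypes 0/2 for the rows of `counts`.
#' @return list `statistic`, `df`, `p_chisq_pooled`, `testable` (`FALSE`
#'   when a genotype group is empty or fewer than two pattern columns
#'   remain).
#' @export
associate_block_with_order <- function(counts, genotypes) {
  counts <- as.matrix(counts)
  g <- if (is.null(rownames(counts))) genotypes
  else genotypes[rownames(counts)]
  g0 <- colSums(counts[g == 0, , drop = FALSE])
  g2 <- colSums(counts[g == 2, , drop = FALSE])
  if (sum(g == 0) == 0L || sum(g == 2) == 0L)
    return(list(statistic = NA_real_, df = NA_integer_,
                p_chisq_pooled = NA_real_, testable = FALSE))
  ct <- chi_square_level_test(g0, g2)
  list(statistic = ct$statistic, df = ct$df, p_chisq_pooled = ct$p,
       testable = ct$testable)
}

#' Genotype-splicing-order association over blocks, groups and levels
#'
#' Applies [filter_for_association()] and [associate_block_with_order()] to
#' every combination and adjusts p-values with Benjamini-Hochberg across
#' all tested (block, group, level) triples.
#'
#' @param level_counts_by_group named list (by group id) of lists (by level,
#'   names `"1"`, `"2"`, ...) of count matrices (rows = allele-samples,
#'   columns = patterns).
#' @param gm genotype matrix as in [group_haplotype_blocks()].
#' @inheritParams filter_for_association
#' @return data.frame `group_id`, `level`, `block_id`, `n_samples`,
#'   `statistic`, `p_chisq_pooled`, `fdr`, `significant`.
#' @export
associate_all <- function(level_counts_by_group, gm, min_samples = 10L,
                          min_reads = 10L, min_minor = 2L) {
  blocks <- group_haplotype_blocks(gm)
  block_geno <- blocks[!duplicated(blocks$block_id), ]
  rows <- list()
  for (gid in names(level_counts_by_group)) {
    for (lv in names(level_counts_by_group[[gid]])) {
      cm <- level_counts_by_group[[gid]][[lv]]
      sample_reads <- rowSums(cm)
      for (b in seq_len(nrow(block_geno))) {
        geno <- as.numeric(strsplit(block_geno$genotype_key[b], ",")[[1]])
        names(geno) <- colnames(gm)
        flt <- filter_for_association(sample_reads, geno, min_samples,
                                      min_reads, min_minor)
        if (!flt$pass) next
        res <- associate_block_with_order(cm[flt$qualifying, , drop = FALSE],
                                          geno)
        rows[[length(rows) + 1L]] <- data.frame(
          group_id = gid, level = as.integer(lv),
          block_id = block_geno$block_id[b],
          n_samples = length(flt$qualifying),
          statistic = res$statistic, p_chisq_pooled = res$p_chisq_pooled,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$fdr <- bh_adjust(out$p_chisq_pooled)
  out$significant <- !is.na(out$fdr) & out$fdr < 0.05
  rownames(out) <- NULL
  out
}
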