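## Calling allele-specific splicing order.
##
## Pairs: two-sided Fisher's exact test on upstream-first/downstream-first
## counts, BH correction, and an absolute frequency-difference effect cutoff.
## Triples: chi-square contingency test per splicing level, BH correction,
## plus a Euclidean-distance threshold on the 6-slot score vectors that is
## calibrated from same-allele cross-replicate distances (1.5 x IQR).

#' Fisher's exact test for an intron pair between alleles
#'
#' @param hap1,hap2 integer vectors `c(n_upstream_first, n_downstream_first)`
#'   per allele.
#' @return list `p` (two-sided exact p-value), `effect` (absolute difference
#'   in the frequency of upstream-first excision between alleles),
#'   `freq_hap1`, `freq_hap2`. `p` is `NA` when an allele has zero total.
#' @export
fisher_pair_test <- function(hap1, hap2) {
  stopifnot(length(hap1) == 2L, length(hap2) == 2L)
  t1 <- sum(hap1); t2 <- sum(hap2)
  if (t1 == 0L || t2 == 0L)
    return(list(p = NA_real_, effect = NA_real_,
                freq_hap1 = NA_real_, freq_hap2 = NA_real_))
  f1 <- hap1[1] / t1; f2 <- hap2[1] / t2
  p <- stats::fisher.test(rbind(hap1, hap2))$p.value
  list(p = p, effect = abs(f1 - f2), freq_hap1 = f1, freq_hap2 = f2)
}

#' Chi-square contingency test of intermediate-isoform counts at one level
#'
#' Pattern columns that are zero in both alleles are dropped before testing
#' (their expected counts would be undefined); no continuity correction is
#' applied. Tables with fewer than two nonzero columns are not testable.
#'
#' @param hap1,hap2 numeric vectors of pattern counts at one splicing level
#'   (same pattern order).
#' @return list `statistic`, `df`, `p`, `testable`.
#' @export
chi_square_level_test <- function(hap1, hap2) {
  stopifnot(length(hap1) == length(hap2))
  keep <- (hap1 + hap2) > 0
  h1 <- hap1[keep]; h2 <- hap2[keep]
  if (length(h1) < 2L || sum(h1) == 0 || sum(h2) == 0)
    return(list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                testable = FALSE))
  ct <- suppressWarnings(stats::chisq.test(rbind(h1, h2), correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, testable = TRUE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] (method `"BH"`) that preserves
#' `NA`s; kept as a named operation so every caller shares one multiple
#' testing route.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Euclidean distance between two splicing-order score vectors
#'
#' @param a,b numeric vectors of equal length (6 slots for triples, in the
#'   same canonical order for the two alleles).
#' @return `sqrt(sum((a - b)^2))`.
#' @export
euclidean_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  sqrt(sum((a - b)^2))
}

#' Calibrate the allele-specific splicing-order distance threshold
#'
#' The threshold is 1.5 times the interquartile range of same-allele
#' distances between biological or technical replicates, pooled over cell
#' lines (note: the IQR times 1.5 itself, not Q3 + 1.5 IQR). Quartiles use
#' linear interpolation between order statistics (quantile type 7).
#'
#' @param replicate_distances numeric vector of same-allele cross-replicate
#'   Euclidean distances (>= 4 values).
#' @return the threshold tau.
#' @seealso `tau_default` for the fixed value 0.379 obtained from 914
#'   replicate intron-group distances in LCLs.
#' @export
calibrate_threshold <- function(replicate_distances) {
  if (length(replicate_distances) < 4L)
    stop("need >= 4 replicate distances to calibrate; use tau_default otherwise")
  1.5 * stats::IQR(replicate_distances, type = 7)
}

#' Default distance threshold for allele-specific splicing order
#'
#' 1.5 x IQR of same-allele cross-replicate score-vector distances in
#' lymphoblastoid cell lines.
#' @export
tau_default <- 0.379

#' Call an intron group allele-specific
#'
#' A group is called when the Euclidean distance between allele score
#' vectors strictly exceeds `tau` and the BH-adjusted chi-square p-value is
#' below `fdr_max` for at least one splicing level.
#'
#' @param d Euclidean distance between the allele score vectors.
#' @param level_fdrs BH-adjusted p-values, one per tested splicing level
#'   (`NA` for untestable levels).
#' @param tau distance threshold (strict `>`); default [tau_default].
#' @param fdr_max FDR cutoff; default 0.05.
#' @return logical.
#' @export
call_allele_specific <- function(d, level_fdrs, tau = tau_default,
                                 fdr_max = 0.05) {
  fdrs <- level_fdrs[!is.na(level_fdrs)]
  length(fdrs) > 0L && d > tau && min(fdrs) < fdr_max
}

#' Classify the type of splicing-order difference between alleles
#'
#' Compares the top-ranked removal order of each allele position by
#' position: identical orders are "different score for same order"; a swap
#' of two consecutive positions is "reversal of first or last two
#' positions"; a swap of the first and last positions is "reversal of first
#' and last positions"; all positions different is "reversal of 3
#' positions".
#'
#' @param top_hap1,top_hap2 top-ranked orders, as `"1->2->3"` strings or
#'   integer permutations of length 3.
#' @return the category, one of the four strings above.
#' @export
classify_difference <- function(top_hap1, top_hap2) {
  o1 <- if (is.character(top_hap1)) parse_order(top_hap1)[[1]] else top_hap1
  o2 <- if (is.character(top_hap2)) parse_order(top_hap2)[[1]] else top_hap2
  stopifnot(length(o1) == 3L, length(o2) == 3L)
  diffpos <- which(o1 != o2)
  if (length(diffpos) == 0L) "different score for same order"
  else if (length(diffpos) == 3L) "reversal of 3 positions"
  else if (identical(diffpos, c(1L, 3L))) "reversal of first and last positions"
  else "reversal of first or last two positions"
}

#' Top-ranked order of a score vector
#'
#' Ties are broken toward the lexicographically smallest permutation (the
#' canonical slot order) and flagged.
#'
#' @param scores data.frame from [order_scores()] (columns `order`, `p`).
#' @return list `order` (string), `tied` (logical).
#' @export
top_order <- function(scores) {
  if (all(is.na(scores$p))) return(list(order = NA_character_, tied = NA))
  i <- which.max(scores$p)  # first maximum = lexicographically smallest
  list(order = scores$order[i],
       tied = sum(scores$p == scores$p[i]) > 1L)
}

#' Compare allelic splicing orders for a set of 3-intron groups
#'
#' Runs the per-level chi-square tests, adjusts them with Benjamini-
#' Hochberg across all tested (group, level) pairs as one family, computes
#' the Euclidean distance between allele score vectors, calls
#' allele-specific groups and classifies the difference type for called
#' groups.
#'
#' @param group_counts named list (by group id) of count data.frames from
#'   [level_pattern_counts()], filtered groups only.
#' @param k group size; default 3.
#' @param tau distance threshold; default [tau_default].
#' @param fdr_max FDR cutoff; default 0.05.
#' @return data.frame with one row per group: `group_id`, per-level
#'   statistics and FDRs (`chisq_L<level>`, `p_L<level>`, `fdr_L<level>`),
#'   `distance`, `top_hap1`, `top_hap2`, `tie_hap1`, `tie_hap2`, `call`,
#'   `difference_class` (NA for uncalled groups).
#' @export
compare_alleles <- function(group_counts, k = 3L, tau = tau_default,
                            fdr_max = 0.05) {
  lv <- seq_len(k - 1L)
  rows <- lapply(names(group_counts), function(gid) {
    counts <- group_counts[[gid]]
    row <- list(group_id = gid)
    for (L in lv) {
      pats <- level_patterns(L, k)
      h1 <- counts$count[counts$allele == "hap1" & counts$level == L][
        match(pats, counts$pattern[counts$allele == "hap1" & counts$level == L])]
      h2 <- counts$count[counts$allele == "hap2" & counts$level == L][
        match(pats, counts$pattern[counts$allele == "hap2" & counts$level == L])]
      ct <- chi_square_level_test(h1, h2)
      row[[paste0("chisq_L", L)]] <- ct$statistic
      row[[paste0("p_L", L)]] <- ct$p
    }
    s1 <- order_scores(counts, "hap1", k)
    s2 <- order_scores(counts, "hap2", k)
    row$distance <- if (attr(s1, "scorable") && attr(s2, "scorable"))
      euclidean_distance(s1$p, s2$p) else NA_real_
    t1 <- top_order(s1); t2 <- top_order(s2)
    row$top_hap1 <- t1$order; row$top_hap2 <- t2$order
    row$tie_hap1 <- t1$tied; row$tie_hap2 <- t2$tied
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) return(out)
  ## one BH family across all tested (group, level) pairs
  pcols <- paste0("p_L", lv)
  pmat <- as.matrix(out[, pcols, drop = FALSE])
  adj <- matrix(bh_adjust(as.vector(pmat)), nrow = nrow(out))
  colnames(adj) <- paste0("fdr_L", lv)
  out <- cbind(out, adj)
  out$call <- vapply(seq_len(nrow(out)), function(i)
    !is.na(out$distance[i]) &&
      call_allele_specific(out$distance[i], unlist(adj[i, ]), tau, fdr_max),
    logical(1))
  out$difference_class <- ifelse(
    out$call & !is.na(out$top_hap1) & !is.na(out$top_hap2),
    mapply(function(a, b) classify_difference(a, b),
           out$top_hap1, out$top_hap2),
    NA_character_)
  rownames(out) <- NULL
  out
}

#' Compare allelic splicing orders for intron pairs
#'
#' Fisher's exact test per pair, BH across pairs, call when FDR < `fdr_max`
#' and the absolute difference in upstream-first frequency is at least
#' `min_effect`.
#'
#' @param pair_counts data.frame with one row per pair: `group_id`,
#'   `hap1_up`, `hap1_down`, `hap2_up`, `hap2_down`.
#' @param fdr_max FDR cutoff; default 0.05.
#' @param min_effect minimum absolute frequency difference; default 0.1
#'   (inclusive).
#' @return input with added `freq_hap1`, `freq_hap2`, `effect`, `p`, `fdr`,
#'   `call`.
#' @export
compare_pairs <- function(pair_counts, fdr_max = 0.05, min_effect = 0.1) {
  res <- lapply(seq_len(nrow(pair_counts)), function(i)
    fisher_pair_test(c(pair_counts$hap1_up[i], pair_counts$hap1_down[i]),
                     c(pair_counts$hap2_up[i], pair_counts$hap2_down[i])))
  pair_counts$freq_hap1 <- vapply(res, `[[`, numeric(1), "freq_hap1")
  pair_counts$freq_hap2 <- vapply(res, `[[`, numeric(1), "freq_hap2")
  pair_counts$effect <- vapply(res, `[[`, numeric(1), "effect")
  pair_counts$p <- vapply(res, `[[`, numeric(1), "p")
  pair_counts$fdr <- bh_adjust(pair_counts$p)
  pair_counts$call <- !is.na(pair_counts$fdr) & pair_counts$fdr < fdr_max &
    pair_counts$effect >= min_effect
  pair_counts
}
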