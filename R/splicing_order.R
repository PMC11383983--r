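#' @section Splicing order:
#' A group of k consecutive introns can be removed in k! different orders.
#' Each read spanning the whole group reports an intermediate isoform: the
#' subset of group introns already excised, encoded here as a k-character
#' bitmask in transcript order ("100" = first intron excised). The splicing
#' level L of a read is the number of excised introns in the group. Scores
#' for each removal order are obtained by multiplying intermediate-isoform
#' frequencies along the order's path through levels 0..k and normalising
#' over the observed orders.
#' @name splicing-order
NULL

## ---- permutations and patterns ----------------------------------------

#' All removal orders of a k-intron group, in canonical (lexicographic) order
#'
#' @param k group size (2 or 3 in practice).
#' @return list of integer permutations; names like `"1->2->3"`.
#' @export
canonical_orders <- function(k) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  p <- perms(seq_len(k))
  names(p) <- vapply(p, function(x) paste(x, collapse = "->"), "")
  ## lexicographic by the permutation itself, not its string
  p[order(vapply(p, function(x) paste(sprintf("%02d", x), collapse = ""), ""))]
}

#' Parse an order name like "1->2->3" into an integer permutation
#' @param x character vector of order names.
#' @return list of integer vectors.
#' @export
parse_order <- function(x) {
  lapply(strsplit(x, "->", fixed = TRUE), as.integer)
}

#' Bitmask string for a set of excised introns
#' @param excised integer vector of excised intron positions within the group.
#' @param k group size.
#' @return character bitmask, e.g. `"110"`.
#' @export
pattern_string <- function(excised, k) {
  m <- rep("0", k)
  m[excised] <- "1"
  paste(m, collapse = "")
}

#' All intermediate-isoform patterns at one splicing level
#' @param level number of excised introns.
#' @param k group size.
#' @return character vector of bitmasks.
#' @export
level_patterns <- function(level, k) {
  if (level == 0) return(paste(rep("0", k), collapse = ""))
  sets <- utils::combn(k, level, simplify = FALSE)
  vapply(sets, pattern_string, "", k = k)
}

## ---- per-read patterns and counts -------------------------------------

#' Intermediate-isoform pattern of each read spanning an intron group
#'
#' Keeps only reads in which every intron of the group has status
#' `excised` or `not_excised`; reads with a `skipped` or `undetermined`
#' status inside the group, or missing any group intron, are excluded from
#' splicing-order analysis.
#'
#' @param group integer vector of transcript-order intron indices (length 2
#'   or 3, strictly increasing and consecutive).
#' @param calls data.frame of intron calls with columns `read_id`,
#'   `intron_index`, `status` (one gene).
#' @return data.frame with `read_id`, `pattern` (bitmask over the group) and
#'   `level`.
#' @export
spanning_patterns <- function(group, calls) {
  stopifnot(all(diff(group) > 0))
  k <- length(group)
  sub <- calls[calls$intron_index %in% group &
                 calls$status %in% c("excised", "not_excised"), , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(read_id = character(), pattern = character(),
                      level = integer(), stringsAsFactors = FALSE))
  n_cov <- table(sub$read_id)
  keep <- names(n_cov)[n_cov == k]
  sub <- sub[sub$read_id %in% keep, , drop = FALSE]
  sub <- sub[order(sub$read_id, match(sub$intron_index, group)), , drop = FALSE]
  bit <- ifelse(sub$status == "excised", "1", "0")
  pat <- tapply(bit, factor(sub$read_id, levels = unique(sub$read_id)),
                paste, collapse = "")
  data.frame(read_id = names(pat), pattern = as.character(pat),
             level = nchar(gsub("0", "", pat)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count intermediate isoforms per splicing level and allele
#'
#' @param patterns data.frame from [spanning_patterns()].
#' @param alleles named character vector or data.frame (`read_id`, `allele`)
#'   mapping reads to `hap1`, `hap2` or `undetermined`; unmapped reads count
#'   as `undetermined`.
#' @param k group size.
#' @return data.frame `allele`, `level`, `pattern`, `count` covering every
#'   possible pattern (zero counts included) for alleles hap1, hap2 and
#'   undetermined.
#' @export
level_pattern_counts <- function(patterns, alleles, k) {
  if (is.data.frame(alleles))
    alleles <- setNames(alleles$allele, alleles$read_id)
  al <- unname(alleles[patterns$read_id])
  al[is.na(al)] <- "undetermined"
  all_pat <- unlist(lapply(0:k, level_patterns, k = k))
  grid <- expand.grid(allele = c("hap1", "hap2", "undetermined"),
                      pattern = all_pat, stringsAsFactors = FALSE)
  grid$level <- nchar(gsub("0", "", grid$pattern))
  tab <- table(factor(al, levels = c("hap1", "hap2", "undetermined")),
               factor(patterns$pattern, levels = all_pat))
  grid$count <- as.integer(tab[cbind(grid$allele, grid$pattern)])
  grid[order(grid$allele, grid$level, grid$pattern),
       c("allele", "level", "pattern", "count")]
}

## ---- coverage filters --------------------------------------------------

#' Coverage filter for 3-intron groups
#'
#' An intron group is analysed only if, for both alleles: (1) each intron of
#' the group is retained (`not_excised`) in at least `min_reads` reads;
#' (2) every intermediate splicing level (1..k-1) is represented by at least
#' `min_reads` reads spanning the whole group; and (3) at each such level the
#' number of reads per allele exceeds twice the number of reads whose allele
#' could not be determined.
#'
#' @param counts data.frame from [level_pattern_counts()].
#' @param retained named list or matrix of per-intron `not_excised` read
#'   counts per allele: `retained[["hap1"]]` is a numeric vector over the
#'   group introns (any read overlapping the intron counts).
#' @param k group size.
#' @param min_reads threshold, default 10 ("at least 10": ties pass).
#' @return logical.
#' @export
passes_triple_filters <- function(counts, retained, k = 3L, min_reads = 10L) {
  lv <- seq_len(k - 1L)
  for (hap in c("hap1", "hap2")) {
    if (any(retained[[hap]] < min_reads)) return(FALSE)
    hc <- counts[counts$allele == hap, , drop = FALSE]
    uc <- counts[counts$allele == "undetermined", , drop = FALSE]
    for (L in lv) {
      n_hap <- sum(hc$count[hc$level == L])
      n_und <- sum(uc$count[uc$level == L])
      if (n_hap < min_reads) return(FALSE)
      if (!(n_hap > 2 * n_und)) return(FALSE)
    }
  }
  TRUE
}

#' Coverage filter for intron pairs
#'
#' Pairs require strictly more than `min_reads` informative reads (one intron
#' excised, the other not) per allele, and more than twice the number of
#' allele-undetermined informative reads.
#'
#' @param n_hap1,n_hap2,n_und informative read counts.
#' @param min_reads threshold, default 10 (strict `>`).
#' @return logical.
#' @export
passes_pair_filters <- function(n_hap1, n_hap2, n_und, min_reads = 10L) {
  n_hap1 > min_reads && n_hap2 > min_reads &&
    n_hap1 > 2 * n_und && n_hap2 > 2 * n_und
}

#' Frequency of upstream-intron-first excision for an intron pair
#'
#' @param n_upstream_first reads with the upstream intron excised and the
#'   downstream intron retained.
#' @param n_downstream_first the converse.
#' @return list with the two counts and `freq_upstream_first`.
#' @export
pair_order_frequency <- function(n_upstream_first, n_downstream_first) {
  tot <- n_upstream_first + n_downstream_first
  list(n_upstream_first = n_upstream_first,
       n_downstream_first = n_downstream_first,
       freq_upstream_first = if (tot > 0) n_upstream_first / tot else NA_real_)
}

## ---- order scores ------------------------------------------------------

#' Intermediate-isoform frequencies per level from counts
#' @noRd
level_frequencies <- function(counts_one_allele, k) {
  out <- counts_one_allele
  out$freq <- NA_real_
  for (L in 0:k) {
    i <- out$level == L
    tot <- sum(out$count[i])
    out$freq[i] <- if (tot > 0) out$count[i] / tot else 0
  }
  out
}

#' Splicing-order scores from intermediate-isoform frequencies
#'
#' For every removal order i of a k-intron group, the raw score
#' `P_i = prod_k f_k` multiplies the frequencies of the intermediate isoforms
#' along the order's path through levels 0..k (the unique patterns at levels
#' 0 and k have frequency 1, so for triples the 4-factor product equals the
#' product over the two intermediate levels). Raw scores are normalised by
#' their sum, `p_i = P_i / sum(P_i)`, so the scores of the observed orders
#' sum to 1. Groups where every raw score is zero are flagged unscorable.
#'
#' @param freq named numeric vector or data.frame (`pattern`, `freq`) giving
#'   intermediate-isoform frequencies at the intermediate levels (levels 0
#'   and k may be omitted; they contribute factor 1).
#' @param k group size.
#' @return data.frame with one row per order in canonical slot order:
#'   `order`, `P` (raw), `p` (normalised; 0 for unobserved orders), plus
#'   attributes `scorable` (logical), `n_observed` and `N` (intermediates per
#'   path, k + 1).
#' @export
order_scores_from_freq <- function(freq, k) {
  if (is.data.frame(freq)) freq <- setNames(freq$freq, freq$pattern)
  ords <- canonical_orders(k)
  P <- vapply(ords, function(o) {
    f <- 1
    for (L in seq_len(k - 1L)) {
      pat <- pattern_string(o[seq_len(L)], k)
      f <- f * (if (pat %in% names(freq)) freq[[pat]] else 0)
    }
    f
  }, numeric(1))
  tot <- sum(P)
  res <- data.frame(order = names(ords), P = unname(P),
                    p = if (tot > 0) unname(P) / tot else rep(NA_real_, length(P)),
                    stringsAsFactors = FALSE)
  attr(res, "scorable") <- tot > 0
  attr(res, "n_observed") <- sum(P > 0)
  attr(res, "N") <- k + 1L
  res
}

#' Splicing-order scores for one allele of an intron group
#'
#' @param counts data.frame from [level_pattern_counts()] restricted to, or
#'   containing, the allele of interest.
#' @param allele which allele to score.
#' @param k group size.
#' @inherit order_scores_from_freq return
#' @export
order_scores <- function(counts, allele = "hap1", k = 3L) {
  one <- counts[counts$allele == allele, , drop = FALSE]
  if (nrow(one) == 0L) stop("no counts for allele ", allele)
  fr <- level_frequencies(one, k)
  mid <- fr[fr$level >= 1 & fr$level <= k - 1, , drop = FALSE]
  order_scores_from_freq(setNames(mid$freq, mid$pattern), k)
}

## ---- mixture-implied quantities (ground truth for the simulator) -------

#' Level frequencies implied by a splicing-order mixture
#'
#' Given weights over removal orders, the implied frequency of an
#' intermediate isoform at level L is the total weight of orders whose first
#' L excised introns form that pattern.
#'
#' @param mixture named numeric vector: names are order strings
#'   (`"1->2->3"`), values are nonnegative weights summing to 1.
#' @param k group size.
#' @return data.frame `level`, `pattern`, `freq`.
#' @export
implied_level_frequencies <- function(mixture, k) {
  stopifnot(abs(sum(mixture) - 1) < 1e-8, all(mixture >= 0))
  ords <- parse_order(names(mixture))
  out <- do.call(rbind, lapply(0:k, function(L) {
    pats <- level_patterns(L, k)
    fr <- vapply(pats, function(p) {
      sum(mixture[vapply(ords, function(o)
        pattern_string(o[seq_len(L)], k) == p, logical(1))])
    }, numeric(1))
    data.frame(level = L, pattern = pats, freq = unname(fr),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Order scores implied by a splicing-order mixture
#'
#' Note that this is the score functional applied to the mixture-implied
#' level frequencies; it equals the indicator of the order for a degenerate
#' mixture, but for general mixtures it can place nonzero score on orders
#' absent from the mixture (frequencies factorise across levels, mixtures
#' need not).
#'
#' @inheritParams implied_level_frequencies
#' @inherit order_scores_from_freq return
#' @export
implied_order_scores <- function(mixture, k) {
  fr <- implied_level_frequencies(mixture, k)
  mid <- fr[fr$level >= 1 & fr$level <= k - 1, , drop = FALSE]
  order_scores_from_freq(setNames(mid$freq, mid$pattern), k)
}
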