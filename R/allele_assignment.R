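## Assignment of reads to parental haplotypes from phased heterozygous SNPs.

#' Observations of phased SNPs on one read
#'
#' For every SNP position covered by an aligned (`M`) base of the read,
#' reports whether the read base matches the haplotype-1 base, the
#' haplotype-2 base, or neither (`other`). Positions under `N` or `D`
#' operations yield no observation, and bases called `N` are skipped.
#' Indels in the variant table are skipped with a warning: only SNPs are
#' informative here.
#'
#' @param read list or one-row data.frame with `read_id`, `pos` (0-based),
#'   `cigar`, `seq`.
#' @param variants data.frame of phased heterozygous variants with columns
#'   `id`, `pos` (0-based), `ref`, `alt`, `hap1`, `hap2` (the base carried
#'   by each haplotype), e.g. from [read_phased_vcf()].
#' @return data.frame `read_id`, `variant_id`, `observed_allele`
#'   (`hap1`/`hap2`/`other`), one row per covered SNP.
#' @export
extract_variant_observations <- function(read, variants) {
  is_snp <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  if (any(!is_snp)) {
    warning(sum(!is_snp), " indel variant(s) skipped; only SNPs are considered")
    variants <- variants[is_snp, , drop = FALSE]
  }
  empty <- data.frame(read_id = character(), variant_id = character(),
                      observed_allele = character(), stringsAsFactors = FALSE)
  if (nrow(variants) == 0L) return(empty)
  ops <- GenomicAlignments::explodeCigarOps(read$cigar)[[1]]
  len <- GenomicAlignments::explodeCigarOpLengths(read$cigar)[[1]]
  ref_adv <- ifelse(ops %in% c("M", "=", "X", "D", "N"), len, 0L)
  qry_adv <- ifelse(ops %in% c("M", "=", "X", "I", "S"), len, 0L)
  ref_start <- read$pos + cumsum(c(0L, ref_adv[-length(ref_adv)]))
  qry_start <- cumsum(c(0L, qry_adv[-length(qry_adv)]))
  rows <- list()
  m_idx <- which(ops %in% c("M", "=", "X"))
  for (j in m_idx) {
    hit <- which(variants$pos >= ref_start[j] &
                   variants$pos < ref_start[j] + len[j])
    for (h in hit) {
      qpos <- qry_start[j] + (variants$pos[h] - ref_start[j])
      base <- substr(read$seq, qpos + 1L, qpos + 1L)
      if (base == "N" || base == "") next
      obs <- if (base == variants$hap1[h]) "hap1"
      else if (base == variants$hap2[h]) "hap2"
      else "other"
      rows[[length(rows) + 1L]] <-
        data.frame(read_id = read$read_id, variant_id = variants$id[h],
                   observed_allele = obs, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign one read to a haplotype from its SNP observations
#'
#' A read is assigned to the majority haplotype when at least
#' `min_informative` variants were identified on it and at least
#' `min_agreement` of them agree with one of the two alleles (exactly 75\%
#' passes). Observations matching neither haplotype count toward the
#' denominator but toward neither allele, so a 50/50 tie is always
#' undetermined.
#'
#' @param observations character vector of `hap1`/`hap2`/`other`
#'   observations, or a data.frame with column `observed_allele`.
#' @param min_informative minimum number of identified variants; default 2.
#' @param min_agreement minimum agreement fraction; default 0.75
#'   (inclusive).
#' @return list `allele` (`hap1`/`hap2`/`undetermined`), `n_informative`,
#'   `agreement`.
#' @export
assign_allele <- function(observations, min_informative = 2L,
                          min_agreement = 0.75) {
  if (is.data.frame(observations)) observations <- observations$observed_allele
  n <- length(observations)
  n1 <- sum(observations == "hap1")
  n2 <- sum(observations == "hap2")
  agreement <- if (n > 0) max(n1, n2) / n else 0
  allele <- "undetermined"
  if (n >= min_informative && agreement >= min_agreement && n1 != n2)
    allele <- if (n1 > n2) "hap1" else "hap2"
  list(allele = allele, n_informative = n, agreement = agreement)
}

#' Assign every read of an alignment set to a haplotype
#'
#' @param reads data.frame of alignments (`read_id`, `chrom`, `pos`,
#'   `cigar`, `seq`).
#' @param variants data.frame of phased heterozygous variants (see
#'   [extract_variant_observations()]); chromosome-matched per read.
#' @inheritParams assign_allele
#' @return data.frame `read_id`, `allele`, `n_informative`, `agreement`
#'   with one row per read (reads with no observation are undetermined).
#' @export
assign_alleles <- function(reads, variants, min_informative = 2L,
                           min_agreement = 0.75) {
  res <- lapply(seq_len(nrow(reads)), function(i) {
    v <- variants[variants$chrom == reads$chrom[i], , drop = FALSE]
    obs <- suppressWarnings(extract_variant_observations(reads[i, ], v))
    a <- assign_allele(obs$observed_allele, min_informative, min_agreement)
    data.frame(read_id = reads$read_id[i], allele = a$allele,
               n_informative = a$n_informative, agreement = a$agreement,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
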