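## End-to-end orchestration: SAM/VCF/BED in, TSV tables out.

#' Pipeline configuration
#'
#' Collects input paths and every analysis threshold, at the documented
#' defaults: 50-nt splice-site windows, 10\% splicing-event size tolerance,
#' distance threshold 0.379, FDR 0.05, 10-read minimum for intron pairs and
#' triples, 20-read minimum per gene, 10-nt minimum 3'-end shift, allelic
#' ratio skew bounds (0.4, 0.6), and the >= 2 SNP / 75\% agreement
#' allele-assignment rule.
#'
#' @param bam path to SAM/BAM alignments.
#' @param vcf path to phased heterozygous SNP VCF.
#' @param annotation path to the intron BED6 track.
#' @param outdir output directory.
#' @param ss_window,size_tol,boundary_tol intron-status parameters.
#' @param tau distance threshold (or `"calibrate"` with
#'   `replicate_distances`).
#' @param replicate_distances optional numeric vector for
#'   [calibrate_threshold()].
#' @param fdr FDR cutoff used by every caller.
#' @param pair_min_reads,triple_min_reads,gene_min_reads coverage filters.
#' @param end_shift_min minimum 3'-end mean shift (nt).
#' @param ratio_bounds allelic-ratio skew bounds.
#' @param agreement_min,min_informative allele-assignment rule.
#' @param polya_tag SAM tag with per-read poly(A) lengths.
#' @param seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return list of class `RunConfig`.
#' @export
run_config <- function(bam, vcf, annotation, outdir,
                       ss_window = 50L, size_tol = 0.10, boundary_tol = 50L,
                       tau = tau_default, replicate_distances = NULL,
                       fdr = 0.05, pair_min_reads = 10L,
                       triple_min_reads = 10L, gene_min_reads = 20L,
                       end_shift_min = 10, ratio_bounds = c(0.4, 0.6),
                       agreement_min = 0.75, min_informative = 2L,
                       polya_tag = "pt", seed = 1L) {
  structure(as.list(environment()), class = "RunConfig")
}

#' Consecutive intron groups of one gene
#'
#' Sliding windows of `k` consecutive analysed introns, in transcript
#' order. Duplicated groups with identical genomic coordinates (identical
#' gene + indices here) are kept once.
#'
#' @param intron_indices sorted transcript-order intron indices of a gene.
#' @param k window size (2 for pairs, 3 for triples).
#' @return list of integer vectors.
#' @export
consecutive_groups <- function(intron_indices, k = 3L) {
  idx <- sort(unique(intron_indices))
  out <- list()
  if (length(idx) < k) return(out)
  for (i in seq_len(length(idx) - k + 1L)) {
    w <- idx[i:(i + k - 1L)]
    if (all(diff(w) == 1L)) out[[length(out) + 1L]] <- w
  }
  out
}

#' Per-intron retained-read counts by allele
#' @noRd
retained_counts <- function(calls, alleles, group) {
  if (is.data.frame(alleles))
    alleles <- setNames(alleles$allele, alleles$read_id)
  sub <- calls[calls$intron_index %in% group &
                 calls$status == "not_excised", , drop = FALSE]
  al <- unname(alleles[sub$read_id]); al[is.na(al)] <- "undetermined"
  lapply(setNames(nm = c("hap1", "hap2", "undetermined")), function(h)
    vapply(group, function(i)
      sum(al == h & sub$intron_index == i), numeric(1)))
}

#' Splicing-order analysis of one dataset
#'
#' Forms consecutive intron triples and pairs per gene, counts intermediate
#' isoforms per allele, applies the coverage filters and scores the groups
#' that pass.
#'
#' @param calls intron-call table from [classify_alignments()].
#' @param alleles allele-call table from [assign_alleles()] (or a named
#'   vector).
#' @param introns intron annotation (as from [read_intron_bed()]).
#' @param min_reads triple/pair read filters; default 10.
#' @return list with `group_counts` (named list of filtered triple count
#'   tables, ready for [compare_alleles()]), `scores` (long data.frame
#'   `group_id`, `allele`, `order`, `P`, `p`), `level_counts` (long
#'   data.frame over all filtered groups) and `pair_counts` (data.frame for
#'   [compare_pairs()]).
#' @export
order_analysis <- function(calls, alleles, introns, min_reads = 10L) {
  if (is.data.frame(alleles))
    allele_map <- setNames(alleles$allele, alleles$read_id)
  else allele_map <- alleles
  group_counts <- list()
  pair_rows <- list()
  for (gene in unique(introns$gene_id)) {
    gi <- introns[introns$gene_id == gene, ]
    gc <- calls[calls$gene_id == gene, , drop = FALSE]
    if (nrow(gc) == 0L) next
    for (grp in consecutive_groups(gi$intron_index, 3L)) {
      gid <- sprintf("%s:%s", gene, paste(grp, collapse = "-"))
      pats <- spanning_patterns(grp, gc)
      if (nrow(pats) == 0L) next
      counts <- level_pattern_counts(pats, allele_map, 3L)
      ret <- retained_counts(gc, allele_map, grp)
      if (passes_triple_filters(counts, ret, 3L, min_reads))
        group_counts[[gid]] <- counts
    }
    for (grp in consecutive_groups(gi$intron_index, 2L)) {
      gid <- sprintf("%s:%s", gene, paste(grp, collapse = "-"))
      pats <- spanning_patterns(grp, gc)
      if (nrow(pats) == 0L) next
      inf <- pats[pats$pattern %in% c("10", "01"), , drop = FALSE]
      al <- unname(allele_map[inf$read_id]); al[is.na(al)] <- "undetermined"
      n_up <- function(h) sum(al == h & inf$pattern == "10")
      n_dn <- function(h) sum(al == h & inf$pattern == "01")
      n1 <- n_up("hap1") + n_dn("hap1"); n2 <- n_up("hap2") + n_dn("hap2")
      nu <- n_up("undetermined") + n_dn("undetermined")
      if (passes_pair_filters(n1, n2, nu, min_reads))
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          group_id = gid, hap1_up = n_up("hap1"), hap1_down = n_dn("hap1"),
          hap2_up = n_up("hap2"), hap2_down = n_dn("hap2"),
          stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, lapply(names(group_counts), function(gid) {
    do.call(rbind, lapply(c("hap1", "hap2"), function(h) {
      s <- order_scores(group_counts[[gid]], h, 3L)
      cbind(data.frame(group_id = gid, allele = h,
                       stringsAsFactors = FALSE), s)
    }))
  }))
  level_counts <- do.call(rbind, lapply(names(group_counts), function(gid)
    cbind(data.frame(group_id = gid, stringsAsFactors = FALSE),
          group_counts[[gid]])))
  pair_counts <- do.call(rbind, pair_rows)
  list(group_counts = group_counts, scores = scores,
       level_counts = level_counts, pair_counts = pair_counts)
}

#' Per-read feature table for the allelic comparisons
#'
#' Joins alignments, intron calls, splice states and allele calls into one
#' read-level table. Reads are assigned to the gene whose intron span they
#' overlap most; the 3'-end position is the alignment end on the plus
#' strand and the alignment start on the minus strand.
#'
#' @param aln alignment table from [read_alignments()].
#' @param calls intron-call table from [classify_alignments()].
#' @param alleles allele-call table from [assign_alleles()].
#' @param introns intron annotation.
#' @return data.frame `read_id`, `gene_id`, `allele`, `polya`, `end_pos`,
#'   `splice_state`.
#' @export
read_feature_table <- function(aln, calls, alleles, introns) {
  spans <- do.call(rbind, lapply(split(introns, introns$gene_id), function(g)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = min(g$start) - 500L, end = max(g$end) + 500L,
               strand = g$strand[1], stringsAsFactors = FALSE)))
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar)
  aln_end <- aln$pos + width
  gene <- character(nrow(aln)); gstrand <- character(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    cand <- spans[spans$chrom == aln$chrom[i] & spans$start < aln_end[i] &
                    spans$end > aln$pos[i], , drop = FALSE]
    if (nrow(cand) == 0L) { gene[i] <- NA_character_; next }
    ov <- pmin(cand$end, aln_end[i]) - pmax(cand$start, aln$pos[i])
    j <- which.max(ov)
    gene[i] <- cand$gene_id[j]; gstrand[i] <- cand$strand[j]
  }
  end_pos <- ifelse(gstrand == "-", aln$pos, aln_end - 1L)
  states <- read_splice_states(calls)
  state_map <- setNames(states$splice_state,
                        paste(states$read_id, states$gene_id))
  allele_map <- setNames(alleles$allele, alleles$read_id)
  al <- unname(allele_map[aln$read_id]); al[is.na(al)] <- "undetermined"
  out <- data.frame(read_id = aln$read_id, gene_id = gene, allele = al,
                    polya = aln$polya, end_pos = end_pos,
                    splice_state = unname(state_map[paste(aln$read_id, gene)]),
                    stringsAsFactors = FALSE)
  out[!is.na(out$gene_id), , drop = FALSE]
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full allele-specific maturation pipeline
#'
#' Chains alignment reading, intron-status classification, haplotype
#' assignment, splicing-order scoring, allele comparison and the allelic
#' feature tables, writing every result as a TSV under `config$outdir`
#' together with a JSON run manifest (package version, seed, configuration
#' and its hash). Identical configuration yields byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a named list with every result table and the output
#'   paths.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(splicord = as.character(utils::packageVersion("splicord")),
            seed = as.character(config$seed))
  outfile <- function(name) file.path(config$outdir, name)

  aln <- run_stage("read_alignments",
                   read_alignments(config$bam, config$polya_tag))
  introns <- run_stage("read_annotation", read_intron_bed(config$annotation))
  snps <- run_stage("read_vcf", read_phased_vcf(config$vcf))

  calls <- run_stage("intron_status",
                     classify_alignments(aln, introns, config$ss_window,
                                         config$size_tol,
                                         config$boundary_tol))
  write_tsv_meta(calls, outfile("status.tsv"), meta)

  alleles <- run_stage("allele_assignment",
                       assign_alleles(aln, snps, config$min_informative,
                                      config$agreement_min))
  write_tsv_meta(alleles, outfile("alleles.tsv"), meta)

  ord <- run_stage("splicing_order",
                   order_analysis(calls, alleles, introns,
                                  config$triple_min_reads))
  if (!is.null(ord$level_counts))
    write_tsv_meta(ord$level_counts, outfile("level_counts.tsv"), meta)
  if (!is.null(ord$scores))
    write_tsv_meta(ord$scores, outfile("scores.tsv"), meta)

  tau <- config$tau
  if (identical(tau, "calibrate"))
    tau <- calibrate_threshold(config$replicate_distances)
  comparison <- run_stage("allele_comparison", {
    if (length(ord$group_counts) > 0L)
      compare_alleles(ord$group_counts, 3L, tau, config$fdr)
    else NULL
  })
  if (!is.null(comparison))
    write_tsv_meta(comparison, outfile("comparison.tsv"), meta)
  pair_comparison <- run_stage("pair_comparison", {
    if (!is.null(ord$pair_counts))
      compare_pairs(ord$pair_counts, config$fdr)
    else NULL
  })
  if (!is.null(pair_comparison))
    write_tsv_meta(pair_comparison, outfile("pair_comparison.tsv"), meta)

  features <- run_stage("feature_table",
                        read_feature_table(aln, calls, alleles, introns))
  polya <- run_stage("polya", polya_table(features, config$gene_min_reads,
                                          config$fdr))
  if (!is.null(polya)) write_tsv_meta(polya, outfile("polya.tsv"), meta)
  polya_cls <- run_stage("polya_by_class",
                         polya_by_splice_state(features,
                                               config$gene_min_reads,
                                               config$fdr))
  if (!is.null(polya_cls))
    write_tsv_meta(polya_cls, outfile("polya_by_class.tsv"), meta)
  ends <- run_stage("three_prime_ends",
                    ends_table(features, config$gene_min_reads, config$fdr,
                               config$end_shift_min))
  if (!is.null(ends)) write_tsv_meta(ends, outfile("ends.tsv"), meta)
  abundance <- run_stage("abundance",
                         abundance_table(features, config$gene_min_reads,
                                         config$fdr, config$ratio_bounds))
  if (!is.null(abundance))
    write_tsv_meta(abundance, outfile("abundance.tsv"), meta)

  cfg <- config[setdiff(names(config), "replicate_distances")]
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(package = "splicord",
                   version = as.character(utils::packageVersion("splicord")),
                   seed = config$seed, tau = tau,
                   config = cfg, config_md5 = unname(tools::md5sum(tmp)))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(tmp)

  invisible(list(alignments = aln, calls = calls, alleles = alleles,
                 order = ord, comparison = comparison,
                 pair_comparison = pair_comparison, features = features,
                 polya = polya, polya_by_class = polya_cls, ends = ends,
                 abundance = abundance, outdir = config$outdir))
}
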