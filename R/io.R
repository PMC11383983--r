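## Readers and writers for the pipeline's interchange formats.
##
## SAM and VCF fixture writing is plain line-based text (the simulator's
## records are simple: M/N/S CIGARs and one numeric tag); files round-trip
## through Rsamtools / vcfR / rtracklayer readers, which validates them.
## TSV outputs carry "#"-prefixed metadata lines before the header.

#' Write a simulated dataset as SAM + VCF + BED + truth TSV
#'
#' @param sim a `SplicordSim` from [simulate_reads()] or [combine_sims()].
#' @param outdir output directory (created if needed).
#' @param polya_tag two-letter SAM tag for the per-read poly(A) length
#'   (float); default `"pt"`.
#' @return invisibly, a named list of the written file paths (`sam`, `vcf`,
#'   `bed`, `truth`).
#' @export
write_fixture <- function(sim, outdir, polya_tag = "pt") {
  if (is.null(sim$records) || nrow(sim$records) == 0L ||
      is.null(sim$truth) || nrow(sim$truth) == 0L)
    stop("empty simulation: nothing to write")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(sam = file.path(outdir, "reads.sam"),
                vcf = file.path(outdir, "variants.vcf"),
                bed = file.path(outdir, "introns.bed"),
                truth = file.path(outdir, "truth.tsv"))

  ## SAM, coordinate-sorted
  rec <- sim$records[order(sim$records$chrom, sim$records$pos), , drop = FALSE]
  chrom_len <- tapply(vapply(sim$models, function(m)
    as.integer(m$span[2] + 2000L), integer(1)),
                      vapply(sim$models, `[[`, "", "chrom"), max)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_len), chrom_len),
           "@PG\tID:splicord\tPN:splicord")
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\t%s:f:%s",
                  rec$read_id, rec$flag, rec$chrom, rec$pos + 1L, rec$mapq,
                  rec$cigar, rec$seq, polya_tag,
                  sprintf("%.1f", rec$polya))
  writeLines(c(hdr, body), paths$sam)

  ## VCF 4.2, phased heterozygous SNPs, GT relative to REF/ALT
  if (!is.null(sim$snps) && nrow(sim$snps) > 0L) {
    s <- sim$snps[order(sim$snps$chrom, sim$snps$pos), , drop = FALSE]
    gt <- ifelse(s$hap1 == s$ref, "0|1", "1|0")
    vhdr <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(chrom_len),
                      chrom_len),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSIM")
    vbody <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.\tGT\t%s",
                     s$chrom, s$pos + 1L, s$id, s$ref, s$alt, gt)
    writeLines(c(vhdr, vbody), paths$vcf)
  }

  ## BED6 intron track; score = transcript-order intron index
  introns <- do.call(rbind, lapply(sim$models, model_introns))
  bed <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", introns$chrom, introns$start,
                 introns$end,
                 sprintf("%s_intron%d", introns$gene_id, introns$intron_index),
                 introns$intron_index, introns$strand)
  writeLines(bed, paths$bed)

  write_tsv_meta(sim$truth, paths$truth,
                 meta = c(source = "splicord simulate"))
  invisible(paths)
}

#' Read spliced long-read alignments from SAM or BAM
#'
#' SAM input is converted with [Rsamtools::asBam()] before reading. The
#' per-read poly(A) length is taken from `polya_tag` when present.
#'
#' @param path SAM or BAM file.
#' @param polya_tag SAM tag holding the poly(A) length; default `"pt"`.
#' @return data.frame `read_id`, `chrom`, `strand`, `pos` (0-based),
#'   `cigar`, `seq`, `polya` (NA when untagged), suitable for
#'   [classify_alignments()] and [assign_alleles()].
#' @export
read_alignments <- function(path, polya_tag = "pt") {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq"),
    tag = polya_tag)
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  polya <- x$tag[[polya_tag]]
  if (is.null(polya)) polya <- rep(NA_real_, length(x$qname))
  data.frame(read_id = x$qname, chrom = as.character(x$rname),
             strand = as.character(x$strand), pos = x$pos - 1L,
             cigar = x$cigar, seq = as.character(x$seq), polya = polya,
             stringsAsFactors = FALSE)
}

#' Read an intron annotation track (BED6)
#'
#' Intron names must encode the gene and transcript-order index as
#' `<gene>_intron<i>` (as written by [write_fixture()]); the BED score
#' column, when present, is used as the index.
#'
#' @param path BED file.
#' @return data.frame `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `intron_index`.
#' @export
read_intron_bed <- function(path) {
  g <- rtracklayer::import(path)
  nm <- g$name
  gene <- sub("_intron[0-9]+$", "", nm)
  idx <- suppressWarnings(as.integer(sub("^.*_intron", "", nm)))
  if (!is.null(g$score) && !anyNA(g$score)) idx <- as.integer(g$score)
  data.frame(gene_id = gene, chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g) - 1L,
             end = GenomicRanges::end(g),
             strand = as.character(GenomicRanges::strand(g)),
             intron_index = idx, stringsAsFactors = FALSE)
}

#' Read phased heterozygous SNPs from a VCF
#'
#' Keeps biallelic SNPs with a phased heterozygous genotype (`0|1` or
#' `1|0`) in the first sample; indels and unphased records are dropped with
#' a message.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return data.frame `id`, `chrom`, `pos` (0-based), `ref`, `alt`, `hap1`,
#'   `hap2`.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  phased_het <- gt %in% c("0|1", "1|0")
  drop <- sum(!(is_snp & phased_het))
  if (drop > 0L)
    message(drop, " non-SNP or non-phased-het record(s) dropped")
  keep <- which(is_snp & phased_het)
  fix <- fix[keep, , drop = FALSE]; gt <- gt[keep]
  data.frame(id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
             ref = fix$REF, alt = fix$ALT,
             hap1 = ifelse(gt == "0|1", fix$REF, fix$ALT),
             hap2 = ifelse(gt == "0|1", fix$ALT, fix$REF),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a TSV with "#"-prefixed metadata lines
#'
#' @param df data.frame.
#' @param path output path.
#' @param meta named character vector written as `#name=value` lines.
#' @export
write_tsv_meta <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta) > 0L)
    writeLines(sprintf("#%s=%s", names(meta), unname(meta)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path TSV path.
#' @return data.frame (metadata lines are skipped; they remain available as
#'   the `"meta"` attribute).
#' @export
read_tsv_meta <- function(path) {
  lines <- readLines(path, n = 100L)
  meta <- grep("^#", lines, value = TRUE)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "meta") <- sub("^#", "", meta)
  df
}
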