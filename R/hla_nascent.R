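## Nascent-transcriptome construction for highly polymorphic loci.
##
## For genes where genome alignment produces artifacts (e.g. the small exon
## 6 of HLA class I genes), splicing order can instead be computed after
## alignment to an enumerated nascent transcriptome: every combination of
## retained introns of the gene, built from the haplotype sequence.

#' Enumerate all retained-intron nascent isoforms of a gene
#'
#' Builds the 2^n isoform sequences of an n-intron gene, one per subset of
#' retained introns, from a haplotype sequence covering the gene span. The
#' fully spliced isoform is the concatenation of the exons; the completely
#' unspliced isoform is the whole gene span. Isoform names encode the gene,
#' haplotype and retained-intron bitmask (transcript order, 5' to 3'), so
#' they are unique and decodable.
#'
#' @param model a `GeneModel`.
#' @param hap_seq haplotype sequence of the gene span (character or
#'   [Biostrings::DNAString]), position 1 = `model$span[1]`; defaults to the
#'   model's own reference sequence.
#' @param hap haplotype label used in isoform names.
#' @return list with `seqs` (a [Biostrings::DNAStringSet], minus-strand
#'   genes reverse-complemented so sequences read 5' to 3' in transcript
#'   orientation), and `info` (data.frame `name`, `mask`, `n_retained`,
#'   `length`, plus `intron_start`/`intron_end` columns giving each retained
#'   intron's interval in isoform coordinates as a semicolon-joined string).
#' @export
enumerate_retained_intron_isoforms <- function(model, hap_seq = NULL,
                                               hap = "hap1") {
  if (is.null(hap_seq)) hap_seq <- model$refseq
  hap_seq <- as.character(hap_seq)
  span_len <- model$span[2] - model$span[1]
  if (nchar(hap_seq) < span_len)
    stop("haplotype sequence shorter than the gene span")
  n <- nrow(model$introns)
  masks <- 0:(2^n - 1L)
  seqs <- character(length(masks))
  info <- vector("list", length(masks))
  for (m in seq_along(masks)) {
    bits <- as.integer(intToBits(masks[m]))[seq_len(n)]  # transcript order
    retained_tx <- which(bits == 1L)
    excised_tx <- setdiff(seq_len(n), retained_tx)
    segs <- molecule_segments(model, excised_tx, model$span[1], model$span[2])
    parts <- vapply(seq_len(nrow(segs)), function(i)
      substr(hap_seq, segs[i, "start"] - model$span[1] + 1L,
             segs[i, "end"] - model$span[1]), "")
    iso <- paste(parts, collapse = "")
    ## isoform-local coordinates of retained introns (genomic orientation)
    loc <- lapply(retained_tx, function(ti) {
      iv <- intron_interval(model, ti)
      before <- sum(pmax(0, pmin(segs[, "end"], iv[1]) - segs[, "start"]))
      c(start = before, end = before + (iv[2] - iv[1]))
    })
    if (model$strand == "-") {
      iso <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(iso)))
      L <- nchar(iso)
      loc <- lapply(loc, function(x) c(start = L - x[["end"]],
                                       end = L - x[["start"]]))
    }
    name <- sprintf("%s_%s_%s", model$gene_id, hap,
                    paste(bits, collapse = ""))
    seqs[m] <- iso
    info[[m]] <- data.frame(
      name = name, mask = paste(bits, collapse = ""),
      n_retained = length(retained_tx), length = nchar(iso),
      retained_introns = paste(retained_tx, collapse = ";"),
      intron_start = paste(vapply(loc, `[[`, numeric(1), "start"),
                           collapse = ";"),
      intron_end = paste(vapply(loc, `[[`, numeric(1), "end"),
                         collapse = ";"),
      stringsAsFactors = FALSE)
  }
  info <- do.call(rbind, info)
  rownames(info) <- NULL
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- info$name
  list(seqs = ss, info = info)
}

#' Write a nascent isoform set as multi-FASTA
#'
#' @param isoforms result of [enumerate_retained_intron_isoforms()].
#' @param path output FASTA path.
#' @export
write_nascent_fasta <- function(isoforms, path) {
  Biostrings::writeXStringSet(isoforms$seqs, path)
  invisible(path)
}

#' Alignment match percentage from CIGAR/NM statistics
#'
#' The edit distance (`NM`) is subtracted from the total of matches (`M`)
#' and insertions (`I`), and the result is divided by the total of matches
#' and insertions: `100 * (M + I - NM) / (M + I)`.
#'
#' @param M aligned/matched bases.
#' @param I inserted bases.
#' @param NM edit distance.
#' @return percentage in `[0, 100]`.
#' @export
alignment_match_percent <- function(M, I, NM) {
  if (any(M < 0) || any(I < 0) || any(NM < 0)) stop("M, I, NM must be >= 0")
  if (any(M + I == 0)) stop("match percentage undefined when M + I = 0")
  if (any(NM > M + I)) stop("NM cannot exceed M + I")
  100 * (M + I - NM) / (M + I)
}

#' Intron calls from transcriptome-style alignment of error-free reads
#'
#' Emulates alignment of simulated reads to the enumerated nascent
#' transcriptome: each read maps end-to-end (all-`M` CIGAR) to the isoform
#' whose retained-intron set matches the read's excision pattern. Introns
#' retained in that isoform are then classified by [classify_intron()]
#' against the isoform's own intron coordinates; introns absent from the
#' isoform are excised by construction. Used to check that splicing-order
#' scores agree between genome-style and transcriptome-style alignment.
#'
#' @param model a `GeneModel`.
#' @param truth per-read truth table from [simulate_reads()] (columns
#'   `read_id`, `pattern`).
#' @return data.frame `read_id`, `gene_id`, `intron_index`, `status`, same
#'   shape as [classify_alignments()] output.
#' @export
transcriptome_splice_calls <- function(model, truth) {
  k <- nrow(model$introns)
  iso <- enumerate_retained_intron_isoforms(model)
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    pat <- truth$pattern[i]
    retained_mask <- chartr("01", "10", pat)  # retained = not excised
    m <- iso$info[iso$info$mask == retained_mask, ]
    st <- setNames(rep("excised", k), seq_len(k))
    if (m$n_retained > 0) {
      rs <- as.numeric(strsplit(m$intron_start, ";")[[1]])
      re <- as.numeric(strsplit(m$intron_end, ";")[[1]])
      ri <- as.integer(strsplit(m$retained_introns, ";")[[1]])
      segs <- data.frame(op = "M", start = 0, end = m$length,
                         stringsAsFactors = FALSE)
      for (j in seq_along(ri))
        st[ri[j]] <- classify_intron(segs, rs[j], re[j], strand = "+")
    }
    rows[[i]] <- data.frame(read_id = truth$read_id[i],
                            gene_id = model$gene_id,
                            intron_index = seq_len(k), status = unname(st),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
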