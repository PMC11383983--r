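#' Build a multi-intron gene model
#'
#' Constructs a strand-aware gene model with alternating exons and introns and
#' a random reference sequence over the gene span. Coordinates are 0-based
#' half-open. Intron and exon indices are always given in transcript
#' orientation (intron 1 is the 5'-most intron of the transcript), so on the
#' minus strand intron 1 occupies the highest genomic coordinates.
#'
#' @param n_introns number of introns (>= 1); the model has `n_introns + 1`
#'   exons.
#' @param exon_len,intron_len lengths in nucleotides; both must be >= 60 so
#'   that the splice-site windows used by [classify_intron()] are meaningful.
#' @param seed integer seed controlling the reference sequence and gene start
#'   offset; identical seeds give byte-identical models.
#' @param gene_id,chrom identifiers used in emitted files.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `GeneModel`: a list with `gene_id`, `chrom`,
#'   `strand`, `exons` and `introns` (two-column matrices of genomic
#'   `[start, end)` intervals sorted by coordinate), `tss`, `span` and
#'   `refseq` (reference sequence of the span, position 1 = `span[1]`).
#' @export
#' @examples
#' gm <- make_gene_model(3, exon_len = 200, intron_len = 1000, seed = 1)
#' nrow(gm$introns)  # 3
make_gene_model <- function(n_introns, exon_len = 200, intron_len = 1000,
                            seed = 1, gene_id = "gene1", chrom = "chrSim",
                            strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (length(n_introns) != 1L || is.na(n_introns) || n_introns < 1)
    stop("n_introns must be >= 1")
  if (exon_len < 60 || intron_len < 60)
    stop("exon_len and intron_len must be >= 60 (splice-site windows would be degenerate)")
  n_introns <- as.integer(n_introns)

  set.seed(seed)
  start <- 1000L + sample.int(1000L, 1L)
  n_ex <- n_introns + 1L
  exon_starts <- start + (0:(n_ex - 1L)) * (exon_len + intron_len)
  exons <- cbind(start = exon_starts, end = exon_starts + exon_len)
  introns <- cbind(start = exons[-n_ex, "end"], end = exons[-1L, "start"])
  rownames(exons) <- rownames(introns) <- NULL
  span <- c(start, exons[n_ex, "end"])
  refseq <- paste(sample(c("A", "C", "G", "T"), span[2] - span[1],
                         replace = TRUE), collapse = "")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, introns = introns,
                 tss = if (strand == "+") span[1] else span[2] - 1L,
                 span = span, refseq = refseq),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s%s): %d exons, %d introns, span [%d, %d)\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons), nrow(x$introns),
              x$span[1], x$span[2]))
  invisible(x)
}

#' Genomic interval of a transcript-order intron
#'
#' @param model a `GeneModel`.
#' @param i intron index in transcript orientation (1 = 5'-most intron).
#' @return numeric `[start, end)` of length 2.
#' @export
intron_interval <- function(model, i) {
  n <- nrow(model$introns)
  if (any(i < 1 | i > n)) stop("intron index out of range")
  g <- if (model$strand == "+") i else n - i + 1L
  model$introns[g, , drop = FALSE]
}

#' Transcript-order intron table for one gene model
#'
#' @param model a `GeneModel`.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand` and transcript-order `intron_index`.
#' @export
model_introns <- function(model) {
  n <- nrow(model$introns)
  idx <- if (model$strand == "+") seq_len(n) else rev(seq_len(n))
  data.frame(gene_id = model$gene_id, chrom = model$chrom,
             start = model$introns[, "start"], end = model$introns[, "end"],
             strand = model$strand, intron_index = idx,
             stringsAsFactors = FALSE)
}

#' Extract a subsequence of the model reference in genomic coordinates
#' @noRd
model_seq <- function(model, start, end) {
  substr(model$refseq, start - model$span[1] + 1L, end - model$span[1])
}
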