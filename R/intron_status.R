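## Excision-status classification of introns from spliced alignments.
##
## Every (read, intron) pair is assigned exactly one of four statuses from
## the read's CIGAR string: excised, not_excised, skipped, undetermined.
## Rules are applied in that order; undetermined is the fall-through.

#' Reference-consuming segments of a CIGAR string
#'
#' @param cigar CIGAR string.
#' @param pos0 0-based leftmost aligned reference position.
#' @return data.frame `op`, `start`, `end` (0-based half-open reference
#'   intervals) for ops consuming the reference (M/=/X, D, N).
#' @export
cigar_ref_segments <- function(cigar, pos0) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  len <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  consumes <- ops %in% c("M", "=", "X", "D", "N")
  adv <- ifelse(consumes, len, 0L)
  start <- pos0 + cumsum(c(0L, adv[-length(adv)]))
  keep <- consumes
  data.frame(op = ifelse(ops %in% c("=", "X"), "M", ops)[keep],
             start = start[keep], end = (start + adv)[keep],
             stringsAsFactors = FALSE)
}

overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

coverage_in <- function(segs, a, b) {
  m <- segs[segs$op == "M", , drop = FALSE]
  if (nrow(m) == 0L || b <= a) return(0)
  sum(overlap_len(m$start, m$end, a, b))
}

#' Classify the excision status of one intron on one read
#'
#' Statuses, applied in order:
#' \describe{
#'   \item{excised}{an `N` (splicing) operation starts within
#'     `boundary_tol` nt of the intron start and ends within `boundary_tol`
#'     nt of the intron end, and the `N` length is within `size_tol` of the
#'     annotated intron size (inclusive at the boundary).}
#'   \item{not_excised}{no `N` operation in the examined region, more than
#'     50\% `M` coverage in the `ss_window`-nt window surrounding each splice
#'     site, and more than 75\% `M` coverage of the portion of the intron the
#'     read maps to. Reads starting (transcript 5' end) within the intron,
#'     with no coverage of the 5' splice site, qualify if they meet the
#'     criteria at the 3' splice site.}
#'   \item{skipped}{an `N` operation overlaps more than half of the window
#'     surrounding the 5' and/or 3' splice site and the portion of the
#'     intron inside the `N` is within `size_tol` of the annotated intron
#'     size (alternative splice sites, skipped exons).}
#'   \item{undetermined}{anything else.}
#' }
#' When several `N` operations overlap the intron, the one with the largest
#' overlap is evaluated first.
#'
#' @param segs data.frame from [cigar_ref_segments()] (or a list with
#'   `cigar` and `pos` to be parsed).
#' @param intron_start,intron_end 0-based half-open intron interval.
#' @param strand gene strand, determines which boundary is the 5' splice
#'   site.
#' @param ss_window total width in nt of the window surrounding each splice
#'   site (half on each side); default 50.
#' @param size_tol relative tolerance on the splicing-event size; default
#'   0.10, inclusive.
#' @param boundary_tol maximum distance in nt between `N` boundaries and the
#'   annotated splice sites for the excised rule; default 50.
#' @return one of `"excised"`, `"not_excised"`, `"skipped"`,
#'   `"undetermined"`, or `NA_character_` when the read does not overlap the
#'   intron's windowed region (the pair is excluded, not undetermined).
#' @export
classify_intron <- function(segs, intron_start, intron_end,
                            strand = "+", ss_window = 50L, size_tol = 0.10,
                            boundary_tol = 50L) {
  if (!is.data.frame(segs))
    segs <- cigar_ref_segments(segs$cigar, segs$pos)
  half <- ss_window / 2
  s <- intron_start; e <- intron_end
  ilen <- e - s
  rs <- min(segs$start); re <- max(segs$end)
  region <- c(s - half, e + half)
  if (re <= region[1] || rs >= region[2]) return(NA_character_)

  ## windows surrounding the two boundaries; 5'SS is the boundary on the
  ## transcript-upstream side (genomic start for "+", genomic end for "-")
  win_s <- c(s - half, s + half)
  win_e <- c(e - half, e + half)
  if (strand == "+") { win5 <- win_s; win3 <- win_e }
  else               { win5 <- win_e; win3 <- win_s }

  nsegs <- segs[segs$op == "N", , drop = FALSE]
  if (nrow(nsegs) > 0L) {
    ov <- overlap_len(nsegs$start, nsegs$end, s, e)
    nsegs <- nsegs[order(-ov), , drop = FALSE]
  }

  ## 1. excised
  if (nrow(nsegs) > 0L) {
    hit <- abs(nsegs$start - s) <= boundary_tol &
      abs(nsegs$end - e) <= boundary_tol &
      abs((nsegs$end - nsegs$start) - ilen) / ilen <= size_tol
    if (any(hit)) return("excised")
  }

  ## 2. not excised: no N in the examined region, coverage criteria
  n_in_region <- nrow(nsegs) > 0L &&
    any(overlap_len(nsegs$start, nsegs$end, region[1], region[2]) > 0)
  if (!n_in_region) {
    mapped <- c(max(s, rs), min(e, re))
    body_ok <- mapped[2] > mapped[1] &&
      coverage_in(segs, mapped[1], mapped[2]) > 0.75 * (mapped[2] - mapped[1])
    cov5_ok <- coverage_in(segs, win5[1], win5[2]) > 0.5 * ss_window
    cov3_ok <- coverage_in(segs, win3[1], win3[2]) > 0.5 * ss_window
    if (cov5_ok && cov3_ok && body_ok) return("not_excised")
    ## read starts (transcript 5' end) within the intron: 3'SS criteria only
    started_within <- if (strand == "+") rs > s && rs < e else re < e && re > s
    if (started_within && cov3_ok && body_ok) return("not_excised")
  }

  ## 3. skipped splice sites
  if (nrow(nsegs) > 0L) {
    for (i in seq_len(nrow(nsegs))) {
      ns <- nsegs$start[i]; ne <- nsegs$end[i]
      ov5 <- overlap_len(ns, ne, win5[1], win5[2])
      ov3 <- overlap_len(ns, ne, win3[1], win3[2])
      ov_body <- overlap_len(ns, ne, s, e)
      if ((ov5 > 0.5 * ss_window || ov3 > 0.5 * ss_window) &&
          abs(ov_body - ilen) / ilen <= size_tol)
        return("skipped")
    }
  }

  "undetermined"
}

#' Classify every (read, intron) pair of an alignment set
#'
#' @param reads data.frame of alignments with columns `read_id`, `chrom`,
#'   `pos` (0-based), `cigar` (e.g. from [read_alignments()]).
#' @param introns data.frame of introns with columns `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `intron_index`
#'   (transcript order), e.g. from [read_intron_bed()] or [model_introns()].
#' @inheritParams classify_intron
#' @return long data.frame `read_id`, `gene_id`, `intron_index`, `status`;
#'   pairs where the read does not overlap the intron's windowed region are
#'   omitted.
#' @export
classify_alignments <- function(reads, introns, ss_window = 50L,
                                size_tol = 0.10, boundary_tol = 50L) {
  if (nrow(reads) == 0L)
    return(data.frame(read_id = character(), gene_id = character(),
                      intron_index = integer(), status = character(),
                      stringsAsFactors = FALSE))
  ops_all <- GenomicAlignments::explodeCigarOps(reads$cigar)
  len_all <- GenomicAlignments::explodeCigarOpLengths(reads$cigar)
  out <- vector("list", nrow(reads))
  half <- ss_window / 2
  for (r in seq_len(nrow(reads))) {
    ops <- ops_all[[r]]; len <- len_all[[r]]
    consumes <- ops %in% c("M", "=", "X", "D", "N")
    adv <- ifelse(consumes, len, 0L)
    start <- reads$pos[r] + cumsum(c(0L, adv[-length(adv)]))
    segs <- data.frame(op = ifelse(ops %in% c("=", "X"), "M", ops)[consumes],
                       start = start[consumes],
                       end = (start + adv)[consumes],
                       stringsAsFactors = FALSE)
    rs <- min(segs$start); re <- max(segs$end)
    cand <- introns[introns$chrom == reads$chrom[r] &
                      introns$start - half < re &
                      introns$end + half > rs, , drop = FALSE]
    if (nrow(cand) == 0L) next
    st <- vapply(seq_len(nrow(cand)), function(i)
      classify_intron(segs, cand$start[i], cand$end[i], cand$strand[i],
                      ss_window = ss_window, size_tol = size_tol,
                      boundary_tol = boundary_tol), "")
    keep <- !is.na(st)
    if (!any(keep)) next
    out[[r]] <- data.frame(read_id = reads$read_id[r],
                           gene_id = cand$gene_id[keep],
                           intron_index = cand$intron_index[keep],
                           status = st[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(read_id = character(), gene_id = character(),
                      intron_index = integer(), status = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Splice-state class of a read spanning two introns or more
#'
#' Reads with only `not_excised` informative statuses are "all_unspliced",
#' reads with both `not_excised` and `excised` statuses are
#' "partially_spliced", and reads with `excised` and no `not_excised`
#' statuses are "all_spliced". Skipped and undetermined statuses do not
#' contribute; reads with no informative status are "not_classifiable".
#'
#' @param statuses character vector of intron statuses of one read (length
#'   >= 2; it is an error to call this on reads spanning fewer than two
#'   introns).
#' @return one of `"all_unspliced"`, `"partially_spliced"`,
#'   `"all_spliced"`, `"not_classifiable"`.
#' @export
classify_read_splice_state <- function(statuses) {
  if (length(statuses) < 2L)
    stop("splice-state classes are defined for reads spanning >= 2 introns")
  n_exc <- sum(statuses == "excised")
  n_ret <- sum(statuses == "not_excised")
  if (n_exc > 0L && n_ret > 0L) "partially_spliced"
  else if (n_exc > 0L) "all_spliced"
  else if (n_ret > 0L) "all_unspliced"
  else "not_classifiable"
}

#' Splice-state class per read from an intron-call table
#'
#' @param calls data.frame from [classify_alignments()].
#' @return data.frame `read_id`, `gene_id`, `n_introns`, `splice_state`;
#'   reads spanning fewer than two introns of a gene are omitted.
#' @export
read_splice_states <- function(calls) {
  if (nrow(calls) == 0L)
    return(data.frame(read_id = character(), gene_id = character(),
                      n_introns = integer(), splice_state = character(),
                      stringsAsFactors = FALSE))
  key <- paste(calls$read_id, calls$gene_id, sep = "\r")
  sp <- split(calls$status, key)
  sp <- sp[lengths(sp) >= 2L]
  if (length(sp) == 0L)
    return(data.frame(read_id = character(), gene_id = character(),
                      n_introns = integer(), splice_state = character(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
  data.frame(read_id = parts[, 1], gene_id = parts[, 2],
             n_introns = lengths(sp),
             splice_state = vapply(sp, classify_read_splice_state, ""),
             stringsAsFactors = FALSE, row.names = NULL)
}
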