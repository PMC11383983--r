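## Read-level simulator for chromatin-associated direct-RNA sequencing.
##
## Emulates multi-intron genes, per-allele phased SNPs, reads whose
## intermediate-isoform patterns are drawn from per-allele splicing-order
## mixtures, per-allele poly(A) tail length distributions, per-allele
## 3'-cleavage-site choice, and a fraction of reads unassignable to an
## allele. Everything downstream can be checked against the emitted truth.

#' Per-allele simulation parameters
#'
#' @param allele_id `"hap1"` or `"hap2"`.
#' @param order_mixture named numeric vector of nonnegative weights summing
#'   to 1 over removal orders of the gene's intron group, names like
#'   `"1->2->3"` (transcript-order intron indices).
#' @param polya_mean,polya_sd poly(A) tail length distribution (nt); reads
#'   draw from Normal(mean, sd) truncated at 0. Nascent chromatin tails
#'   average roughly 140-240 nt per allele.
#' @param end_sites optional data.frame `pos` (genomic 0-based position of
#'   the 3'-end base, within the transcript-last exon), `weight` (summing to
#'   1); `NULL` uses the annotated transcript end.
#' @param depth expected read count (Poisson).
#' @return object of class `AlleleSpec`.
#' @export
allele_spec <- function(allele_id, order_mixture, polya_mean = 180,
                        polya_sd = 30, end_sites = NULL, depth = 100) {
  stopifnot(allele_id %in% c("hap1", "hap2"))
  if (any(order_mixture < 0) || abs(sum(order_mixture) - 1) > 1e-8)
    stop("order_mixture weights must be nonnegative and sum to 1")
  if (!is.null(end_sites)) {
    stopifnot(is.data.frame(end_sites),
              all(c("pos", "weight") %in% names(end_sites)))
    if (abs(sum(end_sites$weight) - 1) > 1e-8)
      stop("end_sites weights must sum to 1")
  }
  if (depth <= 0) stop("depth must be > 0")
  structure(list(allele_id = allele_id, order_mixture = order_mixture,
                 polya_mean = polya_mean, polya_sd = polya_sd,
                 end_sites = end_sites, depth = depth),
            class = "AlleleSpec")
}

#' Generate phased heterozygous SNPs over a gene's exons
#'
#' Places `n_snps` SNPs at distinct exonic positions of the model (so every
#' full-length read observes them), with random ref/alt bases and random
#' phase (haplotype 1 carries the ref or the alt base with equal
#' probability).
#'
#' @param model a [make_gene_model()] `GeneModel`.
#' @param n_snps number of SNPs.
#' @param seed integer seed.
#' @return data.frame `id`, `chrom`, `pos` (0-based), `ref`, `alt`, `hap1`,
#'   `hap2`.
#' @export
phased_snps <- function(model, n_snps = 4L, seed = 1L) {
  set.seed(seed)
  exonic <- unlist(lapply(seq_len(nrow(model$exons)), function(i)
    seq.int(model$exons[i, "start"] + 5L, model$exons[i, "end"] - 6L)))
  pos <- sort(sample(exonic, n_snps))
  ref <- substring(model$refseq, pos - model$span[1] + 1L,
                   pos - model$span[1] + 1L)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  hap1_is_ref <- sample(c(TRUE, FALSE), n_snps, replace = TRUE)
  data.frame(id = sprintf("%s_snp%d", model$gene_id, seq_len(n_snps)),
             chrom = model$chrom, pos = pos, ref = ref, alt = unname(alt),
             hap1 = ifelse(hap1_is_ref, ref, alt),
             hap2 = ifelse(hap1_is_ref, alt, ref),
             stringsAsFactors = FALSE, row.names = NULL)
}

hap_sequence <- function(model, snps, hap) {
  seq <- model$refseq
  if (!is.null(snps) && nrow(snps) > 0L) {
    off <- snps$pos - model$span[1] + 1L
    for (i in seq_along(off))
      substr(seq, off[i], off[i]) <- snps[[hap]][i]
  }
  seq
}

## genomic segments present in a molecule with the given excised set,
## clipped to [lo, hi); returns matrix of [start, end)
molecule_segments <- function(model, excised_tx, lo, hi) {
  n <- nrow(model$introns)
  gen_idx <- if (model$strand == "+") excised_tx else n - excised_tx + 1L
  present <- rbind(model$exons,
                   model$introns[setdiff(seq_len(n), gen_idx), , drop = FALSE])
  present <- present[order(present[, "start"]), , drop = FALSE]
  ## merge adjacent, clip
  segs <- list()
  cur <- present[1, ]
  for (i in seq_len(nrow(present))[-1]) {
    if (present[i, "start"] <= cur["end"]) cur["end"] <- present[i, "end"]
    else { segs[[length(segs) + 1L]] <- cur; cur <- present[i, ] }
  }
  segs[[length(segs) + 1L]] <- cur
  m <- do.call(rbind, segs)
  m[, "start"] <- pmax(m[, "start"], lo)
  m[, "end"] <- pmin(m[, "end"], hi)
  m[m[, "end"] > m[, "start"], , drop = FALSE]
}

#' Simulate aligned direct-RNA reads for one gene and two alleles
#'
#' Each read carries a CIGAR consistent with its true excision pattern
#' (`N` operations exactly spanning excised introns, `M` across retained
#' ones), a base sequence from its haplotype (with per-SNP flip errors), a
#' poly(A) tail length drawn from the allele's truncated normal, and a
#' 3'-end position drawn from the allele's cleavage-site weights with
#' +/- `end_jitter` nt of uniform jitter. A configurable fraction of reads
#' has all but one SNP base masked to `N`, making them unassignable
#' downstream. One RNG stream is used per (gene, allele), derived from the
#' master seed.
#'
#' @param model a `GeneModel`.
#' @param spec1,spec2 [allele_spec()] objects for hap1 and hap2.
#' @param snps phased SNP table from [phased_snps()] (or `NULL` for none).
#' @param seed master seed.
#' @param frac_unassignable fraction of reads with < 2 SNP observations.
#' @param snp_error per-observation probability that a SNP base is flipped
#'   to the other haplotype's base (sequencing error; default 0.05).
#' @param level_probs probabilities over splicing levels 0..k (how far along
#'   excision a molecule is when sequenced); the default weights the
#'   intermediate levels 2.5x the endpoints (proportional to 0.4, 1, ..., 1,
#'   0.4), emulating the enrichment of partially spliced molecules in
#'   chromatin-associated RNA.
#' @param end_jitter maximum absolute jitter (nt) of the 3'-end position.
#' @param trunc_geom_p geometric parameter for 5'-truncation of the molecule
#'   (dnRNA-seq degradation); 0 (default) disables truncation.
#' @return object of class `SplicordSim`: list with `records` (alignment
#'   table: `read_id`, `chrom`, `strand`, `pos`, `cigar`, `seq`, `polya`,
#'   `flag`, `mapq`), `truth` (per-read `read_id`, `gene_id`, `allele`,
#'   `order`, `level`, `pattern`, `polya`, `end_pos`, `unassignable`),
#'   `models`, `snps`, `specs` and `implied` (per-allele mixture-implied
#'   level frequencies and order scores).
#' @export
simulate_reads <- function(model, spec1, spec2, snps = NULL, seed = 1L,
                           frac_unassignable = 0.05, snp_error = 0.05,
                           level_probs = NULL, end_jitter = 5L,
                           trunc_geom_p = 0) {
  k <- nrow(model$introns)
  valid_orders <- names(canonical_orders(k))
  for (sp in list(spec1, spec2))
    if (!all(names(sp$order_mixture) %in% valid_orders))
      stop("order_mixture references intron orders absent from the model")
  if (is.null(level_probs)) {
    w <- c(0.4, rep(1, max(0L, k - 1L)), 0.4)
    level_probs <- w / sum(w)
  }
  stopifnot(length(level_probs) == k + 1)
  gene_hash <- sum(utf8ToInt(model$gene_id)) %% 10000L

  last_exon <- if (model$strand == "+") model$exons[nrow(model$exons), ]
  else model$exons[1, ]

  recs <- list(); truths <- list()
  for (ai in 1:2) {
    sp <- if (ai == 1) spec1 else spec2
    set.seed((seed * 7919L + gene_hash * 31L + ai) %% 2147483647L)
    hap <- sp$allele_id
    hseq <- hap_sequence(model, snps, hap)
    n <- rpois(1L, sp$depth)
    if (n == 0L) next
    ord_name <- sample(names(sp$order_mixture), n, replace = TRUE,
                       prob = sp$order_mixture)
    lev <- sample(0:k, n, replace = TRUE, prob = level_probs)
    polya <- round(pmax(0, rnorm(n, sp$polya_mean, sp$polya_sd)), 1)
    if (is.null(sp$end_sites)) {
      site <- rep(if (model$strand == "+") last_exon["end"] - 1L
                  else last_exon["start"], n)
    } else {
      site <- sp$end_sites$pos[sample.int(nrow(sp$end_sites), n,
                                          replace = TRUE,
                                          prob = sp$end_sites$weight)]
    }
    jit <- sample(seq.int(-end_jitter, end_jitter), n, replace = TRUE)
    end_pos <- pmin(pmax(site + jit, last_exon["start"]), last_exon["end"] - 1L)
    unas <- runif(n) < frac_unassignable
    trunc <- if (trunc_geom_p > 0) rgeom(n, trunc_geom_p) else rep(0L, n)

    for (i in seq_len(n)) {
      o <- parse_order(ord_name[i])[[1]]
      exc <- if (lev[i] > 0) o[seq_len(lev[i])] else integer(0)
      if (model$strand == "+") {
        segs <- molecule_segments(model, exc, model$span[1], end_pos[i] + 1L)
      } else {
        segs <- molecule_segments(model, exc, end_pos[i], model$span[2])
      }
      ## 5'-truncation in molecule coordinates
      t <- trunc[i]
      if (t > 0L) {
        if (model$strand == "+") {
          j <- 1L
          while (t > 0L && nrow(segs) > 0L) {
            w <- segs[j, "end"] - segs[j, "start"]
            if (t >= w) { segs <- segs[-j, , drop = FALSE]; t <- t - w }
            else { segs[j, "start"] <- segs[j, "start"] + t; t <- 0L }
          }
        } else {
          while (t > 0L && nrow(segs) > 0L) {
            j <- nrow(segs)
            w <- segs[j, "end"] - segs[j, "start"]
            if (t >= w) { segs <- segs[-j, , drop = FALSE]; t <- t - w }
            else { segs[j, "end"] <- segs[j, "end"] - t; t <- 0L }
          }
        }
      }
      if (nrow(segs) == 0L) next
      widths <- segs[, "end"] - segs[, "start"]
      gaps <- if (nrow(segs) > 1L) segs[-1L, "start"] - segs[-nrow(segs), "end"]
      else integer(0)
      cig <- paste0(widths[1], "M")
      for (g in seq_along(gaps))
        cig <- paste0(cig, gaps[g], "N", widths[g + 1L], "M")
      seq <- paste(vapply(seq_len(nrow(segs)), function(s)
        substr(hseq, segs[s, "start"] - model$span[1] + 1L,
               segs[s, "end"] - model$span[1]), ""), collapse = "")
      ## SNP errors and unassignable masking operate on the read sequence
      if (!is.null(snps) && nrow(snps) > 0L) {
        covered <- which(vapply(snps$pos, function(p)
          any(p >= segs[, "start"] & p < segs[, "end"]), logical(1)))
        if (length(covered) > 0L) {
          qoff <- vapply(snps$pos[covered], function(p) {
            before <- sum(pmax(0, pmin(segs[, "end"], p) - segs[, "start"]))
            before
          }, numeric(1))
          other <- if (hap == "hap1") "hap2" else "hap1"
          for (s in seq_along(covered)) {
            if (runif(1) < snp_error)
              substr(seq, qoff[s] + 1L, qoff[s] + 1L) <-
                snps[[other]][covered[s]]
          }
          if (unas[i] && length(covered) > 1L) {
            for (s in seq_along(covered)[-1L])
              substr(seq, qoff[s] + 1L, qoff[s] + 1L) <- "N"
          }
        }
      }
      rid <- sprintf("%s_%s_r%05d", model$gene_id, hap, i)
      recs[[length(recs) + 1L]] <- data.frame(
        read_id = rid, chrom = model$chrom, strand = model$strand,
        pos = unname(segs[1L, "start"]), cigar = cig, seq = seq,
        polya = polya[i], flag = if (model$strand == "-") 16L else 0L,
        mapq = 60L, stringsAsFactors = FALSE)
      truths[[length(truths) + 1L]] <- data.frame(
        read_id = rid, gene_id = model$gene_id, allele = hap,
        order = ord_name[i], level = lev[i],
        pattern = pattern_string(exc, k), polya = polya[i],
        end_pos = unname(end_pos[i]), unassignable = unas[i],
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  truth <- do.call(rbind, truths)
  rownames(records) <- rownames(truth) <- NULL
  implied <- list(
    hap1 = list(freq = implied_level_frequencies(spec1$order_mixture, k),
                scores = implied_order_scores(spec1$order_mixture, k)),
    hap2 = list(freq = implied_level_frequencies(spec2$order_mixture, k),
                scores = implied_order_scores(spec2$order_mixture, k)))
  structure(list(records = records, truth = truth,
                 models = setNames(list(model), model$gene_id),
                 snps = snps, specs = list(hap1 = spec1, hap2 = spec2),
                 implied = implied),
            class = "SplicordSim")
}

#' Combine simulations of several genes into one dataset
#'
#' @param ... `SplicordSim` objects with distinct gene ids.
#' @return a combined `SplicordSim` (records sorted by chrom, position).
#' @export
combine_sims <- function(...) {
  sims <- list(...)
  records <- do.call(rbind, lapply(sims, `[[`, "records"))
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  rownames(records) <- NULL
  models <- do.call(c, lapply(sims, `[[`, "models"))
  snps <- do.call(rbind, lapply(sims, `[[`, "snps"))
  structure(list(records = records, truth = truth, models = models,
                 snps = snps,
                 specs = lapply(sims, `[[`, "specs"),
                 implied = lapply(sims, `[[`, "implied")),
            class = "SplicordSim")
}
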