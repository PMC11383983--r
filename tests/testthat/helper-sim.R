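# Shared fixture builders (everything is generated in code at test time).

uniform_mix <- function(k = 3) {
  nm <- names(canonical_orders(k))
  setNames(rep(1 / length(nm), length(nm)), nm)
}

degenerate_mix <- function(order, k = 3) {
  nm <- names(canonical_orders(k))
  setNames(as.numeric(nm == order), nm)
}

random_mix <- function(k = 3) {
  nm <- names(canonical_orders(k))
  w <- runif(length(nm))
  setNames(w / sum(w), nm)
}

# level counts + retained counts straight from the simulator's truth table
# (alleles from truth; unassignable reads counted as undetermined)
truth_group_counts <- function(sim, k = 3) {
  tr <- sim$truth
  al <- ifelse(tr$unassignable, "undetermined", tr$allele)
  names(al) <- tr$read_id
  pats <- data.frame(read_id = tr$read_id, pattern = tr$pattern,
                     level = tr$level, stringsAsFactors = FALSE)
  counts <- level_pattern_counts(pats, al, k)
  retained <- lapply(setNames(nm = c("hap1", "hap2", "undetermined")),
                     function(h) {
    vapply(seq_len(k), function(i) {
      bit <- substr(tr$pattern, i, i)
      sum(bit == "0" & al == h)
    }, numeric(1))
  })
  list(counts = counts, retained = retained)
}

# a three-gene dataset with planted allele-specific effects:
#   geneA: pure splicing-order swap (1->2->3 vs 2->1->3)
#   geneB: identical alleles everywhere (negative control)
#   geneC: poly(A) tail difference (233 vs 143 nt), same splicing order
planted_dataset <- function(seed = 11) {
  u <- uniform_mix(3)
  gmA <- make_gene_model(3, 200, 1000, seed = seed, gene_id = "geneA",
                         chrom = "chrA")
  gmB <- make_gene_model(3, 200, 1000, seed = seed + 1, gene_id = "geneB",
                         chrom = "chrB")
  gmC <- make_gene_model(3, 200, 1000, seed = seed + 2, gene_id = "geneC",
                         chrom = "chrC")
  simA <- simulate_reads(
    gmA,
    allele_spec("hap1", degenerate_mix("1->2->3"), depth = 120),
    allele_spec("hap2", degenerate_mix("2->1->3"), depth = 120),
    phased_snps(gmA, 4, seed = seed + 10), seed = seed)
  simB <- simulate_reads(
    gmB,
    allele_spec("hap1", u, depth = 120),
    allele_spec("hap2", u, depth = 120),
    phased_snps(gmB, 4, seed = seed + 11), seed = seed + 1)
  simC <- simulate_reads(
    gmC,
    allele_spec("hap1", u, polya_mean = 233, polya_sd = 30, depth = 120),
    allele_spec("hap2", u, polya_mean = 143, polya_sd = 30, depth = 120),
    phased_snps(gmC, 4, seed = seed + 12), seed = seed + 2)
  combine_sims(simA, simB, simC)
}
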