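---
title: "Allele-specific splicing order and nascent RNA maturation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific splicing order and nascent RNA maturation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicord)
```

## The problem

Human genes carry many introns that are not necessarily removed in
transcription order, and the removal order of an intron group can shape the
final mRNA (alternative splicing) and its 3' end. Direct RNA nanopore
sequencing of chromatin-associated, polyadenylated RNA samples transcripts
mid-maturation: each long read is a single molecule whose CIGAR string
reveals which introns are already excised, whose native poly(A) tail length
can be estimated per read, and which — when it covers phased heterozygous
SNPs — can be assigned to one parental haplotype. `splicord` turns those
three observations into allele-level comparisons of splicing order,
poly(A) tail length, 3'-end choice and abundance.

## Model and procedure

### Intron excision status

For a read and an annotated intron `[s, e)` the classifier looks at the
read's reference-consuming CIGAR segments:

* **excised** — an `N` operation starts within 50 nt of `s` and ends within
  50 nt of `e`, and its length is within 10% of `e - s`. Both tolerances
  are inclusive (`<=`), so an event exactly 10% off is still excised.
* **not excised** — no `N` operation in the examined region, more than 50%
  `M` coverage of the 50-nt window surrounding each splice site, and more
  than 75% `M` coverage of the intron portion the read maps to. Reads whose
  transcript-5' end starts inside the intron (degraded or truncated
  molecules, so the 5' splice site is not covered) qualify via the 3'
  splice-site criteria alone.
* **skipped** — an `N` overlapping more than half of a splice-site window,
  with the intron portion inside the event within 10% of the intron size
  (alternative splice sites, skipped exons).
* **undetermined** — the fall-through.

Numerical choices: the "50 nt surrounding" a splice site is interpreted as
a 50-nt window centred on the site (25 nt each side), configurable via
`ss_window`; "within 50 nt" for `N` boundaries is a separate parameter
`boundary_tol`; when several `N` operations overlap an intron the one with
the largest overlap is evaluated first (a deterministic rule for an input
the rules do not otherwise order); deletions (`D`) do not count as coverage
— only `M` does. Pairs where the read does not overlap the windowed intron
region yield *no* call rather than "undetermined", so downstream counts are
not diluted by irrelevant pairs. Reads spanning two or more introns are
further classed as all unspliced / partially spliced / all spliced from
their informative (excised / not excised) statuses only.

### Haplotype assignment

Each SNP covered by an `M` base yields an observation: hap1 base, hap2
base, or `other`. A read is assigned to the majority haplotype when it has
at least 2 observations and at least 75% of them agree with one allele;
exactly 75% passes, since only agreement *below* 75% is disqualifying.
`other` observations count in the denominator but toward neither allele —
the conservative reading of an ambiguous rule, flagged here as an
assumption. Indels are ignored. A 50/50 tie can never reach 75%, so no
tie-break is needed.

### Splicing-order scores

For a group of k consecutive introns (k = 3 in practice), reads spanning
the whole group with informative statuses report an intermediate isoform:
the subset of group introns already excised, at splicing level L (number
excised). With `f_k` the frequency of isoform *k* among reads at its level,
the raw score of removal order *i* is the product of the frequencies of the
four intermediates along its path (levels 0 and 3 hold a single pattern of
frequency 1, so the 4-factor product equals the product over the two
intermediate levels — this reconciles the "four intermediates per path"
bookkeeping with the two informative factors). Scores are normalised to
`p_i = P_i / sum(P_i)`; a group where every raw score is zero is reported
unscorable rather than NaN. No pseudocounts are used anywhere. Unobserved
orders get `p_i = 0` in a fixed lexicographic slot order so vectors are
comparable across alleles.

Coverage filters for triples (both alleles): each intron retained in at
least 10 reads (any read overlapping the intron counts — an assumption, as
the rule does not say whether only group-spanning reads qualify); at least
10 group-spanning reads at each intermediate level; per-level counts
greater than twice the allele-undetermined counts. Intron pairs require
strictly more than 10 informative reads per allele and the same 2x rule.
Reads are not deduplicated across overlapping groups.

### Calling allele-specific order

Per intermediate level, a chi-square contingency test (no continuity
correction, pattern columns empty in both alleles dropped) compares the
count distributions; p-values from all (group, level) pairs of a dataset
form one BH family (the family choice is ambiguous in principle, so it is
declared and kept configurable through the interface). The Euclidean
distance between the 6-slot score vectors measures effect size; the
threshold is 1.5 x IQR of same-allele distances between replicates
(`calibrate_threshold()`, linear-interpolation quartiles — declared because
the threshold depends on the quantile rule), with 0.379 as the shipped
default from LCL replicate data. A call requires distance strictly above
the threshold and FDR < 0.05 at one level or more. Called groups are
classified by comparing top orders position by position (ties broken toward
the lexicographically smallest permutation and flagged). Replicate-level
modelling (Dirichlet-multinomial differential usage) is intentionally out
of scope; merged-replicate contingency testing is the implemented caller.

### Allelic features

Poly(A) tails and 3'-end positions use two-sided Wilcoxon rank-sum tests:
exact when both sides have at most 25 tie-free observations, otherwise the
normal approximation with continuity and tie correction (declared — only
the test itself is prescribed). APA calls additionally require a 10-nt
shift between allele *mean* 3'-end positions (means, not per-site modes, as
stated). Abundance skew uses an exact binomial test against 0.5 — a
deliberate, labelled replacement for a replicate-aware overdispersion
model — with calls at FDR < 0.05 and ratio outside (0.4, 0.6), plus an
optional weaker flag (p < 0.01, ratio outside (0.45, 0.55)). BH families
are per feature per dataset. The chi-square tests operate on raw counts, as
contingency tests require.

### Genotype association

Alleles across individuals become independent samples with genotype 0
(reference) or 2 (alternative); SNPs with identical genotype vectors form
haplotype blocks. After requiring 10 allele-samples with 10 reads and a
minor-genotype count of 2, each block is tested by pooling
intermediate-isoform counts per genotype group and applying the chi-square
contingency test. This inherits the assumption that two alleles of one
individual are independent samples, and is *not* equivalent to a
likelihood-based transcript-usage QTL fit — the output column
`p_chisq_pooled` names the method.

## The simulator: what it emulates, and what it does not

`simulate_reads()` draws, per allele: a removal order from the allele's
order mixture; a splicing level from a distribution that weights the
intermediate levels 2.5x the endpoints (chromatin-associated RNA is
enriched for partially spliced molecules); a poly(A) length from a normal
truncated at 0 (the spread of nascent tails per gene is not well
characterised; sd defaults to 30 nt as a free parameter); a 3'-end site
from weighted cleavage sites with ±5 nt jitter; and SNP bases from the
haplotype sequence with a 5% per-observation flip probability, plus a 5%
fraction of reads masked to fewer than two observable SNPs (unassignable
downstream). Optional geometric 5'-truncation (off by default) emulates
degradation. One RNG stream per (gene, allele) derives from the master
seed, so fixtures are byte-reproducible.

The simulator does **not** model basecalling error beyond SNP flips,
alignment ambiguity, raw-signal artifacts of poly(A) estimation, intron
retention correlated between groups, or cytoplasmic deadenylation. Passing
tests therefore demonstrate correctness of the classification rules,
counting, filters and callers under clean alignments — not robustness to
aligner artifacts on real data (for one known artifact class, HLA exon 6,
the package instead provides the retained-intron transcriptome route).

Test problem sizes were chosen to make sampling noise negligible relative
to each tolerance: depth 5000/allele for frequency recovery (±0.02), 200
groups/genes for null calibration (call rate ≤ 7% at FDR 0.05), 100 seeds
at depth 200/allele for order-swap power, totals ≤ 40 for exhaustive oracle
comparisons.

## Degenerate inputs and edge cases

* Empty or single-column contingency tables are "not testable", never an
  error or a silent p = 1.
* Zero-total pair counts yield `NA` frequencies and no Fisher test.
* `classify_read_splice_state()` refuses reads spanning fewer than two
  introns; callers must pre-filter.
* Score vectors of unscorable groups are `NA` and excluded from distance
  computation, so a group is never called on missing evidence.
* `calibrate_threshold()` refuses fewer than 4 replicate distances; the
  fixed default 0.379 is used instead.

## Known limitations

* Intermediate-isoform frequencies factorise across levels in the score;
  a mixture whose levels do not factorise induces nonzero scores on orders
  absent from the generating mixture. Score recovery is therefore recovery
  of the score *functional*, not of mixture weights.
* Groups larger than three introns are supported by the combinatorial code
  but untested beyond k = 3 and unfiltered by design.
* The pooled-chi-square association test trades the power and calibration
  of a full Dirichlet-multinomial usage model for transparency; its
  p-values are valid under independence of allele-samples only.
* The binomial abundance test ignores replicate overdispersion and will be
  anticonservative for genes with strong technical variability.

## A compact example

```{r example, eval = FALSE}
gm   <- make_gene_model(3, exon_len = 200, intron_len = 1000, seed = 1)
snps <- phased_snps(gm, 4, seed = 2)
mix1 <- c("1->2->3" = 1, "1->3->2" = 0, "2->1->3" = 0,
          "2->3->1" = 0, "3->1->2" = 0, "3->2->1" = 0)
mix2 <- c("1->2->3" = 0, "1->3->2" = 0, "2->1->3" = 1,
          "2->3->1" = 0, "3->1->2" = 0, "3->2->1" = 0)
sim <- simulate_reads(gm, allele_spec("hap1", mix1, depth = 150),
                      allele_spec("hap2", mix2, depth = 150), snps, seed = 7)
calls   <- classify_alignments(sim$records, model_introns(gm))
alleles <- assign_alleles(sim$records, snps)
ord     <- order_analysis(calls, alleles, model_introns(gm))
compare_alleles(ord$group_counts)
```
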