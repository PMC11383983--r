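test_that("degenerate mixture: every partially spliced read lies on its path", {
  gm <- make_gene_model(3, 200, 1000, seed = 51)
  sim <- simulate_reads(gm,
                        allele_spec("hap1", degenerate_mix("1->2->3"),
                                    depth = 200),
                        allele_spec("hap2", degenerate_mix("1->2->3"),
                                    depth = 200),
                        seed = 52)
  on_path <- c("000", "100", "110", "111")
  expect_true(all(sim$truth$pattern %in% on_path))
  ## implied score vector of a one-order mixture is that order's indicator
  expect_equal(sim$implied$hap1$scores$p,
               as.numeric(names(canonical_orders(3)) == "1->2->3"))
})

test_that("simulation is deterministic and rejects invalid mixtures", {
  gm <- make_gene_model(2, 200, 1000, seed = 53)
  s1 <- allele_spec("hap1", uniform_mix(2), depth = 50)
  s2 <- allele_spec("hap2", uniform_mix(2), depth = 50)
  a <- simulate_reads(gm, s1, s2, seed = 54)
  b <- simulate_reads(gm, s1, s2, seed = 54)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  ## mixture over 3 introns on a 2-intron model
  bad <- allele_spec("hap1", uniform_mix(3), depth = 50)
  expect_error(simulate_reads(gm, bad, s2, seed = 1), "absent")
  expect_error(allele_spec("hap1", c("1->2" = 0.7, "2->1" = 0.2)), "sum to 1")
  expect_error(allele_spec("hap1", uniform_mix(2), depth = 0), "depth")
})

test_that("every read appears exactly once in records and truth", {
  gm <- make_gene_model(3, 200, 1000, seed = 55)
  sim <- simulate_reads(gm, allele_spec("hap1", uniform_mix(3), depth = 80),
                        allele_spec("hap2", uniform_mix(3), depth = 80),
                        phased_snps(gm, 3, seed = 56), seed = 57)
  expect_equal(anyDuplicated(sim$records$read_id), 0)
  expect_setequal(sim$records$read_id, sim$truth$read_id)
})

test_that("level frequencies converge to the mixture-implied values", {
  gm <- make_gene_model(3, 200, 1000, seed = 58)
  mix <- setNames(c(0.55, 0, 0.45, 0, 0, 0), names(canonical_orders(3)))
  sim <- simulate_reads(gm, allele_spec("hap1", mix, depth = 2500),
                        allele_spec("hap2", mix, depth = 2500),
                        seed = 59, frac_unassignable = 0)
  tr <- sim$truth
  for (L in 1:2) {
    at <- tr[tr$level == L, ]
    obs <- table(factor(at$pattern, levels = level_patterns(L, 3)))
    obs <- obs / sum(obs)
    imp <- sim$implied$hap1$freq
    imp <- imp$freq[imp$level == L]
    expect_lt(max(abs(as.numeric(obs) - imp)), 0.03)
  }
})

test_that("poly(A) tails and 3' ends follow the allele specification", {
  gm <- make_gene_model(2, 300, 1000, seed = 60)
  near <- gm$exons[3, "start"] + 20L
  far <- gm$exons[3, "end"] - 20L
  sim <- simulate_reads(
    gm,
    allele_spec("hap1", uniform_mix(2), polya_mean = 233, polya_sd = 30,
                end_sites = data.frame(pos = c(near, far),
                                       weight = c(0.9, 0.1)),
                depth = 300),
    allele_spec("hap2", uniform_mix(2), polya_mean = 143, polya_sd = 30,
                end_sites = data.frame(pos = c(near, far),
                                       weight = c(0.1, 0.9)),
                depth = 300),
    seed = 61)
  t1 <- sim$truth[sim$truth$allele == "hap1", ]
  t2 <- sim$truth[sim$truth$allele == "hap2", ]
  expect_equal(mean(t1$polya), 233, tolerance = 0.03)
  expect_equal(mean(t2$polya), 143, tolerance = 0.05)
  expect_true(all(sim$truth$polya >= 0))
  ## 3' site choice respects the weights (within jitter)
  expect_gt(mean(abs(t1$end_pos - near) <= 5), 0.8)
  expect_gt(mean(abs(t2$end_pos - far) <= 5), 0.8)
  ## end positions match the alignment ends on the plus strand
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(sim$records$cigar)
  ends <- setNames(sim$records$pos + w - 1L, sim$records$read_id)
  expect_equal(unname(ends[sim$truth$read_id]), sim$truth$end_pos)
})

test_that("fixtures round-trip through the readers", {
  dir <- withr::local_tempdir()
  sim <- planted_dataset(seed = 62)
  paths <- write_fixture(sim, dir)
  aln <- read_alignments(paths$sam)
  expect_equal(nrow(aln), nrow(sim$records))
  expect_setequal(aln$read_id, sim$records$read_id)
  ## poly(A) tag round-trips
  m <- merge(aln, sim$truth[, c("read_id", "polya")], by = "read_id")
  expect_equal(m$polya.x, m$polya.y, tolerance = 0.05)
  introns <- read_intron_bed(paths$bed)
  expect_equal(nrow(introns), 9)  # 3 genes x 3 introns
  vc <- read_phased_vcf(paths$vcf)
  expect_equal(nrow(vc), nrow(sim$snps))
  expect_true(all(vc$hap1 != vc$hap2))
  tr <- read_tsv_meta(paths$truth)
  expect_equal(nrow(tr), nrow(sim$truth))
  ## empty simulation is rejected
  empty <- sim; empty$records <- sim$records[0, ]
  expect_error(write_fixture(empty, dir), "empty")
})

test_that("emitted read counts are Poisson around 2 genes x 2 x depth 100", {
  gmA <- make_gene_model(2, 200, 800, seed = 63, gene_id = "gA",
                         chrom = "c1")
  gmB <- make_gene_model(2, 200, 800, seed = 64, gene_id = "gB",
                         chrom = "c2")
  mk <- function(gm, seed) simulate_reads(
    gm, allele_spec("hap1", uniform_mix(2), depth = 100),
    allele_spec("hap2", uniform_mix(2), depth = 100), seed = seed)
  sim <- combine_sims(mk(gmA, 65), mk(gmB, 66))
  n <- nrow(sim$records)
  expect_gt(n, 400 - 4 * sqrt(400))
  expect_lt(n, 400 + 4 * sqrt(400))
})
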