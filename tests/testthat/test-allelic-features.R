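test_that("gene filters: strict > 20 per allele and 2x undetermined rule", {
  expect_true(passes_gene_filters(21, 21, 10))
  expect_false(passes_gene_filters(20, 30, 0))   # strict >
  expect_false(passes_gene_filters(30, 30, 16))  # 30 < 32
  expect_true(passes_gene_filters(32, 32, 16))   # at least = inclusive
  ## abundance mode: either allele may exceed 20
  expect_true(passes_gene_filters(25, 5, 2, mode = "either"))
  expect_false(passes_gene_filters(25, 3, 2, mode = "either"))  # 3 < 4
})

test_that("poly(A) comparison matches the exact rank-sum enumeration", {
  r <- compare_polya(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)
  expect_equal(r$p, wilcox_oracle(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(compare_polya(c(5, 7, 9), c(5, 7, 9))$p, 1)
  set.seed(6)
  for (i in 1:20) {
    x <- sample(100, sample(3:8, 1))
    y <- sample(200, sample(3:8, 1))
    if (any(duplicated(c(x, y)))) next
    expect_equal(compare_polya(x, y)$p, wilcox_oracle(x, y),
                 tolerance = 1e-9)
  }
})

test_that("binomial skew test matches point-probability enumeration", {
  r <- allelic_ratio_and_skew(60, 40)
  expect_equal(r$ratio, 0.6)
  expect_equal(r$p, binom_oracle(60, 100), tolerance = 1e-9)
  expect_equal(r$p, 0.05689, tolerance = 1e-3)
  expect_equal(allelic_ratio_and_skew(50, 50)$p, 1)
  expect_equal(allelic_ratio_and_skew(50, 50)$ratio, 0.5)
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:12, 1); k <- sample(0:n, 1)
    expect_equal(allelic_ratio_and_skew(k, n - k)$p, binom_oracle(k, n),
                 tolerance = 1e-9)
  }
})

test_that("abundance calls need FDR < 0.05 AND ratio outside (0.4, 0.6)", {
  reads <- rbind(
    data.frame(gene_id = "g1", allele = rep(c("hap1", "hap2"), c(60, 40))),
    data.frame(gene_id = "g2", allele = rep(c("hap1", "hap2"), c(90, 30))),
    data.frame(gene_id = "g3", allele = rep(c("hap1", "hap2"), c(50, 50))))
  tab <- abundance_table(reads)
  ## g1: ratio exactly 0.6 -> never a call, whatever the p-value
  expect_false(tab$call[tab$gene_id == "g1"])
  expect_true(tab$call[tab$gene_id == "g2"])
  expect_false(tab$call[tab$gene_id == "g3"])
})

test_that("3'-end call requires a >= 10 nt mean shift besides the FDR", {
  set.seed(8)
  base <- 5000 + sample(0:3, 60, replace = TRUE)
  reads <- rbind(
    ## tiny but highly significant 9.5 nt shift: no call
    data.frame(gene_id = "g1", allele = "hap1", end_pos = base),
    data.frame(gene_id = "g1", allele = "hap2", end_pos = base + 9.5),
    ## two sites 300 nt apart at 90/10 vs 10/90: call
    data.frame(gene_id = "g2", allele = "hap1",
               end_pos = 5000 + 300 * rbinom(60, 1, 0.1)),
    data.frame(gene_id = "g2", allele = "hap2",
               end_pos = 5000 + 300 * rbinom(60, 1, 0.9)),
    ## identical distributions: no call
    data.frame(gene_id = "g3", allele = "hap1", end_pos = base),
    data.frame(gene_id = "g3", allele = "hap2", end_pos = base))
  reads$read_id <- seq_len(nrow(reads))
  tab <- ends_table(reads)
  expect_false(tab$call[tab$gene_id == "g1"])
  expect_lt(tab$fdr[tab$gene_id == "g1"], 0.05)  # significant, yet no call
  expect_true(tab$call[tab$gene_id == "g2"])
  expect_false(tab$call[tab$gene_id == "g3"])
})

test_that("swapping allele labels mirrors effects, preserves p-values", {
  set.seed(9)
  reads <- data.frame(
    gene_id = "g", read_id = 1:70,
    allele = rep(c("hap1", "hap2"), c(40, 30)),
    polya = c(rnorm(40, 200, 25), rnorm(30, 160, 25)),
    end_pos = c(rnorm(40, 5000, 10), rnorm(30, 5040, 10)))
  swapped <- reads
  swapped$allele <- ifelse(reads$allele == "hap1", "hap2", "hap1")
  p1 <- polya_table(reads); p2 <- polya_table(swapped)
  expect_equal(p1$p, p2$p)
  expect_equal(p1$effect, -p2$effect)
  a1 <- abundance_table(reads); a2 <- abundance_table(swapped)
  expect_equal(a1$ratio, 1 - a2$ratio)
  expect_equal(a1$p, a2$p)
  e1 <- ends_table(reads); e2 <- ends_table(swapped)
  expect_equal(e1$p, e2$p)
  expect_equal(e1$mean_shift, e2$mean_shift)
})

test_that("splice-state stratification tests only classes passing filters", {
  set.seed(10)
  n <- 60
  mk <- function(gene, state, m1, m2) rbind(
    data.frame(gene_id = gene, allele = "hap1", splice_state = state,
               polya = rnorm(n, m1, 20)),
    data.frame(gene_id = gene, allele = "hap2", splice_state = state,
               polya = rnorm(n, m2, 20)))
  ## difference only in partially spliced reads
  reads <- rbind(mk("g", "partially_spliced", 230, 150),
                 mk("g", "all_spliced", 180, 180))
  reads$read_id <- seq_len(nrow(reads))
  tab <- polya_by_splice_state(reads)
  expect_true(tab$call[tab$read_class == "partially_spliced"])
  expect_false(tab$call[tab$read_class == "all_spliced"])
  ## a class below coverage is simply absent
  small <- rbind(mk("g2", "partially_spliced", 230, 150)[1:30, ],
                 mk("g2", "all_spliced", 180, 180))
  small$read_id <- seq_len(nrow(small))
  tab2 <- polya_by_splice_state(small)
  expect_false("partially_spliced" %in% tab2$read_class)
})

test_that("poly(A)/skew enrichment and compartment correlation", {
  e <- polya_skew_enrichment(rep(c(TRUE, FALSE), c(25, 50)),
                             c(rep(TRUE, 20), rep(FALSE, 5),
                               rep(TRUE, 10), rep(FALSE, 40)))
  expect_equal(e$odds_ratio, 16)
  ## p agrees with the hypergeometric oracle on the same 2x2 table
  expect_equal(e$p, fisher_oracle(matrix(c(20, 10, 5, 40), 2)),
               tolerance = 1e-9)
  ## empty margin: not testable
  expect_true(is.na(polya_skew_enrichment(rep(TRUE, 5),
                                          rep(c(TRUE, FALSE), c(2, 3)))$p))
  r <- c(0.2, 0.5, 0.8, 0.4)
  expect_equal(compartment_ratio_correlation(r, r), 1)
  expect_equal(compartment_ratio_correlation(r, 1 - r), -1)
})
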