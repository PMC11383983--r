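test_that("Fisher pair test matches hypergeometric enumeration", {
  r <- fisher_pair_test(c(10, 0), c(0, 10))
  expect_equal(r$p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(r$p, fisher_oracle(rbind(c(10, 0), c(0, 10))),
               tolerance = 1e-9)
  ## identical rows: p = 1, zero effect
  r2 <- fisher_pair_test(c(7, 3), c(7, 3))
  expect_equal(r2$p, 1)
  expect_equal(r2$effect, 0)
  r3 <- fisher_pair_test(c(30, 10), c(10, 30))
  expect_equal(r3$effect, 0.5)
  expect_equal(r3$p, fisher_oracle(rbind(c(30, 10), c(10, 30))),
               tolerance = 1e-9)
  ## zero-total allele: no test
  expect_true(is.na(fisher_pair_test(c(0, 0), c(5, 5))$p))
})

test_that("chi-square level test: closed form, zero columns dropped", {
  ct <- chi_square_level_test(c(30, 10, 0), c(10, 30, 0))
  expect_equal(ct$statistic, 20)  # n(ad-bc)^2/(r1 r2 c1 c2)
  expect_equal(ct$df, 1)
  expect_equal(chi_square_level_test(c(5, 5, 5), c(5, 5, 5))$statistic, 0)
  expect_equal(chi_square_level_test(c(4, 6), c(4, 6))$p, 1)
  ## fewer than two nonzero columns: not testable
  expect_false(chi_square_level_test(c(10, 0), c(20, 0))$testable)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  set.seed(1)
  p <- runif(50)
  expect_equal(bh_adjust(p), bh_oracle(p))
})

test_that("Euclidean distance on score vectors", {
  expect_equal(euclidean_distance(rep(1/6, 6), rep(1/6, 6)), 0)
  expect_equal(euclidean_distance(c(1, 0, 0, 0, 0, 0),
                                  c(0, 1, 0, 0, 0, 0)), sqrt(2))
  expect_equal(euclidean_distance(c(0.5, 0.5, 0, 0, 0, 0),
                                  c(0, 0, 1, 0, 0, 0)), sqrt(1.5))
  ## symmetry and triangle inequality on random probability vectors
  set.seed(2)
  for (i in 1:20) {
    a <- runif(6); a <- a / sum(a)
    b <- runif(6); b <- b / sum(b)
    c_ <- runif(6); c_ <- c_ / sum(c_)
    expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
    expect_lte(euclidean_distance(a, c_),
               euclidean_distance(a, b) + euclidean_distance(b, c_) + 1e-12)
    expect_lte(euclidean_distance(a, b), sqrt(2) + 1e-12)
  }
})

test_that("threshold calibration is 1.5 x IQR with interpolated quartiles", {
  expect_equal(calibrate_threshold(c(0.1, 0.2, 0.3, 0.4)), 0.225)
  expect_equal(calibrate_threshold(rep(0.3, 10)), 0)
  expect_error(calibrate_threshold(c(0.1, 0.2)), ">= 4")
  expect_equal(tau_default, 0.379)
})

test_that("allele-specific call requires d > tau and one level FDR < 0.05", {
  expect_true(call_allele_specific(0.5, c(0.01, 0.2)))
  ## boundary: d equal to tau is not a call (strict >)
  expect_false(call_allele_specific(0.379, c(0.001, 0.001)))
  expect_false(call_allele_specific(1.0, c(0.2, 0.2)))
  expect_false(call_allele_specific(0.5, c(NA, NA)))
  expect_true(call_allele_specific(0.5, c(NA, 0.01)))
})

test_that("difference classes cover the four permutation relations", {
  expect_equal(classify_difference("1->2->3", "2->1->3"),
               "reversal of first or last two positions")
  expect_equal(classify_difference("1->2->3", "1->3->2"),
               "reversal of first or last two positions")
  expect_equal(classify_difference("1->2->3", "3->2->1"),
               "reversal of first and last positions")
  expect_equal(classify_difference("1->2->3", "2->3->1"),
               "reversal of 3 positions")
  expect_equal(classify_difference("1->2->3", "1->2->3"),
               "different score for same order")
  ## exhaustive: every ordered pair of the 6 orders lands in one category
  nm <- names(canonical_orders(3))
  for (a in nm) for (b in nm)
    expect_true(classify_difference(a, b) %in%
                  c("different score for same order",
                    "reversal of first or last two positions",
                    "reversal of first and last positions",
                    "reversal of 3 positions"))
})

test_that("fisher and chi-square match oracles on all small tables", {
  ## all 2x2 tables with row sums <= 10 (totals <= 20)
  for (r1 in 1:10) for (r2 in 1:10) {
    for (a in 0:r1) for (c_ in 0:r2) {
      tab <- rbind(c(a, r1 - a), c(c_, r2 - c_))
      if (any(colSums(tab) == 0)) next
      expect_equal(fisher_pair_test(tab[1, ], tab[2, ])$p,
                   fisher_oracle(tab), tolerance = 1e-8)
    }
  }
  ## random 2x3 tables, totals <= 40
  set.seed(3)
  for (i in 1:100) {
    m <- matrix(rpois(6, 4), nrow = 2)
    keep <- colSums(m) > 0
    m2 <- m[, keep, drop = FALSE]
    if (ncol(m2) < 2 || any(rowSums(m2) == 0)) next
    ct <- chi_square_level_test(m[1, ], m[2, ])
    o <- chisq_oracle(m2)
    expect_equal(ct$statistic, o$statistic, tolerance = 1e-9)
    expect_equal(ct$p, o$p, tolerance = 1e-9)
  }
})

test_that("compare_alleles calls a planted order swap and nothing else", {
  gm <- make_gene_model(3, 200, 1000, seed = 31)
  swap <- simulate_reads(gm,
                         allele_spec("hap1", degenerate_mix("1->2->3"),
                                     depth = 120),
                         allele_spec("hap2", degenerate_mix("2->1->3"),
                                     depth = 120),
                         seed = 32)
  same_mix <- random_mix(3)
  gm2 <- make_gene_model(3, 200, 1000, seed = 33, gene_id = "gene2")
  null <- simulate_reads(gm2, allele_spec("hap1", same_mix, depth = 120),
                         allele_spec("hap2", same_mix, depth = 120),
                         seed = 34)
  gc <- list("gene1:1-2-3" = truth_group_counts(swap)$counts,
             "gene2:1-2-3" = truth_group_counts(null)$counts)
  cmp <- compare_alleles(gc)
  expect_equal(cmp$call, c(TRUE, FALSE))
  expect_equal(cmp$difference_class[1],
               "reversal of first or last two positions")
  expect_equal(cmp$distance[1], sqrt(2), tolerance = 1e-9)
})

test_that("pair comparison: FDR and minimum effect jointly gate the call", {
  pc <- data.frame(group_id = c("g1", "g2", "g3"),
                   hap1_up = c(40, 20, 22), hap1_down = c(5, 20, 18),
                   hap2_up = c(5, 20, 18), hap2_down = c(40, 20, 22))
  out <- compare_pairs(pc)
  expect_true(out$call[1])                   # big swap: called
  expect_false(out$call[2])                  # identical: not called
  expect_false(out$call[3])                  # effect 0.1 but p ~ 1
  expect_equal(out$effect[3], 0.1, tolerance = 1e-9)
})
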