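test_that("canonical order enumeration and pattern encoding", {
  o <- canonical_orders(3)
  expect_length(o, 6)
  expect_equal(names(o)[1], "1->2->3")
  expect_equal(names(o)[6], "3->2->1")
  expect_equal(o[["2->3->1"]], c(2L, 3L, 1L))
  expect_equal(pattern_string(c(1, 3), 3), "101")
  expect_equal(level_patterns(2, 3), c("110", "101", "011"))
  expect_equal(parse_order("3->1->2")[[1]], c(3L, 1L, 2L))
})

test_that("spanning patterns keep only fully informative reads", {
  calls <- data.frame(
    read_id = c("a", "a", "a", "b", "b", "c", "c", "c"),
    intron_index = c(1, 2, 3, 1, 2, 1, 2, 3),
    status = c("excised", "not_excised", "not_excised",
               "excised", "excised",              # b misses intron 3
               "excised", "skipped", "excised"))  # c has a skipped intron
  p <- spanning_patterns(1:3, calls)
  expect_equal(p$read_id, "a")
  expect_equal(p$pattern, "100")
  expect_equal(p$level, 1)
})

test_that("triple filters apply the quoted boundaries for both alleles", {
  mk <- function(n1, n2, nu) {
    pats <- unlist(lapply(0:3, level_patterns, k = 3))
    g <- expand.grid(allele = c("hap1", "hap2", "undetermined"),
                     pattern = pats, stringsAsFactors = FALSE)
    g$level <- nchar(gsub("0", "", g$pattern))
    per <- c(hap1 = n1, hap2 = n2, undetermined = nu)
    ## spread the per-allele level total over the first pattern of each level
    g$count <- 0
    for (al in names(per)) for (L in 0:3) {
      i <- which(g$allele == al & g$level == L)[1]
      g$count[i] <- per[[al]]
    }
    g
  }
  ret_ok <- list(hap1 = rep(10, 3), hap2 = rep(10, 3))
  ## exactly 10 everywhere passes ("at least 10")
  expect_true(passes_triple_filters(mk(10, 10, 0), ret_ok))
  ## 9 spanning reads at a level on one allele fails
  expect_false(passes_triple_filters(mk(10, 9, 0), ret_ok))
  ## 20 reads with 10 undetermined fails (20 is not > 2 x 10)
  expect_false(passes_triple_filters(mk(20, 20, 10), ret_ok))
  expect_true(passes_triple_filters(mk(21, 21, 10), ret_ok))
  ## intron retained in only 9 reads fails
  expect_false(passes_triple_filters(mk(10, 10, 0),
                                     list(hap1 = c(9, 10, 10),
                                          hap2 = rep(10, 3))))
})

test_that("pair filters use strict > 10 and the 2x undetermined rule", {
  expect_true(passes_pair_filters(11, 11, 5))
  expect_false(passes_pair_filters(10, 11, 0))   # strict >
  expect_false(passes_pair_filters(30, 30, 15))  # not > 2 x 15
  expect_true(passes_pair_filters(31, 31, 15))
})

test_that("pair order frequency is the upstream-first fraction", {
  expect_equal(pair_order_frequency(30, 10)$freq_upstream_first, 0.75)
  expect_equal(pair_order_frequency(0, 10)$freq_upstream_first, 0)
  expect_equal(pair_order_frequency(7, 7)$freq_upstream_first, 0.5)
})

test_that("order scores reproduce hand-computed and degenerate cases", {
  ## degenerate: all level-1 mass on {1}, all level-2 mass on {1,2}
  s <- order_scores_from_freq(c("100" = 1, "110" = 1), 3)
  expect_equal(s$p[s$order == "1->2->3"], 1)
  expect_equal(sum(s$p), 1)
  expect_equal(attr(s, "N"), 4L)  # intermediates per path for triples
  ## uniform frequencies: all six orders equal
  u <- order_scores_from_freq(
    c("100" = 1/3, "010" = 1/3, "001" = 1/3,
      "110" = 1/3, "101" = 1/3, "011" = 1/3), 3)
  expect_equal(u$p, rep(1/6, 6))
  ## hand-computed: L1 counts {1}:30 {2}:10 {3}:0; L2 {12}:20 {13}:20 {23}:0
  h <- order_scores_from_freq(
    c("100" = 0.75, "010" = 0.25, "001" = 0,
      "110" = 0.5, "101" = 0.5, "011" = 0), 3)
  expect_equal(h$P, c(0.375, 0.375, 0.125, 0, 0, 0))
  expect_equal(h$p, c(3/7, 3/7, 1/7, 0, 0, 0), tolerance = 1e-12)
  expect_equal(h$order, c("1->2->3", "1->3->2", "2->1->3",
                          "2->3->1", "3->1->2", "3->2->1"))
  ## all-zero raw scores: unscorable, not NaN
  z <- order_scores_from_freq(c("100" = 0, "110" = 0), 3)
  expect_false(attr(z, "scorable"))
  expect_true(all(is.na(z$p)))
})

test_that("order scores match the chain-enumeration oracle on random tables", {
  set.seed(123)
  for (k in 2:3) {
    for (rep in 1:50) {
      counts <- lapply(seq_len(k - 1), function(L) {
        pats <- level_patterns(L, k)
        setNames(rpois(length(pats), 5), pats)
      })
      freq <- lapply(counts, function(x)
        if (sum(x) > 0) x / sum(x) else x)
      fv <- unlist(freq)
      s <- order_scores_from_freq(fv, k)
      o <- score_oracle(freq, k)
      if (attr(s, "scorable")) {
        expect_equal(setNames(s$p, s$order), o, tolerance = 1e-12)
        expect_equal(sum(s$p), 1, tolerance = 1e-12)
      } else {
        expect_true(all(is.na(o)))
      }
    }
  }
})

test_that("scores are invariant to scaling the counts of one level", {
  cnt <- c("100" = 12, "010" = 5, "001" = 3)
  cnt2 <- c("110" = 7, "101" = 1, "011" = 4)
  s1 <- order_scores_from_freq(c(cnt / sum(cnt), cnt2 / sum(cnt2)), 3)
  big <- cnt * 17
  s2 <- order_scores_from_freq(c(big / sum(big), cnt2 / sum(cnt2)), 3)
  expect_equal(s1$p, s2$p)
})

test_that("level counts and scores recover a mixture at high depth", {
  gm <- make_gene_model(3, 200, 1000, seed = 21)
  mix <- setNames(c(0.6, 0, 0.4, 0, 0, 0), names(canonical_orders(3)))
  sim <- simulate_reads(gm, allele_spec("hap1", mix, depth = 2500),
                        allele_spec("hap2", mix, depth = 2500),
                        seed = 22, frac_unassignable = 0)
  tg <- truth_group_counts(sim)
  s <- order_scores(tg$counts, "hap1", 3)
  imp <- implied_order_scores(mix, 3)
  expect_equal(s$p, imp$p, tolerance = 0.05)
  expect_equal(sum(s$p), 1, tolerance = 1e-12)
})

test_that("implied quantities: degenerate mixture gives an indicator", {
  mix <- degenerate_mix("2->1->3")
  imp <- implied_order_scores(mix, 3)
  expect_equal(imp$p[imp$order == "2->1->3"], 1)
  expect_equal(sum(imp$p), 1)
  fr <- implied_level_frequencies(mix, 3)
  expect_equal(fr$freq[fr$pattern == "010"], 1)  # level 1: intron 2 first
  expect_equal(fr$freq[fr$pattern == "110"], 1)  # level 2: then intron 1
})
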