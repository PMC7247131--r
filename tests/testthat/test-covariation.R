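test_that("classify_pair tallies canonical, non-canonical and gapped rows", {
  st <- classify_pair(mk_pair_aln(c("GC", "GC", "AU")), c(1L, 2L))
  expect_identical(st$canonical_counts, c(AU = 1L, GC = 2L))
  expect_identical(st$covarying_variant_count, 2L)
  expect_identical(st$n_noncanonical, 0L)

  st2 <- classify_pair(mk_pair_aln(c("GC", "GU")), c(1L, 2L))
  expect_identical(st2$covarying_variant_count, 0L)  # differ at one position

  st3 <- classify_pair(mk_pair_aln(c("GC", "AU", "GA", "-U")), c(1L, 2L))
  expect_identical(st3$n_noncanonical, 1L)
  expect_identical(st3$n_gapped, 1L)
  expect_identical(st3$covarying_variant_count, 2L)
  expect_identical(st3$n_sequences, 4L)
  # partition invariant
  expect_identical(sum(st3$canonical_counts) + st3$n_noncanonical +
                     st3$n_gapped, st3$n_sequences)
})

test_that("T is treated as U and case is ignored in classification", {
  st <- classify_pair(mk_pair_aln(c("gc", "AT", "ta")), c(1L, 2L))
  expect_identical(st$canonical_counts, c(AU = 1L, GC = 1L, UA = 1L))
  expect_identical(st$covarying_variant_count, 3L)
})

test_that("the permissive covariation rule enforces its printed boundaries", {
  # two variants differing at both positions, no non-canonical rows -> TRUE
  yes <- classify_pair(mk_pair_aln(c(rep("GC", 5), rep("AU", 5))), c(1L, 2L))
  expect_true(r2r_rule(yes))
  # exactly 10% non-canonical is NOT "fewer than 10%" -> FALSE
  ten <- classify_pair(mk_pair_aln(c(rep("GC", 9), rep("AU", 9), "GA", "AC")),
                       c(1L, 2L))
  expect_identical(ten$noncanonical_fraction, 0.10)
  expect_false(r2r_rule(ten))
  # GC/GU differ at only one position -> FALSE
  gu <- classify_pair(mk_pair_aln(c(rep("GC", 10), rep("GU", 10))), c(1L, 2L))
  expect_false(r2r_rule(gu))
})

test_that("adding a canonical-variant sequence never flips the rule off", {
  base <- c(rep("GC", 8), rep("AU", 8))
  st0 <- classify_pair(mk_pair_aln(base), c(1L, 2L))
  expect_true(r2r_rule(st0))
  for (extra in c("UA", "CG", "GU", "UG")) {
    st1 <- classify_pair(mk_pair_aln(c(base, extra)), c(1L, 2L))
    expect_true(r2r_rule(st1))
  }
})

test_that("G statistic matches its closed form on a diagonal 2x2 table", {
  n <- 12L
  aln <- mk_pair_aln(c(rep("GC", n / 2), rep("AU", n / 2)))
  expect_equal(pair_association_score(aln, c(1L, 2L)), 2 * n * log(2))
})

test_that("G statistic is zero for constant columns and errors on tiny n", {
  aln <- mk_pair_aln(c("GC", "GA", "GU", "GG"))  # column 1 constant
  expect_identical(pair_association_score(aln, c(1L, 2L)), 0)
  gappy <- mk_pair_aln(c("G-", "-C", "AU"))
  expect_error(pair_association_score(gappy, c(1L, 2L)), "fewer than 2")
  expect_error(classify_pair(mk_pair_aln(c("GC")), c(1L, 5L)), "invalid pair")
})

test_that("G statistic of independent uniform columns is ~ chi-squared df 9", {
  set.seed(2024)
  n <- 400L
  reps <- 300L
  g <- vapply(seq_len(reps), function(r) {
    a <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
    b <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
    pair_association_score(mk_pair_aln(paste0(a, b)), c(1L, 2L))
  }, numeric(1))
  # df = (4-1)(4-1) = 9; sd of the mean ~ sqrt(2*9/reps) ~ 0.245
  expect_lt(abs(mean(g) - 9), 1)
})

test_that("permutation test: maximal association is significant, ties give 1", {
  aln <- mk_pair_aln(c(rep("GC", 6), rep("AU", 6)))
  res <- permutation_test(aln, c(1L, 2L), n_permutations = 999L, seed = 5L)
  expect_lte(res$p_value, 0.01)
  expect_equal(res$score, 2 * 12 * log(2))

  const <- mk_pair_aln(rep("GC", 8))
  expect_identical(
    permutation_test(const, c(1L, 2L), n_permutations = 99L, seed = 1L)$p_value,
    1)
})

test_that("permutation p-values are deterministic and row-order invariant", {
  set.seed(31)
  types <- sample(c("GC", "AU", "UA", "GA", "CG"), 14, replace = TRUE)
  aln <- mk_pair_aln(types)
  p1 <- permutation_test(aln, c(1L, 2L), n_permutations = 200L, seed = 77L)
  p2 <- permutation_test(aln, c(1L, 2L), n_permutations = 200L, seed = 77L)
  expect_identical(p1, p2)
  shuf <- mk_pair_aln(types[sample(length(types))])
  p3 <- permutation_test(shuf, c(1L, 2L), n_permutations = 200L, seed = 77L)
  expect_identical(p1$p_value, p3$p_value)
})

test_that("summarize_motif detects planted signal and rates it Y", {
  sim <- simulate_alignment("<<<<....>>>>",
                            evolution_params(n_sequences = 24,
                                             compensatory_rate = 1,
                                             noncanonical_noise = 0,
                                             seed = 101L))
  cv <- summarize_motif(sim, n_permutations = 300L, seed = 2L)
  expect_gte(cv$summary$n_significant, 1L)
  expect_identical(cv$summary$rating, "Y")
  expect_lte(cv$summary$n_significant, cv$summary$n_pairs)
})

test_that("summarize_motif on invariant or empty input rates '?'", {
  flat <- mk_aln(rep("GGAACC", 6), "<<..>>")
  cv <- summarize_motif(flat, n_permutations = 99L, seed = 3L)
  expect_identical(cv$summary$n_significant, 0L)
  expect_identical(cv$summary$rating, "?")

  none <- summarize_motif(mk_aln(c("AC", "GU"), ".."),
                          n_permutations = 9L, seed = 1L)
  expect_identical(none$summary$n_pairs, 0L)
  expect_identical(none$summary$rating, "?")
})

test_that("BH-adjusted discoveries on independent columns stay near alpha", {
  set.seed(88)
  fdp <- vapply(1:8, function(s) {
    aln <- independent_alignment(n_seq = 25L, n_pairs = 20L)
    cv <- summarize_motif(aln, alpha = 0.05, n_permutations = 200L, seed = s)
    cv$summary$n_significant / cv$summary$n_pairs
  }, numeric(1))
  # mean false-discovery proportion controlled at alpha (within MC noise)
  expect_lte(mean(fdp), 0.05 + 3 * stats::sd(fdp) / sqrt(length(fdp)) + 1e-9)
})

test_that("covariation_report writes a TSV with a summary header", {
  aln <- read_stockholm(system.file("extdata", "demo_motif.sto",
                                    package = "rleaderScreen"))[[1]]
  tf <- tempfile(fileext = ".tsv")
  rep <- covariation_report(aln, path = tf, n_permutations = 99L, seed = 4L)
  expect_true(file.exists(tf))
  expect_match(readLines(tf, n = 1L), "rating=")
  expect_identical(nrow(rep), 5L)
  expect_true(all(c("p_value", "p_adj", "r2r_covarying") %in% names(rep)))
})
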