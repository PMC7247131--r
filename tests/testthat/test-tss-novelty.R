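mk_occ <- function(start, end, strand = "+", contig = "c1", len = 50000L)
  as.list(motif_occurrences("m1", contig, start, end, strand, len)[1, ])
mk_gene <- function(start, end, strand = "+", contig = "c1")
  as.list(suppressWarnings(gene_records(contig, start, end, strand,
                                        "rpsO"))[1, ])
mk_tss <- function(pos, strand = "+", contig = "c1")
  data.frame(contig = rep_len(contig, length(pos)), pos = as.integer(pos),
             strand = rep_len(strand, length(pos)), stringsAsFactors = FALSE)

test_that("TSS upstream of the motif is consistent", {
  expect_identical(
    tss_consistency(mk_occ(101, 180), mk_gene(301, 900), mk_tss(50)),
    "consistent")
})

test_that("TSS inside the motif or between motif and gene is inconsistent", {
  expect_identical(
    tss_consistency(mk_occ(101, 180), mk_gene(301, 900), mk_tss(140)),
    "inconsistent")
  expect_identical(
    tss_consistency(mk_occ(101, 180), mk_gene(301, 900), mk_tss(220)),
    "inconsistent")
})

test_that("absent or out-of-window TSS records give no-data", {
  expect_identical(
    tss_consistency(mk_occ(101, 180), mk_gene(301, 900), mk_tss(integer())),
    "no-data")
  # TSS on another contig
  expect_identical(
    tss_consistency(mk_occ(101, 180), mk_gene(301, 900),
                    mk_tss(50, contig = "c9")),
    "no-data")
  # gene at 5000: a TSS 2500 nt upstream of it is outside the 2 kb window
  expect_identical(
    tss_consistency(mk_occ(4000, 4100), mk_gene(5000, 5900), mk_tss(2500)),
    "no-data")
})

test_that("an intervening same-strand gene start blocks consistency", {
  ann <- suppressWarnings(gene_records(c("c1", "c1"), c(80, 301),
                                       c(95, 900), c("+", "+"),
                                       c("rpoA", "rpsO")))
  expect_identical(
    tss_consistency(mk_occ(101, 180), mk_gene(301, 900), mk_tss(50),
                    annotations = ann),
    "inconsistent")
})

test_that("minus-strand loci mirror the plus-strand verdicts", {
  L <- 10000L
  cases <- list(c(tss = 50, verdict = NA))
  for (tss_pos in c(50, 140, 220)) {
    fwd <- tss_consistency(mk_occ(101, 180), mk_gene(301, 900),
                           mk_tss(tss_pos))
    rev <- tss_consistency(mk_occ(L + 1 - 180, L + 1 - 101, "-", len = L),
                           mk_gene(L + 1 - 900, L + 1 - 301, "-"),
                           mk_tss(L + 1 - tss_pos, "-"))
    expect_identical(fwd, rev)
  }
})

test_that("verdicts are invariant under coordinate translation", {
  for (shift in c(0L, 5000L, 12345L))
    expect_identical(
      tss_consistency(mk_occ(101 + shift, 180 + shift),
                      mk_gene(301 + shift, 900 + shift),
                      mk_tss(140 + shift)),
      "inconsistent")
})

test_that("strand mismatch between occurrence and gene is an error", {
  expect_error(
    tss_consistency(mk_occ(101, 180, "+"), mk_gene(301, 900, "-"),
                    mk_tss(50)),
    "strand mismatch")
})

test_that("novelty filter eliminates at >= half of the shorter interval", {
  occ <- motif_occurrences("m1", "c1", 101, 200, "+", 50000)
  known <- data.frame(contig = "c1", start = 151L, end = 400L, strand = "+",
                      rna_name = "oldRNA", stringsAsFactors = FALSE)
  res <- novelty_filter(occ, known)
  # overlap 50 nt = 0.5 of the 100 nt occurrence -> eliminated
  expect_false(res$verdicts$keep)
  expect_identical(res$overlaps$rna_name, "oldRNA")
  expect_identical(res$overlaps$overlap_nt, 50L)
})

test_that("opposite strands and tiny overlaps are kept by default", {
  occ <- motif_occurrences("m1", "c1", 101, 300, "+", 50000)
  opp <- data.frame(contig = "c1", start = 101L, end = 300L, strand = "-",
                    rna_name = "anti", stringsAsFactors = FALSE)
  expect_true(novelty_filter(occ, opp)$verdicts$keep)
  # 1 nt overlap between 200 nt intervals: kept at 0.5, eliminated in strict
  near <- data.frame(contig = "c1", start = 300L, end = 499L, strand = "+",
                     rna_name = "near", stringsAsFactors = FALSE)
  expect_true(novelty_filter(occ, near)$verdicts$keep)
  expect_false(novelty_filter(occ, near, strict = TRUE)$verdicts$keep)
})

test_that("raising the overlap threshold never eliminates more motifs", {
  set.seed(17)
  for (rep in 1:8) {
    occ <- motif_occurrences(paste0("m", 1:4), rep("c1", 4),
                             s <- sample(1:2000, 4), s + sample(50:300, 4),
                             sample(c("+", "-"), 4, replace = TRUE), 50000)
    ks <- sample(1:2000, 5)
    known <- data.frame(contig = "c1", start = ks,
                        end = ks + sample(50:300, 5),
                        strand = sample(c("+", "-"), 5, replace = TRUE),
                        rna_name = paste0("r", 1:5), stringsAsFactors = FALSE)
    kept <- lapply(c(0.1, 0.3, 0.6, 0.9), function(th)
      novelty_filter(occ, known, min_overlap_frac = th)$verdicts)
    for (k in 2:length(kept))
      expect_true(all(kept[[k]]$keep >= kept[[k - 1]]$keep))
  }
})

test_that("an empty known-RNA set keeps every motif", {
  occ <- motif_occurrences("m1", "c1", 101, 200, "+", 50000)
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      rna_name = character(), stringsAsFactors = FALSE)
  expect_true(novelty_filter(occ, empty)$verdicts$keep)
  expect_true(novelty_filter(occ, NULL)$verdicts$keep)
})
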