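make_genes <- function(starts, ends, strands, symbols, contig = "c1") {
  suppressWarnings(gene_records(rep(contig, length(starts)), starts, ends,
                                strands, symbols))
}

test_that("chains break at intergenic gaps over the limit", {
  genes <- make_genes(c(301, 1001, 2301), c(900, 1600, 2900), rep("+", 3),
                      c("rpsD", "rpoA", "rplQ"))
  occ <- motif_occurrences("m1", "c1", 101, 180, "+", 20000)
  ch <- downstream_chain(occ[1, ], genes)
  # gap rpoA -> rplQ is 700 nt (> 500): chain stops after two genes
  expect_true(ch$usable)
  expect_identical(ch$genes$symbol, c("rpsD", "rpoA"))
})

test_that("gap boundaries: exactly 500 chains, 501 breaks", {
  mk <- function(second_start) {
    genes <- make_genes(c(301, second_start), c(900, second_start + 500),
                        c("+", "+"), c("rpsD", "rpoA"))
    occ <- motif_occurrences("m1", "c1", 101, 180, "+", 30000)
    downstream_chain(occ[1, ], genes)$genes$symbol
  }
  expect_identical(mk(1401), c("rpsD", "rpoA"))  # gap = 500
  expect_identical(mk(1402), "rpsD")             # gap = 501
})

test_that("the 8 kb downstream-sequence requirement is enforced exactly", {
  genes <- make_genes(301, 900, "+", "rpsO")
  mk <- function(len) {
    occ <- motif_occurrences("m1", "c1", 101, 180, "+", len)
    downstream_chain(occ[1, ], genes)
  }
  expect_false(mk(180 + 7999)$usable)
  expect_match(mk(180 + 7999)$reason, "7999")
  expect_true(mk(180 + 8000)$usable)
  # occurrence on a contig absent from the annotations is an explicit error
  occ2 <- motif_occurrences("m1", "c9", 101, 180, "+", 20000)
  expect_error(downstream_chain(occ2[1, ], genes), "c9")
})

test_that("minus-strand chains equal plus-strand chains under reflection", {
  L <- 25000L
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    starts <- cumsum(c(500, sample(100:800, n - 1, replace = TRUE) +
                         sample(200:900, n - 1, replace = TRUE)))
    ends <- starts + sample(200:900, n, replace = TRUE)
    syms <- paste0("g", seq_len(n))
    fwd_genes <- suppressWarnings(
      gene_records(rep("c1", n), starts, ends, rep("+", n), syms))
    occ <- motif_occurrences("m1", "c1", 101, 180, "+", L)
    fwd <- downstream_chain(occ[1, ], fwd_genes)
    mir <- mirror_coords(data.frame(start = starts, end = ends,
                                    strand = rep("+", n)), L)
    rev_genes <- suppressWarnings(
      gene_records(rep("c1", n), mir$start, mir$end, mir$strand, syms))
    occ_m <- motif_occurrences("m1", "c1", L + 1L - 180L, L + 1L - 101L,
                               "-", L)
    rev <- downstream_chain(occ_m[1, ], rev_genes)
    expect_identical(fwd$usable, rev$usable)
    expect_identical(fwd$genes$symbol, rev$genes$symbol)
  }
})

test_that("opposite-strand genes terminate the chain", {
  genes <- make_genes(c(301, 1001, 1501), c(900, 1400, 2100),
                      c("+", "-", "+"), c("rpsD", "rpoA", "rplQ"))
  occ <- motif_occurrences("m1", "c1", 101, 180, "+", 20000)
  expect_identical(downstream_chain(occ[1, ], genes)$genes$symbol, "rpsD")
})

test_that("genes overlapping the motif are skipped; overlapping genes chain", {
  genes <- make_genes(c(150, 301, 850), c(250, 900, 1500), rep("+", 3),
                      c("ovl", "rpsD", "rpoA"))
  occ <- motif_occurrences("m1", "c1", 101, 180, "+", 20000)
  ch <- downstream_chain(occ[1, ], genes)
  # gene starting inside the motif is not part of the downstream operon;
  # rpoA overlaps rpsD (gap 0) and chains
  expect_identical(ch$genes$symbol, c("rpsD", "rpoA"))
})

test_that("consensus operon retains unanimous chains with support 1", {
  chains <- rep(list(c("rpsD", "rpoA", "rplQ")), 10)
  op <- consensus_operon(chains)
  expect_identical(op$genes, c("rpsD", "rpoA", "rplQ"))
  expect_true(all(op$support[op$genes] == 1))
  expect_identical(op$n_usable, 10L)
})

test_that("low-support genes move to the often-extended list", {
  chains <- c(rep(list(c("rplM", "rpsI")), 5),
              rep(list(c("rplM", "rpsI", "rpsB")), 4),
              list("rplM"))
  op <- consensus_operon(chains)
  expect_identical(op$genes, c("rplM", "rpsI"))
  expect_identical(op$extended, "rpsB")
  expect_equal(unname(op$support[["rpsB"]]), 0.4)
})

test_that("retained genes are ordered by modal then median rank", {
  chains <- list(c("a", "b"), c("b", "a"), c("b", "a"))
  op <- consensus_operon(chains, min_support = 0.5)
  expect_identical(op$genes, c("b", "a"))
  # tie on modal rank -> median rank -> symbol
  chains2 <- list(c("x", "y"), c("y", "x"))
  op2 <- consensus_operon(chains2, min_support = 0.5)
  expect_identical(op2$genes, c("x", "y"))  # all ties -> lexicographic
})

test_that("consensus operon invariants: no invention, support monotonicity", {
  set.seed(11)
  pool <- paste0("g", 1:6)
  for (rep in 1:10) {
    chains <- lapply(1:6, function(i)
      sample(pool, sample(1:5, 1)))
    thresholds <- c(0.2, 0.5, 0.75, 0.9)
    sets <- lapply(thresholds, function(th)
      consensus_operon(chains, min_support = th)$genes)
    for (k in seq_along(sets))
      expect_true(all(sets[[k]] %in% unlist(chains)))
    for (k in 2:length(sets))
      expect_true(all(sets[[k]] %in% sets[[k - 1]]))
  }
})

test_that("zero usable chains yield an explicitly flagged empty operon", {
  op <- consensus_operon(list())
  expect_identical(op$genes, character())
  expect_identical(op$flag, "no usable occurrences")
})

test_that("annotations round-trip through GFF3/BED via the genome fixture", {
  layout <- genome_layout(
    list(name = "ctgA", length = 30000L,
         motifs = data.frame(motif_id = "m1", start = 101L, end = 180L,
                             strand = "+"),
         genes = gene_cascade(180L, c("rpsO", "rpoA"), lengths = 600L,
                              gaps = 200L),
         tss = data.frame(pos = 60L, strand = "+")))
  fix <- generate_genome_fixture(layout)
  genes <- read_gene_annotations(fix$paths$gff)
  expect_identical(genes$symbol, c("rpsO", "rpoA"))
  expect_identical(genes$start, fix$genes$start)
  occ <- read_motif_occurrences(fix$paths$occurrences_bed,
                                fix$paths$contig_lengths_tsv)
  expect_identical(occ$start, 101L)
  expect_identical(occ$end, 180L)
  ch <- downstream_chain(occ[1, ], genes)
  expect_identical(ch$genes$symbol, c("rpsO", "rpoA"))
})
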