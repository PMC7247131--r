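# Synthetic data: alignments with known covariation structure, and genome
# layouts with known operon structure, so every pipeline stage is testable
# without downloads.

#' Parameters for alignment simulation
#'
#' @param n_sequences number of tip sequences (>= 2).
#' @param mean_branch_length expected substitutions per site per branch of
#'   the simulated tree (branch lengths drawn i.i.d. exponential).
#' @param compensatory_rate probability that a substitution event at a paired
#'   column replaces the pair with a different canonical pair (both partners
#'   change together); with the complementary probability the event leaves a
#'   non-canonical pair.
#' @param noncanonical_noise per-tip, per-pair probability of forcing an
#'   unrestored (non-canonical) state after evolution — emulating alignment
#'   or sequencing artefacts on top of the evolutionary signal.
#' @param unpaired_rate rate multiplier for substitutions at unpaired
#'   columns, relative to pair-event rate.
#' @param tree optional `ape::phylo` tree (overrides `n_sequences` and the
#'   random topology).
#' @param seed optional integer; fixed seed implies identical output.
#' @return list of class `evolution_params`.
#' @export
evolution_params <- function(n_sequences = 24L, mean_branch_length = 0.5,
                             compensatory_rate = 0.95,
                             noncanonical_noise = 0.02,
                             unpaired_rate = 1.0, tree = NULL, seed = NULL) {
  stopifnot(n_sequences >= 2L,
            compensatory_rate >= 0, compensatory_rate <= 1,
            noncanonical_noise >= 0, noncanonical_noise <= 1,
            mean_branch_length >= 0, unpaired_rate >= 0)
  structure(list(n_sequences = as.integer(n_sequences),
                 mean_branch_length = mean_branch_length,
                 compensatory_rate = compensatory_rate,
                 noncanonical_noise = noncanonical_noise,
                 unpaired_rate = unpaired_rate, tree = tree, seed = seed),
            class = "evolution_params")
}

.BASES <- c("A", "C", "G", "U")
.CANONICAL_SPLIT <- matrix(c("A","U", "U","A", "G","C", "C","G", "G","U",
                             "U","G"), ncol = 2, byrow = TRUE)
.NONCANONICAL_SPLIT <- local({
  all <- expand.grid(a = c("A","C","G","U"), b = c("A","C","G","U"),
                     stringsAsFactors = FALSE)
  keep <- !paste0(all$a, all$b) %in% c("AU","UA","GC","CG","GU","UG")
  as.matrix(all[keep, ])
})

#' Simulate a structure-annotated alignment on a phylogeny
#'
#' Draws a root sequence with canonical pairs at every annotated pair column,
#' evolves it down a random bifurcating tree (Yule-style topology from
#' [ape::rtree()] with exponential branch lengths), and returns the tip
#' sequences aligned under the input consensus structure. Substitution events
#' occur per column per branch with probability `1 - exp(-bl)` (pair columns
#' evolve as a unit; unpaired columns use `1 - exp(-bl * unpaired_rate)`).
#' A pair-column event is compensatory — a different canonical pair — with
#' probability `compensatory_rate`, else non-canonical. After evolution,
#' each tip/pair is independently forced non-canonical with probability
#' `noncanonical_noise`; the realized non-canonical fraction therefore
#' converges on `noncanonical_noise` when `compensatory_rate = 1`.
#'
#' No indels are simulated and all columns are independent, so the generator
#' reproduces the covariation signal the detectors consume but not alignment
#' error, rate heterogeneity, or base-composition bias of real alignments.
#'
#' @param structure consensus structure string (WUSS / dot-bracket).
#' @param params an [evolution_params()] list.
#' @return a [structured_alignment()] with the input structure as consensus.
#' @export
simulate_alignment <- function(structure, params = evolution_params()) {
  pt <- extract_pairs(structure)
  ncol <- nchar(structure)
  with_preserved_seed(params$seed, {
    tree <- params$tree
    if (is.null(tree))
      tree <- ape::rtree(params$n_sequences, br = stats::rexp,
                         rate = 1 / params$mean_branch_length)
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    root <- ntip + 1L
    # state: character matrix nodes x columns, filled in preorder
    states <- matrix(NA_character_, nrow = nnode, ncol = ncol)
    rootseq <- character(ncol)
    if (length(pt$unpaired))
      rootseq[pt$unpaired] <- sample(.BASES, length(pt$unpaired), replace = TRUE)
    if (nrow(pt$pairs))
      for (k in seq_len(nrow(pt$pairs))) {
        pr <- .CANONICAL_SPLIT[sample.int(6L, 1L), ]
        rootseq[pt$pairs[k, "i"]] <- pr[[1]]
        rootseq[pt$pairs[k, "j"]] <- pr[[2]]
      }
    states[root, ] <- rootseq
    edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
    # preorder traversal: parents always precede children in reorder(.,"postorder") reversed
    po <- ape::reorder.phylo(tree, "postorder")$edge
    for (e in rev(seq_len(nrow(po)))) {
      parent <- po[e, 1]; child <- po[e, 2]
      bl <- tree$edge.length[which(tree$edge[, 1] == parent &
                                     tree$edge[, 2] == child)][1]
      seq <- states[parent, ]
      p_pair <- 1 - exp(-bl)
      p_unp <- 1 - exp(-bl * params$unpaired_rate)
      for (k in seq_len(nrow(pt$pairs))) {
        if (stats::runif(1) < p_pair) {
          i <- pt$pairs[k, "i"]; j <- pt$pairs[k, "j"]
          if (stats::runif(1) < params$compensatory_rate) {
            cur <- paste0(seq[i], seq[j])
            alt <- which(paste0(.CANONICAL_SPLIT[, 1],
                                .CANONICAL_SPLIT[, 2]) != cur)
            pr <- .CANONICAL_SPLIT[sample(alt, 1L), ]
          } else {
            pr <- .NONCANONICAL_SPLIT[sample.int(nrow(.NONCANONICAL_SPLIT), 1L), ]
          }
          seq[i] <- pr[[1]]; seq[j] <- pr[[2]]
        }
      }
      for (col in pt$unpaired) {
        if (stats::runif(1) < p_unp)
          seq[col] <- sample(setdiff(.BASES, seq[col]), 1L)
      }
      states[child, ] <- seq
    }
    tips <- states[seq_len(ntip), , drop = FALSE]
    # per-tip per-pair non-canonical noise
    if (params$noncanonical_noise > 0 && nrow(pt$pairs))
      for (t in seq_len(ntip))
        for (k in seq_len(nrow(pt$pairs)))
          if (stats::runif(1) < params$noncanonical_noise) {
            pr <- .NONCANONICAL_SPLIT[sample.int(nrow(.NONCANONICAL_SPLIT), 1L), ]
            tips[t, pt$pairs[k, "i"]] <- pr[[1]]
            tips[t, pt$pairs[k, "j"]] <- pr[[2]]
          }
    seqs <- apply(tips, 1L, paste, collapse = "")
    names(seqs) <- sprintf("seq%02d", seq_len(ntip))
    structured_alignment(seqs, structure,
                         gf = c(CC = "simulated alignment (rleaderScreen)"))
  })
}

#' Specify a synthetic genome layout
#'
#' Declarative description of one or more contigs with motif occurrences,
#' gene cascades and TSS positions; realized by
#' [generate_genome_fixture()]. Each contig is a list with `name`, `length`,
#' and optional data frames `motifs` (`motif_id`, `start`, `end`, `strand`),
#' `genes` (`symbol`, `start`, `end`, `strand`) and `tss` (`pos`, `strand`).
#' Coordinates are 1-based closed and must fit within the contig.
#'
#' @param ... contig lists.
#' @return list of class `genome_layout`.
#' @export
genome_layout <- function(...) {
  contigs <- list(...)
  for (ctg in contigs) {
    stopifnot(!is.null(ctg$name), !is.null(ctg$length))
    for (part in c("motifs", "genes")) {
      feat <- ctg[[part]]
      if (!is.null(feat) && nrow(feat) &&
          any(feat$start < 1L | feat$end > ctg$length | feat$start > feat$end))
        stop("feature outside contig '", ctg$name, "' (length ",
             ctg$length, ")")
    }
    if (!is.null(ctg$tss) && nrow(ctg$tss) &&
        any(ctg$tss$pos < 1L | ctg$tss$pos > ctg$length))
      stop("TSS outside contig '", ctg$name, "'")
  }
  structure(contigs, class = "genome_layout")
}

#' Lay out a gene cascade downstream of a position
#'
#' Helper constructing the `genes` data frame of a [genome_layout()] contig:
#' genes of the given lengths separated by the given intergenic gaps,
#' starting `first_gap` nt downstream of `from` in transcription direction.
#' On the minus strand the cascade runs leftward (coordinates mirrored).
#'
#' @param from anchor coordinate (e.g. the motif's downstream edge).
#' @param symbols gene symbols in transcription order.
#' @param lengths gene lengths (recycled).
#' @param gaps intergenic gaps between consecutive genes (length
#'   `length(symbols) - 1`, recycled; may be 0 for overlap-free adjacency).
#' @param strand `"+"` or `"-"`.
#' @param first_gap gap between `from` and the first gene (default 100).
#' @return data frame with `symbol`, `start`, `end`, `strand`.
#' @export
gene_cascade <- function(from, symbols, lengths = 600L, gaps = 50L,
                         strand = "+", first_gap = 100L) {
  n <- length(symbols)
  lengths <- rep_len(lengths, n)
  gaps <- if (n > 1L) rep_len(gaps, n - 1L) else integer()
  start <- integer(n); end <- integer(n)
  edge <- from
  for (k in seq_len(n)) {
    gap <- if (k == 1L) first_gap else gaps[[k - 1L]]
    if (strand == "+") {
      start[k] <- edge + gap + 1L
      end[k] <- start[k] + lengths[k] - 1L
      edge <- end[k]
    } else {
      end[k] <- edge - gap - 1L
      start[k] <- end[k] - lengths[k] + 1L
      edge <- start[k]
    }
  }
  data.frame(symbol = symbols, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Realize a genome layout as annotation files
#'
#' Writes the layout's gene annotations (GFF3), motif occurrences (BED),
#' TSS positions (BED) and contig length table (TSV) into `dir` via
#' rtracklayer, and returns the corresponding in-memory tables. Output is
#' deterministic given the spec (the `seed` argument is accepted for
#' interface symmetry with [simulate_alignment()] and reserved for future
#' randomized layouts).
#'
#' @param layout a [genome_layout()].
#' @param dir output directory (created if needed).
#' @param seed optional integer seed.
#' @param map gene->protein map used for the returned `gene_records`.
#' @return list with paths (`gff`, `occurrences_bed`, `tss_bed`,
#'   `contig_lengths_tsv`) and tables (`genes`, `occurrences`, `tss`,
#'   `contig_lengths`).
#' @export
generate_genome_fixture <- function(layout, dir = tempfile("genome_fix"),
                                    seed = NULL,
                                    map = load_gene_protein_map()) {
  stopifnot(inherits(layout, "genome_layout"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- list(); motifs <- list(); tss <- list()
  lens <- data.frame(contig = character(), length = integer(),
                     stringsAsFactors = FALSE)
  for (ctg in layout) {
    lens <- rbind(lens, data.frame(contig = ctg$name,
                                   length = as.integer(ctg$length)))
    if (!is.null(ctg$genes) && nrow(ctg$genes))
      genes[[length(genes) + 1L]] <- cbind(contig = ctg$name, ctg$genes)
    if (!is.null(ctg$motifs) && nrow(ctg$motifs))
      motifs[[length(motifs) + 1L]] <- cbind(contig = ctg$name, ctg$motifs)
    if (!is.null(ctg$tss) && nrow(ctg$tss))
      tss[[length(tss) + 1L]] <- cbind(contig = ctg$name, ctg$tss)
  }
  genes <- if (length(genes)) do.call(rbind, genes) else NULL
  motifs <- if (length(motifs)) do.call(rbind, motifs) else NULL
  tss <- if (length(tss)) do.call(rbind, tss) else NULL
  paths <- list(gff = file.path(dir, "genes.gff3"),
                occurrences_bed = file.path(dir, "occurrences.bed"),
                tss_bed = file.path(dir, "tss.bed"),
                contig_lengths_tsv = file.path(dir, "contig_lengths.tsv"))
  seqlens <- stats::setNames(lens$length, lens$contig)
  gr <- if (!is.null(genes))
    GenomicRanges::GRanges(genes$contig,
                           IRanges::IRanges(genes$start, genes$end),
                           strand = genes$strand)
  else GenomicRanges::GRanges()
  gr$type <- rep("gene", length(gr))
  gr$gene <- if (!is.null(genes)) genes$symbol else character()
  rtracklayer::export(gr, paths$gff, format = "gff3")
  gr <- if (!is.null(motifs))
    GenomicRanges::GRanges(motifs$contig,
                           IRanges::IRanges(motifs$start, motifs$end),
                           strand = motifs$strand)
  else GenomicRanges::GRanges()
  gr$name <- if (!is.null(motifs)) motifs$motif_id else character()
  rtracklayer::export(gr, paths$occurrences_bed, format = "bed")
  gr <- if (!is.null(tss))
    GenomicRanges::GRanges(tss$contig, IRanges::IRanges(tss$pos, tss$pos),
                           strand = tss$strand)
  else GenomicRanges::GRanges()
  gr$name <- sprintf("TSS%03d", seq_along(gr))
  rtracklayer::export(gr, paths$tss_bed, format = "bed")
  utils::write.table(lens, paths$contig_lengths_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(paths = paths,
       genes = if (!is.null(genes))
         gene_records(genes$contig, genes$start, genes$end, genes$strand,
                      genes$symbol, map = map) else NULL,
       occurrences = if (!is.null(motifs))
         motif_occurrences(motifs$motif_id, motifs$contig, motifs$start,
                           motifs$end, motifs$strand, seqlens) else NULL,
       tss = if (!is.null(tss))
         data.frame(contig = tss$contig, pos = as.integer(tss$pos),
                    strand = tss$strand, stringsAsFactors = FALSE) else NULL,
       contig_lengths = lens)
}
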