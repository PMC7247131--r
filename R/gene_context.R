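# Operon inference from gene context.
#
# Coordinates throughout are 1-based, closed intervals (the GFF/GRanges
# convention); BED input and output is converted at the boundary by
# rtracklayer. The intergenic gap between two features is the number of
# nucleotides strictly between them (overlap => gap 0).

#' Build a gene-record table
#'
#' Canonical gene annotation table used by the operon and ligand stages.
#' `product_class` (`"r-protein"` or `"other"`) and `protein` (the r-protein
#' name, e.g. `"S4"`) are filled from a gene->protein map; symbols absent
#' from the map are classed `"other"` with a warning.
#'
#' @param contig,start,end,strand,symbol vectors of equal length (1-based,
#'   closed coordinates; strand `"+"` or `"-"`).
#' @param map gene->protein map data frame (columns `symbol`,
#'   `product_class`, `protein`), default the packaged map
#'   ([load_gene_protein_map()]).
#' @return data frame of class `gene_records` with columns `contig`, `start`,
#'   `end`, `strand`, `symbol`, `product_class`, `protein`.
#' @export
gene_records <- function(contig, start, end, strand, symbol,
                         map = load_gene_protein_map()) {
  stopifnot(all(start <= end), all(strand %in% c("+", "-")))
  idx <- match(symbol, map$symbol)
  if (anyNA(idx)) {
    unknown <- unique(symbol[is.na(idx)])
    warning("gene symbol(s) not in gene->protein map, classed 'other': ",
            paste(unknown, collapse = ", "))
  }
  df <- data.frame(contig = as.character(contig),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   symbol = as.character(symbol),
                   product_class = ifelse(is.na(idx), "other",
                                          map$product_class[idx]),
                   protein = ifelse(is.na(idx), NA_character_,
                                    ifelse(map$product_class[idx] == "r-protein",
                                           map$protein[idx], NA_character_)),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_records", class(df))
  df
}

#' Read gene annotations from GFF3
#'
#' Imports a GFF3 file via rtracklayer, keeps features of the given type, and
#' extracts the gene symbol from the first attribute key present among
#' `symbol_attr`.
#'
#' @param path GFF3 file.
#' @param feature_type feature type(s) to keep (default `"gene"`).
#' @param symbol_attr candidate attribute keys for the gene symbol, tried in
#'   order.
#' @param map gene->protein map, as in [gene_records()].
#' @return a `gene_records` data frame.
#' @export
read_gene_annotations <- function(path, feature_type = "gene",
                                  symbol_attr = c("gene", "Name", "ID"),
                                  map = load_gene_protein_map()) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(gr$type)) gr <- gr[as.character(gr$type) %in% feature_type]
  if (!length(gr)) stop("no '", paste(feature_type, collapse = "/"),
                        "' features in ", path)
  meta <- S4Vectors::mcols(gr)
  key <- intersect(symbol_attr, colnames(meta))
  if (!length(key)) stop("none of the symbol attributes (",
                         paste(symbol_attr, collapse = ", "),
                         ") present in ", path)
  gene_records(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr),
               as.character(GenomicRanges::strand(gr)),
               as.character(meta[[key[1]]]), map = map)
}

#' Motif occurrence table
#'
#' @param motif_id,contig,start,end,strand vectors of equal length.
#' @param contig_length available sequence length of each occurrence's
#'   contig; either a vector parallel to the occurrences or a named vector /
#'   two-column data frame (`contig`, `length`) looked up by contig.
#' @return data frame of class `motif_occurrences`.
#' @export
motif_occurrences <- function(motif_id, contig, start, end, strand,
                              contig_length) {
  contig <- as.character(contig)
  if (is.data.frame(contig_length))
    contig_length <- stats::setNames(contig_length[[2]], contig_length[[1]])
  if (!is.null(names(contig_length)))
    contig_length <- unname(contig_length[contig])
  if (anyNA(contig_length)) stop("missing contig length for: ",
                                 paste(unique(contig[is.na(contig_length)]),
                                       collapse = ", "))
  stopifnot(all(start <= end), all(end <= contig_length))
  df <- data.frame(motif_id = as.character(motif_id), contig = contig,
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   contig_length = as.integer(contig_length),
                   stringsAsFactors = FALSE)
  class(df) <- c("motif_occurrences", class(df))
  df
}

#' Read motif occurrences from BED
#'
#' @param path BED file; the name column carries the motif id.
#' @param contig_lengths named vector, two-column data frame, or TSV path
#'   (`contig`, `length`).
#' @return a `motif_occurrences` data frame (coordinates converted to
#'   1-based closed).
#' @export
read_motif_occurrences <- function(path, contig_lengths) {
  if (is.character(contig_lengths) && length(contig_lengths) == 1L &&
      file.exists(contig_lengths))
    contig_lengths <- .read_tsv(contig_lengths)
  gr <- rtracklayer::import(path, format = "bed")
  motif_occurrences(if (!is.null(gr$name)) gr$name else
                      paste0("motif", seq_along(gr)),
                    as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr), GenomicRanges::end(gr),
                    as.character(GenomicRanges::strand(gr)),
                    contig_lengths)
}

#' Downstream gene chain of one motif occurrence
#'
#' Implements the operon-walk heuristics: an occurrence is usable only when
#' at least `min_downstream` nucleotides of sequence are available downstream
#' of the motif in transcription direction (guarding against truncated
#' contigs); the chain starts at the first gene whose (transcription-sense)
#' start lies strictly downstream of the motif and extends while consecutive
#' genes are on the same strand and separated by at most `max_gap`
#' nucleotides of intergenic sequence. Overlapping or nested same-strand
#' genes chain with gap 0; an opposite-strand gene terminates the chain.
#'
#' @param occurrence single occurrence: one row of a `motif_occurrences`
#'   data frame (or an equivalent list with fields `contig`, `start`, `end`,
#'   `strand`, `contig_length`).
#' @param annotations a `gene_records` data frame.
#' @param max_gap maximum intergenic gap in nt (default 500).
#' @param min_downstream minimum available downstream sequence in nt
#'   (default 8000).
#' @return list with `usable` (logical), `reason` (when unusable), and
#'   `genes` (the chained `gene_records` rows in transcription order).
#' @export
downstream_chain <- function(occurrence, annotations, max_gap = 500L,
                             min_downstream = 8000L) {
  occ <- as.list(occurrence)
  if (is.data.frame(occurrence)) occ <- as.list(occurrence[1, ])
  if (!occ$contig %in% annotations$contig)
    stop("occurrence contig '", occ$contig, "' absent from annotations")
  plus <- occ$strand == "+"
  available <- if (plus) occ$contig_length - occ$end else occ$start - 1L
  if (available < min_downstream)
    return(list(usable = FALSE,
                reason = sprintf("only %d nt downstream (< %d)",
                                 available, min_downstream),
                genes = annotations[0, ]))
  g <- annotations[annotations$contig == occ$contig, , drop = FALSE]
  # transcription-sense start must lie strictly downstream of the motif,
  # skipping genes that overlap the motif itself
  if (plus) {
    g <- g[g$start > occ$end, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
  } else {
    g <- g[g$end < occ$start, , drop = FALSE]
    g <- g[order(-g$end, -g$start), , drop = FALSE]
  }
  chain <- integer()
  prev_edge <- if (plus) occ$end else occ$start
  for (k in seq_len(nrow(g))) {
    if (g$strand[k] != occ$strand) break
    gap <- if (plus) g$start[k] - prev_edge - 1L else prev_edge - g$end[k] - 1L
    gap <- max(0L, gap)
    if (length(chain) && gap > max_gap) break
    chain <- c(chain, k)
    prev_edge <- if (plus) max(prev_edge, g$end[k]) else min(prev_edge, g$start[k])
  }
  list(usable = TRUE, reason = NA_character_,
       genes = g[chain, , drop = FALSE])
}

#' Consensus operon across occurrences of one motif
#'
#' Aggregates per-occurrence downstream gene chains into the consensus
#' regulated operon: a gene symbol is retained when it appears in at least
#' `min_support` of the usable chains (filtering genes that are
#' inconsistently positioned or often absent); retained genes are ordered by
#' their modal rank across chains, ties broken by median rank then symbol.
#' Symbols with support in `[extended_min, min_support)` are reported
#' separately as "often-extended" operon genes rather than discarded.
#'
#' @param chains list of character vectors: the gene symbols of each usable
#'   chain, in transcription order (unusable occurrences excluded by the
#'   caller).
#' @param min_support retention threshold (fraction of usable chains).
#' @param extended_min lower support bound for the often-extended list.
#' @param motif_id optional identifier carried into the result.
#' @return object of class `operon_prediction`: list with `motif_id`,
#'   `genes` (ordered retained symbols), `support` (named fractions),
#'   `extended` (often-extended symbols), `n_usable`, `flag`.
#' @export
consensus_operon <- function(chains, min_support = 0.75, extended_min = 0.25,
                             motif_id = NA_character_) {
  n <- length(chains)  # usable chains with zero genes still count in support
  if (n == 0L)
    return(structure(list(motif_id = motif_id, genes = character(),
                          support = numeric(), extended = character(),
                          n_usable = 0L, flag = "no usable occurrences"),
                     class = "operon_prediction"))
  symbols <- unique(unlist(chains))
  support <- vapply(symbols, function(s)
    mean(vapply(chains, function(ch) s %in% ch, logical(1))), numeric(1))
  retained <- symbols[support >= min_support]
  extended <- symbols[support >= extended_min & support < min_support]
  rank_stats <- lapply(retained, function(s) {
    r <- unlist(lapply(chains, function(ch) which(ch == s)[1]))
    r <- r[!is.na(r)]
    tab <- table(r)
    modal <- as.integer(names(tab)[which.max(tab)])  # smallest mode on ties
    c(modal = modal, median = stats::median(r))
  })
  if (length(retained)) {
    modal <- vapply(rank_stats, `[[`, numeric(1), "modal")
    med <- vapply(rank_stats, `[[`, numeric(1), "median")
    retained <- retained[order(modal, med, retained)]
  }
  ext_order <- order(-support[extended], extended)
  structure(list(motif_id = motif_id, genes = retained,
                 support = support[c(retained, extended[ext_order])],
                 extended = extended[ext_order],
                 n_usable = n, flag = NA_character_),
            class = "operon_prediction")
}

#' @export
print.operon_prediction <- function(x, ...) {
  cat("Operon", if (!is.na(x$motif_id)) paste0(" [", x$motif_id, "]"), ": ",
      if (length(x$genes)) paste(x$genes, collapse = ", ") else "(empty)",
      sep = "")
  if (length(x$extended)) cat("  + often-extended:",
                              paste(x$extended, collapse = ", "))
  cat("  (", x$n_usable, " usable occurrences)\n", sep = "")
  if (!is.na(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}
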