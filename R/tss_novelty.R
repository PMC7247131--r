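# Transcription-start-site consistency and novelty filtering.

#' Read transcription start sites
#'
#' Accepts BED (single-position features, converted from 0-based) or a TSV
#' with columns `contig`, `pos`, `strand`.
#'
#' @param path input file.
#' @return data frame with columns `contig`, `pos` (1-based), `strand`.
#' @export
read_tss <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first) && !grepl("pos", first, fixed = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
               pos = GenomicRanges::start(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
  } else {
    tss <- .read_tsv(path)
    stopifnot(all(c("contig", "pos", "strand") %in% names(tss)))
    tss[c("contig", "pos", "strand")]
  }
}

#' Read previously published RNA intervals
#'
#' @param path BED6 file; the name column carries the RNA name.
#' @return data frame with `contig`, `start`, `end` (1-based closed),
#'   `strand`, `rna_name`.
#' @export
read_known_rnas <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             rna_name = if (!is.null(gr$name)) gr$name else
               paste0("RNA", seq_along(gr)),
             stringsAsFactors = FALSE)
}

#' TSS consistency of one motif occurrence
#'
#' A plausible cis-regulator lies between a transcription start site and the
#' first regulated gene. The locus window is the `window` nucleotides
#' upstream of the first gene's (transcription-sense) start. The verdict is
#' `"consistent"` when some same-strand TSS in the window lies upstream of
#' the motif with no annotated same-strand gene start strictly between the
#' TSS and the motif; `"inconsistent"` when TSSes exist in the window but
#' every one falls inside the motif or between motif and gene start;
#' `"no-data"` when the window contains no TSS.
#'
#' @param occurrence one motif occurrence (row of `motif_occurrences` or
#'   equivalent list).
#' @param first_gene the first chained gene (row of `gene_records`), same
#'   strand as and downstream of the occurrence.
#' @param tss TSS data frame ([read_tss()]).
#' @param annotations optional `gene_records` used for the intervening-gene
#'   check; defaults to none.
#' @param window locus window size in nt (default 2000).
#' @return `"consistent"`, `"inconsistent"` or `"no-data"`.
#' @export
tss_consistency <- function(occurrence, first_gene, tss, annotations = NULL,
                            window = 2000L) {
  occ <- as.list(if (is.data.frame(occurrence)) occurrence[1, ] else occurrence)
  gene <- as.list(if (is.data.frame(first_gene)) first_gene[1, ] else first_gene)
  if (occ$strand != gene$strand)
    stop("strand mismatch between occurrence (", occ$strand,
         ") and first gene (", gene$strand, ")")
  plus <- occ$strand == "+"
  cand <- tss[tss$contig == occ$contig & tss$strand == occ$strand, , drop = FALSE]
  gene_tss_start <- if (plus) gene$start else gene$end
  in_window <- if (plus)
    cand$pos >= gene_tss_start - window & cand$pos < gene_tss_start
  else
    cand$pos <= gene_tss_start + window & cand$pos > gene_tss_start
  cand <- cand[in_window, , drop = FALSE]
  if (!nrow(cand)) return("no-data")
  upstream <- if (plus) cand$pos < occ$start else cand$pos > occ$end
  if (!any(upstream)) return("inconsistent")
  if (is.null(annotations)) return("consistent")
  ann <- annotations[annotations$contig == occ$contig &
                       annotations$strand == occ$strand, , drop = FALSE]
  starts <- if (plus) ann$start else ann$end
  for (pos in cand$pos[upstream]) {
    blocked <- if (plus) any(starts > pos & starts < occ$start)
               else any(starts < pos & starts > occ$end)
    if (!blocked) return("consistent")
  }
  "inconsistent"
}

#' Novelty filter against previously published RNAs
#'
#' A motif is eliminated when any of its occurrences overlaps a same-strand
#' known RNA interval by at least `min_overlap_frac` of the shorter of the
#' two intervals (set `min_overlap_frac = 0` with care; any positive value
#' requires >= 1 nt of overlap). Opposite-strand overlap never eliminates.
#'
#' @param occurrences `motif_occurrences` data frame (several motifs allowed).
#' @param known known-RNA data frame ([read_known_rnas()]).
#' @param min_overlap_frac elimination threshold (default 0.5); use
#'   `1/width` semantics via `strict = TRUE` to eliminate on any 1-nt
#'   overlap.
#' @param strict when `TRUE`, any overlap (>= 1 nt) eliminates.
#' @return list with `verdicts` (data frame `motif_id`, `keep`) and
#'   `overlaps` (data frame of every offending occurrence/known-RNA pair
#'   with overlap length and fraction).
#' @export
novelty_filter <- function(occurrences, known, min_overlap_frac = 0.5,
                           strict = FALSE) {
  overlaps <- list()
  if (!is.null(known) && nrow(known)) {
    for (k in seq_len(nrow(occurrences))) {
      occ <- occurrences[k, ]
      cand <- known[known$contig == occ$contig & known$strand == occ$strand, ,
                    drop = FALSE]
      if (!nrow(cand)) next
      ovl <- pmin(cand$end, occ$end) - pmax(cand$start, occ$start) + 1L
      frac <- ovl / pmin(cand$end - cand$start + 1L, occ$end - occ$start + 1L)
      hit <- if (strict) ovl >= 1L else ovl >= 1L & frac >= min_overlap_frac
      if (any(hit))
        overlaps[[length(overlaps) + 1L]] <- data.frame(
          motif_id = occ$motif_id, occ_contig = occ$contig,
          occ_start = occ$start, occ_end = occ$end,
          rna_name = cand$rna_name[hit], overlap_nt = ovl[hit],
          overlap_frac = frac[hit], stringsAsFactors = FALSE)
    }
  }
  overlaps <- if (length(overlaps)) do.call(rbind, overlaps) else
    data.frame(motif_id = character(), occ_contig = character(),
               occ_start = integer(), occ_end = integer(),
               rna_name = character(), overlap_nt = integer(),
               overlap_frac = numeric(), stringsAsFactors = FALSE)
  ids <- unique(occurrences$motif_id)
  list(verdicts = data.frame(motif_id = ids,
                             keep = !ids %in% overlaps$motif_id,
                             stringsAsFactors = FALSE),
       overlaps = overlaps)
}
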