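#' Structure-annotated multiple sequence alignment
#'
#' Container for an RNA multiple sequence alignment together with a per-column
#' consensus secondary structure (the `#=GC SS_cons` line of a Stockholm
#' file). Sequences are gapped strings over `A,C,G,U,T,-,.` (case preserved;
#' `T` and `U` are treated as equivalent by downstream pairing logic but never
#' rewritten). Unknown per-file (`#=GF`), per-sequence (`#=GS`), per-residue
#' (`#=GR`) and per-column (`#=GC`) annotations are retained verbatim so that
#' a read/write round trip is content-identical.
#'
#' @param sequences named character vector of gapped sequences; names are the
#'   sequence identifiers (unique, may embed coordinates as `name/start-end`).
#' @param consensus_structure single string, same length as every sequence,
#'   in WUSS or dot-bracket notation.
#' @param gf named character vector of `#=GF` annotations (duplicate tags
#'   allowed, order preserved).
#' @param gs list of named character vectors, one per annotated sequence.
#' @param gr list of named character vectors of per-residue annotation strings.
#' @param gc named character vector of additional `#=GC` lines (excluding
#'   `SS_cons`, which is carried in `consensus_structure`).
#' @return an object of class `structured_alignment`.
#' @seealso [read_stockholm()], [write_stockholm()], [extract_pairs()]
#' @export
structured_alignment <- function(sequences, consensus_structure,
                                 gf = character(), gs = list(), gr = list(),
                                 gc = character()) {
  sequences <- vapply(sequences, as.character, character(1))
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence identifier: ",
         names(sequences)[duplicated(names(sequences))][1])
  if (length(consensus_structure) != 1L)
    stop("consensus_structure must be a single string")
  widths <- nchar(sequences)
  if (length(unique(widths)) > 1L) {
    bad <- names(sequences)[widths != widths[1]][1]
    stop("ragged alignment: sequence '", bad, "' has length ",
         nchar(sequences[[bad]]), ", expected ", widths[1])
  }
  if (length(sequences) && nchar(consensus_structure) != widths[1])
    stop("consensus structure length (", nchar(consensus_structure),
         ") does not match alignment length (", widths[1], ")")
  structure(list(sequences = sequences,
                 consensus_structure = consensus_structure,
                 gf = gf, gs = gs, gr = gr, gc = gc),
            class = "structured_alignment")
}

#' @export
print.structured_alignment <- function(x, ...) {
  cat("Structured alignment: ", length(x$sequences), " sequences, ",
      nchar(x$consensus_structure), " columns\n", sep = "")
  np <- nrow(extract_pairs(x$consensus_structure)$pairs)
  cat("Consensus structure: ", np, " base pairs\n", sep = "")
  if ("ID" %in% names(x$gf)) cat("ID: ", x$gf[["ID"]], "\n", sep = "")
  invisible(x)
}

#' @export
length.structured_alignment <- function(x) length(x$sequences)

#' Number of alignment columns
#' @param x a `structured_alignment`
#' @return integer column count
#' @export
alignment_ncol <- function(x) nchar(x$consensus_structure)

# split text into physical lines regardless of whether input is a path,
# a single string with newlines, or a character vector of lines
.as_lines <- function(path_or_text) {
  if (length(path_or_text) == 1L && !grepl("\n", path_or_text) &&
      file.exists(path_or_text))
    return(readLines(path_or_text, warn = FALSE))
  unlist(strsplit(path_or_text, "\n", fixed = TRUE), use.names = FALSE)
}

#' Read Stockholm 1.0 alignments
#'
#' Parses one or more Stockholm alignment blocks (separated by `//`).
#' Interleaved (wrapped) alignments are joined by identifier. The consensus
#' secondary structure is taken from the `#=GC SS_cons` line; its absence is
#' an error because every downstream computation needs the pairing
#' annotation. All other annotation lines are preserved.
#'
#' @param path_or_text a file path, a single string, or a character vector of
#'   lines containing Stockholm 1.0 text.
#' @return a list of [structured_alignment()] objects (possibly length one).
#' @examples
#' txt <- c("# STOCKHOLM 1.0",
#'          "seq1 GGAAACC",
#'          "seq2 GCAAAGC",
#'          "#=GC SS_cons <<...>>",
#'          "//")
#' aln <- read_stockholm(txt)[[1]]
#' aln$consensus_structure
#' @export
read_stockholm <- function(path_or_text) {
  lines <- .as_lines(path_or_text)
  alignments <- list()
  block <- .new_block()
  saw_any <- FALSE
  for (k in seq_along(lines)) {
    line <- lines[[k]]
    if (grepl("^\\s*$", line)) next
    if (grepl("^\\s*//\\s*$", line)) {
      if (block$has_content) alignments[[length(alignments) + 1L]] <- .finish_block(block)
      block <- .new_block()
      saw_any <- TRUE
      next
    }
    if (grepl("^# STOCKHOLM", line)) next
    if (startsWith(line, "#=GF ")) {
      m <- regmatches(line, regexec("^#=GF\\s+(\\S+)\\s+(.*)$", line))[[1]]
      if (length(m) == 3L) {
        v <- stats::setNames(m[3], m[2])
        block$gf <- c(block$gf, v); block$has_content <- TRUE
      }
      next
    }
    if (startsWith(line, "#=GC ")) {
      m <- regmatches(line, regexec("^#=GC\\s+(\\S+)\\s+(\\S+)\\s*$", line))[[1]]
      if (length(m) != 3L) stop("malformed #=GC line: ", line)
      block$gc[[m[2]]] <- paste0(.get0(block$gc, m[2]), m[3])
      block$has_content <- TRUE
      next
    }
    if (startsWith(line, "#=GS ")) {
      m <- regmatches(line, regexec("^#=GS\\s+(\\S+)\\s+(\\S+)\\s+(.*)$", line))[[1]]
      if (length(m) == 4L) {
        block$gs[[m[2]]] <- c(block$gs[[m[2]]], stats::setNames(m[4], m[3]))
        block$has_content <- TRUE
      }
      next
    }
    if (startsWith(line, "#=GR ")) {
      m <- regmatches(line, regexec("^#=GR\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)\\s*$", line))[[1]]
      if (length(m) != 4L) stop("malformed #=GR line: ", line)
      grs <- block$gr[[m[2]]]
      if (is.null(grs)) grs <- character()
      grs[[m[3]]] <- paste0(.get0(grs, m[3]), m[4])
      block$gr[[m[2]]] <- grs
      block$has_content <- TRUE
      next
    }
    if (startsWith(line, "#")) next  # tolerate unknown comment dialects
    m <- regmatches(line, regexec("^(\\S+)\\s+(\\S+)\\s*$", line))[[1]]
    if (length(m) != 3L) stop("unparseable alignment line: ", line)
    id <- m[2]
    if (!id %in% block$order) block$order <- c(block$order, id)
    block$seqs[[id]] <- paste0(.get0(block$seqs, id), m[3])
    block$has_content <- TRUE
  }
  if (block$has_content) alignments[[length(alignments) + 1L]] <- .finish_block(block)
  if (!length(alignments) && !saw_any)
    stop("no Stockholm alignment blocks found")
  alignments
}

.new_block <- function() {
  list(seqs = character(), order = character(), gf = character(),
       gs = list(), gr = list(), gc = character(), has_content = FALSE)
}

.get0 <- function(x, key) if (key %in% names(x)) x[[key]] else ""

.finish_block <- function(block) {
  if (!length(block$order)) stop("alignment block contains no sequences")
  seqs <- unlist(block$seqs[block$order])
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    # reference width: the most common one, ties resolved by first sequence
    tab <- table(widths)
    ref <- as.integer(names(tab)[tab == max(tab)])
    ref <- if (length(ref) > 1L) widths[[1]] else ref
    bad <- names(seqs)[widths != ref][1]
    stop("ragged alignment: sequence '", bad, "' has length ",
         nchar(seqs[[bad]]), " but others have ", ref)
  }
  if (!"SS_cons" %in% names(block$gc))
    stop("no consensus structure: alignment lacks a #=GC SS_cons line")
  ss <- block$gc[["SS_cons"]]
  gc_other <- block$gc[setdiff(names(block$gc), "SS_cons")]
  structured_alignment(seqs, ss, gf = block$gf, gs = block$gs,
                       gr = block$gr, gc = gc_other)
}

#' Write Stockholm 1.0 text
#'
#' Serializes one alignment or a list of alignments to Stockholm 1.0,
#' emitting the consensus structure as `#=GC SS_cons` and all preserved
#' annotations. Sequences are written unwrapped and verbatim (no T/U or case
#' normalization), so `read_stockholm(write_stockholm(x))` reproduces `x`.
#'
#' @param alignments a `structured_alignment` or list thereof (an empty list
#'   yields a header-only document).
#' @param path optional file path; when `NULL` the text is returned.
#' @return invisibly the path, or the Stockholm text as a single string.
#' @export
write_stockholm <- function(alignments, path = NULL) {
  if (inherits(alignments, "structured_alignment")) alignments <- list(alignments)
  out <- character()
  if (!length(alignments)) out <- "# STOCKHOLM 1.0"
  for (aln in alignments) {
    stopifnot(inherits(aln, "structured_alignment"))
    out <- c(out, "# STOCKHOLM 1.0")
    for (i in seq_along(aln$gf))
      out <- c(out, sprintf("#=GF %s %s", names(aln$gf)[i], aln$gf[[i]]))
    for (id in names(aln$gs))
      for (i in seq_along(aln$gs[[id]]))
        out <- c(out, sprintf("#=GS %s %s %s", id,
                              names(aln$gs[[id]])[i], aln$gs[[id]][[i]]))
    labels <- names(aln$sequences)
    gc_labels <- paste("#=GC", c(names(aln$gc), "SS_cons"))
    width <- max(nchar(c(labels, gc_labels,
                         unlist(lapply(names(aln$gr), function(id)
                           paste("#=GR", id, names(aln$gr[[id]])))))))
    pad <- function(s) formatC(s, width = -width)
    for (id in labels) {
      out <- c(out, paste(pad(id), aln$sequences[[id]]))
      for (tag in names(aln$gr[[id]]))
        out <- c(out, paste(pad(paste("#=GR", id, tag)), aln$gr[[id]][[tag]]))
    }
    for (tag in names(aln$gc))
      out <- c(out, paste(pad(paste("#=GC", tag)), aln$gc[[tag]]))
    out <- c(out, paste(pad("#=GC SS_cons"), aln$consensus_structure), "//")
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(path)
}

#' Export ungapped sequences as FASTA
#'
#' Convenience export of the alignment's sequences with all gap characters
#' removed, e.g. for homology searches.
#'
#' @param alignment a `structured_alignment`
#' @param path optional output file; when `NULL` the text is returned.
#' @return invisibly the path, or FASTA text.
#' @export
write_fasta_ungapped <- function(alignment, path = NULL) {
  seqs <- gsub("[-.]", "", alignment$sequences)
  text <- paste0(paste0(">", names(seqs), "\n", seqs, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(path)
}
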