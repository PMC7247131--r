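#' Extract base pairs from a consensus structure string
#'
#' Matches bracket characters of a WUSS / dot-bracket consensus structure into
#' a pair table. Four nested bracket classes (`<>`, `()`, `[]`, `{}`) and the
#' 26 pseudoknot letter classes (`A`..`Z` opening, `a`..`z` closing) are
#' recognised; within a class, brackets match last-in-first-out. Any other
#' character (`.`, `:`, `,`, `_`, `-`, `~` ...) marks an unpaired column.
#' Pairs of different classes may cross (pseudoknots); pairs of one nested
#' class cannot.
#'
#' @param structure single structure string.
#' @return an object of class `pair_table`: a list with `pairs`, an integer
#'   matrix with columns `i`, `j` (1-based column indices, `i < j`, ordered by
#'   `i`), and `unpaired`, the sorted integer vector of unpaired columns.
#' @examples
#' extract_pairs("<<...>>")$pairs
#' @export
extract_pairs <- function(structure) {
  stopifnot(is.character(structure), length(structure) == 1L)
  chars <- strsplit(structure, "")[[1]]
  n <- length(chars)
  openers <- c("<", "(", "[", "{", LETTERS)
  closers <- c(">", ")", "]", "}", letters)
  stacks <- rep(list(integer()), length(openers))
  names(stacks) <- openers
  pairs_i <- integer(); pairs_j <- integer()
  unpaired <- logical(n)
  for (pos in seq_len(n)) {
    ch <- chars[[pos]]
    oi <- match(ch, openers)
    if (!is.na(oi)) {
      stacks[[oi]] <- c(stacks[[oi]], pos)
      next
    }
    ci <- match(ch, closers)
    if (!is.na(ci)) {
      st <- stacks[[ci]]
      if (!length(st))
        stop("unbalanced structure: unmatched closing '", ch,
             "' at column ", pos)
      pairs_i <- c(pairs_i, st[length(st)])
      pairs_j <- c(pairs_j, pos)
      stacks[[ci]] <- st[-length(st)]
      next
    }
    unpaired[[pos]] <- TRUE
  }
  for (oi in seq_along(stacks))
    if (length(stacks[[oi]]))
      stop("unbalanced structure: unmatched opening '", openers[[oi]],
           "' at column ", stacks[[oi]][length(stacks[[oi]])])
  ord <- order(pairs_i)
  structure(list(pairs = cbind(i = pairs_i[ord], j = pairs_j[ord]),
                 unpaired = which(unpaired)),
            class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat("Pair table: ", nrow(x$pairs), " pairs, ", length(x$unpaired),
      " unpaired columns\n", sep = "")
  invisible(x)
}
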