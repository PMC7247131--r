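# Shared fixtures and independent oracles, all built in code.

# quick alignment: unnamed sequences get seq1, seq2, ...
mk_aln <- function(seqs, ss) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  structured_alignment(seqs, ss)
}

# two-column alignment whose rows are the given pair types ("GC", "A-", ...)
mk_pair_aln <- function(types) {
  mk_aln(types, "<>")
}

# --- independent bracket-matching oracle -------------------------------------
# Reduction oracle: repeatedly erase an innermost opener/closer of the same
# class with only non-class characters between them. Quadratic and entirely
# unlike the package's single-pass stack matcher.
oracle_pairs <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  openers <- c("<", "(", "[", "{", LETTERS)
  closers <- c(">", ")", "]", "}", letters)
  pairs <- NULL
  repeat {
    hit <- FALSE
    for (cls in seq_along(openers)) {
      op <- which(chars == openers[cls])
      cl <- which(chars == closers[cls])
      if (!length(op) && !length(cl)) next
      found <- FALSE
      for (j in cl) {
        prior <- op[op < j]
        if (length(prior)) {
          i <- max(prior)
          pairs <- rbind(pairs, c(i, j))
          chars[c(i, j)] <- "*"  # consumed
          found <- TRUE
          break
        }
      }
      if (found) { hit <- TRUE; break }
      if (length(op) || length(cl)) return(NULL)  # unbalanced
    }
    if (!hit) break
  }
  if (any(chars %in% c(openers, closers))) return(NULL)
  if (is.null(pairs)) return(matrix(integer(), ncol = 2))
  pairs[order(pairs[, 1]), , drop = FALSE]
}

# random balanced structure string with nested brackets and optional
# pseudoknot letters
random_structure <- function(n, p_open = 0.3, pknot = TRUE) {
  classes <- if (pknot) list(c("<", ">"), c("(", ")"), c("A", "a")) else
    list(c("<", ">"))
  chars <- character(0)
  stacks <- rep(list(0L), length(classes))
  while (length(chars) < n) {
    cls <- sample(length(classes), 1L)
    r <- runif(1)
    if (r < p_open) {
      chars <- c(chars, classes[[cls]][1]); stacks[[cls]] <- stacks[[cls]] + 1L
    } else if (r < 2 * p_open && stacks[[cls]] > 0L) {
      chars <- c(chars, classes[[cls]][2]); stacks[[cls]] <- stacks[[cls]] - 1L
    } else {
      chars <- c(chars, sample(c(".", ":", "-", "_", ","), 1L))
    }
  }
  for (cls in seq_along(classes))
    chars <- c(chars, rep(classes[[cls]][2], stacks[[cls]]))
  paste(chars, collapse = "")
}

# random alignment for round-trip property tests
random_alignment <- function(n_seq = 5L, n_col = 30L) {
  ss <- random_structure(n_col, pknot = FALSE)
  ss <- substr(ss, 1, n_col)
  # may have truncated closers; make all-unpaired fallback valid
  if (inherits(try(extract_pairs(ss), silent = TRUE), "try-error"))
    ss <- paste(rep(".", n_col), collapse = "")
  seqs <- vapply(seq_len(n_seq), function(k)
    paste(sample(c("A", "C", "G", "U", "T", "-", "."), n_col, replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- paste0("sp", seq_len(n_seq), "/", seq_len(n_seq), "-",
                        n_seq + n_col)
  structured_alignment(seqs, ss,
                       gf = c(ID = paste0("rand", n_seq), AU = "tester"),
                       gc = c(RF = paste(rep("x", n_col), collapse = "")))
}

# independent alignment with i.i.d. uniform columns (no covariation signal)
independent_alignment <- function(n_seq, n_pairs) {
  n_col <- 2L * n_pairs
  m <- matrix(sample(c("A", "C", "G", "U"), n_seq * n_col, replace = TRUE),
              nrow = n_seq)
  ss <- paste(c(rep("<", n_pairs), rep(">", n_pairs)), collapse = "")
  mk_aln(apply(m, 1L, paste, collapse = ""), ss)
}

# mirror a set of intervals on a contig of length L (strand flip)
mirror_coords <- function(df, L) {
  out <- df
  out$start <- L + 1L - df$end
  out$end <- L + 1L - df$start
  out$strand <- ifelse(df$strand == "+", "-", "+")
  out
}
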