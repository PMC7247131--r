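# Covariation evaluation of annotated base-pair columns.
#
# Two complementary signals are computed per pair of alignment columns:
#  * a permissive drawing-style rule: at least two canonical (Watson-Crick or
#    G-U) pair types that differ at BOTH positions, with fewer than 10% of
#    sequences non-canonical at those positions;
#  * a permutation G-test of association between the two columns, a
#    phylogeny-naive stand-in for a statistically well-founded covariation
#    test. It does not correct for shared ancestry and is therefore
#    anti-conservative on strongly structured phylogenies; motif-level claims
#    based on it should be treated as screening evidence only.

.GAP_CHARS <- c("-", ".", "_", "~")
.CANONICAL <- c("AU", "UA", "GC", "CG", "GU", "UG")

# alignment -> character matrix (sequences x columns), uppercased, T -> U
.alignment_chars <- function(alignment) {
  m <- do.call(rbind, strsplit(chartr("Tt", "Uu",
                                      toupper(alignment$sequences)), ""))
  rownames(m) <- names(alignment$sequences)
  m
}

#' Classify one annotated base-pair column
#'
#' Tallies every sequence of the alignment at the two columns of an annotated
#' base pair as canonical (one of `AU, UA, GC, CG, GU, UG`), non-canonical,
#' or gapped (a gap character in either column). The number of covarying
#' canonical variants is the number of observed canonical pair types for
#' which some other observed canonical type differs at *both* positions
#' (so `GC` vs `AU` covary, `GC` vs `GU` do not).
#'
#' @param alignment a [structured_alignment()].
#' @param pair integer vector `c(i, j)` of 1-based column indices, `i < j`.
#' @return an object of class `pair_column_stats` with fields `pair`,
#'   `n_sequences`, `canonical_counts` (named, observed types only),
#'   `n_noncanonical`, `n_gapped`, `noncanonical_fraction`,
#'   `covarying_variant_count`.
#' @export
classify_pair <- function(alignment, pair) {
  i <- pair[[1]]; j <- pair[[2]]
  nc <- alignment_ncol(alignment)
  if (i < 1L || j < 1L || i >= j || j > nc)
    stop("invalid pair indices (", i, ",", j, ") for alignment with ",
         nc, " columns")
  m <- .alignment_chars(alignment)
  a <- m[, i]; b <- m[, j]
  gapped <- a %in% .GAP_CHARS | b %in% .GAP_CHARS
  type <- paste0(a, b)
  canonical <- !gapped & type %in% .CANONICAL
  counts <- table(type[canonical])
  counts <- stats::setNames(as.integer(counts), names(counts))
  n <- length(a)
  structure(list(
    pair = c(i = i, j = j),
    n_sequences = n,
    canonical_counts = counts,
    n_noncanonical = sum(!gapped & !canonical),
    n_gapped = sum(gapped),
    noncanonical_fraction = sum(!gapped & !canonical) / n,
    covarying_variant_count = .covarying_variants(names(counts))
  ), class = "pair_column_stats")
}

# number of observed canonical types that differ from some other observed
# canonical type at both positions
.covarying_variants <- function(types) {
  if (length(types) < 2L) return(0L)
  a <- substr(types, 1, 1); b <- substr(types, 2, 2)
  both_differ <- outer(a, a, "!=") & outer(b, b, "!=")
  sum(apply(both_differ, 1L, any))
}

#' @export
print.pair_column_stats <- function(x, ...) {
  cat("Pair (", x$pair[["i"]], ",", x$pair[["j"]], "): ",
      paste(names(x$canonical_counts), x$canonical_counts,
            sep = ":", collapse = " "),
      " | non-canonical ", x$n_noncanonical,
      ", gapped ", x$n_gapped, " of ", x$n_sequences,
      "; covarying variants ", x$covarying_variant_count, "\n", sep = "")
  invisible(x)
}

#' Permissive two-variant covariation rule
#'
#' A pair column is flagged as covarying when at least two observed canonical
#' pair types differ at both positions and fewer than `max_noncanonical`
#' (strictly) of the sequences are non-canonical at those positions. Gapped
#' sequences count in the denominator but are neither canonical nor
#' non-canonical.
#'
#' @param stats a `pair_column_stats` from [classify_pair()].
#' @param min_variants minimum number of mutually covarying canonical types.
#' @param max_noncanonical strict upper bound on the non-canonical fraction.
#' @return logical scalar.
#' @export
r2r_rule <- function(stats, min_variants = 2L, max_noncanonical = 0.10) {
  stopifnot(inherits(stats, "pair_column_stats"))
  stats$covarying_variant_count >= min_variants &&
    stats$noncanonical_fraction < max_noncanonical
}

# G statistic for two integer-coded vectors (no gaps); 0 if either constant
.g_stat <- function(x, y) {
  ux <- unique(x); uy <- unique(y)
  nx <- length(ux); ny <- length(uy)
  if (nx < 2L || ny < 2L) return(0)
  xi <- match(x, ux); yi <- match(y, uy)
  tab <- matrix(tabulate((yi - 1L) * nx + xi, nx * ny), nx, ny)
  n <- length(x)
  e <- outer(rowSums(tab), colSums(tab)) / n
  pos <- tab > 0L
  2 * sum(tab[pos] * log(tab[pos] / e[pos]))
}

# residues at the two columns with pairwise-gapped sequences removed
.pair_columns <- function(alignment, pair) {
  m <- .alignment_chars(alignment)
  a <- m[, pair[[1]]]; b <- m[, pair[[2]]]
  keep <- !(a %in% .GAP_CHARS | b %in% .GAP_CHARS)
  if (sum(keep) < 2L)
    stop("association score undefined: fewer than 2 sequences ungapped at ",
         "columns (", pair[[1]], ",", pair[[2]], ")")
  list(a = a[keep], b = b[keep])
}

#' G statistic of association between two alignment columns
#'
#' Likelihood-ratio (G) statistic `2 * sum(o * log(o / e))` over the joint
#' residue table of the two columns, with expectations from the marginal
#' products. Sequences gapped at either column are excluded pairwise; the
#' score is 0 when either column is constant. Used as the test statistic of
#' [permutation_test()].
#'
#' @inheritParams classify_pair
#' @return non-negative numeric scalar.
#' @export
pair_association_score <- function(alignment, pair) {
  cols <- .pair_columns(alignment, pair)
  .g_stat(cols$a, cols$b)
}

#' Permutation test of column association
#'
#' Null distribution obtained by independently permuting the residues of each
#' of the two columns across sequences, which preserves column composition
#' while destroying association. The p-value uses the add-one rule
#' `p = (1 + #(null >= observed)) / (1 + n_permutations)`, so constant
#' columns give exactly 1. The null ignores phylogeny: related sequences are
#' treated as independent draws, which overstates significance when the
#' alignment is a few deep clades.
#'
#' @inheritParams classify_pair
#' @param n_permutations number of null draws (>= 1).
#' @param seed optional integer; when supplied the RNG state is set locally
#'   and restored, making the p-value reproducible.
#' @return list with `score` (observed G) and `p_value`.
#' @export
permutation_test <- function(alignment, pair, n_permutations = 1000L,
                             seed = NULL) {
  stopifnot(n_permutations >= 1L)
  cols <- .pair_columns(alignment, pair)
  # null draws start from the sorted residue multisets, so the p-value is
  # invariant under row permutation of the alignment (given the same seed)
  a0 <- sort(cols$a); b0 <- sort(cols$b)
  with_preserved_seed(seed, {
    obs <- .g_stat(cols$a, cols$b)
    exceed <- 0L
    for (b in seq_len(n_permutations)) {
      g <- .g_stat(sample(a0), sample(b0))
      if (g >= obs - 1e-9) exceed <- exceed + 1L
    }
    list(score = obs, p_value = (1 + exceed) / (1 + n_permutations))
  })
}

#' Covariation summary of one motif
#'
#' Computes per-pair classification, the permissive covariation rule, the
#' permutation G-test, and Benjamini-Hochberg adjusted p-values across the
#' motif's annotated pairs; assigns the motif rating `"Y"` (likely RNA
#' candidate) when at least `min_significant` pairs are significant at level
#' `alpha` after adjustment and at least `min_covarying` pairs satisfy the
#' permissive rule, else `"?"` (borderline).
#'
#' @param alignment a [structured_alignment()].
#' @param pair_table optional [extract_pairs()] result; defaults to the
#'   alignment's own consensus structure.
#' @param alpha significance level applied to BH-adjusted p-values.
#' @param n_permutations permutations per pair.
#' @param seed integer seed governing all permutations of this summary.
#' @param min_significant,min_covarying rating thresholds.
#' @return an object of class `motif_covariation`: list with `pairs` (a
#'   data frame: i, j, canonical histogram string, counts, fractions,
#'   `r2r_covarying`, `score`, `p_value`, `p_adj`) and `summary` (n_pairs,
#'   n_r2r_covarying, n_significant, rating).
#' @export
summarize_motif <- function(alignment, pair_table = NULL, alpha = 0.05,
                            n_permutations = 1000L, seed = 1L,
                            min_significant = 1L, min_covarying = 2L) {
  if (is.null(pair_table)) pair_table <- extract_pairs(alignment$consensus_structure)
  np <- nrow(pair_table$pairs)
  if (np == 0L) {
    return(structure(list(
      pairs = data.frame(i = integer(), j = integer(), canonical = character(),
                         n_noncanonical = integer(), n_gapped = integer(),
                         noncanonical_fraction = numeric(),
                         covarying_variant_count = integer(),
                         r2r_covarying = logical(), score = numeric(),
                         p_value = numeric(), p_adj = numeric()),
      summary = list(n_pairs = 0L, n_r2r_covarying = 0L,
                     n_significant = 0L, rating = "?")),
      class = "motif_covariation"))
  }
  rows <- with_preserved_seed(seed, lapply(seq_len(np), function(k) {
    pr <- pair_table$pairs[k, ]
    st <- classify_pair(alignment, pr)
    pt <- permutation_test(alignment, pr, n_permutations = n_permutations)
    data.frame(
      i = pr[["i"]], j = pr[["j"]],
      canonical = paste(names(st$canonical_counts), st$canonical_counts,
                        sep = ":", collapse = ","),
      n_noncanonical = st$n_noncanonical, n_gapped = st$n_gapped,
      noncanonical_fraction = st$noncanonical_fraction,
      covarying_variant_count = st$covarying_variant_count,
      r2r_covarying = r2r_rule(st),
      score = pt$score, p_value = pt$p_value,
      stringsAsFactors = FALSE)
  }))
  pairs <- do.call(rbind, rows)
  pairs$p_adj <- stats::p.adjust(pairs$p_value, method = "BH")
  n_sig <- sum(pairs$p_adj <= alpha)
  n_cov <- sum(pairs$r2r_covarying)
  rating <- if (n_sig >= min_significant && n_cov >= min_covarying) "Y" else "?"
  structure(list(pairs = pairs,
                 summary = list(n_pairs = np, n_r2r_covarying = n_cov,
                                n_significant = n_sig, rating = rating)),
            class = "motif_covariation")
}

#' @export
print.motif_covariation <- function(x, ...) {
  s <- x$summary
  cat("Motif covariation: ", s$n_pairs, " pairs, ", s$n_r2r_covarying,
      " covarying (permissive rule), ", s$n_significant,
      " significant (BH); rating ", s$rating, "\n", sep = "")
  invisible(x)
}

#' Per-pair covariation report
#'
#' Returns [summarize_motif()]'s per-pair table, optionally written as TSV
#' with the motif-level summary in `#`-prefixed header lines.
#'
#' @inheritParams summarize_motif
#' @param path optional output TSV path.
#' @param ... passed to [summarize_motif()].
#' @return the per-pair data frame, with the summary list as attribute
#'   `"summary"`.
#' @export
covariation_report <- function(alignment, path = NULL, ...) {
  cv <- summarize_motif(alignment, ...)
  out <- cv$pairs
  attr(out, "summary") <- cv$summary
  if (!is.null(path)) {
    s <- cv$summary
    hdr <- sprintf("# n_pairs=%d n_r2r_covarying=%d n_significant=%d rating=%s",
                   s$n_pairs, s$n_r2r_covarying, s$n_significant, s$rating)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
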