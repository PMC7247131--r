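# End-to-end screening run: covariation -> operon -> ligand -> TSS ->
# novelty, consolidated into one report row per motif.

#' Run the full candidate r-leader screen
#'
#' Orchestrates the pipeline stages over a set of motifs. Stages are
#' included or skipped explicitly through the configuration, so "no operon
#' data" is distinguishable from "no operon found"; skipped stages are
#' marked `"(skipped)"` / `NA` in the report, never silently empty. A motif
#' is labeled a candidate r-leader when its covariation rating is `"Y"` (or
#' `"?"` when `allow_borderline`), its consensus operon contains at least
#' one r-protein gene, and it passes the novelty filter.
#'
#' @param config a named list or the path of a YAML file with (all file
#'   paths or in-memory objects):
#'   \describe{
#'     \item{alignments}{Stockholm path or list of `structured_alignment`s;
#'       motif ids from the `#=GF ID` tag, the list names, or generated.}
#'     \item{genome}{list with `annotations` (GFF3 path or `gene_records`),
#'       `occurrences` (BED path or `motif_occurrences`), `contig_lengths`
#'       (TSV path / named vector; required with a BED path). Omit to skip
#'       the operon, ligand and TSS stages (covariation-only mode).}
#'     \item{tss}{TSS BED/TSV path or data frame; omit to skip.}
#'     \item{known_rnas}{BED path or data frame; omit to skip novelty.}
#'     \item{operons}{named list of gene-symbol vectors; replaces the operon
#'       stage when gene lists are already curated (covariation optional).}
#'     \item{covariation}{list: `alpha`, `n_permutations`, `seed`,
#'       `min_significant`, `min_covarying`; set `skip = TRUE` to skip.}
#'     \item{ligand}{list: `map`, `known`, `dimers`, `overrides` (paths or
#'       tables; packaged defaults).}
#'     \item{operon}{list: `max_gap`, `min_downstream`, `min_support`.}
#'     \item{novelty}{list: `min_overlap_frac`, `strict`.}
#'     \item{allow_borderline}{logical, default `TRUE`: `"?"`-rated motifs
#'       may still be candidates (flagged in the report).}
#'     \item{lineages}{optional named character vector motif id -> lineage.}
#'     \item{out_dir}{optional; when set, writes `report.tsv`,
#'       `report.json` and per-motif covariation TSVs.}
#'   }
#' @return object of class `screen_report`: list with `report` (one data
#'   frame row per motif) and `details` (per-motif stage results).
#' @export
run_screen <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- config
  covs <- .cfg(cfg, "covariation", list())
  opc <- .cfg(cfg, "operon", list())
  novc <- .cfg(cfg, "novelty", list())
  ligc <- .cfg(cfg, "ligand", list())
  allow_borderline <- isTRUE(.cfg(cfg, "allow_borderline", TRUE))

  # ---- inputs -------------------------------------------------------------
  alignments <- NULL
  if (!is.null(cfg$alignments)) {
    alignments <- cfg$alignments
    if (is.character(alignments)) alignments <- read_stockholm(alignments)
    if (inherits(alignments, "structured_alignment"))
      alignments <- list(alignments)
    ids <- vapply(seq_along(alignments), function(k) {
      aln <- alignments[[k]]
      if ("ID" %in% names(aln$gf)) aln$gf[["ID"]]
      else if (!is.null(names(alignments)) && names(alignments)[k] != "")
        names(alignments)[k]
      else sprintf("motif%02d", k)
    }, character(1))
    names(alignments) <- ids
  }
  map <- .as_table(ligc$map, load_gene_protein_map)
  known <- .as_table(ligc$known, load_known_ligands)
  dimers <- .as_table(ligc$dimers, load_dimer_ligands)

  genome <- cfg$genome
  annotations <- occurrences <- NULL
  if (!is.null(genome)) {
    annotations <- genome$annotations
    if (is.character(annotations))
      annotations <- read_gene_annotations(annotations, map = map)
    occurrences <- genome$occurrences
    if (is.character(occurrences))
      occurrences <- read_motif_occurrences(occurrences,
                                            genome$contig_lengths)
  }
  tss <- cfg$tss
  if (is.character(tss)) tss <- read_tss(tss)
  known_rnas <- cfg$known_rnas
  if (is.character(known_rnas)) known_rnas <- read_known_rnas(known_rnas)

  motif_ids <- unique(c(names(alignments),
                        if (!is.null(occurrences)) occurrences$motif_id,
                        names(.cfg(cfg, "operons", NULL))))
  if (!length(motif_ids)) stop("no motifs found in configuration")

  details <- list()
  # ---- covariation --------------------------------------------------------
  cov_skip <- isTRUE(covs$skip) || is.null(alignments)
  cov_res <- list()
  if (!cov_skip) {
    seed0 <- as.integer(.cfg(covs, "seed", 1L))
    for (k in seq_along(alignments)) {
      id <- names(alignments)[k]
      cov_res[[id]] <- summarize_motif(
        alignments[[k]],
        alpha = .cfg(covs, "alpha", 0.05),
        n_permutations = as.integer(.cfg(covs, "n_permutations", 1000L)),
        seed = seed0 + k - 1L,
        min_significant = .cfg(covs, "min_significant", 1L),
        min_covarying = .cfg(covs, "min_covarying", 2L))
    }
  }
  # ---- operons ------------------------------------------------------------
  operons <- .cfg(cfg, "operons", NULL)   # curated gene lists, if given
  operon_stage <- !is.null(operons) ||
    (!is.null(annotations) && !is.null(occurrences))
  operon_res <- list()
  if (operon_stage && is.null(operons)) {
    for (id in unique(occurrences$motif_id)) {
      occ <- occurrences[occurrences$motif_id == id, , drop = FALSE]
      chains <- list(); first_genes <- list()
      for (r in seq_len(nrow(occ))) {
        ch <- downstream_chain(occ[r, ], annotations,
                               max_gap = .cfg(opc, "max_gap", 500L),
                               min_downstream = .cfg(opc, "min_downstream",
                                                     8000L))
        if (ch$usable) {
          chains[[length(chains) + 1L]] <- ch$genes$symbol
          first_genes[[length(first_genes) + 1L]] <-
            if (nrow(ch$genes)) ch$genes[1, ] else NULL
        }
      }
      operon_res[[id]] <- consensus_operon(
        chains, min_support = .cfg(opc, "min_support", 0.75), motif_id = id)
      details[[id]]$first_genes <- first_genes
    }
    operons <- operon_res
  } else if (!is.null(operons)) {
    operon_res <- lapply(names(operons), function(id) {
      op <- operons[[id]]
      if (inherits(op, "operon_prediction")) op
      else structure(list(motif_id = id, genes = as.character(op),
                          support = stats::setNames(
                            rep(1, length(op)), as.character(op)),
                          extended = character(), n_usable = NA_integer_,
                          flag = "curated gene list"),
                     class = "operon_prediction")
    })
    names(operon_res) <- names(operons)
    operons <- operon_res
  }
  # ---- ligand -------------------------------------------------------------
  ligand_res <- NULL
  if (operon_stage && length(operons)) {
    nonempty <- Filter(function(op) length(op$genes) > 0L, operons)
    if (length(nonempty))
      ligand_res <- two_pass_inference(
        nonempty, map = map, known = known, dimers = dimers,
        ligand_overrides = .cfg(ligc, "overrides", NULL))
  }
  # ---- TSS ----------------------------------------------------------------
  tss_res <- list()
  tss_stage <- !is.null(tss) && !is.null(occurrences) && !is.null(annotations)
  if (tss_stage) {
    for (id in unique(occurrences$motif_id)) {
      occ <- occurrences[occurrences$motif_id == id, , drop = FALSE]
      verdicts <- character()
      for (r in seq_len(nrow(occ))) {
        ch <- downstream_chain(occ[r, ], annotations,
                               max_gap = .cfg(opc, "max_gap", 500L),
                               min_downstream = .cfg(opc, "min_downstream",
                                                     8000L))
        if (!ch$usable || !nrow(ch$genes)) next
        verdicts <- c(verdicts,
                      tss_consistency(occ[r, ], ch$genes[1, ], tss,
                                      annotations = annotations))
      }
      tss_res[[id]] <- table(factor(verdicts, levels = c(
        "consistent", "inconsistent", "no-data")))
    }
  }
  # ---- novelty ------------------------------------------------------------
  novelty_res <- NULL
  if (!is.null(known_rnas) && !is.null(occurrences))
    novelty_res <- novelty_filter(
      occurrences, known_rnas,
      min_overlap_frac = .cfg(novc, "min_overlap_frac", 0.5),
      strict = isTRUE(novc$strict))

  # ---- consolidate --------------------------------------------------------
  lineages <- .cfg(cfg, "lineages", NULL)
  rows <- lapply(sort(motif_ids), function(id) {
    cv <- cov_res[[id]]
    op <- operon_res[[id]]
    lg <- if (!is.null(ligand_res) && id %in% ligand_res$motif_id)
      ligand_res[ligand_res$motif_id == id, ] else NULL
    tt <- tss_res[[id]]
    keep <- if (is.null(novelty_res)) NA else
      novelty_res$verdicts$keep[novelty_res$verdicts$motif_id == id]
    if (!length(keep)) keep <- NA
    rating <- if (is.null(cv)) "(skipped)" else cv$summary$rating
    has_rp <- if (is.null(op)) NA else
      any(!is.na(gene_records_protein(op$genes, map)))
    candidate <- !is.na(has_rp) && has_rp &&
      (rating == "Y" || (allow_borderline && rating == "?")) &&
      (is.na(keep) || keep)
    data.frame(
      motif_id = id,
      lineage = if (!is.null(lineages) && id %in% names(lineages))
        lineages[[id]] else NA_character_,
      n_pairs = if (is.null(cv)) NA_integer_ else cv$summary$n_pairs,
      n_r2r_covarying = if (is.null(cv)) NA_integer_ else
        cv$summary$n_r2r_covarying,
      n_significant = if (is.null(cv)) NA_integer_ else
        cv$summary$n_significant,
      rating = rating,
      operon = if (is.null(op)) "(skipped)" else
        if (length(op$genes)) paste(op$genes, collapse = ",") else "(none)",
      operon_support = if (is.null(op) || !length(op$genes)) NA_character_
        else paste(sprintf("%s:%.2f", op$genes,
                           op$support[op$genes]), collapse = ","),
      often_extended = if (is.null(op) || !length(op$extended))
        NA_character_ else paste(op$extended, collapse = ","),
      ligand = if (is.null(lg)) "(skipped)" else lg$ligand,
      basis = if (is.null(lg)) "(skipped)" else
        paste0(lg$basis, if (isTRUE(lg$at_sign)) " @"),
      tss_consistent = if (is.null(tt)) NA_integer_ else
        unname(tt[["consistent"]]),
      tss_inconsistent = if (is.null(tt)) NA_integer_ else
        unname(tt[["inconsistent"]]),
      tss_no_data = if (is.null(tt)) NA_integer_ else unname(tt[["no-data"]]),
      novelty_keep = keep,
      candidate = candidate,
      stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  res <- structure(list(report = report,
                        details = list(covariation = cov_res,
                                       operons = operon_res,
                                       ligand = ligand_res,
                                       tss = tss_res,
                                       novelty = novelty_res)),
                   class = "screen_report")
  out_dir <- .cfg(cfg, "out_dir", NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(format(report, digits = 4, scientific = FALSE),
                       file.path(out_dir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = 6,
                         na = "null")
    for (id in names(cov_res)) {
      pairs <- cov_res[[id]]$pairs
      utils::write.table(pairs, file.path(out_dir,
                                          paste0(id, "_covariation.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  res
}

# protein names of the r-protein genes among `symbols` (NA for others)
gene_records_protein <- function(symbols, map) {
  idx <- match(symbols, map$symbol)
  ifelse(!is.na(idx) & map$product_class[idx] == "r-protein",
         map$protein[idx], NA_character_)
}

.cfg <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

.as_table <- function(x, loader) {
  if (is.null(x)) loader()
  else if (is.character(x) && length(x) == 1L) loader(x)
  else x
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Screen report: ", nrow(x$report), " motifs, ",
      sum(x$report$candidate), " candidate r-leaders\n", sep = "")
  print(x$report[, c("motif_id", "rating", "operon", "ligand", "basis",
                     "candidate")], row.names = FALSE)
  invisible(x)
}
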