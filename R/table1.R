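# Packaged transcription of the published summary table of 20 novel
# r-leader motifs, and its replay through the ligand-inference engine.

#' Load the packaged r-leader summary table
#'
#' Transcription of the published table of 20 novel r-leader motifs: most
#' likely ligand, ligand basis (`Only`/`Prior`/`Closest`, with `at_sign` for
#' the one basis established by the same screen), regulated genes
#' (comma-separated, transcription order), often-extended genes, lineage,
#' domain, motif rating (`Y` likely / `?` borderline) and whether the motif
#' plausibly resembles the ligand's rRNA binding site. One motif carries a
#' curated `ligand_override` documenting an ambiguity in the printed gene
#' symbol (see the packaged TSV's comments).
#'
#' @param path fixture TSV (default: packaged copy).
#' @return data frame with one row per motif.
#' @export
load_table1 <- function(path = .extdata("table1_motifs.tsv")) {
  t1 <- .read_tsv(path)
  needed <- c("motif_id", "ligand", "basis", "at_sign", "genes",
              "extended_genes", "can_extend", "lineage", "domain", "rating",
              "rrna_similar", "ligand_override")
  stopifnot(all(needed %in% names(t1)))
  t1$at_sign <- as.logical(t1$at_sign)
  t1$can_extend <- as.logical(t1$can_extend)
  t1$rrna_similar <- as.logical(t1$rrna_similar)
  t1
}

#' Replay ligand inference on the packaged summary table
#'
#' Rebuilds each motif's regulated-gene list from the packaged table and runs
#' [two_pass_inference()] with the packaged literature known-ligand table,
#' gene->protein map and dimer declarations; the result can be compared
#' motif-by-motif with the published ligand and basis columns.
#'
#' @param table1 fixture data frame ([load_table1()]).
#' @param map,known,dimers configuration tables (packaged defaults).
#' @return data frame with one row per motif: predicted `ligand`, `basis`,
#'   `at_sign`, published `published_ligand`, `published_basis`,
#'   `published_at_sign`, and `match` (all three agree).
#' @export
replay_table1 <- function(table1 = load_table1(),
                          map = load_gene_protein_map(),
                          known = load_known_ligands(),
                          dimers = load_dimer_ligands()) {
  operons <- stats::setNames(strsplit(table1$genes, ",", fixed = TRUE),
                             table1$motif_id)
  overrides <- table1$ligand_override
  names(overrides) <- table1$motif_id
  overrides <- overrides[!is.na(overrides) & overrides != ""]
  calls <- two_pass_inference(operons, map = map, known = known,
                              dimers = dimers, ligand_overrides = overrides)
  out <- data.frame(motif_id = table1$motif_id,
                    ligand = calls$ligand[match(table1$motif_id,
                                                calls$motif_id)],
                    basis = calls$basis[match(table1$motif_id,
                                              calls$motif_id)],
                    at_sign = calls$at_sign[match(table1$motif_id,
                                                  calls$motif_id)],
                    published_ligand = table1$ligand,
                    published_basis = table1$basis,
                    published_at_sign = table1$at_sign,
                    stringsAsFactors = FALSE)
  out$match <- out$ligand == out$published_ligand &
    out$basis == out$published_basis & out$at_sign == out$published_at_sign
  attr(out, "calls") <- attr(calls, "calls")
  attr(out, "known") <- attr(calls, "known")
  out
}

#' Count of previously published r-leaders
#'
#' The number of r-leader types confirmed or proposed before this screen's
#' 20 novel motifs (the baseline against which the screen's relative
#' increase is computed: `100 * 20 / 35` is an increase of more than 50%).
#'
#' @return integer scalar.
#' @export
n_prior_rleaders <- function() 35L
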