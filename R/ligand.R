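# Ligand prediction: the Only / Prior / Closest decision procedure.
#
# The working assumption, true for every experimentally characterised
# r-leader, is that the ligand is encoded by a gene the leader regulates.
# With one regulated r-protein gene the call is forced ("Only"). With
# several, a regulated protein already established as an r-leader ligand
# elsewhere is preferred ("Prior"); ligands first established by the current
# screen's own "Only" calls participate via a second pass and are tagged
# with "@". Failing both, the first r-protein gene in transcription order is
# taken ("Closest") — the weakest heuristic, since validated ligands of
# multi-gene operons are most often NOT the first gene.

#' Load the gene->protein map
#'
#' Table mapping gene symbols to product class (`r-protein` / `other`) and
#' bacterial r-protein name (archaeal/eukaryotic proteins as `eL15`,
#' `S3ae`, ...). The packaged default covers the symbols appearing in the
#' screen's bundled fixtures plus common r-protein operon genes; supply a
#' fuller table for new genomes.
#'
#' @param path TSV with columns `symbol`, `product_class`, `protein`;
#'   default the packaged map.
#' @return data frame.
#' @export
load_gene_protein_map <- function(path = .extdata("gene_protein_map.tsv")) {
  map <- .read_tsv(path)
  stopifnot(all(c("symbol", "product_class", "protein") %in% names(map)))
  if (anyDuplicated(map$symbol))
    stop("duplicate symbols in gene->protein map")
  bad <- map$product_class == "r-protein" & (is.na(map$protein) | map$protein == "")
  if (any(bad)) stop("r-protein rows must name a protein: ",
                     paste(map$symbol[bad], collapse = ", "))
  map
}

#' Load the known-ligand table
#'
#' R-protein ligands previously established for r-leaders (dimer ligands as
#' joint names, e.g. `S6:S18`). The packaged default is a best-effort
#' literature transcription and is user-replaceable; entries carry
#' `provenance = "literature"`. Entries with `provenance = "this-run"` are
#' only ever added by [two_pass_inference()].
#'
#' @param path TSV with columns `ligand`, `provenance`.
#' @return data frame of class `known_ligand_table`.
#' @export
load_known_ligands <- function(path = .extdata("known_ligands.tsv")) {
  kt <- .read_tsv(path)
  stopifnot(all(c("ligand", "provenance") %in% names(kt)))
  if (any(kt$provenance == "this-run"))
    stop("'this-run' provenance is reserved for second-pass augmentation")
  class(kt) <- c("known_ligand_table", class(kt))
  kt
}

#' Load dimer-ligand declarations
#'
#' Some ligands are obligate dimers (S6:S18): when all member proteins are
#' encoded in one operon they collapse to a single joint ligand name.
#'
#' @param path TSV with columns `joint`, `members` (comma-separated).
#' @return data frame with `joint` and list-column `members`.
#' @export
load_dimer_ligands <- function(path = .extdata("dimer_ligands.tsv")) {
  d <- .read_tsv(path)
  stopifnot(all(c("joint", "members") %in% names(d)))
  d$members <- strsplit(d$members, ",", fixed = TRUE)
  d
}

# collapse dimer members present together into the joint name, keeping
# transcription order (joint name sits at the first member's position)
.collapse_dimers <- function(proteins, dimers) {
  if (is.null(dimers) || !length(proteins)) return(proteins)
  for (k in seq_len(nrow(dimers))) {
    members <- dimers$members[[k]]
    if (all(members %in% proteins)) {
      first <- min(match(members, proteins))
      proteins <- proteins[!proteins %in% members]
      proteins <- append(proteins, dimers$joint[[k]], after = first - 1L)
    }
  }
  proteins
}

#' Predict the r-protein ligand of one motif
#'
#' Applies the decision procedure to a consensus operon. Let P be the
#' distinct r-proteins encoded by the operon's retained genes, after dimer
#' collapse; non-r-protein genes never become ligands and do not block any
#' case.
#'
#' 1. `|P| == 1` -> that protein, basis `"Only"`.
#' 2. Exactly one member of P is in the known-ligand table -> that ligand,
#'    basis `"Prior"` (tagged `at_sign = TRUE` when the matching entry has
#'    provenance `"this-run"`). When second-pass augmentation creates
#'    multiple hits, literature entries take precedence: exactly one
#'    literature hit still resolves as `"Prior"`.
#' 3. Otherwise the protein of the first r-protein gene in transcription
#'    order, basis `"Closest"`.
#'
#' @param operon an [consensus_operon()] result, or a character vector of
#'   gene symbols in transcription order.
#' @param map gene->protein map ([load_gene_protein_map()]).
#' @param known known-ligand table ([load_known_ligands()]).
#' @param dimers dimer declarations ([load_dimer_ligands()]), or `NULL`.
#' @param motif_id optional identifier carried into the call.
#' @return object of class `ligand_call`: list with `motif_id`, `ligand`,
#'   `basis` (`"Only"`, `"Prior"`, `"Closest"`, or `NA` when the operon has
#'   no r-protein gene), `at_sign`, `confidence` (`"high"`, `"medium"`,
#'   `"low"`), and `evidence` (data frame of symbol, protein, role).
#' @export
predict_ligand <- function(operon, map = load_gene_protein_map(),
                           known = load_known_ligands(),
                           dimers = load_dimer_ligands(),
                           motif_id = NULL) {
  symbols <- if (inherits(operon, "operon_prediction")) operon$genes else
    as.character(operon)
  if (is.null(motif_id))
    motif_id <- if (inherits(operon, "operon_prediction")) operon$motif_id
                else NA_character_
  if (!length(symbols)) stop("empty operon gene list")
  idx <- match(symbols, map$symbol)
  if (anyNA(idx))
    warning("symbol(s) not in gene->protein map, classed 'other': ",
            paste(unique(symbols[is.na(idx)]), collapse = ", "))
  cls <- ifelse(is.na(idx), "other", map$product_class[idx])
  prot <- ifelse(cls == "r-protein", map$protein[idx], NA_character_)
  r_idx <- which(cls == "r-protein")
  evidence <- data.frame(symbol = symbols, protein = prot,
                         role = "regulated", stringsAsFactors = FALSE)
  call0 <- function(ligand, basis, at_sign, conf, roles) {
    evidence$role[roles$which] <- roles$role
    structure(list(motif_id = motif_id, ligand = ligand, basis = basis,
                   at_sign = at_sign, confidence = conf, evidence = evidence),
              class = "ligand_call")
  }
  if (!length(r_idx))
    return(structure(list(motif_id = motif_id, ligand = NA_character_,
                          basis = NA_character_, at_sign = FALSE,
                          confidence = NA_character_, evidence = evidence,
                          note = "no candidate ligand: no r-protein gene"),
                     class = "ligand_call"))
  ordered_prot <- unique(prot[r_idx])
  collapsed <- .collapse_dimers(ordered_prot, dimers)
  if (length(collapsed) == 1L)
    return(call0(collapsed, "Only", FALSE, "high",
                 list(which = r_idx, role = "sole-r-protein")))
  hits <- intersect(collapsed, known$ligand)
  hit_call <- function(lig) {
    this_run <- any(known$ligand == lig & known$provenance == "this-run")
    members <- if (grepl(":", lig, fixed = TRUE))
      strsplit(lig, ":", fixed = TRUE)[[1]] else lig
    call0(lig, "Prior", this_run, "medium",
          list(which = r_idx[prot[r_idx] %in% members], role = "prior-ligand"))
  }
  if (length(hits) == 1L) return(hit_call(hits))
  if (length(hits) > 1L) {
    lit <- intersect(hits,
                     known$ligand[known$provenance == "literature"])
    if (length(lit) == 1L) return(hit_call(lit))
  }
  call0(collapsed[1L], "Closest", FALSE, "low",
        list(which = r_idx[1L], role = "closest"))
}

#' @export
print.ligand_call <- function(x, ...) {
  if (is.na(x$basis)) {
    cat("Ligand call", if (!is.na(x$motif_id)) paste0(" [", x$motif_id, "]"),
        ": none (", x$note, ")\n", sep = "")
  } else {
    cat("Ligand call", if (!is.na(x$motif_id)) paste0(" [", x$motif_id, "]"),
        ": ", x$ligand, " (", x$basis, if (x$at_sign) " @", ", confidence ",
        x$confidence, ")\n", sep = "")
  }
  invisible(x)
}

#' Two-pass ligand inference over a batch of motifs
#'
#' Pass 1 resolves every motif against the literature known-ligand table;
#' ligands of the resulting `"Only"` calls are appended to a working copy of
#' the table with provenance `"this-run"`. Pass 2 re-resolves the remaining
#' motifs against the augmented table, so a ligand first established by this
#' screen can support a `"Prior"` call (reported with `at_sign = TRUE`).
#' Results are independent of motif input order; per-motif errors are
#' captured, not propagated.
#'
#' @param operons named list of operons (each an `operon_prediction` or a
#'   character vector of symbols); names are motif ids.
#' @param map,known,dimers as in [predict_ligand()]; `known` must be
#'   literature-only.
#' @param ligand_overrides optional named character vector
#'   (motif id -> ligand name) replacing the ligand of that motif's `"Only"`
#'   call; documents curated resolutions of ambiguous gene annotations. The
#'   override participates in the pass-1 augmentation.
#' @return data frame of class `ligand_calls` with one row per motif
#'   (`motif_id`, `ligand`, `basis`, `at_sign`, `confidence`, `note`), with
#'   the full `ligand_call` objects in attribute `"calls"` and the augmented
#'   known table in attribute `"known"`.
#' @export
two_pass_inference <- function(operons, map = load_gene_protein_map(),
                               known = load_known_ligands(),
                               dimers = load_dimer_ligands(),
                               ligand_overrides = NULL) {
  if (is.null(names(operons)) || any(names(operons) == ""))
    stop("operons must be a named list (names = motif ids)")
  if (any(known$provenance != "literature"))
    stop("the pass-1 known-ligand table must be literature-only")
  run1 <- lapply(names(operons), function(id) {
    tryCatch(predict_ligand(operons[[id]], map = map, known = known,
                            dimers = dimers, motif_id = id),
             error = function(e) structure(
               list(motif_id = id, ligand = NA_character_,
                    basis = NA_character_, at_sign = FALSE,
                    confidence = NA_character_,
                    evidence = NULL, note = conditionMessage(e)),
               class = "ligand_call"))
  })
  names(run1) <- names(operons)
  for (id in names(run1)) {
    cl <- run1[[id]]
    if (!is.na(cl$basis) && cl$basis == "Only" &&
        !is.null(ligand_overrides) && id %in% names(ligand_overrides)) {
      cl$ligand <- unname(ligand_overrides[[id]])
      cl$note <- "ligand overridden by curated fixture annotation"
      run1[[id]] <- cl
    }
  }
  only_ligands <- sort(unique(vapply(
    Filter(function(cl) !is.na(cl$basis) && cl$basis == "Only", run1),
    function(cl) cl$ligand, character(1))))
  additions <- setdiff(only_ligands, known$ligand)
  augmented <- known
  if (length(additions))
    augmented <- rbind(known,
                       data.frame(ligand = additions,
                                  provenance = "this-run",
                                  stringsAsFactors = FALSE))
  calls <- lapply(names(operons), function(id) {
    cl <- run1[[id]]
    if (!is.na(cl$basis) && cl$basis == "Only") return(cl)
    tryCatch(predict_ligand(operons[[id]], map = map, known = augmented,
                            dimers = dimers, motif_id = id),
             error = function(e) run1[[id]])
  })
  names(calls) <- names(operons)
  out <- data.frame(
    motif_id = names(calls),
    ligand = vapply(calls, function(cl) cl$ligand, character(1)),
    basis = vapply(calls, function(cl) cl$basis, character(1)),
    at_sign = vapply(calls, function(cl) isTRUE(cl$at_sign), logical(1)),
    confidence = vapply(calls, function(cl)
      if (is.null(cl$confidence)) NA_character_ else cl$confidence,
      character(1)),
    note = vapply(calls, function(cl)
      if (is.null(cl$note)) NA_character_ else cl$note, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "calls") <- calls
  attr(out, "known") <- augmented
  class(out) <- c("ligand_calls", class(out))
  out
}
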