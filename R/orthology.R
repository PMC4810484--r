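# Reciprocal-best-hit orthology between a reference panel and target
# proteomes (the BackBLAST stage), in two threshold modes: reference-set
# expansion (E <= 1e-30, identity >= 25%) and degrader confirmation
# (E <= 1e-25, identity >= 25%). The identity/E-value filters apply to the
# forward hit only; the back search into the full reference proteome must
# merely return the originating reference as its best hit.

rbh_modes <- list(
  expansion    = list(min_identity = 0.25, max_evalue = 1e-30),
  confirmation = list(min_identity = 0.25, max_evalue = 1e-25))

#' Best passing local-alignment hit of a query in a proteome
#'
#' Scores the query against every target, applies the identity and E-value
#' filters, and returns the passing hit with the highest bit score; ties are
#' broken by lower E-value, then lexicographically smaller target id.
#'
#' @param query protein string.
#' @param proteome named character vector of target proteins.
#' @param min_identity,max_evalue forward filters.
#' @param scoring calibrated [scoring_scheme()].
#' @param query_id optional id carried on the hit.
#' @param database_residues search-space size for the E-value; defaults to
#'   the proteome's total residue count.
#' @param proteome_enc optional pre-encoded proteome (from repeated calls).
#' @return an `alignment_hit` (with `evalue` filled) or `NULL`.
#' @export
best_hit <- function(query, proteome, min_identity = 0.25,
                     max_evalue = 1e-25, scoring = scoring_scheme(),
                     query_id = NULL, database_residues = NULL,
                     proteome_enc = NULL) {
  check_proteome(proteome)
  db <- database_residues %||% sum(nchar(proteome))
  qi <- if (is.character(query)) encode_seq(query, "query") else query
  hits <- sw_batch_cpp(qi, proteome_enc %||% encode_many(proteome),
                       scoring$substitution,
                       scoring$gap_open, scoring$gap_extend)
  sc <- hits[, "score"]
  ev <- scoring$karlin_K * length(qi) * db * exp(-scoring$karlin_lambda * sc)
  identity <- hits[, "matches"] / hits[, "aligned_length"]
  ok <- which(sc > 0 & identity >= min_identity & ev <= max_evalue)
  if (!length(ok)) return(NULL)
  ord <- ok[order(-sc[ok], ev[ok], names(proteome)[ok], method = "radix")]
  i <- ord[1]
  h <- new_hit(query_id, names(proteome)[i],
               list(score = sc[i], matches = hits[i, "matches"],
                    aligned_length = hits[i, "aligned_length"],
                    qstart = hits[i, "qstart"], qend = hits[i, "qend"],
                    tstart = hits[i, "tstart"], tend = hits[i, "tend"]),
               scoring)
  h$evalue <- ev[i]
  h
}

#' Reciprocal-best-hit ortholog map
#'
#' For every panel protein, finds its best passing hit in the target
#' proteome, then searches that target protein back against the complete
#' reference proteome; the pair is flagged reciprocal iff the back search's
#' best hit is the originating panel protein. Using the full reference
#' proteome (not the panel alone) as the back-search database is what rejects
#' out-paralogs.
#'
#' @param panel a `reference_panel` data frame or a named character vector of
#'   panel protein sequences; panel ids must be present in
#'   `reference_proteome`.
#' @param target_proteome,reference_proteome named character vectors.
#' @param mode `"confirmation"` (E <= 1e-25) or `"expansion"` (E <= 1e-30);
#'   both with forward identity >= 25%.
#' @param scoring calibrated [scoring_scheme()].
#' @param target_enc,reference_enc optional pre-encoded proteomes.
#' @return `ortholog_map` data frame (`reference_id`, `target_id`,
#'   `identity`, `evalue`, `bit_score`, `reciprocal`) with attribute `mode`.
#' @export
reciprocal_best_hits <- function(panel, target_proteome, reference_proteome,
                                 mode = c("confirmation", "expansion"),
                                 scoring = scoring_scheme(),
                                 target_enc = NULL, reference_enc = NULL) {
  mode <- match.arg(mode)
  thr <- rbh_modes[[mode]]
  seqs <- panel_sequences(panel)
  check_proteome(target_proteome)
  check_proteome(reference_proteome)
  missing <- setdiff(names(seqs), names(reference_proteome))
  if (length(missing))
    smx_stop("steromine_config_error",
             "panel protein(s) absent from reference proteome: %s",
             paste(missing, collapse = ", "))
  target_enc <- target_enc %||% encode_many(target_proteome)
  reference_enc <- reference_enc %||% encode_many(reference_proteome)
  rows <- lapply(names(seqs), function(rid) {
    fwd <- best_hit(seqs[[rid]], target_proteome,
                    min_identity = thr$min_identity,
                    max_evalue = thr$max_evalue, scoring = scoring,
                    query_id = rid, proteome_enc = target_enc)
    if (is.null(fwd)) return(NULL)
    back <- best_hit(target_proteome[[fwd$target_id]], reference_proteome,
                     min_identity = 0, max_evalue = Inf, scoring = scoring,
                     query_id = fwd$target_id, proteome_enc = reference_enc)
    data.frame(reference_id = rid, target_id = fwd$target_id,
               identity = fwd$identity, evalue = fwd$evalue,
               bit_score = fwd$bit_score,
               reciprocal = !is.null(back) && back$target_id == rid)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(reference_id = character(), target_id = character(),
                      identity = numeric(), evalue = numeric(),
                      bit_score = numeric(), reciprocal = logical())
  structure(out, mode = mode, class = c("ortholog_map", "data.frame"))
}

panel_sequences <- function(panel) {
  if (inherits(panel, "reference_panel") || is.data.frame(panel)) {
    seqs <- setNames(as.list(panel$sequence), panel$protein_id)
  } else if (is.character(panel)) {
    check_proteome(panel)
    seqs <- as.list(panel)
  } else {
    smx_stop("steromine_input_error", "unrecognized panel object")
  }
  if (anyDuplicated(names(seqs)))
    smx_stop("steromine_input_error", "duplicate panel protein ids")
  seqs
}

#' Reciprocal-best-hit identity matrix (heat-map data)
#'
#' One row per panel protein (panel order), one column per genome; a cell
#' holds the forward-hit identity of the reciprocal best hit, or `NA` when no
#' reciprocal hit passes the mode's thresholds.
#'
#' @param panel reference panel (see [reciprocal_best_hits()]).
#' @param genomes named list of target proteomes.
#' @param reference_proteome back-search database.
#' @param mode threshold mode.
#' @param scoring calibrated [scoring_scheme()].
#' @return numeric matrix, `dimnames = list(panel ids, genome ids)`.
#' @export
identity_matrix <- function(panel, genomes, reference_proteome,
                            mode = "confirmation",
                            scoring = scoring_scheme()) {
  if (!length(genomes))
    smx_stop("steromine_input_error", "need at least one genome")
  seqs <- panel_sequences(panel)
  M <- matrix(NA_real_, length(seqs), length(genomes),
              dimnames = list(names(seqs), names(genomes)))
  for (g in names(genomes)) {
    om <- reciprocal_best_hits(panel, genomes[[g]], reference_proteome,
                               mode = mode, scoring = scoring)
    om <- om[om$reciprocal, , drop = FALSE]
    M[om$reference_id, g] <- om$identity
  }
  M
}

#' Write an ortholog map as TSV
#' @param map an `ortholog_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
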