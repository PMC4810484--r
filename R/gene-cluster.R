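# Gene localization: map hits onto replicon coordinates, chain them into
# gene clusters (single linkage over the number of intervening non-hit
# genes, with wraparound on circular replicons), and flag plasmid-borne
# pathways.

#' Map hit proteins onto genome coordinates
#'
#' @param hit_ids protein/gene ids with hits (character vector, or a data
#'   frame with a `protein_id` or `target_id` column); an optional names
#'   attribute or `group` column carries the enzyme-group label.
#' @param annotation annotation table ([read_annotation()] convention).
#' @return `located_gene` data frame sorted by replicon and coordinate;
#'   unresolvable ids are attached as attribute `unresolved` and warned
#'   about, never silently dropped.
#' @export
locate_hits <- function(hit_ids, annotation) {
  if (is.data.frame(hit_ids)) {
    ids <- hit_ids$protein_id %||% hit_ids$target_id
    groups <- hit_ids$group %||% rep(NA_character_, length(ids))
  } else {
    ids <- as.character(hit_ids)
    groups <- names(hit_ids) %||% rep(NA_character_, length(ids))
  }
  if (!all(c("start", "end", "gene_index") %in% names(annotation)))
    smx_stop("steromine_input_error", "annotation lacks coordinate columns")
  if (!length(ids)) {
    out <- annotation[0, ]
    out$group_label <- character(0)
    return(out)
  }
  keep <- !duplicated(ids)
  ids <- ids[keep]; groups <- groups[keep]
  m <- match(ids, annotation$gene_id)
  unresolved <- ids[is.na(m)]
  if (length(unresolved))
    warning(sprintf("%d hit id(s) not in annotation: %s",
                    length(unresolved),
                    paste(head(unresolved, 3), collapse = ", ")))
  out <- annotation[m[!is.na(m)], ]
  out$group_label <- groups[!is.na(m)]
  out <- out[order(out$replicon_id, out$start, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "unresolved") <- unresolved
  out
}

#' Chain located genes into gene clusters
#'
#' Per replicon, single-linkage chaining: two located genes belong to one
#' cluster iff at most `max_gap_genes` non-hit genes lie between them;
#' circular replicons are evaluated with wraparound, so the cluster
#' partition is invariant under rotation of the origin.
#'
#' @param located a [locate_hits()] result (needs `gene_index`).
#' @param replicon_n_genes named integer vector: total gene count per
#'   replicon id (for the wraparound gap).
#' @param max_gap_genes maximum intervening non-hit genes (default 10).
#' @return `gene_cluster_call` data frame: one row per cluster with
#'   `cluster_id`, `genome_id`, `replicon_id`, `replicon_type`, `n_members`,
#'   `members` (comma-joined ids), `span_start`, `span_end`.
#' @export
detect_clusters <- function(located, replicon_n_genes, max_gap_genes = 10) {
  if (!nrow(located))
    return(data.frame(cluster_id = character(), genome_id = character(),
                      replicon_id = character(), replicon_type = character(),
                      n_members = integer(), members = character(),
                      span_start = integer(), span_end = integer()))
  out <- list()
  for (repl in unique(located$replicon_id)) {
    sub <- located[located$replicon_id == repl, ]
    sub <- sub[order(sub$gene_index), ]
    n_total <- replicon_n_genes[[repl]]
    if (is.null(n_total) || is.na(n_total))
      smx_stop("steromine_input_error",
               "total gene count unknown for replicon %s", repl)
    idx <- sub$gene_index
    k <- nrow(sub)
    grp <- seq_len(k)
    if (k > 1) {
      gap <- idx[-1] - idx[-k] - 1L
      for (i in seq_len(k - 1))
        if (gap[i] <= max_gap_genes) grp[i + 1] <- grp[i]
      if (isTRUE(sub$circular[1])) {
        wrap_gap <- n_total - idx[k] + idx[1] - 1L
        if (wrap_gap <= max_gap_genes && grp[1] != grp[k])
          grp[grp == grp[k]] <- grp[1]
      }
    }
    for (g in unique(grp)) {
      mem <- sub[grp == g, ]
      out[[length(out) + 1L]] <- data.frame(
        genome_id = mem$genome_id[1], replicon_id = repl,
        replicon_type = mem$replicon_type[1],
        n_members = nrow(mem),
        members = paste(mem$gene_id, collapse = ","),
        groups = paste(mem$group_label, collapse = ","),
        span_start = min(mem$start), span_end = max(mem$end))
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$genome_id, out$replicon_id, out$span_start,
                   method = "radix"), ]
  out$cluster_id <- sprintf("%s.cl%02d", out$genome_id,
                            as.integer(ave(seq_len(nrow(out)),
                                           out$genome_id, FUN = seq_along)))
  rownames(out) <- NULL
  out[, c("cluster_id", "genome_id", "replicon_id", "replicon_type",
          "n_members", "members", "groups", "span_start", "span_end")]
}

#' Per-genome replicon summary of cluster calls
#'
#' @param clusters a [detect_clusters()] result (possibly spanning genomes).
#' @return data frame per genome: `n_clusters`, `any_plasmid`,
#'   `plasmid_only` (TRUE when every pathway cluster sits on plasmids).
#' @export
replicon_summary <- function(clusters) {
  if (!nrow(clusters))
    return(data.frame(genome_id = character(), n_clusters = integer(),
                      any_plasmid = logical(), plasmid_only = logical()))
  sp <- split(clusters, clusters$genome_id)
  out <- do.call(rbind, lapply(sp, function(cl) data.frame(
    genome_id = cl$genome_id[1],
    n_clusters = nrow(cl),
    any_plasmid = any(cl$replicon_type == "plasmid"),
    plasmid_only = all(cl$replicon_type == "plasmid"))))
  rownames(out) <- NULL
  out
}
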