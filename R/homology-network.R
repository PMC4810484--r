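# Reference-protein binning: build a similarity graph under joint identity
# and E-value thresholds, take connected components as homologous groups,
# then split groups into taxon/substrate subclusters with a CD-HIT-style
# greedy incremental clustering (longest-first, scan clusters in creation
# order, join the first whose representative matches at >= the identity
# threshold).

#' Thresholded protein similarity graph
#'
#' An undirected edge joins two proteins iff their best local alignment
#' passes both the identity and the E-value filter (defaults: identity >=
#' 30%, E <= 1e-30). The E-value search space is the total residue count of
#' the input set.
#'
#' @param proteins named character vector of protein sequences (>= 2).
#' @param min_identity minimum alignment identity (fraction).
#' @param max_evalue maximum Karlin-Altschul E-value.
#' @param scoring a calibrated [scoring_scheme()].
#' @return `homology_graph`: list with `nodes` and an `edges` data frame
#'   (`a`, `b`, `identity`, `evalue`, `bit_score`).
#' @export
build_graph <- function(proteins, min_identity = 0.30, max_evalue = 1e-30,
                        scoring = scoring_scheme()) {
  check_proteome(proteins, min_n = 2)
  ids <- names(proteins)
  enc <- encode_many(proteins)
  db <- sum(nchar(proteins))
  edges <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    idx <- (i + 1L):length(ids)
    hits <- sw_batch_cpp(enc[[i]], enc[idx], scoring$substitution,
                         scoring$gap_open, scoring$gap_extend)
    sc <- hits[, "score"]
    keep <- which(sc > 0)
    if (!length(keep)) next
    identity <- hits[keep, "matches"] / hits[keep, "aligned_length"]
    ev <- scoring$karlin_K * nchar(proteins[i]) * db *
      exp(-scoring$karlin_lambda * sc[keep])
    ok <- identity >= min_identity & ev <= max_evalue
    if (any(ok))
      edges[[length(edges) + 1L]] <- data.frame(
        a = ids[i], b = ids[idx][keep][ok], identity = identity[ok],
        evalue = ev[ok], bit_score = bit_score(sc[keep][ok], scoring))
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(), b = character(), identity = numeric(),
               evalue = numeric(), bit_score = numeric())
  structure(list(nodes = ids, edges = edges), class = "homology_graph")
}

#' Homologous groups as graph components
#'
#' @param graph a [build_graph()] result.
#' @return list of character vectors (one per component, singletons allowed),
#'   ordered by their lexicographically smallest member.
#' @export
connected_components <- function(graph) {
  if (!inherits(graph, "homology_graph"))
    smx_stop("steromine_input_error", "expected a homology_graph")
  g <- igraph::graph_from_data_frame(graph$edges[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = graph$nodes))
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  groups <- lapply(groups, function(x) sort(x))
  unname(groups[order(vapply(groups, `[`, character(1), 1))])
}

# distinct k-mer set of an encoded sequence
kmer_set <- function(s_int, k) {
  L <- length(s_int)
  if (L < k) return(character(0))
  ch <- c(AA_ALPHABET, "X")[s_int + 1L]
  unique(vapply(seq_len(L - k + 1L),
                function(i) paste(ch[i:(i + k - 1L)], collapse = ""),
                character(1)))
}

#' Greedy incremental sequence clustering (CD-HIT style)
#'
#' Proteins are processed longest-first (ties broken lexicographically by
#' id). Each protein joins the first existing cluster -- scanned in creation
#' order -- whose representative it matches at `>= min_identity`, else founds
#' a new cluster with itself as representative. Identity is global-alignment
#' identical pairs over the shorter sequence length (the CD-HIT convention).
#' A shared-word count prefilter of length `word_size` skips comparisons that
#' cannot reach the threshold; it is an optimization only.
#'
#' @param proteins named character vector.
#' @param min_identity clustering identity threshold (default 0.50).
#' @param word_size k-mer length of the prefilter (default 3).
#' @param scoring a [scoring_scheme()].
#' @return `subcluster_set`: list with `clusters` (list of member id vectors,
#'   representative first), `representatives`, and a `membership` data frame.
#' @export
greedy_cluster <- function(proteins, min_identity = 0.50, word_size = 3,
                           scoring = scoring_scheme()) {
  if (word_size < 1)
    smx_stop("steromine_parameter_error", "word_size must be >= 1")
  check_proteome(proteins, min_n = 1)
  ord <- order(-nchar(proteins), names(proteins), method = "radix")
  ids <- names(proteins)[ord]
  enc <- encode_many(proteins[ord])
  words <- lapply(enc, kmer_set, k = word_size)

  reps <- integer(0)       # index (into ord) of each cluster representative
  members <- list()
  member_identity <- list()
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (cl in seq_along(reps)) {
      r <- reps[cl]
      ls <- min(length(enc[[i]]), length(enc[[r]]))
      need <- max(1, (ls - word_size + 1) -
                    word_size * ceiling((1 - min_identity) * ls))
      if (length(intersect(words[[i]], words[[r]])) < need) next
      idy <- global_identity(enc[[i]], enc[[r]], scoring,
                             denominator = "shorter")
      if (idy >= min_identity) {
        members[[cl]] <- c(members[[cl]], ids[i])
        member_identity[[cl]] <- c(member_identity[[cl]], idy)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[length(reps)]] <- ids[i]
      member_identity[[length(reps)]] <- 1
    }
  }
  membership <- do.call(rbind, lapply(seq_along(members), function(cl) {
    data.frame(cluster_id = sprintf("cluster_%03d", cl),
               member_id = members[[cl]],
               is_representative = members[[cl]] == ids[reps[cl]],
               identity_to_representative = member_identity[[cl]])
  }))
  structure(list(clusters = members, representatives = ids[reps],
                 membership = membership,
                 min_identity = min_identity, word_size = word_size),
            class = "subcluster_set")
}

#' Drop subclusters that contain no seed protein
#'
#' The filter that removes potentially non-orthologous proteins: only
#' clusters containing at least one of the original seed reference proteins
#' are retained.
#'
#' @param subclusters a [greedy_cluster()] result.
#' @param seed_ids ids of the seed proteins; must all have been clustered.
#' @return a filtered `subcluster_set`.
#' @export
retain_seeded <- function(subclusters, seed_ids) {
  if (!inherits(subclusters, "subcluster_set"))
    smx_stop("steromine_input_error", "expected a subcluster_set")
  all_members <- unlist(subclusters$clusters, use.names = FALSE)
  unknown <- setdiff(seed_ids, all_members)
  if (length(unknown))
    smx_stop("steromine_input_error", "unknown seed id(s): %s",
             paste(unknown, collapse = ", "))
  keep <- vapply(subclusters$clusters,
                 function(m) any(seed_ids %in% m), logical(1))
  out <- subclusters
  out$clusters <- subclusters$clusters[keep]
  out$representatives <- subclusters$representatives[keep]
  out$membership <- subclusters$membership[
    subclusters$membership$cluster_id %in%
      sprintf("cluster_%03d", which(keep)), , drop = FALSE]
  out
}

#' Write a subcluster set as CD-HIT-like `.clstr` text plus TSV
#' @param subclusters a `subcluster_set`.
#' @param path output path for the `.clstr` text; a `.tsv` sibling is written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(subclusters, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cl in seq_along(subclusters$clusters)) {
    writeLines(sprintf(">Cluster %d", cl - 1L), con)
    m <- subclusters$clusters[[cl]]
    rep_id <- subclusters$representatives[cl]
    for (j in seq_along(m)) {
      tag <- if (m[j] == rep_id) "*" else
        sprintf("at %.2f%%",
                100 * subclusters$membership$identity_to_representative[
                  subclusters$membership$member_id == m[j]][1])
      writeLines(sprintf("%d\t>%s... %s", j - 1L, m[j], tag), con)
    }
  }
  tsv <- sub("\\.[^.]*$", ".tsv", path)
  write.table(subclusters$membership, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

check_proteome <- function(proteins, min_n = 1) {
  if (length(proteins) < min_n)
    smx_stop("steromine_input_error", "need at least %d protein(s)", min_n)
  if (is.null(names(proteins)) || anyNA(names(proteins)) ||
      any(names(proteins) == ""))
    smx_stop("steromine_input_error", "proteins must be named")
  if (anyDuplicated(names(proteins)))
    smx_stop("steromine_input_error", "duplicate protein id: %s",
             names(proteins)[anyDuplicated(names(proteins))])
  invisible(TRUE)
}
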