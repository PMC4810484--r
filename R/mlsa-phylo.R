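# Multilocus phylogeny of steroid-degradation proteins: four marker enzymes
# (KshA-like, HsaA-like, HsaC-like, HsaD-like) extracted per gene cluster,
# aligned, trimmed and concatenated into a supermatrix; trees are built by
# neighbor joining on Poisson-corrected protein distances with bootstrap
# support, and compared with the 16S-like species tree by Robinson-Foulds
# distance. (The original analysis used a maximum-likelihood search; NJ on
# corrected distances is used here and is consistent on the simulated
# regime -- see the methods vignette.)

mlsa_marker_groups <- c("KshA", "HsaA", "HsaC", "HsaD")

#' Extract per-cluster marker protein sets
#'
#' One taxon per gene cluster (a genome with two clusters contributes two
#' taxa). A taxon is retained only when all four marker groups are present
#' in the cluster; incomplete taxa are listed in the `dropped` attribute.
#'
#' @param cluster_calls [detect_clusters()] output (with `groups` column).
#' @param proteomes named list of proteomes (genome id -> named sequences).
#' @param marker_groups enzyme groups used as markers.
#' @return named list: taxon id -> named character vector of marker
#'   sequences (names = marker groups); attribute `dropped` lists excluded
#'   taxa. Errors when no taxon is complete.
#' @export
extract_markers <- function(cluster_calls, proteomes,
                            marker_groups = mlsa_marker_groups) {
  taxa <- list()
  dropped <- character(0)
  for (i in seq_len(nrow(cluster_calls))) {
    cl <- cluster_calls[i, ]
    ids <- strsplit(cl$members, ",", fixed = TRUE)[[1]]
    grs <- strsplit(cl$groups, ",", fixed = TRUE)[[1]]
    sel <- match(marker_groups, grs)
    taxon <- cl$cluster_id
    if (anyNA(sel)) {
      dropped <- c(dropped, taxon)
      next
    }
    seqs <- proteomes[[cl$genome_id]][ids[sel]]
    names(seqs) <- marker_groups
    taxa[[taxon]] <- seqs
  }
  if (!length(taxa))
    smx_stop("steromine_analysis_error",
             "no gene cluster carries all marker groups")
  attr(taxa, "dropped") <- dropped
  taxa
}

#' Concatenated marker supermatrix
#'
#' Aligns each marker block across taxa with [progressive_align()], trims
#' gappy columns, and concatenates blocks in fixed marker order.
#'
#' @param marker_sets [extract_markers()] output (>= 3 taxa).
#' @param scoring a [scoring_scheme()].
#' @param max_gap_fraction trimming threshold per block.
#' @return character matrix (taxa x concatenated columns) with attribute
#'   `blocks`: data frame of per-marker column ranges.
#' @export
build_supermatrix <- function(marker_sets, scoring = scoring_scheme(),
                              max_gap_fraction = 0.5) {
  if (length(marker_sets) < 3)
    smx_stop("steromine_input_error", "need >= 3 taxa")
  taxa <- sort(names(marker_sets))
  markers <- names(marker_sets[[1]])
  blocks <- list()
  mats <- list()
  col0 <- 0L
  for (mk in markers) {
    seqs <- vapply(marker_sets, `[[`, character(1), mk)[taxa]
    aln <- trim_columns(progressive_align(seqs, scoring), max_gap_fraction)
    mats[[mk]] <- aln[taxa, , drop = FALSE]
    blocks[[mk]] <- data.frame(marker = mk, from = col0 + 1L,
                               to = col0 + ncol(aln))
    col0 <- col0 + ncol(aln)
  }
  out <- do.call(cbind, mats)
  rownames(out) <- taxa
  attr(out, "blocks") <- do.call(rbind, blocks)
  class(out) <- c("multiple_alignment", class(out))
  out
}

#' Poisson-corrected protein distance between two alignment rows
#'
#' `d = -ln(1 - p)` with `p` the proportion of differing columns among the
#' columns where neither row is gapped (pairwise deletion).
#'
#' @param row_a,row_b character vectors of aligned residues.
#' @return distance in substitutions per site; errors when `p >= 1`
#'   (saturation) or no shared column exists.
#' @export
protein_distance <- function(row_a, row_b) {
  shared <- row_a != "-" & row_b != "-"
  if (!any(shared))
    smx_stop("steromine_input_error", "no shared non-gap column")
  p <- mean(row_a[shared] != row_b[shared])
  if (p >= 1)
    smx_stop("steromine_analysis_error",
             "saturated pair (p >= 1), distance undefined")
  -log(1 - p)
}

#' Pairwise Poisson-corrected distance matrix of an alignment
#' @param alignment character alignment matrix.
#' @return symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(alignment) {
  n <- nrow(alignment)
  D <- matrix(0, n, n, dimnames = list(rownames(alignment),
                                       rownames(alignment)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- protein_distance(alignment[i, ], alignment[j, ])
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (consistent: recovers the generating topology
#' exactly from additive matrices), implemented in plain R: the Q-criterion
#' pair with the smallest value joins first (ties broken by column-major
#' order), and negative branch-length estimates are clamped to zero.
#'
#' @param D symmetric distance matrix with zero diagonal, >= 3 taxa.
#' @return an `ape::phylo`.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D) || nrow(D) < 3)
    smx_stop("steromine_input_error", "need a square matrix with >= 3 taxa")
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12))
    smx_stop("steromine_input_error",
             "distance matrix must be symmetric with zero diagonal")
  labels <- rownames(D) %||% paste0("t", seq_len(nrow(D)))
  n <- nrow(D)
  active <- seq_len(n)      # node ids of current clusters (tips are 1..n)
  next_id <- n              # internal nodes get ids n+1, n+2, ...
  parent <- child <- integer(0)
  blen <- numeric(0)
  Dm <- unname(D)
  while (length(active) > 3) {
    m <- length(active)
    rs <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(rs, rs, "+")
    diag(Q) <- Inf
    k <- arrayInd(which.min(Q), dim(Q))
    i <- min(k); j <- max(k)
    di <- 0.5 * Dm[i, j] + (rs[i] - rs[j]) / (2 * (m - 2))
    dj <- Dm[i, j] - di
    next_id <- next_id + 1L
    parent <- c(parent, next_id, next_id)
    child <- c(child, active[i], active[j])
    blen <- c(blen, max(di, 0), max(dj, 0))
    newd <- 0.5 * (Dm[i, ] + Dm[j, ] - Dm[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    active <- c(active[keep], next_id)
  }
  # final trifurcation by the three-point formulas
  next_id <- next_id + 1L
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  parent <- c(parent, next_id, next_id, next_id)
  child <- c(child, active[1], active[2], active[3])
  blen <- c(blen, max((d12 + d13 - d23) / 2, 0),
            max((d12 + d23 - d13) / 2, 0),
            max((d13 + d23 - d12) / 2, 0))
  # renumber internal nodes to ape convention: root = n+1, then the rest
  n_internal <- next_id - n
  new_id <- integer(next_id)
  new_id[seq_len(n)] <- seq_len(n)
  old_internal <- (n + 1L):next_id
  new_id[old_internal] <- c(if (n_internal > 1) (n + 2L):(n + n_internal),
                            n + 1L)  # creation order, root (last made) first
  edge <- cbind(new_id[parent], new_id[child])
  storage.mode(edge) <- "integer"
  tr <- list(edge = edge, edge.length = blen, tip.label = labels,
             Nnode = n_internal)
  class(tr) <- "phylo"
  tr
}

# tip descendants per node, resolved bottom-up with plain loops
tip_descendants <- function(tree) {
  n <- length(tree$tip.label)
  n_nodes <- n + tree$Nnode
  kids <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  desc <- vector("list", n_nodes)
  for (v in seq_len(n)) desc[[v]] <- v
  pending <- which(vapply(seq_len(n_nodes), function(v)
    is.null(desc[[v]]) && !is.null(kids[[v]]), logical(1)))
  while (length(pending)) {
    progressed <- FALSE
    still <- integer(0)
    for (v in pending) {
      ch <- kids[[v]]
      if (all(!vapply(ch, function(c) is.null(desc[[c]]), logical(1)))) {
        desc[[v]] <- unlist(desc[ch], use.names = FALSE)
        progressed <- TRUE
      } else {
        still <- c(still, v)
      }
    }
    if (!progressed)
      smx_stop("steromine_input_error", "malformed tree edges")
    pending <- still
  }
  desc
}

# canonical keys of the non-trivial bipartitions of a tree: for each
# internal edge, the lexicographically smaller of the two sorted label sets
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  desc <- tip_descendants(tree)
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= n) next
    side <- sort(tree$tip.label[desc[[ch]]])
    other <- sort(setdiff(tree$tip.label, side))
    if (length(side) < 2 || length(other) < 2) next
    k1 <- paste(side, collapse = "\r")
    k2 <- paste(other, collapse = "\r")
    keys <- c(keys, if (k1 < k2) k1 else k2)
  }
  unique(keys)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal node of the full-data tree with
#' the percentage of replicates containing its subtending bipartition.
#'
#' @param supermatrix character alignment matrix (>= 3 rows).
#' @param n_replicates bootstrap replicates (analysis default 2500; tests
#'   use smaller counts).
#' @param seed RNG seed (same seed, same supports).
#' @return `phylo` with `node.label` holding percentage supports.
#' @export
bootstrap_support <- function(supermatrix, n_replicates = 2500, seed = 1) {
  set.seed(seed)
  base <- nj_tree(distance_matrix(supermatrix))
  nc <- ncol(supermatrix)
  rep_keys <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    tr <- tryCatch(nj_tree(distance_matrix(
      supermatrix[, cols, drop = FALSE])), error = function(e) NULL)
    rep_keys[[r]] <- if (is.null(tr)) NULL else tree_bipartitions(tr)
  }
  rep_keys <- Filter(Negate(is.null), rep_keys)
  n_eff <- length(rep_keys)

  n <- length(base$tip.label)
  desc <- tip_descendants(base)
  labs <- numeric(base$Nnode)
  child_of <- setNames(rep(NA_character_, base$Nnode),
                       as.character(n + seq_len(base$Nnode)))
  for (e in seq_len(nrow(base$edge))) {
    ch <- base$edge[e, 2]
    if (ch <= n) next
    side <- sort(base$tip.label[desc[[ch]]])
    other <- sort(setdiff(base$tip.label, side))
    if (length(side) < 2 || length(other) < 2) next
    k1 <- paste(side, collapse = "\r")
    k2 <- paste(other, collapse = "\r")
    child_of[as.character(ch)] <- if (k1 < k2) k1 else k2
  }
  for (v in seq_len(base$Nnode)) {
    key <- child_of[[v]]
    labs[v] <- if (is.na(key)) 0 else
      100 * sum(vapply(rep_keys, function(ks) key %in% ks, logical(1))) / n_eff
  }
  base$node.label <- round(labs, 1)
  attr(base, "n_replicates") <- n_eff
  base
}

#' Robinson-Foulds distance between two trees
#'
#' Trees are pruned to their shared leaves (>= 3 required); the distance is
#' the number of non-trivial bipartitions present in exactly one of the two
#' unrooted topologies (counted by explicit bipartition comparison). Zero
#' means topological congruence.
#'
#' @param tree_a,tree_b `phylo` objects.
#' @return non-negative integer.
#' @export
rf_distance <- function(tree_a, tree_b) {
  shared <- intersect(tree_a$tip.label, tree_b$tip.label)
  if (length(shared) < 3)
    smx_stop("steromine_input_error", "fewer than 3 shared leaves")
  a <- if (setequal(tree_a$tip.label, shared)) tree_a else
    ape::keep.tip(tree_a, shared)
  b <- if (setequal(tree_b$tip.label, shared)) tree_b else
    ape::keep.tip(tree_b, shared)
  ka <- tree_bipartitions(a)
  kb <- tree_bipartitions(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}
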