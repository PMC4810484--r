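# Independent oracles used to check the dynamic-programming and pipeline
# implementations on small instances.

# --- exhaustive local alignment score: memoized full recursion ------------
# rec(i, j, s) = best score of a local alignment ending exactly at (i, j) in
# state s ("M" aligned pair, "X" gap consuming a_i, "Y" gap consuming b_j).
oracle_sw_score <- function(a, b, scoring = scoring_scheme()) {
  ai <- steromine:::encode_seq(a) + 1L
  bi <- steromine:::encode_seq(b) + 1L
  sub <- scoring$substitution
  og <- scoring$gap_open + scoring$gap_extend
  ge <- scoring$gap_extend
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, s) {
    if (i < 1 || j < 1) return(-Inf)
    key <- paste(i, j, s)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (s == "M") {
      sub[ai[i], bi[j]] +
        max(0, rec(i - 1, j - 1, "M"), rec(i - 1, j - 1, "X"),
            rec(i - 1, j - 1, "Y"))
    } else if (s == "X") {
      max(rec(i - 1, j, "M") - og, rec(i - 1, j, "X") - ge)
    } else {
      max(rec(i, j - 1, "M") - og, rec(i, j - 1, "Y") - ge)
    }
    memo[[key]] <- val
    val
  }
  best <- 0
  for (i in seq_along(ai)) for (j in seq_along(bi))
    best <- max(best, rec(i, j, "M"))
  best
}

# --- exhaustive path-sum forward probability ------------------------------
# Enumerates every state path through the Plan7-lite local architecture and
# sums path probabilities; returns log2 P(seq | model).
oracle_forward_logprob <- function(hmm, sequence) {
  x <- steromine:::encode_for_hmm(hmm, sequence) + 1L
  L <- length(x)
  eta <- L / (L + 2)
  tr <- hmm$transitions
  e <- hmm$match_emissions
  bg <- as.numeric(hmm$background)
  m <- hmm$n_match_states
  total <- 0
  go <- function(pos, state, k, p) {
    if (p == 0) return()
    if (state == "N") {
      if (pos < L) go(pos + 1, "N", 0, p * eta * bg[x[pos + 1]])
      go(pos, "B", 0, p * (1 - eta))
    } else if (state == "B") {
      if (pos < L)
        for (kk in seq_len(m))
          go(pos + 1, "M", kk, p * tr$entry[kk] * e[kk, x[pos + 1]])
    } else if (state == "M") {
      go(pos, "E", 0, p * tr$exitp[k])
      if (k < m) {
        if (pos < L) {
          go(pos + 1, "M", k + 1, p * tr$tMM[k] * e[k + 1, x[pos + 1]])
          go(pos + 1, "I", k, p * tr$tMI[k] * bg[x[pos + 1]])
        }
        go(pos, "D", k + 1, p * tr$tMD[k])
      }
    } else if (state == "I") {
      if (pos < L) {
        go(pos + 1, "I", k, p * tr$tII[k] * bg[x[pos + 1]])
        go(pos + 1, "M", k + 1, p * tr$tIM[k] * e[k + 1, x[pos + 1]])
      }
    } else if (state == "D") {
      if (k == m) {
        go(pos, "E", 0, p)
      } else {
        go(pos, "D", k + 1, p * tr$tDD[k])
        if (pos < L)
          go(pos + 1, "M", k + 1, p * tr$tDM[k] * e[k + 1, x[pos + 1]])
      }
    } else if (state == "E") {
      go(pos, "C", 0, p)
    } else if (state == "C") {
      if (pos == L) total <<- total + p * (1 - eta)
      else go(pos + 1, "C", 0, p * eta * bg[x[pos + 1]])
    }
  }
  go(0, "N", 0, 1)
  log2(total)
}

# --- step-by-step reference implementation of greedy clustering -----------
oracle_greedy <- function(proteins, min_identity = 0.5) {
  ord <- order(-nchar(proteins), names(proteins), method = "radix")
  ids <- names(proteins)[ord]
  seqs <- proteins[ord]
  clusters <- list()
  reps <- character(0)
  for (i in seq_along(ids)) {
    joined <- FALSE
    for (cl in seq_along(clusters)) {
      idy <- steromine:::global_identity(seqs[[i]], proteins[[reps[cl]]],
                                         denominator = "shorter")
      if (idy >= min_identity) {
        clusters[[cl]] <- c(clusters[[cl]], ids[i])
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      clusters[[length(clusters) + 1L]] <- ids[i]
      reps <- c(reps, ids[i])
    }
  }
  clusters
}

# --- transitive-closure connected components via boolean matrix powers ----
oracle_components <- function(nodes, edges) {
  n <- length(nodes)
  A <- diag(TRUE, n)
  dimnames(A) <- list(nodes, nodes)
  for (r in seq_len(nrow(edges))) {
    A[edges$a[r], edges$b[r]] <- TRUE
    A[edges$b[r], edges$a[r]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[A[i, ] > 0] <- cid
    }
  }
  groups <- split(nodes, comp)
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, `[`, character(1), 1))])
}

# --- explicit bipartition enumeration for Robinson-Foulds -----------------
oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  first_tip <- sort(tree$tip.label)[1]
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (!length(kids)) return(tree$tip.label[node])
    unlist(lapply(kids, desc))
  }
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= n) next
    side <- sort(desc(ch))
    other <- sort(setdiff(tree$tip.label, side))
    if (length(side) < 2 || length(other) < 2) next
    key <- if (first_tip %in% side) paste(side, collapse = "|") else
      paste(other, collapse = "|")
    out <- c(out, key)
  }
  unique(out)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# --- degrader decision rule, evaluated literally --------------------------
oracle_rule <- function(present, min_groups, mandatory_idx) {
  sum(present) >= min_groups && all(present[mandatory_idx])
}

# --- brute-force single-linkage gene clustering ---------------------------
# hits: integer gene indices (1-based) of located genes on one replicon
oracle_gene_clusters <- function(hits, n_total, circular, max_gap) {
  k <- length(hits)
  hits <- sort(hits)
  gap_between <- function(a, b) {
    lin <- abs(b - a) - 1L
    if (!circular) return(lin)
    min(lin, n_total - abs(b - a) - 1L)
  }
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    adj[i, j] <- gap_between(hits[i], hits[j]) <= max_gap
  reach <- adj | diag(k)
  repeat {
    r2 <- (reach %*% reach) > 0
    if (identical(r2, reach > 0)) break
    reach <- r2
  }
  comp <- rep(NA_integer_, k)
  cid <- 0
  for (i in seq_len(k)) if (is.na(comp[i])) {
    cid <- cid + 1
    comp[reach[i, ] > 0] <- cid
  }
  unname(lapply(split(hits, comp), sort))
}
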