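# Sequence evolution model for the synthetic-data generator: a reversible
# continuous-time Markov substitution process whose exchangeabilities are the
# BLOSUM62 implied target frequencies, so that simulated divergence stays
# commensurate with the scoring matrix used downstream, plus a simple
# Poisson indel process with geometric lengths.

#' Amino-acid evolution model
#'
#' Builds a reversible rate matrix `R` with off-diagonal rates
#' `R[a,b] = q[a,b] / p[a]` from the BLOSUM62 implied joint frequencies `q`
#' and marginals `p`, normalized to one expected substitution per site per
#' unit time. Branch transition matrices come from the spectral decomposition
#' of the symmetrized rate matrix.
#'
#' @param indel_rate expected indel events per site per unit divergence.
#' @param indel_length_mean geometric mean indel length (residues).
#' @param seed optional integer seed recorded on the model; operations that
#'   consume a model use the caller's RNG stream unless they take a seed
#'   themselves.
#' @return an object of class `evolution_model`.
#' @export
evolution_model <- function(indel_rate = 0.005, indel_length_mean = 3,
                            seed = NULL) {
  if (indel_rate < 0)
    smx_stop("steromine_parameter_error", "indel_rate must be >= 0")
  if (indel_length_mean < 1)
    smx_stop("steromine_parameter_error", "indel_length_mean must be >= 1")
  p <- background_frequencies()
  q <- blosum62_targets()
  R <- q / p  # rows: from-residue
  diag(R) <- 0
  diag(R) <- -rowSums(R)
  rate <- -sum(p * diag(R))
  R <- R / rate
  d2 <- sqrt(p)
  S <- diag(d2) %*% R %*% diag(1 / d2)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  structure(list(p = p, U = eig$vectors, lam = eig$values, d2 = d2,
                 indel_rate = indel_rate,
                 indel_length_mean = indel_length_mean, seed = seed),
            class = "evolution_model")
}

#' Branch transition matrix P(d) = expm(R d)
#' @param model an [evolution_model()].
#' @param d branch length in expected substitutions per site.
#' @return 20 x 20 row-stochastic matrix.
#' @export
transition_matrix <- function(model, d) {
  if (d < 0) smx_stop("steromine_parameter_error", "branch length must be >= 0")
  P <- diag(1 / model$d2) %*% (model$U %*% (exp(model$lam * d) * t(model$U))) %*%
    diag(model$d2)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Expected site identity after divergence d
#' @inheritParams transition_matrix
#' @return probability that a site carries the ancestral residue.
#' @export
expected_identity <- function(model, d) {
  sum(model$p * diag(transition_matrix(model, d)))
}

#' Divergence giving a target expected identity
#' @param model an [evolution_model()].
#' @param identity target site identity, above the model's chance floor.
#' @return branch length d with `expected_identity(model, d) == identity`.
#' @export
divergence_for_identity <- function(model, identity) {
  floor_id <- sum(model$p^2)
  if (identity >= 1) return(0)
  if (identity <= floor_id + 0.005)
    smx_stop("steromine_parameter_error",
             "target identity %.3f at or below the chance floor %.3f",
             identity, floor_id)
  uniroot(function(d) expected_identity(model, d) - identity,
          lower = 1e-6, upper = 60, tol = 1e-8)$root
}

# substitute residues of an encoded sequence along a branch of length d
mutate_residues <- function(seq_int, model, d) {
  if (d == 0) return(seq_int)
  P <- transition_matrix(model, d)
  out <- seq_int
  for (a in unique(seq_int)) {
    idx <- which(seq_int == a)
    if (a >= 20L) next  # X untouched
    out[idx] <- sample.int(20L, length(idx), replace = TRUE,
                           prob = P[a + 1L, ]) - 1L
  }
  out
}

# Poisson indel process; never shrinks a sequence below 10 residues
apply_indels <- function(seq_int, model, d) {
  if (d == 0 || model$indel_rate == 0) return(seq_int)
  n_ev <- rpois(1, model$indel_rate * length(seq_int) * d)
  if (n_ev == 0) return(seq_int)
  bg <- background_frequencies()
  for (i in seq_len(n_ev)) {
    len <- rgeom(1, 1 / model$indel_length_mean) + 1L
    L <- length(seq_int)
    if (runif(1) < 0.5) {  # insertion
      pos <- sample.int(L + 1L, 1) - 1L
      ins <- sample.int(20L, len, replace = TRUE, prob = bg) - 1L
      seq_int <- append(seq_int, ins, after = pos)
    } else if (L - len >= 10L) {  # deletion
      start <- sample.int(L - len + 1L, 1)
      seq_int <- seq_int[-(start:(start + len - 1L))]
    }
  }
  seq_int
}

#' Evolve a protein to a target percent identity
#'
#' Substitutes and indels the ancestor until the realized global-alignment
#' identity (identical pairs over alignment columns) lands within 0.05 of the
#' target, re-drawing with an adjusted divergence up to `max_retries` times.
#'
#' @param ancestor protein string, length >= 10.
#' @param target_identity fraction in (0.05, 1].
#' @param model an [evolution_model()].
#' @param max_retries redraw bound before failing.
#' @return descendant protein string with attribute `realized_identity`.
#' @export
evolve_sequence <- function(ancestor, target_identity,
                            model = evolution_model(), max_retries = 20) {
  if (!is.numeric(target_identity) || target_identity <= 0.05 ||
      target_identity > 1)
    smx_stop("steromine_parameter_error",
             "target_identity must lie in (0.05, 1]")
  anc <- encode_seq(ancestor, "ancestor")
  if (length(anc) < 10)
    smx_stop("steromine_parameter_error", "ancestor must have >= 10 residues")
  if (target_identity == 1)
    return(structure(ancestor, realized_identity = 1))
  d <- divergence_for_identity(model, max(target_identity, 0.12))
  realized <- NA_real_
  for (try in seq_len(max_retries)) {
    cand <- apply_indels(mutate_residues(anc, model, d), model, d)
    realized <- global_identity(anc, cand)
    if (abs(realized - target_identity) <= 0.05)
      return(structure(decode_seq(cand), realized_identity = realized))
    adj <- log(max(target_identity, 0.07)) / log(min(max(realized, 0.02), 0.98))
    d <- d * min(max(adj, 1 / 3), 3)
  }
  smx_stop("steromine_simulation_error",
           "could not reach identity %.2f after %d redraws (last realized %.3f)",
           target_identity, max_retries, realized)
}

#' Evolve labeled sequences along a phylogeny
#'
#' Walks the tree from the root, substituting (and optionally indeling) each
#' root sequence along every branch; zero-length branches transmit sequences
#' unchanged. Expected identity to the root decays monotonically with path
#' length.
#'
#' @param root_sequences named character vector of proteins at the root.
#' @param tree an `ape::phylo` with branch lengths (in expected substitutions
#'   per site after `scale`).
#' @param model an [evolution_model()].
#' @param scale multiplier applied to every branch length.
#' @param indels logical; apply the indel process along branches.
#' @return named list (one element per leaf) of named character vectors.
#' @export
evolve_along_tree <- function(root_sequences, tree, model = evolution_model(),
                              scale = 1, indels = TRUE) {
  if (!inherits(tree, "phylo"))
    smx_stop("steromine_input_error", "tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length))
    smx_stop("steromine_input_error", "tree has no branch lengths")
  if (any(tree$edge.length < 0))
    smx_stop("steromine_input_error", "negative branch lengths")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs_at <- vector("list", ntip + tree$Nnode)
  seqs_at[[root]] <- encode_many(root_sequences)
  for (e in edge_order_root_first(tree)) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    b <- tree$edge.length[e] * scale
    seqs_at[[child]] <- lapply(seqs_at[[parent]], function(s) {
      if (b == 0) return(s)
      s2 <- mutate_residues(s, model, b)
      if (indels) s2 <- apply_indels(s2, model, b) else s2
      s2
    })
  }
  out <- lapply(seq_len(ntip), function(i) {
    vapply(seqs_at[[i]], decode_seq, character(1))
  })
  names(out) <- tree$tip.label
  out
}

# edge indices ordered so every parent is visited before its children
# (breadth-first from the root; plain R)
edge_order_root_first <- function(tree) {
  root <- length(tree$tip.label) + 1L
  ord <- integer(0)
  frontier <- root
  remaining <- seq_len(nrow(tree$edge))
  while (length(frontier)) {
    hit <- remaining[tree$edge[remaining, 1] %in% frontier]
    if (!length(hit)) break
    ord <- c(ord, hit)
    frontier <- tree$edge[hit, 2]
    remaining <- setdiff(remaining, hit)
  }
  ord
}

# root-to-tip path lengths (plain R)
tip_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  depth <- numeric(ntip + tree$Nnode)
  for (e in edge_order_root_first(tree)) {
    depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + tree$edge.length[e]
  }
  setNames(depth[seq_len(ntip)], tree$tip.label)
}
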