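# Progressive multiple alignment for HMM training sets and marker blocks:
# k-mer distances -> average-linkage guide tree -> profile-profile alignment
# with affine gaps, where column-against-column scores are the expected
# BLOSUM62 score between the two frequency profiles (gap mass scores zero,
# which down-weights gappy columns).

aln_matrix <- function(seqs) {
  rows <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  m <- do.call(rbind, rows)
  rownames(m) <- names(seqs)
  m
}

# residue-frequency profile of an alignment (ncol x 20, gaps contribute 0)
profile_freqs <- function(aln) {
  F <- matrix(0, ncol(aln), 20L)
  for (a in seq_along(AA_ALPHABET))
    F[, a] <- colSums(aln == AA_ALPHABET[a])
  F / nrow(aln)
}

#' Progressive multiple alignment
#'
#' Aligns sequences progressively along an average-linkage guide tree built
#' from shared 3-mer distances; profiles are merged by affine-gap global
#' alignment of their column-frequency vectors under BLOSUM62 expected
#' scores. A refinement pass rebuilds the guide tree from the realized
#' pairwise identities of the first alignment and realigns, keeping
#' whichever alignment has the better sum-of-pairs score.
#'
#' @param sequences named character vector; a single sequence is returned
#'   unchanged as a one-row alignment.
#' @param scoring a [scoring_scheme()] supplying substitution scores and gap
#'   penalties.
#' @param refine logical; run the tree-refinement pass.
#' @return character matrix (rows = sequences, columns = alignment columns,
#'   gap = `"-"`), class `multiple_alignment`.
#' @export
progressive_align <- function(sequences, scoring = scoring_scheme(),
                              refine = TRUE) {
  check_proteome(sequences, min_n = 1)
  n <- length(sequences)
  if (n == 1L) {
    m <- aln_matrix(sequences)
    class(m) <- c("multiple_alignment", class(m))
    return(m)
  }
  enc <- encode_many(sequences)
  words <- lapply(enc, kmer_set, k = 3)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(words[[i]], words[[j]]))
    D[i, j] <- D[j, i] <-
      1 - shared / max(1, min(length(words[[i]]), length(words[[j]])))
  }
  out <- align_with_tree(sequences, D, scoring)
  if (refine && n > 2) {
    D2 <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- out[names(sequences)[i], ]; b <- out[names(sequences)[j], ]
      shared <- a != "-" & b != "-"
      idy <- if (any(shared)) mean(a[shared] == b[shared]) else 0
      D2[i, j] <- D2[j, i] <- 1 - idy
    }
    out2 <- align_with_tree(sequences, D2, scoring)
    if (sum_of_pairs(out2, scoring) > sum_of_pairs(out, scoring)) out <- out2
  }
  class(out) <- c("multiple_alignment", class(out))
  out
}

align_with_tree <- function(sequences, D, scoring) {
  n <- length(sequences)
  hc <- hclust(as.dist(D), method = "average")
  profs <- lapply(seq_len(n), function(i) aln_matrix(sequences[i]))
  merged <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0) profs[[-x]] else merged[[x]]
    merged[[k]] <- align_profiles(pick(hc$merge[k, 1]), pick(hc$merge[k, 2]),
                                  scoring)
  }
  out <- merged[[nrow(hc$merge)]]
  out[names(sequences)[names(sequences) %in% rownames(out)], , drop = FALSE]
}

align_profiles <- function(A, B, scoring) {
  sub <- scoring$substitution[1:20, 1:20]
  S <- profile_freqs(A) %*% sub %*% t(profile_freqs(B))
  p <- nw_path_cpp(S, scoring$gap_open, scoring$gap_extend)
  ncolout <- length(p$a)
  out <- matrix("-", nrow(A) + nrow(B), ncolout)
  rownames(out) <- c(rownames(A), rownames(B))
  ia <- p$a > 0
  out[seq_len(nrow(A)), ia] <- A[, p$a[ia], drop = FALSE]
  ib <- p$b > 0
  out[nrow(A) + seq_len(nrow(B)), ib] <- B[, p$b[ib], drop = FALSE]
  out
}

#' Per-column gap fractions of an alignment
#' @param alignment a character alignment matrix.
#' @return numeric vector over columns.
#' @export
gap_fraction <- function(alignment) {
  colMeans(alignment == "-")
}

#' Trim gappy alignment columns
#'
#' Automated surrogate for manual alignment trimming: retains exactly the
#' columns whose gap fraction is `<= max_gap_fraction`, preserving order.
#'
#' @param alignment a character alignment matrix.
#' @param max_gap_fraction columns with a larger gap fraction are removed.
#' @return the trimmed alignment; errors if no column survives.
#' @export
trim_columns <- function(alignment, max_gap_fraction = 0.5) {
  keep <- gap_fraction(alignment) <= max_gap_fraction
  if (!any(keep))
    smx_stop("steromine_analysis_error",
             "trimming removed every alignment column")
  out <- alignment[, keep, drop = FALSE]
  class(out) <- unique(c("multiple_alignment", class(out)))
  out
}

#' Sum-of-pairs score of an alignment
#'
#' Diagnostic alignment quality score: substitution scores summed over all
#' row pairs and columns, with residue-gap pairs scoring `-gap_cost` and
#' gap-gap pairs 0.
#'
#' @param alignment character alignment matrix.
#' @param scoring a [scoring_scheme()].
#' @param gap_cost per-column residue-against-gap penalty.
#' @return numeric score.
#' @export
sum_of_pairs <- function(alignment, scoring = scoring_scheme(), gap_cost = 2) {
  sub <- scoring$substitution
  letters21 <- c(AA_ALPHABET, "X")
  n <- nrow(alignment)
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- alignment[i, ]; b <- alignment[j, ]
    ga <- a == "-"; gb <- b == "-"
    both <- !ga & !gb
    total <- total + sum(sub[cbind(match(a[both], letters21),
                                   match(b[both], letters21))]) -
      gap_cost * sum(xor(ga, gb))
  }
  total
}

check_alignment <- function(alignment) {
  if (!is.matrix(alignment) || !is.character(alignment))
    smx_stop("steromine_input_error", "alignment must be a character matrix")
  invisible(TRUE)
}
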