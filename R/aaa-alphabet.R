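# Amino-acid alphabet, substitution matrix and background frequencies shared
# by every module. The canonical 20-letter alphabet is alphabetical; X is the
# ambiguity letter, encoded as index 20 (0-based) and scored 0 everywhere.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

smx_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "steromine_error")))
}

#' BLOSUM62 substitution scores over the package alphabet
#'
#' Returns the 21 x 21 integer score matrix used throughout: the BLOSUM62
#' matrix shipped with Biostrings, reordered to the package's alphabetical
#' amino-acid order, with the ambiguity letter X scored 0 against everything.
#'
#' @return numeric matrix with dimnames over `c(AA_ALPHABET, "X")`.
#' @export
blosum62_matrix <- function() {
  if (!is.null(.steromine_env$blosum62)) return(.steromine_env$blosum62)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  m <- matrix(0, 21L, 21L, dimnames = list(c(AA_ALPHABET, "X"),
                                           c(AA_ALPHABET, "X")))
  m[1:20, 1:20] <- b
  .steromine_env$blosum62 <- m
  m
}

#' Background amino-acid frequencies
#'
#' The Robinson & Robinson residue frequencies, the standard protein-search
#' background model; used for null sequences, pseudocounts and the
#' substitution process.
#'
#' @return named numeric vector of length 20 summing to 1.
#' @export
background_frequencies <- function() {
  if (!is.null(.steromine_env$bg)) return(.steromine_env$bg)
  p <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
         Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
         L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
         S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  p <- p[AA_ALPHABET]
  p <- p / sum(p)
  .steromine_env$bg <- p
  p
}

# Joint substitution target frequencies compatible with BLOSUM62: scores are
# rounded half-bit log-odds s_ab ~ 2 log2(q_ab / (p_a p_b)), so
# q_ab is proportional to p_a p_b 2^(s_ab / 2); symmetrized and normalized.
blosum62_targets <- function() {
  p <- background_frequencies()
  s <- blosum62_matrix()[1:20, 1:20]
  q <- outer(p, p) * 2^(s / 2)
  q <- (q + t(q)) / 2
  q / sum(q)
}

# encode a protein string to 0-based alphabet indices (X and any ambiguity
# letter not in the 20-letter alphabet -> 20)
encode_seq <- function(x, what = "sequence") {
  if (length(x) != 1L || !is.character(x) || is.na(x) || nchar(x) == 0L)
    smx_stop("steromine_input_error", "%s must be a non-empty string", what)
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(ch, AA_ALPHABET)
  bad <- is.na(idx) & !ch %in% c("X", "B", "Z", "J", "U", "O", "*")
  if (any(bad))
    smx_stop("steromine_input_error", "illegal residue '%s' in %s",
             ch[which(bad)[1]], what)
  idx[is.na(idx)] <- 21L
  as.integer(idx - 1L)
}

decode_seq <- function(idx) {
  paste(c(AA_ALPHABET, "X")[idx + 1L], collapse = "")
}

encode_many <- function(seqs) lapply(seqs, encode_seq)

#' Draw a random protein sequence from background frequencies
#'
#' @param length residue count.
#' @return a protein string.
#' @export
random_protein <- function(length) {
  if (length < 1) smx_stop("steromine_parameter_error", "length must be >= 1")
  paste(sample(AA_ALPHABET, length, replace = TRUE,
               prob = background_frequencies()), collapse = "")
}

# deterministic derived sub-seed, kept below 2^31
subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1013904223 * k) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
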