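# Plan7-lite profile hidden Markov models, built from trimmed subcluster
# alignments and scored by the all-path forward algorithm in log-odds bits
# against an i.i.d. background null. Architecture: N -> B -> (M/I/D chain)
# -> E -> C with self-looping background flanks N and C handling local
# alignment; uniform entry over match states, a constant per-state exit
# probability, and insert emissions equal to the background (so insert
# emission odds cancel). E-values come from a per-model Gumbel tail fitted
# to forward scores of seeded random sequences.

#' Construct a profile HMM directly from parameters
#'
#' Low-level constructor; most users build models from alignments with
#' [build_profile()]. Emission rows and each outgoing-transition set must sum
#' to one (tolerance 1e-9).
#'
#' @param match_emissions m x A matrix of match-state emission probabilities.
#' @param transitions list with vectors `tMM`, `tMI`, `tMD`, `tIM`, `tII`,
#'   `tDM`, `tDD` (length m, indexed by source state; entries for the last
#'   state unused), `entry` (B to match k) and `exitp` (match k to E).
#' @param background length-A background vector (also the insert emissions).
#' @param alphabet character vector of residue letters (default the
#'   20-letter amino-acid alphabet).
#' @param source_subcluster optional id of the training subcluster.
#' @return object of class `profile_hmm` (uncalibrated).
#' @export
profile_hmm <- function(match_emissions, transitions, background,
                        alphabet = AA_ALPHABET, source_subcluster = NULL) {
  m <- nrow(match_emissions)
  if (is.null(m) || m < 1)
    smx_stop("steromine_parameter_error", "need >= 1 match state")
  if (ncol(match_emissions) != length(alphabet) ||
      length(background) != length(alphabet))
    smx_stop("steromine_parameter_error", "emission/alphabet size mismatch")
  if (max(abs(rowSums(match_emissions) - 1)) > 1e-9)
    smx_stop("steromine_parameter_error", "emission rows must sum to 1")
  if (abs(sum(background) - 1) > 1e-9)
    smx_stop("steromine_parameter_error", "background must sum to 1")
  tr <- transitions
  msum <- tr$tMM + tr$tMI + tr$tMD + tr$exitp
  if ((m > 1 && max(abs(msum[-m] - 1)) > 1e-9) ||
      abs(tr$exitp[m] - 1) > 1e-9)
    smx_stop("steromine_parameter_error",
             "match transition rows must sum to 1 (exit included)")
  if (m > 1 && max(abs((tr$tIM + tr$tII)[-m] - 1)) > 1e-9)
    smx_stop("steromine_parameter_error", "insert transitions must sum to 1")
  if (m > 1 && max(abs((tr$tDM + tr$tDD)[-m] - 1)) > 1e-9)
    smx_stop("steromine_parameter_error", "delete transitions must sum to 1")
  if (abs(sum(tr$entry) - 1) > 1e-9)
    smx_stop("steromine_parameter_error", "entry must sum to 1")
  structure(list(n_match_states = m, match_emissions = match_emissions,
                 transitions = tr, background = background,
                 alphabet = alphabet, gumbel = NULL,
                 source_subcluster = source_subcluster),
            class = "profile_hmm")
}

#' Build a profile HMM from a multiple alignment
#'
#' Columns with gap fraction `< 0.5` become match states. Match emissions are
#' residue counts plus `pseudocount_weight` background-distributed
#' pseudocounts, normalized; transitions are counted from each row's state
#' path through the match/insert/delete architecture with Laplace (+1)
#' smoothing. Local-alignment entry is uniform over match states and each
#' match state exits to the end state with probability `1/(m+1)` (the last
#' with probability 1).
#'
#' @param alignment character alignment matrix with >= 2 rows.
#' @param pseudocount_weight total background pseudocount mass added to each
#'   match column; default `20 / (n_rows + 20)`.
#' @return an uncalibrated `profile_hmm`.
#' @export
build_profile <- function(alignment, pseudocount_weight = NULL) {
  check_alignment(alignment)
  n <- nrow(alignment)
  if (n < 2)
    smx_stop("steromine_input_error", "need an alignment with >= 2 rows")
  W <- pseudocount_weight %||% (20 / (n + 20))
  if (W < 0) smx_stop("steromine_parameter_error",
                      "pseudocount_weight must be >= 0")
  gf <- gap_fraction(alignment)
  is_match <- gf < 0.5
  m <- sum(is_match)
  if (m == 0)
    smx_stop("steromine_analysis_error",
             "no alignment column qualifies as a match state")
  bg <- background_frequencies()

  # emissions
  E <- matrix(0, m, 20L, dimnames = list(NULL, AA_ALPHABET))
  mcols <- which(is_match)
  for (k in seq_len(m)) {
    cnt <- table(factor(alignment[, mcols[k]], levels = AA_ALPHABET))
    E[k, ] <- (as.numeric(cnt) + W * bg) / (sum(cnt) + W)
  }
  E <- E / rowSums(E)

  # transition counts from per-row state paths
  cMM <- cMI <- cMD <- cIM <- cII <- cDM <- cDD <- rep(0, m)
  for (r in seq_len(n)) {
    k <- 0L
    prev <- "B"      # previous non-silent-path state at current k
    for (j in seq_len(ncol(alignment))) {
      res <- alignment[r, j] != "-"
      if (is_match[j]) {
        state <- if (res) "M" else "D"
        if (k >= 1) {
          if (prev == "M" && state == "M") cMM[k] <- cMM[k] + 1
          if (prev == "M" && state == "D") cMD[k] <- cMD[k] + 1
          if (prev == "I" && state == "M") cIM[k] <- cIM[k] + 1
          if (prev == "I" && state == "D") cIM[k] <- cIM[k] + 1  # I->D folded into I->M
          if (prev == "D" && state == "M") cDM[k] <- cDM[k] + 1
          if (prev == "D" && state == "D") cDD[k] <- cDD[k] + 1
        }
        k <- k + 1L
        prev <- state
      } else if (res) {
        if (k >= 1 && k < m) {
          if (prev == "M") cMI[k] <- cMI[k] + 1
          if (prev == "I") cII[k] <- cII[k] + 1
          if (prev == "D") cDM[k] <- cDM[k] + 0  # D->I unsupported, ignored
          prev <- "I"
        }
      }
    }
  }
  lap <- function(a, b) {  # Laplace-smoothed two-way split
    tot <- a + b + 2
    (a + 1) / tot
  }
  exitp <- c(rep(1 / (m + 1), max(0, m - 1)), 1)
  pMM <- pMI <- pMD <- rep(0, m)
  if (m > 1) {
    for (k in seq_len(m - 1)) {
      tot <- cMM[k] + cMI[k] + cMD[k] + 3
      core <- c(cMM[k] + 1, cMI[k] + 1, cMD[k] + 1) / tot
      pMM[k] <- core[1] * (1 - exitp[k])
      pMI[k] <- core[2] * (1 - exitp[k])
      pMD[k] <- core[3] * (1 - exitp[k])
    }
  }
  tIM <- c(vapply(seq_len(max(0, m - 1)), function(k) lap(cIM[k], cII[k]),
                  numeric(1)), 1)
  tII <- 1 - tIM
  tDM <- c(vapply(seq_len(max(0, m - 1)), function(k) lap(cDM[k], cDD[k]),
                  numeric(1)), 1)
  tDD <- 1 - tDM
  if (m == 1) { tIM <- 1; tII <- 0; tDM <- 1; tDD <- 0 }
  profile_hmm(E,
              list(tMM = pMM, tMI = pMI, tMD = pMD, tIM = tIM, tII = tII,
                   tDM = tDM, tDD = tDD, entry = rep(1 / m, m),
                   exitp = exitp),
              background = bg,
              source_subcluster = attr(alignment, "subcluster_id"))
}

encode_for_hmm <- function(hmm, sequence) {
  if (identical(hmm$alphabet, AA_ALPHABET)) return(encode_seq(sequence))
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(ch, hmm$alphabet)
  if (anyNA(idx))
    smx_stop("steromine_input_error", "residue outside the model alphabet")
  as.integer(idx - 1L)
}

hmm_cpp_args <- function(hmm) {
  tr <- hmm$transitions
  list(ematch = hmm$match_emissions, bg = as.numeric(hmm$background),
       tMM = tr$tMM, tMI = tr$tMI, tMD = tr$tMD, tIM = tr$tIM, tII = tr$tII,
       tDM = tr$tDM, tDD = tr$tDD, entry = tr$entry, exitp = tr$exitp)
}

#' Forward log-odds score of a sequence under a profile HMM
#'
#' All-path forward score `log2(P(seq | hmm) / P(seq | null))`, where the
#' null emits residues i.i.d. from the background with the same geometric
#' length factor as the model's flanking states (`eta = L / (L + 2)`).
#'
#' @param hmm a `profile_hmm`.
#' @param sequence protein string over the model alphabet.
#' @return log-odds score in bits.
#' @export
forward_score <- function(hmm, sequence) {
  s <- encode_for_hmm(hmm, sequence)
  if (!length(s)) smx_stop("steromine_input_error", "empty sequence")
  a <- hmm_cpp_args(hmm)
  eta <- length(s) / (length(s) + 2)
  do.call(forward_cpp, c(list(seq = s), a, list(eta = eta)))
}

#' Viterbi (best single path) log-odds score
#' @inheritParams forward_score
#' @return log-odds score in bits; never exceeds [forward_score()].
#' @export
viterbi_score <- function(hmm, sequence) {
  s <- encode_for_hmm(hmm, sequence)
  a <- hmm_cpp_args(hmm)
  eta <- length(s) / (length(s) + 2)
  do.call(viterbi_cpp, c(list(seq = s), a, list(eta = eta)))
}

#' Total model probability of a sequence
#'
#' `log2 P(seq | hmm)` with all-path summation, i.e. the forward log-odds
#' plus the null probability of the sequence (background emissions and the
#' geometric length factor). Used by enumeration and probability-conservation
#' checks.
#'
#' @inheritParams forward_score
#' @return log2 probability.
#' @export
forward_logprob <- function(hmm, sequence) {
  s <- encode_for_hmm(hmm, sequence)
  L <- length(s)
  eta <- L / (L + 2)
  bits <- forward_score(hmm, sequence)
  null_log2 <- sum(log2(hmm$background[s + 1L])) + L * log2(eta) +
    log2(1 - eta)
  bits + null_log2
}

#' Calibrate a profile HMM's E-value scale
#'
#' Scores `n_random` seeded random background sequences and fits a Gumbel
#' law to the forward scores by maximum likelihood. E-values are then
#' `database_size * P_gumbel(score' >= score)`.
#'
#' @param hmm a `profile_hmm`.
#' @param n_random number of null sequences (>= 1000).
#' @param length_distribution function(n) returning n sequence lengths;
#'   default: lognormal around 1.1 x model length, floored at 30.
#' @param seed RNG seed.
#' @return the model with its `gumbel` slot set.
#' @export
calibrate_evalue <- function(hmm, n_random = 1000, length_distribution = NULL,
                             seed = 1) {
  if (n_random < 1000)
    smx_stop("steromine_parameter_error", "n_random must be >= 1000")
  set.seed(seed)
  m <- hmm$n_match_states
  lens <- if (is.null(length_distribution))
    pmax(30, round(rlnorm(n_random, log(1.1 * m + 30), 0.25)))
  else length_distribution(n_random)
  A <- length(hmm$alphabet)
  seqs <- lapply(lens, function(L)
    sample.int(A, L, replace = TRUE, prob = hmm$background) - 1L)
  a <- hmm_cpp_args(hmm)
  scores <- do.call(forward_batch_cpp,
                    c(list(seqs = seqs), a,
                      list(etas = lens / (lens + 2))))
  g <- fit_gumbel(scores)
  hmm$gumbel <- list(mu = g$mu, lambda = g$lambda, n_random = n_random,
                     seed = seed)
  hmm
}

#' Gumbel-tail E-value for a forward score
#' @param hmm calibrated `profile_hmm`.
#' @param score forward log-odds score (bits).
#' @param database_size number of sequences in the screened database.
#' @return non-negative E-value, strictly decreasing in `score` and exactly
#'   linear in `database_size`.
#' @export
hmm_evalue <- function(hmm, score, database_size) {
  if (is.null(hmm$gumbel))
    smx_stop("steromine_calibration_error",
             "profile HMM is not calibrated; run calibrate_evalue()")
  z <- hmm$gumbel$lambda * (score - hmm$gumbel$mu)
  database_size * (-expm1(-exp(-z)))
}

#' Screen a proteome with a set of calibrated profile HMMs
#'
#' Scores every (model, protein) pair by the forward algorithm and keeps the
#' pairs whose E-value (database size = number of proteins screened) is at
#' most `max_evalue`.
#'
#' @param hmms named list of calibrated `profile_hmm` objects.
#' @param proteome named character vector of proteins.
#' @param max_evalue screening threshold (default 1e-25).
#' @param genome_id id stamped on the hits for downstream aggregation.
#' @return data frame (`hmm_id`, `protein_id`, `genome_id`, `bits`,
#'   `evalue`), one row per passing pair.
#' @export
screen_proteome <- function(hmms, proteome, max_evalue = 1e-25,
                            genome_id = NA_character_) {
  if (is.null(names(hmms)) && length(hmms))
    names(hmms) <- sprintf("hmm_%03d", seq_along(hmms))
  for (h in hmms)
    if (is.null(h$gumbel))
      smx_stop("steromine_calibration_error",
               "all HMMs must be calibrated before screening")
  check_proteome(proteome)
  lens <- nchar(proteome)
  etas <- lens / (lens + 2)
  enc <- encode_many(proteome)
  nseq <- length(proteome)
  out <- list()
  for (hid in names(hmms)) {
    hmm <- hmms[[hid]]
    a <- hmm_cpp_args(hmm)
    bits <- do.call(forward_batch_cpp,
                    c(list(seqs = enc), a, list(etas = etas)))
    ev <- hmm_evalue(hmm, bits, nseq)
    keep <- which(ev <= max_evalue)
    if (length(keep))
      out[[length(out) + 1L]] <- data.frame(
        hmm_id = hid, protein_id = names(proteome)[keep],
        genome_id = genome_id, bits = bits[keep], evalue = ev[keep])
  }
  if (!length(out))
    return(data.frame(hmm_id = character(), protein_id = character(),
                      genome_id = character(), bits = numeric(),
                      evalue = numeric()))
  do.call(rbind, out)
}

#' Serialize a profile HMM to a self-describing text format
#' @param hmm a `profile_hmm`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_hmm <- function(hmm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("STEROMINE-HMM 1")
  w("NMATCH %d", hmm$n_match_states)
  w("ALPHABET %s", paste(hmm$alphabet, collapse = ""))
  w("SOURCE %s", hmm$source_subcluster %||% "-")
  w("BACKGROUND %s", paste(format(hmm$background, digits = 10),
                           collapse = " "))
  for (k in seq_len(hmm$n_match_states))
    w("MATCH %d %s", k, paste(format(hmm$match_emissions[k, ], digits = 10),
                              collapse = " "))
  for (nm in c("tMM", "tMI", "tMD", "tIM", "tII", "tDM", "tDD", "entry",
               "exitp"))
    w("TRANS %s %s", nm, paste(format(hmm$transitions[[nm]], digits = 10),
                               collapse = " "))
  if (!is.null(hmm$gumbel))
    w("GUMBEL %.10g %.10g %d", hmm$gumbel$mu, hmm$gumbel$lambda,
      hmm$gumbel$n_random)
  w("END")
  invisible(path)
}

#' Read a profile HMM written by [write_profile_hmm()]
#' @param path input file.
#' @return a `profile_hmm`.
#' @export
read_profile_hmm <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "STEROMINE-HMM"))
    smx_stop("steromine_input_error", "not a steromine HMM file: %s", path)
  field <- function(key) {
    l <- lines[startsWith(lines, paste0(key, " "))]
    sub(paste0("^", key, " "), "", l)
  }
  m <- as.integer(field("NMATCH"))
  alphabet <- strsplit(field("ALPHABET"), "")[[1]]
  bg <- as.numeric(strsplit(field("BACKGROUND"), " +")[[1]])
  names(bg) <- alphabet
  E <- matrix(0, m, length(alphabet))
  for (l in field("MATCH")) {
    v <- strsplit(l, " +")[[1]]
    E[as.integer(v[1]), ] <- as.numeric(v[-1])
  }
  tr <- list()
  for (l in field("TRANS")) {
    v <- strsplit(l, " +")[[1]]
    tr[[v[1]]] <- as.numeric(v[-1])
  }
  src <- field("SOURCE")
  hmm <- profile_hmm(E, tr, bg, alphabet,
                     source_subcluster = if (src == "-") NULL else src)
  gl <- field("GUMBEL")
  if (length(gl)) {
    v <- as.numeric(strsplit(gl, " +")[[1]])
    hmm$gumbel <- list(mu = v[1], lambda = v[2], n_random = as.integer(v[3]))
  }
  hmm
}
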