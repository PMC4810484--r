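# Progressive alignment, trimming, profile construction, forward scoring
# and Gumbel E-value calibration.

test_that("identical sequences align gap-free", {
  s <- "ACDEFGHIKLMNP"
  aln <- progressive_align(c(a = s, b = s))
  expect_equal(dim(aln), c(2L, 13L))
  expect_false(any(aln == "-"))
})

test_that("an internal deletion becomes one contiguous gap block", {
  set.seed(71)
  a <- random_protein(80)
  b <- paste0(substr(a, 1, 40), substr(a, 46, 80))
  aln <- progressive_align(c(a = a, b = b))
  expect_equal(ncol(aln), 80L)
  gaps <- which(aln["b", ] == "-")
  expect_equal(length(gaps), 5L)
  expect_equal(gaps, seq(min(gaps), min(gaps) + 4L))
  expect_false(any(aln["a", ] == "-"))
})

test_that("guide-tree order beats typical random merge orders", {
  # two tight subfamilies plus an outlier: merge order matters here
  set.seed(70)
  anc <- random_protein(140)
  a <- as.character(evolve_sequence(anc, 0.55))
  b <- as.character(evolve_sequence(anc, 0.55))
  fam <- c(s1 = as.character(evolve_sequence(a, 0.9)),
           s2 = as.character(evolve_sequence(a, 0.9)),
           s3 = as.character(evolve_sequence(b, 0.9)),
           s4 = as.character(evolve_sequence(b, 0.9)),
           s5 = as.character(evolve_sequence(anc, 0.5)))
  sp_guide <- sum_of_pairs(progressive_align(fam))
  set.seed(72)
  sp_rand <- vapply(1:20, function(i) {
    # same merge machinery under an uninformed random guide tree
    D <- matrix(0, 5, 5)
    D[lower.tri(D)] <- runif(10)
    D <- D + t(D)
    sum_of_pairs(steromine:::align_with_tree(fam, D, scoring_scheme()))
  }, numeric(1))
  expect_gte(sp_guide, mean(sp_rand))
})

test_that("trimming keeps exactly the sparse-gap columns", {
  aln <- rbind(a = c("A", "C", "-", "D"),
               b = c("A", "-", "-", "D"),
               c = c("A", "-", "-", "D"),
               d = c("A", "C", "C", "D"))
  tr <- trim_columns(aln, 0.5)
  expect_equal(ncol(tr), 3L)   # column 3 has 3/4 gaps
  expect_identical(tr[, 2], c(a = "C", b = "-", c = "-", d = "C"))
  gapfree <- progressive_align(c(x = "ACD", y = "ACD"))
  expect_identical(dim(trim_columns(gapfree)), dim(gapfree))
  allgap <- rbind(a = c("-", "-"), b = c("-", "-"), c = c("A", "-"))
  expect_error(trim_columns(allgap, 0.2),
               class = "steromine_analysis_error")
})

test_that("trimming equals a brute-force per-column scan on random cases", {
  set.seed(73)
  for (rep in 1:10) {
    nr <- sample(2:10, 1); nc <- sample(2:10, 1)
    aln <- matrix(sample(c("A", "C", "G", "-"), nr * nc, replace = TRUE,
                         prob = c(.3, .3, .2, .2)), nr, nc)
    rownames(aln) <- paste0("r", seq_len(nr))
    thr <- runif(1, 0.2, 0.8)
    keep <- vapply(seq_len(nc), function(j)
      sum(aln[, j] == "-") / nr <= thr, logical(1))
    if (!any(keep)) next
    expect_identical(trim_columns(aln, thr),
                     structure(aln[, keep, drop = FALSE],
                               class = c("multiple_alignment", "matrix",
                                         "array")))
  }
})

test_that("profiles from identical rows are deterministic emitters", {
  aln <- rbind(a = c("A", "C", "D"), b = c("A", "C", "D"))
  hmm <- build_profile(aln, pseudocount_weight = 0)
  expect_equal(hmm$n_match_states, 3L)
  expect_equal(unname(hmm$match_emissions[1, "A"]), 1)
  expect_equal(unname(hmm$match_emissions[2, "C"]), 1)
  # heavy pseudocounts pull emissions to the background
  hmm_bg <- build_profile(aln, pseudocount_weight = 1e8)
  expect_lt(max(abs(hmm_bg$match_emissions[1, ] -
                      background_frequencies())), 1e-6)
})

test_that("transition training matches hand enumeration on a toy fixture", {
  aln <- rbind(r1 = c("A", "C", "D"), r2 = c("A", "C", "D"),
               r3 = c("A", "-", "D"), r4 = c("A", "-", "D"))
  hmm <- build_profile(aln)
  # column 2 has gap fraction 0.5 (not < 0.5): insert column, so m = 2;
  # paths: two rows M1 -> I1 -> M2, two rows M1 -> M2
  expect_equal(hmm$n_match_states, 2L)
  exit1 <- 1 / 3
  expect_equal(hmm$transitions$tMM[1], (2 + 1) / 7 * (1 - exit1))
  expect_equal(hmm$transitions$tMI[1], (2 + 1) / 7 * (1 - exit1))
  expect_equal(hmm$transitions$tMD[1], (0 + 1) / 7 * (1 - exit1))
  expect_equal(hmm$transitions$tIM[1], (2 + 1) / 4)
  expect_equal(hmm$transitions$exitp, c(exit1, 1))
  allgap_matches <- rbind(a = c("-", "A"), b = c("A", "-"))
  expect_error(build_profile(allgap_matches),
               class = "steromine_analysis_error")
})

test_that("forward probability equals exhaustive path enumeration", {
  hmm <- toy_hmm(2)
  for (s in c("A", "C", "AC", "CA", "AAC", "CCC", "ACAC")) {
    expect_equal(forward_logprob(hmm, s), oracle_forward_logprob(hmm, s),
                 tolerance = 1e-10, info = s)
  }
  hmm3 <- toy_hmm(3)
  for (s in c("AC", "ACA", "CACA"))
    expect_equal(forward_logprob(hmm3, s), oracle_forward_logprob(hmm3, s),
                 tolerance = 1e-10, info = s)
})

test_that("total probability over short sequences is conserved", {
  hmm <- toy_hmm(2)
  seqs <- unlist(lapply(1:3, function(L)
    apply(expand.grid(rep(list(c("A", "C")), L)), 1, paste, collapse = "")))
  dp_mass <- sum(vapply(seqs, function(s) 2^forward_logprob(hmm, s),
                        numeric(1)))
  oracle_mass <- sum(vapply(seqs, function(s)
    2^oracle_forward_logprob(hmm, s), numeric(1)))
  expect_equal(dp_mass, oracle_mass, tolerance = 1e-10)
})

test_that("a fully deterministic model matches its closed form", {
  tr <- list(tMM = c(1, 0), tMI = c(0, 0), tMD = c(0, 0),
             tIM = c(1, 1), tII = c(0, 0), tDM = c(1, 1), tDD = c(0, 0),
             entry = c(1, 0), exitp = c(0, 1))
  E <- rbind(c(1, 0), c(0, 1))
  hmm <- profile_hmm(E, tr, background = c(0.5, 0.5),
                     alphabet = c("A", "C"))
  L <- 2; eta <- L / (L + 2)
  # single path N->B->M1(A)->M2(C)->E->C->T
  expect_equal(forward_logprob(hmm, "AC"),
               log2((1 - eta)^2), tolerance = 1e-12)
  expect_equal(2^forward_logprob(hmm, "CA"), 0)
})

test_that("all-path score dominates the single best path", {
  fam <- toy_family()
  hmm <- build_profile(trim_columns(progressive_align(fam)))
  for (s in c(fam[[1]], random_protein(100)))
    expect_gte(forward_score(hmm, s), viterbi_score(hmm, s))
})

test_that("family members outscore their shuffles almost always", {
  set.seed(74)
  fam <- toy_family()
  hmm <- build_profile(trim_columns(progressive_align(fam)))
  intact <- forward_score(hmm, fam[[1]])
  letters1 <- strsplit(fam[[1]], "")[[1]]
  wins <- vapply(1:100, function(i)
    intact > forward_score(hmm, paste(sample(letters1), collapse = "")),
    logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("Gumbel calibration is seeded, stable, and sane at the median", {
  fam <- toy_family()
  hmm <- build_profile(trim_columns(progressive_align(fam)))
  expect_error(calibrate_evalue(hmm, n_random = 10),
               class = "steromine_parameter_error")
  c1 <- calibrate_evalue(hmm, 1000, seed = 5)
  c2 <- calibrate_evalue(hmm, 1000, seed = 5)
  expect_identical(c1$gumbel, c2$gumbel)
  # E-value at the median calibration score ~ n/2
  set.seed(5)
  lens <- pmax(30, round(rlnorm(1000, log(1.1 * hmm$n_match_states + 30),
                                0.25)))
  seqs <- vapply(lens, function(L) paste(
    sample(names(background_frequencies()), L, replace = TRUE,
           prob = background_frequencies()), collapse = ""), character(1))
  scores <- vapply(seqs, function(s) forward_score(c1, s), numeric(1))
  e_med <- hmm_evalue(c1, median(scores), 1000)
  expect_gt(e_med, 1000 / 2 / 1.5)
  expect_lt(e_med, 1000 / 2 * 1.5)
  # strictly decreasing in score
  expect_gt(hmm_evalue(c1, 10, 100), hmm_evalue(c1, 11, 100))
  # doubling the fitted-lambda sample changes lambda by < 10%
  c3 <- calibrate_evalue(hmm, 2000, seed = 5)
  expect_lt(abs(c3$gumbel$lambda - c1$gumbel$lambda) / c1$gumbel$lambda, 0.1)
})

test_that("screening finds training sequences and demands calibration", {
  fam <- toy_family()
  hmm_raw <- build_profile(trim_columns(progressive_align(fam)))
  expect_error(screen_proteome(list(h = hmm_raw), fam),
               class = "steromine_calibration_error")
  hmm <- calibrate_evalue(hmm_raw, 1000, seed = 6)
  prot <- c(fam, setNames(vapply(1:30, function(i) random_protein(120),
                                 character(1)), sprintf("r%02d", 1:30)))
  hits <- screen_proteome(list(h1 = hmm), prot, genome_id = "gX")
  expect_true(all(names(fam) %in% hits$protein_id))
  expect_false(any(sprintf("r%02d", 1:30) %in% hits$protein_id))
  expect_equal(unique(hits$genome_id), "gX")
  # linearity in database size is exact
  expect_equal(hmm_evalue(hmm, 20, 1000), 2 * hmm_evalue(hmm, 20, 500))
})

test_that("HMM text serialization round-trips", {
  fam <- toy_family()
  hmm <- calibrate_evalue(build_profile(trim_columns(progressive_align(fam))),
                          1000, seed = 8)
  f <- tempfile(fileext = ".hmm")
  write_profile_hmm(hmm, f)
  back <- read_profile_hmm(f)
  expect_equal(back$n_match_states, hmm$n_match_states)
  expect_equal(back$match_emissions, hmm$match_emissions,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(back$gumbel$lambda, hmm$gumbel$lambda, tolerance = 1e-8)
  s <- fam[[1]]
  expect_equal(forward_score(back, s), forward_score(hmm, s),
               tolerance = 1e-6)
})
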