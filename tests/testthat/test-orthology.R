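# Reciprocal-best-hit orthology and the identity matrix.

make_ref_setup <- function(seed = 61) {
  set.seed(seed)
  panel <- generate_reference_panel(n_groups = 4, templates = "cholesterol",
                                    seed = seed, n_accessory = 0)
  ref_prot <- setNames(panel$sequence, panel$protein_id)
  decoys <- setNames(vapply(1:20, function(i) random_protein(150),
                            character(1)), sprintf("ref_dec%02d", 1:20))
  list(panel = panel, reference = c(ref_prot, decoys))
}

test_that("a proteome equal to the reference maps onto itself perfectly", {
  su <- make_ref_setup()
  om <- reciprocal_best_hits(su$panel, su$reference, su$reference)
  expect_equal(nrow(om), 4L)
  expect_true(all(om$reciprocal))
  expect_true(all(om$identity == 1))
  expect_identical(om$reference_id, om$target_id)
})

test_that("a decoy-only proteome yields no best hit at default thresholds", {
  set.seed(62)
  q <- random_protein(200)
  decoys <- setNames(vapply(1:80, function(i) random_protein(180),
                            character(1)), sprintf("d%03d", 1:80))
  expect_null(best_hit(q, decoys))
})

test_that("bit-score ties break toward the lexicographically smaller id", {
  set.seed(63)
  t <- random_protein(100)
  prot <- c(zz = t, aa = t)
  h <- best_hit(t, prot, min_identity = 0, max_evalue = Inf)
  expect_equal(h$target_id, "aa")
})

test_that("planted orthologs are recovered for every panel group", {
  su <- make_ref_setup()
  set.seed(64)
  target <- setNames(vapply(su$panel$sequence, function(s)
    as.character(evolve_sequence(s, 0.6)), character(1)),
    paste0("tgt_", su$panel$group))
  target <- c(target, setNames(vapply(1:30, function(i) random_protein(150),
                                      character(1)), sprintf("td%02d", 1:30)))
  om <- reciprocal_best_hits(su$panel, target, su$reference)
  rec <- om[om$reciprocal, ]
  expect_equal(nrow(rec), 4L)
  expect_identical(sort(rec$target_id), sort(paste0("tgt_", su$panel$group)))
})

test_that("a recent in-paralog stands in for its deleted parent", {
  su <- make_ref_setup()
  set.seed(65)
  ortho <- as.character(evolve_sequence(su$panel$sequence[1], 0.7))
  dup <- as.character(evolve_sequence(ortho, 0.95))
  target <- c(setNames(dup, "dup_gene"),
              setNames(vapply(1:20, function(i) random_protein(150),
                              character(1)), sprintf("x%02d", 1:20)))
  om <- reciprocal_best_hits(su$panel, target, su$reference)
  rec <- om[om$reciprocal, ]
  expect_equal(rec$target_id[rec$reference_id == su$panel$protein_id[1]],
               "dup_gene")
})

test_that("reciprocal relations survive swapping the two roles", {
  su <- make_ref_setup()
  set.seed(66)
  target <- setNames(vapply(su$panel$sequence, function(s)
    as.character(evolve_sequence(s, 0.6)), character(1)),
    paste0("tgt_", su$panel$group))
  om <- reciprocal_best_hits(su$panel, target, su$reference)
  rec <- om[om$reciprocal, ]
  # swapped: target proteins as panel, searched in the reference proteome
  om_back <- reciprocal_best_hits(target, su$reference, target)
  back <- om_back[om_back$reciprocal, ]
  for (i in seq_len(nrow(rec))) {
    j <- which(back$reference_id == rec$target_id[i])
    expect_equal(back$target_id[j], rec$reference_id[i])
  }
})

test_that("expansion-mode maps are subsets of confirmation-mode maps", {
  su <- make_ref_setup()
  set.seed(67)
  target <- setNames(vapply(su$panel$sequence, function(s)
    as.character(evolve_sequence(s, 0.45)), character(1)),
    paste0("t_", su$panel$group))
  om_conf <- reciprocal_best_hits(su$panel, target, su$reference,
                                  mode = "confirmation")
  om_exp <- reciprocal_best_hits(su$panel, target, su$reference,
                                 mode = "expansion")
  expect_true(all(om_exp$reference_id %in% om_conf$reference_id))
})

test_that("identity matrix marks the reference genome at 1 and decoys empty", {
  su <- make_ref_setup()
  set.seed(68)
  non_deg <- setNames(vapply(1:40, function(i) random_protein(160),
                             character(1)), sprintf("nd%03d", 1:40))
  planted <- setNames(vapply(su$panel$sequence, function(s)
    as.character(evolve_sequence(s, 0.5)), character(1)),
    paste0("pl_", su$panel$group))
  deg <- c(planted, setNames(vapply(1:30, function(i) random_protein(160),
                                    character(1)), sprintf("dd%02d", 1:30)))
  M <- identity_matrix(su$panel,
                       list(ref = su$reference, empty = non_deg,
                            planted = deg),
                       su$reference)
  expect_true(all(M[, "ref"] == 1))
  expect_true(all(is.na(M[, "empty"])))
  filled <- M[, "planted"]
  expect_true(all(!is.na(filled)))
  expect_lt(abs(mean(filled) - 0.5), 0.07)
  expect_error(identity_matrix(su$panel, list(), su$reference),
               class = "steromine_input_error")
})

test_that("a panel protein missing from the reference proteome errors", {
  su <- make_ref_setup()
  expect_error(
    reciprocal_best_hits(c(ghost = random_protein(100)),
                         su$reference, su$reference),
    class = "steromine_config_error")
})
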