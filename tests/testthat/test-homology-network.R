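# Similarity-graph binning and greedy subclustering.

test_that("identical proteins form a single full-identity edge", {
  set.seed(2)
  s <- random_protein(120)
  g <- build_graph(c(p1 = s, p2 = s))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$identity, 1)
})

test_that("an unreachable identity threshold empties the edge set", {
  set.seed(2)
  s <- random_protein(120)
  g <- build_graph(c(p1 = s, p2 = s), min_identity = 1.01)
  expect_equal(nrow(g$edges), 0L)
  expect_equal(length(connected_components(g)), 2L)
})

test_that("families diverged to 60% identity bin into their own components", {
  set.seed(21)
  fams <- lapply(1:4, function(f) {
    anc <- random_protein(250)
    setNames(c(anc, vapply(1:2, function(i)
      as.character(evolve_sequence(anc, 0.6)), character(1))),
      sprintf("f%d_m%d", f, 1:3))
  })
  prot <- unlist(fams)
  comps <- connected_components(build_graph(prot))
  expect_equal(length(comps), 4L)
  for (cmp in comps)
    expect_equal(length(unique(substr(cmp, 1, 2))), 1L)
})

test_that("components equal boolean transitive closure on random graphs", {
  set.seed(33)
  for (rep in 1:15) {
    n <- sample(3:10, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    ne <- sample(0:(n * 2), 1)
    edges <- data.frame(
      a = sample(nodes, ne, replace = TRUE),
      b = sample(nodes, ne, replace = TRUE),
      identity = rep(1, ne), evalue = rep(0, ne), bit_score = rep(0, ne))
    edges <- edges[edges$a != edges$b, , drop = FALSE]
    g <- structure(list(nodes = nodes, edges = edges),
                   class = "homology_graph")
    expect_identical(connected_components(g),
                     oracle_components(nodes, edges))
  }
})

test_that("raising the identity threshold never merges components", {
  set.seed(34)
  anc <- random_protein(130)
  prot <- setNames(c(vapply(1:4, function(i)
    as.character(evolve_sequence(anc, 0.45)), character(1)),
    vapply(1:2, function(i) random_protein(130), character(1))),
    paste0("p", 1:6))
  n_lo <- length(connected_components(build_graph(prot, min_identity = 0.25,
                                                  max_evalue = 1e-5)))
  n_hi <- length(connected_components(build_graph(prot, min_identity = 0.5,
                                                  max_evalue = 1e-5)))
  expect_gte(n_hi, n_lo)
})

test_that("greedy clustering groups an identical pair and partitions input", {
  set.seed(4)
  s <- random_protein(100)
  cl <- greedy_cluster(c(a = s, b = s))
  expect_equal(length(cl$clusters), 1L)
  expect_setequal(cl$clusters[[1]], c("a", "b"))

  fam <- toy_family()
  prot <- c(fam, setNames(random_protein(90), "lone"))
  cl2 <- greedy_cluster(prot)
  expect_setequal(unlist(cl2$clusters), names(prot))
  expect_equal(anyDuplicated(unlist(cl2$clusters)), 0L)
  # representative property: member-to-representative identity >= threshold
  for (i in seq_along(cl2$clusters)) {
    rep_id <- cl2$representatives[i]
    for (m in cl2$clusters[[i]])
      expect_gte(steromine:::global_identity(prot[[m]], prot[[rep_id]],
                                             denominator = "shorter"), 0.5)
  }
  expect_error(greedy_cluster(prot, word_size = 0),
               class = "steromine_parameter_error")
})

test_that("template-structured groups split into 1-5 subclusters", {
  # one orthologous group: three template references near 36% pairwise
  # identity, each with close relatives -- the panel regime
  set.seed(44)
  p <- generate_reference_panel(n_groups = 1, seed = 44, n_accessory = 0)
  prot <- setNames(p$sequence, p$protein_id)
  for (tmpl in unique(p$template)) {
    ref <- p$sequence[p$template == tmpl][1]
    rel <- vapply(1:3, function(i)
      as.character(evolve_sequence(ref, 0.85)), character(1))
    names(rel) <- sprintf("%s_rel%d", tmpl, 1:3)
    prot <- c(prot, rel)
  }
  cl <- greedy_cluster(prot)
  expect_gte(length(cl$clusters), 1L)
  expect_lte(length(cl$clusters), 5L)
  # members of one subcluster share a template
  for (cmp in cl$clusters)
    expect_equal(length(unique(sub("[._].*$", "", cmp))), 1L)
})

test_that("retain_seeded keeps exactly the seeded clusters", {
  set.seed(5)
  prot <- setNames(vapply(1:5, function(i) random_protein(60), character(1)),
                   paste0("q", 1:5))
  cl <- greedy_cluster(prot)   # random proteins: one cluster each
  expect_equal(length(cl$clusters), 5L)
  kept <- retain_seeded(cl, c("q2", "q4"))
  expect_setequal(unlist(kept$clusters), c("q2", "q4"))
  all_kept <- retain_seeded(cl, names(prot))
  expect_equal(length(all_kept$clusters), 5L)
  expect_error(retain_seeded(cl, "nope"), class = "steromine_input_error")
})
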