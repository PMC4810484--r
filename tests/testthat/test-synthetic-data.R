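# Synthetic reference panels, controlled sequence divergence, evolution
# along trees, and community generation with truth tables.

test_that("default panel has 8 core groups per template with 2 mandatory", {
  p <- generate_reference_panel(seed = 1)
  core <- p[p$role == "core", ]
  expect_equal(length(unique(core$group)), 8L)
  expect_equal(length(unique(p$template)), 3L)
  expect_true(all(table(core$template) == 8))
  expect_equal(sort(unique(core$group[core$mandatory])), c("HsaC", "KshA"))
  # pathway-specific accessory genes are template-private
  acc <- p[p$role == "accessory", ]
  expect_true(all(table(acc$template) == 6))
  expect_false(any(acc$mandatory))
})

test_that("panel respects forced lengths and is deterministic under seed", {
  p1 <- generate_reference_panel(n_groups = 1, length_range = c(30, 30),
                                 seed = 7, n_accessory = 0)
  expect_true(all(nchar(p1$sequence) == 30))
  expect_equal(nrow(p1), 3L)
  a <- generate_reference_panel(seed = 42)
  b <- generate_reference_panel(seed = 42)
  expect_identical(a, b)
  expect_error(generate_reference_panel(n_groups = 0),
               class = "steromine_parameter_error")
  expect_error(generate_reference_panel(length_range = c(10, 20)),
               class = "steromine_parameter_error")
})

test_that("evolve_sequence hits its identity target", {
  set.seed(3)
  anc <- random_protein(200)
  expect_identical(as.character(evolve_sequence(anc, 1)), anc)
  d <- evolve_sequence(anc, 0.30)
  realized <- attr(d, "realized_identity")
  expect_gte(realized, 0.25)
  expect_lte(realized, 0.35)
  expect_error(evolve_sequence(anc, 0.01),
               class = "steromine_parameter_error")
  expect_error(evolve_sequence("ACDEF", 0.5),
               class = "steromine_parameter_error")
})

test_that("mean realized identity tracks the target across the range", {
  set.seed(11)
  anc <- random_protein(200)
  for (target in c(0.9, 0.7, 0.5, 0.3)) {
    ids <- vapply(seq_len(100), function(i)
      attr(evolve_sequence(anc, target), "realized_identity"), numeric(1))
    expect_lt(abs(mean(ids) - target), 0.03)
  }
})

test_that("evolution along a tree transmits unchanged over zero branches", {
  set.seed(5)
  star <- ape::stree(4, "star")
  star$edge.length <- rep(0, nrow(star$edge))
  root <- c(x = random_protein(80))
  out <- evolve_along_tree(root, star)
  expect_true(all(vapply(out, `[[`, character(1), "x") == root[["x"]]))

  two <- ape::read.tree(text = "(a:0,b:0.5);")
  out2 <- evolve_along_tree(root, two)
  expect_identical(out2$a[["x"]], root[["x"]])
  expect_false(identical(out2$b[["x"]], root[["x"]]))

  nb <- ape::rtree(4); nb$edge.length <- NULL
  expect_error(evolve_along_tree(root, nb),
               class = "steromine_input_error")
})

test_that("leaf-pair identity anticorrelates with patristic distance", {
  set.seed(13)
  tree <- ape::rtree(8)
  tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.4)
  roots <- setNames(vapply(1:60, function(i) random_protein(100),
                           character(1)), paste0("r", 1:60))
  leaves <- evolve_along_tree(roots, tree, indels = FALSE)
  pat <- ape::cophenetic.phylo(tree)
  tips <- tree$tip.label
  pairs <- t(combn(tips, 2))
  mean_id <- apply(pairs, 1, function(pr) {
    mean(vapply(names(roots), function(r)
      mean(strsplit(leaves[[pr[1]]][[r]], "")[[1]] ==
             strsplit(leaves[[pr[2]]][[r]], "")[[1]]), numeric(1)))
  })
  d <- pat[cbind(pairs[, 1], pairs[, 2])]
  expect_lt(cor(mean_id, d, method = "spearman"), -0.8)
})

test_that("community respects the degrader fraction and truth consistency", {
  com <- mini_community()
  truth <- com$truth
  expect_equal(sum(truth$genomes$is_degrader), 3L)
  expect_equal(truth$genomes$is_degrader, nchar(truth$genomes$pathways) > 0)
  # every planted locus appears exactly once in the annotation and agrees
  for (i in seq_len(nrow(truth$loci))) {
    l <- truth$loci[i, ]
    ann <- com$genomes[[l$genome_id]]$annotation
    row <- ann[ann$gene_id == l$gene_id, ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$start, l$start)
    expect_equal(row$replicon_type, l$replicon_type)
    repl <- com$genomes[[l$genome_id]]$replicons
    expect_lte(l$end, repl$length[repl$replicon_id == row$replicon_id])
  }
  # identity control on planted genes
  rng <- com$config$target_identity_range
  expect_lt(abs(mean(truth$loci$identity_to_reference) - mean(rng)), 0.07)
})

test_that("identical configuration and seed give byte-identical outputs", {
  cfg <- community_config(n_genomes = 4, degrader_fraction = 0.5,
                          n_decoys_per_genome = 10, n_near_decoys = 1,
                          seed = 99)
  d1 <- file.path(tempdir(), "com_det_a")
  d2 <- file.path(tempdir(), "com_det_b")
  write_community(generate_community(cfg), d1)
  write_community(generate_community(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
})

test_that("horizontal transfer changes pathway genes but never markers", {
  base <- function(ev) community_config(
    n_genomes = 6, degrader_fraction = 1, pathway_templates = "cholate",
    n_decoys_per_genome = 8, n_near_decoys = 0, hgt_events = ev, seed = 17)
  com0 <- generate_community(base(NULL))
  ev <- data.frame(donor = "G001", recipient = "G004", pathway = "cholate")
  com1 <- generate_community(base(ev))
  expect_identical(com0$markers, com1$markers)
  expect_false(identical(
    com0$genomes$G004$proteome[com0$truth$loci$gene_id[
      com0$truth$loci$genome_id == "G004"]],
    com1$genomes$G004$proteome[com1$truth$loci$gene_id[
      com1$truth$loci$genome_id == "G004"]]))
  bad <- data.frame(donor = "G001", recipient = "G004",
                    pathway = "cholesterol")
  expect_error(generate_community(base(bad)),
               class = "steromine_config_error")
})
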