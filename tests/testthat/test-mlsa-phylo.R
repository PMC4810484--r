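# Marker extraction, supermatrix, Poisson distances, neighbor joining,
# bootstrap and Robinson-Foulds congruence.

test_that("Poisson distance follows its closed form", {
  expect_equal(protein_distance(c("A", "C", "D"), c("A", "C", "D")), 0)
  a <- rep(c("A", "C"), 10)
  b <- c(rep("A", 10), rep("A", 10))  # differs at the 10 C positions
  expect_equal(protein_distance(a, b), -log(1 - 0.5))
  expect_error(protein_distance(c("A", "C"), c("C", "A")),
               class = "steromine_analysis_error")  # p = 1 saturates
  expect_error(protein_distance(c("A", "-"), c("-", "A")),
               class = "steromine_input_error")     # no shared column
})

test_that("distance p equals a hand count under pairwise deletion", {
  set.seed(101)
  for (rep in 1:10) {
    nc <- sample(5:30, 1)
    a <- sample(c("A", "C", "G", "-"), nc, replace = TRUE)
    b <- sample(c("A", "C", "G", "-"), nc, replace = TRUE)
    shared <- which(a != "-" & b != "-")
    if (length(shared) == 0 || all(a[shared] != b[shared])) next
    p_hand <- sum(a[shared] != b[shared]) / length(shared)
    expect_equal(protein_distance(a, b), -log(1 - p_hand))
  }
})

test_that("supermatrix concatenates blocks over sorted taxa", {
  set.seed(102)
  base <- lapply(c(KshA = 220, HsaA = 180, HsaC = 200, HsaD = 160),
                 random_protein)
  taxa <- lapply(setNames(nm = paste0("t", 1:4)), function(t)
    vapply(base, function(s) as.character(evolve_sequence(s, 0.8)),
           character(1)))
  sm <- build_supermatrix(taxa)
  blocks <- attr(sm, "blocks")
  expect_equal(blocks$from[1], 1L)
  expect_equal(blocks$from[-1], head(blocks$to, -1) + 1L)
  expect_equal(tail(blocks$to, 1), ncol(sm))
  # identical marker sets across taxa have zero variable columns
  same <- lapply(setNames(nm = paste0("s", 1:3)), function(t)
    vapply(base, identity, character(1)))
  sm_same <- build_supermatrix(same)
  expect_true(all(apply(sm_same, 2, function(cl) length(unique(cl)) == 1)))
  # input order does not matter
  sm_shuf <- build_supermatrix(taxa[c(3, 1, 4, 2)])
  expect_identical(sm, sm_shuf)
})

test_that("neighbor joining agrees with an independent NJ implementation", {
  set.seed(99)
  for (rep in 1:8) {
    n <- sample(4:9, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(tr)
    D <- D + matrix(runif(n * n, 0, 0.01), n)  # slight non-additive noise
    D <- (D + t(D)) / 2; diag(D) <- 0
    mine <- nj_tree(D)
    theirs <- ape::nj(as.dist(D))
    expect_equal(rf_distance(mine, theirs), 0L, info = rep)
  }
})

test_that("neighbor joining recovers additive trees and validates input", {
  set.seed(103)
  tr <- ape::rtree(5)
  tr$edge.length <- runif(nrow(tr$edge), 0.2, 1)
  D <- ape::cophenetic.phylo(tr)
  out <- nj_tree(D)
  expect_equal(rf_distance(out, tr), 0L)
  # three taxa: closed-form branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- nj_tree(D3)
  expect_equal(sort(t3$edge.length), sort(c((3 + 4 - 5) / 2, (3 + 5 - 4) / 2,
                                            (4 + 5 - 3) / 2)))
  # equidistant taxa: internal branches collapse to zero
  De <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(De) <- 0
  te <- nj_tree(De)
  internal <- te$edge[, 2] > length(te$tip.label)
  expect_true(all(te$edge.length[internal] < 1e-12))
  bad <- D3; bad[1, 2] <- 99
  expect_error(nj_tree(bad), class = "steromine_input_error")
})

test_that("bootstrap supports are seeded and degenerate cases behave", {
  set.seed(104)
  base <- lapply(c(KshA = 150, HsaA = 150, HsaC = 150, HsaD = 150),
                 random_protein)
  taxa <- lapply(setNames(nm = paste0("t", 1:5)), function(t)
    vapply(base, function(s) as.character(evolve_sequence(s, 0.7)),
           character(1)))
  sm <- build_supermatrix(taxa)
  b1 <- bootstrap_support(sm, n_replicates = 25, seed = 3)
  b2 <- bootstrap_support(sm, n_replicates = 25, seed = 3)
  expect_identical(b1$node.label, b2$node.label)
  expect_true(all(b1$node.label >= 0 & b1$node.label <= 100))
  single <- bootstrap_support(sm, n_replicates = 1, seed = 4)
  expect_true(all(single$node.label %in% c(0, 100)))
})

test_that("strong tree-like signal earns full bootstrap support", {
  set.seed(105)
  tree <- ape::read.tree(text = "((a:0.15,b:0.15):0.25,(c:0.15,d:0.15):0.25,(e:0.15,f:0.15):0.25);")
  roots <- setNames(vapply(1:4, function(i) random_protein(250),
                           character(1)), c("KshA", "HsaA", "HsaC", "HsaD"))
  leaves <- evolve_along_tree(roots, tree, indels = FALSE)
  sm <- build_supermatrix(leaves)
  bt <- bootstrap_support(sm, n_replicates = 60, seed = 9)
  expect_equal(rf_distance(bt, tree), 0L)
  expect_true(all(bt$node.label[-1] >= 95))  # [-1] skips the basal node
})

test_that("Robinson-Foulds distance matches bipartition enumeration", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  set.seed(106)
  for (rep in 1:15) {
    n <- sample(4:7, 1)
    a <- ape::rtree(n); b <- ape::rtree(n)
    b$tip.label <- sample(a$tip.label)
    expect_equal(rf_distance(a, b), oracle_rf(a, b), info = rep)
  }
  small <- ape::read.tree(text = "(a,b);")
  expect_error(rf_distance(small, small), class = "steromine_input_error")
})

test_that("marker extraction keeps complete clusters and reports drops", {
  com <- mini_community()
  rep <- mini_report()
  cl <- rep$cluster_calls
  proteomes <- lapply(com$genomes, `[[`, "proteome")
  ms <- extract_markers(cl, proteomes)
  expect_true(length(ms) >= 1)
  expect_true(all(vapply(ms, function(x)
    identical(names(x), c("KshA", "HsaA", "HsaC", "HsaD")), logical(1))))
  # dropping one marker group from the cluster table excludes that taxon
  cl2 <- cl
  cl2$groups[1] <- gsub("KshA", "KstD", cl2$groups[1])
  ms2 <- extract_markers(cl2, proteomes)
  expect_true(cl2$cluster_id[1] %in% attr(ms2, "dropped"))
  expect_error(extract_markers(cl2[1, ], proteomes),
               class = "steromine_analysis_error")
})

test_that("a genome with two pathway clusters contributes two taxa", {
  set.seed(107)
  panel <- generate_reference_panel(seed = 107, n_accessory = 0)
  decoys <- setNames(vapply(1:40, function(i) random_protein(150),
                            character(1)), sprintf("d%03d", 1:40))
  mk <- function(tmpl, ci) {
    sub <- panel[panel$template == tmpl, ]
    list(genes = setNames(sub$sequence, paste0(tmpl, "_", sub$group)),
         labels = data.frame(reference_id = sub$protein_id,
                             group = sub$group, template = tmpl,
                             pathway = tmpl),
         on_plasmid = ci == 2)
  }
  g <- steromine:::assemble_genome("GX", decoys,
                                   list(mk("cholesterol", 1),
                                        mk("cholate", 2)), keep_ids = TRUE)
  loc <- locate_hits(setNames(g$loci$gene_id, g$loci$group), g$annotation)
  repl <- setNames(g$replicons$n_genes, g$replicons$replicon_id)
  cl <- detect_clusters(loc, repl)
  expect_equal(nrow(cl), 2L)
  ms <- extract_markers(cl, list(GX = g$proteome))
  expect_equal(length(ms), 2L)
})
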