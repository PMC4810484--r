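# Hit localization, gene-cluster chaining (with circular wraparound) and
# the plasmid/chromosome summary.

fake_annotation <- function(n, replicon = "chr1", type = "chromosome",
                            circular = TRUE, genome = "G1") {
  starts <- seq(0, by = 1000, length.out = n)
  data.frame(gene_id = sprintf("%s_g%03d", replicon, seq_len(n)),
             genome_id = genome, replicon_id = replicon,
             replicon_type = type, circular = circular,
             start = starts, end = starts + 900, strand = "+",
             gene_index = seq_len(n))
}

test_that("hits resolve to coordinates and unresolved ids are reported", {
  ann <- fake_annotation(10, "p1", "plasmid")
  loc <- locate_hits(c(KshA = "p1_g003"), ann)
  expect_equal(loc$replicon_type, "plasmid")
  expect_equal(loc$start, 2000)
  expect_equal(loc$group_label, "KshA")
  expect_equal(nrow(locate_hits(character(0), ann)), 0L)
  expect_warning(loc2 <- locate_hits(c("p1_g001", "ghost"), ann),
                 "not in annotation")
  expect_equal(attr(loc2, "unresolved"), "ghost")
  expect_equal(nrow(loc2), 1L)
})

test_that("contiguous planted genes form exactly one cluster", {
  ann <- fake_annotation(30)
  loc <- locate_hits(ann$gene_id[11:18], ann)
  cl <- detect_clusters(loc, c(chr1 = 30))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 8L)
})

test_that("groups separated by more than the gap limit split", {
  ann <- fake_annotation(60, circular = FALSE)
  loc <- locate_hits(ann$gene_id[c(1:4, 55:58)], ann)
  cl <- detect_clusters(loc, c(chr1 = 60))
  expect_equal(nrow(cl), 2L)
  expect_equal(sort(cl$n_members), c(4L, 4L))
})

test_that("chaining equals brute-force single linkage on random layouts", {
  set.seed(91)
  for (rep in 1:30) {
    n <- sample(10:30, 1)
    k <- sample(2:min(8, n - 2), 1)
    circular <- runif(1) < 0.5
    gap <- sample(1:6, 1)
    idx <- sort(sample(n, k))
    ann <- fake_annotation(n, circular = circular)
    loc <- locate_hits(ann$gene_id[idx], ann)
    cl <- detect_clusters(loc, c(chr1 = n), max_gap_genes = gap)
    got <- lapply(strsplit(cl$members, ","), function(m)
      sort(match(m, ann$gene_id)))
    got <- got[order(vapply(got, min, numeric(1)))]
    want <- oracle_gene_clusters(idx, n, circular, gap)
    want <- want[order(vapply(want, min, numeric(1)))]
    expect_equal(length(got), length(want), info = rep)
    expect_true(all(mapply(identical, got, want)), info = rep)
  }
})

test_that("rotating a circular replicon's origin keeps the partition", {
  n <- 24
  idx <- c(1, 2, 3, 22, 23, 24, 10, 11)
  for (shift in c(0, 5, 12, 20)) {
    rot <- sort(((idx - 1 + shift) %% n) + 1)
    ann <- fake_annotation(n)
    loc <- locate_hits(ann$gene_id[rot], ann)
    cl <- detect_clusters(loc, c(chr1 = n), max_gap_genes = 4)
    expect_equal(sort(cl$n_members), c(2L, 6L), info = shift)
  }
})

test_that("every located gene lands in exactly one cluster", {
  set.seed(92)
  ann <- fake_annotation(40)
  idx <- sort(sample(40, 12))
  loc <- locate_hits(ann$gene_id[idx], ann)
  cl <- detect_clusters(loc, c(chr1 = 40), max_gap_genes = 3)
  members <- unlist(strsplit(cl$members, ","))
  expect_setequal(members, ann$gene_id[idx])
  expect_equal(anyDuplicated(members), 0L)
})

test_that("plasmid-only pathways are flagged", {
  cl <- data.frame(cluster_id = c("A.cl01", "B.cl01", "B.cl02", "C.cl01"),
                   genome_id = c("A", "B", "B", "C"),
                   replicon_id = c("A_chr", "B_chr", "B_p1", "C_p1"),
                   replicon_type = c("chromosome", "chromosome", "plasmid",
                                     "plasmid"),
                   n_members = c(8L, 4L, 4L, 8L),
                   members = "x", groups = "y",
                   span_start = 0, span_end = 10)
  s <- replicon_summary(cl)
  expect_false(s$plasmid_only[s$genome_id == "A"])
  expect_false(s$plasmid_only[s$genome_id == "B"])
  expect_true(s$any_plasmid[s$genome_id == "B"])
  expect_true(s$plasmid_only[s$genome_id == "C"])
})

test_that("located planted genes match the community truth table", {
  com <- mini_community()
  loci <- com$truth$loci
  g <- loci$genome_id[1]
  sub <- loci[loci$genome_id == g, ]
  loc <- locate_hits(setNames(sub$gene_id, sub$group),
                     com$genomes[[g]]$annotation)
  expect_setequal(loc$gene_id, sub$gene_id)
  expect_equal(loc$start[match(sub$gene_id, loc$gene_id)], sub$start)
  repl <- com$genomes[[g]]$replicons
  cl <- detect_clusters(loc, setNames(repl$n_genes, repl$replicon_id))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, nrow(sub))
  expect_equal(cl$replicon_type, sub$replicon_type[1])
})
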