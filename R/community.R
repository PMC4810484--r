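# Synthetic community generator: annotated genomes with planted pathway
# gene clusters, decoy genes, chromosome/plasmid placement, 16S-like marker
# genes evolved along a known species tree, optional horizontal transfer of
# whole pathways, and a truth table for every downstream stage.

#' Community simulation configuration
#'
#' @param n_genomes number of genomes (= leaves of the species tree).
#' @param degrader_fraction fraction of genomes carrying a planted pathway.
#' @param pathway_templates template names cycled over the degraders.
#' @param target_identity_range band of root-to-leaf identities for planted
#'   pathway genes relative to the panel references (fractions in (0.05, 1]).
#' @param n_decoys_per_genome random background genes per genome.
#' @param n_near_decoys per genome, decoys evolved from panel references to
#'   15-20% identity, exercising the filters near their decision boundary.
#' @param plasmid_probability probability that a degrader's cluster sits on
#'   a plasmid rather than the chromosome.
#' @param hgt_events `NULL` or data frame (`donor`, `recipient`, `pathway`):
#'   the recipient's pathway genes descend from the donor lineage while its
#'   marker gene still follows the species tree.
#' @param species_tree optional `ape::phylo` with branch lengths and
#'   `n_genomes` tips; generated when `NULL`.
#' @param marker_length length of the 16S-like marker sequence.
#' @param decoy_length_range decoy gene length range (residues).
#' @param intergenic_mean mean intergenic spacing (bp, geometric).
#' @param seed master seed; everything downstream is derived from it.
#' @param panel optional [generate_reference_panel()] result.
#' @param model optional [evolution_model()].
#' @return a `community_config` list.
#' @export
community_config <- function(n_genomes = 20, degrader_fraction = 0.5,
                             pathway_templates = c("cholesterol", "cholate",
                                                   "testosterone_cholate"),
                             target_identity_range = c(0.5, 0.7),
                             n_decoys_per_genome = 500, n_near_decoys = 5,
                             plasmid_probability = 0.25, hgt_events = NULL,
                             species_tree = NULL, marker_length = 900,
                             decoy_length_range = c(80, 400),
                             intergenic_mean = 120, seed = 1, panel = NULL,
                             model = NULL) {
  if (degrader_fraction < 0 || degrader_fraction > 1)
    smx_stop("steromine_config_error",
             "degrader_fraction must lie in [0, 1]")
  if (length(target_identity_range) != 2 ||
      target_identity_range[1] <= 0.05 || target_identity_range[2] > 1 ||
      target_identity_range[1] > target_identity_range[2])
    smx_stop("steromine_config_error",
             "target_identity_range must be increasing within (0.05, 1]")
  if (plasmid_probability < 0 || plasmid_probability > 1)
    smx_stop("steromine_config_error", "plasmid_probability must be in [0,1]")
  if (!is.null(hgt_events) &&
      !all(c("donor", "recipient", "pathway") %in% names(hgt_events)))
    smx_stop("steromine_config_error",
             "hgt_events needs columns donor, recipient, pathway")
  if (!is.null(species_tree)) {
    if (!inherits(species_tree, "phylo"))
      smx_stop("steromine_config_error", "species_tree must be a phylo")
    if (length(species_tree$tip.label) != n_genomes)
      smx_stop("steromine_config_error",
               "species_tree must have n_genomes tips")
    if (is.null(species_tree$edge.length))
      smx_stop("steromine_config_error", "species_tree needs branch lengths")
  }
  structure(list(n_genomes = n_genomes,
                 degrader_fraction = degrader_fraction,
                 pathway_templates = pathway_templates,
                 target_identity_range = target_identity_range,
                 n_decoys_per_genome = n_decoys_per_genome,
                 n_near_decoys = n_near_decoys,
                 plasmid_probability = plasmid_probability,
                 hgt_events = hgt_events, species_tree = species_tree,
                 marker_length = marker_length,
                 decoy_length_range = decoy_length_range,
                 intergenic_mean = intergenic_mean, seed = seed,
                 panel = panel, model = model),
            class = "community_config")
}

# random species tree with informative branch lengths
random_species_tree <- function(n) {
  tr <- ape::rtree(n, rooted = TRUE, br = NULL)
  tr$tip.label <- sprintf("G%03d", seq_len(n))
  ne <- nrow(tr$edge)
  is_tip <- tr$edge[, 2] <= n
  len <- numeric(ne)
  len[is_tip] <- runif(sum(is_tip), 0.05, 0.25)
  len[!is_tip] <- runif(sum(!is_tip), 0.08, 0.20)
  tr$edge.length <- len
  tr
}

# place decoy genes and contiguous planted clusters on replicons and assign
# coordinates; genes are non-overlapping intervals with geometric intergenic
# spacing on circular chromosomes (and plasmids when a cluster needs one)
assemble_genome <- function(genome_id, decoys, clusters = list(),
                            intergenic_mean = 120, keep_ids = FALSE) {
  rename <- function(n_genes, offset = 0)
    sprintf("%s_%04d", genome_id, offset + seq_len(n_genes))
  gene_tbl <- data.frame(gene_id = character(), sequence = character(),
                         group = character(), template = character(),
                         pathway = character(), reference_id = character(),
                         cluster_id = character(), replicon = character(),
                         stringsAsFactors = FALSE)
  on_plasmid <- vapply(clusters, function(cl) isTRUE(cl$on_plasmid),
                       logical(1))
  # split decoys: plasmids get a slice of the decoy pool
  n_dec <- length(decoys)
  n_plasmid_dec <- if (any(on_plasmid)) max(5L, round(0.08 * n_dec)) else 0L
  plasmid_dec <- if (n_plasmid_dec > 0) tail(seq_len(n_dec), n_plasmid_dec)
                 else integer(0)
  replicon_of_decoy <- rep("chr", n_dec)
  replicon_of_decoy[plasmid_dec] <- "p1"

  build_replicon <- function(replicon_id, dec_idx, repl_clusters) {
    order_ids <- list()
    dec_ids <- names(decoys)[dec_idx]
    slots <- sample(length(dec_idx) + 1L, length(repl_clusters),
                    replace = FALSE) - 1L
    slots <- sort(slots)
    pos <- 0L
    for (ci in seq_along(repl_clusters)) {
      if (slots[ci] > pos)
        order_ids <- c(order_ids, as.list(dec_ids[(pos + 1L):slots[ci]]))
      order_ids <- c(order_ids, list(names(repl_clusters[[ci]]$genes)))
      pos <- slots[ci]
    }
    if (pos < length(dec_ids))
      order_ids <- c(order_ids, as.list(dec_ids[(pos + 1L):length(dec_ids)]))
    unlist(order_ids)
  }

  # name planted genes
  all_genes <- as.list(decoys)
  planted <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    ids <- if (keep_ids) names(cl$genes)
           else sprintf("%s_c%d_%02d", genome_id, ci, seq_along(cl$genes))
    lab <- cl$labels
    lab$gene_id <- ids
    lab$cluster_id <- sprintf("%s.c%d", genome_id, ci)
    lab$replicon_id <- if (isTRUE(cl$on_plasmid)) paste0(genome_id, "_p1")
                       else paste0(genome_id, "_chr")
    lab$replicon_type <- if (isTRUE(cl$on_plasmid)) "plasmid" else "chromosome"
    genes <- setNames(as.list(cl$genes), ids)
    clusters[[ci]]$genes <- unlist(genes)
    all_genes <- c(all_genes, genes)
    planted[[ci]] <- lab
  }

  ann_rows <- list()
  for (repl in c("chr", if (any(on_plasmid)) "p1")) {
    repl_id <- paste0(genome_id, "_", repl)
    dec_idx <- which(replicon_of_decoy == repl)
    repl_clusters <- clusters[(repl == "p1") == on_plasmid]
    ord <- build_replicon(repl_id, dec_idx, repl_clusters)
    lens <- nchar(unlist(all_genes[ord]))
    gaps <- rgeom(length(ord), 1 / intergenic_mean) + 20L
    starts <- cumsum(c(0L, (3L * (lens + 1L) + gaps)[-length(ord)])) + gaps
    ends <- starts + 3L * (lens + 1L)
    ann_rows[[repl]] <- data.frame(
      gene_id = ord, genome_id = genome_id, replicon_id = repl_id,
      replicon_type = if (repl == "chr") "chromosome" else "plasmid",
      circular = (repl == "chr"),
      start = starts, end = ends,
      strand = sample(c("+", "-"), length(ord), replace = TRUE),
      gene_index = seq_along(ord))
  }
  annotation <- do.call(rbind, ann_rows)
  rownames(annotation) <- NULL
  repl_len <- tapply(annotation$end, annotation$replicon_id, max)
  replicons <- data.frame(
    replicon_id = names(repl_len),
    replicon_type = ifelse(grepl("_p1$", names(repl_len)), "plasmid",
                           "chromosome"),
    circular = !grepl("_p1$", names(repl_len)),
    length = as.integer(repl_len + 200L),
    n_genes = as.integer(table(annotation$replicon_id)[names(repl_len)]))
  rownames(replicons) <- NULL
  loci <- if (length(planted)) {
    l <- do.call(rbind, planted)
    coord <- annotation[match(l$gene_id, annotation$gene_id), ]
    l$start <- coord$start; l$end <- coord$end; l$strand <- coord$strand
    l$gene_index <- coord$gene_index
    l$genome_id <- genome_id
    l
  } else NULL
  list(genome_id = genome_id, proteome = unlist(all_genes),
       annotation = annotation, replicons = replicons, loci = loci)
}

#' Generate a synthetic community with planted pathway clusters
#'
#' Simulates `n_genomes` genomes along a species tree. Every genome carries
#' decoy genes and a 16S-like marker evolved along the tree; the configured
#' fraction of genomes additionally carries one pathway template's eight
#' enzyme genes, evolved along the same species tree (so that, absent
#' horizontal transfer, pathway gene trees are congruent with the species
#' tree) and planted as a contiguous cluster on the chromosome or, with
#' `plasmid_probability`, on a plasmid. Horizontal transfer events re-derive
#' the recipient's pathway genes from the donor lineage while leaving its
#' marker untouched.
#'
#' @param config a [community_config()].
#' @return a `steroid_community`: list with `genomes` (named list of genome
#'   records), `markers`, `species_tree`, `panel`, `truth` (`genomes` and
#'   `loci` data frames) and `config`.
#' @export
generate_community <- function(config) {
  if (!inherits(config, "community_config"))
    smx_stop("steromine_config_error", "config must be a community_config")
  set.seed(config$seed)
  model <- config$model %||% evolution_model()
  panel <- config$panel %||%
    generate_reference_panel(seed = subseed(config$seed, 1),
                             templates = config$pathway_templates,
                             model = model)
  if (!all(config$pathway_templates %in% panel$template))
    smx_stop("steromine_config_error",
             "panel lacks some configured pathway templates")
  set.seed(subseed(config$seed, 2))
  n <- config$n_genomes
  tree <- config$species_tree %||% random_species_tree(n)
  tips <- tree$tip.label

  n_deg <- round(n * config$degrader_fraction)
  degraders <- sort(sample(tips, n_deg))
  template_of <- setNames(rep(config$pathway_templates,
                              length.out = n_deg), degraders)

  # marker genes strictly follow the species tree
  marker_root <- random_protein(config$marker_length)
  markers <- vapply(
    evolve_along_tree(c(marker = marker_root), tree, model, scale = 1),
    `[[`, character(1), 1)

  # pathway genes evolve along the species tree, scaled so root-to-leaf
  # identity sits at the middle of the configured band
  depths <- unname(tip_depths(tree))
  mid_t <- mean(config$target_identity_range)
  pathway_genes <- list()  # template -> leaf -> named seqs
  for (tmpl in unique(template_of)) {
    sub <- panel[panel$template == tmpl, ]
    scale_t <- divergence_for_identity(model, mid_t) / mean(depths)
    pathway_genes[[tmpl]] <- evolve_along_tree(
      setNames(sub$sequence, sub$protein_id), tree, model, scale = scale_t)
  }

  # horizontal transfer: recipient pathway genes re-derived from the donor
  pathways_of <- lapply(setNames(as.list(degraders), degraders),
                        function(d) template_of[[d]])
  if (!is.null(config$hgt_events)) {
    for (r in seq_len(nrow(config$hgt_events))) {
      ev <- config$hgt_events[r, ]
      if (!ev$donor %in% tips || !ev$recipient %in% tips)
        smx_stop("steromine_config_error",
                 "HGT donor/recipient must be species-tree leaves")
      if (!ev$donor %in% degraders ||
          !ev$pathway %in% pathways_of[[ev$donor]])
        smx_stop("steromine_config_error",
                 "HGT pathway '%s' is not planted in donor %s", ev$pathway,
                 ev$donor)
      donor_genes <- pathway_genes[[ev$pathway]][[ev$donor]]
      d_hgt <- 0.1 * divergence_for_identity(model, mid_t)
      transferred <- vapply(donor_genes, function(s) {
        decode_seq(apply_indels(mutate_residues(encode_seq(s), model, d_hgt),
                                model, d_hgt))
      }, character(1))
      pathway_genes[[ev$pathway]][[ev$recipient]] <- transferred
      pathways_of[[ev$recipient]] <- unique(c(pathways_of[[ev$recipient]],
                                              ev$pathway))
    }
  }
  is_degrader <- setNames(tips %in% names(Filter(length, pathways_of)), tips)

  genomes <- list()
  truth_loci <- list()
  for (tip in tips) {
    n_dec <- config$n_decoys_per_genome
    decoys <- setNames(
      vapply(seq_len(n_dec), function(i)
        random_protein(sample(config$decoy_length_range[1]:
                                config$decoy_length_range[2], 1)),
        character(1)),
      sprintf("%s_dec%04d", tip, seq_len(n_dec)))
    if (config$n_near_decoys > 0) {
      nd <- vapply(seq_len(config$n_near_decoys), function(i) {
        ref <- panel$sequence[sample(nrow(panel), 1)]
        tryCatch(as.character(evolve_sequence(ref, runif(1, 0.15, 0.20),
                                              model)),
                 steromine_simulation_error = function(e)
                   random_protein(200))
      }, character(1))
      names(nd) <- sprintf("%s_near%02d", tip, seq_len(config$n_near_decoys))
      decoys <- c(decoys, nd)
    }
    clusters <- list()
    for (tmpl in pathways_of[[tip]] %||% character(0)) {
      sub <- panel[panel$template == tmpl, ]
      genes <- pathway_genes[[tmpl]][[tip]][sub$protein_id]
      clusters[[length(clusters) + 1L]] <- list(
        genes = genes,
        labels = data.frame(reference_id = sub$protein_id,
                            group = sub$group, template = tmpl,
                            pathway = tmpl),
        on_plasmid = runif(1) < config$plasmid_probability)
    }
    g <- assemble_genome(tip, decoys, clusters,
                         intergenic_mean = config$intergenic_mean)
    if (!is.null(g$loci)) {
      ref_seq <- setNames(panel$sequence, panel$protein_id)
      g$loci$identity_to_reference <- vapply(seq_len(nrow(g$loci)),
        function(i) global_identity(g$proteome[[g$loci$gene_id[i]]],
                                    ref_seq[[g$loci$reference_id[i]]]),
        numeric(1))
      truth_loci[[tip]] <- g$loci
    }
    genomes[[tip]] <- g
  }
  loci <- if (length(truth_loci)) do.call(rbind, truth_loci) else
    data.frame()
  rownames(loci) <- NULL
  truth_genomes <- data.frame(
    genome_id = tips,
    is_degrader = unname(is_degrader),
    pathways = vapply(tips, function(t)
      paste(pathways_of[[t]] %||% character(0), collapse = ","), ""),
    n_clusters = vapply(tips, function(t)
      length(pathways_of[[t]] %||% character(0)), integer(1)),
    plasmid_only = vapply(tips, function(t) {
      l <- truth_loci[[t]]
      !is.null(l) && all(l$replicon_type == "plasmid")
    }, logical(1)))
  rownames(truth_genomes) <- NULL
  structure(list(genomes = genomes, markers = markers, species_tree = tree,
                 panel = panel,
                 truth = list(genomes = truth_genomes, loci = loci),
                 config = config),
            class = "steroid_community")
}

#' Write a community to disk (FASTA / GFF3 / TSV / newick / JSON)
#'
#' Emits one protein FASTA and one GFF3 per genome, the marker FASTA, the
#' species tree, the truth tables, and a JSON echo of the configuration.
#' Identical (config, seed) pairs produce byte-identical trees of files.
#'
#' @param community a [generate_community()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(file.path(dir, "proteomes"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), showWarnings = FALSE)
  for (g in community$genomes) {
    write_fasta(g$proteome,
                file.path(dir, "proteomes", paste0(g$genome_id, ".faa")))
    write_gff3(g$annotation, g$replicons,
               file.path(dir, "annotations", paste0(g$genome_id, ".gff3")))
  }
  write_fasta(community$markers, file.path(dir, "markers.faa"))
  ape::write.tree(community$species_tree,
                  file.path(dir, "species_tree.nwk"))
  write.table(community$truth$genomes, file.path(dir, "truth_genomes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(community$truth$loci, file.path(dir, "truth_loci.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- community$config
  cfg$species_tree <- if (is.null(cfg$species_tree)) NULL else
    ape::write.tree(cfg$species_tree)
  cfg$panel <- NULL
  cfg$model <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}
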