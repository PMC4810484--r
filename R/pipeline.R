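# End-to-end pipeline: reference binning -> subclustering -> HMM build and
# calibration -> proteome screening -> degrader classification -> reciprocal
# best-hit confirmation -> pathway assignment -> gene-cluster localization
# -> multilocus phylogeny and congruence against the 16S-like tree. Every
# numeric threshold lives in the pipeline configuration, with the screening
# procedure's published values as defaults.

#' Pipeline configuration (all stage thresholds)
#'
#' Defaults are the screening procedure's stated values: reference binning at
#' identity >= 30% and E <= 1e-30; reference expansion RBH at identity >=
#' 25% and E <= 1e-30; degrader-confirmation RBH at identity >= 25% and E <=
#' 1e-25; subclustering at identity >= 50% with word size 3; HMM screening
#' at E <= 1e-25; the degrader rule at >= 6 of 8 groups including the two
#' mandatory ones; pathway coverage >= 0.7; cluster chaining gap <= 10
#' genes; 2,500 bootstrap replicates.
#'
#' @param binning,rbh_expansion,rbh_confirmation lists with `min_identity`
#'   and `max_evalue`.
#' @param subcluster list with `min_identity` and `word_size`.
#' @param hmm_screen list with `max_evalue`.
#' @param classify list with `min_groups` and `mandatory`.
#' @param pathway list with `coverage_threshold`.
#' @param cluster list with `max_gap_genes`.
#' @param phylo list with `markers` and `bootstrap`.
#' @param calibration list with `n_random` null sequences per HMM.
#' @param n_expansion_genomes related proteomes per template for reference
#'   expansion.
#' @param seed master seed for calibration and bootstrap randomness.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(binning = list(min_identity = 0.30,
                                           max_evalue = 1e-30),
                            rbh_expansion = list(min_identity = 0.25,
                                                 max_evalue = 1e-30),
                            rbh_confirmation = list(min_identity = 0.25,
                                                    max_evalue = 1e-25),
                            subcluster = list(min_identity = 0.50,
                                              word_size = 3),
                            hmm_screen = list(max_evalue = 1e-25),
                            classify = list(min_groups = 6,
                                            mandatory = mandatory_groups),
                            pathway = list(coverage_threshold = 0.7),
                            cluster = list(max_gap_genes = 10),
                            phylo = list(markers = mlsa_marker_groups,
                                         bootstrap = 2500),
                            calibration = list(n_random = 1000),
                            n_expansion_genomes = 4,
                            seed = 1) {
  for (thr in list(binning, rbh_expansion, rbh_confirmation))
    if (thr$min_identity < 0 || thr$min_identity > 1 || thr$max_evalue <= 0)
      smx_stop("steromine_config_error", "invalid identity/E-value threshold")
  if (subcluster$min_identity <= 0 || subcluster$min_identity > 1 ||
      subcluster$word_size < 1)
    smx_stop("steromine_config_error", "invalid subcluster settings")
  if (classify$min_groups < 1)
    smx_stop("steromine_config_error", "min_groups must be >= 1")
  if (pathway$coverage_threshold < 0 || pathway$coverage_threshold > 1)
    smx_stop("steromine_config_error", "coverage_threshold must be in [0,1]")
  if (cluster$max_gap_genes < 0)
    smx_stop("steromine_config_error", "max_gap_genes must be >= 0")
  structure(list(binning = binning, rbh_expansion = rbh_expansion,
                 rbh_confirmation = rbh_confirmation,
                 subcluster = subcluster, hmm_screen = hmm_screen,
                 classify = classify, pathway = pathway, cluster = cluster,
                 phylo = phylo, calibration = calibration,
                 n_expansion_genomes = n_expansion_genomes, seed = seed),
            class = "pipeline_config")
}

#' Build the reference set, subclusters and calibrated HMMs
#'
#' Stages up to HMM calibration: expansion of the reference panel by
#' reciprocal best hits against related proteomes, binning of all reference
#' proteins into homologous groups, greedy subclustering within groups
#' (dropping subclusters without a seed panel protein), alignment, trimming,
#' profile construction, and Gumbel E-value calibration.
#'
#' @param panel a [generate_reference_panel()] result.
#' @param config a [pipeline_config()].
#' @param scoring a calibrated [scoring_scheme()].
#' @return list with `references`, `groups`, `subclusters`, `hmms`,
#'   `hmm_to_group`, `reference_genomes`, `group_of_reference`.
#' @export
build_reference_models <- function(panel, config = pipeline_config(),
                                   scoring = scoring_scheme()) {
  core <- panel_core(panel)
  templates <- unique(panel$template)
  ref_genomes <- list()
  references <- setNames(core$sequence, core$protein_id)
  for (i in seq_along(templates)) {
    tmpl <- templates[i]
    ref_genomes[[tmpl]] <- generate_reference_genome(
      panel, tmpl, seed = subseed(config$seed, 10 + i))
    related <- generate_related_proteomes(
      panel, tmpl, n_genomes = config$n_expansion_genomes,
      seed = subseed(config$seed, 40 + i))
    tpanel <- core[core$template == tmpl, ]
    ref_enc <- encode_many(ref_genomes[[tmpl]]$proteome)
    for (rel in related) {
      om <- reciprocal_best_hits(tpanel, rel,
                                 ref_genomes[[tmpl]]$proteome,
                                 mode = "expansion", scoring = scoring,
                                 reference_enc = ref_enc)
      om <- om[om$reciprocal, , drop = FALSE]
      references <- c(references, rel[om$target_id])
    }
  }
  graph <- build_graph(references,
                       min_identity = config$binning$min_identity,
                       max_evalue = config$binning$max_evalue,
                       scoring = scoring)
  comps <- connected_components(graph)

  # label components by the panel proteins they contain; components sharing
  # a seed group label are pooled (the subclustering stage separates their
  # families again)
  group_of_panel <- setNames(core$group, core$protein_id)
  pooled <- list()
  for (comp in comps) {
    seeds <- intersect(comp, core$protein_id)
    if (!length(seeds)) next
    glab <- unname(group_of_panel[seeds[1]])
    pooled[[glab]] <- c(pooled[[glab]], comp)
  }
  hmms <- list()
  hmm_to_group <- character(0)
  subcluster_sets <- list()
  groups <- list()
  for (glab in names(pooled)) {
    comp <- pooled[[glab]]
    seeds <- intersect(comp, core$protein_id)
    groups[[glab]] <- comp
    sc <- greedy_cluster(references[comp],
                         min_identity = config$subcluster$min_identity,
                         word_size = config$subcluster$word_size,
                         scoring = scoring)
    sc <- retain_seeded(sc, seeds)
    subcluster_sets[[glab]] <- sc
    for (j in seq_along(sc$clusters)) {
      members <- references[sc$clusters[[j]]]
      if (length(members) < 2) next
      aln <- trim_columns(progressive_align(members, scoring))
      attr(aln, "subcluster_id") <- sprintf("%s.sc%d", glab, j)
      hmm <- build_profile(aln)
      hmm <- calibrate_evalue(hmm,
                              n_random = config$calibration$n_random,
                              seed = subseed(config$seed,
                                             1000 + 10 * match(glab, names(groups)) + j))
      hid <- sprintf("%s.h%d", glab, j)
      hmms[[hid]] <- hmm
      hmm_to_group[hid] <- glab
    }
  }
  if (!length(hmms))
    smx_stop("steromine_analysis_error", "no HMM could be built")
  list(references = references, graph = graph, groups = groups,
       subclusters = subcluster_sets, hmms = hmms,
       hmm_to_group = hmm_to_group, reference_genomes = ref_genomes,
       group_of_reference = setNames(panel$group, panel$protein_id))
}

#' Run the full screening pipeline on a community
#'
#' Executes the stages in the screening procedure's order -- HMM screening
#' of every proteome, degrader classification, reciprocal-best-hit
#' confirmation of the called genomes against each pathway panel, pathway
#' assignment by panel coverage, gene-cluster detection and plasmid
#' localization, and the multilocus phylogeny with congruence against the
#' 16S-like tree -- and returns a run report. With `out_dir` set, all
#' tables, trees and a JSON report are persisted; reruns with the same seed
#' are byte-identical.
#'
#' @param community a [generate_community()] result (or
#'   [read_community()] output plus `panel`).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param models optional precomputed [build_reference_models()] result.
#' @param scoring a calibrated [scoring_scheme()].
#' @return a `run_report` list.
#' @export
run_pipeline <- function(community, config = pipeline_config(),
                         out_dir = NULL, models = NULL,
                         scoring = scoring_scheme()) {
  panel <- community$panel
  if (is.null(panel))
    smx_stop("steromine_config_error", "community carries no panel")
  core_groups <- unique(panel_core(panel)$group)
  if (config$classify$min_groups > length(core_groups))
    smx_stop("steromine_config_error",
             "min_groups = %d exceeds the panel's %d groups",
             config$classify$min_groups, length(core_groups))
  models <- models %||% build_reference_models(panel, config, scoring)
  epanel <- enzyme_panel(groups = core_groups,
                         mandatory = config$classify$mandatory,
                         hmm_to_group = models$hmm_to_group)
  templates <- unique(panel$template)
  genomes <- community$genomes
  proteomes <- lapply(genomes, `[[`, "proteome")

  # --- HMM screening and classification -------------------------------
  hits_all <- list()
  verdicts <- list()
  for (gid in names(genomes)) {
    hits <- screen_proteome(models$hmms, proteomes[[gid]],
                            max_evalue = config$hmm_screen$max_evalue,
                            genome_id = gid)
    hits_all[[gid]] <- hits
    call <- classify_degrader(hits, epanel,
                              min_groups = config$classify$min_groups)
    verdicts[[gid]] <- data.frame(
      genome_id = gid, n_groups_present = length(call$groups_present),
      groups_present = paste(call$groups_present, collapse = ","),
      mandatory_satisfied = call$mandatory_satisfied,
      verdict = call$verdict)
  }
  hits_all <- do.call(rbind, hits_all)
  rownames(hits_all) <- NULL
  verdicts <- do.call(rbind, verdicts)
  rownames(verdicts) <- NULL
  called <- verdicts$genome_id[verdicts$verdict == "degrader"]

  # --- RBH confirmation, identity matrices, pathway assignment --------
  omaps <- list()      # omaps[[genome]][[template]]
  id_mats <- list()
  pathway_calls <- list()
  panel_sizes <- vapply(templates, function(t) sum(panel$template == t),
                        integer(1))
  for (tmpl in templates)
    id_mats[[tmpl]] <- matrix(NA_real_, panel_sizes[[tmpl]], length(called),
                              dimnames = list(
                                panel$protein_id[panel$template == tmpl],
                                called))
  ref_enc <- lapply(templates, function(t)
    encode_many(models$reference_genomes[[t]]$proteome))
  names(ref_enc) <- templates
  for (gid in called) {
    omaps[[gid]] <- list()
    target_enc <- encode_many(proteomes[[gid]])
    for (tmpl in templates) {
      tpanel <- panel[panel$template == tmpl, ]
      om <- reciprocal_best_hits(
        tpanel, proteomes[[gid]], models$reference_genomes[[tmpl]]$proteome,
        mode = "confirmation", scoring = scoring,
        target_enc = target_enc, reference_enc = ref_enc[[tmpl]])
      omaps[[gid]][[tmpl]] <- om
      rec <- om[om$reciprocal, , drop = FALSE]
      id_mats[[tmpl]][rec$reference_id, gid] <- rec$identity
    }
    pc <- assign_pathway(omaps[[gid]], panel_sizes,
                         coverage_threshold = config$pathway$coverage_threshold)
    pc$genome_id <- gid
    pc$side_chain <- vapply(pc$pathway, function(t) {
      acc <- panel$protein_id[panel$template == t &
                                (panel$role %||% "core") == "accessory"]
      if (!length(acc)) return(NA_character_)
      side_chain_profile(omaps[[gid]][[t]], acc)
    }, character(1))
    pathway_calls[[gid]] <- pc
  }
  pathway_calls <- if (length(pathway_calls))
    do.call(rbind, pathway_calls) else
    data.frame(pathway = character(), coverage = numeric(),
               assigned = logical(), genome_id = character(),
               side_chain = character())
  rownames(pathway_calls) <- NULL

  # --- gene localization and clustering --------------------------------
  cluster_calls <- list()
  for (gid in called) {
    rec <- do.call(rbind, lapply(omaps[[gid]], function(om)
      om[om$reciprocal, , drop = FALSE]))
    if (!nrow(rec)) next
    hit_df <- data.frame(protein_id = rec$target_id,
                         group = unname(
                           models$group_of_reference[rec$reference_id]))
    located <- locate_hits(hit_df, genomes[[gid]]$annotation)
    n_genes <- setNames(genomes[[gid]]$replicons$n_genes %||%
                          as.integer(table(genomes[[gid]]$annotation$replicon_id)[
                            genomes[[gid]]$replicons$replicon_id]),
                        genomes[[gid]]$replicons$replicon_id)
    cluster_calls[[gid]] <- detect_clusters(
      located, n_genes, max_gap_genes = config$cluster$max_gap_genes)
  }
  cluster_calls <- if (length(cluster_calls))
    do.call(rbind, cluster_calls) else detect_clusters(
      data.frame()[0, ], integer(0))
  rownames(cluster_calls) <- NULL
  summary_tbl <- replicon_summary(cluster_calls)

  # --- multilocus phylogeny and congruence ----------------------------
  phylo_res <- NULL
  if (nrow(cluster_calls) >= 3) {
    marker_sets <- tryCatch(
      extract_markers(cluster_calls, proteomes,
                      marker_groups = config$phylo$markers),
      steromine_analysis_error = function(e) NULL)
    if (!is.null(marker_sets) && length(marker_sets) >= 3) {
      sm <- build_supermatrix(marker_sets, scoring)
      gene_tree <- bootstrap_support(sm, n_replicates = config$phylo$bootstrap,
                                     seed = subseed(config$seed, 7))
      # one taxon per genome for the congruence comparison
      genome_of_taxon <- sub("\\.cl[0-9]+$", "", gene_tree$tip.label)
      keep <- !duplicated(genome_of_taxon)
      gtree <- ape::keep.tip(gene_tree, gene_tree$tip.label[keep])
      gtree$tip.label <- genome_of_taxon[keep]
      marker_aln <- trim_columns(progressive_align(community$markers,
                                                   scoring))
      tree_16s <- nj_tree(distance_matrix(marker_aln))
      phylo_res <- list(
        supermatrix_columns = ncol(sm),
        n_taxa = length(marker_sets),
        dropped_taxa = attr(marker_sets, "dropped"),
        gene_tree = gene_tree,
        gene_tree_by_genome = gtree,
        tree_16s = tree_16s,
        rf_gene_vs_16s = rf_distance(gtree, tree_16s),
        rf_gene_vs_species = if (!is.null(community$species_tree))
          rf_distance(gtree, community$species_tree) else NA_integer_,
        rf_16s_vs_species = if (!is.null(community$species_tree))
          rf_distance(tree_16s, community$species_tree) else NA_integer_)
    }
  }

  report <- structure(list(
    config = config,
    counts = list(
      n_genomes = length(genomes),
      n_reference_proteins = length(models$references),
      n_groups = length(models$groups),
      n_subclusters = sum(vapply(models$subclusters,
                                 function(s) length(s$clusters), integer(1))),
      n_hmms = length(models$hmms),
      n_hmm_hits = nrow(hits_all),
      n_called_degraders = length(called),
      n_gene_clusters = nrow(cluster_calls)),
    hits = hits_all, verdicts = verdicts, identity_matrices = id_mats,
    ortholog_maps = omaps, pathway_calls = pathway_calls,
    cluster_calls = cluster_calls, replicon_summary = summary_tbl,
    phylo = phylo_res, models = models,
    version = as.character(utils::packageVersion("steromine"))),
    class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, community, out_dir)
  report
}

#' In-silico phylogenetic congruence experiment
#'
#' Simulates an all-degrader community carrying a single pathway template
#' under pure vertical descent or with one long-range horizontal transfer
#' (donor and recipient chosen as the most distant leaf pair of the species
#' tree), runs the full pipeline, and reports Robinson-Foulds distances
#' between the concatenated-marker gene tree, the 16S-like tree and the true
#' species tree. Under vertical descent the marker tree is congruent with
#' the 16S tree (RF 0); one long-range transfer breaks congruence (RF > 0).
#'
#' @param seed master seed for community and pipeline.
#' @param hgt logical; add the horizontal-transfer event.
#' @param n_genomes community size.
#' @param n_decoys decoy genes per genome.
#' @param bootstrap bootstrap replicate count.
#' @param template pathway template to plant.
#' @return list with `rf_gene_vs_16s`, `rf_gene_vs_species`,
#'   `rf_16s_vs_species`, `hgt_event` and the full `report`.
#' @export
congruence_experiment <- function(seed, hgt = FALSE, n_genomes = 8,
                                  n_decoys = 30, bootstrap = 100,
                                  template = "cholesterol") {
  base_cfg <- function(hgt_events = NULL)
    community_config(n_genomes = n_genomes, degrader_fraction = 1,
                     pathway_templates = template,
                     target_identity_range = c(0.6, 0.8),
                     n_decoys_per_genome = n_decoys, n_near_decoys = 2,
                     plasmid_probability = 0.2, hgt_events = hgt_events,
                     seed = seed)
  com <- generate_community(base_cfg())
  ev <- NULL
  if (hgt) {
    dm <- ape::cophenetic.phylo(com$species_tree)
    pair <- which(dm == max(dm), arr.ind = TRUE)[1, ]
    ev <- data.frame(donor = rownames(dm)[pair[1]],
                     recipient = colnames(dm)[pair[2]],
                     pathway = template)
    com <- generate_community(base_cfg(ev))
  }
  pcfg <- pipeline_config(phylo = list(markers = mlsa_marker_groups,
                                       bootstrap = bootstrap), seed = seed)
  report <- run_pipeline(com, pcfg)
  if (is.null(report$phylo))
    smx_stop("steromine_analysis_error",
             "congruence experiment yielded no phylogeny")
  list(rf_gene_vs_16s = report$phylo$rf_gene_vs_16s,
       rf_gene_vs_species = report$phylo$rf_gene_vs_species,
       rf_16s_vs_species = report$phylo$rf_16s_vs_species,
       hgt_event = ev, report = report)
}

#' Persist a run report as TSV / newick / JSON files
#' @param report a [run_pipeline()] result.
#' @param community the community the report was computed on.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, community, out_dir) {
  dir.create(file.path(out_dir, "trees"), recursive = TRUE,
             showWarnings = FALSE)
  wt <- function(df, f) write.table(df, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(report$verdicts, "degrader_calls.tsv")
  wt(report$hits, "hmm_hits.tsv")
  wt(report$pathway_calls, "pathway_assignments.tsv")
  wt(report$cluster_calls, "gene_clusters.tsv")
  wt(report$replicon_summary, "replicon_summary.tsv")
  for (tmpl in names(report$identity_matrices)) {
    M <- report$identity_matrices[[tmpl]]
    df <- data.frame(reference_id = rownames(M),
                     round(M, 4), check.names = FALSE)
    wt(df, sprintf("identity_matrix_%s.tsv", tmpl))
  }
  om_all <- do.call(rbind, lapply(names(report$ortholog_maps), function(g) {
    do.call(rbind, lapply(names(report$ortholog_maps[[g]]), function(t) {
      om <- as.data.frame(report$ortholog_maps[[g]][[t]])
      if (nrow(om)) { om$genome_id <- g; om$panel <- t }
      om
    }))
  }))
  if (!is.null(om_all) && nrow(om_all)) wt(om_all, "ortholog_maps.tsv")
  for (sc in names(report$models$subclusters))
    write_clstr(report$models$subclusters[[sc]],
                file.path(out_dir, sprintf("subclusters_%s.clstr", sc)))
  dir.create(file.path(out_dir, "hmms"), showWarnings = FALSE)
  for (hid in names(report$models$hmms))
    write_profile_hmm(report$models$hmms[[hid]],
                      file.path(out_dir, "hmms", paste0(hid, ".hmm")))
  if (!is.null(report$phylo)) {
    ape::write.tree(report$phylo$gene_tree,
                    file.path(out_dir, "trees", "gene_tree.nwk"))
    ape::write.tree(report$phylo$tree_16s,
                    file.path(out_dir, "trees", "tree_16s.nwk"))
  }
  if (!is.null(community$species_tree))
    ape::write.tree(community$species_tree,
                    file.path(out_dir, "trees", "species_tree_true.nwk"))
  json <- list(
    version = report$version,
    seed = report$config$seed,
    config = unclass(report$config),
    counts = report$counts,
    degraders = report$verdicts$genome_id[
      report$verdicts$verdict == "degrader"],
    rf_gene_vs_16s = report$phylo$rf_gene_vs_16s,
    rf_gene_vs_species = report$phylo$rf_gene_vs_species)
  jsonlite::write_json(json, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}
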