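# Reference panel generation: eight orthologous enzyme groups spanning three
# pathway templates (cholesterol, cholate, testosterone/cholate), with the
# two groups required of every degrader call -- the 3-ketosteroid
# 9a-hydroxylase oxygenase (KshA-like) and the ring-cleaving extradiol
# dioxygenase (HsaC-like) -- flagged mandatory.

canonical_groups <- c("KstD", "KshA", "HsaA", "HsaC", "HsaD", "HsaE",
                      "HsaF", "HsaG")
mandatory_groups <- c("KshA", "HsaC")

#' Generate a labeled reference panel of pathway proteins
#'
#' For each enzyme group an ancestral protein is drawn from background
#' frequencies and diverged once per pathway template, so that
#' between-template orthologs sit near `cross_template_identity` -- inside
#' the 30% binning threshold but below the 50% subclustering threshold,
#' which makes templates bin together and subcluster apart, as the reference
#' pathways do.
#'
#' @param n_groups number of enzyme groups (>= 1; default 8). Groups carry
#'   the canonical names (KstD, KshA, HsaA, HsaC, HsaD, HsaE, HsaF, HsaG)
#'   while available; KshA-like and HsaC-like groups are flagged mandatory.
#' @param length_range integer range of ancestor lengths (residues, >= 30;
#'   the default floor of 300 keeps between-template alignment scores well
#'   inside the binning E-value cutoff).
#' @param seed integer seed; identical calls are byte-identical.
#' @param templates pathway template names (one reference per group each).
#' @param cross_template_identity expected identity between orthologs from
#'   different templates.
#' @param n_accessory pathway-specific accessory genes per template
#'   (side-chain degradation and transport genes unique to each reference
#'   cluster); unrelated across templates. They are part of each pathway's
#'   gene cluster and its coverage panel but carry no HMM group.
#' @param model an [evolution_model()].
#' @return `reference_panel` data frame: `template`, `group`, `protein_id`,
#'   `mandatory`, `role` (`"core"`/`"accessory"`), `sequence`.
#' @export
generate_reference_panel <- function(n_groups = 8,
                                     length_range = c(300, 450), seed = 1,
                                     templates = c("cholesterol", "cholate",
                                                   "testosterone_cholate"),
                                     cross_template_identity = 0.36,
                                     n_accessory = 6,
                                     model = evolution_model()) {
  if (!is.numeric(n_groups) || n_groups < 1)
    smx_stop("steromine_parameter_error", "n_groups must be >= 1")
  if (length(length_range) != 2 || any(length_range < 30) ||
      length_range[1] > length_range[2])
    smx_stop("steromine_parameter_error",
             "length_range must be an increasing pair of lengths >= 30")
  set.seed(seed)
  groups <- if (n_groups <= length(canonical_groups))
    canonical_groups[seq_len(n_groups)]
  else c(canonical_groups, sprintf("grp%02d", seq_len(n_groups - 8)))
  # panel references diverge by substitution only, so every family keeps a
  # fixed reference length; indels enter through relatives and communities
  model <- evolution_model(indel_rate = 0,
                           indel_length_mean = model$indel_length_mean,
                           seed = model$seed)
  d_half <- divergence_for_identity(model, cross_template_identity) / 2
  t_half <- expected_identity(model, d_half)
  rows <- list()
  for (g in groups) {
    L <- length_range[1] +
      sample.int(length_range[2] - length_range[1] + 1L, 1) - 1L
    anc <- random_protein(L)
    for (tmpl in templates) {
      seqs <- evolve_sequence(anc, t_half, model)
      rows[[length(rows) + 1L]] <- data.frame(
        template = tmpl, group = g,
        protein_id = paste(tmpl, g, sep = "."),
        mandatory = g %in% mandatory_groups, role = "core",
        sequence = as.character(seqs))
    }
  }
  for (tmpl in templates) {
    for (i in seq_len(n_accessory)) {
      L <- length_range[1] +
        sample.int(length_range[2] - length_range[1] + 1L, 1) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        template = tmpl, group = sprintf("acc%02d", i),
        protein_id = paste(tmpl, sprintf("acc%02d", i), sep = "."),
        mandatory = FALSE, role = "accessory",
        sequence = random_protein(L))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("reference_panel", "data.frame")
  out
}

# core (HMM-bearing) rows of a reference panel
panel_core <- function(panel) {
  if (is.null(panel$role)) return(panel)
  panel[panel$role == "core", , drop = FALSE]
}

#' Related proteomes for reference-set expansion
#'
#' Emulates the close relatives of the reference organisms from which the
#' initial reference set is expanded by reciprocal best hits before
#' subclustering: each related proteome carries one ortholog per enzyme
#' group at high identity to its template's reference, plus decoys.
#'
#' @param panel a [generate_reference_panel()] result.
#' @param template template name.
#' @param n_genomes number of related proteomes.
#' @param identity_range ortholog identity band to the template reference.
#' @param n_decoys decoys per proteome.
#' @param seed integer seed.
#' @param model an [evolution_model()].
#' @return named list of proteomes (named character vectors).
#' @export
generate_related_proteomes <- function(panel, template, n_genomes = 4,
                                       identity_range = c(0.78, 0.90),
                                       n_decoys = 30, seed = 1,
                                       model = evolution_model()) {
  if (!template %in% panel$template)
    smx_stop("steromine_config_error", "template '%s' not in panel", template)
  set.seed(seed)
  sub <- panel[panel$template == template, , drop = FALSE]
  out <- list()
  for (k in seq_len(n_genomes)) {
    orth <- vapply(seq_len(nrow(sub)), function(i)
      as.character(evolve_sequence(sub$sequence[i],
                                   runif(1, identity_range[1],
                                         identity_range[2]), model)),
      character(1))
    names(orth) <- sprintf("%s_rel%d_%s", template, k, sub$group)
    dec <- vapply(seq_len(n_decoys), function(i)
      random_protein(sample(80:400, 1)), character(1))
    names(dec) <- sprintf("%s_rel%d_dec%03d", template, k, seq_len(n_decoys))
    out[[sprintf("%s_rel%d", template, k)]] <- c(orth, dec)
  }
  out
}

#' Synthetic reference genome for one pathway template
#'
#' The template's panel proteins planted as one contiguous gene cluster on a
#' circular chromosome among random decoy genes: the back-search database
#' for reciprocal-best-hit confirmation and the all-identity-1 column of the
#' identity matrix.
#'
#' @param panel a [generate_reference_panel()] result.
#' @param template template name present in the panel.
#' @param n_decoys decoy gene count.
#' @param seed integer seed.
#' @param model an [evolution_model()] (reserved; decoys are background
#'   draws).
#' @return a genome record (list with `genome_id`, `proteome`, `annotation`,
#'   `replicons`, `loci`).
#' @export
generate_reference_genome <- function(panel, template, n_decoys = 80,
                                      seed = 1, model = evolution_model()) {
  if (!template %in% panel$template)
    smx_stop("steromine_config_error", "template '%s' not in panel", template)
  set.seed(seed)
  sub <- panel[panel$template == template, , drop = FALSE]
  genes <- setNames(sub$sequence, sub$protein_id)
  decoys <- setNames(
    vapply(seq_len(n_decoys), function(i) random_protein(sample(80:400, 1)),
           character(1)),
    sprintf("REF_%s_d%03d", template, seq_len(n_decoys)))
  assemble_genome(paste0("REF_", template), decoys,
                  clusters = list(list(
                    genes = genes,
                    labels = data.frame(reference_id = sub$protein_id,
                                        group = sub$group,
                                        template = template,
                                        pathway = template),
                    on_plasmid = FALSE)),
                  keep_ids = TRUE)
}
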