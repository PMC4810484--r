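# Degrader classification: a genome is called a putative steroid degrader
# when its proteome hits at least six of the eight key enzyme groups,
# including both mandatory groups -- the 3-ketosteroid 9a-hydroxylase
# oxygenase subunit (KshA group) and the A-ring extradiol dioxygenase
# (HsaC group). The mandatory groups count toward the six. Pathway labels
# come from reciprocal-best-hit coverage of per-pathway reference panels.

#' Enzyme panel for the degrader decision rule
#'
#' @param groups ordered enzyme-group ids (default the eight canonical
#'   groups).
#' @param mandatory groups that every degrader must hit (default the
#'   KshA-like and HsaC-like groups).
#' @param hmm_to_group named character vector mapping each HMM id to its
#'   enzyme group.
#' @return an `enzyme_panel` list.
#' @export
enzyme_panel <- function(groups = canonical_groups,
                         mandatory = mandatory_groups,
                         hmm_to_group = NULL) {
  if (!all(mandatory %in% groups))
    smx_stop("steromine_config_error", "mandatory must be a subset of groups")
  if (!is.null(hmm_to_group) && !all(hmm_to_group %in% groups))
    smx_stop("steromine_config_error",
             "hmm_to_group maps to unknown group(s)")
  structure(list(groups = groups, mandatory = mandatory,
                 hmm_to_group = hmm_to_group), class = "enzyme_panel")
}

#' Classify one genome as degrader / non-degrader
#'
#' Applies the presence/absence rule to a genome's HMM hits: at least
#' `min_groups` of the panel's enzyme groups present, including every
#' mandatory group.
#'
#' @param hits data frame of [screen_proteome()] hits for one genome.
#' @param panel an [enzyme_panel()] with `hmm_to_group` set.
#' @param min_groups minimum number of groups present (default 6 of 8).
#' @return a `degrader_call` list: `genome_id`, `groups_present`,
#'   `mandatory_satisfied`, `verdict`.
#' @export
classify_degrader <- function(hits, panel, min_groups = 6) {
  if (is.null(panel$hmm_to_group))
    smx_stop("steromine_config_error", "panel has no hmm_to_group map")
  if (min_groups > length(panel$groups))
    smx_stop("steromine_config_error",
             "min_groups exceeds the panel's group count")
  gid <- unique(hits$genome_id)
  if (length(gid) > 1)
    smx_stop("steromine_input_error", "hits span more than one genome")
  unknown <- setdiff(unique(hits$hmm_id), names(panel$hmm_to_group))
  if (length(unknown))
    smx_stop("steromine_config_error", "hit references unknown HMM id: %s",
             unknown[1])
  groups_present <- sort(unique(unname(panel$hmm_to_group[hits$hmm_id])))
  mandatory_ok <- all(panel$mandatory %in% groups_present)
  structure(list(
    genome_id = if (length(gid)) gid else NA_character_,
    groups_present = groups_present,
    mandatory_satisfied = mandatory_ok,
    verdict = if (length(groups_present) >= min_groups && mandatory_ok)
      "degrader" else "non-degrader"), class = "degrader_call")
}

#' Assign pathway labels from reference-panel coverage
#'
#' A pathway label is assigned iff the fraction of that pathway panel's
#' reference proteins with a reciprocal best hit reaches
#' `coverage_threshold` (inclusive). "Large majority" is quantified as 0.7
#' by default.
#'
#' @param ortholog_maps named list of `ortholog_map`s, one per pathway
#'   reference panel, all for the same genome.
#' @param panel_sizes named integer vector: reference protein count of each
#'   panel.
#' @param coverage_threshold minimum coverage fraction.
#' @return data frame (`pathway`, `coverage`, `assigned`).
#' @export
assign_pathway <- function(ortholog_maps, panel_sizes,
                           coverage_threshold = 0.7) {
  if (!length(ortholog_maps))
    smx_stop("steromine_config_error", "need at least one reference panel")
  if (!all(names(ortholog_maps) %in% names(panel_sizes)))
    smx_stop("steromine_config_error", "panel_sizes missing some panels")
  cov <- vapply(names(ortholog_maps), function(p) {
    om <- ortholog_maps[[p]]
    sum(om$reciprocal) / panel_sizes[[p]]
  }, numeric(1))
  data.frame(pathway = names(ortholog_maps), coverage = unname(cov),
             assigned = unname(cov >= coverage_threshold))
}

#' Side-chain degradation gene profile
#'
#' Summarizes how much of a pathway's side-chain degradation gene set a
#' genome carries: `present` at >= 80% hit, `absent` at <= 20%, `partial`
#' in between.
#'
#' @param ortholog_map an `ortholog_map` for the genome.
#' @param side_chain_gene_ids reference ids of the side-chain genes.
#' @param bands upper/lower coverage bounds, default `c(0.8, 0.2)`.
#' @return one of `"present"`, `"partial"`, `"absent"`.
#' @export
side_chain_profile <- function(ortholog_map, side_chain_gene_ids,
                               bands = c(0.8, 0.2)) {
  hit <- side_chain_gene_ids %in%
    ortholog_map$reference_id[ortholog_map$reciprocal]
  frac <- mean(hit)
  if (frac >= bands[1]) "present"
  else if (frac <= bands[2]) "absent"
  else "partial"
}
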