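#!/usr/bin/env Rscript

# Simulate the study community: 20 annotated genomes along a random species
# tree, half of them carrying one steroid-degradation pathway template
# (cholesterol, cholate, or testosterone/cholate) planted as a contiguous
# gene cluster at 50-70% identity to the reference panel, on the chromosome
# or a plasmid, among 500 decoy genes; 16S-like markers evolve along the
# same tree. Writes FASTA/GFF3/newick/TSV under results/community/.

library(steromine)

seed <- 101
cfg <- community_config(
  n_genomes = 20, degrader_fraction = 0.5,
  target_identity_range = c(0.5, 0.7), n_decoys_per_genome = 500,
  n_near_decoys = 5, plasmid_probability = 0.3, seed = seed)
com <- generate_community(cfg)
write_community(com, "results/community")

truth <- com$truth$genomes
message(sprintf("Simulated %d genomes (%d degraders: %s).",
                nrow(truth), sum(truth$is_degrader),
                paste(truth$genome_id[truth$is_degrader], collapse = " ")))
message(sprintf("Planted gene identities to the panel: mean %.3f (band %s).",
                mean(com$truth$loci$identity_to_reference),
                paste(cfg$target_identity_range, collapse = "-")))
message(sprintf("%d of the planted clusters sit on plasmids.",
                sum(truth$plasmid_only)))
message("Community written to results/community/.")
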