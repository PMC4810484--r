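#!/usr/bin/env Rscript

# Figures from the pipeline run of step 02: the reciprocal-best-hit
# identity heat map (reference proteins x called genomes, one panel per
# pathway template) and the gene-position dot map of detected clusters by
# replicon type. PNGs land in results/figures/.

library(steromine)

seed <- 101
com <- generate_community(community_config(
  n_genomes = 20, degrader_fraction = 0.5,
  target_identity_range = c(0.5, 0.7), n_decoys_per_genome = 500,
  n_near_decoys = 5, plasmid_probability = 0.3, seed = seed))
report <- run_pipeline(
  com, pipeline_config(phylo = list(markers = c("KshA", "HsaA", "HsaC",
                                                "HsaD"), bootstrap = 100),
                       seed = seed))

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

for (tmpl in names(report$identity_matrices)) {
  M <- report$identity_matrices[[tmpl]]
  if (!ncol(M) || all(is.na(M))) next
  png(sprintf("results/figures/identity_heatmap_%s.png", tmpl),
      width = 900, height = 700, res = 110)
  pheatmap::pheatmap(replace(M, is.na(M), 0), cluster_rows = FALSE,
                     cluster_cols = FALSE,
                     main = sprintf("RBH identity to the %s panel", tmpl),
                     color = hcl.colors(50, "YlOrRd", rev = TRUE))
  dev.off()
}

cl <- report$cluster_calls
loc <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
  ids <- strsplit(cl$members[i], ",")[[1]]
  ann <- com$genomes[[cl$genome_id[i]]]$annotation
  data.frame(genome = cl$genome_id[i],
             pos = ann$start[match(ids, ann$gene_id)] / 1e6,
             type = cl$replicon_type[i])
}))
png("results/figures/gene_position_dotmap.png", width = 900, height = 600,
    res = 110)
par(mar = c(4, 6, 2, 8), xpd = TRUE)
genomes <- sort(unique(loc$genome))
plot(loc$pos, match(loc$genome, genomes), yaxt = "n",
     pch = 16, cex = 0.8, col = adjustcolor(
       ifelse(loc$type == "plasmid", "firebrick", "steelblue"), 0.6),
     xlab = "Gene position (Mb)", ylab = "")
axis(2, at = seq_along(genomes), labels = genomes, las = 1, cex.axis = 0.7)
legend("topright", inset = c(-0.25, 0), pch = 16,
       col = c("steelblue", "firebrick"),
       legend = c("chromosome", "plasmid"), bty = "n")
dev.off()

message("Figures written to results/figures/ (one heat map per pathway ",
        "panel, plus the cluster dot map).")
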