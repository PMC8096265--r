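#!/usr/bin/env Rscript
# Stage 1: generate the synthetic screen at published scale -- a 5459-shRNA /
# 1010-gene library (5451 target guides + 8 controls), five replicates, gates
# at 7% (reporter-positive) and 77.5% (reporter-negative), 2e6 reads per
# sorted sample, with 5% of genes planted as hits. Writes the manifest, the
# count matrix and the ground truth under results/screen/.

suppressPackageStartupMessages(library(checs))
dir.create("results/screen", showWarnings = FALSE, recursive = TRUE)

manifest <- build_manifest(1010, c(4, 6), n_controls = 8, seed = 2026,
                           n_guides_total = 5451)
cat(sprintf("library: %d shRNAs (%d targeting, %d controls) over %d genes\n",
            nrow(manifest), sum(!manifest$is_control),
            sum(manifest$is_control),
            length(unique(manifest$gene_id[!manifest$is_control]))))
cat(sprintf("coverage at transduction: %.1f cells per shRNA (30e6 cells, 10%%)\n",
            cells_per_guide(30e6, 0.10, nrow(manifest))))

params <- screen_sim_params(seed = 2027)   # defaults are the study conditions
sim <- simulate_screen(manifest, params)
cat(sprintf("simulated %d replicates, %d cells each, %g reads per sample\n",
            params$n_replicates, 550L * nrow(manifest), params$reads_per_sample))
cat(sprintf("planted hits: %d of %d genes (escape %.2f vs background %.2f)\n",
            sum(sim$truth$genes$is_hit), nrow(sim$truth$genes),
            params$hit_escape_prob, params$background_escape_prob))

write_manifest(manifest, "results/screen/manifest.tsv")
write_counts(sim$counts, "results/screen/counts.tsv")
write.table(sim$truth$genes, "results/screen/truth_genes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$guides, "results/screen/truth_guides.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/screen/{manifest,counts,truth_genes,truth_guides}.tsv\n")
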