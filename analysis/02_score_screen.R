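#!/usr/bin/env Rscript
# Stage 2: score the simulated screen -- per-lane normalization, per-replicate
# pos/neg enrichment ratios with the 1e-3 depletion floor, geometric-mean AES,
# gene scores on the natural-log scale, Poisson P-values combined by Fisher's
# method and Bonferroni-corrected -- then check hit recovery against the
# planted truth. Requires stage 1 outputs.

suppressPackageStartupMessages(library(checs))

run_screen_pipeline(list(manifest = "results/screen/manifest.tsv",
                         counts = "results/screen/counts.tsv",
                         out_dir = "results/screen"))

tab <- read.delim("results/screen/gene_scores.tsv")
truth <- read.delim("results/screen/truth_genes.tsv")
hits <- truth$gene_id[truth$is_hit]

cat("\ntop 10 genes by log gene score:\n")
print(tab[1:10, c("rank", "gene_id", "n_guides", "log_gene_score",
                  "combined_p", "bonferroni_p", "direction")],
      row.names = FALSE)

n_hits <- length(hits)
recovered <- sum(hits %in% tab$gene_id[seq_len(n_hits)])
cat(sprintf("\nplanted hits: %d; recovered in the top %d ranks: %d\n",
            n_hits, n_hits, recovered))
cat(sprintf("planted hits with Bonferroni P < 0.05: %d of %d\n",
            sum(tab$bonferroni_p[tab$gene_id %in% hits] < 0.05), n_hits))
cat(sprintf("background genes with Bonferroni P < 0.05: %d of %d\n",
            sum(tab$bonferroni_p[!(tab$gene_id %in% hits)] < 0.05),
            nrow(tab) - n_hits))
cat("ranked table written to results/screen/gene_scores.tsv\n")
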