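#!/usr/bin/env Rscript
# Fusion-transcript integration: classify each gene-transposon fusion as
# activating (splice donor, sense) or truncating (either splice acceptor),
# and test whether fusion-supported genes are enriched among CIS genes
# against the full simulated gene universe.

suppressMessages(library(pbscreen))

fusions <- read_fusions("results/sim/fusions.tsv")
genes <- read_gff3_genes("results/sim/genes.gff3")
ranked <- read.delim("results/cis_genes.tsv")

fusions$effect <- classify_fusion(fusions$feature, fusions$orientation)
print(table(fusions$feature, fusions$effect))

enr <- overlap_enrichment(ranked$name, unique(fusions$gene), genes$name)
message(sprintf("%d of %d CIS genes have fusion support (%d fusion genes, universe %d): p = %.3g, OR = %.2f",
                enr$n_cis_with_fusion, enr$n_cis, enr$n_fusion_genes,
                enr$universe_size, enr$p_two_sided, enr$odds_ratio))

write.table(fusions, "results/fusion_effects.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(as.data.frame(enr), "results/fusion_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/fusion_effects.tsv, results/fusion_enrichment.tsv")
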