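#!/usr/bin/env Rscript
# Associate CIS with genes, roll up per-gene insertion statistics and
# activating/disrupting pattern calls, and rank the CIS genes by insertion
# recurrence (the oncoprint-style hit list). Recovery is checked against
# the generator's ground truth.

suppressMessages(library(pbscreen))

cis <- read.delim("results/cis.tsv")
cis$members <- lapply(strsplit(cis$members, ","), as.integer)
pooled <- read.delim("results/pooled_insertions.tsv")
genes <- read_gff3_genes("results/sim/genes.gff3")
truth_ranking <- readLines("results/sim/truth_ranking.txt")

assoc <- associate_genes(cis, genes)
cg <- cis_gene_table(cis, assoc, pooled, genes)
ranked <- rank_cis_genes(cg, c(brain = 46, spinal = 50))

print(ranked[c("rank", "name", "total_insertions", "n_tumors", "pct_tumors",
               "n_brain", "n_spinal", "label")])
recovered <- intersect(truth_ranking, ranked$name)
message(sprintf("recovered %d/%d ground-truth drivers; top-ranked gene %s a driver",
                length(recovered), length(truth_ranking),
                if (ranked$name[1] %in% truth_ranking) "is" else "is not"))

write.table(ranked, "results/cis_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(assoc, "results/cis_gene_associations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/cis_genes.tsv, results/cis_gene_associations.tsv")
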