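#!/usr/bin/env Rscript
# Simulate the reference screen used throughout the analysis: a 3 x 10 Mb
# genome with TTAA motifs at the random-sequence rate, 80 genes, and a
# 46-brain + 50-spinal tumor cohort carrying five ground-truth drivers
# (pi = 0.4 per tumor, mixed gene-trap / activating patterns) over ~200
# background insertions per tumor. Everything is written as plain text
# under results/sim/.

suppressMessages(library(pbscreen))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026

cfg <- sim_config() # 46 brain + 50 spinal, lambda_bg = 200
genome <- simulate_genome(cfg, seed = seed)
cfg$drivers <- make_drivers(genome, n = 5, pi_brain = 0.4, pi_spinal = 0.4)
screen <- simulate_cohort(genome, cfg, seed = seed)

print(screen)
message("drivers: ", paste(vapply(cfg$drivers, `[[`, "", "gene"),
                           collapse = ", "))

write_insertions(screen$insertions, file.path(out, "insertions.tsv"))
write.table(screen$samples, file.path(out, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_gff3_genes(genome$genes, file.path(out, "genes.gff3"))
write_ttaa_tsv(genome$ttaa, file.path(out, "ttaa.tsv"))
write.table(screen$truth$insertions, file.path(out, "truth_insertions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(screen$truth$ranking, file.path(out, "truth_ranking.txt"))
write_fusions(screen$fusions, file.path(out, "fusions.tsv"))
message("wrote ", out, "/{insertions,samples,truth_insertions,fusions}.tsv, genes.gff3, ttaa.tsv")
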