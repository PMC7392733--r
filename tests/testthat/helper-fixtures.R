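# Small fixture builders shared across test files. Everything is generated
# in code; no data files.

# quick insertion-site rows with sensible defaults
make_sites <- function(sample_id, chrom = "chr1", pos, orientation = "+",
                       transposon_end = "merged", read_count = 1,
                       tissue = "other", tumor_id = sample_id,
                       region_id = "") {
  data.frame(sample_id = sample_id, tumor_id = tumor_id,
             region_id = region_id, tissue = tissue, chrom = chrom,
             pos = pos, orientation = orientation,
             transposon_end = transposon_end, read_count = read_count)
}

# evenly spaced TTAA index on a single toy chromosome
toy_ttaa <- function(n = 20, spacing = 1000, chrom = "chr1") {
  pos <- spacing * seq_len(n) - spacing / 2
  len <- spacing * (n + 1)
  ttaa_index(stats::setNames(list(pos), chrom),
             stats::setNames(len, chrom))
}

toy_gene <- function(name = "GeneA", chrom = "chr1", start = 10000,
                     end = 40000, strand = "+") {
  data.frame(gene_id = name, name = name, chrom = chrom, start = start,
             end = end, strand = strand)
}

# Three-region tumor with one insertion of each clonality type: present in
# all regions, present everywhere but read-filtered in one region, and
# region-private. Expected labels are applied by hand.
three_region_fixture <- function() {
  list(
    R1 = make_sites("T1_R1", pos = c(1000, 2000), read_count = c(5, 3),
                    region_id = "R1"),
    R2 = make_sites("T1_R2", pos = c(1000, 2000, 3000),
                    read_count = c(4, 2, 6), region_id = "R2"),
    R3 = make_sites("T1_R3", pos = c(1000, 2000), read_count = c(7, 1),
                    region_id = "R3"))
}

# hand-coded two-sided Fisher p by hypergeometric enumeration
# (point-probability rule: sum over tables at most as probable as observed)
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(x, m, n, k)
  sum(pr[pr <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# brute-force kernel density: the independent double-loop oracle
kd_brute <- function(positions, h, eval_points) {
  vapply(eval_points, function(x) sum(exp(-(x - positions)^2 / (2 * h^2))),
         numeric(1))
}
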