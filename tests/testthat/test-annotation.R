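fake_cis <- function(chrom = "chr1", apex, start, end, scale = 10000,
                     id = "CIS001") {
  data.frame(cis_id = id, chrom = chrom, apex_pos = apex, start = start,
             end = end, best_scale = scale)
}

test_that("associate_genes handles containment, adjacency and intergenic CIS", {
  genes <- rbind(toy_gene("Left", start = 10000, end = 60000),
                 toy_gene("Right", start = 65000, end = 90000),
                 toy_gene("Far", start = 5e6, end = 5.05e6))
  # CIS inside one gene
  a <- associate_genes(fake_cis(apex = 30000, start = 25000, end = 35000),
                       genes)
  expect_equal(a$name, "Left")
  expect_equal(a$flag, "overlap")
  # CIS spanning the gap between two genes: both reported, apex-nearest first
  b <- associate_genes(fake_cis(apex = 62000, start = 58000, end = 66000),
                       genes)
  expect_equal(b$name, c("Right", "Left")) # apex 62k is closer to Right's midpoint
  # intergenic CIS with max_distance 0: empty association
  c_ <- associate_genes(fake_cis(apex = 2e6, start = 1.99e6, end = 2.01e6),
                        genes)
  expect_equal(nrow(c_), 0)
  # nearest-gene rescue within max_distance
  d <- associate_genes(fake_cis(apex = 4.9e6, start = 4.89e6, end = 4.91e6),
                       genes, max_distance = 2e5)
  expect_equal(d$name, "Far")
  expect_equal(d$flag, "nearest")
})

test_that("the association window is the CIS interval extended by the best scale", {
  genes <- toy_gene("Edge", start = 50000, end = 70000)
  # interval ends 15 kb before the gene; h = 20 kb reaches it
  hit <- associate_genes(fake_cis(apex = 30000, start = 25000, end = 35000,
                                  scale = 20000), genes)
  expect_equal(hit$name, "Edge")
  # h = 10 kb does not
  miss <- associate_genes(fake_cis(apex = 30000, start = 25000, end = 35000,
                                   scale = 10000), genes)
  expect_equal(nrow(miss), 0)
})

test_that("rank_cis_genes orders by insertions, tumors, then name", {
  cg <- data.frame(gene_id = paste0("G", 1:4),
                   name = c("Delta", "Alpha", "Charlie", "Bravo"),
                   total_insertions = c(12, 30, 12, 5),
                   n_tumors = c(9, 20, 9, 4),
                   n_brain = 0, n_spinal = 0, n_other = 0)
  ranked <- rank_cis_genes(cg, c(brain = 46, spinal = 50))
  expect_equal(ranked$name, c("Alpha", "Charlie", "Delta", "Bravo"))
  expect_equal(ranked$rank, 1:4)
  expect_equal(ranked$pct_tumors, 100 * ranked$n_tumors / 96)
  expect_error(rank_cis_genes(cg, 0), "positive")

  single <- rank_cis_genes(cg[1, ], 50)
  expect_equal(single$rank, 1L)
  expect_equal(single$pct_tumors, 100 * 9 / 50)
})

test_that("classify_pattern applies the activation and gene-trap rules", {
  gene <- toy_gene(start = 100000, end = 200000, strand = "+")
  # 10 sense insertions in the first 10% of the gene: activating
  act <- classify_pattern(gene, data.frame(chrom = "chr1",
                                           pos = seq(101000, 110000, 1000),
                                           orientation = "+"))
  expect_equal(act$label, "activating")
  expect_equal(act$sense_fraction, 1)
  expect_lt(act$orientation_binomial_p, 0.05)
  # 12 insertions spread across the body, 6 sense / 6 antisense: disrupting
  inact <- classify_pattern(gene, data.frame(
    chrom = "chr1", pos = seq(105000, 195000, length.out = 12),
    orientation = rep(c("+", "-"), 6)))
  expect_equal(inact$label, "inactivating")
  # a single insertion is always ambiguous
  one <- classify_pattern(gene, data.frame(chrom = "chr1", pos = 150000,
                                           orientation = "+"))
  expect_equal(one$label, "ambiguous")
  expect_equal(one$n, 1L)
  expect_error(classify_pattern(gene, data.frame(chrom = "chr9", pos = 1,
                                                 orientation = "+")),
               "chromosome")
})

test_that("upstream sense insertions on either strand are activating", {
  plus <- toy_gene(start = 100000, end = 150000, strand = "+")
  up_plus <- classify_pattern(plus, data.frame(
    chrom = "chr1", pos = seq(91000, 101000, by = 2000), orientation = "+"))
  expect_equal(up_plus$label, "activating")
  expect_lt(up_plus$median_relative_position, 0.2)
  minus <- toy_gene(start = 100000, end = 150000, strand = "-")
  up_minus <- classify_pattern(minus, data.frame(
    chrom = "chr1", pos = seq(149000, 159000, by = 2000),
    orientation = "-"))
  expect_equal(up_minus$label, "activating")
})

test_that("pattern calls are invariant under genome mirroring", {
  set.seed(61)
  L <- 1e6
  for (i in 1:20) {
    start <- sample.int(5e5, 1) + 1e5
    end <- start + sample(5000:80000, 1)
    strand <- sample(c("+", "-"), 1)
    gene <- toy_gene(start = start, end = end, strand = strand)
    n <- sample(1:12, 1)
    ins <- data.frame(chrom = "chr1",
                      pos = sample(seq(start - 10000, end), n),
                      orientation = sample(c("+", "-"), n, TRUE))
    mirror_gene <- toy_gene(start = L - end + 1, end = L - start + 1,
                            strand = if (strand == "+") "-" else "+")
    mirror_ins <- data.frame(chrom = "chr1", pos = L - ins$pos + 1,
                             orientation = ifelse(ins$orientation == "+",
                                                  "-", "+"))
    a <- classify_pattern(gene, ins)
    b <- classify_pattern(mirror_gene, mirror_ins)
    expect_equal(a$label, b$label)
    expect_equal(a$sense_fraction, b$sense_fraction)
    expect_equal(a$median_relative_position, b$median_relative_position)
  }
})

test_that("per-gene roll-up counts insertions, tumors and tissues coherently", {
  genes <- rbind(toy_gene("Hit", start = 10000, end = 40000),
                 toy_gene("Cold", start = 200000, end = 240000))
  sites <- rbind(
    make_sites("B1", pos = c(15000, 20000), tissue = "brain"),
    make_sites("B2", pos = 25000, tissue = "brain"),
    make_sites("S1", pos = 30000, tissue = "spinal"),
    make_sites("S1", pos = 500000, tissue = "spinal"))
  cis <- fake_cis(apex = 22000, start = 15000, end = 30000)
  assoc <- associate_genes(cis, genes)
  cg <- cis_gene_table(cis, assoc, sites, genes)
  expect_equal(nrow(cg), 1)
  expect_equal(cg$name, "Hit")
  expect_equal(cg$total_insertions, 4L)
  expect_equal(cg$n_tumors, 3L)
  expect_equal(cg$n_brain + cg$n_spinal + cg$n_other, cg$total_insertions)
  ranked <- rank_cis_genes(cg, c(brain = 2, spinal = 1))
  expect_equal(ranked$pct_tumors, 100)
  expect_lte(max(ranked$pct_tumors), 100)
})

test_that("simulated activating drivers are recognized from their insertions", {
  # seeded benchmark: drivers simulated with the activating pattern should be
  # labeled activating from their truth insertions when support is adequate
  cfg <- sim_config(chrom_lengths = c(chr1 = 3e6), n_genes = 10,
                    n_brain = 12, n_spinal = 12, lambda_bg = 5)
  n_cases <- 0; n_correct <- 0
  for (seed in 1:5) {
    gn <- simulate_genome(cfg, seed = 300 + seed)
    cfg2 <- cfg
    cfg2$drivers <- lapply(gn$genes$name[c(2, 5, 8)], driver_spec,
                           pi_brain = 0.9, pi_spinal = 0.9,
                           pattern = "activating")
    scr <- simulate_cohort(gn, cfg2, seed = 600 + seed)
    for (d in cfg2$drivers) {
      tr <- scr$truth$insertions[scr$truth$insertions$gene == d$gene, ]
      if (nrow(tr) < 5) next
      gene <- gn$genes[gn$genes$name == d$gene, ]
      call <- classify_pattern(gene, tr)
      n_cases <- n_cases + 1
      n_correct <- n_correct + (call$label == "activating")
    }
  }
  expect_gte(n_cases, 10)
  expect_gte(n_correct / n_cases, 0.9)
})
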