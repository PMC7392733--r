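test_that("scan_ttaa finds every exact motif, including adjacent ones", {
  expect_equal(scan_ttaa(c(chr1 = "TTAA"))$positions$chr1, 1)
  expect_equal(scan_ttaa(c(chr1 = "TTAATTAA"))$positions$chr1, c(1, 5))
  expect_equal(scan_ttaa(c(chr1 = "ggTTAAcc"))$positions$chr1, 3)
  # N never matches
  expect_length(scan_ttaa(c(chr1 = "TTNATTAN"))$positions$chr1, 0)
  # empty genome is an empty index, not an error
  expect_length(scan_ttaa(character(0))$positions, 0)
})

test_that("scan_ttaa rejects non-DNA characters, naming chrom and offset", {
  expect_error(scan_ttaa(c(chr1 = "TTAA", chrX = "TTXA")),
               "offset 3 of chromosome chrX")
})

test_that("reverse-complementing a sequence mirrors the TTAA position set", {
  set.seed(42)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                       collapse = ""))
    fwd <- scan_ttaa(c(chr1 = s))$positions$chr1
    rev_pos <- scan_ttaa(c(chr1 = rc))$positions$chr1
    # motif at p on the forward strand maps to L - p - 2 on the reverse
    expect_equal(sort(500 - fwd - 2), sort(rev_pos))
  }
})

test_that("TTAA index round-trips through its TSV cache", {
  idx <- toy_ttaa(n = 15)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ttaa_tsv(idx, path)
  back <- read_ttaa_tsv(path)
  expect_equal(back$positions, idx$positions)
  expect_equal(back$seqlengths, idx$seqlengths)
})

test_that("collapse_reads counts reads per distinct insertion key", {
  reads <- make_sites(rep("S1", 5), pos = rep(1000, 5),
                      transposon_end = "5p")[
    c("sample_id", "chrom", "pos", "orientation", "transposon_end")]
  out <- collapse_reads(reads)
  expect_equal(nrow(out), 1)
  expect_equal(out$read_count, 5L)

  # 10 reads over 4 distinct keys: counts match a group-and-count oracle
  keys <- data.frame(sample_id = c("S1", "S1", "S2", "S2"),
                     chrom = c("chr1", "chr1", "chr1", "chr2"),
                     pos = c(100, 200, 100, 100),
                     orientation = c("+", "-", "+", "+"),
                     transposon_end = "5p")
  reps <- c(4, 3, 2, 1)
  reads <- keys[rep(seq_len(4), reps), ]
  reads <- reads[sample.int(nrow(reads)), ] # shuffled input
  out <- collapse_reads(reads)
  expect_equal(nrow(out), 4)
  expect_equal(sum(out$read_count), 10)
  oracle <- reps[order(keys$sample_id, keys$chrom, keys$pos)]
  expect_equal(out$read_count, as.integer(oracle))
})

test_that("collapse_reads is idempotent and conserves total read count", {
  set.seed(7)
  reads <- make_sites(sample(c("S1", "S2"), 60, TRUE),
                      chrom = sample(c("chr1", "chr2"), 60, TRUE),
                      pos = sample(1:10 * 100, 60, TRUE),
                      orientation = sample(c("+", "-"), 60, TRUE),
                      transposon_end = "5p")
  once <- collapse_reads(reads[is_cols <- c("sample_id", "chrom", "pos",
                                            "orientation", "transposon_end")])
  expect_equal(sum(once$read_count), 60)
  twice <- collapse_reads(once)
  expect_identical(once, twice)
})

test_that("collapse_reads reports the row with a missing key field", {
  reads <- data.frame(sample_id = c("S1", NA), chrom = "chr1", pos = 1:2,
                      orientation = "+", transposon_end = "5p")
  expect_error(collapse_reads(reads), "row 2")
  expect_equal(nrow(collapse_reads(reads[0, ])), 0)
})

test_that("merge_ends pairs opposite-end records within tolerance", {
  sites <- rbind(make_sites("S1", pos = 1000, transposon_end = "5p",
                            read_count = 4),
                 make_sites("S1", pos = 1000, transposon_end = "3p",
                            read_count = 6))
  out <- merge_ends(sites, tolerance_bp = 10)
  expect_equal(nrow(out), 1)
  expect_equal(out$transposon_end, "merged")
  expect_equal(out$pos, 1000)
  expect_equal(out$read_count, 10)

  # tolerance 0 with positions 4 bp apart: no merge
  sites$pos[2] <- 1004
  out0 <- merge_ends(sites, tolerance_bp = 0)
  expect_equal(nrow(out0), 2)
  expect_equal(sum(out0$read_count), 10)

  # a lone 5p record passes through unchanged
  single <- make_sites("S1", pos = 500, transposon_end = "5p", read_count = 3)
  expect_equal(merge_ends(single, 10)$transposon_end, "5p")
  expect_error(merge_ends(sites, -1), "non-negative")
})

test_that("merge_ends conserves total read count on random tables", {
  set.seed(11)
  for (i in 1:5) {
    sites <- make_sites(sample(c("S1", "S2"), 40, TRUE),
                        pos = sample(1:20 * 7, 40, TRUE),
                        orientation = sample(c("+", "-"), 40, TRUE),
                        transposon_end = sample(c("5p", "3p"), 40, TRUE),
                        read_count = sample(1:9, 40, TRUE))
    sites <- collapse_reads(sites)
    merged <- merge_ends(sites, tolerance_bp = 5)
    expect_equal(sum(merged$read_count), sum(sites$read_count))
    expect_lte(nrow(merged), nrow(sites))
  }
})

test_that("top_n_filter keeps the top N by read count with deterministic ties", {
  set.seed(3)
  sites <- make_sites("S1", pos = sample.int(1e6, 350),
                      read_count = sample(1:50, 350, TRUE))
  out <- top_n_filter(sites, 300)
  expect_equal(nrow(out), 300)
  expect_gte(min(out$read_count),
             max(sites$read_count[!sites$pos %in% out$pos]))

  # fewer sites than the cap: all retained
  small <- make_sites("S1", pos = 1:10 * 50, read_count = 1:10)
  expect_equal(nrow(top_n_filter(small, 300)), 10)

  # 301 all-tied sites: the 300 smallest (chrom, pos) survive (full-sort oracle)
  tied <- make_sites("S1", chrom = sample(c("chr1", "chr2"), 301, TRUE),
                     pos = sample.int(1e6, 301), read_count = 1)
  kept <- top_n_filter(tied, 300)
  oracle <- tied[order(tied$chrom, tied$pos), ][1:300, ]
  expect_setequal(paste(kept$chrom, kept$pos),
                  paste(oracle$chrom, oracle$pos))
  expect_error(top_n_filter(tied, 0), ">= 1")
})

test_that("top_n_filter output size is min(n, input) and it is idempotent", {
  set.seed(5)
  sites <- make_sites(rep(c("S1", "S2"), c(40, 10)),
                      pos = sample.int(1e5, 50),
                      read_count = sample(1:20, 50, TRUE))
  out <- top_n_filter(sites, 25)
  expect_equal(as.vector(table(out$sample_id)), c(25L, 10L))
  expect_identical(top_n_filter(out, 25), out)
})

test_that("pool_nonredundant keeps per-sample records by default, collapses on request", {
  two <- rbind(make_sites("S1", pos = 5000), make_sites("S2", pos = 5000))
  expect_equal(nrow(pool_nonredundant(two)), 2)
  across <- pool_nonredundant(two, collapse = "across-samples")
  expect_equal(nrow(across), 1)
  expect_equal(across$samples, "S1,S2")
  expect_equal(across$n_samples, 2L)

  dup <- make_sites(c("S1", "S1"), pos = c(7000, 7000), read_count = c(2, 3))
  pooled <- pool_nonredundant(dup)
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$read_count, 5L)

  expect_equal(nrow(pool_nonredundant(make_sites("S1", pos = 1)[0, ])), 0)
})

test_that("pool_nonredundant rejects conflicting tissue labels and unions regions", {
  bad <- rbind(make_sites("S1", pos = 100, tissue = "brain"),
               make_sites("S1", pos = 200, tissue = "spinal"))
  expect_error(pool_nonredundant(bad), "conflicting tissue")

  # two regions of one tumor with the same position collapse at tumor level
  regions <- rbind(
    make_sites("T1_R1", tumor_id = "T1", region_id = "R1", pos = 900),
    make_sites("T1_R2", tumor_id = "T1", region_id = "R2", pos = 900))
  pooled <- pool_nonredundant(regions)
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$samples, "T1_R1,T1_R2")
})

test_that("BED export/import round-trips records with exact coordinates", {
  set.seed(9)
  sites <- make_sites(sample(c("S1", "S2"), 30, TRUE),
                      chrom = sample(c("chr1", "chr2"), 30, TRUE),
                      pos = sample.int(1e7, 30),
                      orientation = sample(c("+", "-"), 30, TRUE),
                      read_count = sample(1:100, 30, TRUE))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(sites, path)
  back <- read_bed(path)
  for (col in c("sample_id", "chrom", "pos", "orientation", "read_count"))
    expect_equal(back[[col]], sites[[col]], info = col)
})

test_that("insertion TSV round-trips and validates", {
  sites <- make_sites(c("S1", "S2"), pos = c(1000, 2000),
                      tissue = c("brain", "spinal"), read_count = c(3, 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_insertions(sites, path)
  back <- read_insertions(path)
  expect_equal(back, sites)
  bad <- sites
  bad$read_count[1] <- 0
  write_insertions(bad, path)
  expect_error(read_insertions(path), "read_count")
})

test_that("GFF3 gene models round-trip through write/read", {
  genes <- data.frame(gene_id = c("G1", "G2"), name = c("Alpha", "Beta"),
                      chrom = c("chr1", "chr2"), start = c(100, 5000),
                      end = c(900, 9000), strand = c("+", "-"))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3_genes(genes, path)
  back <- read_gff3_genes(path)
  expect_equal(back[order(back$gene_id), ], genes, ignore_attr = TRUE)
})
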