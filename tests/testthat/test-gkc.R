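test_that("kernel_density matches closed-form hand evaluations", {
  # a single insertion evaluated at itself has height exp(0) = 1
  expect_equal(kernel_density(5000, 10000, 5000), 1.0)
  # two insertions at 0 and 10 kb, h = 10 kb, midpoint: 2 * exp(-1/8)
  expect_equal(kernel_density(c(0, 10000), 10000, 5000),
               2 * exp(-0.125), tolerance = 1e-12)
  expect_error(kernel_density(c(10, 5), 1000, 7), "sorted")
  expect_error(kernel_density(c(5, 10), 1000, c(9, 7)), "sorted")
  expect_error(kernel_density(1, 0, 1), "> 0")
})

test_that("kernel_density is translation invariant", {
  set.seed(21)
  pos <- sort(runif(50, 0, 1e5))
  ev <- sort(runif(20, 0, 1e5))
  base <- kernel_density(pos, 5000, ev)
  for (shift in c(1e4, -2e3, 7e6))
    expect_equal(kernel_density(pos + shift, 5000, ev + shift), base,
                 tolerance = 1e-12)
})

test_that("kernel_density agrees with the brute-force double loop", {
  set.seed(33)
  for (i in 1:100) {
    n <- sample(1:60, 1)
    h <- runif(1, 100, 5e4)
    pos <- sort(runif(n, 0, 1e6))
    ev <- sort(runif(sample(1:40, 1), 0, 1e6))
    exact <- kernel_density(pos, h, ev)
    expect_lt(max(abs(exact - kd_brute(pos, h, ev)) /
                    pmax(abs(exact), 1e-300)), 1e-9)
  }
})

test_that("truncated evaluation respects its documented error bound", {
  set.seed(34)
  pos <- sort(runif(200, 0, 2e5))
  ev <- sort(runif(100, 0, 2e5))
  h <- 5000
  full <- kernel_density(pos, h, ev)
  trunc <- kernel_density(pos, h, ev, truncate_sd = 6)
  expect_lte(max(abs(full - trunc)), length(pos) * exp(-18))
  # and the fast regular-grid path matches the direct path to fp precision
  grid <- seq(1, 2e5, by = 0.2 * h)
  direct <- kernel_density(pos, h, grid, truncate_sd = 6)
  fast <- pbscreen:::cpp_kd_grid(pos, h, 1, 0.2 * h, length(grid), 6)
  expect_equal(fast, direct, tolerance = 1e-12)
})

test_that("find_peaks returns the grid argmax of a unimodal profile", {
  pos <- sort(c(49000, 50000, 51000))
  grid <- seq(1, 1e5, by = 1000)
  prof <- data.frame(pos = grid, height = kernel_density(pos, 5000, grid))
  pk <- find_peaks(prof, pos, 5000, min_tumors = 0)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$apex_pos, grid[which.max(prof$height)])
  expect_equal(pk$n_insertions, 3L)
})

test_that("two clusters 5h apart give two peaks, each owning its cluster", {
  h <- 2000
  clus1 <- c(19000, 20000, 21000)
  clus2 <- clus1 + 5 * h
  pos <- sort(c(clus1, clus2))
  grid <- sort(unique(c(seq(1, 6e4, by = 0.2 * h), pos)))
  prof <- data.frame(pos = grid, height = kernel_density(pos, h, grid))
  pk <- find_peaks(prof, pos, h, min_tumors = 0)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$n_insertions, c(3L, 3L))
  # members of the first peak are exactly the first cluster
  expect_equal(pos[pk$lo[1]:pk$hi[1]], clus1)
  expect_equal(pos[pk$lo[2]:pk$hi[2]], clus2)
})

test_that("single-tumor support is filtered out; plateaus report leftmost point", {
  pos <- c(1000, 1100, 1200)
  grid <- seq(1, 5000, by = 100)
  prof <- data.frame(pos = grid, height = kernel_density(pos, 500, grid))
  none <- find_peaks(prof, pos, 500, tumor_ids = rep("T1", 3), min_tumors = 2)
  expect_equal(nrow(none), 0)
  some <- find_peaks(prof, pos, 500, tumor_ids = c("T1", "T2", "T1"),
                     min_tumors = 2)
  expect_equal(nrow(some), 1)

  flat <- data.frame(pos = c(1, 2, 3, 4, 5), height = c(0, 2, 2, 2, 1))
  pk <- find_peaks(flat, c(2, 3), 1, min_tumors = 0)
  expect_equal(pk$apex_pos, 2)
})

test_that("peak_pvalue applies the add-one and Bonferroni arithmetic", {
  null <- structure(list(scales = 1000,
                         heights = list("1000" = sort(runif(10000, 0, 5))),
                         n_perm = 100, seed = 1),
                    class = "null_distribution")
  # taller than every null height
  expect_equal(peak_pvalue(99, null, 1000, 1)$raw_p, 1 / 10001)
  # Bonferroni is a plain multiplication, capped at 1
  pv <- peak_pvalue(99, null, 1000, 2)
  expect_equal(pv$adjusted_p, 2 / 10001)
  expect_equal(peak_pvalue(99, null, 1000, 1e9)$adjusted_p, 1)
  # shorter than every null height
  expect_equal(peak_pvalue(-1, null, 1000, 1)$raw_p, 1)
  expect_error(peak_pvalue(1, null, 2000, 1), "not computed at scale")
  null$heights[["1000"]] <- numeric(0)
  expect_error(peak_pvalue(1, null, 1000, 1), "empty null")
})

test_that("sample_null is reproducible by seed and validates the TTAA index", {
  ttaa <- toy_ttaa(n = 50, spacing = 500)
  params <- gkc_params(scales = c(2000, 4000), n_perm = 100, seed = 5)
  a <- sample_null(c(chr1 = 30), ttaa, params)
  b <- sample_null(c(chr1 = 30), ttaa, params)
  expect_identical(a$heights, b$heights)
  params2 <- gkc_params(scales = c(2000, 4000), n_perm = 100, seed = 6)
  c_ <- sample_null(c(chr1 = 30), ttaa, params2)
  expect_false(identical(a$heights, c_$heights))
  expect_error(sample_null(c(chrZ = 10), ttaa, params), "no TTAA")
  # zero insertions: empty null, p values fail downstream
  z <- sample_null(c(chr1 = 0), ttaa, params)
  expect_length(z$heights[["2000"]], 0)
  expect_error(peak_pvalue(1, z, 2000, 1), "empty null")
})

test_that("null peak p values on null data are not anti-conservative", {
  # raw p values of peaks from driver-free insertion data should be
  # stochastically no smaller than uniform (one-sided KS, 5% level)
  set.seed(88)
  ttaa <- ttaa_index(list(chr1 = sort(sample.int(2e6 - 3, 7800))),
                     c(chr1 = 2e6))
  params <- gkc_params(scales = 10000, min_scales_significant = 1,
                       n_perm = 150, seed = 99)
  pvals <- numeric(0)
  for (s in 1:4) {
    pos <- sort(sample(ttaa$positions$chr1, 400, replace = TRUE))
    prof <- data.frame(pos = seq(1, 2e6, by = 2000))
    prof$height <- kernel_density(pos, 10000, prof$pos, truncate_sd = 6)
    pk <- find_peaks(prof, pos, 10000, min_tumors = 0)
    null <- sample_null(c(chr1 = 400), ttaa,
                        gkc_params(scales = 10000,
                                   min_scales_significant = 1,
                                   n_perm = 150, seed = 1000 + s))
    pvals <- c(pvals, peak_pvalue(pk$height, null, 10000, 1)$raw_p)
  }
  pvals <- pvals[seq_len(min(200, length(pvals)))]
  ks <- suppressWarnings(stats::ks.test(pvals, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.05)
})

test_that("call_cis handles empty input and missing chromosomes", {
  ttaa <- toy_ttaa()
  expect_equal(nrow(call_cis(make_sites("S1", pos = 1)[0, ], ttaa)), 0)
  sites <- make_sites("S1", chrom = "chrNope", pos = 100)
  expect_error(call_cis(sites, ttaa), "absent from the TTAA index")
})

test_that("call_cis finds a planted recurrent locus and is deterministic", {
  set.seed(17)
  ttaa <- ttaa_index(list(chr1 = sort(sample.int(5e6 - 3, 19000))),
                     c(chr1 = 5e6))
  # 20 tumors, 40 background insertions each, plus a driver locus hit in 15
  cluster_sites <- ttaa$positions$chr1[
    ttaa$positions$chr1 > 2.49e6 & ttaa$positions$chr1 < 2.51e6]
  rows <- list()
  for (t in 1:20) {
    bg <- sample(ttaa$positions$chr1, 40, replace = TRUE)
    pos <- if (t <= 15) c(bg, sample(cluster_sites, 1)) else bg
    rows[[t]] <- make_sites(sprintf("T%02d", t), pos = pos,
                            orientation = sample(c("+", "-"),
                                                 length(pos), TRUE))
  }
  pooled <- pool_nonredundant(do.call(rbind, rows))
  params <- gkc_params(scales = seq(1e4, 5e4, by = 1e4), n_perm = 150,
                       seed = 4)
  cis <- call_cis(pooled, ttaa, params = params)
  expect_gte(nrow(cis), 1)
  hit <- which(cis$start <= 2.51e6 & cis$end >= 2.49e6)
  expect_length(hit, 1)
  expect_gte(cis$n_tumors[hit], 10)
  expect_true(all(cis$adjusted_p >= cis$raw_p))
  expect_true(all(cis$start <= cis$apex_pos & cis$apex_pos <= cis$end))
  expect_true(all(cis$n_scales_significant >= params$min_scales_significant))

  # byte-identical rerun under the same seed
  again <- call_cis(pooled, ttaa, params = params)
  attributes(cis) <- attributes(again) <- NULL
  expect_identical(cis, again)
})

test_that("adding an insertion inside a CIS never lowers its peak height", {
  set.seed(55)
  pos <- sort(runif(80, 0, 1e6))
  h <- 10000
  grid <- seq(1, 1e6, by = 2000)
  prof <- kernel_density(pos, h, grid)
  apex <- grid[which.max(prof)]
  for (delta in c(-h, -100, 0, 300, h)) {
    pos2 <- sort(c(pos, apex + delta))
    expect_gte(kernel_density(pos2, h, apex), max(prof))
  }
})
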