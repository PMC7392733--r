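#' Configuration for the synthetic screen generator
#'
#' Defines the study conditions a simulated screen emulates: a toy genome
#' with TTAA motifs at the random-sequence rate, non-overlapping gene
#' models, two tumor cohorts (brain and spinal) with ground-truth driver
#' genes targeted at elevated rates, TTAA-constrained background
#' insertions, a clonal/subclonal read-count mixture, optional multi-region
#' sampling, and matched fusion-transcript records.
#'
#' Defaults mirror the screen being emulated: cohorts of 46 brain and 50
#' spinal tumors; a background insertion load of about 200 detectable IS
#' per tumor (the transposon line carries ~20 copies per cell, but bulk
#' sequencing samples many subclones, which is what makes a top-300
#' read-count filter meaningful); TTAA motifs at the random-sequence rate
#' of 1/256 per bp; mouse-like gene lengths (log-normal, median 25 kb).
#'
#' @param chrom_lengths named vector of chromosome lengths (default three
#'   10 Mb chromosomes).
#' @param ttaa_mode `"position-process"` (default; TTAA positions drawn as
#'   a discrete uniform process at `ttaa_rate` per bp) or
#'   `"from-sequence"` (random DNA is generated and scanned, so the index
#'   is exactly reproducible with [scan_ttaa()]).
#' @param ttaa_rate per-bp TTAA start rate for position-process mode
#'   (default 1/256, the expectation for uniform random sequence).
#' @param n_genes number of non-overlapping gene models (default 80).
#' @param gene_length_meanlog,gene_length_sdlog,gene_length_range
#'   log-normal gene length distribution (bp), clamped to the range.
#' @param n_brain,n_spinal cohort sizes (defaults 46 and 50).
#' @param lambda_bg mean background insertions per tumor (negative
#'   binomial, dispersion `bg_dispersion`).
#' @param f_clonal fraction of background insertions that are clonal.
#' @param mu_clonal,mu_subclonal,read_dispersion negative-binomial read
#'   count means for clonal vs subclonal insertions (dispersion size
#'   `read_dispersion`); counts are clamped to >= 1. Defaults 100 / 3 /
#'   1, so a top-300 filter retains clonal events preferentially.
#' @param n_regions regions sampled per tumor (default 1; > 1 activates
#'   multi-region output: clonal insertions appear in every region,
#'   subclonal ones in a single region each).
#' @param p_fusion probability that a driver insertion yields a detectable
#'   fusion transcript record (default 0.5).
#' @param upstream_bp extent of the upstream activation window (default
#'   10 kb before the transcription start).
#' @param activating_fraction activating insertions fall within the first
#'   this fraction of the gene body (default 0.2) or the upstream window.
#' @param drivers list of [driver_spec()]s (default none: a driver-free
#'   null screen).
#' @param donor_chrom,donor_multiplier optional local-hopping stress test:
#'   background insertion rate on `donor_chrom` is multiplied by
#'   `donor_multiplier` (default off).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
                       ttaa_mode = c("position-process", "from-sequence"),
                       ttaa_rate = 1 / 256,
                       n_genes = 80,
                       gene_length_meanlog = log(25000),
                       gene_length_sdlog = 0.5,
                       gene_length_range = c(5000, 150000),
                       n_brain = 46, n_spinal = 50,
                       lambda_bg = 200, bg_dispersion = 10,
                       f_clonal = 0.1, mu_clonal = 100, mu_subclonal = 3,
                       read_dispersion = 1,
                       n_regions = 1, p_fusion = 0.5,
                       upstream_bp = 10000, activating_fraction = 0.2,
                       drivers = NULL,
                       donor_chrom = NULL, donor_multiplier = 1) {
  ttaa_mode <- match.arg(ttaa_mode)
  if (is.null(names(chrom_lengths)) || any(chrom_lengths < 1))
    stopf("`chrom_lengths` must be a named vector of positive lengths")
  for (v in c("ttaa_rate", "n_genes", "bg_dispersion", "mu_clonal",
              "mu_subclonal", "read_dispersion", "n_regions",
              "donor_multiplier"))
    if (get(v) <= 0) stopf("`%s` must be positive", v)
  if (lambda_bg < 0) stopf("`lambda_bg` must be non-negative")
  if (n_brain < 0 || n_spinal < 0 || n_brain + n_spinal < 1)
    stopf("cohort sizes must be non-negative with at least one tumor")
  if (f_clonal < 0 || f_clonal > 1 || p_fusion < 0 || p_fusion > 1)
    stopf("`f_clonal` and `p_fusion` must lie in [0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

#' Ground-truth driver specification
#'
#' @param gene gene name (must exist in the simulated annotation).
#' @param pi_brain,pi_spinal per-tumor insertion probability in each
#'   cohort; unequal values emulate tissue-biased drivers.
#' @param pattern `"inactivating"` (gene-trap style, anywhere in the gene
#'   body, either orientation) or `"activating"` (sense orientation, in
#'   the upstream window or early gene body).
#' @param clonal force driver insertions to be clonal (default `TRUE`:
#'   drivers are early, selected events).
#' @export
driver_spec <- function(gene, pi_brain = 0.4, pi_spinal = 0.4,
                        pattern = c("inactivating", "activating"),
                        clonal = TRUE) {
  pattern <- match.arg(pattern)
  if (pi_brain < 0 || pi_brain > 1 || pi_spinal < 0 || pi_spinal > 1)
    stopf("insertion probabilities must lie in [0, 1]")
  list(gene = gene, pi_brain = pi_brain, pi_spinal = pi_spinal,
       pattern = pattern, clonal = clonal)
}

#' Default driver panel for a simulated screen
#'
#' Picks `n` genes spread evenly across the annotation and assigns them
#' alternating inactivating / activating patterns (tumor-suppressor-heavy,
#' as observed in gene-trap screens).
#'
#' @param genome a [simulate_genome()] result.
#' @param n number of drivers (default 5).
#' @param pi_brain,pi_spinal,clonal passed to [driver_spec()].
#' @export
make_drivers <- function(genome, n = 5, pi_brain = 0.4, pi_spinal = 0.4,
                         clonal = TRUE) {
  idx <- round(seq(1, nrow(genome$genes), length.out = n + 2))[2:(n + 1)]
  patterns <- rep(c("inactivating", "inactivating", "activating"),
                  length.out = n)
  lapply(seq_len(n), function(i)
    driver_spec(genome$genes$name[idx[i]], pi_brain, pi_spinal,
                patterns[i], clonal))
}

#' Simulate a toy genome: TTAA index and gene models
#'
#' In position-process mode the number of TTAA starts per chromosome is
#' binomial at `ttaa_rate` per bp and positions are uniform without
#' replacement; in from-sequence mode uniform random DNA is generated and
#' scanned with [scan_ttaa()], so the emitted index is exactly consistent
#' with the emitted sequence. Genes are placed uniformly at random without
#' overlap; placement failure after many attempts (gene demand exceeding
#' genome capacity) is an error.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give identical genomes.
#' @return A list of class `sim_genome`: `ttaa` ([ttaa_index()]), `genes`
#'   (gene-model data.frame), `chrom_lengths`, `sequences` (named character
#'   vector, from-sequence mode only), `config`.
#' @export
simulate_genome <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    lens <- config$chrom_lengths
    sequences <- NULL
    if (config$ttaa_mode == "from-sequence") {
      sequences <- vapply(names(lens), function(ch)
        paste(sample(c("A", "C", "G", "T"), lens[[ch]], replace = TRUE),
              collapse = ""), "")
      ttaa <- scan_ttaa(sequences)
    } else {
      pos <- lapply(names(lens), function(ch) {
        n <- stats::rbinom(1, max(0, lens[[ch]] - 3), config$ttaa_rate)
        sort(sample.int(max(1, lens[[ch]] - 3), n))
      })
      names(pos) <- names(lens)
      ttaa <- ttaa_index(pos, lens)
    }
    glen <- pmin(pmax(round(stats::rlnorm(config$n_genes,
                                          config$gene_length_meanlog,
                                          config$gene_length_sdlog)),
                      config$gene_length_range[1]),
                 config$gene_length_range[2])
    chrom <- sample(names(lens), config$n_genes, replace = TRUE,
                    prob = lens / sum(lens))
    placed <- lapply(names(lens), function(ch) matrix(numeric(0), ncol = 2))
    names(placed) <- names(lens)
    starts <- numeric(config$n_genes)
    for (i in seq_len(config$n_genes)) {
      ok <- FALSE
      for (try in 1:1000) {
        s <- sample.int(max(1, lens[[chrom[i]]] - glen[i]), 1)
        e <- s + glen[i] - 1
        occ <- placed[[chrom[i]]]
        if (nrow(occ) == 0 || all(e < occ[, 1] | s > occ[, 2])) {
          placed[[chrom[i]]] <- rbind(occ, c(s, e))
          starts[i] <- s
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stopf("could not place gene %d without overlap: gene demand exceeds genome capacity", i)
    }
    genes <- data.frame(gene_id = sprintf("SIMG%03d", seq_len(config$n_genes)),
                        name = sprintf("Simg%03d", seq_len(config$n_genes)),
                        chrom = chrom, start = starts,
                        end = starts + glen - 1,
                        strand = sample(c("+", "-"), config$n_genes,
                                        replace = TRUE))
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    structure(list(ttaa = ttaa, genes = genes, chrom_lengths = lens,
                   sequences = sequences, config = config),
              class = "sim_genome")
  })
}

# TTAA positions inside [start, end] on one chromosome
ttaa_in_window <- function(ttaa, chrom, start, end) {
  p <- ttaa$positions[[chrom]]
  p[p >= start & p <= end]
}

read_counts <- function(n, clonal, config) {
  mu <- ifelse(clonal, config$mu_clonal, config$mu_subclonal)
  pmax(1L, stats::rnbinom(n, mu = mu, size = config$read_dispersion))
}

#' Simulate a two-cohort insertional mutagenesis screen
#'
#' Generates per-tumor insertion tables with ground truth. Per tumor:
#' a negative-binomial number of background insertions placed uniformly
#' over TTAA positions (fair-coin orientation); each driver gene hit with
#' its per-tissue probability, positioned according to its pattern
#' (inactivating: uniform over TTAA in the gene body, random orientation;
#' activating: TTAA in the strand-aware window from `upstream_bp` before
#' the transcription start to `activating_fraction` of the gene body, in
#' the sense orientation); read counts from the clonal/subclonal mixture,
#' with driver insertions forced clonal when their spec says so. With
#' `n_regions > 1`, clonal insertions are replicated across all regions
#' (read counts redrawn per region) and subclonal insertions are assigned
#' to a single region. Each driver insertion emits a fusion record with
#' probability `p_fusion`, with feature and orientation consistent with
#' its pattern (activating -> SD/sense; inactivating -> CbASA if sense
#' else En2SA).
#'
#' @param genome a [simulate_genome()] result.
#' @param config a [sim_config()]; defaults to the genome's.
#' @param seed integer seed; all outputs are deterministic given the seed.
#' @return A list of class `sim_screen`: `insertions` (IS table),
#'   `samples` (sample metadata), `truth` (list: `insertions` with one row
#'   per driver insertion, `ranking` = driver genes by realized insertion
#'   count), `fusions` (fusion-record table), `cohort` (named tumor
#'   counts).
#' @export
simulate_cohort <- function(genome, config = genome$config, seed = 1) {
  stopifnot(inherits(genome, "sim_genome"), inherits(config, "sim_config"))
  genes <- genome$genes
  drivers <- config$drivers %||% list()
  for (d in drivers)
    if (!d$gene %in% genes$name)
      stopf("driver gene %s is absent from the simulated annotation", d$gene)
  ttaa <- genome$ttaa
  chroms <- names(genome$chrom_lengths)
  n_ttaa <- vapply(ttaa$positions[chroms], length, integer(1))
  if (sum(n_ttaa) == 0) stopf("simulated genome has no TTAA positions")
  wt <- n_ttaa
  if (!is.null(config$donor_chrom))
    wt[config$donor_chrom] <- wt[config$donor_chrom] * config$donor_multiplier

  tumors <- data.frame(
    tumor_id = c(sprintf("BT%02d", seq_len(config$n_brain)),
                 sprintf("ST%02d", seq_len(config$n_spinal))),
    tissue = rep(c("brain", "spinal"), c(config$n_brain, config$n_spinal)),
    mouse_id = c(sprintf("M%03d", seq_len(config$n_brain)),
                 sprintf("M%03d", seq_len(config$n_spinal))))

  with_seed(seed, {
    ins <- list(); tru <- list(); fus <- list()
    for (ti in seq_len(nrow(tumors))) {
      tid <- tumors$tumor_id[ti]
      tissue <- tumors$tissue[ti]
      n_bg <- stats::rnbinom(1, mu = config$lambda_bg,
                             size = config$bg_dispersion)
      bg_chrom <- if (n_bg > 0)
        sample(chroms, n_bg, replace = TRUE, prob = wt) else character(0)
      bg_pos <- vapply(bg_chrom, function(ch)
        ttaa$positions[[ch]][sample.int(n_ttaa[[ch]], 1)], numeric(1),
        USE.NAMES = FALSE)
      df <- data.frame(chrom = bg_chrom, pos = bg_pos,
                       orientation = sample(c("+", "-"), n_bg, replace = TRUE),
                       clonal = stats::runif(n_bg) < config$f_clonal,
                       driver_gene = rep(NA_character_, n_bg),
                       pattern = rep(NA_character_, n_bg))
      for (d in drivers) {
        pi <- if (tissue == "brain") d$pi_brain else d$pi_spinal
        if (stats::runif(1) >= pi) next
        g <- genes[genes$name == d$gene, ]
        if (d$pattern == "activating") {
          len <- g$end - g$start + 1
          win <- if (g$strand == "+")
            c(max(1, g$start - config$upstream_bp),
              g$start + round(config$activating_fraction * len))
          else
            c(g$end - round(config$activating_fraction * len),
              g$end + config$upstream_bp)
          cand <- ttaa_in_window(ttaa, g$chrom, win[1], win[2])
          ori <- g$strand
        } else {
          cand <- ttaa_in_window(ttaa, g$chrom, g$start, g$end)
          ori <- sample(c("+", "-"), 1)
        }
        if (length(cand) == 0)
          stopf("no TTAA position available in %s for driver %s",
                d$pattern, d$gene)
        p <- cand[sample.int(length(cand), 1)]
        clon <- d$clonal || stats::runif(1) < config$f_clonal
        df <- rbind(df, data.frame(chrom = g$chrom, pos = p,
                                   orientation = ori, clonal = clon,
                                   driver_gene = d$gene,
                                   pattern = d$pattern))
        tru[[length(tru) + 1]] <- data.frame(
          tumor_id = tid, gene = d$gene, chrom = g$chrom, pos = p,
          orientation = ori, clonal = clon, pattern = d$pattern)
        if (stats::runif(1) < config$p_fusion) {
          sense <- ori == g$strand
          feature <- if (d$pattern == "activating") "SD"
            else if (sense) "CbASA" else "En2SA"
          fus[[length(fus) + 1]] <- data.frame(
            sample_id = tid, gene = d$gene, feature = feature,
            orientation = if (sense) "sense" else "antisense",
            junction_reads = 1L + stats::rpois(1, 3),
            spanning_fragments = stats::rpois(1, 2))
        }
      }
      if (nrow(df) == 0) next
      if (config$n_regions == 1) {
        df$sample_id <- tid
        df$region_id <- ""
        df$read_count <- read_counts(nrow(df), df$clonal, config)
        ins[[length(ins) + 1]] <- df
      } else {
        # clonal insertions appear in every region; each subclonal one is
        # drawn into a single random region
        home <- sample.int(config$n_regions, nrow(df), replace = TRUE)
        for (r in seq_len(config$n_regions)) {
          rid <- sprintf("R%d", r)
          sub <- df[df$clonal | home == r, , drop = FALSE]
          if (nrow(sub) == 0) next
          sub$sample_id <- paste0(tid, "_", rid)
          sub$region_id <- rid
          sub$read_count <- read_counts(nrow(sub), sub$clonal, config)
          ins[[length(ins) + 1]] <- sub
        }
      }
    }
    insertions <- if (length(ins) > 0) do.call(rbind, ins) else
      data.frame(chrom = character(0), pos = numeric(0),
                 orientation = character(0), clonal = logical(0),
                 driver_gene = character(0), pattern = character(0),
                 sample_id = character(0), region_id = character(0),
                 read_count = integer(0))
    insertions$tumor_id <- sub("_R[0-9]+$", "", insertions$sample_id)
    insertions$tissue <- tumors$tissue[match(insertions$tumor_id,
                                             tumors$tumor_id)]
    insertions$transposon_end <- rep("merged", nrow(insertions))
    insertions <- insertions[c("sample_id", "tumor_id", "region_id",
                               "tissue", "chrom", "pos", "orientation",
                               "transposon_end", "read_count", "clonal",
                               "driver_gene", "pattern")]
    # the same TTAA can be drawn twice in one sample: collapse, summing reads
    insertions <- collapse_dups(insertions)

    truth_ins <- if (length(tru) > 0) do.call(rbind, tru) else
      data.frame(tumor_id = character(0), gene = character(0),
                 chrom = character(0), pos = numeric(0),
                 orientation = character(0), clonal = logical(0),
                 pattern = character(0))
    ranking <- names(sort(table(truth_ins$gene), decreasing = TRUE))
    fusions <- if (length(fus) > 0) do.call(rbind, fus) else
      data.frame(sample_id = character(0), gene = character(0),
                 feature = character(0), orientation = character(0),
                 junction_reads = integer(0), spanning_fragments = integer(0))

    samples <- unique(insertions[c("sample_id", "tumor_id", "region_id",
                                   "tissue")])
    samples$mouse_id <- tumors$mouse_id[match(samples$tumor_id,
                                              tumors$tumor_id)]
    samples$n_regions <- rep(config$n_regions, nrow(samples))
    rownames(samples) <- NULL

    structure(list(insertions = insertions, samples = samples,
                   truth = list(insertions = truth_ins, ranking = ranking),
                   fusions = fusions,
                   cohort = c(brain = config$n_brain,
                              spinal = config$n_spinal)),
              class = "sim_screen")
  })
}

# collapse duplicate (sample, chrom, pos, orientation) rows, summing reads
collapse_dups <- function(df) {
  if (nrow(df) == 0) return(df)
  key <- paste(df$sample_id, df$chrom, df$pos, df$orientation, sep = "\x1f")
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  sums <- rowsum(as.numeric(df$read_count), key)
  out$read_count <- as.integer(sums[match(key[first], rownames(sums)), 1])
  out <- out[order(out$sample_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.sim_screen <- function(x, ...) {
  cat(sprintf("Simulated screen: %d insertions in %d samples (%d brain + %d spinal tumors)\n",
              nrow(x$insertions), nrow(x$samples), x$cohort[["brain"]],
              x$cohort[["spinal"]]))
  if (nrow(x$truth$insertions) > 0)
    cat(sprintf("  %d ground-truth driver insertions in %d gene(s)\n",
                nrow(x$truth$insertions),
                length(unique(x$truth$insertions$gene))))
  invisible(x)
}
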