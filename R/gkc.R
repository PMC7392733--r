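#' Parameters for Gaussian kernel convolution CIS calling
#'
#' Common insertion sites (CIS) are detected by smoothing pooled insertion
#' positions with unnormalized Gaussian kernels
#' \eqn{f(x) = \sum_i \exp(-(x - x_i)^2 / (2 h^2))} over a ladder of kernel
#' widths ("window sizes") \eqn{h}, extracting density peaks, and comparing
#' peak heights against a Monte-Carlo null that replaces the observed
#' insertions with uniform draws over TTAA motif positions. With the
#' unnormalized kernel a peak height is directly comparable to the number of
#' insertions piled up locally.
#'
#' @param scales kernel widths h in bp, strictly increasing (default 10 to
#'   100 kb in 10 kb steps).
#' @param alpha family-wise threshold on the Bonferroni-adjusted p value
#'   (default 0.01). With `n_perm` Monte-Carlo replicates the smallest
#'   attainable adjusted p is about `1/n_perm`, so `alpha` should stay well
#'   above that resolution floor; 0.001 is available for stricter calling
#'   when `n_perm` is raised accordingly.
#' @param min_scales_significant number of scales at which a CIS must reach
#'   `alpha` to be reported (default 2).
#' @param n_perm Monte-Carlo replicates (default 1000, minimum 100).
#' @param grid_step_fraction evaluation-grid spacing as a fraction of h
#'   (default 0.2).
#' @param min_tumors minimum distinct tumors supporting a peak (default 2;
#'   a single tumor cannot constitute cross-tumor recurrence).
#' @param min_insertions minimum insertions within one kernel width of a
#'   peak apex (default 2).
#' @param null_mode `"chromosome-matched"` (default) matches the observed
#'   insertion count per chromosome, absorbing chromosome-level rate biases
#'   such as donor-locus proximity; `"genome-wide"` places all insertions
#'   proportional to TTAA counts.
#' @param bonferroni `"candidates"` (default) multiplies raw p values by the
#'   number of observed candidate peaks at the same scale;
#'   `"effective-tests"` uses genome length / h instead.
#' @param weight_reads if `TRUE`, each insertion contributes its read count
#'   to the density instead of 1 (default `FALSE`: each IS counts once).
#' @param exclude_chroms chromosomes dropped before calling (e.g. the donor
#'   chromosome, to guard against local hopping; default none).
#' @param truncate_sd kernel contributions beyond `truncate_sd * h` are
#'   dropped; the absolute profile error is at most
#'   `n * exp(-truncate_sd^2/2)` (default 6, error <= n * 1.5e-8).
#' @param seed integer seed making the Monte-Carlo null reproducible.
#' @return An object of class `gkc_params`.
#' @export
gkc_params <- function(scales = seq(1e4, 1e5, by = 1e4),
                       alpha = 0.01,
                       min_scales_significant = 2,
                       n_perm = 1000,
                       grid_step_fraction = 0.2,
                       min_tumors = 2,
                       min_insertions = 2,
                       null_mode = c("chromosome-matched", "genome-wide"),
                       bonferroni = c("candidates", "effective-tests"),
                       weight_reads = FALSE,
                       exclude_chroms = character(),
                       truncate_sd = 6,
                       seed = 1L) {
  null_mode <- match.arg(null_mode)
  bonferroni <- match.arg(bonferroni)
  if (length(scales) < 1 || any(scales <= 0) || is.unsorted(scales, strictly = TRUE))
    stopf("`scales` must be positive and strictly increasing")
  if (length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stopf("`alpha` must lie in (0, 1)")
  if (n_perm < 100)
    stopf("`n_perm` must be >= 100")
  if (min_scales_significant < 1 || min_scales_significant > length(scales))
    stopf("`min_scales_significant` must lie in 1..length(scales)")
  if (grid_step_fraction <= 0 || grid_step_fraction > 1)
    stopf("`grid_step_fraction` must lie in (0, 1]")
  structure(list(scales = as.numeric(scales), alpha = alpha,
                 min_scales_significant = as.integer(min_scales_significant),
                 n_perm = as.integer(n_perm),
                 grid_step_fraction = grid_step_fraction,
                 min_tumors = as.integer(min_tumors),
                 min_insertions = as.integer(min_insertions),
                 null_mode = null_mode, bonferroni = bonferroni,
                 weight_reads = weight_reads,
                 exclude_chroms = exclude_chroms,
                 truncate_sd = truncate_sd, seed = as.integer(seed)),
            class = "gkc_params")
}

#' Gaussian kernel density of insertion positions
#'
#' Evaluates \eqn{f(x) = \sum_i \exp(-(x - x_i)^2/(2h^2))} at each eval
#' point. Exact by default; set `truncate_sd` to a finite value to drop
#' contributions beyond `truncate_sd * h` (absolute error at most
#' `length(positions) * exp(-truncate_sd^2/2)`).
#'
#' @param positions sorted numeric vector of insertion positions on one
#'   chromosome.
#' @param h kernel width in bp (> 0).
#' @param eval_points sorted numeric vector of evaluation positions.
#' @param truncate_sd truncation radius in units of h (default `Inf`).
#' @return Numeric vector of heights, one per eval point.
#' @examples
#' kernel_density(c(0, 10000), 10000, 5000)  # 2 * exp(-0.125)
#' @export
kernel_density <- function(positions, h, eval_points, truncate_sd = Inf) {
  if (length(h) != 1 || is.na(h) || h <= 0) stopf("`h` must be a single value > 0")
  if (is.unsorted(positions)) stopf("`positions` must be sorted")
  if (is.unsorted(eval_points)) stopf("`eval_points` must be sorted")
  cpp_kernel_density(as.numeric(positions), h, as.numeric(eval_points),
                     truncate_sd)
}

# Density profile for one chromosome: regular grid of spacing
# grid_step_fraction * h over [1, chrom_length], refined with the insertion
# positions themselves so no apex falls between grid points.
density_profile <- function(positions, h, chrom_length, params,
                            refine = TRUE, weights = NULL) {
  s <- params$grid_step_fraction * h
  grid <- seq(1, chrom_length, by = s)
  eval_points <- if (refine) sort(unique(c(grid, positions))) else grid
  if (is.null(weights)) {
    height <- cpp_kernel_density(positions, h, eval_points, params$truncate_sd)
  } else {
    # weighted variant: repeat via weighted sum of per-position kernels
    height <- cpp_kd_weighted(positions, weights, h, eval_points,
                              params$truncate_sd)
  }
  data.frame(pos = eval_points, height = height)
}

#' Extract candidate peaks from a density profile
#'
#' Local maxima of the height profile (strictly greater than the nearest
#' differing neighbor values; plateaus report their leftmost point) that are
#' supported by at least `min_insertions` insertions and `min_tumors`
#' distinct tumors within one kernel width of the apex.
#'
#' @param profile data.frame with columns `pos` and `height` for one
#'   chromosome (as produced on the evaluation grid).
#' @param positions sorted insertion positions underlying the profile.
#' @param h kernel width used for the profile.
#' @param tumor_ids optional vector parallel to `positions`; when `NULL`
#'   the tumor-support filter is disabled.
#' @param min_insertions,min_tumors support filters (see [gkc_params()]).
#' @return data.frame of peaks: `apex_pos`, `height`, `n_insertions`,
#'   `n_tumors`, and member index range `lo`, `hi` into `positions`.
#' @export
find_peaks <- function(profile, positions, h, tumor_ids = NULL,
                       min_insertions = 2, min_tumors = 2) {
  if (nrow(profile) == 0)
    return(data.frame(apex_pos = numeric(0), height = numeric(0),
                      n_insertions = integer(0), n_tumors = integer(0),
                      lo = integer(0), hi = integer(0)))
  idx <- cpp_local_maxima(profile$height)
  apex <- profile$pos[idx]
  height <- profile$height[idx]
  lo <- findInterval(apex - h, positions, left.open = TRUE) + 1L
  hi <- findInterval(apex + h, positions)
  n_ins <- hi - lo + 1L
  n_tum <- if (is.null(tumor_ids)) n_ins else
    vapply(seq_along(apex), function(i)
      if (n_ins[i] < 1) 0L else
        length(unique(tumor_ids[lo[i]:hi[i]])), integer(1))
  keep <- n_ins >= min_insertions &
    (if (is.null(tumor_ids)) TRUE else n_tum >= min_tumors)
  data.frame(apex_pos = apex, height = height, n_insertions = n_ins,
             n_tumors = n_tum, lo = lo, hi = hi)[keep, , drop = FALSE]
}

#' Monte-Carlo null distribution of peak heights over TTAA positions
#'
#' Each replicate places the observed number of insertions uniformly at
#' random (with replacement) over TTAA motif positions -- per chromosome
#' under `"chromosome-matched"`, genome-wide proportional to TTAA counts
#' otherwise -- and records, at every kernel width, the heights of all
#' density peaks (tumor-support filter disabled), the genome-wide maximum
#' height, and the peak count. Null profiles are evaluated on the regular
#' grid of spacing `grid_step_fraction * h`.
#'
#' @param n_by_chrom named integer vector, chromosome -> insertion count to
#'   match.
#' @param ttaa a [ttaa_index()] covering every chromosome with insertions.
#' @param params a [gkc_params()]; uses `scales`, `n_perm`, `null_mode`,
#'   `grid_step_fraction`, `min_insertions`, `truncate_sd`, `seed`.
#' @return An object of class `null_distribution`: per-scale pooled peak
#'   heights, per-replicate genome-wide maxima, mean peaks per replicate.
#' @export
sample_null <- function(n_by_chrom, ttaa, params = gkc_params()) {
  stopifnot(inherits(ttaa, "ttaa_index"))
  n_by_chrom <- n_by_chrom[n_by_chrom > 0]
  chroms <- names(n_by_chrom)
  no_ttaa <- chroms[!vapply(chroms, function(ch)
    length(ttaa$positions[[ch]]) > 0, logical(1))]
  if (length(no_ttaa) > 0)
    stopf("chromosome(s) with insertions but no TTAA positions: %s",
          paste(no_ttaa, collapse = ", "))
  if (length(chroms) == 0) {
    res <- list(heights = rep(list(numeric(0)), length(params$scales)),
                max_per_rep = matrix(0, params$n_perm, length(params$scales)),
                peaks_per_rep = matrix(0L, params$n_perm, length(params$scales)))
  } else {
    res <- with_seed(params$seed,
      cpp_null_peaks(ttaa$positions[chroms], as.integer(n_by_chrom),
                     ttaa$seqlengths[chroms], params$scales,
                     params$grid_step_fraction, params$truncate_sd,
                     params$n_perm, params$min_insertions,
                     params$null_mode == "chromosome-matched"))
  }
  names(res$heights) <- as.character(params$scales)
  structure(list(scales = params$scales,
                 heights = lapply(res$heights, sort),
                 max_per_rep = res$max_per_rep,
                 mean_peaks = colMeans(res$peaks_per_rep),
                 n_perm = params$n_perm, seed = params$seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Monte-Carlo null: %d replicates, %d scales (seed %d)\n",
              x$n_perm, length(x$scales), x$seed))
  cat(sprintf("  mean peaks/replicate: %s\n",
              paste(sprintf("%.0f", x$mean_peaks), collapse = " ")))
  invisible(x)
}

#' Empirical p value of a peak against the Monte-Carlo null
#'
#' `raw_p = (1 + #\{null peak heights >= observed\}) / (1 + total null peak
#' heights)` (add-one correction), pooled over replicates at the peak's
#' scale; `adjusted_p = min(1, raw_p * n_candidates_at_scale)` (Bonferroni
#' over the observed candidate peaks at that scale).
#'
#' @param height observed peak height(s).
#' @param null a [sample_null()] result.
#' @param scale the kernel width at which the peak was found.
#' @param n_candidates_at_scale Bonferroni factor.
#' @return data.frame with columns `raw_p` and `adjusted_p`.
#' @export
peak_pvalue <- function(height, null, scale, n_candidates_at_scale) {
  stopifnot(inherits(null, "null_distribution"))
  key <- as.character(scale)
  if (!key %in% names(null$heights))
    stopf("null distribution was not computed at scale %s", key)
  nh <- null$heights[[key]]
  if (length(nh) == 0)
    stopf("empty null distribution at scale %s: cannot compute p values", key)
  # nh is sorted ascending; count of null >= h by binary search
  ge <- length(nh) - findInterval(height, nh, left.open = TRUE)
  raw <- (1 + ge) / (1 + length(nh))
  data.frame(raw_p = raw,
             adjusted_p = pmin(1, raw * n_candidates_at_scale))
}

#' Call common insertion sites by multi-scale Gaussian kernel convolution
#'
#' Runs the full CIS detection on a pooled insertion set: per chromosome and
#' kernel width, computes the density profile (evaluation grid refined with
#' the insertion positions), extracts supported peaks, assigns each a
#' Monte-Carlo p value against the TTAA-constrained null with Bonferroni
#' correction across candidate peaks at that scale, clusters peaks across
#' scales whose apexes lie within `max(scales)` of each other, and reports a
#' CIS for every cluster significant at `alpha` on at least
#' `min_scales_significant` scales. The representative ("best") scale is the
#' one with the smallest adjusted p (ties to the smaller width, i.e. the
#' sharper localization); the CIS interval spans the member insertions at
#' that scale.
#'
#' @param pooled_sites pooled insertion data.frame (see
#'   [pool_nonredundant()]); columns `chrom`, `pos` required, `tumor_id` and
#'   `tissue` used when present.
#' @param ttaa a [ttaa_index()] covering all insertion chromosomes.
#' @param genes optional gene table; when supplied the result carries gene
#'   associations from [associate_genes()] as attribute `"associations"`.
#' @param params a [gkc_params()].
#' @return data.frame of CIS (one row each) with columns `cis_id`, `chrom`,
#'   `apex_pos`, `start`, `end`, `best_scale`, `raw_p`, `adjusted_p`,
#'   `n_scales_significant`, `n_insertions`, `n_tumors`, per-tissue counts
#'   `n_brain`/`n_spinal`/`n_other`, and a list column `members` of row
#'   indices into `pooled_sites`. The Monte-Carlo null is attached as
#'   attribute `"null"`.
#' @export
call_cis <- function(pooled_sites, ttaa, genes = NULL, params = gkc_params()) {
  stopifnot(inherits(ttaa, "ttaa_index"), inherits(params, "gkc_params"))
  empty <- data.frame(cis_id = character(0), chrom = character(0),
                      apex_pos = numeric(0), start = numeric(0),
                      end = numeric(0), best_scale = numeric(0),
                      raw_p = numeric(0), adjusted_p = numeric(0),
                      n_scales_significant = integer(0),
                      n_insertions = integer(0), n_tumors = integer(0),
                      n_brain = integer(0), n_spinal = integer(0),
                      n_other = integer(0))
  empty$members <- list()
  if (nrow(pooled_sites) == 0) return(empty)
  check_columns(pooled_sites, c("chrom", "pos"), "pooled insertion table")
  sites <- pooled_sites
  sites$.row <- seq_len(nrow(sites))
  sites <- sites[!sites$chrom %in% params$exclude_chroms, , drop = FALSE]
  if (nrow(sites) == 0) return(empty)
  if (is.null(sites$tumor_id))
    sites$tumor_id <- sites$sample_id %||% as.character(seq_len(nrow(sites)))
  if (is.null(sites$tissue)) sites$tissue <- "other"
  bad <- setdiff(unique(sites$chrom), names(ttaa$positions))
  if (length(bad) > 0)
    stopf("insertions on chromosome(s) absent from the TTAA index: %s",
          paste(bad, collapse = ", "))

  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  by_chrom <- split(sites, sites$chrom)
  n_by_chrom <- vapply(by_chrom, nrow, integer(1))

  # candidate peaks at every scale
  cand <- list()
  for (si in seq_along(params$scales)) {
    h <- params$scales[si]
    for (ch in names(by_chrom)) {
      sub <- by_chrom[[ch]]
      w <- if (params$weight_reads) as.numeric(sub$read_count) else NULL
      prof <- density_profile(sub$pos, h, ttaa$seqlengths[[ch]], params,
                              refine = TRUE, weights = w)
      pk <- find_peaks(prof, sub$pos, h, tumor_ids = sub$tumor_id,
                       min_insertions = params$min_insertions,
                       min_tumors = params$min_tumors)
      if (nrow(pk) > 0) {
        pk$chrom <- ch
        pk$scale <- h
        cand[[length(cand) + 1]] <- pk
      }
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)

  null <- sample_null(n_by_chrom, ttaa, params)

  genome_len <- sum(ttaa$seqlengths[names(by_chrom)])
  n_cand_at_scale <- table(factor(cand$scale, levels = params$scales))
  cand$raw_p <- NA_real_
  cand$adjusted_p <- NA_real_
  for (si in seq_along(params$scales)) {
    h <- params$scales[si]
    rows <- which(cand$scale == h)
    if (length(rows) == 0) next
    n_tests <- if (params$bonferroni == "candidates")
      as.integer(n_cand_at_scale[[as.character(h)]]) else
      max(1, floor(genome_len / h))
    pv <- peak_pvalue(cand$height[rows], null, h, n_tests)
    cand$raw_p[rows] <- pv$raw_p
    cand$adjusted_p[rows] <- pv$adjusted_p
  }

  # cluster significant peaks across scales: same chromosome, apex gap <=
  # max(scales). Clustering is restricted to peaks already significant at
  # their own scale; candidate peaks tile the background densely enough
  # that single-linkage over all of them would chain whole chromosomes.
  out <- list()
  gap <- max(params$scales)
  sig <- cand[cand$adjusted_p < params$alpha, , drop = FALSE]
  for (ch in names(by_chrom)) {
    cc <- sig[sig$chrom == ch, , drop = FALSE]
    if (nrow(cc) == 0) next
    cc <- cc[order(cc$apex_pos, cc$scale), , drop = FALSE]
    grp <- cumsum(c(1, diff(cc$apex_pos) > gap))
    for (g in split(seq_len(nrow(cc)), grp)) {
      cl <- cc[g, , drop = FALSE]
      n_sig <- length(unique(cl$scale))
      if (n_sig < params$min_scales_significant) next
      o <- order(cl$adjusted_p, cl$scale, -cl$height)
      best <- cl[o[1], , drop = FALSE]
      mem <- by_chrom[[ch]][best$lo:best$hi, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, apex_pos = best$apex_pos,
        start = min(mem$pos), end = max(mem$pos),
        best_scale = best$scale, raw_p = best$raw_p,
        adjusted_p = best$adjusted_p,
        n_scales_significant = as.integer(n_sig),
        n_insertions = best$n_insertions, n_tumors = best$n_tumors,
        n_brain = sum(mem$tissue == "brain"),
        n_spinal = sum(mem$tissue == "spinal"),
        n_other = sum(mem$tissue == "other"),
        members = I(list(mem$.row)))
    }
  }
  if (length(out) == 0) return(empty)
  cis <- do.call(rbind, out)
  cis <- cis[order(cis$chrom, cis$apex_pos), , drop = FALSE]
  cis <- cbind(cis_id = sprintf("CIS%03d", seq_len(nrow(cis))), cis)
  rownames(cis) <- NULL
  attr(cis, "null") <- null
  attr(cis, "candidates") <- cand[setdiff(names(cand), c("lo", "hi"))]
  attr(cis, "params") <- params
  if (!is.null(genes))
    attr(cis, "associations") <- associate_genes(cis, genes)
  cis
}
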