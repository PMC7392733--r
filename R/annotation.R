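#' Associate CIS with genes
#'
#' A gene is associated with a CIS when its body overlaps the CIS interval
#' extended by the representative kernel width on each side (the kernel's
#' support exceeds the member-insertion span). All overlapping genes are
#' reported, ordered by the distance from the CIS apex to the gene midpoint
#' and flagged `"overlap"`. When a CIS overlaps no gene and `max_distance >
#' 0`, the nearest gene within `max_distance` bp is associated and flagged
#' `"nearest"`; otherwise the CIS carries no association.
#'
#' @param cis CIS table from [call_cis()].
#' @param genes gene-model data.frame (`gene_id`, `name`, `chrom`, `start`,
#'   `end`, `strand`), e.g. from [read_gff3_genes()].
#' @param max_distance nearest-gene rescue distance in bp (default 0:
#'   strict overlap only).
#' @return data.frame with one row per (CIS, gene) association: `cis_id`,
#'   `gene_id`, `name`, `flag`, `apex_dist` (apex to gene midpoint, bp).
#' @export
associate_genes <- function(cis, genes, max_distance = 0) {
  empty <- data.frame(cis_id = character(0), gene_id = character(0),
                      name = character(0), flag = character(0),
                      apex_dist = numeric(0))
  if (nrow(cis) == 0 || nrow(genes) == 0) return(empty)
  cis_gr <- GenomicRanges::GRanges(
    cis$chrom,
    IRanges::IRanges(pmax(1, cis$start - cis$best_scale),
                     cis$end + cis$best_scale))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  ov <- GenomicRanges::findOverlaps(cis_gr, gene_gr)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  out <- data.frame(cis_id = cis$cis_id[qh],
                    gene_id = genes$gene_id[sh],
                    name = genes$name[sh],
                    flag = rep("overlap", length(qh)),
                    apex_dist = abs(cis$apex_pos[qh] -
                                      (genes$start[sh] + genes$end[sh]) / 2))
  if (max_distance > 0) {
    orphan <- which(!cis$cis_id %in% out$cis_id)
    if (length(orphan) > 0) {
      bare <- GenomicRanges::GRanges(cis$chrom[orphan],
                                     IRanges::IRanges(cis$start[orphan],
                                                      cis$end[orphan]))
      nr <- GenomicRanges::distanceToNearest(bare, gene_gr)
      keep <- which(S4Vectors::mcols(nr)$distance <= max_distance)
      if (length(keep) > 0) {
        i <- orphan[S4Vectors::queryHits(nr)[keep]]
        j <- S4Vectors::subjectHits(nr)[keep]
        out <- rbind(out, data.frame(
          cis_id = cis$cis_id[i], gene_id = genes$gene_id[j],
          name = genes$name[j], flag = "nearest",
          apex_dist = abs(cis$apex_pos[i] - (genes$start[j] + genes$end[j]) / 2)))
      }
    }
  }
  out <- out[order(match(out$cis_id, cis$cis_id), out$apex_dist, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Strand-aware window in which insertions are attributed to a gene: the gene
# body plus `upstream_bp` upstream of the transcription start (where sense
# insertions can activate transcription from the transposon promoter).
gene_window <- function(genes, upstream_bp = 10000) {
  plus <- genes$strand == "+"
  data.frame(chrom = genes$chrom,
             start = ifelse(plus, pmax(1, genes$start - upstream_bp), genes$start),
             end = ifelse(plus, genes$end, genes$end + upstream_bp))
}

#' Classify a gene's insertion pattern as activating or disrupting
#'
#' The transposon activates transcription when inserted in the sense
#' orientation at a 5' position (upstream of or early in the gene), and
#' disrupts the transcript when gene-trapped in the body in either
#' orientation. Operationalized as: `activating` iff at least 3 insertions,
#' sense fraction >= 0.8, an exact binomial test of the sense count against
#' 0.5 gives p < 0.05, and the median strand-aware relative position is <=
#' 0.2 of the gene body (0 = transcription start, 1 = end; upstream is
#' negative and therefore counts as early); `inactivating` iff at least 3
#' insertions, not activating, and at least half the insertions fall inside
#' the gene body; `ambiguous` otherwise (in particular whenever fewer than 3
#' insertions are available).
#'
#' @param gene one-row gene-model data.frame (or list) with `chrom`,
#'   `start`, `end`, `strand`.
#' @param insertions data.frame of insertions attributed to the gene
#'   (`chrom`, `pos`, `orientation`).
#' @return One-row data.frame: `label`, `sense_fraction`,
#'   `orientation_binomial_p`, `median_relative_position`, `n`.
#' @export
classify_pattern <- function(gene, insertions) {
  if (nrow(insertions) > 0 && any(insertions$chrom != gene$chrom))
    stopf("insertions on chromosome(s) %s do not match gene chromosome %s",
          paste(setdiff(insertions$chrom, gene$chrom), collapse = ","),
          gene$chrom)
  n <- nrow(insertions)
  if (n == 0)
    return(data.frame(label = "ambiguous", sense_fraction = NA_real_,
                      orientation_binomial_p = NA_real_,
                      median_relative_position = NA_real_, n = 0L))
  len <- max(1, gene$end - gene$start)
  rel <- if (gene$strand == "+") (insertions$pos - gene$start) / len
         else (gene$end - insertions$pos) / len
  sense <- insertions$orientation == gene$strand
  sf <- mean(sense)
  bp <- stats::binom.test(sum(sense), n, p = 0.5)$p.value
  med <- stats::median(rel)
  in_body <- mean(rel >= 0 & rel <= 1)
  label <- if (n < 3) "ambiguous"
    else if (sf >= 0.8 && bp < 0.05 && med <= 0.2) "activating"
    else if (in_body >= 0.5) "inactivating"
    else "ambiguous"
  data.frame(label = label, sense_fraction = sf, orientation_binomial_p = bp,
             median_relative_position = med, n = as.integer(n))
}

#' Per-gene roll-up of CIS-associated insertions
#'
#' For every gene associated with at least one CIS, attributes pooled
#' insertions lying in the gene's strand-aware window (body plus
#' `upstream_bp` upstream of the transcription start), and summarizes:
#' insertion total, tumor recurrence, per-tissue counts and the
#' activating/disrupting pattern call.
#'
#' @param cis CIS table from [call_cis()].
#' @param associations association table from [associate_genes()].
#' @param pooled_sites the pooled insertion table the CIS were called on.
#' @param genes gene-model data.frame.
#' @param upstream_bp upstream attribution window (default 10 kb).
#' @return data.frame with one row per CIS gene: `gene_id`, `name`,
#'   `cis_ids`, `total_insertions`, `n_tumors`, `n_brain`, `n_spinal`,
#'   `n_other`, and the [classify_pattern()] columns.
#' @export
cis_gene_table <- function(cis, associations, pooled_sites, genes,
                           upstream_bp = 10000) {
  empty <- data.frame(gene_id = character(0), name = character(0),
                      cis_ids = character(0), total_insertions = integer(0),
                      n_tumors = integer(0), n_brain = integer(0),
                      n_spinal = integer(0), n_other = integer(0),
                      label = character(0), sense_fraction = numeric(0),
                      orientation_binomial_p = numeric(0),
                      median_relative_position = numeric(0), n = integer(0))
  if (nrow(associations) == 0) return(empty)
  sites <- pooled_sites
  if (is.null(sites$tumor_id)) sites$tumor_id <- sites$sample_id
  if (is.null(sites$tissue)) sites$tissue <- "other"
  win <- gene_window(genes, upstream_bp)
  rows <- lapply(unique(associations$gene_id), function(gid) {
    gi <- match(gid, genes$gene_id)
    sel <- sites$chrom == win$chrom[gi] & sites$pos >= win$start[gi] &
      sites$pos <= win$end[gi]
    sub <- sites[sel, , drop = FALSE]
    pat <- classify_pattern(genes[gi, ], sub)
    cbind(data.frame(gene_id = gid, name = genes$name[gi],
                     cis_ids = paste(sort(unique(
                       associations$cis_id[associations$gene_id == gid])),
                       collapse = ";"),
                     total_insertions = nrow(sub),
                     n_tumors = length(unique(sub$tumor_id)),
                     n_brain = sum(sub$tissue == "brain"),
                     n_spinal = sum(sub$tissue == "spinal"),
                     n_other = sum(sub$tissue == "other")),
          pat)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank CIS genes by insertion recurrence
#'
#' Orders the CIS-gene table by total insertions (descending), breaking ties
#' by tumor recurrence and then gene name, and computes the percentage of
#' cohort tumors carrying at least one insertion in the gene -- the
#' oncoprint-style ranking of screen hits.
#'
#' @param cis_genes table from [cis_gene_table()].
#' @param cohort named vector of tumor counts per tissue (e.g.
#'   `c(brain = 46, spinal = 50)`), or a single total.
#' @return `cis_genes` sorted, with `rank` and `pct_tumors` columns added.
#' @export
rank_cis_genes <- function(cis_genes, cohort) {
  n_total <- sum(cohort)
  if (length(cohort) == 0 || is.na(n_total) || n_total < 1)
    stopf("cohort size must be a positive tumor count")
  if (nrow(cis_genes) == 0) {
    cis_genes$rank <- integer(0)
    cis_genes$pct_tumors <- numeric(0)
    return(cis_genes)
  }
  o <- order(-cis_genes$total_insertions, -cis_genes$n_tumors, cis_genes$name)
  out <- cis_genes[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$pct_tumors <- 100 * out$n_tumors / n_total
  rownames(out) <- NULL
  out
}
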