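#' Classify insertions as clonal, shared-subclonal or private across
#' multi-region samples of one tumor
#'
#' Insertions supported by at least `min_reads` reads in a region are said
#' to be present there; presence is matched across regions at the same
#' chromosome and orientation when positions differ by at most
#' `match_tolerance_bp` (default 0: exact TTAA position, which is safe
#' because piggyBac coordinates are quantized to the motif). An insertion
#' present in every region is `clonal` (an early, selected event), in
#' exactly one region `private`, otherwise `shared_subclonal`. The
#' read-support filter is applied per region, so an insertion with a single
#' supporting read in one region does not count as present there.
#'
#' @param regions named list of per-region insertion tables, or a single
#'   data.frame with a `region_id` column; all from one tumor, at least two
#'   regions.
#' @param min_reads minimum supporting read count per region (default 2).
#' @param match_tolerance_bp position tolerance for matching (default 0).
#' @param genes optional gene table; when given, each matched insertion is
#'   annotated with the gene whose attribution window contains it (NA if
#'   none), so calls can be restricted to CIS genes downstream.
#' @param upstream_bp upstream extent of the gene attribution window.
#' @return data.frame of clonality calls: `chrom`, `pos` (representative,
#'   the smallest matched position), `orientation`, `gene` (if annotated),
#'   `regions_present` (comma-separated), `n_regions_present`,
#'   `n_regions_total`, `label`.
#' @export
match_insertions <- function(regions, min_reads = 2, match_tolerance_bp = 0,
                             genes = NULL, upstream_bp = 10000) {
  if (min_reads < 1) stopf("`min_reads` must be >= 1")
  if (match_tolerance_bp < 0) stopf("`match_tolerance_bp` must be >= 0")
  if (is.data.frame(regions)) {
    check_columns(regions, "region_id", "multi-region insertion table")
    regions <- split(regions, regions$region_id)
  }
  if (length(regions) < 2)
    stopf("clonality analysis needs at least 2 regions of one tumor")
  region_ids <- names(regions) %||% as.character(seq_along(regions))
  all <- do.call(rbind, lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    check_columns(r, c("chrom", "pos", "orientation", "read_count"),
                  sprintf("region table %s", region_ids[i]))
    r <- r[r$read_count >= min_reads, , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    data.frame(region = region_ids[i], chrom = r$chrom, pos = r$pos,
               orientation = r$orientation)
  }))
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      orientation = character(0), gene = character(0),
                      regions_present = character(0),
                      n_regions_present = integer(0),
                      n_regions_total = integer(0), label = character(0))
  if (is.null(all) || nrow(all) == 0) return(empty)
  # group matching positions per (chrom, orientation): single linkage with
  # gaps <= tolerance (identity when tolerance is 0)
  all <- all[order(all$chrom, all$orientation, all$pos), , drop = FALSE]
  co <- paste(all$chrom, all$orientation, sep = "\x1f")
  gid <- integer(nrow(all))
  next_id <- 0L
  for (idx in split(seq_len(nrow(all)), co)) {
    p <- all$pos[idx]
    brk <- cumsum(c(1, diff(p) > match_tolerance_bp))
    gid[idx] <- next_id + brk
    next_id <- next_id + brk[length(brk)]
  }
  calls <- do.call(rbind, lapply(split(seq_len(nrow(all)), gid), function(idx) {
    present <- sort(unique(all$region[idx]))
    np <- length(present)
    data.frame(chrom = all$chrom[idx[1]], pos = min(all$pos[idx]),
               orientation = all$orientation[idx[1]],
               gene = NA_character_,
               regions_present = paste(present, collapse = ","),
               n_regions_present = np,
               n_regions_total = length(regions),
               label = if (np == length(regions)) "clonal"
                       else if (np == 1) "private" else "shared_subclonal")
  }))
  calls <- calls[order(calls$chrom, calls$pos, calls$orientation), , drop = FALSE]
  rownames(calls) <- NULL
  if (!is.null(genes)) {
    win <- gene_window(genes, upstream_bp)
    for (i in seq_len(nrow(calls))) {
      hit <- which(win$chrom == calls$chrom[i] & win$start <= calls$pos[i] &
                     win$end >= calls$pos[i])
      if (length(hit) > 0) calls$gene[i] <- genes$name[hit[1]]
    }
  }
  calls
}

#' Per-gene clonality summary
#'
#' Tallies clonal / shared-subclonal / private insertion calls per gene and
#' reports the modal label (ties resolved toward the more clonal label:
#' clonal > shared_subclonal > private).
#'
#' @param calls clonality calls from [match_insertions()] (gene-annotated).
#' @param cis_genes optional restriction: a character vector of gene names
#'   or a CIS-gene table with a `name` column.
#' @return data.frame: `gene`, `n_clonal`, `n_shared_subclonal`,
#'   `n_private`, `modal_label`.
#' @export
summarize_clonality <- function(calls, cis_genes = NULL) {
  empty <- data.frame(gene = character(0), n_clonal = integer(0),
                      n_shared_subclonal = integer(0), n_private = integer(0),
                      modal_label = character(0))
  if (nrow(calls) == 0) return(empty)
  x <- calls[!is.na(calls$gene), , drop = FALSE]
  if (!is.null(cis_genes)) {
    keep <- if (is.data.frame(cis_genes)) cis_genes$name else cis_genes
    x <- x[x$gene %in% keep, , drop = FALSE]
  }
  if (nrow(x) == 0) return(empty)
  labels <- c("clonal", "shared_subclonal", "private")
  out <- do.call(rbind, lapply(split(x, x$gene), function(g) {
    cnt <- vapply(labels, function(l) sum(g$label == l), integer(1))
    data.frame(gene = g$gene[1], n_clonal = cnt[[1]],
               n_shared_subclonal = cnt[[2]], n_private = cnt[[3]],
               modal_label = labels[which.max(cnt)])
  }))
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
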