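#' Read and write insertion-site tables
#'
#' The interchange format for QI-seq style insertion evidence is a
#' tab-separated table with header and columns `sample_id`, `tumor_id`,
#' `region_id`, `tissue`, `chrom`, `pos`, `orientation`, `transposon_end`,
#' `read_count`. `pos` is the 1-based coordinate of the first base of the
#' TTAA target site; `orientation` is the transposon orientation on the
#' reference (`+`/`-`); `transposon_end` records which ITR library the
#' evidence came from (`5p`, `3p`, or `merged` after end reconciliation).
#'
#' @param path file path.
#' @return `read_insertions()` returns a validated data.frame.
#' @export
read_insertions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  check_columns(df, c("sample_id", "chrom", "pos", "orientation",
                      "transposon_end", "read_count"), "insertion TSV")
  df$pos <- as.numeric(df$pos)
  df$read_count <- as.integer(df$read_count)
  if (is.null(df$tumor_id)) df$tumor_id <- df$sample_id
  if (is.null(df$region_id)) df$region_id <- ""
  if (is.null(df$tissue)) df$tissue <- "other"
  validate_insertions(df)
}

#' @param sites insertion-site data.frame.
#' @rdname read_insertions
#' @export
write_insertions <- function(sites, path) {
  cols <- c("sample_id", "tumor_id", "region_id", "tissue", "chrom", "pos",
            "orientation", "transposon_end", "read_count")
  sites <- sites[intersect(cols, names(sites))]
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_insertions <- function(df, what = "insertion table") {
  if (nrow(df) == 0) return(df)
  if (any(is.na(df$pos) | df$pos < 1))
    stopf("%s: `pos` must be >= 1 (row %d)", what, which(is.na(df$pos) | df$pos < 1)[1])
  if (any(is.na(df$read_count) | df$read_count < 1))
    stopf("%s: `read_count` must be >= 1 (row %d)", what,
          which(is.na(df$read_count) | df$read_count < 1)[1])
  if (!all(df$orientation %in% ORIENTATIONS))
    stopf("%s: `orientation` must be one of %s", what,
          paste(ORIENTATIONS, collapse = ", "))
  if (!is.null(df$tissue) && !all(df$tissue %in% TISSUES))
    stopf("%s: unknown tissue label(s): %s", what,
          paste(unique(setdiff(df$tissue, TISSUES)), collapse = ", "))
  if (!all(df$transposon_end %in% TRANSPOSON_ENDS))
    stopf("%s: `transposon_end` must be one of %s", what,
          paste(TRANSPOSON_ENDS, collapse = ", "))
  df
}

is_key_col <- c("sample_id", "chrom", "pos", "orientation", "transposon_end")

#' Collapse mapped reads into insertion sites
#'
#' Reads mapping to the same genomic location in the same sample count as a
#' single insertion site (IS): one output row per distinct
#' `(sample_id, chrom, pos, orientation, transposon_end)` with `read_count`
#' equal to the number of contributing rows. If the input already carries a
#' `read_count` column, counts are summed instead, which makes the operation
#' idempotent and conserves total read count.
#'
#' @param read_records data.frame with at least the five key columns; one row
#'   per mapped, primer-filtered read (or per already-collapsed IS).
#' @return A collapsed insertion-site data.frame sorted by
#'   `(sample_id, chrom, pos)`.
#' @export
collapse_reads <- function(read_records) {
  check_columns(read_records, is_key_col, "read table")
  if (nrow(read_records) == 0) {
    read_records$read_count <- integer(0)
    return(read_records)
  }
  keyvals <- read_records[is_key_col]
  bad <- Reduce(`|`, lapply(keyvals, function(v) is.na(v) | v == ""))
  if (any(bad))
    stopf("read table: missing key field(s) in row %d", which(bad)[1])
  rc <- if ("read_count" %in% names(read_records))
    as.numeric(read_records$read_count) else rep(1, nrow(read_records))
  key <- do.call(paste, c(keyvals, sep = "\x1f"))
  first <- !duplicated(key)
  out <- read_records[first, , drop = FALSE]
  sums <- rowsum(rc, key)
  out$read_count <- as.integer(sums[match(key[first], rownames(sums)), 1])
  out <- out[order(out$sample_id, out$chrom, out$pos, out$orientation,
                   out$transposon_end), , drop = FALSE]
  rownames(out) <- NULL
  validate_insertions(out, "collapsed table")
}

#' Reconcile 5' and 3' transposon-end libraries
#'
#' QI-seq sequences the two transposon-genome junctions with separate primers,
#' so the same integration event can appear once per end. A `5p` and a `3p`
#' record from the same sample, chromosome and orientation whose positions lie
#' within `tolerance_bp` are unified into one `merged` record at the 5p
#' position with summed read count. Unpaired records pass through unchanged.
#' Pairing is greedy in position order, each record used at most once.
#'
#' @param sites collapsed insertion-site data.frame.
#' @param tolerance_bp non-negative pairing distance in bp (default 10).
#' @return Insertion-site data.frame with ends merged; total read count is
#'   conserved.
#' @export
merge_ends <- function(sites, tolerance_bp = 10) {
  if (length(tolerance_bp) != 1 || is.na(tolerance_bp) || tolerance_bp < 0)
    stopf("`tolerance_bp` must be a single non-negative number")
  check_columns(sites, c(is_key_col, "read_count"), "insertion table")
  if (nrow(sites) == 0) return(sites)
  grp <- paste(sites$sample_id, sites$chrom, sites$orientation, sep = "\x1f")
  pieces <- lapply(split(seq_len(nrow(sites)), grp), function(idx) {
    sub <- sites[idx, , drop = FALSE]
    i5 <- which(sub$transposon_end == "5p")
    i3 <- which(sub$transposon_end == "3p")
    if (length(i5) == 0 || length(i3) == 0) return(sub)
    i5 <- i5[order(sub$pos[i5])]
    i3 <- i3[order(sub$pos[i3])]
    used3 <- rep(FALSE, length(i3))
    for (a in i5) {
      j <- which(!used3 & abs(sub$pos[i3] - sub$pos[a]) <= tolerance_bp)
      if (length(j) > 0) {
        j <- j[which.min(abs(sub$pos[i3[j]] - sub$pos[a]))]
        b <- i3[j]
        used3[j] <- TRUE
        sub$read_count[a] <- sub$read_count[a] + sub$read_count[b]
        sub$transposon_end[a] <- "merged"
        sub$read_count[b] <- NA_integer_ # marks consumed partner
      }
    }
    sub[!is.na(sub$read_count), , drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$sample_id, out$chrom, out$pos, out$orientation,
                   out$transposon_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep the top N insertion sites per sample by read count
#'
#' Retains at most `n` IS per sample, by descending read count; ties at the
#' boundary are broken deterministically by `(chrom, pos)` ascending.
#'
#' @param sites collapsed insertion-site data.frame.
#' @param n maximum IS per sample (default 300, the usual screen depth cut).
#' @return Filtered data.frame sorted by `(sample_id, chrom, pos)`.
#' @export
top_n_filter <- function(sites, n = 300) {
  if (length(n) != 1 || is.na(n) || n < 1)
    stopf("`n` must be a single integer >= 1")
  check_columns(sites, c("sample_id", "chrom", "pos", "read_count"),
                "insertion table")
  if (nrow(sites) == 0) return(sites)
  o <- order(sites$sample_id, -sites$read_count, sites$chrom, sites$pos)
  rank_in_sample <- stats::ave(seq_along(o), sites$sample_id[o],
                               FUN = seq_along)
  keep <- sort(o[rank_in_sample <= n])
  out <- sites[keep, , drop = FALSE]
  out <- out[order(out$sample_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool per-sample insertion sites into a non-redundant set
#'
#' Builds the pooled insertion set used for CIS calling. Within each pooling
#' unit (tumor by default, so multi-region aliquots of one tumor are unioned)
#' duplicate `(chrom, pos)` rows are collapsed with read counts summed. With
#' `collapse = "across-samples"` identical positions are additionally
#' collapsed genome-wide to a single record. Each output row is annotated
#' with the contributing sample ids (`samples`) and their count
#' (`n_samples`).
#'
#' @param sites a single insertion-site data.frame or a list of per-sample
#'   data.frames (rbound together).
#' @param collapse `"within-sample"` (default) or `"across-samples"`.
#' @param unit `"tumor"` (default; unions regions of one tumor) or
#'   `"sample"`.
#' @return Pooled insertion data.frame sorted by `(chrom, pos)`.
#' @export
pool_nonredundant <- function(sites,
                              collapse = c("within-sample", "across-samples"),
                              unit = c("tumor", "sample")) {
  collapse <- match.arg(collapse)
  unit <- match.arg(unit)
  if (is.list(sites) && !is.data.frame(sites))
    sites <- do.call(rbind, sites)
  check_columns(sites, c("sample_id", "chrom", "pos", "read_count"),
                "insertion table")
  if (nrow(sites) == 0) {
    sites$samples <- character(0)
    sites$n_samples <- integer(0)
    return(sites)
  }
  if (is.null(sites$tumor_id)) sites$tumor_id <- sites$sample_id
  if (is.null(sites$tissue)) sites$tissue <- "other"
  tl <- unique(sites[c("sample_id", "tissue")])
  if (anyDuplicated(tl$sample_id))
    stopf("conflicting tissue labels for sample_id %s",
          tl$sample_id[duplicated(tl$sample_id)][1])
  uid <- if (unit == "tumor") sites$tumor_id else sites$sample_id
  key <- if (collapse == "within-sample")
    paste(uid, sites$chrom, sites$pos, sep = "\x1f")
  else
    paste(sites$chrom, sites$pos, sep = "\x1f")
  first <- !duplicated(key)
  out <- sites[first, , drop = FALSE]
  sums <- rowsum(as.numeric(sites$read_count), key)
  out$read_count <- as.integer(sums[match(key[first], rownames(sums)), 1])
  contrib <- lapply(split(sites$sample_id, key), function(s) sort(unique(s)))
  out$samples <- vapply(contrib[match(key[first], names(contrib))],
                        paste, "", collapse = ",")
  out$n_samples <- lengths(contrib[match(key[first], names(contrib))])
  out <- out[order(out$chrom, out$pos, out$tumor_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' BED6 export/import of insertion sites
#'
#' Writes 0-based half-open intervals `[pos - 1, pos + 3)` spanning the 4-bp
#' TTAA target site, with `name = sample_id:read_count`, `score = read_count`
#' and `strand = orientation`. `read_bed()` inverts the conversion exactly,
#' so export followed by import round-trips every record.
#'
#' @param sites insertion-site data.frame.
#' @param path file path.
#' @export
write_bed <- function(sites, path) {
  check_columns(sites, c("sample_id", "chrom", "pos", "orientation",
                         "read_count"), "insertion table")
  bed <- data.frame(chrom = sites$chrom,
                    start = format(sites$pos - 1, scientific = FALSE, trim = TRUE),
                    end = format(sites$pos + 3, scientific = FALSE, trim = TRUE),
                    name = paste0(sites$sample_id, ":", sites$read_count),
                    score = sites$read_count,
                    strand = sites$orientation)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE,
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "integer", "character"))
  names(bed) <- c("chrom", "start", "end", "name", "score", "strand")
  sample_id <- sub(":[0-9]+$", "", bed$name)
  data.frame(sample_id = sample_id,
             tumor_id = sample_id,
             region_id = "",
             tissue = "other",
             chrom = bed$chrom,
             pos = bed$start + 1,
             orientation = bed$strand,
             transposon_end = "merged",
             read_count = bed$score)
}

#' Read gene models from GFF3
#'
#' Imports `type == "gene"` records and keeps `seqid`, `start`, `end`,
#' `strand` and the `ID` and `Name` attributes.
#'
#' @param path GFF3 file path.
#' @return data.frame with columns `gene_id`, `name`, `chrom`, `start`,
#'   `end`, `strand` (1-based inclusive coordinates).
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID)
  data.frame(gene_id = as.character(gr$ID),
             name = nm,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}

#' @param genes gene-model data.frame as returned by [read_gff3_genes()].
#' @rdname read_gff3_genes
#' @export
write_gff3_genes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$Name <- genes$name
  gr$source <- "pbscreen"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
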