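#' TTAA index: the discrete space of possible piggyBac integration sites
#'
#' piggyBac integrates exclusively at TTAA tetranucleotides, so the set of
#' TTAA start positions defines the null space over which random insertions
#' are placed. TTAA is its own reverse complement, so the index carries no
#' strand. Positions are 1-based coordinates of the first T.
#'
#' @param positions named list, chromosome -> strictly increasing integer
#'   vector of 1-based TTAA start positions.
#' @param seqlengths named numeric vector of chromosome lengths, covering at
#'   least the chromosomes in `positions`.
#' @return An object of class `ttaa_index`: a list with elements `positions`
#'   and `seqlengths`.
#' @seealso [scan_ttaa()] to build one from sequence, [read_ttaa_tsv()] /
#'   [write_ttaa_tsv()] for the cached TSV form.
#' @export
ttaa_index <- function(positions, seqlengths) {
  if (is.null(names(positions)) && length(positions) > 0)
    stopf("`positions` must be a named list (chromosome -> positions)")
  chroms <- names(positions)
  miss <- setdiff(chroms, names(seqlengths))
  if (length(miss) > 0)
    stopf("`seqlengths` lacks length(s) for chromosome(s): %s",
          paste(miss, collapse = ", "))
  positions <- lapply(positions, function(p) as.numeric(p))
  for (chrom in chroms) {
    p <- positions[[chrom]]
    if (length(p) > 0) {
      if (is.unsorted(p, strictly = TRUE))
        stopf("TTAA positions on %s are not strictly increasing", chrom)
      if (p[1] < 1)
        stopf("TTAA positions on %s include coordinates < 1", chrom)
      if (p[length(p)] + 3 > seqlengths[[chrom]])
        stopf("TTAA position %d on %s extends past chromosome end (length %d)",
              p[length(p)], chrom, seqlengths[[chrom]])
    }
  }
  structure(list(positions = positions,
                 seqlengths = stats::setNames(as.numeric(seqlengths),
                                              names(seqlengths))),
            class = "ttaa_index")
}

#' @export
print.ttaa_index <- function(x, ...) {
  n <- vapply(x$positions, length, integer(1))
  cat(sprintf("TTAA index: %d chromosome(s), %s motif positions\n",
              length(x$positions), format(sum(n), big.mark = ",")))
  invisible(x)
}

#' Scan genome sequence for TTAA motifs
#'
#' Finds every exact TTAA occurrence (case-insensitive) in each chromosome.
#' `N` never matches. TTAA cannot overlap itself, but adjacent occurrences
#' (e.g. `TTAATTAA`) are both reported.
#'
#' @param genome_sequences named character vector or list of DNA strings over
#'   the alphabet `{A, C, G, T, N}` (case-insensitive), or a
#'   [Biostrings::DNAStringSet].
#' @return A [ttaa_index()].
#' @examples
#' scan_ttaa(c(chr1 = "TTAATTAA"))
#' @export
scan_ttaa <- function(genome_sequences) {
  if (methods::is(genome_sequences, "DNAStringSet")) {
    seqs <- as.character(genome_sequences)
  } else {
    seqs <- unlist(as.list(genome_sequences))
  }
  if (length(seqs) == 0)
    return(ttaa_index(stats::setNames(list(), character(0)), numeric(0)))
  if (is.null(names(seqs)))
    stopf("genome sequences must be named by chromosome")
  bad <- regexpr("[^ACGTNacgtn]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stopf("non-DNA character at offset %d of chromosome %s",
          bad[i], names(seqs)[i])
  }
  dna <- Biostrings::DNAStringSet(toupper(seqs))
  hits <- Biostrings::vmatchPattern("TTAA", dna, fixed = TRUE)
  pos <- lapply(seq_along(hits), function(i) as.numeric(Biostrings::start(hits[[i]])))
  names(pos) <- names(seqs)
  ttaa_index(pos, stats::setNames(nchar(seqs), names(seqs)))
}

#' Cache a TTAA index as TSV
#'
#' Two-column TSV (`chrom`, `pos`) preceded by `#length` comment lines that
#' record chromosome lengths, so the index round-trips exactly.
#'
#' @param index a [ttaa_index()].
#' @param path output file path.
#' @export
write_ttaa_tsv <- function(index, path) {
  stopifnot(inherits(index, "ttaa_index"))
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(index$seqlengths))
    cat(sprintf("#length\t%s\t%.0f\n", chrom, index$seqlengths[[chrom]]), file = con)
  cat("chrom\tpos\n", file = con)
  for (chrom in names(index$positions)) {
    p <- index$positions[[chrom]]
    if (length(p) > 0)
      writeLines(paste(chrom, format(p, scientific = FALSE, trim = TRUE),
                       sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_ttaa_tsv
#' @export
read_ttaa_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#length\t", lines, value = TRUE)
  parts <- strsplit(hdr, "\t", fixed = TRUE)
  seqlen <- stats::setNames(as.numeric(vapply(parts, `[`, "", 3)),
                            vapply(parts, `[`, "", 2))
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = body, header = TRUE,
                          colClasses = c("character", "numeric"))
  pos <- split(df$pos, factor(df$chrom, levels = names(seqlen)))
  pos <- lapply(pos, function(p) sort(unique(p)))
  ttaa_index(pos, seqlen)
}
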