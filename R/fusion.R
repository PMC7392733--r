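#' Classify gene-transposon fusion transcripts
#'
#' The ATP1-S2 transposon cargo carries a promoter + splice donor (SD) unit
#' that drives host-gene transcription when fused in the sense orientation,
#' and two splice acceptors (the carp beta-actin SA, `CbASA`, and the
#' Engrailed-2 exon-2 SA, `En2SA`) plus bidirectional polyA sites that
#' truncate the host transcript in either orientation. Accordingly: `SD` ->
#' `activating` (sense only; an SD fusion in the antisense orientation is
#' biologically inconsistent and raises an error citing the record), and
#' `CbASA` / `En2SA` -> `truncating` regardless of orientation.
#'
#' @param feature character vector in `{"SD", "CbASA", "En2SA"}`.
#' @param orientation character vector in `{"sense", "antisense"}`, the
#'   transposon orientation relative to the gene.
#' @return Character vector of effects (`"activating"` / `"truncating"`).
#' @export
classify_fusion <- function(feature, orientation) {
  if (length(feature) != length(orientation))
    stopf("`feature` and `orientation` must have equal length")
  if (!all(feature %in% c("SD", "CbASA", "En2SA")))
    stopf("unknown fusion feature(s): %s",
          paste(unique(setdiff(feature, c("SD", "CbASA", "En2SA"))),
                collapse = ", "))
  if (!all(orientation %in% c("sense", "antisense")))
    stopf("fusion orientation must be \"sense\" or \"antisense\"")
  bad <- which(feature == "SD" & orientation == "antisense")
  if (length(bad) > 0)
    stopf(paste("record %d: splice-donor (SD) fusion in antisense orientation",
                "is inconsistent with transposon geometry"), bad[1])
  ifelse(feature == "SD", "activating", "truncating")
}

#' Read and write fusion-transcript tables
#'
#' TSV with header and columns `sample_id`, `gene`, `feature`,
#' `orientation`, `junction_reads`, `spanning_fragments` -- the summary
#' output of a split-read fusion caller run on transposon-bearing tumors.
#' Every record must be supported by at least one junction read or spanning
#' fragment.
#'
#' @param path file path.
#' @export
read_fusions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  check_columns(df, c("sample_id", "gene", "feature", "orientation",
                      "junction_reads", "spanning_fragments"), "fusion TSV")
  df$junction_reads <- as.integer(df$junction_reads)
  df$spanning_fragments <- as.integer(df$spanning_fragments)
  if (any(df$junction_reads + df$spanning_fragments < 1))
    stopf("fusion TSV: row %d has no supporting reads",
          which(df$junction_reads + df$spanning_fragments < 1)[1])
  df
}

#' @param fusions fusion-record data.frame.
#' @rdname read_fusions
#' @export
write_fusions <- function(fusions, path) {
  utils::write.table(fusions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Enrichment of fusion-supported genes among CIS genes
#'
#' Two-sided Fisher's exact test of the overlap between the CIS gene set
#' and the set of genes with supporting fusion transcripts, against a
#' supplied gene universe (the universe must be given explicitly, e.g. all
#' annotated genes):
#' `[[overlap, cis_only], [fusion_only, neither]]`.
#'
#' @param cis_genes,fusion_genes,universe character vectors of gene names;
#'   both sets must be contained in `universe`.
#' @return A list: `n_cis_with_fusion`, `n_cis`, `n_fusion_genes`,
#'   `universe_size`, `odds_ratio`, `p_two_sided`.
#' @export
overlap_enrichment <- function(cis_genes, fusion_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stopf("gene universe must be non-empty")
  cis_genes <- unique(cis_genes)
  fusion_genes <- unique(fusion_genes)
  out <- setdiff(union(cis_genes, fusion_genes), universe)
  if (length(out) > 0)
    stopf("gene(s) outside the supplied universe: %s",
          paste(utils::head(out, 5), collapse = ", "))
  ov <- length(intersect(cis_genes, fusion_genes))
  tab <- matrix(c(ov, length(cis_genes) - ov,
                  length(fusion_genes) - ov,
                  length(universe) - length(union(cis_genes, fusion_genes))),
                nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab)
  list(n_cis_with_fusion = ov, n_cis = length(cis_genes),
       n_fusion_genes = length(fusion_genes),
       universe_size = length(universe),
       odds_ratio = unname(ft$estimate), p_two_sided = ft$p.value)
}
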