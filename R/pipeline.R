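#' Run the full screen analysis on an insertion table
#'
#' Convenience wrapper chaining the standard stages: per-sample top-N
#' read-count filter, non-redundant pooling (tumor-level union of regions),
#' multi-scale Gaussian kernel convolution CIS calling against the
#' TTAA-constrained Monte-Carlo null, CIS-gene association, and the ranked
#' CIS-gene table with pattern calls.
#'
#' @param insertions collapsed insertion-site table (see
#'   [read_insertions()] or [simulate_cohort()]).
#' @param ttaa a [ttaa_index()].
#' @param genes gene-model data.frame.
#' @param cohort named tumor counts per tissue.
#' @param params a [gkc_params()].
#' @param top_n per-sample IS cap before pooling (default 300).
#' @param max_distance nearest-gene rescue distance for association.
#' @param upstream_bp upstream attribution window for per-gene roll-ups.
#' @return A list: `pooled` (pooled insertion table), `cis` (CIS table),
#'   `associations`, `genes` (ranked CIS-gene table).
#' @export
screen_pipeline <- function(insertions, ttaa, genes, cohort,
                            params = gkc_params(), top_n = 300,
                            max_distance = 0, upstream_bp = 10000) {
  filtered <- top_n_filter(insertions, top_n)
  pooled <- pool_nonredundant(filtered)
  cis <- call_cis(pooled, ttaa, params = params)
  assoc <- associate_genes(cis, genes, max_distance = max_distance)
  cg <- cis_gene_table(cis, assoc, pooled, genes, upstream_bp = upstream_bp)
  list(pooled = pooled, cis = cis, associations = assoc,
       genes = rank_cis_genes(cg, cohort))
}
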