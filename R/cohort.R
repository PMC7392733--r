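#' Shared and tissue-specific CIS genes
#'
#' Partitions the CIS-gene set by per-tissue insertion support: a gene is
#' `shared` when it has at least one insertion in each tumor type, and
#' tissue-specific when all of its insertions come from one tissue.
#'
#' @param cis_genes CIS-gene table with per-tissue counts `n_brain` and
#'   `n_spinal` (see [cis_gene_table()]).
#' @return A list of class `venn_summary`: `shared`, `brain_specific`,
#'   `spinal_specific` (gene name vectors) and `counts`.
#' @export
shared_specific <- function(cis_genes) {
  check_columns(cis_genes, c("name", "n_brain", "n_spinal"), "CIS-gene table")
  none <- cis_genes$n_brain == 0 & cis_genes$n_spinal == 0
  if (any(none))
    warning(sprintf("%d CIS gene(s) with no brain or spinal insertions excluded",
                    sum(none)))
  x <- cis_genes[!none, , drop = FALSE]
  shared <- x$name[x$n_brain >= 1 & x$n_spinal >= 1]
  brain <- x$name[x$n_brain >= 1 & x$n_spinal == 0]
  spinal <- x$name[x$n_brain == 0 & x$n_spinal >= 1]
  structure(list(shared = shared, brain_specific = brain,
                 spinal_specific = spinal,
                 counts = c(shared = length(shared),
                            brain_specific = length(brain),
                            spinal_specific = length(spinal))),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("CIS genes: %d shared, %d brain-specific, %d spinal-specific\n",
              x$counts[["shared"]], x$counts[["brain_specific"]],
              x$counts[["spinal_specific"]]))
  invisible(x)
}

#' Fisher's exact test of per-gene insertion counts between cohorts
#'
#' Tests whether a gene is hit at different rates in the two tumor cohorts,
#' normalizing for cohort size via the 2x2 table
#' `[[count_brain, n_brain - count_brain], [count_spinal, n_spinal -
#' count_spinal]]`. Two-sided p values use the point-probability rule (sum
#' over tables at most as probable as the observed one) and the odds ratio
#' is the conditional maximum-likelihood estimate, as in
#' [stats::fisher.test()]. Insertion counts are treated as tumor-level
#' events; a count exceeding its cohort size is clamped with a warning when
#' `clamp = TRUE` (the default), otherwise it is an error.
#'
#' @param gene gene name (carried through to the output).
#' @param count_brain,count_spinal insertion counts per tissue.
#' @param n_brain,n_spinal cohort tumor counts (must be positive).
#' @param clamp clamp counts to cohort sizes instead of failing.
#' @return One-row data.frame: `gene`, the four counts, `odds_ratio`,
#'   `p_two_sided`.
#' @examples
#' # Pten-style asymmetry: 8/46 brain vs 22/50 spinal insertions
#' per_gene_fisher("Pten", 8, 22, 46, 50)
#' @export
per_gene_fisher <- function(gene, count_brain, count_spinal, n_brain,
                            n_spinal, clamp = TRUE) {
  if (n_brain < 1 || n_spinal < 1)
    stopf("cohort sizes must be positive")
  if (count_brain < 0 || count_spinal < 0)
    stopf("insertion counts must be non-negative")
  if (count_brain > n_brain || count_spinal > n_spinal) {
    msg <- sprintf("insertion count exceeds cohort size for %s", gene)
    if (!clamp) stopf("%s", msg)
    warning(msg, "; clamping")
    count_brain <- min(count_brain, n_brain)
    count_spinal <- min(count_spinal, n_spinal)
  }
  tab <- matrix(c(count_brain, n_brain - count_brain,
                  count_spinal, n_spinal - count_spinal),
                nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab)
  data.frame(gene = gene, count_brain = count_brain,
             count_spinal = count_spinal, n_brain = n_brain,
             n_spinal = n_spinal,
             odds_ratio = unname(ft$estimate),
             p_two_sided = ft$p.value)
}

#' Cohort comparison across all CIS genes
#'
#' Applies [per_gene_fisher()] to every gene in the CIS-gene table, in table
#' order, optionally adding Benjamini-Hochberg adjusted p values. The
#' default reports raw p values only.
#'
#' @param cis_genes CIS-gene table with `name`, `n_brain`, `n_spinal`.
#' @param cohort named tumor counts, e.g. `c(brain = 46, spinal = 50)`.
#' @param adjust `"none"` (default) or `"benjamini-hochberg"`.
#' @return data.frame of per-gene tests; with BH adjustment an extra
#'   `p_adjusted` column.
#' @export
compare_all <- function(cis_genes, cohort,
                        adjust = c("none", "benjamini-hochberg")) {
  adjust <- match.arg(adjust)
  check_columns(cis_genes, c("name", "n_brain", "n_spinal"), "CIS-gene table")
  if (nrow(cis_genes) == 0) {
    out <- data.frame(gene = character(0), count_brain = integer(0),
                      count_spinal = integer(0), n_brain = integer(0),
                      n_spinal = integer(0), odds_ratio = numeric(0),
                      p_two_sided = numeric(0))
    if (adjust == "benjamini-hochberg") out$p_adjusted <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(cis_genes)), function(i)
    per_gene_fisher(cis_genes$name[i], cis_genes$n_brain[i],
                    cis_genes$n_spinal[i], cohort[["brain"]],
                    cohort[["spinal"]])))
  if (adjust == "benjamini-hochberg")
    out$p_adjusted <- stats::p.adjust(out$p_two_sided, method = "BH")
  rownames(out) <- NULL
  out
}
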