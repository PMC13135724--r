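#' Hypergeometric overrepresentation analysis
#'
#' Tests whether significantly regulated genes are overrepresented in each
#' gene set, using the upper-tail hypergeometric probability (equivalent to
#' the one-tailed Fisher exact test) with the DE-tested genes as the
#' universe.  Up- and down-regulated selections at a given fold-change
#' cutoff are analysed separately, and Benjamini-Hochberg adjustment is
#' applied across the sets of one (direction, cutoff) family.
#'
#' @param de_table DE results with `gene`, `avg_log2fc`, `p_adj`.
#' @param gene_sets tibble from [read_gene_sets()].
#' @param direction `"up"` or `"down"`.
#' @param lfc_cutoff absolute log-fold-change cutoff for selection
#'   (conventional cutoffs: 0.25, 0.5, 0.75).
#' @param alpha adjusted-significance threshold for selection.
#' @param universe character vector; defaults to all genes in `de_table`.
#' @return tibble: `set_name`, `direction`, `logfc_cutoff`, `n_selected`,
#'   `n_set`, `n_overlap`, `overlap_ratio` (overlap / set size within the
#'   universe), `p_hypergeometric`, `p_adj`.
#' @export
ora <- function(de_table, gene_sets, direction = c("up", "down"),
                lfc_cutoff = 0.25, alpha = 0.05, universe = NULL) {
  direction <- match.arg(direction)
  if (is.null(universe)) universe <- unique(de_table$gene)
  N <- length(universe)
  sel <- de_table$p_adj < alpha &
    (if (direction == "up") de_table$avg_log2fc > lfc_cutoff
     else de_table$avg_log2fc < -lfc_cutoff)
  selected <- intersect(unique(de_table$gene[sel]), universe)
  s <- length(selected)
  rows <- purrr::map(seq_len(nrow(gene_sets)), function(i) {
    set_u <- intersect(gene_sets$genes[[i]], universe)
    m <- length(set_u)
    if (m == 0) return(NULL)  # set absent from universe, skipped
    k <- length(intersect(set_u, selected))
    p <- phyper(k - 1, m, N - m, s, lower.tail = FALSE)
    tibble::tibble(set_name = gene_sets$set_name[i], direction = direction,
                   logfc_cutoff = lfc_cutoff, n_selected = s, n_set = m,
                   n_overlap = k, overlap_ratio = k / m,
                   p_hypergeometric = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out$p_adj <- p.adjust(out$p_hypergeometric, "BH")
  out
}
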