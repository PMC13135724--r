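#' Classify X-chromosome genes by inactivation behaviour
#'
#' Combines coordinates with a curated X-inactivation table: genes inside
#' PAR1/PAR2 are classified `PAR` (the locus fact overrides any curated
#' tissue-derived class), other X genes take their curated class
#' (`nonPAR-escape`, `nonPAR-inactive`, `nonPAR-variable`) and default to
#' `nonPAR-unclassified`.  Every X gene receives exactly one class.
#'
#' @param annotation annotation from [annotate_gene_regions()] (X genes are
#'   selected by `chromosome`).
#' @param xci_table optional curated tibble `gene`, `xci_class` overriding
#'   the annotation's own `xci_class` column.
#' @return tibble: `gene`, `gene_class`.
#' @export
classify_x_genes <- function(annotation, xci_table = NULL) {
  x <- dplyr::filter(annotation, sub("^chr", "", .data$chromosome) == "X")
  cls <- x$xci_class
  if (!is.null(xci_table)) {
    idx <- match(x$gene, xci_table$gene)
    cls <- ifelse(is.na(idx), cls, xci_table$xci_class[idx])
  }
  no_coord <- is.na(x$start) | is.na(x$end)
  if (any(no_coord))
    warning("X genes without coordinates set to unclassified: ",
            paste(x$gene[no_coord], collapse = ", "))
  tibble::tibble(
    gene = x$gene,
    gene_class = dplyr::case_when(
      !no_coord & x$par_region %in% c("PAR1", "PAR2") ~ "PAR",
      cls == "escape" ~ "nonPAR-escape",
      cls == "inactive" ~ "nonPAR-inactive",
      cls == "variable" ~ "nonPAR-variable",
      TRUE ~ "nonPAR-unclassified"
    )
  )
}

#' Direction statistics for X-gene classes across cell types
#'
#' From per-cell-type differential-expression tables, computes per class the
#' percentage of member genes significantly up- and down-regulated
#' (`p_adj < alpha`, split by the sign of the fold change), a gene-level
#' roll-up over cell types (up-only / down-only / both), and the cross-type
#' comparison of %up versus %down by Wilcoxon rank-sum for each class.
#'
#' @param de_tables tibble combining per-cell-type DE results (columns
#'   `gene`, `cell_type`, `avg_log2fc`, `p_adj`), e.g. bound rows of
#'   [hurdle_de()] runs.
#' @param classes tibble from [classify_x_genes()].
#' @param alpha adjusted-significance threshold.
#' @return list of class `xci_direction`: `summary` (per cell type x class),
#'   `rollup` (per class gene-level counts), `tests` (per-class Wilcoxon of
#'   %up vs %down across cell types).
#' @export
escape_direction_stats <- function(de_tables, classes, alpha = 0.05) {
  df <- dplyr::inner_join(de_tables, classes, by = "gene")
  if (dplyr::n_distinct(df$cell_type) < 2)
    stop("need DE tables for at least 2 cell types")
  summary <- df |>
    dplyr::group_by(.data$cell_type, .data$gene_class) |>
    dplyr::summarise(
      n_genes_tested = dplyr::n(),
      n_up = sum(.data$p_adj < alpha & .data$avg_log2fc > 0),
      n_down = sum(.data$p_adj < alpha & .data$avg_log2fc < 0),
      .groups = "drop") |>
    dplyr::mutate(pct_up = 100 * .data$n_up / .data$n_genes_tested,
                  pct_down = 100 * .data$n_down / .data$n_genes_tested)
  rollup <- df |>
    dplyr::group_by(.data$gene_class, .data$gene) |>
    dplyr::summarise(
      any_up = any(.data$p_adj < alpha & .data$avg_log2fc > 0),
      any_down = any(.data$p_adj < alpha & .data$avg_log2fc < 0),
      .groups = "drop") |>
    dplyr::group_by(.data$gene_class) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_significant = sum(.data$any_up | .data$any_down),
      up_only = sum(.data$any_up & !.data$any_down),
      down_only = sum(.data$any_down & !.data$any_up),
      both = sum(.data$any_up & .data$any_down),
      .groups = "drop")
  tests <- summary |>
    dplyr::group_split(.data$gene_class) |>
    purrr::map(function(s) {
      ts <- rank_sum_test(s$pct_up, s$pct_down)
      tibble::tibble(gene_class = s$gene_class[1],
                     mean_pct_up = mean(s$pct_up),
                     mean_pct_down = mean(s$pct_down),
                     statistic = ts$statistic, p = ts$p)
    }) |>
    dplyr::bind_rows()
  structure(list(summary = summary, rollup = rollup, tests = tests),
            class = "xci_direction")
}

#' Hartigan's dip statistic
#'
#' The smallest sup-norm distance between the empirical CDF of the sample
#' and any unimodal CDF, computed by the classical greatest-convex-minorant
#' / least-concave-majorant modal-interval algorithm (compiled).  For any
#' sample of `n` distinct values the statistic lies in `[1/(2n), 1/4]`.
#'
#' @param values numeric vector, at least 4 finite values.
#' @return the dip statistic.
#' @export
dip_statistic <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 4) stop("need at least 4 finite values")
  dip_stat_cpp(as.numeric(v))
}

#' Dip test for unimodality with a uniform-null bootstrap
#'
#' Computes [dip_statistic()] and a permutation-style p-value: the fraction
#' of `n_boot` uniform reference samples of the same size whose dip exceeds
#' the observed one (the classical calibration against the uniform,
#' asymptotically the least favourable unimodal null).  Because single-cell
#' expression is zero-inflated, the test can be run on the full vector, on
#' the non-zero subset, or both.
#'
#' @param values numeric vector.
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed integer seed; fixed seed gives an exactly reproducible p.
#' @param subset `"all"`, `"nonzero"`, or `"both"`.
#' @return tibble: `subset`, `dip_statistic`, `p`, `n`, `degenerate`.
#' @export
dip_test <- function(values, n_boot = 100, seed = 1L,
                     subset = c("all", "nonzero", "both")) {
  subset <- match.arg(subset)
  if (n_boot < 100) stop("n_boot must be at least 100")
  run <- function(v, label) {
    v <- v[is.finite(v)]
    n <- length(v)
    if (n >= 4 && length(unique(v)) == 1)
      return(tibble::tibble(subset = label, dip_statistic = 0, p = 1,
                            n = n, degenerate = TRUE))
    if (n < 4)
      return(tibble::tibble(subset = label, dip_statistic = NA_real_,
                            p = NA_real_, n = n, degenerate = TRUE))
    obs <- dip_statistic(v)
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(i) dip_stat_cpp(runif(n)), 0)
    tibble::tibble(subset = label, dip_statistic = obs,
                   p = mean(boot >= obs), n = n, degenerate = FALSE)
  }
  out <- switch(subset,
    all = run(values, "all"),
    nonzero = run(values[values != 0], "nonzero"),
    both = dplyr::bind_rows(run(values, "all"),
                            run(values[values != 0], "nonzero")))
  out
}

#' XIST detection contrast between LOY and non-LOY cells
#'
#' Per cell type, the percentage of cells with any XIST expression in LOY
#' versus non-LOY cells, with a two-proportion chi-square test.  Cell types
#' without LOY cells are omitted; if no cell expresses XIST anywhere the
#' test is skipped.
#'
#' @param matrix a `cell_gene_matrix` (or matrix) containing XIST.
#' @param cells annotation aligned with the matrix rows, with `loy` and
#'   `cell_type`.
#' @return tibble: `cell_type`, `n_loy`, `n_nonloy`, `k_loy`, `k_nonloy`,
#'   `pct_loy`, `pct_nonloy`, `p`.
#' @export
xist_detection_contrast <- function(matrix, cells) {
  m <- if (inherits(matrix, "cell_gene_matrix")) matrix$counts else matrix
  if (!"XIST" %in% colnames(m)) stop("feature XIST absent from matrix")
  pos <- as.numeric(m[, "XIST"]) > 0
  df <- tibble::tibble(cell_type = cells$cell_type, loy = cells$loy,
                       xist = pos) |>
    dplyr::filter(!is.na(.data$loy))
  df |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      n_loy = sum(.data$loy), n_nonloy = sum(!.data$loy),
      k_loy = sum(.data$xist & .data$loy),
      k_nonloy = sum(.data$xist & !.data$loy),
      .groups = "drop") |>
    dplyr::filter(.data$n_loy > 0) |>
    dplyr::mutate(
      pct_loy = 100 * .data$k_loy / .data$n_loy,
      pct_nonloy = 100 * .data$k_nonloy / .data$n_nonloy,
      p = purrr::pmap_dbl(
        list(.data$k_loy, .data$n_loy, .data$k_nonloy, .data$n_nonloy),
        function(k1, n1, k2, n2) {
          if (k1 + k2 == 0) return(NA_real_)
          suppressWarnings(
            prop.test(c(k1, k2), c(n1, n2), correct = FALSE)$p.value)
        }))
}
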