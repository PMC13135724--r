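#' Exact/approximate Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test computed by full enumeration of all group
#' assignments when `min(n1, n2) <= exact_max` (handles ties exactly), and
#' by the normal approximation with tie-corrected variance and continuity
#' correction otherwise.
#'
#' @param x,y numeric samples.
#' @param exact_max enumeration threshold on the smaller group size.
#' @return list: `statistic` (Mann-Whitney U of `x`), `p`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  EU <- n1 * n2 / 2
  if (min(n1, n2) <= exact_max && n1 + n2 <= 24) {
    combs <- combn(n1 + n2, n1)
    obs <- abs(U - EU)
    stats_all <- apply(combs, 2, function(idx)
      abs(sum(r[idx]) - n1 * (n1 + 1) / 2 - EU))
    p <- mean(stats_all >= obs - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 == 0) return(list(statistic = U, p = 1,
                                 method = "degenerate (all tied)"))
    z <- (U - EU - sign(U - EU) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation, tie-corrected"
  }
  list(statistic = U, p = min(p, 1), method = method)
}

# fraction of cells expressing each gene, by group
detection_pct <- function(normalized, idx) {
  Matrix::colSums(normalized[idx, , drop = FALSE] > 0) / sum(idx)
}

#' Two-part hurdle differential expression
#'
#' For each gene, detection (expression > 0) is modelled by logistic
#' regression on the group indicator plus the centred per-cell detection
#' rate, and expression magnitude over expressing cells by Gaussian
#' regression on the same design.  The hurdle statistic is the sum of the
#' two likelihood-ratio chi-squares, referred to a chi-square with the
#' combined degrees of freedom (the continuous part is fitted only with at
#' least two expressing cells per group; otherwise the discrete part alone
#' is used with one degree of freedom).  Genes must be detected in at least
#' `min_pct` of the cells of one group and show `|avg_log2fc| >= min_lfc`.
#' P-values are Bonferroni-adjusted over the genes tested in the run.
#'
#' @param normalized matrix from [log_normalize()] (cells x genes).
#' @param cells per-cell annotation aligned with the matrix rows.
#' @param group name of a logical column of `cells` (e.g. `"loy"`), group 1
#'   = TRUE.
#' @param cell_type restrict to this cell type (NULL = all cells).
#' @param min_pct,min_lfc filters (see [loy_config()]).
#' @param min_cells warn when either group is smaller than this.
#' @return tibble with class `loy_de`: `gene`, `cell_type`, `avg_log2fc`,
#'   `pct_group1`, `pct_group2`, `p_discrete`, `p_continuous`, `p_hurdle`,
#'   `p_adj`, `n1`, `n2`; attribute `n_tests`.
#' @export
hurdle_de <- function(normalized, cells, group = "loy", cell_type = NULL,
                      min_pct = loy_config()$de_min_pct,
                      min_lfc = loy_config()$de_min_lfc,
                      min_cells = 20) {
  keep <- !is.na(cells[[group]])
  if (!is.null(cell_type)) keep <- keep & cells$cell_type == cell_type
  m <- normalized[keep, , drop = FALSE]
  g1 <- as.logical(cells[[group]][keep])
  n1 <- sum(g1); n2 <- sum(!g1)
  if (min(n1, n2) < min_cells)
    warning("small group size: n1 = ", n1, ", n2 = ", n2)
  if (min(n1, n2) == 0) stop("one group is empty")
  pct1 <- detection_pct(m, g1)
  pct2 <- detection_pct(m, !g1)
  cdr <- scale(Matrix::rowMeans(m > 0), scale = FALSE)[, 1]
  grp <- as.numeric(g1)
  X1 <- cbind(1, grp, cdr)       # full design
  X0 <- cbind(1, cdr)            # null design (no group)
  lfc_all <- vapply(seq_len(ncol(m)), function(j)
    avg_log2fc(m[g1, j], m[!g1, j]), 0)
  tested <- which((pct1 >= min_pct | pct2 >= min_pct) & abs(lfc_all) >= min_lfc)
  rows <- purrr::map(tested, function(j) {
    x <- m[, j]
    det <- as.numeric(x > 0)
    # non-convergence warnings arise on saturated detection; the deviance is
    # still the right LR ingredient there
    dev1 <- tryCatch(
      suppressWarnings(glm.fit(X1, det, family = binomial())$deviance),
      error = function(e) NA)
    dev0 <- tryCatch(
      suppressWarnings(glm.fit(X0, det, family = binomial())$deviance),
      error = function(e) NA)
    if (is.na(dev1) || is.na(dev0))
      return(NULL)  # singular design, flagged via attrition
    lr_d <- max(dev0 - dev1, 0)
    expr_idx <- x > 0
    lr_c <- NA_real_
    if (sum(expr_idx & g1) >= 2 && sum(expr_idx & !g1) >= 2) {
      xe <- x[expr_idx]
      f1 <- lm.fit(X1[expr_idx, , drop = FALSE], xe)
      f0 <- lm.fit(X0[expr_idx, , drop = FALSE], xe)
      rss1 <- sum(f1$residuals^2); rss0 <- sum(f0$residuals^2)
      ne <- sum(expr_idx)
      lr_c <- if (rss1 > 0) max(ne * log(rss0 / rss1), 0) else 0
    }
    stat <- lr_d + ifelse(is.na(lr_c), 0, lr_c)
    df <- 1 + !is.na(lr_c)
    tibble::tibble(
      gene = colnames(m)[j],
      avg_log2fc = lfc_all[j],
      pct_group1 = pct1[j], pct_group2 = pct2[j],
      p_discrete = pchisq(lr_d, 1, lower.tail = FALSE),
      p_continuous = if (is.na(lr_c)) NA_real_
                     else pchisq(lr_c, 1, lower.tail = FALSE),
      chisq_hurdle = stat,
      p_hurdle = pchisq(stat, df, lower.tail = FALSE),
      n1 = n1, n2 = n2)
  })
  out <- dplyr::bind_rows(rows)
  n_tests <- nrow(out)
  if (n_tests) {
    out$p_adj <- pmin(out$p_hurdle * n_tests, 1)
    out$cell_type <- cell_type %||% NA_character_
    out <- dplyr::relocate(out, "cell_type", .after = "gene")
  }
  attr(out, "n_tests") <- n_tests
  class(out) <- c("loy_de", class(out))
  out
}

#' Remove male cells expressing XIST
#'
#' Robustness filter: XIST-positive male cells may represent female-cell
#' contamination, so analyses are replicated after dropping them.
#'
#' @param matrix a `cell_gene_matrix` or normalized matrix containing XIST.
#' @param cells annotation aligned with the matrix rows.
#' @return filtered `cells`; attribute `n_removed`; a logical `keep` vector
#'   attribute usable to subset the matrix.
#' @export
exclude_xist_cells <- function(matrix, cells) {
  m <- if (inherits(matrix, "cell_gene_matrix")) matrix$counts else matrix
  if (!"XIST" %in% colnames(m)) stop("feature XIST absent from matrix")
  xist_pos <- as.numeric(m[, "XIST"]) > 0
  out <- cells[!xist_pos, , drop = FALSE]
  attr(out, "n_removed") <- sum(xist_pos)
  attr(out, "keep") <- !xist_pos
  out
}

#' Proportion-expressing pseudobulk differential expression
#'
#' For each gene, the fraction of cells with expression > 0 is computed per
#' (donor, group) pseudobulk sample; LOY and non-LOY donor-level proportions
#' are then compared with the two-sided Wilcoxon rank-sum test
#' ([rank_sum_test()]; exact by enumeration for small donor counts).  Genes
#' must be detected in at least `min_pct` of cells of either group, and the
#' effect (difference of donor-mean proportions, computed over donors
#' contributing both strata) must reach `min_effect` in absolute value.
#' Bonferroni adjustment over the genes tested.
#'
#' @inheritParams hurdle_de
#' @param counts a `cell_gene_matrix` or any cells x genes matrix; detection
#'   is `> 0` on whatever scale is supplied.
#' @param min_effect minimum absolute difference in mean proportion.
#' @param min_donors minimum donors per stratum.
#' @return tibble: `gene`, `cell_type`, `mean_prop_loy`, `mean_prop_nonloy`,
#'   `effect`, `p`, `p_adj`, `n_donors`; attribute `n_tests`.
#' @export
proportion_pseudobulk <- function(counts, cells, group = "loy",
                                  cell_type = NULL,
                                  min_pct = loy_config()$de_min_pct,
                                  min_effect = loy_config()$pseudobulk_min_effect,
                                  min_donors = 3) {
  m <- if (inherits(counts, "cell_gene_matrix")) counts$counts else counts
  keep <- !is.na(cells[[group]])
  if (!is.null(cell_type)) keep <- keep & cells$cell_type == cell_type
  m <- m[keep, , drop = FALSE]
  g1 <- as.logical(cells[[group]][keep])
  donor <- cells$donor[keep]
  pct1 <- detection_pct(m, g1)
  pct2 <- detection_pct(m, !g1)
  # donor-level detection proportions per stratum
  strat <- paste(donor, g1, sep = "|")
  det <- m > 0
  prop_by <- function(idx) {
    f <- factor(donor[idx])
    counts_per <- as.vector(table(f))
    sums <- Matrix::crossprod(
      Matrix::sparse.model.matrix(~ f - 1), det[idx, , drop = FALSE])
    list(donors = levels(f), prop = as.matrix(sums) / counts_per)
  }
  p1 <- prop_by(g1); p2 <- prop_by(!g1)
  if (length(p1$donors) < min_donors || length(p2$donors) < min_donors)
    stop("fewer than ", min_donors, " donors in a stratum")
  both <- intersect(p1$donors, p2$donors)
  tested <- which(pct1 >= min_pct | pct2 >= min_pct)
  rows <- purrr::map(tested, function(j) {
    v1 <- p1$prop[, j]; v2 <- p2$prop[, j]
    mean1 <- mean(p1$prop[match(both, p1$donors), j])
    mean2 <- mean(p2$prop[match(both, p2$donors), j])
    eff <- mean1 - mean2
    if (is.na(eff) || abs(eff) < min_effect) return(NULL)
    ts <- rank_sum_test(v1, v2)
    tibble::tibble(gene = colnames(m)[j],
                   mean_prop_loy = mean1, mean_prop_nonloy = mean2,
                   effect = eff, p = ts$p, method = ts$method,
                   n_donors = length(both))
  })
  out <- dplyr::bind_rows(rows)
  n_tests <- nrow(out)
  if (n_tests) {
    out$p_adj <- pmin(out$p * n_tests, 1)
    out$cell_type <- cell_type %||% NA_character_
    out <- dplyr::relocate(out, "cell_type", .after = "gene")
  }
  attr(out, "n_tests") <- n_tests
  out
}
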