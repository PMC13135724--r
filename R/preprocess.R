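#' Percentile-based Z-scores
#'
#' Maps a metric to a standard normal via its ranks:
#' `Z = qnorm((rank - 0.5) / n)`, average ranks for ties.  Identical values
#' all map to Z = 0.
#'
#' @param x numeric vector.
#' @export
percentile_z <- function(x) {
  qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Per-cell quality-control metrics
#'
#' @param matrix a `cell_gene_matrix`.
#' @param annotation gene annotation used to find mitochondrial genes
#'   (`chromosome` `"MT"`); alternatively pass `mito_genes`.
#' @param mito_genes explicit mitochondrial gene identifiers.
#' @return tibble: `barcode`, `umi_total`, `n_genes`, `mito_fraction`,
#'   and percentile Z-scores `z_umi`, `z_genes`, `z_mito`.
#' @export
qc_metrics <- function(matrix, annotation = NULL, mito_genes = NULL) {
  m <- matrix$counts
  if (is.null(mito_genes) && !is.null(annotation))
    mito_genes <- annotation$gene[sub("^chr", "", annotation$chromosome) == "MT"]
  mito_genes <- intersect(mito_genes, colnames(m))
  tot <- Matrix::rowSums(m)
  mito <- if (length(mito_genes))
    Matrix::rowSums(m[, mito_genes, drop = FALSE]) else rep(0, nrow(m))
  tibble::tibble(
    barcode = matrix$barcodes,
    umi_total = as.numeric(tot),
    n_genes = as.numeric(Matrix::rowSums(m > 0)),
    mito_fraction = ifelse(tot > 0, mito / tot, 0)
  ) |>
    dplyr::mutate(z_umi = percentile_z(.data$umi_total),
                  z_genes = percentile_z(.data$n_genes),
                  z_mito = percentile_z(.data$mito_fraction))
}

#' Quality-control filter
#'
#' Removes cells whose percentile Z-score is below `z_low` (default -3) on
#' any QC metric (UMI total, genes detected, mitochondrial fraction), and
#' additionally cells whose mitochondrial-fraction Z-score is at or above
#' `mito_z_high` (default +2, removing likely apoptotic cells).
#'
#' @param matrix a `cell_gene_matrix`.
#' @inheritParams qc_metrics
#' @param z_low,mito_z_high thresholds (see [loy_config()]).
#' @return list of class `qc_result`: `matrix` (filtered), `report` (counts
#'   removed per rule), `metrics` (per-cell table with a `kept` flag).
#' @export
qc_filter <- function(matrix, annotation = NULL, mito_genes = NULL,
                      z_low = loy_config()$qc_z_low,
                      mito_z_high = loy_config()$qc_mito_z_high) {
  qc <- qc_metrics(matrix, annotation, mito_genes)
  low_out <- qc$z_umi < z_low | qc$z_genes < z_low | qc$z_mito < z_low
  mito_out <- qc$z_mito >= mito_z_high
  kept <- !(low_out | mito_out)
  if (!any(kept)) stop("QC filter removed every cell")
  qc$kept <- kept
  fm <- matrix
  fm$counts <- matrix$counts[kept, , drop = FALSE]
  fm$barcodes <- matrix$barcodes[kept]
  structure(list(
    matrix = fm,
    report = tibble::tibble(
      rule = c("low_z", "high_mito_z", "kept"),
      n = c(sum(low_out), sum(mito_out & !low_out), sum(kept))),
    metrics = qc
  ), class = "qc_result")
}

#' Log-normalize counts
#'
#' `log(1 + count / cell_total * scale_factor)` per cell; depends only on
#' within-cell proportions, so doubling all counts of a cell leaves the
#' result unchanged.
#'
#' @param matrix a `cell_gene_matrix`.
#' @param scale_factor library-size scale factor.
#' @return sparse matrix (cells x genes) of normalized values.
#' @export
log_normalize <- function(matrix, scale_factor = loy_config()$scale_factor) {
  m <- matrix$counts
  tot <- Matrix::rowSums(m)
  if (any(tot == 0)) stop("cells with zero total count: ",
                          paste(head(matrix$barcodes[tot == 0], 3), collapse = ", "))
  norm <- Matrix::Diagonal(x = scale_factor / tot) %*% m
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m)
  methods::as(norm, "CsparseMatrix")
}

#' Select highly variable genes
#'
#' Ranks genes by a variance-stabilized dispersion: a loess trend of
#' log10(variance) on log10(mean) of the normalized values is fit across
#' genes, and the statistic is the ratio of observed to trend-expected
#' variance.  Constant genes are never selected while any gene varies.
#'
#' @param normalized matrix from [log_normalize()].
#' @param k number of genes to keep.
#' @return character vector of `k` gene names, most variable first; the
#'   full ranking table is attached as attribute `ranking`.
#' @export
select_hvg <- function(normalized, k = loy_config()$n_hvg) {
  if (k > ncol(normalized)) stop("k exceeds the number of genes")
  # dispersion is measured on the de-logged (library-size-normalized count)
  # scale, where overdispersion is not masked by the log transform; the
  # robust loess keeps planted outliers from bending the trend
  x <- normalized
  x@x <- expm1(x@x)
  mu <- Matrix::colMeans(x)
  ex2 <- Matrix::colMeans(x^2)
  v <- pmax(ex2 - mu^2, 0) * nrow(x) / max(nrow(x) - 1, 1)
  stat <- rep(0, length(v))
  pos <- v > 0 & mu > 0
  if (any(pos)) {
    lmu <- log10(mu[pos]); lv <- log10(v[pos])
    fit <- tryCatch(loess(lv ~ lmu, degree = 1, span = 0.75,
                          family = "symmetric"),
                    error = function(e) NULL)
    expected <- if (!is.null(fit)) 10^predict(fit) else 10^mean(lv)
    stat[pos] <- v[pos] / pmax(expected, .Machine$double.eps)
  }
  ord <- order(stat, decreasing = TRUE)
  ranking <- tibble::tibble(gene = colnames(normalized)[ord],
                            mean = mu[ord], variance = v[ord],
                            dispersion = stat[ord])
  out <- ranking$gene[seq_len(k)]
  attr(out, "ranking") <- ranking
  out
}

#' Covariate-adjusted scaling and PCA
#'
#' Regresses each gene's normalized expression on the given per-cell
#' covariates (e.g. mitochondrial fraction and sequencing pool), scales the
#' residuals to unit variance, clips at `+/-clip`, and returns principal
#' component scores of the scaled matrix.  Single-level covariates are
#' dropped with a warning.
#'
#' @param normalized matrix from [log_normalize()].
#' @param covariates data frame of per-cell covariates (rows aligned with
#'   cells), or NULL for centring only.
#' @param genes genes to use (e.g. from [select_hvg()]); default all.
#' @param n_pcs number of principal components.
#' @param clip clipping bound for scaled values.
#' @return list: `scaled` (dense cells x genes), `pcs` (cells x n_pcs),
#'   `var_explained`.
#' @export
scale_and_reduce <- function(normalized, covariates = NULL, genes = NULL,
                             n_pcs = loy_config()$n_pcs,
                             clip = loy_config()$scale_clip) {
  if (!is.null(genes)) normalized <- normalized[, genes, drop = FALSE]
  x <- as.matrix(normalized)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    single <- vapply(covariates, function(v) length(unique(v)) < 2, TRUE)
    if (any(single)) {
      warning("dropping single-level covariate(s): ",
              paste(names(covariates)[single], collapse = ", "))
      covariates <- covariates[, !single, drop = FALSE]
    }
  }
  if (!is.null(covariates) && ncol(covariates)) {
    design <- model.matrix(~., data = covariates)
    fit <- lm.fit(design, x)
    res <- fit$residuals
  } else {
    res <- scale(x, center = TRUE, scale = FALSE)
  }
  sds <- apply(res, 2, sd)
  sds[sds < 1e-8] <- 1   # constant after adjustment: leave at zero
  scaled <- sweep(res, 2, sds, "/")
  scaled[scaled > clip] <- clip
  scaled[scaled < -clip] <- -clip
  n_pcs <- min(n_pcs, ncol(scaled), nrow(scaled) - 1)
  pc <- prcomp(scaled, center = FALSE, scale. = FALSE, rank. = n_pcs)
  list(scaled = scaled,
       pcs = pc$x,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Average log2 fold change between two groups of cells
#'
#' `log2((mean(expm1(x1)) + 1) / (mean(expm1(x2)) + 1))` on log-normalized
#' values, the convention used for reported average log fold changes.
#'
#' @param x1,x2 normalized expression values of the two groups.
#' @export
avg_log2fc <- function(x1, x2) {
  log2((mean(expm1(x1)) + 1) / (mean(expm1(x2)) + 1))
}

#' Validate clusters against expected marker genes
#'
#' Tests each cluster one-vs-rest for upregulation of each candidate cell
#' type's markers (one-sided Wilcoxon rank-sum), Bonferroni-corrected within
#' cluster.  A cluster is labelled with the best-supported type (most
#' significant markers; mean marker log2FC breaks ties) or excluded when no
#' type has all markers significant.  Clusters significantly expressing a
#' contamination marker (e.g. CD3 genes in a monocyte subset) are excluded
#' regardless.
#'
#' @param clusters per-cell cluster labels.
#' @param normalized matrix from [log_normalize()], rows aligned with
#'   `clusters`.
#' @param markers tibble `cell_type`, `gene`.
#' @param exclusion_markers character vector of contamination markers.
#' @param alpha significance level before Bonferroni correction.
#' @return tibble: `cluster`, `cell_type` (NA when excluded), `excluded`,
#'   `reason`, `n_markers_sig`, `mean_marker_lfc`.
#' @export
validate_clusters <- function(clusters, normalized, markers,
                              exclusion_markers = NULL, alpha = 0.05) {
  missing <- setdiff(unique(c(markers$gene, exclusion_markers)),
                     colnames(normalized))
  if (length(missing)) {
    warning("markers absent from matrix, skipped: ",
            paste(missing, collapse = ", "))
    markers <- dplyr::filter(markers, !.data$gene %in% missing)
    exclusion_markers <- setdiff(exclusion_markers, missing)
  }
  cl_levels <- sort(unique(clusters))
  if (!nrow(markers)) {
    return(tibble::tibble(cluster = cl_levels, cell_type = NA_character_,
                          excluded = TRUE, reason = "no markers available",
                          n_markers_sig = NA_integer_,
                          mean_marker_lfc = NA_real_))
  }
  res <- purrr::map(cl_levels, function(cl) {
    inside <- clusters == cl
    test_gene <- function(g) {
      x <- normalized[inside, g]; y <- normalized[!inside, g]
      p <- suppressWarnings(
        wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value)
      c(p = p, lfc = avg_log2fc(x, y))
    }
    n_tests <- nrow(markers) + length(exclusion_markers)
    # contamination check first
    if (length(exclusion_markers)) {
      ex <- vapply(exclusion_markers, test_gene, c(p = 0, lfc = 0))
      if (any(ex["p", ] * n_tests < alpha))
        return(tibble::tibble(cluster = cl, cell_type = NA_character_,
                              excluded = TRUE,
                              reason = paste0("contamination:",
                                              paste(exclusion_markers[ex["p", ] * n_tests < alpha],
                                                    collapse = ",")),
                              n_markers_sig = NA_integer_,
                              mean_marker_lfc = NA_real_))
    }
    by_type <- markers |>
      dplyr::group_split(.data$cell_type) |>
      purrr::map(function(mk) {
        r <- vapply(mk$gene, test_gene, c(p = 0, lfc = 0))
        tibble::tibble(cell_type = mk$cell_type[1],
                       n_sig = sum(r["p", ] * n_tests < alpha),
                       n_markers = ncol(r),
                       mean_lfc = mean(r["lfc", ]))
      }) |>
      dplyr::bind_rows() |>
      dplyr::arrange(dplyr::desc(.data$n_sig / .data$n_markers),
                     dplyr::desc(.data$mean_lfc))
    best <- by_type[1, ]
    if (best$n_sig < best$n_markers)
      return(tibble::tibble(cluster = cl, cell_type = NA_character_,
                            excluded = TRUE, reason = "no marker support",
                            n_markers_sig = best$n_sig,
                            mean_marker_lfc = best$mean_lfc))
    tibble::tibble(cluster = cl, cell_type = best$cell_type, excluded = FALSE,
                   reason = NA_character_, n_markers_sig = best$n_sig,
                   mean_marker_lfc = best$mean_lfc)
  })
  dplyr::bind_rows(res)
}
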