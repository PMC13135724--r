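#' Call LOY per cell from dual-source MSY counts
#'
#' A cell is classified as LOY when the summed UMI count over
#' male-specific-region (MSY) genes is zero in *both* counting sources; any
#' single MSY read in either source blocks the call.  This specificity-first
#' rule means ambient contamination can only create false negatives, never
#' false positives.  MSY totals are recorded for every cell (including
#' female cells, where non-zero totals serve as a contamination check), but
#' the `loy` flag is only assigned for male cells; cells with zero total UMI
#' in both sources are uninformative and get `loy = NA`.
#'
#' @param matrix_a,matrix_b `cell_gene_matrix` objects from the two counting
#'   sources; they must share the same barcode universe.
#' @param cells per-cell annotation tibble with at least `barcode`; a `sex`
#'   column restricts calling to males (absent = all male).
#' @param annotation gene annotation with `is_msy` (see
#'   [annotate_gene_regions()]); alternatively give `msy_genes` directly.
#' @param msy_genes explicit character vector of MSY gene identifiers.
#' @return `cells` with columns `msy_total_a`, `msy_total_b` and logical
#'   `loy` added; the number of uninformative cells is attached as attribute
#'   `n_uninformative`.
#' @export
call_loy <- function(matrix_a, matrix_b, cells, annotation = NULL,
                     msy_genes = NULL) {
  stopifnot(inherits(matrix_a, "cell_gene_matrix"),
            inherits(matrix_b, "cell_gene_matrix"))
  if (is.null(msy_genes)) {
    if (is.null(annotation)) stop("provide either annotation or msy_genes")
    msy_genes <- annotation$gene[annotation$is_msy]
  }
  if (!length(msy_genes)) stop("MSY gene list is empty")
  cells <- tibble::as_tibble(cells)
  bcs <- cells$barcode
  missing_a <- setdiff(bcs, matrix_a$barcodes)
  missing_b <- setdiff(bcs, matrix_b$barcodes)
  if (length(missing_a) || length(missing_b))
    stop("barcodes absent from ",
         if (length(missing_a)) "source A" else "source B", ": e.g. ",
         head(c(missing_a, missing_b), 1))
  msy_total <- function(m) {
    g <- intersect(msy_genes, m$features$gene)
    if (!length(g)) stop("no MSY genes present in matrix ",
                         m$source_label %||% "")
    Matrix::rowSums(m$counts[bcs, g, drop = FALSE])
  }
  cells$msy_total_a <- as.integer(msy_total(matrix_a))
  cells$msy_total_b <- as.integer(msy_total(matrix_b))
  male <- if ("sex" %in% names(cells)) cells$sex == "M" else TRUE
  uninformative <- if ("umi_total" %in% names(cells)) cells$umi_total == 0
                   else rep(FALSE, nrow(cells))
  cells$loy <- ifelse(male & !uninformative,
                      cells$msy_total_a + cells$msy_total_b == 0, NA)
  attr(cells, "n_uninformative") <- sum(uninformative & male)
  cells
}

#' Per-donor LOY prevalence and expanded clonality
#'
#' Summarises called cells per donor: number of cells, number and percentage
#' of LOY cells, and the expanded-clonality flag (LOY in `threshold`% or
#' more of the donor's cells).  Donors represented by a single cell are kept
#' but flagged as degenerate.
#'
#' @param cells tibble with `donor` and logical `loy` (NA ignored).
#' @param threshold expanded-clonality percentage threshold.
#' @param by_cell_type also stratify by `cell_type`.
#' @return tibble: `donor`, (`cell_type`,) `n_cells`, `n_loy`, `pct_loy`,
#'   `expanded`, `degenerate`.
#' @export
donor_prevalence <- function(cells, threshold = loy_config()$expanded_pct,
                             by_cell_type = FALSE) {
  cells <- dplyr::filter(cells, !is.na(.data$loy))
  if (!nrow(cells)) stop("no called cells")
  grp <- if (by_cell_type) c("donor", "cell_type") else "donor"
  cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_cells = dplyr::n(), n_loy = sum(.data$loy),
                     .groups = "drop") |>
    dplyr::mutate(pct_loy = 100 * .data$n_loy / .data$n_cells,
                  expanded = .data$pct_loy >= threshold,
                  degenerate = .data$n_cells == 1)
}

#' Cohort and per-cell-type prevalence summary
#'
#' Aggregate LOY percentages: one row per cell type plus a `"(cohort)"` row,
#' computed as 100 * n_loy / n_cells.
#'
#' @param cells tibble with logical `loy` and optionally `cell_type`.
#' @export
prevalence_summary <- function(cells) {
  cells <- dplyr::filter(cells, !is.na(.data$loy))
  total <- tibble::tibble(cell_type = "(cohort)", n_cells = nrow(cells),
                          n_loy = sum(cells$loy))
  out <- if ("cell_type" %in% names(cells)) {
    dplyr::bind_rows(
      cells |>
        dplyr::group_by(.data$cell_type) |>
        dplyr::summarise(n_cells = dplyr::n(), n_loy = sum(.data$loy),
                         .groups = "drop"),
      total)
  } else total
  dplyr::mutate(out, pct_loy = 100 * .data$n_loy / .data$n_cells)
}

#' UMI sensitivity filter
#'
#' Removes the lowest `drop_fraction` of cells by total UMI count (cells at
#' or below the empirical `drop_fraction` quantile, lower type-1 quantile so
#' that exactly the bottom fraction is removed on distinct values).  Used to
#' check that donor-level associations are not driven by low-coverage cells.
#'
#' @param cells tibble with `umi_total`.
#' @param drop_fraction fraction in `[0, 1)`; 0 returns the input unchanged.
#' @return filtered tibble; attributes `cutoff` and `n_removed`.
#' @export
umi_sensitivity_filter <- function(cells, drop_fraction) {
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must lie in [0, 1)")
  if (drop_fraction == 0) {
    attr(cells, "cutoff") <- -Inf
    attr(cells, "n_removed") <- 0L
    return(cells)
  }
  cutoff <- unname(quantile(cells$umi_total, drop_fraction, type = 1))
  out <- dplyr::filter(cells, .data$umi_total > cutoff)
  attr(out, "cutoff") <- cutoff
  attr(out, "n_removed") <- nrow(cells) - nrow(out)
  out
}

empirical_logit <- function(n_loy, n_cells) {
  qlogis((n_loy + 0.5) / (n_cells + 1))
}

#' Donor-level association between LOY prevalence and age
#'
#' Linear regression of the empirical-logit-transformed per-donor LOY
#' percentage on age, adjusting for sequencing pool and up to ten genotype
#' principal components (whichever are present in the donor table).  The
#' empirical logit `log((x + 0.5) / (n - x + 0.5))` keeps donors with 0% or
#' 100% LOY finite.  Collinear covariates are dropped with a flag.
#'
#' @param prevalence tibble from [donor_prevalence()].
#' @param donors donor covariate table.
#' @return object of class `loy_age_assoc` with `tidy()`/`glance()` methods;
#'   key fields: `slope`, `ci_low`, `ci_high`, `p`, `n_donors`.
#' @export
age_association <- function(prevalence, donors) {
  df <- dplyr::inner_join(prevalence, donors, by = "donor")
  if (dplyr::n_distinct(df$age) < 3)
    stop("need at least 3 donors with distinct ages")
  df$elogit <- empirical_logit(df$n_loy, df$n_cells)
  covars <- intersect(c("pool", paste0("pc", 1:10)), names(df))
  # drop single-level factors up front
  dropped <- character()
  for (cv in covars) {
    if (dplyr::n_distinct(df[[cv]]) < 2) {
      covars <- setdiff(covars, cv); dropped <- c(dropped, cv)
    }
  }
  fml <- as.formula(paste("elogit ~ age",
                          if (length(covars))
                            paste("+", paste(covars, collapse = " + "))
                          else ""))
  fit <- lm(fml, data = df)
  aliased <- names(which(is.na(coef(fit))))
  if (length(aliased)) {
    dropped <- c(dropped, aliased)
    keep <- setdiff(covars, unique(sub("[0-9]+$", "", aliased)))
    fit <- lm(as.formula(paste("elogit ~ age",
                               if (length(keep))
                                 paste("+", paste(keep, collapse = " + "))
                               else "")), data = df)
  }
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, "age")
  structure(list(
    fit = fit,
    slope = unname(sm["age", "Estimate"]),
    se = unname(sm["age", "Std. Error"]),
    ci_low = ci[1], ci_high = ci[2],
    p = unname(sm["age", "Pr(>|t|)"]),
    n_donors = nrow(df),
    dropped_covariates = dropped
  ), class = "loy_age_assoc")
}

#' @export
print.loy_age_assoc <- function(x, ...) {
  cat(sprintf(
    "LOY prevalence ~ age: slope %.4f per year (95%% CI %.4f-%.4f), p = %.3g, n = %d donors\n",
    x$slope, x$ci_low, x$ci_high, x$p, x$n_donors))
  if (length(x$dropped_covariates))
    cat("dropped collinear/constant covariates:",
        paste(x$dropped_covariates, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.loy_age_assoc <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
                 statistic = sm[, 3], p.value = sm[, 4])
}

#' @export
glance.loy_age_assoc <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 slope = x$slope, ci_low = x$ci_low, ci_high = x$ci_high,
                 p = x$p, n_donors = x$n_donors)
}

#' Concordance between single-cell and SNP-array clonal fractions
#'
#' Pearson correlation (with Fisher-z confidence interval) between the
#' per-donor LOY fraction called from single cells and the SNP-array clonal
#' fraction, overall or per cell type, with Benjamini-Hochberg adjustment
#' across cell types.
#'
#' @param prevalence tibble from [donor_prevalence()] (optionally
#'   `by_cell_type = TRUE`).
#' @param donors donor table with `snp_clonal_fraction`.
#' @param by_cell_type compute one correlation per cell type.
#' @return tibble: (`cell_type`,) `n`, `r`, `ci_low`, `ci_high`, `p`, `p_adj`.
#' @export
snp_concordance <- function(prevalence, donors, by_cell_type = FALSE) {
  df <- dplyr::inner_join(prevalence, donors, by = "donor") |>
    dplyr::filter(!is.na(.data$snp_clonal_fraction))
  one <- function(d, label = NA_character_) {
    if (nrow(d) < 3)
      return(tibble::tibble(cell_type = label, n = nrow(d), r = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p = NA_real_))
    x <- d$pct_loy / 100; y <- d$snp_clonal_fraction
    if (sd(x) == 0 || sd(y) == 0) {
      warning("zero variance in a clonal-fraction vector; returning NA")
      return(tibble::tibble(cell_type = label, n = nrow(d), r = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p = NA_real_))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble::tibble(cell_type = label, n = nrow(d), r = unname(ct$estimate),
                   ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
                   p = ct$p.value)
  }
  out <- if (by_cell_type) {
    df |>
      dplyr::group_split(.data$cell_type) |>
      purrr::map(~ one(.x, .x$cell_type[1])) |>
      dplyr::bind_rows()
  } else one(df)
  dplyr::mutate(out, p_adj = p.adjust(.data$p, "BH"))
}

#' Independence of autosomal mCA and LOY carrier status
#'
#' Pearson chi-square test (no continuity correction, stated in the output)
#' on the 2x2 donor table of mCA carriage versus LOY carriage.  When a
#' margin is empty the chi-square is undefined and Fisher's exact test is
#' used as a flagged fallback.
#'
#' @param donors tibble with logical columns for the two flags.
#' @param loy_col,mca_col column names.
#' @return list: `statistic`, `p`, `table`, `method`, `fallback`.
#' @export
mca_loy_independence <- function(donors, loy_col = "loy_snp",
                                 mca_col = "mca_flag") {
  loy <- donors[[loy_col]]; mca <- donors[[mca_col]]
  keep <- !is.na(loy) & !is.na(mca)
  tab <- table(factor(loy[keep], c(FALSE, TRUE)),
               factor(mca[keep], c(FALSE, TRUE)),
               dnn = c("loy", "mca"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    ft <- fisher.test(tab)
    return(list(statistic = NA_real_, p = ft$p.value, table = tab,
                method = "Fisher exact (empty margin fallback)",
                fallback = TRUE))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value, table = tab,
       method = "Pearson chi-square, no continuity correction",
       fallback = FALSE)
}
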