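#' LOY-by-pseudotime interaction model for one gene
#'
#' Tests whether LOY modulates a gene's expression trajectory.  The basic
#' mixed model is `expression ~ loy + quantile (+ quantile^2) + age +
#' pc1..pc10 + (1 | donor)`; the augmented model adds `loy:quantile` (and
#' `loy:quantile^2` for the quadratic form).  Both are fitted by maximum
#' likelihood and compared with a likelihood-ratio test whose degrees of
#' freedom equal the number of added interaction terms.  Genes are only
#' tested when detected in at least 1% of the cells of three or more of the
#' six quantiles.  On random-effect non-convergence the model falls back to
#' a fixed donor intercept (flagged).
#'
#' @param gene gene name (column of `normalized`).
#' @param normalized matrix from [log_normalize()], rows aligned with
#'   `cells`.
#' @param cells annotation with `loy`, `quantile`, `donor`.
#' @param donors donor table with `age` and PCs.
#' @param form `"linear"` or `"quadratic"`.
#' @param min_quantiles minimum quantiles in which the gene must be
#'   expressed.
#' @param min_pct detection threshold defining "expressed in a quantile".
#' @return one-row tibble: `gene`, `form`, `interaction_estimate` (the
#'   `loy:quantile` coefficient), `chisq_lrt`, `df`, `p_lrt`, `p_adj` (NA
#'   until adjusted), `n_quantiles_expressed`, `n_cells`, `excluded`,
#'   `fallback`.
#' @export
interaction_model <- function(gene, normalized, cells, donors,
                              form = c("linear", "quadratic"),
                              min_quantiles = 3, min_pct = 0.01) {
  form <- match.arg(form)
  y <- as.numeric(normalized[, gene])
  df <- cells |>
    dplyr::filter(!is.na(.data$loy), !is.na(.data$quantile))
  y <- y[!is.na(cells$loy) & !is.na(cells$quantile)]
  det <- tapply(y > 0, df$quantile, mean)
  nq <- sum(det >= min_pct, na.rm = TRUE)
  empty_row <- function(reason) tibble::tibble(
    gene = gene, form = form, interaction_estimate = NA_real_,
    chisq_lrt = NA_real_, df = NA_integer_, p_lrt = NA_real_,
    p_adj = NA_real_, n_quantiles_expressed = nq, n_cells = nrow(df),
    excluded = TRUE, reason = reason, fallback = NA)
  if (nq < min_quantiles) return(empty_row("expressed_in_too_few_quantiles"))
  dat <- dplyr::inner_join(
    df, donors[, intersect(names(donors), c("donor", "age", paste0("pc", 1:10)))],
    by = "donor")
  dat$y <- y[match(dat$barcode, df$barcode)]
  dat$loy_num <- as.numeric(dat$loy)
  dat$q <- as.numeric(dat$quantile)
  dat$q2 <- dat$q^2
  pcs <- intersect(paste0("pc", 1:10), names(dat))
  base_terms <- c("loy_num", "q", if (form == "quadratic") "q2",
                  "age", pcs)
  int_terms <- c("loy_num:q", if (form == "quadratic") "loy_num:q2")
  f_basic <- as.formula(paste("y ~", paste(base_terms, collapse = " + "),
                              "+ (1 | donor)"))
  f_aug <- as.formula(paste("y ~", paste(c(base_terms, int_terms),
                                         collapse = " + "),
                            "+ (1 | donor)"))
  fit_pair <- function() {
    # boundary (singular random-effect) fits are acceptable for the LRT;
    # only hard failures fall through to the fixed-intercept model
    b <- suppressMessages(suppressWarnings(
      lme4::lmer(f_basic, data = dat, REML = FALSE)))
    a <- suppressMessages(suppressWarnings(
      lme4::lmer(f_aug, data = dat, REML = FALSE)))
    list(basic = b, aug = a)
  }
  fits <- tryCatch(fit_pair(), error = function(e) NULL)
  if (is.null(fits)) {
    # fixed donor intercept fallback
    fb <- as.formula(paste("y ~", paste(base_terms, collapse = " + "), "+ donor"))
    fa <- as.formula(paste("y ~", paste(c(base_terms, int_terms),
                                        collapse = " + "), "+ donor"))
    b <- suppressWarnings(lm(fb, data = dat))
    a <- suppressWarnings(lm(fa, data = dat))
    stat <- max(2 * (as.numeric(logLik(a)) - as.numeric(logLik(b))), 0)
    dfree <- length(int_terms)
    sm <- summary(a)$coefficients
    return(tibble::tibble(
      gene = gene, form = form,
      interaction_estimate = sm["loy_num:q", "Estimate"],
      std_error = sm["loy_num:q", "Std. Error"],
      chisq_lrt = stat, df = dfree,
      p_lrt = pchisq(stat, dfree, lower.tail = FALSE), p_adj = NA_real_,
      n_quantiles_expressed = nq, n_cells = nrow(dat),
      excluded = FALSE, reason = NA_character_, fallback = TRUE))
  }
  lrt <- anova(fits$basic, fits$aug)
  stat <- max(lrt$Chisq[2], 0)
  dfree <- lrt$Df[2]
  est <- lme4::fixef(fits$aug)[["loy_num:q"]]
  se <- sqrt(diag(as.matrix(vcov(fits$aug)))[["loy_num:q"]])
  tibble::tibble(
    gene = gene, form = form, interaction_estimate = unname(est),
    std_error = se,
    chisq_lrt = stat, df = dfree,
    p_lrt = pchisq(stat, dfree, lower.tail = FALSE), p_adj = NA_real_,
    n_quantiles_expressed = nq, n_cells = nrow(dat),
    excluded = FALSE, reason = NA_character_, fallback = FALSE)
}

#' Run linear and quadratic interaction models over a gene panel
#'
#' Applies [interaction_model()] to each gene in both forms and
#' Bonferroni-adjusts over all tests actually performed in the run (the
#' count is recorded as attribute `n_tests`).
#'
#' @inheritParams interaction_model
#' @param genes character vector of genes.
#' @param forms subset of `c("linear", "quadratic")`.
#' @param lineage optional label recorded in the result.
#' @return tibble of per-gene, per-form results.
#' @export
run_dynamics <- function(genes, normalized, cells, donors,
                         forms = c("linear", "quadratic"),
                         lineage = NA_character_, min_quantiles = 3,
                         min_pct = 0.01) {
  if (!length(genes)) stop("empty gene list")
  out <- purrr::map(genes, function(g) {
    purrr::map(forms, function(f)
      interaction_model(g, normalized, cells, donors, f,
                        min_quantiles, min_pct)) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(lineage = lineage, .after = "gene")
  tested <- !out$excluded
  n_tests <- sum(tested)
  out$p_adj[tested] <- pmin(out$p_lrt[tested] * n_tests, 1)
  attr(out, "n_tests") <- n_tests
  out
}
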