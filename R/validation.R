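#' Validation experiments: parameter recovery and type-I calibration
#'
#' Every generative parameter of the synthetic cohort has a downstream
#' estimator, and these experiment drivers check the pairing: cohorts are
#' simulated with a known truth, the pipeline estimator is run, and per
#' replicate the estimate and whether its 95% confidence interval covers
#' the truth are recorded.  The companion `calibration_*` drivers run the
#' same estimators on all-null cohorts and record the p-value, so type-I
#' error can be measured.  Experiment sizes default to desk-scale designs
#' whose coverage/level behaviour was sized analytically (see the methods
#' vignette).
#'
#' @param n_reps number of simulation replicates.
#' @param n_donors,n_cells cohort size per replicate.
#' @param truth generative truth; defaults to [sim_truth()].
#' @param seed base seed; replicate `i` uses `seed + 131 * i`.
#' @return tibble with one row per replicate.
#' @name validation
NULL

validation_seeds <- function(seed, n) {
  as.integer((as.numeric(seed) + 131 * seq_len(n)) %% 2147483647)
}

#' @describeIn validation recovery of the donor age logit-slope by
#'   [age_association()] (true value `truth$age_logit_slope`).
#' @export
recovery_age_slope <- function(n_reps = 150, n_donors = 400, n_cells = 150,
                               truth = sim_truth(), seed = 1L) {
  purrr::map(validation_seeds(seed, n_reps), function(s) {
    don <- simulate_donors(n_donors, truth, seed = s)
    cells <- simulate_cells(don, truth, n_cells, seed = s, celltypes = "NK")
    cells$loy <- cells$loy_true
    aa <- age_association(donor_prevalence(cells), don)
    tibble::tibble(estimate = aa$slope, ci_low = aa$ci_low,
                   ci_high = aa$ci_high,
                   covered = aa$ci_low <= truth$age_logit_slope &
                     truth$age_logit_slope <= aa$ci_high)
  }) |> dplyr::bind_rows()
}

#' @describeIn validation recovery of the monocyte per-quantile odds ratio
#'   by [loy_position_model()] (true value
#'   `exp(truth$quantile_log_or["mono"])`).
#' @export
recovery_quantile_or <- function(n_reps = 120, n_donors = 30, n_cells = 140,
                                 truth = sim_truth(), seed = 1L) {
  target <- exp(unname(truth$quantile_log_or["mono"]))
  purrr::map(validation_seeds(seed, n_reps), function(s) {
    don <- simulate_donors(n_donors, truth, seed = s)
    cells <- simulate_cells(don, truth, n_cells, seed = s,
                            celltypes = c("mono-c", "mono-nc"))
    cells$loy <- cells$loy_true
    r <- loy_position_model(cells, lineage = "mono")
    tibble::tibble(estimate = r$or_estimate, ci_low = r$ci_low,
                   ci_high = r$ci_high,
                   covered = r$ci_low <= target & target <= r$ci_high)
  }) |> dplyr::bind_rows()
}

#' @describeIn validation recovery of a planted LOY-by-quantile interaction
#'   by [interaction_model()].
#' @param interaction planted interaction coefficient.
#' @export
recovery_interaction <- function(n_reps = 100, n_donors = 25, n_cells = 160,
                                 interaction = -0.08, truth = sim_truth(),
                                 seed = 1L) {
  purrr::map(validation_seeds(seed, n_reps), function(s) {
    don <- simulate_donors(n_donors, truth, seed = s)
    cells <- simulate_cells(don, truth, n_cells, seed = s,
                            celltypes = c("mono-c", "mono-nc"))
    cells$loy <- cells$loy_true
    y <- simulate_trajectory_expression(cells, interaction = interaction,
                                        seed = s)
    r <- interaction_model("DYN1", y, cells, don, "linear")
    tibble::tibble(estimate = r$interaction_estimate,
                   std_error = r$std_error,
                   covered = abs(r$interaction_estimate - interaction) <=
                     1.96 * r$std_error)
  }) |> dplyr::bind_rows()
}

# all-null truth shared by the calibration drivers
null_sim_truth <- function() {
  sim_truth(gene_effects = default_gene_effects()[0, ],
            xist_weight = 0,
            quantile_log_or = c("mono" = 0, "B" = 0, "NK" = 0,
                                "CD8" = 0, "CD4Treg" = 0))
}

#' @describeIn validation null p-values of [hurdle_de()] (4 null genes per
#'   replicate).
#' @export
calibration_hurdle <- function(n_reps = 120, n_donors = 8, n_cells = 50,
                               seed = 1L) {
  tr <- null_sim_truth()
  purrr::map(validation_seeds(seed, n_reps), function(s) {
    don <- simulate_donors(n_donors, tr, seed = s)
    cells <- simulate_cells(don, tr, n_cells, seed = s, celltypes = "NK")
    cells$loy <- cells$loy_true
    ex <- simulate_expression(cells, tr, seed = s)
    keep <- Matrix::rowSums(ex$matrix$counts) > 0
    mat <- ex$matrix
    mat$counts <- mat$counts[keep, , drop = FALSE]
    mat$barcodes <- mat$barcodes[keep]
    de <- hurdle_de(log_normalize(mat), cells[keep, ],
                    min_pct = 0, min_lfc = 0, min_cells = 5)
    tibble::tibble(
      p = de$p_hurdle[match(sprintf("NULL%03d", 1:4), de$gene)])
  }) |> dplyr::bind_rows()
}

#' @describeIn validation null p-values of the quantile logistic model.
#' @export
calibration_quantile_model <- function(n_reps = 200, n_donors = 15,
                                       n_cells = 100, seed = 1L) {
  tr <- null_sim_truth()
  purrr::map(validation_seeds(seed, n_reps), function(s) {
    don <- simulate_donors(n_donors, tr, seed = s)
    cells <- simulate_cells(don, tr, n_cells, seed = s,
                            celltypes = c("mono-c", "mono-nc"))
    cells$loy <- cells$loy_true
    tibble::tibble(p = loy_position_model(cells)$p)
  }) |> dplyr::bind_rows()
}

#' @describeIn validation null p-values of the dynamics likelihood-ratio
#'   test.
#' @export
calibration_dynamics <- function(n_reps = 200, n_donors = 10, n_cells = 60,
                                 seed = 1L) {
  tr <- null_sim_truth()
  purrr::map(validation_seeds(seed, n_reps), function(s) {
    don <- simulate_donors(n_donors, tr, seed = s)
    cells <- simulate_cells(don, tr, n_cells, seed = s,
                            celltypes = c("B-in", "B-mem"))
    cells$loy <- cells$loy_true
    y <- simulate_trajectory_expression(cells, interaction = 0, seed = s)
    tibble::tibble(p = interaction_model("DYN1", y, cells, don, "linear")$p_lrt)
  }) |> dplyr::bind_rows()
}

#' @describeIn validation null p-values of [proportion_pseudobulk()] (3 null
#'   genes per replicate).
#' @export
calibration_pseudobulk <- function(n_reps = 100, n_donors = 12, n_cells = 150,
                                   seed = 1L) {
  tr <- null_sim_truth()
  purrr::map(validation_seeds(seed, n_reps), function(s) {
    don <- simulate_donors(n_donors, tr, seed = s)
    cells <- simulate_cells(don, tr, n_cells, seed = s, celltypes = "NK")
    cells$loy <- cells$loy_true
    ex <- simulate_expression(cells, tr, seed = s)
    r <- proportion_pseudobulk(ex$matrix, cells, min_pct = 0, min_effect = 0)
    tibble::tibble(p = r$p[match(sprintf("NULL%03d", 1:3), r$gene)])
  }) |> dplyr::bind_rows()
}

#' Exhaustive specificity check of the dual-source zero-read rule
#'
#' Simulates a cohort with ambient contamination and verifies cell by cell
#' that no cell carrying at least one MSY read in either source is ever
#' called LOY.
#'
#' @param n_cells_total approximate number of cells to simulate.
#' @param seed integer seed.
#' @return list: `n_cells`, `n_with_reads`, `n_violations` (always 0 unless
#'   the rule is broken).
#' @export
specificity_check <- function(n_cells_total = 1e5, seed = 1L) {
  tr <- sim_truth(ambient_msy_rate = 0.3)
  n_donors <- 50
  don <- simulate_donors(n_donors, tr, seed = seed)
  cells <- simulate_cells(don, tr, ceiling(n_cells_total / n_donors),
                          seed = seed)
  msy <- simulate_msy_counts(cells, tr, seed = seed)
  called <- call_loy(msy$a, msy$b, cells, msy_genes = paste0("MSY", 1:8))
  has_read <- called$msy_total_a + called$msy_total_b > 0
  list(n_cells = nrow(called),
       n_with_reads = sum(has_read),
       n_violations = sum(called$loy & has_read, na.rm = TRUE))
}
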