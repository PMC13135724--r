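#' Ground-truth parameters for the synthetic cohort generator
#'
#' Bundles every generative parameter of the synthetic PBMC cohort so that
#' downstream estimators can be checked against known truth.  Defaults encode
#' the study conditions the pipeline is meant to recover: a logit-scale LOY
#' prevalence slope of 0.013 per year of donor age, cell-type base LOY rates
#' matching the observed per-type frequencies (5.6%-18.6%), per-quantile
#' trajectory odds ratios (e.g. 0.91 per pseudotime quantile step on the
#' classical-to-nonclassical monocyte transition), designated gene effects
#' (e.g. IL1B log2FC -0.22 in classical monocytes, escape-gene upregulation
#' +0.3, CD99 -0.67 in Treg), a bimodal XIST mixture in LOY cells, ambient
#' stray MSY reads in true-LOY cells, and noisy SNP-array clonal fractions.
#'
#' @param age_logit_slope per-year effect on logit(LOY clonal fraction).
#' @param age_logit_intercept intercept of the same linear predictor.
#' @param donor_sd logit-scale donor-to-donor SD of the clonal fraction,
#'   beyond age (0.8 reproduces per-donor prevalences spanning roughly
#'   1%-54%).
#' @param base_loy_rates named per-cell-type LOY frequencies.
#' @param celltype_freqs named cell-type composition (normalised internally).
#' @param quantile_log_or named per-lineage log odds per pseudotime quantile
#'   step.
#' @param gene_effects tibble `gene`, `cell_type` (NA = all), `lfc`
#'   (log2 fold change in LOY cells).
#' @param xist_weight probability that a LOY cell activates XIST (the active
#'   mixture component).
#' @param xist_mu_low,xist_mu_high mean XIST counts in the silent and active
#'   components.
#' @param ambient_msy_rate expected stray MSY UMIs per true-LOY cell and
#'   counting source; creates false negatives, never false positives.
#' @param msy_mean expected MSY UMIs per non-LOY cell at median depth.
#' @param snp_noise_sd Gaussian noise SD on the SNP-array clonal fraction.
#' @param snp_floor array detection floor; fractions below it are missing.
#' @param nb_dispersion negative-binomial dispersion of expression counts.
#' @param mean_umi mean per-cell UMI total used for depth scaling.
#' @param t_allele_freq rs2887399 T-allele frequency (additive coding
#'   G/G = 0, G/T = 1, T/T = 2).
#' @param n_pools number of sequencing pools.
#' @param mca_rate donor probability of carrying an autosomal mCA
#'   (independent of LOY).
#' @return list of class `sim_truth`.
#' @export
sim_truth <- function(age_logit_slope = 0.013,
                      age_logit_intercept = -3.3,
                      donor_sd = 0.8,
                      base_loy_rates = c(
                        "CD4nc" = 0.058, "CD4et" = 0.056, "Treg" = 0.1257,
                        "CTL" = 0.088, "CD8nc" = 0.137, "CD8et" = 0.158,
                        "NK" = 0.146, "NKr" = 0.125, "B-in" = 0.123,
                        "B-mem" = 0.084, "mono-c" = 0.186, "mono-nc" = 0.171),
                      celltype_freqs = c(
                        "CD4nc" = 76835, "CD4et" = 67859, "Treg" = 10615,
                        "CTL" = 7880, "CD8nc" = 1809, "CD8et" = 2265,
                        "NK" = 20750, "NKr" = 4366, "B-in" = 20160,
                        "B-mem" = 13126, "mono-c" = 9561, "mono-nc" = 3927),
                      quantile_log_or = c(
                        "mono" = log(0.91), "B" = log(0.92), "NK" = log(0.93),
                        "CD8" = log(1.08), "CD4Treg" = log(1.04)),
                      gene_effects = default_gene_effects(),
                      xist_weight = 0.1,
                      xist_mu_low = 0.02,
                      xist_mu_high = 40,
                      ambient_msy_rate = 0.2,
                      msy_mean = 5,
                      snp_noise_sd = 0.05,
                      snp_floor = 0.02,
                      nb_dispersion = 0.5,
                      mean_umi = 3000,
                      t_allele_freq = 0.3,
                      n_pools = 10L,
                      mca_rate = 0.06) {
  stopifnot(all(base_loy_rates >= 0 & base_loy_rates <= 1),
            xist_weight >= 0 && xist_weight <= 1,
            ambient_msy_rate >= 0, nb_dispersion > 0)
  structure(as.list(environment()), class = "sim_truth")
}

#' Default planted gene effects for the expression simulator
#'
#' Log2 fold changes applied to the negative-binomial mean in LOY cells of
#' the designated cell types (NA = every cell type).  Escape-class X genes
#' are planted as upregulated in all types; IL1B and companions as
#' monocyte-specific downregulation.
#'
#' @export
default_gene_effects <- function() {
  tibble::tibble(
    gene = c("IL1B", "LGALS2", "MYCL", "CD86",
             "CD99",
             "KDM6A", "DDX3X", "KDM5C", "ZRSR2", "JPX", "RPS4X", "EIF1AX",
             "LYPD2", "C1QA"),
    cell_type = c("mono-c", "mono-c", "mono-c", "mono-c",
                  "Treg",
                  NA, NA, NA, NA, NA, NA, NA,
                  "mono-nc", "mono-nc"),
    lfc = c(-0.22, -0.16, -0.55, -0.30,
            -0.67,
            0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3,
            -0.3, -0.3)
  )
}

# which trajectory lineage a cell type belongs to, and whether it is the
# terminal (end) type of that lineage
lineage_map <- function() {
  tibble::tibble(
    cell_type = c("mono-c", "mono-nc", "B-in", "B-mem", "NK", "NKr",
                  "CD8nc", "CD8et", "CD4nc", "Treg", "CD4et", "CTL"),
    lineage = c("mono", "mono", "B", "B", "NK", "NK",
                "CD8", "CD8", "CD4Treg", "CD4Treg", NA, NA),
    terminal = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                 FALSE, TRUE, FALSE, TRUE, NA, NA)
  )
}

# deterministic child streams so adding a stage never perturbs earlier draws
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}

#' Simulate a donor table with known clonal fractions
#'
#' Draws donor ages from an age pyramid matching an elderly blood-donor
#' cohort (bins 19-38 / 39-58 / 59-78 / 79-93 weighted 43:69:227:77, median
#' about 68), then draws each donor's true LOY clonal fraction so that
#' logit(fraction) is linear in age with slope `truth$age_logit_slope` plus
#' `N(0, donor_sd)` noise.  The SNP-array estimate adds truncated Gaussian
#' noise and is censored below the array detection floor.
#'
#' @param n_donors number of donors (>= 2).
#' @param truth a [sim_truth()].
#' @param seed integer seed.
#' @return tibble: `donor`, `age`, `sex`, `pool`, `pc1..pc10`,
#'   `rs2887399_dosage`, `true_clonal_fraction` (ground truth),
#'   `snp_clonal_fraction` (noisy, possibly missing), `mca_flag`.
#' @export
simulate_donors <- function(n_donors, truth = sim_truth(), seed = 1L) {
  stopifnot(n_donors >= 2)
  set.seed(child_seed(seed, 1))
  bins <- matrix(c(19, 38, 39, 58, 59, 78, 79, 93), 2)
  w <- c(43, 69, 227, 77)
  b <- sample.int(4, n_donors, replace = TRUE, prob = w / sum(w))
  age <- floor(runif(n_donors, bins[1, b], bins[2, b] + 1))
  eta <- truth$age_logit_intercept + truth$age_logit_slope * age +
    rnorm(n_donors, 0, truth$donor_sd)
  frac <- plogis(eta)
  snp <- frac + rnorm(n_donors, 0, truth$snp_noise_sd)
  clamped <- snp < 0 | snp > 1
  if (any(clamped)) snp <- pmin(pmax(snp, 0), 1)
  snp[snp < truth$snp_floor] <- NA_real_
  pcs <- matrix(rnorm(n_donors * 10), n_donors, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  don <- tibble::tibble(
    donor = sprintf("D%04d", seq_len(n_donors)),
    age = age,
    sex = "M",
    pool = sprintf("P%02d", sample.int(truth$n_pools, n_donors, replace = TRUE)),
    rs2887399_dosage = rbinom(n_donors, 2, truth$t_allele_freq),
    true_clonal_fraction = frac,
    snp_clonal_fraction = snp,
    mca_flag = runif(n_donors) < truth$mca_rate
  )
  dplyr::bind_cols(don, tibble::as_tibble(pcs))
}

#' Simulate per-cell annotations with known LOY status
#'
#' Each cell receives a donor, a cell type drawn from the composition
#' profile, a pseudotime `U(0, 1)` along its lineage, the 1..6 pseudotime
#' quantile, a UMI total, and a true LOY status drawn from the logistic model
#' `logit P(LOY) = logit(donor fraction) + cell-type offset +
#' step * (quantile - 3.5)`, where the per-quantile step is the lineage's
#' generative log odds ratio.  When both member types of a lineage are
#' simulated, the subtype label is derived from pseudotime (cells before the
#' composition-matched threshold are the start type) and the LOY offset uses
#' the lineage-pooled base rate, so the quantile step is the single source
#' of the within-lineage gradient; types simulated without their lineage
#' partner are standalone, use their own base rate, and carry no pseudotime.
#' A cell type with base rate exactly 0 never yields LOY cells.  With `embedding = TRUE` the cells also get a
#' noisy 2-D curve embedding (`e1`, `e2`) parametrised by pseudotime so that
#' pseudotime fitting can be tested for ordering recovery.
#'
#' @param donors tibble from [simulate_donors()].
#' @param truth a [sim_truth()].
#' @param n_cells_per_donor cells drawn per donor.
#' @param seed integer seed.
#' @param celltypes optional subset of cell types to simulate.
#' @param embedding emit a 2-D noisy curve embedding.
#' @param embedding_noise SD of the embedding noise.
#' @return tibble of per-cell annotations; the realised per-quantile LOY
#'   frequencies are attached as attribute `realized_quantile_freq`.
#' @export
simulate_cells <- function(donors, truth = sim_truth(), n_cells_per_donor = 100,
                           seed = 1L, celltypes = NULL, embedding = FALSE,
                           embedding_noise = 0.02) {
  if (!nrow(donors)) stop("empty donor table")
  set.seed(child_seed(seed, 2))
  freqs <- truth$celltype_freqs
  if (!is.null(celltypes)) freqs <- freqs[names(freqs) %in% celltypes]
  if (!length(freqs)) stop("no cell types selected")
  freqs <- freqs / sum(freqs)
  n <- nrow(donors) * n_cells_per_donor
  di <- rep(seq_len(nrow(donors)), each = n_cells_per_donor)
  lm_ <- lineage_map()
  # a lineage is active when both its member types are simulated; its cells
  # then take their subtype from pseudotime (early = start type), so subtype
  # and trajectory position tell one consistent story
  active <- lm_ |>
    dplyr::filter(!is.na(.data$lineage), .data$cell_type %in% names(freqs)) |>
    dplyr::group_by(.data$lineage) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::ungroup()
  # sampling units: active lineages + standalone cell types
  standalone <- setdiff(names(freqs), active$cell_type)
  unit_names <- c(unique(active$lineage), standalone)
  unit_freq <- c(
    vapply(unique(active$lineage), function(l)
      sum(freqs[active$cell_type[active$lineage == l]]), 0),
    freqs[standalone])
  unit <- sample(unit_names, n, replace = TRUE, prob = unit_freq)
  is_lineage <- unit %in% active$lineage
  pt <- ifelse(is_lineage, runif(n), NA_real_)
  q <- ifelse(is_lineage, pmin(ceiling(pt * 6), 6L), NA_integer_)
  ct <- unit
  lin <- rep(NA_character_, n)
  pooled_rate <- sum(truth$base_loy_rates[names(freqs)] * freqs)
  offset <- rep(0, n)
  for (l in unique(active$lineage)) {
    members <- active[active$lineage == l, ]
    start_t <- members$cell_type[!members$terminal]
    end_t <- members$cell_type[members$terminal]
    thr <- freqs[start_t] / (freqs[start_t] + freqs[end_t])
    sel <- unit == l
    ct[sel] <- ifelse(pt[sel] < thr, start_t, end_t)
    lin[sel] <- l
    lr <- sum(truth$base_loy_rates[members$cell_type] *
                freqs[members$cell_type]) / sum(freqs[members$cell_type])
    offset[sel] <- qlogis(lr) - qlogis(pooled_rate)
  }
  sel <- !is_lineage
  offset[sel] <- qlogis(pmax(truth$base_loy_rates[ct[sel]], 1e-12)) -
    qlogis(pooled_rate)
  step <- ifelse(is.na(lin), 0, truth$quantile_log_or[lin])
  eta <- qlogis(donors$true_clonal_fraction[di]) + offset +
    ifelse(is.na(q), 0, step * (q - 3.5))
  p_loy <- plogis(eta)
  p_loy[truth$base_loy_rates[ct] == 0] <- 0  # type with base rate 0 never LOY
  loy <- runif(n) < p_loy
  umi <- pmax(rnbinom(n, mu = truth$mean_umi, size = 4), 100L)
  cells <- tibble::tibble(
    barcode = sprintf("C%07d", seq_len(n)),
    donor = donors$donor[di],
    sex = "M",
    cell_type = ct,
    lineage = lin,
    pseudotime = pt,
    quantile = as.integer(q),
    umi_total = as.integer(umi),
    loy_true = loy
  )
  if (embedding) {
    cells$e1 <- pt + rnorm(n, 0, embedding_noise)
    cells$e2 <- 4 * pt * (1 - pt) + rnorm(n, 0, embedding_noise)
  }
  rq <- cells |>
    dplyr::filter(!is.na(.data$lineage)) |>
    dplyr::group_by(.data$lineage, .data$quantile) |>
    dplyr::summarise(pct_loy = 100 * mean(.data$loy_true), .groups = "drop")
  attr(cells, "realized_quantile_freq") <- rq
  cells
}

#' Simulate dual-source MSY counts
#'
#' Non-LOY cells draw Poisson MSY totals with a depth-scaled mean,
#' distributed over the MSY gene panel; true-LOY cells draw only
#' Poisson(ambient) stray counts, independently in each counting source.  A
#' non-zero ambient rate therefore creates known false negatives but never a
#' false positive under the dual-source zero-read rule.
#'
#' @param cells tibble from [simulate_cells()].
#' @param truth a [sim_truth()].
#' @param seed integer seed.
#' @param msy_genes MSY gene identifiers (>= 1).
#' @param guaranteed_positive if `TRUE`, non-LOY cells with a Poisson zero
#'   total are bumped to one read (calibration aid that removes sensitivity
#'   limits due to sampling zeros).
#' @return list with `cell_gene_matrix` elements `a` and `b`.
#' @export
simulate_msy_counts <- function(cells, truth = sim_truth(), seed = 1L,
                                msy_genes = paste0("MSY", 1:8),
                                guaranteed_positive = FALSE) {
  if (truth$ambient_msy_rate < 0) stop("ambient rate must be non-negative")
  if (!length(msy_genes)) stop("need at least one MSY gene")
  set.seed(child_seed(seed, 3))
  n <- nrow(cells)
  depth <- cells$umi_total / truth$mean_umi
  one_source <- function() {
    tot <- ifelse(cells$loy_true,
                  rpois(n, truth$ambient_msy_rate),
                  rpois(n, truth$msy_mean * depth))
    if (guaranteed_positive) tot[!cells$loy_true & tot == 0] <- 1L
    zero_depth <- cells$umi_total == 0
    tot[zero_depth] <- 0L
    # split the total across the panel
    g <- length(msy_genes)
    idx <- which(tot > 0)
    m <- matrix(0L, n, g)
    if (length(idx)) {
      spread <- vapply(tot[idx], function(tt)
        as.integer(stats::rmultinom(1, tt, rep(1 / g, g))), integer(g))
      m[idx, ] <- t(spread)
    }
    cell_gene_matrix(m, barcodes = cells$barcode,
                     features = tibble::tibble(gene = msy_genes))
  }
  a <- one_source(); a$source_label <- "cellranger"
  b <- one_source(); b$source_label <- "velocyto"
  list(a = a, b = b)
}

#' Simulate an expression panel with planted LOY effects
#'
#' Counts are negative binomial with gene-specific baselines, depth scaling
#' and common dispersion.  LOY multiplies the mean of each planted effect
#' gene by `2^lfc` in the designated cell types.  XIST is drawn from a
#' two-component mixture in LOY cells (silent low-rate component vs an
#' active component), producing a bimodal non-zero distribution; in non-LOY
#' cells only the silent component applies.
#'
#' @param cells tibble from [simulate_cells()].
#' @param truth a [sim_truth()].
#' @param seed integer seed.
#' @param gene_panel optional tibble `gene`, `baseline`; defaults to the
#'   planted effect genes plus escape/inactive X genes, XIST and null genes.
#' @return list: `matrix` (a `cell_gene_matrix`), `truth_effects` (the
#'   planted non-null gene/cell-type/effect triples).
#' @export
simulate_expression <- function(cells, truth = sim_truth(), seed = 1L,
                                gene_panel = NULL) {
  set.seed(child_seed(seed, 4))
  if (is.null(gene_panel)) gene_panel <- default_gene_panel(truth)
  n <- nrow(cells)
  depth <- cells$umi_total / truth$mean_umi
  genes <- gene_panel$gene
  eff <- truth$gene_effects
  cols <- vector("list", length(genes))
  for (j in seq_along(genes)) {
    gn <- genes[j]
    mu <- gene_panel$baseline[j] * depth
    rows <- which(eff$gene == gn)
    if (length(rows)) {
      for (r in rows) {
        hit <- cells$loy_true &
          (is.na(eff$cell_type[r]) | cells$cell_type == eff$cell_type[r])
        mu[hit] <- mu[hit] * 2^eff$lfc[r]
      }
    }
    if (gn == "XIST") {
      active <- cells$loy_true & (runif(n) < truth$xist_weight)
      cnt <- rpois(n, truth$xist_mu_low * depth)
      cnt[active] <- rnbinom(sum(active), mu = truth$xist_mu_high * depth[active],
                             size = 1 / truth$nb_dispersion)
    } else {
      cnt <- rnbinom(n, mu = mu, size = 1 / truth$nb_dispersion)
    }
    cols[[j]] <- cnt
  }
  m <- do.call(cbind, cols)
  mat <- cell_gene_matrix(m, barcodes = cells$barcode,
                          features = tibble::tibble(gene = genes))
  list(matrix = mat, truth_effects = eff)
}

#' Default simulated gene panel
#'
#' Planted effect genes, escape/inactive/variable X genes, XIST and null
#' autosomal genes with log-normal baseline means.
#'
#' @param truth a [sim_truth()].
#' @param n_null number of null filler genes.
#' @export
default_gene_panel <- function(truth = sim_truth(), n_null = 40) {
  eff_genes <- unique(truth$gene_effects$gene)
  x_extra <- c("XIST", "CD40LG", "TIMP1", "PRKX")
  nulls <- sprintf("NULL%03d", seq_len(n_null))
  genes <- unique(c(eff_genes, x_extra, nulls))
  set.seed(7041)  # fixed panel: baselines are part of the design, not noise
  tibble::tibble(
    gene = genes,
    baseline = ifelse(genes == "XIST", NA_real_,
                      exp(rnorm(length(genes), log(1.5), 0.6)))
  )
}

#' Annotation table for the simulated gene panel
#'
#' Chromosome assignments and coordinates for the default panel: MSY genes
#' inside the MSY span, X genes with curated XCI classes (escape genes used
#' by the planted effects; CD99 in PAR1), the rest autosomal.
#'
#' @param config a [loy_config()].
#' @export
simulated_gene_annotation <- function(config = loy_config()) {
  esc <- c("KDM6A", "DDX3X", "KDM5C", "ZRSR2", "JPX", "RPS4X", "EIF1AX")
  inact <- c("CD40LG", "TIMP1")
  vari <- c("PRKX")
  msy <- paste0("MSY", 1:8)
  nulls <- sprintf("NULL%03d", 1:40)
  auto <- c("IL1B", "LGALS2", "MYCL", "CD86", "LYPD2", "C1QA", nulls)
  x_genes <- c("XIST", esc, inact, vari)
  tibble::tibble(
    gene = c("CD99", x_genes, msy, auto),
    chromosome = c("X", rep("X", length(x_genes)), rep("Y", length(msy)),
                   rep("1", length(auto))),
    start = c(config$par1_start + 1e5,
              seq(7e7, by = 1e5, length.out = length(x_genes)),
              seq(config$msy_start + 1e5, by = 1e5, length.out = length(msy)),
              seq(1e6, by = 1e5, length.out = length(auto))),
    end = c(config$par1_start + 1e5 + 5e4,
            seq(7e7, by = 1e5, length.out = length(x_genes)) + 5e4,
            seq(config$msy_start + 1e5, by = 1e5, length.out = length(msy)) + 5e4,
            seq(1e6, by = 1e5, length.out = length(auto)) + 5e4),
    xci_class = c(NA,
                  "variable",  # XIST itself escapes silencing machinery; class per curated lists
                  rep("escape", length(esc)), rep("inactive", length(inact)),
                  rep("variable", length(vari)),
                  rep(NA, length(msy) + length(auto)))
  ) |> annotate_gene_regions(config)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_donors()], [simulate_cells()],
#' [simulate_msy_counts()] and [simulate_expression()] with one master seed;
#' each stage derives an independent child stream, so adding a stage never
#' perturbs earlier draws and the same seed gives byte-identical output.
#'
#' @param n_donors,n_cells_per_donor cohort size.
#' @param truth a [sim_truth()].
#' @param seed master seed.
#' @param celltypes optional cell-type subset.
#' @param expression also simulate the expression panel.
#' @param embedding emit the 2-D curve embedding.
#' @return list: `donors`, `cells`, `msy` (list a/b), optionally
#'   `expression`, plus `truth`.
#' @export
simulate_cohort <- function(n_donors = 50, n_cells_per_donor = 100,
                            truth = sim_truth(), seed = 1L, celltypes = NULL,
                            expression = FALSE, embedding = FALSE) {
  donors <- simulate_donors(n_donors, truth, seed)
  cells <- simulate_cells(donors, truth, n_cells_per_donor, seed,
                          celltypes = celltypes, embedding = embedding)
  msy <- simulate_msy_counts(cells, truth, seed)
  out <- list(donors = donors, cells = cells, msy = msy, truth = truth)
  if (expression) out$expression <- simulate_expression(cells, truth, seed)
  out
}

#' Simulate expression with a planted LOY-by-pseudotime interaction
#'
#' Generates one gene's (pre-normalized, continuous) expression along a
#' trajectory from the same model class the dynamics module fits:
#' `y = intercept + b_loy * LOY + b_q * quantile + interaction * LOY *
#' quantile (+ quadratic terms) + donor intercept + noise`, so that the
#' interaction estimator can be checked for recovery and calibration.
#'
#' @param cells tibble with `loy` (or `loy_true`), `quantile`, `donor`.
#' @param interaction planted linear interaction coefficient (per quantile
#'   step).
#' @param interaction_q2 planted quadratic interaction (0 = none).
#' @param intercept,b_loy,b_q baseline coefficients.
#' @param donor_sd SD of the donor random intercept.
#' @param sigma residual SD.
#' @param seed integer seed.
#' @param gene column name of the returned one-gene matrix.
#' @return single-column matrix usable as `normalized` in
#'   [interaction_model()].
#' @export
simulate_trajectory_expression <- function(cells, interaction = -0.08,
                                           interaction_q2 = 0,
                                           intercept = 2, b_loy = 0.1,
                                           b_q = 0.05, donor_sd = 0.2,
                                           sigma = 0.6, seed = 1L,
                                           gene = "DYN1") {
  set.seed(child_seed(seed, 5))
  loy <- if ("loy" %in% names(cells) && !all(is.na(cells$loy)))
    as.numeric(cells$loy) else as.numeric(cells$loy_true)
  q <- as.numeric(cells$quantile)
  u <- rnorm(dplyr::n_distinct(cells$donor), 0, donor_sd)
  names(u) <- unique(cells$donor)
  y <- intercept + b_loy * loy + b_q * q + interaction * loy * q +
    interaction_q2 * loy * q^2 + u[cells$donor] +
    rnorm(nrow(cells), 0, sigma)
  matrix(y, ncol = 1, dimnames = list(cells$barcode, gene))
}

#' Serialise simulation truth alongside outputs
#'
#' @param truth a [sim_truth()].
#' @param path output file (JSON text).
#' @export
write_sim_truth <- function(truth, path) {
  tr <- unclass(truth)
  tr$gene_effects <- as.data.frame(tr$gene_effects)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
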