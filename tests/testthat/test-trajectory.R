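test_that("pseudotime recovers ordering on a noiseless parametric curve", {
  t_true <- seq(0, 1, length.out = 400)
  emb <- cbind(t_true, 4 * t_true * (1 - t_true))
  clusters <- ifelse(t_true < 0.5, "start", "end")
  pt <- fit_pseudotime(emb, clusters, "start", "end")
  expect_gte(cor(pt, t_true, method = "spearman"), 0.99)
  expect_true(all(pt >= 0 & pt <= 1))
})

test_that("pseudotime is oriented by the start/end clusters", {
  set.seed(41)
  co <- simulate_cohort(n_donors = 5, n_cells_per_donor = 120, seed = 41,
                        celltypes = c("mono-c", "mono-nc"), embedding = TRUE)
  cells <- co$cells
  pt <- fit_pseudotime(cbind(cells$e1, cells$e2), cells$cell_type,
                       "mono-c", "mono-nc")
  expect_lt(mean(pt[cells$cell_type == "mono-c"]),
            mean(pt[cells$cell_type == "mono-nc"]))
  # flipped anchors reverse the orientation
  pt2 <- fit_pseudotime(cbind(cells$e1, cells$e2), cells$cell_type,
                        "mono-nc", "mono-c")
  expect_lt(cor(pt, pt2), -0.95)
  # ordering matches the generative pseudotime
  expect_gt(cor(pt, cells$pseudotime, method = "spearman"), 0.95)
})

test_that("pseudotime is invariant to permuting the cell order", {
  t_true <- runif(100)
  emb <- cbind(t_true, sin(2 * t_true))
  clusters <- ifelse(t_true < 0.5, "s", "e")
  pt <- fit_pseudotime(emb, clusters, "s", "e")
  perm <- sample(100)
  pt_perm <- fit_pseudotime(emb[perm, ], clusters[perm], "s", "e")
  expect_equal(pt_perm, pt[perm], tolerance = 1e-8)

  expect_error(fit_pseudotime(emb, clusters, "s", "s"), "identical")
  expect_error(fit_pseudotime(emb[1:5, ], clusters[1:5], "s", "e"), "10 cells")
})

test_that("quantile bins are equal-count, rank-invariant, and tie-stable", {
  pt <- runif(600)
  q <- bin_quantiles(pt, 6)
  expect_equal(unname(table(q)), rep(100L, 6), ignore_attr = TRUE)
  expect_true(all(diff(q[order(pt)]) >= 0))      # non-decreasing in pseudotime
  # monotone relabeling leaves bins unchanged
  expect_equal(bin_quantiles(exp(3 * pt)), q)

  # 300 tied + 300 distinct: deterministic boundary via (pt, barcode) order
  ptt <- c(rep(0.5, 300), seq(0.51, 0.99, length.out = 300))
  bc <- sprintf("b%03d", 1:600)
  q1 <- bin_quantiles(ptt, 6, barcode = bc)
  q2 <- bin_quantiles(ptt, 6, barcode = bc)
  expect_identical(q1, q2)
  expect_equal(unname(table(q1)), rep(100L, 6), ignore_attr = TRUE)
  # tied cells fill the first three bins in barcode order
  expect_equal(sort(unique(q1[1:300])), 1:3)
  expect_error(bin_quantiles(runif(3), 6), "fewer")
})

test_that("null predictor gives OR near 1 with nominal coverage", {
  cover <- vapply(rep_seeds(900, 60), function(s) {
    don <- simulate_donors(10, null_truth(), seed = s)
    cells <- simulate_cells(don, null_truth(), 150, seed = s,
                            celltypes = c("B-in", "B-mem"))
    cells$loy <- cells$loy_true
    r <- loy_position_model(cells)
    r$ci_low <= 1 && 1 <= r$ci_high
  }, TRUE)
  expect_gte(mean(cover), 0.85)
})

test_that("quantile and binary-subtype predictors agree in sign on monotone gradients", {
  don <- simulate_donors(30, seed = 43)
  cells <- simulate_cells(don, n_cells_per_donor = 400, seed = 43,
                          celltypes = c("mono-c", "mono-nc"))
  cells$loy <- cells$loy_true
  cells$is_end <- cells$cell_type == "mono-nc"
  rq <- loy_position_model(cells, predictor = "quantile")
  rb <- loy_position_model(cells, predictor = "is_end")
  expect_lt(rq$or_estimate, 1)
  expect_lt(rb$or_estimate, 1)

  don2 <- simulate_donors(30, seed = 44)
  cells2 <- simulate_cells(don2, n_cells_per_donor = 400, seed = 44,
                           celltypes = c("CD8nc", "CD8et"))
  cells2$loy <- cells2$loy_true
  expect_gt(loy_position_model(cells2)$or_estimate, 1)
})

test_that("a genotype-driven subtype bias disappears once dosage is adjusted for", {
  # rs2887399 dosage is made the sole driver of the B-lineage gradient:
  # donors with higher T dosage get a steeper step
  set.seed(45)
  don <- simulate_donors(60, seed = 45)
  cells <- simulate_cells(don, null_truth(), 300, seed = 45,
                          celltypes = c("B-in", "B-mem"))
  dose <- don$rs2887399_dosage[match(cells$donor, don$donor)]
  eta <- qlogis(don$true_clonal_fraction[match(cells$donor, don$donor)]) +
    0.25 * dose * (cells$quantile - 3.5) / 2.5
  cells$loy <- runif(nrow(cells)) < plogis(eta)
  r_uni <- loy_position_model(cells, don, model = "multivariate")
  r_snp <- loy_position_model(cells, don, model = "multivariate_genotype")
  expect_lt(r_uni$p, 0.05)
  expect_gt(r_snp$p, r_uni$p)
})

test_that("age-stratified models use the donor-level median and refit per stratum", {
  co <- called_cohort(n_donors = 40, n_cells = 120, seed = 47,
                      celltypes = c("mono-c", "mono-nc"))
  co$cells$loy <- co$cells$loy_true
  res <- age_stratified_models(co$cells, co$donors, model = "univariate")
  expect_equal(nrow(res), 2)
  expect_setequal(res$strata, c("age<median", "age>=median"))
  # homogeneous planted effect: stratum CIs overlap
  expect_true(res$ci_low[1] <= res$ci_high[2] && res$ci_low[2] <= res$ci_high[1])

  # median must come from donors, not cells: donor cell counts are skewed so
  # the cell-level median age would split differently
  mk <- function(d, age, n) tibble::tibble(
    barcode = paste0(d, seq_len(n)), donor = d, age = age,
    quantile = rep_len(1:6, n), loy = rep_len(c(TRUE, FALSE, FALSE), n))
  cells3 <- dplyr::bind_rows(mk("A", 20, 600), mk("B", 50, 12), mk("C", 80, 12))
  don3 <- tibble::tibble(donor = c("A", "B", "C"), age = c(20, 50, 80),
                         sex = "M")
  r3 <- age_stratified_models(cells3, don3, model = "univariate")
  expect_equal(r3$n_cells[r3$strata == "age<median"], 600)   # donor A only
  expect_equal(r3$n_cells[r3$strata == "age>=median"], 24)
})

test_that("Firth fallback engages under perfect separation and is flagged", {
  cells <- tibble::tibble(
    barcode = as.character(1:60), donor = "D1",
    quantile = rep(1:6, each = 10),
    loy = rep(c(FALSE, TRUE), c(30, 30)))   # separation at quantile 3/4
  r <- loy_position_model(cells)
  expect_true(r$separation)
  expect_true(is.finite(r$or_estimate) && r$or_estimate > 1)
  expect_true(is.finite(r$p))
})

test_that("BH adjustment across a model family is monotone and bounded", {
  set.seed(48)
  fake <- tibble::tibble(p = runif(30))
  adj <- adjust_results(fake)
  expect_true(all(adj$p_adj >= adj$p - 1e-12))
  expect_true(all(adj$p_adj <= 1))
  expect_equal(adj$p_adj, p.adjust(fake$p, "BH"))
})
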