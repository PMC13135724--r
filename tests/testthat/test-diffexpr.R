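test_that("exact rank-sum enumeration reproduces the 4v4 separated p-value", {
  loy <- c(0.1, 0.12, 0.11, 0.13)
  non <- c(0.3, 0.28, 0.31, 0.29)
  r <- rank_sum_test(loy, non)
  expect_equal(r$p, 2 / 70, tolerance = 1e-12)
  expect_match(r$method, "exact")
})

test_that("exact enumeration agrees with brute-force rank reassignment", {
  set.seed(51)
  for (i in 1:25) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- round(rnorm(n1), 1); y <- round(rnorm(n2, 0.3), 1)  # ties possible
    r <- rank_sum_test(x, y)
    # independent oracle: enumerate group assignments of the pooled values
    pooled <- c(x, y); rk <- rank(pooled)
    EU <- n1 * n2 / 2
    obs <- abs(sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2 - EU)
    all_u <- apply(combn(n1 + n2, n1), 2, function(idx)
      abs(sum(rk[idx]) - n1 * (n1 + 1) / 2 - EU))
    expect_equal(r$p, mean(all_u >= obs - 1e-12), tolerance = 1e-12)
  }
})

test_that("hurdle DE on identical groups is an exact null", {
  set.seed(52)
  m <- matrix(rpois(200 * 5, 2), 200, 5,
              dimnames = list(sprintf("c%03d", 1:200), sprintf("g%d", 1:5)))
  m <- rbind(m, m)
  rownames(m) <- sprintf("c%03d", 1:400)
  norm <- log_normalize(tiny_cgm(m, genes = colnames(m)))
  cells <- tibble::tibble(barcode = rownames(m),
                          loy = rep(c(TRUE, FALSE), each = 200))
  de <- hurdle_de(norm, cells, min_pct = 0, min_lfc = 0)
  expect_true(all(abs(de$avg_log2fc) < 1e-12))
  expect_true(all(de$p_hurdle > 0.99))
})

test_that("a detection-only signal is caught and driven by the discrete part", {
  set.seed(53)
  n <- 1000
  # same positive-value distribution, very different dropout
  x1 <- ifelse(runif(n) < 0.5, 0, rpois(n, 5) + 1)
  x2 <- ifelse(runif(n) < 0.9, 0, rpois(n, 5) + 1)
  m <- cbind(sig = c(x1, x2), null = rpois(2 * n, 2))
  rownames(m) <- sprintf("c%04d", 1:(2 * n))
  keep <- rowSums(m) > 0
  norm <- log_normalize(tiny_cgm(m[keep, ], genes = colnames(m)))
  cells <- tibble::tibble(barcode = rownames(m)[keep],
                          loy = rep(c(TRUE, FALSE), each = n)[keep])
  de <- hurdle_de(norm, cells, min_pct = 0, min_lfc = 0)
  sig <- de[de$gene == "sig", ]
  expect_lt(sig$p_adj, 1e-10)
  expect_lt(sig$p_discrete, 1e-10)
  expect_gt(sig$p_continuous, 0.001)
  # additivity: the hurdle statistic is the sum of its parts
  lr_d <- qchisq(sig$p_discrete, 1, lower.tail = FALSE)
  lr_c <- qchisq(sig$p_continuous, 1, lower.tail = FALSE)
  expect_equal(sig$chisq_hurdle, lr_d + lr_c, tolerance = 1e-6)
})

test_that("hurdle detection filter drops genes below 1% in both groups", {
  set.seed(54)
  n <- 600
  rare <- c(rep(1L, 3), rep(0L, n - 3))         # 0.5% in both groups
  m <- cbind(rare = c(rare, rare), common = rpois(2 * n, 3) + 1L)
  rownames(m) <- sprintf("c%04d", 1:(2 * n))
  norm <- log_normalize(tiny_cgm(m, genes = colnames(m)))
  cells <- tibble::tibble(barcode = rownames(m),
                          loy = rep(c(TRUE, FALSE), each = n))
  de <- suppressWarnings(hurdle_de(norm, cells, min_lfc = 0))
  expect_false("rare" %in% de$gene)
  expect_true("common" %in% de$gene)
})

test_that("swapping group labels negates the fold change and preserves p", {
  don <- simulate_donors(8, seed = 55)
  cells <- simulate_cells(don, n_cells_per_donor = 60, seed = 55,
                          celltypes = "NK")
  cells$loy <- cells$loy_true
  ex <- simulate_expression(cells, seed = 55)
  dz <- drop_zero_cells(ex$matrix, cells)
  norm <- log_normalize(dz$matrix)
  de1 <- hurdle_de(norm, dz$cells, min_cells = 5, min_pct = 0, min_lfc = 0)
  flipped <- dplyr::mutate(dz$cells, loy = !loy)
  de2 <- hurdle_de(norm, flipped, min_cells = 5, min_pct = 0, min_lfc = 0)
  shared <- intersect(de1$gene, de2$gene)
  i1 <- match(shared, de1$gene); i2 <- match(shared, de2$gene)
  expect_equal(de1$avg_log2fc[i1], -de2$avg_log2fc[i2], tolerance = 1e-9)
  expect_equal(de1$p_hurdle[i1], de2$p_hurdle[i2], tolerance = 1e-9)
})

test_that("pseudobulk matches the exact Wilcoxon worked example and flags ties", {
  # 4 LOY donors vs 4 non-LOY donors with fully separated proportions
  r <- rank_sum_test(c(0.1, 0.12, 0.11, 0.13), c(0.3, 0.28, 0.31, 0.29))
  expect_equal(r$p, 0.02857143, tolerance = 1e-6)

  # identical proportions across strata for every donor -> p = 1
  set.seed(56)
  n_don <- 6; cells_per <- 40
  donor <- rep(sprintf("D%d", 1:n_don), each = cells_per)
  loy <- rep(rep(c(TRUE, FALSE), each = cells_per / 2), n_don)
  m <- matrix(rep(c(1L, 0L), length.out = n_don * cells_per), ncol = 1,
              dimnames = list(sprintf("c%03d", seq_along(donor)), "g1"))
  cells <- tibble::tibble(barcode = rownames(m), donor = donor, loy = loy)
  r2 <- proportion_pseudobulk(m, cells, min_pct = 0, min_effect = 0)
  expect_equal(r2$p[r2$gene == "g1"], 1)
})

test_that("pseudobulk recovers a planted detection-proportion shift", {
  set.seed(57)
  n_don <- 30; cells_per <- 60
  donor <- rep(sprintf("D%02d", 1:n_don), each = cells_per)
  loy <- rep_len(c(TRUE, FALSE), n_don * cells_per)
  p_det <- ifelse(loy, 0.17, 0.30)
  m <- cbind(hit = rbinom(n_don * cells_per, 1, p_det),
             null = rbinom(n_don * cells_per, 1, 0.25))
  rownames(m) <- sprintf("c%04d", seq_along(donor))
  cells <- tibble::tibble(barcode = rownames(m), donor = donor, loy = loy)
  r <- proportion_pseudobulk(m, cells, min_pct = 0, min_effect = 0.05)
  hit <- r[r$gene == "hit", ]
  expect_lt(hit$p_adj, 0.05)
  expect_lt(hit$effect, 0)
  expect_lt(abs(hit$mean_prop_loy - 0.17), 0.05)
})

test_that("XIST exclusion counts cells and errors when the feature is absent", {
  m <- cbind(XIST = c(0L, 2L, 0L, 1L), other = 1L)
  rownames(m) <- sprintf("c%d", 1:4)
  cells <- tibble::tibble(barcode = rownames(m))
  out <- exclude_xist_cells(m, cells)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_removed"), 2)

  none <- cbind(XIST = rep(0L, 4), other = 1L)
  expect_equal(nrow(exclude_xist_cells(none, cells)), 4)
  expect_error(exclude_xist_cells(m[, "other", drop = FALSE], cells), "XIST")
})

test_that("planted escape-gene effects survive XIST-cell exclusion", {
  tr <- sim_truth(xist_weight = 0.3)
  don <- simulate_donors(16, tr, seed = 58)
  cells <- simulate_cells(don, tr, 500, seed = 58, celltypes = "NK")
  cells$loy <- cells$loy_true
  ex <- simulate_expression(cells, tr, seed = 58)
  dz <- drop_zero_cells(ex$matrix, cells)
  kept <- exclude_xist_cells(dz$matrix, dz$cells)
  expect_gt(attr(kept, "n_removed"), 0)
  sub <- attr(kept, "keep")
  mat <- dz$matrix
  mat$counts <- mat$counts[sub, , drop = FALSE]
  mat$barcodes <- mat$barcodes[sub]
  norm <- log_normalize(mat)
  de <- hurdle_de(norm, kept, min_pct = 0, min_lfc = 0)
  esc <- de[de$gene %in% c("KDM6A", "DDX3X", "KDM5C", "ZRSR2", "RPS4X",
                           "EIF1AX", "JPX"), ]
  expect_gt(median(esc$avg_log2fc), 0)
  expect_true(any(esc$p_adj < 0.05))
})
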