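test_that("dip statistic matches the brute-force unimodal-CDF oracle", {
  for (case in dip_oracle_cases) {
    # the exported wrapper enforces n >= 4; the engine itself is exact for
    # the tiny n = 2, 3 reference cases too
    got <- if (length(case$x) >= 4) dip_statistic(case$x)
           else loytraj:::dip_stat_cpp(case$x)
    expect_equal(got, case$dip, tolerance = 1e-7)
  }
})

test_that("dip statistic respects its theoretical bounds on random inputs", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(4:300, 1)
    x <- switch(sample(3, 1), rnorm(n), runif(n),
                c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 5)))
    d <- dip_statistic(x)
    expect_gte(d, 1 / (2 * n) - 1e-12)
    expect_lte(d, 0.25 + 1e-12)
  }
  expect_error(dip_statistic(c(1, 2, 3)), "4 finite")
})

test_that("dip statistic is location-scale invariant", {
  set.seed(62)
  for (i in 1:40) {
    x <- c(rnorm(40), rnorm(40, 4))
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 5)
    expect_equal(dip_statistic(a * x + b), dip_statistic(x), tolerance = 1e-12)
  }
})

test_that("dip test is calibrated on unimodal data and powered on mixtures", {
  # calibration: unimodal Gaussian, n = 500
  rej <- vapply(rep_seeds(630, 60), function(s) {
    set.seed(s)
    dip_test(rnorm(500), n_boot = 100, seed = s)$p < 0.05
  }, TRUE)
  expect_lte(mean(rej), 0.10)

  # power: well-separated balanced mixture, n = 500
  pow <- vapply(rep_seeds(660, 30), function(s) {
    set.seed(s)
    v <- c(rnorm(250), rnorm(250, 10))
    dip_test(v, n_boot = 100, seed = s)$p < 0.01
  }, TRUE)
  expect_gte(mean(pow), 0.95)
})

test_that("dip test handles subsets, determinism, and degenerate input", {
  v <- c(rep(0, 200), rnorm(150, 3), rnorm(150, 9))
  both <- dip_test(v, n_boot = 100, seed = 7, subset = "both")
  expect_equal(both$subset, c("all", "nonzero"))
  expect_lt(both$p[both$subset == "nonzero"], 0.05)
  again <- dip_test(v, n_boot = 100, seed = 7, subset = "both")
  expect_identical(both$p, again$p)

  deg <- dip_test(rep(2, 50), n_boot = 100, seed = 1)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  expect_error(dip_test(rnorm(10), n_boot = 10), "n_boot")
})

test_that("X-gene classification partitions genes with PAR overriding curation", {
  ann <- annotate_gene_regions(tibble::tibble(
    gene = c("CD99", "KDM6A", "XIST", "TIMP1", "PRKX", "NOCLASS", "SLC25A6"),
    chromosome = "X",
    start = c(1500000, 7e7, 7.3e7, 4.7e7, 3.6e6, 5e7, 1.4e6),
    end = c(1550000, 7.01e7, 7.31e7, 4.71e7, 3.65e6, 5.01e7, 1.45e6),
    xci_class = c("escape", "escape", "variable", "inactive", "variable",
                  NA, "inactive")))
  cls <- classify_x_genes(ann)
  expect_equal(cls$gene_class[cls$gene == "CD99"], "PAR")      # PAR1 by coords
  expect_equal(cls$gene_class[cls$gene == "SLC25A6"], "PAR")   # curated overridden
  expect_equal(cls$gene_class[cls$gene == "KDM6A"], "nonPAR-escape")
  expect_equal(cls$gene_class[cls$gene == "TIMP1"], "nonPAR-inactive")
  expect_equal(cls$gene_class[cls$gene == "NOCLASS"], "nonPAR-unclassified")
  # partition: exactly one class per gene
  expect_equal(nrow(cls), 7)
  expect_false(anyNA(cls$gene_class))
})

test_that("direction summary counts and gene-level roll-up are consistent", {
  classes <- tibble::tibble(
    gene = sprintf("E%02d", 1:26),
    gene_class = "nonPAR-escape")
  # 23 up-only, 2 both, 1 down-only across two cell types
  mk <- function(ct, up, down) tibble::tibble(
    gene = classes$gene, cell_type = ct,
    avg_log2fc = ifelse(seq_len(26) %in% up, 0.5,
                        ifelse(seq_len(26) %in% down, -0.5, 0.01)),
    p_adj = ifelse(seq_len(26) %in% c(up, down), 0.001, 0.9))
  # 23 genes up-only (in either type), 2 up in one type and down in the
  # other, 1 down-only
  de <- dplyr::bind_rows(
    mk("mono-c", up = 1:25, down = 26),
    mk("NK", up = 1:20, down = c(24, 25)))
  res <- escape_direction_stats(de, classes)
  ru <- res$rollup
  expect_equal(ru$up_only, 23)
  expect_equal(ru$both, 2)
  expect_equal(ru$down_only, 1)
  # per-class counts: up + down + rest = tested
  s <- res$summary
  expect_true(all(s$n_up + s$n_down <= s$n_genes_tested))
  expect_true(all(s$pct_up + s$pct_down <= 100 + 1e-9))
})

test_that("all-null DE tables give alpha-level direction noise", {
  set.seed(63)
  classes <- tibble::tibble(gene = sprintf("G%03d", 1:200),
                            gene_class = rep(c("nonPAR-escape",
                                               "nonPAR-inactive"), 100))
  de <- tidyr::expand_grid(gene = classes$gene,
                           cell_type = c("a", "b", "c", "d")) |>
    dplyr::mutate(avg_log2fc = rnorm(dplyr::n()),
                  p_adj = pmin(runif(dplyr::n()) * 4, 1))
  res <- escape_direction_stats(de, classes)
  expect_true(all(res$summary$pct_up < 15))
  expect_true(all(res$tests$p > 0.05))
})

test_that("planted escape upregulation yields pct_up > pct_down everywhere", {
  tr <- sim_truth()
  don <- simulate_donors(20, tr, seed = 64)
  cells <- simulate_cells(don, tr, 600, seed = 64,
                          celltypes = c("NK", "NKr"))
  cells$loy <- cells$loy_true
  ex <- simulate_expression(cells, tr, seed = 64)
  dz <- drop_zero_cells(ex$matrix, cells)
  norm <- log_normalize(dz$matrix)
  de <- dplyr::bind_rows(
    hurdle_de(norm, dz$cells, cell_type = "NK", min_pct = 0, min_lfc = 0),
    hurdle_de(norm, dz$cells, cell_type = "NKr", min_pct = 0, min_lfc = 0))
  classes <- classify_x_genes(simulated_gene_annotation())
  res <- escape_direction_stats(de, classes)
  esc <- dplyr::filter(res$summary, gene_class == "nonPAR-escape")
  expect_gt(nrow(esc), 0)
  # planted direction: never more down than up, and strictly more up in the
  # well-powered (LOY-rich) subset
  expect_true(all(esc$pct_up >= esc$pct_down))
  expect_gt(max(esc$pct_up - esc$pct_down), 0)
})

test_that("XIST detection contrast reports exact percentages and planted signals", {
  m <- matrix(0L, 20000, 2, dimnames = list(sprintf("c%05d", 1:20000),
                                            c("XIST", "other")))
  cells <- tibble::tibble(barcode = rownames(m),
                          cell_type = "mono-c",
                          loy = rep(c(TRUE, FALSE), each = 10000))
  m[1:6, "XIST"] <- 1L            # 6 of 10,000 LOY cells
  m[10001:10002, "XIST"] <- 1L    # 2 of 10,000 non-LOY cells
  r <- xist_detection_contrast(m, cells)
  expect_equal(r$pct_loy, 0.06)
  expect_equal(r$pct_nonloy, 0.02)

  # zero XIST everywhere: percentages 0, test skipped
  m0 <- m; m0[, "XIST"] <- 0L
  r0 <- xist_detection_contrast(m0, cells)
  expect_equal(r0$pct_loy, 0)
  expect_true(is.na(r0$p))

  # planted LOY-specific activation in one cell type only
  tr <- sim_truth(xist_weight = 0.25)
  don <- simulate_donors(10, tr, seed = 65)
  cellsS <- simulate_cells(don, tr, 400, seed = 65)
  cellsS$loy <- cellsS$loy_true
  ex <- simulate_expression(cellsS, tr, seed = 65)
  rs <- xist_detection_contrast(ex$matrix, cellsS)
  expect_true(all(rs$pct_loy >= rs$pct_nonloy))
  expect_lt(min(rs$p, na.rm = TRUE), 0.05)
})
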