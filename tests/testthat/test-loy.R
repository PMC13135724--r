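test_that("the dual-source zero-read rule decides LOY exactly", {
  cells <- tibble::tibble(barcode = c("c1", "c2", "c3", "c4"),
                          donor = "D1", sex = "M",
                          umi_total = c(100L, 100L, 100L, 0L))
  a <- tiny_cgm(matrix(c(0, 0, 7, 0), ncol = 1), barcodes = cells$barcode,
                genes = "MSY1")
  b <- tiny_cgm(matrix(c(0, 1, 0, 0), ncol = 1), barcodes = cells$barcode,
                genes = "MSY1")
  out <- call_loy(a, b, cells, msy_genes = "MSY1")
  expect_identical(out$loy, c(TRUE, FALSE, FALSE, NA))  # 0/0, 0/1, 7/0, no UMI
  expect_equal(attr(out, "n_uninformative"), 1L)

  expect_error(call_loy(a, b, cells, msy_genes = character()), "empty")
  cells2 <- dplyr::mutate(cells, barcode = paste0("zz", barcode))
  expect_error(call_loy(a, b, cells2, msy_genes = "MSY1"), "absent")
})

test_that("female cells keep MSY totals but receive no LOY flag", {
  cells <- tibble::tibble(barcode = c("m1", "f1"), donor = c("D1", "D2"),
                          sex = c("M", "F"), umi_total = c(50L, 50L))
  a <- tiny_cgm(matrix(c(0, 3), ncol = 1), barcodes = cells$barcode,
                genes = "MSY1")
  out <- call_loy(a, a, cells, msy_genes = "MSY1")
  expect_identical(out$loy, c(TRUE, NA))
  expect_equal(out$msy_total_a[2], 3L)
})

test_that("donor prevalence reproduces printed percentages and the 10% boundary", {
  mk <- function(donor, n, k) tibble::tibble(
    barcode = paste0(donor, seq_len(n)), donor = donor,
    loy = c(rep(TRUE, k), rep(FALSE, n - k)))
  cells <- dplyr::bind_rows(mk("hi", 2621, 1416), mk("lo", 1123, 10),
                            mk("edge", 1000, 100))
  prev <- donor_prevalence(cells)
  expect_equal(prev$pct_loy[prev$donor == "hi"], 100 * 1416 / 2621)
  expect_equal(round(prev$pct_loy[prev$donor == "hi"], 1), 54.0)
  expect_true(prev$expanded[prev$donor == "hi"])
  expect_equal(round(prev$pct_loy[prev$donor == "lo"], 2), 0.89)
  expect_false(prev$expanded[prev$donor == "lo"])
  expect_true(prev$expanded[prev$donor == "edge"])  # exactly 10.0% counts

  # cohort bookkeeping: per-donor LOY counts add up
  expect_equal(sum(prev$n_loy), sum(cells$loy))
})

test_that("UMI filter removes exactly the bottom fraction and keeps drop 0 identity", {
  cells <- tibble::tibble(barcode = as.character(1:100), umi_total = 1:100)
  out <- umi_sensitivity_filter(cells, 0.10)
  expect_equal(nrow(out), 90)
  expect_true(all(out$umi_total > 10))
  expect_equal(attr(out, "cutoff"), 10)

  same <- umi_sensitivity_filter(cells, 0)
  expect_equal(nrow(same), 100)
  expect_error(umi_sensitivity_filter(cells, 1), "drop_fraction")
})

test_that("age association survives UMI filtering when LOY is depth-independent", {
  co <- called_cohort(n_donors = 120, n_cells = 120, seed = 21)
  co$cells$loy <- co$cells$loy_true   # isolate the filter from call noise
  base <- age_association(donor_prevalence(co$cells), co$donors)
  for (f in c(0.05, 0.10, 0.15)) {
    filt <- umi_sensitivity_filter(co$cells, f)
    aa <- age_association(donor_prevalence(filt), co$donors)
    expect_lt(abs(aa$slope - base$slope) / abs(base$slope), 0.10)
  }
})

test_that("empirical logit keeps 0% and 100% donors finite", {
  prev <- tibble::tibble(donor = c("a", "b", "c", "d"),
                         n_cells = c(50L, 50L, 50L, 50L),
                         n_loy = c(0L, 50L, 10L, 5L),
                         pct_loy = c(0, 100, 20, 10))
  don <- tibble::tibble(donor = c("a", "b", "c", "d"),
                        age = c(30, 50, 70, 90), sex = "M")
  aa <- age_association(prev, don)
  expect_true(is.finite(aa$slope))
  expect_true(all(is.finite(aa$fit$model$elogit)))
  expect_s3_class(tidy(aa), "tbl_df")
  expect_equal(glance(aa)$n_donors, 4)
})

test_that("permuted donor ages give uniform association p-values", {
  co <- called_cohort(n_donors = 60, n_cells = 100, seed = 23)
  co$cells$loy <- co$cells$loy_true
  prev <- donor_prevalence(co$cells)
  set.seed(99)
  ps <- vapply(1:200, function(i) {
    don <- co$donors
    don$age <- sample(don$age)
    age_association(prev, don)$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("SNP concordance recovers exact and tuned correlations", {
  don <- tibble::tibble(donor = as.character(1:30), age = 50, sex = "M",
                        snp_clonal_fraction = seq(0.02, 0.6, length.out = 30))
  prev <- tibble::tibble(donor = don$donor, n_cells = 100L,
                         n_loy = 1:30, pct_loy = 100 * don$snp_clonal_fraction)
  r <- snp_concordance(prev, don)
  expect_equal(r$r, 1)
  expect_lt(r$p, 1e-10)

  don3 <- tibble::tibble(donor = c("a", "b", "c"), age = 50, sex = "M",
                         snp_clonal_fraction = c(0.3, 0.2, 0.1))
  prev3 <- tibble::tibble(donor = don3$donor, n_cells = 10L, n_loy = 1:3,
                          pct_loy = c(10, 20, 30))
  expect_equal(snp_concordance(prev3, don3)$r, -1)

  # sigma chosen so the population correlation is 0.75
  set.seed(31)
  x <- rnorm(100, 0.2, 0.1)
  sigma <- 0.1 * sqrt(1 / 0.75^2 - 1)
  donT <- tibble::tibble(donor = as.character(1:100), age = 50, sex = "M",
                         snp_clonal_fraction = pmin(pmax(x + rnorm(100, 0, sigma), 0), 1))
  prevT <- tibble::tibble(donor = donT$donor, n_cells = 100L,
                          n_loy = round(100 * pmin(pmax(x, 0), 1)),
                          pct_loy = 100 * x)
  rT <- snp_concordance(prevT, donT)
  expect_lt(abs(rT$r - 0.75), 0.1)
})

test_that("per-cell-type concordance applies BH across cell types", {
  co <- called_cohort(n_donors = 40, n_cells = 150, seed = 25)
  prev <- donor_prevalence(co$cells, by_cell_type = TRUE)
  r <- snp_concordance(prev, co$donors, by_cell_type = TRUE)
  expect_true(all(r$p_adj >= r$p | is.na(r$p)))
  expect_gt(nrow(r), 3)
})

test_that("mCA/LOY independence: exact table values and type-I control", {
  balanced <- tibble::tibble(
    loy_snp = rep(c(TRUE, FALSE), each = 100),
    mca_flag = rep(c(TRUE, FALSE, TRUE, FALSE), each = 50))
  r <- mca_loy_independence(balanced)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  skew <- tibble::tibble(
    loy_snp = rep(c(TRUE, FALSE), each = 100),
    mca_flag = c(rep(TRUE, 90), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 90)))
  r2 <- mca_loy_independence(skew)
  # brute-force Pearson formula oracle on the 2x2 table
  tab <- matrix(c(90, 10, 10, 90), 2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r2$statistic, sum((tab - e)^2 / e))
  expect_lt(r2$p, 0.001)

  set.seed(55)
  rej <- vapply(1:1000, function(i) {
    d <- tibble::tibble(loy_snp = runif(80) < 0.3, mca_flag = runif(80) < 0.2)
    if (any(rowSums(table(d$loy_snp, d$mca_flag)) == 0)) return(NA)
    mca_loy_independence(d)$p < 0.05
  }, TRUE)
  expect_lte(mean(rej, na.rm = TRUE), 0.06)

  empty <- tibble::tibble(loy_snp = c(TRUE, TRUE), mca_flag = c(TRUE, FALSE))
  r3 <- mca_loy_independence(empty)
  expect_true(r3$fallback)
})

test_that("age-association slope is invariant to pool relabeling", {
  co <- called_cohort(n_donors = 80, n_cells = 80, seed = 27)
  prev <- donor_prevalence(co$cells)
  a1 <- age_association(prev, co$donors)
  don2 <- co$donors
  don2$pool <- factor(don2$pool, labels = sample(LETTERS[1:10]))
  a2 <- age_association(prev, don2)
  expect_equal(a1$slope, a2$slope, tolerance = 1e-10)
})
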