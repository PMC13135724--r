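# shared builders for the test suite; everything is generated in code

# deterministic, non-colliding per-replicate seeds
rep_seeds <- function(base, n) as.integer(base + seq_len(n) * 131)

# truth with every planted effect switched off
null_truth <- function() {
  sim_truth(gene_effects = default_gene_effects()[0, ],
            xist_weight = 0,
            quantile_log_or = c("mono" = 0, "B" = 0, "NK" = 0,
                                "CD8" = 0, "CD4Treg" = 0))
}

# drop all-zero cells before log-normalizing a small simulated panel
drop_zero_cells <- function(mat, cells) {
  keep <- Matrix::rowSums(mat$counts) > 0
  mat$counts <- mat$counts[keep, , drop = FALSE]
  mat$barcodes <- mat$barcodes[keep]
  list(matrix = mat, cells = cells[keep, , drop = FALSE], keep = keep)
}

# tiny dense cell_gene_matrix from a plain matrix
tiny_cgm <- function(m, barcodes = NULL, genes = NULL) {
  if (is.null(barcodes)) barcodes <- sprintf("bc%02d", seq_len(nrow(m)))
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(ncol(m)))
  cell_gene_matrix(m, barcodes = barcodes,
                   features = tibble::tibble(gene = genes))
}

# simulated cohort where calls can be compared with truth
called_cohort <- function(n_donors = 15, n_cells = 80, seed = 11,
                          truth = sim_truth(), celltypes = NULL) {
  don <- simulate_donors(n_donors, truth, seed)
  cells <- simulate_cells(don, truth, n_cells, seed, celltypes = celltypes)
  msy <- simulate_msy_counts(cells, truth, seed)
  cells <- call_loy(msy$a, msy$b, cells, msy_genes = paste0("MSY", 1:8))
  list(donors = don, cells = cells, msy = msy, truth = truth)
}
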