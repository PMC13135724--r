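#' Read a sparse cell-by-gene UMI count matrix
#'
#' Reads either an MTX triplet directory (`matrix.mtx` + `barcodes.tsv` +
#' `features.tsv`, cells in rows) or a dense TSV with barcodes in the first
#' column and gene identifiers as column names.  The returned object is
#' validated: counts must be non-negative integers and the sidecar files must
#' match the matrix dimensions.
#'
#' @param path directory containing the MTX triplet, or a TSV file.
#' @param format `"mtx"` or `"tsv"`.
#' @param source_label tag recording the counting source (e.g. `"cellranger"`,
#'   `"velocyto"`); kept alongside the matrix because the LOY call requires
#'   agreement of two independent sources.
#' @return A `cell_gene_matrix`: list with `counts` (sparse dgCMatrix,
#'   cells x genes, dimnames barcodes x genes), `barcodes`, `features`
#'   (tibble with column `gene`, plus `symbol` if present) and `source_label`.
#' @seealso [write_counts_matrix()]
#' @export
read_counts_matrix <- function(path, format = c("mtx", "tsv"),
                               source_label = NULL) {
  format <- match.arg(format)
  if (format == "mtx") {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    barcodes <- readLines(file.path(path, "barcodes.tsv"))
    feat_raw <- readr::read_tsv(file.path(path, "features.tsv"),
                                col_names = FALSE, show_col_types = FALSE,
                                progress = FALSE)
    features <- tibble::tibble(gene = as.character(feat_raw[[1]]))
    if (ncol(feat_raw) > 1) features$symbol <- as.character(feat_raw[[2]])
    if (nrow(m) != length(barcodes))
      stop("barcodes file has ", length(barcodes), " entries but matrix has ",
           nrow(m), " rows")
    if (ncol(m) != nrow(features))
      stop("features file has ", nrow(features), " entries but matrix has ",
           ncol(m), " columns")
    counts <- methods::as(m, "CsparseMatrix")
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    barcodes <- as.character(tab[[1]])
    counts <- methods::as(Matrix::Matrix(as.matrix(tab[, -1]), sparse = TRUE),
                          "CsparseMatrix")
    features <- tibble::tibble(gene = colnames(tab)[-1])
  }
  cell_gene_matrix(counts, barcodes, features, source_label)
}

#' Construct and validate a cell-by-gene matrix object
#'
#' @param counts sparse or dense matrix, cells in rows.
#' @param barcodes unique cell identifiers (defaults to rownames).
#' @param features tibble with a `gene` column (defaults to colnames).
#' @param source_label optional counting-source tag.
#' @export
cell_gene_matrix <- function(counts, barcodes = rownames(counts),
                             features = NULL, source_label = NULL) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (is.null(features)) {
    gn <- colnames(counts) %||% sprintf("gene%04d", seq_len(ncol(counts)))
    features <- tibble::tibble(gene = gn)
  }
  if (is.character(features)) features <- tibble::tibble(gene = features)
  if (is.null(barcodes)) stop("barcodes are required")
  barcodes <- as.character(barcodes)
  if (length(barcodes) != nrow(counts))
    stop("barcodes length (", length(barcodes), ") != number of rows (",
         nrow(counts), ")")
  if (nrow(features) != ncol(counts))
    stop("features length (", nrow(features), ") != number of columns (",
         ncol(counts), ")")
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != floor(v))))
    stop("counts must be non-negative integers")
  dimnames(counts) <- list(barcodes, features$gene)
  structure(list(counts = counts, barcodes = barcodes, features = features,
                 source_label = source_label),
            class = "cell_gene_matrix")
}

#' @export
print.cell_gene_matrix <- function(x, ...) {
  cat(sprintf("<cell_gene_matrix> %d cells x %d genes, %d non-zero%s\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x),
              if (!is.null(x$source_label)) paste0(" [", x$source_label, "]")
              else ""))
  invisible(x)
}

#' @export
dim.cell_gene_matrix <- function(x) dim(x$counts)

#' Write a cell-by-gene matrix as an MTX triplet
#'
#' Inverse of [read_counts_matrix()]; `read(write(x))` reproduces the counts
#' exactly.
#'
#' @param x a `cell_gene_matrix`.
#' @param path output directory (created if missing).
#' @export
write_counts_matrix <- function(x, path) {
  stopifnot(inherits(x, "cell_gene_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
  writeLines(x$barcodes, file.path(path, "barcodes.tsv"))
  feat <- x$features
  if (!"symbol" %in% names(feat)) feat$symbol <- feat$gene
  readr::write_tsv(feat[, c("gene", "symbol")],
                   file.path(path, "features.tsv"), col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read a gene annotation table and resolve genomic regions
#'
#' Reads a TSV with columns `gene`, `chromosome`, `start`, `end` and
#' optionally `xci_class`, then fills `par_region` (PAR1/PAR2/nonPAR on the
#' sex chromosomes, NA elsewhere) and `is_msy` (membership in the
#' male-specific region of chromosome Y) from the configured coordinate
#' spans.  Coordinates are 1-based inclusive; MSY membership requires the
#' gene to lie entirely inside the MSY span (genes straddling a boundary are
#' excluded, favouring specificity).
#'
#' @param path TSV file.
#' @param config a [loy_config()].
#' @return tibble with the input columns plus `par_region` and `is_msy`.
#' @export
read_gene_annotation <- function(path, config = loy_config()) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  annotate_gene_regions(ann, config)
}

#' Resolve PAR and MSY membership on an annotation table
#'
#' @param annotation data frame with `gene`, `chromosome`, `start`, `end`,
#'   optional `xci_class`.
#' @inheritParams read_gene_annotation
#' @export
annotate_gene_regions <- function(annotation, config = loy_config()) {
  req <- c("gene", "chromosome", "start", "end")
  miss <- setdiff(req, names(annotation))
  if (length(miss)) stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  ann <- tibble::as_tibble(annotation)
  if (any(ann$start > ann$end))
    stop("annotation has start > end for: ",
         paste(ann$gene[ann$start > ann$end], collapse = ", "))
  if ("xci_class" %in% names(ann)) {
    ok <- c("escape", "inactive", "variable", "unclassified", NA)
    bad <- setdiff(unique(ann$xci_class), ok)
    if (length(bad)) stop("unknown xci_class token(s): ", paste(bad, collapse = ", "))
  } else {
    ann$xci_class <- NA_character_
  }
  chr <- sub("^chr", "", ann$chromosome)
  sex_chr <- chr %in% c("X", "Y")
  within <- function(s, e, lo, hi) s >= lo & e <= hi
  par1 <- within(ann$start, ann$end, config$par1_start, config$par1_end)
  par2 <- within(ann$start, ann$end, config$par2_start, config$par2_end)
  ann$par_region <- dplyr::case_when(
    sex_chr & par1 ~ "PAR1",
    sex_chr & par2 ~ "PAR2",
    sex_chr ~ "nonPAR",
    TRUE ~ NA_character_
  )
  ann$is_msy <- chr == "Y" &
    within(ann$start, ann$end, config$msy_start, config$msy_end)
  ann
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then tab-separated member genes.
#' Duplicate members within a set are dropped; an empty file yields an empty
#' collection.
#'
#' @param path GMT file.
#' @return tibble with columns `set_name`, `description` and list-column
#'   `genes`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble::tibble(set_name = character(), description = character(),
                          genes = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
  out <- tibble::tibble(
    set_name = vapply(parts, `[[`, "", 1),
    description = vapply(parts, `[[`, "", 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
  if (anyDuplicated(out$set_name)) stop("duplicate set names in GMT file")
  out
}

#' Write gene sets in GMT format
#'
#' @param sets tibble as returned by [read_gene_sets()].
#' @param path output file.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_name[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-donor covariate table
#'
#' TSV with columns `donor`, `age`, `sex`, `pool`, genotype PCs `pc1..pc10`,
#' `rs2887399_dosage` (additive T-allele count, 0/1/2), and optionally
#' `snp_clonal_fraction` and `mca_flag`.  Basic range checks are applied.
#'
#' @param path TSV file.
#' @export
read_donor_table <- function(path) {
  don <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_donor_table(don)
}

validate_donor_table <- function(don) {
  don <- tibble::as_tibble(don)
  if (!all(c("donor", "age", "sex") %in% names(don)))
    stop("donor table needs at least donor, age, sex")
  if (any(don$age <= 0)) stop("ages must be positive")
  if ("rs2887399_dosage" %in% names(don)) {
    d <- don$rs2887399_dosage
    if (!all(d[!is.na(d)] %in% 0:2)) stop("rs2887399_dosage must be 0, 1 or 2")
  }
  if ("snp_clonal_fraction" %in% names(don)) {
    f <- don$snp_clonal_fraction
    if (any(f[!is.na(f)] < 0 | f[!is.na(f)] > 1))
      stop("snp_clonal_fraction must lie in [0, 1]")
  }
  don
}
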