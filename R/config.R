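#' Pipeline configuration
#'
#' Returns the resolved configuration shared by all pipeline stages: the
#' genomic spans that define the male-specific region of chromosome Y (MSY)
#' and the two pseudoautosomal regions (GRCh38, 1-based inclusive), and the
#' thresholds used downstream.  Values can be overridden by arguments or by a
#' flat `key = value` text file (see [read_loy_config()]).
#'
#' The MSY span (2,781,480-56,887,902 on chrY) is the read-count territory
#' whose absence defines LOY per cell.  PAR1/PAR2 spans are the
#' assembly-standard GRCh38 coordinates on chromosome X; genes there have two
#' copies in normal male cells and are classified separately from non-PAR X
#' genes.
#'
#' @param ... named overrides of individual configuration entries.
#' @return A named list of class `loy_config`.
#' @examples
#' cfg <- loy_config()
#' cfg$msy_start
#' @export
loy_config <- function(...) {
  cfg <- list(
    # MSY on chromosome Y, 1-based inclusive
    msy_start = 2781480L,
    msy_end = 56887902L,
    # pseudoautosomal regions on chromosome X (GRCh38)
    par1_start = 10001L,
    par1_end = 2781479L,
    par2_start = 155701383L,
    par2_end = 156030895L,
    # donor-level clonality
    expanded_pct = 10,
    snp_detection_floor = 0.02,
    # differential expression filters
    de_min_pct = 0.01,
    de_min_lfc = 0.1,
    pseudobulk_min_effect = 0.1,
    # preprocessing
    scale_factor = 1e4,
    n_hvg = 500L,
    n_pcs = 30L,
    scale_clip = 10,
    qc_z_low = -3,
    qc_mito_z_high = 2,
    # trajectory
    n_quantiles = 6L,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "loy_config")
}

#' Read configuration overrides from a flat key/value file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values are parsed as numeric where possible.
#'
#' @param path file path.
#' @param base configuration to override, defaults to [loy_config()].
#' @return A `loy_config` list.
#' @export
read_loy_config <- function(path, base = loy_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    base[[key]] <- if (!is.na(num)) num else val
  }
  class(base) <- "loy_config"
  base
}

#' @export
print.loy_config <- function(x, ...) {
  cat("<loy_config>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
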