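#' Fit pseudotime by iterative principal-curve projection
#'
#' Fits a smooth one-dimensional curve through a low-dimensional embedding
#' (any 2-D or low-D representation; if more than three columns are given,
#' the first two principal components are used), projects every cell onto
#' the curve, and uses arc-length position as pseudotime.  The curve is
#' refined iteratively: order cells by current pseudotime, smooth each
#' coordinate along that ordering into a polyline, re-project.  The result
#' is oriented so that the designated start cluster has lower mean
#' pseudotime than the end cluster, then scaled to `[0, 1]`.  The procedure is
#' deterministic and invariant to the order of the input rows.
#'
#' @param embedding matrix/data frame of cell coordinates.
#' @param clusters per-cell labels containing `start_label` and `end_label`.
#' @param start_label,end_label cluster labels anchoring the orientation.
#' @param n_bins number of polyline vertices.
#' @param n_iter refinement iterations.
#' @return numeric pseudotime in `[0, 1]`, one value per row of `embedding`.
#' @export
fit_pseudotime <- function(embedding, clusters, start_label, end_label,
                           n_bins = 50, n_iter = 8) {
  emb <- as.matrix(embedding)
  if (nrow(emb) < 10) stop("need at least 10 cells")
  if (identical(start_label, end_label)) stop("start and end labels are identical")
  if (!all(c(start_label, end_label) %in% clusters))
    stop("start/end label not present in clusters")
  if (ncol(emb) > 3) emb <- prcomp(emb, rank. = 2)$x
  emb <- scale(emb)
  n_bins <- max(5, min(n_bins, floor(nrow(emb) / 4)))
  refine <- function(lambda) {
    sse <- Inf
    for (it in seq_len(n_iter)) {
      br <- quantile(lambda, probs = seq(0, 1, length.out = n_bins + 1))
      br[1] <- -Inf; br[n_bins + 1] <- Inf
      bin <- cut(lambda, unique(br), labels = FALSE, include.lowest = TRUE)
      verts <- apply(emb, 2, function(cc) tapply(cc, bin, mean))
      verts <- verts[stats::complete.cases(verts), , drop = FALSE]
      if (nrow(verts) >= 5) {  # light smoothing of the polyline
        sm <- apply(verts, 2, function(v)
          stats::filter(v, rep(1 / 3, 3), sides = 2))
        keep <- stats::complete.cases(sm)
        verts[keep, ] <- sm[keep, ]
      }
      pr <- project_polyline(emb, verts)
      lambda <- pr$lambda
      sse <- sum(pr$d2)
    }
    list(lambda = lambda, sse = sse)
  }
  # a symmetric manifold can make PC1 orthogonal to the curve parameter, so
  # the fit is started from PC1 and from each raw coordinate and the
  # projection-error-minimising solution wins (all starts are deterministic)
  inits <- c(list(as.numeric(emb %*% prcomp(emb, rank. = 1)$rotation[, 1])),
             lapply(seq_len(ncol(emb)), function(j) emb[, j]))
  fits <- lapply(inits, function(l0)
    if (sd(l0) == 0) list(lambda = l0, sse = Inf) else refine(l0))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "sse"))]]
  lambda <- best$lambda
  m_start <- mean(lambda[clusters == start_label])
  m_end <- mean(lambda[clusters == end_label])
  if (m_start > m_end) lambda <- -lambda
  (lambda - min(lambda)) / max(max(lambda) - min(lambda), .Machine$double.eps)
}

# arc-length position of each point's nearest projection onto the polyline
project_polyline <- function(pts, verts) {
  nv <- nrow(verts)
  seg <- diff(verts)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  best_d2 <- rep(Inf, nrow(pts))
  best_lambda <- rep(0, nrow(pts))
  for (s in seq_len(nv - 1)) {
    d <- seg[s, ]; l2 <- sum(d^2)
    if (l2 == 0) next
    rel <- sweep(pts, 2, verts[s, ])
    t <- pmin(pmax(as.numeric(rel %*% d) / l2, 0), 1)
    proj_d2 <- rowSums((rel - outer(t, d))^2)
    upd <- proj_d2 < best_d2
    best_d2[upd] <- proj_d2[upd]
    best_lambda[upd] <- cum[s] + t[upd] * seg_len[s]
  }
  list(lambda = best_lambda, d2 = best_d2)
}

#' Stratify pseudotime into equal-count quantile bins
#'
#' Splits cells into `k` bins of near-equal size, labelled 1..k in order of
#' increasing pseudotime.  Ties at bin boundaries are resolved by the stable
#' (pseudotime, barcode) lexicographic order, so the labelling is
#' deterministic and a monotone relabelling of pseudotime leaves the bins
#' unchanged.
#'
#' @param pseudotime numeric vector.
#' @param k number of quantile bins.
#' @param barcode optional tie-breaking identifier.
#' @return integer bin labels 1..k.
#' @export
bin_quantiles <- function(pseudotime, k = loy_config()$n_quantiles,
                          barcode = NULL) {
  n <- length(pseudotime)
  if (n < k) stop("fewer observations than bins")
  ord <- if (is.null(barcode)) order(pseudotime) else order(pseudotime, barcode)
  lab <- integer(n)
  lab[ord] <- ceiling(seq_len(n) * k / n)
  lab
}

# Firth-style penalized logistic regression (Jeffreys prior); used as the
# fallback when maximum likelihood separates.
firth_logistic <- function(X, y, max_iter = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    W <- sqrt(w)
    XW <- X * W
    XtWX <- crossprod(XW)
    inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((XW %*% inv) * XW)
    U <- as.numeric(crossprod(X, y - p + h * (0.5 - p)))
    step <- inv %*% U
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.numeric(X %*% beta); p <- plogis(eta)
  W <- sqrt(p * (1 - p)); XtWX <- crossprod(X * W)
  se <- sqrt(diag(solve(XtWX)))
  list(coefficients = setNames(beta, colnames(X)),
       se = setNames(se, colnames(X)))
}

#' Logistic model of LOY status versus trajectory position
#'
#' Fits `loy ~ predictor (+ covariates)` by logistic regression, where the
#' predictor is either the pseudotime quantile treated as a single numeric
#' slope (odds ratio per quantile step) or a binary subtype indicator.
#' Model variants: `univariate`; `multivariate` adds age, sequencing pool
#' and ten genotype PCs; `multivariate_genotype` additionally adjusts for
#' the rs2887399 additive dosage.  Wald confidence intervals; on perfect
#' separation the fit falls back to Firth-penalized likelihood and is
#' flagged.
#'
#' @param cells tibble with `loy` and either `quantile` or the subtype
#'   column, plus `donor`.
#' @param donors donor covariate table (for the multivariate variants).
#' @param predictor `"quantile"` or the name of a logical/binary column.
#' @param model one of `"univariate"`, `"multivariate"`,
#'   `"multivariate_genotype"`.
#' @param lineage optional label recorded in the result.
#' @param strata label recorded in the result (e.g. an age stratum).
#' @return one-row tibble: `lineage`, `predictor`, `model_variant`,
#'   `or_estimate`, `ci_low`, `ci_high`, `p`, `p_adj` (NA until adjusted via
#'   [adjust_results()]), `n_cells`, `strata`, `separation`.
#' @export
loy_position_model <- function(cells, donors = NULL, predictor = "quantile",
                               model = c("univariate", "multivariate",
                                         "multivariate_genotype"),
                               lineage = NA_character_, strata = "all") {
  model <- match.arg(model)
  df <- dplyr::filter(cells, !is.na(.data$loy))
  pred <- df[[predictor]]
  if (is.logical(pred) || is.factor(pred)) pred <- as.numeric(as.factor(pred)) - 1
  df$.pred <- as.numeric(pred)
  covars <- character()
  if (model != "univariate") {
    if (is.null(donors)) stop("multivariate models need the donor table")
    df <- dplyr::inner_join(
      df, donors[, intersect(names(donors),
                             c("donor", "age", "pool", paste0("pc", 1:10),
                               "rs2887399_dosage"))],
      by = "donor")
    covars <- intersect(c("age", "pool", paste0("pc", 1:10)), names(df))
    covars <- covars[vapply(covars, function(cv)
      dplyr::n_distinct(df[[cv]]) > 1, TRUE)]
    if (model == "multivariate_genotype") {
      if (!"rs2887399_dosage" %in% names(df))
        stop("rs2887399_dosage missing from donor table")
      covars <- c(covars, "rs2887399_dosage")
    }
  }
  fml <- as.formula(paste("loy ~ .pred",
                          if (length(covars))
                            paste("+", paste(covars, collapse = " + "))
                          else ""))
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  sm0 <- summary(fit)$coefficients
  separated <- !fit$converged || !".pred" %in% rownames(sm0) ||
    abs(sm0[".pred", "Estimate"]) > 15 || sm0[".pred", "Std. Error"] > 10
  if (separated) {
    X <- model.matrix(fml, df)
    fl <- firth_logistic(X, as.numeric(df$loy))
    est <- fl$coefficients[".pred"]; se <- fl$se[".pred"]
    p <- 2 * pnorm(-abs(est / se))
  } else {
    sm <- summary(fit)$coefficients
    est <- sm[".pred", "Estimate"]; se <- sm[".pred", "Std. Error"]
    p <- sm[".pred", "Pr(>|z|)"]
  }
  tibble::tibble(
    lineage = lineage,
    predictor = if (predictor == "quantile") "quantile" else "binary_subtype",
    model_variant = model,
    or_estimate = exp(est),
    ci_low = exp(est - 1.96 * se),
    ci_high = exp(est + 1.96 * se),
    p = unname(p),
    p_adj = NA_real_,
    n_cells = nrow(df),
    strata = strata,
    separation = separated
  )
}

#' Apply family-wise multiple-testing adjustment to a result table
#'
#' @param results tibble with a `p` column.
#' @param method `p.adjust` method (`"BH"` for trajectory families,
#'   `"bonferroni"` for DE).
#' @export
adjust_results <- function(results, method = "BH") {
  dplyr::mutate(results, p_adj = p.adjust(.data$p, method))
}

#' Age-stratified trajectory models
#'
#' Refits [loy_position_model()] independently in two donor strata defined
#' by the median donor age (computed over donors, not cells).
#'
#' @inheritParams loy_position_model
#' @param median_age stratum boundary; default median donor age.
#' @return two-row tibble with `strata` labels `"age<median"` and
#'   `"age>=median"`.
#' @export
age_stratified_models <- function(cells, donors, predictor = "quantile",
                                  model = "multivariate",
                                  lineage = NA_character_,
                                  median_age = NULL) {
  if (is.null(median_age)) median_age <- median(donors$age)
  young <- donors$donor[donors$age < median_age]
  old <- donors$donor[donors$age >= median_age]
  if (!length(young) || !length(old)) stop("empty age stratum")
  fit_stratum <- function(ids, label) {
    sub <- dplyr::filter(cells, .data$donor %in% ids)
    if (!any(sub$loy, na.rm = TRUE)) {
      warning("stratum ", label, " has no LOY cells")
      return(tibble::tibble(lineage = lineage, predictor = predictor,
                            model_variant = model, or_estimate = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p = NA_real_, p_adj = NA_real_,
                            n_cells = nrow(sub), strata = label,
                            separation = NA))
    }
    loy_position_model(sub, donors, predictor, model, lineage, strata = label)
  }
  dplyr::bind_rows(fit_stratum(young, "age<median"),
                   fit_stratum(old, "age>=median"))
}
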