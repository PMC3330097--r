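# Vegetative-stage PCA and its downstream analyses: PC trajectories, OLS
# regression of PC scores on weather/development covariates with VIF
# screening, extreme-loading gene selection, gene-PC correlation, and
# template matching of expression profiles.

#' Restrict a matrix to vegetative samples and shared significant genes
#'
#' @param mat genes x samples matrix.
#' @param samples sample table aligned with columns.
#' @param sig_genes named list of significant-gene vectors, one per
#'   accession (from time-course screening); the intersection is kept.
#' @return submatrix: intersection genes x vegetative samples.
#' @export
vegetative_subset <- function(mat, samples, sig_genes) {
  samples <- validate_samples(samples)
  stopifnot(ncol(mat) == nrow(samples))
  shared <- Reduce(intersect, sig_genes)
  shared <- intersect(rownames(mat), shared)
  if (!length(shared))
    stop_parse("no genes significant in every accession")
  keep <- samples$flowering_status == "vegetative"
  mat[shared, samples$sample_id[keep], drop = FALSE]
}

#' Per-accession, per-day mean PC score trajectories
#'
#' @param pc `pc_model` whose scores align with `samples` rows.
#' @param samples sample table.
#' @param axes PC axes to summarize.
#' @return data.frame accession, day, axis, mean, se (`NA` for a single
#'   replicate).
#' @export
pc_trajectories <- function(pc, samples, axes = 1:5) {
  stopifnot(inherits(pc, "pc_model"), nrow(pc$scores) == nrow(samples))
  axes <- axes[axes <= ncol(pc$scores)]
  key <- interaction(samples$accession, samples$day, drop = TRUE, sep = "|")
  rows <- list()
  for (ax in axes) {
    sc <- pc$scores[, ax]
    agg <- lapply(split(seq_along(sc), key), function(ix) {
      c(mean = mean(sc[ix]),
        se = if (length(ix) > 1L) stats::sd(sc[ix]) / sqrt(length(ix))
             else NA_real_,
        n = length(ix),
        day = samples$day[ix[1L]])
    })
    acc <- vapply(split(as.character(samples$accession), key), `[`, "",
                  1L)
    rows[[length(rows) + 1L]] <- data.frame(
      accession = acc,
      day = vapply(agg, `[[`, 0, "day"),
      axis = ax,
      mean = vapply(agg, `[[`, 0, "mean"),
      se = vapply(agg, `[[`, 0, "se"),
      n = vapply(agg, `[[`, 0, "n"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$axis, out$accession, out$day), ]
}

#' Variance inflation factors
#'
#' VIF_j = 1/(1 - R2_j) from regressing covariate j on the others;
#' equivalently the diagonal of the inverse correlation matrix. A singular
#' (perfectly collinear) covariate set yields `Inf` for the offending
#' columns.
#'
#' @param X numeric covariate matrix (columns = covariates).
#' @return named numeric vector of VIFs (>= 1).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  R <- stats::cor(X)
  out <- tryCatch(diag(solve(R)), error = function(e) NULL)
  if (is.null(out)) {
    # singular: compute per-covariate R2 by least squares on the rest
    out <- vapply(seq_len(ncol(X)), function(j) {
      fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
      r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1L))
  }
  stats::setNames(pmax(out, 1), colnames(X))
}

#' Regress PC scores on environment and development covariates
#'
#' Ordinary least squares per PC axis: score ~ tmax + precipitation + rln +
#' rd + age by default (minimum temperature is excluded as collinear with
#' maximum temperature; add it via `covariates` if wanted). Rows with
#' missing covariates are dropped (count reported via message). VIFs are
#' computed on the complete-case covariate matrix and covariates at or above
#' `vif_threshold` are flagged. BH correction runs across all covariate
#' p-values of the requested axes.
#'
#' @param pc `pc_model` aligned with `design` rows.
#' @param design joined design table (needs the covariate columns).
#' @param axes PC axes to regress (default first five).
#' @param covariates covariate column names.
#' @param vif_threshold collinearity flag threshold (conventionally 10).
#' @return object of class `pc_regression`: data.frame with axis, term,
#'   beta, se, t, p, q, significant, plus per-axis `adj_r2` and per-covariate
#'   `vif`/`vif_flag` attributes (also exposed as columns).
#' @export
regress_pc_on_covariates <- function(pc, design, axes = 1:5,
                                     covariates = c("tmax", "precipitation",
                                                    "rln", "rd", "age"),
                                     vif_threshold = 10) {
  stopifnot(inherits(pc, "pc_model"), nrow(pc$scores) == nrow(design))
  miss <- setdiff(covariates, names(design))
  if (length(miss))
    stop_parse("design lacks covariate(s): %s", paste(miss, collapse = ", "))
  axes <- axes[axes <= ncol(pc$scores)]
  X <- as.matrix(design[, covariates, drop = FALSE])
  ok <- stats::complete.cases(X)
  if (any(!ok)) message(sprintf("dropping %d sample(s) with NA covariates",
                                sum(!ok)))
  X <- X[ok, , drop = FALSE]
  if (nrow(X) < length(covariates) + 2L)
    stop_parse("fewer samples (%d) than covariates + intercept", nrow(X))
  cov_names <- make.unique(covariates)
  colnames(X) <- cov_names
  vifs <- stats::setNames(vif(X), covariates)
  rows <- list()
  for (ax in axes) {
    y <- pc$scores[ok, ax]
    dat <- as.data.frame(X)
    dat$.y <- y
    fit <- stats::lm(.y ~ ., data = dat)
    sm <- summary(fit)
    co <- sm$coefficients
    est <- stats::coef(fit)[cov_names]  # NA for aliased covariates
    names(est) <- covariates
    sev <- tv <- pv <- stats::setNames(rep(NA_real_, length(covariates)),
                                       covariates)
    present <- intersect(cov_names, rownames(co))
    ix <- match(present, cov_names)
    sev[ix] <- co[present, 2L]; tv[ix] <- co[present, 3L]
    pv[ix] <- co[present, 4L]
    rows[[length(rows) + 1L]] <- data.frame(
      axis = ax, term = covariates, beta = est, se = sev, t = tv, p = pv,
      adj_r2 = sm$adj.r.squared, vif = unname(vifs),
      vif_flag = unname(vifs) >= vif_threshold,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- NA_real_
  has_p <- !is.na(out$p)
  out$q[has_p] <- bh_fdr(out$p[has_p])
  out$significant <- !is.na(out$q) & out$q <= 0.05
  class(out) <- c("pc_regression", "data.frame")
  out
}

#' Genes with extreme loadings on one PC axis
#'
#' Ranks genes by loading and takes the bottom and top
#' `ceiling(alpha_per_tail * n)` (deterministic: ties broken by rank order).
#' With n = 8954 and 2.5% per tail this selects 448 genes.
#'
#' @param loadings named numeric vector: one axis' loadings.
#' @param alpha_per_tail tail fraction, in (0, 0.5).
#' @return character vector of 2 * ceiling(alpha * n) gene ids: lower tail
#'   (ascending) then upper tail (descending).
#' @export
extreme_loading_genes <- function(loadings, alpha_per_tail = 0.025) {
  if (alpha_per_tail <= 0 || alpha_per_tail >= 0.5)
    stop_parse("alpha_per_tail must be in (0, 0.5)")
  n <- length(loadings)
  k <- ceiling(alpha_per_tail * n)
  ord <- order(loadings)
  ids <- names(loadings)
  c(ids[ord[seq_len(k)]], ids[rev(ord)[seq_len(k)]])
}

#' Correlation of one gene's expression with one PC axis
#'
#' Pearson correlation of the gene's per-sample expression with the
#' per-sample PC scores.
#'
#' @param mat genes x samples matrix aligned with the PC scores.
#' @param pc `pc_model`.
#' @param gene gene id.
#' @param axis PC axis.
#' @return list with `r`, `r_squared`, `p` (two-sided); all `NA` for a
#'   zero-variance gene.
#' @export
gene_pc_correlation <- function(mat, pc, gene, axis = 1L) {
  stopifnot(gene %in% rownames(mat), axis <= ncol(pc$scores),
            ncol(mat) == nrow(pc$scores))
  x <- mat[gene, ]
  if (stats::sd(x) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_))
  ct <- stats::cor.test(x, pc$scores[, axis])
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value)
}

#' Template matching of expression profiles
#'
#' Finds all genes whose per-timepoint mean profile has absolute Pearson
#' correlation with a template gene's profile at or above a threshold. The
#' threshold is interpreted on the |r| scale by default; with
#' `threshold_is_r2 = TRUE` an r-squared value (e.g. the 0.47
#' temperature-variance benchmark) is converted via sqrt.
#'
#' @param profiles genes x timepoints matrix (see [profile_matrix()]).
#' @param template_gene row id of the template.
#' @param min_abs_r threshold in (0, 1].
#' @param threshold_is_r2 treat `min_abs_r` as an r-squared.
#' @return object of class `template_match`: `template`, `threshold`
#'   (on the |r| scale), `matches` (data.frame gene, r with |r| >=
#'   threshold, template included with r = 1).
#' @export
template_match <- function(profiles, template_gene, min_abs_r = 0.7,
                           threshold_is_r2 = FALSE) {
  if (min_abs_r <= 0 || min_abs_r > 1)
    stop_parse("threshold must lie in (0, 1]")
  if (!template_gene %in% rownames(profiles))
    stop_parse("template gene '%s' not in profiles", template_gene)
  thr <- if (threshold_is_r2) sqrt(min_abs_r) else min_abs_r
  r <- as.numeric(stats::cor(t(profiles), profiles[template_gene, ]))
  names(r) <- rownames(profiles)
  r[template_gene] <- 1
  hit <- !is.na(r) & abs(r) >= thr
  structure(list(template = template_gene, threshold = thr,
                 matches = data.frame(gene = names(r)[hit], r = r[hit],
                                      row.names = NULL,
                                      stringsAsFactors = FALSE)),
            class = "template_match")
}

#' @export
print.template_match <- function(x, ...) {
  cat(sprintf("template_match: %d genes with |r| >= %.3f to template '%s'\n",
              nrow(x$matches), x$threshold, x$template))
  invisible(x)
}
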