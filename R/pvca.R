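# Principal variance components analysis: PCA of the expression matrix, a
# variance-component model (all factors random) fit to each retained PC score
# vector, and eigenvalue-weighted averaging of the per-PC component
# proportions into factor-level shares of total transcriptional variance.

#' Principal component decomposition of an expression matrix
#'
#' Samples are observations, genes variables; genes are centered by default
#' (log2-scale data is not rescaled).
#'
#' @param mat genes x samples matrix.
#' @param center center each gene.
#' @param scale scale each gene to unit variance.
#' @return object of class `pc_model`: `loadings` (genes x PCs), `scores`
#'   (samples x PCs), `eigenvalues` (score variances, non-increasing),
#'   `proportion` (eigenvalue shares), `center`, `scale`.
#' @export
fit_pca <- function(mat, center = TRUE, scale = FALSE) {
  validate_expression(mat)
  if (ncol(mat) < 2L) stop_parse("PCA needs >= 2 samples")
  p <- stats::prcomp(t(mat), center = center, scale. = scale)
  eig <- p$sdev^2
  structure(list(loadings = p$rotation,
                 scores = p$x,
                 eigenvalues = eig,
                 proportion = if (sum(eig) > 0) eig / sum(eig) else eig,
                 center = p$center, scale = p$scale),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("pc_model: %d components; leading proportions %s\n",
              length(x$eigenvalues),
              paste(sprintf("%.3f", utils::head(x$proportion, 3L)),
                    collapse = ", ")))
  invisible(x)
}

# Identical-grouping check: two nominally different factors that induce the
# same partition of samples are confounded and cannot be separated.
check_confounding <- function(groupings, factors) {
  if (length(factors) < 2L) return(invisible(NULL))
  for (i in seq_len(length(factors) - 1L)) {
    for (j in seq(i + 1L, length(factors))) {
      gi <- as.integer(factor(groupings[[i]]))
      gj <- as.integer(factor(groupings[[j]]))
      if (all(tapply(gj, gi, function(v) length(unique(v))) == 1L) &&
          all(tapply(gi, gj, function(v) length(unique(v))) == 1L))
        stop_parse("factors '%s' and '%s' induce identical groupings",
                   factors[i], factors[j])
    }
  }
  invisible(NULL)
}

term_grouping <- function(design, term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
  miss <- setdiff(parts, names(design))
  if (length(miss))
    stop_parse("model factor(s) not in design: %s", paste(miss, collapse = ", "))
  if (length(parts) == 1L) factor(design[[parts]])
  else interaction(design[parts], drop = TRUE, sep = ":")
}

#' Variance-component estimates for one score vector
#'
#' All model terms are treated as random intercepts and estimated by REML
#' (`lme4`); negative estimates cannot occur. Factors reduced to a single
#' level in the data contribute a zero component (with a warning). A
#' method-of-moments fallback handles degenerate responses REML cannot fit
#' (for example zero residual variance).
#'
#' @param y numeric response (e.g. one PC's scores).
#' @param design data.frame of sample covariates, rows aligned with `y`.
#' @param factors character vector of term labels; interactions as `"A:B"`.
#' @return named numeric vector of variance components: one per factor plus
#'   `"residual"`.
#' @export
estimate_components <- function(y, design, factors) {
  stopifnot(length(y) == nrow(design))
  groupings <- lapply(factors, term_grouping, design = design)
  names(groupings) <- factors
  usable <- vapply(groupings, nlevels, integer(1L)) > 1L
  if (any(!usable))
    warning(sprintf("constant factor(s) given zero component: %s",
                    paste(factors[!usable], collapse = ", ")), call. = FALSE)
  check_confounding(groupings[usable], factors[usable])
  out <- stats::setNames(numeric(length(factors) + 1L),
                         c(factors, "residual"))
  if (stats::var(y) == 0 || !any(usable)) {
    out["residual"] <- stats::var(y)
    return(out)
  }
  dat <- as.data.frame(groupings[usable])
  names(dat) <- paste0("g", seq_len(sum(usable)))
  dat$y <- y
  form <- stats::as.formula(paste(
    "y ~", paste(sprintf("(1 | %s)", names(dat)[names(dat) != "y"]),
                 collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(form, data = dat, REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   check.conv.grad = "ignore",
                   check.conv.hess = "ignore")))),
    error = function(e) NULL)
  if (is.null(fit)) {
    comp <- mom_components(y, groupings[usable])
  } else {
    vc <- as.data.frame(lme4::VarCorr(fit))
    comp <- stats::setNames(vc$vcov, vc$grp)
    names(comp)[names(comp) == "Residual"] <- "residual"
  }
  for (k in seq_along(factors)) {
    if (usable[k]) {
      gname <- paste0("g", cumsum(usable)[k])
      out[factors[k]] <- comp[[gname]] %||% 0
    }
  }
  out["residual"] <- comp[["residual"]] %||% 0
  pmax(out, 0)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# Crude method-of-moments fallback: per factor, (MS_between - MS_within)/n0
# truncated at zero, with the pooled within-group MS of the finest crossing
# as the residual. Used only when REML fails (e.g. zero-noise scores).
mom_components <- function(y, groupings) {
  n <- length(y)
  fine <- interaction(as.data.frame(groupings), drop = TRUE)
  mse <- if (nlevels(fine) < n) {
    sum(tapply(y, fine, function(v) sum((v - mean(v))^2))) / (n - nlevels(fine))
  } else 0
  comp <- lapply(groupings, function(g) {
    a <- nlevels(g)
    msb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2)) /
      (a - 1L)
    n0 <- (n - sum(tapply(y, g, length)^2) / n) / (a - 1L)
    max(0, (msb - mse) / n0)
  })
  c(stats::setNames(unlist(comp), paste0("g", seq_along(groupings))),
    residual = mse)
}

#' Principal variance components analysis
#'
#' Retains all PCs whose eigenvalue share exceeds `min_eig_prop`, fits the
#' random-effects model to each retained PC's scores, normalizes each PC's
#' components (factors plus residual) to proportions, and averages the
#' proportions across PCs weighted by eigenvalue share among retained PCs
#' (`weights = "retained"`) or among all PCs (`"all"`).
#'
#' @param mat genes x samples matrix.
#' @param design sample covariate data.frame aligned with columns of `mat`.
#' @param factors model term labels, e.g.
#'   `c("accession", "flowering_status", "accession:flowering_status")`.
#' @param min_eig_prop retain PCs with eigenvalue share >= this.
#' @param max_pc optional cap on the number of retained PCs.
#' @param weights eigenvalue normalization, `"retained"` (default) or
#'   `"all"`.
#' @return object of class `variance_decomp`: named proportions (factors +
#'   residual) summing to 1, with attributes `per_pc` (component matrix),
#'   `eigenvalues` and `retained`.
#' @export
pvca <- function(mat, design, factors,
                 min_eig_prop = 1e-6, max_pc = NULL,
                 weights = c("retained", "all")) {
  weights <- match.arg(weights)
  pc <- fit_pca(mat)
  retain <- which(pc$proportion >= min_eig_prop)
  if (!is.null(max_pc)) retain <- utils::head(retain, max_pc)
  if (!length(retain)) stop_parse("no principal components retained")
  per_pc <- vapply(retain, function(i) {
    estimate_components(pc$scores[, i], design, factors)
  }, numeric(length(factors) + 1L))
  per_pc <- matrix(per_pc, ncol = length(retain),
                   dimnames = list(c(factors, "residual"),
                                   paste0("PC", retain)))
  props <- apply(per_pc, 2L, function(v) {
    if (sum(v) > 0) v / sum(v) else c(rep(0, length(v) - 1L), 1)
  })
  eig <- pc$eigenvalues[retain]
  w <- if (weights == "retained") eig / sum(eig)
       else pc$eigenvalues[retain] / sum(pc$eigenvalues)
  agg <- drop(props %*% w)
  agg <- agg / sum(agg)
  structure(agg, class = "variance_decomp",
            per_pc = per_pc, eigenvalues = eig, retained = retain)
}

#' @export
print.variance_decomp <- function(x, ...) {
  cat("variance_decomp (proportion of transcriptional variance):\n")
  v <- unclass(x); attributes(v) <- list(names = names(x))
  print(round(v, 4L))
  invisible(x)
}

# Tertile (or n-bin) discretization of a continuous covariate for use as a
# random grouping factor. Quantile bins; if ties collapse the bins, falls
# back to a zero/positive split (rain series), then to a constant factor.
bin_covariate <- function(x, n_bins = 3L) {
  brks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(brks) >= 3L) {
    return(cut(x, breaks = brks, include.lowest = TRUE))
  }
  if (length(unique(x)) >= 2L) return(factor(x > min(x),
                                             labels = c("low", "high")))
  factor(rep("all", length(x)))
}

#' Environmental PVCA
#'
#' Variance decomposition with the developmental/environmental model: age,
#' flowering status, minimum and maximum daily temperature, and daily
#' precipitation. Age enters as a categorical day factor; continuous weather
#' covariates are discretized into `n_bins` quantile bins (tertiles by
#' default) so they can be treated as random effects.
#'
#' @param mat genes x samples matrix.
#' @param design joined design table (see [join_design()]).
#' @param n_bins bins for continuous covariates.
#' @param by_accession decompose each accession's samples separately.
#' @param ... passed to [pvca()].
#' @return a `variance_decomp`, or a named list of them when
#'   `by_accession = TRUE`.
#' @export
pvca_environmental <- function(mat, design, n_bins = 3L,
                               by_accession = FALSE, ...) {
  if (by_accession) {
    accs <- levels(factor(design$accession))
    out <- lapply(accs, function(a) {
      keep <- design$accession == a
      pvca_environmental(mat[, keep, drop = FALSE],
                         design[keep, , drop = FALSE],
                         n_bins = n_bins, by_accession = FALSE, ...)
    })
    return(stats::setNames(out, accs))
  }
  d <- design
  d$age <- factor(d$day)
  d$tmin_bin <- bin_covariate(d$tmin, n_bins)
  d$tmax_bin <- bin_covariate(d$tmax, n_bins)
  d$precip_bin <- bin_covariate(d$precipitation, n_bins)
  res <- pvca(mat, d,
              factors = c("age", "flowering_status", "tmin_bin", "tmax_bin",
                          "precip_bin"), ...)
  names(res)[names(res) == "tmin_bin"] <- "tmin"
  names(res)[names(res) == "tmax_bin"] <- "tmax"
  names(res)[names(res) == "precip_bin"] <- "precipitation"
  res
}
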