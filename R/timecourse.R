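# Gene-wise factorial ANOVA (sequential sums of squares, vectorized across
# genes) and the spline time-course test: natural cubic spline of day versus
# an intercept-only fit, significance from permutation of sample-day labels.

# residual sums of squares of every gene (rows of Y are samples) under the
# least-squares fit to model matrix X
rss_all <- function(Y, X) {
  q <- qr(X)
  colSums(qr.resid(q, Y)^2)
}

#' Gene-wise factorial ANOVA
#'
#' Fits the factorial model term by term (sequential sums of squares, terms
#' in the order given) to every gene and reports per-term F statistics,
#' p-values and BH q-values (adjusted within term across genes). Genes with
#' zero variance get p = 1 by convention so the output covers every gene.
#'
#' @param mat genes x samples matrix.
#' @param design sample covariates aligned with columns of `mat`.
#' @param terms model terms in fitting order, e.g.
#'   `c("accession", "flowering_status", "accession:flowering_status")`.
#' @return data.frame with columns gene, term, statistic, df, p, q.
#' @export
anova_per_gene <- function(mat, design,
                           terms = c("accession", "flowering_status",
                                     "accession:flowering_status")) {
  validate_expression(mat)
  stopifnot(ncol(mat) == nrow(design))
  Y <- t(mat)
  n <- nrow(Y)
  forms <- vapply(seq_along(terms), function(k) {
    paste("~", paste(terms[seq_len(k)], collapse = " + "))
  }, character(1L))
  Xs <- c(list(matrix(1, n, 1L)),
          lapply(forms, function(f) stats::model.matrix(stats::as.formula(f), design)))
  ranks <- vapply(Xs, function(X) qr(X)$rank, integer(1L))
  df_res <- n - ranks[length(ranks)]
  if (df_res <= 0L)
    stop_parse("saturated model: no residual degrees of freedom")
  rss <- vapply(Xs, function(X) rss_all(Y, X), numeric(ncol(Y)))
  rss <- matrix(rss, ncol = length(Xs))
  rss_full <- rss[, length(Xs)]
  ms_res <- rss_full / df_res
  # zero-variance genes: total SS numerically zero relative to the data scale
  zero_var <- rss[, 1L] <= 1e-12 * pmax(1, colSums(Y^2))
  out <- vector("list", length(terms))
  for (k in seq_along(terms)) {
    df_k <- ranks[k + 1L] - ranks[k]
    ss_k <- rss[, k] - rss[, k + 1L]
    f <- (ss_k / df_k) / ms_res
    p <- stats::pf(f, df_k, df_res, lower.tail = FALSE)
    p[!is.finite(f) | zero_var] <- 1
    f[!is.finite(f) | zero_var] <- NA_real_
    out[[k]] <- data.frame(gene = rownames(mat), term = terms[k],
                           statistic = f, df = df_k, p = p,
                           q = bh_fdr(p), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment: q_i = min over j >= i (p sorted ascending) of
#' p_(j) * m / j, mapped back to input order.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_parse("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Spline time-course significance test
#'
#' Per gene, compares a natural cubic spline of day (df basis columns, knots
#' at interior day quantiles) against an intercept-only model with the
#' F-like statistic ((RSS0 - RSS1)/(df1 - df0)) / (RSS1/(n - df1)).
#' Significance comes from permuting the sample-day assignment (`n_perm`
#' permutations shared across genes), so p-values have resolution
#' 1/(n_perm + 1); BH q-values are attached. Zero-variance genes get p = 1.
#'
#' @param mat genes x samples matrix.
#' @param design sample covariates with a `day` column, aligned to columns.
#' @param df spline degrees of freedom (>= 2 distinct days more than df).
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @return data.frame gene, statistic, rss0, rss1, df0, df1, p, q; attribute
#'   `coefficients` holds the fitted spline coefficients (genes x columns).
#' @export
spline_timecourse_test <- function(mat, design, df = 3L, n_perm = 199L,
                                   seed = 1L) {
  validate_expression(mat)
  stopifnot(ncol(mat) == nrow(design))
  if (n_perm < 99L) stop_parse("n_perm must be >= 99")
  day <- design$day
  n_days <- length(unique(day))
  if (n_days < df + 2L)
    stop_parse(paste("only %d distinct days for a df=%d spline basis;",
                     "use df <= %d"), n_days, df, n_days - 2L)
  n <- ncol(mat)
  Y <- t(mat)
  X1 <- cbind(1, splines::ns(day, df = df))
  q1 <- qr(X1)
  df1 <- q1$rank
  rss1 <- colSums(qr.resid(q1, Y)^2)
  rss0 <- colSums(scale(Y, center = TRUE, scale = FALSE)^2)
  stat <- ((rss0 - rss1) / (df1 - 1L)) / (rss1 / (n - df1))
  coefs <- qr.coef(q1, Y)

  set.seed(seed)
  exceed <- integer(nrow(mat))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    rss1p <- colSums(qr.resid(q1, Y[perm, , drop = FALSE])^2)
    statp <- ((rss0 - rss1p) / (df1 - 1L)) / (rss1p / (n - df1))
    exceed <- exceed + (statp >= stat & is.finite(statp) & is.finite(stat))
  }
  p <- (1L + exceed) / (n_perm + 1L)
  p[!is.finite(stat)] <- 1
  res <- data.frame(gene = rownames(mat), statistic = stat,
                    rss0 = rss0, rss1 = rss1,
                    df0 = 1L, df1 = df1,
                    p = p, q = bh_fdr(p), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "coefficients") <- t(coefs)
  res
}

#' Select significant genes from a test-result table
#'
#' @param results data.frame carrying `gene` and `q` columns.
#' @param q_threshold inclusive q-value threshold.
#' @return character vector of genes with q <= threshold, order preserved.
#' @export
select_significant <- function(results, q_threshold) {
  stopifnot(all(c("gene", "q") %in% names(results)))
  results$gene[results$q <= q_threshold]
}
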