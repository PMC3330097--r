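# Independent brute-force oracles and tiny fixture builders. The oracles
# intentionally use the most literal (slow) formulation of each definition
# so they stay independent of the package implementations they check.

# BH step-up straight from the definition: q_i = min_{j >= i} p_(j) * m / j
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in i:m) cand <- min(cand, p[ord[j]] * m / j)
    q[ord[i]] <- min(cand, 1)
  }
  q
}

# silhouette widths by the O(n^2) double loop
brute_silhouette <- function(X, labels) {
  n <- nrow(X)
  labels <- as.integer(factor(labels))
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), 0))
    b <- Inf
    for (k in setdiff(unique(labels), labels[i])) {
      members <- which(labels == k)
      b <- min(b, mean(vapply(members, function(j) d(i, j), 0)))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# hypergeometric upper tail by exhaustive enumeration of all draws
brute_hyper_tail <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K universe elements are set members
  mean(hits >= k)
}

# sequential (type I) per-gene ANOVA via stats::lm / stats::anova
oracle_anova_gene <- function(y, design, terms) {
  f <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  design$y <- y
  as.data.frame(stats::anova(stats::lm(f, data = design)))
}

# balanced two-way random model: expected-mean-squares closed form
ems_components_2x2 <- function(y, A, B) {
  a <- nlevels(factor(A)); b <- nlevels(factor(B))
  n <- length(y) / (a * b)
  gm <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, interaction(A, B), mean)
  ssa <- b * n * sum((mA - gm)^2)
  ssb <- a * n * sum((mB - gm)^2)
  cell <- interaction(A, B)
  sse <- sum((y - mAB[cell])^2)
  ssab <- sum((y - gm)^2) - ssa - ssb - sse
  msa <- ssa / (a - 1); msb <- ssb / (b - 1)
  msab <- ssab / ((a - 1) * (b - 1))
  mse <- sse / (a * b * n - a * b)
  c(A = (msa - msab) / (b * n), B = (msb - msab) / (a * n),
    AB = (msab - mse) / n, residual = mse)
}

# tiny expression fixture with deterministic values
tiny_expr <- function(n_genes = 3L, n_samples = 2L) {
  matrix(seq_len(n_genes * n_samples) + 0.5, n_genes, n_samples,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

tiny_samples <- function(accessions = c("A1", "A2"), days = c(10, 13),
                         reps = 3L) {
  d <- expand.grid(replicate = seq_len(reps), day = days,
                   accession = accessions, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$flowering_status <- ifelse(d$day == max(days), "flowering", "vegetative")
  d$sample_id <- sprintf("%s_d%02d_r%d", d$accession, d$day, d$replicate)
  validate_samples(d[, c("sample_id", "accession", "day", "flowering_status",
                         "replicate")])
}

tiny_env <- function(days = 1:20) {
  data.frame(day = days, tmax = 20 + sin(days), tmin = 8 + cos(days),
             precipitation = ifelse(days %% 5 == 0, 10, 0))
}
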