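# K-means clustering of standardized time profiles, silhouette widths, the
# worst-cluster silhouette stopping rule for choosing K, per-cluster
# environmental variance attribution, and hypergeometric gene-set enrichment.

#' Replicate-mean expression profiles, standardized per gene
#'
#' Per gene, the vector of replicate-mean expression at each
#' (accession, day, flowering status) timepoint, then standardized to mean 0
#' and sd 1 per gene (so Euclidean distance is equivalent, up to scale, to
#' correlation distance). Zero-variance genes are dropped with a message.
#'
#' @param mat genes x samples matrix.
#' @param samples sample table aligned with columns.
#' @param gene_list optional subset of genes (e.g. time-significant genes).
#' @param accession optional single accession to restrict to.
#' @param standardize standardize rows (default TRUE).
#' @return genes x timepoints matrix; column order accession, then day.
#' @export
profile_matrix <- function(mat, samples, gene_list = NULL, accession = NULL,
                           standardize = TRUE) {
  samples <- validate_samples(samples)
  stopifnot(ncol(mat) == nrow(samples))
  mat <- mat[, samples$sample_id, drop = FALSE]
  if (!is.null(accession)) {
    keep <- samples$accession %in% accession
    mat <- mat[, keep, drop = FALSE]
    samples <- samples[keep, , drop = FALSE]
  }
  if (!is.null(gene_list)) {
    miss <- setdiff(gene_list, rownames(mat))
    if (length(miss))
      stop_parse("gene(s) not in matrix: %s",
                 paste(utils::head(miss, 5L), collapse = ", "))
    mat <- mat[gene_list, , drop = FALSE]
  }
  ord <- order(samples$accession, samples$day, samples$flowering_status)
  samples <- samples[ord, , drop = FALSE]
  mat <- mat[, ord, drop = FALSE]
  key <- interaction(samples$accession, samples$day, samples$flowering_status,
                     drop = TRUE, sep = "|", lex.order = TRUE)
  key <- factor(key, levels = unique(as.character(key)))
  groups <- split(seq_len(nrow(samples)), key)
  prof <- vapply(groups, function(ix) rowMeans(mat[, ix, drop = FALSE]),
                 numeric(nrow(mat)))
  prof <- matrix(prof, nrow = nrow(mat),
                 dimnames = list(rownames(mat), names(groups)))
  if (standardize) {
    sds <- apply(prof, 1L, stats::sd)
    flat <- sds == 0 | !is.finite(sds)
    if (any(flat)) {
      message(sprintf("dropping %d zero-variance gene(s): %s", sum(flat),
                      paste(utils::head(rownames(prof)[flat], 5L),
                            collapse = ", ")))
      prof <- prof[!flat, , drop = FALSE]
      sds <- sds[!flat]
    }
    prof <- (prof - rowMeans(prof)) / sds
  }
  prof
}

#' Silhouette widths for a labeled set of profiles
#'
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)) with a(i) the mean Euclidean
#' distance to the other members of i's cluster and b(i) the smallest mean
#' distance to any other cluster. Members of singleton clusters get s = 0.
#'
#' @param profiles numeric matrix, rows are items.
#' @param labels integer/factor cluster labels, one per row.
#' @return numeric vector of silhouette widths in \[-1, 1\].
#' @export
silhouette_widths <- function(profiles, labels) {
  labels <- as.integer(factor(labels))
  stopifnot(length(labels) == nrow(profiles))
  if (length(unique(labels)) < 2L)
    stop_parse("silhouettes need >= 2 clusters")
  D <- as.matrix(stats::dist(profiles))
  ks <- sort(unique(labels))
  sizes <- tabulate(labels)
  # mean distance from every point to every cluster (own cluster excludes self)
  md <- vapply(ks, function(k) {
    s <- rowSums(D[, labels == k, drop = FALSE])
    own <- labels == k
    s[own] <- s[own] / max(1L, sizes[k] - 1L)
    s[!own] <- s[!own] / sizes[k]
    s
  }, numeric(nrow(D)))
  a <- md[cbind(seq_len(nrow(D)), labels)]
  md[cbind(seq_len(nrow(D)), labels)] <- Inf
  b <- apply(md, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[labels] == 1L] <- 0
  s[!is.finite(s)] <- 0
  s
}

#' K-means clustering with silhouette diagnostics
#'
#' Best-of-restarts K-means (within-cluster sum of squares criterion) on
#' standardized profiles; deterministic under `seed`.
#'
#' @param profiles genes x timepoints matrix (see [profile_matrix()]).
#' @param K number of clusters (2 <= K <= n rows).
#' @param n_restarts random restarts.
#' @param seed RNG seed.
#' @return object of class `gene_clustering`: `labels` (named integer),
#'   `K`, `silhouette` (per gene), `cluster_silhouette` (per-cluster means),
#'   `worst` (minimum per-cluster mean), `tot_withinss`.
#' @export
kmeans_cluster <- function(profiles, K, n_restarts = 10L, seed = 1L) {
  if (K < 2L || K > nrow(profiles))
    stop_parse("K must be in [2, n_genes]")
  set.seed(seed)
  km <- stats::kmeans(profiles, centers = K, nstart = n_restarts,
                      iter.max = 100L)
  sil <- silhouette_widths(profiles, km$cluster)
  csil <- tapply(sil, km$cluster, mean)
  structure(list(labels = stats::setNames(km$cluster, rownames(profiles)),
                 K = K,
                 silhouette = stats::setNames(sil, rownames(profiles)),
                 cluster_silhouette = csil,
                 worst = min(csil),
                 tot_withinss = km$tot.withinss),
            class = "gene_clustering")
}

#' @export
print.gene_clustering <- function(x, ...) {
  cat(sprintf("gene_clustering: K = %d, %d genes, worst-cluster silhouette %.3f\n",
              x$K, length(x$labels), x$worst))
  invisible(x)
}

#' Silhouette-guided selection of the number of clusters
#'
#' Scans K upward and picks the smallest K at which the mean silhouette of
#' the worst cluster is <= 0 and stays <= 0 for the next
#' `persistence_window` values of K (the stopping rule: the worst cluster
#' has degenerated and further splitting does not recover it). If the rule
#' never fires by `K_max`, returns `K_max` with a warning.
#'
#' @param profiles genes x timepoints matrix.
#' @param K_min,K_max scan range (K_min >= 2).
#' @param persistence_window how many successive K beyond the trigger must
#'   also have worst-cluster silhouette <= 0 (0 = first trigger wins).
#' @param n_restarts,seed passed to [kmeans_cluster()].
#' @return list with `K_star`, `clustering` (the fit at `K_star`) and
#'   `diagnostics` (data.frame of K, worst-cluster and mean silhouette).
#' @export
select_cluster_number <- function(profiles, K_min = 2L, K_max,
                                  persistence_window = 3L,
                                  n_restarts = 10L, seed = 1L) {
  if (K_min < 2L) stop_parse("K_min must be >= 2")
  if (K_max > nrow(profiles) / 2) stop_parse("K_max must be <= n_genes/2")
  ks <- seq.int(K_min, K_max)
  fits <- vector("list", length(ks))
  worst <- rep(NA_real_, length(ks))
  meansil <- rep(NA_real_, length(ks))
  K_star <- NA_integer_
  for (i in seq_along(ks)) {
    fits[[i]] <- kmeans_cluster(profiles, ks[i], n_restarts, seed + i)
    worst[i] <- fits[[i]]$worst
    meansil[i] <- mean(fits[[i]]$silhouette)
    # check whether some earlier K now satisfies the persistence rule
    for (j in seq_len(i)) {
      if (i - j >= persistence_window && all(worst[j:i] <= 0)) {
        K_star <- ks[j]
        break
      }
    }
    if (!is.na(K_star)) break
  }
  scanned <- !vapply(fits, is.null, logical(1L))
  if (is.na(K_star)) {
    warning("worst-cluster silhouette rule never fired; returning K_max",
            call. = FALSE)
    K_star <- K_max
  }
  list(K_star = K_star,
       clustering = fits[[match(K_star, ks)]],
       diagnostics = data.frame(K = ks[scanned],
                                worst_cluster_silhouette = worst[scanned],
                                mean_silhouette = meansil[scanned]))
}

#' Bin variance proportions into the four reporting bins
#'
#' @param p proportions in \[0, 1\].
#' @return factor with levels `<25%`, `25-50%`, `50-75%`, `>75%`.
#' @export
variance_bins <- function(p) {
  cut(p, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
      labels = c("<25%", "25-50%", "50-75%", ">75%"))
}

#' Per-cluster environmental variance decomposition
#'
#' Runs the environmental PVCA model on each cluster's member-gene submatrix
#' and bins each factor proportion into the four reporting bins (<25%,
#' 25-50%, 50-75%, >75%). Clusters smaller than `min_size` are skipped and
#' flagged.
#'
#' @param mat genes x samples matrix (replicate-level).
#' @param clustering `gene_clustering` (labels index rows of `mat`).
#' @param design joined design table aligned with columns of `mat`.
#' @param min_size smallest cluster to decompose.
#' @param ... passed to [pvca_environmental()].
#' @return list: `proportions` (clusters x factors matrix), `bins` (same
#'   shape, factor bins), `skipped` (cluster ids below `min_size`).
#' @export
cluster_pvca <- function(mat, clustering, design, min_size = 5L, ...) {
  labs <- clustering$labels
  ks <- sort(unique(labs))
  res <- list(); skipped <- integer(0)
  for (k in ks) {
    members <- names(labs)[labs == k]
    if (length(members) < min_size) {
      skipped <- c(skipped, k)
      next
    }
    dec <- pvca_environmental(mat[members, , drop = FALSE], design, ...)
    res[[as.character(k)]] <- unclass(dec)[]
  }
  if (!length(res))
    return(list(proportions = NULL, bins = NULL, skipped = skipped))
  prop <- do.call(rbind, res)
  rownames(prop) <- names(res)
  bins <- apply(prop, 2L, function(col) as.character(variance_bins(col)))
  rownames(bins) <- rownames(prop)
  list(proportions = prop, bins = bins, skipped = skipped)
}

#' Hypergeometric over-representation of a gene set in a cluster
#'
#' Upper-tail probability of at least k overlaps when n cluster members are
#' drawn without replacement from a universe of N genes containing K set
#' members. The set and members are intersected with the universe first.
#'
#' @param member_genes cluster member gene ids (must lie in `universe`).
#' @param set gene-set member ids.
#' @param universe background gene ids.
#' @return list with `k` (overlap), `n` (cluster size), `K` (set size in
#'   universe), `N` (universe size), and `p`.
#' @export
hypergeom_enrichment <- function(member_genes, set, universe) {
  universe <- unique(universe)
  member_genes <- unique(member_genes)
  if (length(setdiff(member_genes, universe)))
    stop_parse("cluster members outside the universe")
  set_u <- intersect(unique(set), universe)
  if (!length(universe) || !length(set_u)) {
    warning("empty universe or set after intersection; p = 1", call. = FALSE)
    return(list(k = 0L, n = length(member_genes), K = length(set_u),
                N = length(universe), p = 1))
  }
  k <- length(intersect(member_genes, set_u))
  n <- length(member_genes)
  K <- length(set_u)
  N <- length(universe)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(k = k, n = n, K = K, N = N, p = p)
}

#' Stress/GO annotation of clusters by gene-set enrichment
#'
#' Tests every (cluster, set) pair with the hypergeometric upper tail, then
#' applies BH correction across all pairs. With `p_mode = "raw"` the
#' enriched flag uses the unadjusted p (the classical p <= 0.01 convention)
#' instead of the BH q.
#'
#' @param clustering `gene_clustering`.
#' @param gene_sets `gene_set_collection` (or named list of id vectors).
#' @param universe background; defaults to the clustered genes.
#' @param alpha enrichment threshold.
#' @param p_mode `"q"` (BH, default) or `"raw"`.
#' @param category_map optional data.frame (set, category) with categories
#'   `"abiotic"`/`"biotic"`; enables the cluster-level summary.
#' @return list: `table` (long data.frame cluster, set, k, n, K, N, p, q,
#'   enriched), `matrix` (binary clusters x sets), `summary` (counts of
#'   clusters enriched for both/abiotic-only/biotic-only, if mapped).
#' @export
stress_annotation <- function(clustering, gene_sets,
                              universe = NULL, alpha = 0.05,
                              p_mode = c("q", "raw"),
                              category_map = NULL) {
  p_mode <- match.arg(p_mode)
  labs <- clustering$labels
  if (is.null(universe)) universe <- names(labs)
  ks <- sort(unique(labs))
  rows <- list()
  for (k in ks) {
    members <- intersect(names(labs)[labs == k], universe)
    for (s in names(gene_sets)) {
      h <- suppressWarnings(
        hypergeom_enrichment(members, gene_sets[[s]], universe))
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = k, set = s, k = h$k, n = h$n, K = h$K, N = h$N,
                   p = h$p, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$q <- bh_fdr(tab$p)
  tab$enriched <- if (p_mode == "q") tab$q <= alpha else tab$p <= alpha
  m <- matrix(0L, length(ks), length(gene_sets),
              dimnames = list(as.character(ks), names(gene_sets)))
  m[cbind(match(tab$cluster, ks), match(tab$set, names(gene_sets)))] <-
    as.integer(tab$enriched)
  summary <- NULL
  if (!is.null(category_map)) {
    cat_of <- stats::setNames(category_map$category, category_map$set)
    enr <- tab[tab$enriched, , drop = FALSE]
    per_cluster <- split(cat_of[enr$set], enr$cluster)
    kinds <- vapply(per_cluster, function(cc) {
      ab <- "abiotic" %in% cc; bi <- "biotic" %in% cc
      if (ab && bi) "both" else if (ab) "abiotic_only"
      else if (bi) "biotic_only" else "none"
    }, character(1L))
    summary <- c(both = sum(kinds == "both"),
                 abiotic_only = sum(kinds == "abiotic_only"),
                 biotic_only = sum(kinds == "biotic_only"))
  }
  list(table = tab, matrix = m, summary = summary)
}
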