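test_that("profiles are replicate means, standardized, with flat genes dropped", {
  samples <- tiny_samples(accessions = "A1", days = c(10, 13), reps = 3)
  mat <- rbind(g1 = c(1, 2, 3, 7, 8, 9),
               g_const = rep(4, 6))
  colnames(mat) <- samples$sample_id
  raw <- profile_matrix(mat, samples, standardize = FALSE)
  expect_equal(unname(raw["g1", ]), c(2, 8))
  expect_message(std <- profile_matrix(mat, samples), "g_const")
  expect_identical(rownames(std), "g1")
  expect_equal(mean(std["g1", ]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(std["g1", ]), 1, tolerance = 1e-12)
})

test_that("within-cluster profile correlations exceed between-cluster ones", {
  sim <- simulate_experiment(sim_config(n_genes = 120, seed = 61,
    fractions = c(accession = 0, flowering = 0, environment = 0,
                  cluster = 0.7),
    n_clusters = 4, null_fraction = 0, never_fraction = 0))
  prof <- profile_matrix(sim$expr, sim$samples)
  lab <- sim$truth$genes$cluster[match(rownames(prof),
                                       sim$truth$genes$gene_id)]
  cc <- stats::cor(t(prof))
  same <- outer(lab, lab, "==") & upper.tri(cc)
  diff <- outer(lab, lab, "!=") & upper.tri(cc)
  expect_gt(mean(cc[same]), mean(cc[diff]) + 0.5)
})

test_that("silhouette widths match the brute-force double loop", {
  set.seed(71)
  X <- matrix(rnorm(40 * 5), 40, 5)
  labels <- sample(1:4, 40, replace = TRUE)
  expect_lt(max(abs(silhouette_widths(X, labels) -
                      brute_silhouette(X, labels))), 1e-10)
  # independent library cross-check
  sil <- cluster::silhouette(labels, stats::dist(X))
  expect_lt(max(abs(silhouette_widths(X, labels) - sil[, "sil_width"])),
            1e-10)
})

test_that("silhouette geometry: separation, symmetry, singletons", {
  tight <- rbind(matrix(rnorm(30, sd = 0.01), 15, 2),
                 matrix(rnorm(30, mean = 10, sd = 0.01), 15, 2))
  s <- silhouette_widths(tight, rep(1:2, each = 15))
  expect_true(all(s > 0.99))

  # a point exactly half way between two mirror-image clusters scores ~0
  X <- rbind(c(-1, 0), c(-1, 0.1), c(0, 0), c(1, 0), c(1, 0.1))
  s2 <- silhouette_widths(X, c(1, 1, 1, 2, 2))
  expect_lt(abs(s2[3]), 0.05)

  s3 <- silhouette_widths(rbind(c(0, 0), c(1, 0), c(1.1, 0)), c(1, 2, 2))
  expect_identical(unname(s3[1]), 0)  # singleton convention
})

test_that("k-means recovers planted structure deterministically", {
  set.seed(81)
  blobs <- rbind(matrix(rnorm(60, mean = 0, sd = 0.2), 30, 2),
                 matrix(rnorm(60, mean = 5, sd = 0.2), 30, 2))
  rownames(blobs) <- sprintf("g%02d", 1:60)
  cl <- kmeans_cluster(blobs, 2, seed = 1)
  expect_identical(length(unique(cl$labels[1:30])), 1L)
  expect_identical(length(unique(cl$labels[31:60])), 1L)
  expect_identical(cl$labels, kmeans_cluster(blobs, 2, seed = 1)$labels)

  sim <- simulate_experiment(sim_config(n_genes = 200, seed = 83,
    fractions = c(accession = 0.05, flowering = 0.1, environment = 0.05,
                  cluster = 0.6),
    n_clusters = 5, null_fraction = 0, never_fraction = 0))
  prof <- profile_matrix(sim$expr, sim$samples)
  fit <- kmeans_cluster(prof, 5, n_restarts = 10, seed = 3)
  truth <- sim$truth$genes$cluster[match(rownames(prof),
                                         sim$truth$genes$gene_id)]
  expect_gt(mclust::adjustedRandIndex(fit$labels, truth), 0.95)
})

test_that("the worst-cluster silhouette rule selects a sane cluster number", {
  sim <- simulate_experiment(sim_config(n_genes = 200, seed = 85,
    fractions = c(accession = 0, flowering = 0, environment = 0,
                  cluster = 0.7),
    n_clusters = 5, null_fraction = 0, never_fraction = 0))
  prof <- profile_matrix(sim$expr, sim$samples)
  sel <- suppressWarnings(select_cluster_number(prof, 2, 8,
                                                persistence_window = 2,
                                                seed = 4))
  d <- sel$diagnostics
  expect_true(all(d$worst_cluster_silhouette[d$K <= 5] > 0))
  expect_gt(sel$K_star, 5)

  # an unstructured blob triggers the rule inside the scan range
  set.seed(1)
  blob <- matrix(rnorm(150 * 6), 150, 6,
                 dimnames = list(sprintf("g%03d", 1:150), NULL))
  sel2 <- select_cluster_number(blob, 2, 20, persistence_window = 0,
                                n_restarts = 1, seed = 11)
  expect_lt(sel2$K_star, 20)
  first <- min(sel2$diagnostics$K[sel2$diagnostics$worst_cluster_silhouette <= 0])
  expect_identical(sel2$K_star, first)  # window 0 = first trigger
})

test_that("variance bins follow the reporting thresholds", {
  expect_identical(as.character(variance_bins(c(0.10, 0.30, 0.60, 0.80))),
                   c("<25%", "25-50%", "50-75%", ">75%"))
})

test_that("cluster-level attribution flags a flowering-driven cluster", {
  cfg <- sim_config(n_genes = 150, seed = 91,
                    fractions = c(accession = 0, flowering = 0.7,
                                  environment = 0, cluster = 0.1),
                    n_clusters = 2, null_fraction = 0, never_fraction = 0)
  sim <- simulate_experiment(cfg)
  design <- join_design(sim$samples, sim$env)
  keep <- sim$samples$accession == "A2"
  prof <- profile_matrix(sim$expr, sim$samples, accession = "A2")
  cl <- kmeans_cluster(prof, 2, seed = 5)
  cp <- cluster_pvca(sim$expr[, keep], cl, design[keep, ])
  expect_true(all(cp$proportions[, "flowering_status"] > 0.5))
  expect_true(all(cp$bins[, "flowering_status"] %in% c("50-75%", ">75%")))
})

test_that("hypergeometric tails match exhaustive enumeration", {
  set.seed(101)
  for (i in 1:20) {
    N <- sample(6:15, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    universe <- sprintf("u%02d", seq_len(N))
    set_g <- universe[seq_len(K)]
    members <- sample(universe, n)
    h <- hypergeom_enrichment(members, set_g, universe)
    expect_lt(abs(h$p - brute_hyper_tail(h$k, K, N, n)), 1e-12)
  }
  # worked example: universe 10, set 5, cluster 4, overlap 4
  h <- hypergeom_enrichment(c("u1", "u2", "u3", "u4"),
                            sprintf("u%d", 1:5), sprintf("u%d", 1:10))
  expect_equal(h$p, (choose(5, 4) * choose(5, 0)) / choose(10, 4),
               tolerance = 1e-12)

  h0 <- hypergeom_enrichment(c("u9", "u10"), sprintf("u%d", 1:5),
                             sprintf("u%d", 1:10))
  expect_identical(h0$p, 1)  # zero overlap
  hu <- hypergeom_enrichment(c("u1", "u2"), sprintf("u%d", 1:10),
                             sprintf("u%d", 1:10))
  expect_identical(hu$p, 1)  # set == universe
})

test_that("stress annotation flags planted sets and only those", {
  sim <- simulate_experiment(sim_config(n_genes = 300, seed = 103,
    fractions = c(accession = 0.05, flowering = 0.1, environment = 0,
                  cluster = 0.6),
    n_clusters = 3, null_fraction = 0, never_fraction = 0))
  prof <- profile_matrix(sim$expr, sim$samples)
  cl <- kmeans_cluster(prof, 3, seed = 7)
  tg <- sim$truth$genes
  gene_sets <- split(tg$gene_id, paste0("stress_", tg$cluster))
  enr <- stress_annotation(cl, gene_sets, alpha = 0.01)
  flagged <- enr$table[enr$table$enriched, ]
  expect_identical(nrow(flagged), 3L)  # one planted set per cluster
  # each cluster pairs with exactly the set it was built from
  agree <- mapply(function(cluster, set) {
    members <- names(cl$labels)[cl$labels == cluster]
    mean(members %in% gene_sets[[set]]) > 0.9
  }, flagged$cluster, flagged$set)
  expect_true(all(agree))

  # a cluster identical to a set reaches a near-floor p-value
  verb <- flagged[1, ]
  expect_lt(min(enr$table$p), 1e-12)

  # category summary
  map <- data.frame(set = names(gene_sets),
                    category = c("abiotic", "abiotic", "biotic"))
  enr2 <- stress_annotation(cl, gene_sets, alpha = 0.01, category_map = map)
  expect_identical(sum(enr2$summary), 3L)
})

test_that("random clusters are enriched at roughly the nominal rate", {
  set.seed(107)
  universe <- sprintf("g%04d", 1:2000)
  labels <- sample(1:20, 2000, replace = TRUE)
  names(labels) <- universe
  cl <- structure(list(labels = labels), class = "gene_clustering")
  gene_sets <- lapply(1:25, function(i) sample(universe, 300))
  names(gene_sets) <- paste0("set", 1:25)
  enr <- stress_annotation(cl, gene_sets, universe = universe,
                           alpha = 0.05, p_mode = "raw")
  rate <- mean(enr$table$p <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(enr$table)) + 0.02)
})
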