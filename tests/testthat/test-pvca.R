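test_that("fit_pca matches a dense eigendecomposition and reconstructs", {
  set.seed(7)
  mat <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20)))
  pc <- fit_pca(mat)
  # oracle: eigenvalues of the gene-gene sample covariance
  eig_oracle <- eigen(stats::cov(scale(t(mat), center = TRUE, scale = FALSE)),
                      symmetric = TRUE)$values
  k <- length(pc$eigenvalues)
  expect_lt(max(abs(pc$eigenvalues - eig_oracle[seq_len(k)])), 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-10))
  recon <- pc$scores %*% t(pc$loadings) +
    matrix(pc$center, nrow(pc$scores), length(pc$center), byrow = TRUE)
  expect_lt(max(abs(recon - t(mat))), 1e-8)
})

test_that("degenerate matrices are handled: rank one and constant", {
  v <- c(1, 2, 3, 4)
  mat <- outer(c(2, -1, 0.5), v)
  dimnames(mat) <- list(c("g1", "g2", "g3"), sprintf("s%d", 1:4))
  pc <- fit_pca(mat)
  expect_equal(pc$proportion[1], 1, tolerance = 1e-12)

  const <- matrix(5, 3, 4, dimnames = dimnames(mat))
  pc0 <- fit_pca(const)
  expect_true(all(pc0$eigenvalues == 0))
})

test_that("variance components isolate the driving factor", {
  design <- data.frame(A = rep(c("x", "y"), each = 12),
                       B = rep(rep(c("u", "v"), each = 6), 2))
  set.seed(3)
  y_a <- ifelse(design$A == "x", 5, -5) + rnorm(24, sd = 0.01)
  comp <- estimate_components(y_a, design, c("A", "B"))
  expect_gt(comp["A"] / sum(comp), 0.99)

  y_noise <- rnorm(24)
  comp2 <- estimate_components(y_noise, design, c("A", "B"))
  expect_gt(comp2["residual"] / sum(comp2), 0.8)
})

test_that("REML agrees with the balanced-design expected-mean-squares oracle", {
  # one-way balanced: REML equals the EMS estimator when interior
  set.seed(11)
  A <- rep(c("a", "b", "c", "d"), each = 10)
  eff <- rnorm(4, sd = 3)
  y <- eff[as.integer(factor(A))] + rnorm(40)
  comp <- estimate_components(y, data.frame(A = A), "A")
  msb <- 10 * sum((tapply(y, A, mean) - mean(y))^2) / 3
  msw <- sum((y - ave(y, A))^2) / 36
  expect_equal(unname(comp["A"]), (msb - msw) / 10, tolerance = 1e-6)
  expect_equal(unname(comp["residual"]), msw, tolerance = 1e-6)

  # crossed 2x2 with interaction, 30 replicates per cell
  set.seed(19)
  A <- rep(c("a1", "a2"), each = 60)
  B <- rep(rep(c("b1", "b2"), each = 30), 2)
  aeff <- rnorm(2, sd = 2); beff <- rnorm(2, sd = 1)
  y <- aeff[as.integer(factor(A))] + beff[as.integer(factor(B))] + rnorm(120)
  oracle <- ems_components_2x2(y, A, B)
  comp <- estimate_components(y, data.frame(A = A, B = B),
                              c("A", "B", "A:B"))
  for (k in c("A", "B")) {
    if (oracle[k] > 0.5)  # interior solutions only
      expect_lt(abs(comp[k] - oracle[k]) / oracle[k], 0.25)
  }
  expect_lt(abs(comp["residual"] - oracle["residual"]) / oracle["residual"],
            0.25)
})

test_that("confounded factors are reported as such", {
  design <- data.frame(A = rep(c("x", "y"), each = 6),
                       A2 = rep(c("p", "q"), each = 6))
  expect_error(estimate_components(rnorm(12), design, c("A", "A2")),
               "identical groupings")
})

test_that("pvca proportions sum to one and ignore gene order", {
  sim <- simulate_experiment(sim_config(n_genes = 150, seed = 23,
                                        n_clusters = 3))
  design <- join_design(sim$samples, sim$env)
  terms <- c("accession", "flowering_status", "accession:flowering_status")
  dec <- pvca(sim$expr, design, terms)
  expect_equal(sum(dec), 1, tolerance = 1e-8)
  expect_true(all(dec >= 0))
  set.seed(2)
  dec2 <- pvca(sim$expr[sample(nrow(sim$expr)), ], design, terms)
  expect_equal(as.numeric(dec), as.numeric(dec2), tolerance = 1e-6)
})

test_that("a single-factor noiseless matrix attributes all variance to it", {
  samples <- tiny_samples()
  x <- ifelse(samples$accession == "A1", -0.5, 0.5)
  mat <- outer(seq(0.5, 2, length.out = 6), x)
  dimnames(mat) <- list(sprintf("g%d", 1:6), samples$sample_id)
  dec <- pvca(mat, samples, c("accession", "flowering_status"))
  expect_equal(unname(dec["accession"]), 1, tolerance = 1e-8)

  # single retained PC: aggregation equals that PC's raw component shares
  pc <- fit_pca(mat)
  shares <- estimate_components(pc$scores[, 1], samples,
                                c("accession", "flowering_status"))
  expect_equal(as.numeric(dec), as.numeric(shares / sum(shares)),
               tolerance = 1e-8)
})

test_that("an interaction term stays near zero when none is planted", {
  cfg <- sim_config(n_genes = 800, veg_timepoints = c(2, 2),
                    flowering_timepoints = c(2, 2),
                    fractions = c(accession = 0.35, flowering = 0.35,
                                  environment = 0, cluster = 0),
                    n_clusters = 0, null_fraction = 0, never_fraction = 0,
                    drop_replicate = FALSE, seed = 29)
  sim <- simulate_experiment(cfg)
  design <- join_design(sim$samples, sim$env)
  dec <- pvca(sim$expr, design,
              c("accession", "flowering_status",
                "accession:flowering_status"))
  expect_lt(dec["accession:flowering_status"], 0.02)
})

test_that("environmental pvca attributes precipitation-driven expression", {
  sim <- simulate_experiment(sim_config(n_genes = 250, seed = 37,
                                        fractions = c(accession = 0,
                                                      flowering = 0,
                                                      environment = 0,
                                                      cluster = 0),
                                        n_clusters = 0, null_fraction = 1,
                                        never_fraction = 0))
  design <- join_design(sim$samples, sim$env)
  keep <- design$accession == "A1"
  d1 <- design[keep, ]
  z <- as.numeric(scale(d1$precipitation))
  set.seed(41)
  coefs <- rnorm(250, sd = 1.2)
  mat <- outer(coefs, z) + matrix(rnorm(250 * sum(keep), sd = 0.4),
                                  250, sum(keep))
  dimnames(mat) <- list(sprintf("g%03d", 1:250), d1$sample_id)
  dec <- pvca_environmental(mat, d1)
  nonres <- dec[setdiff(names(dec), "residual")]
  expect_identical(names(which.max(nonres)), "precipitation")

  # permutation null: shuffling weather across days kills the attribution
  d_shuf <- d1
  set.seed(43)
  shuf <- sample(nrow(d_shuf))
  d_shuf[, c("tmax", "tmin", "precipitation")] <-
    d_shuf[shuf, c("tmax", "tmin", "precipitation")]
  mat_null <- matrix(rnorm(250 * sum(keep)), 250, sum(keep),
                     dimnames = dimnames(mat))
  dec_null <- pvca_environmental(mat_null, d_shuf)
  expect_true(all(dec_null[c("tmin", "tmax", "precipitation")] < 0.05))
})

test_that("flowering-dominant data ranks flowering above the weather terms", {
  cfg <- sim_config(n_genes = 300, seed = 47,
                    fractions = c(accession = 0.05, flowering = 0.55,
                                  environment = 0.05, cluster = 0),
                    n_clusters = 0, null_fraction = 0, never_fraction = 0)
  sim <- simulate_experiment(cfg)
  design <- join_design(sim$samples, sim$env)
  dec <- pvca_environmental(sim$expr, design, by_accession = TRUE)
  for (a in names(dec)) {
    d <- dec[[a]]
    expect_gt(d["flowering_status"],
              max(d[c("tmin", "tmax", "precipitation")]))
  }
})
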