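# Synthetic field-experiment generator. The generative model per gene g and
# sample s is
#   y_gs = mu_g + a_g*x_acc(s) + f_g*x_flow(s)
#          + cT_g*z_tmax(s) + cP_g*z_ppt(s) + b_g*tau_{k(g)}(s) + eps_gs
# with x_* effect-coded +/-1/2 contrasts, z_* covariates standardized across
# samples, tau_k unit-variance temporal templates, eps ~ N(0, v_resid).
# Variance fractions are defined on the per-gene sample-variance scale of the
# balanced design: the accession term contributes fraction[\"accession\"] of
# total_var to a signal gene's variance, etc.

#' Configuration for a synthetic field experiment
#'
#' Defaults emulate a two-accession spring field season: replicated sampling
#' every 3 days, 6 vegetative + 2 flowering timepoints for the earlier-bolting
#' accession and 8 + 2 for the later one (bolting at days 34 and 40), three
#' replicates with one late replicate dropped, and autocorrelated weather
#' with mean daily low 8.7 degC / high 23.7 degC and rain on 8 of 30 days.
#'
#' @param n_genes number of genes.
#' @param accessions character vector of accession names (length 2 default).
#' @param veg_timepoints vegetative timepoints per accession (recycled).
#' @param flowering_timepoints flowering timepoints per accession (recycled).
#' @param replicates replicates per (accession, day) sample.
#' @param interval days between successive samples.
#' @param start_day first sampling day (days after germination).
#' @param fractions named variance fractions for `accession`, `flowering`,
#'   `environment` (split equally between tmax and precipitation) and
#'   `cluster`; the residual absorbs the remainder. Must be >= 0, sum <= 1.
#' @param total_var per-gene total variance on the balanced design.
#' @param n_clusters number of co-expressed temporal clusters.
#' @param null_fraction fraction of expressed genes with no planted effects.
#' @param never_fraction fraction of genes never expressed (low baseline).
#' @param baseline_mean,baseline_sd log2 baseline distribution of expressed
#'   genes; the default sd 3 reproduces ~0.98 inter-replicate correlation.
#' @param never_mean,never_sd baseline distribution of never-expressed genes.
#' @param bg_quantile background quantile of all values below which a
#'   measurement is called absent.
#' @param flip_rate probability that a detection flag is flipped (noise).
#' @param drop_replicate drop one replicate of one late sample (unbalanced
#'   design, mirroring a lost array).
#' @param seed integer seed; all simulation randomness derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       accessions = c("A1", "A2"),
                       veg_timepoints = c(6, 8),
                       flowering_timepoints = c(2, 2),
                       replicates = 3,
                       interval = 3,
                       start_day = 16,
                       fractions = c(accession = 0.15, flowering = 0.25,
                                     environment = 0.10, cluster = 0.30),
                       total_var = 1,
                       n_clusters = 8,
                       null_fraction = 0.2,
                       never_fraction = 0.1,
                       baseline_mean = 8, baseline_sd = 3,
                       never_mean = 3.5, never_sd = 0.4,
                       bg_quantile = 0.4,
                       flip_rate = 0.01,
                       drop_replicate = TRUE,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$veg_timepoints <- rep_len(veg_timepoints, length(accessions))
  cfg$flowering_timepoints <- rep_len(flowering_timepoints, length(accessions))
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  fr <- cfg$fractions
  need <- c("accession", "flowering", "environment", "cluster")
  if (!all(need %in% names(fr)))
    stop_parse("fractions must name %s", paste(need, collapse = ", "))
  fr <- fr[need]
  if (any(fr < 0) || sum(fr) > 1 + 1e-12)
    stop_parse("variance fractions must be >= 0 and sum to <= 1")
  cfg$fractions <- fr
  if (cfg$n_genes < 1 || cfg$replicates < 1 || cfg$interval < 1)
    stop_parse("counts must be positive")
  if (any(cfg$veg_timepoints < 1) || any(cfg$flowering_timepoints < 0))
    stop_parse("need >= 1 vegetative timepoint and >= 0 flowering timepoints")
  if (cfg$null_fraction < 0 || cfg$null_fraction > 1 ||
      cfg$never_fraction < 0 || cfg$never_fraction > 1 ||
      cfg$null_fraction + cfg$never_fraction > 1)
    stop_parse("null_fraction + never_fraction must lie in [0, 1]")
  if (cfg$bg_quantile < 0 || cfg$bg_quantile > 1 ||
      cfg$flip_rate < 0 || cfg$flip_rate > 1)
    stop_parse("bg_quantile and flip_rate must lie in [0, 1]")
  if (fr[["cluster"]] > 0 && cfg$n_clusters < 1)
    stop_parse("cluster variance planted but n_clusters < 1")
  cfg
}

#' Build the sample table implied by a simulation configuration
#'
#' Deterministic (no randomness except the configured replicate drop, which
#' is itself deterministic): per accession, vegetative then flowering
#' timepoints every `interval` days from `start_day`.
#'
#' @param cfg `sim_config`.
#' @return validated sample table.
#' @export
design_from_config <- function(cfg) {
  rows <- list()
  for (i in seq_along(cfg$accessions)) {
    nv <- cfg$veg_timepoints[i]; nf <- cfg$flowering_timepoints[i]
    days <- cfg$start_day + cfg$interval * (seq_len(nv + nf) - 1L)
    status <- rep(c("vegetative", "flowering"), c(nv, nf))
    rows[[i]] <- expand.grid(replicate = seq_len(cfg$replicates),
                             tp = seq_len(nv + nf), KEEP.OUT.ATTRS = FALSE)
    rows[[i]]$accession <- cfg$accessions[i]
    rows[[i]]$day <- days[rows[[i]]$tp]
    rows[[i]]$flowering_status <- status[rows[[i]]$tp]
  }
  d <- do.call(rbind, rows)
  if (isTRUE(cfg$drop_replicate) && length(cfg$accessions) >= 2L) {
    # lose the last replicate of the 6th timepoint (or the last vegetative
    # one if fewer) of the second accession
    tp_drop <- min(6L, cfg$veg_timepoints[2L])
    drop <- d$accession == cfg$accessions[2L] & d$tp == tp_drop &
      d$replicate == cfg$replicates
    d <- d[!drop, , drop = FALSE]
  }
  d$tp <- NULL
  d$sample_id <- sprintf("%s_d%02d_r%d", d$accession, d$day, d$replicate)
  validate_samples(d[, c("sample_id", "accession", "day",
                         "flowering_status", "replicate")])
}

#' Simulate a daily weather series
#'
#' Daily minimum and maximum temperatures follow independent AR(1) processes
#' around their stationary means, with `tmax` forced above `tmin`. Rain falls
#' on a Bernoulli fraction of days with amounts uniform on `rain_range`.
#'
#' @param n_days number of days.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param tmin_mean,tmax_mean stationary means (degrees C).
#' @param sd_t stationary standard deviation of each temperature series.
#' @param ar AR(1) coefficient.
#' @param rain_prob daily probability of rain.
#' @param rain_range range (mm) of rain amounts on rainy days.
#' @return validated environment series (day, tmax, tmin, precipitation).
#' @export
simulate_environment <- function(n_days, seed = NULL,
                                 tmin_mean = 8.7, tmax_mean = 23.7,
                                 sd_t = 2.5, ar = 0.6,
                                 rain_prob = 8 / 30,
                                 rain_range = c(2.5, 31.8)) {
  stopifnot(n_days >= 1)
  if (!is.null(seed)) set.seed(seed)
  innov_sd <- sd_t * sqrt(1 - ar^2)
  ar1 <- function(mu) {
    x <- numeric(n_days)
    x[1L] <- mu + stats::rnorm(1L, sd = sd_t)
    for (t in seq_len(n_days)[-1L])
      x[t] <- mu + ar * (x[t - 1L] - mu) + stats::rnorm(1L, sd = innov_sd)
    x
  }
  tmin <- ar1(tmin_mean)
  tmax <- ar1(tmax_mean)
  tmax <- pmax(tmax, tmin + 0.5)
  rain <- stats::rbinom(n_days, 1L, rain_prob) *
    stats::runif(n_days, rain_range[1L], rain_range[2L])
  validate_environment(data.frame(day = seq_len(n_days),
                                  tmax = round(tmax, 1),
                                  tmin = round(tmin, 1),
                                  precipitation = round(rain, 1)))
}

# Unit-variance temporal templates over the sample grid: smooth
# natural-cubic-spline curves of day, arranged as the vertices of a regular
# simplex inside the smooth subspace (pairwise correlation -1/(K-1)). The
# simplex layout keeps every template well separated from every other (so
# planted clusters are identifiable at any seed) while spreading each
# template's energy across the low-frequency basis (so a low-df spline
# time-course test sees all of them). A random rotation within the smooth
# subspace varies the curves from seed to seed.
make_templates <- function(day, n_clusters) {
  ud <- sort(unique(day))
  df_t <- min(length(ud) - 2L, max(3L, n_clusters - 1L))
  if (n_clusters > df_t + 1L)
    stop_parse("n_clusters = %d needs >= %d distinct sampling days",
               n_clusters, n_clusters + 2L)
  basis <- scale(splines::ns(day, df = df_t), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(basis))[, seq_len(df_t), drop = FALSE]
  if (n_clusters == 1L) {
    dirs <- matrix(stats::rnorm(df_t), df_t, 1L)
    dirs <- dirs / sqrt(sum(dirs^2))
  } else {
    K <- n_clusters
    # unit simplex vertices in R^(K-1), mutual cosine -1/(K-1)
    P <- diag(K) - 1 / K
    V <- eigen(P, symmetric = TRUE)$vectors[, seq_len(K - 1L), drop = FALSE]
    V <- V / sqrt((K - 1) / K)
    rot <- qr.Q(qr(matrix(stats::rnorm(df_t * (K - 1L)), df_t)))[,
      seq_len(K - 1L), drop = FALSE]
    dirs <- rot %*% t(V)
  }
  tpl <- Q %*% dirs
  scale(tpl, center = TRUE, scale = apply(tpl, 2L, stats::sd))
}

#' Simulate a full synthetic field experiment with ground truth
#'
#' @param cfg `sim_config`.
#' @return list with elements `expr` (genes x samples log2 matrix), `flags`
#'   (detection calls), `samples`, `env`, `pheno`, and `truth`. `truth` holds
#'   per-gene planted effects (`genes` data.frame: role, cluster, accession /
#'   flowering effects, environment coefficients), the pre-flip `presence`
#'   matrix, the detection `threshold`, the cluster `templates`, and
#'   `realized_fractions` computed from the planted term vectors.
#' @export
simulate_experiment <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed)
  samples <- design_from_config(cfg)
  n_s <- nrow(samples)
  env <- simulate_environment(max(samples$day) + 2L)
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))

  n_never <- round(cfg$never_fraction * cfg$n_genes)
  n_null <- round(cfg$null_fraction * cfg$n_genes)
  role <- rep(c("never", "null", "signal"),
              c(n_never, n_null, cfg$n_genes - n_never - n_null))
  signal <- role == "signal"
  n_sig <- sum(signal)

  fr <- cfg$fractions * cfg$total_var
  v_resid <- cfg$total_var - sum(fr)

  # sample-level covariate codes
  x_acc <- ifelse(samples$accession == cfg$accessions[1L], -0.5, 0.5)
  x_flow <- ifelse(samples$flowering_status == "vegetative", -0.5, 0.5)
  std <- function(v) if (stats::sd(v) > 0) as.numeric(scale(v)) else rep(0, length(v))
  idx <- match(samples$day, env$day)
  z_tmax <- std(env$tmax[idx])
  z_ppt <- std(env$precipitation[idx])

  rsign <- function(n) sample(c(-1, 1), n, replace = TRUE)
  a <- f <- ct <- cp <- b <- numeric(cfg$n_genes)
  a[signal] <- rsign(n_sig) * 2 * sqrt(fr[["accession"]])
  f[signal] <- rsign(n_sig) * 2 * sqrt(fr[["flowering"]])
  ct[signal] <- rsign(n_sig) * sqrt(fr[["environment"]] / 2)
  cp[signal] <- rsign(n_sig) * sqrt(fr[["environment"]] / 2)

  cluster <- rep(NA_integer_, cfg$n_genes)
  templates <- NULL
  tau <- matrix(0, cfg$n_genes, n_s)
  if (fr[["cluster"]] > 0 && cfg$n_clusters >= 1L) {
    templates <- make_templates(samples$day, cfg$n_clusters)
    cluster[signal] <- rep_len(seq_len(cfg$n_clusters), n_sig)
    b[signal] <- sqrt(fr[["cluster"]])
    tau[signal, ] <- t(templates[, cluster[signal], drop = FALSE]) * b[signal]
  }

  mu <- numeric(cfg$n_genes)
  mu[role == "never"] <- stats::rnorm(n_never, cfg$never_mean, cfg$never_sd)
  mu[role != "never"] <- stats::rnorm(cfg$n_genes - n_never,
                                      cfg$baseline_mean, cfg$baseline_sd)

  det_sd <- sqrt(v_resid)
  values <- mu +
    outer(a, x_acc) + outer(f, x_flow) +
    outer(ct, z_tmax) + outer(cp, z_ppt) + tau +
    matrix(stats::rnorm(cfg$n_genes * n_s, sd = det_sd), cfg$n_genes, n_s)
  dimnames(values) <- list(gene_ids, samples$sample_id)

  threshold <- as.numeric(stats::quantile(values, cfg$bg_quantile))
  presence <- values > threshold
  flags <- presence
  if (cfg$flip_rate > 0) {
    flip <- matrix(stats::runif(length(flags)) < cfg$flip_rate,
                   nrow(flags), ncol(flags))
    flags <- xor(flags, flip)
  }

  # rosette leaf number grows ~linearly with age; diameter saturates, so the
  # two phenotypes are informative beyond age (keeps covariate VIFs moderate)
  pheno <- data.frame(
    sample_id = samples$sample_id,
    rln = pmax(2, round(2 + 0.45 * samples$day + stats::rnorm(n_s, sd = 1.5))),
    rd = round(pmax(0.5, 9 * (1 - exp(-samples$day / 12)) +
                      stats::rnorm(n_s, sd = 0.5)), 1))

  # realized per-factor variance fractions from the planted term vectors,
  # averaged over signal genes (population variance across samples)
  pvar <- function(v) mean((v - mean(v))^2)
  if (n_sig > 0) {
    realized <- c(
      accession = mean(a[signal]^2) * pvar(x_acc),
      flowering = mean(f[signal]^2) * pvar(x_flow),
      environment = mean(ct[signal]^2) * pvar(z_tmax) +
        mean(cp[signal]^2) * pvar(z_ppt),
      cluster = if (any(b > 0))
        mean(rowMeans((tau[signal, , drop = FALSE] -
                         rowMeans(tau[signal, , drop = FALSE]))^2)) else 0,
      residual = det_sd^2)
    realized <- realized / sum(realized)
  } else {
    realized <- c(accession = 0, flowering = 0, environment = 0, cluster = 0,
                  residual = 1)
  }

  truth <- list(
    genes = data.frame(gene_id = gene_ids, role = role, cluster = cluster,
                       acc_effect = a, flow_effect = f,
                       tmax_coef = ct, precip_coef = cp,
                       cluster_amp = b, baseline = mu,
                       stringsAsFactors = FALSE),
    presence = presence,
    threshold = threshold,
    templates = templates,
    realized_fractions = realized)

  list(expr = validate_expression(values),
       flags = validate_flags(flags, values),
       samples = samples, env = env,
       pheno = validate_phenotypes(pheno, samples),
       truth = truth, config = cfg)
}
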