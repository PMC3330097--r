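# End-to-end orchestration: one configuration drives simulate/load -> census
# -> PVCA -> ANOVA -> spline time-course -> clustering -> enrichment ->
# vegetative PCA/template matching, with TSV outputs and a JSON run report.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulation = list(n_genes = 600L),
    inputs = NULL,
    analysis = list(
      anova_terms = c("accession", "flowering_status",
                      "accession:flowering_status"),
      spline_df = 3L,
      n_perm = 199L,
      q_timecourse = 0.05,
      q_cluster = 0.01,
      K_min = 2L, K_max = 10L, persistence_window = 2L,
      kmeans_restarts = 5L,
      enrichment_alpha = 0.05,
      template_threshold = 0.7,
      alpha_per_tail = 0.025,
      n_axes = 5L))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load a pipeline configuration
#'
#' @param config `NULL` (defaults), a named list overriding defaults, or a
#'   path to a YAML file with the same structure.
#' @return complete configuration list.
#' @export
pipeline_config <- function(config = NULL) {
  base <- default_pipeline_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_config(base, config)
}

validate_pipeline_config <- function(cfg) {
  if (!is.null(cfg$inputs)) {
    need <- c("expression", "flags", "samples", "environment")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss))
      stop_parse("pipeline inputs missing: %s (environmental model needs %s)",
                 paste(miss, collapse = ", "), paste(need, collapse = ", "))
    gone <- !vapply(unlist(cfg$inputs[need]), file.exists, logical(1L))
    if (any(gone))
      stop_parse("input file(s) not found: %s",
                 paste(unlist(cfg$inputs[need])[gone], collapse = ", "))
  }
  invisible(cfg)
}

#' Run the full field-transcriptome pipeline
#'
#' Stages: simulate (or load), census, pvca, anova, timecourse, cluster,
#' enrich, vegpca. All stage outputs are written as TSV under `outdir`
#' together with `run_report.json` (config echo, seed registry, per-stage
#' row counts and wall time, warnings). Re-running with the same
#' configuration reproduces the outputs.
#'
#' @param config see [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return the run report, invisibly (list, also written as JSON).
#' @export
run_pipeline <- function(config = NULL, outdir = tempfile("fieldexpr_run_")) {
  cfg <- pipeline_config(config)
  validate_pipeline_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  an <- cfg$analysis
  report <- list(config = cfg, seeds = list(), stages = list(),
                 warnings = character(0))
  note <- function(stage, t0, ...) {
    report$stages[[stage]] <<- c(list(
      elapsed_s = round(as.numeric(Sys.time()) - t0, 3)), list(...))
  }

  # -- stage 1: simulate or load ---------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (is.null(cfg$inputs)) {
    sim_args <- cfg$simulation
    sim_args$seed <- cfg$seed
    sim <- simulate_experiment(do.call(sim_config, sim_args))
    expr <- sim$expr; flags <- sim$flags; samples <- sim$samples
    env <- sim$env; pheno <- sim$pheno
    write_expression(expr, file.path(outdir, "expression.tsv"))
    write_flags(flags, file.path(outdir, "flags.tsv"))
    write_tsv(samples, file.path(outdir, "samples.tsv"))
    write_tsv(env, file.path(outdir, "environment.csv"), sep = ",")
    write_tsv(pheno, file.path(outdir, "phenotypes.tsv"))
    write_tsv(sim$truth$genes, file.path(outdir, "truth_genes.tsv"))
    report$seeds$simulate <- cfg$seed
    note("simulate", t0, n_genes = nrow(expr), n_samples = ncol(expr))
  } else {
    expr <- read_expression(cfg$inputs$expression)
    flags <- read_flags(cfg$inputs$flags)
    samples <- read_samples(cfg$inputs$samples)
    env <- read_environment(cfg$inputs$environment)
    pheno <- if (!is.null(cfg$inputs$phenotypes))
      read_phenotypes(cfg$inputs$phenotypes) else NULL
    sim <- NULL
    note("simulate", t0, n_genes = nrow(expr), n_samples = ncol(expr),
         loaded = TRUE)
  }
  design <- join_design(samples, env, pheno)
  accs <- levels(factor(samples$accession))

  # -- stage 2: detection census ---------------------------------------------
  t0 <- as.numeric(Sys.time())
  census <- call_expressed(flags, samples)
  write_tsv(cbind(census$timepoint_info,
                  n_expressed = unname(census$counts[census$timepoint_info$timepoint])),
            file.path(outdir, "census_timepoints.tsv"))
  if (length(census$accession_sets) >= 2L) {
    vc <- venn_counts(census$accession_sets)
    write_tsv(vc, file.path(outdir, "census_venn.tsv"))
  }
  absent <- absent_everywhere(census, rownames(expr))
  note("census", t0, n_expressed_union = length(census$union),
       n_absent = length(absent))

  # -- stage 3: global + environmental PVCA ----------------------------------
  t0 <- as.numeric(Sys.time())
  dec <- pvca(expr, design, factors = an$anova_terms)
  write_tsv(data.frame(factor = names(dec), proportion = as.numeric(dec)),
            file.path(outdir, "pvca_global.tsv"))
  env_dec <- pvca_environmental(expr, design, by_accession = TRUE)
  env_tab <- do.call(rbind, lapply(names(env_dec), function(a) {
    data.frame(accession = a, factor = names(env_dec[[a]]),
               proportion = as.numeric(env_dec[[a]]))
  }))
  write_tsv(env_tab, file.path(outdir, "pvca_environmental.tsv"))
  note("pvca", t0, n_factors = length(dec))

  # -- stage 4: factorial ANOVA ----------------------------------------------
  t0 <- as.numeric(Sys.time())
  aov_tab <- anova_per_gene(expr, design, terms = an$anova_terms)
  write_tsv(aov_tab, file.path(outdir, "anova.tsv"))
  note("anova", t0, n_rows = nrow(aov_tab))

  # -- stage 5: spline time-course per accession -----------------------------
  t0 <- as.numeric(Sys.time())
  tc <- list(); sig05 <- list(); sig01 <- list()
  for (a in accs) {
    keep <- samples$accession == a
    tc[[a]] <- spline_timecourse_test(expr[, keep, drop = FALSE],
                                      design[keep, , drop = FALSE],
                                      df = an$spline_df,
                                      n_perm = an$n_perm,
                                      seed = cfg$seed + match(a, accs))
    tc[[a]]$accession <- a
    sig05[[a]] <- select_significant(tc[[a]], an$q_timecourse)
    sig01[[a]] <- select_significant(tc[[a]], an$q_cluster)
  }
  write_tsv(do.call(rbind, tc), file.path(outdir, "timecourse.tsv"))
  report$seeds$timecourse <- cfg$seed + seq_along(accs)
  note("timecourse", t0,
       n_significant = vapply(sig05, length, integer(1L)))

  # -- stage 6: clustering per accession -------------------------------------
  t0 <- as.numeric(Sys.time())
  clusterings <- list(); lab_rows <- list()
  for (a in accs) {
    genes <- sig01[[a]]
    if (length(genes) < 2L * an$K_min) {
      report$warnings <- c(report$warnings, sprintf(
        "accession %s: %d significant genes, skipping clustering",
        a, length(genes)))
      next
    }
    prof <- profile_matrix(expr, samples, gene_list = genes, accession = a)
    sel <- withCallingHandlers(
      select_cluster_number(prof, K_min = an$K_min,
                                 K_max = min(an$K_max, nrow(prof) %/% 2L),
                            persistence_window = an$persistence_window,
                            n_restarts = an$kmeans_restarts,
                            seed = cfg$seed),
      warning = function(w) {
        report$warnings <<- c(report$warnings,
                              sprintf("cluster[%s]: %s", a,
                                      conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    clusterings[[a]] <- sel
    lab_rows[[a]] <- data.frame(accession = a,
                                gene = names(sel$clustering$labels),
                                cluster = as.integer(sel$clustering$labels),
                                silhouette = as.numeric(sel$clustering$silhouette))
    write_tsv(sel$diagnostics,
              file.path(outdir, sprintf("cluster_diagnostics_%s.tsv", a)))
  }
  if (length(lab_rows))
    write_tsv(do.call(rbind, lab_rows), file.path(outdir, "clusters.tsv"))
  report$seeds$cluster <- cfg$seed
  note("cluster", t0,
       K_star = vapply(clusterings, function(x) as.numeric(x$K_star),
                       numeric(1L)))

  # -- stage 7: per-cluster PVCA + gene-set enrichment -----------------------
  t0 <- as.numeric(Sys.time())
  gene_sets <- if (!is.null(cfg$inputs$gene_sets)) {
    read_gene_sets(cfg$inputs$gene_sets)
  } else if (!is.null(sim) && any(!is.na(sim$truth$genes$cluster))) {
    # planted clusters double as annotation sets for the synthetic run
    tg <- sim$truth$genes[!is.na(sim$truth$genes$cluster), ]
    split(tg$gene_id, paste0("planted_set_", tg$cluster))
  } else NULL
  enrich_n <- 0L
  for (a in names(clusterings)) {
    cl <- clusterings[[a]]$clustering
    in_acc <- samples$accession == a
    cp <- cluster_pvca(expr[, in_acc, drop = FALSE], cl,
                       design[in_acc, , drop = FALSE])
    if (!is.null(cp$proportions))
      write_tsv(data.frame(cluster = rownames(cp$proportions),
                           cp$proportions, check.names = FALSE),
                file.path(outdir, sprintf("cluster_pvca_%s.tsv", a)))
    if (!is.null(gene_sets)) {
      enr <- stress_annotation(cl, gene_sets, alpha = an$enrichment_alpha)
      write_tsv(enr$table, file.path(outdir, sprintf("enrichment_%s.tsv", a)))
      write_tsv(data.frame(cluster = rownames(enr$matrix), enr$matrix,
                           check.names = FALSE),
                file.path(outdir, sprintf("enrichment_matrix_%s.tsv", a)))
      enrich_n <- enrich_n + nrow(enr$table)
    }
  }
  note("enrich", t0, n_tests = enrich_n)

  # -- stage 8: vegetative PCA, regression, templates ------------------------
  t0 <- as.numeric(Sys.time())
  veg <- tryCatch(vegetative_subset(expr, samples, sig05),
                  error = function(e) NULL)
  if (!is.null(veg) && ncol(veg) > length(an$anova_terms) + 2L) {
    vdesign <- design[match(colnames(veg), design$sample_id), , drop = FALSE]
    vpc <- fit_pca(veg)
    write_tsv(data.frame(sample_id = rownames(vpc$scores),
                         vpc$scores[, seq_len(min(an$n_axes, ncol(vpc$scores))),
                                    drop = FALSE], check.names = FALSE),
              file.path(outdir, "vegpca_scores.tsv"))
    traj <- pc_trajectories(vpc, vdesign, axes = seq_len(an$n_axes))
    write_tsv(traj, file.path(outdir, "vegpca_trajectories.tsv"))
    reg <- tryCatch(
      regress_pc_on_covariates(vpc, vdesign, axes = seq_len(an$n_axes)),
      error = function(e) {
        report$warnings <<- c(report$warnings, conditionMessage(e)); NULL
      })
    if (!is.null(reg))
      write_tsv(as.data.frame(reg), file.path(outdir, "vegpca_regression.tsv"))
    tails <- lapply(seq_len(min(2L, ncol(vpc$scores))), function(ax) {
      extreme_loading_genes(vpc$loadings[, ax], an$alpha_per_tail)
    })
    write_tsv(data.frame(axis = rep(seq_along(tails), lengths(tails)),
                         gene = unlist(tails)),
              file.path(outdir, "vegpca_extreme_genes.tsv"))
    template <- names(which.max(abs(vpc$loadings[, 1L])))
    prof_all <- profile_matrix(veg, samples[samples$flowering_status ==
                                              "vegetative", , drop = FALSE])
    tm <- template_match(prof_all, template, an$template_threshold)
    write_tsv(tm$matches, file.path(outdir, "template_matches.tsv"))
    note("vegpca", t0, n_genes = nrow(veg), template = template,
         n_matches = nrow(tm$matches))
  } else {
    report$warnings <- c(report$warnings,
                         "vegetative subset unavailable; vegpca stage skipped")
    note("vegpca", t0, skipped = TRUE)
  }

  report$n_stages <- length(report$stages)
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
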