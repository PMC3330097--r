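#' @keywords internal
"_PACKAGE"

# ---- validation helpers ----------------------------------------------------

stop_parse <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_unique <- function(x, what, where) {
  dup <- unique(x[duplicated(x)])
  if (length(dup))
    stop_parse("duplicate %s in %s: %s", what, where,
               paste(utils::head(dup, 5L), collapse = ", "))
  invisible(x)
}

#' Validate a log2 expression matrix
#'
#' An expression matrix is a plain numeric matrix with unique gene ids as
#' rownames and unique sample ids as colnames, all values finite (log2-scale
#' intensities).
#'
#' @param mat numeric matrix, genes x samples.
#' @return the validated matrix, invisibly usable downstream.
#' @export
validate_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop_parse("expression data must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop_parse("expression matrix needs gene rownames and sample colnames")
  check_unique(rownames(mat), "gene id", "expression matrix")
  check_unique(colnames(mat), "sample id", "expression matrix")
  if (!all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    stop_parse("non-finite expression value at gene '%s', sample '%s'",
               rownames(mat)[bad[1L]], colnames(mat)[bad[2L]])
  }
  mat
}

#' Validate detection flags against a paired expression matrix
#'
#' @param flags logical matrix with the same dimnames as `mat`.
#' @param mat optional expression matrix to check axis agreement against.
#' @return the validated logical matrix.
#' @export
validate_flags <- function(flags, mat = NULL) {
  if (!is.matrix(flags) || !is.logical(flags))
    stop_parse("detection flags must be a logical matrix")
  if (anyNA(flags)) stop_parse("detection flags must not contain NA")
  check_unique(rownames(flags), "gene id", "detection flags")
  check_unique(colnames(flags), "sample id", "detection flags")
  if (!is.null(mat)) {
    if (!identical(dimnames(flags), dimnames(mat)))
      stop_parse("detection flags are not aligned with the expression matrix")
  }
  flags
}

#' Validate a sample table
#'
#' Columns: `sample_id`, `accession`, `day` (days after germination),
#' `flowering_status` (`"vegetative"` or `"flowering"`), `replicate`.
#'
#' @param samples data.frame.
#' @return the validated data.frame with `flowering_status` as factor.
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "accession", "day", "flowering_status", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop_parse("sample table is missing column(s): %s", paste(miss, collapse = ", "))
  check_unique(samples$sample_id, "sample_id", "sample table")
  if (any(samples$day < 0)) stop_parse("sample days must be non-negative")
  if (any(samples$replicate < 1)) stop_parse("replicate indices must be >= 1")
  bad <- setdiff(unique(samples$flowering_status), c("vegetative", "flowering"))
  if (length(bad))
    stop_parse("unknown flowering_status value(s): %s", paste(bad, collapse = ", "))
  samples$flowering_status <- factor(samples$flowering_status,
                                     levels = c("vegetative", "flowering"))
  samples$accession <- factor(samples$accession)
  samples
}

#' Validate a daily environment series
#'
#' Columns: `day`, `tmax`, `tmin` (degrees C), `precipitation` (mm).
#'
#' @param env data.frame.
#' @return the validated data.frame.
#' @export
validate_environment <- function(env) {
  need <- c("day", "tmax", "tmin", "precipitation")
  miss <- setdiff(need, names(env))
  if (length(miss))
    stop_parse("environment series is missing column(s): %s", paste(miss, collapse = ", "))
  check_unique(env$day, "day", "environment series")
  if (any(env$tmax < env$tmin))
    stop_parse("tmax < tmin on day(s): %s",
               paste(env$day[env$tmax < env$tmin], collapse = ", "))
  if (any(env$precipitation < 0)) stop_parse("precipitation must be >= 0")
  env
}

#' Validate a phenotype table
#'
#' Columns: `sample_id`, `rln` (rosette leaf number), `rd` (rosette
#' diameter). Missing phenotype values are allowed (`NA`).
#'
#' @param pheno data.frame.
#' @param samples optional sample table; phenotype ids must be a subset.
#' @return the validated data.frame.
#' @export
validate_phenotypes <- function(pheno, samples = NULL) {
  need <- c("sample_id", "rln", "rd")
  miss <- setdiff(need, names(pheno))
  if (length(miss))
    stop_parse("phenotype table is missing column(s): %s", paste(miss, collapse = ", "))
  check_unique(pheno$sample_id, "sample_id", "phenotype table")
  if (any(pheno$rln < 0, na.rm = TRUE) || any(pheno$rd < 0, na.rm = TRUE))
    stop_parse("phenotype values must be >= 0")
  if (!is.null(samples)) {
    unknown <- setdiff(pheno$sample_id, samples$sample_id)
    if (length(unknown))
      stop_parse("phenotype sample_id(s) not in sample table: %s",
                 paste(utils::head(unknown, 5L), collapse = ", "))
  }
  pheno
}

# ---- readers / writers -----------------------------------------------------

# Shared TSV reading with ragged-row detection. '.' decimal only, '#' comments.
read_tsv_checked <- function(path, sep = "\t") {
  nf <- utils::count.fields(path, sep = sep, comment.char = "#", quote = "")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L)
    stop_parse("ragged rows in '%s': rows have %s fields", path,
               paste(unique(nf), collapse = "/"))
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    comment.char = "#", quote = "", stringsAsFactors = FALSE)
}

numeric_matrix_from_df <- function(df, path) {
  ids <- as.character(df[[1L]])
  check_unique(ids, "gene id", path)
  check_unique(names(df)[-1L], "sample id", path)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(vals, 2L, as.numeric))) &
                   !is.na(vals), arr.ind = TRUE)
    if (nrow(bad))
      stop_parse("non-numeric cell in '%s' at row %d, column '%s'",
                 path, bad[1L, 1L], colnames(vals)[bad[1L, 2L]])
    vals <- apply(vals, 2L, as.numeric)
  }
  rownames(vals) <- ids
  vals
}

#' Read a gene x sample expression matrix from TSV
#'
#' First column gene ids, header row of sample ids. Round-trips through
#' [write_expression()] value-identically.
#'
#' @param path TSV file path.
#' @return validated numeric matrix (genes x samples).
#' @export
read_expression <- function(path) {
  validate_expression(numeric_matrix_from_df(read_tsv_checked(path), path))
}

#' Write an expression matrix to TSV
#'
#' @param mat expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  validate_expression(mat)
  df <- data.frame(gene_id = rownames(mat),
                   formatC(mat, digits = 17, format = "g"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read detection (present/absent) flags from TSV
#'
#' Same layout as [read_expression()]; cells are `TRUE`/`FALSE` or 0/1.
#'
#' @param path TSV file path.
#' @return logical matrix (genes x samples).
#' @export
read_flags <- function(path) {
  df <- read_tsv_checked(path)
  ids <- as.character(df[[1L]])
  check_unique(ids, "gene id", path)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  lg <- array(NA, dim(vals), dimnames = list(ids, colnames(vals)))
  lg[] <- vals %in% c("TRUE", "1", "T", TRUE, 1)
  bad <- !(vals %in% c("TRUE", "FALSE", "T", "F", "0", "1", TRUE, FALSE, 0, 1))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop_parse("non-boolean cell in '%s' at row %d, column '%s'",
               path, w[1L], colnames(vals)[w[2L]])
  }
  validate_flags(lg)
}

#' Write detection flags to TSV
#' @param flags logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flags <- function(flags, path) {
  validate_flags(flags)
  df <- data.frame(gene_id = rownames(flags), flags + 0L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample table from TSV
#' @param path TSV path with columns sample_id, accession, day,
#'   flowering_status, replicate.
#' @return validated data.frame.
#' @export
read_samples <- function(path) validate_samples(read_tsv_checked(path))

#' Read a daily environment series from CSV
#' @param path CSV path with header `day,tmax,tmin,precipitation`.
#' @return validated data.frame.
#' @export
read_environment <- function(path) validate_environment(read_tsv_checked(path, sep = ","))

#' Read a phenotype table from TSV (NA allowed)
#' @param path TSV path with columns sample_id, rln, rd.
#' @return validated data.frame.
#' @export
read_phenotypes <- function(path) validate_phenotypes(read_tsv_checked(path))

#' Write a data.frame to TSV (generic pipeline output)
#' @param df data.frame.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, sep = "\t") {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17, format = "g"))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT dialect: one set per line, `name TAB description TAB member TAB ...`.
#' Member ids are kept verbatim; restriction to an analysis universe happens
#' at enrichment time.
#'
#' @param path GMT file path.
#' @return object of class `gene_set_collection`: a named list of character
#'   vectors with a `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop_parse("GMT line %d has %d field(s); need name, description, >=1 member",
                 i, length(f))
    nms[i] <- f[1L]; desc[i] <- f[2L]
    sets[[i]] <- unique(f[-(1:2)])
  }
  check_unique(nms, "set name", path)
  names(sets) <- nms
  structure(sets, descriptions = stats::setNames(desc, nms),
            class = "gene_set_collection")
}

#' Sizes of the sets in a collection
#' @param sets `gene_set_collection`.
#' @return named integer vector.
#' @export
gene_set_sizes <- function(sets) vapply(sets, length, integer(1L))

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
              length(x), min(gene_set_sizes(x)), max(gene_set_sizes(x))))
  invisible(x)
}

#' Join samples, environment, and phenotypes into one design table
#'
#' One row per sample carrying accession, day (also exposed as `age`),
#' flowering status, replicate, that day's weather, and (optionally)
#' phenotypes. Every sampled day must be present in the environment series.
#'
#' @param samples sample table.
#' @param env environment series.
#' @param pheno optional phenotype table; samples without a phenotype row get
#'   `NA`.
#' @return design data.frame with one row per sample, input order preserved.
#' @export
join_design <- function(samples, env, pheno = NULL) {
  samples <- validate_samples(samples)
  env <- validate_environment(env)
  missing_days <- setdiff(unique(samples$day), env$day)
  if (length(missing_days))
    stop_parse("environment series missing sampled day(s): %s",
               paste(sort(missing_days), collapse = ", "))
  idx <- match(samples$day, env$day)
  out <- cbind(samples,
               age = samples$day,
               env[idx, c("tmax", "tmin", "precipitation"), drop = FALSE])
  rownames(out) <- NULL
  if (!is.null(pheno)) {
    pheno <- validate_phenotypes(pheno, samples)
    pidx <- match(out$sample_id, pheno$sample_id)
    out$rln <- pheno$rln[pidx]
    out$rd <- pheno$rd[pidx]
  }
  stopifnot(nrow(out) == nrow(samples))
  out
}
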