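# Present-call aggregation: a gene counts as expressed at a timepoint only if
# it is flagged present in every available replicate of that
# (accession, day) sample.

#' Expressed-gene census from detection flags
#'
#' Applies the all-replicates rule per (accession, day, flowering status)
#' group: a gene is expressed at that timepoint iff flagged present on every
#' available replicate array (the rule degrades gracefully to "all available
#' replicates" when one replicate is missing).
#'
#' @param flags logical genes x samples matrix.
#' @param samples sample table aligned with `flags` columns.
#' @return object of class `expression_census`: list with `timepoint_sets`
#'   (named list of gene-id vectors, one per accession_day group),
#'   `timepoint_info` (data.frame mapping set name to accession, day,
#'   flowering status, and n replicates), `accession_sets` (union over
#'   timepoints per accession), `union` (genes expressed anywhere), and
#'   `counts` (per-timepoint expressed-gene counts).
#' @export
call_expressed <- function(flags, samples) {
  samples <- validate_samples(samples)
  flags <- validate_flags(flags)
  if (!setequal(colnames(flags), samples$sample_id) ||
      ncol(flags) != nrow(samples))
    stop_parse("flag columns do not match the sample table")
  flags <- flags[, samples$sample_id, drop = FALSE]
  key <- interaction(samples$accession, samples$day, samples$flowering_status,
                     drop = TRUE, sep = "|")
  groups <- split(seq_len(nrow(samples)), key)
  if (any(lengths(groups) == 0L))
    stop_parse("timepoint with zero replicates")
  genes <- rownames(flags)
  tp_sets <- lapply(groups, function(ix) {
    genes[rowSums(flags[, ix, drop = FALSE]) == length(ix)]
  })
  info <- do.call(rbind, lapply(names(groups), function(nm) {
    ix <- groups[[nm]]
    data.frame(timepoint = nm,
               accession = as.character(samples$accession[ix[1L]]),
               day = samples$day[ix[1L]],
               flowering_status = as.character(samples$flowering_status[ix[1L]]),
               n_replicates = length(ix), stringsAsFactors = FALSE)
  }))
  acc_sets <- lapply(split(info$timepoint, info$accession), function(tps) {
    sort(unique(unlist(tp_sets[tps], use.names = FALSE)))
  })
  structure(list(
    timepoint_sets = tp_sets,
    timepoint_info = info,
    accession_sets = acc_sets,
    union = sort(unique(unlist(tp_sets, use.names = FALSE))),
    counts = vapply(tp_sets, length, integer(1L))),
    class = "expression_census")
}

#' @export
print.expression_census <- function(x, ...) {
  cat(sprintf("expression_census: %d timepoints, %d genes expressed overall\n",
              length(x$timepoint_sets), length(x$union)))
  invisible(x)
}

#' Venn-region counts for 2 or 3 named gene sets
#'
#' @param sets named list of >= 2 character vectors (e.g. accession unions
#'   from [call_expressed()]).
#' @return data.frame with one row per region of the Venn partition: a
#'   membership column per set and the region `count`; counts sum to the
#'   union size.
#' @export
venn_counts <- function(sets) {
  if (is.null(names(sets)) || length(sets) < 2L)
    stop_parse("venn_counts needs >= 2 named sets")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(sets)))
  patt <- apply(member, 1L, paste, collapse = "")
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(sets)
  grid <- grid[rowSums(grid) > 0L, , drop = FALSE]
  key <- apply(grid, 1L, paste, collapse = "")
  grid$count <- as.integer(table(factor(patt, levels = key)))
  rownames(grid) <- NULL
  grid
}

#' Genes never called expressed anywhere
#'
#' @param census `expression_census`.
#' @param universe full gene-id vector.
#' @return character vector: `universe` minus the census union.
#' @export
absent_everywhere <- function(census, universe) {
  stopifnot(inherits(census, "expression_census"))
  setdiff(universe, census$union)
}
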