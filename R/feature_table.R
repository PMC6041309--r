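# Taxonomic ranks tracked per feature, coarse to fine.
TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

# Depth used to decide whether an aggregation target is "at or above" the
# table's current resolution. Sequence-level features (genotypes, OTUs) sit
# below genus, hence depth 7.
.level_depth <- function(level) {
  switch(level,
    genotype = 7L, otu = 7L,
    genus = 6L, family = 5L, order = 4L, class = 3L, phylum = 2L, domain = 1L,
    stop("unknown level: ", level)
  )
}

#' Construct a feature count table
#'
#' A `feature_table` holds non-negative integer counts of sequence features
#' (denoised genotypes, OTUs, or taxa after aggregation) per sample, together
#' with a taxonomic lineage for every feature. It is the central container of
#' the pipeline: decontamination, diversity and similarity analyses all
#' consume it.
#'
#' @param counts integer matrix, features in rows, samples in columns. Row and
#'   column names are used as feature and sample identifiers and must be
#'   unique.
#' @param lineages character matrix with one row per feature and up to six
#'   columns (`domain` ... `genus`). Unknown ranks must carry an explicit
#'   `unclassified_<parent>` placeholder, never an empty string; use
#'   [fill_lineage()] to normalise.
#' @param level resolution of the features: one of `"genotype"`, `"otu"`,
#'   `"genus"`, `"phylum"` (intermediate ranks are also accepted after
#'   aggregation).
#' @return an object of class `feature_table` with elements `counts`,
#'   `lineages`, `level`.
#' @export
feature_table <- function(counts, lineages, level = "genotype") {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid count at feature '%s', sample '%s': %s",
      rownames(counts)[bad[1, 1]] %||% bad[1, 1],
      colnames(counts)[bad[1, 2]] %||% bad[1, 2],
      format(counts[bad[1, , drop = FALSE]])
    ), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) stop("counts must have feature ids as rownames")
    rownames(counts) <- character(0)
  }
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature id: ",
         rownames(counts)[duplicated(rownames(counts))][1], call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         colnames(counts)[duplicated(colnames(counts))][1], call. = FALSE)

  if (!is.matrix(lineages)) lineages <- as.matrix(lineages)
  if (nrow(lineages) != nrow(counts))
    stop("lineages must have one row per feature")
  if (ncol(lineages) > length(TAX_RANKS))
    stop("lineages may have at most ", length(TAX_RANKS), " ranks")
  colnames(lineages) <- TAX_RANKS[seq_len(ncol(lineages))]
  rownames(lineages) <- rownames(counts)
  if (any(is.na(lineages)) || any(!nzchar(lineages)))
    stop("lineages must not contain empty ranks; use unclassified_<parent> placeholders")

  level <- match.arg(level, c("genotype", "otu", TAX_RANKS))
  structure(list(counts = counts, lineages = lineages, level = level),
            class = "feature_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples (level: %s)\n",
              nrow(x$counts), ncol(x$counts), x$level))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Pad a lineage with unclassified placeholders
#'
#' Fills missing ranks with `unclassified_<deepest known taxon>` so every
#' feature carries a complete lineage down to genus, and placeholder taxa
#' remain distinguishable (an unclassified Lachnospiraceae genus is a
#' different taxon from an unclassified Ruminococcaceae genus).
#'
#' @param ranks character vector of known ranks, coarse to fine.
#' @param n_ranks total number of ranks to return.
#' @return character vector of length `n_ranks`.
#' @export
fill_lineage <- function(ranks, n_ranks = length(TAX_RANKS)) {
  ranks <- ranks[nzchar(ranks)]
  if (length(ranks) >= n_ranks) return(ranks[seq_len(n_ranks)])
  deepest <- if (length(ranks) == 0) "root" else ranks[length(ranks)]
  # collapse nested placeholders: unclassified_unclassified_X -> unclassified_X
  stem <- sub("^(unclassified_)+", "", deepest)
  c(ranks, rep(paste0("unclassified_", stem), n_ranks - length(ranks)))
}

#' Relative-abundance view of a feature table
#'
#' Counts are the primary representation; relative abundances are always
#' derived on demand. Columns of samples with at least one read sum to 1;
#' an all-zero sample yields an all-zero column and a warning (it is flagged,
#' not an error).
#'
#' @param table a [feature_table()].
#' @return numeric matrix of per-sample relative abundances.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  totals <- colSums(table$counts)
  empty <- totals == 0
  if (any(empty))
    warning("all-zero sample(s): ",
            paste(colnames(table$counts)[empty], collapse = ", "))
  totals[empty] <- 1
  sweep(table$counts, 2, totals, "/")
}

#' Aggregate features to a coarser taxonomic rank
#'
#' Sums counts of all features sharing the lineage prefix down to
#' `target_level`. Placeholder ranks aggregate by their full placeholder
#' string, so e.g. `unclassified_Lachnospiraceae` stays distinct from
#' `unclassified_Ruminococcaceae` at genus level. Per-sample totals are
#' conserved exactly, and aggregating a table already at `target_level` is
#' the identity up to row order.
#'
#' @param table a [feature_table()].
#' @param target_level a rank at or above the table's level, usually
#'   `"genus"` or `"phylum"`.
#' @return a [feature_table()] at `target_level`.
#' @export
aggregate_taxa <- function(table, target_level) {
  stopifnot(inherits(table, "feature_table"))
  target_level <- match.arg(target_level, TAX_RANKS)
  depth <- match(target_level, TAX_RANKS)
  if (depth > .level_depth(table$level) ||
      (depth == 6L && !table$level %in% c("genotype", "otu", "genus")))
    stop("cannot aggregate below current level (", table$level, " -> ",
         target_level, ")")
  if (depth > ncol(table$lineages))
    stop("lineages do not reach rank ", target_level)

  prefix <- table$lineages[, seq_len(depth), drop = FALSE]
  key <- apply(prefix, 1, paste, collapse = ";")
  agg <- rowsum(matrix(as.numeric(table$counts), nrow = nrow(table$counts),
                       dimnames = dimnames(table$counts)),
                group = key, reorder = TRUE)
  keys <- rownames(agg)
  lin <- prefix[match(keys, key), , drop = FALSE]
  ids <- unname(lin[, depth])
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  rownames(agg) <- ids
  rownames(lin) <- ids
  feature_table(agg, lin, level = target_level)
}

#' Subset a feature table by samples and/or features
#'
#' @param table a [feature_table()].
#' @param samples sample ids or indices to keep (default all).
#' @param features feature ids or indices to keep (default all).
#' @return a [feature_table()].
#' @export
subset_samples <- function(table, samples = NULL, features = NULL) {
  stopifnot(inherits(table, "feature_table"))
  counts <- table$counts
  lineages <- table$lineages
  if (!is.null(features)) {
    counts <- counts[features, , drop = FALSE]
    lineages <- lineages[features, , drop = FALSE]
  }
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  feature_table(counts, lineages, level = table$level)
}

#' Collapse a lineage matrix to semicolon-delimited strings
#' @param lineages character matrix of ranks.
#' @return character vector.
#' @export
lineage_strings <- function(lineages) {
  vapply(seq_len(nrow(lineages)),
         function(i) paste(lineages[i, ], collapse = ";"), character(1))
}
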