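# Alpha diversity (Shannon, Hill numbers), phylum summaries and core-taxon
# detection by prevalence and median relative abundance.

#' Shannon diversity of a count vector
#'
#' Natural-log Shannon index -sum(p_i * ln p_i) over the positive counts.
#'
#' @param counts non-negative numeric vector with at least one positive
#'   entry.
#' @return Shannon index in nats.
#' @export
shannon <- function(counts) {
  stopifnot(all(counts >= 0))
  p <- counts[counts > 0]
  if (length(p) == 0) stop("Shannon diversity undefined for all-zero counts")
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Hill number (effective number of taxa) of order q
#'
#' (sum p_i^q)^(1/(1-q)), with the q -> 1 limit exp(Shannon) evaluated
#' explicitly. q = 0 gives richness, q = 2 the inverse Simpson index.
#'
#' @param counts non-negative numeric vector with at least one positive
#'   entry.
#' @param q diversity order, q >= 0.
#' @return effective number of equally abundant taxa.
#' @export
hill <- function(counts, q) {
  stopifnot(all(counts >= 0))
  if (q < 0) stop("Hill order q must be non-negative")
  p <- counts[counts > 0]
  if (length(p) == 0) stop("Hill number undefined for all-zero counts")
  p <- p / sum(p)
  if (q == 0) return(length(p))
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Per-sample alpha diversity of a feature table
#'
#' @param table a [feature_table()], conventionally at OTU/genotype level.
#' @param q Hill orders to evaluate (default 0, 1, 2).
#' @return data.frame with `sample_id`, `shannon` and one `hill_q<q>`
#'   column per order. All-zero samples get NA.
#' @export
alpha_diversity <- function(table, q = c(0, 1, 2)) {
  stopifnot(inherits(table, "feature_table"))
  res <- data.frame(sample_id = colnames(table$counts),
                    stringsAsFactors = FALSE)
  ok <- colSums(table$counts) > 0
  res$shannon <- NA_real_
  res$shannon[ok] <- apply(table$counts[, ok, drop = FALSE], 2, shannon)
  for (qq in q) {
    col <- paste0("hill_q", qq)
    res[[col]] <- NA_real_
    res[[col]][ok] <- apply(table$counts[, ok, drop = FALSE], 2, hill, q = qq)
  }
  res
}

#' Core taxa of a sample group
#'
#' A taxon is core when its median within-sample relative abundance across
#' the group's samples is strictly greater than `abund_min` AND it is
#' detected (>= 1 read) in at least `prev_min` of the samples. Zeros count
#' towards the median and SD (a taxon absent from a sample contributes 0).
#'
#' @param table a [feature_table()], conventionally at genus level.
#' @param metadata sample metadata.
#' @param group group label to profile.
#' @param abund_min median relative-abundance threshold (default 0.001,
#'   i.e. >0.1\%; strict).
#' @param prev_min prevalence threshold (default 0.75; inclusive).
#' @return data.frame with `taxon`, `lineage`, `median_abundance`,
#'   `sd_abundance`, `prevalence`, `prevalence_pct`, sorted by lineage;
#'   attributes `group` and `n`.
#' @export
core_taxa <- function(table, metadata, group,
                      abund_min = 0.001, prev_min = 0.75) {
  stopifnot(inherits(table, "feature_table"))
  ids <- metadata$sample_id[metadata$group == group]
  ids <- intersect(ids, colnames(table$counts))
  if (length(ids) == 0) stop("no samples in group: ", group)
  sub <- subset_samples(table, samples = ids)
  rel <- suppressWarnings(relative_abundance(sub))
  med <- apply(rel, 1, stats::median)
  sdv <- apply(rel, 1, .sd0)
  npos <- rowSums(sub$counts >= 1)
  prev <- npos / length(ids)
  keep <- med > abund_min & prev >= prev_min
  lin <- lineage_strings(sub$lineages[keep, , drop = FALSE])
  out <- data.frame(taxon = rownames(sub$counts)[keep],
                    lineage = lin,
                    median_abundance = med[keep],
                    sd_abundance = sdv[keep],
                    prevalence = prev[keep],
                    prevalence_pct = round(100 * npos[keep] / length(ids)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$lineage), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "group") <- group
  attr(out, "n") <- length(ids)
  out
}

#' Per-group phylum composition summary
#'
#' Aggregates the table to phylum level and reports, for each group, the
#' median and SD across samples of the relative abundances of the four
#' major phyla (Actinobacteria, Bacteroidetes, Firmicutes, Proteobacteria)
#' plus a pooled "other" category. Medians are not additive and need not
#' sum to 1 within a group.
#'
#' @param table a [feature_table()] aggregable to phylum.
#' @param metadata sample metadata.
#' @param major phyla reported individually.
#' @return data.frame with `group`, `phylum`, `median`, `sd`, `n`.
#' @export
phylum_summary <- function(table, metadata,
                           major = c("Actinobacteria", "Bacteroidetes",
                                     "Firmicutes", "Proteobacteria")) {
  stopifnot(inherits(table, "feature_table"))
  ph <- if (table$level == "phylum") table else aggregate_taxa(table, "phylum")
  rel <- suppressWarnings(relative_abundance(ph))
  phyla <- ph$lineages[, "phylum"]
  rows <- lapply(c(major, "other"), function(p) {
    if (p == "other") colSums(rel[!phyla %in% major, , drop = FALSE])
    else colSums(rel[phyla == p, , drop = FALSE])
  })
  names(rows) <- c(major, "other")
  grp <- metadata$group[match(colnames(rel), metadata$sample_id)]
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    idx <- which(grp == g)
    do.call(rbind, lapply(names(rows), function(p) {
      data.frame(group = g, phylum = p,
                 median = stats::median(rows[[p]][idx]),
                 sd = .sd0(rows[[p]][idx]), n = length(idx),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Coverage of a core-taxon set within each sample
#'
#' For each sample of the group: the fraction of its detected taxa that are
#' core, and the fraction of its reads falling in core taxa.
#'
#' @param core a [core_taxa()] table computed on the same group.
#' @param table the [feature_table()] the core set was derived from.
#' @param metadata sample metadata.
#' @param group group label.
#' @return list with `per_sample` (data.frame `sample_id`, `taxa_fraction`,
#'   `read_fraction`) and the group medians `median_taxa_fraction`,
#'   `median_read_fraction`.
#' @export
core_read_coverage <- function(core, table, metadata, group) {
  stopifnot(inherits(table, "feature_table"))
  ids <- intersect(metadata$sample_id[metadata$group == group],
                   colnames(table$counts))
  if (length(ids) == 0) stop("no samples in group: ", group)
  counts <- table$counts[, ids, drop = FALSE]
  is_core <- rownames(counts) %in% core$taxon
  present <- counts >= 1
  n_present <- colSums(present)
  depths <- colSums(counts)
  taxa_fraction <- ifelse(n_present > 0,
                          colSums(present & is_core) / pmax(n_present, 1), 0)
  read_fraction <- ifelse(depths > 0,
                          colSums(counts * is_core) / pmax(depths, 1), 0)
  per_sample <- data.frame(sample_id = ids,
                           taxa_fraction = taxa_fraction,
                           read_fraction = read_fraction,
                           row.names = NULL, stringsAsFactors = FALSE)
  list(per_sample = per_sample,
       median_taxa_fraction = stats::median(taxa_fraction),
       median_read_fraction = stats::median(read_fraction))
}
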