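# Cross-sample and cross-group similarity: Spearman correlations between
# paired dam and calf communities, Friedman + Nemenyi blocked comparisons,
# Bray-Curtis dissimilarity and principal coordinates analysis, shared-taxon
# Venn partitions and the dam-calf co-existence matrix.

#' Spearman rank correlation of two composition vectors
#'
#' Pearson correlation of average-assigned ranks. When comparing two
#' samples' compositions the vectors should span the union of taxa detected
#' in either sample, zeros filled (the many tied zeros receive average
#' ranks).
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return Spearman's rho in [-1, 1]; NA (with a warning) when either
#'   vector has zero rank variance, where the coefficient is undefined.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    warning("zero rank variance; Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

# Union-support composition pair for two sample columns of a relative
# abundance matrix: taxa absent from both samples are dropped.
.union_pair <- function(rel, s1, s2) {
  keep <- rel[, s1] > 0 | rel[, s2] > 0
  list(x = rel[keep, s1], y = rel[keep, s2])
}

#' Paired dam-calf community correlations
#'
#' For every dam-calf pair (a dam sample row whose `dam_of` names the calf
#' animal), computes the Spearman correlation between the calf's
#' composition in `calf_group` and the dam's composition at each site.
#' Pairs missing any sample are dropped as whole blocks (with a message).
#'
#' @param table a [feature_table()] at genus level.
#' @param metadata sample metadata with `dam_of` links.
#' @param calf_group calf group compared (default `"newborn"`).
#' @param dam_sites dam site groups (the comparison conditions).
#' @return a `paired_correlations` list: `rho` (blocks x sites matrix),
#'   `medians`, `sds`, `blocks` (calf animal ids), `conditions`.
#' @export
paired_group_correlations <- function(table, metadata,
                                      calf_group = "newborn",
                                      dam_sites = c("dam_oral", "dam_feces",
                                                    "dam_vestibule")) {
  stopifnot(inherits(table, "feature_table"))
  rel <- suppressWarnings(relative_abundance(table))
  dam_rows <- metadata[!is.na(metadata$dam_of) &
                         metadata$group %in% dam_sites, , drop = FALSE]
  calves <- unique(dam_rows$dam_of)
  rows <- list()
  for (calf in calves) {
    calf_sample <- metadata$sample_id[metadata$animal_id == calf &
                                        metadata$group == calf_group]
    site_samples <- vapply(dam_sites, function(site) {
      s <- dam_rows$sample_id[dam_rows$dam_of == calf &
                                dam_rows$group == site]
      if (length(s) == 1) s else NA_character_
    }, character(1))
    have <- length(calf_sample) == 1 &&
      all(c(calf_sample, site_samples) %in% colnames(rel))
    if (!have) {
      message("dropping incomplete dam-calf block: ", calf)
      next
    }
    rows[[calf]] <- vapply(site_samples, function(s) {
      p <- .union_pair(rel, calf_sample, s)
      spearman_rho(p$x, p$y)
    }, numeric(1))
  }
  if (length(rows) < 2)
    stop("fewer than 2 complete dam-calf blocks; paired comparison undefined")
  rho <- do.call(rbind, rows)
  colnames(rho) <- dam_sites
  structure(list(rho = rho,
                 medians = apply(rho, 2, stats::median),
                 sds = apply(rho, 2, stats::sd),
                 blocks = rownames(rho),
                 conditions = dam_sites),
            class = "paired_correlations")
}

#' @export
print.paired_correlations <- function(x, ...) {
  cat(sprintf("paired_correlations: %d blocks x %d conditions\n",
              nrow(x$rho), ncol(x$rho)))
  print(round(rbind(median = x$medians, sd = x$sds), 3))
  invisible(x)
}

#' Friedman rank sum test for blocked data
#'
#' Ranks the k conditions within each of the n blocks (average ranks for
#' ties) and tests for equal mean ranks with the tie-corrected statistic
#' (k-1) * sum_j (R_j - n(k+1)/2)^2 / (A - C), where R_j are rank column
#' sums, A the sum of squared ranks and C = n k (k+1)^2 / 4. Without ties
#' this reduces to the classical 12/(nk(k+1)) * sum (R_j - n(k+1)/2)^2.
#' The p-value comes from the chi-squared upper tail with k-1 df.
#'
#' @param blocked numeric matrix, blocks in rows, conditions in columns; no
#'   missing values.
#' @return an `lb_test` list: `statistic`, `df`, `p`, `mean_ranks`.
#' @export
friedman_test <- function(blocked) {
  blocked <- as.matrix(blocked)
  if (any(!is.finite(blocked))) stop("incomplete block(s) in Friedman test")
  n <- nrow(blocked); k <- ncol(blocked)
  if (n < 2 || k < 2) stop("Friedman test needs >= 2 blocks and >= 2 conditions")
  r <- t(apply(blocked, 1, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  if (A == C) {
    stat <- 0
  } else {
    stat <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
  }
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  structure(list(statistic = stat, df = k - 1L, p = min(max(p, 0), 1),
                 mean_ranks = Rj / n,
                 method = "Friedman rank sum test"),
            class = "lb_test")
}

#' Nemenyi post-hoc test after Friedman
#'
#' Pairwise comparison of mean ranks for unreplicated blocked data with the
#' q (studentized range) approximation: for conditions i, j the statistic
#' q_ij = (Rbar_i - Rbar_j) / sqrt(k(k+1)/(6n)) is referred, after scaling
#' by sqrt(2), to the studentized range distribution with k groups and
#' infinite degrees of freedom.
#'
#' @param blocked numeric matrix, blocks x conditions.
#' @return symmetric k x k matrix of two-sided p-values, unit diagonal.
#' @export
nemenyi_posthoc <- function(blocked) {
  blocked <- as.matrix(blocked)
  if (any(!is.finite(blocked))) stop("incomplete block(s) in Nemenyi test")
  n <- nrow(blocked); k <- ncol(blocked)
  if (n < 2 || k < 2) stop("Nemenyi test needs >= 2 blocks and >= 2 conditions")
  mean_ranks <- colMeans(t(apply(blocked, 1, rank)))
  qstat <- abs(outer(mean_ranks, mean_ranks, "-")) /
    sqrt(k * (k + 1) / (6 * n))
  p <- stats::ptukey(qstat * sqrt(2), nmeans = k, df = Inf,
                     lower.tail = FALSE)
  diag(p) <- 1
  dimnames(p) <- list(colnames(blocked), colnames(blocked))
  p
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' 1 - 2 * sum(min(x_i, y_i)) / (sum x + sum y); 0 for identical vectors, 1
#' for disjoint supports.
#'
#' @param x,y equal-length non-negative vectors, not both all-zero.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero vectors")
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Pairwise Bray-Curtis dissimilarity matrix of a feature table
#'
#' Computed on per-sample relative abundances.
#'
#' @param table a [feature_table()].
#' @return symmetric samples x samples matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  rel <- suppressWarnings(relative_abundance(table))
  n <- ncol(rel)
  d <- matrix(0, n, n, dimnames = list(colnames(rel), colnames(rel)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- bray_curtis(rel[, i], rel[, j])
    }
  }
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres -D^2/2 and eigendecomposes it. Axes are ordered by
#' decreasing eigenvalue; negative eigenvalues (which arise for
#' non-Euclidean dissimilarities such as Bray-Curtis) are excluded from the
#' coordinates and from the variance-explained denominator, which uses the
#' sum of positive eigenvalues only. Their presence is flagged in
#' `negative_eigenvalues`.
#'
#' @param d square symmetric dissimilarity matrix with zero diagonal.
#' @return a `pcoa_result` list: `coordinates` (samples x axes),
#'   `eigenvalues` (all, including any negative ones),
#'   `variance_explained` (\% per retained axis), `negative_eigenvalues`
#'   (logical flag).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-12,
                                              check.attributes = FALSE)))
    stop("pcoa needs a square symmetric dissimilarity matrix")
  if (any(abs(diag(d)) > 1e-12)) stop("pcoa needs a zero diagonal")
  n <- nrow(d)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-8
  pos <- eig > tol
  coords <- fit$points[, seq_len(min(sum(pos), ncol(fit$points))),
                       drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  varexp <- 100 * eig[pos][seq_len(ncol(coords))] / sum(eig[pos])
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 variance_explained = varexp,
                 negative_eigenvalues = any(eig < -tol)),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d axes (axis 1: %.1f%% variance)%s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              x$variance_explained[1],
              if (x$negative_eigenvalues) " [negative eigenvalues present]"
              else ""))
  invisible(x)
}

#' Shared-taxon (Venn) partition across groups
#'
#' A taxon is "present" in a group when its median relative abundance
#' across the group's samples is > 0, i.e. it is detected in a strict
#' majority of the samples. Returns the taxon count of every exclusive
#' intersection region; region counts sum to the size of the taxon
#' universe (taxa present in at least one group).
#'
#' @param table a [feature_table()] at genus level.
#' @param metadata sample metadata.
#' @param groups two or more group labels.
#' @return list with `regions` (named integer vector; names are group
#'   subsets joined by `&`), `universe_size`, and the logical `membership`
#'   matrix (taxa x groups).
#' @export
shared_taxa_partition <- function(table, metadata, groups) {
  stopifnot(inherits(table, "feature_table"), length(groups) >= 2)
  rel <- suppressWarnings(relative_abundance(table))
  membership <- vapply(groups, function(g) {
    ids <- intersect(metadata$sample_id[metadata$group == g], colnames(rel))
    if (length(ids) == 0) stop("no samples in group: ", g)
    apply(rel[, ids, drop = FALSE], 1, stats::median) > 0
  }, logical(nrow(rel)))
  in_universe <- rowSums(membership) > 0
  membership <- membership[in_universe, , drop = FALSE]
  key <- apply(membership, 1, function(m) paste(groups[m], collapse = "&"))
  all_regions <- unlist(lapply(seq_along(groups), function(m) {
    utils::combn(groups, m, paste, collapse = "&")
  }))
  regions <- stats::setNames(integer(length(all_regions)), all_regions)
  tab <- table(key)
  regions[names(tab)] <- as.integer(tab)
  list(regions = regions, universe_size = sum(in_universe),
       membership = membership)
}

#' Dam-calf taxon co-existence matrix
#'
#' Restricted to taxa detected at >= `hit_cutoff` reads in more than
#' `newborn_prevalence_min` of the calves in `calf_group`. For each such
#' taxon and each dam site, reports the fraction of dams in which the taxon
#' reaches >= `hit_cutoff` reads, among the dams whose own calf carries the
#' taxon at >= `hit_cutoff` reads.
#'
#' @param table a [feature_table()] at genus level.
#' @param metadata sample metadata with `dam_of` links.
#' @param calf_group calf group (default `"newborn"`).
#' @param dam_sites dam site groups.
#' @param hit_cutoff detection cutoff in reads per taxon per animal
#'   (default 20, inclusive).
#' @param newborn_prevalence_min strict lower bound on the fraction of
#'   calves carrying the taxon (default 0.5).
#' @return list with `matrix` (taxa x dam sites; NA where no dam's calf
#'   carries the taxon), `calf_occurrence` (fraction of calves carrying
#'   each taxon) and `n_pairs`.
#' @export
coexistence_matrix <- function(table, metadata, calf_group = "newborn",
                               dam_sites = c("dam_feces", "dam_vestibule",
                                             "dam_oral"),
                               hit_cutoff = 20,
                               newborn_prevalence_min = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  counts <- table$counts
  calf_md <- metadata[metadata$group == calf_group, , drop = FALSE]
  calf_samples <- intersect(calf_md$sample_id, colnames(counts))
  if (length(calf_samples) == 0) stop("no samples in group: ", calf_group)
  calf_hits <- counts[, calf_samples, drop = FALSE] >= hit_cutoff
  occurrence <- rowMeans(calf_hits)
  qualify <- occurrence > newborn_prevalence_min
  if (!any(qualify)) {
    warning("no taxa pass the co-existence cutoffs")
    return(list(matrix = matrix(numeric(0), 0, length(dam_sites),
                                dimnames = list(NULL, dam_sites)),
                calf_occurrence = occurrence[0], n_pairs = 0L))
  }
  dam_rows <- metadata[!is.na(metadata$dam_of) &
                         metadata$group %in% dam_sites, , drop = FALSE]
  pairs <- unique(dam_rows$dam_of)
  taxa <- rownames(counts)[qualify]
  mat <- matrix(NA_real_, length(taxa), length(dam_sites),
                dimnames = list(taxa, dam_sites))
  for (site in dam_sites) {
    num <- den <- stats::setNames(numeric(length(taxa)), taxa)
    for (calf in pairs) {
      calf_sample <- metadata$sample_id[metadata$animal_id == calf &
                                          metadata$group == calf_group]
      dam_sample <- dam_rows$sample_id[dam_rows$dam_of == calf &
                                         dam_rows$group == site]
      if (length(calf_sample) != 1 || length(dam_sample) != 1) next
      in_calf <- counts[taxa, calf_sample] >= hit_cutoff
      in_dam <- counts[taxa, dam_sample] >= hit_cutoff
      den <- den + in_calf
      num <- num + (in_calf & in_dam)
    }
    mat[, site] <- ifelse(den > 0, num / den, NA_real_)
  }
  list(matrix = mat, calf_occurrence = occurrence[qualify],
       n_pairs = length(pairs))
}
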