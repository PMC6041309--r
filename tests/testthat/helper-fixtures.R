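# Fixture builders and independent oracles shared across the test files.

# small feature table built directly from a matrix
make_table <- function(counts, genera = NULL, level = "genotype") {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("f%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  if (is.null(genera)) genera <- rownames(counts)
  lineages <- t(vapply(genera, function(g)
    fill_lineage(c("Bacteria", "Firmicutes", "Bacilli", "Bacillales",
                   "Staphylococcaceae", g)), character(6)))
  rownames(lineages) <- rownames(counts)
  feature_table(counts, lineages, level = level)
}

make_metadata <- function(table, controls = character(0),
                          groups = NULL) {
  ids <- colnames(table$counts)
  if (is.null(groups)) {
    groups <- ifelse(ids %in% controls, "control", "newborn")
  }
  data.frame(sample_id = ids, animal_id = paste0("a_", ids),
             group = groups, stringsAsFactors = FALSE)
}

# brute-force decontamination oracle: literal per-(feature, sample)
# application of the ratio rule, written independently of decontaminate()
brute_force_verdicts <- function(counts, controls, threshold = 4,
                                 pooling = "pooled") {
  samples <- setdiff(colnames(counts), controls)
  ctrl <- counts[, controls, drop = FALSE]
  if (pooling == "pooled") {
    ctrl_rel <- rowSums(ctrl) / sum(ctrl)
  } else {
    per <- sapply(seq_along(controls), function(j) {
      d <- sum(ctrl[, j]); if (d == 0) rep(0, nrow(ctrl)) else ctrl[, j] / d
    })
    ctrl_rel <- apply(per, 1, max)
  }
  out <- matrix(NA_character_, nrow(counts), length(samples),
                dimnames = list(rownames(counts), samples))
  for (s in samples) {
    depth <- sum(counts[, s])
    for (f in rownames(counts)) {
      rel <- if (depth == 0) 0 else counts[f, s] / depth
      out[f, s] <-
        if (ctrl_rel[f] == 0) "sample_only"
        else if (rel > threshold * ctrl_rel[f]) "accepted_shared"
        else "rejected"
    }
  }
  out
}

# Spearman oracle: average ranks then the Pearson product-moment formula
rank_pearson <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exhaustive within-block permutation distribution of the Friedman
# statistic for k = 3
friedman_permutation_p <- function(m, stat_fun) {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  n <- nrow(m)
  idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), n)))
  obs <- stat_fun(m)
  all_stats <- apply(idx, 1, function(ii) {
    mm <- t(sapply(seq_len(n), function(b) m[b, perms[ii[b], ]]))
    stat_fun(mm)
  })
  mean(all_stats >= obs - 1e-12)
}
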