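# Spearman correlations, blocked tests, Bray-Curtis/PCoA, Venn partitions
# and the co-existence matrix.

test_that("Spearman rho: monotone cases, ties against the rank-Pearson oracle", {
  expect_equal(spearman_rho(1:5, c(2, 4, 5, 7, 11)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  x <- c(1, 2, 2, 3); y <- c(2, 1, 3, 4)
  expect_equal(spearman_rho(x, y), rank_pearson(x, y))
  set.seed(3)
  for (rep in 1:20) {
    x <- sample(0:3, 8, replace = TRUE)
    y <- sample(0:3, 8, replace = TRUE)
    if (sd(rank(x)) == 0 || sd(rank(y)) == 0) next
    expect_equal(spearman_rho(x, y), rank_pearson(x, y))
  }
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "zero rank variance")
  expect_true(is.na(r))
})

test_that("paired dam-calf correlations: identity cells and block dropping", {
  counts <- matrix(c(10, 20, 30, 5,
                     10, 20, 30, 5,     # dam oral identical to calf
                     30, 20, 10, 0,
                     1, 2, 50, 40,
                     12, 18, 33, 4,
                     28, 21, 12, 1,
                     2, 2, 48, 39), 4, 7)
  rownames(counts) <- paste0("g", 1:4)
  colnames(counts) <- c("c1_n", "d1_o", "d1_f", "d1_v",
                        "c2_n", "d2_f", "d2_v")  # dam 2 lacks an oral sample
  tab <- make_table(counts, level = "genus")
  md <- data.frame(
    sample_id = colnames(counts),
    animal_id = c("calf01", "dam01", "dam01", "dam01",
                  "calf02", "dam02", "dam02"),
    group = c("newborn", "dam_oral", "dam_feces", "dam_vestibule",
              "newborn", "dam_feces", "dam_vestibule"),
    dam_of = c(NA, "calf01", "calf01", "calf01", NA, "calf02", "calf02"),
    stringsAsFactors = FALSE)
  expect_message(
    expect_error(paired_group_correlations(tab, md), "fewer than 2"),
    "calf02")

  # complete second block
  md2 <- rbind(md, data.frame(sample_id = "d2_o", animal_id = "dam02",
                              group = "dam_oral", dam_of = "calf02"))
  tab2 <- make_table(cbind(counts, d2_o = c(13, 17, 34, 3)),
                     level = "genus")
  pc <- paired_group_correlations(tab2, md2)
  expect_equal(dim(pc$rho), c(2L, 3L))
  expect_equal(unname(pc$rho["calf01", "dam_oral"]), 1)
  expect_true(all(abs(pc$rho) <= 1))
})

test_that("Friedman statistic: closed form, tie degeneracy, tie-free cross-check", {
  # perfect rank agreement over n = 10 blocks, k = 3
  m <- t(sapply(1:10, function(i) c(0.1, 0.5, 0.9)))
  ft <- friedman_test(m)
  expect_equal(ft$statistic, 20)
  expect_equal(ft$df, 2L)
  expect_equal(ft$p, pchisq(20, 2, lower.tail = FALSE))
  # identical columns: all ties, statistic 0, p 1
  ft0 <- friedman_test(matrix(5, 4, 3))
  expect_equal(ft0$statistic, 0)
  expect_equal(ft0$p, 1)
  # tie-free data agree with the base-R implementation
  set.seed(29)
  for (rep in 1:10) {
    m <- matrix(rnorm(5 * 4), 5, 4)
    base <- stats::friedman.test(m)
    ours <- friedman_test(m)
    expect_equal(ours$statistic, unname(base$statistic))
    expect_equal(ours$p, base$p.value)
  }
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)), "incomplete")
})

test_that("Friedman chi-squared p approximates the exact permutation p in the tail", {
  set.seed(37)
  checked <- 0
  while (checked < 8) {
    m <- matrix(rnorm(12), 4, 3)
    ft <- friedman_test(m)
    if (ft$p > 0.15) next   # the chi-squared reference is a tail approximation
    p_perm <- friedman_permutation_p(m, function(x) friedman_test(x)$statistic)
    expect_lt(abs(ft$p - p_perm), 0.02)
    checked <- checked + 1
  }
})

test_that("Nemenyi post-hoc: identical columns, separation, sqrt(n) monotonicity", {
  set.seed(43)
  base <- matrix(rnorm(20), 10, 2)
  m <- cbind(base[, 1], base[, 1], base[, 2])
  p <- nemenyi_posthoc(m)
  expect_equal(p[1, 2], 1)         # equal mean ranks
  expect_true(isSymmetric(p))
  expect_equal(diag(p), rep(1, 3))

  # perfectly separated columns, n = 10: mean rank gaps 1, 1, 2.
  # Oracle: numerically integrated studentized-range tail
  # P(Q > q) = 1 - k * int phi(z) [Phi(z) - Phi(z - q)]^(k-1) dz
  sr_tail <- function(q, k) {
    1 - k * integrate(function(z)
      dnorm(z) * (pnorm(z) - pnorm(z - q))^(k - 1),
      -Inf, Inf, rel.tol = 1e-10)$value
  }
  sep <- t(sapply(1:10, function(i) c(1, 2, 3) + rnorm(3, 0, 0.01)))
  psep <- nemenyi_posthoc(sep)
  q_adj <- 1 / sqrt(3 * 4 / (12 * 10))    # adjacent gap, scaled
  expect_equal(psep[1, 2], sr_tail(q_adj, 3), tolerance = 1e-6)
  expect_equal(psep[2, 3], psep[1, 2])
  # the extreme pair is clearly significant; adjacent pairs are not quite
  expect_lt(psep[1, 3], 0.001)
  expect_true(psep[1, 2] > 0.05 && psep[1, 2] < 0.08)
  # doubling n at the same mean rank gap can only shrink p
  sep2 <- rbind(sep, sep)
  expect_true(all(nemenyi_posthoc(sep2)[upper.tri(psep)] <=
                    psep[upper.tri(psep)] + 1e-12))
})

test_that("Bray-Curtis: identity, disjoint supports, hand computation, bounds", {
  expect_equal(bray_curtis(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(bray_curtis(c(5, 0, 0), c(0, 2, 3)), 1)
  expect_equal(bray_curtis(c(6, 4, 0), c(2, 4, 4)), 0.4)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(47)
  for (rep in 1:20) {
    x <- rpois(6, 3); y <- rpois(6, 3)
    if (sum(x) + sum(y) == 0) next
    d <- bray_curtis(x, y)
    expect_true(d >= 0 && d <= 1)
    expect_equal(d, bray_curtis(y, x))
  }
})

test_that("Bray-Curtis matrix agrees with vegan's vegdist", {
  skip_if_not_installed("vegan")
  set.seed(53)
  tab <- make_table(matrix(rpois(40, 10), 8, 5))
  d <- bray_curtis_matrix(tab)
  rel <- relative_abundance(tab)
  ref <- as.matrix(vegan::vegdist(t(rel), method = "bray"))
  expect_equal(unname(d), unname(ref), tolerance = 1e-12)
})

test_that("PCoA: collinear geometry, Euclidean reconstruction, negative-eigenvalue flag", {
  # three points on a line: one axis, 100% of the variance
  d <- as.matrix(dist(matrix(c(0, 1, 2), 3, 1)))
  res <- pcoa(d)
  expect_equal(res$variance_explained[1], 100)
  expect_equal(unname(sort(abs(diff(sort(res$coordinates[, 1]))))), c(1, 1))

  set.seed(59)
  pts <- matrix(rnorm(40), 20, 2)
  d2 <- as.matrix(dist(pts))
  res2 <- pcoa(d2)
  rec <- as.matrix(dist(res2$coordinates[, 1:2]))
  expect_lt(max(abs(rec - d2)), 1e-9)
  expect_false(res2$negative_eigenvalues)
  expect_true(all(res2$variance_explained >= 0))
  expect_lte(sum(res2$variance_explained), 100 + 1e-9)

  # Bray-Curtis is generally non-Euclidean: negative eigenvalues flagged
  tab <- make_table(matrix(rpois(60, 3), 6, 10))
  res3 <- pcoa(bray_curtis_matrix(tab))
  expect_true(res3$negative_eigenvalues)
  expect_true(ncol(res3$coordinates) >= 2)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("shared-taxon partition: identity, disjoint and brute-force set algebra", {
  counts <- matrix(c(9, 9, 0, 0,
                     9, 9, 0, 0,
                     0, 0, 9, 9), 3, 4, byrow = FALSE)
  # columns: two group-A samples then two group-B samples
  counts <- cbind(a1 = c(9, 4, 0), a2 = c(8, 5, 0),
                  b1 = c(0, 3, 9), b2 = c(0, 4, 8))
  rownames(counts) <- c("onlyA", "both", "onlyB")
  tab <- make_table(counts, level = "genus")
  md <- make_metadata(tab, groups = c("newborn", "newborn",
                                      "dam_oral", "dam_oral"))
  part <- shared_taxa_partition(tab, md, c("newborn", "dam_oral"))
  expect_equal(unname(part$regions["newborn"]), 1L)
  expect_equal(unname(part$regions["dam_oral"]), 1L)
  expect_equal(unname(part$regions["newborn&dam_oral"]), 1L)
  expect_equal(sum(part$regions), part$universe_size)

  # presence needs a strict majority of samples: median > 0
  counts2 <- cbind(a1 = c(5L, 5L), a2 = c(0L, 5L), a3 = c(0L, 5L),
                   b1 = c(0L, 1L), b2 = c(0L, 1L))
  rownames(counts2) <- c("minority", "majority")
  tab2 <- make_table(counts2, level = "genus")
  md2 <- make_metadata(tab2, groups = c(rep("newborn", 3),
                                        rep("dam_oral", 2)))
  part2 <- shared_taxa_partition(tab2, md2, c("newborn", "dam_oral"))
  expect_equal(part2$universe_size, 1L)  # "minority" is in no group's majority
  expect_equal(unname(part2$regions["newborn&dam_oral"]), 1L)

  # random 3-group case against direct set algebra
  set.seed(61)
  for (rep in 1:10) {
    counts <- matrix(rbinom(20 * 9, 1, 0.4) * rpois(180, 9), 20, 9)
    rownames(counts) <- paste0("g", 1:20)
    colnames(counts) <- paste0("s", 1:9)
    tab <- make_table(counts, level = "genus")
    groups <- rep(c("newborn", "dam_oral", "dam_feces"), each = 3)
    md <- make_metadata(tab, groups = groups)
    part <- shared_taxa_partition(tab, md,
                                  c("newborn", "dam_oral", "dam_feces"))
    rel <- suppressWarnings(relative_abundance(tab))
    present <- sapply(unique(groups), function(g)
      apply(rel[, groups == g, drop = FALSE], 1, median) > 0)
    expect_equal(part$universe_size, sum(rowSums(present) > 0))
    # exclusive single-group regions
    for (g in unique(groups)) {
      excl <- sum(present[, g] & rowSums(present[, setdiff(unique(groups), g)]) == 0)
      expect_equal(unname(part$regions[g]), excl)
    }
    expect_equal(sum(part$regions), part$universe_size)
  }
})

test_that("co-existence matrix: cutoffs, saturation and conditional counting oracle", {
  # 3 dam-calf pairs, one dam site; taxon rows probe the >=20 boundary
  counts <- cbind(
    c1 = c(19, 25, 30), c2 = c(19, 25, 0), c3 = c(19, 25, 30),
    d1o = c(100, 25, 19), d2o = c(100, 25, 50), d3o = c(100, 25, 20))
  rownames(counts) <- c("below", "everywhere", "mixed")
  tab <- make_table(counts, level = "genus")
  md <- data.frame(
    sample_id = colnames(counts),
    animal_id = c("calf01", "calf02", "calf03", "dam01", "dam02", "dam03"),
    group = c(rep("newborn", 3), rep("dam_oral", 3)),
    dam_of = c(NA, NA, NA, "calf01", "calf02", "calf03"),
    stringsAsFactors = FALSE)
  cx <- coexistence_matrix(tab, md, dam_sites = "dam_oral")
  # 19 reads everywhere: never detected, excluded outright
  expect_false("below" %in% rownames(cx$matrix))
  # detected in every calf and every dam mouth: fraction 1
  expect_equal(unname(cx$matrix["everywhere", "dam_oral"]), 1)
  # "mixed": in calves 1 and 3 (>=20); dam1 has 19 (no), dam3 has 20 (yes)
  expect_equal(unname(cx$matrix["mixed", "dam_oral"]), 0.5)
  expect_equal(unname(cx$calf_occurrence["everywhere"]), 1)

  # no qualifying taxa -> empty matrix with a warning
  md0 <- md; tab0 <- make_table(counts * 0L + 1L, level = "genus")
  expect_warning(cx0 <- coexistence_matrix(tab0, md0,
                                           dam_sites = "dam_oral"),
                 "no taxa")
  expect_equal(nrow(cx0$matrix), 0L)
})
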