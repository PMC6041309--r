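# Negative-control ratio filtering: control profiles, per-cell verdicts,
# whole-table decontamination against a brute-force oracle, rarity filter
# and the per-sample report.

test_that("control relative abundance: pooled and max-per-control modes", {
  counts <- matrix(c(10, 90, 0, 50, 2, 48), 2, 3,
                   dimnames = list(c("f1", "f2"), c("c1", "c2", "c3")))
  tab <- make_table(counts)
  pooled <- control_relative_abundance(tab, c("c1", "c2", "c3"), "pooled")
  expect_equal(unname(pooled["f1"]), 12 / 200)
  expect_equal(sum(pooled), 1)
  mx <- control_relative_abundance(tab, c("c1", "c2", "c3"),
                                   "max_per_control")
  expect_equal(unname(mx["f1"]), 0.10)
  # feature absent from all controls
  tab2 <- make_table(rbind(counts, f3 = c(0, 0, 0)))
  expect_equal(unname(
    control_relative_abundance(tab2, c("c1", "c2", "c3"))["f3"]), 0)
  # all-empty controls are an instructive error
  tab3 <- make_table(matrix(c(5, 0), 1, 2,
                            dimnames = list("f1", c("s", "c"))))
  expect_error(control_relative_abundance(tab3, "c"), "undefined")
})

test_that("per-cell verdicts use a strict ratio inequality", {
  expect_equal(classify_feature(0.05, 0.01, 4), "accepted_shared")
  # exactly four-fold is NOT "more than four times": rejected
  expect_equal(classify_feature(0.04, 0.01, 4), "rejected")
  expect_equal(classify_feature(0.02, 0, 4), "sample_only")
  expect_equal(classify_feature(0, 0, 4), "sample_only")
})

test_that("decontaminate matches the brute-force per-pair oracle on random tables", {
  set.seed(11)
  for (rep in 1:25) {
    nf <- sample(3:50, 1); ns <- sample(3:20, 1)
    counts <- matrix(rpois(nf * ns, lambda = sample(c(0.5, 2, 10), 1)),
                     nf, ns)
    rownames(counts) <- sprintf("f%02d", seq_len(nf))
    colnames(counts) <- sprintf("s%02d", seq_len(ns))
    ctrl <- sample(colnames(counts), sample(1:3, 1))
    if (sum(counts[, ctrl]) == 0) counts[1, ctrl[1]] <- 5
    tab <- make_table(counts)
    md <- make_metadata(tab, controls = ctrl)
    pooling <- sample(c("pooled", "max_per_control"), 1)
    thr <- sample(c(1, 4, 6), 1)
    res <- decontaminate(tab, md, decontam_config(ratio_threshold = thr,
                                                  control_pooling = pooling))
    expect_identical(res$verdicts,
                     brute_force_verdicts(counts, ctrl, thr, pooling))
  }
})

test_that("verdict invariants: shared-only labels, count monotonicity, conservation", {
  set.seed(23)
  counts <- matrix(rpois(200, 3), 20, 10)
  rownames(counts) <- sprintf("f%02d", 1:20)
  colnames(counts) <- sprintf("s%02d", 1:10)
  tab <- make_table(counts)
  md <- make_metadata(tab, controls = c("s09", "s10"))
  res <- decontaminate(tab, md)

  in_controls <- rowSums(counts[, c("s09", "s10")]) > 0
  expect_true(all(res$verdicts[!in_controls, ] == "sample_only"))
  expect_true(all(res$filtered$counts <= tab$counts))
  # filtered totals = sample_only + accepted_shared reads, per sample
  samples <- colnames(res$verdicts)
  kept <- colSums(counts[, samples] * (res$verdicts != "rejected"))
  expect_equal(colSums(res$filtered$counts[, samples]), kept)
  # controls pass through untouched
  expect_identical(res$filtered$counts[, c("s09", "s10")],
                   tab$counts[, c("s09", "s10")])
  # read fractions sum to one
  rf <- res$read_fractions
  expect_equal(rf$sample_only + rf$accepted_shared + rf$rejected,
               rep(1, nrow(rf)))
})

test_that("raising the ratio threshold never turns rejected into accepted", {
  set.seed(31)
  counts <- matrix(rpois(150, 4), 15, 10)
  rownames(counts) <- sprintf("f%02d", 1:15)
  colnames(counts) <- sprintf("s%02d", 1:10)
  tab <- make_table(counts)
  md <- make_metadata(tab, controls = "s10")
  v4 <- decontaminate(tab, md, decontam_config(ratio_threshold = 4))$verdicts
  v8 <- decontaminate(tab, md, decontam_config(ratio_threshold = 8))$verdicts
  expect_false(any(v4 == "rejected" & v8 == "accepted_shared"))
})

test_that("a dominant control feature is rejected; a control-enriched study is fully recovered", {
  counts <- matrix(c(1, 99, 90, 10), 2, 2,
                   dimnames = list(c("contam", "true"), c("s", "c")))
  tab <- make_table(counts)
  md <- make_metadata(tab, controls = "c")
  res <- decontaminate(tab, md)
  expect_equal(unname(res$verdicts["contam", "s"]), "rejected")
  expect_equal(unname(res$filtered$counts["contam", "s"]), 0L)

  # spike-in recovery: contaminant features >= 50x enriched in controls
  set.seed(41)
  contam_p <- c(rep(0.24, 4), rep(0.01, 4))      # contaminants dominate controls
  sample_p <- c(rep(0.24 / 50, 4), rep(0.2452, 4)) # and are >=50x rarer in samples
  counts <- cbind(
    sapply(1:6, function(i) rmultinom(1, 5000, sample_p)[, 1]),
    sapply(1:2, function(i) rmultinom(1, 5000, contam_p)[, 1]))
  rownames(counts) <- c(paste0("contam", 1:4), paste0("true", 1:4))
  colnames(counts) <- c(paste0("s", 1:6), paste0("c", 1:2))
  tab <- make_table(counts)
  md <- make_metadata(tab, controls = c("c1", "c2"))
  res <- decontaminate(tab, md)
  expect_true(all(res$verdicts[paste0("contam", 1:4), ] == "rejected"))
  expect_true(all(res$filtered$counts[paste0("true", 1:4),
                                      paste0("s", 1:6)] ==
                    tab$counts[paste0("true", 1:4), paste0("s", 1:6)]))
})

test_that("rarity filter removes totals strictly below the minimum", {
  counts <- cbind(a = c(100, 100, 400), b = c(149, 150, 600))
  rownames(counts) <- c("low", "edge", "high")
  tab <- make_table(counts)
  filt <- rarity_filter(tab, min_total = 250)
  expect_setequal(rownames(filt$counts), c("edge", "high"))  # 250 kept, 249 dropped
  expect_identical(rarity_filter(tab, 0)$counts, tab$counts)
  expect_warning(rarity_filter(tab, 1e6), "every feature")
  # control reads do not count towards the totals
  counts2 <- cbind(s = c(200L), ctrl = c(100L))
  rownames(counts2) <- "f1"
  tab2 <- make_table(counts2)
  expect_equal(nrow(rarity_filter(tab2, 250, controls = "ctrl")$counts), 0L)
})

test_that("decontamination report reproduces fractions and group summaries", {
  counts <- matrix(c(40, 5, 55, 0,
                     10, 0, 0, 0,
                     0, 1, 30, 69), 4, 3,
                   dimnames = list(paste0("f", 1:4), c("sA", "sB", "c1")))
  tab <- make_table(counts)
  md <- make_metadata(tab, controls = "c1")
  # force verdict classes on sA: f1 sample_only, f2 accepted, f3 rejected
  res <- decontaminate(tab, md, decontam_config(ratio_threshold = 4))
  rf <- res$read_fractions
  rA <- rf[rf$sample_id == "sA", ]
  expect_equal(rA$sample_only, 0.40)
  expect_equal(rA$accepted_shared, 0.05)
  expect_equal(rA$rejected, 0.55)
  rB <- rf[rf$sample_id == "sB", ]
  expect_equal(unlist(rB[, -1], use.names = FALSE), c(1, 0, 0))

  rep_ <- decontamination_report(res, tab, md)
  # raw vs decontaminated totals recomputed by direct summation
  g <- rep_$per_group
  nb <- g[g$group == "newborn", ]
  expect_equal(nb$reads_raw_median,
               median(colSums(counts[, c("sA", "sB")])))
  expect_equal(nb$reads_decont_median,
               median(colSums(res$filtered$counts[, c("sA", "sB")])))
})
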