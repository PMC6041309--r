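# Negative-control based removal of reagent/instrument contaminant
# sequences. The decision is made per (feature, sample): a feature shared
# with the negative controls is accepted in a sample only if its relative
# abundance there is MORE than `ratio_threshold` times its relative
# abundance in the controls (strict inequality); otherwise it is rejected
# in that sample. Features never seen in any control are untouched
# ("sample_only"). A dataset-wide rarity filter is applied afterwards.

#' Decontamination configuration
#'
#' @param ratio_threshold positive ratio a shared feature must exceed to be
#'   accepted (default 4: "more than four times as high" as in the
#'   controls, strict).
#' @param control_pooling `"pooled"` sums counts over all negative controls
#'   before computing the control profile; `"max_per_control"` takes each
#'   feature's maximum per-control relative abundance. Pooling stabilises
#'   the denominator when controls are shallow.
#' @param rarity_min_total minimum dataset-wide read total a feature needs
#'   to survive the rarity filter (default 250; strict `<` removal, so a
#'   feature seen exactly 250 times is kept).
#' @return a `decontam_config` list.
#' @export
decontam_config <- function(ratio_threshold = 4,
                            control_pooling = c("pooled", "max_per_control"),
                            rarity_min_total = 250) {
  stopifnot(is.numeric(ratio_threshold), ratio_threshold > 0,
            is.numeric(rarity_min_total), rarity_min_total >= 0)
  structure(list(ratio_threshold = ratio_threshold,
                 control_pooling = match.arg(control_pooling),
                 rarity_min_total = as.integer(rarity_min_total)),
            class = "decontam_config")
}

#' Per-feature relative abundance in the negative controls
#'
#' Under `pooled` pooling this is each feature's summed count across
#' controls divided by the total reads across controls (the vector sums to
#' 1 when any control read exists). Under `max_per_control` it is the
#' maximum of the feature's per-control relative abundances.
#'
#' @param table a [feature_table()].
#' @param controls control sample ids, all present in the table.
#' @param pooling `"pooled"` or `"max_per_control"`.
#' @return named numeric vector, one entry per feature.
#' @export
control_relative_abundance <- function(table, controls,
                                       pooling = c("pooled",
                                                   "max_per_control")) {
  stopifnot(inherits(table, "feature_table"), length(controls) > 0)
  pooling <- match.arg(pooling)
  missing <- setdiff(controls, colnames(table$counts))
  if (length(missing) > 0)
    stop("control sample(s) not in table: ", paste(missing, collapse = ", "))
  ctrl <- table$counts[, controls, drop = FALSE]
  depths <- colSums(ctrl)
  if (all(depths == 0))
    stop("all negative controls are empty; the control profile and hence ",
         "decontamination are undefined")
  if (pooling == "pooled") {
    rowSums(ctrl) / sum(depths)
  } else {
    depths[depths == 0] <- 1
    apply(sweep(ctrl, 2, depths, "/"), 1, max)
  }
}

#' Classify one (feature, sample) observation
#'
#' @param sample_rel_abund feature's relative abundance in the sample.
#' @param control_rel_abund feature's relative abundance in the controls.
#' @param threshold acceptance ratio (strict `>`).
#' @return `"sample_only"`, `"accepted_shared"` or `"rejected"`.
#' @export
classify_feature <- function(sample_rel_abund, control_rel_abund,
                             threshold = 4) {
  stopifnot(threshold > 0,
            sample_rel_abund >= 0, sample_rel_abund <= 1,
            control_rel_abund >= 0, control_rel_abund <= 1)
  if (control_rel_abund == 0) return("sample_only")
  if (sample_rel_abund > threshold * control_rel_abund) return("accepted_shared")
  "rejected"
}

#' Remove contaminant sequences using negative controls
#'
#' Applies the per-sample ratio test to every feature of every non-control
#' sample. Control samples pass through unfiltered; they are retained for
#' reporting only. The result carries the full verdict matrix, the filtered
#' table (rejected counts zeroed), per-sample read fractions in the three
#' verdict classes, and the control profile used.
#'
#' @param table a [feature_table()] at genotype or OTU level.
#' @param metadata sample metadata with at least one `control` sample.
#' @param config a [decontam_config()].
#' @return a `decontam_result` list with elements `verdicts` (features x
#'   non-control samples character matrix), `filtered` ([feature_table()]),
#'   `read_fractions` (data.frame), `control_profile`, `config`.
#' @export
decontaminate <- function(table, metadata, config = decontam_config()) {
  stopifnot(inherits(table, "feature_table"),
            inherits(config, "decontam_config"))
  validate_metadata(metadata, table, require_controls = TRUE)
  controls <- intersect(control_ids(metadata), colnames(table$counts))
  if (length(controls) == 0) stop("no control samples present in the table")
  samples <- setdiff(colnames(table$counts), controls)

  ctrl_profile <- control_relative_abundance(table, controls,
                                             config$control_pooling)
  counts <- table$counts[, samples, drop = FALSE]
  depths <- colSums(counts)
  rel <- sweep(counts, 2, pmax(depths, 1), "/")

  # vectorised form of classify_feature() over the whole matrix
  shared <- ctrl_profile > 0
  accepted <- rel > config$ratio_threshold * ctrl_profile
  verdicts <- matrix("sample_only", nrow(counts), ncol(counts),
                     dimnames = dimnames(counts))
  verdicts[shared & accepted] <- "accepted_shared"
  verdicts[shared & !accepted] <- "rejected"

  filtered_counts <- table$counts
  rej <- verdicts == "rejected"
  filtered_counts[, samples][rej] <- 0L
  filtered <- feature_table(filtered_counts, table$lineages,
                            level = table$level)

  frac <- function(class) {
    colSums(counts * (verdicts == class)) / pmax(depths, 1)
  }
  read_fractions <- data.frame(
    sample_id = samples,
    sample_only = frac("sample_only"),
    accepted_shared = frac("accepted_shared"),
    rejected = frac("rejected"),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(verdicts = verdicts, filtered = filtered,
                 read_fractions = read_fractions,
                 control_profile = ctrl_profile,
                 controls = controls, config = config),
            class = "decontam_result")
}

#' @export
print.decontam_result <- function(x, ...) {
  cat(sprintf(
    "decontam_result: %d features x %d samples (+%d controls)\n",
    nrow(x$verdicts), ncol(x$verdicts), length(x$controls)))
  cat(sprintf("mean read fractions: %.1f%% sample-only, %.1f%% accepted, %.1f%% rejected\n",
              100 * mean(x$read_fractions$sample_only),
              100 * mean(x$read_fractions$accepted_shared),
              100 * mean(x$read_fractions$rejected)))
  invisible(x)
}

#' Remove dataset-wide rare features
#'
#' Drops every feature whose summed count over all analysed (non-control)
#' samples is strictly below `min_total`. Applied after decontamination, on
#' the filtered table.
#'
#' @param table a [feature_table()].
#' @param min_total minimum total (default 250; a feature totalling exactly
#'   250 reads is kept).
#' @param controls control sample ids excluded from the totals (and kept in
#'   the output unchanged); default none.
#' @return a [feature_table()] without the rare features.
#' @export
rarity_filter <- function(table, min_total = 250, controls = NULL) {
  stopifnot(inherits(table, "feature_table"), min_total >= 0)
  samples <- setdiff(colnames(table$counts), controls)
  totals <- rowSums(table$counts[, samples, drop = FALSE])
  keep <- totals >= min_total
  if (!any(keep))
    warning("rarity filter removed every feature (min_total = ",
            min_total, ")")
  subset_samples(table, features = which(keep))
}

#' Per-sample and per-group decontamination report
#'
#' Returns the per-sample read fractions of the three verdict classes
#' together with per-class feature counts, and a per-group summary of raw
#' vs decontaminated reads and feature counts (median and SD), in the
#' layout of a sequencing-characteristics table.
#'
#' @param result a [decontaminate()] result.
#' @param table the original (unfiltered) [feature_table()].
#' @param metadata sample metadata.
#' @return list with `per_sample` and `per_group` data.frames.
#' @export
decontamination_report <- function(result, table, metadata) {
  stopifnot(inherits(result, "decontam_result"),
            inherits(table, "feature_table"))
  samples <- colnames(result$verdicts)
  counts <- table$counts[, samples, drop = FALSE]
  nfeat <- function(class) {
    colSums(counts > 0 & result$verdicts == class)
  }
  per_sample <- cbind(result$read_fractions,
                      data.frame(n_sample_only = nfeat("sample_only"),
                                 n_accepted_shared = nfeat("accepted_shared"),
                                 n_rejected = nfeat("rejected"),
                                 row.names = NULL))

  all_ids <- colnames(table$counts)
  raw_reads <- colSums(table$counts)
  dec_reads <- colSums(result$filtered$counts)
  raw_feat <- colSums(table$counts > 0)
  dec_feat <- colSums(result$filtered$counts > 0)
  grp <- metadata$group[match(all_ids, metadata$sample_id)]
  med_sd <- function(x) c(median = stats::median(x), sd = .sd0(x))
  per_group <- do.call(rbind, lapply(split(seq_along(all_ids), grp), function(i) {
    data.frame(group = grp[i[1]], n = length(i),
               reads_raw_median = stats::median(raw_reads[i]),
               reads_raw_sd = .sd0(raw_reads[i]),
               reads_decont_median = stats::median(dec_reads[i]),
               reads_decont_sd = .sd0(dec_reads[i]),
               features_raw_median = stats::median(raw_feat[i]),
               features_raw_sd = .sd0(raw_feat[i]),
               features_decont_median = stats::median(dec_feat[i]),
               features_decont_sd = .sd0(dec_feat[i]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  list(per_sample = per_sample, per_group = per_group)
}

# SD that is 0 rather than NA for a single observation
.sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
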