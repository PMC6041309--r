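# Total bacterial load per swab from 16S qPCR: standard-curve conversion
# from Ct to copy numbers, group comparisons of copy numbers by ratio of
# medians and Mann-Whitney U test.

#' qPCR standard curve
#'
#' The usual log-linear calibration Ct = slope * log10(copies) + intercept.
#' A perfect-efficiency assay doubles each cycle, i.e. slope
#' -1/log10(2) = -3.3219.
#'
#' @param slope Ct change per log10 copies; must be negative.
#' @param intercept Ct at one copy.
#' @param dynamic_range lower/upper copy numbers within which the curve was
#'   calibrated; conversions outside it are flagged.
#' @return a `standard_curve` list.
#' @export
standard_curve <- function(slope = -1 / log10(2), intercept = 40,
                           dynamic_range = c(10, 1e8)) {
  stopifnot(is.numeric(slope), slope < 0,
            length(dynamic_range) == 2, all(dynamic_range > 0),
            dynamic_range[1] < dynamic_range[2])
  structure(list(slope = slope, intercept = intercept,
                 dynamic_range = dynamic_range),
            class = "standard_curve")
}

#' Convert qPCR Ct values to 16S copies per swab
#'
#' copies = dilution * 10^((ct - intercept) / slope). Values outside the
#' curve's dynamic range are still returned but flagged in the
#' `out_of_range` attribute (samples expected above range should be diluted
#' more before amplification).
#'
#' @param ct cycle-threshold value(s); must be finite.
#' @param curve a [standard_curve()].
#' @param dilution pre-amplification dilution factor (>= 1).
#' @return numeric vector of copies per swab with attribute `out_of_range`.
#' @export
copies_from_ct <- function(ct, curve = standard_curve(), dilution = 1) {
  stopifnot(inherits(curve, "standard_curve"), all(dilution >= 1))
  if (any(!is.finite(ct))) stop("non-finite Ct value")
  copies <- dilution * 10^((ct - curve$intercept) / curve$slope)
  flag <- copies < curve$dynamic_range[1] | copies > curve$dynamic_range[2]
  attr(copies, "out_of_range") <- flag
  copies
}

#' Read a qPCR table
#'
#' TSV with columns `sample_id`, `group`, and either `copies_per_swab` or
#' `ct` (+ optional `dilution_factor`, default 1). Ct values are converted
#' through `curve`.
#'
#' @param path qPCR TSV file.
#' @param curve [standard_curve()] used when only Ct values are present.
#' @return data.frame with `sample_id`, `group`, `copies_per_swab`.
#' @export
read_qpcr_table <- function(path, curve = standard_curve()) {
  q <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "group") %in% names(q)))
  if (is.null(q$copies_per_swab)) {
    if (is.null(q$ct)) stop("qPCR table needs copies_per_swab or ct")
    dil <- q$dilution_factor %||% rep(1, nrow(q))
    q$copies_per_swab <- as.numeric(copies_from_ct(q$ct, curve, dil))
  }
  if (any(q$copies_per_swab <= 0)) stop("copies_per_swab must be positive")
  q
}

#' Ratio of median copy numbers between two groups
#'
#' @param qpcr data.frame with `group` and `copies_per_swab`.
#' @param group_a numerator group label.
#' @param group_b denominator group label.
#' @return median(a) / median(b). Medians of even-sized groups are the
#'   midpoint of the two central values.
#' @export
group_copy_ratio <- function(qpcr, group_a, group_b) {
  a <- qpcr$copies_per_swab[qpcr$group == group_a]
  b <- qpcr$copies_per_swab[qpcr$group == group_b]
  if (length(a) == 0) stop("empty group: ", group_a)
  if (length(b) == 0) stop("empty group: ", group_b)
  stats::median(a) / stats::median(b)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null enumeration when the combined sample size is at most 16 and
#' the data are tie-free; otherwise the normal approximation with tie and
#' continuity correction. Constant pooled data yield p = 1 with a warning.
#'
#' @param a,b numeric vectors, each non-empty.
#' @return list with `statistic` (U of the first sample), `p`, `method`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  if (length(unique(c(a, b))) == 1) {
    warning("constant pooled data; Mann-Whitney p set to 1")
    return(structure(list(statistic = length(a) * length(b) / 2, p = 1,
                          method = "Mann-Whitney U (degenerate)"),
                     class = "lb_test"))
  }
  exact <- (length(a) + length(b) <= 16) && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p = wt$p.value,
                 method = if (exact) "Mann-Whitney U (exact)"
                          else "Mann-Whitney U (normal approximation)"),
            class = "lb_test")
}

#' @export
print.lb_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g\n", x$method, x$statistic,
              if (!is.null(x$df)) sprintf(", df = %d", x$df) else "", x$p))
  invisible(x)
}

#' Compare bacterial loads between groups
#'
#' Convenience wrapper reporting the median ratio and the Mann-Whitney
#' p-value for two groups of a qPCR table.
#'
#' @param qpcr qPCR data.frame.
#' @param group_a,group_b group labels.
#' @return list with `ratio`, `median_a`, `median_b`, `test`.
#' @export
compare_loads <- function(qpcr, group_a, group_b) {
  a <- qpcr$copies_per_swab[qpcr$group == group_a]
  b <- qpcr$copies_per_swab[qpcr$group == group_b]
  list(ratio = group_copy_ratio(qpcr, group_a, group_b),
       median_a = stats::median(a), median_b = stats::median(b),
       test = mann_whitney(a, b))
}
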