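# Readers and writers for the plain-text tables the pipeline consumes:
# a counts TSV (features x samples, or a mothur .shared file), a taxonomy
# TSV (feature id, semicolon-delimited lineage, optionally mothur
# cons.taxonomy with bootstrap values), and a sample-metadata TSV.

SAMPLE_GROUPS <- c("newborn", "calf_24h", "calf_7d",
                   "dam_feces", "dam_oral", "dam_vestibule", "control")

.strip_bootstrap <- function(lineage) {
  # "Bacteria(100);Firmicutes(97);" -> "Bacteria;Firmicutes"
  lineage <- gsub("\\([0-9.]+\\)", "", lineage)
  lineage <- gsub("\"", "", lineage)
  sub(";+$", "", trimws(lineage))
}

.parse_lineages <- function(strings) {
  parts <- strsplit(.strip_bootstrap(strings), ";", fixed = TRUE)
  t(vapply(parts, function(p) fill_lineage(trimws(p)),
           character(length(TAX_RANKS))))
}

#' Read a feature count table with taxonomy
#'
#' Accepts either a plain TSV (first column feature id, remaining columns
#' samples) or a mothur-style `.shared` file (columns `label`, `Group`,
#' `numOtus`, then one column per feature; samples as rows). The taxonomy
#' file may be a bare two-column TSV (id, lineage) or a mothur
#' `cons.taxonomy` file (`OTU`, `Size`, `Taxonomy`); bootstrap values in
#' parentheses are stripped. An optional `# level: <level>` comment on the
#' first line of the counts file sets the feature level.
#'
#' Features present in the counts but absent from the taxonomy are kept with
#' an all-placeholder lineage and a warning.
#'
#' @param path counts TSV (or mothur shared) file.
#' @param taxonomy_path taxonomy TSV file.
#' @param level feature level, overridden by a `# level:` header if present.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, taxonomy_path, level = "genotype") {
  stopifnot(file.exists(path), file.exists(taxonomy_path))
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*level:", first)) {
    level <- trimws(sub("^#\\s*level:", "", first))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (identical(tolower(names(raw)[1:3]), c("label", "group", "numotus"))) {
    # mothur shared dialect: samples are rows
    samples <- raw[[2]]
    mat <- t(as.matrix(raw[, -(1:3), drop = FALSE]))
    colnames(mat) <- samples
  } else {
    mat <- as.matrix(raw[, -1, drop = FALSE])
    rownames(mat) <- raw[[1]]
  }
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 ncol = ncol(mat), dimnames = dimnames(mat)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid count at feature '%s', sample '%s': '%s'",
                 rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]],
                 mat[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }

  tax_raw <- utils::read.delim(taxonomy_path, header = TRUE, sep = "\t",
                               check.names = FALSE,
                               colClasses = "character",
                               stringsAsFactors = FALSE)
  if (ncol(tax_raw) >= 3 &&
      identical(tolower(names(tax_raw)[1:3]), c("otu", "size", "taxonomy"))) {
    tax <- stats::setNames(tax_raw[[3]], tax_raw[[1]])
  } else {
    tax <- stats::setNames(tax_raw[[2]], tax_raw[[1]])
  }
  missing <- setdiff(rownames(num), names(tax))
  if (length(missing) > 0) {
    warning(length(missing), " feature(s) missing from taxonomy, ",
            "assigned all-placeholder lineages: ",
            paste(utils::head(missing, 3), collapse = ", "),
            if (length(missing) > 3) ", ...")
    tax[missing] <- ""
  }
  lineages <- .parse_lineages(unname(tax[rownames(num)]))
  rownames(lineages) <- rownames(num)

  tab <- feature_table(num, lineages, level = level)
  if (any(colSums(tab$counts) == 0))
    warning("empty sample column(s): ",
            paste(colnames(tab$counts)[colSums(tab$counts) == 0],
                  collapse = ", "))
  tab
}

#' Write a feature table (and its taxonomy) to TSV
#'
#' Writes the counts with a `# level:` header so that
#' `read_feature_table(write_feature_table(x))` reproduces `x` exactly
#' (counts, ids, lineages and level).
#'
#' @param table a [feature_table()].
#' @param path counts TSV output path.
#' @param taxonomy_path taxonomy TSV output path; default `<path>.taxonomy`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path,
                                taxonomy_path = paste0(path, ".taxonomy")) {
  stopifnot(inherits(table, "feature_table"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# level: ", table$level), con)
  ids <- rownames(table$counts) %||% character(0)
  df <- data.frame(feature_id = ids,
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  tax <- data.frame(feature_id = ids,
                    lineage = lineage_strings(table$lineages),
                    stringsAsFactors = FALSE)
  utils::write.table(tax, taxonomy_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a TSV with columns `sample_id`, `animal_id`, `group` and
#' optionally `dam_of` (the calf animal id a dam sample is paired with) and
#' `preamp_cycles`.
#'
#' @param path metadata TSV file.
#' @return a validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  stopifnot(file.exists(path))
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_metadata(md)
}

#' Validate sample metadata, optionally against a feature table
#'
#' Checks column presence, group labels, uniqueness of sample ids, the
#' one-to-one match with a feature table's samples, and the consistency of
#' dam-calf links (`dam_of` must point at a calf animal id present in the
#' metadata).
#'
#' @param metadata data.frame of sample metadata.
#' @param table optional [feature_table()] the metadata must cover.
#' @param require_controls error if no `control` samples are present.
#' @return the metadata, invisibly usable.
#' @export
validate_metadata <- function(metadata, table = NULL,
                              require_controls = FALSE) {
  needed <- c("sample_id", "animal_id", "group")
  miss <- setdiff(needed, names(metadata))
  if (length(miss) > 0) stop("metadata missing column(s): ",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(metadata$group), SAMPLE_GROUPS)
  if (length(bad) > 0) stop("unknown group label(s): ",
                            paste(bad, collapse = ", "))
  if (!is.null(table)) {
    stopifnot(inherits(table, "feature_table"))
    missing <- setdiff(colnames(table$counts), metadata$sample_id)
    if (length(missing) > 0)
      stop("samples absent from metadata: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  if (require_controls && !any(metadata$group == "control"))
    stop("no control samples in metadata; decontamination is undefined ",
         "without negative controls")
  if (!is.null(metadata$dam_of)) {
    links <- metadata$dam_of[!is.na(metadata$dam_of)]
    calves <- metadata$animal_id[metadata$group %in%
                                   c("newborn", "calf_24h", "calf_7d")]
    orphan <- setdiff(links, calves)
    if (length(orphan) > 0)
      stop("dam_of link(s) point at unknown calf animal id(s): ",
           paste(orphan, collapse = ", "))
  }
  metadata
}

#' Sample ids of the negative controls
#' @param metadata sample metadata.
#' @return character vector of control sample ids.
#' @export
control_ids <- function(metadata) {
  metadata$sample_id[metadata$group == "control"]
}
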