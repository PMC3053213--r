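# Reading/writing the tab-delimited tables the pipeline exchanges:
# expression matrix, sample manifest, annotation maps, results.

TIMEPOINT_LEVELS <- c("BL", "EF", "LF")
GROUP_LEVELS <- c("ISR", "NO_ISR")
PATTERN_LEVELS <- c("CONSISTENT_ISR_GT", "CONSISTENT_NOISR_GT",
                    "DIVERGENT_ISR_GT", "DIVERGENT_NOISR_GT", "UNDETERMINED")

#' Validate an expression matrix
#'
#' An expression matrix is a numeric matrix of log2 normalized intensities
#' with unique probe identifiers as rownames and unique sample identifiers as
#' colnames.  Missing values are allowed (`NA`); anything non-finite that is
#' not `NA` is rejected.
#'
#' @param mat numeric matrix, probes x samples.
#' @return `mat`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stopf("expression matrix must be a numeric matrix")
  }
  # R drops a zero-length dimension's names to NULL; tolerate that
  if ((is.null(rownames(mat)) && nrow(mat) > 0L) ||
      (is.null(colnames(mat)) && ncol(mat) > 0L)) {
    stopf("expression matrix must carry probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(mat))) {
    dup <- rownames(mat)[duplicated(rownames(mat))][1L]
    stopf("duplicated probe identifier: '%s'", dup)
  }
  if (anyDuplicated(colnames(mat))) {
    dup <- colnames(mat)[duplicated(colnames(mat))][1L]
    stopf("duplicated sample identifier: '%s'", dup)
  }
  bad <- !is.finite(mat) & !is.na(mat)
  if (any(bad)) stopf("expression matrix contains non-finite values")
  invisible(mat)
}

#' Read a probes x samples expression matrix from TSV
#'
#' Expects a header row of sample identifiers whose first column is
#' `probe_id`, followed by one row per probe of log2 intensities.
#'
#' @param path path to a tab-delimited file.
#' @param missing_token string encoding a missing value (default `"NA"`).
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
read_expression_matrix <- function(path, missing_token = "NA") {
  if (!file.exists(path)) stopf("expression matrix file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = missing_token,
                          colClasses = "character",
                          check.names = FALSE, quote = "")
  if (ncol(df) < 2L) stopf("expression matrix needs a probe column and at least one sample")
  probes <- df[[1L]]
  if (anyDuplicated(probes)) {
    stopf("duplicated probe identifier: '%s'", probes[duplicated(probes)][1L])
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- is.na(num) & !is.na(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stopf("non-numeric cell at probe '%s', sample '%s': '%s'",
          probes[idx[1L]], colnames(vals)[idx[2L]], vals[idx[1L], idx[2L]])
  }
  dimnames(num) <- list(probes, colnames(vals))
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix as TSV
#' @param mat validated expression matrix.
#' @param path output path.
#' @param missing_token token used for `NA` cells.
#' @export
write_expression_matrix <- function(mat, path, missing_token = "NA") {
  validate_expression_matrix(mat)
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = missing_token,
                     row.names = FALSE)
  invisible(path)
}

normalize_group <- function(x) {
  g <- toupper(gsub("[ -]", "_", trimws(as.character(x))))
  g[g %in% c("NOISR", "NON_ISR", "NO_ISR", "CONTROL")] <- "NO_ISR"
  bad <- !g %in% GROUP_LEVELS
  if (any(bad)) stopf("unknown group label: '%s'", x[bad][1L])
  g
}

#' Validate a sample manifest
#'
#' Enforces the longitudinal design invariants: `time_days == 0` exactly for
#' baseline (`BL`) records, at most one record per (subject, timepoint), and
#' a group label constant within subject.
#'
#' @param manifest data.frame with columns `sample_id`, `subject_id`,
#'   `group`, `time_days`, `timepoint`, `age`, `sex`.
#' @return the manifest with normalized group/sex labels.
#' @export
validate_manifest <- function(manifest) {
  required <- c("sample_id", "subject_id", "group", "time_days",
                "timepoint", "age", "sex")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols)) {
    stopf("manifest is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  manifest$group <- normalize_group(manifest$group)
  manifest$sex <- toupper(trimws(as.character(manifest$sex)))
  if (!all(manifest$sex %in% c("F", "M"))) {
    stopf("sex must be 'F' or 'M'")
  }
  if (!all(manifest$timepoint %in% TIMEPOINT_LEVELS)) {
    stopf("timepoint must be one of %s", paste(TIMEPOINT_LEVELS, collapse = "/"))
  }
  manifest$time_days <- as.numeric(manifest$time_days)
  manifest$age <- as.numeric(manifest$age)
  if (any(manifest$time_days < 0)) stopf("time_days must be >= 0")
  bl <- manifest$timepoint == "BL"
  if (any(manifest$time_days[bl] != 0)) {
    stopf("BL record with nonzero time_days (sample '%s')",
          manifest$sample_id[bl & manifest$time_days != 0][1L])
  }
  if (any(manifest$time_days[!bl] == 0)) {
    stopf("follow-up record with time_days = 0 (sample '%s')",
          manifest$sample_id[!bl & manifest$time_days == 0][1L])
  }
  if (anyDuplicated(manifest$sample_id)) stopf("duplicated sample_id")
  key <- paste(manifest$subject_id, manifest$timepoint)
  if (anyDuplicated(key)) {
    stopf("subject '%s' has more than one '%s' record",
          manifest$subject_id[duplicated(key)][1L],
          manifest$timepoint[duplicated(key)][1L])
  }
  n_groups <- tapply(manifest$group, manifest$subject_id,
                     function(g) length(unique(g)))
  if (any(n_groups > 1L)) {
    stopf("subject '%s' has inconsistent group labels",
          names(n_groups)[n_groups > 1L][1L])
  }
  manifest
}

#' Read a sample manifest from TSV
#' @param path tab-delimited file with the manifest columns.
#' @return validated manifest data.frame.
#' @export
read_sample_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "")
  validate_manifest(df)
}

#' Write a sample manifest as TSV
#' @param manifest validated manifest.
#' @param path output path.
#' @export
write_sample_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  cols <- c("sample_id", "subject_id", "group", "time_days", "timepoint",
            "age", "sex")
  utils::write.table(manifest[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summarize a longitudinal manifest
#'
#' @param manifest validated manifest (may have zero rows).
#' @return list with `n_subjects`, `n_per_timepoint` (named over BL/EF/LF),
#'   `n_total_profiles`, and `n_per_group`.
#' @export
summarize_manifest <- function(manifest) {
  if (nrow(manifest) == 0L) {
    return(list(
      n_subjects = 0L,
      n_per_timepoint = stats::setNames(integer(3L), TIMEPOINT_LEVELS),
      n_total_profiles = 0L,
      n_per_group = stats::setNames(integer(2L), GROUP_LEVELS)
    ))
  }
  manifest <- validate_manifest(manifest)
  tp <- table(factor(manifest$timepoint, levels = TIMEPOINT_LEVELS))
  subj_group <- unique(manifest[, c("subject_id", "group")])
  grp <- table(factor(subj_group$group, levels = GROUP_LEVELS))
  list(
    n_subjects = length(unique(manifest$subject_id)),
    n_per_timepoint = stats::setNames(as.integer(tp), names(tp)),
    n_total_profiles = nrow(manifest),
    n_per_group = stats::setNames(as.integer(grp), names(grp))
  )
}

#' Construct an annotation map
#'
#' @param probe_to_gene data.frame with columns `probe_id`, `gene_symbol`.
#' @param probe_to_terms data.frame with columns `probe_id`, `term_id`
#'   (one pair per row; a probe may map to many terms).  Optional.
#' @return list of class `annotation_map`.
#' @export
annotation_map <- function(probe_to_gene,
                           probe_to_terms = data.frame(probe_id = character(),
                                                       term_id = character())) {
  stopifnot(all(c("probe_id", "gene_symbol") %in% names(probe_to_gene)),
            all(c("probe_id", "term_id") %in% names(probe_to_terms)))
  probe_to_gene$probe_id <- as.character(probe_to_gene$probe_id)
  probe_to_gene$gene_symbol <- as.character(probe_to_gene$gene_symbol)
  probe_to_terms$probe_id <- as.character(probe_to_terms$probe_id)
  probe_to_terms$term_id <- as.character(probe_to_terms$term_id)
  structure(list(probe_to_gene = probe_to_gene,
                 probe_to_terms = probe_to_terms),
            class = "annotation_map")
}

#' Read annotation tables from TSV
#'
#' @param gene_path TSV with columns `probe_id`, `gene_symbol`.
#' @param term_path optional TSV with columns `probe_id`, `term_id`.
#' @return an [annotation_map()].
#' @export
read_annotation <- function(gene_path, term_path = NULL) {
  g <- utils::read.delim(gene_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  t <- if (is.null(term_path)) {
    data.frame(probe_id = character(), term_id = character())
  } else {
    utils::read.delim(term_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "")
  }
  annotation_map(g, t)
}

#' Map probe identifiers to gene symbols
#'
#' @param probes character vector of probe identifiers.
#' @param ann an [annotation_map()].
#' @return list with `mapping` (data.frame `probe_id`, `gene_symbol`;
#'   unmapped probes get `NA`), `unmapped` (character vector), and
#'   `n_distinct_genes` (count of distinct symbols among mapped probes).
#' @export
map_probes_to_genes <- function(probes, ann) {
  stopifnot(inherits(ann, "annotation_map"))
  probes <- as.character(probes)
  idx <- match(probes, ann$probe_to_gene$probe_id)
  symbol <- ann$probe_to_gene$gene_symbol[idx]
  symbol[!is.na(symbol) & !nzchar(symbol)] <- NA_character_
  mapping <- data.frame(probe_id = probes, gene_symbol = symbol,
                        stringsAsFactors = FALSE)
  unmapped <- probes[is.na(symbol)]
  list(mapping = mapping,
       unmapped = unmapped,
       n_distinct_genes = length(unique(symbol[!is.na(symbol)])))
}

#' The 36 validated ISR probe sets
#'
#' The published table of 36 U133A probe sets replicated across the
#' CardioGene and deCODE cohorts, with their gene symbols (32 distinct) and
#' reported trajectory patterns.  Shipped as a plain-text table under
#' `extdata`.
#'
#' @return data.frame with `probe_id`, `gene_symbol`, `pattern`.
#' @export
validated_probesets <- function() {
  path <- system.file("extdata", "isr_validated_probesets.tsv",
                      package = "tvide", mustWork = TRUE)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}

RESULT_COLUMNS <- c("probe_id", "gene_symbol", "rss_null", "rss_alt",
                    "statistic", "p_value", "q_value", "pattern", "selected")

#' Write per-probe test results as TSV
#'
#' Column order is stable (`probe_id, gene_symbol, rss_null, rss_alt,
#' statistic, p_value, q_value, pattern, selected`) and numeric columns are
#' serialized with full precision so a read-back reproduces the input.
#'
#' @param results data.frame of per-probe test results.
#' @param path output path.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results)) stopf("results must not be NULL")
  out <- data.frame(probe_id = character(), gene_symbol = character(),
                    rss_null = numeric(), rss_alt = numeric(),
                    statistic = numeric(), p_value = numeric(),
                    q_value = numeric(), pattern = character(),
                    selected = logical(), stringsAsFactors = FALSE)
  if (nrow(results)) {
    for (col in RESULT_COLUMNS) {
      if (!col %in% names(results)) {
        results[[col]] <- if (col %in% c("gene_symbol", "pattern")) {
          NA_character_
        } else if (col == "selected") NA else NA_real_
      }
    }
    out <- results[, RESULT_COLUMNS]
  }
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) sprintf("%.10g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path TSV path.
#' @return results data.frame.
#' @export
read_results_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  for (col in c("rss_null", "rss_alt", "statistic", "p_value", "q_value")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$selected <- as.logical(df$selected)
  df
}
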