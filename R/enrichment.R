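# Over-representation of annotation categories (gene-ontology style) among
# selected genes, by one-sided Fisher's exact test or its EASE variant.

#' Gene-level term table from a probe-level annotation map
#'
#' Joins `probe -> gene` and `probe -> term` so a gene inherits the union of
#' its probes' categories.
#'
#' @param ann an [annotation_map()].
#' @return data.frame with unique `gene_symbol`, `term_id` pairs.
#' @export
gene_term_table <- function(ann) {
  stopifnot(inherits(ann, "annotation_map"))
  merged <- merge(ann$probe_to_gene, ann$probe_to_terms, by = "probe_id")
  out <- unique(merged[, c("gene_symbol", "term_id")])
  out <- out[nzchar(out$gene_symbol) & !is.na(out$gene_symbol), ]
  rownames(out) <- NULL
  out
}

# Upper-tail P(X >= k) for X ~ Hypergeom(N, K, n); vectorized.
hyper_upper_tail <- function(k, K, n, N) {
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

as_gene_terms <- function(ann) {
  if (inherits(ann, "annotation_map")) return(gene_term_table(ann))
  stopifnot(all(c("gene_symbol", "term_id") %in% names(ann)))
  unique(ann[, c("gene_symbol", "term_id")])
}

#' Test annotation categories for over-representation
#'
#' For each category with at least one annotated universe gene, builds the
#' 2x2 table (selected-in-term, selected-out; rest-in-term, rest-out) and
#' computes the one-sided hypergeometric upper-tail p-value — the chance of
#' seeing at least `k` in-term genes among `n` selected when `K` of the `N`
#' universe genes carry the term.  `mode = "ease"` recomputes the tail after
#' removing one selected in-term gene (`k -> max(k - 1, 0)`), the
#' conservative EASE score.  Genes without annotation count toward the
#' out-of-term margin.  BH adjustment runs across the reported terms.
#'
#' @param selected character vector of selected gene symbols (subset of
#'   `universe`).
#' @param universe character vector of background gene symbols (typically
#'   all QC-passing probes mapped to symbols, deduplicated).
#' @param ann an [annotation_map()] or a data.frame with `gene_symbol`,
#'   `term_id`.
#' @param mode `"fisher"` or `"ease"`.
#' @param alpha significance threshold recorded on each row.
#' @param two_sided if `TRUE`, use the two-sided Fisher p instead of the
#'   over-representation tail.
#' @return data.frame `term_id, k, K, n, N, odds_ratio, p_value, q_value,
#'   mode, significant`, sorted by p-value.
#' @export
fisher_overrepresentation <- function(selected, universe, ann,
                                      mode = c("fisher", "ease"),
                                      alpha = 0.05, two_sided = FALSE) {
  mode <- match.arg(mode)
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  if (!length(universe)) stopf("universe is empty")
  if (!all(selected %in% universe)) {
    stopf("selected genes must be a subset of the universe")
  }
  gt <- as_gene_terms(ann)
  gt <- gt[gt$gene_symbol %in% universe, , drop = FALSE]
  terms <- sort(unique(gt$term_id))
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(terms, function(tm) {
    in_term <- unique(gt$gene_symbol[gt$term_id == tm])
    K <- length(in_term)
    k <- sum(selected %in% in_term)
    k_eff <- if (mode == "ease") max(k - 1L, 0L) else k
    p <- if (two_sided) {
      stats::fisher.test(matrix(c(k_eff, n - k_eff, K - k_eff,
                                  N - K - n + k_eff), 2L))$p.value
    } else {
      hyper_upper_tail(k_eff, K, n, N)
    }
    or <- (k * (N - K - n + k)) / max((n - k) * (K - k), .Machine$double.eps)
    data.frame(term_id = tm, k = k, K = K, n = n, N = N,
               odds_ratio = if (k == 0L) 0 else or,
               p_value = min(p, 1), mode = mode,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), odds_ratio = numeric(),
                      p_value = numeric(), mode = character(),
                      stringsAsFactors = FALSE)
  }
  out$q_value <- if (nrow(out)) fdr_qvalues(out$p_value, "bh") else numeric(0L)
  out$significant <- out$q_value < alpha
  out[order(out$p_value, out$term_id), ]
}

#' Descriptive per-category membership report
#'
#' Lists every category containing at least one selected gene together with
#' its (sorted, duplicate-free) selected members — the unthresholded view
#' used when no category reaches significance.
#'
#' @param selected character vector of selected gene symbols.
#' @param ann an [annotation_map()] or gene/term data.frame.
#' @return data.frame `term_id, n_genes, genes` (comma-joined members).
#' @export
category_coverage_report <- function(selected, ann) {
  selected <- unique(as.character(selected))
  gt <- as_gene_terms(ann)
  gt <- gt[gt$gene_symbol %in% selected, , drop = FALSE]
  if (!nrow(gt)) {
    return(data.frame(term_id = character(), n_genes = integer(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  members <- lapply(split(gt$gene_symbol, gt$term_id),
                    function(g) sort(unique(g)))
  data.frame(term_id = names(members),
             n_genes = lengths(members),
             genes = vapply(members, paste, character(1L), collapse = ","),
             row.names = NULL, stringsAsFactors = FALSE)
}
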