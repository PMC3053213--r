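# Genome-wide scan orchestration: per-probe tests, multiplicity adjustment,
# selection, trajectory-pattern classification, and the hypothesis-driven
# baseline comparison.

#' Benjamini-Hochberg or Storey q-values
#'
#' `method = "bh"` returns the step-up adjusted values
#' `q_(i) = min_(j >= i) m p_(j) / j` (monotone by construction, capped at
#' 1).  `method = "storey"` additionally estimates the null proportion
#' pi0 by the smoother method (natural cubic smoothing spline of the
#' lambda-censored estimates, evaluated at the largest lambda) and scales
#' the BH values by it.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param method `"bh"` or `"storey"`.
#' @return q-values in the input order.
#' @export
fdr_qvalues <- function(p_values, method = c("bh", "storey")) {
  method <- match.arg(method)
  p <- as.numeric(p_values)
  if (!length(p)) return(numeric(0L))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  if (method == "storey") {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1L))
    pi0 <- if (m >= 20L) {
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      stats::predict(fit, x = max(lambda))$y
    } else {
      min(pi0_l[length(pi0_l)], 1)
    }
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
    q <- pmin(q * pi0, 1)
  }
  q
}

#' Select significant probes at an FDR threshold
#'
#' @param results data.frame with `probe_id` and `q_value`.
#' @param alpha FDR threshold; selection uses the strict rule `q < alpha`.
#' @return character vector of selected probe identifiers, ordered by
#'   ascending q-value then probe id.
#' @export
select_significant <- function(results, alpha = 0.05) {
  keep <- !is.na(results$q_value) & results$q_value < alpha
  sel <- results[keep, c("probe_id", "q_value")]
  sel$probe_id[order(sel$q_value, sel$probe_id)]
}

#' Classify a probe's trajectory pattern
#'
#' Evaluates both group curves on a uniform grid over the basis domain.
#' When the sign of `ISR - NO_ISR` is the same strictly positive (or
#' strictly negative) value at every grid point the pattern is CONSISTENT
#' with that direction; when signs vary (including touching zero at some
#' times, e.g. curves that coincide at baseline and then separate) the
#' pattern is DIVERGENT, directed by the sign of the time-averaged
#' difference; identical curves are UNDETERMINED.
#'
#' @param fit_isr,fit_noisr `tvi_fit` objects on the same basis.
#' @param basis the shared [build_tvi_basis()] object.
#' @param grid_size number of grid points (default 101).
#' @param tol absolute tolerance treating a difference as zero.
#' @return one of `"CONSISTENT_ISR_GT"`, `"CONSISTENT_NOISR_GT"`,
#'   `"DIVERGENT_ISR_GT"`, `"DIVERGENT_NOISR_GT"`, `"UNDETERMINED"`.
#' @export
classify_pattern <- function(fit_isr, fit_noisr, basis, grid_size = 101L,
                             tol = 1e-12) {
  stopifnot(inherits(basis, "tvi_basis"))
  if (!identical(fit_isr$basis[c("knot_days", "degree", "domain")],
                 basis[c("knot_days", "degree", "domain")]) ||
      !identical(fit_noisr$basis[c("knot_days", "degree", "domain")],
                 basis[c("knot_days", "degree", "domain")])) {
    stopf("fits must share the classification basis")
  }
  grid <- seq(basis$domain[1L], basis$domain[2L], length.out = grid_size)
  d <- predict_curve(fit_isr, grid) - predict_curve(fit_noisr, grid)
  s <- sign(d)
  s[abs(d) <= tol] <- 0
  if (all(s == 0)) return("UNDETERMINED")
  if (all(s == 1)) return("CONSISTENT_ISR_GT")
  if (all(s == -1)) return("CONSISTENT_NOISR_GT")
  avg <- mean(d)
  if (avg > tol) "DIVERGENT_ISR_GT"
  else if (avg < -tol) "DIVERGENT_NOISR_GT"
  else "UNDETERMINED"
}

#' Run the time-course differential-expression scan
#'
#' Applies the time-varying intercept test ([bootstrap_pvalue()]) to every
#' probe: one shared basis is built from the manifest's sampling times, each
#' probe's bootstrap stream is seeded from a hash of its identifier plus the
#' master seed (so results do not depend on probe order or on
#' serial/parallel execution), q-values are computed over all tested probes,
#' and each probe's trajectory pattern is classified.
#'
#' Probes with missing values are fitted on their complete samples
#' (pairwise deletion); a probe left without both groups or two distinct
#' times gets `NA` results and is excluded from the FDR adjustment.
#'
#' @param mat preprocessed expression matrix.
#' @param manifest validated manifest covering every matrix sample.
#' @param n_bootstrap bootstrap resamples per probe.
#' @param seed master seed.
#' @param degree,knot_policy,knot passed to [build_tvi_basis()].
#' @param scheme bootstrap resampling scheme, see [bootstrap_pvalue()].
#' @param fdr_method `"bh"` or `"storey"`.
#' @param alpha FDR selection threshold.
#' @param annotation optional [annotation_map()] used to attach gene symbols.
#' @param threads number of worker processes (forked; results identical to
#'   serial).
#' @return data.frame with columns `probe_id, gene_symbol, rss_null,
#'   rss_alt, statistic, p_value, q_value, pattern, selected`.
#' @export
run_timecourse_scan <- function(mat, manifest,
                                n_bootstrap = 1000L, seed = 1L,
                                degree = 1L,
                                knot_policy = "median_followup", knot = NULL,
                                scheme = "subject_block_residual",
                                fdr_method = "bh", alpha = 0.05,
                                annotation = NULL, threads = 1L) {
  validate_expression_matrix(mat)
  manifest <- validate_manifest(manifest)
  idx <- match(colnames(mat), manifest$sample_id)
  if (anyNA(idx)) stopf("matrix samples missing from manifest")
  times <- manifest$time_days[idx]
  groups <- manifest$group[idx]
  subjects <- manifest$subject_id[idx]
  if (length(unique(groups)) < 2L) stopf("both groups must be present")

  probes <- rownames(mat)
  if (!length(probes)) {
    return(data.frame(probe_id = character(), gene_symbol = character(),
                      rss_null = numeric(), rss_alt = numeric(),
                      statistic = numeric(), p_value = numeric(),
                      q_value = numeric(), pattern = character(),
                      selected = logical(), stringsAsFactors = FALSE))
  }
  basis <- build_tvi_basis(times, degree = degree,
                           knot_policy = knot_policy, knot = knot)

  test_one <- function(g) {
    y <- mat[g, ]
    ok <- !is.na(y)
    if (length(unique(times[ok])) < 2L ||
        length(unique(groups[ok])) < 2L) {
      return(list(rss_null = NA_real_, rss_alt = NA_real_,
                  statistic = NA_real_, p_value = NA_real_,
                  pattern = "UNDETERMINED"))
    }
    bt <- bootstrap_pvalue(y[ok], times[ok], groups[ok], basis,
                           n_bootstrap = n_bootstrap,
                           seed = derive_seed(seed, g),
                           scheme = scheme, subjects = subjects[ok])
    list(rss_null = bt$rss_null, rss_alt = bt$rss_alt,
         statistic = bt$statistic, p_value = bt$p_value,
         pattern = classify_pattern(bt$fit_isr, bt$fit_noisr, basis))
  }
  rows <- if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(probes, test_one, mc.cores = threads)
  } else {
    lapply(probes, test_one)
  }

  res <- data.frame(
    probe_id = probes,
    gene_symbol = NA_character_,
    rss_null = vapply(rows, `[[`, numeric(1L), "rss_null"),
    rss_alt = vapply(rows, `[[`, numeric(1L), "rss_alt"),
    statistic = vapply(rows, `[[`, numeric(1L), "statistic"),
    p_value = vapply(rows, `[[`, numeric(1L), "p_value"),
    q_value = NA_real_,
    pattern = vapply(rows, `[[`, character(1L), "pattern"),
    selected = FALSE,
    stringsAsFactors = FALSE
  )
  tested <- !is.na(res$p_value)
  if (any(tested)) {
    res$q_value[tested] <- fdr_qvalues(res$p_value[tested], fdr_method)
  }
  res$selected <- !is.na(res$q_value) & res$q_value < alpha
  if (!is.null(annotation)) {
    res$gene_symbol <- map_probes_to_genes(probes, annotation)$mapping$gene_symbol
  }
  res
}

#' Baseline-only group comparison for a candidate gene list
#'
#' The hypothesis-driven check: for each listed probe, compare baseline
#' (day 0) expression between ISR and no-ISR subjects with Welch's
#' unequal-variance t test, BH-adjusting within the list.  Probes absent
#' from the matrix are reported with `missing = TRUE` rather than failing.
#'
#' @param mat expression matrix.
#' @param manifest validated manifest.
#' @param probe_list character vector of probe identifiers to test.
#' @return data.frame `probe_id, difference, statistic, p_value, q_value,
#'   missing`; `difference` is mean(ISR) - mean(NO_ISR) at baseline.
#' @export
baseline_comparison <- function(mat, manifest, probe_list) {
  validate_expression_matrix(mat)
  manifest <- validate_manifest(manifest)
  bl <- manifest[manifest$timepoint == "BL", ]
  cols <- match(bl$sample_id, colnames(mat))
  bl <- bl[!is.na(cols), ]
  cols <- cols[!is.na(cols)]
  if (!nrow(bl) || length(unique(bl$group)) < 2L) {
    stopf("baseline samples must exist in both groups")
  }
  isr <- bl$group == "ISR"
  out <- data.frame(probe_id = as.character(probe_list),
                    difference = NA_real_, statistic = NA_real_,
                    p_value = NA_real_, q_value = NA_real_,
                    missing = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    g <- out$probe_id[i]
    if (!g %in% rownames(mat)) {
      out$missing[i] <- TRUE
      next
    }
    y <- mat[g, cols]
    a <- y[isr]; b <- y[!isr]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) {
      out$missing[i] <- TRUE
      next
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    out$difference[i] <- mean(a) - mean(b)
    out$statistic[i] <- unname(tt$statistic)
    out$p_value[i] <- tt$p.value
  }
  ok <- !out$missing
  if (any(ok)) out$q_value[ok] <- fdr_qvalues(out$p_value[ok], "bh")
  out
}
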