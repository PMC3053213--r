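# Probe-level QC filtering and covariate adjustment applied ahead of the
# time-course analysis.

#' Remove probes sitting at the detection floor
#'
#' A probe is excluded when its value falls below `threshold` (log2 scale) in
#' strictly more than `fraction` of the samples — the standard low-intensity
#' rule for U133A-style arrays (threshold 6.0 in more than two thirds of
#' samples).  Missing values do not count as below-threshold; the denominator
#' is the total sample count.
#'
#' @param mat expression matrix (probes x samples).
#' @param threshold log2 cutoff (default 6.0).
#' @param fraction proportion of samples that must be below the cutoff,
#'   strict inequality (default 2/3).
#' @return list with `matrix` (retained probes, original order) and `report`
#'   (list: `n_input_probes`, `n_removed`, `removed_probe_ids`, `threshold`,
#'   `fraction_rule`).
#' @export
filter_low_expression <- function(mat, threshold = 6.0, fraction = 2 / 3) {
  validate_expression_matrix(mat)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stopf("fraction must lie in (0, 1]")
  }
  n_samples <- ncol(mat)
  n_below <- rowSums(mat < threshold, na.rm = TRUE)
  remove <- n_below > fraction * n_samples
  report <- list(
    n_input_probes = nrow(mat),
    n_removed = sum(remove),
    removed_probe_ids = rownames(mat)[remove],
    threshold = threshold,
    fraction_rule = fraction
  )
  list(matrix = mat[!remove, , drop = FALSE], report = report)
}

#' Regress age and sex out of every probe
#'
#' Fits, per probe, ordinary least squares of expression on an intercept plus
#' centred age and a 0/1 sex regressor (F = 0, M = 1) over all samples, and
#' returns the residuals plus the fitted intercept.  Because the covariates
#' are centred, the intercept is the probe's grand mean, so each probe's
#' overall level is preserved while the output is exactly orthogonal to age
#' and sex.  A covariate that is constant across samples is dropped with a
#' warning rather than an error.
#'
#' @param mat expression matrix; samples must match `manifest$sample_id`.
#' @param manifest validated manifest supplying `age` and `sex`.
#' @return adjusted expression matrix of the same shape.
#' @export
adjust_age_sex <- function(mat, manifest) {
  validate_expression_matrix(mat)
  manifest <- validate_manifest(manifest)
  idx <- match(colnames(mat), manifest$sample_id)
  if (anyNA(idx)) {
    stopf("sample '%s' missing from manifest",
          colnames(mat)[is.na(idx)][1L])
  }
  age <- manifest$age[idx]
  male <- as.numeric(manifest$sex[idx] == "M")
  covars <- list(age = age - mean(age), sex = male - mean(male))
  keep <- vapply(covars, function(v) stats::sd(v) > 0, logical(1L))
  if (!all(keep)) {
    warnf("constant covariate column(s) dropped: %s",
          paste(names(covars)[!keep], collapse = ", "))
  }
  covars <- covars[keep]
  if (!length(covars)) return(mat)
  X <- cbind(1, do.call(cbind, covars))
  qrX <- qr(X)
  out <- mat
  complete <- !apply(mat, 1L, anyNA)
  if (any(complete)) {
    # one shared design: residuals for all complete probes in one pass
    Yt <- t(mat[complete, , drop = FALSE])
    res <- qr.resid(qrX, Yt)
    out[complete, ] <- t(res) + rowMeans(mat[complete, , drop = FALSE])
  }
  for (g in which(!complete)) {
    ok <- !is.na(mat[g, ])
    if (sum(ok) <= ncol(X)) next
    fit <- stats::lm.fit(X[ok, , drop = FALSE], mat[g, ok])
    out[g, ok] <- fit$residuals + mean(mat[g, ok])
  }
  out
}
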