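# Sex-concordance QC: predict each sample's sex from marker-probe
# expression and flag disagreements with the manifest.

# Nearest-shrunken-centroid machinery (soft-thresholded class centroids on
# standardized expression), two classes F/M.
nsc_train <- function(X, y, shrinkage) {
  # X: samples x markers; y: factor with levels F, M
  n <- nrow(X)
  classes <- levels(y)
  overall <- colMeans(X)
  nk <- table(y)
  centroids <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                        numeric(ncol(X))))
  # pooled within-class SD per marker
  ss <- numeric(ncol(X))
  for (k in classes) {
    Xi <- X[y == k, , drop = FALSE]
    ss <- ss + colSums(sweep(Xi, 2L, colMeans(Xi))^2)
  }
  s <- sqrt(ss / (n - length(classes)))
  s0 <- stats::median(s)
  mk <- sqrt(1 / as.numeric(nk[classes]) + 1 / n)
  d <- sweep(centroids, 2L, overall) /
    (outer(mk, s + s0))
  d_shrunk <- sign(d) * pmax(abs(d) - shrinkage, 0)
  shrunk_centroids <- sweep(outer(mk, s + s0) * d_shrunk, 2L, overall, "+")
  list(classes = classes, centroids = shrunk_centroids, s = s, s0 = s0,
       prior = as.numeric(nk[classes]) / n,
       active = colSums(abs(d_shrunk)) > 0)
}

nsc_predict <- function(fit, X) {
  if (!any(fit$active)) return(rep("undetermined", nrow(X)))
  scale2 <- (fit$s + fit$s0)^2
  score <- vapply(seq_along(fit$classes), function(k) {
    rowSums(sweep(X, 2L, fit$centroids[k, ])^2 / rep(scale2, each = nrow(X))) -
      2 * log(fit$prior[k])
  }, numeric(nrow(X)))
  fit$classes[max.col(-score, ties.method = "first")]
}

nsc_pick_shrinkage <- function(X, y, grid, folds = 5L) {
  n <- nrow(X)
  folds <- min(folds, n)
  fold_id <- rep_len(seq_len(folds), n)[order(stats::runif(n))]
  err <- vapply(grid, function(delta) {
    mistakes <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2L) next
      fit <- nsc_train(X[tr, , drop = FALSE], droplevels(y[tr]), delta)
      pred <- nsc_predict(fit, X[!tr, , drop = FALSE])
      mistakes <- mistakes + sum(pred != as.character(y[!tr]))
    }
    mistakes
  }, numeric(1L))
  # ties broken toward the larger shrinkage (simpler classifier)
  grid[max(which(err == min(err)))]
}

#' Check recorded sex against expression-predicted sex
#'
#' Trains a classifier of sex on the given marker probes (all samples with a
#' recorded sex serve as training data, as in array QC practice) and flags
#' samples whose prediction disagrees with the manifest.
#' `method = "shrunken_centroid"` uses soft-thresholded class centroids on
#' standardized marker expression, with the shrinkage threshold chosen by
#' internal cross-validation unless supplied; `method = "lda"` uses
#' two-class linear discriminant analysis.
#'
#' @param mat expression matrix containing the marker probes.
#' @param manifest validated manifest with recorded sex.
#' @param marker_probes character vector of sex-marker probe identifiers.
#' @param method `"shrunken_centroid"` or `"lda"`.
#' @param shrinkage optional fixed soft-threshold for the centroid method; a
#'   value large enough to zero every centroid difference yields
#'   `"undetermined"` predictions with a warning.
#' @param seed seed for the cross-validation fold split.
#' @return data.frame with `sample_id`, `recorded_sex`, `predicted_sex`,
#'   `mismatch_flag` (`NA` when the prediction is undetermined).
#' @export
sex_check <- function(mat, manifest, marker_probes,
                      method = c("shrunken_centroid", "lda"),
                      shrinkage = NULL, seed = 1L) {
  method <- match.arg(method)
  validate_expression_matrix(mat)
  manifest <- validate_manifest(manifest)
  missing_markers <- setdiff(marker_probes, rownames(mat))
  if (length(missing_markers)) {
    stopf("marker probe(s) absent from matrix: %s",
          paste(missing_markers, collapse = ", "))
  }
  idx <- match(colnames(mat), manifest$sample_id)
  if (anyNA(idx)) stopf("matrix samples missing from manifest")
  recorded <- manifest$sex[idx]
  if (length(unique(recorded)) < 2L) {
    stopf("both sexes must be represented in the manifest for training")
  }
  X <- t(mat[marker_probes, , drop = FALSE])
  if (anyNA(X)) stopf("marker probes must have complete values")
  if (any(apply(X, 2L, stats::sd) == 0)) {
    stopf("zero-variance marker probe(s); review the marker list")
  }
  y <- factor(recorded, levels = c("F", "M"))

  predicted <- switch(method,
    shrunken_centroid = {
      if (is.null(shrinkage)) {
        n <- nrow(X)
        overall <- colMeans(X)
        fit0 <- nsc_train(X, y, 0)
        dmax <- {
          mk <- sqrt(1 / as.numeric(table(y)) + 1 / n)
          d <- sweep(fit0$centroids, 2L, overall) /
            outer(mk, fit0$s + fit0$s0)
          max(abs(d))
        }
        grid <- unique(c(0, stats::quantile(seq(0, dmax, length.out = 50),
                                            c(0.25, 0.5, 0.75, 0.9))))
        shrinkage <- with_seed(seed, nsc_pick_shrinkage(X, y, grid))
      }
      fit <- nsc_train(X, y, shrinkage)
      if (!any(fit$active)) {
        warnf("all centroid differences shrunk to zero; predictions undetermined")
      }
      nsc_predict(fit, X)
    },
    lda = {
      fit <- MASS::lda(X, grouping = y)
      as.character(stats::predict(fit, X)$class)
    }
  )
  mismatch <- ifelse(predicted == "undetermined", NA,
                     predicted != recorded)
  data.frame(sample_id = colnames(mat),
             recorded_sex = recorded,
             predicted_sex = predicted,
             mismatch_flag = mismatch,
             stringsAsFactors = FALSE)
}
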