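# Independent oracles used to check the implementation: brute-force segment
# means for the degree-0 spline model, rejection-cutoff enumeration for BH,
# and binomial-coefficient tail sums for the hypergeometric test.

# Degree-0 time-varying intercept model reduces to per-segment means; the
# statistic follows by direct arithmetic.
oracle_segment_T <- function(y, t, g, knot) {
  seg_rss <- function(v) if (length(v) == 0L) 0 else sum((v - mean(v))^2)
  pre <- t <= knot
  rss0 <- seg_rss(y[pre]) + seg_rss(y[!pre])
  rss1 <- 0
  for (grp in unique(g)) {
    sel <- g == grp
    rss1 <- rss1 + seg_rss(y[sel & pre]) + seg_rss(y[sel & !pre])
  }
  list(rss_null = rss0, rss_alt = rss1,
       statistic = if (rss1 == 0) Inf else (rss0 - rss1) / rss1)
}

# BH adjusted value of p_i = smallest level alpha at which the step-up
# procedure rejects p_i; enumerate candidate cutoffs directly.
oracle_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  alphas <- sort(unique(c(pmin(m * ps / seq_len(m), 1), 1)))
  eps <- 1e-10  # float-equality guard: candidate cutoffs are m*p/j round-trips
  vapply(p, function(pi) {
    for (a in alphas) {
      ok <- which(ps <= a * seq_len(m) / m + eps)
      if (length(ok) && pi <= ps[max(ok)] + eps) return(a)
    }
    1
  }, numeric(1L))
}

# Upper-tail hypergeometric probability P(X >= k) from binomial coefficients.
oracle_hyper_tail <- function(k, K, n, N) {
  if (k <= max(0L, n + K - N)) return(1)
  js <- k:min(K, n)
  if (!length(js) || k > min(K, n)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# Small hand-built longitudinal manifest: 4 subjects x up to 3 draws.
tiny_manifest <- function() {
  data.frame(
    sample_id = c("A_BL", "A_EF", "A_LF", "B_BL", "B_EF",
                  "C_BL", "C_LF", "D_BL"),
    subject_id = c("A", "A", "A", "B", "B", "C", "C", "D"),
    group = c(rep("ISR", 5), rep("NO_ISR", 3)),
    time_days = c(0, 18, 182, 0, 21, 0, 175, 0),
    timepoint = c("BL", "EF", "LF", "BL", "EF", "BL", "LF", "BL"),
    age = c(62, 62, 62, 71, 71, 58, 58, 66),
    sex = c("F", "F", "F", "M", "M", "M", "M", "F"),
    stringsAsFactors = FALSE
  )
}

# Matrix whose samples match tiny_manifest(), deterministic values.
tiny_matrix <- function(n_probes = 3L) {
  m <- tiny_manifest()
  set.seed(99)
  mat <- matrix(round(stats::rnorm(n_probes * nrow(m), 8, 1), 4),
                n_probes, nrow(m),
                dimnames = list(sprintf("%06d_at", 100000L + seq_len(n_probes)),
                                m$sample_id))
  mat
}

# Simulated discovery/replication pair sharing one signal spec.
sim_pair <- function(n_subjects = 40L, rep_subjects = 60L, spec, seed = 1L) {
  d1 <- cohort_design("cardiogene", n_subjects = n_subjects)
  d2 <- cohort_design("decode", n_subjects = rep_subjects)
  m1 <- simulate_manifest(d1, seed = seed)
  m2 <- simulate_manifest(d2, seed = seed + 500L)
  e1 <- simulate_expression(m1, spec, seed = seed + 1L)
  e2 <- simulate_expression(m2, spec, seed = seed + 501L, truth = e1$truth)
  list(disc = list(manifest = m1, matrix = e1$matrix, truth = e1$truth),
       repl = list(manifest = m2, matrix = e2$matrix, truth = e2$truth))
}
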