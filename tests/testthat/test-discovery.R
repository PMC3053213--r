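test_that("BH q-values match the step-up arithmetic and handle ties", {
  expect_equal(fdr_qvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4L))
  expect_equal(fdr_qvalues(rep(0.05, 5L)), rep(0.05, 5L))
  expect_equal(fdr_qvalues(0.3), 0.3)
  expect_equal(fdr_qvalues(numeric(0)), numeric(0))
  expect_error(fdr_qvalues(c(0.5, 0)), "0, 1")
  expect_error(fdr_qvalues(c(0.5, 1.2)), "0, 1")
  # matches stats::p.adjust (an independent implementation path)
  set.seed(31)
  p <- runif(50)
  expect_equal(fdr_qvalues(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("BH q-values equal the rejection-cutoff enumeration oracle", {
  set.seed(32)
  for (i in 1:200) {
    m <- sample(1:8, 1L)
    p <- round(runif(m), 3)
    p[p == 0] <- 0.001
    expect_equal(fdr_qvalues(p), oracle_bh(p), tolerance = 1e-12,
                 info = paste(p, collapse = ","))
  }
})

test_that("Storey q-values scale BH by an estimated null proportion", {
  set.seed(33)
  # mostly-null p set: pi0 estimate < 1 so storey <= bh
  p <- c(runif(180), rbeta(20, 0.2, 8))
  q_bh <- fdr_qvalues(p, "bh")
  q_st <- fdr_qvalues(p, "storey")
  expect_true(all(q_st <= q_bh + 1e-12))
  expect_true(all(q_st > 0 & q_st <= 1))
})

test_that("selection is strict at the threshold and order-invariant", {
  res <- data.frame(probe_id = c("c", "a", "b"),
                    q_value = c(0.05, 0.01, 0.049))
  expect_equal(select_significant(res), c("a", "b"))
  expect_equal(select_significant(res[c(2, 3, 1), ]), c("a", "b"))
  expect_equal(select_significant(data.frame(probe_id = "x", q_value = 0.9)),
               character(0))
})

test_that("pattern classification separates consistent from divergent", {
  t <- c(0, 0, 14, 14, 180, 180)
  b <- build_tvi_basis(t, degree = 1L)
  fit_at <- function(y) fit_curve(y, t, b)
  base <- c(5, 5, 6, 6, 5.5, 5.5)

  # constant offset -> consistent, ISR above
  expect_equal(classify_pattern(fit_at(base + 1), fit_at(base), b),
               "CONSISTENT_ISR_GT")
  expect_equal(classify_pattern(fit_at(base), fit_at(base + 1), b),
               "CONSISTENT_NOISR_GT")
  # equal at baseline, linear separation -> divergent, ISR above
  sep <- t / 180
  expect_equal(classify_pattern(fit_at(base + sep), fit_at(base), b),
               "DIVERGENT_ISR_GT")
  # identical curves -> undetermined
  expect_equal(classify_pattern(fit_at(base), fit_at(base), b),
               "UNDETERMINED")
  # crossing curves -> divergent, direction from time-averaged difference
  cross <- classify_pattern(fit_at(base + (sep - 0.2)), fit_at(base), b)
  expect_match(cross, "^DIVERGENT")

  # antisymmetry: swapping fits flips direction, preserves the class
  flip <- c(CONSISTENT_ISR_GT = "CONSISTENT_NOISR_GT",
            CONSISTENT_NOISR_GT = "CONSISTENT_ISR_GT",
            DIVERGENT_ISR_GT = "DIVERGENT_NOISR_GT",
            DIVERGENT_NOISR_GT = "DIVERGENT_ISR_GT",
            UNDETERMINED = "UNDETERMINED")
  set.seed(34)
  for (i in 1:20) {
    y1 <- rnorm(6, 6); y2 <- rnorm(6, 6)
    lab <- classify_pattern(fit_at(y1), fit_at(y2), b)
    expect_equal(classify_pattern(fit_at(y2), fit_at(y1), b),
                 unname(flip[lab]))
  }
})

test_that("the scan is deterministic, order-invariant and handles edge cases", {
  m <- simulate_manifest(cohort_design("custom", n_subjects = 16L), seed = 35L)
  ex <- simulate_expression(m, signal_spec(n_probes = 12L,
                                           frac_main_effect = 0.25,
                                           delta_main = 2),
                            seed = 36L)
  res <- run_timecourse_scan(ex$matrix, m, n_bootstrap = 199L, seed = 37L)
  expect_equal(nrow(res), 12L)
  expect_true(all(res$rss_alt <= res$rss_null + 1e-10))

  # probe order must not change per-probe results
  perm <- sample(nrow(ex$matrix))
  res_perm <- run_timecourse_scan(ex$matrix[perm, ], m,
                                  n_bootstrap = 199L, seed = 37L)
  reord <- res_perm[match(res$probe_id, res_perm$probe_id), ]
  expect_equal(reord$p_value, res$p_value)
  expect_equal(reord$statistic, res$statistic)

  # parallel equals serial
  res_par <- run_timecourse_scan(ex$matrix, m, n_bootstrap = 199L,
                                 seed = 37L, threads = 2L)
  expect_equal(res_par$p_value, res$p_value)

  # empty matrix -> empty result, no error
  empty <- run_timecourse_scan(ex$matrix[0L, , drop = FALSE], m)
  expect_equal(nrow(empty), 0L)

  # missing values: pairwise dropped, still tested
  holey <- ex$matrix
  holey[1L, 1:3] <- NA
  res_na <- run_timecourse_scan(holey, m, n_bootstrap = 199L, seed = 37L)
  expect_false(is.na(res_na$p_value[1L]))
})

test_that("baseline comparison matches a closed-form Welch computation", {
  m <- tiny_manifest()
  mat <- tiny_matrix(2L)
  # 2 ISR + 2 NO_ISR baseline samples; hand-check probe 1
  bl <- m[m$timepoint == "BL", ]
  y <- mat[1L, bl$sample_id]
  a <- y[bl$group == "ISR"]; b <- y[bl$group == "NO_ISR"]
  se <- sqrt(var(a) / 2 + var(b) / 2)
  t_hand <- (mean(a) - mean(b)) / se
  res <- baseline_comparison(mat, m, rownames(mat))
  expect_equal(res$statistic[1L], t_hand, tolerance = 1e-12)
  expect_equal(res$difference[1L], mean(a) - mean(b), tolerance = 1e-12)

  # identical groups -> difference 0, p = 1
  mat2 <- mat
  mat2[1L, bl$sample_id] <- c(5, 7, 5, 7)
  res2 <- baseline_comparison(mat2, m, rownames(mat2)[1L])
  expect_equal(res2$difference[1L], 0)
  expect_equal(res2$p_value[1L], 1, tolerance = 1e-12)

  # absent probe recorded as missing, not fatal
  res3 <- baseline_comparison(mat, m, c("nope_at", rownames(mat)[1L]))
  expect_true(res3$missing[1L])
  expect_false(res3$missing[2L])
})

test_that("a planted baseline shift is detected at the stated power", {
  d <- cohort_design("custom", n_subjects = 100L, isr_fraction = 0.5)
  m <- simulate_manifest(d, seed = 38L)
  bl <- m$timepoint == "BL"
  set.seed(39)
  sigma <- 0.5
  y <- rnorm(nrow(m), 8, sigma) + 2 * sigma * (m$group == "ISR") * bl
  mat <- rbind(shift_at = y)
  colnames(mat) <- m$sample_id
  res <- baseline_comparison(mat, m, "shift_at")
  expect_lt(res$p_value[1L], 0.01)
})
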