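test_that("floor filter applies the strict more-than rule", {
  mk <- function(vals) matrix(vals, nrow = 1,
                              dimnames = list("p1", paste0("s", seq_along(vals))))
  # 5 of 6 below threshold: 5 > (2/3)*6 = 4 -> removed
  f <- filter_low_expression(mk(c(5, 5, 5, 5, 5, 8)))
  expect_equal(f$report$n_removed, 1L)
  # exactly 4 of 6 below: 4 is not > 4 -> retained
  f2 <- filter_low_expression(mk(c(5, 5, 5, 5, 8, 8)))
  expect_equal(f2$report$n_removed, 0L)
  # all at/above threshold -> retained
  f3 <- filter_low_expression(mk(rep(6, 6)))
  expect_equal(f3$report$n_removed, 0L)
  expect_error(filter_low_expression(mk(rep(6, 6)), fraction = 0), "fraction")
})

test_that("floor filter is idempotent and preserves probe order", {
  set.seed(11)
  mat <- matrix(runif(300, 4, 10), 30, 10,
                dimnames = list(sprintf("p%02d", 1:30), sprintf("s%02d", 1:10)))
  once <- filter_low_expression(mat)
  twice <- filter_low_expression(once$matrix)
  expect_identical(twice$matrix, once$matrix)
  expect_equal(twice$report$n_removed, 0L)
  expect_identical(rownames(once$matrix),
                   rownames(mat)[!rownames(mat) %in% once$report$removed_probe_ids])
  expect_equal(once$report$n_input_probes,
               once$report$n_removed + nrow(once$matrix))
})

test_that("age/sex adjustment removes covariate signal and keeps levels", {
  m <- simulate_manifest(cohort_design("custom", n_subjects = 25L), seed = 12L)
  # no covariate effect, zero noise -> output equals input
  spec0 <- signal_spec(n_probes = 4L, frac_main_effect = 0,
                       frac_interaction = 0, sigma_noise = 0,
                       sigma_subject = 0, beta_age_sd = 0, beta_sex_sd = 0)
  ex0 <- simulate_expression(m, spec0, seed = 13L)
  adj0 <- adjust_age_sex(ex0$matrix, m)
  expect_equal(adj0, ex0$matrix, tolerance = 1e-10)

  # planted age slope: adjusted output decorrelated from age, level preserved,
  # and residuals match a direct normal-equations solve
  age <- m$age
  male <- as.numeric(m$sex == "M")
  set.seed(14)
  y <- 8 + 0.05 * age + 0.4 * male + rnorm(nrow(m), 0, 0.1)
  mat <- rbind(p1 = y)
  colnames(mat) <- m$sample_id
  adj <- adjust_age_sex(mat, m)
  expect_lt(abs(cor(adj["p1", ], age)), 1e-10)
  expect_lt(abs(cor(adj["p1", ], male)), 1e-10)
  expect_equal(mean(adj["p1", ]), mean(y), tolerance = 1e-10)
  X <- cbind(1, age, male)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(adj["p1", ]), unname(y - X %*% beta + mean(y))[, 1L],
               tolerance = 1e-10)
  # refitting the covariates on the adjusted data gives ~zero coefficients
  refit <- solve(t(X) %*% X, t(X) %*% adj["p1", ])
  expect_lt(max(abs(refit[-1L])), 1e-8)
})

test_that("constant covariates are dropped with a warning, not an error", {
  m <- tiny_manifest()
  m$sex <- "F"  # all-female manifest
  mat <- tiny_matrix(2L)
  expect_warning(adj <- adjust_age_sex(mat, m), "sex")
  # age is still adjusted
  age <- m$age[match(colnames(mat), m$sample_id)]
  expect_lt(abs(cor(adj[1L, ], age)), 1e-10)
})

test_that("sex_check recovers planted sex and flags a swapped record", {
  d <- cohort_design("custom", n_subjects = 40L, female_fraction = 0.5)
  m <- simulate_manifest(d, seed = 15L)
  spec <- signal_spec(n_probes = 20L, frac_main_effect = 0,
                      frac_interaction = 0, n_sex_markers = 4L,
                      sex_marker_effect = 3, sigma_noise = 0.3,
                      sigma_subject = 0.2)
  ex <- simulate_expression(m, spec, seed = 16L)
  markers <- ex$truth$probe_id[ex$truth$sex_marker]

  for (method in c("shrunken_centroid", "lda")) {
    chk <- sex_check(ex$matrix, m, markers, method = method)
    expect_equal(sum(chk$mismatch_flag), 0L, info = method)
  }

  # swap one subject's recorded sex: exactly those samples get flagged
  m_bad <- m
  victim <- unique(m$subject_id)[1L]
  rows <- m_bad$subject_id == victim
  m_bad$sex[rows] <- ifelse(m_bad$sex[rows] == "F", "M", "F")
  chk <- sex_check(ex$matrix, m_bad, markers)
  expect_setequal(chk$sample_id[which(chk$mismatch_flag)],
                  m_bad$sample_id[rows])
  # lda and shrunken centroid agree on well-separated data
  chk_lda <- sex_check(ex$matrix, m_bad, markers, method = "lda")
  expect_equal(chk$predicted_sex, chk_lda$predicted_sex)
})

test_that("fully shrunken centroids abstain with a warning", {
  m <- tiny_manifest()
  mat <- tiny_matrix(3L)
  expect_warning(
    chk <- sex_check(mat, m, rownames(mat), shrinkage = 1e6),
    "undetermined")
  expect_true(all(chk$predicted_sex == "undetermined"))
  expect_true(all(is.na(chk$mismatch_flag)))
  # zero-variance marker -> error advising review
  mat0 <- mat; mat0[1L, ] <- 5
  expect_error(sex_check(mat0, m, rownames(mat0)), "zero-variance")
})
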