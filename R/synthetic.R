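# Synthetic longitudinal cohorts emulating the CardioGene (three-draw,
# nested retention) and deCODE (two-draw) stent-implantation designs, with
# per-probe ground truth for power/calibration testing.

#' Describe a longitudinal cohort design
#'
#' Templates encode the two study designs the generator emulates.  The
#' `cardiogene` template has baseline, early follow-up (2-4 weeks) and late
#' follow-up (5-7 months, or ~12 months for a fraction of late draws), with
#' late follow-up nested inside early follow-up (312 -> 203 -> 166 subjects).
#' The `decode` template has baseline plus a single ~6-month follow-up
#' (97 -> 86).  With `exact = TRUE` (the default for named templates)
#' retention, group and sex counts are fixed at `round(n * fraction)` so the
#' template reproduces the published profile totals deterministically; with
#' `exact = FALSE` they are Bernoulli draws.
#'
#' @param template one of `"cardiogene"`, `"decode"`, `"custom"`.
#' @param n_subjects number of enrolled subjects (all get a baseline draw).
#' @param isr_fraction fraction of subjects developing in-stent restenosis.
#' @param early_window_days,late_window_days,late_alt_window_days sampling
#'   windows in days post-stent.
#' @param p_late_at_12mo probability a late draw falls in the alternate
#'   (~12 month) window.
#' @param retention_early probability/fraction of subjects with an early
#'   follow-up draw.
#' @param retention_late probability/fraction with a late draw; conditional
#'   on having the early draw when `nested = TRUE`.
#' @param nested whether late follow-up is nested within early follow-up.
#' @param age_mean,age_sd subject age distribution (years).
#' @param female_fraction fraction of female subjects.
#' @param exact use exact counts instead of Bernoulli retention.
#' @return list of class `cohort_design`.
#' @export
cohort_design <- function(template = c("cardiogene", "decode", "custom"),
                          n_subjects = NULL,
                          isr_fraction = NULL,
                          early_window_days = c(14, 28),
                          late_window_days = c(150, 210),
                          late_alt_window_days = c(350, 380),
                          p_late_at_12mo = NULL,
                          retention_early = NULL,
                          retention_late = NULL,
                          nested = NULL,
                          age_mean = NULL,
                          age_sd = NULL,
                          female_fraction = NULL,
                          exact = TRUE) {
  template <- match.arg(template)
  defaults <- switch(template,
    cardiogene = list(n_subjects = 312L, isr_fraction = 52 / 312,
                      p_late_at_12mo = 0.2,
                      retention_early = 203 / 312, retention_late = 166 / 203,
                      nested = TRUE, age_mean = 65.6, age_sd = 10.4,
                      female_fraction = 100 / 312),
    decode = list(n_subjects = 97L, isr_fraction = 28 / 97,
                  p_late_at_12mo = 0,
                  retention_early = 0, retention_late = 86 / 97,
                  nested = FALSE, age_mean = 64.8, age_sd = 10.0,
                  female_fraction = 19 / 97),
    custom = list(n_subjects = 100L, isr_fraction = 0.2, p_late_at_12mo = 0.2,
                  retention_early = 0.7, retention_late = 0.8, nested = TRUE,
                  age_mean = 65, age_sd = 10, female_fraction = 0.3)
  )
  design <- list(
    template = template,
    n_subjects = as.integer(n_subjects %||% defaults$n_subjects),
    isr_fraction = isr_fraction %||% defaults$isr_fraction,
    early_window_days = early_window_days,
    late_window_days = late_window_days,
    late_alt_window_days = late_alt_window_days,
    p_late_at_12mo = p_late_at_12mo %||% defaults$p_late_at_12mo,
    retention_early = retention_early %||% defaults$retention_early,
    retention_late = retention_late %||% defaults$retention_late,
    nested = nested %||% defaults$nested,
    age_mean = age_mean %||% defaults$age_mean,
    age_sd = age_sd %||% defaults$age_sd,
    female_fraction = female_fraction %||% defaults$female_fraction,
    exact = isTRUE(exact)
  )
  fr <- c(design$isr_fraction, design$p_late_at_12mo, design$retention_early,
          design$retention_late, design$female_fraction)
  if (any(fr < 0 | fr > 1)) stopf("fractions/probabilities must lie in [0, 1]")
  if (design$n_subjects < 1L) stopf("n_subjects must be >= 1")
  win_ok <- function(w) length(w) == 2L && w[1L] > 0 && w[2L] >= w[1L]
  if (!win_ok(design$early_window_days) || !win_ok(design$late_window_days) ||
      !win_ok(design$late_alt_window_days)) {
    stopf("sampling windows must be positive intervals [lo, hi]")
  }
  if (design$early_window_days[2L] >= design$late_window_days[1L] ||
      design$late_window_days[2L] > design$late_alt_window_days[1L]) {
    stopf("sampling windows must be non-overlapping and ordered")
  }
  structure(design, class = "cohort_design")
}

# Pick exactly round(n * frac) of n units (or Bernoulli draws when
# exact = FALSE); returns a logical vector.
draw_membership <- function(n, frac, exact) {
  if (n == 0L) return(logical(0L))
  if (exact) {
    k <- round(n * frac)
    member <- logical(n)
    member[sample.int(n, k)] <- TRUE
    member
  } else {
    stats::runif(n) < frac
  }
}

#' Simulate a longitudinal sample manifest
#'
#' Every subject gets a baseline (`BL`) record at day 0.  Early follow-up
#' (`EF`) times are uniform over the early window; late follow-up (`LF`)
#' times are uniform over the late window, or over the alternate ~12-month
#' window with probability `p_late_at_12mo`.  Under a nested design the late
#' draw is only offered to subjects who provided the early draw.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed; identical seeds give identical manifests.
#' @return validated manifest data.frame.
#' @export
simulate_manifest <- function(design, seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(seed, {
    n <- design$n_subjects
    subject_id <- sprintf("S%04d", seq_len(n))
    isr <- draw_membership(n, design$isr_fraction, design$exact)
    female <- draw_membership(n, design$female_fraction, design$exact)
    age <- round(stats::rnorm(n, design$age_mean, design$age_sd), 1)
    age <- pmin(pmax(age, 25), 95)

    has_ef <- draw_membership(n, design$retention_early, design$exact)
    if (design$nested) {
      idx_ef <- which(has_ef)
      has_lf <- logical(n)
      has_lf[idx_ef[draw_membership(length(idx_ef), design$retention_late,
                                    design$exact)]] <- TRUE
    } else {
      has_lf <- draw_membership(n, design$retention_late, design$exact)
    }

    runi <- function(k, w) round(stats::runif(k, w[1L], w[2L]))
    ef_time <- rep(NA_real_, n)
    ef_time[has_ef] <- runi(sum(has_ef), design$early_window_days)
    lf_time <- rep(NA_real_, n)
    at_12mo <- stats::runif(n) < design$p_late_at_12mo
    lf_time[has_lf & !at_12mo] <- runi(sum(has_lf & !at_12mo),
                                       design$late_window_days)
    lf_time[has_lf & at_12mo] <- runi(sum(has_lf & at_12mo),
                                      design$late_alt_window_days)

    rec <- function(keep, tp, tm) {
      if (!any(keep)) return(NULL)
      data.frame(
        sample_id = paste0(subject_id[keep], "_", tp),
        subject_id = subject_id[keep],
        group = ifelse(isr[keep], "ISR", "NO_ISR"),
        time_days = tm[keep],
        timepoint = tp,
        age = age[keep],
        sex = ifelse(female[keep], "F", "M"),
        stringsAsFactors = FALSE
      )
    }
    manifest <- rbind(
      rec(rep(TRUE, n), "BL", rep(0, n)),
      rec(has_ef, "EF", ef_time),
      rec(has_lf, "LF", lf_time)
    )
    rownames(manifest) <- NULL
    validate_manifest(manifest)
  })
}

#' Describe the per-probe signal structure of a synthetic matrix
#'
#' Probes are partitioned into null, main-effect (a constant log2 offset in
#' the ISR group) and interaction probes (divergence accruing linearly from
#' zero at baseline to `delta_interaction` at the latest follow-up time).
#' A designated fraction of (null) probes sit near the detection floor so the
#' quality-control filter has something to remove; optional sex-marker probes
#' carry a large sex effect for sex-concordance QC testing.
#'
#' @param n_probes number of probes.
#' @param frac_main_effect,frac_interaction fractions of probes carrying each
#'   signal type (the remainder are null).
#' @param delta_main log2 offset added to the ISR group at all times.
#' @param delta_interaction log2 divergence reached at the maximum follow-up
#'   time.
#' @param sigma_noise residual SD (log2).
#' @param sigma_subject subject random-effect SD (log2).
#' @param beta_age_sd,beta_sex_sd SDs of the per-probe covariate effects
#'   (drawn `N(0, sd)` per probe; age is centred before use).
#' @param floor_value detection-floor anchor on the log2 scale; designated
#'   floor probes are generated ~1.5 units below it and all values are
#'   left-censored 2.5 units below it.
#' @param frac_floor_probes fraction of probes generated near/below floor.
#' @param n_sex_markers number of probes given a strong sex effect.
#' @param sex_marker_effect log2 male-minus-female shift for marker probes.
#' @param mu_range range of baseline probe means for regular probes.
#' @param shared_subject_effect if `TRUE`, one subject effect is shared by
#'   all probes (more realistic, correlated probes); default draws it
#'   independently per probe so probe-level fits stay independent.
#' @return list of class `signal_spec`.
#' @export
signal_spec <- function(n_probes = 200L,
                        frac_main_effect = 0.05,
                        frac_interaction = 0.05,
                        delta_main = 0.75,
                        delta_interaction = 1.0,
                        sigma_noise = 0.5,
                        sigma_subject = 0.3,
                        beta_age_sd = 0.01,
                        beta_sex_sd = 0.1,
                        floor_value = 6.0,
                        frac_floor_probes = 0,
                        n_sex_markers = 0L,
                        sex_marker_effect = 3.0,
                        mu_range = c(7, 12),
                        shared_subject_effect = FALSE) {
  if (frac_main_effect + frac_interaction > 1) {
    stopf("signal fractions must sum to at most 1")
  }
  if (any(c(frac_main_effect, frac_interaction, frac_floor_probes) < 0)) {
    stopf("fractions must be >= 0")
  }
  if (any(c(sigma_noise, sigma_subject, beta_age_sd, beta_sex_sd) < 0)) {
    stopf("SDs must be >= 0")
  }
  structure(as.list(environment()), class = "signal_spec")
}

#' Simulate a log2 expression matrix with known ground truth
#'
#' The value for probe g on sample (i, t) is
#' `mu_g + beta_age_g (age_i - mean age) + beta_sex_g male_i + b_ig +
#'  f_g(group_i, t) + eps`, where `f_g` is zero for null probes,
#' `delta_main * 1[ISR]` for main-effect probes and
#' `delta_interaction * (t / t_max) * 1[ISR]` for interaction probes.
#' Values are left-censored at the detection limit (`floor_value - 2.5`).
#'
#' @param manifest validated manifest.
#' @param spec a [signal_spec()].
#' @param seed integer seed.
#' @param truth optional ground-truth table from a previous call; reusing it
#'   fixes the probe identities and the null/main/interaction/floor/marker
#'   partition, so an independent replication cohort carries signal on the
#'   same probes as the discovery cohort.
#' @return list with `matrix` (probes x samples) and `truth` (data.frame
#'   `probe_id`, `label`, `delta`, `floor_probe`, `sex_marker`).
#' @export
simulate_expression <- function(manifest, spec, seed = 1L, truth = NULL) {
  stopifnot(inherits(spec, "signal_spec"))
  manifest <- validate_manifest(manifest)
  if (nrow(manifest) == 0L) stopf("manifest is empty")
  with_seed(seed, {
    ns <- nrow(manifest)
    if (!is.null(truth)) {
      np <- nrow(truth)
      probe_id <- truth$probe_id
      label <- truth$label
      floor_probe <- truth$floor_probe
      sex_marker <- truth$sex_marker
    } else {
      np <- as.integer(spec$n_probes)
      probe_id <- sprintf("%06d_at", 200000L + seq_len(np))

      n_main <- round(spec$frac_main_effect * np)
      n_int <- round(spec$frac_interaction * np)
      label <- rep("null", np)
      lab_idx <- sample.int(np, n_main + n_int)
      label[lab_idx[seq_len(n_main)]] <- "main_effect"
      if (n_int > 0) label[lab_idx[n_main + seq_len(n_int)]] <- "interaction"

      null_idx <- which(label == "null")
      n_floor <- round(spec$frac_floor_probes * np)
      n_marker <- as.integer(spec$n_sex_markers)
      if (n_floor + n_marker > length(null_idx)) {
        stopf("not enough null probes for the requested floor/sex-marker counts")
      }
      special <- null_idx[sample.int(length(null_idx), n_floor + n_marker)]
      floor_probe <- logical(np); floor_probe[special[seq_len(n_floor)]] <- TRUE
      sex_marker <- logical(np)
      if (n_marker > 0) sex_marker[special[n_floor + seq_len(n_marker)]] <- TRUE
    }

    mu <- stats::runif(np, spec$mu_range[1L], spec$mu_range[2L])
    mu[floor_probe] <- spec$floor_value - 1.5 +
      stats::runif(sum(floor_probe), -0.3, 0.3)
    beta_age <- stats::rnorm(np, 0, spec$beta_age_sd)
    beta_sex <- stats::rnorm(np, 0, spec$beta_sex_sd)
    beta_sex[sex_marker] <- spec$sex_marker_effect

    age_c <- manifest$age - mean(manifest$age)
    male <- as.numeric(manifest$sex == "M")
    isr <- as.numeric(manifest$group == "ISR")
    t_max <- max(manifest$time_days)
    t_frac <- if (t_max > 0) manifest$time_days / t_max else rep(0, ns)

    delta <- rep(0, np)
    delta[label == "main_effect"] <- spec$delta_main
    delta[label == "interaction"] <- spec$delta_interaction
    # per-probe group effect profile over samples (np x ns)
    f_profile <- matrix(0, np, ns)
    if (any(label == "main_effect")) {
      f_profile[label == "main_effect", ] <-
        spec$delta_main * matrix(isr, sum(label == "main_effect"), ns,
                                 byrow = TRUE)
    }
    if (any(label == "interaction")) {
      f_profile[label == "interaction", ] <-
        spec$delta_interaction * matrix(isr * t_frac,
                                        sum(label == "interaction"), ns,
                                        byrow = TRUE)
    }

    subj <- factor(manifest$subject_id)
    n_subj <- nlevels(subj)
    if (spec$shared_subject_effect) {
      b_subj <- stats::rnorm(n_subj, 0, spec$sigma_subject)
      b <- matrix(b_subj[as.integer(subj)], np, ns, byrow = TRUE)
    } else {
      b_subj <- matrix(stats::rnorm(np * n_subj, 0, spec$sigma_subject),
                       np, n_subj)
      b <- b_subj[, as.integer(subj), drop = FALSE]
    }

    eps <- matrix(stats::rnorm(np * ns, 0, spec$sigma_noise), np, ns)
    values <- mu +
      outer(beta_age, age_c) +
      outer(beta_sex, male) +
      b + f_profile + eps
    values <- pmax(values, spec$floor_value - 2.5)
    dimnames(values) <- list(probe_id, manifest$sample_id)
    validate_expression_matrix(values)

    truth <- data.frame(probe_id = probe_id, label = label, delta = delta,
                        floor_probe = floor_probe, sex_marker = sex_marker,
                        stringsAsFactors = FALSE)
    list(matrix = values, truth = truth)
  })
}

#' Write a ground-truth table as TSV
#' @param truth ground-truth data.frame from [simulate_expression()].
#' @param path output path.
#' @export
ground_truth_table <- function(truth, path) {
  stopifnot(all(c("probe_id", "label", "delta") %in% names(truth)))
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth table written by [ground_truth_table()]
#' @param path TSV path.
#' @return ground-truth data.frame.
#' @export
read_ground_truth <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}
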