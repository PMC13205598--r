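# Algorithmic sex-bias forensics.
#
# Quantifies how a generative run distorts the demographic composition and the
# sex-specific disease structure of a cohort: female representation shift,
# per-disease sex-stratified prevalence and distributional fidelity, bias
# amplification across runs, sex-signal portability between real and synthetic
# data, prevalence-error thresholding, and standardized effect sizes.

female_share <- function(x) {
  sexes <- vapply(x$records, `[[`, "", "sex")
  mean(sexes == "female", na.rm = TRUE)
}

#' Sex bias delta
#'
#' Percentage-point difference in female representation between the synthetic
#' and real cohorts: `100 * (female share synth - female share real)`.
#'
#' @param real,synth `ehr_cohort`s with sex recorded.
#' @return signed percentage points.
#' @export
sex_bias_delta <- function(real, synth) {
  100 * (female_share(synth) - female_share(real))
}

#' Per-disease sex-stratified fidelity table
#'
#' For every non-anchor disease: prevalence by sex in real and synthetic data,
#' the female-male prevalence difference (percentage points), the per-sex KS
#' statistic on age at first diagnosis (among the diagnosed), and the
#' sex-specific prevalence shift
#' `(synth - real in women) - (synth - real in men)` in percentage points.
#'
#' @param real,synth `ehr_cohort`s sharing a vocabulary.
#' @return data frame, one row per disease.
#' @export
per_feature_sex_stats <- function(real, synth) {
  tr <- flatten(real); ts <- flatten(synth)
  codes <- setdiff(real$vocabulary, real$anchor_code)
  rows <- lapply(codes, function(cd) {
    fl <- paste0("flag_", cd); ag <- paste0("age_", cd)
    pr <- function(tab, sex) mean(tab[[fl]][tab$sex == sex], na.rm = TRUE)
    ks_sex <- function(sex) {
      a <- tr[[ag]][tr$sex == sex & tr[[fl]]]
      b <- ts[[ag]][ts$sex == sex & ts[[fl]]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (!length(a) || !length(b)) return(NA_real_)
      ks_statistic(a, b)
    }
    pfr <- pr(tr, "female"); pmr <- pr(tr, "male")
    pfs <- pr(ts, "female"); pms <- pr(ts, "male")
    data.frame(code = cd,
               prevalence_female_real = pfr, prevalence_male_real = pmr,
               prevalence_female_synth = pfs, prevalence_male_synth = pms,
               female_male_diff_pp_real = 100 * (pfr - pmr),
               female_male_diff_pp_synth = 100 * (pfs - pms),
               ks_female = ks_sex("female"), ks_male = ks_sex("male"),
               sexspec_shift_pp = 100 * ((pfs - pfr) - (pms - pmr)))
  })
  do.call(rbind, rows)
}

#' Feature amplification across runs
#'
#' Per disease, the Pearson correlation across generative runs between the
#' disease's sex-specific prevalence shift and the run's sex bias delta.
#'
#' @param shifts matrix or data frame of sex-specific shifts, one row per run,
#'   one column per disease.
#' @param deltas numeric vector of per-run sex bias deltas (percentage points).
#' @return named numeric vector of correlations (`NA` where either series has
#'   zero variance).
#' @export
feature_amplification <- function(shifts, deltas) {
  shifts <- as.matrix(shifts)
  if (nrow(shifts) < 3) stop("feature_amplification needs >= 3 runs")
  if (nrow(shifts) != length(deltas)) stop("one delta per run required")
  apply(shifts, 2, function(s) {
    if (stats::sd(s) == 0 || stats::sd(deltas) == 0) return(NA_real_)
    stats::cor(s, deltas)
  })
}

# design matrix for the sex-prediction model: all columns except sex,
# booleans as 0/1, missing ages imputed to source medians, standardized by
# source statistics
sex_model_matrix <- function(x, stats_from = NULL) {
  s <- table_schema(x)
  cols <- setdiff(names(s), "sex")
  M <- matrix(0, nrow(x), length(cols), dimnames = list(NULL, cols))
  for (k in seq_along(cols)) {
    v <- x[[cols[k]]]
    M[, k] <- if (is.logical(v)) as.numeric(v) else as.numeric(v)
  }
  if (is.null(stats_from)) {
    med <- apply(M, 2, stats::median, na.rm = TRUE)
    med[is.na(med)] <- 0
    for (k in seq_len(ncol(M))) M[is.na(M[, k]), k] <- med[k]
    mu <- colMeans(M); sdv <- apply(M, 2, stats::sd); sdv[sdv == 0 | is.na(sdv)] <- 1
    stats_from <- list(median = med, mean = mu, sd = sdv)
  } else {
    for (k in seq_len(ncol(M))) M[is.na(M[, k]), k] <- stats_from$median[k]
  }
  M <- sweep(sweep(M, 2, stats_from$mean), 2, stats_from$sd, "/")
  list(M = M, stats = stats_from)
}

#' Sex-signal portability AUROC
#'
#' Fits an L2-regularized logistic model predicting sex on the source cohort
#' (features = every flattened column except sex, standardized by
#' source-cohort statistics, missing ages imputed to the source median) and
#' reports the AUROC on the target cohort. `direction = "real_to_synth"`
#' trains on real and tests on synthetic; `"synth_to_real"` the reverse.
#'
#' @param real,synth `ehr_cohort`s.
#' @param direction `"real_to_synth"` or `"synth_to_real"`.
#' @param seed RNG seed (glmnet coordinate descent is deterministic; the seed
#'   fixes any internal subsampling).
#' @return AUROC on the target cohort.
#' @export
sex_transfer_auroc <- function(real, synth,
                               direction = c("real_to_synth", "synth_to_real"),
                               seed = 1L) {
  direction <- match.arg(direction)
  tr <- flatten(real); ts <- flatten(synth)
  src <- if (direction == "real_to_synth") tr else ts
  tgt <- if (direction == "real_to_synth") ts else tr
  y_src <- src$sex == "female"
  y_tgt <- tgt$sex == "female"
  if (length(unique(y_src)) < 2 || length(unique(y_tgt)) < 2)
    stop("both cohorts must contain both sexes")
  em_src <- sex_model_matrix(src)
  em_tgt <- sex_model_matrix(tgt, stats_from = em_src$stats)
  set.seed(seed)
  fit <- glmnet::glmnet(em_src$M, factor(y_src), family = "binomial",
                        alpha = 0, lambda = 1 / length(y_src),
                        standardize = FALSE)
  p <- as.numeric(stats::predict(fit, em_tgt$M, type = "response"))
  auroc(p, y_tgt)
}

#' Prevalence-error curve
#'
#' Per non-anchor disease: real and synthetic prevalence and the relative
#' error `|p_synth - p_real| / p_real` (undefined when the real prevalence is
#' zero). For each threshold `t`: the Pearson correlation of real vs synthetic
#' prevalences and the relative-error RMSE over diseases with real prevalence
#' `>= t`.
#'
#' @param real,synth `ehr_cohort`s sharing a vocabulary.
#' @param thresholds prevalence thresholds (default `c(0, 0.013, 0.05)`).
#' @return list with `per_disease` data frame and `summary` data frame
#'   (threshold, n diseases, prevalence correlation, relative-error RMSE).
#' @export
prevalence_error_curve <- function(real, synth, thresholds = c(0, 0.013, 0.05)) {
  tr <- flatten(real); ts <- flatten(synth)
  codes <- setdiff(real$vocabulary, real$anchor_code)
  p_r <- vapply(codes, function(cd) mean(tr[[paste0("flag_", cd)]]), 0.0)
  p_s <- vapply(codes, function(cd) mean(ts[[paste0("flag_", cd)]]), 0.0)
  rel <- ifelse(p_r > 0, abs(p_s - p_r) / p_r, NA_real_)
  per_disease <- data.frame(code = codes, prevalence_real = p_r,
                            prevalence_synth = p_s, relative_error = rel)
  summary <- do.call(rbind, lapply(thresholds, function(t) {
    keep <- p_r >= t & !is.na(rel)
    data.frame(threshold = t, n_diseases = sum(keep),
               prevalence_correlation =
                 if (sum(keep) >= 3) stats::cor(p_r[keep], p_s[keep]) else NA_real_,
               relative_error_rmse =
                 if (any(keep)) sqrt(mean(rel[keep]^2)) else NA_real_)
  }))
  list(per_disease = per_disease, summary = summary)
}

#' Standardized effect sizes between real and synthetic tables
#'
#' Continuous columns: Cohen's d with the pooled standard deviation. Boolean
#' columns (proportions): Cohen's h, `2*asin(sqrt(p_synth)) -
#' 2*asin(sqrt(p_real))`. Zero pooled SD is flagged as `NA`.
#'
#' @param real,synth `patient_feature_table`s sharing a schema.
#' @return data frame with column, type, and effect size (synthetic minus
#'   real orientation).
#' @export
effect_sizes <- function(real, synth) {
  check_shared_schema(real, synth)
  s <- table_schema(real)
  rows <- lapply(names(s), function(cl) {
    if (s[[cl]] == "continuous") {
      a <- real[[cl]][!is.na(real[[cl]])]
      b <- synth[[cl]][!is.na(synth[[cl]])]
      if (length(a) < 2 || length(b) < 2)
        return(data.frame(column = cl, type = "d", effect = NA_real_))
      sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                   (length(a) + length(b) - 2))
      eff <- if (sp == 0) NA_real_ else (mean(b) - mean(a)) / sp
      data.frame(column = cl, type = "d", effect = eff)
    } else if (s[[cl]] == "boolean") {
      h <- 2 * asin(sqrt(mean(synth[[cl]]))) - 2 * asin(sqrt(mean(real[[cl]])))
      data.frame(column = cl, type = "h", effect = h)
    } else NULL
  })
  do.call(rbind, rows)
}

#' Full bias report
#'
#' Cohort-level sex bias delta and transfer AUROCs plus the per-disease
#' sex-stratified table, prevalence-error curve, and effect sizes.
#'
#' @param real,synth `ehr_cohort`s sharing a vocabulary.
#' @param seed RNG seed for the transfer models.
#' @return a `bias_report` list.
#' @export
bias_report <- function(real, synth, seed = 1L) {
  structure(list(
    sex_bias_delta = sex_bias_delta(real, synth),
    transfer_auroc_real_to_synth =
      sex_transfer_auroc(real, synth, "real_to_synth", seed = seed),
    transfer_auroc_synth_to_real =
      sex_transfer_auroc(real, synth, "synth_to_real", seed = seed),
    per_feature = per_feature_sex_stats(real, synth),
    prevalence_error = prevalence_error_curve(real, synth),
    effect_sizes = effect_sizes(flatten(real), flatten(synth))),
    class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("<bias_report> sex bias delta %+.2f pp\n", x$sex_bias_delta))
  cat(sprintf("  transfer AUROC real->synth %.3f, synth->real %.3f\n",
              x$transfer_auroc_real_to_synth, x$transfer_auroc_synth_to_real))
  invisible(x)
}
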