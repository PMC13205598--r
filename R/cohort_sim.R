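# Ground-truth cohort simulator.
#
# Stands in for an access-restricted population-health extract: a
# diabetes-anchored cohort with a configurable comorbidity catalog spanning a
# wide prevalence spectrum, sex-specific prevalence differences, temporally
# ordered onsets, a chronic-kidney-disease endpoint whose hazard depends on
# pre-diabetes history, and an age-dependent sex difference in diagnosis rates
# (women higher in early adulthood and late life, men higher in middle age).
# Every generative parameter is known, so each audit can be validated by
# parameter recovery. A bias injector reproduces, with known magnitude, the
# pathologies a generative model can exhibit (demographic skew, mode collapse
# on rare codes, decorrelation, delayed trajectories, missing fields).

#' Specify one comorbidity
#'
#' @param code diagnosis code (opaque string).
#' @param base_prevalence baseline assignment probability in (0, 1).
#' @param female_multiplier odds-scale multiplier applied for women.
#' @param onset_age_mean,onset_age_sd Normal onset-age parameters (years).
#' @param risk_weight contribution to the endpoint logit when the disease is
#'   present before the diabetes diagnosis.
#' @param age_profile odds multipliers over onset-age bands
#'   (young `<45`, mid `45-65`, old `>65`): either a named numeric vector
#'   `c(young=, mid=, old=)` or a list with `female` and `male` vectors.
#' @return a `disease_spec` list.
#' @export
disease_spec <- function(code, base_prevalence, female_multiplier = 1,
                         onset_age_mean = 55, onset_age_sd = 10,
                         risk_weight = 0,
                         age_profile = c(young = 1, mid = 1, old = 1)) {
  stopifnot(base_prevalence > 0, base_prevalence < 1, onset_age_sd > 0,
            female_multiplier > 0)
  if (!is.list(age_profile))
    age_profile <- list(female = age_profile, male = age_profile)
  structure(list(code = code, base_prevalence = base_prevalence,
                 female_multiplier = female_multiplier,
                 onset_age_mean = onset_age_mean, onset_age_sd = onset_age_sd,
                 risk_weight = risk_weight, age_profile = age_profile),
            class = "disease_spec")
}

#' Default comorbidity catalog
#'
#' A deterministic catalog of `n` diseases with prevalences geometrically
#' spaced from 0.35 down to 5e-4, onset-age means cycling over early / middle
#' / late adulthood, mild sex multipliers, and a shared sex-specific age
#' profile producing higher female diagnosis rates before 45 and after 65 and
#' higher male rates in between. A handful of middle-age, high-prevalence
#' diseases carry positive endpoint risk weights.
#'
#' @param n number of diseases (default 80).
#' @return list of [disease_spec()]s.
#' @export
default_diseases <- function(n = 80) {
  prev <- 0.35 * (5e-4 / 0.35)^((seq_len(n) - 1) / (n - 1))
  onset_mean <- rep(c(32, 55, 74), length.out = n)
  fm <- rep(c(1.25, 0.85, 1.1, 0.9, 1.0), length.out = n)
  profile <- list(female = c(young = 1.25, mid = 0.80, old = 1.30),
                  male   = c(young = 0.85, mid = 1.25, old = 0.90))
  rw <- numeric(n)
  rw[onset_mean == 55 & prev > 0.02] <- 0.7       # common mid-life risk factors
  lapply(seq_len(n), function(i)
    disease_spec(code = sprintf("D%02d", i), base_prevalence = prev[i],
                 female_multiplier = fm[i], onset_age_mean = onset_mean[i],
                 onset_age_sd = 9, risk_weight = rw[i], age_profile = profile))
}

#' Simulation configuration
#'
#' Defaults encode the study conditions: adult diabetes diagnosis age
#' Normal(60.56, 13.83) truncated at 18, an 80-comorbidity catalog, a logistic
#' chronic-kidney-disease endpoint driven by diagnosis age and pre-diabetes
#' history, and diagnosis years spanning 2003-2022.
#'
#' @param n_patients cohort size (desk-scale default 2000).
#' @param female_fraction probability a patient is female.
#' @param dm_age_mean,dm_age_sd,dm_age_floor truncated-Normal parameters for
#'   age at diabetes diagnosis (years).
#' @param diseases list of [disease_spec()]s.
#' @param endpoint_intercept,endpoint_age_coef logistic endpoint model:
#'   `logit P(CKD) = intercept + age_coef * dm_age + sum(risk_weight * flag)`
#'   over diseases present before the diabetes age.
#' @param year_range integer `c(min, max)` calendar years for diagnosis_year.
#' @param anchor_code,endpoint_code code names for the anchor and endpoint.
#' @param seed integer RNG seed; simulation is deterministic given the seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 2000, female_fraction = 0.5,
                       dm_age_mean = 60.56, dm_age_sd = 13.83,
                       dm_age_floor = 18, diseases = default_diseases(),
                       endpoint_intercept = -4, endpoint_age_coef = 0.03,
                       year_range = c(2003L, 2022L),
                       anchor_code = "DM", endpoint_code = "CKD", seed = 1L) {
  stopifnot(n_patients >= 1, female_fraction > 0, female_fraction < 1,
            dm_age_sd > 0, length(year_range) == 2)
  structure(as.list(environment()), class = "sim_config")
}

age_band <- function(age) {
  b <- ifelse(age < 45, "young", ifelse(age <= 65, "mid", "old"))
  factor(b, levels = c("young", "mid", "old"))
}

# vectorized per-patient draws shared by simulate_cohort and the Monte-Carlo
# Bayes oracle: returns sex, dm_age, onset matrix, flag matrix, endpoint prob
sim_draw <- function(cfg, n) {
  female <- stats::runif(n) < cfg$female_fraction
  lo <- stats::pnorm((cfg$dm_age_floor - cfg$dm_age_mean) / cfg$dm_age_sd)
  dm_age <- cfg$dm_age_mean +
    cfg$dm_age_sd * stats::qnorm(lo + stats::runif(n) * (1 - lo))
  d <- length(cfg$diseases)
  onset <- matrix(NA_real_, n, d)
  flag <- matrix(FALSE, n, d)
  eta <- cfg$endpoint_intercept + cfg$endpoint_age_coef * dm_age
  for (j in seq_len(d)) {
    ds <- cfg$diseases[[j]]
    a <- pmin(100, pmax(0, stats::rnorm(n, ds$onset_age_mean, ds$onset_age_sd)))
    band <- as.integer(age_band(a))
    prof <- ifelse(female, ds$age_profile$female[band], ds$age_profile$male[band])
    lg <- stats::qlogis(ds$base_prevalence) +
      log(ds$female_multiplier) * female + log(prof)
    f <- stats::runif(n) < stats::plogis(lg)
    onset[f, j] <- a[f]
    flag[, j] <- f
    if (ds$risk_weight != 0)
      eta <- eta + ds$risk_weight * (f & !is.na(a) & a <= dm_age)
  }
  p_end <- stats::plogis(eta)
  list(female = female, dm_age = dm_age, onset = onset, flag = flag,
       p_end = p_end)
}

#' Simulate a diabetes-anchored cohort
#'
#' Per patient: sex ~ Bernoulli(female_fraction); diabetes age from the
#' truncated Normal; each disease assigned with probability
#' `plogis(qlogis(base_prevalence) + log(female_multiplier) * I(female) +
#' log(age_profile[band(onset age)]))`, onset age Normal clipped to
#' `[0, 100]`; the endpoint with the logistic model of [sim_config()], onset
#' uniformly 0.5-15 years after the diabetes age; visits are onsets grouped by
#' identical rounded (1 decimal) age, sorted ascending; `diagnosis_year`
#' uniform over `year_range`. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an `ehr_cohort`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  dr <- sim_draw(config, n)
  has_end <- stats::runif(n) < dr$p_end
  end_age <- dr$dm_age + stats::runif(n, 0.5, 15)
  years <- sample(seq(config$year_range[1], config$year_range[2]), n,
                  replace = TRUE)
  codes <- vapply(config$diseases, `[[`, "", "code")
  vocab <- c(config$anchor_code, codes, config$endpoint_code)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    f <- dr$flag[i, ]
    ev_codes <- c(config$anchor_code, codes[f],
                  if (has_end[i]) config$endpoint_code)
    ev_ages <- round(c(dr$dm_age[i], dr$onset[i, f][seq_len(sum(f))],
                       if (has_end[i]) end_age[i]), 1)
    o <- order(ev_ages)
    ev_ages <- ev_ages[o]; ev_codes <- ev_codes[o]
    ua <- unique(ev_ages)
    visits <- lapply(ua, function(a) visit(a, ev_codes[ev_ages == a]))
    records[[i]] <- patient_record(
      id = sprintf("p%06d", i),
      sex = if (dr$female[i]) "female" else "male",
      visits = visits, diagnosis_year = years[i])
  }
  cohort(records, vocabulary = vocab, anchor_code = config$anchor_code,
         endpoint_code = config$endpoint_code)
}

#' True marginals implied by a simulation configuration
#'
#' Pure function of the configuration; used by parameter-recovery tests.
#' Disease prevalences by sex are exact (the onset-age band probabilities are
#' Normal tail probabilities, so the assignment probability integrates in
#' closed form over the three bands). The Bayes-optimal endpoint AUROC is
#' estimated by Monte Carlo from the generative model when `mc_n > 0`: labels
#' are drawn from the true per-patient endpoint probability and that
#' probability itself is used as the score.
#'
#' @param config a [sim_config()].
#' @param mc_n Monte-Carlo draws for the Bayes AUROC (0 to skip).
#' @param mc_seed seed for the Monte-Carlo draw.
#' @return list with `female_fraction`, a per-disease `prevalence` data frame
#'   (overall and by sex, sex gap in percentage points), the endpoint model,
#'   and `bayes_auroc` (NA when skipped).
#' @export
ground_truth <- function(config, mc_n = 0, mc_seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  rows <- lapply(config$diseases, function(ds) {
    z <- c(45, 65)
    pb <- stats::pnorm((z - ds$onset_age_mean) / ds$onset_age_sd)
    band_p <- c(pb[1], pb[2] - pb[1], 1 - pb[2])
    prev_sex <- vapply(c("female", "male"), function(s) {
      lg <- stats::qlogis(ds$base_prevalence) +
        log(ds$female_multiplier) * (s == "female") +
        log(ds$age_profile[[s]])
      sum(band_p * stats::plogis(lg))
    }, 0.0)
    data.frame(code = ds$code,
               prevalence_female = prev_sex[["female"]],
               prevalence_male = prev_sex[["male"]],
               prevalence = config$female_fraction * prev_sex[["female"]] +
                 (1 - config$female_fraction) * prev_sex[["male"]],
               sex_gap_pp = 100 * (prev_sex[["female"]] - prev_sex[["male"]]),
               risk_weight = ds$risk_weight)
  })
  prevalence <- do.call(rbind, rows)
  bayes <- NA_real_
  if (mc_n > 0) {
    set.seed(mc_seed)
    dr <- sim_draw(config, mc_n)
    y <- stats::runif(mc_n) < dr$p_end
    bayes <- auroc(dr$p_end, y)
  }
  list(female_fraction = config$female_fraction, prevalence = prevalence,
       endpoint_intercept = config$endpoint_intercept,
       endpoint_age_coef = config$endpoint_age_coef,
       bayes_auroc = bayes)
}

# ---- bias injector -----------------------------------------------------------

#' Bias-injection configuration
#'
#' Emulates documented generative failure modes with known magnitude so the
#' audits can be validated by recovery: demographic over-representation of
#' women, mode collapse on rare codes, destroyed pairwise correlation, delayed
#' trajectories for one sex, and missing sex / anchor fields.
#'
#' @param female_shift_pp percentage points added to the female share
#'   (achieved by relabelling randomly chosen male records as female).
#' @param rare_dropout probability of deleting each occurrence of a rare code.
#' @param rare_threshold codes with empirical prevalence below this are rare.
#' @param corr_flip_pairs list of `c(a, b)` code pairs; the second code's
#'   occurrences are reassigned to uniformly random patients, destroying its
#'   co-assignment with the first.
#' @param trajectory_delay_years years added to every non-anchor onset age for
#'   `delay_sex` patients.
#' @param delay_sex `"female"` or `"male"`.
#' @param sex_missing_rate probability of blanking a record's sex.
#' @param anchor_missing_rate probability of deleting a record's anchor code.
#' @return a `bias_config` list.
#' @export
bias_config <- function(female_shift_pp = 0, rare_dropout = 0,
                        rare_threshold = 0, corr_flip_pairs = list(),
                        trajectory_delay_years = 0, delay_sex = "female",
                        sex_missing_rate = 0, anchor_missing_rate = 0) {
  probs <- c(rare_dropout, rare_threshold, sex_missing_rate, anchor_missing_rate)
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(as.list(environment())[c("female_shift_pp", "rare_dropout",
                                     "rare_threshold", "corr_flip_pairs",
                                     "trajectory_delay_years", "delay_sex",
                                     "sex_missing_rate", "anchor_missing_rate")],
            class = "bias_config")
}

# rebuild a record's visits from (age, code) events: round to 1 decimal,
# group identical ages, sort ascending
rebuild_record <- function(rec, ages, codes) {
  keep <- !is.na(ages)
  ages <- round(ages[keep], 1); codes <- codes[keep]
  if (!length(ages)) { rec$visits <- list(); return(rec) }
  o <- order(ages); ages <- ages[o]; codes <- codes[o]
  ua <- unique(ages)
  rec$visits <- lapply(ua, function(a) visit(a, codes[ages == a]))
  rec
}

record_events <- function(rec) {
  k <- lengths(lapply(rec$visits, `[[`, "codes"))
  list(ages = rep(vapply(rec$visits, `[[`, 0.0, "age"), k),
       codes = unlist(lapply(rec$visits, `[[`, "codes"), use.names = FALSE))
}

#' Inject known bias into a cohort
#'
#' Applies the pathologies configured in [bias_config()] to a copy of the
#' cohort. With an all-zero configuration the input is returned unchanged.
#'
#' @param x an `ehr_cohort`.
#' @param bias a [bias_config()].
#' @param seed integer seed.
#' @return a modified `ehr_cohort`.
#' @export
inject_bias <- function(x, bias, seed = 1L) {
  stopifnot(inherits(x, "ehr_cohort"), inherits(bias, "bias_config"))
  idle <- bias$female_shift_pp == 0 && bias$rare_dropout == 0 &&
    length(bias$corr_flip_pairs) == 0 && bias$trajectory_delay_years == 0 &&
    bias$sex_missing_rate == 0 && bias$anchor_missing_rate == 0
  if (idle) return(x)
  set.seed(seed)
  recs <- x$records
  n <- length(recs)
  sexes <- vapply(recs, `[[`, "", "sex")

  if (bias$female_shift_pp != 0) {
    share <- mean(sexes == "female", na.rm = TRUE) + bias$female_shift_pp / 100
    if (share <= 0 || share >= 1)
      stop("female_shift_pp pushes the female share out of (0,1)")
    k <- round(abs(bias$female_shift_pp) / 100 * n)
    from <- if (bias$female_shift_pp > 0) "male" else "female"
    to <- setdiff(c("female", "male"), from)
    pool <- which(sexes == from)
    if (length(pool) < k) stop("not enough ", from, " records to relabel")
    flip <- sample(pool, k)
    for (i in flip) recs[[i]]$sex <- to
    sexes[flip] <- to
  }

  if (bias$rare_dropout > 0 || length(bias$corr_flip_pairs) ||
      bias$trajectory_delay_years != 0 || bias$anchor_missing_rate > 0) {
    ev <- lapply(recs, record_events)

    if (bias$rare_dropout > 0) {
      counts <- table(factor(unlist(lapply(ev, `[[`, "codes"), use.names = FALSE),
                             levels = x$vocabulary))
      rare <- setdiff(names(counts)[counts / n < bias$rare_threshold],
                      c(x$anchor_code))
      for (i in seq_len(n)) {
        hit <- ev[[i]]$codes %in% rare &
          stats::runif(length(ev[[i]]$codes)) < bias$rare_dropout
        ev[[i]]$ages <- ev[[i]]$ages[!hit]; ev[[i]]$codes <- ev[[i]]$codes[!hit]
      }
    }

    for (pair in bias$corr_flip_pairs) {
      b <- pair[2]
      carriers <- list()
      for (i in seq_len(n)) {
        j <- which(ev[[i]]$codes == b)
        if (length(j)) {
          carriers[[length(carriers) + 1L]] <- ev[[i]]$ages[j[1]]
          ev[[i]]$ages <- ev[[i]]$ages[-j]; ev[[i]]$codes <- ev[[i]]$codes[-j]
        }
      }
      if (length(carriers)) {
        targets <- sample(n, length(carriers), replace = FALSE)
        for (t in seq_along(targets)) {
          i <- targets[t]
          ev[[i]]$ages <- c(ev[[i]]$ages, carriers[[t]])
          ev[[i]]$codes <- c(ev[[i]]$codes, b)
        }
      }
    }

    if (bias$trajectory_delay_years != 0) {
      for (i in which(sexes == bias$delay_sex)) {
        shift <- ev[[i]]$codes != x$anchor_code
        ev[[i]]$ages[shift] <- pmax(0, ev[[i]]$ages[shift] +
                                      bias$trajectory_delay_years)
      }
    }

    if (bias$anchor_missing_rate > 0) {
      blank <- stats::runif(n) < bias$anchor_missing_rate
      for (i in which(blank)) {
        keep <- ev[[i]]$codes != x$anchor_code
        ev[[i]]$ages <- ev[[i]]$ages[keep]; ev[[i]]$codes <- ev[[i]]$codes[keep]
      }
    }

    for (i in seq_len(n)) recs[[i]] <- rebuild_record(recs[[i]], ev[[i]]$ages,
                                                      ev[[i]]$codes)
  }

  if (bias$sex_missing_rate > 0) {
    blank <- stats::runif(n) < bias$sex_missing_rate
    for (i in which(blank)) recs[[i]]$sex <- NA_character_
  }

  cohort(recs, vocabulary = x$vocabulary, anchor_code = x$anchor_code,
         endpoint_code = x$endpoint_code)
}

# ---- YAML config serialization -------------------------------------------------

#' Read and write simulation / bias configurations as YAML
#'
#' [sim_config()] and [bias_config()] objects round-trip through plain YAML so
#' that generative conditions can be version-controlled next to results.
#'
#' @param x a `sim_config` or `bias_config`.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   reconstructed configuration object.
#' @export
write_config <- function(x, path) {
  stopifnot(inherits(x, c("sim_config", "bias_config")))
  obj <- unclass(x)
  obj$.type <- class(x)[1]
  if (!is.null(obj$diseases))
    obj$diseases <- lapply(obj$diseases, unclass)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  type <- obj$.type
  obj$.type <- NULL
  if (type == "sim_config") {
    obj$diseases <- lapply(obj$diseases, function(d) {
      d$age_profile <- lapply(d$age_profile, unlist)
      do.call(disease_spec, d)
    })
    obj$year_range <- as.integer(unlist(obj$year_range))
    do.call(sim_config, obj)
  } else {
    obj$corr_flip_pairs <- lapply(obj$corr_flip_pairs, unlist)
    do.call(bias_config, obj)
  }
}
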