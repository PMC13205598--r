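test_that("sex bias delta is the female-share difference in percentage points", {
  co <- small_sim(100, seed = 1)
  expect_equal(sex_bias_delta(co, co), 0)
  mk <- function(n_f, n_m) {
    recs <- c(lapply(seq_len(n_f), function(i)
      patient_record(paste0("f", i), "female", list(visit(50, "DM")))),
      lapply(seq_len(n_m), function(i)
        patient_record(paste0("m", i), "male", list(visit(50, "DM")))))
    cohort(recs, c("DM", "CKD"))
  }
  expect_equal(sex_bias_delta(mk(50, 50), mk(53, 47)), 3)
})

test_that("injected female shift is recovered within the binomial band", {
  co <- simulate_cohort(sim_config(n_patients = 20000,
                                   diseases = default_diseases(8), seed = 31))
  shifted <- inject_bias(co, bias_config(female_shift_pp = 3), seed = 5)
  d <- sex_bias_delta(co, shifted)
  expect_lt(abs(d - 3), 0.7)
})

test_that("per-feature sex table computes shifts and per-sex KS", {
  co <- small_sim(400, n_diseases = 6, seed = 32)
  tab <- per_feature_sex_stats(co, co)
  expect_true(all(tab$sexspec_shift_pp == 0))
  expect_true(all(tab$ks_female[!is.na(tab$ks_female)] == 0))
  # worked example: 0.10/0.10 real, 0.12 women / 0.10 men synthetic -> +2 pp
  mk <- function(pf, pm, seed) {
    set.seed(seed)
    recs <- lapply(1:2000, function(i) {
      sex <- if (i <= 1000) "female" else "male"
      has <- stats::runif(1) < (if (sex == "female") pf else pm)
      vs <- list(visit(50, "DM"))
      if (has) vs <- c(vs, list(visit(55, "X")))
      patient_record(paste0("p", i), sex, vs)
    })
    cohort(recs, c("DM", "X", "CKD"))
  }
  # deterministic construction instead of sampling noise: use exact counts
  mk2 <- function(kf, km) {
    recs <- lapply(1:2000, function(i) {
      sex <- if (i <= 1000) "female" else "male"
      j <- if (sex == "female") i else i - 1000
      has <- j <= (if (sex == "female") kf else km)
      vs <- list(visit(50, "DM"))
      if (has) vs <- c(vs, list(visit(55, "X")))
      patient_record(paste0("p", i), sex, vs)
    })
    cohort(recs, c("DM", "X", "CKD"))
  }
  tab2 <- per_feature_sex_stats(mk2(100, 100), mk2(120, 100))
  x_row <- tab2[tab2$code == "X", ]
  expect_equal(x_row$sexspec_shift_pp, 2)
  expect_equal(x_row$female_male_diff_pp_synth, 2)
})

test_that("feature amplification correlates shifts with deltas across runs", {
  deltas <- c(1, 2, 3, 4, 5)
  shifts <- cbind(prop = 2 * deltas, anti = -deltas,
                  noise = c(0.3, -0.1, 0.2, -0.4, 0.1))
  r <- feature_amplification(shifts, deltas)
  expect_equal(unname(r["prop"]), 1)
  expect_equal(unname(r["anti"]), -1)
  expect_lt(abs(r["noise"]), 1)
  flat <- cbind(const = rep(1, 5))
  expect_true(is.na(feature_amplification(flat, deltas)))
  expect_error(feature_amplification(shifts[1:2, ], deltas[1:2]), ">= 3")
})

test_that("sex transfer AUROC finds separable signals and stays null otherwise", {
  # one perfectly sex-determined feature in both cohorts
  mk <- function(seed) {
    set.seed(seed)
    recs <- lapply(1:300, function(i) {
      sex <- sample(c("female", "male"), 1)
      vs <- list(visit(50, "DM"))
      if (sex == "female") vs <- c(vs, list(visit(55, "FX")))
      patient_record(paste0("p", i), sex, vs)
    })
    cohort(recs, c("DM", "FX", "CKD"))
  }
  expect_gt(sex_transfer_auroc(mk(1), mk(2), "real_to_synth"), 0.99)
  # sex independent of all features -> null AUROC
  aucs <- vapply(1:4, function(k) {
    dis <- lapply(default_diseases(5), function(d) { d$female_multiplier <- 1
      d$age_profile <- list(female = c(young = 1, mid = 1, old = 1),
                            male = c(young = 1, mid = 1, old = 1)); d })
    a <- simulate_cohort(sim_config(n_patients = 400, diseases = dis,
                                    seed = 60 + k))
    b <- simulate_cohort(sim_config(n_patients = 400, diseases = dis,
                                    seed = 80 + k))
    sex_transfer_auroc(a, b, "real_to_synth", seed = k)
  }, 0.0)
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
  # symmetric directions coincide on identical cohorts
  co <- small_sim(200, seed = 33)
  expect_equal(sex_transfer_auroc(co, co, "real_to_synth"),
               sex_transfer_auroc(co, co, "synth_to_real"))
})

test_that("prevalence error curve reacts to rare-code dropout as designed", {
  co <- simulate_cohort(sim_config(n_patients = 5000,
                                   diseases = default_diseases(20), seed = 34))
  pec_id <- prevalence_error_curve(co, co)
  expect_true(all(pec_id$per_disease$relative_error[
    !is.na(pec_id$per_disease$relative_error)] == 0))
  expect_true(all(pec_id$summary$prevalence_correlation == 1))
  # worked example: p_r = .1, p_s = .12 -> relative error 0.2
  expect_equal(abs(0.12 - 0.1) / 0.1, 0.2)
  dropped <- inject_bias(co, bias_config(rare_dropout = 0.8,
                                         rare_threshold = 0.05), seed = 6)
  pec <- prevalence_error_curve(co, dropped)$summary
  rmse0 <- pec$relative_error_rmse[pec$threshold == 0]
  rmse5 <- pec$relative_error_rmse[pec$threshold == 0.05]
  expect_gt(rmse0, rmse5)
  corr <- pec$prevalence_correlation
  expect_true(all(diff(corr) >= -1e-9))   # non-decreasing in the threshold
})

test_that("effect sizes follow the Cohen d/h conventions", {
  mk <- function(x, f) {
    d <- data.frame(x = x, f = f)
    attr(d, "schema") <- c(x = "continuous", f = "boolean")
    class(d) <- c("patient_feature_table", "data.frame")
    d
  }
  set.seed(35)
  a <- mk(stats::rnorm(4000, 0, 1), stats::runif(4000) < 0.5)
  b <- mk(stats::rnorm(4000, 1, 1), stats::runif(4000) < 0.5)
  es <- effect_sizes(a, b)
  expect_equal(es$effect[es$column == "x"], 1, tolerance = 0.08)
  expect_equal(effect_sizes(a, a)$effect, c(0, 0))
  # h for known proportions
  a2 <- mk(1:10, rep(c(TRUE, FALSE), 5))
  b2 <- mk(1:10, rep(TRUE, 10))
  expect_equal(es2 <- effect_sizes(a2, b2)$effect[2],
               2 * asin(1) - 2 * asin(sqrt(0.5)))
})

test_that("per-disease outputs are invariant to record order", {
  co <- small_sim(150, seed = 36)
  synth <- small_sim(150, seed = 37)
  perm <- cohort(synth$records[sample(150)], synth$vocabulary,
                 synth$anchor_code, synth$endpoint_code)
  expect_equal(per_feature_sex_stats(co, synth), per_feature_sex_stats(co, perm))
  expect_equal(prevalence_error_curve(co, synth)$summary,
               prevalence_error_curve(co, perm)$summary)
})
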