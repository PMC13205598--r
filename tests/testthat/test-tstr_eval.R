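test_that("build_task restricts features to the pre-anchor history", {
  co <- cohort(list(
    patient_record("a", "female", list(visit(55, "HTN"), visit(60, "DM"),
                                       visit(70, "CKD")), 2010L),
    patient_record("b", "male", list(visit(60, "DM"), visit(65, "HTN")),
                   2012L)),
    c("DM", "HTN", "CKD"))
  task <- build_task(co)
  # HTN at 55 before anchor at 60 -> flag 1, age 55; label 1 (CKD at 70)
  expect_equal(unname(task$X[1, "flag_HTN"]), 1)
  expect_equal(unname(task$X[1, "age_HTN"]), 55)
  expect_true(task$y[1])
  # HTN at 65 after anchor -> excluded entirely (flag 0, sentinel age)
  expect_equal(unname(task$X[2, "flag_HTN"]), 0)
  expect_equal(unname(task$X[2, "age_HTN"]), -1)
  expect_false(task$y[2])
  # the endpoint code contributes no feature column
  expect_false(any(grepl("CKD", colnames(task$X))))
})

test_that("no feature changes when post-anchor visits are deleted (leakage oracle)", {
  co <- refine_for_prediction(small_sim(150, seed = 51))$cohort
  task <- build_task(co)
  cut_recs <- lapply(co$records, function(rec) {
    a_anchor <- synthehr:::first_code_age(rec, co$anchor_code)
    rec$visits <- Filter(function(v) v$age <= a_anchor, rec$visits)
    rec
  })
  task2 <- build_task(cohort(cut_recs, co$vocabulary, co$anchor_code,
                             co$endpoint_code))
  expect_equal(task$X, task2$X)
})

test_that("the cyclic-boosted additive classifier learns and ranks signal", {
  set.seed(52)
  n <- 2000
  X <- cbind(signal = stats::rnorm(n), noise1 = stats::rnorm(n),
             noise2 = stats::rnorm(n))
  y <- stats::runif(n) < stats::plogis(2 * X[, "signal"])
  clf <- cyclic_boost_classifier()
  m <- clf$fit(X, y)
  p <- clf$predict_prob(m, X)
  expect_gt(auroc(p, y), 0.8)
  imp <- clf$importance(m)
  expect_equal(names(which.max(imp)), "signal")
  # probability output is calibrated to [0, 1]
  expect_true(all(p >= 0 & p <= 1))
})

test_that("TSTR scenarios behave on separable, null, and identical pools", {
  co <- refine_for_prediction(small_sim(600, seed = 53))$cohort
  sp <- split_cohort(co, 0.7, seed = 1)
  tr <- build_task(sp$train)
  te <- build_task(sp$test)
  cv <- list(repeats = 2, folds = 3)
  # separable task: label available as a feature
  tr_sep <- tr; tr_sep$X <- cbind(tr$X, leak = as.numeric(tr$y))
  te_sep <- te; te_sep$X <- cbind(te$X, leak = as.numeric(te$y))
  fit_sep <- run_tstr(tr_sep, NULL, te_sep, "real", cv = cv, seed = 2)
  expect_gt(fit_sep$auroc_mean, 0.99)
  # shuffled labels: null AUROC
  tr_null <- tr
  set.seed(3); tr_null$y <- sample(tr_null$y)
  fit_null <- run_tstr(tr_null, NULL, te, "real", cv = cv, seed = 2)
  expect_lt(abs(fit_null$auroc_mean - 0.5), 0.1)
  # synthetic scenario with synth = copy of real matches the real scenario
  fit_real <- run_tstr(tr, NULL, te, "real", cv = cv, seed = 2)
  fit_synth <- run_tstr(tr, tr, te, "synthetic", cv = cv, seed = 2)
  expect_lt(abs(fit_synth$auroc_mean - fit_real$auroc_mean),
            3 * stats::sd(c(fit_real$auroc_cv, fit_synth$auroc_cv)))
  # hybrid pool is the plain concatenation
  fit_hyb <- run_tstr(tr, tr, te, "hybrid", cv = cv, seed = 2)
  expect_true(is.finite(fit_hyb$auroc_mean))
  expect_error(run_tstr(tr, NULL, te, "hybrid"), "synthetic training task")
})

test_that("stratified AUROC handles single and degenerate strata", {
  co <- refine_for_prediction(small_sim(500, seed = 54))$cohort
  sp <- split_cohort(co, 0.7, seed = 2)
  tr <- build_task(sp$train); te <- build_task(sp$test)
  fit <- run_tstr(tr, NULL, te, "real", cv = list(repeats = 1, folds = 3),
                  seed = 4)
  by_sex <- auroc_by_group(fit, "sex")
  expect_setequal(by_sex$stratum, c("female", "male"))
  expect_true(all(by_sex$n > 0))
  by_year <- auroc_by_group(fit, "diagnosis_year")
  expect_equal(sum(by_year$n), length(te$y))
  # single-year test set collapses to the overall AUROC
  te1 <- te; te1$diagnosis_year <- rep(2010L, length(te$y))
  fit1 <- run_tstr(tr, NULL, te1, "real", cv = list(repeats = 1, folds = 2),
                   seed = 4)
  tab1 <- auroc_by_group(fit1, "diagnosis_year")
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$auroc_mean, mean(fit1$auroc_cv))
})

test_that("hyperbolic weighted tau matches exhaustive enumeration on 4 items", {
  items <- c("a", "b", "c", "d")
  expect_equal(hyperbolic_weighted_tau(items, items), 1)
  expect_equal(hyperbolic_weighted_tau(items, rev(items)), -1)
  # enumerate all 24 permutations without extra packages
  perm4 <- do.call(rbind, lapply(1:4, function(i)
    do.call(rbind, lapply(setdiff(1:4, i), function(j)
      do.call(rbind, lapply(setdiff(1:4, c(i, j)), function(k)
        c(i, j, k, setdiff(1:4, c(i, j, k)))))))))
  for (r in seq_len(nrow(perm4))) {
    other <- items[perm4[r, ]]
    expect_equal(hyperbolic_weighted_tau(items, other),
                 unname(oracle_hwt(items, other)))
  }
  expect_error(hyperbolic_weighted_tau(items, c("a", "b", "c", "x")),
               "same feature set")
})

test_that("equal weights reduce the weighted tau to the unweighted Kendall tau", {
  set.seed(55)
  items <- letters[1:8]
  for (i in 1:10) {
    other <- sample(items)
    got <- hyperbolic_weighted_tau(items, other, weights = "equal")
    want <- stats::cor(seq_along(items), match(items, other),
                       method = "kendall")
    expect_equal(got, want)
  }
})

test_that("prediction distribution stability summarizes CV-vs-full differences", {
  co <- refine_for_prediction(small_sim(400, seed = 56))$cohort
  sp <- split_cohort(co, 0.7, seed = 3)
  fit <- run_tstr(build_task(sp$train), NULL, build_task(sp$test), "real",
                  cv = list(repeats = 1, folds = 3), seed = 5)
  pds <- prediction_distribution_stability(fit)
  expect_length(pds$quantiles, 5)
  expect_true(all(diff(pds$quantiles) >= 0))
  expect_equal(dim(pds$differences), dim(fit$cv_predictions))
  # identical cv and full models give all-zero differences
  fit0 <- fit
  fit0$cv_predictions <- matrix(fit$full_predictions,
                                nrow = length(fit$full_predictions), ncol = 3)
  expect_true(all(prediction_distribution_stability(fit0)$quantiles == 0))
  # rank stability: within-scenario taus are defined and bounded
  taus <- rank_stability(fit, max_pairs = 3)
  expect_true(all(taus >= -1 & taus <= 1))
})
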