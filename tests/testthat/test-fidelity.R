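perm_copy <- function(ft, seed = 1) {
  set.seed(seed)
  out <- ft[sample(nrow(ft)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "schema") <- attr(ft, "schema")
  class(out) <- class(ft)
  out
}

test_that("boundary adherence counts out-of-range and missing values per rule", {
  r <- random_table(40, seed = 1)
  expect_equal(boundary_adherence(r, perm_copy(r))$score, 1)
  # single-column table: 1 of 4 values out of range -> 0.75
  mk <- function(v) {
    d <- data.frame(x = v)
    attr(d, "schema") <- c(x = "continuous")
    class(d) <- c("patient_feature_table", "data.frame")
    d
  }
  expect_equal(boundary_adherence(mk(c(0, 1, 2, 3)),
                                  mk(c(0.5, 1, 2, 99)))$score, 0.75)
  # synthetic missing where real has none is invalid
  expect_equal(boundary_adherence(mk(c(0, 1, 2, 3)),
                                  mk(c(0.5, 1, 2, NA)))$score, 0.75)
  # ... but valid when the real column has missing values
  expect_equal(boundary_adherence(mk(c(0, 1, 2, NA)),
                                  mk(c(0.5, 1, 2, NA)))$score, 1)
})

test_that("category adherence flags invented categories", {
  r <- random_table(40, seed = 2)
  expect_equal(category_adherence(r, perm_copy(r))$score, 1)
  s <- r
  s$sex[seq_len(20)] <- "unknown"
  # sex broken in half the rows, flag column untouched -> mean(0.5, 1)
  expect_equal(category_adherence(r, s)$score, 0.75)
})

test_that("KS complement matches the brute-force ECDF oracle", {
  mk <- function(v) {
    d <- data.frame(x = v)
    attr(d, "schema") <- c(x = "continuous")
    class(d) <- c("patient_feature_table", "data.frame")
    d
  }
  expect_equal(ks_complement(mk(c(1, 2, 3, 4)), mk(c(1, 2, 3, 10)))$score, 0.75)
  expect_equal(ks_complement(mk(c(0, 0, 0)), mk(c(1, 1, 1)))$score, 0)
  set.seed(31)
  for (i in 1:100) {
    a <- round(stats::rnorm(sample(5:50, 1)), 2)
    b <- round(stats::rnorm(sample(5:50, 1), sample(0:2, 1)), 2)
    expect_equal(1 - synthehr:::ks_statistic(a, b), 1 - oracle_ks(a, b))
  }
})

test_that("TV complement matches the half-sum oracle", {
  mk <- function(v) {
    d <- data.frame(x = v, stringsAsFactors = FALSE)
    attr(d, "schema") <- c(x = "categorical")
    class(d) <- c("patient_feature_table", "data.frame")
    d
  }
  # {A:.6,B:.4} vs {A:.4,B:.6} -> 1 - 0.2
  expect_equal(tv_complement(mk(rep(c("A", "B"), c(6, 4))),
                             mk(rep(c("A", "B"), c(4, 6))))$score, 0.8)
  expect_equal(tv_complement(mk(rep("A", 5)), mk(rep("B", 5)))$score, 0)
  set.seed(32)
  for (i in 1:100) {
    a <- sample(letters[1:4], 50, replace = TRUE)
    b <- sample(letters[2:6], 50, replace = TRUE)
    expect_equal(tv_complement(mk(a), mk(b))$score, 1 - oracle_tvd(a, b))
  }
})

test_that("correlation similarity follows 1 - |dr|/2 with degenerate pairs skipped", {
  mk2 <- function(x, y) {
    d <- data.frame(x = x, y = y)
    attr(d, "schema") <- c(x = "continuous", y = "continuous")
    class(d) <- c("patient_feature_table", "data.frame")
    d
  }
  r <- mk2(1:10, 1:10)                    # r = +1
  s <- mk2(1:10, 10:1)                    # r = -1
  expect_equal(correlation_similarity(r, s)$score, 0)
  # r_real = 0.5, r_synth = 0.1 -> 0.8 (construct via known bivariate samples)
  set.seed(33)
  n <- 5000
  xr <- stats::rnorm(n); yr <- 0.5 * xr + sqrt(1 - 0.25) * stats::rnorm(n)
  xs <- stats::rnorm(n); ys <- 0.1 * xs + sqrt(1 - 0.01) * stats::rnorm(n)
  got <- correlation_similarity(mk2(xr, yr), mk2(xs, ys))$score
  expect_equal(got, 1 - abs(stats::cor(xr, yr) - stats::cor(xs, ys)) / 2)
  expect_equal(got, 0.8, tolerance = 0.05)
  # zero-variance pair flagged
  z <- mk2(rep(1, 10), 1:10)
  expect_true(nrow(correlation_similarity(z, z)$skipped) == 1)
})

test_that("contingency similarity matches a brute-force Cramer's V oracle", {
  set.seed(34)
  for (i in 1:100) {
    a <- sample(letters[1:3], 50, replace = TRUE)
    b <- if (i %% 2) a else sample(letters[1:3], 50, replace = TRUE)
    expect_equal(synthehr:::cramers_v(a, b), oracle_cramers_v(a, b),
                 tolerance = 1e-12)
  }
  mk2 <- function(x, y) {
    d <- data.frame(x = x, y = y, stringsAsFactors = FALSE)
    attr(d, "schema") <- c(x = "categorical", y = "categorical")
    class(d) <- c("patient_feature_table", "data.frame")
    d
  }
  # perfectly associated real vs independent synthetic -> ~ 0
  r <- mk2(rep(c("a", "b"), 50), rep(c("x", "y"), 50))
  set.seed(35)
  s <- mk2(sample(c("a", "b"), 100, TRUE), sample(c("x", "y"), 100, TRUE))
  expect_lt(contingency_similarity(r, s)$score, 0.2)
  # both degenerate on one column -> V = 0 on both sides -> pair score 1
  d1 <- mk2(rep("a", 10), rep(c("x", "y"), 5))
  expect_equal(contingency_similarity(d1, d1)$score, 1)
})

test_that("sliced Wasserstein distance is 0 on identical tables and stable in
           the number of directions", {
  r <- random_table(60, seed = 3)
  expect_equal(sliced_wasserstein(r, perm_copy(r), n_directions = 50)$distance, 0)
  # single feature, point masses at 0 and 1: each unit direction u gives |u|*1
  mk <- function(v) {
    d <- data.frame(x = v)
    attr(d, "schema") <- c(x = "continuous")
    class(d) <- c("patient_feature_table", "data.frame")
    d
  }
  got <- sliced_wasserstein(mk(rep(c(0, 1), 10)), mk(rep(1, 20)),
                            n_directions = 400, seed = 7)$distance
  expect_equal(got, 0.5, tolerance = 1e-9)  # |ECDF gap| = 0.5 on [0, 1]
  # Monte-Carlo stability across direction counts
  s <- random_table(60, seed = 4)
  d1 <- sliced_wasserstein(r, s, n_directions = 500, seed = 1)$distance
  d2 <- sliced_wasserstein(r, s, n_directions = 1000, seed = 2)$distance
  expect_lt(abs(d1 - d2) / d1, 0.15)
})

test_that("co-occurrence correlation captures temporal precedence", {
  fwd <- toy_cohort(list(
    list(id = "1", sex = "male", visits = list(list(age = 40, codes = "A"),
                                            list(age = 50, codes = "B"))),
    list(id = "2", sex = "female", visits = list(list(age = 41, codes = "A"),
                                            list(age = 51, codes = "C"))),
    list(id = "3", sex = "female", visits = list(list(age = 42, codes = "B"),
                                            list(age = 52, codes = "C")))),
    vocabulary = c("DM", "A", "B", "C"))
  rev <- toy_cohort(list(
    list(id = "1", sex = "male", visits = list(list(age = 40, codes = "B"),
                                            list(age = 50, codes = "A"))),
    list(id = "2", sex = "female", visits = list(list(age = 41, codes = "C"),
                                            list(age = 51, codes = "A"))),
    list(id = "3", sex = "female", visits = list(list(age = 42, codes = "C"),
                                            list(age = 52, codes = "B")))),
    vocabulary = c("DM", "A", "B", "C"))
  expect_equal(cooccurrence_correlation(fwd, fwd)$score, 1)
  expect_lt(cooccurrence_correlation(fwd, rev)$score, 0)
  # frequencies match a hand count: f(A->B) = 1/3 in fwd
  f <- cooccurrence_correlation(fwd, fwd)$real_freq
  expect_equal(f["A", "B"], 1 / 3)
  expect_equal(f["B", "A"], 0)
  # no multi-code patients -> undefined
  solo <- toy_cohort(list(
    list(id = "1", sex = "male", visits = list(list(age = 40, codes = "A")))),
    vocabulary = c("DM", "A", "B", "C"))
  expect_true(cooccurrence_correlation(solo, solo)$undefined)
})

test_that("same-visit co-occurrence counts for neither direction", {
  same <- toy_cohort(list(
    list(id = "1", sex = "male",
         visits = list(list(age = 40, codes = c("A", "B"))))),
    vocabulary = c("DM", "A", "B"))
  f <- synthehr:::precedence_frequencies(same)
  expect_equal(f["A", "B"], 0)
  expect_equal(f["B", "A"], 0)
})

test_that("identity suite: all fidelity metrics are perfect on a row-permuted copy", {
  real <- small_sim(150, n_diseases = 6, seed = 41)
  perm <- cohort(real$records[sample(150)], real$vocabulary, real$anchor_code,
                 real$endpoint_code)
  rep <- fidelity_report(real, perm, n_directions = 100, seed = 2)
  expect_equal(rep$BAS, 1)
  expect_equal(rep$CAS, 1)
  expect_equal(rep$KSS, 1)
  expect_equal(rep$TVS, 1)
  expect_equal(rep$CrSS, 1)
  expect_equal(rep$CtSS, 1)
  expect_equal(rep$SWD, 0)
  expect_equal(rep$CoC, 1)
})

test_that("metrics are invariant to row order in both inputs", {
  r <- random_table(40, seed = 5)
  s <- random_table(40, seed = 6)
  for (f in list(boundary_adherence, category_adherence, ks_complement,
                 tv_complement, correlation_similarity))
    expect_equal(f(r, s)$score, f(perm_copy(r, 8), perm_copy(s, 9))$score)
})

test_that("KS complement degrades monotonically under growing noise", {
  r <- random_table(200, seed = 7)
  scores <- vapply(c(0, 2, 5, 10, 20), function(amp) {
    set.seed(77)
    s <- r
    s$age_at_diabetes <- s$age_at_diabetes + stats::runif(200, -amp, amp)
    s$visit_count <- s$visit_count + stats::runif(200, -amp, amp)
    ks_complement(r, s)$score
  }, 0.0)
  expect_true(all(diff(scores) <= 1e-9))
})
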