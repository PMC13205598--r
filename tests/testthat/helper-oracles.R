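# Independent brute-force oracles used to validate the metric implementations.
# Each is written as the most literal possible transcription of the metric's
# definition (double loops, exhaustive enumeration), with no code shared with
# the package internals.

oracle_ks <- function(a, b) {
  # max ECDF gap, evaluated by scanning every observed value
  vals <- sort(unique(c(a, b)))
  gaps <- sapply(vals, function(v) abs(mean(a <= v) - mean(b <= v)))
  max(gaps)
}

oracle_tvd <- function(a, b) {
  lev <- union(unique(a), unique(b))
  pa <- sapply(lev, function(l) mean(a == l))
  pb <- sapply(lev, function(l) mean(b == l))
  sum(abs(pa - pb)) / 2
}

oracle_cramers_v <- function(a, b) {
  la <- unique(a); lb <- unique(b)
  if (length(la) < 2 || length(lb) < 2) return(0)
  obs <- outer(la, lb, Vectorize(function(x, y) sum(a == x & b == y)))
  n <- length(a)
  expct <- outer(rowSums(obs), colSums(obs)) / n
  chi2 <- sum((obs - expct)^2 / expct)
  sqrt(chi2 / (n * (min(length(la), length(lb)) - 1)))
}

oracle_dtw <- function(a, b) {
  # memoized recursion over warping paths (match / insert / delete)
  n <- length(a); m <- length(b)
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (i < 1 || j < 1) return(if (i == 0 && j == 0) 0 else Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- abs(a[i] - b[j]) + min(rec(i - 1, j - 1), rec(i - 1, j), rec(i, j - 1))
    memo[i, j] <<- v
    v
  }
  rec(n, m)
}

oracle_hwt <- function(rank_a, rank_b) {
  items <- rank_a
  w <- function(r) 1 / (1 + r)
  side <- function(ref, other) {
    pa <- sapply(items, function(it) which(ref == it) - 1)
    pb <- sapply(items, function(it) which(other == it) - 1)
    num <- 0; den <- 0
    for (i in seq_along(items)) for (j in seq_along(items)) {
      if (i >= j) next
      wt <- w(pa[i]) + w(pa[j])
      s <- sign(pa[i] - pa[j]) * sign(pb[i] - pb[j])
      num <- num + wt * s
      den <- den + wt
    }
    num / den
  }
  (side(rank_a, rank_b) + side(rank_b, rank_a)) / 2
}

oracle_nrs_matches <- function(real, synth, tol = 0.01) {
  # exhaustive pairwise match scan on a flattened table
  s <- attr(real, "schema")
  cont <- names(s)[s == "continuous"]
  disc <- names(s)[s != "continuous"]
  rng <- sapply(cont, function(cl) {
    r <- real[[cl]][!is.na(real[[cl]])]
    if (!length(r) || max(r) == min(r)) 1 else max(r) - min(r)
  })
  matched <- logical(nrow(synth))
  for (i in seq_len(nrow(synth))) {
    for (j in seq_len(nrow(real))) {
      ok <- TRUE
      for (cl in disc) {
        a <- synth[[cl]][i]; b <- real[[cl]][j]
        if (is.na(a) != is.na(b) || (!is.na(a) && a != b)) { ok <- FALSE; break }
      }
      if (ok) for (cl in cont) {
        a <- synth[[cl]][i]; b <- real[[cl]][j]
        if (is.na(a) != is.na(b) ||
            (!is.na(a) && abs(a - b) > tol * rng[[cl]])) { ok <- FALSE; break }
      }
      if (ok) { matched[i] <- TRUE; break }
    }
  }
  matched
}

# small hand-built cohorts ------------------------------------------------------

toy_cohort <- function(rows, vocabulary = c("DM", "HTN", "CKD"),
                       anchor = "DM", endpoint = "CKD") {
  # rows: list of list(id, sex, visits = list(c(age, codes...)), year)
  recs <- lapply(rows, function(r) {
    vs <- lapply(r$visits, function(v) visit(v$age, v$codes))
    patient_record(r$id, r$sex, vs, r$year %||% NA_integer_)
  })
  cohort(recs, vocabulary, anchor, endpoint)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_sim <- function(n = 300, n_diseases = 8, seed = 1, ...) {
  simulate_cohort(sim_config(n_patients = n,
                             diseases = default_diseases(n_diseases),
                             seed = seed, ...))
}

# random feature tables with a mixed schema for property tests
random_table <- function(n = 50, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    sex = sample(c("female", "male"), n, replace = TRUE),
    age_at_diabetes = round(stats::rnorm(n, 60, 10), 1),
    flag_A = sample(c(TRUE, FALSE), n, replace = TRUE),
    age_A = round(stats::rnorm(n, 50, 15), 1),
    visit_count = as.numeric(sample(1:10, n, replace = TRUE)),
    stringsAsFactors = FALSE)
  d$age_A[!d$flag_A] <- NA
  attr(d, "schema") <- c(sex = "categorical", age_at_diabetes = "continuous",
                         flag_A = "boolean", age_A = "continuous",
                         visit_count = "continuous")
  class(d) <- c("patient_feature_table", "data.frame")
  d
}
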