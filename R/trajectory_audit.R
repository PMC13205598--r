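# Biomedical trajectory plausibility: sex differences in per-person diagnosis
# rates across 5-year age bins, with Wald confidence bands, compared between
# cohorts by exact dynamic time warping.

#' Sex-difference diagnosis-rate trajectory
#'
#' Partitions visit ages into `bin_width`-year bins over `age_range` (the last
#' bin is open-ended at the top). Per bin and sex, the diagnosis rate is the
#' total number of diagnosis events whose visit age falls in the bin divided
#' by the total number of individuals of that sex in the cohort. The primary
#' series is `diff = female rate - male rate` with a 95% Wald interval based
#' on the Poisson-rate approximation
#' `diff +/- 1.96 * sqrt(c_f / n_f^2 + c_m / n_m^2)` (event counts `c`,
#' individuals `n`; rates per person can exceed 1, so a Poisson rather than a
#' binomial variance is used).
#'
#' @param x an `ehr_cohort` with both sexes present.
#' @param bin_width bin width in years (default 5).
#' @param age_range `c(min, max)` ages defining the bins (default `c(18, 100)`).
#' @return a `trajectory_series` data frame: bin edges, per-sex event counts
#'   and rates, `diff`, `ci_low`, `ci_high`, and `populated` (any event in the
#'   bin).
#' @export
rate_difference_series <- function(x, bin_width = 5, age_range = c(18, 100)) {
  stopifnot(inherits(x, "ehr_cohort"))
  sexes <- vapply(x$records, `[[`, "", "sex")
  n_f <- sum(sexes == "female", na.rm = TRUE)
  n_m <- sum(sexes == "male", na.rm = TRUE)
  if (n_f == 0 || n_m == 0) stop("both sexes must be present")
  edges <- seq(age_range[1], age_range[2], by = bin_width)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  hi[length(hi)] <- Inf                     # final bin open-ended
  long <- cohort_long(x)
  long$sex <- sexes[long$row]
  counts <- function(sex) {
    a <- long$age[long$sex == sex & !is.na(long$age)]
    vapply(seq_along(lo), function(b) sum(a >= lo[b] & a < hi[b]), 0L)
  }
  c_f <- counts("female"); c_m <- counts("male")
  rate_f <- c_f / n_f; rate_m <- c_m / n_m
  diff <- rate_f - rate_m
  se <- sqrt(c_f / n_f^2 + c_m / n_m^2)
  out <- data.frame(bin_low = lo, bin_high = c(hi[-length(hi)], age_range[2]),
                    count_female = c_f, count_male = c_m,
                    rate_female = rate_f, rate_male = rate_m,
                    diff = diff, ci_low = diff - 1.96 * se,
                    ci_high = diff + 1.96 * se,
                    populated = (c_f + c_m) > 0)
  class(out) <- c("trajectory_series", "data.frame")
  out
}

#' Exact dynamic time warping distance
#'
#' Dynamic-programming DTW with local cost `|a_i - b_j|`, symmetric steps
#' (match, insert, delete) and no window constraint; returns the un-normalized
#' cumulative cost of the optimal warping path. A pure time shift of a pattern
#' is absorbed by the warping (e.g. `dtw_distance(c(0,1,0), c(0,0,1,0)) == 0`).
#'
#' @param a,b non-empty numeric series.
#' @return the optimal cumulative alignment cost (>= 0).
#' @export
dtw_distance <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) stop("series must be non-empty")
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    cost <- abs(a[i] - b)
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- cost[j] + min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  D[n + 1, m + 1]
}

#' Trajectory plausibility report
#'
#' Computes the sex-difference rate trajectory for the original cohort and
#' each replica, restricts each comparison to the bins populated (any event)
#' in both cohorts, and reports the DTW distance between the difference
#' series, sorted ascending.
#'
#' @param original an `ehr_cohort`.
#' @param replicas named list of `ehr_cohort`s.
#' @param bin_width,age_range passed to [rate_difference_series()].
#' @return data frame with `replica` and `dtw` columns, sorted by distance.
#' @export
trajectory_report <- function(original, replicas, bin_width = 5,
                              age_range = c(18, 100)) {
  if (!length(replicas)) stop("at least one replica required")
  if (is.null(names(replicas)))
    names(replicas) <- paste0("replica_", seq_along(replicas))
  so <- rate_difference_series(original, bin_width, age_range)
  dists <- vapply(replicas, function(rep_cohort) {
    sr <- rate_difference_series(rep_cohort, bin_width, age_range)
    keep <- so$populated & sr$populated
    if (!any(keep)) stop("no common populated bins")
    dtw_distance(so$diff[keep], sr$diff[keep])
  }, 0.0)
  out <- data.frame(replica = names(replicas), dtw = unname(dists))
  out[order(out$dtw), , drop = FALSE]
}
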