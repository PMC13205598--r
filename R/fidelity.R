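# Distribution-and-structure fidelity metrics.
#
# Column-wise metrics operate on flattened patient feature tables that share a
# schema; the co-occurrence correlation operates on the cohorts themselves.
# Every metric is implemented from its textual definition and cross-checked in
# the test suite against independent brute-force oracles. Scores in [0, 1]
# where stated, higher = more faithful; the sliced Wasserstein distance is a
# distance (lower = better).

schema_cols <- function(x, kinds) {
  s <- table_schema(x)
  names(s)[s %in% kinds]
}

check_shared_schema <- function(real, synth) {
  if (!identical(table_schema(real), table_schema(synth)))
    stop("real and synthetic tables must share a column schema")
}

#' Boundary adherence score
#'
#' Per continuous column, the fraction of synthetic values inside the real
#' column's `[min, max]`; a missing synthetic value counts as valid only if
#' the real column also contains missing values. Aggregate = mean over
#' continuous columns.
#'
#' @param real,synth `patient_feature_table`s sharing a schema.
#' @return list with `score` and a named `per_column` vector (`score` is `NA`
#'   and flagged `undefined` when there are no continuous columns).
#' @export
boundary_adherence <- function(real, synth) {
  check_shared_schema(real, synth)
  cols <- schema_cols(real, "continuous")
  if (!length(cols)) return(list(score = NA_real_, per_column = numeric(),
                                 undefined = TRUE))
  per <- vapply(cols, function(cl) {
    r <- real[[cl]]; s <- synth[[cl]]
    lo <- suppressWarnings(min(r, na.rm = TRUE))
    hi <- suppressWarnings(max(r, na.rm = TRUE))
    ok <- ifelse(is.na(s), anyNA(r), !is.na(s) & s >= lo & s <= hi)
    mean(ok)
  }, 0.0)
  list(score = mean(per), per_column = per, undefined = FALSE)
}

#' Category adherence score
#'
#' Per discrete (categorical or boolean) column, the fraction of synthetic
#' values belonging to the real category set; missing is a valid category only
#' if present in the real column. Aggregate = mean over discrete columns.
#'
#' @inheritParams boundary_adherence
#' @return list with `score` and `per_column`.
#' @export
category_adherence <- function(real, synth) {
  check_shared_schema(real, synth)
  cols <- schema_cols(real, c("categorical", "boolean"))
  if (!length(cols)) return(list(score = NA_real_, per_column = numeric(),
                                 undefined = TRUE))
  per <- vapply(cols, function(cl) {
    r <- real[[cl]]; s <- synth[[cl]]
    cats <- unique(r[!is.na(r)])
    mean(ifelse(is.na(s), anyNA(r), s %in% cats))
  }, 0.0)
  list(score = mean(per), per_column = per, undefined = FALSE)
}

# maximum ECDF gap between two samples (two-sample KS statistic)
ks_statistic <- function(r, s) {
  grid <- sort(unique(c(r, s)))
  Fr <- stats::ecdf(r)(grid)
  Fs <- stats::ecdf(s)(grid)
  max(abs(Fr - Fs))
}

#' Kolmogorov-Smirnov complement score
#'
#' Per continuous column, `1 - D` where `D` is the two-sample KS statistic
#' (maximum ECDF gap) after removing missing values; mean over columns.
#' Columns empty after missing removal are skipped and flagged.
#'
#' @inheritParams boundary_adherence
#' @return list with `score`, `per_column`, and `skipped` column names.
#' @export
ks_complement <- function(real, synth) {
  check_shared_schema(real, synth)
  cols <- schema_cols(real, "continuous")
  if (!length(cols)) stop("ks_complement needs at least one continuous column")
  per <- rep(NA_real_, length(cols)); names(per) <- cols
  for (cl in cols) {
    r <- real[[cl]][!is.na(real[[cl]])]
    s <- synth[[cl]][!is.na(synth[[cl]])]
    if (!length(r) || !length(s)) next
    per[cl] <- 1 - ks_statistic(r, s)
  }
  list(score = mean(per, na.rm = TRUE), per_column = per,
       skipped = cols[is.na(per)])
}

# category frequency table over the union of levels (NA kept as a level)
freq_over_union <- function(r, s) {
  lv <- union(unique(r), unique(s))
  lv_chr <- as.character(lv); lv_chr[is.na(lv)] <- "<NA>"
  rc <- as.character(r); rc[is.na(rc)] <- "<NA>"
  sc <- as.character(s); sc[is.na(sc)] <- "<NA>"
  list(p = as.vector(table(factor(rc, lv_chr))) / length(rc),
       q = as.vector(table(factor(sc, lv_chr))) / length(sc))
}

#' Total-variation complement score
#'
#' Per discrete column, `1 - TVD` where the total variation distance is half
#' the sum of absolute category-frequency differences over the union of
#' categories; mean over discrete columns.
#'
#' @inheritParams boundary_adherence
#' @return list with `score` and `per_column`.
#' @export
tv_complement <- function(real, synth) {
  check_shared_schema(real, synth)
  cols <- schema_cols(real, c("categorical", "boolean"))
  if (!length(cols)) stop("tv_complement needs at least one discrete column")
  per <- vapply(cols, function(cl) {
    f <- freq_over_union(real[[cl]], synth[[cl]])
    1 - sum(abs(f$p - f$q)) / 2
  }, 0.0)
  list(score = mean(per), per_column = per)
}

#' Correlation similarity score
#'
#' Per unordered pair of continuous columns, `1 - |r_real - r_synth| / 2`
#' using Pearson correlation on pairwise-complete observations (the division
#' by 2 bounds the score in `[0, 1]`); mean over pairs. Pairs with zero
#' variance in either dataset are skipped and flagged.
#'
#' @inheritParams boundary_adherence
#' @return list with `score`, `per_pair` data frame, and `skipped` pairs.
#' @export
correlation_similarity <- function(real, synth) {
  check_shared_schema(real, synth)
  cols <- schema_cols(real, "continuous")
  if (length(cols) < 2) stop("correlation_similarity needs >= 2 continuous columns")
  prs <- utils::combn(cols, 2)
  score <- rep(NA_real_, ncol(prs))
  for (k in seq_len(ncol(prs))) {
    a <- prs[1, k]; b <- prs[2, k]
    rr <- suppressWarnings(stats::cor(real[[a]], real[[b]],
                                      use = "pairwise.complete.obs"))
    rs <- suppressWarnings(stats::cor(synth[[a]], synth[[b]],
                                      use = "pairwise.complete.obs"))
    if (is.na(rr) || is.na(rs)) next
    score[k] <- 1 - abs(rr - rs) / 2
  }
  per_pair <- data.frame(col_a = prs[1, ], col_b = prs[2, ], score = score)
  list(score = mean(score, na.rm = TRUE), per_pair = per_pair,
       skipped = per_pair[is.na(score), c("col_a", "col_b")])
}

# Cramer's V on two discretized vectors over the union of observed levels;
# degenerate tables (a single level on either margin) give V = 0
cramers_v <- function(a, b) {
  a <- as.character(a); a[is.na(a)] <- "<NA>"
  b <- as.character(b); b[is.na(b)] <- "<NA>"
  tab <- table(a, b)
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  if (!is.finite(chi2)) return(0)
  n <- sum(tab)
  sqrt(as.numeric(chi2) / (n * (min(nrow(tab), ncol(tab)) - 1)))
}

# discretize a continuous column into equal-width bins with edges from the
# real data; values outside the real range fall into the outer bins
bin_by_real <- function(r, s, n_bins = 10) {
  lo <- suppressWarnings(min(r, na.rm = TRUE))
  hi <- suppressWarnings(max(r, na.rm = TRUE))
  if (!is.finite(lo) || lo == hi) {
    f <- function(x) ifelse(is.na(x), NA_character_, "b1")
    return(list(r = f(r), s = f(s)))
  }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  cutf <- function(x) {
    idx <- findInterval(pmin(pmax(x, lo), hi), edges, rightmost.closed = TRUE)
    ifelse(is.na(x), NA_character_, paste0("b", pmin(idx, n_bins)))
  }
  list(r = cutf(r), s = cutf(s))
}

#' Contingency similarity score
#'
#' Per unordered column pair: any continuous member is discretized into
#' equal-width bins (default 10, edges from the real data); Cramer's V is
#' computed in both datasets over the union of observed levels; the pair score
#' is `1 - |V_real - V_synth|`; aggregate = mean over pairs.
#'
#' @inheritParams boundary_adherence
#' @param n_bins bins for discretizing continuous columns.
#' @return list with `score` and `per_pair` data frame.
#' @export
contingency_similarity <- function(real, synth, n_bins = 10) {
  check_shared_schema(real, synth)
  s <- table_schema(real)
  cols <- names(s)
  if (length(cols) < 2) stop("contingency_similarity needs >= 2 columns")
  disc <- lapply(cols, function(cl) {
    if (s[[cl]] == "continuous") bin_by_real(real[[cl]], synth[[cl]], n_bins)
    else list(r = real[[cl]], s = synth[[cl]])
  })
  names(disc) <- cols
  prs <- utils::combn(cols, 2)
  score <- numeric(ncol(prs))
  for (k in seq_len(ncol(prs))) {
    a <- prs[1, k]; b <- prs[2, k]
    vr <- cramers_v(disc[[a]]$r, disc[[b]]$r)
    vs <- cramers_v(disc[[a]]$s, disc[[b]]$s)
    score[k] <- 1 - abs(vr - vs)
  }
  list(score = mean(score),
       per_pair = data.frame(col_a = prs[1, ], col_b = prs[2, ], score = score))
}

# exact 1-D Wasserstein-1 distance between two empirical distributions:
# integral of |ECDF difference| over the merged support
wasserstein1d <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  if (length(grid) < 2) return(0)
  Fa <- stats::ecdf(a)(grid)
  Fb <- stats::ecdf(b)(grid)
  k <- length(grid)
  sum(abs(Fa[-k] - Fb[-k]) * diff(grid))
}

# numeric encoding for multivariate metrics: continuous as-is (missing ->
# real-column median), booleans 0/1, categoricals one-hot over real levels
encode_numeric <- function(real, synth) {
  s <- table_schema(real)
  enc_r <- list(); enc_s <- list()
  for (cl in names(s)) {
    if (s[[cl]] == "continuous") {
      med <- stats::median(real[[cl]], na.rm = TRUE)
      if (is.na(med)) med <- 0
      r <- real[[cl]]; r[is.na(r)] <- med
      v <- synth[[cl]]; v[is.na(v)] <- med
      enc_r[[cl]] <- r; enc_s[[cl]] <- v
    } else if (s[[cl]] == "boolean") {
      enc_r[[cl]] <- as.numeric(real[[cl]])
      enc_s[[cl]] <- as.numeric(synth[[cl]])
    } else {
      lv <- unique(real[[cl]][!is.na(real[[cl]])])
      for (l in lv) {
        nm <- paste0(cl, "=", l)
        enc_r[[nm]] <- as.numeric(!is.na(real[[cl]]) & real[[cl]] == l)
        enc_s[[nm]] <- as.numeric(!is.na(synth[[cl]]) & synth[[cl]] == l)
      }
    }
  }
  list(real = do.call(cbind, enc_r), synth = do.call(cbind, enc_s))
}

#' Sliced Wasserstein distance
#'
#' Encodes both tables numerically (flags 0/1, categoricals one-hot, missing
#' continuous values imputed to the real column median), min-max normalizes
#' each feature by the real-data bounds (zero-range features are excluded),
#' draws `n_directions` unit vectors uniformly on the sphere, and averages the
#' exact 1-D Wasserstein-1 distances of the projections.
#'
#' @inheritParams boundary_adherence
#' @param n_directions number of random projection directions.
#' @param seed RNG seed for the directions.
#' @return list with `distance` and `n_features` used.
#' @export
sliced_wasserstein <- function(real, synth, n_directions = 1000, seed = 1L) {
  check_shared_schema(real, synth)
  enc <- encode_numeric(real, synth)
  lo <- apply(enc$real, 2, min); hi <- apply(enc$real, 2, max)
  keep <- hi > lo
  if (!any(keep)) stop("no features with nonzero range")
  R <- sweep(sweep(enc$real[, keep, drop = FALSE], 2, lo[keep]), 2,
             hi[keep] - lo[keep], "/")
  S <- sweep(sweep(enc$synth[, keep, drop = FALSE], 2, lo[keep]), 2,
             hi[keep] - lo[keep], "/")
  d <- ncol(R)
  set.seed(seed)
  U <- matrix(stats::rnorm(n_directions * d), d, n_directions)
  U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  PR <- R %*% U; PS <- S %*% U
  w <- vapply(seq_len(n_directions), function(k) wasserstein1d(PR[, k], PS[, k]),
              0.0)
  list(distance = mean(w), n_features = d)
}

# ordered-precedence frequencies: for each ordered code pair (a, b), the
# fraction of patients in whom a's first occurrence is at a strictly earlier
# visit index than b's
precedence_frequencies <- function(x) {
  codes <- setdiff(x$vocabulary, x$anchor_code)
  n <- length(x$records)
  m <- length(codes)
  idx <- matrix(NA_integer_, n, m, dimnames = list(NULL, codes))
  long <- cohort_long(x)
  long <- long[code != x$anchor_code]
  if (nrow(long)) {
    first <- long[, .(vidx = min(vidx)), by = .(row, code)]
    idx[cbind(first$row, match(first$code, codes))] <- first$vidx
  }
  f <- matrix(0, m, m, dimnames = list(codes, codes))
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a == b) next
    f[a, b] <- sum(!is.na(idx[, a]) & !is.na(idx[, b]) & idx[, a] < idx[, b]) / n
  }
  f
}

#' Temporal co-occurrence correlation
#'
#' For every ordered pair of non-anchor codes `(a, b)`, computes the fraction
#' of patients in whom `a`'s first occurrence is at a strictly earlier visit
#' index than `b`'s (same-visit co-occurrence counts for neither direction),
#' then the Pearson correlation between the real and synthetic frequency
#' vectors over all ordered pairs.
#'
#' @param real,synth `ehr_cohort`s sharing a vocabulary.
#' @return list with `score` (correlation in `[-1, 1]`; `NA` and flagged
#'   `undefined` when either vector has fewer than 2 distinct values) and the
#'   two frequency vectors.
#' @export
cooccurrence_correlation <- function(real, synth) {
  if (!setequal(real$vocabulary, synth$vocabulary))
    stop("cohorts must share a vocabulary")
  fr <- precedence_frequencies(real)
  fs <- precedence_frequencies(synth)
  fs <- fs[rownames(fr), colnames(fr)]
  off <- row(fr) != col(fr)
  vr <- fr[off]; vs <- fs[off]
  if (length(unique(vr)) < 2 || length(unique(vs)) < 2)
    return(list(score = NA_real_, undefined = TRUE, real_freq = fr,
                synth_freq = fs))
  list(score = stats::cor(vr, vs), undefined = FALSE,
       real_freq = fr, synth_freq = fs)
}

#' Full fidelity report
#'
#' Runs every distribution-and-structure metric on a real/synthetic cohort
#' pair: the column-wise metrics on the flattened tables and the temporal
#' co-occurrence correlation on the cohorts.
#'
#' @param real,synth `ehr_cohort`s sharing a vocabulary.
#' @param n_directions projections for the sliced Wasserstein distance.
#' @param seed RNG seed for the sliced Wasserstein directions.
#' @return a `fidelity_report` list with elements `BAS`, `CAS`, `KSS`, `TVS`,
#'   `CrSS`, `CtSS`, `SWD`, `CoC` plus per-column/per-pair breakdowns.
#' @export
fidelity_report <- function(real, synth, n_directions = 1000, seed = 1L) {
  tr <- flatten(real); ts <- flatten(synth)
  bas <- boundary_adherence(tr, ts)
  cas <- category_adherence(tr, ts)
  kss <- ks_complement(tr, ts)
  tvs <- tv_complement(tr, ts)
  crss <- correlation_similarity(tr, ts)
  ctss <- contingency_similarity(tr, ts)
  swd <- sliced_wasserstein(tr, ts, n_directions = n_directions, seed = seed)
  coc <- cooccurrence_correlation(real, synth)
  structure(list(BAS = bas$score, CAS = cas$score, KSS = kss$score,
                 TVS = tvs$score, CrSS = crss$score, CtSS = ctss$score,
                 SWD = swd$distance, CoC = coc$score,
                 detail = list(BAS = bas, CAS = cas, KSS = kss, TVS = tvs,
                               CrSS = crss, CtSS = ctss, SWD = swd, CoC = coc)),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("<fidelity_report>\n")
  for (m in c("BAS", "CAS", "KSS", "TVS", "CrSS", "CtSS", "SWD", "CoC"))
    cat(sprintf("  %-5s %.4f\n", m, x[[m]]))
  invisible(x)
}
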