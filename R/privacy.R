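# Privacy and novelty suite: new-row synthesis, attribute-disclosure
# protection, and zero-knowledge membership inference with orientation
# correction.
#
# The threat model for the disclosure attacks assumes the adversary knows a
# set of key attributes (by default sex and age at diabetes diagnosis) and
# tries to infer a sensitive attribute; the membership attack assumes zero
# knowledge and scores candidates by (negative) distance to the closest
# synthetic record.

# split a feature table into a range-normalized continuous matrix and an
# integer-coded discrete matrix; normalization bounds come from `ref`
split_encode <- function(x, ref) {
  s <- table_schema(ref)
  cont <- names(s)[s == "continuous"]
  disc <- names(s)[s != "continuous"]
  C <- matrix(NA_real_, nrow(x), length(cont))
  for (k in seq_along(cont)) {
    r <- ref[[cont[k]]]
    lo <- suppressWarnings(min(r, na.rm = TRUE))
    hi <- suppressWarnings(max(r, na.rm = TRUE))
    rng <- if (is.finite(hi - lo) && hi > lo) hi - lo else 1
    C[, k] <- (x[[cont[k]]] - lo) / rng
  }
  D <- matrix(0L, nrow(x), length(disc))
  for (k in seq_along(disc)) {
    v <- as.character(x[[disc[k]]]); v[is.na(v)] <- "<NA>"
    lv <- unique(c(as.character(ref[[disc[k]]]), "<NA>"))
    D[, k] <- match(v, lv, nomatch = 0L)
  }
  list(C = C, D = D)
}

#' New row synthesis score
#'
#' A synthetic row matches a real row iff all discrete values are identical
#' (missing positions must coincide), and every continuous value is within
#' `tol` times the real column range of the real value (missing matches only
#' missing). The score is 1 minus the fraction of matching synthetic rows.
#' Also reports the mean diagnosis count (number of `TRUE` flags) among the
#' matched synthetic rows, a diagnostic for trivially short records.
#'
#' @param real,synth `patient_feature_table`s sharing a schema.
#' @param tol continuous tolerance relative to the real column range
#'   (default 0.01).
#' @return list with `score`, `match_fraction`,
#'   `mean_diagnosis_count_of_matches`, and the logical `matched` vector.
#' @export
new_row_synthesis <- function(real, synth, tol = 0.01) {
  check_shared_schema(real, synth)
  if (!nrow(real)) stop("real table is empty")
  s <- table_schema(real)
  cont <- names(s)[s == "continuous"]
  disc <- names(s)[s != "continuous"]
  rngs <- vapply(cont, function(cl) {
    r <- real[[cl]]
    lo <- suppressWarnings(min(r, na.rm = TRUE))
    hi <- suppressWarnings(max(r, na.rm = TRUE))
    if (is.finite(hi - lo) && hi > lo) hi - lo else 1
  }, 0.0)
  dr <- lapply(disc, function(cl) { v <- as.character(real[[cl]]); v[is.na(v)] <- "<NA>"; v })
  ds <- lapply(disc, function(cl) { v <- as.character(synth[[cl]]); v[is.na(v)] <- "<NA>"; v })
  matched <- logical(nrow(synth))
  for (i in seq_len(nrow(synth))) {
    cand <- rep(TRUE, nrow(real))
    for (k in seq_along(disc)) {
      cand <- cand & (dr[[k]] == ds[[k]][i])
      if (!any(cand)) break
    }
    if (!any(cand)) next
    for (k in seq_along(cont)) {
      sv <- synth[[cont[k]]][i]
      rv <- real[[cont[k]]]
      cand <- cand & if (is.na(sv)) is.na(rv) else
        (!is.na(rv) & abs(rv - sv) <= tol * rngs[k])
      if (!any(cand)) break
    }
    matched[i] <- any(cand)
  }
  flags <- names(s)[s == "boolean"]
  dc <- if (length(flags)) rowSums(as.matrix(synth[, flags, drop = FALSE])) else
    rep(0, nrow(synth))
  list(score = 1 - mean(matched), match_fraction = mean(matched),
       mean_diagnosis_count_of_matches =
         if (any(matched)) mean(dc[matched]) else NA_real_,
       matched = matched)
}

# majority-vote attribute-inference attack: for each target (real) row, find
# synthetic rows agreeing on the keys; predict the sensitive value by majority
# vote, falling back to `fallback` when no synthetic row matches
attack_accuracy <- function(real, synth, key_cols, sensitive_col, tol,
                            fallback) {
  s <- table_schema(real)
  truth <- as.character(real[[sensitive_col]]); truth[is.na(truth)] <- "<NA>"
  sens <- as.character(synth[[sensitive_col]]); sens[is.na(sens)] <- "<NA>"
  correct <- logical(nrow(real))
  key_cont <- key_cols[s[key_cols] == "continuous"]
  key_disc <- key_cols[s[key_cols] != "continuous"]
  rngs <- vapply(key_cont, function(cl) {
    r <- real[[cl]]
    lo <- suppressWarnings(min(r, na.rm = TRUE))
    hi <- suppressWarnings(max(r, na.rm = TRUE))
    if (is.finite(hi - lo) && hi > lo) hi - lo else 1
  }, 0.0)
  kd_r <- lapply(key_disc, function(cl) { v <- as.character(real[[cl]]); v[is.na(v)] <- "<NA>"; v })
  kd_s <- lapply(key_disc, function(cl) { v <- as.character(synth[[cl]]); v[is.na(v)] <- "<NA>"; v })
  for (i in seq_len(nrow(real))) {
    cand <- rep(TRUE, nrow(synth))
    for (k in seq_along(key_disc)) cand <- cand & (kd_s[[k]] == kd_r[[k]][i])
    for (k in seq_along(key_cont)) {
      rv <- real[[key_cont[k]]][i]
      sv <- synth[[key_cont[k]]]
      cand <- cand & if (is.na(rv)) is.na(sv) else
        (!is.na(sv) & abs(sv - rv) <= tol * rngs[k])
    }
    guess <- if (any(cand)) names(which.max(table(sens[cand]))) else fallback
    correct[i] <- guess == truth[i]
  }
  mean(correct)
}

#' Disclosure protection score
#'
#' Simulates a correct-attribution attack: the adversary knows `key_cols` for
#' every real row, finds synthetic rows agreeing on the keys (continuous keys
#' within `tol` of the real column range) and predicts the sensitive value by
#' majority vote (falling back to the modal real category when nothing
#' matches). In `"full"` mode the attack runs on all real rows and the
#' baseline always guesses the modal real category; in `"estimate"` mode the
#' attack is averaged over random subsamples and the baseline is the expected
#' accuracy of a uniform random guess over the observed categories. The score
#' is `clamp(1 - max(0, acc_attack - acc_base) / (1 - acc_base), 0, 1)`; when
#' the baseline accuracy is 1 (a single category) the score is defined as 1.
#'
#' @param real,synth `patient_feature_table`s sharing a schema.
#' @param key_cols attacker-known columns (default sex and age at diabetes).
#' @param sensitive_col discrete column under attack.
#' @param mode `"full"` or `"estimate"`.
#' @param n_subsamples,subsample_size subsampling plan for `"estimate"` mode.
#' @param tol continuous key tolerance relative to the real column range.
#' @param seed RNG seed (estimate mode).
#' @return list with `score`, `acc_attack`, `acc_base`.
#' @export
disclosure_protection <- function(real, synth,
                                  key_cols = c("sex", "age_at_diabetes"),
                                  sensitive_col = "flag_CKD",
                                  mode = c("full", "estimate"),
                                  n_subsamples = 5, subsample_size = 200,
                                  tol = 0.01, seed = 1L) {
  check_shared_schema(real, synth)
  mode <- match.arg(mode)
  s <- table_schema(real)
  if (!sensitive_col %in% names(s) || s[[sensitive_col]] == "continuous")
    stop("sensitive_col must be a discrete column")
  truth <- as.character(real[[sensitive_col]]); truth[is.na(truth)] <- "<NA>"
  modal <- names(which.max(table(truth)))
  if (mode == "full") {
    acc_base <- mean(truth == modal)
    acc_attack <- attack_accuracy(real, synth, key_cols, sensitive_col, tol,
                                  fallback = modal)
  } else {
    k <- length(unique(truth))
    acc_base <- 1 / k
    set.seed(seed)
    acc <- vapply(seq_len(n_subsamples), function(b) {
      idx <- sample(nrow(real), min(subsample_size, nrow(real)))
      attack_accuracy(real[idx, , drop = FALSE], synth, key_cols,
                      sensitive_col, tol, fallback = modal)
    }, 0.0)
    acc_attack <- mean(acc)
  }
  score <- if (acc_base >= 1) 1 else
    clamp01(1 - max(0, acc_attack - acc_base) / (1 - acc_base))
  list(score = score, acc_attack = acc_attack, acc_base = acc_base,
       mode = mode)
}

#' Zero-knowledge membership inference attack
#'
#' The attacker scores each candidate row by the negative of its distance to
#' the nearest synthetic row under a mixed-type distance: range-normalized
#' absolute difference for continuous columns (capped at 1; both missing = 0,
#' one missing = 1), 0/1 mismatch for discrete columns, averaged over columns.
#' AUROC of member vs non-member scores is reported together with the
#' orientation-invariant `auroc_star = max(a, 1 - a)` and the advantage
#' `delta = |a - 0.5|`. Member and non-member sets are balanced by
#' downsampling the larger (fixed seed).
#'
#' @param members rows drawn from the generator's training data
#'   (`patient_feature_table`).
#' @param nonmembers held-out real rows.
#' @param synth the synthetic table the attacker observes.
#' @param seed RNG seed for balancing.
#' @return list with `auroc`, `auroc_star`, `delta`, and the group sizes.
#' @export
membership_inference <- function(members, nonmembers, synth, seed = 1L) {
  check_shared_schema(members, synth)
  check_shared_schema(nonmembers, synth)
  if (!nrow(synth)) stop("synthetic table is empty")
  set.seed(seed)
  n <- min(nrow(members), nrow(nonmembers))
  if (nrow(members) > n) members <- members[sample(nrow(members), n), , drop = FALSE]
  if (nrow(nonmembers) > n) nonmembers <- nonmembers[sample(nrow(nonmembers), n), , drop = FALSE]
  ref <- split_encode(synth, synth)
  em <- split_encode(members, synth)
  en <- split_encode(nonmembers, synth)
  dm <- min_mixed_distance(em$C, ref$C, em$D, ref$D)
  dn <- min_mixed_distance(en$C, ref$C, en$D, ref$D)
  a <- auroc(c(-dm, -dn), c(rep(TRUE, n), rep(FALSE, n)))
  list(auroc = a, auroc_star = auroc_star(a), delta = mia_delta(a),
       n_members = n, n_nonmembers = n)
}

#' Full privacy report
#'
#' Runs [new_row_synthesis()], [disclosure_protection()] (estimate mode) and
#' [membership_inference()] on flattened cohorts.
#'
#' @param members training-side real cohort (`ehr_cohort`).
#' @param nonmembers held-out real cohort.
#' @param synth synthetic cohort.
#' @param sensitive_col sensitive attribute for the disclosure attack.
#' @param seed RNG seed.
#' @return a `privacy_report` list.
#' @export
privacy_report <- function(members, nonmembers, synth,
                           sensitive_col = "flag_CKD", seed = 1L) {
  tm <- flatten(members); tn <- flatten(nonmembers); ts <- flatten(synth)
  nrs <- new_row_synthesis(tm, ts)
  dpe <- disclosure_protection(tm, ts, sensitive_col = sensitive_col,
                               mode = "estimate", seed = seed)
  mia <- membership_inference(tm, tn, ts, seed = seed)
  structure(list(NRS = nrs$score, match_fraction = nrs$match_fraction,
                 mean_diagnosis_count_of_matches = nrs$mean_diagnosis_count_of_matches,
                 DPeS = dpe$score, MIA_auroc = mia$auroc,
                 MIA_auroc_star = mia$auroc_star, MIA_delta = mia$delta,
                 detail = list(NRS = nrs, DPeS = dpe, MIA = mia)),
            class = "privacy_report")
}

#' @export
print.privacy_report <- function(x, ...) {
  cat("<privacy_report>\n")
  cat(sprintf("  NRS        %.4f\n  DPeS       %.4f\n", x$NRS, x$DPeS))
  cat(sprintf("  MIA AUROC  %.4f (AUROC* %.4f, delta %.4f)\n",
              x$MIA_auroc, x$MIA_auroc_star, x$MIA_delta))
  invisible(x)
}
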