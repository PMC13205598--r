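# Refinement pipeline for raw generated cohorts.
#
# A generative sampler can emit records without the diabetes anchor or a sex,
# visits that are empty or carry only an age, repeated chronic diagnoses,
# multiple age labels inside one visit, or visits lacking an age altogether.
# The pipeline repairs or discards these, in a fixed rule order, and accounts
# for every discard.

#' Refine a raw generated cohort
#'
#' Applies, in order: (1) drop records lacking the anchor code or a sex;
#' (2) drop visits that are empty or carry only age information (no codes);
#' (3) per chronic code, keep only its first visit occurrence within each
#' record; (4) within a visit carrying multiple age labels, keep the maximum;
#' (5) impute a missing visit age as the arithmetic mean of the adjacent
#' visits' ages (boundary visits copy their single neighbour). Records whose
#' every visit still lacks an age are dropped and counted. By default every
#' vocabulary code is treated as chronic for rule (3).
#'
#' @param x a raw `ehr_cohort`.
#' @param chronic_codes codes subject to the first-occurrence rule
#'   (default: the whole vocabulary).
#' @return list with `cohort` (the refined cohort) and `report`, a
#'   `discard_report` with fields `fraction_no_anchor`, `fraction_no_sex`,
#'   `fraction_no_age`, `fraction_total_discarded` and the backing counts.
#' @export
refine_cohort <- function(x, chronic_codes = x$vocabulary) {
  stopifnot(inherits(x, "ehr_cohort"))
  n_in <- length(x$records)
  n_no_anchor <- 0L; n_no_sex <- 0L; n_no_age <- 0L
  out <- vector("list", n_in)
  j <- 0L
  for (rec in x$records) {
    if (!record_has_code(rec, x$anchor_code)) { n_no_anchor <- n_no_anchor + 1L; next }
    if (is.na(rec$sex)) { n_no_sex <- n_no_sex + 1L; next }
    vs <- rec$visits
    # (2) drop empty / age-only visits
    vs <- Filter(function(v) length(v$codes) > 0L, vs)
    # (3) first occurrence per chronic code
    seen <- character()
    vs2 <- list()
    for (v in vs) {
      keep <- !(v$codes %in% intersect(seen, chronic_codes))
      seen <- union(seen, v$codes)
      if (any(keep)) {
        v$codes <- v$codes[keep]
        vs2[[length(vs2) + 1L]] <- v
      }
    }
    vs <- vs2
    # (4) multiple age labels -> keep the maximum
    vs <- lapply(vs, function(v) {
      a <- v$ages[!is.na(v$ages)]
      v$age <- if (length(a)) max(a) else NA_real_
      v$ages <- v$age
      v
    })
    # (5) impute missing ages from neighbours
    ages <- vapply(vs, `[[`, 0.0, "age")
    if (length(ages) && all(is.na(ages))) { n_no_age <- n_no_age + 1L; next }
    if (anyNA(ages)) {
      for (k in which(is.na(ages))) {
        prev <- if (k > 1) ages[k - 1] else NA_real_
        nxt <- if (k < length(ages)) ages[k + 1] else NA_real_
        # neighbours may themselves be missing: use nearest known on each side
        if (is.na(prev) && k > 1) {
          known <- which(!is.na(ages[seq_len(k - 1)]))
          if (length(known)) prev <- ages[max(known)]
        }
        if (is.na(nxt) && k < length(ages)) {
          known <- which(!is.na(ages[seq(k + 1, length(ages))]))
          if (length(known)) nxt <- ages[k + min(known)]
        }
        ages[k] <- mean(c(prev, nxt), na.rm = TRUE)
      }
      for (k in seq_along(vs)) { vs[[k]]$age <- ages[k]; vs[[k]]$ages <- ages[k] }
    }
    if (!length(vs)) { n_no_age <- n_no_age + 1L; next }
    rec$visits <- vs
    j <- j + 1L
    out[[j]] <- rec
  }
  out <- out[seq_len(j)]
  discarded <- n_in - j
  report <- discard_report(
    n_input = n_in, n_output = j,
    counts = c(no_anchor = n_no_anchor, no_sex = n_no_sex, no_age = n_no_age))
  list(cohort = cohort(out, vocabulary = x$vocabulary,
                       anchor_code = x$anchor_code,
                       endpoint_code = x$endpoint_code),
       report = report)
}

#' Prediction-specific exclusions
#'
#' Drops records whose visit ages are not non-decreasing and records whose
#' endpoint age precedes the anchor age. Run after [refine_cohort()].
#'
#' @param x a refined `ehr_cohort`.
#' @return list with `cohort` and a `discard_report` carrying
#'   `fraction_non_ascending` and `fraction_endpoint_before_anchor`.
#' @export
refine_for_prediction <- function(x) {
  stopifnot(inherits(x, "ehr_cohort"))
  n_in <- length(x$records)
  n_nonasc <- 0L; n_endfirst <- 0L
  keep <- logical(n_in)
  for (i in seq_len(n_in)) {
    rec <- x$records[[i]]
    ages <- vapply(rec$visits, `[[`, 0.0, "age")
    if (length(ages) > 1 && any(diff(ages) < 0)) { n_nonasc <- n_nonasc + 1L; next }
    a_anchor <- first_code_age(rec, x$anchor_code)
    a_end <- first_code_age(rec, x$endpoint_code)
    if (!is.na(a_end) && !is.na(a_anchor) && a_end < a_anchor) {
      n_endfirst <- n_endfirst + 1L; next
    }
    keep[i] <- TRUE
  }
  report <- discard_report(
    n_input = n_in, n_output = sum(keep),
    counts = c(non_ascending = n_nonasc, endpoint_before_anchor = n_endfirst))
  list(cohort = cohort(x$records[keep], vocabulary = x$vocabulary,
                       anchor_code = x$anchor_code,
                       endpoint_code = x$endpoint_code),
       report = report)
}

first_code_age <- function(rec, code) {
  for (v in rec$visits) if (code %in% v$codes) return(v$age)
  NA_real_
}

discard_report <- function(n_input, n_output, counts) {
  fr <- if (n_input > 0) counts / n_input else counts * 0
  names(fr) <- paste0("fraction_", names(counts))
  structure(c(list(n_input = n_input, n_output = n_output,
                   fraction_total_discarded =
                     if (n_input > 0) 1 - n_output / n_input else 0),
              as.list(fr), as.list(stats::setNames(counts, paste0("n_", names(counts))))),
            class = "discard_report")
}

#' @export
print.discard_report <- function(x, ...) {
  cat(sprintf("<discard_report> %d -> %d records (%.2f%% discarded)\n",
              x$n_input, x$n_output, 100 * x$fraction_total_discarded))
  for (nm in grep("^fraction_(?!total)", names(x), value = TRUE, perl = TRUE))
    cat(sprintf("  %-32s %.4f\n", nm, x[[nm]]))
  invisible(x)
}
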