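# Domain types for longitudinal diabetes-anchored records.
#
# A patient is sex + an ordered sequence of visits; each visit is an age (in
# years) plus a set of diagnosis codes. One code is the diabetes anchor, one
# is the chronic-kidney-disease endpoint. All downstream metrics consume
# either the cohort itself or its flattened one-row-per-patient table.

#' Construct a visit
#'
#' @param age age in years at visit time (non-negative; one decimal is
#'   sufficient resolution). May be `NA` in raw generated cohorts.
#' @param codes character vector of diagnosis codes; deduplicated (a visit
#'   carries a *set* of codes). In raw generated cohorts a visit may carry
#'   multiple candidate ages; pass them via `ages`.
#' @param ages optional numeric vector of all raw age labels attached to the
#'   visit (generated cohorts only); defaults to `age`.
#' @return a `visit` list with elements `age`, `codes`, `ages`.
#' @export
visit <- function(age, codes = character(), ages = NULL) {
  codes <- unique(as.character(codes))
  age <- if (length(age) == 0L || all(is.na(age))) NA_real_ else as.numeric(age)[1]
  if (!is.na(age) && age < 0) stop("visit age must be >= 0")
  structure(list(age = age, codes = codes, ages = as.numeric(ages %||% age)),
            class = "ehr_visit")
}

#' Construct a patient record
#'
#' @param id opaque identifier (unique within a cohort).
#' @param sex `"female"`, `"male"`, or `NA` (missing).
#' @param visits list of [visit()] objects in the record's canonical temporal
#'   order (order is preserved exactly; it is not re-sorted here).
#' @param diagnosis_year optional calendar year of the diabetes-anchor visit.
#' @return a `patient_record` list.
#' @export
patient_record <- function(id, sex, visits, diagnosis_year = NA_integer_) {
  if (!is.na(sex) && !sex %in% c("female", "male"))
    stop("sex must be 'female', 'male', or NA")
  structure(list(id = as.character(id), sex = as.character(sex),
                 visits = visits,
                 diagnosis_year = as.integer(diagnosis_year)),
            class = "patient_record")
}

#' Construct a cohort
#'
#' @param records list of [patient_record()]s with unique ids.
#' @param vocabulary ordered character vector of diagnosis codes; every code
#'   appearing in any visit must be in the vocabulary.
#' @param anchor_code diabetes anchor code (default `"DM"`).
#' @param endpoint_code chronic-kidney-disease endpoint code (default `"CKD"`).
#' @return an `ehr_cohort` object.
#' @export
cohort <- function(records, vocabulary, anchor_code = "DM", endpoint_code = "CKD") {
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate patient ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seen <- unique(unlist(lapply(records, function(r)
    unlist(lapply(r$visits, `[[`, "codes"), use.names = FALSE)), use.names = FALSE))
  unknown <- setdiff(seen, vocabulary)
  if (length(unknown)) stop("codes outside vocabulary: ", paste(unknown, collapse = ", "))
  structure(list(records = records, vocabulary = as.character(vocabulary),
                 anchor_code = anchor_code, endpoint_code = endpoint_code),
            class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf("<ehr_cohort> %d records, %d codes (anchor %s, endpoint %s)\n",
              length(x$records), length(x$vocabulary), x$anchor_code, x$endpoint_code))
  invisible(x)
}

#' @export
length.ehr_cohort <- function(x) length(x$records)

record_codes <- function(rec) unique(unlist(lapply(rec$visits, `[[`, "codes"),
                                            use.names = FALSE))

#' Does a record carry the anchor / endpoint code?
#' @param rec a [patient_record()].
#' @param code diagnosis code to look for.
#' @return logical.
#' @export
record_has_code <- function(rec, code) code %in% record_codes(rec)

# ---- serialization: JSON-lines, one record per line -------------------------

#' Write a cohort as JSON-lines
#'
#' One record per line with keys `id`, `sex`, `visits = [{age, codes}]` and
#' optional `diagnosis_year`. A header line (`{"vocabulary": ..., ...}`) with
#' the declared vocabulary and anchor/endpoint codes is written first so that
#' `read_cohort(write_cohort(c)) == c` even when some codes are unobserved.
#'
#' @param x an `ehr_cohort`.
#' @param path output file path.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "ehr_cohort"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  header <- jsonlite::toJSON(list(vocabulary = x$vocabulary,
                                  anchor_code = jsonlite::unbox(x$anchor_code),
                                  endpoint_code = jsonlite::unbox(x$endpoint_code)),
                             null = "null", na = "null")
  writeLines(header, con)
  for (r in x$records) {
    visits <- lapply(r$visits, function(v)
      list(age = if (is.na(v$age)) NULL else jsonlite::unbox(v$age),
           codes = as.character(v$codes)))
    obj <- list(id = jsonlite::unbox(r$id),
                sex = if (is.na(r$sex)) NULL else jsonlite::unbox(r$sex),
                visits = visits)
    if (!is.na(r$diagnosis_year)) obj$diagnosis_year <- jsonlite::unbox(r$diagnosis_year)
    writeLines(jsonlite::toJSON(obj, null = "null", na = "null"), con)
  }
  invisible(path)
}

#' Read a JSON-lines cohort
#'
#' Inverse of [write_cohort()]. The vocabulary is the union of the declared
#' header vocabulary (if present) and all observed codes; visit order is
#' preserved exactly as serialized.
#'
#' @param path path to a JSON-lines cohort file.
#' @return an `ehr_cohort`.
#' @export
read_cohort <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  vocab <- character(); anchor <- "DM"; endpoint <- "CKD"
  start <- 1L
  if (length(lines)) {
    first <- tryCatch(jsonlite::fromJSON(lines[1], simplifyVector = TRUE),
                      error = function(e) stop("parse error at line 1: ", conditionMessage(e)))
    if (!is.null(first$vocabulary) && is.null(first$id)) {
      vocab <- as.character(first$vocabulary)
      anchor <- first$anchor_code %||% anchor
      endpoint <- first$endpoint_code %||% endpoint
      start <- 2L
    }
  }
  records <- vector("list", max(0L, length(lines) - start + 1L))
  j <- 0L
  for (i in seq_along(lines)) {
    if (i < start) next
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) stop("parse error at line ", i, ": ",
                                             conditionMessage(e)))
    if (is.null(obj$id)) stop("parse error at line ", i, ": missing 'id'")
    if (is.null(obj$visits)) stop("parse error at line ", i, ": missing 'visits'")
    visits <- lapply(obj$visits, function(v)
      visit(age = if (is.null(v$age)) NA_real_ else v$age,
            codes = unlist(v$codes, use.names = FALSE) %||% character()))
    j <- j + 1L
    records[[j]] <- patient_record(
      id = obj$id,
      sex = if (is.null(obj$sex)) NA_character_ else obj$sex,
      visits = visits,
      diagnosis_year = if (is.null(obj$diagnosis_year)) NA_integer_ else obj$diagnosis_year)
  }
  records <- records[seq_len(j)]
  seen <- unique(unlist(lapply(records, record_codes), use.names = FALSE))
  cohort(records, vocabulary = union(vocab, seen),
         anchor_code = anchor, endpoint_code = endpoint)
}

# ---- flattening -------------------------------------------------------------

#' Flatten a cohort to a one-row-per-patient feature table
#'
#' The tabular substrate all column-wise metrics operate on. Per patient:
#' `sex` (categorical), `age_at_diabetes` (age at the first visit carrying the
#' anchor code; `NA` when absent), and for each vocabulary code other than the
#' anchor a presence flag `flag_<code>` (boolean) plus `age_<code>`, the age of
#' the first visit containing the code (`NA` when the flag is `FALSE`), and
#' `visit_count` (continuous). The column schema (continuous / categorical /
#' boolean per column) is attached as attribute `"schema"`.
#'
#' @param x an `ehr_cohort`.
#' @param include_ages if `FALSE`, the per-comorbidity age columns are dropped
#'   (flags-only substrate).
#' @return a `data.frame` of class `patient_feature_table`.
#' @export
flatten <- function(x, include_ages = TRUE) {
  stopifnot(inherits(x, "ehr_cohort"))
  n <- length(x$records)
  codes <- setdiff(x$vocabulary, x$anchor_code)
  long <- cohort_long(x)                       # patient row, visit idx, age, code
  sex <- vapply(x$records, `[[`, "", "sex")
  visit_count <- vapply(x$records, function(r) length(r$visits), 0L)
  out <- data.frame(sex = sex, age_at_diabetes = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(long)) {
    first <- long[, .(age = age[which.min(vidx)]), by = .(row, code)]
    adm <- first[code == x$anchor_code]
    out$age_at_diabetes[adm$row] <- adm$age
  } else first <- data.table::data.table(row = integer(), code = character(),
                                         age = numeric())
  for (cd in codes) {
    f <- rep(FALSE, n); a <- rep(NA_real_, n)
    hit <- first[code == cd]
    if (nrow(hit)) { f[hit$row] <- TRUE; a[hit$row] <- hit$age }
    out[[paste0("flag_", cd)]] <- f
    if (include_ages) out[[paste0("age_", cd)]] <- a
  }
  out$visit_count <- as.numeric(visit_count)
  schema <- c(sex = "categorical", age_at_diabetes = "continuous",
              stats::setNames(rep("boolean", length(codes)), paste0("flag_", codes)))
  if (include_ages)
    schema <- c(schema, stats::setNames(rep("continuous", length(codes)),
                                        paste0("age_", codes)))
  schema <- c(schema, visit_count = "continuous")
  out <- out[, names(schema)]
  attr(out, "schema") <- schema
  class(out) <- c("patient_feature_table", "data.frame")
  out
}

# long view: one row per (patient, visit, code), with visit index and age
cohort_long <- function(x) {
  recs <- x$records
  rows <- lapply(seq_along(recs), function(i) {
    vs <- recs[[i]]$visits
    if (!length(vs)) return(NULL)
    k <- lengths(lapply(vs, `[[`, "codes"))
    if (sum(k) == 0L) return(NULL)
    data.table::data.table(
      row = i,
      vidx = rep(seq_along(vs), k),
      age = rep(vapply(vs, `[[`, 0.0, "age"), k),
      code = unlist(lapply(vs, `[[`, "codes"), use.names = FALSE))
  })
  out <- data.table::rbindlist(rows)
  if (!nrow(out))
    out <- data.table::data.table(row = integer(), vidx = integer(),
                                  age = numeric(), code = character())
  out
}

#' Column schema of a feature table
#' @param x a `patient_feature_table`.
#' @return named character vector mapping column name to
#'   `continuous|categorical|boolean`.
#' @export
table_schema <- function(x) {
  s <- attr(x, "schema")
  if (is.null(s)) stop("no schema attached; build the table with flatten()")
  s
}

#' Export a feature table as CSV plus a sidecar schema file
#' @param x a `patient_feature_table`.
#' @param path CSV output path; schema is written to `<path>.schema.csv`.
#' @export
write_feature_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  s <- table_schema(x)
  utils::write.csv(data.frame(column = names(s), type = unname(s)),
                   paste0(path, ".schema.csv"), row.names = FALSE)
  invisible(path)
}

# structural equality used by round-trip tests
cohorts_equal <- function(a, b) {
  if (length(a$records) != length(b$records)) return(FALSE)
  if (!identical(sort(a$vocabulary), sort(b$vocabulary))) return(FALSE)
  for (i in seq_along(a$records)) {
    ra <- a$records[[i]]; rb <- b$records[[i]]
    if (!identical(ra$id, rb$id) || !identical(ra$sex, rb$sex)) return(FALSE)
    if (!identical(ra$diagnosis_year, rb$diagnosis_year)) return(FALSE)
    if (length(ra$visits) != length(rb$visits)) return(FALSE)
    for (j in seq_along(ra$visits)) {
      va <- ra$visits[[j]]; vb <- rb$visits[[j]]
      ok_age <- (is.na(va$age) && is.na(vb$age)) ||
        (!is.na(va$age) && !is.na(vb$age) && isTRUE(all.equal(va$age, vb$age)))
      if (!ok_age || !setequal(va$codes, vb$codes)) return(FALSE)
    }
  }
  TRUE
}
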