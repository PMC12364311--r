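# shared argument plumbing for the extract_* family: resolve the codelist,
# query the store, and optionally save/return the per-patient variable table.
finalize_variable <- function(result, varname, t, out_save_disk, out_filepath,
                              return_output, root) {
  if (out_save_disk || !is.null(out_filepath)) {
    save_variable(result, varname = varname, t = t,
                  out_filepath = out_filepath, root = root)
  }
  if (return_output) result[] else invisible(NULL)
}

#' Extract a history-of variable
#'
#' Binary flag per cohort patient: 1 if the patient has at least one record
#' matching the codelist dated on or before `indexdt + t`, 0 otherwise.
#' Works for medical history (observation table, medcodeid codelists) and
#' prescription history (drugissue table, prodcodeid codelists) alike.
#'
#' @param cohort Table with `patid` and `indexdt` columns.
#' @param codelist,codelist_vector,codelist_df Codelist, by name / vector /
#'   data frame (see [resolve_codelist()]).
#' @param db,db_filepath,store Store, by name / path / open handle
#'   (see [resolve_store()]).
#' @param tab Store table to query (default `"observation"`; use
#'   `"drugissue"` for prescriptions).
#' @param t Offset in days added to each index date (longitudinal
#'   extraction; default 0).
#' @param varname Name of the output flag column (default `"ho"`).
#' @param out_save_disk Save the variable under `data/extraction/`
#'   (see [save_variable()]).
#' @param out_filepath Explicit output path (implies saving).
#' @param return_output Return the table (default `TRUE`).
#' @param root Workspace root.
#'
#' @return A `data.table` with one row per cohort patient: `patid` and the
#'   0/1 flag column, in cohort row order.
#' @export
extract_ho <- function(cohort, codelist = NULL, codelist_vector = NULL,
                       codelist_df = NULL, db = NULL, db_filepath = NULL,
                       store = NULL, tab = "observation", t = 0,
                       varname = "ho", out_save_disk = FALSE,
                       out_filepath = NULL, return_output = TRUE, root = ".") {
  cohort <- as.data.table(cohort)
  q <- db_query(codelist, db = db, db_filepath = db_filepath, store = store,
                tab = tab, codelist_vector = codelist_vector,
                codelist_df = codelist_df, root = root)
  qtype <- if (table_code_column(tab) == "prodcodeid") "drug" else "med"
  flagv <- combine_query_boolean(cohort, q, query_type = qtype,
                                 time_prev = Inf, time_post = 0, t = t)
  out <- data.table(patid = cohort$patid, v = flagv)
  setnames(out, "v", varname)
  finalize_variable(out, varname, t, out_save_disk, out_filepath,
                    return_output, root)
}

#' Extract a time-to-event variable
#'
#' For each cohort patient, the time from `indexdt + t` until the first
#' matching record strictly after that date, or until censoring. Two output
#' columns: `<varname>_time` (days) and `<varname>_indicator` (1 = event
#' observed on or before `censdt`, 0 = censored). Events dated exactly on
#' the offset index date do not count (survival times are strictly
#' positive); events after `censdt` are ignored.
#'
#' @inheritParams extract_ho
#' @param cohort Must also contain a `censdt` column with
#'   `censdt >= indexdt` for every patient.
#' @param varname Stem of the output column names (default `"event"`).
#'
#' @return A `data.table`: `patid`, `<varname>_time`, `<varname>_indicator`,
#'   one row per cohort patient.
#' @export
extract_time_until <- function(cohort, codelist = NULL, codelist_vector = NULL,
                               codelist_df = NULL, db = NULL,
                               db_filepath = NULL, store = NULL,
                               tab = "observation", t = 0,
                               varname = "event", out_save_disk = FALSE,
                               out_filepath = NULL, return_output = TRUE,
                               root = ".") {
  cohort <- as.data.table(cohort)
  if (!"censdt" %in% names(cohort)) {
    stop("cohort must contain a censdt column for time-until extraction",
         call. = FALSE)
  }
  if (anyNA(cohort$censdt)) {
    stop(sprintf("missing censdt for patid(s): %s",
                 paste(cohort$patid[is.na(cohort$censdt)], collapse = ", ")),
         call. = FALSE)
  }
  q <- db_query(codelist, db = db, db_filepath = db_filepath, store = store,
                tab = tab, codelist_vector = codelist_vector,
                codelist_df = codelist_df, root = root)
  qtype <- if (table_code_column(tab) == "prodcodeid") "drug" else "med"
  dcol <- query_date_column(qtype)

  anchor <- cohort$indexdt + t
  q <- as.data.table(q)
  q[, .aurumehr_date := as.Date(q[[dcol]])]
  first_after <- merge(
    q[!is.na(.aurumehr_date), .(patid, .aurumehr_date)],
    data.table(patid = cohort$patid, anchor = anchor),
    by = "patid")[.aurumehr_date > anchor,
                  .(event_date = min(.aurumehr_date)), by = patid]

  out <- data.table(patid = cohort$patid, anchor = anchor,
                    censdt = as.Date(cohort$censdt))
  out <- merge(out, first_after, by = "patid", all.x = TRUE, sort = FALSE)
  event <- !is.na(out$event_date) & out$event_date <= out$censdt
  time <- ifelse(event, as.integer(out$event_date - out$anchor),
                 as.integer(out$censdt - out$anchor))
  res <- data.table(patid = out$patid, time = as.integer(time),
                    indicator = as.integer(event))
  setnames(res, c("time", "indicator"),
           paste0(varname, c("_time", "_indicator")))
  res <- res[match(cohort$patid, res$patid)]
  finalize_variable(res, varname, t, out_save_disk, out_filepath,
                    return_output, root)
}

#' Extract most recent valid test result(s)
#'
#' Most recent `numobs` test values per patient inside the window
#' `[indexdt + t - time_prev, indexdt + t + time_post]`, restricted to
#' values in `[lower_bound, upper_bound]`; rows with missing values are
#' dropped by default.
#'
#' @inheritParams extract_ho
#' @inheritParams combine_query
#' @param numunitid If `TRUE`, keep the metadata columns (`obsdate`,
#'   `medcodeid`, `numunitid`) alongside the value.
#' @param varname Name of the value column (default `"test"`).
#'
#' @return A `data.table` with up to `numobs` rows per patient; patients
#'   with no valid in-window result are absent.
#' @export
extract_test_data <- function(cohort, codelist = NULL, codelist_vector = NULL,
                              codelist_df = NULL, db = NULL,
                              db_filepath = NULL, store = NULL,
                              tab = "observation", time_prev = Inf,
                              time_post = 0, lower_bound = -Inf,
                              upper_bound = Inf, numobs = 1L,
                              value_na_rm = TRUE, numunitid = FALSE, t = 0,
                              varname = "test", out_save_disk = FALSE,
                              out_filepath = NULL, return_output = TRUE,
                              root = ".") {
  cohort <- as.data.table(cohort)
  q <- db_query(codelist, db = db, db_filepath = db_filepath, store = store,
                tab = tab, codelist_vector = codelist_vector,
                codelist_df = codelist_df, root = root)
  out <- combine_query(cohort, q, query_type = "test", time_prev = time_prev,
                       time_post = time_post, lower_bound = lower_bound,
                       upper_bound = upper_bound, numobs = numobs,
                       value_na_rm = value_na_rm, reduce_output = TRUE, t = t)
  if (!numunitid) {
    out <- out[, intersect(c("patid", "value"), names(out)), with = FALSE]
  }
  setnames(out, "value", varname)
  finalize_variable(out, varname, t, out_save_disk, out_filepath,
                    return_output, root)
}

#' Extract the variability of test results
#'
#' Sample standard deviation (divisor n - 1) of all valid in-window,
#' in-bounds test values per patient; `NA` when a patient has fewer than two
#' such values.
#'
#' @inheritParams extract_test_data
#' @param varname Name of the output column (default `"test_var"`).
#'
#' @return A `data.table` with one row per cohort patient: `patid` and the
#'   standard-deviation column.
#' @export
extract_test_data_var <- function(cohort, codelist = NULL,
                                  codelist_vector = NULL, codelist_df = NULL,
                                  db = NULL, db_filepath = NULL, store = NULL,
                                  tab = "observation", time_prev = Inf,
                                  time_post = 0, lower_bound = -Inf,
                                  upper_bound = Inf, t = 0,
                                  varname = "test_var", out_save_disk = FALSE,
                                  out_filepath = NULL, return_output = TRUE,
                                  root = ".") {
  cohort <- as.data.table(cohort)
  q <- db_query(codelist, db = db, db_filepath = db_filepath, store = store,
                tab = tab, codelist_vector = codelist_vector,
                codelist_df = codelist_df, root = root)
  vals <- combine_query(cohort, q, query_type = "test", time_prev = time_prev,
                        time_post = time_post, lower_bound = lower_bound,
                        upper_bound = upper_bound, numobs = .Machine$integer.max,
                        value_na_rm = TRUE, reduce_output = TRUE, t = t)
  sds <- vals[, .(v = if (.N >= 2L) sd(value) else NA_real_), by = patid]
  out <- data.table(patid = cohort$patid)
  out <- merge(out, sds, by = "patid", all.x = TRUE, sort = FALSE)
  out <- out[match(cohort$patid, out$patid)]
  setnames(out, "v", varname)
  finalize_variable(out, varname, t, out_save_disk, out_filepath,
                    return_output, root)
}
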