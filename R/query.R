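#' Load or construct a codelist
#'
#' A codelist is a set of codes denoting one clinical concept. It can be
#' given as a bare character vector of codes, as a data frame with a
#' `medcodeid`, `prodcodeid` or `ICD10` column (extra columns are treated as
#' annotations and propagated through queries), or by name — a CSV stored at
#' `codelists/analysis/<name>.csv` under the workspace root. Precedence when
#' several are given: `codelist_vector` > `codelist_df` > `codelist`.
#'
#' @param codelist Name of a CSV codelist under `codelists/analysis/`
#'   (without the `.csv` suffix).
#' @param codelist_vector Character vector of codes.
#' @param codelist_df Data frame with a code column.
#' @param code_kind Which code column the list is keyed on:
#'   `"medcodeid"`, `"prodcodeid"` or `"ICD10"`. For vectors this names the
#'   resulting column; for data frames/CSVs the stated column must exist
#'   unless exactly one of the three is present already.
#' @param root Workspace root (default `"."`).
#'
#' @return A `data.table` whose first column is the code column.
#' @export
resolve_codelist <- function(codelist = NULL, codelist_vector = NULL,
                             codelist_df = NULL, code_kind = "medcodeid",
                             root = ".") {
  stopifnot(code_kind %in% c("medcodeid", "prodcodeid", "ICD10"))
  if (!is.null(codelist_vector)) {
    out <- data.table(code = as.character(codelist_vector))
    setnames(out, "code", code_kind)
    return(out)
  }
  if (!is.null(codelist_df)) {
    out <- as.data.table(codelist_df)
  } else if (!is.null(codelist)) {
    path <- file.path(root, "codelists", "analysis", paste0(codelist, ".csv"))
    if (!file.exists(path)) {
      stop(sprintf("codelist file not found: %s", path), call. = FALSE)
    }
    out <- fread(path, colClasses = list(
      character = intersect(c("medcodeid", "prodcodeid", "ICD10"),
                            names(fread(path, nrows = 0L)))))
  } else {
    stop("no codelist given: supply codelist, codelist_vector or codelist_df",
         call. = FALSE)
  }
  present <- intersect(c("medcodeid", "prodcodeid", "ICD10"), names(out))
  if (!code_kind %in% present) {
    if (length(present) == 1L) {
      code_kind <- present
    } else {
      stop(sprintf("codelist must contain a %s column", code_kind), call. = FALSE)
    }
  }
  data.table::set(out, j = code_kind, value = as.character(out[[code_kind]]))
  if (any(!nzchar(out[[code_kind]]) | is.na(out[[code_kind]]))) {
    stop("codelist contains empty codes", call. = FALSE)
  }
  setcolorder(out, code_kind)
  out[]
}

# which code column keys a given store table
table_code_column <- function(tab) {
  if (grepl("drugissue|drug_issue", tab, ignore.case = TRUE)) return("prodcodeid")
  if (grepl("hes_primary", tab, ignore.case = TRUE)) return("ICD10")
  "medcodeid"
}

table_date_column <- function(tab) {
  if (grepl("drugissue|drug_issue", tab, ignore.case = TRUE)) return("issuedate")
  if (grepl("hes_primary", tab, ignore.case = TRUE)) return("admidate")
  "obsdate"
}

#' Query a store table for codelist matches
#'
#' Returns every row of a store table whose code column (`medcodeid` for
#' observation-like tables, `prodcodeid` for drugissue, `ICD10` for
#' hes_primary) is in the codelist. When the codelist carries annotation
#' columns (e.g. condition or subgroup), they are joined onto the result by
#' code. Date columns come back parsed as `Date`.
#'
#' @inheritParams resolve_codelist
#' @param db Store name under `data/sql/` (see [resolve_store()]).
#' @param db_filepath Explicit path to a store file.
#' @param store An already-open store handle (left open on return).
#' @param tab Table to query (default `"observation"`).
#' @param rm_duplicates If `TRUE`, exact-duplicate rows are dropped from the
#'   result.
#'
#' @return A `data.table` of matching records (plus annotation columns).
#' @export
db_query <- function(codelist = NULL, db = NULL, db_filepath = NULL,
                     store = NULL, tab = "observation",
                     codelist_vector = NULL, codelist_df = NULL,
                     rm_duplicates = FALSE, root = ".") {
  code_col <- table_code_column(tab)
  cl <- resolve_codelist(codelist, codelist_vector, codelist_df,
                         code_kind = code_col, root = root)
  if (!code_col %in% names(cl)) {
    stop(sprintf("codelist kind %s is incompatible with table '%s' (needs %s)",
                 names(cl)[1], tab, code_col), call. = FALSE)
  }
  with_store(db = db, db_filepath = db_filepath, store = store, root = root,
             function(handle) {
    con <- store_con(handle)
    if (!DBI::dbExistsTable(con, tab)) {
      stop(sprintf("table '%s' not found in store", tab), call. = FALSE)
    }
    codes <- unique(cl[[code_col]])
    res <- list()
    for (i in seq(1L, length(codes), by = 500L)) {   # keep IN() clauses bounded
      chunk <- codes[i:min(i + 499L, length(codes))]
      sql <- sprintf('SELECT * FROM "%s" WHERE "%s" IN (%s)', tab, code_col,
                     paste(rep("?", length(chunk)), collapse = ","))
      res[[length(res) + 1L]] <- as.data.table(
        DBI::dbGetQuery(con, sql, params = as.list(chunk)))
    }
    out <- rbindlist(res)
    if (nrow(out) == 0L && length(res) > 0L) out <- res[[1L]]
    if (rm_duplicates) out <- unique(out)
    dcol <- intersect(table_date_column(tab), names(out))
    for (col in dcol) {
      data.table::set(out, j = col, value = as.Date(out[[col]]))
    }
    ann <- setdiff(names(cl), code_col)
    if (length(ann) > 0L) {
      out <- merge(out, cl, by = code_col, all.x = TRUE, sort = FALSE,
                   allow.cartesian = TRUE)
    }
    out[]
  })
}

# event-date column of a query result, by query type
query_date_column <- function(query_type) {
  switch(query_type, drug = "issuedate", "obsdate")
}

#' Merge a query with a cohort inside an index-date window
#'
#' For each cohort patient, keeps query rows whose event date falls in the
#' closed window `[indexdt + t - time_prev, indexdt + t + time_post]`, then
#' returns the most recent `numobs` rows per patient (event date descending;
#' date ties broken by higher value for test queries, stable input order
#' otherwise). For `query_type = "test"`, rows with missing values are
#' dropped when `value_na_rm` and values outside `[lower_bound, upper_bound]`
#' are always dropped.
#'
#' @param cohort Table with `patid` and `indexdt` columns.
#' @param query A [db_query()] result.
#' @param query_type `"med"`, `"test"` or `"drug"`; selects the event-date
#'   column (`obsdate` vs `issuedate`) and which columns a reduced output
#'   keeps.
#' @param time_prev Days before the (offset) index date the window extends
#'   (default `Inf`: unbounded history).
#' @param time_post Days after it (default 0).
#' @param lower_bound,upper_bound Valid range for test values.
#' @param numobs Maximum rows returned per patient (default 1).
#' @param value_na_rm Drop test rows with missing value (default `TRUE`).
#' @param reduce_output If `TRUE` (default), trim to `patid`, event date and
#'   code — plus `value` and `numunitid` for tests.
#' @param t Offset in days added to every index date, for longitudinal
#'   extraction at fixed intervals after baseline (default 0).
#'
#' @return A `data.table`; patients with no qualifying rows are absent.
#' @export
combine_query <- function(cohort, query, query_type = c("med", "test", "drug"),
                          time_prev = Inf, time_post = 0,
                          lower_bound = -Inf, upper_bound = Inf,
                          numobs = 1L, value_na_rm = TRUE,
                          reduce_output = TRUE, t = 0) {
  query_type <- match.arg(query_type)
  if (time_prev < 0 || time_post < 0) {
    stop("time_prev and time_post must be non-negative", call. = FALSE)
  }
  cohort <- as.data.table(cohort)
  if (!"indexdt" %in% names(cohort)) {
    stop("cohort must contain an indexdt column", call. = FALSE)
  }
  query <- as.data.table(query)
  dcol <- query_date_column(query_type)
  if (!dcol %in% names(query)) {
    stop(sprintf("query lacks event-date column '%s'", dcol), call. = FALSE)
  }

  m <- merge(query, cohort[, .(patid, indexdt)], by = "patid", sort = FALSE)
  m[, .aurumehr_date := as.Date(m[[dcol]])]
  anchor <- m$indexdt + t
  keep <- !is.na(m$.aurumehr_date) &
    (is.infinite(time_prev) | m$.aurumehr_date >= anchor - time_prev) &
    (is.infinite(time_post) | m$.aurumehr_date <= anchor + time_post)
  m <- m[keep]
  if (query_type == "test") {
    if (value_na_rm) m <- m[!is.na(value)]
    m <- m[is.na(value) | (value >= lower_bound & value <= upper_bound)]
  }
  # most recent first; for tests equal dates break toward the higher value
  m[, .aurumehr_ord := seq_len(.N)]
  if (query_type == "test") {
    setorderv(m, c("patid", ".aurumehr_date", "value", ".aurumehr_ord"),
              order = c(1L, -1L, -1L, 1L))
  } else {
    setorderv(m, c("patid", ".aurumehr_date", ".aurumehr_ord"),
              order = c(1L, -1L, 1L))
  }
  m <- m[, head(.SD, numobs), by = patid]
  m[, c(".aurumehr_date", ".aurumehr_ord") := NULL]
  if (reduce_output) {
    keep_cols <- switch(query_type,
      med  = c("patid", dcol, "medcodeid"),
      drug = c("patid", dcol, "prodcodeid"),
      test = c("patid", dcol, "medcodeid", "value", "numunitid"))
    m <- m[, intersect(keep_cols, names(m)), with = FALSE]
  }
  m[patid_order(m$patid)]
}

#' Flag cohort patients with a record in an index-date window
#'
#' @inheritParams combine_query
#' @param query_type Selects the event-date column, as in [combine_query()].
#'
#' @return An integer 0/1 vector aligned with the rows of `cohort`: 1 iff
#'   the patient has at least one query row in the closed window
#'   `[indexdt + t - time_prev, indexdt + t + time_post]`. Patients absent
#'   from the query get 0.
#' @export
combine_query_boolean <- function(cohort, query, query_type = c("med", "test", "drug"),
                                  time_prev = Inf, time_post = 0, t = 0) {
  query_type <- match.arg(query_type)
  hits <- combine_query(cohort, query, query_type = query_type,
                        time_prev = time_prev, time_post = time_post,
                        numobs = 1L, value_na_rm = FALSE,
                        reduce_output = TRUE, t = t)
  as.integer(as.data.table(cohort)$patid %chin% hits$patid)
}

#' Brute-force history flags from the raw files
#'
#' The independent oracle for history-of extraction: never touches the
#' store. Loops over every raw observation file in a directory; for each,
#' parses `obsdate`, subsets to the codelist, merges with the cohort and
#' drops records after the index date; any surviving record flags the
#' patient. The same on-or-before-index convention is applied as in the
#' store-backed path, so the two are comparable record for record.
#'
#' @param raw_dir Directory of raw files.
#' @param cohort Table with `patid` and `indexdt`.
#' @param codelist_vector Character vector of medcodeids.
#' @param delimiter,date_format Passed to [read_raw_file()].
#'
#' @return Integer 0/1 vector aligned with the rows of `cohort`.
#' @export
brute_force_history <- function(raw_dir, cohort, codelist_vector,
                                delimiter = "\t", date_format = "dmy") {
  cohort <- as.data.table(cohort)
  stopifnot(all(c("patid", "indexdt") %in% names(cohort)))
  fns <- list.files(raw_dir, pattern = "observation", ignore.case = TRUE)
  fns <- fns[grepl("\\.txt$", fns, ignore.case = TRUE)]
  if (length(fns) == 0L) {
    stop(sprintf("no raw observation files in %s", raw_dir), call. = FALSE)
  }
  status <- rep(0L, nrow(cohort))                                   # step 1
  names(status) <- cohort$patid
  for (fn in sort(fns)) {
    obs <- read_raw_file(file.path(raw_dir, fn), "observation",     # step 2
                         delimiter = delimiter, date_format = date_format)
    obs <- obs[medcodeid %chin% codelist_vector]                    # step 3
    m <- merge(obs, cohort[, .(patid, indexdt)], by = "patid")      # step 4
    m <- m[!is.na(obsdate) & obsdate <= indexdt]
    status[unique(m$patid)] <- 1L                                   # step 5
  }
  unname(status)
}

#' @importFrom data.table setcolorder
NULL
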