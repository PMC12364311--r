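#' Build a cohort table from raw patient files
#'
#' Scans a directory for any file whose name contains `patient`
#' (case-insensitive), reads each with the patient-file reader and
#' concatenates them. A cohort is ultimately a set of patient IDs plus the
#' per-patient dates needed downstream; inclusion/exclusion criteria beyond
#' an ID subset are ordinary table filtering and are left to the caller.
#'
#' @param filepath Directory containing the raw patient files.
#' @param patids Optional character vector of patient IDs; when given, only
#'   those rows are returned.
#' @param set If `TRUE`, adds a `set` column parsed from each source
#'   filename, as needed for the set-aware ingest fast path
#'   (see [add_to_database()]).
#' @param delimiter,date_format Passed to [read_raw_file()].
#'
#' @return A `data.table` of patient rows, sorted by patid (numeric-aware),
#'   so the result does not depend on file read order. Duplicate patids
#'   across files are an error.
#' @export
extract_cohort <- function(filepath, patids = NULL, set = FALSE,
                           delimiter = "\t", date_format = "dmy") {
  if (!dir.exists(filepath)) {
    stop(sprintf("directory not found: %s", filepath), call. = FALSE)
  }
  fns <- list.files(filepath, pattern = "patient", ignore.case = TRUE)
  fns <- fns[grepl("\\.txt$", fns, ignore.case = TRUE)]
  if (length(fns) == 0L) {
    stop(sprintf("no patient files found in %s", filepath), call. = FALSE)
  }
  parts <- lapply(sort(fns), function(fn) {
    dt <- read_raw_file(file.path(filepath, fn), "patient",
                        delimiter = delimiter, date_format = date_format)
    if (set) dt[, set := parse_filename(fn)$set_number]
    dt
  })
  out <- rbindlist(parts, use.names = TRUE, fill = TRUE)
  dups <- out$patid[duplicated(out$patid)]
  if (length(dups) > 0L) {
    stop(sprintf("duplicate patid(s) across patient files: %s",
                 paste(unique(dups), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(patids)) out <- out[patid %chin% as.character(patids)]
  out[patid_order(out$patid)]
}

#' Assign index dates to a patient table
#'
#' Every downstream variable is computed relative to a per-patient index
#' date. The index date may be a fixed calendar date, a per-patient date
#' column, or the elementwise maximum of the two (e.g. the later of
#' 2010-01-01 and the date a patient turned 50).
#'
#' @param pat Patient table (as from [extract_cohort()]).
#' @param fixed_date Optional fixed `Date` (or text parseable as one).
#' @param date_col Optional name of a date column in `pat`.
#'
#' @return `pat` with an `indexdt` column: the fixed date if only
#'   `fixed_date` is given; the column if only `date_col` is given; their
#'   elementwise maximum if both are. A missing value in `date_col` is an
#'   error (the affected patids are listed) — an undefined index date cannot
#'   silently propagate.
#' @export
assign_index_dates <- function(pat, fixed_date = NULL, date_col = NULL) {
  pat <- as.data.table(pat)
  if (is.null(fixed_date) && is.null(date_col)) {
    stop("supply fixed_date, date_col, or both", call. = FALSE)
  }
  if (!is.null(date_col)) {
    if (!date_col %in% names(pat)) {
      stop(sprintf("column '%s' not found", date_col), call. = FALSE)
    }
    col <- as.Date(pat[[date_col]])
    if (anyNA(col)) {
      stop(sprintf("missing %s for patid(s): %s", date_col,
                   paste(pat$patid[is.na(col)], collapse = ", ")), call. = FALSE)
    }
  }
  out <- copy(pat)
  if (is.null(date_col)) {
    out[, indexdt := as.Date(fixed_date)]
  } else if (is.null(fixed_date)) {
    out[, indexdt := as.Date(out[[date_col]])]
  } else {
    out[, indexdt := pmax(as.Date(fixed_date), as.Date(out[[date_col]]))]
  }
  out[]
}
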