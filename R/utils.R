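#' @importFrom data.table data.table as.data.table setDT setDF fread fwrite
#'   rbindlist setorder setorderv setnames copy %chin% :=
#' @importFrom stats rbinom rpois runif sd
#' @importFrom utils head
NULL

# data.table NSE variables
utils::globalVariables(c(
  ".", ".N", ".SD", "patid", "medcodeid", "prodcodeid", "obsdate", "issuedate",
  "value", "numunitid", "indexdt", "censdt", "set", "flag", "code",
  ".aurumehr_date", ".aurumehr_ord", "category", "anchor", "event_date",
  "wt_value", "wt_date", "ht_value", "ht_date", "chol_value", "chol_date",
  "hdl_value", "hdl_date", "derived_value", "derived_date",
  "direct_value", "direct_date", "h1", "h2"
))

#' Parse date text as dd/mm/yyyy or ISO-8601
#'
#' Raw Aurum-style extracts carry dates as text, conventionally `dd/mm/yyyy`
#' (UK source system); ISO `yyyy-mm-dd` is also accepted. Cells that parse
#' under neither convention become `NA` and are counted in a single warning
#' rather than raising an error, so one bad cell cannot abort a bulk ingest.
#'
#' @param x Character vector of date text (or `Date`, returned unchanged).
#' @param date_format Preferred format for ambiguous text: `"dmy"` (default)
#'   or `"ymd"`.
#' @param context Label used in the warning when cells fail to parse.
#'
#' @return A `Date` vector the same length as `x`.
#' @export
#'
#' @examples
#' parse_ehr_date(c("01/06/1995", "1995-06-01", "not-a-date"))
parse_ehr_date <- function(x, date_format = "dmy", context = "date") {
  if (inherits(x, "Date")) return(x)
  if (is.numeric(x)) x <- as.character(x)
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  blank <- is.na(x) | !nzchar(trimws(x))
  todo <- !blank
  if (any(todo)) {
    fmts <- if (identical(date_format, "dmy")) {
      c("%d/%m/%Y", "%Y-%m-%d")
    } else {
      c("%Y-%m-%d", "%d/%m/%Y")
    }
    for (fmt in fmts) {
      if (!any(todo)) break
      parsed <- as.Date(x[todo], format = fmt)
      ok <- !is.na(parsed)
      out[which(todo)[ok]] <- parsed[ok]
      todo[which(todo)[ok]] <- FALSE
    }
  }
  n_bad <- sum(todo)
  if (n_bad > 0L) {
    warning(sprintf("%d %s value(s) could not be parsed and were set to NA",
                    n_bad, context), call. = FALSE)
  }
  out
}

# numeric-aware ordering of text patids: "10" sorts after "2"
patid_order <- function(patid) {
  num <- suppressWarnings(as.numeric(patid))
  if (anyNA(num)) order(patid) else order(num, patid)
}

# Dates -> ISO text so they sort lexicographically == chronologically in SQLite
dates_to_iso <- function(dt) {
  for (col in names(dt)) {
    if (inherits(dt[[col]], "Date")) {
      data.table::set(dt, j = col, value = format(dt[[col]], "%Y-%m-%d"))
    }
  }
  dt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
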