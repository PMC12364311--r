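# Helpers shared across test files. Fixtures are always built in code at
# test time; nothing binary is stored in the repository.

# A store whose tables are given directly as data frames (dates become
# ISO text, as the ingest path stores them). Caller closes the handle.
store_with <- function(...) {
  tabs <- list(...)
  path <- tempfile(fileext = ".sqlite")
  h <- connect_database(path)
  for (nm in names(tabs)) {
    dt <- data.table::as.data.table(tabs[[nm]])
    for (col in names(dt)) {
      if (inherits(dt[[col]], "Date")) {
        data.table::set(dt, j = col, value = format(dt[[col]], "%Y-%m-%d"))
      }
    }
    DBI::dbWriteTable(h$con, nm, dt, overwrite = TRUE)
  }
  h
}

# minimal observation rows
obs_rows <- function(patid, medcodeid, obsdate, value = NA_real_,
                     numunitid = NA_character_) {
  data.table::data.table(patid = as.character(patid),
                         medcodeid = as.character(medcodeid),
                         obsdate = as.Date(obsdate),
                         value = as.numeric(value),
                         numunitid = as.character(numunitid))
}

cohort_rows <- function(patid, indexdt, censdt = NULL) {
  out <- data.table::data.table(patid = as.character(patid),
                                indexdt = as.Date(indexdt))
  if (!is.null(censdt)) out$censdt <- as.Date(censdt)
  out
}

# independent brute-force filter for windowed test queries: plain loops,
# shared by unit and acceptance tests as the oracle for combine_query
oracle_window_values <- function(obs, cohort, codes, time_prev, time_post,
                                 lower, upper, numobs) {
  out <- list()
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patid[i]
    idx <- cohort$indexdt[i]
    rows <- obs[obs$patid == pid & obs$medcodeid %in% codes, ]
    keep <- !is.na(rows$obsdate) &
      rows$obsdate >= idx - time_prev & rows$obsdate <= idx + time_post &
      !is.na(rows$value) & rows$value >= lower & rows$value <= upper
    rows <- rows[keep, ]
    if (nrow(rows) == 0) next
    ord <- order(-as.numeric(rows$obsdate), -rows$value)
    rows <- rows[ord, ][seq_len(min(numobs, nrow(rows))), ]
    out[[length(out) + 1]] <- data.frame(patid = pid, value = rows$value)
  }
  if (length(out) == 0) return(data.frame(patid = character(0), value = numeric(0)))
  do.call(rbind, out)
}

# two-pass sample standard deviation, kept independent of stats::sd
oracle_two_pass_sd <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) return(NA_real_)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}

read_table_df <- function(handle, tab) {
  DBI::dbReadTable(handle$con, tab)
}
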