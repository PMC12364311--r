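#' Connect to an on-disk SQLite store
#'
#' The store is a single-file SQLite database holding one table per ingested
#' file type (observation, drugissue, linked files, ...). Queries against it
#' replace reading thousands of raw text files into memory.
#'
#' @param db_path Path of the database file; created if absent. The parent
#'   directory must already exist.
#'
#' @return A store handle (class `aurum_store`). Operations on a closed
#'   handle fail cleanly.
#' @seealso [close_database()], [add_to_database()], [cprd_extract()]
#' @export
connect_database <- function(db_path) {
  if (!dir.exists(dirname(db_path))) {
    stop(sprintf("parent directory does not exist: %s", dirname(db_path)),
         call. = FALSE)
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  h <- new.env(parent = emptyenv())
  h$con <- con
  h$db_path <- db_path
  h$open <- TRUE
  class(h) <- "aurum_store"
  h
}

#' Close a store handle
#'
#' Closing an already-closed handle is a no-op.
#' @param handle A store handle from [connect_database()].
#' @return Invisibly `NULL`.
#' @export
close_database <- function(handle) {
  stopifnot(inherits(handle, "aurum_store"))
  if (isTRUE(handle$open)) {
    DBI::dbDisconnect(handle$con)
    handle$open <- FALSE
  }
  invisible(NULL)
}

store_con <- function(handle) {
  if (!inherits(handle, "aurum_store")) stop("not a store handle", call. = FALSE)
  if (!isTRUE(handle$open)) stop("store handle is closed", call. = FALSE)
  handle$con
}

#' @export
print.aurum_store <- function(x, ...) {
  cat(sprintf("<aurum_store> %s (%s)\n", x$db_path,
              if (isTRUE(x$open)) "open" else "closed"))
  if (isTRUE(x$open)) {
    cat("tables:", paste(list_tables(x), collapse = ", "), "\n")
  }
  invisible(x)
}

#' List the tables in a store
#' @param handle A store handle.
#' @return Character vector of table names.
#' @export
list_tables <- function(handle) {
  DBI::dbListTables(store_con(handle))
}

# normalize a subset spec: NULL, character vector of patids, or
# data.frame(patid, set). Returns NULL or a list(kind=, ids=|pairs=).
normalize_subset <- function(subset_patids) {
  if (is.null(subset_patids)) return(NULL)
  if (is.data.frame(subset_patids)) {
    if (!all(c("patid", "set") %in% names(subset_patids))) {
      stop("pair-form subset_patids needs columns patid and set", call. = FALSE)
    }
    pairs <- as.data.table(subset_patids)[, .(patid = as.character(patid),
                                              set = as.integer(set))]
    if (anyDuplicated(pairs$patid)) {
      stop("each patid must map to exactly one set in subset_patids", call. = FALSE)
    }
    return(list(kind = "pairs", pairs = pairs))
  }
  list(kind = "ids", ids = as.character(subset_patids))
}

subset_ids_for_file <- function(spec, filename) {
  if (is.null(spec)) return(NULL)
  if (spec$kind == "ids") return(spec$ids)
  # set fast path: only patids whose set matches the file's set token
  s <- parse_filename(filename)$set_number
  spec$pairs[set == s, patid]
}

#' Add one raw file to the store
#'
#' Reads a single raw `.txt` file (in chunks, so files larger than memory
#' are supported), keeps only rows whose `patid` is in the cohort subset,
#' and writes them to the target table. Dates are stored as ISO-8601 text,
#' which sorts lexicographically in date order inside SQLite.
#'
#' When `subset_patids` is a data frame with columns `patid` and `set`, the
#' file's `setX` token selects which patids are even candidates: a file from
#' set 1 is filtered only against patids with `set == 1`, which is much
#' faster than matching against the full cohort when the cohort is large.
#'
#' @param handle An open store handle.
#' @param filepath Path to the raw file.
#' @param filetype File type; selects the reader and the default table name.
#' @param subset_patids Optional cohort filter: a character vector of patids,
#'   or a data frame with columns `patid` and `set` (the fast path).
#' @param mode `"overwrite"` creates/replaces the table; `"append"` adds to
#'   an existing one (appending to a missing table is an error directing you
#'   to overwrite first).
#' @param table_name Target table (default: the filetype).
#' @param extract_txt_func Optional custom reader, as in [read_raw_file()].
#' @param delimiter,date_format Passed to the reader.
#' @param chunk_size Rows per read chunk (default 1e6).
#'
#' @return Invisibly, the integer number of rows added.
#' @export
add_to_database <- function(handle, filepath, filetype,
                            subset_patids = NULL,
                            mode = c("append", "overwrite"),
                            table_name = NULL, extract_txt_func = NULL,
                            delimiter = "\t", date_format = "dmy",
                            chunk_size = 1e6) {
  con <- store_con(handle)
  mode <- match.arg(mode)
  if (!file.exists(filepath)) {
    stop(sprintf("file not found: %s", filepath), call. = FALSE)
  }
  if (is.null(extract_txt_func) && !filetype %in% aurum_filetypes) {
    stop(sprintf("unknown filetype '%s' and no extract_txt_func given", filetype),
         call. = FALSE)
  }
  tab <- table_name %||% filetype
  if (mode == "append" && !DBI::dbExistsTable(con, tab)) {
    stop(sprintf("table '%s' does not exist; use mode = 'overwrite' for the first file",
                 tab), call. = FALSE)
  }
  ids <- subset_ids_for_file(normalize_subset(subset_patids), basename(filepath))

  total <- if (is.null(extract_txt_func)) count_file_rows(filepath, delimiter) else NA_integer_
  added <- 0L
  first <- TRUE
  skip <- 0L
  repeat {
    dt <- read_raw_file(filepath, filetype, extract_txt_func = extract_txt_func,
                        delimiter = delimiter, date_format = date_format,
                        skip_rows = skip, n_rows = chunk_size)
    n_read <- nrow(dt)
    if (!is.null(ids)) dt <- dt[patid %chin% ids]
    dt <- dates_to_iso(dt)
    if (first && mode == "overwrite") {
      DBI::dbWriteTable(con, tab, dt, overwrite = TRUE)
    } else if (nrow(dt) > 0L || (first && !DBI::dbExistsTable(con, tab))) {
      DBI::dbWriteTable(con, tab, dt, append = TRUE)
    }
    added <- added + nrow(dt)
    first <- FALSE
    skip <- skip + n_read
    if (!is.null(extract_txt_func) || is.na(total) || skip >= total) break
  }
  invisible(added)
}

#' Ingest every matching raw file in a directory
#'
#' Wrapper around [add_to_database()]: scans `filepath` for filenames
#' containing `str_match` (default: the filetype, with `drug_issue` also
#' matching `drugissue`), orders them deterministically by (set, part, name),
#' ingests the first with `mode = "overwrite"` and the rest with
#' `mode = "append"`. Re-running it therefore rebuilds the table identically
#' rather than double-loading.
#'
#' @inheritParams add_to_database
#' @param filepath Directory containing the raw files.
#' @param str_match Substring (case-insensitive) the filenames must contain;
#'   defaults to `filetype`.
#' @param rm_duplicates If `TRUE`, the finished table is rebuilt keeping
#'   distinct rows only — deduplication is global across the whole extract,
#'   not per file.
#' @param build_index If `TRUE`, builds an index on (`patid`, code column)
#'   after the load. Off by default: queries work unindexed, and the index
#'   roughly doubles load time and file size.
#'
#' @return Invisibly, the total number of rows in the finished table.
#' @export
cprd_extract <- function(handle, filepath, filetype, subset_patids = NULL,
                         str_match = NULL, table_name = NULL,
                         rm_duplicates = FALSE, extract_txt_func = NULL,
                         delimiter = "\t", date_format = "dmy",
                         chunk_size = 1e6, build_index = FALSE) {
  con <- store_con(handle)
  if (!dir.exists(filepath)) {
    stop(sprintf("directory not found: %s", filepath), call. = FALSE)
  }
  pattern <- str_match %||% filetype
  fns <- list.files(filepath, pattern = "\\.txt$", ignore.case = TRUE)
  hit <- grepl(pattern, fns, ignore.case = TRUE)
  if (pattern == "drugissue") hit <- hit | grepl("drug_issue", fns, ignore.case = TRUE)
  fns <- fns[hit]
  if (length(fns) == 0L) {
    stop(sprintf("no files matching '%s' in %s", pattern, filepath), call. = FALSE)
  }
  keys <- lapply(fns, function(fn) {
    p <- tryCatch(parse_filename(fn), error = function(e) NULL)
    if (is.null(p)) list(set = Inf, part = Inf) else
      list(set = p$set_number, part = p$part_number %||% Inf)
  })
  ord <- order(vapply(keys, `[[`, numeric(1), "set"),
               vapply(keys, function(k) as.numeric(k$part %||% Inf), numeric(1)),
               fns)
  fns <- fns[ord]

  tab <- table_name %||% filetype
  for (i in seq_along(fns)) {
    add_to_database(handle, file.path(filepath, fns[i]), filetype,
                    subset_patids = subset_patids,
                    mode = if (i == 1L) "overwrite" else "append",
                    table_name = tab, extract_txt_func = extract_txt_func,
                    delimiter = delimiter, date_format = date_format,
                    chunk_size = chunk_size)
  }
  if (rm_duplicates) {
    tmp <- paste0(tab, "_dedup_tmp")
    DBI::dbExecute(con, sprintf(
      'CREATE TABLE "%s" AS SELECT DISTINCT * FROM "%s"', tmp, tab))
    DBI::dbExecute(con, sprintf('DROP TABLE "%s"', tab))
    DBI::dbExecute(con, sprintf('ALTER TABLE "%s" RENAME TO "%s"', tmp, tab))
  }
  if (build_index) {
    code_col <- switch(filetype, drugissue = "prodcodeid",
                       hes_primary = "ICD10", "medcodeid")
    cols <- DBI::dbListFields(con, tab)
    idx_cols <- intersect(c("patid", code_col), cols)
    DBI::dbExecute(con, sprintf('CREATE INDEX IF NOT EXISTS "idx_%s" ON "%s" (%s)',
                                tab, tab,
                                paste(sprintf('"%s"', idx_cols), collapse = ", ")))
  }
  n <- DBI::dbGetQuery(con, sprintf('SELECT COUNT(*) AS n FROM "%s"', tab))$n
  invisible(as.integer(n))
}
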